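# Shared fixtures: tiny volumes and a down-scaled synthetic world used by
# the unit tests (the acceptance tests build the full-scale world).

tiny_volume <- function(values, dim3 = NULL, voxel = 4, id = "t") {
  if (is.null(dim3)) dim3 <- dim(values)
  gm_volume(array(values, dim3), voxel, id)
}

random_volume <- function(dim3 = c(5, 6, 4), voxel = 4, seed = 1, id = "r") {
  set.seed(seed)
  gm_volume(array(runif(prod(dim3)), dim3), voxel, id)
}

# Small-grid synthetic configuration; effects = NULL avoids the (cached but
# non-trivial) default calibration where coupling is irrelevant.
small_synth <- function(seed = 1, n_train = 30, n_male = 20, n_female = 20,
                        effects = NULL, noise_sd = 0.05) {
  synth_config(seed = seed, n_train = n_train, n_male = n_male,
               n_female = n_female, grid_dim = c(12L, 14L, 12L),
               voxel_size_mm = 4, noise_sd = noise_sd, effects = effects)
}

# Dense separable-convolution oracle with replicate boundary, written
# independently of the implementation (explicit triple loop over offsets).
dense_gauss3_oracle <- function(a, sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  off <- -r:r
  w <- exp(-off^2 / (2 * sigma_vox^2)); w <- w / sum(w)
  d <- dim(a)
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (di in seq_along(off)) for (dj in seq_along(off))
      for (dk in seq_along(off)) {
        acc <- acc + w[di] * w[dj] * w[dk] *
          a[clamp(i + off[di], d[1]), clamp(j + off[dj], d[2]),
            clamp(k + off[dk], d[3])]
      }
    out[i, j, k] <- acc
  }
  out
}
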