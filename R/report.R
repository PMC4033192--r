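# Full analysis of a scored cohort, mirroring the published table layout:
# descriptive marker summary with gender comparison, site ANOVA, per-marker
# ANCOVA, gender-stratified PLS with VIP-ranked top markers, adjusted
# correlations, quartile contrasts (Holm m = 4), cognitive comparisons and
# the combined healthy/risky analysis.

cognitive_columns <- function(df) {
  grep("^(mmse|cdr|adas)_(bl|m12|m24|m36)$", names(df), value = TRUE)
}

descriptive_table <- function(cohort, markers) {
  rows <- lapply(markers, function(m) {
    out <- data.frame(marker = m, stringsAsFactors = FALSE)
    for (g in c("male", "female")) {
      v <- cohort[[m]][cohort$gender == g]
      v <- v[!is.na(v)]
      out[[paste0("n_", g)]] <- length(v)
      out[[paste0("mean_", g)]] <- mean(v)
      out[[paste0("sd_", g)]] <- stats::sd(v)
      out[[paste0("normality_", g)]] <-
        if (length(v) >= 3L) normality_test(v) else NA_character_
    }
    vm <- cohort[[m]][cohort$gender == "male"]
    vf <- cohort[[m]][cohort$gender == "female"]
    vm <- vm[!is.na(vm)]; vf <- vf[!is.na(vf)]
    both_normal <- out$normality_male == "normal" &&
      out$normality_female == "normal"
    if (isTRUE(both_normal)) {
      an <- stats::anova(stats::lm(c(vm, vf) ~ rep(c("m", "f"),
                                                   c(length(vm), length(vf)))))
      out$gender_test <- "anova"
      out$p_gender_diff <- an$`Pr(>F)`[1]
    } else {
      kw <- stats::kruskal.test(list(vm, vf))
      out$gender_test <- "kruskal_wallis"
      out$p_gender_diff <- kw$p.value
    }
    out
  })
  do.call(rbind, rows)
}

top_markers_by_vip <- function(pls, k = 4L) {
  names(sort(pls$vip, decreasing = TRUE))[seq_len(min(k, length(pls$vip)))]
}

cognitive_contrasts <- function(cohort_g, contrasts_by_marker, gender) {
  measures <- c("age", cognitive_columns(cohort_g))
  rows <- list()
  for (meas in measures) {
    per_marker <- lapply(names(contrasts_by_marker), function(m) {
      grp <- contrasts_by_marker[[m]]
      a <- cohort_g[[meas]][grp$g1]
      b <- cohort_g[[meas]][grp$g4]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2L || length(b) < 2L) return(NULL)
      tst <- suppressWarnings(compare_groups(a, b))
      data.frame(gender = gender, marker = m, measure = meas,
                 n1 = tst$n_a, mean1 = tst$mean_a, sd1 = tst$sd_a,
                 n4 = tst$n_b, mean4 = tst$mean_b, sd4 = tst$sd_b,
                 test = tst$test, p_raw = tst$p, stringsAsFactors = FALSE)
    })
    per_marker <- do.call(rbind, per_marker)
    if (!is.null(per_marker) && nrow(per_marker) > 0) {
      per_marker$p_holm <- holm_adjust(per_marker$p_raw)
      rows[[meas]] <- per_marker
    }
  }
  do.call(rbind, rows)
}

#' Run the full gender-stratified health-marker analysis
#'
#' @param cohort data.frame with `subject_id`, `age`, `gender`, `site`,
#'   `brainage` (years), the 17 marker columns and optional cognitive
#'   columns (`mmse_/cdr_/adas_` x `bl/m12/m24/m36`).
#' @param markers marker column names (default [marker_names()] present in
#'   the cohort).
#' @param top_k number of VIP-ranked markers carried into the quartile and
#'   combined analyses (default 4; the Holm family size).
#' @return An object of class `analysis_report` (a named list of result
#'   tables) with a `log` of per-stage subject counts.
#' @export
run_full_analysis <- function(cohort, markers = NULL, top_k = 4L) {
  stopifnot(is.data.frame(cohort), "brainage" %in% names(cohort))
  if (is.null(markers)) markers <- intersect(marker_names(), names(cohort))
  if (length(markers) == 0L) stop("no marker columns found", call. = FALSE)
  cohort$gender <- tolower(as.character(cohort$gender))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  note("cohort: %d subjects (%d male, %d female), %d markers",
       nrow(cohort), sum(cohort$gender == "male"),
       sum(cohort$gender == "female"), length(markers))

  report <- list(table1 = descriptive_table(cohort, markers))

  # site ANOVA per gender
  report$site_anova <- do.call(rbind, lapply(c("male", "female"), function(g) {
    sub <- cohort[cohort$gender == g, ]
    if (length(unique(sub$site)) < 2L) {
      note("site ANOVA skipped for %s: fewer than 2 sites", g)
      return(data.frame(gender = g, F = NA_real_, p = NA_real_,
                        df1 = NA_integer_, df2 = NA_integer_, n = nrow(sub)))
    }
    sa <- site_anova(sub$brainage, sub$site)
    data.frame(gender = g, F = sa$F, p = sa$p, df1 = sa$df[1],
               df2 = sa$df[2], n = sa$n)
  }))

  # per-marker ANCOVA with gender interaction
  report$ancova <- do.call(rbind, lapply(markers, function(m)
    ancova_gender(cohort$brainage, cohort[[m]], cohort$gender, marker = m)))

  ref <- marker_reference()
  report$pls <- list(); report$top_markers <- list()
  report$adjusted_correlations <- list(); report$quartiles <- list()
  report$cognitive <- list(); report$combined <- list()

  for (g in c("male", "female")) {
    sub <- cohort[cohort$gender == g, ]
    pls <- pls_regression(sub[, markers, drop = FALSE], sub$brainage)
    note("%s PLS: %d complete cases, %d components, R^2 = %.3f",
         g, pls$n_complete_cases, pls$n_components, pls$r_squared)
    report$pls[[g]] <- pls
    top <- top_markers_by_vip(pls, top_k)
    report$top_markers[[g]] <- top

    # adjusted correlations for the top markers (age + site covariates)
    report$adjusted_correlations[[g]] <- do.call(rbind, lapply(top, function(m) {
      okm <- !is.na(sub[[m]])
      ac <- adjusted_correlation(sub[[m]][okm], sub$brainage[okm],
                                 covariates = sub[okm, c("age", "site")])
      data.frame(gender = g, marker = m, r = ac$r, p = ac$p,
                 method = ac$method, n = ac$n, stringsAsFactors = FALSE)
    }))

    # quartile contrasts with Holm over the top-marker family
    qrows <- list(); groups <- list()
    for (m in top) {
      okm <- !is.na(sub[[m]]) & !is.na(sub$brainage)
      q <- stats::quantile(sub[[m]][okm], c(0.25, 0.75), type = 7,
                           names = FALSE)
      groups[[m]] <- list(g1 = okm & sub[[m]] <= q[1],
                          g4 = okm & sub[[m]] >= q[2])
      qrows[[m]] <- quartile_contrast(sub$brainage[okm], sub[[m]][okm],
                                      marker = m, gender = g)
    }
    qtab <- do.call(rbind, qrows)
    qtab$p_holm <- holm_adjust(qtab$p_raw)
    report$quartiles[[g]] <- qtab

    report$cognitive[[g]] <- cognitive_contrasts(sub, groups, g)

    flip <- intersect(top, unique(ref$marker[ref$flip]))
    split <- tryCatch(combined_group_split(sub, top, flip),
                      error = function(e) {
                        note("combined split failed for %s: %s", g,
                             conditionMessage(e)); NULL
                      })
    if (!is.null(split) &&
        (sum(split$healthy) < 2L || sum(split$risky) < 2L)) {
      note("%s combined groups too small to test (healthy n=%d, risky n=%d)",
           g, sum(split$healthy), sum(split$risky))
      split <- NULL
    }
    if (!is.null(split)) {
      note("%s combined groups: healthy n=%d, risky n=%d, both-flagged n=%d",
           g, sum(split$healthy), sum(split$risky), sum(split$both))
      tst <- suppressWarnings(
        compare_groups(sub$brainage[split$healthy],
                       sub$brainage[split$risky]))
      comb <- data.frame(gender = g, measure = "brainage",
                         n_healthy = tst$n_a, mean_healthy = tst$mean_a,
                         sd_healthy = tst$sd_a, n_risky = tst$n_b,
                         mean_risky = tst$mean_b, sd_risky = tst$sd_b,
                         test = tst$test, p = tst$p,
                         stringsAsFactors = FALSE)
      for (meas in c("age", cognitive_columns(sub))) {
        a <- sub[[meas]][split$healthy]; b <- sub[[meas]][split$risky]
        a <- a[!is.na(a)]; b <- b[!is.na(b)]
        if (length(a) < 2L || length(b) < 2L) next
        tm <- suppressWarnings(compare_groups(a, b))
        comb <- rbind(comb, data.frame(
          gender = g, measure = meas, n_healthy = tm$n_a,
          mean_healthy = tm$mean_a, sd_healthy = tm$sd_a,
          n_risky = tm$n_b, mean_risky = tm$mean_b, sd_risky = tm$sd_b,
          test = tm$test, p = tm$p, stringsAsFactors = FALSE))
      }
      report$combined[[g]] <- comb
      report$combined_split <- c(report$combined_split,
                                 stats::setNames(list(split), g))
    }
  }
  report$log <- log
  structure(report, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  for (line in x$log) cat(" -", line, "\n")
  invisible(x)
}

fmt6 <- function(df) {
  for (i in seq_along(df))
    if (is.numeric(df[[i]])) df[[i]] <- signif(df[[i]], 6)
  df
}

#' Write an analysis report to a directory
#'
#' Emits `table1.csv`, `site_anova.csv`, `table3_ancova.csv`,
#' `pls_{male,female}.csv`, `quartiles_{male,female}.csv`,
#' `combined_{male,female}.csv`, `cognitive_comparisons.csv`,
#' `adjusted_correlations.csv` and a markdown `summary.md`. All floats are
#' rounded to 6 significant digits.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) utils::write.csv(
    fmt6(df), file.path(dir, name), row.names = FALSE)
  wr(report$table1, "table1.csv")
  wr(report$site_anova, "site_anova.csv")
  wr(report$ancova, "table3_ancova.csv")
  for (g in names(report$pls)) {
    pls <- report$pls[[g]]
    wr(data.frame(marker = names(pls$vip), weight = pls$weights,
                  vip = pls$vip, contribution = pls$contribution,
                  r_squared = pls$r_squared,
                  n_components = pls$n_components,
                  n_complete_cases = pls$n_complete_cases),
       sprintf("pls_%s.csv", g))
  }
  for (g in names(report$quartiles))
    wr(report$quartiles[[g]], sprintf("quartiles_%s.csv", g))
  for (g in names(report$combined))
    wr(report$combined[[g]], sprintf("combined_%s.csv", g))
  cog <- do.call(rbind, report$cognitive)
  if (!is.null(cog)) wr(cog, "cognitive_comparisons.csv")
  adj <- do.call(rbind, report$adjusted_correlations)
  if (!is.null(adj)) wr(adj, "adjusted_correlations.csv")
  md <- c("# BrainAGE health-marker analysis", "",
          "## Stage log", paste("-", report$log), "",
          "## PLS variance explained")
  for (g in names(report$pls))
    md <- c(md, sprintf("- %s: R^2 = %.3f (%d components, n = %d)", g,
                        report$pls[[g]]$r_squared,
                        report$pls[[g]]$n_components,
                        report$pls[[g]]$n_complete_cases))
  md <- c(md, "", "## Top markers (VIP rank)")
  for (g in names(report$top_markers))
    md <- c(md, sprintf("- %s: %s", g,
                        paste(report$top_markers[[g]], collapse = ", ")))
  md <- c(md, "", "## Quartile contrasts (|mean difference|, years)")
  for (g in names(report$quartiles)) {
    q <- report$quartiles[[g]]
    md <- c(md, sprintf("- %s %s: %.1f years (%s, Holm p = %.3g)",
                        g, q$marker, q$abs_diff, q$test, q$p_holm))
  }
  writeLines(md, file.path(dir, "summary.md"))
  invisible(dir)
}
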