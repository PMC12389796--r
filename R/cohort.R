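#' Fit every session of a synthetic cohort
#'
#' Streams over the cohort: simulates each session recording from its
#' scenario, runs the filter + GLM chain, applies lesion-side mirroring,
#' and stacks the per-session response amplitudes. Recordings are
#' discarded after fitting, so memory stays flat over long training
#' courses.
#'
#' @param cohort Output of [build_paper_like_cohort()].
#' @param filter A [filter_spec()].
#' @param hrf Optional [hrf_spec()] override.
#' @param montages Named list of montage objects covering every montage
#'   name in the cohort.
#' @return Tibble of mirrored response amplitudes: `subject`, `group`,
#'   `session_id`, `day_index`, `channel`, `task`, `chromophore`,
#'   `coefficient`, `se`, `r2`, `resid_sd`.
#' @export
fit_cohort <- function(cohort, filter = filter_spec(), hrf = NULL,
                       montages = list(clinical28 = load_montage("clinical28"),
                                       healthy33 = load_montage("healthy33"))) {
  out <- vector("list", sum(vapply(cohort, function(s) nrow(s$sessions), 0L)))
  k <- 0L
  for (subj in cohort) {
    montage <- montages[[subj$montage]]
    if (is.null(montage)) stop_invalid("no montage object for '", subj$montage, "'")
    for (i in seq_len(nrow(subj$sessions))) {
      ses <- subj$sessions[i, ]
      sched <- build_schedule(subj$protocol, n_blocks = ses$n_blocks,
                              seed = child_seed(subj$scenario$seed, 301,
                                                ses$session_id),
                              session_id = ses$session_id,
                              day_index = ses$day_index)
      rec <- simulate_session(montage, sched, subj$scenario)
      coefs <- fit_session(rec, filter = filter, hrf = hrf)
      coefs <- mirror_responses(coefs, subj$meta, montage)
      coefs <- tibble::add_column(coefs, subject = subj$meta$subject_id,
                                  group = subj$meta$group, .before = 1)
      k <- k + 1L
      out[[k]] <- coefs
    }
  }
  dplyr::bind_rows(out)
}

#' Cohort statistical report
#'
#' The group statistical layer applied to a tidy asymmetry table:
#' session-averaged aligned-rank-transform factorial ANOVAs (hand x
#' channel pair for LC, hemisphere x channel pair for TRAC; separately
#' per chromophore), per-pair Wilcoxon signed-rank tests with
#' Benjamini-Yekutieli adjustment, daily-slope regressions on
#' subject-averaged day values, and (when clinical scores are supplied)
#' Pearson correlations of subject-level means with clinical outcome.
#'
#' @param asym Asymmetry table from [compute_asymmetry_table()] with
#'   `subject`, `session_id`, `day_index` columns.
#' @param clinical Optional tibble: `subject`, `baseline_arat`,
#'   `improvement`.
#' @param include_subject_term Subject blocking term in the ART ANOVA.
#' @param alpha Significance level for slope flags.
#' @param slopes Fit daily-slope regressions (needs >= 3 distinct days).
#' @return A `stats_report` list: `anova`, `pair_tests`, `slopes`,
#'   `correlations` tibbles.
#' @export
cohort_stats <- function(asym, clinical = NULL, include_subject_term = TRUE,
                         alpha = 0.05, slopes = TRUE) {
  avg <- average_levels(asym, "sessions")
  fams <- unique(avg[, c("index_kind", "chromophore")])
  anova_rows <- list(); pair_rows <- list()
  for (i in seq_len(nrow(fams))) {
    kind <- fams$index_kind[i]; chrom <- fams$chromophore[i]
    sub <- avg[avg$index_kind == kind & avg$chromophore == chrom, ]
    axis <- if (kind == "TRAC") "hemisphere" else "hand"
    sub <- sub[!is.na(sub[[axis]]) & !is.na(sub$pair), ]
    if (nrow(sub) == 0) next
    unit <- "pair"
    an <- tryCatch(
      art_anova(sub, value = "value", subject = "subject",
                factor_a = axis, factor_b = unit,
                include_subject_term = include_subject_term),
      error = function(e) NULL)
    if (!is.null(an)) {
      an <- tibble::add_column(an, index_kind = kind, chromophore = chrom,
                               .before = 1)
      anova_rows[[length(anova_rows) + 1L]] <- an
    }
    pw <- pairwise_wilcoxon(sub, value = "value", unit = "pair",
                            condition = axis, subject = "subject")
    pair_rows[[length(pair_rows) + 1L]] <-
      tibble::add_column(pw, index_kind = kind, chromophore = chrom,
                         .before = 1)
  }
  slope_tbl <- NULL
  if (slopes) {
    daily <- average_levels(asym, "sessions_within_day")
    pooled <- average_levels(daily, "subjects")
    grp <- intersect(c("pair", "channel", "hand", "hemisphere",
                       "index_kind", "chromophore"), names(pooled))
    slope_tbl <- daily_slopes(pooled, day = "day_index", groups = grp,
                              family = c("index_kind", "chromophore"),
                              alpha = alpha)
  }
  corr <- NULL
  if (!is.null(clinical) && nrow(clinical) >= 3) {
    metrics <- subject_metrics(avg)
    corr <- clinical_correlation(metrics, clinical)
  }
  structure(list(anova = dplyr::bind_rows(anova_rows),
                 pair_tests = dplyr::bind_rows(pair_rows),
                 slopes = slope_tbl, correlations = corr),
            class = "stats_report")
}

# subject-level scalar metrics: mean index value per subject, index kind,
# chromophore and axis level (hemisphere for TRAC, hand for LC)
subject_metrics <- function(avg) {
  axis <- ifelse(avg$index_kind == "TRAC", avg$hemisphere, avg$hand)
  avg$metric <- paste(avg$index_kind, avg$chromophore, axis, sep = "_")
  dplyr::summarise(dplyr::group_by(avg, .data$subject, .data$metric),
                   value = mean(.data$value), .groups = "drop")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("<stats_report>\n")
  if (!is.null(x$anova) && nrow(x$anova)) {
    cat("ART ANOVA:\n")
    for (i in seq_len(nrow(x$anova))) {
      r <- x$anova[i, ]
      cat(sprintf("  %-4s %-3s %-12s F=%8.2f df=%3d df.res=%4d p=%.4g\n",
                  r$index_kind, r$chromophore, r$effect, r$F, r$df,
                  r$df_res, r$p))
    }
  }
  if (!is.null(x$pair_tests) && nrow(x$pair_tests)) {
    nsig <- sum(x$pair_tests$p_adj < 0.05, na.rm = TRUE)
    cat("pair tests: ", nrow(x$pair_tests), " (", nsig,
        " significant after BY)\n", sep = "")
  }
  if (!is.null(x$slopes) && nrow(x$slopes)) {
    cat("daily slopes: ", nrow(x$slopes), " (", sum(x$slopes$sig_raw), " *, ",
        sum(x$slopes$sig_fdr), " **)\n", sep = "")
  }
  if (!is.null(x$correlations) && nrow(x$correlations))
    cat("clinical correlations: ", nrow(x$correlations), "\n", sep = "")
  invisible(x)
}

#' Full in-memory cohort analysis
#'
#' [fit_cohort()] + [compute_asymmetry_table()] + [cohort_stats()],
#' analyzed separately per group (patients in the lesion-referenced
#' frame, healthy in left/right coordinates).
#'
#' @inheritParams fit_cohort
#' @inheritParams cohort_stats
#' @param kinds Index kinds to compute.
#' @return List with `coefficients`, `asymmetry`, and per-group
#'   `stats` (`patient`, `healthy`; absent groups NULL).
#' @export
analyze_cohort <- function(cohort, filter = filter_spec(), hrf = NULL,
                           kinds = c("LC", "TRAC"),
                           include_subject_term = TRUE, slopes = TRUE,
                           montages = list(clinical28 = load_montage("clinical28"),
                                           healthy33 = load_montage("healthy33"))) {
  coefs <- fit_cohort(cohort, filter = filter, hrf = hrf,
                      montages = montages)
  clin <- cohort_clinical(cohort)
  res <- list(coefficients = coefs)
  asym_all <- list()
  stats <- list(patient = NULL, healthy = NULL)
  for (g in intersect(c("patient", "healthy"), unique(coefs$group))) {
    mname <- unique(vapply(cohort, function(s)
      if (s$meta$group == g) s$montage else NA_character_, ""))
    mname <- mname[!is.na(mname)][1]
    asym <- compute_asymmetry_table(coefs[coefs$group == g, ],
                                    montages[[mname]], kinds = kinds)
    asym_all[[g]] <- asym
    stats[[g]] <- cohort_stats(asym,
                               clinical = if (g == "patient") clin,
                               include_subject_term = include_subject_term,
                               slopes = slopes)
  }
  res$asymmetry <- dplyr::bind_rows(asym_all)
  res$stats <- stats
  res
}

cohort_clinical <- function(cohort) {
  rows <- lapply(cohort, function(s) {
    if (s$meta$group != "patient" || is.null(s$meta$clinical)) return(NULL)
    tibble::tibble(subject = s$meta$subject_id,
                   baseline_arat = s$meta$clinical$baseline_arat,
                   improvement = s$meta$clinical$improvement)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out else NULL
}
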