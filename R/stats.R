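#' Average an asymmetry table over a grouping level
#'
#' Arithmetic means of `value` within groups, with group sizes recorded.
#' `"sessions"` averages each subject/unit/chromophore cell over all
#' sessions (and days); `"sessions_within_day"` keeps the day axis (the
#' input to daily-slope regressions); `"subjects"` and `"channels"`
#' collapse those axes.
#'
#' @param table Tidy asymmetry tibble (see [compute_asymmetry_table()])
#'   with a `value` column.
#' @param over One of `"sessions"`, `"sessions_within_day"`,
#'   `"subjects"`, `"channels"`.
#' @return Tibble with the remaining grouping columns, mean `value`, and
#'   the group size `n_averaged`.
#' @export
average_levels <- function(table, over = c("sessions", "sessions_within_day",
                                           "subjects", "channels")) {
  over <- match.arg(over)
  drop_cols <- switch(over,
    sessions = c("session_id", "day_index"),
    sessions_within_day = "session_id",
    subjects = "subject",
    channels = c("channel", "pair"))
  keys <- setdiff(names(table), c(drop_cols, "value", "overflow",
                                  "n_averaged", "se", "r2", "resid_sd"))
  dplyr::summarise(dplyr::group_by(table, dplyr::across(dplyr::all_of(keys))),
                   value = mean(.data$value), n_averaged = dplyr::n(),
                   .groups = "drop")
}

# ---- aligned rank transform -------------------------------------------------

# Balanced-design sums of squares on a fully crossed subject x A x B layout.
# Factors are mutually orthogonal in a complete balanced design, so the
# means-based decomposition is exact and fast.
art_f_one <- function(r, subj, fa, fb, effect, include_subject_term) {
  N <- length(r)
  grand <- mean(r)
  m_a <- tapply(r, fa, mean); m_b <- tapply(r, fb, mean)
  m_ab <- tapply(r, list(fa, fb), mean)
  a <- length(m_a); b <- length(m_b); s <- N / (a * b)
  ss_a <- b * s * sum((m_a - grand)^2)
  ss_b <- a * s * sum((m_b - grand)^2)
  ss_ab <- s * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + grand)^2)
  ss_tot <- sum((r - grand)^2)
  df <- c(a = a - 1, b = b - 1, ab = (a - 1) * (b - 1))
  ss <- c(a = ss_a, b = ss_b, ab = ss_ab)
  ss_model <- ss_a + ss_b + ss_ab
  df_model <- sum(df)
  if (include_subject_term) {
    m_s <- tapply(r, subj, mean)
    ss_model <- ss_model + a * b * sum((m_s - grand)^2)
    df_model <- df_model + s - 1
  }
  df_res <- N - 1 - df_model
  ss_res <- ss_tot - ss_model
  msr <- ss_res / df_res
  f <- if (ss[effect] <= 1e-10 * max(ss_tot, 1)) 0 else (ss[effect] / df[effect]) / msr
  p <- if (f == 0) 1 else stats::pf(f, df[effect], df_res, lower.tail = FALSE)
  list(F = f, df = unname(df[effect]), df_res = df_res, p = p)
}

#' Aligned-rank-transform factorial ANOVA
#'
#' Nonparametric repeated-measures factorial ANOVA by the aligned rank
#' transform: for each effect (factor A, factor B, and their interaction)
#' the data are aligned (the full-cell-mean decomposition keeps that
#' effect's estimated contribution plus residuals and strips all other
#' effects), the aligned values are ranked with average ties, and a
#' standard factorial ANOVA is run on the ranks; only the aligned effect's
#' row is reported. Three separate alignments are performed per analysis.
#' F statistics are invariant under any rank-preserving monotone transform
#' of the data.
#'
#' The design must be complete and balanced: exactly one value per
#' subject x A x B cell (average sessions first, see [average_levels()]).
#' With `include_subject_term = TRUE` (the default) the subject enters the
#' rank ANOVA as a blocking factor, the proper repeated-measures layout;
#' `FALSE` reproduces the plain two-factor layout whose residual degrees
#' of freedom some published analyses report.
#'
#' @param data Data frame of one value per cell.
#' @param value,subject,factor_a,factor_b Column names (strings).
#' @param include_subject_term Include the subject blocking term.
#' @return Tibble with rows `factor_a`, `factor_b`, `interaction`:
#'   columns `effect`, `F`, `df`, `df_res`, `p`.
#' @export
art_anova <- function(data, value = "value", subject = "subject",
                      factor_a = "hand", factor_b = "channel",
                      include_subject_term = TRUE) {
  y <- data[[value]]
  subj <- factor(data[[subject]])
  fa <- factor(data[[factor_a]])
  fb <- factor(data[[factor_b]])
  if (anyNA(y)) stop_invalid("missing values in the response")
  counts <- table(subj, fa, fb)
  if (any(counts != 1))
    stop_invalid("design must be complete and balanced (one value per ",
                 "subject x factor cell); average over sessions first")
  grand <- mean(y)
  m_a <- tapply(y, fa, mean); m_b <- tapply(y, fb, mean)
  m_ab <- tapply(y, list(fa, fb), mean)
  cell <- m_ab[cbind(as.integer(fa), as.integer(fb))]
  resid <- y - cell
  eff <- list(
    a = m_a[as.integer(fa)] - grand,
    b = m_b[as.integer(fb)] - grand,
    ab = cell - m_a[as.integer(fa)] - m_b[as.integer(fb)] + grand)
  rows <- lapply(c("a", "b", "ab"), function(e) {
    r <- rank(resid + eff[[e]], ties.method = "average")
    art_f_one(r, subj, fa, fb, e, include_subject_term)
  })
  tibble::tibble(
    effect = c(factor_a, factor_b, "interaction"),
    F = vapply(rows, `[[`, 0, "F"),
    df = vapply(rows, `[[`, 0, "df"),
    df_res = vapply(rows, `[[`, 0, "df_res"),
    p = vapply(rows, `[[`, 0, "p"))
}

# ---- Wilcoxon / BY ----------------------------------------------------------

# Signed-rank test on paired differences with the package's conventions:
# zeros dropped (count reported), exact distribution for n <= 25 without
# ties, normal approximation with continuity correction otherwise.
signed_rank_test <- function(d) {
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p = 1, n = 0L, n_zero = n_zero,
                all_zero = TRUE))
  ties <- anyDuplicated(abs(d)) > 0
  exact <- n <= 25 && !ties
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value, n = n,
       n_zero = n_zero, all_zero = FALSE)
}

#' Per-unit Wilcoxon signed-rank tests with Benjamini-Yekutieli adjustment
#'
#' For each unit (e.g. homotopic channel pair), the paired per-subject
#' values of two conditions are compared with the two-sided Wilcoxon
#' signed-rank test; p-values are then adjusted across units with the
#' Benjamini-Yekutieli procedure (FDR control under arbitrary
#' dependence). Run it separately per index kind and chromophore family.
#'
#' @param data Long tibble with one row per subject x unit x condition.
#' @param value,unit,condition,subject Column names. `condition` must
#'   have exactly two levels; differences are first level minus second
#'   (level order of `factor(condition)`).
#' @param min_n Units with fewer paired observations are flagged
#'   `underpowered` (still tested).
#' @return Tibble: `unit`, `n`, `n_zero`, `statistic`, `p`, `p_adj`,
#'   `underpowered`, `all_zero`.
#' @export
pairwise_wilcoxon <- function(data, value = "value", unit = "pair",
                              condition = "hemisphere",
                              subject = "subject", min_n = 5L) {
  cond <- factor(data[[condition]])
  if (nlevels(cond) != 2)
    stop_invalid("condition must have exactly two levels")
  lv <- levels(cond)
  units <- unique(data[[unit]])
  rows <- lapply(units, function(u) {
    sub <- data[data[[unit]] == u, ]
    w <- tidyr::pivot_wider(sub[, c(subject, condition, value)],
                            names_from = dplyr::all_of(condition),
                            values_from = dplyr::all_of(value))
    d <- w[[lv[1]]] - w[[lv[2]]]
    d <- d[!is.na(d)]
    t <- signed_rank_test(d)
    tibble::tibble(unit = u, n = t$n, n_zero = t$n_zero,
                   statistic = t$statistic, p = t$p,
                   underpowered = t$n < min_n, all_zero = t$all_zero)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- p.adjust(out$p, method = "BY")
  out[, c("unit", "n", "n_zero", "statistic", "p", "p_adj",
          "underpowered", "all_zero")]
}

#' Daily-slope linear regressions
#'
#' Ordinary least-squares regression of index values on day number,
#' fitted separately for each combination of the `groups` columns; slope
#' p-values (two-sided t-test) are Benjamini-Yekutieli adjusted within
#' families defined by the `family` columns (by default across channels
#' within each index kind and chromophore). Feed it day-averaged values
#' ([average_levels()] with `"sessions_within_day"`).
#'
#' @param data Tibble with columns `value`, a day column, and the
#'   grouping columns.
#' @param day Day-number column name.
#' @param groups Columns defining one regression each.
#' @param family Subset of `groups` defining each BY adjustment family.
#' @param alpha Significance level for the flags.
#' @return Tibble: grouping columns, `slope`, `intercept`, `n_days`, `p`,
#'   `p_adj`, `sig_raw` (`*`, any raw p < alpha), `sig_fdr` (`**`,
#'   survives BY).
#' @export
daily_slopes <- function(data, day = "day_index",
                         groups = c("channel", "index_kind", "chromophore"),
                         family = c("index_kind", "chromophore"),
                         alpha = 0.05) {
  groups <- intersect(groups, names(data))
  family <- intersect(family, groups)
  fit_one <- function(df, ...) {
    if (length(unique(df[[day]])) < 3)
      stop_invalid("need >= 3 distinct days per regression")
    # a constant series carries no trend information: slope 0, p 1
    if (sd(df$value) < 1e-12)
      return(tibble::tibble(slope = 0, intercept = mean(df$value),
                            n_days = length(unique(df[[day]])), p = 1))
    m <- lm(df$value ~ df[[day]])
    sm <- suppressWarnings(summary(m))$coefficients
    p <- sm[2, 4]
    if (!is.finite(p)) p <- if (abs(sm[2, 1]) < 1e-12) 1 else 0
    tibble::tibble(slope = sm[2, 1], intercept = sm[1, 1],
                   n_days = length(unique(df[[day]])), p = p)
  }
  out <- dplyr::group_modify(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(groups))), fit_one)
  out <- dplyr::ungroup(out)
  out <- dplyr::mutate(
    dplyr::group_by(out, dplyr::across(dplyr::all_of(family))),
    p_adj = p.adjust(.data$p, method = "BY"))
  out <- dplyr::ungroup(out)
  out$sig_raw <- out$p < alpha
  out$sig_fdr <- out$p_adj < alpha
  out
}

#' Correlations between asymmetry metrics and clinical outcomes
#'
#' Pearson correlation (two-sided) between each subject-level metric and
#' each clinical variable. Zero-variance metrics are reported as missing
#' with a flag rather than an error.
#'
#' @param metrics Tibble with columns `subject`, `metric`, `value` (one
#'   row per subject per metric).
#' @param clinical Tibble with column `subject` plus one column per
#'   clinical variable (e.g. `baseline_arat`, `improvement`).
#' @return Tibble: `clinical_var`, `metric`, `n`, `r`, `p`, `degenerate`.
#' @export
clinical_correlation <- function(metrics, clinical) {
  vars <- setdiff(names(clinical), "subject")
  rows <- list()
  for (v in vars) {
    for (m in unique(metrics$metric)) {
      sub <- metrics[metrics$metric == m, ]
      merged <- dplyr::inner_join(sub, clinical[, c("subject", v)],
                                  by = "subject")
      x <- merged$value; y <- merged[[v]]
      ok <- is.finite(x) & is.finite(y)
      x <- x[ok]; y <- y[ok]
      if (length(x) < 3)
        stop_invalid("need >= 3 subjects with both values")
      degenerate <- sd(x) == 0 || sd(y) == 0
      if (degenerate) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          clinical_var = v, metric = m, n = length(x),
          r = NA_real_, p = NA_real_, degenerate = TRUE)
      } else {
        ct <- cor.test(x, y, method = "pearson")
        rows[[length(rows) + 1L]] <- tibble::tibble(
          clinical_var = v, metric = m, n = length(x),
          r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
      }
    }
  }
  dplyr::bind_rows(rows)
}
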