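test_that("averaging levels takes plain means and records group sizes", {
  tab <- tibble::tibble(subject = "S1", session_id = c(1L, 2L),
                        day_index = c(1L, 1L), pair = "P01",
                        channel = "c", hand = NA, hemisphere = "lesioned",
                        chromophore = "HbO", index_kind = "TRAC",
                        value = c(0.1, 0.3), overflow = FALSE)
  avg <- average_levels(tab, "sessions")
  expect_equal(avg$value, 0.2)
  expect_equal(avg$n_averaged, 2L)
  # single session: identity on the value
  avg1 <- average_levels(tab[1, ], "sessions")
  expect_equal(avg1$value, 0.1)
})

test_that("averaging over subjects and channels commutes on balanced tables", {
  set.seed(41)
  tab <- tidyr::expand_grid(subject = sprintf("S%d", 1:5),
                            channel = sprintf("c%d", 1:4),
                            chromophore = "HbO", index_kind = "TRAC")
  tab$value <- rnorm(nrow(tab))
  a <- average_levels(average_levels(tab, "subjects"), "channels")
  b <- average_levels(average_levels(tab, "channels"), "subjects")
  expect_equal(a$value, b$value, tolerance = 1e-12)
  expect_equal(a$value, mean(tab$value))
})

test_that("ART alignment strips the other effects exactly", {
  toy <- tidyr::expand_grid(subject = 1:4, A = c("x", "y"),
                            B = c("p", "q", "r"))
  toy$value <- ifelse(toy$A == "x", 1, 3)  # pure additive A effect
  an <- art_anova(toy, factor_a = "A", factor_b = "B")
  expect_equal(an$F[an$effect == "B"], 0)
  expect_equal(an$F[an$effect == "interaction"], 0)
  expect_equal(an$p[an$effect == "B"], 1)
})

test_that("ART F statistics agree with a factorial ANOVA on aligned ranks", {
  set.seed(42)
  d <- tidyr::expand_grid(subject = sprintf("S%d", 1:6), A = c("a1", "a2"),
                          B = sprintf("b%d", 1:3))
  d$value <- rnorm(nrow(d)) + (d$A == "a1") * 0.5
  an <- art_anova(d, factor_a = "A", factor_b = "B")
  # oracle: align per the definition, rank, then stats::aov
  grand <- mean(d$value)
  mA <- ave(d$value, d$A); mB <- ave(d$value, d$B)
  cell <- ave(d$value, d$A, d$B)
  for (eff in c("A", "B", "interaction")) {
    aligned <- switch(eff,
      A = d$value - cell + (mA - grand),
      B = d$value - cell + (mB - grand),
      interaction = d$value - mA - mB + grand)
    r <- rank(aligned)
    fit <- stats::aov(r ~ factor(subject) + factor(A) * factor(B), data = d)
    sm <- summary(fit)[[1]]
    row <- switch(eff, A = "factor(A)", B = "factor(B)",
                  interaction = "factor(A):factor(B)")
    f_oracle <- sm[trimws(rownames(sm)) == row, "F value"]
    expect_equal(an$F[an$effect == switch(eff, A = "A", B = "B",
                                          interaction = "interaction")],
                 f_oracle, tolerance = 1e-8)
  }
})

test_that("ART degrees of freedom match the repeated-measures layouts", {
  set.seed(43)
  pat <- tidyr::expand_grid(subject = 1:15, hand = c("a", "i"),
                            channel = sprintf("P%02d", 1:14))
  pat$value <- rnorm(nrow(pat))
  an <- art_anova(pat, factor_a = "hand", factor_b = "channel",
                  include_subject_term = FALSE)
  expect_equal(an$df, c(1, 13, 13))
  expect_equal(unique(an$df_res), 392)
  an2 <- art_anova(pat, factor_a = "hand", factor_b = "channel",
                   include_subject_term = TRUE)
  expect_equal(unique(an2$df_res), 392 - 14)
  hea <- tidyr::expand_grid(subject = 1:9, hand = c("l", "r"),
                            channel = sprintf("P%02d", 1:7))
  hea$value <- rnorm(nrow(hea))
  an3 <- art_anova(hea, factor_a = "hand", factor_b = "channel")
  expect_equal(unique(an3$df_res), 104)
  # unbalanced designs are rejected with advice to average first
  expect_error(art_anova(pat[-1, ], factor_a = "hand",
                         factor_b = "channel"), "average")
})

test_that("ART is invariant under positive affine transforms", {
  # the alignment step is linear in the data and ranks ignore positive
  # affine maps, so y -> a*y + b leaves every F statistic unchanged
  set.seed(44)
  d <- tidyr::expand_grid(subject = 1:8, A = c("a", "b"),
                          B = sprintf("c%d", 1:4))
  d$value <- rnorm(nrow(d)) + (d$B == "c1") * 0.8
  f1 <- art_anova(d, factor_a = "A", factor_b = "B")$F
  d2 <- d; d2$value <- 3.7 * d$value + 11
  f2 <- art_anova(d2, factor_a = "A", factor_b = "B")$F
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("signed-rank p-values match exhaustive sign enumeration", {
  d <- tibble::tibble(
    subject = rep(sprintf("S%d", 1:6), 2),
    pair = "P01",
    hemisphere = rep(c("lesioned", "intact"), each = 6),
    value = c(10 + 1:6, rep(10, 6)))  # differences 1..6, all positive
  out <- pairwise_wilcoxon(d)
  expect_equal(out$p, 2 / 64)  # exact two-sided
  expect_equal(out$p, wilcoxon_exact_oracle(1:6))
  expect_false(out$underpowered)

  # random differences against the enumeration oracle
  set.seed(45)
  for (i in 1:5) {
    diffs <- round(rnorm(8), 2)
    diffs <- diffs[diffs != 0][1:6]
    dd <- tibble::tibble(subject = rep(sprintf("S%d", 1:6), 2), pair = "x",
                         hemisphere = rep(c("a", "b"), each = 6),
                         value = c(10 + diffs, rep(10, 6)))
    if (anyDuplicated(abs(diffs))) next
    expect_equal(pairwise_wilcoxon(dd)$p, wilcoxon_exact_oracle(diffs))
  }

  # all-zero differences: p = 1 with a flag
  dz <- tibble::tibble(subject = rep(sprintf("S%d", 1:6), 2), pair = "z",
                       hemisphere = rep(c("a", "b"), each = 6), value = 1)
  outz <- pairwise_wilcoxon(dz)
  expect_equal(outz$p, 1)
  expect_true(outz$all_zero)
})

test_that("Benjamini-Yekutieli adjustment matches the brute-force oracle", {
  # worked example: m = 2, raw (0.01, 0.04) -> (0.03, 0.06)
  expect_equal(p.adjust(c(0.01, 0.04), "BY"), c(0.03, 0.06))
  expect_equal(by_adjust_oracle(c(0.01, 0.04)), c(0.03, 0.06))
  # m = 1: identity
  expect_equal(p.adjust(0.2, "BY"), 0.2)
  set.seed(46)
  for (m in 1:10) {
    p <- runif(m)
    expect_equal(p.adjust(p, "BY"), by_adjust_oracle(p), tolerance = 1e-12)
  }
  # adjusted p never below raw p
  p <- runif(8)
  expect_true(all(p.adjust(p, "BY") >= p))
})

test_that("pairwise tests adjust within the unit family", {
  set.seed(47)
  d <- tidyr::expand_grid(subject = sprintf("S%d", 1:10),
                          pair = sprintf("P%02d", 1:4),
                          hemisphere = c("lesioned", "intact"))
  d$value <- rnorm(nrow(d)) + (d$hemisphere == "lesioned") * 2
  out <- pairwise_wilcoxon(d)
  expect_equal(nrow(out), 4)
  expect_equal(out$p_adj, p.adjust(out$p, "BY"))
  expect_true(all(out$p_adj >= out$p))
})

test_that("daily slopes recover exact linear trends", {
  d <- tibble::tibble(channel = "c1", index_kind = "TRAC",
                      chromophore = "HbO", day_index = 1:10,
                      value = 0.5 - 0.05 * (1:10))
  out <- daily_slopes(d)
  expect_equal(out$slope, -0.05, tolerance = 1e-12)
  expect_lt(out$p, 1e-10)
  expect_true(out$sig_raw && out$sig_fdr)
  # constant series: zero slope, flagged uninformative
  dc <- d; dc$value <- 0.3
  outc <- daily_slopes(dc)
  expect_equal(outc$slope, 0)
  expect_equal(outc$p, 1)
  expect_error(daily_slopes(d[1:2, ]), "3 distinct days")
})

test_that("slope t-test is calibrated on white noise", {
  set.seed(48)
  rej <- replicate(1000, {
    d <- tibble::tibble(channel = "c", index_kind = "TRAC",
                        chromophore = "HbO", day_index = 1:10,
                        value = rnorm(10))
    daily_slopes(d)$p < 0.05
  })
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("clinical correlations handle exact and degenerate cases", {
  clin <- tibble::tibble(subject = sprintf("S%d", 1:8),
                         baseline_arat = c(35, 44, 10, 52, 20, 31, 47, 5))
  metrics <- tibble::tibble(subject = clin$subject, metric = "TRAC_HbO",
                            value = 2 * clin$baseline_arat + 1)
  out <- clinical_correlation(metrics, clin)
  expect_equal(out$r, 1, tolerance = 1e-12)
  # constant metric: missing with flag
  mc <- metrics; mc$value <- 3
  outc <- clinical_correlation(mc, clin)
  expect_true(outc$degenerate)
  expect_true(is.na(outc$r))
  expect_error(clinical_correlation(metrics[1:2, ], clin[1:2, ]), ">= 3")
  # independence null: mean correlation near zero
  set.seed(49)
  rs <- replicate(300, {
    mm <- metrics; mm$value <- rnorm(8)
    clinical_correlation(mm, clin)$r
  })
  expect_lt(abs(mean(rs)), 0.08)
})
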