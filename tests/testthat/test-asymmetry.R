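test_that("LC and TRAC match their defining values", {
  expect_equal(lc(1, 1), 0)
  expect_equal(lc(1, -1), 1)
  expect_equal(lc(-1, 1), -1)
  expect_equal(lc(1, 0), 1 / sqrt(2))
  expect_equal(lc(0, 0), 0)     # zero-response convention
  expect_equal(trac(0.5, 0.5), 0)
  expect_equal(trac(0.3, -0.3), 1)
  expect_error(lc(Inf, 1), "finite")
  expect_error(trac(NA_real_, 1), "finite")
})

test_that("LC/TRAC are bounded, antisymmetric and scale-equivariant", {
  set.seed(11)
  a <- runif(1e5, -10, 10); b <- runif(1e5, -10, 10)
  v <- lc(a, b)
  expect_lte(max(abs(v)), 1)
  expect_equal(lc(b, a), -v)
  # |index| = 1 iff b = -a (nonzero): opposite pairs saturate exactly
  expect_equal(abs(lc(a, -a)), rep(1, length(a)))
  expect_true(all(abs(v[abs(a + b) > 1e-8]) < 1))
  # sign(c) equivariance, e.g. c = -2
  expect_equal(trac(-2 * 0.4, -2 * 0.1), -trac(0.4, 0.1))
  cs <- runif(100, -3, 3); cs <- cs[cs != 0]
  aa <- runif(length(cs), -2, 2); bb <- runif(length(cs), -2, 2)
  expect_equal(lc(cs * aa, cs * bb), sign(cs) * lc(aa, bb),
               tolerance = 1e-12)
})

test_that("reconstructed legacy formulas reproduce their failure modes", {
  # eq1 is polarity-insensitive
  expect_equal(as.numeric(alt_laterality(1, 0.5, "eq1")), 1 / 3)
  expect_equal(as.numeric(alt_laterality(-1, -0.5, "eq1")), 1 / 3)
  set.seed(12)
  a <- rnorm(1e4); b <- rnorm(1e4)
  expect_equal(as.numeric(alt_laterality(a, b, "eq1")),
               as.numeric(alt_laterality(-a, -b, "eq1")))

  # eq2 saturates at exactly +/-1 for any opposite-sign pair
  expect_equal(as.numeric(alt_laterality(0.5, -0.3, "eq2")), 1)
  opp <- sign(a) != sign(b) & a != 0 & b != 0
  expect_true(all(abs(alt_laterality(a[opp], b[opp], "eq2")) == 1))
  expect_true(all(abs(alt_laterality(a, b, "eq2")) <= 1))

  # eq3 is singular when the denominator vanishes and unbounded nearby
  v <- alt_laterality(0.5, -0.5, "eq3")
  expect_true(attr(v, "overflow"))
  expect_identical(as.numeric(v), Inf)
  near <- alt_laterality(1, -1 + 1e-4, "eq3")
  expect_gt(abs(near), 1e3)

  # zeroing strategy: negative inputs replaced by 0, losing polarity
  z <- alt_laterality(0.5, -0.3, "eq3_zeroed")
  expect_equal(as.numeric(z), 1)  # (0.5 - 0) / (0.5 + 0)
  zz <- alt_laterality(-0.2, -0.3, "eq3_zeroed")
  expect_true(attr(zz, "overflow") == FALSE && as.numeric(zz) == 0)
})

test_that("stability report counts saturation and overflow correctly", {
  r <- stability_report(c(1, -1, 0.5))
  expect_equal(r$frac_at_unity, 2 / 3)
  r2 <- stability_report(c(0.995, 0.2))
  expect_equal(r2$frac_above_099, 1 / 2)
  expect_equal(r2$frac_at_unity, 0)
  expect_lte(r2$p95_abs, r2$max_abs)
  # continuous draws never sit exactly at +/-1
  set.seed(13)
  r3 <- stability_report(runif(1000, -1, 1))
  expect_equal(r3$frac_at_unity, 0)
  # overflowed values count as +Inf in the maximum
  r4 <- stability_report(c(0.5, 2), overflow = c(FALSE, TRUE))
  expect_identical(r4$max_abs, Inf)
  expect_equal(r4$n_overflow, 1)
  expect_error(stability_report(numeric(0)), "empty")
})

test_that("the bounded index is markedly more stable than the legacy forms", {
  # same response sample, four indices: the package's formula should show
  # no saturation while eq2 saturates and eq3 blows up
  set.seed(14)
  a <- rnorm(5000); b <- a * 0.6 + rnorm(5000)  # correlated hemispheres
  r_lc <- stability_report(lc(a, b))
  v2 <- alt_laterality(a, b, "eq2")
  v3 <- alt_laterality(a, b, "eq3")
  r2 <- stability_report(v2)
  r3 <- stability_report(v3)
  expect_equal(r_lc$frac_at_unity, 0)
  expect_gt(r2$frac_at_unity, 0.2)      # frequent hard saturation
  expect_gt(r3$p95_abs, 1)              # heavy-tailed, unbounded
  expect_gt(r3$max_abs, 100)
  expect_lte(r_lc$max_abs, 1)
})

test_that("asymmetry table wiring matches the montage geometry", {
  m <- load_montage("clinical28")
  # symmetric responses: all LC = 0; task-identical responses: TRAC = 0
  grid <- expand.grid(channel = m$channels$channel,
                      task = c("affected", "intact"),
                      chromophore = c("HbO", "HbR"),
                      stringsAsFactors = FALSE)
  grid$coefficient <- 1.7
  tab <- compute_asymmetry_table(tibble::as_tibble(grid), m)
  expect_equal(sum(tab$index_kind == "LC"), 14 * 2 * 2)   # pair x hand x chrom
  expect_equal(sum(tab$index_kind == "TRAC"), 28 * 2)     # channel x chrom
  expect_true(all(tab$value == 0))
  expect_setequal(unique(tab$hemisphere[tab$index_kind == "TRAC"]),
                  c("lesioned", "intact"))

  # planted lesioned-dominant pattern: lesioned TRAC > 0 > intact TRAC
  amp <- patient_amplitudes(m, "left")
  amp$task <- ifelse(amp$task == "mi_right", "affected", "intact")
  names(amp)[names(amp) == "amplitude"] <- "coefficient"
  tab2 <- compute_asymmetry_table(amp, m, kinds = "TRAC")
  les <- tab2$value[tab2$hemisphere == "lesioned"]
  int <- tab2$value[tab2$hemisphere == "intact"]
  expect_equal(unique(round(les, 10)), 0.2)
  expect_equal(unique(round(int, 10)), -0.05)

  # missing task coefficient: unit skipped with a warning
  expect_warning(compute_asymmetry_table(grid[-1, ], m, kinds = "LC"),
                 "skipped")
})

test_that("healthy subjects are wired in left/right coordinates", {
  m <- tiny_montage()
  resp <- tiny_responses(c(1, 1, 2, 2, 3, 3, 4, 4))
  tab <- compute_asymmetry_table(resp, m)
  expect_setequal(unique(tab$hemisphere[tab$index_kind == "TRAC"]),
                  c("left", "right"))
  # left channel L1: contra task = mi_right (3), ipsi = mi_left (1)
  v <- tab$value[which(tab$index_kind == "TRAC" & tab$channel == "L1")]
  expect_equal(v, trac(3, 1))
  # LC for mi_left: contra = R1 (2), ipsi = L1 (1)
  vlc <- tab$value[which(tab$index_kind == "LC" & tab$hand == "mi_left" &
                           tab$pair == "P01")]
  expect_equal(vlc, lc(2, 1))
})
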