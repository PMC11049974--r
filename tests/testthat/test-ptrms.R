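make_scan <- function(iso = c(100, 50, 25, 10, 5, 2), prim = c(1e6, 2e5, 5e4),
                      p = 2.2, t = 0) {
  d <- data.frame(time_min = t)
  for (i in 1:6) d[[paste0("mz", 68 + i)]] <- iso[i]
  d$mz21 <- prim[1]; d$mz37 <- prim[2]; d$mz55 <- prim[3]
  d$p_drift_mbar <- p
  d
}

test_that("primary-ion normalization is gain-invariant and linear", {
  s <- make_scan()
  n1 <- normalize_cps(s)
  # common gain on every channel including primary ions cancels
  s2 <- s; for (ch in c(paste0("mz", 69:74), "mz21", "mz37", "mz55"))
    s2[[ch]] <- 2 * s2[[ch]]
  expect_equal(unlist(normalize_cps(s2)[paste0("ncps", 69:74)]),
               unlist(n1[paste0("ncps", 69:74)]))
  # doubling only the isotopologue channels doubles ncps
  s3 <- s; for (ch in paste0("mz", 69:74)) s3[[ch]] <- 2 * s3[[ch]]
  expect_equal(unlist(normalize_cps(s3)[paste0("ncps", 69:74)]),
               2 * unlist(n1[paste0("ncps", 69:74)]))
  # hand computation on one row with the stated weights and pressures
  expect_equal(n1$ncps69,
               100 / (1e6 + 2e5 + 5e4) * (2.2 / 2.2) * 1e6)
  nh <- normalize_cps(make_scan(p = 2.3), w37 = 0.5, w55 = 0.25)
  expect_equal(nh$ncps69, 100 / (1e6 + 0.5 * 2e5 + 0.25 * 5e4) *
                 (2.2 / 2.3) * 1e6)
})

test_that("scans with a dead primary-ion signal are flagged, not zeroed", {
  s <- rbind(make_scan(t = 0), make_scan(prim = c(0, 0, 0), t = 1))
  expect_warning(n <- normalize_cps(s), "rejected")
  expect_false(n$rejected[1])
  expect_true(n$rejected[2])
  expect_true(is.na(n$ncps69[2]))
  expect_error(normalize_cps(make_scan(p = -1)), "pressure")
})

test_that("background subtraction is exact, clamped, and rejects bad input", {
  s <- normalize_cps(make_scan())
  expect_equal(unlist(subtract_background(s, s)[paste0("ncps", 69:74)]),
               stats::setNames(rep(0, 6), paste0("ncps", 69:74)))
  zero_bg <- stats::setNames(rep(0, 6), paste0("ncps", 69:74))
  expect_equal(subtract_background(s, zero_bg)$ncps69, s$ncps69)
  # 10% background leaves 90%
  bg <- stats::setNames(unlist(s[paste0("ncps", 69:74)]) * 0.1,
                        paste0("ncps", 69:74))
  expect_equal(subtract_background(s, bg)$ncps70, 0.9 * s$ncps70)
  expect_error(subtract_background(s, rbind(s, s)), "longer")
})

test_that("emission rate follows the calibration arithmetic", {
  expect_equal(emission_rate(0, 2, 0.01)$emission, 0)
  e1 <- emission_rate(150, cal_factor = 0.004, leaf_area = 0.0057)
  expect_equal(e1$emission, 150 * 0.004 / 0.0057)
  expect_equal(emission_rate(150, 0.004, 2 * 0.0057)$emission,
               e1$emission / 2)
  expect_error(emission_rate(150, leaf_area = 0.0057), "cal_factor")
  expect_error(emission_rate(150, 0.004, -1), "leaf_area")
})

test_that("atom-weighted labeling handles the canonical cases", {
  expect_equal(fractional_labeling(c(0, 0, 0, 0, 0, 7)), 1)
  expect_equal(fractional_labeling(c(3, 0, 0, 0, 0, 3)), 0.5)
  expect_equal(fractional_labeling(c(10, 20, 30, 20, 10, 10)), 0.46)
  # scale invariance
  expect_equal(fractional_labeling(1e5 * c(10, 20, 30, 20, 10, 10)), 0.46)
  expect_warning(f <- fractional_labeling(rep(0, 6)), "all-zero")
  expect_true(is.na(f))
  expect_error(fractional_labeling(c(-1, 1, 1, 1, 1, 1)), "negative")
})

test_that("labeling of a Binomial(5, p) channel split returns p", {
  for (p in seq(0, 1, by = 0.05)) {
    expect_equal(fractional_labeling(dbinom(0:5, 5, p)), p, tolerance = 1e-12)
  }
})

test_that("natural-abundance correction methods behave as documented", {
  x <- dbinom(0:5, 5, 0.3) * 500
  conv <- as.vector(natural_abundance_matrix(0.011) %*% x)
  expect_equal(correct_isoprene_channels(conv, "binomial"), x,
               tolerance = 1e-9)
  expect_identical(correct_isoprene_channels(conv, "none"), conv)
  # the quick m/z 70 rule removes ~5.5% of the unlabeled channel from ch1
  v <- c(1000, 60, 0, 0, 0, 0)
  out <- correct_isoprene_channels(v, "mz70")
  expect_equal(out[2], 60 - 5 * 0.011 * 1000)
  expect_equal(out[-2], v[-2])
})

test_that("channel pipeline reproduces the generating labeling curve", {
  grid <- seq(0, 30, 1)
  p <- pool_sizes(30, 60, 20)
  run <- generate_label_run(p, J = 12, m = 0.9, grid = grid,
                            channel_frac = 0, background_cps = 8)
  bg <- generate_label_run(p, J = 12, m = 0.9, grid = grid, total_cps = 0,
                           background_cps = 8)
  cv <- ptrms_label_curve(run, background = bg, nat_corr = "binomial")
  expect_equal(cv$f_label, label_fraction(grid, p, 12, 0.9),
               tolerance = 1e-9)
  # with 1% channel noise the recovered curve stays within the noise scale
  set.seed(404)
  runN <- generate_label_run(p, J = 12, m = 0.9, grid = grid,
                             channel_frac = 0.01, background_cps = 8)
  cvN <- ptrms_label_curve(runN, background = bg, nat_corr = "binomial")
  expect_lt(max(abs(cvN$f_label - label_fraction(grid, p, 12, 0.9))), 0.05)
})
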