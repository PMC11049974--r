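test_that("labeling starts at zero, stays in [0, m], and plateaus at m", {
  p <- pool_sizes(41.65, 85.59, 38.09)
  expect_equal(label_fraction(0, p, J = 28.65, m = 0.912), 0)
  # frozen value derived from independent ODE integration of the cascade
  expect_equal(label_fraction(20, p, J = 28.65, m = 0.912), 0.9080474,
               tolerance = 1e-6)
  expect_equal(label_fraction(1000, p, J = 28.65, m = 0.912), 0.912,
               tolerance = 1e-12)
  set.seed(101)
  for (i in 1:25) {
    d <- draw_model_params()
    f <- label_fraction(default_grid(), d$pools, d$J, d$m)
    expect_true(all(f >= 0 & f <= d$m))
    expect_true(all(diff(f) >= -1e-12))  # non-decreasing
  }
})

test_that("the three closed-form coefficients always sum to one", {
  coef_sum <- function(A, B, C) {
    A^2 / ((A - B) * (A - C)) + B^2 / ((B - A) * (B - C)) +
      C^2 / ((C - A) * (C - B))
  }
  for (r in ref_rows()) {
    expect_equal(coef_sum(r$A, r$B, r$C), 1, tolerance = 1e-10)
  }
  set.seed(202)
  for (i in 1:50) {
    d <- draw_model_params()
    expect_equal(coef_sum(d$pools$A, d$pools$B, d$pools$C), 1,
                 tolerance = 1e-10)
  }
})

test_that("closed form agrees with the ODE oracle including degenerate pools", {
  r <- reference_parameters()[1, ]
  p <- pool_sizes(r$A, r$B, r$C)
  grid <- default_grid()
  oracle <- cascade_ode_oracle(grid, p, r$J, r$m)
  expect_lt(max(abs(oracle$f_label - label_fraction(grid, p, r$J, r$m))),
            1e-6)
  # equal pools: closed form is singular, the oracle still integrates and
  # label_fraction transparently falls back to it
  peq <- pool_sizes(10, 10, 10)
  ceq <- cascade_ode_oracle(seq(0, 50, 1), peq, J = 5, m = 1)
  expect_equal(ceq$f_label[1], 0, tolerance = 1e-9)
  expect_true(all(diff(ceq$f_label) >= -1e-10))
  expect_equal(ceq$f_label[length(ceq$f_label)], 1, tolerance = 1e-3)
  expect_equal(label_fraction(c(5, 1, 25), peq, 5, 1),
               ceq$f_label[match(c(5, 1, 25), ceq$time_min)],
               tolerance = 1e-8)
  # near-degenerate pair exercises the same fallback
  pnd <- pool_sizes(20, 20 * (1 + 1e-9), 35)
  expect_false(pools_distinct(pnd))
  expect_equal(label_fraction(10, pnd, 8, 0.9),
               cascade_ode_oracle(c(5, 10), pnd, 8, 0.9)$f_label[2],
               tolerance = 1e-8)
})

test_that("fast equilibration saturates within the first grid step", {
  f <- label_fraction(c(0.5, 1), pool_sizes(10, 12, 14), J = 1e4, m = 0.9)
  expect_equal(f, c(0.9, 0.9), tolerance = 1e-6)
})

test_that("noiseless round trips recover J and m for every published row", {
  grid <- default_grid()
  for (r in ref_rows()) {
    p <- pool_sizes(r$A, r$B, r$C)
    cv <- label_curve(grid, label_fraction(grid, p, r$J, r$m))
    fit <- fit_flux(cv, p, init_J = 1, init_m = 0.5)
    expect_true(fit$converged)
    expect_equal(fit$J, r$J, tolerance = 1e-3)
    expect_equal(fit$m, r$m, tolerance = 1e-3)
    expect_lt(fit$rss, 1e-10)
  }
})

test_that("fit is unbiased under modest additive noise", {
  set.seed(303)
  r <- reference_parameters()[10, ]  # low-flux row, slowest kinetics
  p <- pool_sizes(r$A, r$B, r$C)
  grid <- default_grid()
  f0 <- label_fraction(grid, p, r$J, r$m)
  Js <- replicate(60, {
    cv <- label_curve(grid, pmin(pmax(f0 + rnorm(length(grid), 0, 0.01), 0), 1))
    fit_flux(cv, p)$J
  })
  expect_lt(abs(mean(Js) - r$J) / r$J, 0.05)
})

test_that("degenerate inputs yield diagnostics, not silent estimates", {
  p <- pool_sizes(40, 80, 35)
  grid <- default_grid()
  # all-zero and all-plateau curves are not identifiable
  expect_false(fit_flux(label_curve(grid, rep(0, length(grid))), p)$converged)
  expect_false(fit_flux(label_curve(grid, rep(0.9, length(grid))), p)$converged)
  # non-finite input is rejected outright
  expect_error(label_curve(c(0, 1, 2), c(0, NA, 0.5)), "non-finite")
  expect_error(label_curve(c(0, 1), c(0, 0.5, 0.9)), "equal length")
  expect_error(label_curve(c(0, 2, 1), c(0, 0.3, 0.5)), "increasing")
  # fewer points than needed for 2 parameters
  expect_error(fit_flux(label_curve(c(0, 1), c(0, 0.4)), p), "at least 3")
})

test_that("sub-grid time constants give huge se_J, not false precision", {
  p <- pool_sizes(5, 6, 7)
  grid <- seq(0, 50, 5)  # time constants ~0.002 min at J = 3000
  f <- label_fraction(grid, p, J = 3000, m = 0.9)
  fit <- fit_flux(label_curve(grid, f), p)
  expect_true(is.infinite(fit$se_J) || fit$se_J > fit$J)
})

test_that("label curves round-trip through CSV/TSV files", {
  grid <- seq(0, 10, 1)
  p <- pool_sizes(20, 30, 10)
  cv <- label_curve(grid, label_fraction(grid, p, 10, 0.9))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(cv), path, row.names = FALSE)
  expect_equal(read_label_curve(path)$f_label, cv$f_label, tolerance = 1e-12)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fit <- fit_flux(cv, p)
  tab <- write_flux_fits(list(s1 = fit), tsv)
  reread <- utils::read.delim(tsv)
  expect_equal(reread$J, fit$J, tolerance = 1e-9)
  expect_identical(names(reread),
                   c("sample_id", "J", "se_J", "m", "se_m", "rss",
                     "n_points", "converged"))
})
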