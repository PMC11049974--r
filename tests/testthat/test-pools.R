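test_that("standard-curve inverse prediction matches hand computation", {
  sc <- data.frame(amount_pmol = c(0, 10), intensity = c(0, 100))
  expect_equal(as.numeric(quantify_standard_curve(50, sc)), 5)
  expect_equal(as.numeric(quantify_standard_curve(0, sc)), 0)
  # 3-point least squares by hand: slope 10.2, intercept 0
  sc3 <- data.frame(amount_pmol = c(0, 10, 20), intensity = c(2, 98, 206))
  expect_equal(as.numeric(quantify_standard_curve(51, sc3)), 5,
               tolerance = 1e-12)
  neg <- quantify_standard_curve(-30, sc)
  expect_equal(as.numeric(neg), 0)
  expect_equal(attr(neg, "clamped"), 1L)
  expect_error(quantify_standard_curve(5, data.frame(amount_pmol = c(0, 10),
                                                     intensity = c(100, 0))),
               "non-monotone|singular")
  expect_error(quantify_standard_curve(5, data.frame(amount_pmol = c(10, 10),
                                                     intensity = c(1, 2))),
               "increasing")
})

test_that("internal-standard factor recovers known matrix suppression", {
  sc <- data.frame(amount_pmol = c(0, 50, 100),
                   intensity = c(0, 5000, 10000))  # slope 100
  endo <- c(200, 50, 30, 400, 600, 900)
  istd <- 20  # expected increment 2000
  # no suppression: spiked adds exactly the expected channel-0 signal
  f1 <- istd_matrix_factor(endo + c(2000, 0, 0, 0, 0, 0), endo, istd, sc)
  expect_equal(as.numeric(f1), 1)
  # half the expected increment -> factor 0.5 (pool doubled downstream)
  f2 <- istd_matrix_factor(endo + c(1000, 0, 0, 0, 0, 0), endo, istd, sc)
  expect_equal(as.numeric(f2), 0.5)
  # forward-constructed 20% suppression with a spiked-run gain of 1.3:
  # heavy channels scale by 1.3 and the spike contributes 0.8 of expectation
  spiked <- 1.3 * endo + c(0.8 * 1.3 * 2000, 0, 0, 0, 0, 0)
  f3 <- istd_matrix_factor(spiked, endo, istd, sc)
  expect_equal(as.numeric(f3), 0.8 * 1.3, tolerance = 1e-12)
  expect_equal(attr(f3, "endogenous_scale"), 1.3, tolerance = 1e-12)
  # unlabeled extract: heavy channels empty, fall back flagged
  endo0 <- c(500, 20, 5, 0, 0, 0)
  f4 <- istd_matrix_factor(endo0 + c(1600, 0, 0, 0, 0, 0), endo0, istd, sc)
  expect_equal(as.numeric(f4), 0.8)
  expect_true(attr(f4, "low_confidence"))
})

test_that("natural-abundance correction inverts the forward convolution", {
  M <- natural_abundance_matrix(0.011)
  expect_equal(colSums(M), rep(1, 6), tolerance = 1e-12)
  # pure unlabeled round trip
  pure <- c(1000, 0, 0, 0, 0, 0)
  expect_equal(natural_abundance_correct(as.vector(M %*% pure)), pure,
               tolerance = 1e-9)
  # identity at p13 = 0
  expect_identical(natural_abundance_correct(pure, p13 = 0), pure)
  set.seed(505)
  for (i in 1:20) {
    x <- stats::runif(6, 0, 100)
    obs <- as.vector(M %*% x)
    expect_equal(natural_abundance_correct(obs), x, tolerance = 1e-10)
    # total signal conserved
    expect_equal(sum(natural_abundance_correct(obs)), sum(obs),
                 tolerance = 1e-10)
  }
  expect_error(natural_abundance_correct(pure, p13 = 0.6), "0.5")
})

test_that("metabolite label fraction matches the atom-weighted formula", {
  expect_equal(metabolite_label_fraction(c(0, 0, 0, 0, 0, 4)), 1)
  expect_equal(metabolite_label_fraction(c(2, 0, 0, 0, 0, 2)), 0.5)
  expect_equal(metabolite_label_fraction(rep(1, 6)), 0.5)
})

test_that("plastidial pool estimation follows the label-ratio rule", {
  expect_equal(plastidial_pool(50, 0.9, 0.9), 50)
  expect_equal(plastidial_pool(50, 0.45, 0.90), 25)
  expect_warning(capped <- plastidial_pool(50, 0.95, 0.90), "capped")
  expect_equal(capped, 50)
  expect_error(plastidial_pool(50, 0.5, 0), "undefined|positive")
  # homogeneity in total, invariance to common label rescaling
  expect_equal(plastidial_pool(100, 0.3, 0.6), 2 * plastidial_pool(50, 0.3, 0.6))
  expect_equal(plastidial_pool(50, 0.3, 0.6), plastidial_pool(50, 0.15, 0.3))
})

test_that("pool workflow recovers generated plastidial fractions", {
  study <- generate_study(design = study_design(n_per_cell = 1, seed = 9),
                          noise = zero_noise(), flux_model = "table1",
                          frac_dxp = 0.7, frac_mecdp = 0.9)
  pt <- estimate_pools(study$pool_measurements, study$standard_curves)
  tr <- study$truth
  for (i in seq_len(nrow(tr))) {
    rows <- pt[pt$sample_id == tr$sample_id[i], ]
    a <- rows[rows$metabolite == "DXP", ]
    expect_equal(a$plastidial_pool, tr$A[i], tolerance = 1e-6)
    expect_equal(a$plastidial_pool / a$total_pool, 0.7, tolerance = 1e-6)
    expect_equal(rows[rows$metabolite == "MEcDP", "plastidial_pool"],
                 tr$B[i], tolerance = 1e-6)
    expect_equal(rows[rows$metabolite == "IDP+DMADP", "plastidial_pool"],
                 tr$C[i], tolerance = 1e-6)
    expect_equal(rows$matrix_factor, rep(tr$matrix_factor[i], 3),
                 tolerance = 1e-6)
  }
})
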