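test_that("the spectral mode sits at the apex, ties broken toward q = 0", {
  sp <- legendre_transform(analytic_pf(function(q) 0.8 * q - 0.05 * q^2))
  expect_equal(spectral_mode(sp), 0.8, tolerance = 1e-10)
  # a flat-topped spectrum: tie at the apex resolved toward |q| smallest
  flat <- mfspectra:::new_mf_spectrum(q = c(-0.2, -0.1, 0, 0.1, 0.2),
                                      alpha = c(0.9, 0.85, 0.8, 0.75, 0.7),
                                      f = c(-0.1, 0, 0, 0, -0.1))
  expect_equal(spectral_mode(flat), 0.8)
  # a single-point monofractal collapse
  pt <- mfspectra:::new_mf_spectrum(q = 0, alpha = 0.62, f = 0)
  expect_equal(spectral_mode(pt), 0.62)
  expect_error(spectral_mode(tibble::tibble()), class = "mfspectra_error_input")
})

quad_spectrum <- function(a = 12.5, m = 0.8, step = 0.02, half = 0.4) {
  alpha <- seq(m - half, m + half, by = step)
  analytic_spectrum(alpha, -a * (alpha - m)^2)
}

test_that("broadness of a sampled quadratic matches the analytic roots", {
  sp <- quad_spectrum()
  br <- broadness(sp, threshold = 0.2)
  root <- sqrt(0.2 / 12.5)
  expect_lt(abs(br$alpha1 - (0.8 - root)), 1e-3)
  expect_lt(abs(br$alpha2 - (0.8 + root)), 1e-3)
  expect_lt(abs(br$B - 2 * root), 1e-3)
  expect_false(br$relaxed)
  # symmetry of the two half-widths
  SM <- spectral_mode(sp)
  expect_equal(SM - br$alpha1, br$alpha2 - SM, tolerance = 1e-10)
})

test_that("quadratic closed forms hold for SM, slopes and broadness", {
  for (a in c(5, 12.5, 30)) {
    sp <- quad_spectrum(a = a, m = 0.75, step = 0.02, half = 0.5)
    d <- mf_descriptors(sp, threshold = 0.2)
    expect_equal(d$SM, 0.75, tolerance = 1e-9)
    expect_lt(abs(d$B - 2 * sqrt(0.2 / a)), 1e-3)
    expect_lt(abs(d$LS + d$RS), 0.05)
    expect_equal(d$LS, 0.2 / sqrt(0.2 / a), tolerance = 0.05)
  }
})

test_that("slopes and tangents follow their defining formulas", {
  br <- list(alpha1 = 0.7, alpha2 = 0.95, threshold_used = 0.2,
             left_bracket = list(alpha_l = 0.69, f_l = -0.22,
                                 alpha_u = 0.71, f_u = -0.18),
             right_bracket = list(alpha_l = 0.96, f_l = -0.24,
                                  alpha_u = 0.94, f_u = -0.16))
  st <- slopes_tangents(0.8, br)
  expect_equal(st$LS, 2.0, tolerance = 1e-12)
  expect_equal(st$RS, -0.2 / 0.15, tolerance = 1e-12)
  expect_equal(st$LT, (-0.18 - -0.22) / (0.71 - 0.69), tolerance = 1e-12)  # 2.0
  expect_equal(st$LT, 2.0, tolerance = 1e-12)
  expect_equal(st$RT, (-0.16 - -0.24) / (0.94 - 0.96), tolerance = 1e-12)
  # apex coinciding with a crossing is degenerate
  br_bad <- br; br_bad$alpha1 <- 0.8
  expect_error(slopes_tangents(0.8, br_bad), class = "mfspectra_error_descriptor")
})

test_that("broadness shrinks monotonically with the threshold", {
  sp <- quad_spectrum()
  b1 <- broadness(sp, threshold = 0.1)$B
  b2 <- broadness(sp, threshold = 0.2)$B
  expect_lt(b1, b2)
  # and on an estimated multifractal spectrum
  spc <- multifractal_spectrum(simulate_cascade(2048, p = 0.3, seed = 5))
  expect_lt(broadness(spc, 0.1)$B, broadness(spc, 0.2)$B)
})

test_that("undefined sides raise typed errors naming the side", {
  # spectrum never dips below -0.2 on the right
  alpha <- seq(0.5, 1.0, by = 0.02)
  f <- ifelse(alpha < 0.8, -2 * (0.8 - alpha), -0.05 * (alpha - 0.8) / 0.2)
  sp <- analytic_spectrum(alpha, f)
  err <- tryCatch(broadness(sp, 0.2), error = function(e) e)
  expect_s3_class(err, "mfspectra_error_descriptor")
  expect_match(conditionMessage(err), "right")
})

test_that("auto-relaxation halves the threshold until defined and records it", {
  # shallow quadratic: minimum f = -0.09, so 0.2 and 0.1 fail but 0.05 works
  sp <- quad_spectrum(a = 0.5625, m = 0.8, step = 0.02, half = 0.4)
  expect_equal(min(sp$f), -0.09, tolerance = 1e-9)
  expect_error(broadness(sp, 0.2), class = "mfspectra_error_descriptor")
  expect_message(br <- broadness(sp, 0.2, auto_relax = TRUE), "relaxed")
  expect_equal(br$threshold_used, 0.05)
  expect_true(br$relaxed)
  # the relax floor stops the halving
  low <- quad_spectrum(a = 0.005, m = 0.8, step = 0.02, half = 0.4)
  expect_error(broadness(low, 0.2, auto_relax = TRUE, relax_floor = 0.05),
               class = "mfspectra_error_descriptor")
})

test_that("group regularity ordering is recovered on paired cohort-like signals", {
  n_pairs <- 50
  res <- vapply(seq_len(n_pairs), function(s) {
    p <- paired_group_signals(seed = s)
    dh <- descriptors_of(p$high)
    dl <- descriptors_of(p$low)
    c(sm_h = dh$SM, sm_l = dl$SM, ls_h = dh$LS, ls_l = dl$LS)
  }, numeric(4))
  expect_gt(mean(res["sm_l", ]) - mean(res["sm_h", ]), 0)
  expect_gt(mean(res["ls_h", ]) - mean(res["ls_l", ]), 0)
})
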