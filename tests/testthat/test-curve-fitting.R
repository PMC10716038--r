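test_that("curve containers validate their inputs", {
  expect_error(titration_curve(1:3, 1:4), "equal length")
  expect_error(titration_curve(c(1, 2, 2, 1), rep(0, 4)), "4 distinct")
  expect_error(dose_response_curve(1:4, 1:4, top = 1, bottom = 1), "different")
})

test_that("noiseless one-site curves invert exactly", {
  g <- titration_grid(2000, n = 16)
  cv <- titration_curve(g, 0.05 + 0.9 * g / (g + 39))
  f <- fit_one_site(cv)
  expect_true(f$converged)
  expect_equal(f$kd, 39, tolerance = 1e-3)
  expect_equal(f$a, 0.9, tolerance = 1e-4)
  expect_equal(f$r0, 0.05, tolerance = 1e-4)
})

test_that("a constant response is refused, not fitted", {
  f <- fit_one_site(titration_curve(titration_grid(100, 8), rep(0.3, 8)))
  expect_false(f$converged)
  expect_true("constant_response_kd_unidentifiable" %in% f$flags)
})

test_that("depletion-aware fit corrects the biased plain hyperbola", {
  kd <- 5; lt <- 50 # labeled at 10x Kd: strong depletion
  g <- titration_grid(5000, n = 16)
  bound <- oracle_binary_complex(kd, g, lt) / lt
  cv <- titration_curve(g, 0.02 + 0.8 * bound, labeled_total = lt)
  f_dep <- fit_one_site(cv, depletion = TRUE)
  f_hyp <- fit_one_site(cv)
  expect_equal(f_dep$kd, kd, tolerance = 1e-4)
  # the plain hyperbola lands near the half-saturation concentration
  # (~ Kd + labeled/2), several-fold off the true constant
  expect_gt(f_hyp$kd / kd, 3)
})

test_that("global fit shares Kd across replicates, even with opposite
          amplitude signs", {
  g <- titration_grid(1000, n = 16)
  set.seed(5)
  mk <- function(a, r0, noise) {
    titration_curve(g, r0 + a * g / (g + 25) +
                      stats::rnorm(length(g), 0, noise))
  }
  f <- fit_global(list(mk(1, 0, 0.02), mk(0.8, 0.1, 0.02)))
  expect_true(f$converged)
  expect_equal(f$kd, 25, tolerance = 0.15)
  expect_lt(abs(log(f$kd / 25)), 2 * f$kd_se / f$kd + 0.05)

  # one curve: identical to the single-curve fit
  cv <- mk(1, 0, 0.02)
  f1 <- fit_global(list(cv))
  fs <- fit_one_site(cv)
  expect_equal(f1$kd, fs$kd, tolerance = 1e-6)

  # opposite signs, same Kd
  f2 <- fit_global(list(mk(1, 0, 0), mk(-1, 0, 0)))
  expect_true(f2$converged)
  expect_equal(f2$kd, 25, tolerance = 1e-4)
  expect_lt(prod(f2$per_curve$a), 0)
})

test_that("simultaneous signed two-component fit is exact on clean data;
          the piecewise protocol's bias is frozen", {
  g <- titration_grid(500, n = 16)
  cv <- titration_curve(g, g / (g + 2.9) - g / (g + 25))
  si <- fit_two_site_signed(cv, mode = "simultaneous")
  expect_true(si$converged)
  expect_equal(si$kd_pos, 2.9, tolerance = 1e-6)
  expect_equal(si$kd_neg, 25, tolerance = 1e-6)
  expect_equal(si$a_pos, 1, tolerance = 1e-6)
  expect_equal(si$a_neg, -1, tolerance = 1e-6)

  # the split protocol is systematically biased: each segment absorbs the
  # other component's tail; these regression values document that bias
  pw <- fit_two_site_signed(cv, mode = "piecewise")
  expect_equal(pw$kd_pos, 2.0889, tolerance = 1e-3)
  expect_equal(pw$kd_neg, 49.406, tolerance = 1e-3)
  pwc <- fit_two_site_signed(cv, mode = "piecewise", fixed_max_response = 1)
  expect_equal(pwc$kd_pos, 4.4683, tolerance = 1e-3)
  expect_equal(pwc$kd_neg, 9.7022, tolerance = 1e-3)

  # amplitude scale invariance
  cv10 <- titration_curve(g, 10 * (g / (g + 2.9) - g / (g + 25)))
  si10 <- fit_two_site_signed(cv10, mode = "simultaneous")
  expect_equal(si10$kd_pos, si$kd_pos, tolerance = 1e-6)
  expect_equal(si10$kd_neg, si$kd_neg, tolerance = 1e-6)

  # single positive component: the negative site is unidentifiable
  cv1 <- titration_curve(g, g / (g + 2.9))
  s1 <- fit_two_site_signed(cv1, mode = "simultaneous")
  expect_false(s1$converged)
  expect_true("negative_component_unresolved" %in% s1$flags)
})

test_that("fixed-asymptote dose-response fits recover the midpoint", {
  g <- titration_grid(9, n = 16)
  # noiseless, hill fixed: exact midpoint recovery
  cv <- dose_response_curve(g, 0 + 1 / (1 + (g / 0.09)), top = 1, bottom = 0)
  f <- fit_dose_response(cv, hill = "fixed")
  expect_true(f$converged)
  expect_equal(f$ic50, 0.09, tolerance = 1e-6)

  # triplicate curves at 5% noise: midpoint within 10% at this seed
  sim <- gen_dose_response(1, 0, 0.09, 1, g, noise_sd = 0.05,
                           replicates = 3, seed = 1)
  fn <- fit_dose_response(sim$curve)
  expect_true(fn$converged)
  expect_equal(fn$ic50, 0.09, tolerance = 0.1)

  # a curve that never descends is refused
  flat <- dose_response_curve(g, rep(1, length(g)), top = 1, bottom = 0)
  ff <- fit_dose_response(flat)
  expect_false(ff$converged)
  expect_true("no_descent_from_top" %in% ff$flags)
})

test_that("one-site recovery and CI coverage over 500 pooled titrations", {
  set.seed(42)
  n <- 500
  kds <- exp(stats::runif(n, log(1), log(500)))
  g <- titration_grid(2000, n = 16)
  gg <- rep(g, 3) # triplicate titrations pooled, as in a global fit
  err <- numeric(n); cover <- logical(n)
  for (i in seq_len(n)) {
    resp <- 0.02 + gg / (gg + kds[i]) + stats::rnorm(length(gg), 0, 0.03)
    f <- fit_one_site(titration_curve(gg, resp,
                                      replicate = rep(1:3, each = 16)))
    err[i] <- abs(f$kd - kds[i]) / kds[i]
    cover[i] <- abs(log(f$kd) - log(kds[i])) <= 1.96 * f$kd_se / f$kd
  }
  expect_lt(stats::median(err), 0.05)
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.98)
})

test_that("fits are invariant under concentration-unit rescaling", {
  g <- titration_grid(2000, n = 16)
  set.seed(9)
  resp <- 0.05 + 0.9 * g / (g + 39) + stats::rnorm(length(g), 0, 0.02)
  f_um <- fit_one_site(titration_curve(g, resp))
  f_nm <- fit_one_site(titration_curve(g * 1000, resp)) # same data in nM
  expect_equal(f_nm$kd, f_um$kd * 1000, tolerance = 1e-6)
  expect_equal(f_nm$rss, f_um$rss, tolerance = 1e-8)
})
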