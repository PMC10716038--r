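test_that("measured_kd validates its fields and exposes Ka", {
  expect_error(measured_kd(0), "> 0")
  expect_error(measured_kd(5, -1), ">= 0")
  k <- measured_kd(108, 12, n = 3, label = "THD1 vs beta3-CT")
  expect_equal(ka(k), 1 / 108)
})

# the four bundled squares with hand-computed quadrature expectations
paper_squares <- function() reference_constants("squares")

test_that("cycle product and quadrature sigma match hand arithmetic", {
  sq <- paper_squares()
  expected <- list( # computed by direct arithmetic on the printed constants
    c(Q = 918 / 5832, s = (918 / 5832) *
        sqrt((12 / 108)^2 + (2 / 9)^2 + (40 / 102)^2 + (27 / 54)^2)),
    c(Q = 684 / 544, s = (684 / 544) *
        sqrt((2 / 34)^2 + (2 / 9)^2 + (11 / 76)^2 + (1 / 16)^2)),
    c(Q = 1962 / 2268, s = (1962 / 2268) *
        sqrt((12 / 108)^2 + 0^2 + (55 / 218)^2 + (3 / 21)^2)),
    c(Q = 1395 / 1086, s = (1395 / 1086) *
        sqrt((11 / 181)^2 + (1 / 5)^2 + (36 / 279)^2 + (3 / 6)^2))
  )
  for (i in seq_along(sq)) {
    cp <- cycle_product(sq[[i]])
    expect_equal(cp$Q, expected[[i]][["Q"]], tolerance = 1e-12)
    expect_equal(cp$sigma_Q, expected[[i]][["s"]], tolerance = 1e-12)
  }
})

test_that("the four evaluations reproduce the printed values and verdicts", {
  sq <- paper_squares()
  printed <- list(c(0.16, 0.11, 2), c(1.3, 0.4, 1), c(0.9, 0.3, 1),
                  c(1.3, 0.7, 1)) # (Q, sigma, decimals)
  verdicts <- c("inconsistent", "consistent", "consistent", "consistent")
  for (i in seq_along(sq)) {
    v <- consistency_verdict(sq[[i]])
    d <- printed[[i]][3]
    expect_equal(round(v$Q, d), printed[[i]][1])
    expect_equal(round(v$sigma_Q, d), printed[[i]][2])
    expect_identical(v$verdict, verdicts[i])
  }
  # z-score spot checks against the informal reading of the evaluations
  expect_equal(consistency_verdict(sq[[1]])$z, 7.85, tolerance = 0.01)
  expect_lt(consistency_verdict(sq[[2]])$z, 1)
})

test_that("degenerate squares are handled explicitly", {
  same <- energy_square(5, 5, 5, 5)
  cp <- cycle_product(same)
  expect_identical(cp$Q, 1)
  expect_identical(cp$sigma_Q, 0)
  expect_identical(consistency_verdict(same)$verdict, "consistent")

  off <- energy_square(5, 5, 10, 5) # sigma 0 but Q != 1
  v <- consistency_verdict(off)
  expect_identical(v$z, Inf)
  expect_identical(v$verdict, "inconsistent")
  expect_true("zero_uncertainty_nonunit_Q" %in% v$flags)
})

test_that("Monte Carlo propagation cross-checks the quadrature sigma", {
  sq <- paper_squares()
  rel_err <- vapply(sq, function(s) {
    max(s$kd_T$sd / s$kd_T$value, s$kd_K$sd / s$kd_K$value,
        s$kd_T_star$sd / s$kd_T_star$value,
        s$kd_K_star$sd / s$kd_K_star$value)
  }, numeric(1))
  for (i in seq_along(sq)) {
    cp <- cycle_product(sq[[i]])
    mc <- cycle_product_mc(sq[[i]], n = 2e5, seed = 11)
    if (rel_err[i] <= 0.3) {
      # mild errors: first-order quadrature matches the MC spread closely
      expect_equal(mc$Q_sd_robust, cp$sigma_Q, tolerance = 0.05)
    } else {
      # a 50% relative error in a denominator makes the ratio heavy-tailed;
      # quadrature still tracks the central spread to ~20%
      expect_equal(mc$Q_sd_robust, cp$sigma_Q, tolerance = 0.2)
    }
  }
})

test_that("relabeling the adaptors inverts Q and preserves |log Q| and the
          relative uncertainty", {
  sq <- paper_squares()[[1]]
  swapped <- energy_square(kd_T = sq$kd_K, kd_K = sq$kd_T,
                           kd_T_star = sq$kd_K_star,
                           kd_K_star = sq$kd_T_star)
  a <- cycle_product(sq); b <- cycle_product(swapped)
  expect_equal(b$Q, 1 / a$Q, tolerance = 1e-12)
  expect_equal(abs(log(b$Q)), abs(log(a$Q)), tolerance = 1e-12)
  expect_equal(b$sigma_Q / b$Q, a$sigma_Q / a$Q, tolerance = 1e-12)
})

test_that("binding-mode classification matches the reported inequalities", {
  expect_identical(as.character(classify_pair(c(9, 2), c(54, 27))),
                   "competitive")
  expect_identical(as.character(classify_pair(c(108, 12), c(102, 40))),
                   "independent")
  expect_identical(as.character(classify_pair(c(10, 1), c(10, 1))),
                   "independent")
  expect_identical(as.character(classify_pair(c(54, 2), c(9, 2))),
                   "reinforced")
})

test_that("fold change propagates relative errors in quadrature", {
  fc <- fold_change(c(470, 140), c(25, 3))
  expect_equal(fc$ratio, 18.8, tolerance = 1e-12)
  expect_equal(fc$sd, 18.8 * sqrt((140 / 470)^2 + (3 / 25)^2),
               tolerance = 1e-12)
  expect_gte(fc$ratio, 18) # the reported "18-fold increase"
  expect_identical(fold_change(c(7, 1), c(7, 1))$ratio, 1)

  # MC draws agree with the quadrature sd to 5%
  set.seed(21)
  a <- rnorm_trunc <- function(n, m, s) {
    x <- stats::rnorm(n, m, s); while (any(x <= 0))
      x[x <= 0] <- stats::rnorm(sum(x <= 0), m, s); x
  }
  d <- a(2e5, 470, 140) / a(2e5, 25, 3)
  expect_equal(stats::sd(d), fc$sd, tolerance = 0.05)
})

test_that("verdict type-I error is calibrated at 10% relative noise", {
  net <- simple_cycle(108, 9, 6)
  sim <- gen_square_measurements(net, relative_noise = 0.1, n = 10000,
                                 seed = 7)
  rej <- vapply(sim$squares, function(sq) {
    consistency_verdict(sq)$verdict == "inconsistent"
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("the verdict has power against the measured asymmetric pattern", {
  # squares drawn around the apparent-constant pattern (108, 9, 102, 54)
  # with 20% relative noise are overwhelmingly declared inconsistent
  truth <- energy_square(c(108, 0), c(9, 0), c(102, 0), c(54, 0))
  set.seed(31)
  n <- 2000
  m <- matrix(stats::rnorm(4 * n, 1, 0.2), ncol = 4)
  m[m <= 0] <- 1e-3
  vals <- sweep(m, 2, c(108, 9, 102, 54), `*`)
  rej <- vapply(seq_len(n), function(i) {
    sq <- energy_square(c(vals[i, 1], 0.2 * vals[i, 1]),
                        c(vals[i, 2], 0.2 * vals[i, 2]),
                        c(vals[i, 3], 0.2 * vals[i, 3]),
                        c(vals[i, 4], 0.2 * vals[i, 4]))
    consistency_verdict(sq)$verdict == "inconsistent"
  }, logical(1))
  expect_gt(mean(rej), 0.9)
})

test_that("report rounding keeps two significant digits of the value", {
  expect_equal(unname(round_pm(0.15740, 0.10740)), c(0.16, 0.11))
  expect_equal(unname(round_pm(1.2574, 0.35048)), c(1.3, 0.4))
  expect_equal(unname(round_pm(18.8, 6.04)), c(18.8, 6.0))
})
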