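test_that("network constructors reject invalid inputs", {
  expect_error(simple_cycle(1, 1, 0), "> 0")
  expect_error(simple_cycle(-5, 9, 1), "> 0")
  expect_error(adapter_contact_cycle(108, 9, 1, kd_TK = 0, chi = 1), "> 0")
  expect_error(two_state_tail(0, 1, 1, 1, 1, 1, 1), "> 0")
  expect_error(eq_network(c(T = -1)), ">= 0")
  expect_error(eq_network(c(T = 1),
                          complexes = list(TX = list(comp = c(T = 1, X = 1),
                                                     beta = 1))),
               "undeclared")
  expect_error(eq_network(c(T = 1, I = 1),
                          complexes = list(TI = list(comp = c(T = 1, I = 1),
                                                     beta = -2))),
               "beta")
})

test_that("binary solve matches the closed-form depletion quadratic", {
  for (prm in list(c(kd = 9, t = 9, i = 0.2), c(kd = 0.5, t = 3, i = 2),
                   c(kd = 120, t = 40, i = 15))) {
    net <- eq_network(c(T = prm[["t"]], I = prm[["i"]]),
                      complexes = list(TI = list(comp = c(T = 1, I = 1),
                                                 beta = 1 / prm[["kd"]])))
    st <- solve_equilibrium(net)
    expect_equal(st$bound[["TI"]],
                 oracle_binary_complex(prm[["kd"]], prm[["t"]], prm[["i"]]),
                 tolerance = 1e-9)
  }
  # the spec-level worked example: T=9, I=0.2, Kd=9 -> half the tail bound
  st <- solve_equilibrium(eq_network(
    c(T = 9, I = 0.2),
    complexes = list(TI = list(comp = c(T = 1, I = 1), beta = 1 / 9))))
  expect_equal(st$bound[["TI"]], 0.09944, tolerance = 1e-3)
  expect_equal(st$bound[["TI"]] / 0.2, 0.497, tolerance = 1e-2)
})

test_that("species containing an absent monomer have zero concentration", {
  net <- simple_cycle(108, 9, 6, totals = c(T = 0, K = 50, I = 1))
  st <- solve_equilibrium(net)
  expect_identical(st$bound[["TI"]], 0)
  expect_identical(st$bound[["TIK"]], 0)
  expect_gt(st$bound[["KI"]], 0)
})

test_that("solver agrees with the nested-bisection oracle on ternary nets", {
  cases <- list(
    list(t = 50, k = 20, i = 0.5, kd_t = 108, kd_k = 9, alpha = 1),
    list(t = 300, k = 36, i = 0.1, kd_t = 108, kd_k = 9, alpha = 6),
    list(t = 5, k = 5, i = 5, kd_t = 2, kd_k = 3, alpha = 0.2),
    list(t = 1000, k = 0.5, i = 10, kd_t = 50, kd_k = 0.1, alpha = 10)
  )
  for (cs in cases) {
    b_ti <- 1 / cs$kd_t; b_ki <- 1 / cs$kd_k
    b_tik <- 1 / (cs$kd_t * cs$kd_k * cs$alpha)
    net <- simple_cycle(cs$kd_t, cs$kd_k, cs$alpha,
                        totals = c(T = cs$t, K = cs$k, I = cs$i))
    st <- solve_equilibrium(net)
    orc <- oracle_ternary_free(cs$t, cs$k, cs$i, b_ti, b_ki, b_tik)
    expect_equal(unname(st$free[c("T", "K", "I")]), unname(orc),
                 tolerance = 1e-6)
  }
})

test_that("mass conservation holds to 1e-9 over random networks", {
  set.seed(101)
  worst <- 0
  for (r in 1:1000) {
    st <- solve_equilibrium(random_network())
    worst <- max(worst, st$max_conservation_residual)
    # complexes obey their formation constants exactly
    net <- st$network
    for (j in seq_len(nrow(net$N))) {
      lhs <- st$bound[[j]]
      rhs <- exp(net$log_beta[[j]]) *
        prod(st$free^net$N[j, ])
      expect_lt(abs(lhs - rhs), 1e-8 * max(rhs, 1e-300))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("derived step constants form an exactly consistent square", {
  sq <- derived_step_kds(simple_cycle(108, 9, 6))
  expect_equal(sq$kd_T$value, 108)
  expect_equal(sq$kd_K$value, 9)
  expect_equal(sq$kd_T_star$value, 648)
  expect_equal(sq$kd_K_star$value, 54)
  expect_equal(cycle_product(sq)$Q, 1, tolerance = 1e-12)

  # alpha = 1 forces independence
  sq1 <- derived_step_kds(simple_cycle(108, 9, 1))
  expect_equal(sq1$kd_T_star$value, 108)
  expect_equal(sq1$kd_K_star$value, 9)

  # product is 1 to machine precision for any constructible network
  set.seed(77)
  for (r in 1:200) {
    p <- 10^stats::runif(5, -2, 2)
    net <- adapter_contact_cycle(p[1], p[2], p[3], p[4], p[5])
    expect_equal(cycle_product(derived_step_kds(net))$Q, 1,
                 tolerance = 1e-10)
    net2 <- two_state_tail(p[3], p[1], p[2], p[4], p[5], p[1], p[2],
                           kd_TK = p[4], chi = p[5])
    expect_equal(cycle_product(derived_step_kds(net2, "I_in"))$Q, 1,
                 tolerance = 1e-10)
    expect_equal(cycle_product(derived_step_kds(net2, "I_act"))$Q, 1,
                 tolerance = 1e-10)
  }

  # a network without the ternary complex is rejected
  net_no3 <- eq_network(
    c(T = 0, K = 0, I = 0.1),
    complexes = list(TI = list(comp = c(T = 1, I = 1), beta = 1 / 108),
                     KI = list(comp = c(K = 1, I = 1), beta = 1 / 9)),
    roles = list(T = "T", K = "K", I = "I"))
  expect_error(derived_step_kds(net_no3), "TIK")
})

test_that("removing the direct contact recovers the simple cycle", {
  totals <- c(T = 80, K = 30, I = 2)
  st0 <- solve_equilibrium(simple_cycle(108, 9, 6, totals = totals))
  st1 <- solve_equilibrium(
    adapter_contact_cycle(108, 9, 6, kd_TK = 1e6, chi = 1, totals = totals))
  common <- intersect(names(st0$bound), names(st1$bound))
  expect_equal(st1$free[c("T", "K", "I")], st0$free[c("T", "K", "I")],
               tolerance = 1e-4)
  expect_equal(st1$bound[common], st0$bound[common], tolerance = 1e-4)
})

test_that("a stabilizing contact strictly increases the ternary population", {
  totals <- c(T = 50, K = 20, I = 1)
  b1 <- solve_equilibrium(
    adapter_contact_cycle(108, 9, 6, kd_TK = 100, chi = 1,
                          totals = totals))$bound[["TIK"]]
  b10 <- solve_equilibrium(
    adapter_contact_cycle(108, 9, 6, kd_TK = 100, chi = 10,
                          totals = totals))$bound[["TIK"]]
  expect_gt(b10, b1)
})

test_that("two-state tail limits collapse to single-state behavior", {
  totals <- c(T = 100, K = 40, I = 1)
  make <- function(L) two_state_tail(L, 110, 2, 9, 90, 6, 1, totals = totals)
  tail_bound <- function(st) sum(st$bound[grepl("I", names(st$bound))])

  st_lo <- solve_equilibrium(make(1e-9))
  st_in <- solve_equilibrium(simple_cycle(110, 9, 6, totals = totals))
  expect_equal(st_lo$free[["T"]], st_in$free[["T"]], tolerance = 1e-6)
  expect_equal(st_lo$bound[["TI_in"]], st_in$bound[["TI"]], tolerance = 1e-6)
  expect_equal(st_lo$bound[["TIK_in"]], st_in$bound[["TIK"]],
               tolerance = 1e-6)

  st_hi <- solve_equilibrium(make(1e9))
  st_act <- solve_equilibrium(simple_cycle(2, 90, 1, totals = totals))
  expect_equal(st_hi$free[["T"]], st_act$free[["T"]], tolerance = 1e-6)
  expect_equal(st_hi$bound[["TI_act"]], st_act$bound[["TI"]],
               tolerance = 1e-6)

  # identical constants in both states: output independent of L
  same <- function(L) {
    st <- solve_equilibrium(two_state_tail(L, 50, 50, 7, 7, 3, 3,
                                           totals = totals))
    c(st$free[["T"]], st$free[["K"]], tail_bound(st))
  }
  expect_equal(same(0.01), same(100), tolerance = 1e-8)
})

test_that("occupancy titrations behave like one-site isotherms", {
  net <- eq_network(
    c(T = 0, I = 0.001),
    complexes = list(TI = list(comp = c(T = 1, I = 1), beta = 1 / 9)),
    roles = list(T = "T", K = NA, I = "I"))
  grid <- titration_grid(900, n = 20)
  cv <- occupancy_titration(net, labeled = "I", titrant = "T", grid = grid)
  # midpoint at titrant ~ Kd when the labeled total is trace-level
  expect_equal(fit_one_site(cv)$kd, 9, tolerance = 1e-3)
  mid <- exp(stats::approx(cv$response, log(cv$conc), xout = 0.5)$y)
  expect_equal(mid, 9, tolerance = 0.02)
  # monotone non-decreasing in the titrant
  expect_true(all(diff(cv$response) >= -1e-12))
  # titrating the labeled species itself is refused
  expect_error(occupancy_titration(net, labeled = "I", titrant = "I",
                                   grid = grid), "differ")
})

test_that("apparent Kd is self-consistent and shows the competition shift", {
  net <- eq_network(
    c(T = 0, K = 0, I = 0.1),
    complexes = list(TI = list(comp = c(T = 1, I = 1), beta = 1 / 108),
                     KI = list(comp = c(K = 1, I = 1), beta = 1 / 9)),
    roles = list(T = "T", K = "K", I = "I"))
  # no competitor: the apparent constant is the network constant
  ak0 <- apparent_kd(net, titrant = "T")
  expect_true(ak0$converged)
  expect_equal(ak0$value, 108, tolerance = 0.01)
  # ternary-forbidden network, K fixed at 90 uM: classic competitive shift
  # Kd,app = Kd_T * (1 + [K]_free / Kd_K) with [K]_free ~ 89.93
  ak <- apparent_kd(net, titrant = "T", competitor = "K",
                    competitor_total = 90)
  kfree <- 90 - oracle_binary_complex(9, 90, 0.1)
  expect_equal(ak$value, 108 * (1 + kfree / 9), tolerance = 0.02)

  # with independent coupling (alpha = 1) the competitor has no effect
  net1 <- simple_cycle(108, 9, 1)
  a_no <- apparent_kd(net1, titrant = "T")$value
  a_with <- apparent_kd(net1, titrant = "T", competitor = "K",
                        competitor_total = 100)$value
  expect_equal(a_with, a_no, tolerance = 1e-4)
})

test_that("bound fraction of tail by T is K-independent when alpha = 1", {
  for (ktot in c(0, 1, 10, 100)) {
    net <- simple_cycle(108, 9, 1, totals = c(T = 150, K = ktot, I = 0.1))
    st <- solve_equilibrium(net)
    expect_equal(bound_fraction(st, "I", "T"),
                 oracle_binary_complex(108, 150, 0.1) / 0.1,
                 tolerance = 1e-6)
  }
})
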