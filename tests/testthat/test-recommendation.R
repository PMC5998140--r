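test_that("maximum rates of the non-structural model follow the closed form", {
  p1 <- printed_tnfm_params("Pinghe-low")
  mx <- tnfm_max_rates(p1)
  expect_equal(unname(mx$rates), c(1 / 3.0033e-3 - 163.33,
                                   1 / 3.8371e-3 - 171.25,
                                   1 / 4.3251e-3 - 133.45))
  expect_equal(unname(round(mx$rates)), c(170, 89, 98))
  expect_equal(mx$yield, 6510, tolerance = 10 / 6510)

  flat <- tnfm_params(A = 1e-3, N0 = 100, P0 = 100, K0 = 100,
                      c1 = 0.01, c2 = 0.01, c3 = 0.01)
  expect_equal(unname(tnfm_max_rates(flat)$rates), c(0, 0, 0))

  bad <- tnfm_params(A = 1e-3, N0 = 100, P0 = 100, K0 = 100,
                     c1 = -1e-3, c2 = 0.01, c3 = 0.01)
  expect_error(tnfm_max_rates(bad), "no finite maximum")
})

test_that("closed-form maximum rates agree with a dense grid argmax", {
  p4 <- printed_tnfm_params("Xianyou-low")
  mx <- tnfm_max_rates(p4)
  # coarse pass then local refinement to sub-kg resolution
  g <- seq(0, 300, by = 5)
  grid <- expand.grid(n = g, p = g, k = g)
  best <- grid[which.max(tnfm_predict(p4, grid$n, grid$p, grid$k)), ]
  ref <- expand.grid(n = seq(best$n - 6, best$n + 6, by = 0.25),
                     p = seq(best$p - 6, best$p + 6, by = 0.25),
                     k = seq(best$k - 6, best$k + 6, by = 0.25))
  best2 <- ref[which.max(tnfm_predict(p4, ref$n, ref$p, ref$k)), ]
  expect_true(all(abs(unlist(best2) - mx$rates) <= 1))
})

test_that("the maximum-rate point zeroes the numerical gradient", {
  for (site in printed_tnfm$site) {
    pp <- printed_tnfm_params(site)
    mx <- tnfm_max_rates(pp)
    h <- 1e-3
    num <- vapply(1:3, function(j) {
      e <- numeric(3); e[j] <- h
      x <- mx$rates
      (tnfm_predict(pp, x[1] + e[1], x[2] + e[2], x[3] + e[3]) -
       tnfm_predict(pp, x[1] - e[1], x[2] - e[2], x[3] - e[3])) / (2 * h)
    }, 0)
    expect_lt(max(abs(num)) * 1, 1e-6 * mx$yield)
  }
})

test_that("economic rates solve the marginal-product fixed point", {
  p1 <- printed_tnfm_params("Pinghe-low")
  mx <- tnfm_max_rates(p1)

  # zero nutrient-price limit: economic equals maximum
  free <- price_spec(1e-12, 1e-12, 1e-12, 1)
  e0 <- tnfm_econ_rates(p1, free)
  expect_equal(unname(e0$rates), unname(mx$rates), tolerance = 1e-6)

  pr <- .price_from_ratios(5, 5, 5)
  eco <- tnfm_econ_rates(p1, pr)
  expect_true(eco$converged)
  expect_true(all(eco$rates < mx$rates))
  expect_lt(eco$yield, mx$yield)

  # direct-substitution residual: re-applying the rate equations at the
  # converged economic yield reproduces the rates
  p <- unclass(p1)
  again <- 1 / (p[c("c1", "c2", "c3")] +
                  c(pr$alpha, pr$beta, pr$gamma) / eco$yield) -
    p[c("N0", "P0", "K0")]
  expect_lt(max(abs(unname(again) - unname(eco$rates))), 0.1)
})

test_that("economic iteration converges in few steps at market-like prices", {
  # grain/fertilizer price ratios for rice span roughly 1-3
  for (site in printed_tnfm$site) {
    pp <- printed_tnfm_params(site)
    mx <- tnfm_max_rates(pp)
    ys <- c()
    for (a in c(1, 2, 3)) for (b in c(1, 2, 3)) for (g in c(1, 2, 3)) {
      eco <- tnfm_econ_rates(pp, .price_from_ratios(a, b, g))
      expect_true(eco$converged)
      expect_lte(eco$iterations, 5L)
      expect_true(all(eco$rates <= mx$rates + 1e-9))
    }
  }
})

test_that("the economic-yield sequence is monotone after the first step", {
  pp <- printed_tnfm_params("Xianyou-high")
  p <- unclass(pp)
  ratios <- c(10, 10, 10)  # harshest prices: strongest pull below maximum
  y <- tnfm_max_rates(pp)$yield
  ys <- numeric(8)
  for (it in 1:8) {
    r <- 1 / (p[c("c1", "c2", "c3")] + ratios / y) - p[c("N0", "P0", "K0")]
    y <- tnfm_predict(pp, r[1], r[2], r[3])
    ys[it] <- y
  }
  expect_true(all(diff(ys[-1]) <= 0) || all(diff(ys[-1]) >= 0))
})

test_that("quadratic-model recommendations mirror the published table", {
  dec <- tpfm_params(0, 2, 2, 2, -1, -1, -1, 0, 0, 0)
  expect_equal(unname(tpfm_max_rates(dec)$rates), c(1, 1, 1))

  # published rates require full-precision coefficients: the critical-point
  # solve amplifies rounding in 4-digit printed coefficients, so the
  # comparison runs on the de-novo OLS fit
  b1 <- fitted_builtin("tpfm")[["Pinghe-low"]]$params
  mx <- tpfm_max_rates(b1)
  expect_equal(unname(round(mx$rates)), c(174, 87, 102))
  expect_equal(mx$yield, 6562, tolerance = 10 / 6562)

  # indefinite curvature: no maximum, failed minor named
  b2 <- printed_tpfm_params("Pinghe-medium")
  expect_error(tpfm_max_rates(b2), "G3")
})

test_that("quadratic economic rates equate marginal products to price ratios", {
  b1 <- printed_tpfm_params("Pinghe-low")
  pr <- .price_from_ratios(2, 2.5, 2)
  eco <- tpfm_econ_rates(b1, pr)
  g <- tpfm_gradient(b1, eco$rates[1], eco$rates[2], eco$rates[3])
  expect_equal(g, c(2, 2.5, 2), tolerance = 1e-8)

  e0 <- tpfm_econ_rates(b1, price_spec(1e-12, 1e-12, 1e-12, 1))
  expect_equal(unname(e0$rates), unname(tpfm_max_rates(b1)$rates),
               tolerance = 1e-6)

  # economic never exceeds maximum yield on negative-definite surfaces
  set.seed(31)
  n_checked <- 0
  while (n_checked < 25) {
    b <- rand_tpfm()
    G <- tpfm_hessian_minors(b)
    if (!(G[1] < 0 && G[2] > 0 && G[3] < 0)) next
    n_checked <- n_checked + 1
    mx <- tpfm_max_rates(b)
    eco <- tpfm_econ_rates(b, .price_from_ratios(stats::runif(1, 0.5, 5),
                                                 stats::runif(1, 0.5, 5),
                                                 stats::runif(1, 0.5, 5)))
    expect_lte(eco$yield, mx$yield + 1e-9)
  }
})

test_that("recommend() assembles maximum and economic blocks", {
  fit <- fitted_builtin("tnfm")[["Pinghe-low"]]
  rec <- recommend(fit)
  expect_s3_class(rec, "recommendation")
  expect_null(rec$eco_rates)
  rec2 <- recommend(fit, prices = price_spec(4.3, 5.0, 5.2, 2.8))
  expect_true(all(rec2$eco_rates <= rec2$max_rates))
  expect_lte(rec2$iterations_used, 5L)
})
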