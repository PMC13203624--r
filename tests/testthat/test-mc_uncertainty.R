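# asymptotic standard error of the empirical q-quantile of the reduction
# distribution: reduction = 100 * (1 - r0 * exp(s * Z)), so the density at
# the q-quantile follows from the normal density by the delta method
quantile_se <- function(q, n, ratio, s) {
  z <- qnorm(1 - q)  # upper reduction quantiles come from lower ratio tails
  slope <- 100 * ratio * s * exp(s * z)
  sqrt(q * (1 - q) / n) * slope / dnorm(z)
}

test_that("sample_pair degenerates correctly and honours the copula", {
  # gsd = 1: no uncertainty
  d <- sample_pair(100, 90, gsd = 1, rho = 0.85, n_iter = 50, seed = 1)
  expect_equal(d$con, rep(100, 50))
  expect_equal(d$dfm, rep(90, 50))
  # rho = 1 with equal GSDs: the ratio is exactly constant
  d <- sample_pair(100, 90, gsd = 1.3, rho = 1, n_iter = 200, seed = 2)
  expect_equal(d$con / d$dfm, rep(100 / 90, 200))
  # sample log-scale correlation close to the requested rho
  d <- sample_pair(6127.30, 5360.84, gsd = 1.20, rho = 0.85,
                   n_iter = 10000, seed = 3)
  expect_equal(cor(log(d$con), log(d$dfm)), 0.85, tolerance = 0.02)
  # medians sit at the deterministic values (median parameterization)
  expect_equal(median(d$con), 6127.30, tolerance = 0.01 * 6127.30)
  expect_error(sample_pair(1, 1, gsd = 0.9, rho = 0, n_iter = 10, seed = 1),
               "gsd")
})

test_that("mc_summary handles degenerate and null cases", {
  cfg <- mc_config(n_iter = 2000, seed = 5)
  s <- mc_summary(100, 90, gsd = 1, config = cfg)
  expect_equal(c(s$p5, s$p50, s$p95), rep(10, 3))
  expect_equal(s$prob_dfm_lower, 1)
  # identical pair: the reduction distribution is centred at zero
  s <- mc_summary(50, 50, gsd = 1.2, config = mc_config(n_iter = 20000, seed = 6))
  expect_equal(s$p50, 0, tolerance = 0.5)
  expect_equal(s$prob_dfm_lower, 0.5, tolerance = 0.02)
  expect_true(s$p5 <= s$p50 && s$p50 <= s$p95)
})

test_that("analytic summary matches independently computed closed-form values", {
  # frozen with an external normal-CDF computation
  s <- analytic_summary(6127.30, 5360.84, gsd = 1.20, rho = 0.85)
  expect_equal(s$p5, -3.109799, tolerance = 1e-6)
  expect_equal(s$p50, 12.508935, tolerance = 1e-6)
  expect_equal(s$p95, 25.761795, tolerance = 1e-6)
  expect_equal(s$prob_dfm_lower, 0.909582, tolerance = 1e-6)
  s <- analytic_summary(1.77, 1.66, gsd = 1.25, rho = 0.85)
  expect_equal(s$p95, 23.294533, tolerance = 1e-6)
  expect_equal(s$prob_dfm_lower, 0.700197, tolerance = 1e-6)
  # rho = 1 (equal GSDs): spread collapses to the deterministic value
  s <- analytic_summary(100, 90, gsd = 1.3, rho = 1)
  expect_equal(unname(s$quantiles), rep(10, 3))
  expect_equal(s$prob_dfm_lower, 1)
  # the median is always the deterministic reduction
  set.seed(8)
  for (i in 1:20) {
    con <- runif(1, 1, 100); dfm <- runif(1, 1, 100)
    s <- analytic_summary(con, dfm, gsd = runif(1, 1.01, 1.4),
                          rho = runif(1, 0, 0.95))
    expect_equal(s$p50, percent_reduction(con, dfm))
    # complementary probability under pair swap (up to the sign flip of mu)
    s_rev <- analytic_summary(dfm, con, gsd = 1.2, rho = 0.5)
    s_fwd <- analytic_summary(con, dfm, gsd = 1.2, rho = 0.5)
    expect_equal(s_fwd$prob_dfm_lower + s_rev$prob_dfm_lower, 1)
  }
})

test_that("Monte Carlo percentiles agree with the analytic oracle", {
  set.seed(9)
  for (i in 1:10) {
    con <- runif(1, 1, 1000)
    dfm <- con * runif(1, 0.7, 1.2)
    gsd <- runif(1, 1.05, 1.5)
    rho <- runif(1, 0, 0.95)
    n <- 10000
    mc <- mc_summary(con, dfm, gsd, mc_config(n_iter = n, rho = rho, seed = i))
    an <- analytic_summary(con, dfm, gsd, rho)
    s <- sqrt(2 * (1 - rho)) * log(gsd)
    for (q in c(0.05, 0.5, 0.95)) {
      nm <- sprintf("p%g", 100 * q)
      se <- quantile_se(q, n, dfm / con, s)
      expect_lt(abs(mc$quantiles[[nm]] - an$quantiles[[nm]]), 3 * se)
    }
    p <- an$prob_dfm_lower
    se_p <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mc$prob_dfm_lower - p), 3 * se_p + 1e-12)
  }
})

test_that("probability is monotone in GSD and in rho", {
  gsds <- c(1.05, 1.1, 1.2, 1.3, 1.5)
  probs <- sapply(gsds, function(g) {
    analytic_summary(100, 88, g, rho = 0.5)$prob_dfm_lower
  })
  expect_true(all(diff(probs) <= 0))   # more uncertainty, less confidence
  rhos <- c(0, 0.25, 0.5, 0.75, 0.95)
  probs <- sapply(rhos, function(r) {
    analytic_summary(100, 88, 1.2, rho = r)$prob_dfm_lower
  })
  expect_true(all(diff(probs) >= 0))   # shared errors cancel in the ratio
})

test_that("run_mc is reproducible with stable per-record substreams", {
  tab <- pig_lcia_table()
  cfg <- mc_config(n_iter = 500, seed = 42)
  out1 <- run_mc(tab, config = cfg)
  out2 <- run_mc(tab, config = cfg)
  expect_equal(nrow(out1), 30L)
  expect_identical(out1, out2)
  expect_true(all(out1$p5 <= out1$p50 & out1$p50 <= out1$p95))
  # dropping a record leaves the other records' draws untouched
  sub <- impact_table(as.data.frame(tab)[-1, ])
  out_sub <- run_mc(sub, config = cfg)
  merged <- merge(out1, out_sub, by = c("category", "scenario"))
  expect_equal(merged$p50.x, merged$p50.y)
  # missing GSD entry is a configuration error naming the category
  expect_error(run_mc(tab, gsd_map = c(climate_change = 1.1), config = cfg),
               "climate_change_land_use", class = "herdfit_config_error")
})
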