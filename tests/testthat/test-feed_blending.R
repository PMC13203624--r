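test_that("blend_fraction follows the linear ramp and its bounds", {
  expect_equal(blend_fraction(1, 30), 0)          # day 1: all feed 1
  expect_equal(blend_fraction(3, 4), 50)          # (100/4) * 2
  for (d in c(2L, 7L, 30L)) {
    expect_equal(blend_fraction(d, d), 100 - 100 / d)  # ramp end
    pd <- blend_fraction(seq_len(d), d)
    expect_true(all(diff(pd) > 0))                # monotone
    expect_equal(unique(round(diff(pd), 10)), 100 / d) # affine, slope 100/d
    expect_true(all(pd >= 0 & pd < 100))
  }
  expect_error(blend_fraction(0, 5), "day_in_phase")
  expect_error(blend_fraction(6, 5), "day_in_phase")
})

test_that("daily_blend conserves intake and prices the blend per kg", {
  ph <- list(duration_days = 5L, daily_intake = 2.5,
             feed1_price = 0.40, feed2_price = 0.30)
  day3 <- daily_blend(ph, 3)                      # PD = 40
  expect_equal(day3$feed2_pct, 40)
  expect_equal(day3$feed1_kg, 1.5)
  expect_equal(day3$feed2_kg, 1.0)
  # CTC at 70/30 split of 0.40/0.30 prices is 0.37 per kg
  ph10 <- list(duration_days = 10L, daily_intake = 1,
               feed1_price = 0.40, feed2_price = 0.30)
  expect_equal(daily_blend(ph10, 4)$day_cost, 0.37)
  # equal prices: cost independent of the blend
  php <- list(duration_days = 7L, daily_intake = 2, feed1_price = 0.5,
              feed2_price = 0.5)
  costs <- daily_blend(php, 1:7)$day_cost
  expect_equal(costs, rep(0.5 * 2, 7))
})

test_that("cost models match hand-enumerated cases", {
  one <- phase_plan(data.frame(duration_days = 30, daily_intake = 2.0,
                               feed1_id = "a", feed1_price = 0.5))
  expect_equal(con_total_cost(one), 30.0)
  expect_equal(con_total_cost(phase_plan(rbind(one, one))), 60.0)

  # 2-day ramp, intake 1, FP1 = 1, FP2 = 0: day 1 costs 1, day 2 costs 0.5
  ramp <- phase_plan(data.frame(duration_days = 2, daily_intake = 1,
                                feed1_id = "a", feed1_price = 1,
                                feed2_id = "b", feed2_price = 0))
  expect_equal(dfm_total_cost(ramp)$total_cost, 1.5)

  # single 1-day phase: all feed 1
  single <- phase_plan(data.frame(duration_days = 1, daily_intake = 2.2,
                                  feed1_id = "a", feed1_price = 0.3))
  expect_equal(dfm_total_cost(single)$total_cost, 0.3 * 2.2)

  # missing feed-2 price on a multi-day phase is a configuration error
  bad <- phase_plan(data.frame(duration_days = 3, daily_intake = 1,
                               feed1_id = "a", feed1_price = 0.3))
  expect_error(dfm_total_cost(bad), class = "herdfit_config_error")
})

test_that("randomized plans conserve mass and bound the daily-blend cost", {
  for (seed in 1:25) {
    plan <- generate_phase_plan(n_phases = sample(4:6, 1), seed = seed)
    sched <- blend_schedule(plan)
    expect_equal(sched$feed1_pct + sched$feed2_pct, rep(100, nrow(sched)))
    expect_equal(sched$feed1_kg + sched$feed2_kg,
                 rep(plan$daily_intake, plan$duration_days))
    cda <- dfm_total_cost(plan)$total_cost
    lo <- sum(plan$duration_days * pmin(plan$feed1_price, plan$feed2_price) *
                plan$daily_intake)
    hi <- sum(plan$duration_days * pmax(plan$feed1_price, plan$feed2_price) *
                plan$daily_intake)
    expect_gte(cda, lo - 1e-9)
    expect_lte(cda, hi + 1e-9)
    # equal prices: blending cannot change the cost
    eq <- plan
    eq$feed2_price <- eq$feed1_price
    expect_equal(dfm_total_cost(eq)$total_cost, con_total_cost(eq))
  }
})

test_that("quantity bookkeeping: blending redistributes but conserves intake", {
  plan <- two_phase_plan()
  qr <- quantity_ratio(plan, plan)
  expect_equal(qr$total_kg_dfm, qr$total_kg_con)
  expect_equal(qr$total_kg_con, sum(plan$duration_days * plan$daily_intake))
  # within a phase the ramp moves mass monotonically from feed 1 to feed 2
  sched <- blend_schedule(plan)
  ph1 <- sched[sched$phase == 1, ]
  expect_true(all(diff(ph1$feed2_kg) > 0))
  expect_true(all(diff(ph1$feed1_kg) < 0))
  expect_error(quantity_ratio(plan, plan[1, ]), "phase counts")
  expect_error(phase_plan(data.frame()), "at least one phase")
})
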