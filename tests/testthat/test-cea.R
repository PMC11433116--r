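# bare outcome objects for direct comparisons
outcome <- function(strategy, cost, qaly) {
  structure(list(strategy = strategy, total_cost = cost, total_qaly = qaly,
                 undiscounted_ly = NA_real_, per_state_cost = numeric()),
            class = "cea_outcome")
}

test_that("incremental comparison arithmetic and dominance classes", {
  r <- compare_strategies(outcome("X", 2e6 + 1553049, 2.5 + 0.110733),
                          outcome("Y", 2e6, 2.5), wtp = 7.5e6)
  expect_equal(r$icer, 14025268, tolerance = 1e-4)
  expect_identical(r$dominance, "tradeoff-NE")
  expect_false(r$cost_effective)

  same <- compare_strategies(outcome("X", 1e6, 2), outcome("Y", 1e6, 2))
  expect_identical(same$delta_cost, 0)
  expect_identical(same$delta_qaly, 0)
  expect_true(is.na(same$icer))
  expect_identical(same$nmb_at_wtp, 0)

  dom <- compare_strategies(outcome("X", 1e6 - 100, 2.1), outcome("Y", 1e6, 2))
  expect_identical(dom$dominance, "dominant")
  expect_true(dom$cost_effective)
  expect_identical(
    compare_strategies(outcome("X", 1e6 + 100, 1.9),
                       outcome("Y", 1e6, 2))$dominance, "dominated")
})

test_that("fee-shift identity holds to machine precision", {
  br <- run_base_case("rare")
  bn <- run_base_case("non_rare")
  expect_equal(br$result$delta_qaly, bn$result$delta_qaly, tolerance = 1e-12)
  expect_equal(br$result$delta_cost - bn$result$delta_cost, 775000,
               tolerance = 1e-9)
  expect_equal(br$result$icer - bn$result$icer,
               775000 / br$result$delta_qaly, tolerance = 1e-10)
})

test_that("ICER is invariant to a constant cost added to both arms", {
  m <- packaged_model("rare")
  b0 <- run_base_case("rare", model = m)
  m$strategies$PBT$upfront_cost <- m$strategies$PBT$upfront_cost + 123456
  m$strategies$`3DCRT`$upfront_cost <- m$strategies$`3DCRT`$upfront_cost + 123456
  b1 <- run_base_case("rare", model = m)
  expect_equal(b1$result$icer, b0$result$icer, tolerance = 1e-12)
})

test_that("base-case verdicts follow the threshold rule", {
  br <- run_base_case("rare")
  bn <- run_base_case("non_rare")
  expect_gt(br$result$icer, 7.5e6)
  expect_false(br$result$cost_effective)
  expect_lt(bn$result$icer, 7.5e6)
  expect_true(bn$result$cost_effective)

  tab <- as_cea_table(br)
  expect_identical(tab$strategy, c("PBT", "3DCRT"))
  expect_true(all(tab$cost_yen == round(tab$cost_yen)))
})

test_that("convention sweep covers the grid and responds to conventions", {
  sw <- convention_sweep("rare", drainage_utilities = c(0.63, 0.87))
  expect_identical(nrow(sw), 3L * 2L * 2L * 2L)
  expect_true(all(is.finite(sw$icer)))
  # half-cycle correction lies between start- and end-weighted accrual
  pick <- function(tm) sw$qaly_pbt[sw$reward_timing == tm &
                                   sw$discount_timing == "end" &
                                   sw$drainage_utility == 0.63 &
                                   sw$rp_cost_stacking]
  expect_true(pick("end") < pick("half") && pick("half") < pick("start"))
})
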