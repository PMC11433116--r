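test_that("degenerate dynamics propagate exactly", {
  # all transitions off: cohort stays put (validation skipped deliberately,
  # death is unreachable by construction)
  m0 <- two_state_model(hazard = 0)
  tr <- run_cohort(m0, "A", validate = FALSE)
  expect_true(all(tr$occupancy[, "start"] == 1))
  expect_true(all(tr$inflow == 0))

  # hazard 1: whole cohort in terminal care after cycle 1, dead from cycle 2
  m1 <- two_state_model(hazard = 1)
  tr <- run_cohort(m1, "A")
  expect_identical(tr$occupancy["1", "terminal_care"], 1)
  expect_true(all(tr$occupancy[as.character(2:20), "death"] == 1))

  # absorbing rows are identity rows
  M <- build_matrix(packaged_model("rare"), "PBT", 13)
  expect_identical(M["death", "death"], 1)
  expect_identical(sum(M["death", ]), 1)
})

test_that("windows close: event-free row after year 2 has only the hazard", {
  M <- build_matrix(packaged_model("rare"), "PBT", 9)
  expect_equal(M["no_late_ae", "no_late_ae"], 0.9458, tolerance = 1e-12)
  expect_identical(M["no_late_ae", "bsc"], 0.0542)
  expect_identical(sum(M["no_late_ae", ] > 0), 2L)
})

test_that("over-specified rows fail naming the state and cycle", {
  m <- two_state_model(hazard = 0.7)
  m$rules <- rbind(m$rules, transition_rule("A", "start", "death", 0.5))
  expect_error(build_matrix(m, "A", 3), "start.*cycle 3")
})

test_that("undiscounted utility accrual matches hand values", {
  # utility 1 everywhere alive, no hazard, no discounting: 20 x 0.25 = 5 QALY
  for (timing in c("start", "end", "half")) {
    st <- model_settings(annual_discount_rate = 0, reward_timing = timing)
    m <- two_state_model(u_start = 1, hazard = 0, settings = st)
    out <- accumulate(m, run_cohort(m, "A", validate = FALSE))
    expect_equal(out$total_qaly, 5, tolerance = 1e-12)
    expect_equal(out$undiscounted_ly, 5, tolerance = 1e-12)
  }
  # single occupied state at utility 0.91: 0.91 * 5 = 4.55
  st <- model_settings(annual_discount_rate = 0)
  m <- two_state_model(u_start = 0.91, hazard = 0, settings = st)
  out <- accumulate(m, run_cohort(m, "A", validate = FALSE))
  expect_equal(out$total_qaly, 4.55, tolerance = 1e-12)
})

test_that("two-state cohort QALY matches the geometric closed form to 1e-10", {
  for (seed in 1:100) {
    m <- random_model(seed, n_ae_states = 0)
    h <- m$rules$probability[m$rules$from == "start"]
    u <- m$states$start$utility
    out <- run_strategy(m, "A")
    expect_equal(out$total_qaly, two_state_qaly(u, h, m$settings),
                 tolerance = 1e-10)
  }
  # and under the other accrual conventions
  for (timing in c("end", "half")) {
    m <- random_model(7, n_ae_states = 0)
    m$settings$reward_timing <- timing
    h <- m$rules$probability[m$rules$from == "start"]
    out <- run_strategy(m, "A")
    expect_equal(out$total_qaly,
                 two_state_qaly(m$states$start$utility, h, m$settings),
                 tolerance = 1e-10)
  }
})

test_that("occupancy is conserved and death is monotone", {
  models <- c(list(packaged_model("rare")),
              lapply(1:8, random_model))
  for (m in models) {
    for (arm in strategy_ids(m)) {
      tr <- run_cohort(m, arm)
      expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-10)
      expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-15))
      expect_true(all(tr$occupancy >= -1e-15))
    }
  }
})

test_that("raising the discount rate lowers discounted totals", {
  p <- laec_parameters()
  m_lo <- build_laec_model(p, "rare",
                           settings = model_settings(annual_discount_rate = 0.03))
  m_hi <- build_laec_model(p, "rare",
                           settings = model_settings(annual_discount_rate = 0.07))
  for (arm in c("PBT", "3DCRT")) {
    o_lo <- run_strategy(m_lo, arm)
    o_hi <- run_strategy(m_hi, arm)
    expect_lt(o_hi$total_qaly, o_lo$total_qaly)
    up <- m_lo$strategies[[arm]]$upfront_cost
    expect_lt(o_hi$total_cost - up, o_lo$total_cost - up)
  }
})

test_that("equalising the arms' probabilities isolates the fee difference", {
  m <- build_laec_model(equalised_params(), "rare")
  a <- run_strategy(m, "PBT")
  b <- run_strategy(m, "3DCRT")
  expect_equal(a$total_qaly, b$total_qaly, tolerance = 1e-12)
  expect_equal(a$total_cost - b$total_cost,
               m$strategies$PBT$upfront_cost - m$strategies$`3DCRT`$upfront_cost,
               tolerance = 1e-9)
})

test_that("cumulative Grade 3 incidence under 3D-CRT matches the trial rates", {
  tr <- run_cohort(packaged_model("rare"), "3DCRT")
  first_entry <- colSums(tr$inflow)
  expect_equal(first_entry[["rp_g3"]], 0.04, tolerance = 0.02 / 0.04)
  expect_equal(first_entry[["pe_g3"]], 0.09, tolerance = 0.02 / 0.09)
  expect_equal(first_entry[["pce_g3"]] + first_entry[["pce_g3_pe_g2"]],
               0.16, tolerance = 0.02 / 0.16)
})

test_that("trace table decomposes the accumulated totals", {
  m <- packaged_model("non_rare")
  tr <- run_cohort(m, "PBT")
  out <- accumulate(m, tr)
  tt <- trace_table(m, tr)
  expect_equal(sum(tt$discounted_qaly), out$total_qaly, tolerance = 1e-10)
  expect_equal(sum(tt$discounted_cost),
               out$total_cost - m$strategies$PBT$upfront_cost,
               tolerance = 1e-9)
})

test_that("outcome invariants hold on the packaged models", {
  for (fee in c("rare", "non_rare")) {
    m <- packaged_model(fee)
    for (arm in strategy_ids(m)) {
      o <- run_strategy(m, arm)
      expect_lte(o$total_qaly, o$undiscounted_ly)
      expect_lte(o$undiscounted_ly, 5)
      expect_gte(o$total_cost, m$strategies[[arm]]$upfront_cost)
    }
  }
})
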