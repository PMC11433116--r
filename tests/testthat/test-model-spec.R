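test_that("packaged models validate cleanly and encode the fee structure", {
  mr <- packaged_model("rare")
  mn <- packaged_model("non_rare")
  expect_identical(nrow(validate_model(mr)), 0L)
  expect_identical(nrow(validate_model(mn)), 0L)

  expect_identical(mr$strategies$PBT$upfront_cost, 2375000 + 1325370)
  expect_identical(mr$strategies$`3DCRT`$upfront_cost, 727600 + 1325370)
  expect_identical(mn$strategies$PBT$upfront_cost - mr$strategies$PBT$upfront_cost,
                   -775000)

  # the two fee levels differ in exactly one number: the PBT upfront cost
  expect_identical(mr$states, mn$states)
  expect_identical(mr$rules, mn$rules)
  expect_identical(mr$settings, mn$settings)
  expect_identical(mr$strategies$`3DCRT`, mn$strategies$`3DCRT`)

  expect_error(packaged_model("cheap"), "arg")
})

test_that("arm-specific transition probabilities match the parameter table", {
  m <- packaged_model("rare")
  M_crt <- build_matrix(m, "3DCRT", 1)
  M_pbt <- build_matrix(m, "PBT", 1)
  expect_identical(M_crt["no_late_ae", "pe_g3"], 0.06)
  expect_identical(M_pbt["no_late_ae", "pe_g3"], 0)
  expect_identical(M_crt["no_late_ae", "pce_g3"], 0.075)
  expect_identical(M_pbt["no_late_ae", "pce_g3"], 0.001)
  expect_identical(M_crt["no_late_ae", "bsc"], 0.0542)
})

test_that("event-free outgoing mass in cycle 1 reproduces the table column", {
  # eleven onset probabilities + the BSC hazard sum to 0.6782 for 3D-CRT,
  # leaving a stay probability of 0.3218
  M <- build_matrix(packaged_model("rare"), "3DCRT", 1)
  expect_equal(M["no_late_ae", "no_late_ae"], 0.3218, tolerance = 1e-12)
  expect_equal(sum(M["no_late_ae", ]) - M["no_late_ae", "no_late_ae"],
               0.6782, tolerance = 1e-12)
})

test_that("row sums are exactly 1 for every strategy and cycle", {
  for (fee in c("rare", "non_rare")) {
    m <- packaged_model(fee)
    for (arm in strategy_ids(m))
      for (cyc in seq_len(m$settings$horizon_cycles)) {
        M <- build_matrix(m, arm, cyc)
        expect_lt(max(abs(rowSums(M) - 1)), 1e-12)
      }
  }
})

test_that("constructed invariant violations are reported as data", {
  m <- packaged_model("rare")

  # outgoing mass above 1
  m_bad <- m
  m_bad$rules <- rbind(m_bad$rules,
                       transition_rule("shared", "rp_g1", "rp_g2", 0.99))
  v <- validate_model(m_bad)
  expect_true(any(grepl("row sum", v$message) & v$entity == "rp_g1"))

  # utility ordering violated within the RP family
  m_bad <- m
  m_bad$states$rp_g1$utility <- 0.80  # below RP G2's 0.83
  v <- validate_model(m_bad)
  expect_true(any(grepl("utility ordering", v$message) & v$entity == "rp"))

  # utility outside [0, 1] and negative cost
  m_bad <- m
  m_bad$states$pe_g1$utility <- 1.2
  m_bad$states$pe_g3$entry_cost <- -5
  v <- validate_model(m_bad)
  expect_true(any(grepl("utility", v$message) & v$entity == "pe_g1"))
  expect_true(any(grepl("cost", v$message) & v$entity == "pe_g3"))

  # no death state
  m_bad <- m
  m_bad$states <- m_bad$states[setdiff(state_ids(m), "death")]
  v <- validate_model(m_bad)
  expect_true(any(v$entity == "death"))

  # dangling residual target
  m_bad <- m
  m_bad$states$drainage$residual_target <- "nowhere"
  v <- validate_model(m_bad)
  expect_true(any(grepl("residual target", v$message)))

  # death unreachable
  m_iso <- two_state_model(hazard = 0)
  v <- validate_model(m_iso)
  expect_true(any(grepl("unreachable", v$message)))
})
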