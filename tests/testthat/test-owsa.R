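test_that("the tornado registry expands arm-specific cells and excludes fees", {
  entries <- owsa_parameters()
  expect_true("p_noae_to_pce_g3__3dcrt" %in% entries$entry_id)
  expect_true("p_noae_to_pce_g3__pbt" %in% entries$entry_id)
  expect_identical(entries$arm[entries$entry_id == "p_any_to_bsc"], "both")
  expect_identical(entries$arm[entries$entry_id == "u_no_late_ae"], "both")
  expect_false("c_3dcrt_fee" %in% entries$entry_id)
  expect_false(any(grepl("pbt_fee", entries$entry_id)))
})

test_that("one-way analysis: clamping, zero bases and cost neutrality", {
  ow <- run_owsa("rare")
  df <- as.data.frame(ow)

  # sorted by decreasing range, ties broken lexicographically
  expect_true(all(diff(df$icer_range) <= 1e-9))

  # zero-base parameter: both perturbed values are 0 and the range is 0
  z <- df[df$entry_id == "p_noae_to_pe_g3__pbt", ]
  expect_identical(z$low_value, 0)
  expect_identical(z$high_value, 0)
  expect_equal(z$icer_range, 0, tolerance = 1e-9)

  # utility perturbations above 1 are clamped and flagged
  u <- df[df$entry_id == "u_no_late_ae", ]
  expect_identical(u$high_value, 1)
  expect_true(u$clamped)
  # the BSC->death certainty clamps on the high side as well
  bd <- df[df$entry_id == "p_bsc_to_death", ]
  expect_identical(bd$high_value, 1)
  expect_identical(bd$low_value, 0.8)
  expect_true(bd$clamped)

  # perturbing any cost leaves incremental effectiveness untouched
  costs <- df[df$kind == "cost", ]
  base_de <- run_base_case("rare")$result$delta_qaly
  expect_equal(costs$delta_qaly_low, rep(base_de, nrow(costs)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(costs$delta_qaly_high, rep(base_de, nrow(costs)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the most sensitive parameter is the event-free utility", {
  for (fee in c("rare", "non_rare")) {
    ow <- run_owsa(fee)
    expect_identical(ow$entry_id[1], "u_no_late_ae")
  }
})

test_that("the most sensitive cost is the pericardial drainage fee", {
  ow <- run_owsa("rare")
  df <- as.data.frame(ow)
  expect_identical(df$entry_id[df$kind == "cost"][1], "c_drainage")
})
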