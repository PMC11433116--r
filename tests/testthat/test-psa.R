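test_that("triangular sampler: support, mean and degenerate case", {
  set.seed(11)
  x <- rtriangular(10000, 0.8, 1, 1.2)
  expect_true(all(x >= 0.8 & x <= 1.2))
  tri_sd <- sqrt((0.8^2 + 1 + 1.2^2 - 0.8 - 0.96 - 1.2) / 18)
  expect_lt(abs(mean(x) - 1), 3 * tri_sd / sqrt(10000))
  expect_identical(rtriangular(5, 2, 2, 2), rep(2, 5))
  expect_error(rtriangular(1, 1, 0.5, 2))
})

test_that("sampled parameter sets respect support, certainties and ordering", {
  base <- laec_parameters()
  for (k in 1:40) {
    set.seed(k)
    s <- sample_parameters(base)$params
    for (col in c("pbt", "x3dcrt")) {
      b <- base[[col]]
      v <- s[[col]]
      fixed <- !base$perturbable |
        (base$kind == "probability" & (b <= 0 | b >= 1))
      expect_identical(v[fixed], b[fixed])
      hi <- ifelse(base$kind == "cost", 1.2 * b, pmin(1.2 * b, 1))
      expect_true(all(v[!fixed] >= 0.8 * b[!fixed] - 1e-12 &
                      v[!fixed] <= hi[!fixed] + 1e-12))
    }
    # zero and one cells never move
    expect_identical(s$pbt[s$param_id == "p_noae_to_pe_g3"], 0)
    expect_identical(s$x3dcrt[s$param_id == "p_bsc_to_death"], 1)
    # grade ordering within each family
    for (fam in c("rp", "pe", "pce")) {
      i <- which(base$family %in% fam)
      expect_false(is.unsorted(rev(s$x3dcrt[i][order(base$grade[i])])))
    }
    # utilities and costs shared across arms
    shared_rows <- base$kind != "probability"
    expect_identical(s$pbt[shared_rows], s$x3dcrt[shared_rows])
  }
})

test_that("sampled draws build models that validate cleanly", {
  for (k in 1:15) {
    set.seed(100 + k)
    m <- sample_draw(fee_level = "rare")
    expect_identical(nrow(validate_model(m)), 0L)
  }
})

test_that("draws are reproducible and prefix-stable in the number of draws", {
  p1 <- run_psa("rare", n_draws = 8, seed = 99)
  p2 <- run_psa("rare", n_draws = 8, seed = 99)
  expect_identical(p1$draws, p2$draws)

  p3 <- run_psa("rare", n_draws = 16, seed = 99)
  expect_identical(p3$draws[1:8, ], p1$draws)
})

test_that("zero sampling width reproduces the base case in every draw", {
  base_icer <- run_base_case("rare")$result$icer
  p <- run_psa("rare", n_draws = 3, seed = 5, rel_width = 0)
  expect_equal(p$draws$icer, rep(base_icer, 3), tolerance = 1e-12)
})

test_that("empirical mean of an unconstrained scalar matches the mode", {
  base <- laec_parameters()
  set.seed(2024)
  b <- base$x3dcrt[base$param_id == "c_drainage"]
  draws <- replicate(800, {
    sample_parameters(base)$params$x3dcrt[base$param_id == "c_drainage"]
  })
  tri_sd <- b * 0.2 / sqrt(6)
  expect_lt(abs(mean(draws) - b), 3 * tri_sd / sqrt(length(draws)))
})

test_that("acceptability curve: limits, monotonicity and fee dominance", {
  # with one shared draw per parameter the PBT arm gains QALYs in every draw,
  # so the curve is the ICER rule and must be non-decreasing
  ps <- run_psa("rare", n_draws = 150, seed = 3, shared_probabilities = TRUE)
  expect_true(all(ps$draws$delta_qaly > 0))
  expect_true(all(diff(ps$ceac$probability) >= 0))
  expect_identical(ceac(ps, 0)$probability, mean(ps$draws$delta_cost < 0))
  expect_identical(ceac(ps, 1e12)$probability, mean(ps$draws$delta_qaly > 0))

  # same seed, lower fee: identical effectiveness draws, costs shifted by
  # exactly the fee difference, so the non-rare curve dominates everywhere
  pr <- run_psa("rare", n_draws = 120, seed = 17)
  pn <- run_psa("non_rare", n_draws = 120, seed = 17)
  expect_identical(pr$draws$delta_qaly, pn$draws$delta_qaly)
  expect_equal(pr$draws$delta_cost - pn$draws$delta_cost, rep(775000, 120),
               tolerance = 1e-9)
  expect_true(all(pn$ceac$probability >= pr$ceac$probability))

  expect_error(run_psa("rare", n_draws = 0), "n_draws")
})
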