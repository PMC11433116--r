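test_that("random models are valid, reproducible and structurally complete", {
  for (seed in 1:100) {
    m <- random_model(seed, n_ae_states = (seed %% 7))
    expect_identical(nrow(validate_model(m)), 0L)
  }
  expect_equal(random_model(13), random_model(13), tolerance = 0)

  m0 <- random_model(4, n_ae_states = 0)
  expect_identical(sort(state_ids(m0)), c("death", "start", "terminal_care"))

  m <- random_model(5, n_ae_states = 6)
  expect_identical(length(m$strategies), 2L)
  expect_false(m$strategies$A$upfront_cost == m$strategies$B$upfront_cost)
  # arm-specific onsets differ
  on_a <- m$rules[m$rules$strategy == "A" & m$rules$from == "start", ]
  on_b <- m$rules[m$rules$strategy == "B" & m$rules$from == "start", ]
  expect_false(all(on_a$probability == on_b$probability))
})

test_that("zero-width perturbation is the identity", {
  m <- random_model(21)
  m2 <- perturb_model(m, relative_width = 0, seed = 9)
  attr(m2, "perturb_flags") <- NULL
  expect_equal(m2, m, tolerance = 0)
})

test_that("perturbed models stay valid and within the stated support", {
  for (seed in c(2, 8, 31)) {
    m <- random_model(seed)
    m2 <- perturb_model(m, relative_width = 0.2, seed = seed + 1)
    expect_identical(nrow(validate_model(m2)), 0L)
    for (id in state_ids(m)) {
      u0 <- m$states[[id]]$utility
      u1 <- m2$states[[id]]$utility
      expect_true(u1 >= 0.8 * u0 - 1e-12 && u1 <= min(1.2 * u0, 1) + 1e-12)
    }
    p0 <- m$rules$probability
    p1 <- m2$rules$probability
    interior <- p0 > 0 & p0 < 1
    expect_identical(p1[!interior], p0[!interior])
    expect_true(all(p1[interior] >= 0.8 * p0[interior] - 1e-12 &
                    p1[interior] <= pmin(1.2 * p0[interior], 1) + 1e-12))
  }
})

test_that("perturbation draws are centred on the base value", {
  m <- random_model(3, n_ae_states = 0)
  c0 <- m$states$terminal_care$entry_cost  # unconstrained scalar
  draws <- vapply(1:400, function(s)
    perturb_model(m, 0.2, seed = s)$states$terminal_care$entry_cost,
    numeric(1))
  tri_sd <- c0 * 0.2 / sqrt(6)
  expect_lt(abs(mean(draws) - c0), 3 * tri_sd / sqrt(length(draws)))
})
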