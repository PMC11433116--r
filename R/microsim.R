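#' Individual-level microsimulation of a model
#'
#' Independent validation path for the cohort engine: `n` patients are
#' simulated one transition at a time by sampling rows of the per-cycle
#' transition matrices, with exactly the same cost and utility accrual
#' conventions as [accumulate()] (upfront cost at time zero undiscounted,
#' per-cycle rewards weighted by the state selected by `reward_timing`,
#' entry costs on state changes). By the law of large numbers the patient
#' means converge to the cohort totals; the function returns Monte Carlo
#' standard errors so agreement can be judged on a known scale.
#'
#' Only the model definition and matrix construction are shared with the
#' cohort engine; occupancy propagation and accrual are implemented
#' separately.
#'
#' @param model A validated `cea_model`.
#' @param strategy Arm id.
#' @param n Number of simulated patients.
#' @param seed Seed for the trajectory sampling.
#' @return List with `mean_cost`, `se_cost`, `mean_qaly`, `se_qaly`,
#'   `occupancy` (matrix of state fractions per cycle 0..horizon), `n` and
#'   `seed`.
#' @examples
#' \donttest{
#' m <- packaged_model("rare")
#' simulate_patients(m, "3DCRT", n = 5000, seed = 1)[c("mean_qaly", "se_qaly")]
#' }
#' @export
simulate_patients <- function(model, strategy, n, seed = 1) {
  .assert_valid(model)
  stopifnot(strategy %in% strategy_ids(model), n >= 1)
  env <- .state_env(model)
  st <- model$settings
  h <- st$horizon_cycles
  disc <- .disc_factors(st)
  y1 <- .year1_cycles(st)
  cyc_frac <- st$cycle_length_months / 12
  groups <- .matrix_groups(model, strategy, env)

  set.seed(seed)
  cur <- rep(match(model$start_state, env$ids), n)
  cost <- rep(model$strategies[[strategy]]$upfront_cost, n)
  qaly <- numeric(n)
  counts <- matrix(0L, h + 1, env$n, dimnames = list(0:h, env$ids))
  counts[1, ] <- tabulate(cur, env$n)

  for (grp in groups) {
    M <- grp$M
    for (t in grp$cycles) {
      nxt <- cur
      for (s in unique(cur)) {
        idx <- which(cur == s)
        if (env$absorbing[s]) next
        nxt[idx] <- sample.int(env$n, length(idx), replace = TRUE,
                               prob = M[s, ])
      }
      counts[t + 1, ] <- tabulate(nxt, env$n)
      w <- switch(st$reward_timing, start = cur, end = nxt, half = NULL)
      fu <- if (t <= y1) st$followup_cost_year1 else st$followup_cost_later
      state_cost <- if (t <= y1) env$cost_y1 else env$cost_later
      percyc <- fu * env$accrues + state_cost
      if (st$reward_timing == "half") {
        qaly <- qaly + disc[t] * cyc_frac *
          0.5 * (env$utility[cur] + env$utility[nxt])
        cost <- cost + disc[t] * 0.5 * (percyc[cur] + percyc[nxt])
      } else {
        qaly <- qaly + disc[t] * cyc_frac * env$utility[w]
        cost <- cost + disc[t] * percyc[w]
      }
      moved <- nxt != cur
      if (any(moved))
        cost[moved] <- cost[moved] + disc[t] * env$entry[nxt[moved]]
      cur <- nxt
    }
  }
  list(mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n),
       mean_qaly = mean(qaly), se_qaly = stats::sd(qaly) / sqrt(n),
       occupancy = counts / n, n = n, seed = seed)
}
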