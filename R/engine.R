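# precomputed per-model state attribute vectors used by the engine,
# the microsimulation and the accumulators
.state_env <- function(model) {
  ids <- state_ids(model)
  list(ids = ids,
       n = length(ids),
       utility = .state_field(model, "utility"),
       entry = .state_field(model, "entry_cost"),
       cost_y1 = .state_field(model, "cost_cycle_year1"),
       cost_later = .state_field(model, "cost_cycle_later"),
       accrues = .state_lgl(model, "accrues_followup"),
       absorbing = .state_lgl(model, "is_absorbing"),
       resid = match(vapply(model$states, `[[`, "", "residual_target"), ids))
}

# raw matrix for one strategy at one cycle; rules_sub already filtered to
# strategy + shared rows
.build_matrix_raw <- function(env, rules_sub, cycle) {
  M <- matrix(0, env$n, env$n, dimnames = list(env$ids, env$ids))
  act <- rules_sub$window_start <= cycle & rules_sub$window_end >= cycle
  if (any(act)) {
    fi <- match(rules_sub$from[act], env$ids)
    ti <- match(rules_sub$to[act], env$ids)
    pp <- rules_sub$probability[act]
    for (k in seq_along(fi)) M[fi[k], ti[k]] <- M[fi[k], ti[k]] + pp[k]
  }
  rs <- rowSums(M)
  resid <- 1 - rs
  if (any(resid < -1e-9 & !env$absorbing)) {
    bad <- which(resid < -1e-9 & !env$absorbing)[1]
    stop(sprintf("outgoing probabilities of state '%s' exceed 1 (sum %.6g) at cycle %d",
                 env$ids[bad], rs[bad], cycle), call. = FALSE)
  }
  for (s in seq_len(env$n)) {
    if (env$absorbing[s]) {
      M[s, ] <- 0; M[s, s] <- 1
    } else {
      M[s, env$resid[s]] <- M[s, env$resid[s]] + max(resid[s], 0)
    }
  }
  M
}

#' Per-cycle transition matrix of one strategy
#'
#' Applies exactly the transition rules whose cycle window contains `cycle`,
#' routes each row's residual mass to the state's residual target (itself for
#' ordinary states, the forced exit for tunnel states) and returns a square
#' row-stochastic matrix. Absorbing states get identity rows. An over-specified
#' row (outgoing mass above 1) is an error naming the state and cycle.
#'
#' @param model A validated `cea_model`.
#' @param strategy Arm id.
#' @param cycle 1-based cycle index within the horizon.
#' @return Matrix of transition probabilities indexed `[from, to]`, with
#'   attributes `cycle` and `strategy`.
#' @examples
#' M <- build_matrix(packaged_model("rare"), "3DCRT", 1)
#' sum(M["no_late_ae", ])  # 1
#' @export
build_matrix <- function(model, strategy, cycle) {
  stopifnot(strategy %in% strategy_ids(model),
            cycle >= 1, cycle <= model$settings$horizon_cycles)
  env <- .state_env(model)
  sub <- model$rules[model$rules$strategy %in% c("shared", strategy), ,
                     drop = FALSE]
  M <- .build_matrix_raw(env, sub, cycle)
  attr(M, "cycle") <- cycle
  attr(M, "strategy") <- strategy
  M
}

# cycles grouped by identical active-rule sets: matrices only change at
# window boundaries, so one matrix per group is built
.matrix_groups <- function(model, strategy, env = .state_env(model)) {
  h <- model$settings$horizon_cycles
  sub <- model$rules[model$rules$strategy %in% c("shared", strategy), ,
                     drop = FALSE]
  cuts <- sort(unique(c(1, pmax(pmin(sub$window_start, h + 1), 1),
                        sub$window_end[is.finite(sub$window_end) &
                                       sub$window_end < h] + 1)))
  cuts <- cuts[cuts <= h]
  ends <- c(cuts[-1] - 1, h)
  lapply(seq_along(cuts), function(i)
    list(cycles = cuts[i]:ends[i],
         M = .build_matrix_raw(env, sub, cuts[i])))
}

#' Propagate the cohort through the model
#'
#' Starts the whole cohort in the start state and applies the per-cycle
#' transition matrices for `horizon_cycles` cycles, tracking both state
#' occupancy and per-cycle inflow (the cohort fraction newly entering each
#' state, used to charge entry costs exactly once per entering fraction).
#'
#' @param model A `cea_model`; validated before running.
#' @param strategy Arm id.
#' @param validate Validate the model first? Internal callers that have just
#'   validated it skip the repeat check.
#' @return An object of class `cea_trace`: list with `strategy`, `occupancy`
#'   ((horizon + 1) x states matrix, row `"0"` is the initial distribution)
#'   and `inflow` (same shape; row for cycle `t` holds mass entering each
#'   state during cycle `t` from a different state).
#' @examples
#' tr <- run_cohort(packaged_model("rare"), "PBT")
#' rowSums(tr$occupancy)[1:3]  # all 1
#' @export
run_cohort <- function(model, strategy, validate = TRUE) {
  if (validate) .assert_valid(model)
  stopifnot(strategy %in% strategy_ids(model))
  env <- .state_env(model)
  h <- model$settings$horizon_cycles
  occ <- matrix(0, h + 1, env$n, dimnames = list(0:h, env$ids))
  inflow <- matrix(0, h + 1, env$n, dimnames = list(0:h, env$ids))
  occ[1, model$start_state] <- 1
  for (grp in .matrix_groups(model, strategy, env)) {
    M <- grp$M
    Moff <- M; diag(Moff) <- 0
    for (t in grp$cycles) {
      prev <- occ[t, ]
      occ[t + 1, ] <- prev %*% M
      inflow[t + 1, ] <- prev %*% Moff
    }
  }
  structure(list(strategy = strategy, occupancy = occ, inflow = inflow),
            class = "cea_trace")
}

#' @export
print.cea_trace <- function(x, ...) {
  h <- nrow(x$occupancy) - 1
  cat(sprintf("<cea_trace> strategy %s, %d cycles; death occupancy at horizon: %.4f\n",
              x$strategy, h,
              if ("death" %in% colnames(x$occupancy))
                x$occupancy[h + 1, "death"] else NA_real_))
  invisible(x)
}

# per-cycle discount factors and reward weights shared by the cohort
# accumulator and the microsimulation
.disc_factors <- function(settings) {
  t <- seq_len(settings$horizon_cycles)
  expo <- if (settings$discount_timing == "end") t else t - 1
  (1 + settings$annual_discount_rate)^(-expo * settings$cycle_length_months / 12)
}

.year1_cycles <- function(settings) round(12 / settings$cycle_length_months)

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Applies the model's accrual conventions: the upfront strategy cost is
#' charged undiscounted at time zero; each cycle accrues utility times the
#' cycle length (in years) and the per-cycle state costs, weighted by the
#' occupancy selected by `reward_timing` (default: occupancy at cycle start,
#' i.e. the state occupied during the cycle); entry costs are charged on the
#' inflow of the cycle; everything except the upfront cost is discounted with
#' the per-cycle factor implied by `discount_timing`.
#'
#' @param model The `cea_model` the trace came from.
#' @param trace A `cea_trace` from [run_cohort()].
#' @return An object of class `cea_outcome`: `strategy`, `total_cost` (yen,
#'   discounted), `total_qaly` (discounted), `undiscounted_ly` (life-years)
#'   and `per_state_cost` (discounted yen by state, plus `"(upfront)"`).
#' @examples
#' m <- packaged_model("rare")
#' accumulate(m, run_cohort(m, "3DCRT"))
#' @export
accumulate <- function(model, trace) {
  stopifnot(inherits(trace, "cea_trace"))
  env <- .state_env(model)
  if (!identical(colnames(trace$occupancy), env$ids))
    stop("trace does not match model: state sets differ", call. = FALSE)
  if (!trace$strategy %in% strategy_ids(model))
    stop("trace strategy '", trace$strategy, "' not in model", call. = FALSE)
  .accumulate_env(env, model$settings,
                  model$strategies[[trace$strategy]]$upfront_cost, trace)
}

# vectorised accrual over a whole trace; env from .state_env()
.accumulate_env <- function(env, st, upfront, trace) {
  h <- st$horizon_cycles
  disc <- .disc_factors(st)
  y1 <- min(.year1_cycles(st), h)
  cyc_frac <- st$cycle_length_months / 12

  W <- switch(st$reward_timing,
              start = trace$occupancy[seq_len(h), , drop = FALSE],
              end = trace$occupancy[seq_len(h) + 1, , drop = FALSE],
              half = 0.5 * (trace$occupancy[seq_len(h), , drop = FALSE] +
                            trace$occupancy[seq_len(h) + 1, , drop = FALSE]))
  # per-cycle state cost matrix: follow-up (where accrued) plus the state's
  # own first-year/later cost
  percyc <- rbind(
    matrix(st$followup_cost_year1 * env$accrues + env$cost_y1,
           y1, env$n, byrow = TRUE),
    matrix(st$followup_cost_later * env$accrues + env$cost_later,
           h - y1, env$n, byrow = TRUE))
  inflow <- trace$inflow[seq_len(h) + 1, , drop = FALSE]
  per_state <- colSums(disc * (W * percyc)) +
    colSums(disc * inflow) * env$entry
  names(per_state) <- env$ids
  structure(list(strategy = trace$strategy,
                 total_cost = upfront + sum(per_state),
                 total_qaly = cyc_frac * sum(disc * (W %*% env$utility)),
                 undiscounted_ly = cyc_frac * sum(W[, !env$absorbing]),
                 per_state_cost = c(per_state, "(upfront)" = upfront)),
            class = "cea_outcome")
}

# fast internal path: propagate and accrue one arm with a precomputed env
.eval_strategy <- function(model, strategy, env) {
  h <- model$settings$horizon_cycles
  occ <- matrix(0, h + 1, env$n, dimnames = list(0:h, env$ids))
  inflow <- matrix(0, h + 1, env$n, dimnames = list(0:h, env$ids))
  occ[1, model$start_state] <- 1
  for (grp in .matrix_groups(model, strategy, env)) {
    M <- grp$M
    Moff <- M; diag(Moff) <- 0
    for (t in grp$cycles) {
      prev <- occ[t, ]
      occ[t + 1, ] <- prev %*% M
      inflow[t + 1, ] <- prev %*% Moff
    }
  }
  tr <- structure(list(strategy = strategy, occupancy = occ, inflow = inflow),
                  class = "cea_trace")
  .accumulate_env(env, model$settings,
                  model$strategies[[strategy]]$upfront_cost, tr)
}

#' @export
print.cea_outcome <- function(x, ...) {
  cat(sprintf("<cea_outcome> %s: cost %s yen, effectiveness %.4f QALY (%.3f LY undiscounted)\n",
              x$strategy, format(round(x$total_cost), big.mark = ","),
              x$total_qaly, x$undiscounted_ly))
  invisible(x)
}

#' Run one strategy end to end
#'
#' @param model A `cea_model`.
#' @param strategy Arm id.
#' @param validate Validate the model before running?
#' @return A `cea_outcome` (see [accumulate()]).
#' @export
run_strategy <- function(model, strategy, validate = TRUE) {
  if (validate) .assert_valid(model)
  stopifnot(strategy %in% strategy_ids(model))
  .eval_strategy(model, strategy, .state_env(model))
}

#' Tidy per-cycle trace table
#'
#' Long-format export of a cohort trace with the discounted cost and QALY
#' contribution of every (cycle, state) cell, suitable for writing to CSV.
#'
#' @param model The `cea_model` the trace came from.
#' @param trace A `cea_trace`.
#' @return A `data.frame` with columns `cycle`, `state`, `occupancy`,
#'   `inflow`, `discounted_cost`, `discounted_qaly`.
#' @export
trace_table <- function(model, trace) {
  env <- .state_env(model)
  st <- model$settings
  h <- st$horizon_cycles
  disc <- .disc_factors(st)
  y1 <- .year1_cycles(st)
  cyc_frac <- st$cycle_length_months / 12
  rows <- vector("list", h)
  for (t in seq_len(h)) {
    w <- switch(st$reward_timing,
                start = trace$occupancy[t, ],
                end = trace$occupancy[t + 1, ],
                half = 0.5 * (trace$occupancy[t, ] + trace$occupancy[t + 1, ]))
    fu <- if (t <= y1) st$followup_cost_year1 else st$followup_cost_later
    state_cost <- if (t <= y1) env$cost_y1 else env$cost_later
    rows[[t]] <- data.frame(
      cycle = t, state = env$ids,
      occupancy = as.numeric(trace$occupancy[t + 1, ]),
      inflow = as.numeric(trace$inflow[t + 1, ]),
      discounted_cost = as.numeric(
        disc[t] * (w * (fu * env$accrues + state_cost) +
                   trace$inflow[t + 1, ] * env$entry)),
      discounted_qaly = as.numeric(disc[t] * cyc_frac * w * env$utility),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
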