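#' Define a health state
#'
#' A health state carries the utility weight and cost attributes used by the
#' cohort engine. Per-cycle costs are split into a first-year and a later
#' value because Japanese follow-up fees differ between the first year after
#' chemoradiotherapy and subsequent years; states whose published cost already
#' includes the follow-up fee set `accrues_followup = FALSE` so the generic
#' follow-up cost is not charged on top.
#'
#' `residual_target` receives whatever probability mass is left in the state's
#' row after all explicit transition rules are applied. For ordinary states it
#' is the state itself (the "stay" probability); for one-cycle tunnel states
#' (pericardial drainage, pericardiotomy) it is the forced next state, so the
#' state can never be occupied for two consecutive cycles.
#'
#' @param id Short unique token identifying the state.
#' @param label Human-readable name.
#' @param utility Utility weight per cycle, in `[0, 1]`.
#' @param entry_cost Cost (yen) charged once for each cohort fraction entering
#'   the state (a hospitalization episode, for instance).
#' @param cost_cycle_year1,cost_cycle_later State-specific cost (yen) accrued
#'   for every cycle spent in the state, during and after the first year.
#' @param accrues_followup Should the model-wide follow-up cost (see
#'   [model_settings()]) be charged while in this state?
#' @param residual_target State id receiving the row's residual probability
#'   mass; defaults to the state itself.
#' @param is_absorbing Absorbing states keep their occupants forever and
#'   accrue nothing in the packaged model.
#' @param is_terminal_care Marks the terminal-care (BSC) state.
#' @param ae_family,ae_grade Optional adverse-event family token and integer
#'   severity rank within the family, used to validate utility monotonicity
#'   and to enforce grade ordering when sampling utilities.
#' @return An object of class `health_state`.
#' @seealso [model_definition()], [validate_model()]
#' @export
health_state <- function(id, label = id, utility, entry_cost = 0,
                         cost_cycle_year1 = 0,
                         cost_cycle_later = cost_cycle_year1,
                         accrues_followup = TRUE,
                         residual_target = id,
                         is_absorbing = FALSE,
                         is_terminal_care = FALSE,
                         ae_family = NA_character_,
                         ae_grade = NA_integer_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.numeric(utility), length(utility) == 1L)
  structure(
    list(id = id, label = label, utility = as.numeric(utility),
         entry_cost = as.numeric(entry_cost),
         cost_cycle_year1 = as.numeric(cost_cycle_year1),
         cost_cycle_later = as.numeric(cost_cycle_later),
         accrues_followup = isTRUE(accrues_followup),
         residual_target = residual_target,
         is_absorbing = isTRUE(is_absorbing),
         is_terminal_care = isTRUE(is_terminal_care),
         ae_family = as.character(ae_family),
         ae_grade = as.integer(ae_grade)),
    class = "health_state")
}

#' Define a treatment strategy (decision-tree arm)
#'
#' @param id Arm token, e.g. `"PBT"` or `"3DCRT"`.
#' @param upfront_cost Cost (yen) charged once at time zero: the radiotherapy
#'   fee plus admission and chemotherapy during chemoradiotherapy.
#' @return An object of class `strategy_definition`.
#' @export
strategy_definition <- function(id, upfront_cost) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.numeric(upfront_cost), length(upfront_cost) == 1L)
  structure(list(id = id, upfront_cost = as.numeric(upfront_cost)),
            class = "strategy_definition")
}

#' Define time-windowed transition rules
#'
#' Builds one or more rows of the rule table of a [model_definition()]. A rule
#' applies its per-cycle probability while `window_start <= cycle <=
#' window_end` (cycles are 1-based); outside the window it contributes
#' nothing. `window_end = Inf` means the rule applies until the horizon.
#'
#' @param strategy Arm id the rule belongs to, or `"shared"` for rules applied
#'   in every arm.
#' @param from,to State ids.
#' @param probability Per-cycle transition probability in `[0, 1]`.
#' @param window_start,window_end First and last cycle (inclusive) at which
#'   the rule applies.
#' @return A `data.frame` with one row per rule (vectorised over arguments).
#' @export
transition_rule <- function(strategy, from, to, probability,
                            window_start = 1, window_end = Inf) {
  data.frame(strategy = strategy, from = from, to = to,
             probability = as.numeric(probability),
             window_start = as.numeric(window_start),
             window_end = as.numeric(window_end),
             stringsAsFactors = FALSE)
}

#' Model settings: cycle length, horizon, discounting and accrual conventions
#'
#' @param cycle_length_months Length of one Markov cycle in months.
#' @param horizon_cycles Number of cycles simulated.
#' @param annual_discount_rate Annual discount rate applied to both costs and
#'   QALYs.
#' @param wtp_threshold Willingness-to-pay threshold (yen per QALY).
#' @param followup_cost_year1,followup_cost_later Routine follow-up cost (yen
#'   per cycle) during the first year and afterwards, charged in every alive
#'   state with `accrues_followup = TRUE`.
#' @param reward_timing Which occupancy weights per-cycle rewards: `"start"`
#'   (state occupied during the cycle, the TreeAge stage-reward convention and
#'   the default), `"end"` (post-transition occupancy) or `"half"` (the
#'   half-cycle correction, averaging the two).
#' @param discount_timing `"end"` discounts cycle `t` rewards by
#'   `(1 + r)^(-t * cycle_length / 12)`; `"start"` uses exponent `t - 1`.
#' @return An object of class `model_settings`.
#' @export
model_settings <- function(cycle_length_months = 3,
                           horizon_cycles = 20,
                           annual_discount_rate = 0.03,
                           wtp_threshold = 7.5e6,
                           followup_cost_year1 = 45615,
                           followup_cost_later = 28480,
                           reward_timing = c("start", "end", "half"),
                           discount_timing = c("end", "start")) {
  reward_timing <- match.arg(reward_timing)
  discount_timing <- match.arg(discount_timing)
  stopifnot(cycle_length_months > 0, horizon_cycles >= 1,
            annual_discount_rate >= 0, annual_discount_rate < 1)
  structure(
    list(cycle_length_months = as.numeric(cycle_length_months),
         horizon_cycles = as.integer(horizon_cycles),
         annual_discount_rate = as.numeric(annual_discount_rate),
         wtp_threshold = as.numeric(wtp_threshold),
         followup_cost_year1 = as.numeric(followup_cost_year1),
         followup_cost_later = as.numeric(followup_cost_later),
         reward_timing = reward_timing,
         discount_timing = discount_timing),
    class = "model_settings")
}

#' Assemble a full state-transition model
#'
#' @param states List of [health_state()] objects.
#' @param rules `data.frame` of transition rules (rows as produced by
#'   [transition_rule()]).
#' @param strategies List of two [strategy_definition()] objects.
#' @param settings A [model_settings()] object.
#' @param start_state Id of the state holding the whole cohort at time zero.
#' @return An object of class `cea_model`.
#' @examples
#' m <- packaged_model("rare")
#' state_ids(m)
#' @export
model_definition <- function(states, rules, strategies,
                             settings = model_settings(),
                             start_state) {
  stopifnot(is.list(states), is.data.frame(rules), is.list(strategies))
  names(states) <- vapply(states, `[[`, "", "id")
  names(strategies) <- vapply(strategies, `[[`, "", "id")
  structure(list(states = states, rules = rules, strategies = strategies,
                 settings = settings, start_state = start_state),
            class = "cea_model")
}

#' @export
print.cea_model <- function(x, ...) {
  cat(sprintf("<cea_model> %d states, %d transition rules, strategies: %s\n",
              length(x$states), nrow(x$rules),
              paste(names(x$strategies), collapse = " vs ")))
  cat(sprintf("  start: %s | %d cycles x %g months | discount %.1f%%/yr | accrual: %s\n",
              x$start_state, x$settings$horizon_cycles,
              x$settings$cycle_length_months,
              100 * x$settings$annual_discount_rate,
              x$settings$reward_timing))
  invisible(x)
}

#' State ids of a model
#' @param model A `cea_model`.
#' @return Character vector of state ids in model order.
#' @export
state_ids <- function(model) names(model$states)

#' Strategy ids of a model
#' @param model A `cea_model`.
#' @return Character vector of arm ids.
#' @export
strategy_ids <- function(model) names(model$strategies)

# named numeric vector of one state field across all states
.state_field <- function(model, field) {
  vapply(model$states, function(s) as.numeric(s[[field]]),
         numeric(1))
}

.state_lgl <- function(model, field) {
  vapply(model$states, function(s) isTRUE(s[[field]]), logical(1))
}

#' Validate a model definition
#'
#' Checks every structural invariant the cohort engine relies on and returns
#' the violations as data, not errors: utilities in `[0, 1]`, non-negative
#' costs, a unique absorbing `death` state with zero utility and cost, a
#' unique terminal-care state, rule references to declared states, per-cycle
#' outgoing probability mass at most 1 from every state under every strategy,
#' reachability of death from the start state, and utility monotonicity
#' within each graded adverse-event family.
#'
#' @param model A `cea_model`.
#' @return A `data.frame` with columns `entity` and `message`; zero rows when
#'   the model is valid.
#' @examples
#' nrow(validate_model(packaged_model("rare")))  # 0
#' @export
validate_model <- function(model) {
  v <- list()
  bad <- function(entity, message) {
    v[[length(v) + 1L]] <<- data.frame(entity = entity, message = message,
                                       stringsAsFactors = FALSE)
  }
  ids <- state_ids(model)
  if (anyDuplicated(ids)) bad("states", "duplicate state ids")

  for (s in model$states) {
    if (is.na(s$utility) || s$utility < 0 || s$utility > 1)
      bad(s$id, sprintf("utility %s outside [0, 1]", format(s$utility)))
    if (s$entry_cost < 0) bad(s$id, "negative entry cost")
    if (s$cost_cycle_year1 < 0 || s$cost_cycle_later < 0)
      bad(s$id, "negative per-cycle cost")
    if (!s$residual_target %in% ids)
      bad(s$id, sprintf("residual target '%s' is not a declared state",
                        s$residual_target))
  }

  if (!"death" %in% ids) {
    bad("death", "no state with id 'death'")
  } else {
    d <- model$states[["death"]]
    if (!d$is_absorbing) bad("death", "death state is not absorbing")
    if (d$utility != 0) bad("death", "death state utility is not 0")
    if (d$entry_cost != 0 || d$cost_cycle_year1 != 0 || d$cost_cycle_later != 0)
      bad("death", "death state has non-zero costs")
  }
  n_abs <- sum(.state_lgl(model, "is_absorbing"))
  if (n_abs != 1L) bad("states", sprintf("%d absorbing states (expected 1)", n_abs))
  n_tc <- sum(.state_lgl(model, "is_terminal_care"))
  if (n_tc != 1L) bad("states", sprintf("%d terminal-care states (expected 1)", n_tc))

  if (length(model$strategies) != 2L)
    bad("strategies", sprintf("%d strategies (expected 2)", length(model$strategies)))
  for (st in model$strategies)
    if (st$upfront_cost < 0) bad(st$id, "negative upfront cost")

  if (!model$start_state %in% ids)
    bad("start_state", sprintf("start state '%s' not declared", model$start_state))

  r <- model$rules
  arm_ok <- c("shared", strategy_ids(model))
  flag_rules <- function(which_bad, msg) {
    for (i in which(which_bad))
      bad(sprintf("rule %s->%s [%s]", r$from[i], r$to[i], r$strategy[i]),
          if (grepl("%s", msg, fixed = TRUE))
            sprintf(msg, format(r$probability[i])) else msg)
  }
  flag_rules(!r$from %in% ids, "unknown from-state")
  flag_rules(!r$to %in% ids, "unknown to-state")
  flag_rules(!r$strategy %in% arm_ok, "unknown strategy")
  flag_rules(is.na(r$probability) | r$probability < 0 | r$probability > 1,
             "probability %s outside [0, 1]")
  flag_rules(r$window_start < 1 | r$window_end < r$window_start,
             "invalid cycle window")

  # outgoing probability mass <= 1 per (strategy, from, cycle); cycle groups
  # suffice because rule activity only changes at window boundaries
  if (nrow(r) && all(r$from %in% ids) && all(r$to %in% ids)) {
    h <- model$settings$horizon_cycles
    cuts <- sort(unique(pmin(pmax(c(1, r$window_start,
                                    r$window_end[is.finite(r$window_end)] + 1), 1), h)))
    for (arm in strategy_ids(model)) {
      sub <- r[r$strategy %in% c("shared", arm), , drop = FALSE]
      for (cyc in cuts) {
        act <- sub[sub$window_start <= cyc & sub$window_end >= cyc, , drop = FALSE]
        if (!nrow(act)) next
        sums <- tapply(act$probability, act$from, sum)
        over <- sums[sums > 1 + 1e-12]
        for (nm in names(over))
          bad(nm, sprintf("outgoing row sum %.6g > 1 for strategy %s at cycle %d",
                          over[[nm]], arm, cyc))
      }
    }
  }

  # death must be reachable from the start state via positive-probability
  # edges (explicit rules of any arm plus residual targets)
  if (model$start_state %in% ids && "death" %in% ids) {
    adj <- lapply(ids, function(s) model$states[[s]]$residual_target)
    names(adj) <- ids
    pos <- r[r$probability > 0, , drop = FALSE]
    for (i in seq_len(nrow(pos)))
      adj[[pos$from[i]]] <- c(adj[[pos$from[i]]], pos$to[i])
    seen <- model$start_state
    frontier <- seen
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier])), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (!"death" %in% seen) bad("start_state", "death unreachable from start state")
  }

  # grade-monotone utilities within each adverse-event family
  fam <- vapply(model$states, function(s) s$ae_family, character(1))
  for (f in unique(fam[!is.na(fam)])) {
    in_f <- model$states[which(fam == f)]
    g <- vapply(in_f, function(s) as.numeric(s$ae_grade), numeric(1))
    uu <- vapply(in_f, function(s) s$utility, numeric(1))
    o <- order(g)
    if (is.unsorted(rev(uu[o])))
      bad(f, sprintf("utility ordering violated in family '%s' (%s)",
                     f, paste(sprintf("grade %g: %.3g", g[o], uu[o]),
                              collapse = ", ")))
  }

  if (length(v)) do.call(rbind, v)
  else data.frame(entity = character(), message = character(),
                  stringsAsFactors = FALSE)
}

# stop with a readable message when a model fails validation
.assert_valid <- function(model) {
  viol <- validate_model(model)
  if (nrow(viol))
    stop("invalid model: ",
         paste(sprintf("[%s] %s", viol$entity, viol$message), collapse = "; "),
         call. = FALSE)
  invisible(model)
}
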