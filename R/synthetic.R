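#' Generate a random, valid synthetic model
#'
#' Emits a model with the same statistical structure as the packaged one so
#' every pipeline stage can be exercised on inputs it has never seen: an
#' event-free start state; `n_ae_states` graded adverse-event states grouped
#' into families of up to three grades with utilities sampled in decreasing
#' grade order (monotone by construction); window-limited onset rules with
#' per-arm probabilities scaled so row sums stay strictly below 1; recovery
#' transitions toward lower grades; a shared per-cycle terminal-care hazard
#' from every alive state; a zero-utility terminal-care state followed by
#' death after one cycle; and two strategies differing in upfront cost and
#' onset probabilities. The emitted model always passes [validate_model()].
#'
#' With `n_ae_states = 0` the model collapses to start / terminal care /
#' death, whose discounted QALY total has a geometric closed form — the
#' sharpest available oracle for the cohort engine.
#'
#' @param seed Seed making the model reproducible.
#' @param n_ae_states Number of adverse-event states (0 allowed).
#' @param horizon Horizon in cycles.
#' @param windows Candidate onset-window lengths (cycles) sampled per state.
#' @return A validated `cea_model`.
#' @examples
#' m <- random_model(1, n_ae_states = 5)
#' nrow(validate_model(m))  # 0
#' @export
random_model <- function(seed, n_ae_states = 6, horizon = 20,
                         windows = c(4, 8)) {
  stopifnot(n_ae_states >= 0, horizon >= 2)
  set.seed(seed)
  hazard <- stats::runif(1, 0.02, 0.10)
  u_start <- stats::runif(1, 0.85, 0.95)

  states <- list(
    health_state("start", "Event-free", u_start),
    health_state("terminal_care", "Terminal care", 0,
                 entry_cost = round(stats::runif(1, 1e5, 8e5)),
                 accrues_followup = FALSE, is_terminal_care = TRUE),
    health_state("death", "Death", 0, accrues_followup = FALSE,
                 is_absorbing = TRUE))
  rules <- transition_rule("shared", "terminal_care", "death", 1)
  ae_ids <- character(0)

  if (n_ae_states > 0) {
    n_fam <- ceiling(n_ae_states / 3)
    fam_sizes <- diff(round(seq(0, n_ae_states, length.out = n_fam + 1)))
    k <- 0
    for (f in seq_len(n_fam)) {
      fam <- paste0("ae", f)
      # strictly decreasing utilities below the start state's
      uu <- sort(stats::runif(fam_sizes[f], 0.30, u_start), decreasing = TRUE)
      for (g in seq_len(fam_sizes[f])) {
        k <- k + 1
        id <- sprintf("%s_g%d", fam, g)
        ae_ids <- c(ae_ids, id)
        states[[length(states) + 1]] <- health_state(
          id, sprintf("Family %d grade %d", f, g), uu[g],
          entry_cost = if (g == fam_sizes[f] && g > 1)
            round(stats::runif(1, 0, 6e5)) else 0,
          cost_cycle_year1 = round(stats::runif(1, 0, 6e4)),
          ae_family = fam, ae_grade = as.integer(g))
        if (g > 1)  # recovery toward the previous grade, shared
          rules <- rbind(rules, transition_rule(
            "shared", id, sprintf("%s_g%d", fam, g - 1),
            stats::runif(1, 0.1, 0.4)))
      }
    }
    # arm-specific onsets: scale raw weights so (sum + hazard) < 0.9
    raw <- stats::runif(n_ae_states)
    for (arm in c("A", "B")) {
      total <- stats::runif(1, 0.2, 0.6)
      fac <- if (arm == "A") 1 else stats::runif(1, 0.2, 0.9)
      pp <- raw / sum(raw) * total * fac
      wend <- sample(windows, n_ae_states, replace = TRUE)
      rules <- rbind(rules, transition_rule(arm, "start", ae_ids, pp,
                                            1, wend))
    }
  }
  for (s in c("start", ae_ids))
    rules <- rbind(rules, transition_rule("shared", s, "terminal_care", hazard))

  up_a <- round(stats::runif(1, 1e6, 4e6))
  strategies <- list(
    strategy_definition("A", up_a),
    strategy_definition("B", up_a - round(stats::runif(1, 1e5, 9e5))))

  settings <- model_settings(
    horizon_cycles = horizon,
    followup_cost_year1 = round(stats::runif(1, 2e4, 6e4)),
    followup_cost_later = round(stats::runif(1, 1e4, 4e4)))

  m <- model_definition(states, rules, strategies, settings,
                        start_state = "start")
  .assert_valid(m)
}

# all perturbable scalar locations of a generic model
.model_scalars <- function(model) {
  out <- list()
  for (id in state_ids(model)) {
    s <- model$states[[id]]
    if (s$is_absorbing) next
    out[[length(out) + 1]] <- list(kind = "utility", state = id)
    for (fld in c("entry_cost", "cost_cycle_year1", "cost_cycle_later"))
      if (s[[fld]] > 0)
        out[[length(out) + 1]] <- list(kind = "cost", state = id, field = fld)
  }
  for (i in seq_len(nrow(model$rules))) {
    p <- model$rules$probability[i]
    if (p > 0 && p < 1)
      out[[length(out) + 1]] <- list(kind = "probability", rule = i)
  }
  for (st in strategy_ids(model))
    out[[length(out) + 1]] <- list(kind = "cost", strategy = st)
  for (fld in c("followup_cost_year1", "followup_cost_later"))
    if (model$settings[[fld]] > 0)
      out[[length(out) + 1]] <- list(kind = "cost", setting = fld)
  out
}

#' Perturb every scalar of a model with one triangular draw
#'
#' Bridge between the synthetic-model generator and the probabilistic
#' machinery: applies one PSA-style draw (triangular, mode at the current
#' value, limits at `+/- relative_width`) to every utility, cost and
#' strictly-interior transition probability of an arbitrary model, and
#' returns the perturbed model. Utility grade ordering within adverse-event
#' families is enforced by bounded redraw then sorting; draws that push an
#' outgoing row sum above 1 are redrawn, with capping at the original values
#' as the deterministic fallback. `relative_width = 0` returns a model
#' identical to the input.
#'
#' @param model A validated `cea_model`.
#' @param relative_width Relative half-width of the triangular draws.
#' @param seed Seed.
#' @param max_retries Bounded retries per constraint.
#' @return A validated `cea_model`; attribute `"perturb_flags"` records
#'   constraint fallbacks.
#' @export
perturb_model <- function(model, relative_width = 0.2, seed = 1,
                          max_retries = 100) {
  .assert_valid(model)
  set.seed(seed)
  flags <- list(utility_sorted = FALSE, rows_rescaled = FALSE)

  draw_utils <- function(m) {
    for (id in state_ids(m)) {
      s <- m$states[[id]]
      if (s$is_absorbing) next
      m$states[[id]]$utility <-
        min(.tri_rel(model$states[[id]]$utility, relative_width), 1)
    }
    m
  }
  fam_states <- split(
    state_ids(model),
    vapply(model$states, function(s) s$ae_family, character(1)))
  fam_states <- fam_states[!is.na(names(fam_states)) & names(fam_states) != "NA"]
  fams_ok <- function(m) {
    for (ids in fam_states) {
      g <- vapply(ids, function(i) as.numeric(m$states[[i]]$ae_grade), 0)
      uu <- vapply(ids, function(i) m$states[[i]]$utility, 0)
      if (is.unsorted(rev(uu[order(g)]))) return(FALSE)
    }
    TRUE
  }
  out <- draw_utils(model)
  tries <- 0
  while (!fams_ok(out) && tries < max_retries) {
    out <- draw_utils(out)
    tries <- tries + 1
  }
  if (!fams_ok(out)) {
    for (ids in fam_states) {
      g <- vapply(ids, function(i) as.numeric(out$states[[i]]$ae_grade), 0)
      uu <- vapply(ids, function(i) out$states[[i]]$utility, 0)
      uu <- sort(uu, decreasing = TRUE)
      for (j in seq_along(ids))
        out$states[[ids[order(g)][j]]]$utility <- uu[j]
    }
    flags$utility_sorted <- TRUE
  }

  for (id in state_ids(out)) {
    s <- model$states[[id]]
    if (s$is_absorbing) next
    for (fld in c("entry_cost", "cost_cycle_year1", "cost_cycle_later"))
      out$states[[id]][[fld]] <- .tri_rel(s[[fld]], relative_width)
  }
  for (st in strategy_ids(out))
    out$strategies[[st]]$upfront_cost <-
      .tri_rel(model$strategies[[st]]$upfront_cost, relative_width)
  for (fld in c("followup_cost_year1", "followup_cost_later"))
    out$settings[[fld]] <- .tri_rel(model$settings[[fld]], relative_width)

  draw_probs <- function(m) {
    for (i in seq_len(nrow(m$rules))) {
      p <- model$rules$probability[i]
      if (p > 0 && p < 1)
        m$rules$probability[i] <- min(.tri_rel(p, relative_width), 1)
    }
    m
  }
  rows_ok <- function(m) !nrow(validate_model(m))
  out <- draw_probs(out)
  tries <- 0
  while (!rows_ok(out) && tries < max_retries) {
    out <- draw_probs(out)
    tries <- tries + 1
  }
  if (!rows_ok(out)) {
    out$rules$probability <- pmin(out$rules$probability,
                                  model$rules$probability)
    flags$rows_rescaled <- TRUE
  }
  .assert_valid(out)
  attr(out, "perturb_flags") <- flags
  out
}
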