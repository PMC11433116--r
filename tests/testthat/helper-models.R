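# small hand-built models used across tests

# start -> terminal care -> death chain; hazard h per cycle from start
two_state_model <- function(u_start = 0.9, hazard = 0.05, horizon = 20,
                            upfront_a = 2e6, upfront_b = 1.5e6,
                            settings = NULL) {
  if (is.null(settings)) settings <- model_settings(horizon_cycles = horizon)
  settings$horizon_cycles <- as.integer(horizon)
  model_definition(
    states = list(
      health_state("start", utility = u_start),
      health_state("terminal_care", utility = 0, accrues_followup = FALSE,
                   is_terminal_care = TRUE),
      health_state("death", utility = 0, accrues_followup = FALSE,
                   is_absorbing = TRUE)),
    rules = rbind(
      transition_rule("shared", "start", "terminal_care", hazard),
      transition_rule("shared", "terminal_care", "death", 1)),
    strategies = list(strategy_definition("A", upfront_a),
                      strategy_definition("B", upfront_b)),
    settings = settings,
    start_state = "start")
}

# closed-form discounted QALY of the two-state chain under each accrual
# convention: occupancy of the start state during cycle t is (1-h)^(t-1),
# after cycle t it is (1-h)^t; terminal care has utility 0
two_state_qaly <- function(u, h, settings) {
  t <- seq_len(settings$horizon_cycles)
  expo <- if (settings$discount_timing == "end") t else t - 1
  disc <- (1 + settings$annual_discount_rate)^
    (-expo * settings$cycle_length_months / 12)
  w <- switch(settings$reward_timing,
              start = (1 - h)^(t - 1),
              end = (1 - h)^t,
              half = 0.5 * ((1 - h)^(t - 1) + (1 - h)^t))
  sum(settings$cycle_length_months / 12 * u * w * disc)
}

# registry copy with the PBT probability cells replaced by the 3D-CRT ones
equalised_params <- function() {
  p <- laec_parameters()
  i <- p$kind == "probability"
  p$pbt[i] <- p$x3dcrt[i]
  p
}
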