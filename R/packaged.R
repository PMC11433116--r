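#' Parameter table of the packaged esophageal-cancer model
#'
#' Returns the registry of scalar model inputs: per-cycle transition
#' probabilities (one value per arm), utility weights and unit costs. The
#' values ship with the package as a JSON data file and are the social
#' insurance fees and published utility estimates underlying the base-case
#' analysis. Each row is one independently perturbable scalar of the
#' sensitivity analyses; probability rows carry separate PBT and 3D-CRT
#' cells, utility and cost rows a single shared value stored in both cells.
#'
#' The PBT radiotherapy fee itself is not part of the registry: the two fee
#' levels (2,375,000 yen, the "rare-cancer" schedule, and 1,600,000 yen, the
#' "non-rare" schedule) define two separate base cases and are never
#' perturbed.
#'
#' @param path Optional path to a registry JSON file; defaults to the
#'   packaged one.
#' @return A `data.frame` with columns `param_id`, `kind` (`probability`,
#'   `utility`, `cost`), `family`, `grade`, `pbt`, `x3dcrt`.
#' @examples
#' head(laec_parameters())
#' @export
laec_parameters <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "laec_parameters.json", package = "pbtcea",
                        mustWork = TRUE)
  p <- jsonlite::fromJSON(path)
  stopifnot(all(c("param_id", "kind", "family", "grade", "pbt", "x3dcrt")
                %in% names(p)))
  p$grade <- as.integer(p$grade)
  p
}

# fetch one registry value (arm: "pbt" or "x3dcrt")
.pv <- function(params, id, arm = "x3dcrt") {
  i <- match(id, params$param_id)
  if (is.na(i)) stop("unknown parameter id: ", id, call. = FALSE)
  params[[arm]][i]
}

#' PBT radiotherapy fee for a fee level
#' @param fee_level `"rare"` (2,375,000 yen) or `"non_rare"` (1,600,000 yen).
#' @return The fee in yen.
#' @export
pbt_fee <- function(fee_level = c("rare", "non_rare")) {
  fee_level <- match.arg(fee_level)
  c(rare = 2375000, non_rare = 1600000)[[fee_level]]
}

# onset targets from the event-free state with their registry ids and
# window ends (cycles): pneumonitis-family onsets stop after year 1,
# effusion onsets after year 2
.laec_onsets <- function() {
  data.frame(
    param_id = c("p_noae_to_rp_g1", "p_noae_to_rp_g2", "p_noae_to_rp_g3",
                 "p_noae_to_rp_g1_pe_g1", "p_noae_to_rp_g1_pce_g2",
                 "p_noae_to_pe_g1", "p_noae_to_pe_g2", "p_noae_to_pe_g3",
                 "p_noae_to_pce_g2", "p_noae_to_pce_g3",
                 "p_noae_to_pce_g3_pe_g2"),
    to = c("rp_g1", "rp_g2", "rp_g3", "rp_g1_pe_g1", "rp_g1_pce_g2",
           "pe_g1", "pe_g2", "pe_g3", "pce_g2", "pce_g3", "pce_g3_pe_g2"),
    window_end = c(4, 4, 4, 4, 4, 8, 8, 8, 8, 8, 8),
    stringsAsFactors = FALSE)
}

#' Build the esophageal-cancer model from a parameter table
#'
#' Assembles the full two-arm model (17 health states) from a registry as
#' returned by [laec_parameters()]: the event-free start state; graded
#' radiation pneumonitis (RP G1-G3), pleural effusion (PE G1-G3) and
#' pericardial effusion (PCE G2-G3) states; three overlap states; the
#' pericardial drainage and pericardiotomy tunnel states; resolved PCE; best
#' supportive care (BSC); and death. Onset transitions out of the event-free
#' state apply during the first year (RP family) or the first two years (PE
#' and PCE families); a shared per-cycle BSC hazard applies from every alive
#' state, and BSC is followed by death after one cycle.
#'
#' Where the published PBT and 3D-CRT probability cells are equal the rule is
#' emitted once as `"shared"`; unequal cells become one rule per arm, which is
#' how probabilistic draws that differ by arm enter the model.
#'
#' @param params Registry `data.frame` (see [laec_parameters()]).
#' @param fee_level Which PBT fee base case to build.
#' @param pbt_fee_yen Optional explicit PBT fee overriding `fee_level`.
#' @param drainage_utility Utility assigned to the drainage and
#'   pericardiotomy tunnel states. Not published; defaults to the PCE G3
#'   utility (patients remain in a decompensated cardiac state during the
#'   intervention).
#' @param rp_cost_stacking If `TRUE` (default) the RP G2 treatment cost is
#'   charged on top of routine follow-up; if `FALSE` it replaces it.
#' @param utility_order `"strict"` (default) tags the graded states with
#'   their adverse-event family so [validate_model()] enforces grade-monotone
#'   utilities; `"ignore"` omits the tags, for models where a single utility
#'   is deliberately perturbed on its own (one-way sensitivity analysis).
#' @param settings A [model_settings()]; its follow-up costs are overridden
#'   by the registry values.
#' @param validate Validate the assembled model? Callers that guarantee the
#'   constraints by construction (the probabilistic sampler) may skip it.
#' @return A validated `cea_model`.
#' @export
build_laec_model <- function(params = laec_parameters(),
                             fee_level = c("rare", "non_rare"),
                             pbt_fee_yen = NULL,
                             drainage_utility = NULL,
                             rp_cost_stacking = TRUE,
                             utility_order = c("strict", "ignore"),
                             settings = model_settings(),
                             validate = TRUE) {
  fee_level <- match.arg(fee_level)
  utility_order <- match.arg(utility_order)
  if (is.null(pbt_fee_yen)) pbt_fee_yen <- pbt_fee(fee_level)
  g <- function(id) .pv(params, id)  # shared scalars
  if (is.null(drainage_utility)) drainage_utility <- g("u_pce_g3")

  rp2_extra <- g("c_rp_g2")
  states <- list(
    health_state("no_late_ae", "No late adverse events", g("u_no_late_ae")),
    health_state("rp_g1", "RP Grade 1", g("u_rp_g1"),
                 ae_family = "rp", ae_grade = 1L),
    health_state("rp_g2", "RP Grade 2", g("u_rp_g2"),
                 cost_cycle_year1 = rp2_extra,
                 accrues_followup = rp_cost_stacking,
                 ae_family = "rp", ae_grade = 2L),
    health_state("rp_g3", "RP Grade 3", g("u_rp_g3"),
                 entry_cost = g("c_rp_g3"), ae_family = "rp", ae_grade = 3L),
    health_state("pe_g1", "PE Grade 1", g("u_pe_g1"),
                 ae_family = "pe", ae_grade = 1L),
    health_state("pe_g2", "PE Grade 2", g("u_pe_g2"),
                 cost_cycle_year1 = g("c_pe_g2_year1"),
                 cost_cycle_later = g("c_pe_g2_later"),
                 accrues_followup = FALSE,  # published cost includes follow-up
                 ae_family = "pe", ae_grade = 2L),
    health_state("pe_g3", "PE Grade 3", g("u_pe_g3"),
                 entry_cost = g("c_pe_g3"),
                 residual_target = "pe_g2",  # treated episode resolves to G2
                 ae_family = "pe", ae_grade = 3L),
    health_state("pce_g2", "PCE Grade 2", g("u_pce_g2"),
                 ae_family = "pce", ae_grade = 1L),
    health_state("pce_g3", "PCE Grade 3", g("u_pce_g3"),
                 ae_family = "pce", ae_grade = 2L),
    health_state("pce_g3_pe_g2", "PCE Grade 3 + PE Grade 2",
                 g("u_pce_g3_pe_g2"), ae_family = "pce", ae_grade = 3L),
    health_state("rp_g1_pe_g1", "RP Grade 1 + PE Grade 1", g("u_rp_g1_pe_g1")),
    health_state("rp_g1_pce_g2", "RP Grade 1 + PCE Grade 2",
                 g("u_rp_g1_pce_g2")),
    health_state("drainage", "Pericardial drainage", drainage_utility,
                 entry_cost = g("c_drainage"),
                 residual_target = "pericardiotomy"),  # one-cycle tunnel
    health_state("pericardiotomy", "Pericardiotomy", drainage_utility,
                 entry_cost = g("c_pericardiotomy"),
                 residual_target = "resolved_pce"),    # one-cycle tunnel
    health_state("resolved_pce", "Resolved PCE", g("u_resolved_pce")),
    health_state("bsc", "Best supportive care", g("u_bsc"),
                 entry_cost = g("c_bsc"), accrues_followup = FALSE,
                 is_terminal_care = TRUE),
    health_state("death", "Death", 0, accrues_followup = FALSE,
                 is_absorbing = TRUE))

  # one logical rule per table row; rows whose PBT and 3D-CRT cells agree
  # become a single shared rule, others one rule per arm
  alive <- setdiff(vapply(states, `[[`, "", "id"), c("bsc", "death"))
  on <- .laec_onsets()
  spec <- data.frame(
    param_id = c(on$param_id, "p_rp_g3_to_rp_g2", "p_rp_g2_to_rp_g1",
                 "p_pce_g3_to_drainage", "p_pce_g3_to_drainage",
                 "p_drainage_to_pce_g2", "p_bsc_to_death",
                 rep("p_any_to_bsc", length(alive))),
    from = c(rep("no_late_ae", nrow(on)), "rp_g3", "rp_g2", "pce_g3",
             "pce_g3_pe_g2", "drainage", "bsc", alive),
    to = c(on$to, "rp_g2", "rp_g1", "drainage", "drainage", "pce_g2",
           "death", rep("bsc", length(alive))),
    window_end = c(on$window_end, rep(Inf, 6 + length(alive))),
    stringsAsFactors = FALSE)
  ri <- match(spec$param_id, params$param_id)
  pb <- params$pbt[ri]; cr <- params$x3dcrt[ri]
  shared <- pb == cr
  rules <- data.frame(
    strategy = c(rep("shared", sum(shared)),
                 rep(c("PBT", "3DCRT"), each = sum(!shared))),
    from = c(spec$from[shared], rep(spec$from[!shared], 2)),
    to = c(spec$to[shared], rep(spec$to[!shared], 2)),
    probability = c(cr[shared], pb[!shared], cr[!shared]),
    window_start = 1,
    window_end = c(spec$window_end[shared], rep(spec$window_end[!shared], 2)),
    stringsAsFactors = FALSE)

  strategies <- list(
    strategy_definition("PBT", pbt_fee_yen + g("c_admission_crt")),
    strategy_definition("3DCRT", g("c_3dcrt_fee") + g("c_admission_crt")))

  settings$followup_cost_year1 <- g("c_followup_year1")
  settings$followup_cost_later <- g("c_followup_later")

  if (utility_order == "ignore")
    states <- lapply(states, function(s) {
      s$ae_family <- NA_character_; s$ae_grade <- NA_integer_; s
    })

  m <- model_definition(states, rules, strategies, settings,
                        start_state = "no_late_ae")
  if (validate) .assert_valid(m) else m
}

#' The packaged base-case model
#'
#' Convenience wrapper: [build_laec_model()] on the packaged parameter table.
#' The two fee levels differ in exactly one number, the PBT upfront fee
#' (2,375,000 vs 1,600,000 yen, a difference of 775,000 yen).
#'
#' @inheritParams build_laec_model
#' @return A validated `cea_model`.
#' @examples
#' m <- packaged_model("rare")
#' m$strategies$PBT$upfront_cost   # 3,700,370 yen
#' @export
packaged_model <- function(fee_level = c("rare", "non_rare")) {
  fee_level <- match.arg(fee_level)
  build_laec_model(laec_parameters(), fee_level)
}
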