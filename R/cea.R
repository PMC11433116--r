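#' Incremental cost-effectiveness comparison of two strategies
#'
#' Computes incremental cost, incremental effectiveness, the ICER (from
#' unrounded deltas), net monetary benefit at the willingness-to-pay
#' threshold, a dominance classification and the cost-effectiveness verdict.
#'
#' @param comparator `cea_outcome` of the evaluated strategy (PBT in the
#'   packaged analysis).
#' @param reference `cea_outcome` of the standard of care.
#' @param wtp Willingness-to-pay threshold (yen per QALY).
#' @return An object of class `cea_result` with elements `comparator`,
#'   `reference`, `delta_cost`, `delta_qaly`, `icer` (`NA` when
#'   `delta_qaly == 0`), `nmb_at_wtp`, `dominance` (one of `"dominant"`,
#'   `"dominated"`, `"tradeoff-NE"`, `"tradeoff-SW"`) and `cost_effective`.
#' @examples
#' m <- packaged_model("rare")
#' compare_strategies(run_strategy(m, "PBT"), run_strategy(m, "3DCRT"),
#'                    wtp = 7.5e6)
#' @export
compare_strategies <- function(comparator, reference, wtp = 7.5e6) {
  stopifnot(inherits(comparator, "cea_outcome"),
            inherits(reference, "cea_outcome"))
  dc <- comparator$total_cost - reference$total_cost
  de <- comparator$total_qaly - reference$total_qaly
  icer <- if (de == 0) NA_real_ else dc / de
  dominance <-
    if (dc <= 0 && de >= 0 && !(dc == 0 && de == 0)) "dominant"
    else if (dc >= 0 && de <= 0 && !(dc == 0 && de == 0)) "dominated"
    else if (dc > 0 && de > 0) "tradeoff-NE"
    else if (dc < 0 && de < 0) "tradeoff-SW"
    else "indifferent"
  cost_effective <- dominance == "dominant" ||
    (de > 0 && !is.na(icer) && icer <= wtp)
  structure(list(comparator = comparator$strategy,
                 reference = reference$strategy,
                 delta_cost = dc, delta_qaly = de, icer = icer,
                 wtp = wtp, nmb_at_wtp = wtp * de - dc,
                 dominance = dominance, cost_effective = cost_effective),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> %s vs %s\n", x$comparator, x$reference))
  cat(sprintf("  incremental cost:          %s yen\n",
              format(round(x$delta_cost), big.mark = ",")))
  cat(sprintf("  incremental effectiveness: %.6f QALY\n", x$delta_qaly))
  cat(sprintf("  ICER:                      %s yen/QALY\n",
              if (is.na(x$icer)) "undefined"
              else format(round(x$icer), big.mark = ",")))
  cat(sprintf("  NMB at %s yen/QALY: %s yen (%s; %scost-effective)\n",
              format(x$wtp, big.mark = ",", scientific = FALSE),
              format(round(x$nmb_at_wtp), big.mark = ","), x$dominance,
              if (x$cost_effective) "" else "not "))
  invisible(x)
}

#' Deterministic base-case analysis
#'
#' End-to-end run of the packaged model (or a user model) for one PBT fee
#' level: both arms are propagated through the cohort engine, costs and QALYs
#' accumulated, and PBT compared against 3D-CRT at the willingness-to-pay
#' threshold.
#'
#' @param fee_level `"rare"` (PBT fee 2,375,000 yen) or `"non_rare"`
#'   (1,600,000 yen).
#' @param model Optional `cea_model` overriding the packaged one (its first
#'   strategy is the comparator).
#' @param wtp Willingness-to-pay threshold; defaults to the model settings.
#' @return An object of class `cea_base_case`: `fee_level`, `model`,
#'   `outcomes` (list of two `cea_outcome`) and `result` (a `cea_result`).
#' @examples
#' run_base_case("rare")
#' @export
run_base_case <- function(fee_level = c("rare", "non_rare"), model = NULL,
                          wtp = NULL) {
  fee_level <- match.arg(fee_level)
  if (is.null(model)) model <- packaged_model(fee_level)
  if (is.null(wtp)) wtp <- model$settings$wtp_threshold
  arms <- strategy_ids(model)
  outcomes <- lapply(arms, function(a) run_strategy(model, a))
  names(outcomes) <- arms
  result <- compare_strategies(outcomes[[1]], outcomes[[2]], wtp)
  structure(list(fee_level = fee_level, model = model,
                 outcomes = outcomes, result = result),
            class = "cea_base_case")
}

#' @export
print.cea_base_case <- function(x, ...) {
  cat(sprintf("Base case (%s fee level)\n", x$fee_level))
  print(as_cea_table(x), row.names = FALSE)
  cat(sprintf("Verdict at %s yen/QALY: %s\n",
              format(x$result$wtp, big.mark = ",", scientific = FALSE),
              if (x$result$cost_effective) "cost-effective"
              else "not cost-effective"))
  invisible(x)
}

#' Base-case results as a publication-shaped table
#'
#' @param bc A `cea_base_case`.
#' @return A `data.frame` with one row per strategy and columns `strategy`,
#'   `cost_yen`, `incremental_cost_yen`, `effectiveness_qaly`,
#'   `incremental_effectiveness_qaly`, `icer_yen_per_qaly` (monetary values
#'   rounded to integer yen, QALYs to 4 decimals).
#' @export
as_cea_table <- function(bc) {
  stopifnot(inherits(bc, "cea_base_case"))
  o <- bc$outcomes; r <- bc$result
  data.frame(
    strategy = names(o),
    cost_yen = round(vapply(o, `[[`, 0, "total_cost")),
    incremental_cost_yen = c(round(r$delta_cost), NA),
    effectiveness_qaly = round(vapply(o, `[[`, 0, "total_qaly"), 4),
    incremental_effectiveness_qaly = c(round(r$delta_qaly, 4), NA),
    icer_yen_per_qaly = c(round(r$icer), NA),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Sweep accrual and costing conventions of the base case
#'
#' The original TreeAge implementation leaves several conventions
#' under-specified: how per-cycle rewards are weighted (state at cycle start,
#' at cycle end, or the half-cycle correction), whether discounting starts at
#' the first cycle, which utility the unpublished drainage/pericardiotomy
#' tunnel states carry, and whether the RP Grade 2 treatment cost stacks on
#' routine follow-up. This helper recomputes the full base case over the
#' cartesian grid of those choices so their impact can be inspected directly.
#'
#' @param fee_level Fee level of the base case.
#' @param drainage_utilities Candidate tunnel-state utilities.
#' @return A `data.frame` with one row per convention combination: the
#'   convention columns plus `cost_pbt`, `cost_3dcrt`, `qaly_pbt`,
#'   `qaly_3dcrt`, `delta_cost`, `delta_qaly`, `icer`.
#' @export
convention_sweep <- function(fee_level = c("rare", "non_rare"),
                             drainage_utilities = c(0.63, 0.57, 0.87)) {
  fee_level <- match.arg(fee_level)
  grid <- expand.grid(reward_timing = c("start", "end", "half"),
                      discount_timing = c("end", "start"),
                      drainage_utility = drainage_utilities,
                      rp_cost_stacking = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  params <- laec_parameters()
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    st <- model_settings(reward_timing = grid$reward_timing[i],
                         discount_timing = grid$discount_timing[i])
    m <- build_laec_model(params, fee_level,
                          drainage_utility = grid$drainage_utility[i],
                          rp_cost_stacking = grid$rp_cost_stacking[i],
                          settings = st)
    bc <- run_base_case(fee_level, model = m)
    data.frame(grid[i, , drop = FALSE],
               cost_pbt = bc$outcomes$PBT$total_cost,
               cost_3dcrt = bc$outcomes$`3DCRT`$total_cost,
               qaly_pbt = bc$outcomes$PBT$total_qaly,
               qaly_3dcrt = bc$outcomes$`3DCRT`$total_qaly,
               delta_cost = bc$result$delta_cost,
               delta_qaly = bc$result$delta_qaly,
               icer = bc$result$icer,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
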