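#' Write a model definition to a JSON configuration file
#'
#' Serialises every field of the model (states, transition rules, strategies,
#' settings, start state) to a structured JSON document at full numeric
#' precision, so that [read_model()] reproduces the model exactly.
#' Open-ended rule windows (`window_end = Inf`) are stored as `null`.
#'
#' @param model A `cea_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cea_model"))
  rules <- model$rules
  rules$window_end[!is.finite(rules$window_end)] <- NA_real_
  doc <- list(
    schema = "pbtcea-model/1",
    start_state = model$start_state,
    settings = unclass(model$settings),
    strategies = lapply(model$strategies, unclass),
    states = lapply(model$states, function(s) {
      s <- unclass(s)
      if (is.na(s$ae_family)) s$ae_family <- NULL
      if (is.na(s$ae_grade)) s$ae_grade <- NULL
      s
    }),
    rules = rules)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

# required scalar field, with informative error naming the key
.need <- function(x, key, where) {
  if (is.null(x[[key]]))
    stop(sprintf("model configuration is missing '%s' in %s", key, where),
         call. = FALSE)
  x[[key]]
}

.num1 <- function(x, key, where) {
  v <- .need(x, key, where)
  v <- suppressWarnings(as.numeric(v))
  if (length(v) != 1L || is.na(v))
    stop(sprintf("malformed number for '%s' in %s", key, where), call. = FALSE)
  v
}

#' Read a model definition from a JSON configuration file
#'
#' Inverse of [write_model()]: rebuilds the `cea_model` and validates it,
#' rejecting configurations with missing fields, unknown state references or
#' malformed numbers with an error naming the offending key.
#'
#' @param path Path to a configuration written by [write_model()] (or by
#'   hand in the same schema).
#' @return A validated `cea_model`.
#' @examples
#' f <- tempfile(fileext = ".json")
#' write_model(packaged_model("rare"), f)
#' m <- read_model(f)
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (key in c("start_state", "settings", "strategies", "states", "rules"))
    .need(doc, key, "the configuration root")

  st <- doc$settings
  settings <- model_settings(
    cycle_length_months = .num1(st, "cycle_length_months", "settings"),
    horizon_cycles = .num1(st, "horizon_cycles", "settings"),
    annual_discount_rate = .num1(st, "annual_discount_rate", "settings"),
    wtp_threshold = .num1(st, "wtp_threshold", "settings"),
    followup_cost_year1 = .num1(st, "followup_cost_year1", "settings"),
    followup_cost_later = .num1(st, "followup_cost_later", "settings"),
    reward_timing = .need(st, "reward_timing", "settings"),
    discount_timing = .need(st, "discount_timing", "settings"))

  states <- lapply(names(doc$states), function(id) {
    s <- doc$states[[id]]
    health_state(
      id = .need(s, "id", sprintf("state '%s'", id)),
      label = .need(s, "label", sprintf("state '%s'", id)),
      utility = .num1(s, "utility", sprintf("state '%s'", id)),
      entry_cost = .num1(s, "entry_cost", sprintf("state '%s'", id)),
      cost_cycle_year1 = .num1(s, "cost_cycle_year1", sprintf("state '%s'", id)),
      cost_cycle_later = .num1(s, "cost_cycle_later", sprintf("state '%s'", id)),
      accrues_followup = isTRUE(.need(s, "accrues_followup",
                                      sprintf("state '%s'", id))),
      residual_target = .need(s, "residual_target", sprintf("state '%s'", id)),
      is_absorbing = isTRUE(s$is_absorbing),
      is_terminal_care = isTRUE(s$is_terminal_care),
      ae_family = if (is.null(s$ae_family)) NA_character_ else s$ae_family,
      ae_grade = if (is.null(s$ae_grade)) NA_integer_ else as.integer(s$ae_grade))
  })

  strategies <- lapply(names(doc$strategies), function(id) {
    s <- doc$strategies[[id]]
    strategy_definition(.need(s, "id", sprintf("strategy '%s'", id)),
                        .num1(s, "upfront_cost", sprintf("strategy '%s'", id)))
  })

  r <- doc$rules
  for (key in c("strategy", "from", "to", "probability", "window_start",
                "window_end"))
    if (is.null(r[[key]]))
      stop(sprintf("model configuration is missing '%s' in rules", key),
           call. = FALSE)
  if (any(is.na(suppressWarnings(as.numeric(r$probability)))))
    stop("malformed number for 'probability' in rules", call. = FALSE)
  rules <- data.frame(strategy = as.character(r$strategy),
                      from = as.character(r$from),
                      to = as.character(r$to),
                      probability = as.numeric(r$probability),
                      window_start = as.numeric(r$window_start),
                      window_end = as.numeric(r$window_end),
                      stringsAsFactors = FALSE)
  rules$window_end[is.na(rules$window_end)] <- Inf

  m <- model_definition(states, rules, strategies, settings,
                        start_state = doc$start_state)
  viol <- validate_model(m)
  if (nrow(viol))
    stop("configuration at '", path, "' is not a valid model: ",
         paste(sprintf("[%s] %s", viol$entity, viol$message), collapse = "; "),
         call. = FALSE)
  m
}
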