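#' Write base-case outputs to a directory
#'
#' Writes the publication-shaped strategy table (`base_case.csv`), the full
#' result bundle (`base_case.json`) and a run manifest.
#'
#' @param bc A `cea_base_case`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_base_case <- function(bc, dir) {
  stopifnot(inherits(bc, "cea_base_case"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as_cea_table(bc), file.path(dir, "base_case.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(fee_level = bc$fee_level,
         outcomes = lapply(bc$outcomes, function(o)
           o[c("strategy", "total_cost", "total_qaly", "undiscounted_ly")]),
         result = unclass(bc$result)),
    file.path(dir, "base_case.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(dir, analysis = "base_case", fee_level = bc$fee_level,
                 settings = unclass(bc$model$settings))
  invisible(dir)
}

#' Write one-way sensitivity outputs to a directory
#'
#' @param owsa A `cea_owsa`.
#' @param dir Output directory.
#' @return The directory path, invisibly.
#' @export
write_owsa <- function(owsa, dir) {
  stopifnot(inherits(owsa, "cea_owsa"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(owsa), file.path(dir, "tornado.csv"),
                   row.names = FALSE)
  write_manifest(dir, analysis = "owsa", fee_level = attr(owsa, "fee_level"),
                 icer_base = attr(owsa, "icer_base"))
  invisible(dir)
}

#' Write probabilistic sensitivity outputs to a directory
#'
#' Writes the draw-level table (`psa_draws.csv`), the acceptability curve
#' (`ceac.csv`) and a manifest recording the seed and the at-threshold
#' probability.
#'
#' @param psa A `cea_psa`.
#' @param dir Output directory.
#' @return The directory path, invisibly.
#' @export
write_psa <- function(psa, dir) {
  stopifnot(inherits(psa, "cea_psa"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(psa$draws, file.path(dir, "psa_draws.csv"),
                   row.names = FALSE)
  utils::write.csv(psa$ceac, file.path(dir, "ceac.csv"), row.names = FALSE)
  write_manifest(dir, analysis = "psa", fee_level = psa$fee_level,
                 seed = psa$seed, n_draws = psa$n_draws,
                 rel_width = psa$rel_width,
                 shared_probabilities = psa$shared_probabilities,
                 prob_ce_at_threshold = psa$prob_ce_at_threshold)
  invisible(dir)
}

#' Write a run manifest
#'
#' Records, next to every analysis output, what produced it: package version,
#' timestamp, and the analysis parameters passed as `...`.
#'
#' @param dir Output directory.
#' @param ... Named fields to record.
#' @return Path of the manifest file, invisibly.
#' @export
write_manifest <- function(dir, ...) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    c(list(package = "pbtcea",
           version = as.character(utils::packageVersion("pbtcea")),
           r_version = as.character(getRversion()),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      list(...)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
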