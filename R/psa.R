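#' Triangular random draws
#'
#' Inverse-CDF sampler for the triangular distribution with lower limit `a`,
#' mode `m` and upper limit `b` (mean `(a + m + b) / 3`). Degenerate
#' distributions (`a == b`) return the mode.
#'
#' @param n Number of draws.
#' @param a,m,b Lower limit, mode, upper limit (`a <= m <= b`).
#' @return Numeric vector of length `n`.
#' @export
rtriangular <- function(n, a, m, b) {
  stopifnot(a <= m, m <= b)
  if (a == b) return(rep(m, n))
  u <- stats::runif(n)
  f <- (m - a) / (b - a)
  ifelse(u < f,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

# triangular draw around base value b with relative half-width w
.tri_rel <- function(b, w) {
  if (b == 0) return(0)
  rtriangular(1, (1 - w) * b, b, (1 + w) * b)
}

# utility family ids and grades of the registry
.utility_families <- function(params) {
  idx <- which(params$kind == "utility" & !is.na(params$family))
  split(idx, params$family[idx])
}

#' Sample one probabilistic-sensitivity-analysis parameter set
#'
#' Draws every registry scalar from a triangular distribution with mode at
#' its base value and limits at `+/- rel_width` (the published procedure uses
#' 20%). Utilities and costs are drawn once and applied to both arms;
#' transition-probability cells are drawn independently per arm, because each
#' probability row of the parameter table carries a separate cell per arm
#' (`shared_probabilities = TRUE` restores a single draw for rows whose two
#' cells are equal). Cells at the structural boundaries 0 and 1 are
#' certainties and are not sampled. Utilities are clamped at 1 and the grade
#' ordering within each adverse-event family is enforced by redrawing the
#' family (up to `max_retries`), falling back to sorting the drawn values;
#' a draw pushing any outgoing row sum above 1 is redrawn the same way, with
#' proportional rescaling as the deterministic fallback. Fallbacks are
#' flagged, not silent.
#'
#' @param params Registry `data.frame` (see [laec_parameters()]).
#' @param rel_width Relative half-width of the triangular distributions.
#' @param shared_probabilities Draw equal probability cells jointly?
#' @param fee_level Fee level used when checking row-sum feasibility.
#' @param max_retries Bounded number of redraws per constraint.
#' @return List with `params` (the sampled registry), and logical flags
#'   `utility_sorted` and `rows_rescaled` recording constraint fallbacks.
#' @export
sample_parameters <- function(params = laec_parameters(), rel_width = 0.2,
                              shared_probabilities = FALSE,
                              fee_level = "rare", max_retries = 100) {
  base <- params
  flags <- list(utility_sorted = FALSE, rows_rescaled = FALSE)

  draw_utilities <- function(p) {
    for (i in which(p$kind == "utility" & p$perturbable)) {
      v <- min(.tri_rel(base$x3dcrt[i], rel_width), 1)
      p$pbt[i] <- v; p$x3dcrt[i] <- v
    }
    p
  }
  fam_ok <- function(p, idx) {
    o <- order(p$grade[idx])
    !is.unsorted(rev(p$x3dcrt[idx][o]))
  }
  draw_probs <- function(p) {
    for (i in which(p$kind == "probability" & p$perturbable)) {
      for (col in c("pbt", "x3dcrt")) {
        b <- base[[col]][i]
        if (b <= 0 || b >= 1) next  # structural certainty, not sampled
        if (shared_probabilities && identical(base$pbt[i], base$x3dcrt[i])) {
          if (col == "x3dcrt") { p$x3dcrt[i] <- p$pbt[i]; next }
        }
        p[[col]][i] <- min(.tri_rel(b, rel_width), 1)
      }
    }
    p
  }

  # utilities: family-wise redraw until grade-monotone, then sort fallback
  sampled <- draw_utilities(base)
  for (idx in .utility_families(params)) {
    tries <- 0
    while (!fam_ok(sampled, idx) && tries < max_retries) {
      for (i in idx) {
        v <- min(.tri_rel(base$x3dcrt[i], rel_width), 1)
        sampled$pbt[i] <- v; sampled$x3dcrt[i] <- v
      }
      tries <- tries + 1
    }
    if (!fam_ok(sampled, idx)) {
      o <- order(sampled$grade[idx])
      v <- sort(sampled$x3dcrt[idx], decreasing = TRUE)
      sampled$x3dcrt[idx][o] <- v
      sampled$pbt[idx][o] <- v
      flags$utility_sorted <- TRUE
    }
  }

  for (i in which(params$kind == "cost" & params$perturbable)) {
    v <- .tri_rel(base$x3dcrt[i], rel_width)
    sampled$pbt[i] <- v; sampled$x3dcrt[i] <- v
  }

  # probabilities: redraw whole block while any outgoing row sum of the
  # packaged structure would exceed 1 (checked directly on the registry:
  # onset row, recovery rows and tunnel rows each plus the BSC hazard)
  rows_ok <- function(p) {
    v <- function(id, col) p[[col]][match(id, p$param_id)]
    onset_ids <- .laec_onsets()$param_id
    for (col in c("pbt", "x3dcrt")) {
      h <- v("p_any_to_bsc", col)
      sums <- c(sum(vapply(onset_ids, v, 0, col = col)),
                v("p_rp_g3_to_rp_g2", col), v("p_rp_g2_to_rp_g1", col),
                v("p_pce_g3_to_drainage", col), v("p_drainage_to_pce_g2", col))
      if (any(sums + h > 1 + 1e-12)) return(FALSE)
    }
    TRUE
  }
  sampled <- draw_probs(sampled)
  tries <- 0
  while (!rows_ok(sampled) && tries < max_retries) {
    sampled <- draw_probs(sampled)
    tries <- tries + 1
  }
  if (!rows_ok(sampled)) {
    # deterministic fallback: cap every sampled probability at its base
    # value, which reproduces at most the base row sums (all feasible)
    pi <- which(sampled$kind == "probability")
    sampled$pbt[pi] <- pmin(sampled$pbt[pi], base$pbt[pi])
    sampled$x3dcrt[pi] <- pmin(sampled$x3dcrt[pi], base$x3dcrt[pi])
    flags$rows_rescaled <- TRUE
  }
  c(list(params = sampled), flags)
}

#' One probabilistic draw as a standalone model
#'
#' @inheritParams sample_parameters
#' @return A validated `cea_model` built from one sampled parameter set.
#' @export
sample_draw <- function(params = laec_parameters(),
                        fee_level = c("rare", "non_rare"), rel_width = 0.2,
                        shared_probabilities = FALSE) {
  fee_level <- match.arg(fee_level)
  s <- sample_parameters(params, rel_width, shared_probabilities, fee_level)
  m <- build_laec_model(s$params, fee_level)
  attr(m, "psa_flags") <- s[c("utility_sorted", "rows_rescaled")]
  m
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: per draw, one parameter
#' set is sampled (see [sample_parameters()]), both arms are evaluated on it,
#' and the incremental cost and effectiveness are recorded. The master seed
#' spawns one sub-seed per draw, so increasing `n_draws` extends the draw
#' sequence without changing earlier draws.
#'
#' @param fee_level Fee level of the base case.
#' @param n_draws Number of Monte Carlo draws.
#' @param seed Master seed (recorded in the result).
#' @param params Registry to sample around.
#' @param rel_width Relative half-width of the triangular distributions.
#' @param shared_probabilities See [sample_parameters()].
#' @param wtp_grid Willingness-to-pay grid for the acceptability curve.
#' @return An object of class `cea_psa`: `fee_level`, `seed`, `n_draws`,
#'   `draws` (`data.frame` with `draw`, `delta_cost`, `delta_qaly`, `icer`,
#'   fallback flags), `ceac` (`data.frame` `wtp`, `probability`),
#'   `prob_ce_at_threshold` and the threshold used.
#' @examples
#' \donttest{run_psa("non_rare", n_draws = 100, seed = 1)}
#' @export
run_psa <- function(fee_level = c("rare", "non_rare"), n_draws = 1000,
                    seed = 20240927, params = laec_parameters(),
                    rel_width = 0.2, shared_probabilities = FALSE,
                    wtp_grid = seq(0, 2e7, by = 5e5)) {
  fee_level <- match.arg(fee_level)
  stopifnot(n_draws >= 1)
  wtp <- 7.5e6
  if (!wtp %in% wtp_grid) wtp_grid <- sort(c(wtp_grid, wtp))
  set.seed(seed)
  draw_seeds <- sample.int(.Machine$integer.max, n_draws, replace = TRUE)
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    set.seed(draw_seeds[i])
    s <- sample_parameters(params, rel_width, shared_probabilities, fee_level)
    # constraints hold by construction here, so the build skips revalidation
    m <- build_laec_model(s$params, fee_level, validate = FALSE)
    env <- .state_env(m)
    a <- .eval_strategy(m, "PBT", env)
    b <- .eval_strategy(m, "3DCRT", env)
    dc <- a$total_cost - b$total_cost
    de <- a$total_qaly - b$total_qaly
    rows[[i]] <- data.frame(draw = i, delta_cost = dc, delta_qaly = de,
                            icer = if (de == 0) NA_real_ else dc / de,
                            utility_sorted = s$utility_sorted,
                            rows_rescaled = s$rows_rescaled)
  }
  draws <- do.call(rbind, rows)
  cc <- ceac(draws, wtp_grid)
  structure(list(fee_level = fee_level, seed = seed, n_draws = n_draws,
                 rel_width = rel_width,
                 shared_probabilities = shared_probabilities,
                 draws = draws, ceac = cc, wtp_threshold = wtp,
                 prob_ce_at_threshold =
                   cc$probability[match(wtp, cc$wtp)]),
            class = "cea_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of draws with positive net monetary benefit at each
#' willingness-to-pay value. When incremental effectiveness is positive in
#' every draw this equals the fraction of draws whose ICER lies below the
#' threshold.
#'
#' @param draws A `cea_psa` object or its `draws` data frame.
#' @param wtp_grid Willingness-to-pay values (yen/QALY).
#' @return `data.frame` with columns `wtp` and `probability`.
#' @export
ceac <- function(draws, wtp_grid = seq(0, 2e7, by = 5e5)) {
  if (inherits(draws, "cea_psa")) draws <- draws$draws
  stopifnot(nrow(draws) > 0)
  data.frame(wtp = wtp_grid,
             probability = vapply(wtp_grid, function(w)
               mean(w * draws$delta_qaly - draws$delta_cost > 0), numeric(1)))
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("<cea_psa> %s fee level, %d draws (seed %s)\n",
              x$fee_level, x$n_draws, format(x$seed)))
  cat(sprintf("  P(cost-effective at %s yen/QALY) = %.3f\n",
              format(x$wtp_threshold, big.mark = ",", scientific = FALSE),
              x$prob_ce_at_threshold))
  cat(sprintf("  delta QALY: median %.4f [IQR %.4f, %.4f]; %.1f%% of draws with loss\n",
              stats::median(x$draws$delta_qaly),
              stats::quantile(x$draws$delta_qaly, 0.25),
              stats::quantile(x$draws$delta_qaly, 0.75),
              100 * mean(x$draws$delta_qaly < 0)))
  invisible(x)
}

#' Plot a cost-effectiveness acceptability curve
#'
#' @param psa A `cea_psa` (or a list of them for overlayed curves).
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_ceac <- function(psa) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_ceac requires ggplot2", call. = FALSE)
  if (inherits(psa, "cea_psa")) psa <- list(psa)
  df <- do.call(rbind, lapply(psa, function(p)
    data.frame(fee_level = p$fee_level, p$ceac)))
  ggplot2::ggplot(df, ggplot2::aes(.data$wtp, .data$probability,
                                   colour = .data$fee_level)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 7.5e6, linetype = 2) +
    ggplot2::labs(x = "Willingness to pay (yen/QALY)",
                  y = "Probability cost-effective")
}
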