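# Scenario definitions: national vs per-ED scope, partial adoption, and the
# COPD admission-reduction sensitivity analysis.

#' Define a simulation scenario
#'
#' @param scope `"national"` (the default) or `"ed"` for a single emergency
#'   department with `ed_visits` annual visits.
#' @param ed_visits Annual ED visit volume (> 0); required when
#'   `scope = "ed"`, disallowed otherwise. The published ED sizes are
#'   30,000 (small), 80,000 (medium), and 130,000 (large) visits/year.
#' @param adoption_rate Fraction of eligible nebulizer visits switched to
#'   BAN, in `(0, 1]`. All intervention deltas scale linearly with it.
#' @param copd_reduction Optional replacement for the COPD
#'   admission-reduction parameter's mean (row `S`), in `[0, 1]`; its SD is
#'   rescaled proportionally. The published sensitivity analysis attenuates
#'   the base 0.456 to 0.228 and 0.137.
#' @return A `ban_scenario` object.
#' @examples
#' ban_scenario()
#' ban_scenario("ed", ed_visits = 30000)
#' ban_scenario(adoption_rate = 0.25, copd_reduction = 0.137)
#' @export
ban_scenario <- function(scope = c("national", "ed"), ed_visits = NULL,
                         adoption_rate = 1, copd_reduction = NULL) {
  scope <- match.arg(scope)
  if (scope == "ed") {
    if (is.null(ed_visits) || !is.numeric(ed_visits) || ed_visits <= 0) {
      stop("`ed_visits` must be a positive number when scope = \"ed\"")
    }
  } else if (!is.null(ed_visits)) {
    stop("`ed_visits` is only meaningful when scope = \"ed\"")
  }
  if (!is.numeric(adoption_rate) || adoption_rate <= 0 || adoption_rate > 1) {
    stop("`adoption_rate` must be in (0, 1], got ", adoption_rate)
  }
  if (!is.null(copd_reduction) &&
      (copd_reduction < 0 || copd_reduction > 1)) {
    stop("`copd_reduction` must be in [0, 1], got ", copd_reduction)
  }
  structure(list(scope = scope, ed_visits = ed_visits,
                 adoption_rate = adoption_rate,
                 copd_reduction = copd_reduction),
            class = "ban_scenario")
}

#' @export
print.ban_scenario <- function(x, ...) {
  cat("<ban_scenario> ", scenario_label(x), "\n", sep = "")
  invisible(x)
}

scenario_label <- function(s) {
  paste0(if (s$scope == "national") "national"
         else paste0("ed_", format(s$ed_visits, scientific = FALSE)),
         "; adoption ", s$adoption_rate,
         if (!is.null(s$copd_reduction))
           paste0("; copd_reduction ", s$copd_reduction))
}

#' Scale national outcomes to a single ED
#'
#' A department seeing `ed_visits` annual visits with the national case mix
#' receives the fraction `ed_visits / (A + B)` of national adult plus
#' pediatric ED volume, so every cohort-total outcome scales by that factor.
#' The factor uses the draw's *realized* visit volumes, so per-ED outcome
#' SDs inherit the national volume uncertainty. The per-unit device price
#' difference is left unscaled.
#'
#' @param outcomes Named outcome vector from [compute_outcomes()].
#' @param ed_visits Annual ED visit volume, > 0.
#' @param draw The parameter draw the outcomes were computed from.
#' @return Scaled outcome vector.
#' @export
scale_to_ed <- function(outcomes, ed_visits, draw) {
  if (ed_visits <= 0) stop("`ed_visits` must be > 0")
  f <- ed_visits / (draw[["A"]] + draw[["B"]])
  sc <- scalable_outcomes()
  outcomes[sc] <- outcomes[sc] * f
  outcomes
}

#' Apply a partial adoption rate to outcomes
#'
#' BAN effects accrue only to adopting visits and non-adopters contribute
#' zero delta, so every cohort-total outcome — units, supply cost, averted
#' admissions, savings, bed-hours — is multiplied by the adoption rate. The
#' per-unit price difference is unchanged.
#'
#' @param outcomes Named outcome vector from [compute_outcomes()].
#' @param rate Adoption fraction in `(0, 1]`.
#' @return Scaled outcome vector.
#' @export
apply_adoption <- function(outcomes, rate) {
  if (rate <= 0 || rate > 1) stop("adoption `rate` must be in (0, 1]")
  if (rate == 1) return(outcomes)
  sc <- scalable_outcomes()
  outcomes[sc] <- outcomes[sc] * rate
  outcomes
}

#' Attenuate the COPD admission-reduction parameter
#'
#' Returns a copy of the table with row `S`'s mean replaced by `target_s`
#' and its SD rescaled to preserve the SD/mean ratio; all other rows are
#' untouched.
#'
#' @param table A `ban_parameter_table`.
#' @param target_s New mean for the COPD admission-reduction proportion,
#'   in `[0, 1]`.
#' @return A new `ban_parameter_table`.
#' @examples
#' apply_copd_reduction(default_parameter_table(), 0.137)[18, ]
#' @export
apply_copd_reduction <- function(table, target_s) {
  if (!is.numeric(target_s) || target_s < 0 || target_s > 1) {
    stop("`target_s` must be in [0, 1], got ", target_s)
  }
  i <- which(table$label == "S")
  if (length(i) != 1L) stop("table has no unique row with label S")
  ratio <- if (table$mean[i] > 0) table$sd[i] / table$mean[i] else 0
  table$mean[i] <- target_s
  table$sd[i] <- target_s * ratio
  table
}

#' Run the full published scenario grid
#'
#' One Monte Carlo summary per cell family of the published report tables:
#' the base case and both sensitivity analyses (COPD admission-reduction in
#' {0.456, 0.228, 0.137}; adoption in {0.25, 0.5, 0.75, 1}), each at
#' national scope and at the three ED sizes (30,000 / 80,000 / 130,000
#' visits/year).
#'
#' @param table Parameter table (default: the packaged table).
#' @param seed Master seed; each cell uses a sub-seed derived from it.
#' @param n_iterations Iterations per cell (default 1000).
#' @return A named list of [run_simulation()] summaries, keyed by scenario
#'   label.
#' @export
standard_report_suite <- function(table = default_parameter_table(),
                                  seed = 20250404L, n_iterations = 1000L) {
  scopes <- list(list(scope = "national", ed_visits = NULL),
                 list(scope = "ed", ed_visits = 30000),
                 list(scope = "ed", ed_visits = 80000),
                 list(scope = "ed", ed_visits = 130000))
  cells <- list()
  for (sc in scopes) {
    for (s_target in c(NA, 0.456, 0.228, 0.137)) {
      cells[[length(cells) + 1L]] <- ban_scenario(
        sc$scope, sc$ed_visits,
        copd_reduction = if (is.na(s_target)) NULL else s_target)
    }
    for (rate in c(0.25, 0.5, 0.75)) {
      cells[[length(cells) + 1L]] <- ban_scenario(
        sc$scope, sc$ed_visits, adoption_rate = rate)
    }
  }
  sub_seeds <- derive_seeds(seed, length(cells))
  out <- list()
  for (i in seq_along(cells)) {
    sim <- run_simulation(table, n_iterations = n_iterations,
                          seed = sub_seeds[i], scenario = cells[[i]])
    out[[scenario_label(cells[[i]])]] <- sim
  }
  out
}
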