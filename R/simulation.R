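# Seeded Monte Carlo engine. One master seed deterministically spawns one
# sub-seed per iteration; within an iteration parameters are sampled in
# alphabetical label order. Results are therefore invariant to how
# iterations might be batched and to the serialization order of the table.

derive_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed",
                                                  envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max, n, replace = TRUE)
}

sampling_bounds <- function(units) {
  if (identical(units, "proportion")) c(0, 1) else c(0, Inf)
}

#' Draw one joint parameter realization
#'
#' Samples every parameter independently from its family: clipped normal
#' (proportions clipped to `[0, 1]`, volumes/costs/durations to
#' `[0, Inf)`), BetaPERT, moment-matched lognormal, or point. Labels are
#' sampled in alphabetical order regardless of row order in the table, and
#' draws come from R's global RNG stream, so `set.seed()` before the call
#' fixes the draw.
#'
#' @param table A validated `ban_parameter_table`.
#' @return Named numeric vector over the table's labels (alphabetical).
#' @examples
#' set.seed(1)
#' draw_parameters(default_parameter_table())
#' @export
draw_parameters <- function(table) {
  ord <- order(table$label)
  vals <- numeric(nrow(table))
  labs <- character(nrow(table))
  for (k in seq_along(ord)) {
    r <- table[ord[k], ]
    b <- sampling_bounds(r$units)
    vals[k] <- switch(r$dist_family,
      normal = sample_normal(1L, r$mean, r$sd, lower = b[1], upper = b[2]),
      lognormal = sample_lognormal_from_moments(1L, r$mean, r$sd),
      betapert = sample_betapert(1L, r$min, r$mode, r$max),
      point = r$mean,
      stop("unknown dist_family '", r$dist_family, "'"))
    labs[k] <- r$label
  }
  stats::setNames(vals, labs)
}

#' Run the Monte Carlo simulation
#'
#' For each iteration: seed the RNG with the iteration's sub-seed, draw all
#' parameters, evaluate the outcome model under `scenario`, and record every
#' outcome. The scenario's `copd_reduction`, if set, is applied to the table
#' before any sampling. Deterministic given `(table, n_iterations, seed,
#' scenario)`.
#'
#' @param table A `ban_parameter_table`.
#' @param n_iterations Number of iterations, `>= 1` (default 1000, the
#'   published run size).
#' @param seed Master seed (integer).
#' @param scenario A [ban_scenario()].
#' @param keep_iterations Retain the per-iteration outcome matrix in the
#'   result (`$iterations`) for export and audit.
#' @param los_rule Passed to [net_bed_hours()].
#' @return A `ban_simulation` object: list with `summary` (data frame with
#'   per-outcome `mean`, `sd`, `q2.5`, `q50`, `q97.5`), `n_iterations`,
#'   `seed`, `scenario`, and optionally `iterations`.
#' @examples
#' sim <- run_simulation(default_parameter_table(), n_iterations = 100,
#'                       seed = 42)
#' sim$summary[sim$summary$outcome == "savings_total", ]
#' @export
run_simulation <- function(table, n_iterations = 1000L, seed = 20250404L,
                           scenario = ban_scenario(),
                           keep_iterations = FALSE,
                           los_rule = "discharged_only") {
  if (!inherits(scenario, "ban_scenario")) {
    stop("`scenario` must be created with ban_scenario()")
  }
  if (n_iterations < 1L) stop("`n_iterations` must be >= 1")
  if (!is.null(scenario$copd_reduction)) {
    table <- apply_copd_reduction(table, scenario$copd_reduction)
  }
  assert_valid_parameter_table(table)

  seeds <- derive_seeds(seed, n_iterations)
  records <- matrix(NA_real_, nrow = n_iterations,
                    ncol = length(outcome_names()),
                    dimnames = list(NULL, outcome_names()))
  for (i in seq_len(n_iterations)) {
    set.seed(seeds[i])
    draw <- draw_parameters(table)
    records[i, ] <- compute_outcomes(draw, scenario, los_rule = los_rule)
  }
  structure(list(summary = summarize_iterations(records),
                 n_iterations = n_iterations, seed = seed,
                 scenario = scenario,
                 iterations = if (keep_iterations) as.data.frame(records)),
            class = "ban_simulation")
}

#' Summarize per-iteration outcome records
#'
#' Sample mean, sample SD (`n - 1` denominator), and 2.5% / 50% / 97.5%
#' quantiles per outcome. Quantiles use R's default type-7 linear
#' interpolation. A single record yields SD 0 with a `degenerate` flag.
#'
#' @param records Matrix or data frame, one row per iteration, one column
#'   per outcome; at least one row.
#' @return Data frame with columns `outcome`, `mean`, `sd`, `q2.5`, `q50`,
#'   `q97.5`, `degenerate`.
#' @examples
#' summarize_iterations(cbind(x = c(2, 4, 6)))
#' @export
summarize_iterations <- function(records) {
  records <- as.matrix(records)
  if (nrow(records) < 1L) stop("at least one iteration record is required")
  degenerate <- nrow(records) == 1L
  sds <- if (degenerate) rep(0, ncol(records)) else apply(records, 2,
                                                          stats::sd)
  qs <- apply(records, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE, type = 7)
  data.frame(outcome = colnames(records),
             mean = colMeans(records),
             sd = unname(sds),
             q2.5 = qs[1, ], q50 = qs[2, ], q97.5 = qs[3, ],
             degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Extract one outcome's summary statistic
#'
#' Convenience accessor for `sim$summary`.
#'
#' @param sim A `ban_simulation`.
#' @param outcome An element of [outcome_names()].
#' @param stat One of `"mean"`, `"sd"`, `"q2.5"`, `"q50"`, `"q97.5"`.
#' @return A single number.
#' @export
outcome_stat <- function(sim, outcome, stat = "mean") {
  i <- match(outcome, sim$summary$outcome)
  if (is.na(i)) stop("unknown outcome '", outcome, "'")
  sim$summary[[stat]][i]
}

#' @export
print.ban_simulation <- function(x, ...) {
  cat("<ban_simulation> ", x$n_iterations, " iterations, seed ", x$seed,
      ", scenario: ", scenario_label(x$scenario), "\n", sep = "")
  print(x$summary, ...)
  invisible(x)
}

#' Write per-iteration outcomes to a delimited file
#'
#' @param sim A `ban_simulation` run with `keep_iterations = TRUE`.
#' @param path Output CSV path (one row per iteration, one column per
#'   outcome).
#' @return `path`, invisibly.
#' @export
write_iterations <- function(sim, path) {
  if (is.null(sim$iterations)) {
    stop("simulation was run without `keep_iterations = TRUE`")
  }
  utils::write.csv(sim$iterations, path, row.names = FALSE)
  invisible(path)
}
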