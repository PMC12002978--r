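# Report rendering: "mean (+/-SD)" cells at the granularity the published
# tables use, alongside the raw machine-readable values (never rounded).

outcome_kind <- function(outcome) {
  if (outcome == "marginal_cost_per_unit") return("dollars_per_unit")
  if (grepl("savings|cost", outcome)) return("dollars")
  if (outcome == "net_bed_hours") return("bed_hours")
  if (grepl("^averted_", outcome)) return("admissions")
  "units"
}

#' Rounding profile for a report scope
#'
#' National reports round units to the nearest 10, dollars to the nearest
#' $1,000, and bed-hours to the nearest 1,000, with SDs at the same
#' granularity; per-ED reports round means for dollars to the nearest $100
#' and bed-hours to the nearest 10, with SDs one decade finer (so a $258.7
#' SD renders as ±$260, matching the granularity convention of per-ED
#' budget tables). Averted admissions round to whole visits and the
#' per-unit price difference to cents in both profiles.
#'
#' @param scope `"national"` or `"ed"`.
#' @return List with per-outcome-kind granularities under `mean`, and the
#'   divisor applied to them for SDs under `sd_divisor`.
#' @export
rounding_profile <- function(scope = c("national", "ed")) {
  scope <- match.arg(scope)
  if (scope == "national") {
    list(mean = list(units = 10, dollars = 1000, bed_hours = 1000,
                     admissions = 1, dollars_per_unit = 0.01),
         sd_divisor = 1)
  } else {
    list(mean = list(units = 10, dollars = 100, bed_hours = 10,
                     admissions = 1, dollars_per_unit = 0.01),
         sd_divisor = 10)
  }
}

sd_granularity <- function(profile, kind) {
  floor_g <- if (kind == "dollars_per_unit") 0.01 else 1
  max(profile$mean[[kind]] / profile$sd_divisor, floor_g)
}

round_to <- function(x, granularity) round(x / granularity) * granularity

format_quantity <- function(x, kind, granularity) {
  v <- round_to(x, granularity)
  digits <- if (granularity < 1) 2L else 0L
  s <- formatC(v, format = "f", digits = digits, big.mark = ",")
  if (kind %in% c("dollars", "dollars_per_unit")) {
    if (v < 0) paste0("-$", sub("^-", "", s)) else paste0("$", s)
  } else {
    s
  }
}

#' Render a simulation summary as publication-style table rows
#'
#' Produces one `"mean (+/-SD)"` cell per outcome at the scope's rounding
#' granularity while retaining the raw unrounded mean and SD, so the
#' machine-readable columns lose no information. A negative marginal supply
#' cost (comparator dearer than BAN) is flagged in a `note` column.
#'
#' @param sim A `ban_simulation`.
#' @param profile A [rounding_profile()]; defaults to the profile matching
#'   the simulation's scenario scope.
#' @return Data frame with columns `outcome`, `rendered`, `mean`, `sd`,
#'   `note`.
#' @examples
#' sim <- run_simulation(default_parameter_table(), n_iterations = 100,
#'                       seed = 1)
#' render_summary(sim)
#' @export
render_summary <- function(sim, profile = NULL) {
  if (is.null(profile)) profile <- rounding_profile(sim$scenario$scope)
  s <- sim$summary
  rows <- lapply(seq_len(nrow(s)), function(i) {
    kind <- outcome_kind(s$outcome[i])
    rendered <- paste0(
      format_quantity(s$mean[i], kind, profile$mean[[kind]]),
      " (±", format_quantity(s$sd[i], kind, sd_granularity(profile, kind)),
      ")")
    note <- if (s$outcome[i] == "marginal_supply_cost" && s$mean[i] < 0) {
      "negative: comparator price exceeds BAN price"
    } else {
      ""
    }
    data.frame(outcome = s$outcome[i], rendered = rendered,
               mean = s$mean[i], sd = s$sd[i], note = note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flatten a report suite into one delimited table
#'
#' One row per scenario x outcome, with the scenario descriptor, raw
#' summary statistics, and the rendered cell.
#'
#' @param suite Output of [standard_report_suite()].
#' @return Data frame with columns `scenario`, `scope`, `ed_visits`,
#'   `adoption_rate`, `copd_reduction`, `outcome`, `mean`, `sd`, `q2.5`,
#'   `q50`, `q97.5`, `rendered`.
#' @export
flatten_report_suite <- function(suite) {
  rows <- lapply(names(suite), function(key) {
    sim <- suite[[key]]
    sc <- sim$scenario
    rendered <- render_summary(sim)
    cbind(data.frame(scenario = key, scope = sc$scope,
                     ed_visits = if (is.null(sc$ed_visits)) NA_real_
                       else sc$ed_visits,
                     adoption_rate = sc$adoption_rate,
                     copd_reduction = if (is.null(sc$copd_reduction))
                       NA_real_ else sc$copd_reduction,
                     stringsAsFactors = FALSE),
          sim$summary[, c("outcome", "mean", "sd", "q2.5", "q50", "q97.5")],
          rendered = rendered$rendered)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

simulation_to_list <- function(sim) {
  list(seed = sim$seed, n_iterations = sim$n_iterations,
       scenario = list(scope = sim$scenario$scope,
                       ed_visits = sim$scenario$ed_visits,
                       adoption_rate = sim$scenario$adoption_rate,
                       copd_reduction = sim$scenario$copd_reduction),
       summary = lapply(seq_len(nrow(sim$summary)), function(i) {
         as.list(sim$summary[i, c("outcome", "mean", "sd", "q2.5", "q50",
                                  "q97.5")])
       }))
}

#' Write a simulation summary to disk
#'
#' @param sim A `ban_simulation`.
#' @param path Output path.
#' @param format `"delimited"` (CSV of the summary data frame plus rendered
#'   cells) or `"structured"` (YAML with seed, iteration count, scenario
#'   descriptor, and per-outcome statistics).
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path, format = c("delimited",
                                                   "structured")) {
  format <- match.arg(format)
  if (format == "delimited") {
    out <- cbind(sim$summary[, c("outcome", "mean", "sd", "q2.5", "q50",
                                 "q97.5")],
                 rendered = render_summary(sim)$rendered,
                 seed = sim$seed, n_iterations = sim$n_iterations,
                 scenario = scenario_label(sim$scenario))
    utils::write.csv(out, path, row.names = FALSE)
  } else {
    yaml::write_yaml(simulation_to_list(sim), path, precision = 15L)
  }
  invisible(path)
}
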