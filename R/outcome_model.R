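# Deterministic per-draw arithmetic of the budget-impact model. A "draw" is
# one joint realization of all 22 parameters as a named numeric vector.
# Every outcome is a multilinear polynomial in the draw values, so the
# expectation of each outcome under independent sampling equals the same
# arithmetic evaluated at the per-parameter distribution means — the basis
# of analytic_expectation(), the model's closed-form oracle.

#' Names of the model's outcomes
#'
#' The fields of the per-draw outcome vector produced by
#' [compute_outcomes()] and summarized by [run_simulation()].
#'
#' @return Character vector of outcome names.
#' @export
outcome_names <- function() {
  c("ban_units", "marginal_cost_per_unit", "marginal_supply_cost",
    "averted_ped_asthma", "averted_adult_asthma", "averted_copd",
    "savings_ped_asthma", "savings_adult_asthma", "savings_copd",
    "savings_total", "net_bed_hours", "los_cost_savings")
}

# Outcomes that are per-cohort totals and therefore scale with ED size and
# adoption rate; the per-unit device price difference does not.
scalable_outcomes <- function() {
  setdiff(outcome_names(), "marginal_cost_per_unit")
}

#' Annual eligible visit counts per subgroup
#'
#' Splits national ED volume into the three modeled subgroups — pediatric
#' asthma, adult asthma, and adult COPD/emphysema — and the subsets that
#' receive nebulizer therapy. Counts stay fractional; rounding is a
#' reporting concern.
#'
#' @param draw Named numeric vector with one realized value per parameter
#'   label (see [draw_parameters()]).
#' @return Data frame with columns `subgroup`, `visits`, `neb_visits`.
#' @examples
#' eligible_visits(mean_draw(default_parameter_table()))
#' @export
eligible_visits <- function(draw) {
  visits <- c(ped_asthma = draw[["B"]] * draw[["C"]],
              adult_asthma = draw[["A"]] * draw[["D"]],
              copd = draw[["A"]] * draw[["E"]])
  share <- c(ped_asthma = draw[["F"]],
             adult_asthma = draw[["G"]],
             copd = draw[["H"]])
  data.frame(subgroup = names(visits),
             visits = unname(visits),
             neb_visits = unname(visits * share),
             stringsAsFactors = FALSE)
}

#' Annual nebulizer units needed
#'
#' One nebulizer unit is consumed per nebulizer-treated ED visit, so the
#' unit count is the sum of nebulizer visits over the three subgroups.
#'
#' @param counts Output of [eligible_visits()].
#' @return Units per year (fractional).
#' @export
ban_units <- function(counts) sum(counts$neb_visits)

#' Marginal annual supply cost of replacing CN with BAN
#'
#' @param units Annual nebulizer units.
#' @param ban_price,cn_price Per-unit prices (USD), `>= 0`.
#' @return `units * (ban_price - cn_price)`, in USD/year; negative when the
#'   comparator is dearer (permitted, flagged downstream in reports).
#' @export
marginal_supply_cost <- function(units, ban_price, cn_price) {
  if (ban_price < 0 || cn_price < 0) stop("prices must be >= 0")
  units * (ban_price - cn_price)
}

#' Admissions averted per subgroup
#'
#' Baseline admissions among nebulizer-treated visits (`neb_visits *`
#' admission rate) times the subgroup's percent reduction in admission after
#' converting to BAN.
#'
#' @inheritParams eligible_visits
#' @param counts Output of [eligible_visits()].
#' @return Named vector (`ped_asthma`, `adult_asthma`, `copd`) of averted
#'   admissions per year.
#' @export
averted_admissions <- function(draw, counts) {
  neb <- stats::setNames(counts$neb_visits, counts$subgroup)
  c(ped_asthma = neb[["ped_asthma"]] * draw[["J"]] * draw[["Q"]],
    adult_asthma = neb[["adult_asthma"]] * draw[["K"]] * draw[["R"]],
    copd = neb[["copd"]] * draw[["L"]] * draw[["S"]])
}

#' Dollar savings from averted admissions
#'
#' @param averted Named vector from [averted_admissions()].
#' @inheritParams eligible_visits
#' @return Named vector with per-subgroup savings plus their exact sum
#'   under `total`, in USD/year.
#' @export
admission_savings <- function(averted, draw) {
  s <- c(ped_asthma = averted[["ped_asthma"]] * draw[["U"]],
         adult_asthma = averted[["adult_asthma"]] * draw[["V"]],
         copd = averted[["copd"]] * draw[["W"]])
  c(s, total = sum(s))
}

#' Net annual ED bed-hour reduction
#'
#' The pediatric length-of-stay reduction net of the adult asthma increase,
#' converted from minutes to bed-hours. The LOS effects apply only to visits
#' that are not admitted at the baseline admission rate (an admitted
#' patient's ED stay ends with the boarding process, not with symptom
#' resolution), so each subgroup's nebulizer visits are weighted by
#' `(1 - baseline admission rate)`. COPD contributes no LOS term. The
#' `"all_visits"` rule — applying the effects to every nebulizer visit — is
#' retained for comparison as the explicitly rejected variant.
#'
#' @inheritParams eligible_visits
#' @param counts Output of [eligible_visits()].
#' @param los_rule `"discharged_only"` (the model's rule) or `"all_visits"`.
#' @return Bed-hours per year; positive values are a net reduction.
#' @export
net_bed_hours <- function(draw, counts,
                          los_rule = c("discharged_only", "all_visits")) {
  los_rule <- match.arg(los_rule)
  neb <- stats::setNames(counts$neb_visits, counts$subgroup)
  w_ped <- if (los_rule == "discharged_only") 1 - draw[["J"]] else 1
  w_adult <- if (los_rule == "discharged_only") 1 - draw[["K"]] else 1
  (neb[["ped_asthma"]] * w_ped * draw[["O"]] -
     neb[["adult_asthma"]] * w_adult * draw[["P"]]) / 60
}

#' Dollar value of the net bed-hour change
#'
#' @param bed_hours Net bed-hours from [net_bed_hours()].
#' @inheritParams eligible_visits
#' @return `bed_hours` times the per-bed-hour cost (USD/year); negative
#'   net hours pass through as a cost with unchanged sign.
#' @export
los_cost_savings <- function(bed_hours, draw) bed_hours * draw[["T"]]

#' Evaluate the full outcome model for one parameter draw
#'
#' Composes the cohort, supply-cost, admission, and length-of-stay pieces
#' into the complete outcome vector, then applies the scenario's ED scaling
#' and adoption multiplier (see [ban_scenario()]).
#'
#' @inheritParams eligible_visits
#' @param scenario A [ban_scenario()]. Note the scenario's `copd_reduction`
#'   field is a *table* transformation and must be applied before drawing
#'   (done automatically by [run_simulation()] and
#'   [analytic_expectation()]); it is ignored here.
#' @param los_rule Passed to [net_bed_hours()].
#' @return Named numeric vector over [outcome_names()].
#' @export
compute_outcomes <- function(draw, scenario = ban_scenario(),
                             los_rule = "discharged_only") {
  counts <- eligible_visits(draw)
  units <- ban_units(counts)
  per_unit <- draw[["M"]] - draw[["N"]]
  averted <- averted_admissions(draw, counts)
  savings <- admission_savings(averted, draw)
  hours <- net_bed_hours(draw, counts, los_rule = los_rule)
  out <- c(ban_units = units,
           marginal_cost_per_unit = per_unit,
           marginal_supply_cost = marginal_supply_cost(
             units, draw[["M"]], draw[["N"]]),
           averted_ped_asthma = averted[["ped_asthma"]],
           averted_adult_asthma = averted[["adult_asthma"]],
           averted_copd = averted[["copd"]],
           savings_ped_asthma = savings[["ped_asthma"]],
           savings_adult_asthma = savings[["adult_asthma"]],
           savings_copd = savings[["copd"]],
           savings_total = savings[["total"]],
           net_bed_hours = hours,
           los_cost_savings = los_cost_savings(hours, draw))
  if (scenario$scope == "ed") {
    out <- scale_to_ed(out, scenario$ed_visits, draw)
  }
  apply_adoption(out, scenario$adoption_rate)
}

#' Per-parameter distribution means as a draw
#'
#' Normal and lognormal parameters contribute their stated arithmetic mean,
#' BetaPERT parameters their PERT mean `(min + 4 mode + max) / 6`, and point
#' parameters their value.
#'
#' @param table A `ban_parameter_table`.
#' @return Named numeric vector over the table's labels.
#' @export
mean_draw <- function(table) {
  vals <- vapply(seq_len(nrow(table)), function(i) {
    r <- table[i, ]
    switch(r$dist_family,
           normal = r$mean,
           lognormal = r$mean,
           point = r$mean,
           betapert = betapert_mean(r$min, r$mode, r$max),
           stop("unknown dist_family '", r$dist_family, "'"))
  }, numeric(1))
  stats::setNames(vals, table$label)[sort(table$label)]
}

#' Closed-form expectation of every model outcome
#'
#' Because all parameters are sampled independently and every outcome is a
#' sum of products of distinct parameters, the expectation of each outcome
#' equals the outcome evaluated at the per-parameter means. For ED-scoped
#' scenarios the scale factor `V / (A + B)` is evaluated at the mean visit
#' volumes; the Jensen gap of that ratio is negligible at the default
#' coefficients of variation (~10%) and is quantified in the package
#' vignette.
#'
#' @param table A `ban_parameter_table`.
#' @param scenario A [ban_scenario()]; its `copd_reduction` field, if set,
#'   is applied to the table first.
#' @param los_rule Passed to [net_bed_hours()].
#' @return Named numeric vector over [outcome_names()].
#' @examples
#' analytic_expectation(default_parameter_table())[["savings_total"]]
#' @export
analytic_expectation <- function(table, scenario = ban_scenario(),
                                 los_rule = "discharged_only") {
  assert_valid_parameter_table(table)
  if (!is.null(scenario$copd_reduction)) {
    table <- apply_copd_reduction(table, scenario$copd_reduction)
  }
  compute_outcomes(mean_draw(table), scenario, los_rule = los_rule)
}

#' Deterministic supply cost at the most-likely device prices
#'
#' Expected annual units (from the closed-form expectation) times the
#' difference of the *most-likely* (mode) per-unit prices of BAN and CN.
#' This deterministic figure is distinct from the Monte Carlo
#' `marginal_supply_cost`, which differences independently sampled prices
#' per iteration; both are first-class outputs and reports label which is
#' which.
#'
#' @param table A `ban_parameter_table` whose rows `M` and `N` are BetaPERT
#'   (or point) price distributions.
#' @return USD/year.
#' @export
supply_cost_mode_difference <- function(table) {
  units <- analytic_expectation(table)[["ban_units"]]
  price <- function(label) {
    r <- table[table$label == label, ]
    if (r$dist_family == "betapert") r$mode else r$mean
  }
  units * (price("M") - price("N"))
}
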