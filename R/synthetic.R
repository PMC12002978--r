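# Synthetic parameter tables with controlled statistical structure, so
# every pipeline stage is testable independently of the packaged defaults.
# These live in the package (not the test suite) so installed users can
# smoke-test the full pipeline.

#' Collapse a table to zero variance
#'
#' Normal and lognormal rows keep their mean with SD set to 0; BetaPERT
#' rows become point parameters at their PERT mean. The resulting model is
#' fully deterministic: every draw equals [mean_draw()] and every simulated
#' outcome SD is exactly 0. Idempotent.
#'
#' @param base A valid `ban_parameter_table`.
#' @return A zero-variance `ban_parameter_table`.
#' @examples
#' zv <- zero_variance_table(default_parameter_table())
#' @export
zero_variance_table <- function(base) {
  assert_valid_parameter_table(base)
  for (i in seq_len(nrow(base))) {
    fam <- base$dist_family[i]
    if (fam %in% c("normal", "lognormal")) {
      base$sd[i] <- 0
    } else if (fam == "betapert") {
      base$mean[i] <- betapert_mean(base$min[i], base$mode[i], base$max[i])
      base$dist_family[i] <- "point"
      base$min[i] <- base$mode[i] <- base$max[i] <- NA_real_
    }
  }
  meta <- attr(base, "metadata")
  if (!grepl("\\[zero variance\\]$", meta)) {
    attr(base, "metadata") <- paste0(meta, " [zero variance]")
  }
  base
}

#' Randomly perturbed valid parameter table
#'
#' Jitters the packaged table's central values multiplicatively by
#' `Normal(1, cv)` draws clipped away from zero, repairs any proportion
#' that leaves `[0, 1]`, keeps BetaPERT min/mode/max ordering by applying
#' one common multiplier to all three range values, and (for `cv > 0`)
#' resets each normal/lognormal SD to 10% of its new mean. Always passes
#' [validate_parameter_table()]. `cv = 0` returns the packaged table
#' unchanged.
#'
#' @param seed Integer seed for the jitter.
#' @param cv Coefficient of variation of the multiplicative jitter, in
#'   `[0, 0.5]`.
#' @return A valid `ban_parameter_table`.
#' @examples
#' t1 <- perturbed_table(seed = 1, cv = 0.2)
#' nrow(validate_parameter_table(t1)) # 0
#' @export
perturbed_table <- function(seed, cv = 0.1) {
  if (cv < 0 || cv > 0.5) stop("`cv` must be in [0, 0.5], got ", cv)
  base <- default_parameter_table()
  if (cv == 0) return(base)
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  for (i in seq_len(nrow(base))) {
    m <- sample_normal(1L, 1, cv, lower = 0.05, upper = Inf)
    if (base$dist_family[i] == "betapert") {
      base$min[i] <- base$min[i] * m
      base$mode[i] <- base$mode[i] * m
      base$max[i] <- base$max[i] * m
      if (identical(base$units[i], "proportion")) {
        base$min[i] <- min(base$min[i], 1)
        base$mode[i] <- min(base$mode[i], 1)
        base$max[i] <- min(base$max[i], 1)
      }
    } else {
      base$mean[i] <- base$mean[i] * m
      if (identical(base$units[i], "proportion")) {
        base$mean[i] <- min(base$mean[i], 1)
      }
      base$sd[i] <- 0.1 * base$mean[i]
    }
  }
  attr(base, "metadata") <- paste0("perturbed table (seed ", seed,
                                   ", cv ", cv, ")")
  assert_valid_parameter_table(base)
}

#' Hand-auditable worked example
#'
#' A tiny zero-variance economy with round numbers — 1000 pediatric ED
#' visits, all asthma, half treated with a nebulizer, a 10% admission rate
#' halved by BAN at $1000 per admission, a one-hour pediatric LOS reduction
#' valued at $1/bed-hour, and device prices of $2 (BAN) vs $1 (CN). All
#' adult inputs are zero, so each outcome is a one-line pencil computation:
#' 500 nebulizer visits and units; $500 supply cost; 25 averted admissions
#' and $25,000 savings; 450 net bed-hours (500 x 0.9 x 60 / 60) worth $450.
#'
#' @return A list with elements `table` (a valid zero-variance
#'   `ban_parameter_table`) and `outcomes` (the hand-computed outcome
#'   vector the model must reproduce exactly).
#' @export
tiny_worked_example <- function() {
  base <- default_parameter_table()
  vals <- c(A = 0, B = 1000, C = 1, D = 0, E = 0, F = 0.5, G = 0, H = 0,
            J = 0.1, K = 0, L = 0, M = 2, N = 1, O = 60, P = 0,
            Q = 0.5, R = 0, S = 0, T = 1, U = 1000, V = 0, W = 0)
  for (i in seq_len(nrow(base))) {
    base$dist_family[i] <- "point"
    base$mean[i] <- vals[[base$label[i]]]
    base$sd[i] <- NA_real_
    base$min[i] <- base$mode[i] <- base$max[i] <- NA_real_
  }
  attr(base, "metadata") <- "tiny hand-auditable worked example"
  outcomes <- c(ban_units = 500, marginal_cost_per_unit = 1,
                marginal_supply_cost = 500,
                averted_ped_asthma = 25, averted_adult_asthma = 0,
                averted_copd = 0,
                savings_ped_asthma = 25000, savings_adult_asthma = 0,
                savings_copd = 0, savings_total = 25000,
                net_bed_hours = 450, los_cost_savings = 450)
  list(table = assert_valid_parameter_table(base), outcomes = outcomes)
}
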