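# Independent expectation oracle: the model's expected outcomes recomputed
# with literal arithmetic from the default input values, never through the
# package's outcome pipeline. Because all parameters are sampled
# independently and every outcome is a sum of products of distinct
# parameters, these plug-in values are exact expectations.

oracle <- local({
  A <- 111e6; B <- 22e6
  C <- 0.022; D <- 0.0086; E <- 0.0094
  F <- 0.66; G <- 0.57; H <- 0.41
  J <- 0.077; K <- 0.0576; L <- 0.412
  Q <- 0.333; R <- 0.72; S <- 0.456
  T <- 58.20; U <- 5200; V <- 6688; W <- 6852
  O <- 59; P <- 13.1
  pert_M <- (5.43 + 4 * 5.45 + 9.07) / 6
  pert_N <- (0.69 + 4 * 0.75 + 1.83) / 6

  visits_ped <- B * C
  visits_adult <- A * D
  visits_copd <- A * E
  neb_ped <- visits_ped * F
  neb_adult <- visits_adult * G
  neb_copd <- visits_copd * H
  units <- neb_ped + neb_adult + neb_copd

  averted_ped <- neb_ped * J * Q
  averted_adult <- neb_adult * K * R
  averted_copd <- neb_copd * L * S

  hours_discharged <- (neb_ped * (1 - J) * O - neb_adult * (1 - K) * P) / 60
  hours_all <- (neb_ped * O - neb_adult * P) / 60

  list(
    visits_ped = visits_ped, visits_adult = visits_adult,
    visits_copd = visits_copd,
    neb_ped = neb_ped, neb_adult = neb_adult, neb_copd = neb_copd,
    units = units,
    pert_M = pert_M, pert_N = pert_N,
    per_unit_sampled = pert_M - pert_N,
    supply_mode_diff = units * (5.45 - 0.75),
    supply_sampled = units * (pert_M - pert_N),
    averted_ped = averted_ped, averted_adult = averted_adult,
    averted_copd = averted_copd,
    savings_ped = averted_ped * U,
    savings_adult = averted_adult * V,
    savings_copd = averted_copd * W,
    savings_total = averted_ped * U + averted_adult * V + averted_copd * W,
    hours_discharged = hours_discharged,
    hours_all = hours_all,
    los_savings = hours_discharged * T,
    ed_factor_30k = 30000 / (A + B)
  )
})

# Published point estimates the model must reproduce.
published <- list(
  units = 1291400,
  savings_ped = 42630000, savings_adult = 150880000,
  savings_copd = 551100000, savings_total = 744610000,
  bed_hours = 178000, los_savings = 10360000,
  supply_mode_diff = 6059000, per_unit_sampled = 5.17,
  ed30_units = 290, ed30_savings_copd = 124200, ed30_bed_hours = 40,
  s137_total = 358962000
)

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# A fast valid table for pipeline tests: default with small-but-nonzero
# uncertainty everywhere.
expect_no_findings <- function(table) {
  rep <- validate_parameter_table(table)
  expect_identical(nrow(rep), 0L, info = paste(rep$message, collapse = "; "))
}
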