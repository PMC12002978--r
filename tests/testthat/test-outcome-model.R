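mean_default <- mean_draw(default_parameter_table())

test_that("cohort arithmetic at the input means matches the oracle", {
  counts <- eligible_visits(mean_default)
  expect_equal(counts$visits[counts$subgroup == "ped_asthma"],
               oracle$visits_ped)       # 484,000
  expect_equal(counts$visits[counts$subgroup == "adult_asthma"],
               oracle$visits_adult)
  expect_equal(counts$visits[counts$subgroup == "copd"],
               oracle$visits_copd)
  expect_equal(counts$neb_visits,
               c(oracle$neb_ped, oracle$neb_adult, oracle$neb_copd))
  expect_equal(ban_units(counts), oracle$units)  # 1,291,356
})

test_that("degenerate cohorts behave additively", {
  zero <- mean_default
  zero[c("C", "D", "E")] <- 0
  expect_equal(eligible_visits(zero)$neb_visits, rep(0, 3))
  one <- data.frame(subgroup = c("ped_asthma", "adult_asthma", "copd"),
                    visits = c(500000, 0, 0),
                    neb_visits = c(319440, 0, 0))
  expect_equal(ban_units(one), 319440)
})

test_that("marginal supply cost is the unit count times the price gap", {
  expect_equal(marginal_supply_cost(oracle$units, 5.45, 0.75),
               oracle$supply_mode_diff)
  expect_equal(marginal_supply_cost(1000, 3, 3), 0)
  expect_equal(marginal_supply_cost(0, 5.45, 0.75), 0)
  expect_lt(marginal_supply_cost(10, 1, 2), 0)   # comparator dearer
  expect_error(marginal_supply_cost(10, -1, 2), ">= 0")
})

test_that("averted admissions and their savings match the oracle", {
  counts <- eligible_visits(mean_default)
  averted <- averted_admissions(mean_default, counts)
  expect_equal(unname(averted),
               c(oracle$averted_ped, oracle$averted_adult,
                 oracle$averted_copd))
  savings <- admission_savings(averted, mean_default)
  expect_equal(unname(savings[c("ped_asthma", "adult_asthma", "copd")]),
               c(oracle$savings_ped, oracle$savings_adult,
                 oracle$savings_copd))
  # additivity to full precision
  expect_identical(savings[["total"]],
                   sum(savings[c("ped_asthma", "adult_asthma", "copd")]))
})

test_that("admission-reduction bounds behave as expected", {
  counts <- eligible_visits(mean_default)
  full <- mean_default
  full[c("Q", "R", "S")] <- 1
  expect_equal(unname(averted_admissions(full, counts)),
               counts$neb_visits * mean_default[c("J", "K", "L")],
               ignore_attr = TRUE)
  none <- mean_default
  none[c("Q", "R", "S")] <- 0
  expect_equal(unname(averted_admissions(none, counts)), rep(0, 3))
})

test_that("net bed-hours follow the discharged-only rule and pin the rejected variant", {
  counts <- eligible_visits(mean_default)
  expect_equal(net_bed_hours(mean_default, counts), oracle$hours_discharged)
  expect_equal(net_bed_hours(mean_default, counts, los_rule = "all_visits"),
               oracle$hours_all)
  # the two rules are materially different designs, not a rounding nuance
  expect_gt(oracle$hours_all - oracle$hours_discharged, 17000)

  no_los <- mean_default
  no_los[c("O", "P")] <- 0
  expect_equal(net_bed_hours(no_los, eligible_visits(no_los)), 0)
})

test_that("LOS dollar savings pass the sign through unmodified", {
  expect_equal(los_cost_savings(oracle$hours_discharged, mean_default),
               oracle$los_savings)
  expect_equal(los_cost_savings(0, mean_default), 0)
  expect_equal(los_cost_savings(-100, mean_default),
               -100 * mean_default[["T"]])
})

test_that("analytic expectation reproduces every oracle outcome", {
  e <- analytic_expectation(default_parameter_table())
  expect_equal(e[["ban_units"]], oracle$units)
  expect_equal(e[["marginal_cost_per_unit"]], oracle$per_unit_sampled)
  expect_equal(e[["marginal_supply_cost"]], oracle$supply_sampled)
  expect_equal(e[["savings_ped_asthma"]], oracle$savings_ped)
  expect_equal(e[["savings_adult_asthma"]], oracle$savings_adult)
  expect_equal(e[["savings_copd"]], oracle$savings_copd)
  expect_equal(e[["savings_total"]], oracle$savings_total)
  expect_equal(e[["net_bed_hours"]], oracle$hours_discharged)
  expect_equal(e[["los_cost_savings"]], oracle$los_savings)
})

test_that("a zero-variance table makes any draw equal the expectation", {
  zv <- zero_variance_table(default_parameter_table())
  set.seed(5)
  draw <- draw_parameters(zv)
  expect_equal(compute_outcomes(draw), analytic_expectation(zv))
  # and the zero-variance expectation equals the full table's expectation
  expect_equal(analytic_expectation(zv),
               analytic_expectation(default_parameter_table()))
})

test_that("scaling both visit volumes by k scales every national outcome by k", {
  k <- 3.7
  zv <- zero_variance_table(default_parameter_table())
  scaled <- zv
  scaled$mean[scaled$label %in% c("A", "B")] <-
    scaled$mean[scaled$label %in% c("A", "B")] * k
  base <- analytic_expectation(zv)
  up <- analytic_expectation(scaled)
  sc <- setdiff(outcome_names(), "marginal_cost_per_unit")
  expect_equal(up[sc], base[sc] * k)
  expect_equal(up[["marginal_cost_per_unit"]],
               base[["marginal_cost_per_unit"]])
})

test_that("outcomes are non-decreasing in their own multiplicative factors", {
  bump <- function(label, outcome) {
    lo <- mean_default
    hi <- mean_default
    hi[[label]] <- hi[[label]] * 1.01
    compute_outcomes(hi)[[outcome]] - compute_outcomes(lo)[[outcome]]
  }
  expect_gt(bump("F", "ban_units"), 0)
  expect_gt(bump("S", "savings_copd"), 0)
  expect_gt(bump("U", "savings_ped_asthma"), 0)
  expect_gt(bump("O", "net_bed_hours"), 0)
  expect_gt(bump("T", "los_cost_savings"), 0)
  # the adult LOS increase enters with a negative sign
  expect_lt(bump("P", "net_bed_hours"), 0)
})

test_that("the deterministic mode-difference supply cost is exposed separately", {
  tab <- default_parameter_table()
  expect_equal(supply_cost_mode_difference(tab), oracle$supply_mode_diff)
  # distinct from the sampled-difference expectation
  expect_false(isTRUE(all.equal(supply_cost_mode_difference(tab),
                                analytic_expectation(tab)[["marginal_supply_cost"]])))
})

test_that("the tiny worked example is reproduced exactly", {
  ex <- tiny_worked_example()
  draw <- mean_draw(ex$table)
  expect_equal(compute_outcomes(draw), ex$outcomes)
  expect_equal(analytic_expectation(ex$table), ex$outcomes)
})
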