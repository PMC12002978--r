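test_that("scenario construction enforces its invariants", {
  expect_error(ban_scenario("ed"), "ed_visits")
  expect_error(ban_scenario("national", ed_visits = 30000), "scope")
  expect_error(ban_scenario(adoption_rate = 0), "\\(0, 1\\]")
  expect_error(ban_scenario(adoption_rate = 1.5), "\\(0, 1\\]")
  expect_error(ban_scenario(copd_reduction = 1.2), "\\[0, 1\\]")
  s <- ban_scenario("ed", ed_visits = 80000, adoption_rate = 0.5)
  expect_s3_class(s, "ban_scenario")
})

test_that("ED scaling uses realized visit volumes and composes", {
  d <- mean_draw(default_parameter_table())
  nat <- compute_outcomes(d)
  # identity at the national volume
  expect_equal(scale_to_ed(nat, d[["A"]] + d[["B"]], d), nat)
  # composition: scale to V1 then rescale by V2/V1 equals scale to V2
  v1 <- scale_to_ed(nat, 30000, d)
  v2 <- scale_to_ed(nat, 130000, d)
  sc <- setdiff(outcome_names(), "marginal_cost_per_unit")
  rescaled <- v1
  rescaled[sc] <- rescaled[sc] * 130000 / 30000
  expect_equal(rescaled, v2)
  # the per-unit price gap never scales
  expect_equal(v1[["marginal_cost_per_unit"]],
               nat[["marginal_cost_per_unit"]])
})

test_that("small-ED expectations match proportional national scaling", {
  ed <- analytic_expectation(default_parameter_table(),
                             ban_scenario("ed", ed_visits = 30000))
  expect_equal(ed[["ban_units"]], oracle$units * oracle$ed_factor_30k)
  expect_equal(ed[["savings_copd"]],
               oracle$savings_copd * oracle$ed_factor_30k)
  expect_equal(ed[["net_bed_hours"]],
               oracle$hours_discharged * oracle$ed_factor_30k)
})

test_that("adoption is exactly linear per draw", {
  set.seed(8)
  tab <- default_parameter_table()
  for (i in 1:10) {
    d <- draw_parameters(tab)
    full <- compute_outcomes(d, ban_scenario())
    for (rate in c(0.25, 0.5, 0.75)) {
      part <- compute_outcomes(d, ban_scenario(adoption_rate = rate))
      sc <- setdiff(outcome_names(), "marginal_cost_per_unit")
      expect_equal(part[sc], full[sc] * rate)
      expect_equal(part[["marginal_cost_per_unit"]],
                   full[["marginal_cost_per_unit"]])
    }
  }
  expect_equal(apply_adoption(full, 1), full)
})

test_that("the COPD-reduction transform rescales only row S", {
  tab <- default_parameter_table()
  adj <- apply_copd_reduction(tab, 0.137)
  i <- which(adj$label == "S")
  expect_equal(adj$mean[i], 0.137)
  expect_equal(adj$sd[i] / adj$mean[i], tab$sd[i] / tab$mean[i])
  expect_equal(as.data.frame(adj[-i, ]), as.data.frame(tab[-i, ]))
  expect_error(apply_copd_reduction(tab, 1.5), "\\[0, 1\\]")

  # identity target leaves the expectation unchanged
  expect_equal(analytic_expectation(apply_copd_reduction(tab, 0.456)),
               analytic_expectation(tab))
})

test_that("COPD-attributable savings scale linearly with the target; asthma is invariant", {
  tab <- default_parameter_table()
  base <- analytic_expectation(tab)
  for (target in c(0.228, 0.137, 0)) {
    adj <- analytic_expectation(tab,
                                ban_scenario(copd_reduction = target))
    expect_equal(adj[["savings_copd"]],
                 base[["savings_copd"]] * target / 0.456)
    expect_equal(adj[["savings_ped_asthma"]], base[["savings_ped_asthma"]])
    expect_equal(adj[["savings_adult_asthma"]],
                 base[["savings_adult_asthma"]])
    expect_equal(adj[["savings_total"]],
                 base[["savings_ped_asthma"]] +
                   base[["savings_adult_asthma"]] +
                   base[["savings_copd"]] * target / 0.456)
  }
})

test_that("the report suite covers every published cell family", {
  suite <- standard_report_suite(seed = 3L, n_iterations = 5L)
  keys <- names(suite)
  # 4 scopes x (base + 3 COPD targets + 3 partial adoptions)
  expect_length(suite, 28L)
  for (v in c("ed_30000", "ed_80000", "ed_130000")) {
    expect_true(any(grepl(v, keys, fixed = TRUE)))
  }
  for (s in c("0.456", "0.228", "0.137")) {
    expect_true(any(grepl(paste0("copd_reduction ", s), keys)))
  }
  for (a in c("0.25", "0.5", "0.75")) {
    expect_true(any(grepl(paste0("adoption ", a), keys)))
  }
  expect_true(all(vapply(suite, inherits, logical(1), "ban_simulation")))
})
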