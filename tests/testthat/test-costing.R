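test_that("largest-remainder apportionment is exact", {
  expect_equal(unname(allocate_volumes(3900000)),
               c(78000, 117000, 390000, 585000, 2730000))
  expect_equal(allocate_volumes(100, 1.0), 100)
  expect_equal(allocate_volumes(7, c(0.5, 0.5)), c(4, 3))
  expect_error(allocate_volumes(100, c(0.6, 0.5)), "sum to 1")
  expect_error(allocate_volumes(-1), "non-negative")

  # any split sums back to the total
  set.seed(9)
  for (i in 1:10) {
    sh <- runif(5); sh <- sh / sum(sh)
    tot <- sample.int(1e7, 1)
    v <- allocate_volumes(tot, sh)
    expect_equal(sum(v), tot)
    expect_true(all(v == round(v)))
  }
})

test_that("scenario costs reproduce the published tier arithmetic exactly", {
  s <- tier_schedule()
  full <- scenario_full_itsdm(s)
  expect_equal(unname(full$tier_cost_usd),
               c(2520960, 1857960, 2893800, 3650400, 14660100))
  expect_equal(full$total_usd, 25583220)
  expect_equal(full$total_zar, 281415420)

  poc <- scenario_widespread_poc(s)
  expect_equal(unname(poc$volumes),
               c(585000, 0, 0, 585000, 2730000))
  expect_equal(unname(poc$tier_cost_usd[1]), 18907200)
  expect_equal(poc$total_usd, 37217700)

  expect_equal(scenario_cost(c(0, 0, 0, 0, 0))$total_usd, 0)
  expect_error(scenario_cost(c(-1, 0, 0, 0, 0)), "non-negative")
  expect_error(scenario_cost(c(0.5, 0, 0, 0, 0)), "whole tests")
})

test_that("scenario comparison reports savings and unit-cost ratios", {
  cmp <- compare_scenarios(scenario_widespread_poc(), scenario_full_itsdm())
  expect_equal(cmp$saving_usd, 11634480)
  expect_equal(cmp$saving_zar, 11634480 * 11)

  self <- compare_scenarios(scenario_full_itsdm(), scenario_full_itsdm())
  expect_equal(self$saving_usd, 0)

  # antisymmetry
  rev <- compare_scenarios(scenario_full_itsdm(), scenario_widespread_poc())
  expect_equal(rev$saving_usd, -cmp$saving_usd)

  # a community-lab test runs $2.05 above the metro rate (+38% rounded)...
  expect_equal(cmp$unit_cost_diff["T3", "T5"], 2.05)
  expect_equal(round(cmp$unit_cost_pct["T3", "T5"] - 100), 38)
  # ...but just 23% of the point-of-care rate
  expect_equal(round(cmp$unit_cost_pct["T3", "T1"]), 23)
})

test_that("currency conversion is an exact product", {
  expect_equal(to_zar(25583220), 281415420)
  expect_equal(to_zar(0), 0)
  expect_equal(to_zar(11634480), 127979280)
  expect_equal(to_zar(100, tier_schedule(zar_per_usd = 14.5)), 1450)
})

test_that("the expansion saving equals the volume-weighted unit-cost gaps", {
  # saving = V_T2 (c1 - c2) + V_T3 (c1 - c3), since the counterfactual
  # books the whole extension volume at the tier-1 rate
  s <- tier_schedule()
  v <- allocate_volumes(3900000, schedule = s)
  c1 <- s$cost_per_test[["T1"]]
  identity_val <- v[["T2"]] * (c1 - s$cost_per_test[["T2"]]) +
    v[["T3"]] * (c1 - s$cost_per_test[["T3"]])
  cmp <- compare_scenarios(scenario_widespread_poc(s), scenario_full_itsdm(s), s)
  expect_equal(cmp$saving_usd, identity_val)
  expect_equal(identity_val, 117000 * 16.44 + 390000 * 24.90)

  # identity holds for arbitrary totals, not just the published one
  for (tot in c(100001, 2.5e6, 7.7e6)) {
    cmp2 <- compare_scenarios(scenario_widespread_poc(s, tot),
                              scenario_full_itsdm(s, tot), s)
    v2 <- allocate_volumes(tot, schedule = s)
    expect_equal(cmp2$saving_usd,
                 v2[["T2"]] * (c1 - s$cost_per_test[["T2"]]) +
                   v2[["T3"]] * (c1 - s$cost_per_test[["T3"]]))
  }
})

test_that("cent arithmetic is order-independent", {
  s <- tier_schedule()
  v <- allocate_volumes(3899999, schedule = s)
  tot1 <- scenario_cost(v, s)$total_usd
  tot2 <- sum(rev(v * s$cost_per_test))
  # the cent route is exact; the float route agrees to within a cent
  expect_lt(abs(tot1 - tot2), 0.01)
  expect_equal(tot1 * 100, round(tot1 * 100))
})
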