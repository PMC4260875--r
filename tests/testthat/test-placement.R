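# geometry helper: 1 degree of latitude ~ 111.2 km, candidates on one meridian
worked_example <- function() {
  fac <- make_facilities(lat = c(-30.0, -30.5, -31.5), lon = 25,
                         volume = 6000, id = c("A", "B", "C"))
  cand <- make_labs(lat = c(-30.25, -31.35, -31.65), lon = 25,
                    id = c("c1", "c2", "c3"), capacity = 0, gp = TRUE)
  list(fac = fac, cand = cand)
}

test_that("greedy covering reproduces the worked three-candidate trace", {
  w <- worked_example()
  plan <- propose_sites(w$fac, w$cand, tier_schedule(), min_gain = 1)
  expect_identical(plan$sites$candidate_id, c("c1", "c2"))
  expect_identical(plan$covered_by$c1, c("A", "B"))
  expect_identical(plan$covered_by$c2, "C")
  expect_length(plan$residual_ids, 0L)

  # the first site absorbs T3-scale volume, the second a hub-scale remnant
  expect_identical(plan$sites$proposed_tier, c("T3", "T2"))

  # exhaustive subset enumeration confirms 2 is the minimum cover size
  d <- outer(seq_len(3), seq_len(3), function(i, j)
    great_circle_km(cbind(w$fac$latitude[i], w$fac$longitude[i]),
                    cbind(w$cand$latitude[j], w$cand$longitude[j])))
  sets <- lapply(1:3, function(j) which(d[, j] <= 100))
  expect_equal(brute_force_min_cover(sets, 1:3), 2)
})

test_that("degenerate placement inputs behave as documented", {
  w <- worked_example()
  empty <- propose_sites(w$fac[0, ], w$cand, tier_schedule())
  expect_equal(nrow(empty$sites), 0L)
  expect_length(empty$residual_ids, 0L)

  # one candidate in reach of everything -> one-site plan
  one <- make_labs(lat = -30.7, lon = 25, id = "hub", capacity = 0)
  plan1 <- propose_sites(w$fac, one, tier_schedule(), min_gain = 1)
  expect_equal(nrow(plan1$sites), 1L)
  expect_length(plan1$residual_ids, 0L)

  # no candidate in range -> everything residual on-site tier 1
  far <- make_labs(lat = -23, lon = 31, id = "far", capacity = 0)
  plan2 <- propose_sites(w$fac, far, tier_schedule())
  expect_equal(nrow(plan2$sites), 0L)
  expect_setequal(plan2$residual_ids, w$fac$id)
  expect_equal(plan2$residual_volume, sum(w$fac$annual_volume))
})

test_that("isolated single clinics default to on-site POC under min_gain = 2", {
  w <- worked_example()
  plan <- propose_sites(w$fac, w$cand, tier_schedule(), min_gain = 2)
  expect_identical(plan$sites$candidate_id, "c1")  # covers A and B
  expect_setequal(plan$residual_ids, "C")          # not worth a dedicated hub
})

test_that("absorbed volumes are conserved and the plan is deterministic", {
  set.seed(31)
  fac <- random_facilities(30)
  cand <- random_labs(8)
  cand$instrument_capacity_per_day <- 0L
  p1 <- propose_sites(fac, cand, tier_schedule(), min_gain = 1)
  p2 <- propose_sites(fac, cand, tier_schedule(), min_gain = 1)
  expect_identical(p1, p2)
  expect_equal(sum(p1$sites$annual_volume) + p1$residual_volume,
               sum(fac$annual_volume))
  s <- plan_summary(p1, tier_schedule(), national_total = sum(fac$annual_volume))
  expect_equal(sum(s$annual_volume), sum(fac$annual_volume))
  expect_equal(sum(s$share_of_national), 1)
  expect_equal(sum(s$n_sites), nrow(p1$sites) + length(p1$residual_ids))
})

test_that("greedy cover stays within (ln n + 1) of the exhaustive optimum", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(6:12, 1)
    fac <- make_facilities(lat = runif(n, -32, -28), lon = runif(n, 22, 28),
                           volume = 20000)
    # candidates sit near facilities so every facility is coverable
    m <- sample(3:6, 1)
    anchor <- sample(n, m, replace = TRUE)
    cand <- make_labs(lat = fac$latitude[anchor] + runif(m, -0.3, 0.3),
                      lon = fac$longitude[anchor] + runif(m, -0.3, 0.3),
                      id = sprintf("c%02d", 1:m), capacity = 0)
    d <- outer(seq_len(n), seq_len(m), function(i, j)
      great_circle_km(cbind(fac$latitude[i], fac$longitude[i]),
                      cbind(cand$latitude[j], cand$longitude[j])))
    sets <- lapply(seq_len(m), function(j) which(d[, j] <= 100))
    coverable <- sort(unique(unlist(sets)))

    plan <- propose_sites(fac, cand, tier_schedule(), min_gain = 1)
    expect_setequal(plan$residual_ids, fac$id[setdiff(seq_len(n), coverable)])

    if (length(coverable)) {
      opt <- brute_force_min_cover(sets, coverable)
      expect_lte(nrow(plan$sites), (log(length(coverable)) + 1) * opt)
    }
  }
})

test_that("empty plans summarize to zero", {
  plan <- propose_sites(random_facilities(3, seed = 1)[0, ],
                        random_labs(2, seed = 1), tier_schedule())
  s <- plan_summary(plan, tier_schedule())
  expect_equal(sum(s$n_sites), 0L)
  expect_equal(sum(s$annual_volume), 0)
})
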