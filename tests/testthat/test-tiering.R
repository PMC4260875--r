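test_that("tier classification follows the volume breaks with inclusive upper bounds", {
  got <- classify_tier(c(5, 35, 120, 250, 650), c(1, 8, 30, 80, 150))
  expect_equal(got$tier, c("T1", "T2", "T3", "T4", "T5"))
  expect_true(all(got$clinic_count_consistent))

  expect_equal(classify_tier(10)$tier, "T1")
  expect_equal(classify_tier(10.01)$tier, "T2")
  expect_equal(classify_tier(40)$tier, "T2")
  expect_equal(classify_tier(300)$tier, "T4")
  expect_equal(classify_tier(300.5)$tier, "T5")

  expect_warning(z <- classify_tier(0), "zero demand")
  expect_equal(z$tier, "T1")
  expect_error(classify_tier(-1), "non-negative")

  # monotone step function of volume
  v <- sort(runif(200, 0, 800))
  tn <- as.integer(sub("T", "", suppressWarnings(classify_tier(v)$tier)))
  expect_true(all(diff(tn) >= 0))
})

test_that("clinic counts annotate but never decide the tier", {
  got <- classify_tier(120, clinics_served = 200)
  expect_equal(got$tier, "T3")          # volume says T3
  expect_false(got$clinic_count_consistent)  # 200 clinics is T5-like
})

test_that("capacity margins compare installed instruments to demand", {
  ta <- classify_tier(300, 80, lab_id = "L1")
  chk <- capacity_check(ta, n_instruments = 2)
  expect_equal(chk$margin, 2 * 384 - 300)   # 468
  expect_false(chk$flagged)

  ta2 <- classify_tier(150, lab_id = "L2")  # T3, capacity 150
  chk2 <- capacity_check(ta2)
  expect_equal(chk2$margin, 0)
  expect_false(chk2$flagged)

  # an (historically) tier-1 site whose demand crept above its instrument
  ta3 <- classify_tier(5, lab_id = "L3")
  ta3$daily_volume <- 12
  chk3 <- capacity_check(ta3)
  expect_equal(chk3$margin, -2)
  expect_true(chk3$flagged)

  ta_bad <- ta; ta_bad$tier <- "T9"
  expect_error(capacity_check(ta_bad), "unknown tier")
})

test_that("support graph links every low-tier site to its nearest high-tier parent", {
  loc <- data.frame(id = c("a", "b", "c"),
                    latitude = c(-30, -30.2, -33),
                    longitude = c(25, 25.2, 28))
  ta <- classify_tier(c(5, 120, 250), lab_id = c("a", "b", "c"))
  edges <- build_support_graph(ta, loc)
  expect_equal(nrow(edges), 1L)
  expect_identical(edges$child_id, "a")
  expect_identical(edges$parent_id, "b")   # the nearby T3, not the far T4

  # a T1 closer to a T4 than to any T3 gets the T4 parent
  loc2 <- data.frame(id = c("poc", "t3", "t4"),
                     latitude = c(-30, -32, -30.1),
                     longitude = c(25, 27, 25.1))
  ta2 <- classify_tier(c(4, 100, 250), lab_id = c("poc", "t3", "t4"))
  expect_identical(build_support_graph(ta2, loc2)$parent_id, "t4")

  ta3 <- classify_tier(c(5, 20), lab_id = c("x", "y"))
  expect_error(build_support_graph(ta3, data.frame(id = c("x", "y"),
                                                   latitude = c(-30, -31),
                                                   longitude = c(25, 26))),
               "orphan.*x.*y|x, y")
})

test_that("support graph matches brute-force nearest-qualifying search and is a forest", {
  set.seed(21)
  n <- 18
  loc <- data.frame(id = sprintf("s%02d", 1:n),
                    latitude = runif(n, -34, -23),
                    longitude = runif(n, 17, 32))
  vols <- sample(c(5, 30, 100, 250, 500), n, replace = TRUE)
  vols[1:2] <- c(5, 500)  # guarantee at least one child and one parent
  ta <- classify_tier(vols, lab_id = loc$id)
  edges <- build_support_graph(ta, loc)

  tn <- as.integer(sub("T", "", ta$tier))
  children <- ta$lab_id[tn < 3]
  expect_setequal(edges$child_id, children)
  expect_false(anyDuplicated(edges$child_id) > 0)  # forest: one parent each
  expect_true(all(as.integer(sub("T", "", edges$parent_tier)) >
                    as.integer(sub("T", "", edges$child_tier))))

  for (k in seq_len(nrow(edges))) {
    ci <- match(edges$child_id[k], loc$id)
    parents <- which(tn >= 3)
    d <- great_circle_km(cbind(loc$latitude[ci], loc$longitude[ci]),
                         cbind(loc$latitude[parents], loc$longitude[parents]))
    expect_identical(edges$parent_id[k],
                     loc$id[parents][which.min(d + 1e-12 * rank(loc$id[parents]))])
  }
})

test_that("super-laboratory candidates are connected high-volume clusters", {
  loc <- data.frame(id = c("m1", "m2", "far"),
                    latitude = c(-26.2, -26.35, -29.9),
                    longitude = c(28.0, 28.1, 31.0))
  ta <- classify_tier(c(500, 400, 450), lab_id = loc$id)
  cand <- superlab_candidates(ta, loc, tier_schedule())
  expect_length(cand, 1L)
  expect_identical(cand[[1]]$lab_ids, c("m1", "m2"))
  expect_equal(cand[[1]]$combined_daily_volume, 900)

  # all labs far apart: nothing to consolidate
  loc2 <- data.frame(id = c("a", "b"), latitude = c(-26, -33),
                     longitude = c(18, 31))
  ta2 <- classify_tier(c(500, 500), lab_id = loc2$id)
  expect_length(superlab_candidates(ta2, loc2, tier_schedule()), 0L)

  # chain a-b-c (a and c linked only through b) forms one 3-site cluster
  loc3 <- data.frame(id = c("a", "b", "c"), latitude = c(-26, -26.7, -27.4),
                     longitude = c(28, 28, 28))
  ta3 <- classify_tier(c(400, 400, 400), lab_id = loc3$id)
  cand3 <- superlab_candidates(ta3, loc3, tier_schedule())
  expect_length(cand3, 1L)
  expect_identical(cand3[[1]]$lab_ids, c("a", "b", "c"))
})

test_that("per-lab demand aggregation conserves the national total", {
  net <- small_network(seed = 5)
  testing <- net$labs[net$labs$instrument_capacity_per_day > 0, ]
  a <- assign_nearest(net$facilities, testing, tier_schedule())
  tiers <- tier_laboratories(a, net$facilities, testing, tier_schedule())
  expect_equal(sum(tiers$daily_volume) * tier_schedule()$working_days_per_year,
               sum(net$facilities$annual_volume))
  expect_equal(sum(tiers$clinics_served), nrow(net$facilities))
})
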