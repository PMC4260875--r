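# a one-district assignment table at a fixed referral distance
fixed_assignment <- function(distance_km, n_fac = 30) {
  structure(data.frame(
    facility_id = sprintf("F%03d", seq_len(n_fac)),
    lab_id = "L001",
    distance_km = distance_km,
    covered = distance_km <= 100,
    stringsAsFactors = FALSE
  ), class = c("assignment_table", "data.frame"))
}

test_that("pre-analytic time is zero when there is nothing to wait for", {
  p <- tat_params(courier_base_delay_h = 0, batching_interval_h = 0)
  rec <- generate_tat_records(fixed_assignment(0, n_fac = 5), p,
                              n_per_facility = 4)
  expect_equal(rec$pre_analytic_h, rep(0, 20))
  expect_equal(rec$total_h, rec$pre_analytic_h + rec$ltr_h)
  expect_true(all(rec$ltr_h >= 0))
})

test_that("same seed reproduces records; doubling distance never shortens the pre-analytic leg", {
  a1 <- fixed_assignment(120)
  r1 <- generate_tat_records(a1, tat_params(seed = 7))
  r1b <- generate_tat_records(a1, tat_params(seed = 7))
  expect_identical(r1, r1b)

  a2 <- a1
  a2$distance_km <- a1$distance_km * 2
  r2 <- generate_tat_records(a2, tat_params(seed = 7))
  expect_true(all(r2$pre_analytic_h >= r1$pre_analytic_h))
})

test_that("unassigned facilities are reported by id", {
  a <- fixed_assignment(10, n_fac = 3)
  a$lab_id[2] <- NA
  expect_error(generate_tat_records(a, tat_params()), "F002")
})

test_that("district banding counts and labels follow the normalized edges", {
  rec <- data.frame(
    district_id = c("D1", "D1", "D1", "D2", "D2"),
    ltr_h = c(24, 60, 60, 24, 24),
    stringsAsFactors = FALSE
  )
  s <- summarize_tat(rec, threshold_h = 48)
  d1 <- s[s$district_id == "D1", ]
  expect_equal(d1$fraction_within, 1 / 3)
  expect_identical(d1$band, "<35%")
  d2 <- s[s$district_id == "D2", ]
  expect_equal(d2$fraction_within, 1)
  expect_identical(d2$band, "96-100%")

  all24 <- data.frame(district_id = "D1", ltr_h = rep(24, 10))
  expect_identical(summarize_tat(all24)$band, "96-100%")

  expect_error(summarize_tat(rec, band_edges = c(50, 40)), "increasing")
  expect_error(summarize_tat(rec[0, ]), "no TAT records")
})

test_that("within-threshold fractions are monotone in the threshold and aggregate consistently", {
  net <- small_network(seed = 6)
  testing <- net$labs[net$labs$instrument_capacity_per_day > 0, ]
  a <- assign_nearest(net$facilities, testing, tier_schedule())
  rec <- generate_tat_records(a, tat_params(seed = 2), net$facilities,
                              n_per_facility = 5)
  s24 <- summarize_tat(rec, threshold_h = 24)
  s48 <- summarize_tat(rec, threshold_h = 48)
  expect_true(all(s48$fraction_within >= s24$fraction_within))
  # national fraction is the sample-weighted mean of district fractions
  expect_equal(attr(s48, "national_fraction"),
               sum(s48$fraction_within * s48$n) / sum(s48$n))
})

test_that("a remote laboratory-free district falls below the national median band fraction", {
  net <- generate_network(network_config(seed = 1))
  testing <- net$labs[net$labs$instrument_capacity_per_day > 0, ]
  a <- assign_nearest(net$facilities, testing, tier_schedule())
  rec <- generate_tat_records(a, tat_params(seed = 1), net$facilities,
                              n_per_facility = 3)
  s <- summarize_tat(rec, threshold_h = 48)
  dd <- merge(s, net$districts, by.x = "district_id", by.y = "id")
  # the lab-free district whose facilities travel farthest
  far <- dd$district_id[!dd$has_cd4_lab]
  mean_d <- tapply(a$distance_km,
                   net$facilities$district_id[match(a$facility_id,
                                                    net$facilities$id)],
                   mean)
  worst <- far[which.max(mean_d[far])]
  expect_lt(dd$fraction_within[dd$district_id == worst],
            stats::median(dd$fraction_within))
})

test_that("opening a local laboratory strictly improves a district's turnaround", {
  before <- fixed_assignment(400)
  after <- fixed_assignment(30)
  fac <- make_facilities(lat = rep(-30, 30), lon = seq(24, 26, length.out = 30),
                         district = "D01",
                         id = sprintf("F%03d", 1:30))
  p <- tat_params(seed = 5)
  rb <- generate_tat_records(before, p, fac)
  ra <- generate_tat_records(after, p, fac)
  cmp <- before_after(rb, ra, "D01")
  expect_lt(cmp$delta[["median_pre_analytic_h"]], 0)
  expect_lt(cmp$delta[["median_total_h"]], 0)
  # calibrated defaults: local service brings the median courier leg < 5 h,
  # remote referral leaves it > 15 h
  expect_lt(cmp$after[["median_pre_analytic_h"]], 5)
  expect_gt(cmp$before[["median_pre_analytic_h"]], 15)
  expect_lt(cmp$after[["median_ltr_h"]], 18)

  same <- before_after(rb, rb, "D01")
  expect_equal(unname(same$delta), rep(0, 4))

  expect_error(before_after(rb, ra, "D99"), "absent")
})
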