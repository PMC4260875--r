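#' Run the full tiered service delivery planning pipeline
#'
#' One call from registries to plan: assigns every referring facility to
#' its nearest CD4 testing laboratory, builds the coverage report,
#' classifies laboratories into service tiers from their assigned demand,
#' checks instrument capacity, links lower-tier sites to their parent
#' laboratories, proposes new decentralized sites for the uncovered
#' facilities by greedy maximal covering, and costs the full tiered
#' expansion against the widespread point-of-care counterfactual.
#'
#' @param facilities A `facility_registry`.
#' @param labs A `laboratory_registry`; rows with
#'   `instrument_capacity_per_day > 0` are treated as current testing
#'   sites, all rows with `offers_general_pathology = TRUE` as candidate
#'   hosts for new services.
#' @param schedule A [tier_schedule()].
#' @param min_gain Passed to [propose_sites()].
#' @return An object of class `itsdm` holding `assignments`, `coverage`,
#'   `tiers`, `capacity`, `support`, `plan`, `plan_summary`, `scenarios`
#'   (full tiered model vs widespread POC, with their comparison) and the
#'   inputs.
#' @examples
#' \donttest{
#' net <- generate_network(network_config(n_facilities = 400, n_districts = 12,
#'                                        n_labs = 8, n_gp_labs = 20,
#'                                        n_lab_free_districts = 3,
#'                                        total_annual_tests = 300000))
#' fit <- itsdm(net$facilities, net$labs)
#' summary(fit)
#' }
#' @export
itsdm <- function(facilities, labs, schedule = tier_schedule(),
                  min_gain = 2L) {
  schedule <- as_schedule(schedule)
  testing <- labs[labs$instrument_capacity_per_day > 0, , drop = FALSE]
  if (nrow(testing) == 0L) stop("no testing laboratory in `labs`", call. = FALSE)

  assignments <- assign_nearest(facilities, testing, schedule)
  coverage <- coverage_report(assignments, facilities, testing, schedule)
  tiers <- tier_laboratories(assignments, facilities, testing, schedule)
  capacity <- capacity_check(tiers, schedule,
                             n_instruments = pmax(1L, testing$instrument_capacity_per_day %/%
                                                    schedule$instrument_capacity[tiers$tier]))
  support <- tryCatch(
    build_support_graph(tiers, testing),
    error = function(e) NULL
  )

  uncovered <- facilities[facilities$id %in% coverage$uncovered_ids, ,
                          drop = FALSE]
  candidates <- labs[isTRUE_vec(labs$offers_general_pathology) &
                       labs$instrument_capacity_per_day == 0, , drop = FALSE]
  plan <- propose_sites(uncovered, candidates, schedule, min_gain = min_gain)
  total <- sum(facilities$annual_volume)
  psum <- plan_summary(plan, schedule, national_total = total)

  full <- scenario_full_itsdm(schedule, total_annual = total)
  poc <- scenario_widespread_poc(schedule, total_annual = total)
  scenarios <- list(full_itsdm = full, widespread_poc = poc,
                    comparison = compare_scenarios(poc, full, schedule))

  structure(list(
    facilities = facilities, labs = labs, schedule = schedule,
    assignments = assignments, coverage = coverage, tiers = tiers,
    capacity = capacity, support = support, plan = plan,
    plan_summary = psum, scenarios = scenarios
  ), class = "itsdm")
}

#' @export
print.itsdm <- function(x, ...) {
  cat("Tiered service delivery plan\n")
  cat(sprintf("  %d facilities, %d testing laboratories, %s tests/yr\n",
              nrow(x$facilities), nrow(x$tiers),
              format(sum(x$facilities$annual_volume), big.mark = ",")))
  cat(sprintf("  coverage at %g km: %.1f%% of facilities (%.1f%% of volume)\n",
              x$coverage$radius_km, 100 * x$coverage$fraction_covered,
              100 * x$coverage$fraction_covered_volume))
  cat(sprintf("  proposed new sites: %d hubs/labs + %d on-site POC\n",
              nrow(x$plan$sites), length(x$plan$residual_ids)))
  cmp <- x$scenarios$comparison
  cat(sprintf("  expansion saving (tiered vs widespread POC): $%s (R%s)\n",
              format(cmp$saving_usd, big.mark = ","),
              format(cmp$saving_zar, big.mark = ",")))
  invisible(x)
}

#' @export
summary.itsdm <- function(object, ...) {
  x <- object
  print(x)
  cat("\nLaboratory tiers:\n")
  print(table(x$tiers$tier))
  cat("\nProposed sites by tier:\n")
  print(x$plan_summary)
  cat("\nScenario totals (USD):\n")
  print(c(full_itsdm = x$scenarios$full_itsdm$total_usd,
          widespread_poc = x$scenarios$widespread_poc$total_usd))
  invisible(x)
}

#' Map a planned network
#'
#' Base-graphics map: facilities as small points (uncovered in red),
#' testing laboratories as filled triangles scaled by tier, and the
#' service precincts as circles.
#'
#' @param x An `itsdm` object.
#' @param precincts Draw precinct circles (default `TRUE`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.itsdm <- function(x, precincts = TRUE, ...) {
  fac <- x$facilities
  uncovered <- fac$id %in% x$coverage$uncovered_ids
  graphics::plot(fac$longitude, fac$latitude, pch = 16, cex = 0.3,
                 col = ifelse(uncovered, "red", grDevices::grey(0.6)),
                 xlab = "longitude", ylab = "latitude", asp = 1, ...)
  testing <- x$labs[x$labs$instrument_capacity_per_day > 0, , drop = FALSE]
  if (precincts) {
    th <- seq(0, 2 * pi, length.out = 65)
    r_deg <- x$schedule$radius_km / 111.32
    for (i in seq_len(nrow(testing))) {
      graphics::lines(testing$longitude[i] +
                        r_deg * cos(th) / cos(testing$latitude[i] * pi / 180),
                      testing$latitude[i] + r_deg * sin(th),
                      col = grDevices::adjustcolor("steelblue", 0.5))
    }
  }
  graphics::points(testing$longitude, testing$latitude, pch = 17,
                   col = "darkblue",
                   cex = 0.7 + 0.25 * tier_number(x$tiers$tier))
  invisible(x)
}
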