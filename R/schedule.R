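#' Tier schedule: the parameters of the six-tier service framework
#'
#' A tier schedule bundles every tunable parameter of the tiered service
#' delivery model: the daily-volume break points that separate the five
#' testing tiers, the advisory clinic-count ranges per tier, per-instrument
#' daily capacities, the per-test cost of each tier, the national
#' tier volume shares used for scenario costing, the service-precinct
#' radius, and unit-conversion constants (working days per year, ZAR/USD).
#'
#' The defaults are the published reference values for the South African
#' CD4 programme: breaks 10/40/150/300 samples per day (tier 5 unbounded,
#' with an optional 600/day super-laboratory consolidation threshold),
#' instrument capacities 10/30/150/384/768/1536 samples per 8-hour day,
#' per-test costs USD 32.32/15.88/7.42/6.24/5.37 for tiers 1-5 (the
#' coordinating tier 6 carries no testing cost), tier volume shares
#' 2/3/10/15/70 percent, a 100 km precinct radius (20 km for tier-2
#' POC-hub catchments), 260 working days per year and R11 per USD.
#'
#' Tier breaks are interpreted with inclusive upper bounds: tier 1 is
#' (0, 10] samples/day, tier 2 (10, 40], tier 3 (40, 150], tier 4
#' (150, 300] and tier 5 everything above 300.
#'
#' @param volume_breaks Named numeric vector of daily-volume upper bounds
#'   for tiers 1-5; must be strictly increasing and end in `Inf`.
#' @param clinic_count_range 5x2 matrix (rows = tiers 1-5) of advisory
#'   lower/upper bounds on the number of clinics a site of that tier serves.
#' @param instrument_capacity Samples/day per instrument for tiers 1-6.
#' @param cost_per_test USD per test for tiers 1-5; must be strictly
#'   decreasing (economies of scale).
#' @param volume_shares Proportion of national annual volume handled by
#'   each of tiers 1-5; must sum to 1.
#' @param superlab_break Combined daily volume above which co-located
#'   high-tier laboratories become super-laboratory consolidation
#'   candidates.
#' @param working_days_per_year Days/year used for annual-to-daily volume
#'   conversion; must lie in `[200, 365]`.
#' @param radius_km Service-precinct radius in kilometres.
#' @param hub_radius_km Catchment radius for tier-2 POC-hubs.
#' @param zar_per_usd ZAR/USD exchange rate for currency conversion.
#' @return An object of class `tier_schedule` (a validated list).
#' @examples
#' sched <- tier_schedule()
#' sched$cost_per_test[["T1"]] # 32.32
#' tier_schedule(radius_km = 200)$radius_km
#' @seealso [load_tier_schedule()] to build one from a config file,
#'   [classify_tier()] which consumes the breaks.
#' @export
tier_schedule <- function(volume_breaks = c(T1 = 10, T2 = 40, T3 = 150,
                                            T4 = 300, T5 = Inf),
                          clinic_count_range = default_clinic_ranges(),
                          instrument_capacity = c(T1 = 10, T2 = 30, T3 = 150,
                                                  T4 = 384, T5 = 768,
                                                  T6 = 1536),
                          cost_per_test = c(T1 = 32.32, T2 = 15.88, T3 = 7.42,
                                            T4 = 6.24, T5 = 5.37),
                          volume_shares = c(T1 = 0.02, T2 = 0.03, T3 = 0.10,
                                            T4 = 0.15, T5 = 0.70),
                          superlab_break = 600,
                          working_days_per_year = 260,
                          radius_km = 100,
                          hub_radius_km = 20,
                          zar_per_usd = 11) {
  if (length(volume_breaks) != 5L || any(diff(volume_breaks) <= 0)) {
    stop("`volume_breaks` must be 5 strictly increasing daily-volume bounds",
         call. = FALSE)
  }
  if (!is.infinite(volume_breaks[[5L]])) {
    stop("the top tier must be unbounded: `volume_breaks[5]` must be Inf",
         call. = FALSE)
  }
  if (length(cost_per_test) != 5L || any(diff(cost_per_test) >= 0)) {
    stop("`cost_per_test` must be 5 strictly decreasing USD amounts (T1..T5)",
         call. = FALSE)
  }
  if (any(cost_per_test <= 0)) stop("per-test costs must be positive", call. = FALSE)
  if (!isTRUE(radius_km > 0) || !isTRUE(hub_radius_km > 0)) {
    stop("precinct radii must be positive", call. = FALSE)
  }
  if (working_days_per_year < 200 || working_days_per_year > 365) {
    stop("`working_days_per_year` must lie in [200, 365]", call. = FALSE)
  }
  if (zar_per_usd <= 0) stop("`zar_per_usd` must be positive", call. = FALSE)
  if (length(instrument_capacity) != 6L || any(instrument_capacity < 0)) {
    stop("`instrument_capacity` must give non-negative capacity for tiers 1-6",
         call. = FALSE)
  }
  if (length(volume_shares) != 5L || abs(sum(volume_shares) - 1) > 1e-9) {
    stop("`volume_shares` must be 5 proportions summing to 1", call. = FALSE)
  }
  clinic_count_range <- as.matrix(clinic_count_range)
  if (!all(dim(clinic_count_range) == c(5L, 2L))) {
    stop("`clinic_count_range` must be a 5x2 matrix (tiers 1-5, lo/hi)",
         call. = FALSE)
  }

  tiers <- paste0("T", 1:5)
  names(volume_breaks) <- tiers
  names(cost_per_test) <- tiers
  names(volume_shares) <- tiers
  names(instrument_capacity) <- paste0("T", 1:6)
  rownames(clinic_count_range) <- tiers
  colnames(clinic_count_range) <- c("min", "max")

  structure(list(
    volume_breaks = volume_breaks,
    clinic_count_range = clinic_count_range,
    instrument_capacity = instrument_capacity,
    cost_per_test = cost_per_test,
    # integer cents: all money arithmetic downstream is exact
    cost_cents = as.integer(round(cost_per_test * 100)),
    volume_shares = volume_shares,
    superlab_break = superlab_break,
    working_days_per_year = working_days_per_year,
    radius_km = radius_km,
    hub_radius_km = hub_radius_km,
    zar_per_usd = zar_per_usd
  ), class = "tier_schedule")
}

# advisory clinic counts per tier: 1 / <=10 / 11-50 / 51-100 / >100
default_clinic_ranges <- function() {
  rbind(c(1, 1), c(2, 10), c(11, 50), c(51, 100), c(101, Inf))
}

#' Load a tier schedule from a configuration file or list
#'
#' Reads a YAML or JSON key/value configuration whose keys are the
#' arguments of [tier_schedule()]; keys that are absent keep their
#' published default. An already-parsed named list is accepted directly,
#' and an empty / `NULL` config yields the default schedule.
#'
#' @param config Path to a `.yaml`/`.yml`/`.json` file, a named list of
#'   overrides, or `NULL`.
#' @return A `tier_schedule`.
#' @export
load_tier_schedule <- function(config = NULL) {
  if (is.null(config)) return(tier_schedule())
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("`config` must be a file path or a named list", call. = FALSE)
  if (length(config) == 0L) return(tier_schedule())
  known <- names(formals(tier_schedule))
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown tier-schedule keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(config$volume_breaks)) {
    vb <- unlist(config$volume_breaks)
    vb[is.character(vb) & vb %in% c("Inf", ".inf")] <- Inf
    config$volume_breaks <- as.numeric(vb)
  }
  do.call(tier_schedule, config)
}

#' @export
print.tier_schedule <- function(x, ...) {
  cat("Tier schedule (5 testing tiers + coordinating tier 6)\n")
  tab <- data.frame(
    daily_volume_break = x$volume_breaks,
    clinics_min = x$clinic_count_range[, "min"],
    clinics_max = x$clinic_count_range[, "max"],
    instrument_capacity = x$instrument_capacity[1:5],
    cost_per_test_usd = x$cost_per_test,
    volume_share = x$volume_shares,
    row.names = paste0("T", 1:5)
  )
  print(tab, ...)
  cat(sprintf("T6 instrument capacity: %d/day; super-lab break: %g/day\n",
              x$instrument_capacity[["T6"]], x$superlab_break))
  cat(sprintf("precinct radius %g km (hub %g km); %d working days/yr; R%g/USD\n",
              x$radius_km, x$hub_radius_km, x$working_days_per_year,
              x$zar_per_usd))
  invisible(x)
}

as_schedule <- function(schedule) {
  if (!inherits(schedule, "tier_schedule")) {
    stop("`schedule` must be a tier_schedule (see tier_schedule())",
         call. = FALSE)
  }
  schedule
}
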