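#' Configuration for the synthetic network generator
#'
#' The generator emulates the statistical structure of a national CD4
#' referral network: 52 districts in 9 provinces over a country-sized
#' rectangular extent, ~4,756 referring facilities with the published
#' category mix, heavy-tailed per-facility annual volumes rescaled to an
#' exact national total of 3.9 million tests, ~65 testing laboratories
#' concentrated in metropolitan districts with 14 districts left without a
#' local laboratory, and a wider layer of general-pathology laboratories
#' (260 laboratories in total) that are candidates for hosting new
#' decentralized services.
#'
#' @param n_districts,n_provinces,n_facilities,n_labs Network dimensions.
#' @param n_gp_labs Number of general-pathology-only laboratories (no CD4
#'   instruments; candidate hosts for new tiers). Default brings total
#'   laboratories to 260.
#' @param n_lab_free_districts Districts deliberately left without a CD4
#'   testing laboratory (their samples are referred across district
#'   borders).
#' @param total_annual_tests National annual volume; per-facility volumes
#'   are apportioned to sum to this exactly.
#' @param category_mix Named proportions over facility categories
#'   (normalized internally).
#' @param metro_fraction Share of districts designated metropolitan
#'   (denser, higher-volume).
#' @param metro_weight Facility-allocation weight of a metro district
#'   relative to a rural one.
#' @param metro_volume_boost Multiplier on volume weights for facilities in
#'   metro districts.
#' @param district_size_dispersion Log-normal sdlog of the per-district
#'   facility-allocation weight (district size heterogeneity).
#' @param volume_dispersion Log-normal sdlog of the per-facility volume
#'   weight (heavy-tail shape).
#' @param extent_lat,extent_lon Country extent, decimal degrees.
#' @param seed Integer seed; identical seeds give identical networks.
#' @return A list of class `network_config`.
#' @export
network_config <- function(n_districts = 52, n_provinces = 9,
                           n_facilities = 4756, n_labs = 65,
                           n_gp_labs = 195, n_lab_free_districts = 14,
                           total_annual_tests = 3900000,
                           category_mix = c(mobile = 0.19, satellite = 0.04,
                                            phc = 0.65, cdc = 0.01,
                                            chc = 0.05,
                                            district_hospital = 0.05,
                                            regional_hospital = 0.01),
                           metro_fraction = 0.15, metro_weight = 6,
                           metro_volume_boost = 3,
                           district_size_dispersion = 0.7,
                           volume_dispersion = 1.5,
                           extent_lat = c(-34.8, -22.1),
                           extent_lon = c(16.5, 32.9),
                           seed = 1L) {
  if (any(c(n_districts, n_provinces, n_facilities, n_labs,
            total_annual_tests) <= 0)) {
    stop("all network counts must be positive", call. = FALSE)
  }
  if (n_labs > n_facilities) {
    stop("infeasible config: more laboratories than facilities", call. = FALSE)
  }
  if (n_lab_free_districts >= n_districts) {
    stop("infeasible config: every district would be laboratory-free",
         call. = FALSE)
  }
  if (any(category_mix < 0) || sum(category_mix) <= 0) {
    stop("category_mix must be non-negative with positive sum", call. = FALSE)
  }
  bad <- setdiff(names(category_mix), facility_categories)
  if (length(bad)) {
    stop("unknown categories in category_mix: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  category_mix <- category_mix / sum(category_mix)
  structure(as.list(environment()), class = "network_config")
}

# volume-weight multiplier per facility category: hospitals refer far more
# tests than mobile outreach clinics; tuned so that ~2/3 of national volume
# originates from primary-care-type facilities (mobile/satellite/PHC),
# ~27% from hospital-attached clinics and the rest from community centres
category_volume_multiplier <- c(
  mobile = 0.3, satellite = 0.7, phc = 1.25, cdc = 2, chc = 2,
  district_hospital = 5.5, regional_hospital = 8, tertiary_hospital = 10,
  parastatal = 0.5
)

#' Generate a synthetic facility/laboratory network
#'
#' Districts are laid out as jittered grid cells over the country extent
#' and grouped into provinces by proximity; facilities are drawn per
#' district from a two-component spatial mixture (a tight "town" cluster
#' plus a dispersed rural scatter, tighter and denser in metro districts).
#' Annual volumes are heavy-tailed log-normal draws with category and
#' metro multipliers, apportioned by largest remainder so they sum exactly
#' to the configured national total. CD4 laboratories go preferentially to
#' high-volume districts (every hosting district gets one, the remainder
#' follow volume), leaving the configured number of districts
#' laboratory-free; general-pathology laboratories cover all districts.
#'
#' @param config A [network_config()].
#' @return A list of class `tiernet_network` with elements `facilities`
#'   (a `facility_registry`), `labs` (a `laboratory_registry`; rows with
#'   `instrument_capacity_per_day > 0` are CD4 testing sites) and
#'   `districts` (a data.frame with centroids, province, metro flag and
#'   totals).
#' @export
generate_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  set.seed(config$seed)
  cfg <- config

  ## district centroids on a jittered grid
  nc <- ceiling(sqrt(cfg$n_districts))
  nr <- ceiling(cfg$n_districts / nc)
  cell_lon <- diff(cfg$extent_lon) / nc
  cell_lat <- diff(cfg$extent_lat) / nr
  grid <- expand.grid(ix = seq_len(nc), iy = seq_len(nr))
  keep <- sample(nrow(grid), cfg$n_districts)
  cen_lon <- cfg$extent_lon[1] + (grid$ix[keep] - 0.5) * cell_lon +
    stats::runif(cfg$n_districts, -0.15, 0.15) * cell_lon
  cen_lat <- cfg$extent_lat[1] + (grid$iy[keep] - 0.5) * cell_lat +
    stats::runif(cfg$n_districts, -0.15, 0.15) * cell_lat
  district_id <- sprintf("D%02d", seq_len(cfg$n_districts))

  ## provinces: spatial clusters of district centroids
  km <- stats::kmeans(cbind(cen_lon, cen_lat), centers = cfg$n_provinces,
                      nstart = 5)
  province <- sprintf("P%d", km$cluster)

  ## metro designation
  n_metro <- max(1L, round(cfg$metro_fraction * cfg$n_districts))
  metro <- rep(FALSE, cfg$n_districts)
  metro[sample(cfg$n_districts, n_metro)] <- TRUE

  ## facilities per district: metro districts denser, and district sizes
  ## heterogeneous (facility counts track population density, so remote
  ## low-volume districts are also facility-sparse)
  dweight <- ifelse(metro, cfg$metro_weight, 1) *
    stats::rlnorm(cfg$n_districts, 0, cfg$district_size_dispersion)
  fac_district <- sample(cfg$n_districts, cfg$n_facilities, replace = TRUE,
                         prob = dweight)
  ## within-district locations: town cluster + rural scatter
  town_share <- ifelse(metro[fac_district], 0.75, 0.35)
  in_town <- stats::runif(cfg$n_facilities) < town_share
  sd_deg <- ifelse(in_town, 0.06, 0.2 * min(cell_lon, cell_lat))
  fac_lon <- cen_lon[fac_district] + stats::rnorm(cfg$n_facilities, 0, sd_deg)
  fac_lat <- cen_lat[fac_district] + stats::rnorm(cfg$n_facilities, 0, sd_deg)

  ## categories and heavy-tailed volumes
  category <- sample(names(cfg$category_mix), cfg$n_facilities,
                     replace = TRUE, prob = cfg$category_mix)
  w <- category_volume_multiplier[category] *
    ifelse(metro[fac_district] & in_town, cfg$metro_volume_boost, 1) *
    stats::rlnorm(cfg$n_facilities, 0, cfg$volume_dispersion)
  volumes <- largest_remainder(w / sum(w) * cfg$total_annual_tests,
                               cfg$total_annual_tests)

  facilities <- facility_registry(data.frame(
    id = sprintf("F%04d", seq_len(cfg$n_facilities)),
    name = sprintf("Facility %04d", seq_len(cfg$n_facilities)),
    category = category,
    district_id = district_id[fac_district],
    latitude = fac_lat, longitude = fac_lon,
    annual_volume = volumes,
    stringsAsFactors = FALSE
  ))

  district_volume <- as.numeric(tapply(volumes,
                                       factor(fac_district,
                                              levels = seq_len(cfg$n_districts)),
                                       sum, default = 0))

  ## lab-free districts: the lowest-volume non-metro districts
  rank_vol <- order(district_volume + ifelse(metro, Inf, 0))
  lab_free <- rank_vol[seq_len(cfg$n_lab_free_districts)]
  hosting <- setdiff(seq_len(cfg$n_districts), lab_free)
  if (cfg$n_labs < length(hosting)) {
    hosting <- hosting[order(district_volume[hosting],
                             decreasing = TRUE)][seq_len(cfg$n_labs)]
  }
  ## one lab per hosting district, remainder by volume share
  extra <- cfg$n_labs - length(hosting)
  labs_per <- rep(1, length(hosting))
  if (extra > 0) {
    share <- district_volume[hosting] / sum(district_volume[hosting])
    labs_per <- labs_per + largest_remainder(share * extra, extra)
  }

  lab_rows <- list()
  for (k in seq_along(hosting)) {
    d <- hosting[k]
    nl <- labs_per[k]
    ## labs sit at the district's busiest facilities (town core)
    infac <- which(fac_district == d)
    anchor <- infac[order(volumes[infac], decreasing = TRUE)]
    anchor <- anchor[seq_len(min(nl, length(anchor)))]
    anchor <- rep_len(anchor, nl)
    demand <- district_volume[d] / 260 / nl
    tier_k <- tier_of_volume(demand, tier_schedule())
    cap_unit <- tier_schedule()$instrument_capacity[[tier_k]]
    n_inst <- pmax(1, ceiling(demand * 1.5 / cap_unit))
    lab_rows[[k]] <- data.frame(
      district = d,
      latitude = fac_lat[anchor] + stats::rnorm(nl, 0, 0.01),
      longitude = fac_lon[anchor] + stats::rnorm(nl, 0, 0.01),
      capacity = cap_unit * n_inst,
      stringsAsFactors = FALSE
    )
  }
  lab_rows <- do.call(rbind, lab_rows)
  cd4_labs <- data.frame(
    id = sprintf("L%03d", seq_len(nrow(lab_rows))),
    latitude = lab_rows$latitude, longitude = lab_rows$longitude,
    district_id = district_id[lab_rows$district],
    tier = NA_character_,
    instrument_capacity_per_day = as.integer(lab_rows$capacity),
    offers_general_pathology = TRUE,
    stringsAsFactors = FALSE
  )

  ## general-pathology-only laboratories: one per district, rest by
  ## facility count
  gp <- NULL
  if (cfg$n_gp_labs > 0) {
    n_fac_d <- tabulate(fac_district, cfg$n_districts)
    gp_per <- rep(1, cfg$n_districts)
    extra_gp <- cfg$n_gp_labs - cfg$n_districts
    if (extra_gp > 0) {
      gp_per <- gp_per + largest_remainder(n_fac_d / sum(n_fac_d) * extra_gp,
                                           extra_gp)
    } else {
      gp_per <- rep(0, cfg$n_districts)
      gp_per[sample(cfg$n_districts, cfg$n_gp_labs)] <- 1
    }
    gp_district <- rep(seq_len(cfg$n_districts), gp_per)
    ## host sites scatter like mid-size facilities around district centres
    gp <- data.frame(
      id = sprintf("G%03d", seq_along(gp_district)),
      latitude = cen_lat[gp_district] +
        stats::rnorm(length(gp_district), 0, 0.25 * cell_lat),
      longitude = cen_lon[gp_district] +
        stats::rnorm(length(gp_district), 0, 0.25 * cell_lon),
      district_id = district_id[gp_district],
      tier = NA_character_,
      instrument_capacity_per_day = 0L,
      offers_general_pathology = TRUE,
      stringsAsFactors = FALSE
    )
  }

  labs <- laboratory_registry(rbind(cd4_labs, gp))

  districts <- data.frame(
    id = district_id, province = province,
    latitude = cen_lat, longitude = cen_lon,
    metro = metro,
    n_facilities = tabulate(fac_district, cfg$n_districts),
    annual_volume = district_volume,
    has_cd4_lab = seq_len(cfg$n_districts) %in% hosting,
    stringsAsFactors = FALSE
  )

  structure(list(facilities = facilities, labs = labs, districts = districts,
                 config = config),
            class = "tiernet_network")
}

#' @export
print.tiernet_network <- function(x, ...) {
  cd4 <- sum(x$labs$instrument_capacity_per_day > 0)
  cat(sprintf(paste0("Synthetic network: %d facilities, %d districts ",
                     "(%d without a CD4 lab), %d CD4 + %d general labs, ",
                     "%s tests/yr\n"),
              nrow(x$facilities), nrow(x$districts),
              sum(!x$districts$has_cd4_lab), cd4, nrow(x$labs) - cd4,
              format(sum(x$facilities$annual_volume), big.mark = ",")))
  invisible(x)
}
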