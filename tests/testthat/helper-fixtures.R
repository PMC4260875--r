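# in-code fixtures: tiny registries built programmatically

make_facilities <- function(lat, lon, volume = 1000,
                            category = "phc", district = "D01",
                            id = sprintf("F%03d", seq_along(lat))) {
  facility_registry(data.frame(
    id = id, name = paste("fac", id), category = category,
    district_id = district, latitude = lat, longitude = lon,
    annual_volume = volume, stringsAsFactors = FALSE
  ))
}

make_labs <- function(lat, lon, id = sprintf("L%03d", seq_along(lat)),
                      district = "D01", capacity = 384, gp = TRUE) {
  laboratory_registry(data.frame(
    id = id, latitude = lat, longitude = lon, district_id = district,
    tier = NA_character_, instrument_capacity_per_day = capacity,
    offers_general_pathology = gp, stringsAsFactors = FALSE
  ))
}

# random registry over a small extent, for round-trip / oracle properties
random_facilities <- function(n, seed = NULL, volume_max = 5000) {
  if (!is.null(seed)) set.seed(seed)
  make_facilities(
    lat = runif(n, -34, -23), lon = runif(n, 17, 32),
    volume = sample.int(volume_max, n, replace = TRUE),
    category = sample(c("mobile", "satellite", "phc", "chc",
                        "district_hospital"), n, replace = TRUE),
    district = sample(sprintf("D%02d", 1:5), n, replace = TRUE)
  )
}

random_labs <- function(m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  make_labs(lat = runif(m, -34, -23), lon = runif(m, 17, 32),
            id = sprintf("L%03d", sample(900, m)))
}

# independent brute-force nearest-lab search (the oracle never calls
# assign_nearest internals): plain double loop over geosphere distances
brute_force_nearest <- function(facilities, labs) {
  sapply(seq_len(nrow(facilities)), function(i) {
    d <- sapply(seq_len(nrow(labs)), function(j) {
      geosphere::distHaversine(
        c(facilities$longitude[i], facilities$latitude[i]),
        c(labs$longitude[j], labs$latitude[j]), r = 6371008.8) / 1000
    })
    cand <- which(d <= min(d) + 1e-9)
    labs$id[cand[order(labs$id[cand])][1L]]
  })
}

# exhaustive minimum set cover over candidate coverage sets (list of
# integer vectors); returns the size of the smallest complete cover
brute_force_min_cover <- function(sets, universe) {
  m <- length(sets)
  for (k in seq_len(m)) {
    combs <- utils::combn(m, k, simplify = FALSE)
    for (cc in combs) {
      if (all(universe %in% unlist(sets[cc]))) return(k)
    }
  }
  Inf
}

# small default-structure network for pipeline tests (fast)
small_network <- function(seed = 42) {
  generate_network(network_config(
    n_districts = 12, n_provinces = 3, n_facilities = 400, n_labs = 9,
    n_gp_labs = 24, n_lab_free_districts = 3, total_annual_tests = 300000,
    seed = seed
  ))
}
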