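#' Classify testing sites into service tiers by daily volume
#'
#' Tier membership is a step function of daily sample volume against the
#' schedule's breaks, with inclusive upper bounds: tier 1 handles up to 10
#' samples/day, tier 2 up to 40, tier 3 up to 150, tier 4 up to 300 and
#' tier 5 anything above. Clinic counts never decide the tier; they are an
#' advisory consistency annotation checked against the schedule's
#' clinic-count ranges (published descriptions of clinic loads per tier are
#' mutually inconsistent, so they cannot be a constraint).
#'
#' @param daily_volume Non-negative samples/day (vectorized).
#' @param clinics_served Optional integer count(s) of referring clinics.
#' @param schedule A [tier_schedule()].
#' @param lab_id Optional site id(s) carried into the result.
#' @return A data.frame of class `tier_assignment` with columns `lab_id`,
#'   `tier`, `daily_volume`, `clinics_served`, `clinic_count_consistent`,
#'   `capacity_margin` (single-instrument capacity minus demand).
#' @examples
#' classify_tier(c(5, 35, 120, 250, 650))$tier
#' @export
classify_tier <- function(daily_volume, clinics_served = NA_integer_,
                          schedule = tier_schedule(), lab_id = NULL) {
  schedule <- as_schedule(schedule)
  if (any(is.na(daily_volume)) || any(daily_volume < 0)) {
    stop("daily_volume must be non-negative", call. = FALSE)
  }
  if (any(daily_volume == 0)) {
    warning("site(s) with zero demand classified as tier 1", call. = FALSE)
  }
  breaks <- schedule$volume_breaks
  # inclusive upper bounds: volume <= breaks[k] => tier k
  tier_idx <- vapply(daily_volume,
                     function(v) which(v <= breaks)[1L], integer(1))
  n <- length(daily_volume)
  clinics_served <- rep_len(as.integer(clinics_served), n)
  rng <- schedule$clinic_count_range
  consistent <- !is.na(clinics_served) &
    clinics_served >= rng[tier_idx, "min"] &
    clinics_served <= rng[tier_idx, "max"]
  consistent[is.na(clinics_served)] <- NA
  out <- data.frame(
    lab_id = if (is.null(lab_id)) paste0("site", seq_len(n)) else
      as.character(lab_id),
    tier = paste0("T", tier_idx),
    daily_volume = daily_volume,
    clinics_served = clinics_served,
    clinic_count_consistent = consistent,
    capacity_margin = schedule$instrument_capacity[tier_idx] - daily_volume,
    stringsAsFactors = FALSE
  )
  class(out) <- c("tier_assignment", "data.frame")
  out
}

#' Derive per-laboratory demand and tiers from an assignment
#'
#' Aggregates assigned annual facility volumes per laboratory, converts to
#' daily demand using the schedule's working days, and classifies each
#' laboratory with [classify_tier()]. Laboratories with no assigned
#' facilities get zero demand (tier 1, flagged by the zero-demand warning).
#'
#' @param assignments Output of [assign_nearest()].
#' @param facilities,labs The registries used for the assignment.
#' @param schedule A [tier_schedule()].
#' @return A `tier_assignment` data.frame, one row per laboratory in `labs`.
#' @export
tier_laboratories <- function(assignments, facilities, labs,
                              schedule = tier_schedule()) {
  schedule <- as_schedule(schedule)
  vol <- facilities$annual_volume[match(assignments$facility_id, facilities$id)]
  annual <- tapply(vol, factor(assignments$lab_id, levels = labs$id), sum,
                   default = 0)
  clinics <- tapply(rep(1L, nrow(assignments)),
                    factor(assignments$lab_id, levels = labs$id), sum,
                    default = 0L)
  suppressWarnings(
    classify_tier(as.numeric(annual) / schedule$working_days_per_year,
                  clinics_served = as.integer(clinics),
                  schedule = schedule, lab_id = labs$id)
  )
}

#' Compare installed instrument capacity to assigned demand
#'
#' Capacity at a site is the schedule's per-instrument daily capacity for
#' its tier times the number of instruments installed; the margin is
#' capacity minus daily demand, and sites with negative margin are flagged
#' as under-capacity. Positive margins are expected (capacity redundancy
#' retained for service growth and disaster recovery).
#'
#' @param tier_assignments A `tier_assignment` table.
#' @param schedule A [tier_schedule()].
#' @param n_instruments Instruments per site (recycled; default 1).
#' @return A data.frame `lab_id, tier, capacity, demand, margin, flagged`.
#' @examples
#' ta <- classify_tier(250, 80, lab_id = "L1")
#' capacity_check(ta, n_instruments = 2) # 2 x 384 - 250
#' @export
capacity_check <- function(tier_assignments, schedule = tier_schedule(),
                           n_instruments = 1L) {
  schedule <- as_schedule(schedule)
  tiers <- tier_assignments$tier
  bad <- !tiers %in% names(schedule$instrument_capacity)
  if (any(bad)) {
    stop("unknown tier(s): ", paste(unique(tiers[bad]), collapse = ", "),
         call. = FALSE)
  }
  n_instruments <- rep_len(as.integer(n_instruments), nrow(tier_assignments))
  capacity <- schedule$instrument_capacity[tiers] * n_instruments
  margin <- capacity - tier_assignments$daily_volume
  data.frame(
    lab_id = tier_assignments$lab_id,
    tier = tiers,
    capacity = as.numeric(capacity),
    demand = tier_assignments$daily_volume,
    margin = as.numeric(margin),
    flagged = margin < 0,
    stringsAsFactors = FALSE
  )
}

tier_number <- function(tier) as.integer(sub("^T", "", tier))

#' Build the hierarchical parent-support graph
#'
#' Every tier-1 and tier-2 site is linked to its nearest laboratory of tier
#' 3 or higher, which acts as its "parent" for quality control, training
#' and equipment support. The parent need not be tier 3: a closer tier-4 or
#' tier-5 laboratory qualifies equally. The result is a forest — each child
#' has exactly one parent, and parents always sit strictly higher in the
#' tier hierarchy.
#'
#' @param tier_assignments A `tier_assignment` table.
#' @param locations A data.frame with `id, latitude, longitude` (for
#'   instance a `laboratory_registry`) covering every site in
#'   `tier_assignments`.
#' @param min_parent_tier Lowest tier allowed to act as parent (default 3).
#' @return A data.frame of `SupportEdge`s: `child_id, parent_id,
#'   child_tier, parent_tier, distance_km`.
#' @export
build_support_graph <- function(tier_assignments, locations,
                                min_parent_tier = 3L) {
  tn <- tier_number(tier_assignments$tier)
  children <- which(tn < min_parent_tier)
  parents <- which(tn >= min_parent_tier)
  if (length(children) == 0L) {
    return(data.frame(child_id = character(), parent_id = character(),
                      child_tier = character(), parent_tier = character(),
                      distance_km = numeric(), stringsAsFactors = FALSE))
  }
  if (length(parents) == 0L) {
    stop("no qualifying parent site (tier >= ", min_parent_tier,
         ") for orphan site(s): ",
         paste(tier_assignments$lab_id[children], collapse = ", "),
         call. = FALSE)
  }
  loc <- locations[match(tier_assignments$lab_id, locations$id), , drop = FALSE]
  if (anyNA(loc$latitude)) {
    stop("locations missing for some sites", call. = FALSE)
  }
  d <- distance_matrix_km(
    data.frame(id = tier_assignments$lab_id[children],
               latitude = loc$latitude[children],
               longitude = loc$longitude[children]),
    data.frame(id = tier_assignments$lab_id[parents],
               latitude = loc$latitude[parents],
               longitude = loc$longitude[parents]))
  ord <- order(tier_assignments$lab_id[parents])
  pick <- apply(d[, ord, drop = FALSE], 1L, function(row) {
    ord[which(row <= min(row) + 1e-9)[1L]]
  })
  data.frame(
    child_id = tier_assignments$lab_id[children],
    parent_id = tier_assignments$lab_id[parents][pick],
    child_tier = tier_assignments$tier[children],
    parent_tier = tier_assignments$tier[parents][pick],
    distance_km = d[cbind(seq_along(children), pick)],
    stringsAsFactors = FALSE
  )
}

#' Find super-laboratory consolidation candidates
#'
#' High-volume (tier 4/5) laboratories lying within one precinct radius of
#' each other, whose combined daily demand exceeds the schedule's
#' super-laboratory break (default 600 samples/day), are candidates for
#' consolidation into a single centralized "super-laboratory". Clusters are
#' the connected components of the within-radius proximity graph restricted
#' to tier-4/5 sites.
#'
#' @param tier_assignments A `tier_assignment` table.
#' @param locations A data.frame with `id, latitude, longitude`.
#' @param schedule A [tier_schedule()].
#' @return A list of candidate clusters; each element is a list with
#'   `lab_ids` and `combined_daily_volume`.
#' @export
superlab_candidates <- function(tier_assignments, locations,
                                schedule = tier_schedule()) {
  schedule <- as_schedule(schedule)
  high <- which(tier_number(tier_assignments$tier) >= 4L)
  if (length(high) < 2L) return(list())
  ids <- tier_assignments$lab_id[high]
  loc <- locations[match(ids, locations$id), , drop = FALSE]
  d <- distance_matrix_km(data.frame(id = ids, latitude = loc$latitude,
                                     longitude = loc$longitude),
                          data.frame(id = ids, latitude = loc$latitude,
                                     longitude = loc$longitude))
  adj <- d <= schedule$radius_km
  comp <- connected_components(adj)
  out <- list()
  for (k in unique(comp)) {
    members <- which(comp == k)
    if (length(members) < 2L) next
    vol <- sum(tier_assignments$daily_volume[high][members])
    if (vol > schedule$superlab_break) {
      out[[length(out) + 1L]] <- list(lab_ids = sort(ids[members]),
                                      combined_daily_volume = vol)
    }
  }
  out
}

# label connected components of a logical adjacency matrix (BFS)
connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    k <- k + 1L
    queue <- i
    comp[i] <- k
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}
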