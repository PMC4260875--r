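#' Propose new decentralized testing sites by greedy maximal covering
#'
#' Formalizes map-based siting of new tier-1/2/3 services as a greedy
#' maximal covering heuristic. Candidates are (a) laboratories that already
#' offer general pathology (potential tier-2 POC-hubs or tier-3 community
#' laboratories) and (b) the uncovered facilities themselves (potential
#' on-site tier-1 POC). At each step the candidate covering the most
#' still-uncovered facilities is selected (ties broken by largest covered
#' annual volume, then smallest candidate id); its proposed tier is
#' obtained by [classify_tier()] on the daily volume it would absorb. If
#' the absorbed volume classifies the site as tier 1/2, its catchment is
#' restricted to the schedule's hub radius (default 20 km) and the
#' selection re-evaluated, since POC-hubs only consolidate nearby clinics.
#' Selection stops when no candidate newly covers at least `min_gain`
#' facilities; every remaining facility becomes an on-site tier-1 POC in
#' the residual.
#'
#' The procedure is deterministic: no randomness, documented tie-breaks.
#'
#' @param uncovered A `facility_registry` (or data.frame) of facilities
#'   outside all current service precincts.
#' @param candidates A `laboratory_registry` of candidate host sites;
#'   only rows with `offers_general_pathology = TRUE` are used.
#' @param schedule A [tier_schedule()]; supplies `radius_km` (tier-3
#'   catchment), `hub_radius_km` (tier-1/2 catchment) and working days.
#' @param min_gain Minimum number of newly covered facilities for a hub to
#'   be worth opening (default 2: a single isolated clinic is served
#'   on-site rather than via a dedicated hub).
#' @return A list of class `placement_plan`: `sites` (data.frame
#'   `candidate_id, proposed_tier, n_covered, annual_volume, daily_volume`),
#'   `covered_by` (named list: facility ids newly covered by each site),
#'   `residual_ids` (facilities left to on-site tier-1), `residual_volume`.
#' @export
propose_sites <- function(uncovered, candidates, schedule = tier_schedule(),
                          min_gain = 2L) {
  schedule <- as_schedule(schedule)
  sites <- data.frame(candidate_id = character(), proposed_tier = character(),
                      n_covered = integer(), annual_volume = numeric(),
                      daily_volume = numeric(), stringsAsFactors = FALSE)
  covered_by <- list()
  if (nrow(uncovered) == 0L) {
    return(structure(list(sites = sites, covered_by = covered_by,
                          residual_ids = character(), residual_volume = 0),
                     class = "placement_plan"))
  }
  cand <- candidates[isTRUE_vec(candidates$offers_general_pathology), ,
                     drop = FALSE]
  open <- rep(TRUE, nrow(uncovered))
  names(open) <- uncovered$id
  wd <- schedule$working_days_per_year

  if (nrow(cand) > 0L) {
    d <- distance_matrix_km(uncovered, cand)
    repeat {
      best <- NULL
      for (j in seq_len(nrow(cand))) {
        res <- candidate_gain(d[, j], open, uncovered$annual_volume,
                              schedule, wd)
        if (res$gain < min_gain) next
        if (is.null(best) ||
            res$gain > best$gain ||
            (res$gain == best$gain && res$volume > best$volume) ||
            (res$gain == best$gain && res$volume == best$volume &&
               cand$id[j] < cand$id[best$j])) {
          best <- c(res, list(j = j))
        }
      }
      if (is.null(best)) break
      ids <- uncovered$id[best$members]
      sites <- rbind(sites, data.frame(
        candidate_id = cand$id[best$j], proposed_tier = best$tier,
        n_covered = best$gain, annual_volume = best$volume,
        daily_volume = best$volume / wd, stringsAsFactors = FALSE))
      covered_by[[cand$id[best$j]]] <- ids
      open[best$members] <- FALSE
      if (!any(open)) break
    }
  }

  residual <- uncovered$id[open]
  structure(list(
    sites = sites,
    covered_by = covered_by,
    residual_ids = residual,
    residual_volume = sum(uncovered$annual_volume[open])
  ), class = "placement_plan")
}

# coverage set, absorbed volume and proposed tier for one candidate given
# the currently open (uncovered) facilities
candidate_gain <- function(dist_col, open, volumes, schedule, wd) {
  in_range <- open & dist_col <= schedule$radius_km
  vol <- sum(volumes[in_range])
  tier <- tier_of_volume(vol / wd, schedule)
  if (tier <= 2L) {
    # POC-hub scale: consolidate only clinics within the hub radius
    in_range <- open & dist_col <= schedule$hub_radius_km
    vol <- sum(volumes[in_range])
    tier <- tier_of_volume(vol / wd, schedule)
  }
  list(gain = sum(in_range), members = which(in_range), volume = vol,
       tier = paste0("T", tier))
}

tier_of_volume <- function(daily, schedule) {
  which(daily <= schedule$volume_breaks)[1L]
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Summarize a placement plan by tier
#'
#' @param plan A `placement_plan` from [propose_sites()].
#' @param schedule A [tier_schedule()].
#' @param national_total Optional national annual test volume; when given,
#'   each tier's absorbed share of it is reported.
#' @return A data.frame, one row per tier T1..T5, with `n_sites`,
#'   `annual_volume` absorbed and `share_of_national` (NA if no total
#'   supplied). Residual on-site tier-1 facilities are counted as tier-1
#'   sites.
#' @export
plan_summary <- function(plan, schedule = tier_schedule(),
                         national_total = NULL) {
  stopifnot(inherits(plan, "placement_plan"))
  tiers <- paste0("T", 1:5)
  n_sites <- annual <- stats::setNames(numeric(5), tiers)
  if (nrow(plan$sites)) {
    agg_n <- tapply(rep(1L, nrow(plan$sites)),
                    factor(plan$sites$proposed_tier, levels = tiers), sum,
                    default = 0)
    agg_v <- tapply(plan$sites$annual_volume,
                    factor(plan$sites$proposed_tier, levels = tiers), sum,
                    default = 0)
    n_sites <- n_sites + as.numeric(agg_n)
    annual <- annual + as.numeric(agg_v)
  }
  n_sites[["T1"]] <- n_sites[["T1"]] + length(plan$residual_ids)
  annual[["T1"]] <- annual[["T1"]] + plan$residual_volume
  data.frame(
    tier = tiers,
    n_sites = as.integer(n_sites),
    annual_volume = annual,
    share_of_national = if (is.null(national_total)) NA_real_ else
      annual / national_total,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @export
print.placement_plan <- function(x, ...) {
  cat("Placement plan:", nrow(x$sites), "proposed hub/laboratory site(s),",
      length(x$residual_ids), "residual on-site tier-1 facilities\n")
  if (nrow(x$sites)) print(x$sites, ...)
  invisible(x)
}
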