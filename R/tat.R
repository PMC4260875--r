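#' Parameters of the turnaround-time simulator
#'
#' The pre-analytic leg is modelled as a fixed dispatch delay plus courier
#' travel at constant speed plus a uniform batching wait (samples
#' accumulate until the next courier run). The laboratory leg (LTR:
#' registration to authorization) is a log-normal processing time plus two
#' structural delays: samples arriving after the laboratory's same-day
#' cutoff wait overnight for the next processing run — which is how longer
#' courier distances degrade laboratory TAT in this model — and
#' laboratories loaded beyond instrument capacity add a penalty
#' proportional to the excess.
#'
#' Defaults are calibrated to the qualitative remote-district contrast: a
#' ~400 km referral gives a median pre-analytic time above 15 h, while a
#' local (~30 km) laboratory brings the median under 5 h and overall LTR
#' under ~18 h.
#'
#' @param courier_speed_km_per_h Effective courier speed including stops.
#' @param courier_base_delay_h Fixed handling/dispatch delay, hours.
#' @param batching_interval_h Courier run interval; the batching wait is
#'   uniform on `[0, batching_interval_h]`.
#' @param lab_processing_median_h,lab_processing_sdlog Log-normal LTR
#'   processing component (median in hours, dispersion on the log scale).
#' @param overload_penalty_h Added LTR hours per unit of demand/capacity
#'   excess above 1.
#' @param dispatch_window_h Clock window (start, end) in which clinics
#'   dispatch samples.
#' @param lab_open_h,lab_cutoff_h Laboratory receiving window; arrivals
#'   outside it wait for the next opening.
#' @param seed Integer seed.
#' @return A list of class `tat_params`.
#' @export
tat_params <- function(courier_speed_km_per_h = 30,
                       courier_base_delay_h = 0.5,
                       batching_interval_h = 5,
                       lab_processing_median_h = 6,
                       lab_processing_sdlog = 1.0,
                       overload_penalty_h = 6,
                       dispatch_window_h = c(8, 12),
                       lab_open_h = 8, lab_cutoff_h = 16,
                       seed = 1L) {
  p <- as.list(environment())
  positives <- c("courier_speed_km_per_h", "lab_processing_median_h",
                 "lab_processing_sdlog")
  for (nm in positives) {
    if (p[[nm]] <= 0) stop("`", nm, "` must be positive", call. = FALSE)
  }
  for (nm in c("courier_base_delay_h", "batching_interval_h",
               "overload_penalty_h")) {
    if (p[[nm]] < 0) stop("`", nm, "` must be non-negative", call. = FALSE)
  }
  structure(p, class = "tat_params")
}

#' Simulate per-sample turnaround-time records
#'
#' Draws `n_per_facility` sample journeys for every assigned facility and
#' returns one record per sample with its pre-analytic, laboratory (LTR)
#' and total turnaround components (`total_h = pre_analytic_h + ltr_h`).
#'
#' @param assignments An [assign_nearest()] table; every facility must have
#'   an assigned laboratory.
#' @param params A [tat_params()].
#' @param facilities Optional `facility_registry` used to attach
#'   `district_id` to each record.
#' @param n_per_facility Samples simulated per facility.
#' @param lab_load Optional named vector of demand/capacity ratios per
#'   laboratory id; ratios above 1 incur the overload penalty.
#' @return A data.frame of class `tat_records`: `sample_id, facility_id,
#'   district_id, lab_id, distance_km, pre_analytic_h, ltr_h, total_h`.
#' @export
generate_tat_records <- function(assignments, params = tat_params(),
                                 facilities = NULL, n_per_facility = 10L,
                                 lab_load = NULL) {
  stopifnot(inherits(params, "tat_params"))
  unassigned <- is.na(assignments$lab_id)
  if (any(unassigned)) {
    stop("facilities without an assigned laboratory: ",
         paste(assignments$facility_id[unassigned], collapse = ", "),
         call. = FALSE)
  }
  set.seed(params$seed)
  n_fac <- nrow(assignments)
  n <- n_fac * n_per_facility
  fac_idx <- rep(seq_len(n_fac), each = n_per_facility)

  dispatch <- stats::runif(n, params$dispatch_window_h[1],
                           params$dispatch_window_h[2])
  batch_wait <- stats::runif(n, 0, params$batching_interval_h)
  travel <- assignments$distance_km[fac_idx] / params$courier_speed_km_per_h
  pre <- params$courier_base_delay_h + travel + batch_wait

  ## same-day cutoff: arrivals outside [open, cutoff) wait for next opening
  arrival <- (dispatch + pre) %% 24
  wait <- ifelse(arrival >= params$lab_open_h & arrival < params$lab_cutoff_h,
                 0, (params$lab_open_h - arrival) %% 24)

  proc <- stats::rlnorm(n, log(params$lab_processing_median_h),
                        params$lab_processing_sdlog)
  excess <- if (is.null(lab_load)) 0 else {
    pmax(0, lab_load[assignments$lab_id[fac_idx]] - 1)
  }
  excess[is.na(excess)] <- 0
  ltr <- wait + proc + params$overload_penalty_h * excess

  district <- if (is.null(facilities)) NA_character_ else {
    facilities$district_id[match(assignments$facility_id[fac_idx],
                                 facilities$id)]
  }
  out <- data.frame(
    sample_id = sprintf("S%07d", seq_len(n)),
    facility_id = assignments$facility_id[fac_idx],
    district_id = district,
    lab_id = assignments$lab_id[fac_idx],
    distance_km = assignments$distance_km[fac_idx],
    pre_analytic_h = pre,
    ltr_h = ltr,
    total_h = pre + ltr,
    stringsAsFactors = FALSE
  )
  class(out) <- c("tat_records", "data.frame")
  out
}

default_band_edges <- c(35, 85, 95)
default_band_labels <- c("<35%", "35-85%", "86-95%", "96-100%")

#' District-level turnaround-time banding
#'
#' For each district, computes the fraction of samples whose laboratory
#' (LTR) turnaround is within the threshold, and assigns the district to a
#' performance band. The default bands are contiguous percentage intervals
#' `[0,35) [35,85) [85,95) [95,100]`, a normalization of the published
#' choropleth legend (whose printed bands have small gaps).
#'
#' @param records A `tat_records` table (or any data.frame with
#'   `district_id` and `ltr_h`).
#' @param threshold_h TAT threshold in hours (default 48; use 24 for the
#'   strict mode).
#' @param band_edges Increasing percentage cut points defining the bands.
#' @param band_labels Labels, one more than `band_edges`.
#' @return A data.frame of class `district_tat_summary`: `district_id, n,
#'   fraction_within, band`, plus attributes `threshold_h` and
#'   `national_fraction`.
#' @export
summarize_tat <- function(records, threshold_h = 48,
                          band_edges = default_band_edges,
                          band_labels = default_band_labels) {
  if (nrow(records) == 0L) stop("no TAT records", call. = FALSE)
  if (any(diff(band_edges) <= 0)) {
    stop("band edges must be strictly increasing", call. = FALSE)
  }
  if (length(band_labels) != length(band_edges) + 1L) {
    stop("need one more label than band edges", call. = FALSE)
  }
  grp <- split(records$ltr_h, records$district_id)
  n <- vapply(grp, length, integer(1))
  frac <- vapply(grp, function(v) mean(v <= threshold_h), numeric(1))
  band <- band_labels[findInterval(100 * frac, band_edges) + 1L]
  band[n == 0L] <- NA_character_
  out <- data.frame(district_id = names(grp), n = n,
                    fraction_within = frac, band = band,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "threshold_h") <- threshold_h
  attr(out, "national_fraction") <- mean(records$ltr_h <= threshold_h)
  class(out) <- c("district_tat_summary", "data.frame")
  out
}

#' Before/after comparison of turnaround times in a district
#'
#' Paired summary of two simulated record sets (for example before and
#' after opening a local tier-3 laboratory): medians of the pre-analytic
#' and total turnaround components, fractions within the threshold, and
#' their deltas (after minus before).
#'
#' @param records_before,records_after `tat_records` tables.
#' @param district District id present in both sets.
#' @param threshold_h TAT threshold for the within-threshold fractions.
#' @return A list of class `tat_comparison` with `before`, `after` and
#'   `delta` rows of `median_pre_analytic_h`, `median_total_h`,
#'   `fraction_within`.
#' @export
before_after <- function(records_before, records_after, district,
                         threshold_h = 48) {
  pick <- function(r, label) {
    sub <- r[r$district_id %in% district, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("district '", district, "' absent from the ", label, " records",
           call. = FALSE)
    }
    c(median_pre_analytic_h = stats::median(sub$pre_analytic_h),
      median_ltr_h = stats::median(sub$ltr_h),
      median_total_h = stats::median(sub$total_h),
      fraction_within = mean(sub$ltr_h <= threshold_h))
  }
  b <- pick(records_before, "before")
  a <- pick(records_after, "after")
  structure(list(district = district, threshold_h = threshold_h,
                 before = b, after = a, delta = a - b),
            class = "tat_comparison")
}

#' @export
print.tat_comparison <- function(x, ...) {
  cat(sprintf("District %s (threshold %g h)\n", x$district, x$threshold_h))
  print(rbind(before = x$before, after = x$after, delta = x$delta), ...)
  invisible(x)
}
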