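#' Apportion a national annual volume across tiers
#'
#' Splits a total annual test volume into per-tier integer volumes by the
#' given shares using largest-remainder apportionment, so the parts always
#' sum exactly to the total. With the default schedule shares
#' (2/3/10/15/70%) and 3.9 million tests this yields
#' 78,000 / 117,000 / 390,000 / 585,000 / 2,730,000.
#'
#' @param total_annual Total tests per year (non-negative integer).
#' @param shares Per-tier proportions summing to 1 (default: the schedule's
#'   `volume_shares`).
#' @param schedule A [tier_schedule()] supplying default shares.
#' @return Named integer-valued numeric vector of per-tier annual volumes.
#' @examples
#' allocate_volumes(3900000)
#' allocate_volumes(7, c(0.5, 0.5)) # 4 3 — largest remainder
#' @export
allocate_volumes <- function(total_annual, shares = NULL,
                             schedule = tier_schedule()) {
  if (is.null(shares)) shares <- as_schedule(schedule)$volume_shares
  if (abs(sum(shares) - 1) > 1e-9) {
    stop("`shares` must sum to 1 (got ", format(sum(shares)), ")",
         call. = FALSE)
  }
  if (total_annual < 0) stop("`total_annual` must be non-negative", call. = FALSE)
  largest_remainder(shares * total_annual, total_annual)
}

# integer apportionment of `weights` (already scaled to sum to `total`):
# floor everything, hand out the shortfall to the largest fractional parts
# (ties: first position)
largest_remainder <- function(scaled, total) {
  base <- floor(scaled)
  shortfall <- round(total - sum(base))
  if (shortfall > 0) {
    frac <- scaled - base
    top_up <- order(frac, decreasing = TRUE)[seq_len(shortfall)]
    base[top_up] <- base[top_up] + 1
  }
  base
}

#' Cost a per-tier volume allocation
#'
#' Multiplies each tier's annual volume by its per-test cost and totals the
#' result. All arithmetic is carried out in integer cents, so totals are
#' exact and independent of summation order. Tier 6 (the coordinating
#' reference tier) carries no testing cost and must not receive volume.
#'
#' @param volumes Per-tier annual volumes, a numeric vector of length 5
#'   (tiers 1-5), e.g. from [allocate_volumes()].
#' @param schedule A [tier_schedule()].
#' @param name Scenario label (`"full_itsdm"`, `"widespread_poc"` or any
#'   custom string).
#' @return An object of class `cost_scenario`: per-tier volumes, unit costs,
#'   per-tier annual cost (USD), `total_usd` and `total_zar`.
#' @examples
#' sc <- scenario_cost(allocate_volumes(3900000))
#' sc$total_usd # 25583220
#' @export
scenario_cost <- function(volumes, schedule = tier_schedule(),
                          name = "custom") {
  schedule <- as_schedule(schedule)
  if (length(volumes) != 5L) {
    stop("`volumes` must give annual volumes for tiers 1-5", call. = FALSE)
  }
  if (any(is.na(volumes)) || any(volumes < 0)) {
    stop("volumes must be non-negative", call. = FALSE)
  }
  if (any(volumes != round(volumes))) {
    stop("volumes must be whole tests/year (use allocate_volumes())",
         call. = FALSE)
  }
  volumes <- stats::setNames(as.numeric(volumes), paste0("T", 1:5))
  cents <- volumes * as.numeric(schedule$cost_cents)
  total_cents <- sum(cents)
  structure(list(
    name = name,
    volumes = volumes,
    cost_per_test = schedule$cost_per_test,
    tier_cost_usd = stats::setNames(cents / 100, paste0("T", 1:5)),
    total_usd = total_cents / 100,
    total_zar = total_cents / 100 * schedule$zar_per_usd,
    zar_per_usd = schedule$zar_per_usd
  ), class = "cost_scenario")
}

#' The full tiered-model expansion scenario
#'
#' Costs each tier's allocated volume at that tier's own per-test rate:
#' decentralized tiers 1-3 absorb the service-extension volume at their
#' (cheaper, laboratory-based) rates while tiers 4-5 continue at theirs.
#'
#' @param schedule A [tier_schedule()].
#' @param total_annual National annual test volume (default 3,900,000).
#' @param shares Per-tier shares (default: the schedule's).
#' @return A `cost_scenario` named `"full_itsdm"`.
#' @export
scenario_full_itsdm <- function(schedule = tier_schedule(),
                                total_annual = 3900000, shares = NULL) {
  scenario_cost(allocate_volumes(total_annual, shares, schedule), schedule,
                name = "full_itsdm")
}

#' The widespread point-of-care counterfactual scenario
#'
#' The costing counterfactual in which no tier-2 or tier-3 services are
#' created: the entire extension volume (the combined tier-1/2/3
#' allocation) is tested at the tier-1 point-of-care rate, while tiers 4-5
#' continue at their own rates. With the published defaults the extension
#' volume is 585,000 tests costed at USD 32.32 each.
#'
#' @inheritParams scenario_full_itsdm
#' @return A `cost_scenario` named `"widespread_poc"` with the whole
#'   extension volume booked under tier 1.
#' @export
scenario_widespread_poc <- function(schedule = tier_schedule(),
                                    total_annual = 3900000, shares = NULL) {
  v <- allocate_volumes(total_annual, shares, schedule)
  poc <- c(sum(v[1:3]), 0, 0, v[[4L]], v[[5L]])
  scenario_cost(poc, schedule, name = "widespread_poc")
}

#' Compare two cost scenarios
#'
#' Reports the absolute saving of scenario `b` relative to scenario `a`
#' (`total(a) - total(b)`, so a positive saving means `b` is cheaper), in
#' USD and ZAR, together with the pairwise unit-cost comparison between
#' tiers: absolute differences and percentage ratios.
#'
#' @param a,b `cost_scenario` objects built under the same schedule.
#' @param schedule A [tier_schedule()].
#' @return An object of class `scenario_comparison` with `saving_usd`,
#'   `saving_zar`, `unit_cost_diff` (5x5 matrix, row minus column) and
#'   `unit_cost_pct` (row cost as a percentage above/of the column cost).
#' @examples
#' cmp <- compare_scenarios(scenario_widespread_poc(), scenario_full_itsdm())
#' cmp$saving_usd # 11634480
#' @export
compare_scenarios <- function(a, b, schedule = tier_schedule()) {
  stopifnot(inherits(a, "cost_scenario"), inherits(b, "cost_scenario"))
  schedule <- as_schedule(schedule)
  cents <- as.numeric(schedule$cost_cents)
  diff_mat <- outer(cents, cents, "-") / 100
  pct_mat <- outer(cents, cents, "/") * 100
  dimnames(diff_mat) <- dimnames(pct_mat) <-
    list(paste0("T", 1:5), paste0("T", 1:5))
  structure(list(
    a = a$name, b = b$name,
    saving_usd = a$total_usd - b$total_usd,
    saving_zar = (a$total_usd - b$total_usd) * schedule$zar_per_usd,
    unit_cost_diff = diff_mat,
    unit_cost_pct = pct_mat
  ), class = "scenario_comparison")
}

#' Convert a USD amount to ZAR
#'
#' @param usd Amount in USD.
#' @param schedule A [tier_schedule()] carrying the exchange rate.
#' @return Exact product `usd * zar_per_usd`.
#' @export
to_zar <- function(usd, schedule = tier_schedule()) {
  schedule <- as_schedule(schedule)
  if (schedule$zar_per_usd <= 0) stop("exchange rate must be positive", call. = FALSE)
  usd * schedule$zar_per_usd
}

#' @export
print.cost_scenario <- function(x, ...) {
  cat(sprintf("Cost scenario '%s'\n", x$name))
  tab <- data.frame(annual_volume = x$volumes,
                    cost_per_test_usd = x$cost_per_test,
                    annual_cost_usd = x$tier_cost_usd)
  print(tab, ...)
  cat(sprintf("total: $%s  (R%s at R%g/USD)\n",
              format(x$total_usd, big.mark = ","),
              format(x$total_zar, big.mark = ","), x$zar_per_usd))
  invisible(x)
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: saving $%s (R%s)\n", x$a, x$b,
              format(x$saving_usd, big.mark = ","),
              format(x$saving_zar, big.mark = ",")))
  invisible(x)
}
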