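#' Incremental cost-effectiveness ratio with quadrant classification
#'
#' Computes delta-cost / delta-effect and classifies the point on the
#' cost-effectiveness plane by the signs of (delta-effect, delta-cost):
#' NE (more effective, more costly), SE (more effective, less costly:
#' dominant), NW (less effective, more costly: dominated), SW (less
#' effective, less costly). In the SW quadrant the positive ratio reads as
#' money saved per unit of effect lost (equivalently the ICER of the
#' comparator). A zero effect difference yields an undefined ICER with a
#' dominance note.
#'
#' @param delta_cost Incremental cost (intervention minus comparator).
#' @param delta_effect Incremental effect (LYs or QALYs).
#' @return List with `value` (ratio, NA when undefined), `quadrant`
#'   (`"NE"`, `"SE"`, `"NW"`, `"SW"` or `"axis"`) and `label` (`"icer"`,
#'   `"dominant"`, `"dominated"`, `"equal-effect"`).
#' @export
#' @examples
#' icer(-64.3, -0.0291) # money saved per QALY lost, SW
icer <- function(delta_cost, delta_effect) {
  if (delta_effect == 0) {
    label <- if (delta_cost < 0) "dominant" else if (delta_cost > 0) "dominated" else "equal-effect"
    return(list(value = NA_real_, quadrant = "axis", label = label))
  }
  quadrant <- if (delta_effect > 0) {
    if (delta_cost >= 0) "NE" else "SE"
  } else {
    if (delta_cost >= 0) "NW" else "SW"
  }
  label <- switch(quadrant, SE = "dominant", NW = "dominated", "icer")
  list(value = delta_cost / delta_effect, quadrant = quadrant, label = label)
}

#' Incremental net monetary benefit
#'
#' @param delta_cost Incremental cost.
#' @param delta_effect Incremental effect (QALYs).
#' @param wtp Willingness-to-pay threshold (currency per effect unit), >= 0.
#' @return wtp * delta_effect - delta_cost; positive values indicate the
#'   intervention is cost-effective at that threshold.
#' @export
inmb <- function(delta_cost, delta_effect, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * delta_effect - delta_cost
}

#' Cost-effectiveness acceptability curve from PSA draws
#'
#' For each willingness-to-pay value, the probability that the intervention
#' is cost-effective is the share of draws with positive incremental net
#' monetary benefit; draws with INMB exactly zero are split evenly between
#' the strategies.
#'
#' @param delta_cost,delta_effect Vectors of per-draw incrementals
#'   (intervention minus comparator).
#' @param thresholds Willingness-to-pay grid (default 0 to 50,000 by 500).
#' @return Data frame with columns `wtp`, `p_intervention`, `p_comparator`.
#' @export
ceac <- function(delta_cost, delta_effect, thresholds = seq(0, 50000, by = 500)) {
  n <- length(delta_cost)
  if (n == 0) stop("at least one PSA draw is required")
  stopifnot(length(delta_effect) == n)
  p <- vapply(thresholds, function(l) {
    b <- l * delta_effect - delta_cost
    (sum(b > 0) + 0.5 * sum(b == 0)) / n
  }, numeric(1))
  data.frame(wtp = thresholds, p_intervention = p, p_comparator = 1 - p)
}

#' Cost-effectiveness plane quadrant shares
#'
#' Shares of PSA draws in each quadrant by the signs of
#' (delta-effect, delta-cost). Draws on an axis are assigned to the
#' non-negative side (delta-effect = 0 counts as effect >= 0; delta-cost = 0
#' as cost >= 0), so the four shares always sum to 1.
#'
#' @inheritParams ceac
#' @return Named numeric vector `c(NE, SE, NW, SW)` of proportions.
#' @export
quadrant_shares <- function(delta_cost, delta_effect) {
  n <- length(delta_cost)
  if (n == 0) stop("at least one PSA draw is required")
  e_pos <- delta_effect >= 0
  c_pos <- delta_cost >= 0
  c(NE = mean(e_pos & c_pos), SE = mean(e_pos & !c_pos),
    NW = mean(!e_pos & c_pos), SW = mean(!e_pos & !c_pos))
}

#' Assemble a cost-effectiveness result
#'
#' Combines per-arm lifetime totals into the incremental statistics reported
#' by the model. Incrementals are intervention (TXA) minus comparator
#' (no-TXA) throughout.
#'
#' @param txa,no_txa Per-arm totals from [lifetime_outputs()].
#' @param wtp Willingness-to-pay threshold for the INMB.
#' @return An object of class `txace_ce_result`: per-arm totals,
#'   incrementals (`delta_cost`, `delta_ly`, `delta_qaly`), `icer_ly`,
#'   `icer_qaly` (as returned by [icer()]), `inmb` and `wtp`.
#' @export
ce_result <- function(txa, no_txa, wtp = 20000) {
  delta_cost <- txa$cost - no_txa$cost
  delta_ly <- txa$ly - no_txa$ly
  delta_qaly <- txa$qaly - no_txa$qaly
  structure(list(
    txa = txa, no_txa = no_txa,
    delta_cost = delta_cost, delta_ly = delta_ly, delta_qaly = delta_qaly,
    icer_ly = icer(delta_cost, delta_ly),
    icer_qaly = icer(delta_cost, delta_qaly),
    inmb = inmb(delta_cost, delta_qaly, wtp),
    wtp = wtp
  ), class = "txace_ce_result")
}

#' @export
print.txace_ce_result <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = 2, big.mark = " ")
  cat("Cost-effectiveness result (TXA vs no-TXA)\n")
  cat(sprintf("  %-10s %12s %12s\n", "", "no-TXA", "TXA"))
  cat(sprintf("  %-10s %12s %12s\n", "cost (GBP)", fmt(x$no_txa$cost), fmt(x$txa$cost)))
  cat(sprintf("  %-10s %12.3f %12.3f\n", "LYs", x$no_txa$ly, x$txa$ly))
  cat(sprintf("  %-10s %12.3f %12.3f\n", "QALYs", x$no_txa$qaly, x$txa$qaly))
  cat(sprintf("  incremental: cost %.2f, LY %.4f, QALY %.4f\n",
              x$delta_cost, x$delta_ly, x$delta_qaly))
  cat(sprintf("  ICER: %s/LY, %s/QALY (%s quadrant)\n",
              fmt(x$icer_ly$value), fmt(x$icer_qaly$value), x$icer_qaly$quadrant))
  cat(sprintf("  INMB at %s GBP/QALY: %s\n", fmt(x$wtp), fmt(x$inmb)))
  invisible(x)
}
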