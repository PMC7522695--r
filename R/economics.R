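#' Incremental cost-effectiveness ratio
#'
#' Differences are comparator minus reference, computed from unrounded
#' discounted totals. Dominance is classified before any division: a
#' comparator that is cheaper and more effective is `"dominant"`, one that
#' is costlier and less effective is `"dominated"`; equal QALYs with a
#' cost difference yield a `"cost-only"` result rather than an error, and
#' identical totals are `"equivalent"`. Only in the remaining cases is the
#' ratio `delta_cost / delta_qaly` reported.
#'
#' @param reference,comparator lists with unrounded `cost` and `qaly`
#'   discounted totals.
#' @return an object of class `gist_icer` with `delta_cost`, `delta_qaly`,
#'   `icer` (`NA` unless status is `"icer"`) and `status`.
#' @export
icer <- function(reference, comparator) {
  dc <- comparator$cost - reference$cost
  dq <- comparator$qaly - reference$qaly
  status <- if (dq == 0 && dc == 0) "equivalent"
  else if (dq == 0) "cost-only"
  else if (dq > 0 && dc <= 0) "dominant"
  else if (dq < 0 && dc >= 0) "dominated"
  else "icer"
  structure(list(delta_cost = dc, delta_qaly = dq,
                 icer = if (status == "icer") dc / dq else NA_real_,
                 status = status),
            class = "gist_icer")
}

#' @export
print.gist_icer <- function(x, ...) {
  cat(sprintf("incremental cost: $%s, incremental QALY: %.4g\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_qaly))
  if (x$status == "icer")
    cat(sprintf("ICER: $%s per QALY\n", format(round(x$icer), big.mark = ",")))
  else
    cat("status:", x$status, "\n")
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = WTP x QALY - cost`. For a positive QALY difference, the
#' comparator having the larger NMB is equivalent to its ICER lying at or
#' below the willingness-to-pay threshold, but the NMB comparison stays
#' well-behaved when the ICER is undefined or sign-pathological, so all
#' decision logic in this package routes through NMB differences.
#'
#' @param totals list with `cost` and `qaly`.
#' @param wtp willingness-to-pay per QALY, `>= 0`.
#' @return net monetary benefit in dollars.
#' @export
nmb <- function(totals, wtp) {
  stopifnot(wtp >= 0)
  wtp * totals$qaly - totals$cost
}
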