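#' Alkylarylketone anchor series
#'
#' The homologous C8--C14 alkylarylketone ladder (propiophenone through
#' octanophenone) used to convert retention times into retention indices.
#' Each ketone with carbon number n anchors the index 100 * n.
#'
#' @param carbon_number Integer carbon numbers (within 8--14).
#' @param rt_min Retention times (minutes), strictly increasing with carbon
#'   number.
#' @return An `anchor_series` data frame with columns `carbon_number`,
#'   `rt_min`.
#' @export
anchor_series <- function(carbon_number, rt_min) {
  carbon_number <- as.integer(carbon_number)
  rt_min <- as.numeric(rt_min)
  if (length(carbon_number) != length(rt_min))
    stop("carbon_number and rt_min must have equal length")
  if (length(carbon_number) < 2L)
    stop("at least two anchor ketones are required")
  if (any(carbon_number < 8L | carbon_number > 14L))
    stop("anchor carbon numbers must lie in 8..14")
  o <- order(carbon_number)
  carbon_number <- carbon_number[o]; rt_min <- rt_min[o]
  if (anyDuplicated(carbon_number))
    stop("duplicate anchor carbon numbers")
  if (any(diff(rt_min) <= 0))
    stop("anchor retention times must increase strictly with carbon number")
  if (any(rt_min <= 0))
    stop("anchor retention times must be positive")
  structure(data.frame(carbon_number = carbon_number, rt_min = rt_min),
            class = c("anchor_series", "data.frame"))
}

#' Retention index by bracketed linear interpolation
#'
#' Converts a retention time to a dimensionless retention index by linear
#' interpolation between the bracketing anchor ketones: for
#' `t_n <= rt <= t_(n+1)`,
#' `RI = 100 * n + 100 * (rt - t_n) / (t_(n+1) - t_n)`.
#' Peaks eluting before the first or after the last anchor get `NA`
#' (extrapolation is not attempted; early-eluting compounds are reported
#' without an index).
#'
#' @param rt Retention time(s) in minutes (vectorised).
#' @param anchors An [anchor_series()].
#' @return Numeric retention index (or `NA` outside the anchor range).
#' @export
compute_retention_index <- function(rt, anchors) {
  if (!inherits(anchors, "anchor_series")) anchors <- anchor_series(anchors$carbon_number, anchors$rt_min)
  tA <- anchors$rt_min; cn <- anchors$carbon_number
  vapply(as.numeric(rt), function(t) {
    if (is.na(t) || t < tA[1] || t > tA[length(tA)]) return(NA_real_)
    i <- findInterval(t, tA, rightmost.closed = TRUE)
    100 * cn[i] + 100 * (t - tA[i]) / (tA[i + 1] - tA[i]) *
      (cn[i + 1] - cn[i])
  }, numeric(1))
}

#' Back-fit an anchor bracket from published (retention time, index) pairs
#'
#' When the original ketone ladder is unavailable but several (Rt, RI)
#' pairs from the same bracket are, a least-squares line RI ~ Rt recovers
#' the local index scale; inverting it at RI = 100 * n yields surrogate
#' anchor times.  Useful to reproduce published indices for held-out
#' retention times within one bracket.
#'
#' @param rt,ri Numeric vectors of observed retention times (minutes) and
#'   their published retention indices, all from one anchor bracket.
#' @param carbon_numbers Integer carbon numbers of the two surrogate
#'   anchors to synthesise (default the bracket containing the data).
#' @return An [anchor_series()] with the two surrogate anchors.
#' @export
backfit_anchor_bracket <- function(rt, ri, carbon_numbers = NULL) {
  stopifnot(length(rt) == length(ri), length(rt) >= 2)
  fit <- stats::lm(ri ~ rt)
  b <- stats::coef(fit)
  if (b[2] <= 0) stop("retention index must increase with retention time")
  if (is.null(carbon_numbers)) {
    n_lo <- floor(min(ri) / 100)
    carbon_numbers <- c(n_lo, n_lo + 1L)
  }
  anchor_series(carbon_numbers, (100 * carbon_numbers - b[1]) / b[2])
}
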