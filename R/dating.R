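# Rate-based divergence dating from percent K2P distances.

#' Divergence time from a pairwise rate
#'
#' Linear molecular-clock conversion t = d / rate, where `d_percent` is the
#' pairwise K2P divergence in percent and `rate` the pairwise divergence rate
#' in percent per million years. The default 2.1%/My is the dasyurid
#' cytochrome-b calibration; with it, an 8.16% mean divergence dates to
#' ~3.9 My.
#'
#' @param d_percent percent K2P divergence (scalar or vector), >= 0.
#' @param rate pairwise divergence rate, percent per My (> 0).
#' @return divergence time(s) in million years.
#' @export
rate_divergence_time <- function(d_percent, rate = 2.1) {
  if (!is.numeric(rate) || rate <= 0) stop("rate must be > 0")
  if (any(d_percent < 0, na.rm = TRUE)) stop("d_percent must be >= 0")
  d_percent / rate
}

#' Divergence time from 12S transversion distance (Springer regression)
#'
#' Applies t = (d% - 0.0584) / 0.0854 to a transversion-only K2P percent
#' distance at 12S rRNA. A distance below the regression intercept yields a
#' negative time; it is returned as-is with attribute
#' `below_intercept = TRUE` rather than clamped, so callers can report
#' "below intercept resolution".
#'
#' @param d_percent transversion-only K2P percent divergence, >= 0.
#' @param intercept,slope regression constants (defaults 0.0584, 0.0854).
#' @return time(s) in million years; attribute `below_intercept` flags
#'   negative results.
#' @export
springer_12s_time <- function(d_percent, intercept = 0.0584, slope = 0.0854) {
  if (any(d_percent < 0, na.rm = TRUE)) stop("d_percent must be >= 0")
  t <- (d_percent - intercept) / slope
  attr(t, "below_intercept") <- !is.na(t) & t < 0
  t
}

#' Date a group distance summary
#'
#' Converts the mean/min/max percent distances of a [group_summary()] table
#' into point/low/high divergence-time estimates under either rule.
#'
#' @param summary data frame from [group_summary()] with `as_percent = TRUE`.
#' @param mode `"rate"` (cytb-style linear clock) or `"springer"` (12S).
#' @param rate pairwise rate for `mode = "rate"`, percent/My.
#' @return data frame `group_a`, `group_b`, `type`, `point`, `low`, `high`
#'   (My), `rule`.
#' @export
date_group_summary <- function(summary, mode = c("rate", "springer"),
                               rate = 2.1) {
  mode <- match.arg(mode)
  if (!isTRUE(attr(summary, "as_percent")))
    stop("summary must be on the percent scale")
  f <- if (mode == "rate") function(d) rate_divergence_time(d, rate)
       else function(d) as.numeric(springer_12s_time(d))
  data.frame(group_a = summary$group_a, group_b = summary$group_b,
             type = summary$type,
             point = f(summary$mean), low = f(summary$min),
             high = f(summary$max), rule = mode,
             stringsAsFactors = FALSE)
}
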