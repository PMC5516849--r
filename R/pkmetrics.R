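#' Area under the plasma curve above an efficacy threshold
#'
#' Trapezoidal integral of `max(C(t) - threshold, 0)` over the full time
#' span of the trajectory. Crossing points between the curve and the
#' threshold are resolved exactly on each linear piece, so the result
#' equals the integral of the piecewise-linear interpolant.
#'
#' @param tc a `time_course` (or any data.frame with `time` and
#'   `plasma_conc` columns).
#' @param threshold efficacy threshold, mg/l; nonnegative.
#' @return AUC above threshold, mg h/l.
#' @export
auc_above_threshold <- function(tc, threshold = 0) {
  if (threshold < 0) stop("threshold must be nonnegative", call. = FALSE)
  t <- tc$time; c0 <- tc$plasma_conc
  if (is.null(t) || is.null(c0) || length(t) < 2L)
    stop("time course is empty or lacks a plasma trajectory",
         call. = FALSE)
  y <- c0 - threshold
  total <- 0
  for (i in seq_len(length(t) - 1L)) {
    y1 <- y[i]; y2 <- y[i + 1L]; dt <- t[i + 1L] - t[i]
    if (y1 >= 0 && y2 >= 0) {
      total <- total + dt * (y1 + y2) / 2
    } else if (y1 > 0 && y2 < 0) {
      f <- y1 / (y1 - y2)
      total <- total + dt * f * y1 / 2
    } else if (y1 < 0 && y2 > 0) {
      f <- y2 / (y2 - y1)
      total <- total + dt * f * y2 / 2
    }
  }
  total
}

#' Peak plasma concentration and its time
#'
#' @param tc a `time_course`.
#' @return named list `cmax` (mg/l) and `tmax` (h, first time the
#'   maximum is achieved).
#' @export
cmax_tmax <- function(tc) {
  t <- tc$time; c0 <- tc$plasma_conc
  if (is.null(t) || is.null(c0) || length(t) < 1L)
    stop("time course is empty or lacks a plasma trajectory",
         call. = FALSE)
  i <- which.max(c0)
  list(cmax = c0[i], tmax = t[i])
}
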