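#' Finite unions of disjoint open intervals
#'
#' The concrete representation of a measurable part of a continuous
#' distribution. Intervals are treated as open; endpoint status is not
#' tracked because boundary points carry no probability mass. Overlapping or
#' touching intervals are merged and the result is sorted, so the
#' representation is canonical.
#'
#' @param lo,hi Numeric vectors of equal length with `lo < hi`; infinite
#'   endpoints are allowed.
#' @return An object of class `"interval_union"`: a two-column matrix
#'   (`lo`, `hi`) of disjoint sorted intervals, possibly with zero rows.
#' @examples
#' interval_union(c(0, 2), c(1, 3))
#' interval_union(c(0, 0.5), c(0.6, 2))   # touching pieces merge
#' @export
interval_union <- function(lo = numeric(0), hi = numeric(0)) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (length(lo) != length(hi)) stop("`lo` and `hi` must have equal length")
  if (any(is.na(lo)) || any(is.na(hi))) stop("interval endpoints must not be NA")
  if (any(lo >= hi)) stop("each interval needs lo < hi")
  if (length(lo)) {
    o <- order(lo)
    lo <- lo[o]; hi <- hi[o]
    keep_lo <- lo[1]; keep_hi <- hi[1]
    out_lo <- numeric(0); out_hi <- numeric(0)
    for (i in seq_along(lo)[-1]) {
      if (lo[i] <= keep_hi) {          # overlap or touch: merge
        keep_hi <- max(keep_hi, hi[i])
      } else {
        out_lo <- c(out_lo, keep_lo); out_hi <- c(out_hi, keep_hi)
        keep_lo <- lo[i]; keep_hi <- hi[i]
      }
    }
    out_lo <- c(out_lo, keep_lo); out_hi <- c(out_hi, keep_hi)
    lo <- out_lo; hi <- out_hi
  }
  structure(cbind(lo = lo, hi = hi), class = "interval_union")
}

#' @export
print.interval_union <- function(x, digits = 4, ...) {
  if (nrow(x) == 0) {
    cat("Empty interval union\n")
  } else {
    cat("Interval union:", format_intervals(x, digits), "\n")
  }
  invisible(x)
}

#' @rdname interval_union
#' @param x An `interval_union`.
#' @param digits Display digits.
#' @export
format_intervals <- function(x, digits = 4) {
  if (nrow(x) == 0) return("{}")
  paste(sprintf("(%s, %s)", signif(x[, "lo"], digits), signif(x[, "hi"], digits)),
        collapse = " U ")
}

#' @rdname interval_union
#' @export
iu_is_empty <- function(x) nrow(x) == 0

#' Total length of an interval union
#' @param x An [interval_union()].
#' @return The Lebesgue measure (possibly `Inf`).
#' @export
iu_length <- function(x) {
  if (nrow(x) == 0) return(0)
  sum(x[, "hi"] - x[, "lo"])
}

#' Intersect two interval unions
#' @param x,y [interval_union()] objects (a length-2 numeric vector is also
#'   accepted for `y`).
#' @return Their intersection as an `interval_union`.
#' @export
iu_intersect <- function(x, y) {
  if (!inherits(y, "interval_union")) y <- interval_union(y[1], y[2])
  lo <- numeric(0); hi <- numeric(0)
  for (i in seq_len(nrow(x))) for (j in seq_len(nrow(y))) {
    a <- max(x[i, "lo"], y[j, "lo"]); b <- min(x[i, "hi"], y[j, "hi"])
    if (a < b) { lo <- c(lo, a); hi <- c(hi, b) }
  }
  interval_union(lo, hi)
}

#' Union of two interval unions
#' @param x,y [interval_union()] objects.
#' @return Their union as an `interval_union`.
#' @export
iu_union <- function(x, y) {
  interval_union(c(x[, "lo"], y[, "lo"]), c(x[, "hi"], y[, "hi"]))
}

# TRUE if x is contained in y up to measure zero (used for support checks).
.iu_within <- function(x, y, tol = 1e-12) {
  if (nrow(x) == 0) return(TRUE)
  abs(iu_length(iu_intersect(x, y)) - iu_length(x)) <= tol ||
    (is.infinite(iu_length(x)) && is.infinite(iu_length(iu_intersect(x, y))))
}
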