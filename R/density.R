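#' Continuous density models with declared monotone structure
#'
#' A density model couples an evaluator `p(x)` on a support `(a, b)` with a
#' declaration of breakpoints partitioning the support into segments, each
#' monotone increasing, monotone decreasing or constant. The declaration is
#' what makes level-set computation (the continuous half of the Hahn split)
#' reliable: on a declared monotone segment the equation `p(x) = t` has at
#' most one solution, found by grid bracketing plus bisection.
#'
#' Two built-in families carry closed forms for mass and the
#' \eqn{\int p \ln p} integral: [exponential_density()] and
#' [piecewise_density()]. `density_model()` itself builds a generic model
#' whose integrals are computed by adaptive quadrature
#' ([stats::integrate()]).
#'
#' @param pdf Vectorized density function.
#' @param support Length-2 numeric `(a, b)`; infinite endpoints allowed.
#' @param breaks Increasing interior breakpoints splitting the support into
#'   segments (may be empty).
#' @param shapes Character vector, one per segment, each of
#'   `"increasing"`, `"decreasing"` or `"constant"`.
#' @param family Family tag (informational for generic models).
#' @param params Named list of family parameters.
#' @param check If `TRUE` (default), spot-check the declared monotonicity on
#'   sampled points and the unit total mass.
#' @param tol Tolerance for the total-mass check.
#' @return An object of class `"density_model"` with fields `family`,
#'   `params`, `support`, `pdf` and `segments` (data frame `lo`, `hi`,
#'   `shape`, `level` -- `level` is the height of a constant segment, `NA`
#'   otherwise).
#' @examples
#' tri <- density_model(function(x) ifelse(x < 1, x, 2 - x), c(0, 2),
#'                      breaks = 1, shapes = c("increasing", "decreasing"),
#'                      family = "triangular")
#' part_summary(tri, interval_union(0, 2))
#' @export
density_model <- function(pdf, support, breaks = numeric(0), shapes,
                          family = "custom", params = list(),
                          check = TRUE, tol = 1e-6) {
  support <- as.numeric(support)
  if (length(support) != 2 || support[1] >= support[2])
    stop("`support` must be (a, b) with a < b")
  breaks <- sort(as.numeric(breaks))
  if (any(breaks <= support[1]) || any(breaks >= support[2]))
    stop("`breaks` must lie strictly inside the support")
  edges <- c(support[1], breaks, support[2])
  nseg <- length(edges) - 1
  shapes <- match.arg(shapes, c("increasing", "decreasing", "constant"),
                      several.ok = TRUE)
  if (length(shapes) != nseg)
    stop(sprintf("need %d segment shapes, got %d", nseg, length(shapes)))
  level <- rep(NA_real_, nseg)
  for (s in seq_len(nseg)) {
    if (shapes[s] == "constant") {
      m <- .finite_probe(edges[s], edges[s + 1])
      level[s] <- pdf(mean(m))
    }
  }
  obj <- structure(list(family = family, params = params, support = support,
                        pdf = pdf,
                        segments = data.frame(lo = edges[-length(edges)],
                                              hi = edges[-1],
                                              shape = shapes, level = level,
                                              stringsAsFactors = FALSE)),
                   class = c(paste0(family, "_density_model"), "density_model"))
  if (check) .check_density(obj, tol)
  obj
}

# A finite sub-interval of (a,b) on which to probe an evaluator.
.finite_probe <- function(a, b) {
  if (is.infinite(a)) a <- if (is.infinite(b)) -1 else b - 1
  if (is.infinite(b)) b <- a + 1
  c(a, b)
}

.check_density <- function(x, tol) {
  for (s in seq_len(nrow(x$segments))) {
    seg <- x$segments[s, ]
    pr <- .finite_probe(seg$lo, seg$hi)
    xs <- seq(pr[1] + 1e-9 * (pr[2] - pr[1]), pr[2] - 1e-9 * (pr[2] - pr[1]),
              length.out = 17)
    v <- x$pdf(xs)
    if (any(v < -1e-12))
      stop("density evaluates negative inside its support")
    d <- diff(v)
    ok <- switch(seg$shape,
                 increasing = all(d >= -1e-9 * max(abs(v))),
                 decreasing = all(d <= 1e-9 * max(abs(v))),
                 constant = all(abs(v - v[1]) <= 1e-9 * max(abs(v), 1)))
    if (!ok)
      stop(sprintf("segment (%g, %g) declared %s but sampled values disagree",
                   seg$lo, seg$hi, seg$shape))
  }
  m <- mass_on(x, interval_union(x$support[1], x$support[2]))
  if (abs(m - 1) > tol)
    stop(sprintf("density integrates to %.10g, not 1 (tol %g)", m, tol))
  invisible(x)
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf("Density model (family: %s) on (%g, %g)\n",
              x$family, x$support[1], x$support[2]))
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(x$params), sep = " = ",
                           collapse = ", "), "\n")
  for (s in seq_len(nrow(x$segments)))
    cat(sprintf("  segment (%g, %g): %s\n", x$segments$lo[s],
                x$segments$hi[s], x$segments$shape[s]))
  invisible(x)
}

# ---- family integrals ------------------------------------------------------
# .mass_interval: integral of p over (a, b); .plnp_interval: integral of
# p*log(p) over (a, b). Both assume (a, b) inside the support. Closed forms
# for the built-in families, adaptive quadrature otherwise.

.mass_interval <- function(x, a, b) {
  switch(x$family,
         exponential = {
           r <- x$params$rate
           exp(-r * a) - if (is.finite(b)) exp(-r * b) else 0
         },
         piecewise_constant = {
           br <- x$params$breaks; h <- x$params$heights
           lo <- pmax(a, br[-length(br)]); hi <- pmin(b, br[-1])
           sum(h * pmax(hi - lo, 0))
         },
         stats::integrate(x$pdf, a, b, rel.tol = 1e-10,
                          abs.tol = 1e-12)$value)
}

.plnp_interval <- function(x, a, b) {
  switch(x$family,
         exponential = {
           r <- x$params$rate
           ea <- exp(-r * a)
           eb <- if (is.finite(b)) exp(-r * b) else 0
           # integral of x p(x) dx = (a + 1/r) e^{-ra} - (b + 1/r) e^{-rb}
           J <- (a + 1 / r) * ea - if (is.finite(b)) (b + 1 / r) * eb else 0
           log(r) * (ea - eb) - r * J
         },
         piecewise_constant = {
           br <- x$params$breaks; h <- x$params$heights
           lo <- pmax(a, br[-length(br)]); hi <- pmin(b, br[-1])
           sum(ifelse(h > 0, h * log(h), 0) * pmax(hi - lo, 0))
         },
         {
           f <- function(t) { v <- x$pdf(t); ifelse(v > 0, v * log(v), 0) }
           stats::integrate(f, a, b, rel.tol = 1e-10, abs.tol = 1e-12)$value
         })
}

#' Probability mass of a region
#'
#' Integrates a density over a finite union of intervals, using the family's
#' closed forms when available and adaptive quadrature otherwise.
#'
#' @param x A [density_model()].
#' @param region An [interval_union()] (or length-2 numeric) inside the
#'   support.
#' @return Mass in `[0, 1]`.
#' @examples
#' e <- exponential_density(2)
#' mass_on(e, interval_union(1, Inf))   # exp(-2)
#' @export
mass_on <- function(x, region) {
  region <- .as_region(x, region)
  if (nrow(region) == 0) return(0)
  sum(vapply(seq_len(nrow(region)),
             function(i) .mass_interval(x, region[i, "lo"], region[i, "hi"]),
             numeric(1)))
}

.as_region <- function(x, region) {
  if (is.null(region)) region <- interval_union(x$support[1], x$support[2])
  if (!inherits(region, "interval_union")) {
    region <- as.numeric(region)
    if (length(region) != 2) stop("region must be an interval_union or (lo, hi)")
    region <- interval_union(region[1], region[2])
  }
  tol <- 1e-12
  if (nrow(region) &&
      (any(region[, "lo"] < x$support[1] - tol) ||
       any(region[, "hi"] > x$support[2] + tol)))
    stop("region extends outside the density support")
  iu_intersect(region, interval_union(x$support[1], x$support[2]))
}

#' @export
part_summary.density_model <- function(x, part = NULL) {
  region <- .as_region(x, part)
  cP <- mass_on(x, region)
  if (cP <= 0) stop("region has zero probability mass")
  plnp <- sum(vapply(seq_len(nrow(region)),
                     function(i) .plnp_interval(x, region[i, "lo"],
                                                region[i, "hi"]),
                     numeric(1)))
  # conditional differential entropy of p/c restricted to the region
  H <- log(cP) - plnp / cP
  .new_part_summary(cP, H, iu_length(region))
}

# ---- exponential family ----------------------------------------------------

#' Exponential density model
#'
#' The density `rate * exp(-rate * x)` on `(0, Inf)`, declared monotone
#' decreasing, with closed forms for mass and entropy on any interval (used
#' for the truncated-density summaries the recursive splitter needs). Its
#' whole-support diversity is `exp(1 - log(rate)) = e / rate`.
#'
#' @param rate Positive rate parameter.
#' @return A `density_model` of family `"exponential"`.
#' @examples
#' e <- exponential_density(2)
#' part_summary(e, NULL)$diversity   # e / 2
#' @export
exponential_density <- function(rate) {
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number")
  force(rate)
  density_model(function(x) rate * exp(-rate * x), c(0, Inf),
                shapes = "decreasing", family = "exponential",
                params = list(rate = rate), check = FALSE)
}

# ---- piecewise-constant family --------------------------------------------

#' Piecewise-constant density model
#'
#' A step density given by `breaks` (length n + 1, increasing, finite) and
#' `heights` (length n, non-negative). All segments are declared constant;
#' entropy and mass are exact sums. The construction used for designed null
#' sets ([realize_continuous()]) is of this family.
#'
#' @param breaks Increasing finite numeric vector of segment edges.
#' @param heights Non-negative heights, one per segment; must integrate
#'   to one within `tol` unless `renormalize = TRUE`.
#' @param tol Total-mass tolerance.
#' @param renormalize Divide heights by the total integral first.
#' @return A `density_model` of family `"piecewise_constant"`.
#' @examples
#' pw <- piecewise_density(c(0, 4, 10, 11), c(0.05, 0.1, 0.2))
#' part_summary(pw, NULL)$diversity   # 10
#' @export
piecewise_density <- function(breaks, heights, tol = 1e-9,
                              renormalize = FALSE) {
  breaks <- as.numeric(breaks); heights <- as.numeric(heights)
  if (length(breaks) != length(heights) + 1)
    stop("need length(breaks) == length(heights) + 1")
  if (any(!is.finite(breaks)) || is.unsorted(breaks, strictly = TRUE))
    stop("`breaks` must be finite and strictly increasing")
  if (any(!is.finite(heights)) || any(heights < 0))
    stop("`heights` must be finite and non-negative")
  total <- sum(heights * diff(breaks))
  if (renormalize) {
    if (total <= 0) stop("total mass must be positive")
    heights <- heights / total
  } else if (abs(total - 1) > tol) {
    stop(sprintf("piecewise density integrates to %.10g, not 1 (tol %g)",
                 total, tol))
  }
  force(breaks); force(heights)
  pdf <- function(x) {
    i <- findInterval(x, breaks, rightmost.closed = TRUE)
    out <- numeric(length(x))
    ok <- i >= 1 & i <= length(heights)
    out[ok] <- heights[i[ok]]
    out
  }
  m <- density_model(pdf, range(breaks), breaks = breaks[-c(1, length(breaks))],
                     shapes = rep("constant", length(heights)),
                     family = "piecewise_constant",
                     params = list(breaks = breaks, heights = heights),
                     check = FALSE)
  m$segments$level <- heights
  m
}

# ---- level sets ------------------------------------------------------------

#' Partition a region by a density level
#'
#' Splits a region into the sets where the density is below, at, or above a
#' threshold `t` (up to measure-zero boundary points). Crossing points are
#' bracketed on declared monotone segments by a grid scan and refined by
#' bisection; the `at` component is nonempty only where a constant segment's
#' height matches `t` within tolerance -- isolated crossing points have
#' measure zero and are never placed in `at`.
#'
#' @param x A [density_model()].
#' @param t Positive threshold.
#' @param region [interval_union()] to partition (default: full support).
#' @param grid_n Points per segment used to bracket sign changes.
#' @param root_tol Bisection stops when the bracket is narrower than this.
#' @param at_tol Relative tolerance for constant-level matches:
#'   a constant segment joins `at` when `|level - t| <= at_tol * max(t, 1)`.
#' @param tail_tol An infinite tail is truncated for scanning where its
#'   remaining mass falls below this.
#' @return List with `below`, `at`, `above` (interval unions).
#' @examples
#' e <- exponential_density(2)
#' level_partition(e, 2 / exp(1))$above   # (0, 0.5)
#' @export
level_partition <- function(x, t, region = NULL, grid_n = 1024,
                            root_tol = 1e-10, at_tol = 1e-9,
                            tail_tol = 1e-12) {
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t <= 0)
    stop("`t` must be a single positive number")
  region <- .as_region(x, region)
  below <- interval_union(); at <- interval_union(); above <- interval_union()
  add <- function(iu, a, b) iu_union(iu, interval_union(a, b))
  for (s in seq_len(nrow(x$segments))) {
    seg <- x$segments[s, ]
    pieces <- iu_intersect(region, c(seg$lo, seg$hi))
    for (k in seq_len(nrow(pieces))) {
      a <- pieces[k, "lo"]; b <- pieces[k, "hi"]
      if (seg$shape == "constant") {
        lev <- seg$level
        if (abs(lev - t) <= at_tol * max(t, 1)) at <- add(at, a, b)
        else if (lev < t) below <- add(below, a, b)
        else above <- add(above, a, b)
        next
      }
      res <- .split_monotone(x, t, a, b, seg$shape, grid_n, root_tol, tail_tol)
      if (!is.null(res$below)) below <- add(below, res$below[1], res$below[2])
      if (!is.null(res$above)) above <- add(above, res$above[1], res$above[2])
    }
  }
  list(below = below, at = at, above = above)
}

# Split one monotone piece (a, b) at the level t. Returns a list with
# optional `below` / `above` interval endpoints.
.split_monotone <- function(x, t, a, b, shape, grid_n, root_tol, tail_tol) {
  a_s <- a; b_s <- b
  # truncate infinite ends for scanning where the remaining mass is negligible
  if (is.infinite(b_s)) {
    b_s <- max(a + 1, 2 * abs(a) + 1)
    while (.mass_interval(x, b_s, Inf) > tail_tol) b_s <- 2 * b_s + 1
  }
  if (is.infinite(a_s)) {
    a_s <- min(b - 1, -2 * abs(b) - 1)
    while (.mass_interval(x, -Inf, a_s) > tail_tol) a_s <- 2 * a_s - 1
  }
  xs <- seq(a_s, b_s, length.out = grid_n)
  f <- x$pdf(xs) - t
  sgn <- sign(f)
  ch <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(ch) > 1)
    stop(sprintf(paste0("segment (%g, %g) is declared %s but p(x) - %g ",
                        "changes sign %d times; check the segment declaration"),
                 a, b, shape, t, length(ch)))
  side <- function(v) if (v < 0) "below" else "above"
  if (length(ch) == 0) {
    # no crossing: the whole piece (including any truncated tail) lies on the
    # side of the interior values; for a decreasing tail p -> 0 stays below
    rep_v <- if (shape == "decreasing" && is.infinite(b)) f[length(f)] else
      f[which.max(abs(f))]
    out <- list(); out[[side(rep_v)]] <- c(a, b)
    return(out)
  }
  lo <- xs[ch]; hi <- xs[ch + 1]
  flo <- f[ch]
  while (hi - lo > root_tol) {
    mid <- (lo + hi) / 2
    fm <- x$pdf(mid) - t
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  cross <- (lo + hi) / 2
  out <- list()
  out[[side(flo)]] <- c(a, cross)
  out[[side(-flo)]] <- c(cross, b)
  out
}
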