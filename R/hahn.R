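#' One-step ternary Hahn decomposition of a part
#'
#' Splits a part A into the explicit Hahn triple (P, Z, N) of the signed
#' degree-of-uniformity measure restricted to A. The threshold is
#' \eqn{c_A / D_A} (the reciprocal of A's degree of uniformity): atoms or
#' density regions strictly below it form the strictly positive part P (more
#' uniform than A), those at the threshold form the null part Z (exactly as
#' uniform as A), and those above form the strictly negative part N (more
#' concentrated than A).
#'
#' Exact threshold equality almost never survives floating point, so the
#' discrete comparison uses a relative tolerance band: atom i joins Z when
#' `|p_i - threshold| <= z_tol * threshold`. Ties between the band and a
#' strict side resolve toward Z, keeping designed null sets intact under
#' rounding noise.
#'
#' @param x A [discrete_distribution()] or [density_model()].
#' @param part Part to split (labels, or an [interval_union()]; `NULL` means
#'   the full support).
#' @param z_tol Relative width of the null band (discrete), or the `at`
#'   tolerance passed to [level_partition()] (continuous).
#' @param ... Further arguments passed to [level_partition()] for continuous
#'   sources (`grid_n`, `root_tol`, `tail_tol`).
#' @return An object of class `"hahn_triple"`: list with `parent` (the part),
#'   `threshold`, `positive`, `null`, `negative` (parts, possibly empty,
#'   always present) and `summaries` (a list of [part_summary()] objects for
#'   the parent and each nonempty member).
#' @examples
#' hahn_split(fixture_binomial(8, 0.4))
#' hahn_split(fixture_null_example())   # designed ternary split
#' @export
hahn_split <- function(x, part = NULL, z_tol = 1e-9, ...) {
  UseMethod("hahn_split")
}

#' @export
hahn_split.discrete_distribution <- function(x, part = NULL, z_tol = 1e-9,
                                             ...) {
  if (is.null(part)) part <- x$labels
  idx <- .part_idx(x, part)
  parent_sum <- part_summary(x, x$labels[idx])
  thr <- parent_sum$mass / parent_sum$diversity
  p <- x$probs[idx]
  in_z <- abs(p - thr) <= z_tol * thr
  pos <- x$labels[idx][!in_z & p < thr]
  nul <- x$labels[idx][in_z]
  neg <- x$labels[idx][!in_z & p > thr]
  .new_hahn_triple(x, x$labels[idx], thr, pos, nul, neg, parent_sum,
                   empty = character(0))
}

#' @export
hahn_split.density_model <- function(x, part = NULL, z_tol = 1e-9, ...) {
  region <- .as_region(x, part)
  parent_sum <- part_summary(x, region)
  thr <- parent_sum$mass / parent_sum$diversity
  lp <- level_partition(x, thr, region, at_tol = z_tol, ...)
  .new_hahn_triple(x, region, thr, lp$below, lp$at, lp$above, parent_sum,
                   empty = interval_union())
}

.part_is_empty <- function(part) {
  if (inherits(part, "interval_union")) iu_is_empty(part) else length(part) == 0
}

.new_hahn_triple <- function(x, parent, thr, pos, nul, neg, parent_sum,
                             empty) {
  summaries <- list(parent = parent_sum)
  for (nm in c("positive", "null", "negative")) {
    part <- switch(nm, positive = pos, null = nul, negative = neg)
    if (!.part_is_empty(part)) summaries[[nm]] <- part_summary(x, part)
  }
  structure(list(parent = parent, threshold = thr, positive = pos,
                 null = nul, negative = neg, summaries = summaries),
            class = "hahn_triple")
}

.format_part <- function(part, digits = 4) {
  if (inherits(part, "interval_union")) format_intervals(part, digits)
  else if (length(part) == 0) "{}"
  else paste0("{", paste(part, collapse = ","), "}")
}

#' @export
print.hahn_triple <- function(x, digits = 4, ...) {
  cat(sprintf("Hahn triple of %s (threshold c/D = %.6g)\n",
              .format_part(x$parent, digits), x$threshold))
  for (nm in c("positive", "null", "negative")) {
    part <- x[[nm]]
    if (.part_is_empty(part)) {
      cat(sprintf("  %-8s: empty\n", nm))
    } else {
      s <- x$summaries[[nm]]
      cat(sprintf("  %-8s: %s  c = %.4g, D/c = %.4g\n", nm,
                  .format_part(part, digits), s$mass, s$dou))
    }
  }
  invisible(x)
}

#' Classify a part against a reference degree of uniformity
#'
#' Decides whether a part is strictly positive, strictly negative, or null
#' with respect to the signed measure built from a reference degree of
#' uniformity, or mixed if none applies. The pointwise characterization is
#' used: a part is strictly positive exactly when every atom probability
#' (density value) is below `1 / ref_dou`, strictly negative when every one
#' is above, and null when every one equals it.
#'
#' @inheritParams hahn_split
#' @param ref_dou Positive reference degree of uniformity.
#' @return One of `"strictly_positive"`, `"strictly_negative"`, `"null"`,
#'   `"mixed"`.
#' @examples
#' z <- fixture_null_example()
#' classify_part(z, 5:10, 10)   # "null"
#' @export
classify_part <- function(x, part, ref_dou, z_tol = 1e-9) {
  if (!is.numeric(ref_dou) || length(ref_dou) != 1 || !is.finite(ref_dou) ||
      ref_dou <= 0)
    stop("`ref_dou` must be a single positive number")
  thr <- 1 / ref_dou
  if (inherits(x, "discrete_distribution")) {
    p <- x$probs[.part_idx(x, part)]
    at <- abs(p - thr) <= z_tol * thr
    below <- !at & p < thr
    above <- !at & p > thr
    if (all(below)) return("strictly_positive")
    if (all(above)) return("strictly_negative")
    if (all(at)) return("null")
    return("mixed")
  }
  region <- .as_region(x, part)
  if (part_summary(x, region)$mass <= 0) stop("part has zero mass")
  lp <- level_partition(x, thr, region, at_tol = z_tol)
  nb <- !iu_is_empty(lp$below); na <- !iu_is_empty(lp$at)
  nv <- !iu_is_empty(lp$above)
  if (nb && !na && !nv) return("strictly_positive")
  if (nv && !na && !nb) return("strictly_negative")
  if (na && !nb && !nv) return("null")
  "mixed"
}

#' Brute-force maximality check for a Hahn triple
#'
#' Test-support operation: enumerates every subset of a (small) discrete
#' part, evaluates the signed measure of each via
#' \eqn{m(S) = c_S \ln\{(D_S/c_S) / (D_A/c_A)\}}, classifies each subset as
#' strictly positive / null / strictly negative by checking the sign of m on
#' *all* of its nonempty subsets, and confirms that [hahn_split()]'s members
#' are exactly the maximal such sets. Cost grows as 3^n, so the part size is
#' capped.
#'
#' @param x A [discrete_distribution()].
#' @param part Part to check (default: full support), at most `max_atoms`
#'   atoms.
#' @param z_tol Relative tolerance used both by the reference split and for
#'   deciding `m = 0`.
#' @param max_atoms Refusal threshold (default 20; runtime is already
#'   minutes-scale well below it).
#' @return List with `confirmed` (logical), the maximal `positive`, `null`,
#'   `negative` sets found by enumeration, the `split` they are compared to,
#'   and `counterexamples` (character description of any disagreement).
#' @examples
#' maximality_oracle(fixture_null_example())$confirmed
#' @export
maximality_oracle <- function(x, part = NULL, z_tol = 1e-9, max_atoms = 20) {
  if (!inherits(x, "discrete_distribution"))
    stop("the maximality oracle supports discrete distributions only")
  if (is.null(part)) part <- x$labels
  idx <- .part_idx(x, part)
  n <- length(idx)
  if (n > max_atoms)
    stop(sprintf("part has %d atoms; enumeration is capped at %d", n,
                 max_atoms))
  p <- x$probs[idx]
  labs <- x$labels[idx]
  ref <- part_summary(x, labs)$dou
  nmask <- bitwShiftL(1L, n) - 1L
  m_val <- rep(NA_real_, nmask)            # m for every nonempty mask
  bits <- lapply(seq_len(nmask), function(mask)
    which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L))
  for (mask in seq_len(nmask)) {
    pp <- p[bits[[mask]]]
    cS <- sum(pp)
    H <- -sum((pp / cS) * log(pp / cS))
    m_val[mask] <- cS * log((exp(H) / cS) / ref)
  }
  m_tol <- z_tol * max(abs(m_val), 1)
  # all-subsets sign classification by lattice induction: a mask has sign s on
  # all subsets iff it has sign s itself and so do all masks with one bit less
  all_pos <- logical(nmask); all_neg <- logical(nmask); all_nul <- logical(nmask)
  for (mask in seq_len(nmask)) {
    subs <- vapply(bits[[mask]],
                   function(b) bitwAnd(mask, bitwNot(bitwShiftL(1L, b - 1L))),
                   integer(1))
    subs <- subs[subs > 0L]
    all_pos[mask] <- m_val[mask] > m_tol && all(all_pos[subs])
    all_neg[mask] <- m_val[mask] < -m_tol && all(all_neg[subs])
    all_nul[mask] <- abs(m_val[mask]) <= m_tol && all(all_nul[subs])
  }
  maximal <- function(flag) {
    ok <- which(flag)
    if (!length(ok)) return(character(0))
    # union of all qualifying sets; maximality holds iff the union qualifies
    u <- Reduce(bitwOr, ok)
    if (!flag[u]) return(NULL)             # no unique maximum (cannot happen)
    labs[bits[[u]]]
  }
  enum <- list(positive = maximal(all_pos), null = maximal(all_nul),
               negative = maximal(all_neg))
  split <- hahn_split(x, labs, z_tol = z_tol)
  counter <- character(0)
  for (nm in names(enum)) {
    got <- sort(as.character(split[[nm]]))
    want <- sort(as.character(enum[[nm]]))
    if (!identical(got, want))
      counter <- c(counter, sprintf("%s: split gives {%s}, enumeration gives {%s}",
                                    nm, paste(got, collapse = ","),
                                    paste(want, collapse = ",")))
  }
  list(confirmed = length(counter) == 0, positive = enum$positive,
       null = enum$null, negative = enum$negative, split = split,
       counterexamples = counter)
}
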