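#' Construct a discrete probability distribution
#'
#' Builds a validated discrete distribution from labelled atoms. Atoms with
#' probability exactly zero are dropped at construction (and recorded), so
#' downstream entropy sums never meet a `0 * log(0)` term.
#'
#' @param labels Vector of unique atom identifiers (coerced to character;
#'   insertion order is preserved and is the display order only -- no
#'   computation depends on it).
#' @param probs Non-negative numeric vector, one entry per label. May be raw
#'   counts if `renormalize = TRUE`.
#' @param tol Tolerance for the `sum(probs) == 1` check (default `1e-9`).
#' @param renormalize If `TRUE`, `probs` are divided by their sum instead of
#'   being required to sum to one (use for count or percentage histograms).
#' @return An object of class `"discrete_distribution"`: a list with
#'   `labels`, `probs` and `dropped` (labels of removed zero atoms).
#' @examples
#' d <- discrete_distribution(0:8, dbinom(0:8, 8, 0.4))
#' d
#' @seealso [part_summary()], [hahn_split()], [read_histogram()]
#' @export
discrete_distribution <- function(labels, probs, tol = 1e-9,
                                  renormalize = FALSE) {
  labels <- as.character(labels)
  probs <- as.numeric(probs)
  if (length(labels) != length(probs))
    stop("`labels` and `probs` must have equal length")
  if (anyDuplicated(labels))
    stop("`labels` must be unique")
  if (any(!is.finite(probs)))
    stop("all probabilities must be finite")
  if (any(probs < 0))
    stop("probabilities must be non-negative")
  if (renormalize) {
    s <- sum(probs)
    if (s <= 0) stop("total probability mass must be positive")
    probs <- probs / s
  } else if (abs(sum(probs) - 1) > tol) {
    stop(sprintf("probabilities sum to %.12g, not 1 (tol %g); use renormalize = TRUE for count data",
                 sum(probs), tol))
  }
  dropped <- labels[probs == 0]
  keep <- probs > 0
  structure(list(labels = labels[keep], probs = probs[keep],
                 dropped = dropped),
            class = "discrete_distribution")
}

#' @export
print.discrete_distribution <- function(x, ...) {
  cat(sprintf("Discrete distribution with %d atoms\n", length(x$labels)))
  n <- min(length(x$labels), 10L)
  for (i in seq_len(n))
    cat(sprintf("  %-8s %.6g\n", x$labels[i], x$probs[i]))
  if (length(x$labels) > n) cat(sprintf("  ... %d more\n", length(x$labels) - n))
  if (length(x$dropped))
    cat(sprintf("  (%d zero-probability atom(s) dropped: %s)\n",
                length(x$dropped), paste(x$dropped, collapse = ", ")))
  invisible(x)
}

# Resolve a part (vector of labels) to atom indices; errors on unknown labels.
.part_idx <- function(dist, part) {
  part <- as.character(part)
  if (length(part) == 0) stop("part is empty")
  if (anyDuplicated(part)) part <- unique(part)
  idx <- match(part, dist$labels)
  if (anyNA(idx))
    stop("part contains labels absent from the distribution: ",
         paste(part[is.na(idx)], collapse = ", "))
  idx
}

#' Summarize a part of a distribution
#'
#' Computes the four quantities attached to a measurable part P: its mass
#' \eqn{c_P}, conditional Shannon entropy
#' \eqn{H_P = -\sum_{i \in P} (p_i/c_P) \ln(p_i/c_P)} in nats, diversity
#' \eqn{D_P = e^{H_P}} (the Hill number of order one of the renormalized
#' restriction), and degree of uniformity \eqn{D_P/c_P}. For continuous
#' parts the entropy is differential, so `diversity` may be below one, but
#' the degree of uniformity is always positive.
#'
#' @param x A [discrete_distribution()] or a [density_model][density_model].
#' @param part For discrete sources, a vector of labels (need not be
#'   contiguous); for continuous sources, an [interval_union()].
#' @return An object of class `"part_summary"` with fields `mass`, `entropy`,
#'   `diversity`, `dou` and `size` (atom count, or total interval length).
#' @examples
#' b <- fixture_binomial(8, 0.4)
#' part_summary(b, c(7, 8))   # dou approximately 153.94
#' part_summary(b, 3)         # dou = 1 / p_3
#' @export
part_summary <- function(x, part) UseMethod("part_summary")

.new_part_summary <- function(mass, entropy, size) {
  entropy <- entropy + 0   # normalize IEEE negative zero (singleton parts)
  structure(list(mass = mass, entropy = entropy,
                 diversity = exp(entropy), dou = exp(entropy) / mass,
                 size = size),
            class = "part_summary")
}

#' @export
part_summary.discrete_distribution <- function(x, part) {
  idx <- .part_idx(x, part)
  p <- x$probs[idx]
  cP <- sum(p)
  if (cP <= 0) stop("part has zero probability mass")
  w <- p / cP
  H <- -sum(w * log(w))
  .new_part_summary(cP, H, length(idx))
}

#' @export
print.part_summary <- function(x, ...) {
  cat(sprintf("Part summary: c = %.6g, H = %.6g nats, D = %.6g, D/c = %.6g\n",
              x$mass, x$entropy, x$diversity, x$dou))
  invisible(x)
}

#' Signed degree-of-uniformity measure of a part
#'
#' Evaluates the signed measure \eqn{m_{ref}(P) = c_P \ln\{(D_P/c_P)/ref\}}
#' of a part relative to a reference degree of uniformity. The sign tells
#' whether the part is more uniform (positive), equally uniform (zero) or
#' less uniform (negative) than the reference; for a discrete part the same
#' value is obtained atomwise as \eqn{-\sum_{i} p_i \ln(p_i \cdot ref)}.
#'
#' @param ref_dou Positive reference degree of uniformity (typically the
#'   `dou` of a parent part or of a whole distribution).
#' @inheritParams part_summary
#' @return The signed measure value (a single number).
#' @examples
#' z <- fixture_null_example()
#' uniformity_measure(10, z, 5:10)   # 0: {5..10} is a null set
#' uniformity_measure(10, z, 1:4)    # 0.2 * log(2)
#' @export
uniformity_measure <- function(ref_dou, x, part) {
  if (!is.numeric(ref_dou) || length(ref_dou) != 1 || !is.finite(ref_dou) ||
      ref_dou <= 0)
    stop("`ref_dou` must be a single positive number")
  s <- part_summary(x, part)
  s$mass * log(s$dou / ref_dou)
}

#' Relative degree of uniformity of two parts
#'
#' Returns the ratio R of the degrees of uniformity of two parts, possibly
#' taken from different distributions: part 1 is R times more uniformly
#' distributed than part 2 (equivalently, part 2 is R times more
#' concentrated).
#'
#' @param x1,x2 Sources ([discrete_distribution()] or density models).
#' @param part1,part2 Parts of `x1` and `x2` respectively.
#' @return The ratio `dou(part1) / dou(part2)`.
#' @examples
#' z <- fixture_null_example()
#' compare_parts(z, 1:4, z, 11)   # 20 / 5 = 4
#' @export
compare_parts <- function(x1, part1, x2, part2) {
  part_summary(x1, part1)$dou / part_summary(x2, part2)$dou
}
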