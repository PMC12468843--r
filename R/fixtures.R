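#' Binomial pmf fixture
#'
#' Exact Binomial(n, p) probabilities computed by the multiplicative
#' recurrence `p_{k+1} = p_k * (n - k) / (k + 1) * p / (1 - p)`, labelled
#' `0..n`. The B(8, 0.4) case is the canonical discrete demonstration of the
#' recursive decomposition.
#'
#' @param n Number of trials (>= 1).
#' @param p Success probability in (0, 1).
#' @return A [discrete_distribution()] over `0..n`.
#' @examples
#' fixture_binomial(8, 0.4)
#' @export
fixture_binomial <- function(n, p) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("`n` must be a positive integer")
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1)
    stop("`p` must be in (0, 1)")
  probs <- numeric(n + 1)
  probs[1] <- (1 - p)^n
  for (k in 0:(n - 1))
    probs[k + 2] <- probs[k + 1] * (n - k) / (k + 1) * p / (1 - p)
  discrete_distribution(0:n, probs, tol = 1e-9)
}

#' Exponential density fixture
#'
#' Convenience alias for [exponential_density()]; the rate-2 case is the
#' canonical continuous demonstration.
#'
#' @param rate Positive rate.
#' @return A `density_model`.
#' @export
fixture_exponential <- function(rate) exponential_density(rate)

#' The 11-atom designed null-set distribution
#'
#' Four atoms of probability 0.05, six of 0.1 and one of 0.2, labelled
#' `1..11`: the smallest discrete distribution realizing a non-trivial null
#' set ({5..10}, as uniform as the whole, D/c = 10) between a strictly
#' positive part ({1..4}, D/c = 20) and a strictly negative one ({11},
#' D/c = 5).
#'
#' @return A [discrete_distribution()].
#' @examples
#' hahn_split(fixture_null_example())
#' @export
fixture_null_example <- function() {
  realize_discrete(null_design(10, 0.6, 2, 0.5))
}

#' Synthetic unimodal incidence histogram
#'
#' Emulates an age-stratified incidence histogram: a unimodal distribution
#' over `bins` age bands (labelled "0-4", "5-9", ...) peaking at `peak_bin`
#' (around 12% at the mode with the defaults) and tapering geometrically on
#' both sides, with a small seeded jitter that keeps all probabilities
#' distinct. Strict unimodality with no ties makes every Hahn split binary
#' (empty Z), mirroring real incidence curves; the generator is a pure
#' function of its arguments.
#'
#' @param bins Number of age bands (>= 3).
#' @param peak_bin Zero-based index of the modal band, in `0..(bins-1)`.
#' @param decay Geometric taper per band away from the mode, in (0, 1).
#' @param seed Integer seed for the jitter.
#' @return A [discrete_distribution()] with age-band labels.
#' @examples
#' fixture_incidence(20, 4, 0.8, seed = 7)
#' @export
fixture_incidence <- function(bins, peak_bin, decay, seed) {
  if (!is.numeric(bins) || bins < 3 || bins != round(bins))
    stop("`bins` must be an integer >= 3")
  if (!is.numeric(peak_bin) || peak_bin < 0 || peak_bin >= bins ||
      peak_bin != round(peak_bin))
    stop("`peak_bin` must be in 0..(bins - 1)")
  if (!is.numeric(decay) || decay <= 0 || decay >= 1)
    stop("`decay` must be in (0, 1)")
  set.seed(as.integer(seed))
  i <- seq_len(bins) - 1
  w <- decay^abs(i - peak_bin)
  # multiplicative jitter small enough to never reorder neighbouring bands
  gap <- min(decay, 1 / decay - 1)
  w <- w * (1 + stats::runif(bins, -gap / 4, gap / 4))
  labels <- sprintf("%d-%d", i * 5, i * 5 + 4)
  discrete_distribution(labels, w, renormalize = TRUE)
}

#' Synthetic monotone load histogram
#'
#' Emulates a monotonically loaded profile (e.g. stress fractions along a
#' beam): strictly increasing probabilities over positions `0..(bins-1)`,
#' built from seeded positive increments and normalized. Strict monotonicity
#' means no two atoms are equal, so every Hahn split of the result is binary.
#'
#' @param bins Number of positions (>= 2).
#' @param seed Integer seed.
#' @return A [discrete_distribution()] labelled by position.
#' @examples
#' fixture_monotone_load(21, seed = 3)
#' @export
fixture_monotone_load <- function(bins, seed) {
  if (!is.numeric(bins) || bins < 2 || bins != round(bins))
    stop("`bins` must be an integer >= 2")
  set.seed(as.integer(seed))
  w <- cumsum(stats::runif(bins, 0.2, 1))
  discrete_distribution(seq_len(bins) - 1, w, renormalize = TRUE)
}
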