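# Independent oracles and shared fixtures for the test suite. The oracle
# functions recompute every quantity directly from raw probability vectors,
# never through the package's part/summary machinery.

# Degree of uniformity of a set of probabilities, straight from the formulas.
oracle_dou <- function(p) {
  cP <- sum(p)
  H <- -sum((p / cP) * log(p / cP))
  exp(H) / cP
}

# Signed measure of a part against a reference dou, atomwise form
# m(P) = -sum p_i log(p_i * ref^{-1} ... ) i.e. -sum p_i log(p_i / thr)
# with thr = 1/ref; equals c * log(dou/ref).
oracle_m <- function(p, ref_dou) {
  -sum(p * log(p * ref_dou))
}

# Random discrete distribution with n atoms (labels 1..n), no zero atoms.
random_dist <- function(n) {
  w <- stats::rexp(n) + 1e-3
  discrete_distribution(seq_len(n), w / sum(w))
}

# Random partition of a label vector into 2..k nonempty blocks.
random_partition <- function(labels, k = 3) {
  k <- min(k, length(labels))
  g <- sample(seq_len(k), length(labels), replace = TRUE)
  # make sure no block is empty
  g[sample(length(labels), k)] <- seq_len(k)
  split(labels, g)
}

# Discrete carry-over fixture: a 12-atom distribution with whole-support
# diversity exactly 10, a designed 6-atom null band at p = 1/10, a
# NON-uniform 5-atom positive part (so the P branch splits again while Z is
# carried over) and a singleton negative atom of mass 0.22. The free shape
# parameter of the positive part is solved here by uniroot from the entropy
# balance -(sum p log p) = log(10).
carryover_dist <- function() {
  w <- 0.22
  mP <- 1 - 0.6 - w                       # positive-part mass, 5 atoms: 4 a + b
  need <- log(10) - 0.6 * log(10) - w * log(1 / w)  # -(4a log a + b log b)
  f <- function(a) {
    b <- mP - 4 * a
    -(4 * a * log(a) + b * log(b)) - need
  }
  a <- stats::uniroot(f, c(mP / 5 + 1e-9, mP / 4 - 1e-6), tol = 1e-14)$root
  b <- mP - 4 * a
  discrete_distribution(1:12, c(rep(a, 4), b, rep(0.1, 6), w))
}

# Continuous carry-over fixture: piecewise-constant density with diversity
# exactly 10 whose positive part has two bands (heights 0.04 and 0.06), a
# null band at height 0.1 and a negative band at height 0.2. Band masses
# solved in closed form from the entropy balance.
carryover_density <- function() {
  h1 <- 0.04; h2 <- 0.06
  m1 <- (0.2 * log(0.05) - 0.2 * log(h2)) / (log(h1) - log(h2))
  m2 <- 0.2 - m1
  l1 <- m1 / h1; l2 <- m2 / h2
  piecewise_density(c(0, l1, l1 + l2, l1 + l2 + 6, l1 + l2 + 7),
                    c(h1, h2, 0.1, 0.2))
}

# Quadrature oracle for continuous summaries: mass, and conditional
# differential entropy of p restricted to (a, b), via stats::integrate on
# the raw pdf (independent of the package's closed forms).
oracle_region <- function(pdf, a, b) {
  m <- stats::integrate(pdf, a, b, rel.tol = 1e-12)$value
  plnp <- stats::integrate(function(x) {
    v <- pdf(x); ifelse(v > 0, v * log(v), 0)
  }, a, b, rel.tol = 1e-12)$value
  H <- log(m) - plnp / m
  list(mass = m, entropy = H, dou = exp(H) / m)
}
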