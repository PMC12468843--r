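#' Solve the mass-balance system of a designed null set
#'
#' For a target ternary split into parts P (degree of uniformity
#' `D * eta1`), Z (exactly `D`) and N (`D * eta2`), the masses must satisfy
#' the geometric-mean conservation constraint
#' `eta1^cP * eta2^cN = 1` together with `cP + cN = 1 - cZ`. This linear
#' system (in logs) has the unique solution
#' \deqn{c_P = \frac{-\ln\eta_2 (1 - c_Z)}{\ln\eta_1 - \ln\eta_2}, \qquad
#'       c_N = \frac{\ln\eta_1 (1 - c_Z)}{\ln\eta_1 - \ln\eta_2},}
#' which every output is validated against. (Note the numerators: the
#' assignment must pair \eqn{c_P} with \eqn{-\ln\eta_2} -- pairing it with
#' \eqn{\ln\eta_1} satisfies the constraint only in the symmetric case
#' \eqn{\eta_1 \eta_2 = 1}.)
#'
#' @param cZ Null-part mass, in `[0, 1)`.
#' @param eta1 Uniformity ratio of P relative to the whole, `> 1`.
#' @param eta2 Uniformity ratio of N relative to the whole, in `(0, 1)`.
#' @return Named numeric vector `c(cP = ..., cN = ...)`.
#' @examples
#' solve_masses(0.6, 2, 0.5)    # cP = cN = 0.2
#' solve_masses(0.4, 4, 0.5)    # cP = 0.2, cN = 0.4
#' @export
solve_masses <- function(cZ, eta1, eta2) {
  if (!is.numeric(cZ) || length(cZ) != 1 || cZ < 0 || cZ >= 1)
    stop("`cZ` must be in [0, 1)")
  if (!is.numeric(eta1) || length(eta1) != 1 || !is.finite(eta1) || eta1 <= 1)
    stop("`eta1` must be > 1")
  if (!is.numeric(eta2) || length(eta2) != 1 || eta2 <= 0 || eta2 >= 1)
    stop("`eta2` must be in (0, 1)")
  den <- log(eta1) - log(eta2)
  cP <- -log(eta2) * (1 - cZ) / den
  cN <- log(eta1) * (1 - cZ) / den
  stopifnot(abs(eta1^cP * eta2^cN - 1) <= 1e-10,
            abs(cP + cN - (1 - cZ)) <= 1e-12)
  c(cP = cP, cN = cN)
}

#' Design a distribution containing a non-trivial null set
#'
#' Packages the free parameters of the null-set construction -- the target
#' whole-distribution diversity `D`, the null mass `cZ`, and the uniformity
#' ratios `eta1 > 1` (for P) and `eta2 < 1` (for N) -- together with the
#' solved masses and, for discrete realizations, the implied atom counts
#' `nP = cP * D * eta1`, `nZ = cZ * D`, `nN = cN * D * eta2` (each atom of P,
#' Z, N carries probability `1/(D*eta1)`, `1/D`, `1/(D*eta2)` respectively).
#'
#' @param D Target whole-distribution diversity (positive).
#' @param cZ,eta1,eta2 See [solve_masses()].
#' @return An object of class `"null_design"` with fields `D`, `cZ`, `eta1`,
#'   `eta2`, `cP`, `cN`, `atom_counts` (named vector `nP`, `nZ`, `nN`) and
#'   `feasible_discrete` (are all counts integers within `1e-9`).
#' @examples
#' null_design(10, 0.6, 2, 0.5)   # the 11-atom example design
#' @export
null_design <- function(D, cZ, eta1, eta2) {
  if (!is.numeric(D) || length(D) != 1 || !is.finite(D) || D <= 0)
    stop("`D` must be a single positive number")
  m <- solve_masses(cZ, eta1, eta2)
  counts <- c(nP = unname(m["cP"]) * D * eta1, nZ = cZ * D,
              nN = unname(m["cN"]) * D * eta2)
  feas <- all(abs(counts - round(counts)) <= 1e-9 & round(counts) >= 0)
  structure(list(D = D, cZ = cZ, eta1 = eta1, eta2 = eta2,
                 cP = unname(m["cP"]), cN = unname(m["cN"]),
                 atom_counts = counts, feasible_discrete = feas),
            class = "null_design")
}

#' @export
print.null_design <- function(x, ...) {
  cat(sprintf("Null-set design: D = %g, cZ = %g, eta1 = %g, eta2 = %g\n",
              x$D, x$cZ, x$eta1, x$eta2))
  cat(sprintf("  solved masses: cP = %.6g, cN = %.6g\n", x$cP, x$cN))
  cat(sprintf("  atom counts (nP, nZ, nN) = (%g, %g, %g)%s\n",
              x$atom_counts["nP"], x$atom_counts["nZ"], x$atom_counts["nN"],
              if (x$feasible_discrete) "" else "  [discrete-infeasible]"))
  invisible(x)
}

#' Realize a null-set design as a discrete distribution
#'
#' Lays out `nP` atoms of probability `1/(D*eta1)`, then `nZ` atoms of `1/D`,
#' then `nN` atoms of `1/(D*eta2)`, labelled `1..(nP+nZ+nN)`. Splitting the
#' result with [hahn_split()] recovers exactly the designed triple, with
#' degrees of uniformity `D*eta1`, `D` and `D*eta2`.
#'
#' @param design A [null_design()].
#' @return A [discrete_distribution()].
#' @examples
#' realize_discrete(null_design(10, 0.6, 2, 0.5))   # the 11-atom example
#' @export
realize_discrete <- function(design) {
  stopifnot(inherits(design, "null_design"))
  counts <- design$atom_counts
  bad <- which(abs(counts - round(counts)) > 1e-9)
  if (length(bad))
    stop(sprintf("design is discrete-infeasible: %s = %.6g is not an integer",
                 names(counts)[bad[1]], counts[bad[1]]))
  n <- round(counts)
  probs <- c(rep(1 / (design$D * design$eta1), n["nP"]),
             rep(1 / design$D, n["nZ"]),
             rep(1 / (design$D * design$eta2), n["nN"]))
  discrete_distribution(seq_along(probs), probs, tol = 1e-9,
                        renormalize = FALSE)
}

#' Realize a null-set design as a piecewise-constant density
#'
#' Builds consecutive constant segments of lengths `cP*D*eta1`, `cZ*D`,
#' `cN*D*eta2` with heights `1/(D*eta1)`, `1/D`, `1/(D*eta2)`. No
#' integrality is needed; the whole-support diversity of the realization
#' equals the design `D`, and [hahn_split()] returns the three segments as
#' (P, Z, N).
#'
#' @param design A [null_design()].
#' @return A [piecewise_density()] model.
#' @examples
#' realize_continuous(null_design(10, 0.6, 2, 0.5))   # heights .05/.1/.2 on (0,11)
#' @export
realize_continuous <- function(design) {
  stopifnot(inherits(design, "null_design"))
  lens <- c(design$cP * design$D * design$eta1,
            design$cZ * design$D,
            design$cN * design$D * design$eta2)
  heights <- c(1 / (design$D * design$eta1), 1 / design$D,
               1 / (design$D * design$eta2))
  keep <- lens > 0
  piecewise_density(c(0, cumsum(lens[keep])), heights[keep])
}
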