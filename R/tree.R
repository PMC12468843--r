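#' Build the recursive ternary localization tree
#'
#' Applies the ternary Hahn decomposition recursively. Each node's part is
#' split at threshold `c/D`; the strictly positive (P) and strictly negative
#' (N) children are split further, while a null (Z) child is uniform and
#' terminal -- it is carried over into deeper level views at its ordered
#' position. Within every level, parts are ordered left to right by strictly
#' decreasing degree of uniformity.
#'
#' A branch stops on: a singleton part (discrete), a trivial split (P and N
#' both empty, i.e. a uniform part), `max_depth`, or mass below `min_mass`.
#' The root is level 0; level k holds the parts produced by k split rounds
#' plus all earlier-terminated parts.
#'
#' @param x A [discrete_distribution()] or [density_model()].
#' @param part Root part (default: full support). Any measurable part can be
#'   the root; the decomposition does not require starting from the whole
#'   distribution.
#' @param max_depth Maximum number of split rounds. Defaults to unlimited
#'   for discrete sources (they terminate naturally at singletons and
#'   uniform parts) and 3 for continuous sources (the recursion has no
#'   natural end on a continuum).
#' @param min_mass Branches with mass below this stop (default 0 = off).
#' @param z_tol Null-band tolerance, see [hahn_split()].
#' @param ... Passed to [hahn_split()] (continuous root-finding controls).
#' @return An object of class `"localization_tree"`: list with `nodes` (list
#'   of node records: `id`, `parent`, `role`, `part`, `summary`,
#'   `created_level`, `children`, `terminal_reason`), `config` and `source`
#'   (a short description of the input).
#' @examples
#' tr <- build_tree(fixture_binomial(8, 0.4))
#' tr
#' level_view(tr, 2)
#' @export
build_tree <- function(x, part = NULL, max_depth = NULL, min_mass = 0,
                       z_tol = 1e-9, ...) {
  discrete <- inherits(x, "discrete_distribution")
  if (is.null(max_depth)) max_depth <- if (discrete) Inf else 3
  if (is.null(part)) {
    part <- if (discrete) x$labels else
      interval_union(x$support[1], x$support[2])
  } else if (!discrete) {
    part <- .as_region(x, part)
  }
  if (discrete) part <- x$labels[.part_idx(x, part)]
  nodes <- list()
  new_node <- function(parent, role, part, level) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, parent = parent, role = role, part = part,
                         summary = part_summary(x, part),
                         created_level = level,
                         children = integer(0), terminal_reason = "none")
    id
  }
  grow <- function(id) {
    node <- nodes[[id]]
    if (node$role == "Z") {
      nodes[[id]]$terminal_reason <<- "null_set"; return(invisible())
    }
    if (discrete && length(node$part) == 1) {
      nodes[[id]]$terminal_reason <<- "singleton"; return(invisible())
    }
    if (node$created_level >= max_depth) {
      nodes[[id]]$terminal_reason <<- "max_depth"; return(invisible())
    }
    if (min_mass > 0 && node$summary$mass < min_mass) {
      nodes[[id]]$terminal_reason <<- "min_mass"; return(invisible())
    }
    tri <- hahn_split(x, node$part, z_tol = z_tol, ...)
    if (.part_is_empty(tri$positive) && .part_is_empty(tri$negative)) {
      nodes[[id]]$terminal_reason <<- "uniform"; return(invisible())
    }
    kids <- integer(0)
    for (role in c("P", "Z", "N")) {
      p <- switch(role, P = tri$positive, Z = tri$null, N = tri$negative)
      if (.part_is_empty(p)) next
      kids <- c(kids, new_node(id, role, p, node$created_level + 1L))
    }
    nodes[[id]]$children <<- kids
    for (k in kids) grow(k)
  }
  root <- new_node(NA_integer_, "root", part, 0L)
  grow(root)
  structure(list(nodes = nodes,
                 config = list(max_depth = max_depth, min_mass = min_mass,
                               z_tol = z_tol),
                 source = .source_label(x),
                 discrete = discrete),
            class = "localization_tree")
}

.source_label <- function(x) {
  if (inherits(x, "discrete_distribution"))
    sprintf("discrete distribution with %d atoms", length(x$labels))
  else
    sprintf("%s density on (%g, %g)", x$family, x$support[1], x$support[2])
}

#' Depth of a localization tree
#' @param tree A [build_tree()] result.
#' @return The largest `created_level` among nodes.
#' @export
tree_depth <- function(tree) {
  max(vapply(tree$nodes, function(n) n$created_level, integer(1)))
}

#' Parts alive at a level of the tree
#'
#' Returns the parts making up level k of the decomposition, left to right:
#' nodes created at level k, plus every part that terminated earlier and is
#' carried over (null sets, singletons, uniform parts) at its original
#' position. The degree of uniformity is strictly decreasing along the
#' returned order.
#'
#' @param tree A [build_tree()] result.
#' @param k Level, between 1 and [tree_depth()].
#' @return A data frame with one row per part: `id`, `part` (formatted
#'   label), `size`, `mass`, `entropy`, `diversity`, `dou`, `created_level`,
#'   `terminal_reason`. The raw parts are attached as attribute `"parts"`.
#' @export
level_view <- function(tree, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > tree_depth(tree))
    stop(sprintf("level must be between 1 and %d", tree_depth(tree)))
  ids <- integer(0)
  visit <- function(id) {
    node <- tree$nodes[[id]]
    if (node$created_level == k ||
        (node$terminal_reason != "none" && node$created_level <= k &&
         length(node$children) == 0)) {
      ids <<- c(ids, id)
    } else {
      for (ch in node$children) visit(ch)
    }
  }
  visit(1L)
  rows <- lapply(ids, function(id) {
    n <- tree$nodes[[id]]
    data.frame(id = n$id, part = .format_part(n$part), size = n$summary$size,
               mass = n$summary$mass, entropy = n$summary$entropy,
               diversity = n$summary$diversity, dou = n$summary$dou,
               created_level = n$created_level,
               terminal_reason = n$terminal_reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "parts") <- lapply(ids, function(id) tree$nodes[[id]]$part)
  out
}

#' Pairwise degree-of-uniformity ratios at a level
#'
#' Forms the matrix `R[i, j] = dou_i / dou_j` over the parts of a level,
#' quantifying how many times more uniformly distributed part i is than
#' part j (`R[i, j] * R[j, i] = 1`, diagonal 1).
#'
#' @inheritParams level_view
#' @return A square matrix with parts as dimnames.
#' @export
ratio_report <- function(tree, k) {
  lv <- level_view(tree, k)
  r <- outer(lv$dou, lv$dou, "/")
  dimnames(r) <- list(lv$part, lv$part)
  r
}

#' @export
print.localization_tree <- function(x, digits = 2, annotate = c("dou", "size"),
                                    ...) {
  annotate <- match.arg(annotate)
  cat(sprintf("Localization tree of %s (depth %d)\n", x$source,
              tree_depth(x)))
  rec <- function(id, prefix, branch) {
    n <- x$nodes[[id]]
    ann <- if (annotate == "dou")
      sprintf("D/c = %s", format(round(n$summary$dou, digits), nsmall = digits))
    else sprintf("n = %g", n$summary$size)
    tag <- if (n$terminal_reason %in% c("none")) "" else
      sprintf(" [%s]", n$terminal_reason)
    cat(sprintf("%s%s%s %s  %s%s\n", prefix, branch,
                if (n$role == "root") "root" else n$role,
                .format_part(n$part, digits + 2), ann, tag))
    kids <- n$children
    for (i in seq_along(kids)) {
      last <- i == length(kids)
      rec(kids[i],
          paste0(prefix, if (nzchar(branch))
            (if (startsWith(branch, "`")) "   " else "|  ") else ""),
          if (last) "`- " else "|- ")
    }
  }
  rec(1L, "", "")
  invisible(x)
}

#' Audit the nested ordering of uniformity across a tree level
#'
#' Property check on a built tree: for randomly chosen pairs of distinct
#' same-level parts, random measurable subsets of the left (more uniform)
#' part must have a strictly larger degree of uniformity than random subsets
#' of the right part. This nested monotonicity is what the recursive Hahn
#' construction guarantees; the audit is a numerical regression of it.
#'
#' @param tree A [build_tree()] result.
#' @param x The source the tree was built from.
#' @param n_samples Number of sampled subset pairs.
#' @param seed Integer seed making the audit reproducible.
#' @return List with `n_pairs`, `violations`, `counterexamples` (data frame,
#'   empty when all pass) and `trivial` (`TRUE` if the tree has no level
#'   with two parts).
#' @examples
#' b <- fixture_binomial(8, 0.4)
#' monotonicity_audit(build_tree(b), b, n_samples = 50, seed = 1)$violations
#' @export
monotonicity_audit <- function(tree, x, n_samples = 200, seed = 1) {
  depth <- tree_depth(tree)
  levels_ok <- Filter(function(k) nrow(level_view(tree, k)) >= 2,
                      seq_len(max(depth, 0)))
  if (!length(levels_ok))
    return(list(n_pairs = 0L, violations = 0L,
                counterexamples = data.frame(), trivial = TRUE))
  set.seed(seed)
  viol <- list()
  for (s in seq_len(n_samples)) {
    k <- if (length(levels_ok) == 1) levels_ok else sample(levels_ok, 1)
    lv <- level_view(tree, k)
    parts <- attr(lv, "parts")
    ij <- sort(sample(nrow(lv), 2))
    s1 <- .random_subpart(x, parts[[ij[1]]])
    s2 <- .random_subpart(x, parts[[ij[2]]])
    d1 <- part_summary(x, s1)$dou
    d2 <- part_summary(x, s2)$dou
    if (!(d1 > d2)) {
      viol[[length(viol) + 1L]] <-
        data.frame(level = k, left = .format_part(s1), right = .format_part(s2),
                   dou_left = d1, dou_right = d2, stringsAsFactors = FALSE)
    }
  }
  ce <- if (length(viol)) do.call(rbind, viol) else data.frame()
  list(n_pairs = n_samples, violations = length(viol), counterexamples = ce,
       trivial = FALSE)
}

# Random nonempty measurable subset of a part: a label subset (discrete) or
# a random sub-interval of one component (continuous; infinite tails are
# truncated where the remaining component mass drops below 0.1%).
.random_subpart <- function(x, part) {
  if (inherits(x, "discrete_distribution")) {
    n <- length(part)
    if (n == 1) return(part)
    sz <- sample(n, 1)
    return(sample(part, sz))
  }
  i <- if (nrow(part) == 1) 1L else
    sample(nrow(part), 1, prob = pmin(part[, "hi"] - part[, "lo"], 1e6))
  a <- part[i, "lo"]; b <- part[i, "hi"]
  if (is.infinite(b)) {
    b <- max(a + 1, 2 * abs(a) + 1)
    comp_mass <- mass_on(x, interval_union(a, Inf))
    while (mass_on(x, interval_union(a, b)) < 0.999 * comp_mass) b <- 2 * b + 1
  }
  u <- sort(stats::runif(2, a, b))
  while (u[2] - u[1] < 1e-9 * (b - a)) u <- sort(stats::runif(2, a, b))
  interval_union(u[1], u[2])
}

#' Interior breakpoints of a continuous tree level
#'
#' Collects the finite interval endpoints of the parts alive at level k of a
#' tree built over a density, excluding the endpoints of the root part
#' itself. These are the cut points the recursive splitter has introduced up
#' to that level.
#'
#' @inheritParams level_view
#' @return Sorted numeric vector of interior breakpoints.
#' @examples
#' tr <- build_tree(exponential_density(2), max_depth = 2)
#' round(level_breakpoints(tr, 2), 2)   # 0.21 0.50 1.00
#' @export
level_breakpoints <- function(tree, k) {
  if (tree$discrete)
    stop("breakpoints are defined for continuous trees only")
  parts <- attr(level_view(tree, k), "parts")
  ends <- unlist(lapply(parts, function(p) c(p[, "lo"], p[, "hi"])))
  root <- tree$nodes[[1]]$part
  ends <- ends[is.finite(ends)]
  ends <- setdiff(ends, c(root[, "lo"], root[, "hi"]))
  sort(unique(ends))
}
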