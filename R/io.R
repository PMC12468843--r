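#' Read a histogram file as a discrete distribution
#'
#' Reads a CSV or TSV file with a header and columns `label` plus either
#' `prob` (probabilities summing to one) or `count` (arbitrary non-negative
#' weights, normalized). The separator is chosen by file extension
#' (`.tsv`/`.tab` = tab, otherwise comma).
#'
#' @param path File path (UTF-8).
#' @param renormalize Force normalization even for a `prob` column.
#' @param tol Sum-to-one tolerance when not renormalizing.
#' @return A [discrete_distribution()].
#' @seealso [write_histogram()]
#' @export
read_histogram <- function(path, renormalize = FALSE, tol = 1e-9) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = NA)
  if (!"label" %in% names(df))
    stop("histogram file needs a `label` column")
  if ("prob" %in% names(df)) {
    discrete_distribution(df$label, df$prob, tol = tol,
                          renormalize = renormalize)
  } else if ("count" %in% names(df)) {
    discrete_distribution(df$label, df$count, renormalize = TRUE)
  } else {
    stop("histogram file needs a `prob` or `count` column")
  }
}

#' Write a discrete distribution as a histogram CSV
#' @param x A [discrete_distribution()].
#' @param path Output path (`.tsv`/`.tab` extension writes tab-separated).
#' @return `path`, invisibly.
#' @export
write_histogram <- function(x, path) {
  stopifnot(inherits(x, "discrete_distribution"))
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(data.frame(label = x$labels, prob = x$probs),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a density specification
#'
#' JSON files declare a family: `{"family": "exponential", "rate": 2}` or
#' `{"family": "piecewise_constant", "breaks": [...], "heights": [...]}`.
#' Piecewise tables are also accepted as CSV with columns `break` and
#' `height` (one more break than heights; the last height cell is ignored
#' and may be empty).
#'
#' @param path Path to a `.json` or `.csv` density specification.
#' @return A [density_model()].
#' @seealso [write_density()]
#' @export
read_density <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    spec <- jsonlite::fromJSON(path)
    if (is.null(spec$family)) stop("density JSON needs a `family` field")
    switch(spec$family,
           exponential = exponential_density(spec$rate),
           piecewise_constant = piecewise_density(spec$breaks, spec$heights),
           stop("unknown density family: ", spec$family))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(df) <- sub("^break\\.?$", "break", names(df))
    if (!all(c("break", "height") %in% names(df)))
      stop("piecewise density CSV needs `break` and `height` columns")
    piecewise_density(df[["break"]], df[["height"]][-nrow(df)])
  }
}

#' Write a density model's specification as JSON
#' @param x A built-in family [density_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density <- function(x, path) {
  stopifnot(inherits(x, "density_model"))
  spec <- switch(x$family,
                 exponential = list(family = "exponential",
                                    rate = x$params$rate),
                 piecewise_constant = list(family = "piecewise_constant",
                                           breaks = x$params$breaks,
                                           heights = x$params$heights),
                 stop("only built-in families can be serialized"))
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# JSON-safe numeric: infinities become the strings "Inf" / "-Inf".
.num_out <- function(v) {
  lapply(v, function(z) if (is.finite(z)) z else if (z > 0) "Inf" else "-Inf")
}
.num_in <- function(v) vapply(v, function(z) {
  if (is.character(z)) switch(z, `Inf` = Inf, `-Inf` = -Inf,
                              as.numeric(z)) else as.numeric(z)
}, numeric(1))

#' Export a localization tree to JSON
#'
#' Writes every node with its id, role, part (labels, or a list of
#' `[lo, hi]` interval endpoint pairs with infinities encoded as the strings
#' `"Inf"`/`"-Inf"`), summary quantities at full precision, creation level,
#' terminal reason and child ids, plus the tree's config and source
#' provenance. Key order is stable, so identical trees export to identical
#' files. [read_tree()] round-trips the file.
#'
#' @param tree A [build_tree()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "localization_tree"))
  nodes <- lapply(tree$nodes, function(n) {
    part <- if (tree$discrete) as.list(n$part) else
      lapply(seq_len(nrow(n$part)),
             function(i) .num_out(c(n$part[i, "lo"], n$part[i, "hi"])))
    list(id = n$id, role = n$role, part = part,
         c = n$summary$mass, H = n$summary$entropy, D = n$summary$diversity,
         dou = n$summary$dou, created_level = n$created_level,
         terminal_reason = n$terminal_reason, children = as.list(n$children))
  })
  out <- list(format = "ineqtree/tree", version = 1L,
              discrete = tree$discrete, source = tree$source,
              config = list(max_depth = .num_out(tree$config$max_depth)[[1]],
                            min_mass = tree$config$min_mass,
                            z_tol = tree$config$z_tol),
              nodes = nodes)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a localization tree exported by [write_tree()]
#' @param path Path to a tree JSON file.
#' @return A `"localization_tree"` object (structure and summaries; the
#'   source distribution itself is not stored).
#' @export
read_tree <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(raw$format, "ineqtree/tree"))
    stop("not an ineqtree tree JSON file")
  discrete <- isTRUE(raw$discrete)
  nodes <- lapply(raw$nodes, function(n) {
    part <- if (discrete) as.character(unlist(n$part)) else {
      ends <- lapply(n$part, .num_in)
      interval_union(vapply(ends, `[`, numeric(1), 1),
                     vapply(ends, `[`, numeric(1), 2))
    }
    list(id = as.integer(n$id),
         parent = NA_integer_,   # re-derived below
         role = n$role, part = part,
         # keep the stored numbers verbatim so re-export is bit-identical
         summary = structure(list(mass = n$c, entropy = n$H,
                                  diversity = n$D, dou = n$dou,
                                  size = if (discrete) length(part) else
                                    iu_length(part)),
                             class = "part_summary"),
         created_level = as.integer(n$created_level),
         children = as.integer(unlist(n$children)),
         terminal_reason = n$terminal_reason)
  })
  for (i in seq_along(nodes)) for (ch in nodes[[i]]$children)
    nodes[[ch]]$parent <- nodes[[i]]$id
  structure(list(nodes = nodes,
                 config = list(max_depth = .num_in(list(raw$config$max_depth)),
                               min_mass = raw$config$min_mass,
                               z_tol = raw$config$z_tol),
                 source = raw$source, discrete = discrete),
            class = "localization_tree")
}
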