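#' Dated ultrametric tree (chronogram)
#'
#' A thin wrapper around an [ape::phylo] tree carrying per-node ages in
#' millions of years (age = height above the present). Construction checks
#' ultrametricity: all leaves must sit at age 0 within `tol * root_age`.
#'
#' @param tree an `ape::phylo` with branch lengths in My.
#' @param tol relative ultrametricity tolerance (default 1e-6).
#' @return an object of class `chronogram`: list with `tree`, `ages`
#'   (numeric, indexed by node number), `root_age`, `tol`.
#' @export
chronogram <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  ages <- chronogram_node_ages(tree)
  n_tip <- length(tree$tip.label)
  root_age <- max(ages)
  dev <- abs(ages[seq_len(n_tip)])
  if (root_age > 0 && max(dev) > tol * root_age) {
    worst <- which.max(dev)
    stop(sprintf(
      "tree is not ultrametric within tolerance: leaf '%s' deviates by %g My (root age %g)",
      tree$tip.label[worst], dev[worst], root_age), call. = FALSE)
  }
  ages[seq_len(n_tip)] <- 0
  structure(list(tree = tree, ages = ages, root_age = root_age, tol = tol),
            class = "chronogram")
}

# node ages (height above the most distant-from-root leaf) for a phylo
chronogram_node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' @export
print.chronogram <- function(x, ...) {
  cat(sprintf("chronogram: %d tips, root age %.4g My\n",
              length(x$tree$tip.label), x$root_age))
  invisible(x)
}

#' Read a dated Newick tree as a chronogram
#'
#' Branch lengths are interpreted as millions of years; node ages are
#' computed as distances to the descendant leaves and ultrametricity is
#' checked within a relative tolerance. Plain and gzip-compressed files are
#' accepted.
#'
#' @param source path to a Newick file (optionally `.gz`).
#' @param tol relative ultrametricity tolerance.
#' @return a [chronogram].
#' @export
read_dated_newick <- function(source, tol = 1e-6) {
  txt <- read_text_maybe_gz(source)
  tree <- ape::read.tree(text = paste(txt, collapse = "\n"))
  if (is.null(tree)) stop(sprintf("could not parse Newick in '%s'", source),
                          call. = FALSE)
  chronogram(tree, tol = tol)
}

#' Write a chronogram as dated Newick
#'
#' @param x a [chronogram].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dated_newick <- function(x, path) {
  stopifnot(inherits(x, "chronogram"))
  ape::write.tree(x$tree, file = path, digits = 17)
  invisible(path)
}

#' Age of the most recent common ancestor of a leaf set
#'
#' @param x a [chronogram].
#' @param leaf_set character vector of tip labels (>= 1).
#' @return the MRCA age in My (0 for a single leaf).
#' @export
node_age <- function(x, leaf_set) {
  stopifnot(inherits(x, "chronogram"))
  unknown <- setdiff(leaf_set, x$tree$tip.label)
  if (length(unknown))
    stop(sprintf("unknown leaf label(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (length(leaf_set) == 1) return(0)
  node <- ape::getMRCA(x$tree, leaf_set)
  unname(x$ages[node])
}

#' Per-clade age offsets between two chronograms (macroevolutionary lag)
#'
#' For each mapped clade, finds the MRCA of the given leaf sets in each tree
#' and reports `lag = age_A - age_B`; a positive lag means the tree-A
#' (nematocyst) node is older than the corresponding tree-B (organismal)
#' node. Leaf sets that are not monophyletic in a tree are computed on the
#' MRCA anyway and flagged, since gene trees are often incongruent with the
#' species tree.
#'
#' @param tree_a,tree_b [chronogram] objects (A = nematocyst convention).
#' @param clade_map data.frame with columns `clade`, `leaves_a`, `leaves_b`
#'   (comma-separated tip labels).
#' @return an object of class `lag_report`: list with `per_clade` (clade,
#'   age_a, age_b, lag, monophyletic_a, monophyletic_b) and `summary`
#'   (min/max/mean lag).
#' @export
compute_lag <- function(tree_a, tree_b, clade_map) {
  stopifnot(inherits(tree_a, "chronogram"), inherits(tree_b, "chronogram"))
  req <- c("clade", "leaves_a", "leaves_b")
  if (!all(req %in% names(clade_map)))
    stop("clade_map needs columns clade, leaves_a, leaves_b", call. = FALSE)
  one <- function(tree, leaves) {
    ls <- trimws(strsplit(leaves, ",")[[1]])
    age <- node_age(tree, ls)
    mono <- is_monophyletic_set(tree, ls)
    list(age = age, mono = mono)
  }
  rows <- lapply(seq_len(nrow(clade_map)), function(i) {
    a <- one(tree_a, clade_map$leaves_a[i])
    b <- one(tree_b, clade_map$leaves_b[i])
    data.frame(clade = clade_map$clade[i], age_a = a$age, age_b = b$age,
               lag = a$age - b$age, monophyletic_a = a$mono,
               monophyletic_b = b$mono, stringsAsFactors = FALSE)
  })
  per_clade <- do.call(rbind, rows)
  if (any(!per_clade$monophyletic_a | !per_clade$monophyletic_b))
    warning("some leaf sets are not monophyletic; lag computed on their MRCA",
            call. = FALSE)
  structure(list(per_clade = per_clade,
                 summary = c(min = min(per_clade$lag),
                             max = max(per_clade$lag),
                             mean = mean(per_clade$lag))),
            class = "lag_report")
}

is_monophyletic_set <- function(x, leaves) {
  if (length(leaves) == 1) return(TRUE)
  node <- ape::getMRCA(x$tree, leaves)
  desc <- sort(x$tree$tip.label[phangorn_free_desc(x$tree, node)])
  identical(desc, sort(leaves))
}

#' @export
print.lag_report <- function(x, ...) {
  cat(sprintf("lag report: %d clades, lag %.4g to %.4g My (mean %.4g)\n",
              nrow(x$per_clade), x$summary["min"], x$summary["max"],
              x$summary["mean"]))
  invisible(x)
}

read_text_maybe_gz <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}
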