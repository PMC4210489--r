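#' Read chronograms from a newick or NEXUS file
#'
#' Reads one or more rooted, time-calibrated trees. Branch lengths are
#' interpreted as millions of years (Myr). NEXUS translate tables are resolved
#' to full tip labels. Every tree is validated: branch lengths must be present,
#' trees must have at least two tips, and polytomies are rejected unless
#' \code{resolve_polytomies = TRUE}, in which case they are randomly resolved
#' with zero-length internal edges (the birth-death likelihood assumes binary
#' trees).
#'
#' @param path Path to the tree file.
#' @param format One of \code{"auto"}, \code{"newick"}, \code{"nexus"}.
#'   \code{"auto"} sniffs for a \code{#NEXUS} header.
#' @param resolve_polytomies Logical; randomly resolve multifurcations with
#'   zero-length edges instead of rejecting them.
#' @return A list of \code{phylo} objects (class \code{multiPhylo}), in file
#'   order.
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus"),
                       resolve_polytomies = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (format == "auto") {
    head_lines <- readLines(path, n = 5L, warn = FALSE)
    format <- if (any(grepl("^\\s*#NEXUS", head_lines, ignore.case = TRUE)))
      "nexus" else "newick"
  }
  trees <- tryCatch(
    suppressWarnings(
      if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(trees)) stop("failed to parse ", format, " file '", path,
                           "': no trees found", call. = FALSE)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!is.null(attr(trees, "TipLabel")))
    trees <- ape::.uncompressTipLabel(trees)
  trees <- unclass(trees)
  out <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    out[[i]] <- tryCatch(
      validate_chronogram(tr, resolve_polytomies = resolve_polytomies),
      error = function(e) stop("tree ", i, " in '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  class(out) <- "multiPhylo"
  out
}

# Structural validation shared by the reader and the simulator output.
validate_chronogram <- function(tree, resolve_polytomies = FALSE) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (ape::Ntip(tree) < 2L) stop("tree has fewer than 2 tips")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    if (!resolve_polytomies)
      stop("tree contains polytomies; set resolve_polytomies = TRUE to ",
           "randomly resolve them with zero-length edges")
    tree <- ape::multi2di(tree, random = TRUE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

#' Node ages of a chronogram
#'
#' Ages in Myr before the present (tips at age ~0, increasing into the past),
#' for all nodes (tips first, internal nodes after, in \code{phylo} node
#' numbering). The present is taken as the maximum root-to-tip depth.
#'
#' @param tree A \code{phylo} chronogram.
#' @return Numeric vector of length \code{Ntip + Nnode}.
#' @export
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths) - depths
}

#' Check a tree for ultrametricity
#'
#' A chronogram is ultrametric when every tip is equidistant from the root.
#' This check is report-style: it never throws. Deviations are measured
#' against the median tip depth (so a single aberrant tip is the one
#' reported, not the conforming majority) and compared with a tolerance
#' relative to the tree height.
#'
#' @param tree A \code{phylo} object with branch lengths.
#' @param tol Relative tolerance (fraction of tree height); default
#'   \code{1e-6}.
#' @return A list of class \code{ultra_check} with elements \code{pass},
#'   \code{max_deviation} (absolute, Myr), \code{relative_deviation},
#'   \code{height}, and \code{bad_tips}.
#' @export
check_ultrametric <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"), ape::Ntip(tree) >= 2L)
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  height <- max(ape::node.depth.edgelength(tree))
  dev <- abs(depths - stats::median(depths))
  bad <- dev > tol * height
  structure(list(
    pass = !any(bad),
    max_deviation = max(dev),
    relative_deviation = max(dev) / height,
    height = height,
    bad_tips = tree$tip.label[bad]
  ), class = "ultra_check")
}

#' @export
print.ultra_check <- function(x, ...) {
  cat(sprintf("Ultrametricity check: %s (height %.6g Myr, max deviation %.3g)\n",
              if (x$pass) "PASS" else "FAIL", x$height, x$max_deviation))
  if (!x$pass)
    cat("  violating tips:", paste(utils::head(x$bad_tips, 10), collapse = ", "),
        if (length(x$bad_tips) > 10) "..." else "", "\n")
  invisible(x)
}

#' Force a nearly ultrametric tree to be exactly ultrametric
#'
#' Extends terminal branches so every tip reaches the maximum depth. Intended
#' for trees that fail \code{\link{check_ultrametric}} by numerical noise only;
#' this is an opt-in repair, not a default.
#'
#' @param tree A \code{phylo} object.
#' @return The adjusted tree.
#' @export
extend_tips_ultrametric <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths)
  is_tip_edge <- tree$edge[, 2] <= ape::Ntip(tree)
  tip_depth <- depths[tree$edge[is_tip_edge, 2]]
  tree$edge.length[is_tip_edge] <- tree$edge.length[is_tip_edge] +
    (height - tip_depth)
  tree
}
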