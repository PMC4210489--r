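#' Branching times of an ultrametric chronogram
#'
#' Extracts the internal-node ages of a chronogram as a descending vector:
#' the sufficient statistic for birth-death likelihoods on ultrametric trees.
#' Ages are in Myr before the (possibly re-based) present.
#'
#' @param tree A \code{phylo} chronogram, ultrametric within \code{tol}.
#' @param tol Relative ultrametricity tolerance; trees failing it are
#'   rejected.
#' @return An object of class \code{branching_times}: a list with
#'   \code{times} (descending ages, length \code{n - 1}; the first entry is
#'   the crown age), \code{n} (number of represented lineages at the analysis
#'   present) and \code{t_cut} (re-base offset in Myr; 0 for untruncated
#'   trees).
#' @export
branching_times <- function(tree, tol = 1e-6) {
  chk <- check_ultrametric(tree, tol = tol)
  if (!chk$pass)
    stop("tree is not ultrametric within tolerance (relative deviation ",
         format(chk$relative_deviation, digits = 3), "); see check_ultrametric()")
  ages <- node_ages(tree)[ape::Ntip(tree) + seq_len(tree$Nnode)]
  new_branching_times(sort(ages, decreasing = TRUE), n = ape::Ntip(tree),
                      t_cut = 0)
}

new_branching_times <- function(times, n, t_cut = 0) {
  stopifnot(length(times) == n - 1L, all(times > 0),
            !is.unsorted(rev(times)))
  structure(list(times = as.numeric(times), n = as.integer(n),
                 t_cut = as.numeric(t_cut)),
            class = "branching_times")
}

#' @export
print.branching_times <- function(x, ...) {
  cat(sprintf("Branching times: %d lineages, crown age %.4g Myr%s\n",
              x$n, x$times[1],
              if (x$t_cut > 0) sprintf(" (re-based at %.4g Myr)", x$t_cut) else ""))
  invisible(x)
}

#' Truncate branching times at a time horizon
#'
#' Keeps only branching events older than \code{t_cut} Myr before the present
#' and re-bases the age axis so the horizon becomes the new analysis present.
#' The number of represented lineages becomes the number of lineages crossing
#' the horizon (1 + the number of retained branching events, for a
#' crown-rooted tree). Truncation composes additively:
#' \code{truncate_at(truncate_at(bt, a), b)} equals
#' \code{truncate_at(bt, a + b)}.
#'
#' @param bt A \code{branching_times} object.
#' @param t_cut Horizon in Myr before the current present;
#'   \code{0 <= t_cut < crown age}.
#' @return A re-based \code{branching_times} object with \code{t_cut}
#'   recording the cumulative offset.
#' @export
truncate_at <- function(bt, t_cut) {
  stopifnot(inherits(bt, "branching_times"), is.numeric(t_cut), t_cut >= 0)
  if (t_cut == 0) return(bt)
  if (t_cut >= bt$times[1])
    stop("t_cut (", t_cut, ") is at or beyond the crown age (", bt$times[1],
         "): fewer than 2 lineages would remain")
  keep <- bt$times > t_cut
  new_branching_times(bt$times[keep] - t_cut, n = sum(keep) + 1L,
                      t_cut = bt$t_cut + t_cut)
}

#' Lineage-through-time curve
#'
#' The number of reconstructed lineages as a step function of age. For a
#' crown-rooted chronogram the count is 2 just below the crown age and
#' \code{n} at age 0; each branching time adds one lineage going toward the
#' present.
#'
#' @param x A \code{phylo} chronogram or a \code{branching_times} object.
#' @param ... Passed to \code{branching_times} when \code{x} is a tree.
#' @return A data frame of class \code{ltt_curve} with columns \code{age}
#'   (Myr, descending from the crown age to 0), \code{lineages}, and
#'   \code{log10_lineages}. Row \code{i} gives the count on the age interval
#'   \code{[age[i], age[i-1])}.
#' @export
ltt_curve <- function(x, ...) {
  bt <- if (inherits(x, "branching_times")) x else branching_times(x, ...)
  ages <- c(bt$times, 0)                 # descending; crown first
  counts <- c(seq.int(2L, bt$n), bt$n)   # count just below each age
  out <- data.frame(age = ages, lineages = counts,
                    log10_lineages = log10(counts))
  class(out) <- c("ltt_curve", "data.frame")
  out
}

#' Evaluate an LTT curve at given ages
#'
#' @param curve An \code{ltt_curve}.
#' @param ages Ages (Myr) at which to evaluate the step function. Ages at or
#'   above the crown age give 1 (single stem lineage); the curve is
#'   right-continuous in time (left-continuous in age).
#' @return Integer lineage counts.
#' @export
ltt_at <- function(curve, ages) {
  crown <- curve$age[1]
  n <- curve$lineages[nrow(curve)]
  # lineage count at age a = 1 + number of branching times > a (crown-rooted)
  btimes <- curve$age[-nrow(curve)]
  vapply(ages, function(a) {
    if (a >= crown) 1L else 1L + sum(btimes > a)
  }, integer(1))
}

#' Pointwise median LTT over a set of curves
#'
#' The median lineage count over curves at each age of a common evaluation
#' grid, as used to summarize an LTT plot over a posterior sample of trees.
#'
#' @param curves A non-empty list of \code{ltt_curve} objects.
#' @param ages Evaluation grid (Myr).
#' @return A data frame with columns \code{age}, \code{lineages} (median,
#'   possibly half-integer), and \code{log10_lineages}.
#' @export
median_ltt <- function(curves, ages) {
  if (length(curves) == 0) stop("empty curve set")
  counts <- vapply(curves, ltt_at, numeric(length(ages)), ages = ages)
  med <- apply(matrix(counts, nrow = length(ages)), 1, stats::median)
  data.frame(age = ages, lineages = med, log10_lineages = log10(med))
}

#' Write an LTT curve as TSV
#'
#' @param curve A data frame with \code{age}, \code{lineages},
#'   \code{log10_lineages}.
#' @param path Output path.
#' @export
write_ltt <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
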