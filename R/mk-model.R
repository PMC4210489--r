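# One-parameter symmetric 2-state Markov (Mk) model for a binary habitat
# character, with maximum-likelihood rate estimation and marginal ancestral
# state reconstruction by the inside-outside (up/down partials) scheme.
# States are coded 0 ("other") and 1 ("arid_semiarid") internally.

#' Transition probabilities of the symmetric 2-state Mk model
#'
#' \code{P(same) = (1 + exp(-2 q dt))/2}, \code{P(diff) = (1 - exp(-2 q dt))/2}.
#'
#' @param q Symmetric exchange rate (transitions per Myr), \code{>= 0}.
#' @param dt Elapsed time (branch length), \code{>= 0}.
#' @return A 2x2 stochastic matrix (rows: ancestral state 0/1).
#' @export
mk_transition_matrix <- function(q, dt) {
  if (q < 0) stop("rate q must be non-negative")
  same <- 0.5 * (1 + exp(-2 * q * dt))
  matrix(c(same, 1 - same, 1 - same, same), 2, 2)
}

# Coerce a character vector/factor of states to internal 0/1/NA coding,
# named by taxon.
coerce_states <- function(states) {
  if (is.factor(states)) states <- as.character(states)
  if (is.character(states)) {
    out <- ifelse(states %in% c("arid_semiarid", "arid", "1"), 1L,
                  ifelse(states %in% c("other", "0"), 0L, NA_integer_))
    unknown <- !is.na(states) & is.na(out) & !states %in% c("?", "-", "NA", "")
    if (any(unknown))
      stop("unrecognized state value(s): ",
           paste(unique(states[unknown]), collapse = ", "))
  } else {
    out <- as.integer(states)
    if (any(!out %in% c(0L, 1L) & !is.na(out)))
      stop("numeric states must be 0, 1 or NA")
  }
  names(out) <- names(states)
  out
}

# Align a named state vector with a tree's tips; missing taxa -> NA partials.
tip_state_matrix <- function(tree, states) {
  states <- coerce_states(states)
  if (is.null(names(states)))
    stop("states must be named by taxon label")
  extra <- setdiff(names(states)[!is.na(states)], tree$tip.label)
  if (length(extra))
    stop("character table has taxa absent from the tree: ",
         paste(utils::head(extra, 5), collapse = ", "))
  s <- states[tree$tip.label]
  if (sum(!is.na(s)) < 2)
    stop("fewer than 2 tips with non-missing states")
  part <- matrix(1, ape::Ntip(tree), 2)
  part[which(s == 0L), 2] <- 0
  part[which(s == 1L), 1] <- 0
  part
}

# Per-node child lists and branch lengths, plus a postorder node sequence
# (children before parents).
tree_topology <- function(tree) {
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  elen <- ape::reorder.phylo(tree, "postorder")$edge.length
  children <- split(edge[, 2], edge[, 1])
  branch <- split(elen, edge[, 1])
  postorder_nodes <- unique(edge[, 1])      # parents after their children
  parent_of <- integer(max(edge))
  parent_of[edge[, 2]] <- edge[, 1]
  edge_len_to <- numeric(max(edge))
  edge_len_to[edge[, 2]] <- elen
  list(children = children, branch = branch,
       postorder_nodes = postorder_nodes, parent_of = parent_of,
       edge_len_to = edge_len_to,
       root = postorder_nodes[length(postorder_nodes)])
}

# Felsenstein pruning: per-node normalized partials (conditional likelihoods
# of the subtree below each node) and cumulative log scalers. attr "zero"
# flags an impossible configuration (likelihood exactly 0, e.g. at q = 0
# with incompatible tip states).
mk_down_pass <- function(tree, tip_part, q, topo = tree_topology(tree)) {
  ntip <- ape::Ntip(tree)
  partials <- matrix(0, ntip + tree$Nnode, 2)
  partials[seq_len(ntip), ] <- tip_part
  logscale <- numeric(ntip + tree$Nnode)
  zero <- FALSE
  for (v in topo$postorder_nodes) {
    key <- as.character(v)
    kids <- topo$children[[key]]
    lens <- topo$branch[[key]]
    part <- c(1, 1)
    for (j in seq_along(kids)) {
      P <- mk_transition_matrix(q, lens[j])
      part <- part * as.vector(P %*% partials[kids[j], ])
      logscale[v] <- logscale[v] + logscale[kids[j]]
    }
    f <- sum(part)
    if (f == 0) {
      zero <- TRUE
      partials[v, ] <- 0
    } else {
      partials[v, ] <- part / f
      logscale[v] <- logscale[v] + log(f)
    }
  }
  structure(list(partials = partials, logscale = logscale), zero = zero)
}

#' Log-likelihood of a binary character under the symmetric Mk model
#'
#' Felsenstein pruning over the tree with the 2-state symmetric transition
#' probabilities, combining the root partials with the root state prior
#' (uniform by default, which is also the model's stationary distribution).
#' Missing states contribute flat tip partials.
#'
#' @param tree A \code{phylo} tree (chronogram or phylogram; branch lengths
#'   in the same units as \code{1/q}).
#' @param states Named vector of tip states: \code{0}/\code{1}, the strings
#'   \code{"other"}/\code{"arid_semiarid"}, or \code{NA}/\code{"?"} for
#'   missing.
#' @param q Symmetric exchange rate, \code{>= 0}.
#' @param root_prior Root state prior, default \code{c(0.5, 0.5)}.
#' @return Log-likelihood (\code{-Inf} for data impossible under the model,
#'   e.g. incompatible states at \code{q = 0}).
#' @export
mk_loglik <- function(tree, states, q, root_prior = c(0.5, 0.5)) {
  if (q < 0) stop("rate q must be non-negative")
  tip_part <- tip_state_matrix(tree, states)
  down <- mk_down_pass(tree, tip_part, q)
  root <- tree_topology(tree)$root
  tot <- sum(root_prior * down$partials[root, ])
  if (attr(down, "zero") || tot == 0) return(-Inf)
  log(tot) + down$logscale[root]
}

#' Maximum-likelihood estimate of the Mk exchange rate
#'
#' One-dimensional bounded maximization of \code{\link{mk_loglik}} in
#' \code{log q}. Solutions at the search boundary (in particular
#' \code{q_hat ~ 0} when all scored tips share one state) are flagged.
#'
#' @inheritParams mk_loglik
#' @param interval Search interval for \code{q} (natural scale).
#' @return A list of class \code{mk_fit}: \code{q}, \code{loglik},
#'   \code{boundary} (logical), \code{n_scored}.
#' @export
fit_mk <- function(tree, states, interval = c(1e-8, 100),
                   root_prior = c(0.5, 0.5)) {
  s <- coerce_states(states)
  if (all(is.na(s))) stop("all tip states are missing")
  obj <- function(lq) -mk_loglik(tree, states, exp(lq), root_prior)
  opt <- stats::optimize(obj, interval = log(interval), tol = 1e-10)
  q_hat <- exp(opt$minimum)
  span <- diff(log(interval))
  boundary <- (opt$minimum - log(interval[1]) < 1e-3 * span) ||
    (log(interval[2]) - opt$minimum < 1e-3 * span)
  structure(list(q = q_hat, loglik = -opt$objective, boundary = boundary,
                 n_scored = sum(!is.na(s))),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk fit: q = %.6g per Myr, logL = %.4f (%d scored tips)%s\n",
              x$q, x$loglik, x$n_scored,
              if (x$boundary) " [boundary solution]" else ""))
  invisible(x)
}

#' Marginal ancestral state reconstruction under the symmetric Mk model
#'
#' For every internal node, the marginal log-likelihood of each state (the
#' likelihood of all tip data with that node's state fixed and all other
#' node states summed out), computed by an inside-outside (down/up partials)
#' pass. A node's preferred state is called \code{"significant"} when it
#' beats the alternative by at least \code{delta} log-likelihood units
#' (default 2.0), otherwise \code{"ambiguous"}. At every node the
#' log-sum-exp of the two per-state values equals the total data
#' log-likelihood (exact marginalization identity).
#'
#' @inheritParams mk_loglik
#' @param delta Significance threshold on the log-likelihood difference.
#' @return A data frame of class \code{asr_result}, one row per internal
#'   node: \code{node} (phylo node id), \code{anchor} (two tip labels whose
#'   MRCA the node is), \code{lnL_other}, \code{lnL_arid}, \code{best_state},
#'   \code{delta_lnl}, \code{call}. Attribute \code{total_loglik} carries
#'   the data log-likelihood.
#' @export
marginal_asr <- function(tree, states, q, root_prior = c(0.5, 0.5),
                         delta = 2.0) {
  if (q < 0) stop("rate q must be non-negative")
  tip_part <- tip_state_matrix(tree, states)
  topo <- tree_topology(tree)
  down <- mk_down_pass(tree, tip_part, q, topo)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  root <- topo$root
  total <- {
    tot <- sum(root_prior * down$partials[root, ])
    if (attr(down, "zero") || tot == 0) -Inf else log(tot) + down$logscale[root]
  }
  # Up (outside) pass, preorder: up[v, s] is the likelihood of all data
  # outside v's subtree given v is in state s, including the root prior;
  # normalized with its own log scaler.
  up <- matrix(0, ntip + nnode, 2)
  upscale <- numeric(ntip + nnode)
  up[root, ] <- root_prior
  for (v in rev(topo$postorder_nodes)) {
    key <- as.character(v)
    kids <- topo$children[[key]]
    lens <- topo$branch[[key]]
    for (j in seq_along(kids)) {
      child <- kids[j]
      # sibling contributions at the parent state
      sib_term <- c(1, 1)
      sib_scale <- 0
      for (jj in seq_along(kids)) {
        if (jj == j) next
        Pb <- mk_transition_matrix(q, lens[jj])
        sib_term <- sib_term * as.vector(Pb %*% down$partials[kids[jj], ])
        sib_scale <- sib_scale + down$logscale[kids[jj]]
      }
      Pc <- mk_transition_matrix(q, lens[j])
      u <- as.vector(t(Pc) %*% (up[v, ] * sib_term))
      f <- sum(u)
      if (f == 0) {
        up[child, ] <- 0
        upscale[child] <- -Inf
      } else {
        up[child, ] <- u / f
        upscale[child] <- upscale[v] + sib_scale + log(f)
      }
    }
  }
  internal <- (ntip + 1L):(ntip + nnode)
  lnl <- matrix(-Inf, nnode, 2)
  for (i in seq_along(internal)) {
    v <- internal[i]
    joint <- up[v, ] * down$partials[v, ]
    lnl[i, ] <- ifelse(joint > 0,
                       log(joint) + upscale[v] + down$logscale[v], -Inf)
  }
  best <- ifelse(lnl[, 2] > lnl[, 1], "arid_semiarid", "other")
  dl <- abs(lnl[, 2] - lnl[, 1])
  dl[is.nan(dl)] <- 0   # both -Inf: impossible data, no preference
  anchors <- vapply(internal, function(v) {
    tips <- node_descendant_tips(topo, v, ntip)
    paste(tree$tip.label[c(tips[1], tips[length(tips)])], collapse = "|")
  }, character(1))
  out <- data.frame(node = internal, anchor = anchors,
                    lnL_other = lnl[, 1], lnL_arid = lnl[, 2],
                    best_state = best, delta_lnl = dl,
                    call = ifelse(dl >= delta, "significant", "ambiguous"))
  attr(out, "total_loglik") <- total
  attr(out, "q") <- q
  class(out) <- c("asr_result", "data.frame")
  out
}

# Tip indices descending from node v.
node_descendant_tips <- function(topo, v, ntip) {
  stack <- v
  tips <- integer(0)
  while (length(stack)) {
    x <- stack[[1]]
    stack <- stack[-1]
    if (x <= ntip) tips <- c(tips, x)
    else stack <- c(stack, topo$children[[as.character(x)]])
  }
  sort(tips)
}

#' Read a taxon-state character table
#'
#' Tab-separated table with columns \code{taxon} and \code{state}
#' (\code{"arid_semiarid"}, \code{"other"}, or \code{"?"} for missing).
#'
#' @param path File path.
#' @return Named state vector suitable for \code{\link{mk_loglik}}.
#' @export
read_character_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("taxon", "state") %in% names(tab)))
    stop("character table needs 'taxon' and 'state' columns")
  stats::setNames(tab$state, tab$taxon)
}

#' Write a character table as TSV
#'
#' @param states Named state vector (0/1/NA or state strings).
#' @param path Output path.
#' @param header Optional comment lines (e.g. simulation provenance).
#' @export
write_character_table <- function(states, path, header = NULL) {
  s <- coerce_states(states)
  lab <- ifelse(is.na(s), "?", ifelse(s == 1L, "arid_semiarid", "other"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("taxon\tstate", con)
  writeLines(paste(names(s), lab, sep = "\t"), con)
  invisible(path)
}

#' Prune a tree to one representative tip per group
#'
#' Keeps, for each group (e.g. genus), the tip with the fewest missing
#' character observations, breaking ties lexicographically by tip label.
#'
#' @param tree A \code{phylo} tree.
#' @param groups Named vector mapping tip label to group.
#' @param n_missing Optional named vector of per-tip missing-data counts
#'   (default all 0, so selection is purely lexicographic).
#' @return The pruned tree; kept tips are relabeled by their group name.
#' @export
prune_to_one_per_group <- function(tree, groups, n_missing = NULL) {
  stopifnot(!is.null(names(groups)))
  tips <- intersect(tree$tip.label, names(groups))
  if (length(tips) == 0) stop("no tree tips named in 'groups'")
  if (is.null(n_missing))
    n_missing <- stats::setNames(rep(0, length(tips)), tips)
  keep <- vapply(split(tips, groups[tips]), function(members) {
    members[order(n_missing[members], members)][1]
  }, character(1))
  pruned <- ape::keep.tip(tree, unname(keep))
  pruned$tip.label <- names(keep)[match(pruned$tip.label, keep)]
  pruned
}

#' Write an ancestral-state reconstruction table as TSV
#'
#' @param asr An \code{asr_result}.
#' @param path Output path.
#' @export
write_asr_table <- function(asr, path) {
  utils::write.table(asr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
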