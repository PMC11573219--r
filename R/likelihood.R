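# topology tables used by the pruning engine and the MCMC kernel

# parent vector, children matrix (Nnode x 2) and a postorder listing of
# internal nodes. Because every internal node is strictly older than its
# children, sorting internal nodes by age ascending is a valid postorder.
tree_tables <- function(tree) {
  ntip <- n_tips(tree)
  nnode <- 2L * ntip - 1L
  parent <- integer(nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  ord <- order(tree$edge[, 1L])
  children <- matrix(tree$edge[ord, 2L], ncol = 2L, byrow = TRUE)
  internals <- (ntip + 1L):nnode
  list(
    parent = parent,
    children = children,
    postorder = internals[order(tree$ages[internals])]
  )
}

# expected substitutions on the branch above each node (root entry 0)
branch_distances <- function(tree, parent, branch_rates) {
  d <- numeric(length(tree$ages))
  nonroot <- which(parent > 0L)
  dur <- tree$ages[parent[nonroot]] - tree$ages[nonroot]
  r <- if (length(branch_rates) == 1L) branch_rates else branch_rates[nonroot]
  d[nonroot] <- r * dur
  d
}

# 0-based pattern matrix in tree tip order; NA -> -1 (missing)
pattern_codes <- function(aln, tree) {
  idx <- match(tree$tip.label, aln$tip.label)
  if (anyNA(idx)) {
    stop_betsig("alignment labels do not match tree tips", "betsig_data_error")
  }
  m <- aln$patterns[idx, , drop = FALSE] - 1L
  m[is.na(m)] <- -1L
  storage.mode(m) <- "integer"
  m
}

#' Phylogenetic log likelihood
#'
#' Computes `log p(D | T, model, rates)` by Felsenstein's pruning algorithm
#' over compressed site patterns, with per-node rescaling for numerical
#' stability. Branch distances are `rate * duration`: a strict clock supplies
#' one rate for every branch, a relaxed clock one rate per branch (indexed by
#' the ape number of the node below the branch).
#'
#' @param tree A [timetree()].
#' @param branch_rates A single rate (strict clock) or a numeric vector of
#'   length `2n - 1` with per-branch rates (the root entry is ignored), in
#'   substitutions/site/time.
#' @param model A [subst_model()].
#' @param aln A [bets_alignment()] whose labels match the tree's tips.
#' @return The log likelihood (a scalar; `-Inf` if the data are impossible
#'   under the model).
#' @export
phylo_log_likelihood <- function(tree, branch_rates, model, aln) {
  tt <- tree_tables(tree)
  dist <- branch_distances(tree, tt$parent, branch_rates)
  pruning_loglik_cpp(
    tt$children, tt$postorder, dist, pattern_codes(aln, tree),
    aln$weights, model$pi, model$kappa, model_gamma_rates(model)
  )
}
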