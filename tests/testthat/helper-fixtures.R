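# shared fixtures and independent oracles, all built in code

random_alignment_matrix <- function(ntax, nsites, missing = 0) {
  m <- matrix(sample(c("A", "C", "G", "T"), ntax * nsites, replace = TRUE),
              nrow = ntax, dimnames = list(paste0("t", seq_len(ntax)), NULL))
  if (missing > 0) m[sample(length(m), missing)] <- "N"
  m
}

column_multiset <- function(m) sort(apply(m, 2, paste, collapse = ""))

# exhaustive phylogenetic likelihood: sum over every assignment of states to
# internal nodes, using transition_matrix(); independent of the pruning code
brute_force_loglik <- function(tree, rate, model, aln) {
  ntip <- length(tree$tip.label)
  nnode <- 2L * ntip - 1L
  parent <- integer(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  cat_rates <- if (is.null(model$gamma_shape)) 1 else
    discrete_gamma_rates(model$gamma_shape, model$gamma_ncat)
  idx <- match(tree$tip.label, aln$tip.label)
  pat <- aln$patterns[idx, , drop = FALSE]
  total <- 0
  for (s in seq_along(aln$weights)) {
    site_lik <- 0
    for (rc in cat_rates) {
      P <- lapply(seq_len(nnode), function(v) {
        if (v == root) return(NULL)
        d <- rc * rate * (tree$ages[parent[v]] - tree$ages[v])
        transition_matrix_single(model, d)
      })
      # enumerate internal states
      states <- as.matrix(expand.grid(rep(list(1:4), ntip - 1L)))
      lik <- 0
      for (row in seq_len(nrow(states))) {
        assign_int <- states[row, ]           # internal node v -> state
        state_of <- function(v) if (v <= ntip) pat[v, s] else assign_int[v - ntip]
        p <- unname(model$pi[state_of(root)])
        if (is.na(p)) p <- 1  # missing at a tip handled below; root is internal
        for (v in seq_len(nnode)) {
          if (v == root) next
          x <- state_of(v)
          a <- state_of(parent[v])
          p <- p * if (is.na(x)) 1 else P[[v]][a, x]
        }
        lik <- lik + p
      }
      site_lik <- site_lik + lik / length(cat_rates)
    }
    total <- total + aln$weights[s] * log(site_lik)
  }
  total
}

# single-category transition matrix (no gamma averaging), for the oracle
transition_matrix_single <- function(model, d) {
  m <- model
  m$gamma_shape <- NULL
  transition_matrix(m, d)
}

# serial 3-taxon tree with hand-set ages for prior oracles
three_taxon_serial_tree <- function() {
  # tips: t1 age 0, t2 age 0.3, t3 age 0.1; coalescences at 0.8 ((t1,t2)) and 1.5
  edge <- rbind(c(4, 5), c(4, 3), c(5, 1), c(5, 2))
  timetree(edge, ages = c(0, 0.3, 0.1, 1.5, 0.8), tip_label = c("t1", "t2", "t3"))
}
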