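# Independent oracles used across tests.

# Brute-force column likelihood: explicit sum over all internal-node state
# assignments (feasible for <= 5 tips). Stays independent of the pruning code
# path: transition matrices come from the model's generator via expm-free
# closed summation over assignments.
brute_force_loglik <- function(tree, column, model, lambda) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- ape::Ntip(tr)
  nnode <- tr$Nnode
  k <- length(model$states)
  Ps <- lapply(seq_len(nrow(tr$edge)), function(e)
    transition_matrix(model, lambda * tr$edge.length[e]))
  internal <- (ntip + 1):(ntip + nnode)
  combos <- expand.grid(rep(list(seq_len(k)), nnode))
  root <- tr$edge[nrow(tr$edge), 1]
  obs <- match(column[tr$tip.label], model$states)
  tot <- 0
  for (ci in seq_len(nrow(combos))) {
    st <- integer(ntip + nnode)
    st[internal] <- unlist(combos[ci, ])
    st[seq_len(ntip)] <- obs
    p <- model$freqs[st[root]]
    for (e in seq_len(nrow(tr$edge)))
      p <- p * Ps[[e]][st[tr$edge[e, 1]], st[tr$edge[e, 2]]]
    tot <- tot + p
  }
  log(tot)
}

# Closed-form JC69 transition probabilities for the two-taxon checks.
jc_p_same <- function(t) 1 / 4 + 3 / 4 * exp(-4 * t / 3)
jc_p_diff <- function(t) 1 / 4 - 1 / 4 * exp(-4 * t / 3)

# Adaptive-quadrature epoch integral of the informativeness density.
quad_epoch <- function(lambda, t1, t2) {
  stats::integrate(function(t) 16 * lambda^2 * t * exp(-4 * lambda * t),
                   t1, t2, rel.tol = 1e-12, abs.tol = 1e-12)$value
}

random_ultrametric <- function(n_tips, depth = NULL) {
  if (is.null(depth)) depth <- stats::runif(1, 0.5, 2)
  tr <- phytools::pbtree(n = n_tips, scale = depth, quiet = TRUE)
  validate_tree(tr)
}
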