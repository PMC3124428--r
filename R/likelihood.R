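# Felsenstein pruning machinery. Partial likelihoods are carried as
# (n_states x n_columns) matrices so a whole locus is evaluated in one pass;
# the per-column rate enters only through the product rate * branch length,
# which for a reversible model gives the conditional update
#   L_parent <- A (exp(evals %o% (rate * len)) * (B L_child))
# from the spectral form P(t) = A exp(Dt) B.

state_partial <- function(char, model, alphabet) {
  k <- length(model$states)
  if (char %in% missing_codes(alphabet)) return(rep(1, k))
  set <- if (alphabet == "PROTEIN") AA_STATE_SETS[[char]] else DNA_STATE_SETS[[char]]
  if (is.null(set))
    stop(sprintf("unknown %s state '%s'", alphabet, char), call. = FALSE)
  as.numeric(model$states %in% set)
}

# Precompute everything the pruning pass needs for a reconciled
# alignment/tree pair: postorder edge list and tip partial matrices.
tip_partials <- function(alignment, tree, model) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- ape::Ntip(tr)
  k <- length(model$states)
  n <- ncol(alignment$seq)
  chars <- unique(as.vector(alignment$seq))
  lut <- vapply(chars, state_partial, numeric(k), model = model,
                alphabet = alignment$alphabet)
  partials <- array(0, dim = c(k, n, ntip))
  idx <- match(tr$tip.label, alignment$taxa)
  if (anyNA(idx))
    stop("tree tip absent from alignment (reconcile first)", call. = FALSE)
  for (i in seq_len(ntip)) {
    partials[, , i] <- lut[, match(alignment$seq[idx[i], ], chars)]
  }
  list(edge = tr$edge, edge_length = tr$edge.length,
       ntip = ntip, nnode = tr$Nnode, ncol = n,
       root = tr$edge[nrow(tr$edge), 1], partials = partials)
}

# Column-wise log-likelihood at rate `lambda` (scalar, or one rate per
# column). Returns a vector of length ncol; -Inf where a column cannot be
# explained (e.g. a variable column at lambda = 0).
pruning_loglik <- function(tp, model, lambda) {
  k <- length(model$states)
  n <- tp$ncol
  scalar <- length(lambda) == 1L
  if (!scalar && length(lambda) != n)
    stop("lambda must be scalar or one value per column", call. = FALSE)
  if (scalar) {
    Pcache <- lapply(tp$edge_length, function(len) {
      if (lambda * len == 0) return(diag(k))   # exact identity, no roundoff
      P <- model$A %*% (exp(model$evals * (lambda * len)) * model$B)
      P[P < 0] <- 0
      P
    })
  }
  L <- vector("list", tp$ntip + tp$nnode)
  for (i in seq_len(tp$ntip)) L[[i]] <- tp$partials[, , i, drop = TRUE]
  if (n == 1L) for (i in seq_len(tp$ntip)) L[[i]] <- matrix(L[[i]], nrow = k)
  logscale <- numeric(n)
  for (e in seq_len(nrow(tp$edge))) {
    child <- tp$edge[e, 2]
    parent <- tp$edge[e, 1]
    Lc <- L[[child]]
    if (scalar) {
      cond <- Pcache[[e]] %*% Lc
    } else {
      t_ <- lambda * tp$edge_length[e]
      E <- exp(outer(model$evals, t_))
      cond <- model$A %*% (E * (model$B %*% Lc))
      cond[cond < 0] <- 0
      zero_t <- t_ == 0
      if (any(zero_t)) cond[, zero_t] <- Lc[, zero_t]
    }
    cs <- .colSums(cond, k, n)
    zero <- cs == 0
    cs[zero] <- 1
    cond <- cond / rep(cs, each = k)
    logscale <- logscale + log(cs)   # log(1)=0 for zeroed columns; they end at -Inf
    L[[parent]] <- if (is.null(L[[parent]])) cond else L[[parent]] * cond
  }
  lik <- .colSums(model$freqs * L[[tp$root]], k, n)
  log(lik) + logscale
}

#' Log-likelihood of one alignment column on a tree
#'
#' Computes the pruning (Felsenstein) log-likelihood of a single site pattern
#' on a fixed ultrametric tree under a reversible substitution model, with all
#' branch lengths multiplied by the site rate `lambda`. Ambiguity codes are
#' expanded to state sets; missing states (`-`, `?`, `N`/`X`) contribute a
#' vector of ones.
#'
#' @param column named character vector of observed states, names matching the
#'   tree's tip labels.
#' @param tree a rooted tree with branch lengths ([ape::phylo]).
#' @param model a [substitution_model()]; defaults to JC69 / POISSON20 chosen
#'   from the observed states.
#' @param lambda non-negative site rate (substitutions per site per unit tree
#'   time). Vectorised: one log-likelihood is returned per rate.
#' @return numeric vector of log-likelihoods, `-Inf` when a variable column is
#'   evaluated at `lambda = 0`.
#' @examples
#' tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
#' site_loglik(c(A = "A", B = "A"), tr, lambda = 1)
#' @export
site_loglik <- function(column, tree, model = NULL, lambda) {
  stopifnot(inherits(tree, "phylo"), all(lambda >= 0))
  if (is.null(names(column)))
    stop("`column` must be named by taxon", call. = FALSE)
  alphabet <- if (is.null(model)) NULL
              else if (length(model$states) == 20) "PROTEIN" else "DNA"
  aln <- alignment(stats::setNames(as.character(column), names(column)),
                   locus = "site", alphabet = alphabet)
  if (is.null(model)) model <- default_model(aln$alphabet)
  rec <- reconcile(aln, tree)
  tp <- tip_partials(rec$alignment, rec$tree, model)
  vapply(lambda, function(l) pruning_loglik(tp, model, l), numeric(1))
}
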