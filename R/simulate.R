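#' Random ultrametric tree
#'
#' Simulates a pure-birth (Yule) topology and rescales node heights so the
#' root-to-tip distance equals `depth` exactly. Reproducible from `seed`
#' (R's Mersenne-Twister generator with inversion sampling).
#'
#' @param n_tips number of tips (>= 2).
#' @param depth root-to-tip distance of the returned chronogram.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @return a validated ultrametric [ape::phylo] with a `depth` attribute.
#' @export
sim_ultrametric_tree <- function(n_tips, depth = 1, seed = NULL) {
  stopifnot(n_tips >= 2, depth > 0)
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister",
                               normal.kind = "Inversion")
  tr <- phytools::pbtree(n = n_tips, scale = depth, quiet = TRUE)
  validate_tree(tr)
}

#' Simulate an alignment with known per-site rates
#'
#' Evolves `n_sites` independent sites down an ultrametric tree under a
#' reversible substitution model: the root state of each site is drawn from
#' the model's stationary frequencies and each branch applies the transition
#' matrix \eqn{\exp(Q \lambda_i \ell)} for the site's rate \eqn{\lambda_i}.
#' Site rates come from a constant, gamma, or user-supplied rate model, and
#' the generating rates are returned so estimator recovery can be scored
#' against the truth.
#'
#' @param tree ultrametric tree over which to simulate.
#' @param n_sites number of alignment columns.
#' @param rates site-rate model: a single number (constant rate), a numeric
#'   vector of length `n_sites` (explicit rates), or
#'   `list(shape =, mean =)` for gamma-distributed rates.
#' @param model a [substitution_model()] (default JC69).
#' @param seed integer seed for reproducibility; `NULL` leaves the RNG state
#'   untouched.
#' @param locus locus label for the returned alignment.
#' @return `list(alignment = pi_alignment, true_rates = pi_rates)`, the
#'   latter carrying the generating rate of every site (`status = "TRUE"`
#'   rows are not produced — simulated truth is always `OK`).
#' @examples
#' tr <- sim_ultrametric_tree(8, depth = 1, seed = 1)
#' sim <- simulate_locus(tr, 20, rates = 0.5, seed = 2)
#' sim$alignment
#' @export
simulate_locus <- function(tree, n_sites, rates = 1, model = NULL, seed = NULL,
                           locus = "sim") {
  stopifnot(inherits(tree, "phylo"), n_sites >= 1)
  if (is.null(model)) model <- substitution_model("JC69")
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister",
                               normal.kind = "Inversion")
  lam <- draw_site_rates(rates, n_sites)
  k <- length(model$states)
  tr <- stats::reorder(tree, "postorder")
  nedge <- nrow(tr$edge)
  ntot <- ape::Ntip(tr) + tr$Nnode
  root <- tr$edge[nedge, 1]
  states <- matrix(NA_integer_, ntot, n_sites)
  states[root, ] <- sample.int(k, n_sites, replace = TRUE, prob = model$freqs)
  for (e in rev(seq_len(nedge))) {   # preorder: parents before children
    parent <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    states[child, ] <- evolve_branch(states[parent, ], lam * tr$edge.length[e],
                                     model)
  }
  tipmat <- matrix(model$states[states[seq_len(ape::Ntip(tr)), ]],
                   nrow = ape::Ntip(tr))
  rownames(tipmat) <- tr$tip.label
  aln <- validate_alignment(tipmat, locus,
                            if (k == 20) "PROTEIN" else "DNA", NULL)
  true_rates <- tibble::tibble(locus = locus, site = seq_len(n_sites),
                               rate = lam, status = "OK", loglik = NA_real_,
                               model = model$name)
  attr(true_rates, "depth") <- tree_depth(tree)
  class(true_rates) <- c("pi_rates", class(true_rates))
  list(alignment = aln, true_rates = true_rates)
}

draw_site_rates <- function(rates, n_sites) {
  if (is.list(rates)) {
    stopifnot(!is.null(rates$shape), rates$shape > 0)
    mean_ <- if (is.null(rates$mean)) 1 else rates$mean
    stopifnot(mean_ > 0)
    stats::rgamma(n_sites, shape = rates$shape,
                  scale = mean_ / rates$shape)
  } else if (length(rates) == 1) {
    rep(as.numeric(rates), n_sites)
  } else {
    if (length(rates) != n_sites)
      stop("explicit rate vector must have length n_sites", call. = FALSE)
    as.numeric(rates)
  }
}

# Per-site transition sampling: sites are grouped by parent state, then the
# transition probabilities P[s, ] at each site's own elapsed time come from
# the spectral form in one vectorised block per state.
evolve_branch <- function(parent_states, times, model) {
  k <- length(model$states)
  out <- integer(length(parent_states))
  E <- exp(outer(model$evals, times))      # k x n
  u <- stats::runif(length(parent_states))
  for (s in seq_len(k)) {
    idx <- which(parent_states == s)
    if (!length(idx)) next
    probs <- crossprod(model$B, model$A[s, ] * E[, idx, drop = FALSE])  # k x n_idx
    probs[probs < 0] <- 0
    cum <- apply(probs, 2, cumsum)
    cum <- cum / rep(cum[k, ], each = k)
    out[idx] <- max.col(t(cum >= rep(u[idx], each = k)), ties.method = "first")
  }
  out
}

#' Rate-recovery experiment
#'
#' Simulates a locus with known per-site rates, re-estimates the rates with
#' [estimate_rates()], and scores the recovery: mean bias, median relative
#' error over sites with positive true rate, and the Spearman rank
#' correlation between true and estimated rates.
#'
#' @inheritParams simulate_locus
#' @param model_est model used for estimation (defaults to the generating
#'   model).
#' @param lambda_max passed to [estimate_rates()].
#' @return a one-row tibble: `n_sites`, `n_estimated`, `n_faulty`, `bias`,
#'   `median_rel_error`, `rank_correlation` (NA when fewer than two distinct
#'   true rates or no estimable sites), plus the full per-site comparison as
#'   attribute `sites`.
#' @export
recovery_experiment <- function(tree, n_sites, rates, model = NULL,
                                seed = NULL, model_est = NULL,
                                lambda_max = NULL) {
  sim <- simulate_locus(tree, n_sites, rates = rates, model = model, seed = seed)
  est <- estimate_rates(sim$alignment, tree,
                        model = if (is.null(model_est)) model else model_est,
                        lambda_max = lambda_max)
  cmp <- tibble::tibble(site = sim$true_rates$site,
                        true = sim$true_rates$rate,
                        estimated = est$rate,
                        status = est$status)
  ok <- !is.na(cmp$estimated)
  pos <- ok & cmp$true > 0
  res <- tibble::tibble(
    n_sites = n_sites,
    n_estimated = sum(ok),
    n_faulty = sum(!ok),
    bias = if (any(ok)) mean(cmp$estimated[ok] - cmp$true[ok]) else NA_real_,
    median_rel_error = if (any(pos))
      stats::median(abs(cmp$estimated[pos] - cmp$true[pos]) / cmp$true[pos])
      else NA_real_,
    rank_correlation = if (length(unique(cmp$true[ok])) >= 2)
      suppressWarnings(stats::cor(cmp$true[ok], cmp$estimated[ok],
                                  method = "spearman"))
      else NA_real_
  )
  attr(res, "sites") <- cmp
  res
}

#' Write a simulation fixture triplet
#'
#' Writes the alignment (FASTA), tree (Newick) and generating rates (rate
#' TSV) of one simulation to `dir`, as benchmark inputs for the pipeline.
#'
#' @param sim result of [simulate_locus()].
#' @param tree the tree the locus was simulated on.
#' @param dir output directory (created if needed).
#' @param stem file stem (default the locus name).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(sim, tree, dir, stem = NULL) {
  if (is.null(stem)) stem <- sim$alignment$locus
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(alignment = file.path(dir, paste0(stem, ".fasta")),
             tree = file.path(dir, paste0(stem, ".nwk")),
             rates = file.path(dir, paste0(stem, ".rates.tsv")))
  fasta <- as.vector(rbind(paste0(">", sim$alignment$taxa),
                           apply(sim$alignment$seq, 1, paste, collapse = "")))
  write_lf(fasta, paths["alignment"])
  write_lf(ape::write.tree(tree), paths["tree"])
  write_rate_table(sim$true_rates, paths["rates"])
  invisible(paths)
}
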