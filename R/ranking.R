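#' Rank loci by integrated informativeness over an epoch
#'
#' Integrates each locus's informativeness exactly (closed form per rated
#' site, summed; see [epoch_integral()]) over an epoch of interest and ranks
#' loci by the integral. Integration values are largest for loci with the
#' highest probability of substitution in the epoch that is not obscured by
#' subsequent evolution. Ranking uses competition ranks ("1, 1, 3"); exact
#' ties are flagged and ordered by locus label.
#'
#' @param rates a `pi_rates` tibble.
#' @param epoch numeric pair `c(t_start, t_end)`, `0 <= t_start < t_end <=`
#'   tree depth, times measured from the present toward the root.
#' @param basis ranking basis: `"per_site"` (default; informativeness per
#'   rated site, the cost-effectiveness comparison) or `"net"`.
#' @param depth tree depth; defaults to the rate table's `depth` attribute.
#' @return a tibble of class `pi_ranking`, sorted by descending integral on
#'   the chosen basis: `rank`, `locus`, `t_start`, `t_end`, `integral_net`,
#'   `integral_persite`, `tie`.
#' @examples
#' rates <- tibble::tibble(
#'   locus = rep(c("fast", "slow"), each = 2), site = rep(1:2, 2),
#'   rate = rep(c(2, 0.1), each = 2), status = "OK",
#'   loglik = NA_real_, model = "JC69")
#' rank_loci(rates, epoch = c(2, 3), depth = 3)   # deep epoch: slow wins
#' @export
rank_loci <- function(rates, epoch, basis = c("per_site", "net"), depth = NULL) {
  basis <- match.arg(basis)
  rates <- as_rates(rates)
  if (is.null(depth)) depth <- attr(rates, "depth")
  if (is.null(depth)) depth <- Inf
  epoch <- check_epoch(epoch, depth)
  tab <- tidy_integrals(rates, epoch)
  key <- if (basis == "per_site") tab$integral_persite else tab$integral_net
  ord <- order(-key, tab$locus)
  tab <- tab[ord, ]
  key <- key[ord]
  tab$rank <- as.integer(rank(-key, ties.method = "min"))
  tab$tie <- duplicated(key) | duplicated(key, fromLast = TRUE)
  out <- tab[, c("rank", "locus", "t_start", "t_end",
                 "integral_net", "integral_persite", "tie")]
  attr(out, "basis") <- basis
  attr(out, "depth") <- depth
  class(out) <- c("pi_ranking", class(out))
  out
}

tidy_integrals <- function(rates, epoch) {
  loci <- unique(rates$locus)
  purrr::map_dfr(loci, function(lc) {
    lam <- rates$rate[rates$locus == lc]
    lam <- lam[!is.na(lam)]
    net <- if (length(lam)) sum(epoch_integral(lam, epoch[1], epoch[2])) else 0
    tibble::tibble(locus = lc, t_start = epoch[1], t_end = epoch[2],
                   integral_net = net,
                   integral_persite = if (length(lam)) net / length(lam) else 0)
  })
}

#' Rankings over multiple epochs
#'
#' Computes an independent [rank_loci()] ranking for each epoch (epochs may
#' overlap), plus a combined wide table of per-epoch integrals.
#'
#' @param rates a `pi_rates` tibble.
#' @param epochs a list of epochs, each `c(t_start, t_end)`.
#' @inheritParams rank_loci
#' @return a list with elements `rankings` (list of `pi_ranking`, one per
#'   epoch, named `"t1-t2"`) and `combined` (wide tibble: one row per locus,
#'   one integral column per epoch on the chosen basis).
#' @export
multi_epoch_ranking <- function(rates, epochs, basis = c("per_site", "net"),
                                depth = NULL) {
  basis <- match.arg(basis)
  if (!length(epochs)) stop("at least one epoch is required", call. = FALSE)
  if (!is.list(epochs)) epochs <- list(epochs)
  rankings <- purrr::map(epochs, function(ep)
    rank_loci(rates, ep, basis = basis, depth = depth))
  names(rankings) <- vapply(epochs, function(ep)
    sprintf("%g-%g", ep[1], ep[2]), character(1))
  col <- if (basis == "per_site") "integral_persite" else "integral_net"
  combined <- purrr::imap(rankings, function(r, nm) {
    tibble::tibble(locus = r$locus, value = r[[col]]) |>
      dplyr::rename(!!paste0("integral_", nm) := "value")
  }) |>
    purrr::reduce(dplyr::left_join, by = "locus")
  list(rankings = rankings, combined = combined)
}

#' Profile loci from alignments or precomputed rates
#'
#' One-call orchestration of the pipeline: reconciles each locus with the
#' tree, estimates per-site rates where alignments are given (precomputed
#' `pi_rates` pass through untouched — the direct-rates path), optionally
#' expands NEXUS partitions into pseudo-loci, and evaluates net and per-site
#' informativeness profiles on a shared grid.
#'
#' @param x a `pi_alignment`, a list of them, or a `pi_rates` tibble.
#' @param tree a validated ultrametric tree; required when `x` holds
#'   alignments, optional (depth source) for precomputed rates.
#' @param model,lambda_max passed to [estimate_rates()].
#' @param partitions_as_loci if `TRUE` (default), named partitions of a
#'   partitioned alignment are profiled as separate pseudo-loci.
#' @inheritParams pi_profile
#' @return a `pi_profile` tibble (see [pi_profile()]); the rate table used is
#'   attached as attribute `rates`.
#' @export
profile_loci <- function(x, tree = NULL, model = NULL, lambda_max = NULL,
                         partitions_as_loci = TRUE, grid = NULL, n_grid = 1000,
                         per_site_denominator = c("n_rates", "length")) {
  if (is.data.frame(x)) {
    rates <- as_rates(x)
    depth <- attr(x, "depth")
    if (is.null(depth) && !is.null(tree)) depth <- tree_depth(tree)
    if (is.null(depth)) stop("supply `tree` (or a depth attribute on the rates)",
                             call. = FALSE)
  } else {
    if (is.null(tree)) stop("`tree` is required to estimate rates", call. = FALSE)
    if (inherits(x, "pi_alignment")) x <- list(x)
    if (partitions_as_loci)
      x <- purrr::flatten(purrr::map(x, split_partitions))
    rates <- estimate_rates(x, tree, model = model, lambda_max = lambda_max)
    depth <- attr(rates, "depth")
  }
  prof <- pi_profile(rates, depth = depth, grid = grid, n_grid = n_grid,
                     per_site_denominator = per_site_denominator)
  attr(prof, "rates") <- rates
  prof
}
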