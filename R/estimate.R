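#' Estimate per-site substitution rates on a fixed ultrametric tree
#'
#' For every alignment column, finds the maximum-likelihood site rate
#' \eqn{\hat\lambda} on the fixed tree by bracketed scalar optimisation of the
#' pruning log-likelihood over \eqn{[0, \lambda_{max}]}. Invariant columns
#' (all non-missing states identical) are assigned rate 0 without
#' optimisation (`INVARIANT_ZERO`); columns with fewer than two non-missing
#' states are `FAULTY` and carry a missing rate; maxima at the upper bound
#' are clamped and flagged `CLAMPED_MAX`. Identical columns are computed once
#' and cached — results are identical with caching on or off.
#'
#' @param x a `pi_alignment`, or a (optionally named) list of them for
#'   multi-locus estimation.
#' @param tree a validated ultrametric tree ([read_tree()]); taxa are
#'   reconciled per locus (tree-only taxa pruned, alignment-only taxa error).
#' @param model a [substitution_model()]; default JC69 for DNA, POISSON20 for
#'   protein.
#' @param lambda_max upper bound of the rate search, in substitutions per
#'   site per unit tree time. Default `20 / depth`: twenty expected
#'   substitutions over the tree height, beyond saturation.
#' @param rel_tol relative convergence tolerance of the optimiser (default
#'   `1e-6`).
#' @param cache reuse results across identical columns (default `TRUE`).
#' @return a tibble of class `pi_rates` with one row per site: `locus`,
#'   `site` (1-based), `rate` (`NA` for faulty sites), `status` (`OK`,
#'   `INVARIANT_ZERO`, `CLAMPED_MAX`, `FAULTY`), `loglik`, `model`. The tree
#'   depth is attached as attribute `depth`. Use [glance()] for the per-locus
#'   summary table.
#' @examples
#' tr <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
#' aln <- alignment(c(A = "AAGA", B = "AAGA", C = "ACGA", D = "ACGA"))
#' estimate_rates(aln, tr)
#' @export
estimate_rates <- function(x, tree, model = NULL, lambda_max = NULL,
                           rel_tol = 1e-6, cache = TRUE) {
  if (inherits(x, "pi_alignment")) x <- list(x)
  stopifnot(length(x) >= 1, all(vapply(x, inherits, logical(1), "pi_alignment")))
  depth <- tree_depth(tree)
  out <- purrr::map(x, function(aln)
    estimate_locus(aln, tree, model, lambda_max, rel_tol, cache))
  res <- dplyr::bind_rows(out)
  attr(res, "depth") <- depth
  class(res) <- c("pi_rates", class(res))
  res
}

estimate_locus <- function(aln, tree, model, lambda_max, rel_tol, cache) {
  if (ncol(aln$seq) < 1) stop("empty alignment", call. = FALSE)
  rec <- reconcile(aln, tree)
  if (is.null(model)) model <- default_model(aln$alphabet)
  if (!identical(length(model$states) == 20, aln$alphabet == "PROTEIN"))
    stop(sprintf("model %s does not match alphabet %s", model$name, aln$alphabet),
         call. = FALSE)
  depth <- tree_depth(rec$tree)
  if (is.null(lambda_max)) lambda_max <- 20 / depth
  stopifnot(lambda_max > 0)

  seqm <- rec$alignment$seq
  n <- ncol(seqm)
  keys <- apply(seqm, 2, paste, collapse = "")
  if (cache) {
    ukeys <- unique(keys)
    umap <- match(keys, ukeys)
    ucols <- match(ukeys, keys)
  } else {
    umap <- seq_len(n)
    ucols <- seq_len(n)
  }
  sub <- rec$alignment
  sub$seq <- seqm[, ucols, drop = FALSE]
  fit <- optimise_columns(sub, rec$tree, model, lambda_max, rel_tol)
  tibble::tibble(
    locus = aln$locus,
    site = seq_len(n),
    rate = fit$rate[umap],
    status = fit$status[umap],
    loglik = fit$loglik[umap],
    model = model$name
  )
}

# ML rate per column: coarse quadratic grid to bracket the optimum, then a
# vectorised golden-section refinement in which every still-active column is
# evaluated at its own rate in a single pruning pass.
optimise_columns <- function(aln, tree, model, lambda_max, rel_tol) {
  miss <- missing_codes(aln$alphabet)
  tp <- tip_partials(aln, tree, model)
  n <- tp$ncol
  rate <- rep(NA_real_, n)
  status <- rep("FAULTY", n)
  loglik <- rep(NA_real_, n)

  obs_counts <- apply(aln$seq, 2, function(col) sum(!col %in% miss))
  invariant <- apply(aln$seq, 2, function(col) {
    obs <- col[!col %in% miss]
    length(obs) >= 2 && length(unique(obs)) == 1
  })
  estimable <- obs_counts >= 2

  inv <- which(invariant & estimable)
  if (length(inv)) {
    rate[inv] <- 0
    status[inv] <- "INVARIANT_ZERO"
    tpi <- subset_tp(tp, inv)
    loglik[inv] <- pruning_loglik(tpi, model, 0)
  }
  act <- which(estimable & !invariant)
  if (length(act)) {
    tpa <- subset_tp(tp, act)
    ngrid <- 32L
    grid <- lambda_max * (0:ngrid / ngrid)^2
    ll <- vapply(grid, function(l) pruning_loglik(tpa, model, l),
                 numeric(length(act)))
    ll <- matrix(ll, nrow = length(act))
    kbest <- apply(ll, 1, function(r) {
      if (all(!is.finite(r))) NA_integer_ else which.max(r)
    })
    bad <- is.na(kbest)
    okc <- which(!bad)
    if (length(okc)) {
      lo <- grid[pmax(kbest[okc] - 1L, 1L)]
      hi <- grid[pmin(kbest[okc] + 1L, ngrid + 1L)]
      gs <- golden_section(subset_tp(tpa, okc), model, lo, hi,
                           tol = rel_tol * lambda_max)
      lhat <- gs$x
      lhat_ll <- gs$f
      # boundary clamp: optimum indistinguishable from the box edge
      at_max <- (lambda_max - lhat) <= 1e-3 * lambda_max
      if (any(at_max)) {
        tpm <- subset_tp(subset_tp(tpa, okc), which(at_max))
        ll_max <- pruning_loglik(tpm, model, lambda_max)
        clamp <- at_max
        clamp[at_max] <- ll_max >= lhat_ll[at_max] - 1e-6
        lhat[clamp] <- lambda_max
        lhat_ll[clamp] <- ll_max[clamp[at_max]]
        status[act[okc][clamp]] <- "CLAMPED_MAX"
      }
      status[act[okc]][!is.finite(lhat_ll)] <- "FAULTY"
      keep <- is.finite(lhat_ll)
      ii <- act[okc]
      rate[ii[keep]] <- lhat[keep]
      loglik[ii[keep]] <- lhat_ll[keep]
      st <- status[ii]
      st[keep & st == "FAULTY"] <- "OK"
      status[ii] <- st
    }
  }
  list(rate = rate, status = status, loglik = loglik)
}

subset_tp <- function(tp, cols) {
  tp$partials <- tp$partials[, cols, , drop = FALSE]
  tp$ncol <- length(cols)
  tp
}

golden_section <- function(tp, model, lo, hi, tol, max_iter = 200L) {
  phi <- (sqrt(5) - 1) / 2
  x1 <- hi - phi * (hi - lo)
  x2 <- lo + phi * (hi - lo)
  f1 <- pruning_loglik(tp, model, x1)
  f2 <- pruning_loglik(tp, model, x2)
  for (iter in seq_len(max_iter)) {
    if (max(hi - lo) <= tol) break
    left <- f1 >= f2   # maximum in [lo, x2]
    hi[left] <- x2[left]
    x2[left] <- x1[left]
    f2[left] <- f1[left]
    x1[left] <- hi[left] - phi * (hi[left] - lo[left])
    lo[!left] <- x1[!left]
    x1[!left] <- x2[!left]
    f1[!left] <- f2[!left]
    x2[!left] <- lo[!left] + phi * (hi[!left] - lo[!left])
    xnew <- ifelse(left, x1, x2)
    fnew <- pruning_loglik(tp, model, xnew)
    f1[left] <- fnew[left]
    f2[!left] <- fnew[!left]
  }
  x <- (lo + hi) / 2
  list(x = x, f = pruning_loglik(tp, model, x))
}

#' Estimate the ML rate of a single column
#'
#' Column-level counterpart of [estimate_rates()], mirroring its status
#' taxonomy.
#'
#' @inheritParams site_loglik
#' @inheritParams estimate_rates
#' @return a one-row tibble: `site`, `rate`, `status`, `loglik`.
#' @export
estimate_site_rate <- function(column, tree, model = NULL, lambda_max = NULL,
                               rel_tol = 1e-6) {
  aln <- alignment(stats::setNames(as.character(column), names(column)),
                   locus = "site")
  res <- estimate_rates(aln, validate_tree(tree), model = model,
                        lambda_max = lambda_max, rel_tol = rel_tol)
  tibble::as_tibble(res)[, c("site", "rate", "status", "loglik")]
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a per-site rate table
#'
#' Strips the `pi_rates` class and attributes, returning the plain per-site
#' tibble.
#'
#' @param x a `pi_rates` tibble.
#' @param ... unused.
#' @return a tibble with one row per site.
#' @method tidy pi_rates
#' @export
tidy.pi_rates <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("locus", "site", "rate", "status", "loglik", "model")])
}

#' Per-locus summary of a rate estimation
#'
#' One row per locus: the model used, locus length, the number of sites for
#' which a substitution rate could be calculated, and the number of faulty
#' sites.
#'
#' @param x a `pi_rates` tibble from [estimate_rates()].
#' @param ... unused.
#' @return a tibble with columns `locus`, `model`, `length`, `n_rates`,
#'   `n_faulty`.
#' @method glance pi_rates
#' @export
glance.pi_rates <- function(x, ...) {
  tidy(x) |>
    dplyr::group_by(.data$locus, .data$model) |>
    dplyr::summarise(
      length = dplyr::n(),
      n_rates = sum(.data$status != "FAULTY"),
      n_faulty = sum(.data$status == "FAULTY"),
      .groups = "drop"
    ) |>
    dplyr::select("locus", "model", "length", "n_rates", "n_faulty")
}
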