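#' Substitution models for site-rate estimation
#'
#' Builds a time-reversible substitution model whose generator matrix Q is
#' scaled so that one unit of time at rate 1 produces one expected
#' substitution per site (\eqn{-\sum_i \pi_i Q_{ii} = 1}). DNA models operate
#' on the four nucleotides; `POISSON20` is the equal-rates, uniform-frequency
#' 20-state amino-acid model.
#'
#' @param name one of `"JC69"`, `"K80"`, `"HKY85"`, `"GTR"`, `"POISSON20"`.
#' @param frequencies stationary base/residue frequencies. Ignored for JC69 and
#'   POISSON20 (uniform by definition); defaults to uniform otherwise. Must be
#'   positive and is renormalised to sum to 1.
#' @param kappa transition/transversion rate ratio for K80 and HKY85.
#' @param exchangeabilities for GTR, the six symmetric exchangeability
#'   parameters in the order AC, AG, AT, CG, CT, GT.
#' @return an object of class `pi_model`: the state set, stationary
#'   frequencies, normalised generator `Q`, and its spectral decomposition used
#'   to compute transition probabilities.
#' @examples
#' m <- substitution_model("JC69")
#' rowSums(m$Q)                       # zero by construction
#' substitution_model("HKY85", frequencies = c(0.3, 0.2, 0.2, 0.3), kappa = 4)
#' @export
substitution_model <- function(name = c("JC69", "K80", "HKY85", "GTR", "POISSON20"),
                               frequencies = NULL, kappa = 2,
                               exchangeabilities = rep(1, 6)) {
  name <- toupper(name[1])
  name <- match.arg(name, c("JC69", "K80", "HKY85", "GTR", "POISSON20"))
  if (name == "POISSON20") {
    states <- AA_STATES
    freqs <- rep(1 / 20, 20)
    rmat <- matrix(1, 20, 20)
  } else {
    states <- DNA_STATES
    freqs <- switch(name,
      JC69 = rep(0.25, 4),
      {
        f <- if (is.null(frequencies)) rep(0.25, 4) else frequencies
        if (length(f) != 4 || any(f <= 0))
          stop("`frequencies` must be 4 positive values (A, C, G, T)", call. = FALSE)
        f / sum(f)
      }
    )
    if (name == "K80") freqs <- rep(0.25, 4)
    # symmetric exchangeabilities, order AC AG AT CG CT GT
    ex <- switch(name,
      JC69 = rep(1, 6),
      K80 = c(1, kappa, 1, 1, kappa, 1),
      HKY85 = c(1, kappa, 1, 1, kappa, 1),
      GTR = {
        if (length(exchangeabilities) != 6 || any(exchangeabilities < 0))
          stop("GTR needs 6 non-negative exchangeabilities (AC, AG, AT, CG, CT, GT)",
               call. = FALSE)
        exchangeabilities
      }
    )
    rmat <- matrix(0, 4, 4)
    rmat[2, 1] <- rmat[1, 2] <- ex[1]
    rmat[3, 1] <- rmat[1, 3] <- ex[2]
    rmat[4, 1] <- rmat[1, 4] <- ex[3]
    rmat[3, 2] <- rmat[2, 3] <- ex[4]
    rmat[4, 2] <- rmat[2, 4] <- ex[5]
    rmat[4, 3] <- rmat[3, 4] <- ex[6]
  }
  model <- build_model(name, states, freqs, rmat)
  model
}

# Assemble Q = R diag(pi), zero the diagonal to rows summing to 0, normalise to
# one expected substitution per unit time, and precompute the spectral form
# P(t) = A exp(D t) B via the symmetrised generator (valid for reversible Q).
build_model <- function(name, states, freqs, rmat) {
  k <- length(states)
  diag(rmat) <- 0
  Q <- rmat %*% diag(freqs)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  if (mu <= 0) stop("degenerate model: zero total substitution rate", call. = FALSE)
  Q <- Q / mu
  dimnames(Q) <- list(states, states)
  sp <- sqrt(freqs)
  S <- diag(sp) %*% Q %*% diag(1 / sp)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  structure(list(
    name = name,
    states = states,
    freqs = freqs,
    Q = Q,
    evals = es$values,
    A = diag(1 / sp) %*% es$vectors,    # P(t) = A diag(exp(evals * t)) B
    B = t(es$vectors) %*% diag(sp)
  ), class = "pi_model")
}

#' @export
print.pi_model <- function(x, ...) {
  cat(sprintf("<pi_model %s: %d states, rate-normalised reversible Q>\n",
              x$name, length(x$states)))
  invisible(x)
}

#' Transition probability matrix
#'
#' Computes \eqn{P(t) = e^{Qt}} for a reversible model from its precomputed
#' spectral decomposition.
#'
#' @param model a [substitution_model()].
#' @param t elapsed time (rate times branch length), a single non-negative
#'   number.
#' @return a stochastic matrix of transition probabilities between states.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "pi_model"), length(t) == 1, t >= 0)
  P <- model$A %*% (exp(model$evals * t) * model$B)
  dimnames(P) <- list(model$states, model$states)
  P
}

#' Default model for an alignment alphabet
#'
#' JC69 for DNA, the 20-state Poisson model for protein: the simplest
#' reversible, assumption-light choices. Richer models (K80, HKY85, GTR) are
#' opt-in via [substitution_model()] or [fit_model()].
#'
#' @param alphabet `"DNA"` or `"PROTEIN"`.
#' @return a `pi_model`.
#' @export
default_model <- function(alphabet) {
  substitution_model(if (identical(alphabet, "PROTEIN")) "POISSON20" else "JC69")
}

#' Fit global model parameters on an alignment
#'
#' Fits the free parameters of K80, HKY85 or GTR once, globally, by maximising
#' the sum of site log-likelihoods over all variable columns at a shared rate
#' of 1 on the fixed tree. Base frequencies are taken as the empirical counts.
#' The fitted model is then used for per-site rate estimation.
#'
#' @param alignment a [read_alignment()] object.
#' @param tree an ultrametric tree from [read_tree()].
#' @param name `"K80"`, `"HKY85"` or `"GTR"`.
#' @return a fitted `pi_model` with an added `loglik` attribute.
#' @export
fit_model <- function(alignment, tree, name = c("HKY85", "K80", "GTR")) {
  name <- match.arg(name)
  stopifnot(inherits(alignment, "pi_alignment"))
  if (alignment$alphabet != "DNA")
    stop("parametric model fitting is implemented for DNA alignments", call. = FALSE)
  rec <- reconcile(alignment, tree)
  freqs <- empirical_frequencies(rec$alignment)
  cols <- variable_columns(rec$alignment)
  if (!length(cols)) stop("no variable columns to fit a model on", call. = FALSE)
  tp <- subset_tp(tip_partials(rec$alignment, rec$tree, substitution_model("JC69")),
                  cols)
  objective <- function(par) {
    model <- switch(name,
      K80 = substitution_model("K80", kappa = exp(par[1])),
      HKY85 = substitution_model("HKY85", frequencies = freqs, kappa = exp(par[1])),
      GTR = substitution_model("GTR", frequencies = freqs,
                               exchangeabilities = c(exp(par), 1))
    )
    -sum(pruning_loglik(tp, model, 1))
  }
  npar <- if (name == "GTR") 5 else 1
  fit <- stats::optim(rep(0, npar), objective,
                      method = if (npar == 1) "Brent" else "Nelder-Mead",
                      lower = if (npar == 1) -5 else -Inf,
                      upper = if (npar == 1) 7 else Inf)
  model <- switch(name,
    K80 = substitution_model("K80", kappa = exp(fit$par[1])),
    HKY85 = substitution_model("HKY85", frequencies = freqs, kappa = exp(fit$par[1])),
    GTR = substitution_model("GTR", frequencies = freqs,
                             exchangeabilities = c(exp(fit$par), 1))
  )
  attr(model, "loglik") <- -fit$value
  model
}

empirical_frequencies <- function(alignment) {
  chars <- toupper(alignment$seq)
  counts <- vapply(DNA_STATES, function(s) sum(chars == s), numeric(1))
  counts[counts == 0] <- 1  # pseudo-count keeps frequencies positive
  counts / sum(counts)
}

variable_columns <- function(alignment) {
  which(apply(alignment$seq, 2, function(col) {
    obs <- col[!col %in% MISSING_DNA]
    length(unique(obs)) > 1
  }))
}

MISSING_DNA <- c("-", "?", "N", "X")
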