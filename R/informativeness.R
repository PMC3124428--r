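#' Phylogenetic informativeness of a site
#'
#' The informativeness density of a site evolving at rate \eqn{\lambda},
#' evaluated at historical time \eqn{t} (measured from the present at the
#' tips toward the root):
#' \deqn{\rho(t; \lambda) = 16 \lambda^2 t e^{-4 \lambda t}.}
#' It predicts the site's power to resolve a divergence at time \eqn{t}:
#' zero at the present, rising to a maximum at \eqn{t = 1/(4\lambda)} of
#' height \eqn{4\lambda/e}, and decaying as subsequent substitutions obscure
#' the signal. Integrated over all time each site carries one unit of
#' informativeness.
#'
#' @param t historical time(s), non-negative, in tree-time units.
#' @param lambda site rate(s), non-negative, substitutions/site/unit time.
#'   `t` and `lambda` are recycled against each other.
#' @return numeric vector of informativeness densities.
#' @examples
#' informativeness(0.25, 1)      # the peak for lambda = 1: 4/e
#' informativeness(seq(0, 2, 0.5), lambda = 0.8)
#' @export
informativeness <- function(t, lambda) {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  if (any(lambda < 0)) stop("`lambda` must be non-negative", call. = FALSE)
  16 * lambda^2 * t * exp(-4 * lambda * t)
}

#' Closed-form epoch integral of informativeness
#'
#' Integrates \eqn{\rho(t;\lambda)} exactly over an epoch
#' \eqn{[t_1, t_2]}:
#' \deqn{\int_{t_1}^{t_2} \rho(t;\lambda)\,dt =
#'   (1 + 4\lambda t_1) e^{-4\lambda t_1} - (1 + 4\lambda t_2) e^{-4\lambda t_2}.}
#' For \eqn{\lambda = 0} the integral is 0; as \eqn{t_2 \to \infty} with
#' \eqn{t_1 = 0} it tends to 1.
#'
#' @param lambda site rate(s), non-negative (vectorised).
#' @param t_start,t_end epoch bounds, `0 <= t_start < t_end`.
#' @return the integral(s), in units of informativeness.
#' @examples
#' epoch_integral(1, 0, 0.25)    # 1 - 2/e
#' @export
epoch_integral <- function(lambda, t_start, t_end) {
  if (any(lambda < 0)) stop("`lambda` must be non-negative", call. = FALSE)
  if (any(t_start < 0) || any(t_end <= t_start))
    stop("epoch must satisfy 0 <= t_start < t_end", call. = FALSE)
  term <- function(t) (1 + 4 * lambda * t) * exp(-4 * lambda * t)
  ifelse(lambda == 0, 0, term(t_start) - term(t_end))
}

check_epoch <- function(epoch, depth) {
  if (length(epoch) != 2 || anyNA(epoch))
    stop("an epoch is a numeric pair c(t_start, t_end)", call. = FALSE)
  if (epoch[1] < 0 || epoch[2] <= epoch[1])
    stop("epoch must satisfy 0 <= t_start < t_end", call. = FALSE)
  if (epoch[2] > depth * (1 + 1e-9))
    stop(sprintf("epoch [%g, %g] outside the allowed range [0, %g] (tree depth)",
                 epoch[1], epoch[2], depth), call. = FALSE)
  epoch
}

#' Informativeness profiles over a time grid
#'
#' Evaluates, for each locus in a rate table, the net informativeness
#' \eqn{\sum_i \rho(t, \lambda_i)} over its rated (non-faulty) sites and the
#' per-site informativeness (net divided by the number of rated sites) on a
#' shared time grid from the present to the tree depth.
#'
#' @param rates a `pi_rates` tibble ([estimate_rates()] or
#'   [read_rate_table()]).
#' @param depth tree depth; taken from the rate table's `depth` attribute if
#'   absent.
#' @param grid time points (strictly increasing, within `[0, depth]`), or
#'   `NULL` to use `n_grid` evenly spaced points on `[0, depth]`.
#' @param n_grid grid resolution when `grid` is `NULL` (default 1000).
#' @param per_site_denominator `"n_rates"` divides net by the number of rated
#'   sites (default — faulty sites carry no signal estimate); `"length"`
#'   divides by the full locus length.
#' @return a tibble of class `pi_profile`, long format: `time`, `locus`,
#'   `net`, `per_site`; attributes `depth` and `n_rates` (named per-locus
#'   counts). An all-faulty locus yields a zero profile with a warning.
#' @examples
#' rates <- tibble::tibble(locus = "L1", site = 1:3, rate = c(0.5, 1, 2),
#'                         status = "OK", loglik = NA_real_, model = "JC69")
#' pi_profile(rates, depth = 2, n_grid = 5)
#' @export
pi_profile <- function(rates, depth = NULL, grid = NULL, n_grid = 1000,
                       per_site_denominator = c("n_rates", "length")) {
  per_site_denominator <- match.arg(per_site_denominator)
  rates <- as_rates(rates)
  if (is.null(depth)) depth <- attr(rates, "depth")
  if (is.null(depth)) stop("`depth` is required (no depth attribute on rates)",
                           call. = FALSE)
  if (is.null(grid)) grid <- seq(0, depth, length.out = n_grid)
  if (!length(grid)) stop("empty time grid", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing", call. = FALSE)
  if (grid[1] < 0 || grid[length(grid)] > depth * (1 + 1e-9))
    stop(sprintf("grid must lie within [0, %g]", depth), call. = FALSE)

  loci <- unique(rates$locus)
  curves <- purrr::map(loci, function(lc) {
    sub <- rates[rates$locus == lc, ]
    lam <- sub$rate[!is.na(sub$rate)]
    denom <- if (per_site_denominator == "n_rates") length(lam) else nrow(sub)
    if (!length(lam)) {
      warning(sprintf("locus '%s' has no rated sites; profile is zero", lc),
              call. = FALSE)
      net <- rep(0, length(grid))
    } else {
      net <- colSums(informativeness(rep(grid, each = length(lam)),
                                     rep(lam, times = length(grid))) |>
                       matrix(nrow = length(lam)))
    }
    tibble::tibble(time = grid, locus = lc, net = net,
                   per_site = if (denom > 0) net / denom else net * 0)
  })
  out <- dplyr::bind_rows(curves)
  attr(out, "depth") <- depth
  attr(out, "n_rates") <- stats::setNames(
    vapply(loci, function(lc) sum(!is.na(rates$rate[rates$locus == lc])),
           integer(1)), loci)
  class(out) <- c("pi_profile", class(out))
  out
}

# Accept a pi_rates tibble or any data frame with locus/site/rate columns.
as_rates <- function(rates) {
  if (!is.data.frame(rates) ||
      !all(c("locus", "site", "rate") %in% names(rates)))
    stop("`rates` must be a data frame with columns locus, site, rate",
         call. = FALSE)
  rates
}
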