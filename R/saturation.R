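# Prospective multinomial model of sequencing saturation for rare cell
# types: the probability that, after sequencing n cells, each of k rare
# types (sampling probability p_type) has been seen at least c times.

#' Required per-type cell count from the rarest type's size
#'
#' `c = ceiling(frac * n_rarest)`, the convention used to derive the
#' sufficient-sampling requirement (e.g. c = 81 from a rarest type of 101
#' cells at 80%).
#'
#' @param n_rarest cells in the rarest type.
#' @param frac required fraction (default 0.8).
#' @return integer c.
#' @export
required_cells_per_type <- function(n_rarest, frac = 0.8) {
  as.integer(ceiling(frac * n_rarest))
}

#' Saturation specification
#'
#' @param k number of rare types (>= 1).
#' @param p_type per-type sampling probability (0 < p_type <= 1/k).
#' @param c required cells per type (>= 1).
#' @return validated list of class `saturation_spec`.
#' @export
saturation_spec <- function(k, p_type, c) {
  stopifnot(k >= 1, p_type > 0, p_type <= 1 / k, c >= 1)
  structure(list(k = as.integer(k), p_type = p_type, c = as.integer(c)),
            class = "saturation_spec")
}

#' Probability that every rare type reaches c sampled cells
#'
#' Under the multinomial, the k rare-type counts are approximated as
#' independent Poisson(n * p_type) variables (excellent when k * p_type is
#' small); the success probability is `P(Poisson(n p) >= c)^k`. An exact
#' multinomial Monte-Carlo mode is available as a cross-check. For k = 1 the
#' binomial closed form is exact.
#'
#' @param n cells sequenced (>= 0); vectorized.
#' @param spec a `saturation_spec`.
#' @param method "auto" (default: exact binomial when k = 1, else the
#'   Poisson approximation), "poisson", "binomial" (k = 1 only), or
#'   "montecarlo".
#' @param n_rep Monte-Carlo replicates (default 10000).
#' @param seed Monte-Carlo seed.
#' @return probability (with a `se` attribute for Monte Carlo).
#' @export
success_probability <- function(n, spec, method = c("auto", "poisson",
                                                    "binomial", "montecarlo"),
                                n_rep = 10000, seed = 1) {
  method <- match.arg(method)
  if (method == "auto") method <- if (spec$k == 1) "binomial" else "poisson"
  stopifnot(all(n >= 0))
  if (method == "poisson") {
    return(stats::ppois(spec$c - 1, n * spec$p_type, lower.tail = FALSE)^spec$k)
  }
  if (method == "binomial") {
    stopifnot(spec$k == 1)
    return(stats::pbinom(spec$c - 1, n, spec$p_type, lower.tail = FALSE))
  }
  est <- vapply(n, function(ni) {
    withr_seed(seed, {
      probs <- c(rep(spec$p_type, spec$k), 1 - spec$k * spec$p_type)
      draws <- stats::rmultinom(n_rep, ni, probs)
      mean(colSums(draws[seq_len(spec$k), , drop = FALSE] >= spec$c) == spec$k)
    })
  }, numeric(1))
  attr(est, "se") <- sqrt(est * (1 - est) / n_rep)
  est
}

#' Smallest n reaching a target success probability
#'
#' Bisection on the monotone success curve; returns the minimal integer n
#' with `success_probability(n) >= p_star`.
#'
#' @param spec a `saturation_spec`.
#' @param p_star target probability in (0, 1).
#' @param n_max search cap (default 1e9); an unreachable target returns NA
#'   with a warning.
#' @return integer n* (or NA).
#' @export
required_cells <- function(spec, p_star, n_max = 1e9) {
  stopifnot(p_star > 0, p_star < 1)
  f <- function(n) success_probability(n, spec)
  if (f(n_max) < p_star) {
    warning("target probability unreachable within n_max")
    return(NA_integer_)
  }
  lo <- 0; hi <- n_max
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (f(mid) >= p_star) hi <- mid else lo <- mid
  }
  as.integer(hi)
}

#' Saturation curve over a grid of sequencing depths
#'
#' @param spec a `saturation_spec`.
#' @param n_grid ascending integer grid.
#' @return data frame `n`, `probability` (non-decreasing).
#' @export
saturation_curve <- function(spec, n_grid) {
  stopifnot(!is.unsorted(n_grid))
  data.frame(n = n_grid, probability = success_probability(n_grid, spec))
}
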