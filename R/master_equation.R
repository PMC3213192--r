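#' Birth and death rates of the cytosolic molecule count
#'
#' The number of cytosolic molecules `n` evolves as a one-step (birth-death)
#' continuous-time Markov chain on `{0, ..., N_T}`. A "birth" (`n -> n+1`) is
#' a membrane molecule dissociating, at total rate `k_off * (N_T - n)`. A
#' "death" (`n -> n-1`) is a cytosolic molecule activating, either
#' spontaneously at rate `k_on * (V_on/V) * n` or by recruitment at rate
#' `k_fb * (V_fb/V) * n * (N_T - n)`. The boundary rates vanish by
#' construction: no birth at `n = N_T` (empty membrane), no death at `n = 0`
#' (empty cytosol); at `n = N_T` recruitment is impossible and only the
#' spontaneous term remains.
#'
#' @param n cytosolic count(s) in `0..N_T` (vectorized).
#' @param m a `polarity_model`.
#' @return A list with numeric vectors `birth` and `death`.
#' @export
transition_rates <- function(n, m) {
  stopifnot(all(n >= 0), all(n <= m$N_T))
  list(birth = m$k_off * (m$N_T - n),
       death = m$k_on * (m$V_on / m$V) * n +
               m$k_fb * (m$V_fb / m$V) * n * (m$N_T - n))
}

#' Stationary distribution of the cytosolic count
#'
#' One-step birth-death processes satisfy detailed balance at stationarity,
#' `p_n * birth(n) = p_{n+1} * death(n+1)`, so the stationary probability mass
#' function follows from the product recursion
#' `p_n / p_0 = prod_{m=1..n} birth(m-1) / death(m)`. The recursion is
#' evaluated in log space with a single normalization pass, which is stable
#' for `N_T` up to at least `1e5`.
#'
#' Far below the critical number `N_star` the mass concentrates at `n = N_T`
#' (everything cytosolic, the buffered off state); far above it the
#' distribution is essentially Poisson with expectation `rho_star * V`
#' (= `N_star`); near the transition it becomes bimodal even though the
#' deterministic equation has a unique equilibrium.
#'
#' With `k_on = 0` the state `n = N_T` is absorbing (an empty membrane can
#' never re-activate), which is signalled and the point mass at `N_T`
#' returned.
#'
#' @param m a `polarity_model` with `N_T >= 1`.
#' @param min_mode_mass passed to [classify_modality()].
#' @return An object of class `stationary_pmf`: list with `n` (0..N_T), `p`
#'   (probabilities summing to 1), `modality`, `modes` (local-maximum
#'   indices into `n`, i.e. count values), and `mean`.
#' @export
stationary_distribution <- function(m, min_mode_mass = 1e-4) {
  validate_params(m)
  N <- as.integer(m$N_T)
  stopifnot(N >= 1)
  if (m$k_on == 0) {
    warning("absorbing state at n = N_T (k_on = 0): ",
            "stationary distribution is the point mass there", call. = FALSE)
    p <- c(rep(0, N), 1)
  } else {
    n <- 1:N
    r <- transition_rates(0:N, m)
    # log p_n - log p_0 = cumsum over m of log(birth(m-1)) - log(death(m))
    logratio <- cumsum(log(r$birth[n]) - log(r$death[n + 1L]))
    logp <- c(0, logratio)
    logp <- logp - max(logp)
    p <- exp(logp)
    p <- p / sum(p)
  }
  out <- list(n = 0:N, p = p, mean = sum((0:N) * p))
  cls <- classify_modality(out, min_mode_mass = min_mode_mass)
  out$modality <- cls$modality
  out$modes <- cls$modes
  class(out) <- "stationary_pmf"
  out
}

#' Classify the modality of a discrete probability mass function
#'
#' Finds strict local maxima of `p` after merging plateaus (runs of equal
#' probabilities, which tie easily in discrete distributions, are treated as
#' one candidate mode located at the run's midpoint). Boundary points count
#' as maxima. The pmf is `bimodal` if at least two maxima each carry at least
#' `min_mode_mass` peak probability, otherwise `unimodal`.
#'
#' @param pmf a list with fields `n` and `p` (e.g. a `stationary_pmf`).
#' @param min_mode_mass minimum peak probability for a mode to count.
#'   Default `1e-4`.
#' @param plateau_tol relative tolerance for treating neighboring
#'   probabilities as tied. Default `1e-12`.
#' @return list with `modality` (`"unimodal"` or `"bimodal"`) and `modes`
#'   (the count values `n` at the modes).
#' @export
classify_modality <- function(pmf, min_mode_mass = 1e-4, plateau_tol = 1e-12) {
  p <- pmf$p
  n <- pmf$n
  stopifnot(length(p) == length(n), all(p >= 0))
  scale <- max(p)
  # merge plateaus: group consecutive entries equal within tolerance
  grp <- cumsum(c(1L, as.integer(abs(diff(p)) > plateau_tol * scale)))
  gp <- tapply(p, grp, function(z) z[1])
  gidx <- tapply(seq_along(p), grp, function(z) z[ceiling(length(z) / 2)])
  k <- length(gp)
  left <- c(-Inf, gp[-k])
  right <- c(gp[-1], -Inf)
  is_max <- gp > left & gp > right
  modes_idx <- gidx[is_max & gp >= min_mode_mass]
  modes <- n[modes_idx]
  list(modality = if (length(modes) >= 2) "bimodal" else "unimodal",
       modes = as.numeric(modes))
}

#' Total variation distance to a truncated Poisson distribution
#'
#' Compares a pmf over `{0..N_T}` with a Poisson distribution of the given
#' mean truncated to the same support and renormalized. Used to check the
#' high-density limit, where the stationary cytosolic count is essentially
#' Poisson with expectation `N_star`.
#'
#' @param pmf a `stationary_pmf` (or list with `n`, `p`).
#' @param mean Poisson expectation, > 0.
#' @return total variation distance in `[0, 1]`.
#' @export
compare_to_poisson <- function(pmf, mean) {
  stopifnot(mean > 0)
  q <- stats::dpois(pmf$n, lambda = mean)
  q <- q / sum(q)
  0.5 * sum(abs(pmf$p - q))
}

#' @export
print.stationary_pmf <- function(x, ...) {
  cat(sprintf("Stationary cytosolic-count pmf on 0..%d: mean = %.4g, %s",
              max(x$n), x$mean, x$modality))
  cat(" (modes at n =", paste(x$modes, collapse = ", "), ")\n")
  invisible(x)
}

#' @export
plot.stationary_pmf <- function(x, ...) {
  graphics::plot(x$n, x$p, type = "h", xlab = "cytosolic count n",
                 ylab = expression(P[n]), ...)
  invisible(x)
}
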