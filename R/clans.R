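#' Clan genealogy statistics of a trajectory
#'
#' Clans group membrane molecules by descent: every recruit joins its
#' recruiter's clan, a dissociating molecule loses its identity, and each
#' spontaneous on-event founds a fresh clan. A clan that loses its last
#' member is extinct forever, so between on-events the number of clans can
#' only fall. This extracts the surviving-clan count series and the two
#' crossing times used by the neutral-drift analysis: the clan half-life
#' (first time the count reaches `ceiling(K/2)`, where `K` is the initial
#' clan number) and the single-clan time (first time one clan remains).
#'
#' @param traj a `polarity_traj` (positions must be recorded for
#'   `winner_spread`; counts suffice for the rest).
#' @return An object of class `clan_stats`: list with `times`, `n_surviving`,
#'   `K`, `t_half_hat`, `t_single_hat` (NA if not reached), `winner_id`
#'   (clan label, or NA if no single survivor), and `winner_spread`
#'   (circular sd of the winner's positions at the single-clan time, as a
#'   fraction of `L`; NA if unavailable).
#' @export
clan_trajectory <- function(traj) {
  n_surv <- traj$n_clans
  times <- traj$t
  K <- n_surv[1]
  half_target <- ceiling(K / 2)
  i_half <- which(n_surv <= half_target)[1]
  i_single <- which(n_surv == 1 & traj$N_m > 0)[1]
  winner_id <- NA_integer_
  winner_spread <- NA_real_
  if (!is.na(i_single) && !is.null(traj$clan_ids)) {
    ids <- traj$clan_ids[[i_single]]
    winner_id <- ids[1]
    winner_spread <- circular_sd(traj$positions[[i_single]])
  }
  out <- list(times = times, n_surviving = n_surv, K = K,
              t_half_hat = if (is.na(i_half)) NA_real_ else times[i_half],
              t_single_hat = if (is.na(i_single)) NA_real_ else times[i_single],
              winner_id = winner_id, winner_spread = winner_spread)
  class(out) <- "clan_stats"
  out
}

#' @export
print.clan_stats <- function(x, ...) {
  cat(sprintf("clan_stats: K = %d initial clans; t_half = %s, t_single = %s min\n",
              x$K, format(x$t_half_hat), format(x$t_single_hat)))
  if (!is.na(x$winner_id)) {
    cat(sprintf("  winner clan %d, spread %.4g (fraction of L)\n",
                x$winner_id, x$winner_spread))
  }
  invisible(x)
}

# circular standard deviation of positions given as fractions of the circle,
# returned as a fraction of the circumference
circular_sd <- function(pos) {
  if (length(pos) == 0) return(NA_real_)
  theta <- 2 * pi * pos
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  if (rbar <= 0) return(Inf)
  sqrt(-2 * log(rbar)) / (2 * pi)
}

# extinction probability by time t of a linear birth-death process started
# from one individual, per-capita birth lambda and death mu
bd_extinction_prob <- function(t, lambda, mu) {
  if (lambda == 0) return(1 - exp(-mu * t))
  if (abs(lambda - mu) < 1e-9 * mu) {        # critical case
    return(lambda * t / (1 + lambda * t))
  }
  r <- lambda - mu
  mu * (exp(r * t) - 1) / (lambda * exp(r * t) - mu)
}

# time at which the surviving-clan count S(t) first reaches c_target with
# probability 1/2. Clans are treated as independent birth-death processes of
# n0 founders each, so S(t) ~ Binomial(K, q(t)) with q the clan survival
# probability; because S is non-increasing (no on-events), the first-passage
# time is below t exactly when S(t) <= c_target, so the median crossing time
# solves P(S(t) <= c_target | S(t) >= 1) = 1/2 (conditioning on S >= 1
# mirrors mass conservation, which keeps the last clan alive).
clan_count_median_time <- function(K, n0, lambda, mu, c_target) {
  stopifnot(K >= 2, c_target >= 1, c_target < K, mu > 0)
  f <- function(t) {
    P1 <- bd_extinction_prob(t, lambda, mu)
    q <- 1 - P1^n0
    p0 <- stats::dbinom(0, K, q)
    (stats::pbinom(c_target, K, q) - p0) / (1 - p0) - 0.5
  }
  # ultimate clan-survival probability bounds reachability (supercritical)
  if (lambda > mu) {
    q_inf <- 1 - (mu / lambda)^n0
    p0_inf <- stats::dbinom(0, K, q_inf)
    reach <- (stats::pbinom(c_target, K, q_inf) - p0_inf) / (1 - p0_inf)
    if (!is.finite(reach) || reach < 0.5) return(Inf)
  }
  upper <- 10 * (n0 * K + 1) / mu
  while (f(upper) < 0) {
    upper <- upper * 10
    if (upper > 1e12 / mu) return(Inf)
  }
  stats::uniroot(f, c(1e-12 / mu, upper), tol = 1e-10 / mu)$root
}

clan_rates <- function(m, N_m) {
  lambda <- m$k_fb * (m$V_fb / m$V) * (m$N_T - N_m)
  mu <- m$k_off
  stopifnot(mu > 0)
  c(lambda = lambda, mu = mu)
}

#' Expected clan half-life under neutral drift
#'
#' Between on-events each clan is, to leading order, an independent linear
#' birth-death process: every member dies (dissociates) at rate `k_off` and
#' gives birth (recruits) at rate `k_fb*(V_fb/V)*N_c`. With the cytosol at
#' its quasi-stationary level the two rates balance (`lambda = mu = k_off`,
#' the critical case of neutral drift). A clan of `n0 = N_m/K` founders is
#' extinct by time `t` with probability `P(t)^n0`, with `P` the
#' single-lineage extinction probability (`lambda*t/(1+lambda*t)` in the
#' critical case), so the surviving count is approximately
#' `Binomial(K, 1 - P(t)^n0)`. Because the count can only fall, its
#' first-passage time below a level `c` is at most `t` exactly when
#' `S(t) <= c`; the half-life returned is the median of that first-passage
#' time at `c = ceiling(K/2)` (the parity convention of the estimator in
#' [clan_trajectory()]). The time scale is set by the clan size:
#' `t_half ~ N_m / (K * k_off * ln 2)` for large clans in the critical case.
#'
#' @param m a `polarity_model`.
#' @param K number of initial clans, >= 2.
#' @param N_m membrane molecule number; default the deterministic
#'   equilibrium `N_T - N_star` (must be positive).
#' @return clan half-life in minutes (Inf if the level is never reached,
#'   e.g. strongly supercritical growth).
#' @export
clan_half_life <- function(m, K, N_m = NULL) {
  stopifnot(K >= 2, K == round(K))
  if (is.null(N_m)) N_m <- m$N_T - derive_constants(m)$N_star
  stopifnot(N_m > 0)
  r <- clan_rates(m, N_m)
  clan_count_median_time(K, N_m / K, r[["lambda"]], r[["mu"]],
                         ceiling(K / 2))
}

#' Expected time to a single surviving clan
#'
#' Same first-passage calculus as [clan_half_life()] with level `c = 1`:
#' the median time at which a single clan holds the whole membrane
#' population. By construction it dominates the half-life for `K > 2` and
#' coincides with it exactly at `K = 2` (halving two clans is reaching one).
#' In the critical case the large-`K` time scale is `~ N_m / k_off`,
#' independent of `K`.
#'
#' @inheritParams clan_half_life
#' @return single-clan time in minutes.
#' @export
single_clan_time <- function(m, K, N_m = NULL) {
  stopifnot(K >= 2, K == round(K))
  if (is.null(N_m)) N_m <- m$N_T - derive_constants(m)$N_star
  stopifnot(N_m > 0)
  r <- clan_rates(m, N_m)
  clan_count_median_time(K, N_m / K, r[["lambda"]], r[["mu"]], 1)
}

#' Spatial spread of the winning clan
#'
#' Once a single clan survives, slow membrane diffusion keeps its members in
#' a small neighborhood of the ancestral site. This measures the circular
#' standard deviation of the winner's positions and compares it to the
#' locality bound (see [regime_bounds()]): under the bound the spread stays
#' well below the membrane size, while fast diffusion spreads the winner
#' uniformly.
#'
#' @param state a `particle_state` (or any list with `positions` and
#'   `clan_ids`) in which exactly one clan survives; anything else is an
#'   error, not a guess.
#' @param m a `polarity_model`.
#' @param local_threshold spread (fraction of `L`) below which the clan is
#'   called local. Default 0.2.
#' @return list with `spread` (circular sd as fraction of `L`),
#'   `spread_um` (same in micrometers), `n` members, and logical `local`.
#' @export
winner_locality <- function(state, m, local_threshold = 0.2) {
  ids <- unique(state$clan_ids)
  if (length(ids) != 1L) {
    stop("winner_locality is defined only when exactly one clan survives (",
         length(ids), " present)", call. = FALSE)
  }
  spread <- circular_sd(state$positions)
  list(spread = spread, spread_um = spread * m$L,
       n = length(state$positions),
       local = is.finite(spread) && spread <= local_threshold)
}
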