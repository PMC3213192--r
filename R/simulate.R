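#' Initialize a particle state on the circular membrane
#'
#' Places `round(membrane_fraction * N_T)` molecules uniformly at random on
#' the circle and assigns clan labels by partitioning the circle into
#' `n_clans` equal arcs: all molecules within one arc found one clan. The
#' remaining molecules form the well-mixed cytosolic pool. Positions are
#' stored as fractions of the circumference in `[0, 1)`.
#'
#' @param m a `polarity_model`.
#' @param membrane_fraction initial fraction of molecules on the membrane,
#'   in `[0, 1]`. Default 0.1.
#' @param n_clans number of equal arcs used to seed clans. Default 50.
#' @return An object of class `particle_state`: list with `t`, `positions`,
#'   `clan_ids`, `N_c`, `N_T`, `next_clan`.
#' @export
init_state <- function(m, membrane_fraction = 0.1, n_clans = 50) {
  stopifnot(membrane_fraction >= 0, membrane_fraction <= 1,
            n_clans >= 1, n_clans == round(n_clans))
  N_m <- round(membrane_fraction * m$N_T)
  positions <- stats::runif(N_m)
  clan_ids <- as.integer(floor(positions * n_clans)) + 1L
  st <- list(t = 0, positions = positions, clan_ids = clan_ids,
             N_c = as.integer(m$N_T - N_m), N_T = as.integer(m$N_T),
             next_clan = as.integer(n_clans + 1L))
  class(st) <- "particle_state"
  st
}

#' @export
print.particle_state <- function(x, ...) {
  cat(sprintf("particle_state at t = %g min: N_m = %d, N_c = %d (N_T = %d), %d clan(s)\n",
              x$t, length(x$positions), x$N_c, x$N_T,
              length(unique(x$clan_ids))))
  invisible(x)
}

#' Advance a particle state by one operator-split time step
#'
#' One fixed step of the membrane simulation: (a) each membrane molecule
#' dissociates with probability `k_off*dt`; (b) each surviving membrane
#' molecule recruits with probability `k_fb*(V_fb/V)*N_c*dt`, placing the
#' recruit at its own position with its clan id; (c) a Poisson number of
#' spontaneous on-events (`k_on*(V_on/V)*N_c*dt` expected) appear at uniform
#' positions, each founding a fresh clan; (d) all membrane molecules take a
#' wrapped Gaussian step of variance `2*D_m*dt`. Dissociation is sampled
#' before recruitment on the pre-step membrane set; any fixed convention is
#' consistent as `dt -> 0`. Mass is conserved exactly. `dt` must keep every
#' per-molecule event probability below 0.1 (hard error otherwise).
#'
#' @param state a `particle_state`.
#' @param m a `polarity_model`.
#' @param dt time step, minutes.
#' @param n_steps number of steps to take. Default 1.
#' @return the advanced `particle_state`.
#' @export
step_state <- function(state, m, dt, n_steps = 1) {
  res <- run_membrane_core(state$positions, as.integer(state$clan_ids),
                           as.integer(state$N_c), as.integer(state$next_clan),
                           as.integer(state$N_T),
                           m$k_off, m$k_on * m$V_on / m$V,
                           m$k_fb * m$V_fb / m$V, m$D_m / m$L^2,
                           state$t, state$t + n_steps * dt, dt,
                           record_stride = n_steps, record_full = FALSE)
  st <- list(t = res$final_t, positions = res$final_pos,
             clan_ids = res$final_clan, N_c = res$final_N_c,
             N_T = state$N_T, next_clan = res$final_next_clan)
  class(st) <- "particle_state"
  st
}

#' Perturbation schedule for a simulation run
#'
#' @param t_end simulated duration, minutes.
#' @param events list of perturbation events built with [evt_reseed()],
#'   [evt_add_cytosol()], [evt_remove_cytosol()]; times must be strictly
#'   increasing and within `[0, t_end]`.
#' @param record_every recording interval, minutes.
#' @return an object of class `sim_schedule`.
#' @export
make_schedule <- function(t_end, events = list(), record_every = 0.1) {
  stopifnot(t_end > 0, record_every > 0)
  times <- vapply(events, function(e) e$time, numeric(1))
  if (length(times)) {
    stopifnot(all(diff(times) > 0), all(times >= 0), all(times <= t_end))
  }
  structure(list(t_end = t_end, events = events,
                 record_every = record_every),
            class = "sim_schedule")
}

#' @rdname make_schedule
#' @param time event time, minutes.
#' @param fraction_cytosol fraction of the current cytosolic pool moved onto
#'   the membrane (restimulation).
#' @param membrane_window_fraction width of the single randomly placed
#'   membrane window receiving the reseeded molecules, as a fraction of `L`.
#' @export
evt_reseed <- function(time, fraction_cytosol, membrane_window_fraction) {
  stopifnot(fraction_cytosol >= 0, fraction_cytosol <= 1,
            membrane_window_fraction > 0, membrane_window_fraction <= 1)
  list(time = time, type = "reseed", fraction_cytosol = fraction_cytosol,
       membrane_window_fraction = membrane_window_fraction)
}

#' @rdname make_schedule
#' @param count number of molecules added to / removed from the cytosol;
#'   the total `N_T` changes accordingly and the change is recorded.
#' @export
evt_add_cytosol <- function(time, count) {
  stopifnot(count >= 0, count == round(count))
  list(time = time, type = "add_cytosol", count = as.integer(count))
}

#' @rdname make_schedule
#' @export
evt_remove_cytosol <- function(time, count) {
  stopifnot(count >= 0, count == round(count))
  list(time = time, type = "remove_cytosol", count = as.integer(count))
}

apply_event <- function(ev, st) {
  if (ev$type == "reseed") {
    n_move <- round(ev$fraction_cytosol * st$N_c)
    if (n_move > 0) {
      start <- stats::runif(1)
      newpos <- (start + stats::runif(n_move) * ev$membrane_window_fraction) %% 1
      newids <- st$next_clan + seq_len(n_move) - 1L
      st$positions <- c(st$positions, newpos)
      st$clan_ids <- c(st$clan_ids, as.integer(newids))
      st$N_c <- st$N_c - n_move
      st$next_clan <- as.integer(st$next_clan + n_move)
    }
  } else if (ev$type == "add_cytosol") {
    st$N_c <- st$N_c + ev$count
    st$N_T <- st$N_T + ev$count
  } else if (ev$type == "remove_cytosol") {
    if (ev$count > st$N_c) {
      stop("remove_cytosol: count (", ev$count, ") exceeds current N_c (",
           st$N_c, ")", call. = FALSE)
    }
    st$N_c <- st$N_c - ev$count
    st$N_T <- st$N_T - ev$count
  } else {
    stop("unknown event type: ", ev$type, call. = FALSE)
  }
  st
}

#' Default operator-splitting time step
#'
#' `dt = 0.1 / (maximum total per-molecule rate)`, so every per-step event
#' probability stays below 0.1 even when the whole pool is cytosolic.
#'
#' @param m a `polarity_model`.
#' @return time step in minutes.
#' @export
default_dt <- function(m) {
  rate <- m$k_off + m$k_fb * (m$V_fb / m$V) * m$N_T +
    m$k_on * (m$V_on / m$V)
  if (rate <= 0) return(0.01)
  0.1 / rate
}

#' Simulate the stochastic particle model on the circular membrane
#'
#' Runs the fixed-step operator-split particle simulation (see
#' [step_state()] for the sub-step convention), applying any scheduled
#' perturbations at their times, and records the state every
#' `record_every` minutes. Runs are reproducible: identical model, schedule
#' and `seed` give identical trajectories.
#'
#' @param object a `polarity_model`.
#' @param nsim number of replicate trajectories. Default 1.
#' @param seed integer seed; replicate streams are derived from it by
#'   drawing one sub-seed per replicate. `NULL` uses the current RNG state.
#' @param t_end simulated minutes (ignored if `schedule` given). Default 60.
#' @param record_every recording interval, minutes (ignored if `schedule`
#'   given). Default 0.1.
#' @param schedule a [make_schedule()] object with perturbation events.
#' @param membrane_fraction,n_clans initial condition, see [init_state()].
#' @param dt time step; default [default_dt()] (adjusted so recording times
#'   are integer multiples of it).
#' @param record `"full"` stores positions and clan ids at every record;
#'   `"counts"` stores only counts (cheaper for long runs).
#' @param ... unused.
#' @return For `nsim = 1` an object of class `polarity_traj`; otherwise a
#'   list of them (class `polarity_sim_list`).
#' @export
simulate.polarity_model <- function(object, nsim = 1, seed = NULL,
                                    t_end = 60, record_every = 0.1,
                                    schedule = NULL,
                                    membrane_fraction = 0.1, n_clans = 50,
                                    dt = NULL,
                                    record = c("full", "counts"), ...) {
  record <- match.arg(record)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule)) schedule <- make_schedule(t_end, list(), record_every)
  if (nsim == 1) {
    return(run_one(object, schedule, membrane_fraction, n_clans, dt, record,
                   seed = seed))
  }
  sub_seeds <- sample.int(.Machine$integer.max, nsim)
  out <- lapply(seq_len(nsim), function(i) {
    set.seed(sub_seeds[i])
    run_one(object, schedule, membrane_fraction, n_clans, dt, record,
            seed = sub_seeds[i])
  })
  class(out) <- "polarity_sim_list"
  out
}

run_one <- function(m, schedule, membrane_fraction, n_clans, dt, record,
                    seed = NULL) {
  validate_params(m)
  if (is.null(dt)) dt <- default_dt(m)
  record_every <- schedule$record_every
  # align dt with the recording grid
  stride <- max(1L, as.integer(ceiling(record_every / dt - 1e-9)))
  dt <- record_every / stride
  full <- identical(record, "full")

  st <- init_state(m, membrane_fraction, n_clans)
  recs <- list(t = 0, N_c = st$N_c, N_m = length(st$positions),
               N_T = st$N_T, n_clans = length(unique(st$clan_ids)))
  positions <- if (full) list(st$positions) else NULL
  clan_ids <- if (full) list(st$clan_ids) else NULL

  breakpoints <- c(vapply(schedule$events, function(e) e$time, numeric(1)),
                   schedule$t_end)
  ev_idx <- seq_along(schedule$events)
  t_cur <- 0
  for (k in seq_along(breakpoints)) {
    t_next <- breakpoints[k]
    if (t_next > t_cur + 1e-12) {
      res <- run_membrane_core(st$positions, as.integer(st$clan_ids),
                               as.integer(st$N_c), as.integer(st$next_clan),
                               as.integer(st$N_T),
                               m$k_off, m$k_on * m$V_on / m$V,
                               m$k_fb * m$V_fb / m$V, m$D_m / m$L^2,
                               t_cur, t_next, dt,
                               record_stride = stride, record_full = full)
      recs$t <- c(recs$t, res$t)
      recs$N_c <- c(recs$N_c, res$N_c)
      recs$N_m <- c(recs$N_m, res$N_m)
      recs$N_T <- c(recs$N_T, rep(st$N_T, length(res$t)))
      recs$n_clans <- c(recs$n_clans, res$n_clans)
      if (full) {
        positions <- c(positions, res$positions)
        clan_ids <- c(clan_ids, res$clan_ids)
      }
      st$positions <- res$final_pos
      st$clan_ids <- res$final_clan
      st$N_c <- res$final_N_c
      st$next_clan <- res$final_next_clan
      st$t <- res$final_t
      t_cur <- res$final_t
    }
    if (k <= length(ev_idx)) {
      st <- apply_event(schedule$events[[k]], st)
    }
  }

  out <- list(t = recs$t, N_c = recs$N_c, N_m = recs$N_m, N_T = recs$N_T,
              n_clans = recs$n_clans,
              positions = positions, clan_ids = clan_ids,
              params = m, schedule = schedule, seed = seed, dt = dt,
              final_state = st)
  class(out) <- "polarity_traj"
  out
}

#' @export
print.polarity_traj <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("polarity_traj: %d records over %g min (dt = %g)\n",
              n, x$t[n], x$dt))
  cat(sprintf("  final: N_m = %d, N_c = %d, N_T = %d, surviving clans = %d\n",
              x$N_m[n], x$N_c[n], x$N_T[n], x$n_clans[n]))
  invisible(x)
}

#' @export
print.polarity_sim_list <- function(x, ...) {
  cat("list of", length(x), "polarity_traj replicates\n")
  invisible(x)
}

#' Kymograph of a membrane trajectory
#'
#' Bins the recorded membrane positions into `n_bins` equal half-open arcs
#' (bin 1 starts at angle 0) at each recorded time. Row sums equal the
#' membrane counts.
#'
#' @param traj a `polarity_traj` recorded with `record = "full"`.
#' @param n_bins number of angular bins, >= 2. Default 60.
#' @return A numeric matrix, time (rows) by angular bin (columns), with the
#'   record times as rownames attribute `t`.
#' @export
kymograph <- function(traj, n_bins = 60) {
  stopifnot(n_bins >= 2)
  if (is.null(traj$positions)) {
    stop("trajectory was recorded with record = 'counts'; positions missing",
         call. = FALSE)
  }
  kmat <- t(vapply(traj$positions, function(p) {
    tabulate(pmin(floor(p * n_bins) + 1L, n_bins), nbins = n_bins)
  }, integer(n_bins)))
  attr(kmat, "t") <- traj$t
  kmat
}

#' @export
plot.polarity_traj <- function(x, n_bins = 60, ...) {
  if (!is.null(x$positions)) {
    kmat <- kymograph(x, n_bins)
    graphics::image(x = x$t, y = seq(0, 1, length.out = n_bins),
                    z = kmat, xlab = "time (min)",
                    ylab = "membrane position (fraction of L)",
                    col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE), ...)
  } else {
    graphics::plot(x$t, x$N_m, type = "l", xlab = "time (min)",
                   ylab = expression(N[m]), ...)
  }
  invisible(x)
}
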