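#' Simulate the circuit with a finitely diffusing inactive pool
#'
#' Brownian-dynamics variant of the circuit in which the well-mixed-cytosol
#' assumption is dropped: inactive molecules diffuse at a finite rate `D_c`
#' (still faster than the active rate `D_m`) and recruitment becomes a
#' proximity reaction with a reaction radius. Supported geometries:
#' `"sphere_surface_interior"` (active molecules on the surface of a sphere
#' of radius `L`, inactive molecules in its interior), `"disk2d"` (both
#' forms on one periodic planar membrane of side `L`), and `"box3d"` (both
#' forms in one periodic volume of side `L`).
#'
#' Per fixed step: inactive molecules take Gaussian steps of componentwise
#' variance `2*D_c*dt` (reflected at the sphere surface), active molecules
#' take steps of variance `2*D_m*dt` on their manifold (tangent-plane step
#' plus radial re-projection on the sphere); each (active, inactive) pair
#' within `reaction_radius` reacts with probability `p_react`, converting the
#' inactive molecule to active at the active molecule's position with its
#' clan id (at most one conversion per inactive molecule per step, recruiter
#' drawn uniformly among neighbors); spontaneous activation happens in place
#' with probability `k_on*dt` (projected to the surface in the sphere case);
#' inactivation happens in place with probability `k_off*dt` (released just
#' inside the surface in the sphere case).
#'
#' This scheme approximates diffusion-limited bimolecular kinetics; its
#' correspondence with the well-mixed composite rate is given by
#' [effective_rate_map()].
#'
#' @param m a `polarity_model` with finite `D_c` and geometry not
#'   `"circle1d"`. `k_on` here is the per-inactive-molecule rate (the whole
#'   compartment is within reach, `V_on = V`).
#' @param reaction_radius recruitment radius, um.
#' @param p_react per-pair reaction probability per step, in `[0, 1]`.
#' @param t_end simulated minutes.
#' @param record_every recording interval, minutes.
#' @param dt time step, minutes.
#' @param seed integer seed (optional).
#' @param active_fraction initial fraction of molecules active. Default 0.1.
#' @param n_clans initial clan regions (nearest-center partition).
#'   Default 50.
#' @param record `"counts"` (default) or `"full"`.
#' @return An object of class `geometry_traj`: list with `t`, `N_active`,
#'   `N_inactive`, `n_clans`, optional position/clan records, the model and
#'   scheme parameters.
#' @export
simulate_geometry <- function(m, reaction_radius, p_react, t_end,
                              record_every = 0.5, dt = NULL, seed = NULL,
                              active_fraction = 0.1, n_clans = 50,
                              record = c("counts", "full")) {
  record <- match.arg(record)
  validate_params(m)
  if (m$geometry == "circle1d") {
    stop("simulate_geometry requires geometry disk2d, box3d or ",
         "sphere_surface_interior; use simulate() for circle1d", call. = FALSE)
  }
  if (!is.finite(m$D_c)) {
    stop("simulate_geometry requires finite D_c ",
         "(the well-mixed limit is the master equation)", call. = FALSE)
  }
  stopifnot(reaction_radius > 0, p_react >= 0, p_react <= 1, t_end > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dt)) dt <- 0.05 / max(m$k_off, m$k_on, 1e-8)

  geom_code <- switch(m$geometry, disk2d = 0L, box3d = 1L,
                      sphere_surface_interior = 2L)
  dim <- if (geom_code == 0L) 2L else 3L
  sphere <- geom_code == 2L
  # boxes are simulated on the unit torus: rescale lengths by L
  scale <- if (sphere) 1 else m$L
  D_m <- m$D_m / scale^2
  D_c <- m$D_c / scale^2
  radius <- reaction_radius / scale
  R_sphere <- if (sphere) m$L else 0

  N_a0 <- round(active_fraction * m$N_T)
  N_i0 <- m$N_T - N_a0
  runif_sphere <- function(n, R) {
    if (n == 0) return(matrix(numeric(0), ncol = 3))
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u / sqrt(rowSums(u^2)) * R
  }
  runif_ball <- function(n, R) {
    if (n == 0) return(matrix(numeric(0), ncol = 3))
    runif_sphere(n, R) * stats::runif(n)^(1 / 3)
  }
  if (sphere) {
    act <- runif_sphere(N_a0, R_sphere)
    inact <- runif_ball(N_i0, R_sphere)
    centers <- runif_sphere(n_clans, R_sphere)
  } else {
    act <- matrix(stats::runif(N_a0 * dim), ncol = dim)
    inact <- matrix(stats::runif(N_i0 * dim), ncol = dim)
    centers <- matrix(stats::runif(n_clans * dim), ncol = dim)
  }
  clan <- if (N_a0 > 0) {
    apply(act, 1, function(x) {
      d2 <- rowSums((centers - matrix(x, nrow = n_clans, ncol = dim,
                                      byrow = TRUE))^2)
      which.min(d2)
    })
  } else {
    integer(0)
  }

  stride <- max(1L, as.integer(round(record_every / dt)))
  res <- run_geometry_core(act, matrix(as.integer(clan), ncol = 1), inact,
                           as.integer(n_clans + 1L), geom_code, R_sphere,
                           m$k_off, m$k_on, p_react, radius, D_m, D_c,
                           0, t_end, dt, stride, identical(record, "full"))
  out <- list(t = c(0, res$t),
              N_active = c(N_a0, res$N_active),
              N_inactive = c(N_i0, res$N_inactive),
              n_clans = c(length(unique(clan)), res$n_clans),
              N_T = m$N_T,
              active_positions = res$active_positions,
              clan_ids = res$clan_ids,
              final_active = res$final_active,
              final_inactive = res$final_inactive,
              final_clan = res$final_clan,
              params = m, reaction_radius = reaction_radius,
              p_react = p_react, dt = dt, seed = seed)
  class(out) <- "geometry_traj"
  out
}

#' @export
print.geometry_traj <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("geometry_traj (%s): %d records over %g min; final N_active = %d / %d\n",
              x$params$geometry, n, x$t[n], x$N_active[n], x$N_T))
  invisible(x)
}

#' Well-mixed composite rate implied by a proximity-reaction scheme
#'
#' Maps the discrete-step reaction scheme of [simulate_geometry()] onto the
#' mass-action composite `k_fb * V_fb` of the well-mixed model, so that
#' finite-diffusion runs can be placed on the analytic phase plane. In the
#' fast-diffusion limit the probability that a given inactive molecule lies
#' within the reaction kernel of a given active molecule is
#' `kernel_volume / V`, and the pair reacts with probability `p_react` per
#' step, so the per-pair rate is `p_react * kernel_volume / (V * dt)` and
#' the composite `k_fb * V_fb = p_react * kernel_volume / dt` (independent of
#' the compartment volume, as a mass-action constant must be). Kernel
#' volumes: disk of area `pi r^2` (2-D), ball of volume `4/3 pi r^3` (3-D),
#' half-ball `2/3 pi r^3` for a surface-bound active molecule reaching into
#' the sphere interior.
#'
#' The map neglects local depletion around active molecules (the
#' diffusion-limited correction), so it is an upper bound that becomes exact
#' as `D_c` grows or `p_react` shrinks.
#'
#' @param m a `polarity_model` (supplies the geometry and sizes).
#' @param reaction_radius recruitment radius, um.
#' @param p_react per-pair reaction probability per step.
#' @param dt time step, minutes.
#' @return list with `kernel_volume`, `k_fb_V_fb` (composite, volume
#'   independent), `pair_rate` (per pair per minute, = `k_fb_V_fb / V`), and
#'   `V` (compartment measure in um^dim).
#' @export
effective_rate_map <- function(m, reaction_radius, p_react, dt) {
  stopifnot(reaction_radius > 0, dt > 0, p_react >= 0, p_react <= 1)
  r <- reaction_radius
  kernel <- switch(m$geometry,
    disk2d = pi * r^2,
    box3d = 4 / 3 * pi * r^3,
    sphere_surface_interior = 2 / 3 * pi * r^3,
    circle1d = stop("no reaction-radius scheme for the well-mixed 1-D model",
                    call. = FALSE))
  V <- switch(m$geometry,
    disk2d = m$L^2,
    box3d = m$L^3,
    sphere_surface_interior = 4 / 3 * pi * m$L^3)
  k_fb_V_fb <- p_react * kernel / dt
  list(kernel_volume = kernel, k_fb_V_fb = k_fb_V_fb,
       pair_rate = k_fb_V_fb / V, V = V)
}
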