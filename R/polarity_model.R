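#' Construct a positive-feedback polarity model
#'
#' Defines the minimal two-state positive-feedback circuit: a single molecular
#' species switches between an inactive, cytosolic form and an active,
#' membrane-bound form. Three mass-action mechanisms connect the states:
#' spontaneous inactivation of membrane molecules at rate `k_off`; spontaneous
#' activation of cytosolic molecules within a shell of volume `V_on` near the
#' membrane at rate `k_on`; and recruitment, in which an active molecule
#' converts an inactive molecule lying within its feedback volume `V_fb` at
#' rate `k_fb`, placing the recruit at its own membrane position. The total
#' number of molecules `N_T` is conserved.
#'
#' Defaults are literature-derived rates for Cdc42-like cycling on
#' a 1-D circular membrane with a well-mixed cytosol: composite rates quoted
#' for a unit reaction domain (`V = V_on = V_fb = 1`), so `k_on` and `k_fb`
#' act directly as per-molecule propensity coefficients and the critical
#' molecule number is `k_off / k_fb = 900`. Lateral diffusion is physical
#' (`D_m` in um^2/min) on a membrane of circumference `L` um; only the
#' dimensionless ratio `D_m / L^2` enters the dynamics. The default `L`
#' corresponds to a 10-um-diameter yeast cell.
#'
#' @param k_off spontaneous inactivation (membrane to cytosol) rate, 1/min.
#' @param k_on spontaneous activation rate constant, 1/min.
#' @param k_fb recruitment (positive feedback) rate constant, 1/min.
#' @param V total compartment volume (area in 2-D), reaction-volume units.
#' @param V_on shell volume available for spontaneous activation events.
#' @param V_fb feedback neighborhood volume per active molecule.
#' @param N_T total (conserved) molecule number, a nonnegative integer.
#' @param D_m lateral diffusivity of active molecules, um^2/min.
#' @param D_c diffusivity of the inactive pool, um^2/min; `Inf` (default)
#'   asserts the well-mixed cytosol assumption.
#' @param geometry one of `"circle1d"`, `"sphere_surface_interior"`,
#'   `"disk2d"`, `"box3d"`. The well-mixed (`D_c = Inf`) model is 1-D only.
#' @param L size descriptor of the active compartment, um: circle
#'   circumference, sphere radius, or periodic box side.
#'
#' @return An object of class `polarity_model`: a validated parameter list.
#' @seealso [derive_constants()], [steady_states()],
#'   [stationary_distribution()], [simulate.polarity_model()]
#' @examples
#' m <- polarity_model(N_T = 1500)
#' summary(m)
#' @export
polarity_model <- function(k_off = 9, k_on = 5e-4, k_fb = 0.01,
                           V = 1, V_on = 1, V_fb = 1,
                           N_T = 900,
                           D_m = 1.2, D_c = Inf,
                           geometry = c("circle1d", "sphere_surface_interior",
                                        "disk2d", "box3d"),
                           L = 2 * pi * 5) {
  geometry <- match.arg(geometry)
  m <- list(k_off = k_off, k_on = k_on, k_fb = k_fb,
            V = V, V_on = V_on, V_fb = V_fb,
            N_T = N_T, D_m = D_m, D_c = D_c,
            geometry = geometry, L = L)
  class(m) <- "polarity_model"
  validate_params(m)
  m
}

#' Validate a polarity model parameter set
#'
#' Checks the structural invariants: nonnegative rates, positive volumes with
#' `V_on <= V` and `V_fb <= V`, integer `N_T >= 0`, positive diffusivities and
#' size, and that a finite inactive-pool diffusivity is only combined with a
#' geometry that resolves the inactive pool in space (the 1-D circular model
#' assumes a well-mixed cytosol).
#'
#' @param m a `polarity_model` (or a plain list with the same fields).
#' @return `m`, invisibly, if valid; otherwise an error naming the field.
#' @export
validate_params <- function(m) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  for (f in c("k_off", "k_on", "k_fb", "V", "V_on", "V_fb", "N_T",
              "D_m", "D_c", "L")) {
    chk(num1(m[[f]]), sprintf("field '%s' must be a single number", f))
  }
  chk(m$k_off >= 0, "rate 'k_off' must be >= 0")
  chk(m$k_on >= 0, "rate 'k_on' must be >= 0")
  chk(m$k_fb >= 0, "rate 'k_fb' must be >= 0")
  chk(m$V > 0, "volume 'V' must be > 0")
  chk(m$V_on > 0, "volume 'V_on' must be > 0")
  chk(m$V_fb > 0, "volume 'V_fb' must be > 0")
  chk(m$V_on <= m$V, "'V_on' must not exceed the compartment volume 'V'")
  chk(m$V_fb <= m$V, "'V_fb' must not exceed the compartment volume 'V'")
  chk(m$N_T >= 0 && m$N_T == round(m$N_T),
      "'N_T' must be a nonnegative integer")
  chk(m$D_m >= 0, "diffusivity 'D_m' must be >= 0")
  chk(m$D_c > 0, "diffusivity 'D_c' must be > 0 (use Inf for well-mixed)")
  chk(m$L > 0, "size descriptor 'L' must be > 0")
  chk(is.character(m$geometry) && length(m$geometry) == 1L &&
        m$geometry %in% c("circle1d", "sphere_surface_interior",
                          "disk2d", "box3d"),
      "'geometry' must be one of circle1d, sphere_surface_interior, disk2d, box3d")
  chk(!(is.finite(m$D_c) && m$geometry == "circle1d"),
      "finite 'D_c' requires a spatial inactive pool: geometry must not be 'circle1d'")
  invisible(m)
}

#' Derived constants of the positive-feedback circuit
#'
#' Computes the constants that govern the rescaled cytosolic rate equation
#' and the stochastic analysis:
#' \describe{
#'   \item{`rho_T`}{total molecule density `N_T / V`, the upper bound for the
#'     cytosolic density.}
#'   \item{`rho_star`}{the critical density `k_off / (k_fb * V_fb)`,
#'     a property of the circuit alone, independent of cell volume and
#'     molecule number.}
#'   \item{`alpha_on_off`}{dimensionless spontaneous on-to-off ratio
#'     `(k_on * V_on) / (k_off * V)`.}
#'   \item{`beta_on_fb`}{dimensionless on-to-feedback ratio
#'     `(k_on * V_on) / (k_fb * V_fb)`, the small parameter of the clan
#'     (genealogy) analysis.}
#'   \item{`R0`}{`rho_T / rho_star`, the analogue of the basic reproductive
#'     ratio in SIS epidemic models: membrane accumulation is repressed for
#'     `R0 < 1` and permitted for `R0 > 1`.}
#'   \item{`N_star`}{critical molecule number `rho_star * V`.}
#' }
#'
#' @param m a `polarity_model`.
#' @return An object of class `derived_constants` (named list of the six
#'   fields above).
#' @examples
#' derive_constants(polarity_model(N_T = 1800))
#' @export
derive_constants <- function(m) {
  validate_params(m)
  if (m$k_fb == 0 || m$V_fb == 0) {
    stop("no-feedback model: k_fb and V_fb must be positive for the ",
         "critical density rho_star = k_off/(k_fb*V_fb) to be defined",
         call. = FALSE)
  }
  rho_T <- m$N_T / m$V
  rho_star <- m$k_off / (m$k_fb * m$V_fb)
  d <- list(
    rho_T = rho_T,
    rho_star = rho_star,
    alpha_on_off = if (m$k_off > 0) (m$k_on * m$V_on) / (m$k_off * m$V) else Inf,
    beta_on_fb = (m$k_on * m$V_on) / (m$k_fb * m$V_fb),
    R0 = if (rho_star > 0) rho_T / rho_star else Inf,
    N_star = rho_star * m$V
  )
  if (m$N_T == 0) d$R0 <- 0
  class(d) <- "derived_constants"
  d
}

#' Closed-form regime bounds for single-clan polarization
#'
#' Two inequalities delimit the parameter range in which the membrane
#' population consolidates into one localized clan.
#'
#' *Single-clan (on-event rarity) bound.* Over the consolidation time
#' `T_single ~ N_m / k_off`, spontaneous on-events inject an expected
#' `k_on * (V_on/V) * N_c * T_single` membrane molecules (each on-clan is a
#' critical lineage whose expected size stays at 1). With the cytosol at its
#' quasi-stationary level `N_c ~ rho_star * V`, the injected fraction of the
#' membrane population is exactly the on-to-feedback ratio
#' `beta_on_fb = (k_on*V_on)/(k_fb*V_fb)`. All but a fraction `delta` of
#' membrane molecules belong to a single clan provided
#' `beta_on_fb <= delta`.
#'
#' *Locality bound.* The winning clan stays within a small neighborhood of
#' its ancestral region provided its diffusive spread at consolidation,
#' `sqrt(2 * D_m * T_single)` with `T_single <= N_T / k_off`, is below a
#' fraction of the membrane size, i.e.
#' `N_T <= C_locality * k_off * L^2 / D_m`. The order-unity constant
#' `C_locality` absorbs the size of the initial clan regions (set by `K`)
#' and the geometry; it is exposed as a parameter.
#'
#' @param m a `polarity_model`.
#' @param K number of initial clans (membrane partitions), integer >= 1.
#' @param delta tolerated non-winner fraction of membrane molecules,
#'   in (0, 1). Default 0.1.
#' @param C_locality order-unity constant of the locality bound. Default 0.5.
#' @return An object of class `regime_bounds`: list with logical
#'   `single_clan_bound_ok` and `locality_bound_ok`, the echoed `delta`, `K`,
#'   `C_locality`, and the two dimensionless margins
#'   (`on_fraction = beta_on_fb`, `locality_ratio = N_T * D_m /
#'   (C_locality * k_off * L^2)`).
#' @export
regime_bounds <- function(m, K = 50, delta = 0.1, C_locality = 0.5) {
  stopifnot(K >= 1, K == round(K), delta > 0, delta < 1, C_locality > 0)
  d <- derive_constants(m)
  on_fraction <- d$beta_on_fb
  locality_ratio <- if (m$k_off > 0) {
    (m$N_T * m$D_m) / (C_locality * m$k_off * m$L^2)
  } else {
    Inf
  }
  out <- list(single_clan_bound_ok = on_fraction <= delta,
              locality_bound_ok = locality_ratio <= 1,
              delta = delta, K = as.integer(K), C_locality = C_locality,
              on_fraction = on_fraction, locality_ratio = locality_ratio)
  class(out) <- "regime_bounds"
  out
}

#' @export
print.polarity_model <- function(x, ...) {
  cat("Positive-feedback polarity model (", x$geometry, ")\n", sep = "")
  cat(sprintf("  rates [1/min]: k_off = %g, k_on = %g, k_fb = %g\n",
              x$k_off, x$k_on, x$k_fb))
  cat(sprintf("  volumes: V = %g, V_on = %g, V_fb = %g\n",
              x$V, x$V_on, x$V_fb))
  cat(sprintf("  molecules: N_T = %d\n", as.integer(x$N_T)))
  cat(sprintf("  diffusion [um^2/min]: D_m = %g, D_c = %s; size L = %g um\n",
              x$D_m, if (is.finite(x$D_c)) format(x$D_c) else "Inf (well-mixed)",
              x$L))
  invisible(x)
}

#' @export
summary.polarity_model <- function(object, ...) {
  d <- derive_constants(object)
  out <- list(model = object, constants = d)
  class(out) <- "summary.polarity_model"
  out
}

#' @export
print.summary.polarity_model <- function(x, ...) {
  print(x$model)
  print(x$constants)
  invisible(x)
}

#' @export
print.derived_constants <- function(x, ...) {
  cat("Derived constants:\n")
  cat(sprintf("  rho_T  = %g (total density)\n", x$rho_T))
  cat(sprintf("  rho*   = %g (critical density)\n", x$rho_star))
  cat(sprintf("  N*     = %g (critical molecule number)\n", x$N_star))
  cat(sprintf("  R0     = %g (= rho_T / rho*; off for R0 < 1)\n", x$R0))
  cat(sprintf("  alpha  = %g (spontaneous on-to-off ratio)\n", x$alpha_on_off))
  cat(sprintf("  beta   = %g (on-to-feedback ratio)\n", x$beta_on_fb))
  invisible(x)
}

#' @export
print.regime_bounds <- function(x, ...) {
  cat("Single-clan regime bounds (K =", x$K, "):\n")
  cat(sprintf("  on-event rarity: beta_on_fb = %.4g <= delta = %g : %s\n",
              x$on_fraction, x$delta, x$single_clan_bound_ok))
  cat(sprintf("  locality: N_T*D_m/(C*k_off*L^2) = %.4g <= 1 : %s\n",
              x$locality_ratio, x$locality_bound_ok))
  invisible(x)
}

#' Model coefficients
#'
#' Returns the rate constants and reaction volumes as a named numeric vector.
#'
#' @param object a `polarity_model`.
#' @param ... unused.
#' @export
coef.polarity_model <- function(object, ...) {
  c(k_off = object$k_off, k_on = object$k_on, k_fb = object$k_fb,
    V = object$V, V_on = object$V_on, V_fb = object$V_fb,
    N_T = object$N_T, D_m = object$D_m, D_c = object$D_c, L = object$L)
}
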