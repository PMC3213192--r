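#' Rescaled rate of change of the cytosolic density
#'
#' The continuum description of the circuit tracks the cytosolic density
#' `rho_c = N_c / V`. In time rescaled by the off-rate (`tau = k_off * t`)
#' the rate equation reads
#' \deqn{d\rho_c/d\tau = (\rho_T - \rho_c)(1 - \rho_c/\rho^*) - \alpha \rho_c}
#' where `rho_T`, `rho_star` and `alpha = alpha_on_off` are the derived
#' constants of the model. The first term is the off-flux from the membrane
#' net of recruitment; the last is the spontaneous activation drain.
#'
#' @param rho_c cytosolic density (vectorized), in `[0, rho_T]`.
#' @param consts a `derived_constants` object (see [derive_constants()]).
#' @return `d rho_c / d tau`, same length as `rho_c`.
#' @export
cytosol_rate <- function(rho_c, consts) {
  (consts$rho_T - rho_c) * (1 - rho_c / consts$rho_star) -
    consts$alpha_on_off * rho_c
}

#' Steady states of the cytosolic density equation
#'
#' The right-hand side of the rescaled rate equation is quadratic in `rho_c`,
#' so there are at most two equilibria. Without spontaneous activation
#' (`alpha = 0`) they are exactly `rho_T` and `rho_star`: below the critical
#' density (`rho_T < rho_star`) all molecules sit in the cytosol and the
#' membrane is empty; above it the cytosol saturates at `rho_star` and
#' `(rho_T - rho_star) * V` molecules occupy the membrane. The smaller root is
#' always the stable one; stability is exchanged at `rho_T = rho_star`
#' (a transcritical bifurcation). For `alpha > 0` the two real roots straddle
#' `min/max(rho_T, rho_star)`; the larger always exceeds `rho_T` and is
#' unphysical (there cannot be more molecules than `N_T`), leaving a unique
#' stable physical equilibrium, and the crossing is smoothed (imperfect
#' transcritical bifurcation with `alpha` as imperfection parameter).
#'
#' Roots are computed from the quadratic in a cancellation-safe form (the
#' smaller root via `2c / (-b + sqrt(disc))`), which stays accurate near the
#' bifurcation point where the naive formula loses precision.
#'
#' @param consts a `derived_constants` object.
#' @param degenerate_tol roots closer than `degenerate_tol * rho_star` are
#'   reported as a degenerate double root. Default `1e-9`.
#' @return An object of class `steady_states`: list with `roots` (increasing),
#'   `stability` (`"stable"`/`"unstable"` per root), `physical` (root within
#'   `[0, rho_T]`), `bifurcation_type` (`"transcritical"`,
#'   `"imperfect_transcritical"` or `"none"`), `degenerate` flag, and
#'   `membrane_fraction` (equilibrium fraction of molecules on the membrane,
#'   from the stable physical root).
#' @export
steady_states <- function(consts, degenerate_tol = 1e-9) {
  rho_T <- consts$rho_T
  rho_s <- consts$rho_star
  alpha <- consts$alpha_on_off
  stopifnot(is.finite(rho_T), is.finite(rho_s), rho_s > 0, alpha >= 0)
  # quadratic a x^2 + b x + c = 0, a > 0
  a <- 1 / rho_s
  b <- -(1 + rho_T / rho_s + alpha)
  c0 <- rho_T
  disc <- b * b - 4 * a * c0
  disc <- max(disc, 0)
  sq <- sqrt(disc)
  root_small <- 2 * c0 / (-b + sq)
  root_large <- (-b + sq) / (2 * a)
  degenerate <- (root_large - root_small) < degenerate_tol * rho_s
  roots <- c(root_small, root_large)
  stability <- c("stable", "unstable")
  physical <- roots >= -degenerate_tol * rho_s & roots <= rho_T * (1 + 1e-12)
  bifurcation_type <- if (alpha == 0) "transcritical" else "imperfect_transcritical"
  if (degenerate && alpha == 0) {
    warning("degenerate double root: rho_T = rho_star at alpha = 0 ",
            "(transcritical point)", call. = FALSE)
  }
  stable_root <- root_small
  membrane_fraction <- if (rho_T > 0) max(0, 1 - stable_root / rho_T) else 0
  out <- list(roots = roots, stability = stability, physical = physical,
              bifurcation_type = bifurcation_type, degenerate = degenerate,
              membrane_fraction = membrane_fraction)
  class(out) <- "steady_states"
  out
}

#' @export
print.steady_states <- function(x, ...) {
  cat("Cytosolic-density steady states (", x$bifurcation_type, "):\n", sep = "")
  for (i in seq_along(x$roots)) {
    cat(sprintf("  rho_c = %.8g  [%s%s]\n", x$roots[i], x$stability[i],
                if (x$physical[i]) "" else ", unphysical"))
  }
  cat(sprintf("  equilibrium membrane fraction: %.6g\n", x$membrane_fraction))
  invisible(x)
}

#' Integrate the cytosolic-density rate equation
#'
#' Solves the deterministic rate equation in physical time (minutes) with
#' `deSolve`, starting from `rho0`. The trajectory is confined to
#' `[0, rho_T]` and converges to the stable root of [steady_states()].
#'
#' @param m a `polarity_model`.
#' @param rho0 initial cytosolic density in `[0, rho_T]`.
#' @param t_end final time, minutes.
#' @param n_out number of output times (including 0). Default 200.
#' @return A data.frame with columns `time` (min) and `rho_c`.
#' @export
integrate_density <- function(m, rho0, t_end, n_out = 200) {
  consts <- derive_constants(m)
  stopifnot(rho0 >= 0, rho0 <= consts$rho_T + 1e-12, t_end > 0, n_out >= 2)
  times <- seq(0, t_end, length.out = n_out)
  rhs <- function(t, y, p) list(m$k_off * cytosol_rate(y, consts))
  sol <- deSolve::ode(y = c(rho_c = rho0), times = times, func = rhs,
                      parms = NULL, method = "lsoda")
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed (solver reported istate = ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  }
  data.frame(time = sol[, "time"], rho_c = sol[, "rho_c"])
}

#' Bifurcation scan over the total density
#'
#' Evaluates [steady_states()] along a grid of total densities `rho_T` (the
#' natural control parameter: `rho_star` does not depend on molecule number,
#' `rho_T` does), returning the branch table used to draw the transcritical
#' bifurcation diagram and the equilibrium membrane-fraction curve. With
#' `axis = "N_T"` the grid is interpreted as molecule numbers at fixed `V`.
#'
#' @param m a `polarity_model` (supplies `rho_star`, `alpha`, and `V`).
#' @param grid strictly increasing grid of `rho_T` (or `N_T`) values.
#' @param axis `"rho_T"` (default) or `"N_T"`.
#' @return A data.frame of class `bifurcation_scan` with columns `rho_T`,
#'   `root_small`, `root_large`, `stability_small`, `stability_large`,
#'   `physical_large`, and `membrane_fraction`.
#' @export
bifurcation_scan <- function(m, grid, axis = c("rho_T", "N_T")) {
  axis <- match.arg(axis)
  stopifnot(length(grid) >= 1, all(diff(grid) > 0), all(grid >= 0))
  base <- derive_constants(utils::modifyList(m, list(N_T = max(1, m$N_T))))
  rho_T_grid <- if (axis == "N_T") grid / m$V else grid
  rows <- lapply(rho_T_grid, function(rt) {
    cst <- base
    cst$rho_T <- rt
    cst$R0 <- rt / cst$rho_star
    ss <- suppressWarnings(steady_states(cst))
    data.frame(rho_T = rt,
               root_small = ss$roots[1], root_large = ss$roots[2],
               stability_small = ss$stability[1],
               stability_large = ss$stability[2],
               physical_large = ss$physical[2],
               membrane_fraction = ss$membrane_fraction)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bifurcation_scan", "data.frame")
  out
}

#' @export
plot.bifurcation_scan <- function(x, ...) {
  graphics::plot(x$rho_T, x$membrane_fraction, type = "l",
                 xlab = expression(rho[T]),
                 ylab = "equilibrium membrane fraction", ...)
  invisible(x)
}
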