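#' Operational polarization detector
#'
#' A membrane state is polarized when more than `min_count` molecules are on
#' the membrane and at least half of them (`mass_threshold`) sit inside one
#' contiguous arc covering a small fraction (15-25%) of the membrane. The
#' detector scans `n_scan` equally spaced circular windows of width
#' `window_fraction * L` and reports the best one. With the default
#' `n_scan = 360` the scan discretization (1 degree) is far below the window
#' widths.
#'
#' @param x membrane positions as fractions of `L` in `[0, 1)`, or a
#'   `particle_state`, or a `polarity_traj` record index can be extracted by
#'   the caller.
#' @param window_fraction window width as a fraction of the membrane,
#'   in (0, 1). Default 0.15.
#' @param min_count polarization requires strictly more than this many
#'   membrane molecules. Default 20.
#' @param mass_threshold minimum fraction of membrane molecules inside the
#'   best window. Default 0.5.
#' @param n_scan number of window start positions scanned. Default 360.
#' @return An object of class `polarization_call`: list with `polarized`,
#'   `window_fraction`, `best_window_start`, `in_window_fraction`,
#'   `n_membrane`.
#' @export
detect_cluster <- function(x, window_fraction = 0.15, min_count = 20,
                           mass_threshold = 0.5, n_scan = 360) {
  stopifnot(window_fraction > 0, window_fraction < 1, n_scan >= 2)
  pos <- if (is.list(x)) x$positions else x
  n <- length(pos)
  if (n == 0) {
    out <- list(polarized = FALSE, window_fraction = window_fraction,
                best_window_start = NA_real_, in_window_fraction = NA_real_,
                n_membrane = 0L)
    class(out) <- "polarization_call"
    return(out)
  }
  sorted <- sort(pos)
  ext <- c(sorted, sorted + 1)
  starts <- (seq_len(n_scan) - 1) / n_scan
  eps <- 1e-12
  lo <- findInterval(starts - eps, ext)
  hi <- findInterval(starts + window_fraction - eps, ext)
  counts <- hi - lo
  best <- which.max(counts)
  in_frac <- counts[best] / n
  out <- list(polarized = (n > min_count) && (in_frac >= mass_threshold),
              window_fraction = window_fraction,
              best_window_start = starts[best],
              in_window_fraction = in_frac,
              n_membrane = as.integer(n))
  class(out) <- "polarization_call"
  out
}

#' @export
print.polarization_call <- function(x, ...) {
  cat(sprintf("polarization: %s (N_m = %d; %.1f%% of membrane molecules in best %g-window at %.3f)\n",
              if (isTRUE(x$polarized)) "YES" else "no", x$n_membrane,
              100 * x$in_window_fraction, x$window_fraction,
              x$best_window_start))
  invisible(x)
}

traj_list <- function(runs) {
  if (inherits(runs, "polarity_traj")) list(runs) else runs
}

#' Polarization frequency over recorded states
#'
#' Fraction of post-burn-in (run, time) samples that the detector calls
#' polarized, with a binomial standard error.
#'
#' @param runs a `polarity_traj` or list of them (positions recorded).
#' @param window_fraction,min_count,mass_threshold,n_scan passed to
#'   [detect_cluster()].
#' @param burn_in samples with `t < burn_in` are discarded. Default 0.
#' @return list with `frequency`, `se`, and `n_samples`.
#' @export
polarization_frequency <- function(runs, window_fraction = 0.15,
                                   burn_in = 0, min_count = 20,
                                   mass_threshold = 0.5, n_scan = 360) {
  runs <- traj_list(runs)
  stopifnot(length(runs) >= 1)
  hits <- 0L
  total <- 0L
  for (tr in runs) {
    stopifnot(burn_in < max(tr$t))
    keep <- which(tr$t >= burn_in)
    for (i in keep) {
      call <- detect_cluster(tr$positions[[i]], window_fraction, min_count,
                             mass_threshold, n_scan)
      hits <- hits + as.integer(isTRUE(call$polarized))
      total <- total + 1L
    }
  }
  p <- hits / total
  list(frequency = p, se = sqrt(p * (1 - p) / total), n_samples = total)
}

#' Classify the dynamical regime of a parameter set
#'
#' Applies the operational regime taxonomy to a set of replicate runs at
#' identical parameters:
#' \itemize{
#'   \item `OFF` - the membrane stays essentially empty (mean membrane
#'     fraction below `off_eps`): the buffered state below the critical
#'     density.
#'   \item `POLARIZED` - polarization frequency at least `pol_threshold`.
#'   \item `MULTI_CLAN` - more than `clan_threshold` clans survive at the end
#'     *and* the membrane distribution is spatially enriched (the best
#'     15%-window holds at least `enrich_factor` times its uniform share):
#'     several distinct clusters coexist.
#'   \item `HOMOGENEOUS_ON` - membrane occupied but spatially uniform.
#' }
#' A spatially uniform membrane is classified `HOMOGENEOUS_ON` even when many
#' clan labels survive: label diversity without spatial structure is the
#' homogeneous on state, whereas the multi-clan regime of the phase diagram
#' means multiple spatially distinct clusters.
#'
#' @param m the `polarity_model` the runs were simulated at.
#' @param runs replicate `polarity_traj` objects (positions recorded).
#' @param window_fraction window used for the polarization frequency.
#'   Default 0.25.
#' @param burn_in discarded initial minutes. Default 1/4 of the run.
#' @param off_eps,pol_threshold,clan_threshold,enrich_factor classification
#'   thresholds (artifact choices, exposed here).
#' @return An object of class `regime_call`: list with `label` (one of
#'   `"OFF"`, `"POLARIZED"`, `"MULTI_CLAN"`, `"HOMOGENEOUS_ON"`) and the
#'   measured diagnostics.
#' @export
classify_regime <- function(m, runs, window_fraction = 0.25, burn_in = NULL,
                            off_eps = 0.02, pol_threshold = 0.3,
                            clan_threshold = 1.5, enrich_factor = 2) {
  runs <- traj_list(runs)
  stopifnot(length(runs) >= 1)
  if (is.null(burn_in)) burn_in <- max(runs[[1]]$t) / 4
  mf <- unlist(lapply(runs, function(tr) {
    keep <- tr$t >= burn_in
    tr$N_m[keep] / tr$N_T[keep]
  }))
  mean_mf <- mean(mf)
  diag <- list(mean_membrane_fraction = mean_mf)
  if (mean_mf < off_eps) {
    label <- "OFF"
    diag$pol_frequency <- NA_real_
  } else {
    pf <- polarization_frequency(runs, window_fraction, burn_in)
    diag$pol_frequency <- pf$frequency
    if (pf$frequency >= pol_threshold) {
      label <- "POLARIZED"
    } else {
      end_clans <- vapply(runs, function(tr) tr$n_clans[length(tr$n_clans)],
                          numeric(1))
      enrich <- unlist(lapply(runs, function(tr) {
        keep <- which(tr$t >= burn_in)
        vapply(keep, function(i) {
          dc <- detect_cluster(tr$positions[[i]], window_fraction = 0.15)
          if (is.na(dc$in_window_fraction)) NA_real_
          else dc$in_window_fraction / 0.15
        }, numeric(1))
      }))
      diag$mean_end_clans <- mean(end_clans)
      diag$mean_enrichment <- mean(enrich, na.rm = TRUE)
      if (mean(end_clans) > clan_threshold &&
          is.finite(diag$mean_enrichment) &&
          diag$mean_enrichment >= enrich_factor) {
        label <- "MULTI_CLAN"
      } else {
        label <- "HOMOGENEOUS_ON"
      }
    }
  }
  out <- c(list(label = label), diag)
  class(out) <- "regime_call"
  out
}

#' @export
print.regime_call <- function(x, ...) {
  cat("regime:", x$label, "\n")
  cat(sprintf("  mean membrane fraction = %.4g", x$mean_membrane_fraction))
  if (!is.na(x$pol_frequency)) {
    cat(sprintf(", polarization frequency = %.3g", x$pol_frequency))
  }
  cat("\n")
  invisible(x)
}

#' Phase-diagram scan over molecule number and compartment size
#'
#' Classifies the regime on a grid of total molecule numbers and compartment
#' sizes. The size axis scales the reaction compartment `V` and the membrane
#' size `L` together (a linear size factor for the 1-D circular membrane), so
#' the on/off boundary follows the density `N_T / V` while the locality
#' (clustering vs homogeneous) boundary moves with `L^2`. Each cell is also
#' labelled analytically: `OFF` expected when `R0 <= 1`; `POLARIZED` expected
#' when `R0 > 1` and both regime bounds hold ([regime_bounds()]); otherwise
#' the cell is near a boundary (`NA`) and does not count against agreement.
#'
#' @param m base `polarity_model`.
#' @param N_T_grid molecule numbers (>= 2 values).
#' @param size_grid size factors multiplying `V` and `L` (>= 2 values); the
#'   scaled `V` must stay >= `V_on`, `V_fb`.
#' @param reps replicates per cell. Default 5.
#' @param seed integer seed for the whole scan.
#' @param t_end,record_every,... forwarded to [simulate.polarity_model()].
#' @param K,delta,C_locality forwarded to [regime_bounds()].
#' @return An object of class `phase_diagram`: data.frame with columns
#'   `N_T`, `size`, `label`, `expected`, plus attribute `agreement` (fraction
#'   of cells matching their analytic expectation, among decided cells).
#' @export
phase_scan <- function(m, N_T_grid, size_grid, reps = 5, seed = NULL,
                       t_end = 30, record_every = 0.5,
                       K = 50, delta = 0.1, C_locality = 0.5, ...) {
  stopifnot(length(N_T_grid) >= 2, length(size_grid) >= 2,
            all(N_T_grid == round(N_T_grid)), all(N_T_grid >= 0),
            all(size_grid > 0))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (s in size_grid) {
    for (N in N_T_grid) {
      mm <- utils::modifyList(m, list(N_T = N, V = m$V * s, L = m$L * s))
      class(mm) <- "polarity_model"
      row <- tryCatch({
        d <- derive_constants(mm)
        rb <- regime_bounds(mm, K = K, delta = delta,
                            C_locality = C_locality)
        runs <- simulate(mm, nsim = reps, t_end = t_end,
                         record_every = record_every, ...)
        call <- classify_regime(mm, runs)
        expected <- if (d$R0 <= 1) "OFF"
          else if (rb$single_clan_bound_ok && rb$locality_bound_ok) "POLARIZED"
          else NA_character_
        data.frame(N_T = N, size = s, label = call$label,
                   expected = expected,
                   R0 = d$R0, stringsAsFactors = FALSE)
      }, error = function(e) {
        warning("phase_scan cell (N_T = ", N, ", size = ", s, ") failed: ",
                conditionMessage(e), call. = FALSE)
        data.frame(N_T = N, size = s, label = NA_character_,
                   expected = NA_character_, R0 = NA_real_,
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  decided <- !is.na(out$expected) & !is.na(out$label)
  attr(out, "agreement") <- if (any(decided)) {
    mean(out$label[decided] == out$expected[decided])
  } else {
    NA_real_
  }
  class(out) <- c("phase_diagram", "data.frame")
  out
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat("phase diagram (", nrow(x), "cells ); agreement with analytic overlay:",
      format(attr(x, "agreement")), "\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.phase_diagram <- function(x, ...) {
  labs <- c(OFF = 1, POLARIZED = 2, MULTI_CLAN = 3, HOMOGENEOUS_ON = 4)
  z <- matrix(labs[x$label], nrow = length(unique(x$N_T)))
  graphics::image(x = sort(unique(x$N_T)), y = sort(unique(x$size)), z = z,
                  xlab = expression(N[T]), ylab = "size factor",
                  col = c("grey85", "firebrick", "orange", "steelblue"),
                  zlim = c(1, 4), ...)
  invisible(x)
}
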