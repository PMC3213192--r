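#' Run configuration objects
#'
#' A `run_config` bundles everything needed to reproduce a simulation run:
#' the model parameters, the schedule (duration, recording interval,
#' perturbation events), the initial condition and the seed. Configurations
#' round-trip losslessly through JSON ([write_run_config()] /
#' [read_run_config()]); unknown keys in a file are rejected loudly.
#'
#' @param m a `polarity_model`.
#' @param schedule a [make_schedule()] object.
#' @param membrane_fraction,n_clans initial condition (see [init_state()]).
#' @param seed integer seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(m, schedule = make_schedule(60), membrane_fraction = 0.1,
                       n_clans = 50, seed = 1L) {
  validate_params(m)
  stopifnot(inherits(schedule, "sim_schedule"))
  structure(list(params = m, schedule = schedule,
                 membrane_fraction = membrane_fraction,
                 n_clans = as.integer(n_clans), seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path file path for the JSON configuration.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$params <- unclass(x$params)
  if (!is.finite(x$params$D_c)) x$params$D_c <- "Inf"
  x$schedule <- unclass(x$schedule)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  allowed <- c("params", "schedule", "membrane_fraction", "n_clans", "seed")
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  for (key in allowed) {
    if (is.null(x[[key]])) stop("config key missing: ", key, call. = FALSE)
  }
  p <- x$params
  p_allowed <- c("k_off", "k_on", "k_fb", "V", "V_on", "V_fb", "N_T",
                 "D_m", "D_c", "geometry", "L")
  extra <- setdiff(names(p), p_allowed)
  if (length(extra)) {
    stop("unknown config keys under params: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (identical(p$D_c, "Inf")) p$D_c <- Inf
  m <- do.call(polarity_model, p)
  sch <- x$schedule
  events <- lapply(sch$events, function(e) {
    switch(e$type,
      reseed = evt_reseed(e$time, e$fraction_cytosol,
                          e$membrane_window_fraction),
      add_cytosol = evt_add_cytosol(e$time, e$count),
      remove_cytosol = evt_remove_cytosol(e$time, e$count),
      stop("unknown event type in config: ", e$type, call. = FALSE))
  })
  run_config(m,
             make_schedule(sch$t_end, events, sch$record_every),
             membrane_fraction = x$membrane_fraction,
             n_clans = x$n_clans, seed = x$seed)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config: seed =", x$seed, "\n")
  print(x$params)
  cat(sprintf("  schedule: t_end = %g min, record_every = %g, %d event(s)\n",
              x$schedule$t_end, x$schedule$record_every,
              length(x$schedule$events)))
  invisible(x)
}

#' Execute a run configuration
#'
#' @param config a `run_config`.
#' @param record `"full"` or `"counts"`.
#' @return a `polarity_traj`.
#' @export
run_config_simulate <- function(config, record = "full") {
  simulate(config$params, nsim = 1, seed = config$seed,
           schedule = config$schedule,
           membrane_fraction = config$membrane_fraction,
           n_clans = config$n_clans, record = record)
}

#' Small deterministic fixture trajectories
#'
#' Generates tiny canned runs (at most 200 molecules, at most 2 simulated
#' minutes) with known qualitative structure, for tests and examples.
#' Scenarios: `"off_state"` (membrane empty throughout), `"two_clans"`
#' (exactly two clans initially), `"polarized"` (final state passes
#' [detect_cluster()]), `"homogeneous"` (occupied, spatially uniform
#' membrane).
#'
#' @param scenario one of the four tags above.
#' @param seed integer seed. Default 1.
#' @return a `polarity_traj`.
#' @export
make_fixture <- function(scenario = c("off_state", "polarized", "homogeneous",
                                      "two_clans"), seed = 1) {
  scenario <- match.arg(scenario)
  switch(scenario,
    off_state = {
      m <- polarity_model(N_T = 100, k_on = 0)
      simulate(m, seed = seed, t_end = 1, record_every = 0.05,
               membrane_fraction = 0)
    },
    two_clans = {
      m <- polarity_model(N_T = 100, k_on = 0, k_fb = 0.09)
      simulate(m, seed = seed, t_end = 0.5, record_every = 0.05,
               membrane_fraction = 0.5, n_clans = 2)
    },
    polarized = {
      m <- polarity_model(N_T = 200, k_off = 0.5, k_on = 0, k_fb = 1e-4,
                          D_m = 1e-4)
      sch <- make_schedule(1, list(evt_reseed(0.05, 0.9, 0.1)),
                           record_every = 0.05)
      simulate(m, seed = seed, schedule = sch, membrane_fraction = 0)
    },
    homogeneous = {
      m <- polarity_model(N_T = 200, k_off = 0.1, k_on = 0, k_fb = 1e-4)
      simulate(m, seed = seed, t_end = 0.5, record_every = 0.05,
               membrane_fraction = 1)
    })
}

#' Write / read a trajectory as columnar text
#'
#' Plain-text trajectory container: a JSON header line embedding the exact
#' model parameters, seed and step size, followed by a tab-separated long
#' table with one row per membrane molecule per record (records with an
#' empty membrane keep one row with missing position). Round-trips through
#' [read_trajectory()].
#'
#' @param traj a `polarity_traj` recorded with positions.
#' @param path output file path.
#' @export
write_trajectory <- function(traj, path) {
  if (is.null(traj$positions)) {
    stop("trajectory was recorded with record = 'counts'; nothing to write",
         call. = FALSE)
  }
  meta <- list(params = {
    p <- unclass(traj$params)
    if (!is.finite(p$D_c)) p$D_c <- "Inf"
    p
  }, seed = traj$seed, dt = traj$dt)
  header <- paste0("# neutraldrift trajectory v1 ",
                   jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  rows <- lapply(seq_along(traj$t), function(i) {
    n <- traj$N_m[i]
    data.frame(rec = i, t = traj$t[i], N_c = traj$N_c[i], N_m = n,
               N_T = traj$N_T[i], n_clans = traj$n_clans[i],
               pos = if (n > 0) traj$positions[[i]] else NA_real_,
               clan = if (n > 0) traj$clan_ids[[i]] else NA_integer_)
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "# neutraldrift trajectory v1 ")) {
    stop("not a neutraldrift trajectory file: ", path, call. = FALSE)
  }
  meta <- jsonlite::fromJSON(sub("^# neutraldrift trajectory v1 ", "", header))
  if (identical(meta$params$D_c, "Inf")) meta$params$D_c <- Inf
  m <- do.call(polarity_model, meta$params)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1)
  recs <- split(tab, tab$rec)
  ord <- order(as.integer(names(recs)))
  recs <- recs[ord]
  first <- function(col) vapply(recs, function(r) r[[col]][1], numeric(1))
  out <- list(t = unname(first("t")),
              N_c = as.integer(unname(first("N_c"))),
              N_m = as.integer(unname(first("N_m"))),
              N_T = as.integer(unname(first("N_T"))),
              n_clans = as.integer(unname(first("n_clans"))),
              positions = lapply(recs, function(r) {
                if (r$N_m[1] == 0) numeric(0) else r$pos
              }),
              clan_ids = lapply(recs, function(r) {
                if (r$N_m[1] == 0) integer(0) else as.integer(r$clan)
              }),
              params = m, seed = meta$seed, dt = meta$dt)
  names(out$positions) <- NULL
  names(out$clan_ids) <- NULL
  class(out) <- "polarity_traj"
  out
}
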