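# Time stepping: configuration, the per-step event/solve loop, and the
# trajectory container.

#' Simulation configuration
#'
#' Thresholds are fractions of the current mean cell diameter D.  Defaults
#' follow common practice for this model family: edges exchange neighbours
#' when shorter than 2.5% of D, new post-exchange edges are 3.75% of D (long
#' enough that the exchange does not immediately reverse), polyline segments
#' are kept between 2.5% and 25% of D (which yields roughly 2-3 intermediate
#' nodes per edge for near-isotropic cells).
#'
#' @param dt time increment; `NULL` (the default) selects a stable value
#'   adaptively every step from the overdamped stability bound
#'   `dt < k * L / gamma` evaluated over all segments (dashpot coefficient k
#'   of the segment's end nodes, segment length L, tension gamma), scaled by
#'   `dt_safety`.  Elapsed simulated time is accumulated from the actual
#'   increments.
#' @param n_steps maximum number of steps.
#' @param t1_threshold_frac neighbour-exchange length threshold delta / D.
#' @param post_t1_length_frac length of a freshly created edge / D; must
#'   exceed `t1_threshold_frac`.
#' @param seg_max_frac,seg_min_frac polyline segment length bounds / D.
#' @param embargo_steps steps a fresh edge is protected from re-exchange.
#' @param mode `"polyline"` (all edges segmented) or `"monoline"`
#'   (cell-cell edges stay single straight rods).
#' @param seed integer seed recorded with the run.
#' @param snapshot_stride record every `snapshot_stride`-th step (plus the
#'   first and last).
#' @param stationarity_tol,stationarity_window the run stops early once the
#'   largest nodal displacement per step stays below
#'   `stationarity_tol * D` for `stationarity_window` consecutive steps.
#' @param clamp_frac per-step displacement clamp as a fraction of the
#'   minimum segment length (see [advance_step()]).
#' @param dt_safety safety factor for the automatic `dt`.
#' @return an object of class `polycell_config`.
#' @export
sim_config <- function(dt = NULL, n_steps = 5000L,
                       t1_threshold_frac = 0.025,
                       post_t1_length_frac = 0.0375,
                       seg_max_frac = 0.25, seg_min_frac = 0.025,
                       embargo_steps = 0L,
                       mode = c("polyline", "monoline"),
                       seed = 1L, snapshot_stride = 10L,
                       stationarity_tol = 1e-5, stationarity_window = 50L,
                       clamp_frac = 0.4, dt_safety = 0.3) {
  mode <- match.arg(mode)
  cfg <- list(dt = dt, n_steps = as.integer(n_steps),
              t1_threshold_frac = t1_threshold_frac,
              post_t1_length_frac = post_t1_length_frac,
              seg_max_frac = seg_max_frac, seg_min_frac = seg_min_frac,
              embargo_steps = as.integer(embargo_steps), mode = mode,
              seed = as.integer(seed),
              snapshot_stride = as.integer(snapshot_stride),
              stationarity_tol = stationarity_tol,
              stationarity_window = as.integer(stationarity_window),
              clamp_frac = clamp_frac, dt_safety = dt_safety)
  validate_config(cfg)
  structure(cfg, class = "polycell_config")
}

#' @keywords internal
validate_config <- function(cfg) {
  bad <- character(0L)
  if (!is.null(cfg$dt) && (!is.finite(cfg$dt) || cfg$dt <= 0))
    bad <- c(bad, "dt must be positive")
  if (cfg$seg_min_frac >= cfg$seg_max_frac)
    bad <- c(bad, "seg_min_frac must be smaller than seg_max_frac")
  if (cfg$post_t1_length_frac <= cfg$t1_threshold_frac)
    bad <- c(bad, "post_t1_length_frac must exceed t1_threshold_frac")
  if (cfg$t1_threshold_frac <= 0) bad <- c(bad, "t1_threshold_frac must be positive")
  if (cfg$n_steps < 0L) bad <- c(bad, "n_steps must be non-negative")
  if (cfg$embargo_steps < 0L) bad <- c(bad, "embargo_steps must be non-negative")
  if (length(bad)) stop("invalid configuration: ", paste(bad, collapse = "; "))
  invisible(cfg)
}

#' Automatic stable time increment for a tissue
#'
#' Overdamped explicit geometry updates are stable when
#' `dt < k * L / gamma` for the smallest nodal dashpot coefficient k,
#' shortest admissible segment L and largest tension; a safety factor is
#' applied.
#' @param ts a tissue. @param config a [sim_config()].
#' @return time increment.
#' @export
auto_dt <- function(ts, config) {
  coef <- assemble_viscous_matrix(ts)
  kmin <- min(coef[coef > 0])
  gmax <- max(vapply(active_edges(ts), function(ei) ts$edges[[ei]]$tension,
                     numeric(1L)), 1e-12)
  lmin <- config$seg_min_frac * mean_cell_diameter(ts)
  config$dt_safety * kmin * lmin / gmax
}

#' Run a simulation
#'
#' Advances the tissue through the per-step cycle coarsen -> T1 exchange ->
#' refine -> viscous solve, recording snapshots at the configured stride and
#' a log of all topological events.  The run ends at `n_steps` or earlier
#' once motion has ceased (see [sim_config()]).
#'
#' @param ts initial tissue.
#' @param config a [sim_config()].
#' @param tensions optional [tension_table()]; required for runs where T1
#'   exchanges can create interface classes absent from the initial tissue.
#' @return an object of class `polycell_trajectory`: list with `snapshots`
#'   (tissues), `snapshot_steps`, `times`, `events`, `status` (one of
#'   `"stationary"`, `"max_steps"`, `"error"`), `config`, and `scenario`
#'   metadata when launched through [run_pair()].
#' @export
run_simulation <- function(ts, config, tensions = NULL) {
  stopifnot(inherits(ts, "polycell_tissue"))
  if (!inherits(config, "polycell_config")) config <- do.call(sim_config, config)
  snaps <- list(ts)
  snap_steps <- 0L
  times <- 0
  events <- list()
  status <- "max_steps"
  quiet <- 0L
  t_now <- 0
  step <- 0L
  # areas are constrained to their targets, so the mean diameter is constant
  # for threshold purposes; refresh it occasionally in case cells disappear
  D <- mean_cell_diameter(ts)
  while (step < config$n_steps) {
    step <- step + 1L
    res <- tryCatch({
      rc <- refine_and_coarsen(ts, config, step, refine = FALSE, D = D)
      ev1 <- rc$events
      t1 <- apply_t1_exchanges(rc$tissue, config, step, tensions, D = D)
      ev2 <- t1$events
      rf <- refine_and_coarsen(t1$tissue, config, step, coarsen = FALSE, D = D)
      ev3 <- rf$events
      pg <- apply_pinch_guard(rf$tissue, config, step, D = D)
      ev4 <- pg$events
      sol <- advance_step(pg$tissue, config, D = D)
      ev <- rbind(ev1, ev2, ev3, ev4)
      list(tissue = sol$tissue, max_disp = sol$max_disp, dt = sol$dt,
           events = ev)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status <- "error"
      attr(status, "message") <- conditionMessage(res)
      break
    }
    ts <- res$tissue
    t_now <- t_now + res$dt
    if (!is.null(res$events)) events[[length(events) + 1L]] <- res$events
    if (step %% 200L == 0L) D <- mean_cell_diameter(ts)
    if (res$max_disp < config$stationarity_tol * D) quiet <- quiet + 1L
    else quiet <- 0L
    last <- quiet >= config$stationarity_window || step == config$n_steps
    if (step %% config$snapshot_stride == 0L || last) {
      snaps[[length(snaps) + 1L]] <- ts
      snap_steps <- c(snap_steps, step)
      times <- c(times, t_now)
    }
    if (quiet >= config$stationarity_window) { status <- "stationary"; break }
  }
  structure(list(snapshots = snaps, snapshot_steps = snap_steps,
                 times = times,
                 events = if (length(events)) do.call(rbind, events)
                          else empty_events(),
                 status = status, config = config, scenario = NA_character_),
            class = "polycell_trajectory")
}

#' Terminal tissue of a trajectory
#' @param traj a trajectory.
#' @return the last recorded tissue.
#' @export
terminal_tissue <- function(traj) traj$snapshots[[length(traj$snapshots)]]

#' @export
print.polycell_trajectory <- function(x, ...) {
  cat("polycell trajectory:", length(x$snapshots), "snapshots,",
      x$snapshot_steps[length(x$snapshot_steps)], "steps, status:",
      x$status, "\n")
  if (!is.na(x$scenario)) cat("  scenario:", x$scenario, "\n")
  cat("  mode:", x$config$mode, "| dt:",
      if (is.null(x$config$dt)) "adaptive" else signif(x$config$dt, 4L),
      "| events:", nrow(x$events), "\n")
  invisible(x)
}
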