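# Trajectory persistence as line-delimited structured text.
#
# Snapshot schema (one record per line, whitespace separated, ids 0-based):
#   polycell-snapshot 1
#   time <t> step <k>
#   medium <label>
#   node <id> <x> <y> <junction|intermediate>
#   edge <id> <left> <right> <tension> <embargo> <connector> <chain ids...>
#   cell <id> <type> <target_area> <mu> <loop tokens...>
# Region fields use `M` for the medium and 0-based cell ids otherwise.
# Loop tokens are `f<edge-id>` (traverse in chain order) or `r<edge-id>`
# (reversed); loops are counter-clockwise.  Coordinates are written with
# %.17g so a write/read round trip reproduces the tissue exactly.

fmt_g <- function(x) sprintf("%.17g", x)

#' Write one tissue snapshot to a text file
#' @param ts a tissue. @param file path. @param time,step metadata.
#' @export
write_snapshot <- function(ts, file, time = 0, step = 0L) {
  con <- file(file, "w")
  on.exit(close(con))
  out <- c("polycell-snapshot 1",
           paste("time", fmt_g(time), "step", step),
           paste("medium", ts$medium_label))
  reg <- function(r) if (r == MEDIUM) "M" else as.character(r - 1L)
  for (nid in active_nodes(ts))
    out <- c(out, paste("node", nid - 1L, fmt_g(ts$pos[nid, 1L]),
                        fmt_g(ts$pos[nid, 2L]),
                        c("junction", "intermediate")[ts$kind[nid]]))
  for (ei in active_edges(ts)) {
    e <- ts$edges[[ei]]
    out <- c(out, paste("edge", ei - 1L, reg(e$rl), reg(e$rr),
                        fmt_g(e$tension), e$embargo,
                        as.integer(isTRUE(e$connector)),
                        paste(e$chain - 1L, collapse = " ")))
  }
  for (ci in active_cells(ts)) {
    cl <- ts$cells[[ci]]
    toks <- ifelse(cl$loop > 0L, paste0("f", cl$loop - 1L),
                   paste0("r", -cl$loop - 1L))
    out <- c(out, paste("cell", ci - 1L, cl$type, fmt_g(cl$target_area),
                        fmt_g(cl$mu), paste(toks, collapse = " ")))
  }
  writeLines(out, con)
  invisible(file)
}

#' Read a tissue snapshot written by [write_snapshot()]
#' @param file path.
#' @return list with elements `tissue`, `time`, `step`.
#' @export
read_snapshot <- function(file) {
  lines <- readLines(file)
  if (!startsWith(lines[1L], "polycell-snapshot"))
    stop("not a polycell snapshot file: ", file)
  toks <- strsplit(lines, " +")
  hdr <- toks[[2L]]
  time <- as.numeric(hdr[2L]); step <- as.integer(hdr[4L])
  medium_label <- toks[[3L]][2L]
  tag <- vapply(toks, `[[`, character(1L), 1L)
  nrec <- toks[tag == "node"]
  ids <- vapply(nrec, function(x) as.integer(x[2L]) + 1L, integer(1L))
  nmax <- max(ids)
  pos <- matrix(NA_real_, nmax, 2L)
  kind <- rep(NA_integer_, nmax)
  for (x in nrec) {
    i <- as.integer(x[2L]) + 1L
    pos[i, ] <- as.numeric(x[3:4])
    kind[i] <- if (x[5L] == "junction") 1L else 2L
  }
  reg <- function(s) if (s == "M") MEDIUM else as.integer(s) + 1L
  erec <- toks[tag == "edge"]
  emax <- max(vapply(erec, function(x) as.integer(x[2L]) + 1L, integer(1L)))
  edges <- vector("list", emax)
  for (x in erec) {
    i <- as.integer(x[2L]) + 1L
    edges[[i]] <- list(chain = as.integer(x[-(1:7)]) + 1L,
                       rl = reg(x[3L]), rr = reg(x[4L]),
                       tension = as.numeric(x[5L]),
                       embargo = as.integer(x[6L]),
                       connector = x[7L] == "1")
  }
  crec <- toks[tag == "cell"]
  cmax <- max(vapply(crec, function(x) as.integer(x[2L]) + 1L, integer(1L)))
  cells <- vector("list", cmax)
  for (x in crec) {
    i <- as.integer(x[2L]) + 1L
    cells[[i]] <- list(type = x[3L], target_area = as.numeric(x[4L]),
                       mu = as.numeric(x[5L]))
  }
  ts <- new_tissue(pos, kind, edges, cells, medium_label)
  list(tissue = ts, time = time, step = step)
}

#' Write a trajectory to a directory
#'
#' Writes `snapshot_<step>.txt` files, the event log `events.tsv`, the
#' metrics table `metrics.csv` and a `manifest.yaml` echoing the
#' configuration, seed, per-kind event counts and termination status --
#' together these suffice to reproduce and audit the run.
#'
#' @param traj a trajectory. @param dir output directory (created).
#' @param interface_class forwarded to [aggregate_metrics()].
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir, interface_class = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(traj$snapshots))
    write_snapshot(traj$snapshots[[k]],
                   file.path(dir, sprintf("snapshot_%06d.txt",
                                          traj$snapshot_steps[k])),
                   time = traj$times[k], step = traj$snapshot_steps[k])
  utils::write.table(traj$events, file.path(dir, "events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  am <- aggregate_metrics(traj, interface_class,
                          angle_method = if (traj$config$mode == "monoline")
                            "nearest_segment" else "arc_tangent")
  utils::write.csv(am, file.path(dir, "metrics.csv"), row.names = FALSE)
  manifest <- list(
    package = "polycell",
    version = as.character(utils::packageVersion("polycell")),
    scenario = if (is.na(traj$scenario)) "custom" else traj$scenario,
    seed = traj$config$seed,
    mode = traj$config$mode,
    status = traj$status,
    steps = traj$snapshot_steps[length(traj$snapshot_steps)],
    config = unclass(traj$config),
    event_counts = as.list(table(traj$events$kind)))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a trajectory directory written by [write_trajectory()]
#' @param dir directory path.
#' @return a `polycell_trajectory` (with config and scenario restored from
#'   the manifest).
#' @export
read_trajectory <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  files <- sort(list.files(dir, pattern = "^snapshot_.*\\.txt$",
                           full.names = TRUE))
  snaps <- lapply(files, read_snapshot)
  ev_file <- file.path(dir, "events.tsv")
  events <- if (file.exists(ev_file))
    utils::read.delim(ev_file, stringsAsFactors = FALSE) else empty_events()
  cfg_raw <- man$config
  if (!is.null(cfg_raw$dt)) cfg_raw$dt <- as.numeric(cfg_raw$dt)
  cfg <- structure(cfg_raw, class = "polycell_config")
  structure(list(
    snapshots = lapply(snaps, `[[`, "tissue"),
    snapshot_steps = vapply(snaps, `[[`, integer(1L), "step"),
    times = vapply(snaps, `[[`, numeric(1L), "time"),
    events = events, status = man$status, config = cfg,
    scenario = if (identical(man$scenario, "custom")) NA_character_
               else man$scenario),
    class = "polycell_trajectory")
}
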