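#' Write / read a holding-current trace as CSV + JSON sidecar
#'
#' The trace goes to `<path>` as a two-column CSV (`t_s`, `I_pA`); drug
#' events, metadata and (optionally) the generator ground truth go to a
#' JSON sidecar `<path>.json`.
#'
#' @param trace A [trace_recording()].
#' @param path CSV file path.
#' @param truth Optional [trace_ground_truth()] to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, truth = NULL) {
  stopifnot(inherits(trace, "trace_recording"))
  utils::write.csv(data.frame(t_s = trace$t, I_pA = trace$I), path,
                   row.names = FALSE)
  side <- list(events = trace$events, meta = trace$meta)
  if (!is.null(truth)) {
    gt <- unclass(truth)
    gt$component_shifts <- as.list(gt$component_shifts)
    side$ground_truth <- gt
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trace_csv
#' @return `read_trace_csv()`: a list with `trace` and (if present in
#'   the sidecar) `truth`.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  side_path <- paste0(path, ".json")
  events <- NULL; meta <- list(); truth <- NULL
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!is.null(side$events) && length(side$events))
      events <- as.data.frame(side$events)
    if (!is.null(side$meta)) meta <- as.list(side$meta)
    if (!is.null(side$ground_truth)) {
      gt <- side$ground_truth
      truth <- trace_ground_truth(gt$baseline_pA,
                                  unlist(gt$component_shifts),
                                  gt$ipsc_times %||% numeric(0),
                                  gt$ipsc_amplitudes %||% numeric(0),
                                  gt$noise_sd %||% 0)
    }
  }
  list(trace = trace_recording(df$t_s, df$I_pA, events, meta),
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a 9-marker skeleton as wide CSV
#'
#' Wide format: `t_s`, then `<marker>_x`, `<marker>_y`, `<marker>_z`
#' for each marker in the fixed order of [tonicgl_markers].
#'
#' @param skel A [skeleton_3d()].
#' @param path CSV file path.
#' @return `path` invisibly; `read_skeleton_csv()` returns a
#'   [skeleton_3d()].
#' @export
write_skeleton_csv <- function(skel, path) {
  stopifnot(inherits(skel, "skeleton_3d"))
  cols <- list(t_s = skel$t)
  for (m in tonicgl_markers)
    for (c3 in c("x", "y", "z"))
      cols[[paste0(m, "_", c3)]] <- skel$pos[, m, c3]
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_skeleton_csv
#' @export
read_skeleton_csv <- function(path) {
  df <- utils::read.csv(path)
  n <- nrow(df)
  pos <- array(NA_real_, c(n, 9, 3))
  for (mi in seq_along(tonicgl_markers))
    for (ci in 1:3)
      pos[, mi, ci] <- df[[paste0(tonicgl_markers[mi], "_",
                                  c("x", "y", "z")[ci])]]
  skeleton_3d(df$t_s, pos)
}

#' Write / read spike data as CSV
#'
#' Event-list CSV with columns `cell_id` (1-based) and `t_s`; the
#' population size and duration are kept in a JSON sidecar.
#'
#' @param spikes A [spike_data()].
#' @param path CSV file path.
#' @return `path` invisibly; `read_spikes_csv()` returns a
#'   [spike_data()].
#' @export
write_spikes_csv <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_data"))
  utils::write.csv(data.frame(cell_id = spikes$cell, t_s = spikes$time),
                   path, row.names = FALSE)
  jsonlite::write_json(list(n_cells = spikes$n_cells,
                            duration = spikes$duration,
                            population = spikes$population),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  df <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  spike_data(df$cell_id, df$t_s, side$n_cells, side$duration,
             side$population %||% "")
}
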