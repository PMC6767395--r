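#' Write / read a session bundle directory
#'
#' Serializes a `ca1_session` as a directory of portable files:
#' `tracking.csv` (t, x, y), `spikes.csv` (unit_id, cell_class, t),
#' `epochs.csv`, `states.csv`, `arena.json`, and -- when present --
#' `lfp.rds` (the LFP matrix is numeric and large, so it is stored as a
#' compressed R object) and `ground_truth.rds`.
#'
#' @param session a `ca1_session`
#' @param path directory to create
#' @export
write_session_bundle <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session$tracking, file.path(path, "tracking.csv"),
                   row.names = FALSE)
  sp <- do.call(rbind, lapply(seq_along(session$spike_times), function(i)
    if (length(session$spike_times[[i]]))
      data.frame(unit_id = i,
                 cell_class = session$units$cell_class[i],
                 t = session$spike_times[[i]])))
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE)
  utils::write.csv(session$epochs, file.path(path, "epochs.csv"),
                   row.names = FALSE)
  utils::write.csv(session$states, file.path(path, "states.csv"),
                   row.names = FALSE)
  jsonlite::write_json(session$arena, file.path(path, "arena.json"),
                       auto_unbox = TRUE)
  if (!is.null(session$lfp)) saveRDS(session$lfp, file.path(path, "lfp.rds"))
  saveRDS(session$ground_truth, file.path(path, "ground_truth.rds"))
  invisible(path)
}

#' @rdname write_session_bundle
#' @param path bundle directory
#' @return a `ca1_session`
#' @export
read_session_bundle <- function(path) {
  tracking <- utils::read.csv(file.path(path, "tracking.csv"))
  arena <- jsonlite::read_json(file.path(path, "arena.json"),
                               simplifyVector = TRUE)
  attr(tracking, "arena") <- arena
  sp <- utils::read.csv(file.path(path, "spikes.csv"))
  n_units <- max(sp$unit_id)
  spike_times <- lapply(seq_len(n_units), function(i) sp$t[sp$unit_id == i])
  units <- unique(sp[, c("unit_id", "cell_class")])
  units <- units[order(units$unit_id), ]
  lfp_path <- file.path(path, "lfp.rds")
  gt_path <- file.path(path, "ground_truth.rds")
  structure(list(
    tracking = tracking, units = units, spike_times = spike_times,
    lfp = if (file.exists(lfp_path)) readRDS(lfp_path) else NULL,
    epochs = utils::read.csv(file.path(path, "epochs.csv")),
    states = utils::read.csv(file.path(path, "states.csv")),
    arena = arena,
    ground_truth = if (file.exists(gt_path)) readRDS(gt_path) else NULL),
    class = "ca1_session")
}
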