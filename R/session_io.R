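# Plain-text session serialization: trials.tsv, eye/trial_<id>.csv,
# spikes/cell_<id>.tsv, session.yaml.

#' Write a session to disk
#'
#' Serializes a `pc_session` as plain text: `trials.tsv` (one row per
#' trial), `eye/trial_<id>.csv` (`time_s,x_deg,y_deg`),
#' `spikes/<cell_id>.tsv` (`time_s`, `type` in `{SS, CS}`), and
#' `session.yaml` (seed, kinematics configuration, per-cell ground truth).
#' All times are seconds from session start.
#'
#' @param session a `pc_session`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(file.path(dir, "eye"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "spikes"), showWarnings = FALSE)
  write.table(session$trials, file.path(dir, "trials.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  for (tr in session$eye) {
    df <- data.frame(time_s = tr$time, x_deg = tr$x, y_deg = tr$y)
    write.table(df, file.path(dir, "eye",
                              sprintf("trial_%04d.csv", tr$trial_id)),
                sep = ",", row.names = FALSE, quote = FALSE)
  }
  for (cell in session$cells) {
    df <- rbind(
      data.frame(time_s = cell$ss_times,
                 type = rep("SS", length(cell$ss_times))),
      data.frame(time_s = cell$cs_times,
                 type = rep("CS", length(cell$cs_times))))
    df <- df[order(df$time_s), ]
    write.table(df, file.path(dir, "spikes",
                              paste0(cell$cell_id, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  meta <- list(
    seed = session$seed,
    sampling_rate = session$kin$sampling_rate,
    kin = lapply(unclass(session$kin), function(x)
      if (is.numeric(x)) as.list(x) else x),
    cells = lapply(session$cells, function(cell) {
      gt <- cell$ground_truth
      gt_fields <- if (!is.null(gt)) unclass(gt) else list()
      gt_fields$region <- NULL
      c(list(cell_id = cell$cell_id, region = cell$region,
             duration = cell$duration), gt_fields)
    })
  )
  yaml::write_yaml(meta, file.path(dir, "session.yaml"))
  invisible(dir)
}

#' Read a session from disk
#'
#' Inverse of [write_session()]. Ground-truth cell configurations are
#' restored from `session.yaml` when present.
#'
#' @param dir session directory.
#' @return a `pc_session`.
#' @export
read_session <- function(dir) {
  trials <- read.delim(file.path(dir, "trials.tsv"),
                       stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "session.yaml"))
  fs <- meta$sampling_rate
  eye <- lapply(trials$trial_id, function(id) {
    df <- read.csv(file.path(dir, "eye", sprintf("trial_%04d.csv", id)))
    structure(list(time = df$time_s, x = df$x_deg, y = df$y_deg,
                   sampling_rate = fs, speed = NULL, acceleration = NULL,
                   preprocessed = FALSE, trial_id = id),
              class = "eye_trace")
  })
  cells <- lapply(meta$cells, function(cm) {
    df <- read.delim(file.path(dir, "spikes", paste0(cm$cell_id, ".tsv")),
                     stringsAsFactors = FALSE)
    structure(list(cell_id = cm$cell_id, region = cm$region,
                   ss_times = df$time_s[df$type == "SS"],
                   cs_times = df$time_s[df$type == "CS"],
                   trials = trials, duration = cm$duration,
                   ground_truth = NULL),
              class = "cell_recording")
  })
  kin <- meta$kin
  for (nm in c("rt_mean", "rt_sd", "amp_mean", "amp_sd", "dur_mean",
               "dur_sd")) {
    kin[[nm]] <- unlist(kin[[nm]])
  }
  kin <- do.call(kinematics_config, kin[names(kin) %in%
                                          names(formals(kinematics_config))])
  structure(list(trials = trials, eye = eye, cells = cells,
                 kin = kin, seed = meta$seed),
            class = "pc_session")
}
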