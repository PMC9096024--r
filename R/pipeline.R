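# Pipeline orchestration: simulate -> detect -> classify -> metrics ->
# reciprocity -> dpca, with exclusion bookkeeping and a summary report.

#' Default pipeline configuration
#'
#' Collects every tunable threshold of the analysis chain under a named key
#' with its conventional default: 6 SD detection threshold, sigma = 50 ms SS
#' kernel (25 ms for CS), R^2 > 0.75 ramping rule, 0.5 Hz CS inclusion,
#' +/-3 SD CS modulation band, 100 ms dPCA bins, 100 decoder iterations,
#' 5-trial inclusion rule, p < 0.05, 6 deg spatial window, 100 ms
#' reaction-time floor, 350 Hz sampling, 20 ms Savitzky-Golay window.
#'
#' @param seed session seed.
#' @param n_blocks number of 16-trial blocks to simulate.
#' @param kin a [kinematics_config()].
#' @param pop_spec population specification for [generate_population()];
#'   the default simulates a small mixed medial/lateral population.
#' @param out_dir output directory (`NULL` keeps everything in memory).
#' @return a named list of configuration entries.
#' @export
pipeline_config <- function(seed = 1, n_blocks = 10,
                            kin = kinematics_config(),
                            pop_spec = default_pop_spec(),
                            out_dir = NULL) {
  list(
    seed = seed, n_blocks = n_blocks, kin = kin, pop_spec = pop_spec,
    out_dir = out_dir,
    threshold_mult = 6, low_mult = 1,
    sigma_ss = 0.050, sigma_cs = 0.025,
    ramp_r2 = 0.75, cs_min_rate = 0.5, cs_n_sd = 3,
    dpca_bin = 0.100, dpca_window = c(-0.6, 0.8), dpca_lambda = 0,
    n_iter = 100, n_shuffles = 100,
    min_trials = 5, alpha = 0.05,
    target_window_deg = 6, rt_floor = 0.100,
    sampling_rate = 350, sg_window = 0.020
  )
}

#' A small default synthetic population
#'
#' Two facilitation, two suppression, and one ramping cell per region, with
#' suppression cells at a higher baseline than facilitation cells (the
#' upbound/downbound arrangement).
#'
#' @return a `pop_spec` list for [generate_population()].
#' @export
default_pop_spec <- function() {
  mk <- function(region) list(
    cell_config(region, baseline_rate_ss = 55,
                instruction_profile = "facilitation", instruction_gain = 20,
                saccade_profile = "facilitation", saccade_gain = 30,
                cs_gain_saccade = 1),
    cell_config(region, baseline_rate_ss = 56,
                saccade_profile = "facilitation", saccade_gain = 25,
                condition_gain = 1.2),
    cell_config(region, baseline_rate_ss = 65,
                instruction_profile = "suppression", instruction_gain = 20,
                saccade_profile = "suppression", saccade_gain = 25),
    cell_config(region, baseline_rate_ss = 68,
                saccade_profile = "suppression", saccade_gain = 30,
                cs_gain_instruction = 1),
    cell_config(region, baseline_rate_ss = 60,
                instruction_profile = "ramp", ramp_slope = 150,
                saccade_profile = "facilitation", saccade_gain = 20)
  )
  list(medial = mk("medial"), lateral = mk("lateral"))
}

#' Run the full analysis pipeline
#'
#' Simulates a session, runs the detection chain, classifies every cell,
#' computes population metrics, CS-SS reciprocity, and dPCA decoding, and
#' returns a machine-readable report with exclusion counts at every filter.
#' With `out_dir` set, all stage outputs are written as TSV/JSON plus the
#' serialized session.
#'
#' @param config a [pipeline_config()].
#' @return a list (class `pcsacc_report`) with elements `session`,
#'   `classification`, `metrics`, `reciprocity`, `dpca`, and `counts`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  session <- generate_population(config$pop_spec, config$kin,
                                 config$n_blocks, config$seed)
  session <- detect_session(session,
                            threshold_mult = config$threshold_mult,
                            low_mult = config$low_mult)
  tr <- session$trials
  counts <- list(
    n_trials = nrow(tr),
    n_correct = sum(tr$outcome == "correct"),
    n_error = sum(tr$outcome == "error"),
    n_excluded_rt = sum(tr$outcome == "excluded"),
    n_cells = length(session$cells)
  )
  if (counts$n_correct == 0L) {
    report <- list(session = session, classification = NULL, metrics = NULL,
                   reciprocity = NULL, dpca = NULL, counts = counts,
                   status = "no correct trials; downstream stages skipped")
    class(report) <- "pcsacc_report"
    return(report)
  }
  cls <- classify_population(session)
  counts$n_included <- sum(cls$included[cls$condition == "pro"])
  counts$n_saccade_related <- sum(cls$saccade_related[cls$condition == "pro"])
  analysed <- Filter(function(cell) check_inclusion(cell,
                                                    config$min_trials),
                     session$cells)
  metrics <- if (length(analysed)) {
    data.frame(
      cell_id = vapply(analysed, function(x) x$cell_id, character(1)),
      region = vapply(analysed, function(x) x$region, character(1)),
      modulation_ratio = vapply(analysed, modulation_ratio, numeric(1)),
      baseline_rate = vapply(analysed, baseline_rate, numeric(1)),
      stringsAsFactors = FALSE)
  } else NULL
  recip <- reciprocity_table(analysed, sigma_cs = config$sigma_cs,
                             sigma_ss = config$sigma_ss)
  counts$n_cs_included <- if (is.null(recip)) 0L else
    length(unique(recip$cell_id))
  dp <- tryCatch({
    tensor <- build_tensor(session$cells, window = config$dpca_window,
                           bin = config$dpca_bin,
                           min_trials = config$min_trials)
    fit <- fit_dpca(tensor, lambda = config$dpca_lambda)
    dec <- decode_stimulus(fit, tensor, n_iter = config$n_iter,
                           n_shuffles = config$n_shuffles,
                           seed = split_seed(config$seed, 777L))
    list(marg_var = fit$marg_var,
         var_comp = lapply(fit$marginalizations, `[[`, "var_comp"),
         accuracy = dec$accuracy, significant = dec$significant,
         threshold = dec$threshold, time = dec$time,
         dropped = tensor$dropped)
  }, error = function(e) list(status = conditionMessage(e)))
  report <- list(session = session, classification = cls,
                 metrics = metrics, reciprocity = recip, dpca = dp,
                 counts = counts)
  class(report) <- "pcsacc_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_session(session, file.path(config$out_dir, "session"))
    write.table(session$trials, file.path(config$out_dir, "trials.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(session$saccades)) {
      write.table(session$saccades,
                  file.path(config$out_dir, "saccades.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    write.table(cls, file.path(config$out_dir, "cells.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    if (!is.null(metrics)) {
      write.table(metrics, file.path(config$out_dir, "metrics.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(recip)) {
      write.table(recip, file.path(config$out_dir, "recip.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(dp, file.path(config$out_dir, "dpca.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    jsonlite::write_json(counts, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.pcsacc_report <- function(x, ...) {
  cat("pcsacc pipeline report\n")
  cat(sprintf("  trials: %d (%d correct, %d error, %d excluded RT)\n",
              x$counts$n_trials, x$counts$n_correct, x$counts$n_error,
              x$counts$n_excluded_rt))
  cat(sprintf("  cells: %d (%s included, %s saccade-related)\n",
              x$counts$n_cells,
              x$counts$n_included %||% "-",
              x$counts$n_saccade_related %||% "-"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
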