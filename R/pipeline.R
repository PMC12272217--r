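# End-to-end pipeline driver: simulate -> preprocess -> RESS -> decode, any
# prefix, with a machine-readable JSON report. One master seed drives
# per-stage derived streams so stages can be reproduced in isolation.

#' Subset epochs by trial index
#'
#' @param epochs An [eeg_epochs()].
#' @param trials Integer or logical trial index.
#' @return The subsetted `eeg_epochs`.
#' @export
subset_epochs <- function(epochs, trials) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  epochs$data <- epochs$data[trials, , , drop = FALSE]
  epochs$metadata <- epochs$metadata[trials, , drop = FALSE]
  epochs
}

#' Run the frequency-tagging analysis pipeline
#'
#' Executes, in order, any prefix of: session simulation, preprocessing
#' (band-pass, bad-channel interpolation, average reference, epoching),
#' per-condition RESS fitting at both tag frequencies, and per-condition
#' left/right decoding with a permutation-calibrated null. Returns (and
#' optionally writes) a report of per-stage parameters, counts and results;
#' with a fixed config the report is reproducible bit-for-bit.
#'
#' @param config A [sim_config()]; its `seed` seeds every stage.
#' @param stages Character vector, a prefix of
#'   `c("simulate", "preprocess", "ress", "decode")`.
#' @param out_dir Optional directory for artifacts: BrainVision recording,
#'   ground-truth TSV, RESS filter JSONs, decoding TSV and `report.json`.
#' @param n_perm Permutations for the decoding null (default 200).
#' @param prune Optional list with `unmixing` and `class_scores` to run
#'   component pruning; synthetic sessions contain no simulated artifacts,
#'   so the default `NULL` skips it.
#' @param bandpass Logical; run the broadband FIR step (default TRUE).
#' @return An object of class `freqtag_report` (a nested list; also written
#'   as JSON when `out_dir` is given).
#' @examples
#' \donttest{
#' rep <- run_pipeline(sim_config(n_trials_per_condition = 10, seed = 3),
#'                     n_perm = 50)
#' rep$decode$control$mean_accuracy
#' }
#' @export
run_pipeline <- function(config = sim_config(),
                         stages = c("simulate", "preprocess", "ress",
                                    "decode"),
                         out_dir = NULL, n_perm = 200L, prune = NULL,
                         bandpass = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  all_stages <- c("simulate", "preprocess", "ress", "decode")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (!identical(stages, all_stages[seq_along(stages)]))
    stop_invalid("stages must be a prefix of simulate/preprocess/ress/decode")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  report <- list(package = "freqtag",
                 seed = config$seed,
                 config = unclass(config))
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- simulate ---
  sess <- run_stage("simulate", function() simulate_session(config))
  report$simulate <- list(
    n_trials = nrow(sess$ground_truth),
    n_conditions = length(config$conditions),
    n_channels = nrow(sess$recording$data),
    n_events = nrow(sess$recording$events),
    duration_s = ncol(sess$recording$data) / config$sfreq)
  if (!is.null(out_dir)) {
    write_brainvision(sess$recording, file.path(out_dir, "session"))
    write_ground_truth(sess, file.path(out_dir, "ground_truth.tsv"))
  }
  if (length(stages) == 1L) return(finish_report(report, out_dir))

  # --- preprocess ---
  epochs <- run_stage("preprocess", function() {
    rec <- sess$recording
    if (bandpass) rec <- bandpass_filter(rec)
    bad <- detect_bad_channels(rec)
    rec <- spherical_interpolate(rec, bad)
    rec <- rereference_average(rec)
    if (!is.null(prune))
      rec <- prune_components(rec, prune$unmixing, prune$class_scores)
    ep <- epoch_recording(rec, 0, sum(config$phase_durations))
    attr(ep, "bad_channels") <- bad
    ep
  })
  report$preprocess <- list(
    bandpass = bandpass,
    bad_channels = as.list(attr(epochs, "bad_channels")),
    n_interpolated = length(attr(epochs, "bad_channels")),
    n_pruned = if (is.null(prune)) 0L else NA_integer_,
    n_epochs = dim(epochs$data)[1],
    n_dropped = epochs$n_dropped,
    effective_rank = epochs$effective_rank)
  if (length(stages) == 2L) return(finish_report(report, out_dir))

  # --- ress: one filter per condition x tag frequency ---
  cue_onset <- config$phase_durations[["fixation"]]
  filters <- run_stage("ress", function() {
    out <- list()
    for (cond in names(config$conditions)) {
      idx <- which(epochs$metadata$condition == cond)
      for (sd in names(config$tag_freqs)) {
        f <- config$tag_freqs[[sd]]
        out[[paste(cond, sd, sep = ".")]] <-
          ress(epochs, f = f, trials = idx, cue_onset = cue_onset)
      }
    }
    out
  })
  report$ress <- list(
    n_filters = length(filters),
    target_freqs = as.list(config$tag_freqs),
    top_eigenvalues = lapply(filters, function(f) f$eigenvalues[1]))
  if (!is.null(out_dir))
    for (nm in names(filters))
      write_ress(filters[[nm]], file.path(out_dir,
                                          paste0("ress_", nm, ".json")))
  if (length(stages) == 3L) return(finish_report(report, out_dir))

  # --- decode per condition ---
  results <- run_stage("decode", function() {
    out <- list()
    for (cond in names(config$conditions)) {
      idx <- which(epochs$metadata$condition == cond)
      sub <- subset_epochs(epochs, idx)
      feats <- extract_features(
        sub, filters[[paste(cond, "left", sep = ".")]],
        filters[[paste(cond, "right", sep = ".")]],
        window = cue_onset + c(0, config$phase_durations[["cue"]]))
      out[[cond]] <- permutation_null(
        feats, n_perm = n_perm,
        seed = derive_seed(config$seed, paste0("decode_", cond)))
    }
    out
  })
  report$decode <- lapply(results, function(r) {
    list(n_trials = r$n, mean_accuracy = r$mean_accuracy,
         fold_accuracies = r$fold_accuracies,
         boundary_95 = r$boundary_95, boundary_99 = r$boundary_99,
         significant_05 = r$significant_05,
         significant_01 = r$significant_01, n_perm = r$n_perm)
  })
  if (!is.null(out_dir))
    write_decode_results(results, file.path(out_dir, "decoding.tsv"))
  finish_report(report, out_dir)
}

finish_report <- function(report, out_dir) {
  class(report) <- "freqtag_report"
  if (!is.null(out_dir))
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  report
}

#' @export
print.freqtag_report <- function(x, ...) {
  cat("<freqtag_report>\n")
  if (!is.null(x$simulate))
    cat(sprintf("  simulate: %d trials, %d channels, %.0f s\n",
                x$simulate$n_trials, x$simulate$n_channels,
                x$simulate$duration_s))
  if (!is.null(x$preprocess))
    cat(sprintf("  preprocess: %d epochs, %d interpolated, rank %d\n",
                x$preprocess$n_epochs, x$preprocess$n_interpolated,
                x$preprocess$effective_rank))
  if (!is.null(x$ress))
    cat(sprintf("  ress: %d filters\n", x$ress$n_filters))
  if (!is.null(x$decode))
    for (nm in names(x$decode))
      cat(sprintf(
        "  decode[%s]: %.1f%% (95th %.1f%%, 99th %.1f%%, p<.05 %s)\n",
        nm, x$decode[[nm]]$mean_accuracy, x$decode[[nm]]$boundary_95,
        x$decode[[nm]]$boundary_99, x$decode[[nm]]$significant_05))
  invisible(x)
}
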