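# Single-trial decoding of the attended hemifield.
#
# Features are the amplitudes of the two RESS components (13 and 15 Hz)
# over the cueing phase; a linear discriminant classifier with pooled
# within-class covariance is scored by stratified fivefold cross-validation,
# and chance level is calibrated by a 200-permutation null distribution
# whose 95th/99th percentiles give the alpha = .05/.01 significance
# boundaries.

#' Extract per-trial RESS amplitude features
#'
#' Back-projects both RESS filters on the epochs, narrow-band filters each
#' component at its own frequency, and takes the RMS amplitude over the cue
#' window as the per-trial feature.
#'
#' @param epochs An [eeg_epochs()] with `side` metadata.
#' @param filt_left,filt_right [ress()] filters at the left/right tag
#'   frequencies (13 and 15 Hz by default conventions).
#' @param window Feature window in epoch seconds (default the cue phase,
#'   `c(3, 6)`).
#' @param fwhm FWHM of the per-component narrow-band filter, Hz.
#' @return A data.frame of class `trial_features` with `amp_13`, `amp_15`
#'   (columns named `amp_<f>` after the filters' frequencies), `label`
#'   (attended side) and `condition`.
#' @export
extract_features <- function(epochs, filt_left, filt_right,
                             window = c(3, 6), fwhm = 1) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(filt_left, "ress"),
            inherits(filt_right, "ress"))
  sel <- which(epochs$times >= window[1] & epochs$times < window[2])
  if (length(sel) < 2L) stop_invalid("feature window outside the epochs")
  amp_of <- function(filt) {
    comp <- predict(filt, epochs)
    apply(comp, 1L, function(x) {
      nb <- gaussian_bandpass(x, filt$f, fwhm, epochs$sfreq)
      sqrt(mean(nb[sel]^2))
    })
  }
  out <- data.frame(a = amp_of(filt_left), b = amp_of(filt_right),
                    label = epochs$metadata$side,
                    condition = epochs$metadata$condition)
  names(out)[1:2] <- paste0("amp_", c(filt_left$f, filt_right$f))
  class(out) <- c("trial_features", "data.frame")
  out
}

# Closed-form two-class linear discriminant with pooled covariance.
# Returns the linear decision rule; predictions agree with MASS::lda under
# proportional priors (cross-checked in the unit suite).
lda_train <- function(x, y) {
  lev <- sort(unique(y))
  x0 <- x[y == lev[1], , drop = FALSE]
  x1 <- x[y == lev[2], , drop = FALSE]
  m0 <- colMeans(x0)
  m1 <- colMeans(x1)
  n0 <- nrow(x0)
  n1 <- nrow(x1)
  Sp <- (crossprod(sweep(x0, 2L, m0)) + crossprod(sweep(x1, 2L, m1))) /
    (n0 + n1 - 2)
  w <- solve(Sp, m1 - m0)
  cut <- sum(w * (m0 + m1)) / 2 - log(n1 / n0)
  list(w = w, cut = cut, levels = lev)
}

lda_predict_class <- function(fit, x) {
  fit$levels[(as.matrix(x) %*% fit$w > fit$cut) + 1L]
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so every fold's class proportions match the data's.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in unique(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validated LDA accuracy
#'
#' Splits trials into `k` stratified folds (seeded), trains a pooled-
#' covariance linear discriminant on each training set and averages the
#' fold accuracies.
#'
#' @param features A `trial_features` data.frame (or any data.frame whose
#'   numeric columns are the features), with a `label` column.
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling the fold assignment.
#' @return An object of class `ssvep_decode` with `fold_accuracies` and
#'   `mean_accuracy` (percent); the permutation fields are unset until
#'   [permutation_null()] is run.
#' @export
lda_crossval <- function(features, k = 5L, seed = NULL) {
  xy <- features_matrix(features)
  x <- xy$x
  y <- xy$y
  if (length(y) < 10L) stop_invalid("need at least 10 trials")
  if (length(unique(y)) != 2L) stop_invalid("exactly two classes required")
  if (min(table(y)) < k)
    stop_invalid("fewer trials in a class than folds; stratification ",
                 "cannot guarantee both classes per fold")
  if (!is.null(seed)) set.seed(seed)
  fold <- stratified_folds(y, k)
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- lda_train(x[tr, , drop = FALSE], y[tr])
    mean(lda_predict_class(fit, x[!tr, , drop = FALSE]) == y[!tr])
  }, numeric(1))
  structure(list(fold_accuracies = 100 * acc, mean_accuracy = 100 * mean(acc),
                 k = k, n = length(y), seed = seed,
                 null_distribution = NULL, boundary_95 = NA_real_,
                 boundary_99 = NA_real_, significant_05 = NA,
                 significant_01 = NA),
            class = "ssvep_decode")
}

features_matrix <- function(features) {
  if (!is.data.frame(features)) stop_invalid("features must be a data.frame")
  if (!"label" %in% names(features)) stop_invalid("missing 'label' column")
  num <- vapply(features, is.numeric, logical(1))
  num["label"] <- FALSE
  x <- as.matrix(features[, num, drop = FALSE])
  if (any(!is.finite(x))) stop_invalid("features must be finite")
  list(x = x, y = as.character(features$label))
}

#' Permutation-calibrated chance boundaries for the LDA decoder
#'
#' Re-scores the dataset under `n_perm` random label permutations (class
#' counts preserved, cross-validation folds re-drawn each time) and places
#' the observed accuracy against the empirical null: the 95th and 99th
#' percentiles of the null distribution are the alpha = .05 and .01
#' significance boundaries, and the observed accuracy is significant when
#' strictly above them.
#'
#' @param features As in [lda_crossval()].
#' @param n_perm Number of label permutations (default 200; fewer than 20
#'   makes the percentile estimate unstable and triggers a warning).
#' @param k Folds (default 5).
#' @param seed Integer seed for folds and permutations.
#' @return A complete `ssvep_decode` object: observed `mean_accuracy`,
#'   `null_distribution` (percent), `boundary_95`, `boundary_99`,
#'   `significant_05`, `significant_01`.
#' @export
permutation_null <- function(features, n_perm = 200L, k = 5L, seed = 1L) {
  if (n_perm < 20L) warning("n_perm < 20: percentile estimates unstable")
  xy <- features_matrix(features)
  set.seed(seed)
  res <- lda_crossval(features, k = k, seed = NULL)
  null <- vapply(seq_len(n_perm), function(p) {
    perm <- features
    perm$label <- sample(xy$y)
    lda_crossval(perm, k = k, seed = NULL)$mean_accuracy
  }, numeric(1))
  res$null_distribution <- null
  res$boundary_95 <- unname(quantile(null, 0.95, type = 7))
  res$boundary_99 <- unname(quantile(null, 0.99, type = 7))
  res$significant_05 <- res$mean_accuracy > res$boundary_95
  res$significant_01 <- res$mean_accuracy > res$boundary_99
  res$n_perm <- n_perm
  res$seed <- seed
  res
}

#' @export
print.ssvep_decode <- function(x, ...) {
  cat(sprintf("<ssvep_decode> %d trials, %d-fold stratified CV: %.1f%%\n",
              x$n, x$k, x$mean_accuracy))
  if (!is.null(x$null_distribution))
    cat(sprintf(
      "  permutation null (%d): mean %.1f%%, boundaries 95th = %.1f%%, 99th = %.1f%%\n  significant: p<.05 %s, p<.01 %s\n",
      length(x$null_distribution), mean(x$null_distribution),
      x$boundary_95, x$boundary_99, x$significant_05, x$significant_01))
  invisible(x)
}

#' @export
summary.ssvep_decode <- function(object, ...) {
  print(object)
  cat("  fold accuracies:",
      paste(sprintf("%.1f", object$fold_accuracies), collapse = ", "), "\n")
  invisible(object)
}

#' Baseline/response SNR threshold from a shallow decision tree
#'
#' Separates fixation-phase from cue/target-phase single-trial SNR values
#' with a decision tree restricted to a depth of two and at most two
#' features, and reads the root-node split as the discrimination threshold
#' (the horizontal line over the SSVEP time courses).
#'
#' @param fixation_snr Numeric vector (or <= 2-column matrix) of per-trial
#'   baseline SNR values.
#' @param task_snr Same shape, per-trial SNR during the cue/target phases.
#' @param k Folds for the held-out accuracy check (default 5).
#' @param seed Seed for the accuracy check folds.
#' @return An object of class `phase_threshold`: `threshold` (root split),
#'   `cv_accuracy` (percent), `informative` flag, and the fitted `tree`.
#' @export
fit_phase_threshold <- function(fixation_snr, task_snr, k = 5L, seed = 1L) {
  fx <- as.matrix(fixation_snr)
  tk <- as.matrix(task_snr)
  if (ncol(fx) > 2L || ncol(tk) > 2L)
    stop_invalid("at most two features are considered")
  if (nrow(fx) == 0L || nrow(tk) == 0L)
    stop_invalid("both phases need at least one trial")
  x <- rbind(fx, tk)
  colnames(x) <- paste0("snr", seq_len(ncol(x)))
  y <- factor(rep(c("fixation", "task"), c(nrow(fx), nrow(tk))))
  if (diff(range(x)) == 0)
    stop(errorCondition("degenerate single-valued SNR input",
                        class = c("freqtag_degenerate", "error")))
  dat <- data.frame(y = y, x)
  ctl <- rpart::rpart.control(maxdepth = 2L, minsplit = 4L, cp = 0,
                              xval = 0L)
  tree <- rpart::rpart(y ~ ., data = dat, method = "class", control = ctl)
  if (is.null(tree$splits) || nrow(tree$splits) == 0L)
    stop(errorCondition("decision tree found no split",
                        class = c("freqtag_degenerate", "error")))
  threshold <- unname(tree$splits[1L, "index"])

  set.seed(seed)
  fold <- stratified_folds(as.character(y), k)
  acc <- vapply(seq_len(k), function(f) {
    fit <- rpart::rpart(y ~ ., data = dat[fold != f, ], method = "class",
                        control = ctl)
    pred <- predict(fit, dat[fold == f, , drop = FALSE], type = "class")
    mean(pred == y[fold == f])
  }, numeric(1))
  cv_acc <- 100 * mean(acc)
  structure(list(threshold = threshold, cv_accuracy = cv_acc,
                 informative = cv_acc > 55, tree = tree),
            class = "phase_threshold")
}

#' @export
print.phase_threshold <- function(x, ...) {
  cat(sprintf(
    "<phase_threshold> root split at %.3g (held-out accuracy %.1f%%%s)\n",
    x$threshold, x$cv_accuracy,
    if (x$informative) "" else "; uninformative"))
  invisible(x)
}

#' Write decoding results to TSV
#'
#' One row per result, mirroring a per-condition results table: condition,
#' mean accuracy, boundaries and significance flags.
#'
#' @param results Named list of `ssvep_decode` objects (names = condition).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_decode_results <- function(results, path) {
  rows <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(condition = nm, n_trials = r$n,
               mean_accuracy = r$mean_accuracy,
               boundary_95 = r$boundary_95, boundary_99 = r$boundary_99,
               significant_05 = r$significant_05,
               significant_01 = r$significant_01)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
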