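# Two-phase perceptual visibility-threshold staircase.
#
# The protocol presents blocks of four 1-s stimuli (the two flickers plus two
# static catch stimuli) in random order. A descending staircase starts at 5%
# of the maximal amplitude modulation depth and decreases in steps of 0.1
# percentage points until a block accumulates more than two errors (missed
# flickers or responses to static stimuli); an ascending staircase then
# refines the threshold in steps of +0.02 percentage points until both
# flickers in a block are detected. The periliminal depth is the final
# ascending depth; the subliminal depth sits one ascending step (0.0002)
# below it.

#' Simulated observer for the visibility-threshold staircase
#'
#' Detection follows a logistic psychometric function of modulation depth:
#' `P(detect) = guess + (1 - guess - lapse) / (1 + exp(-beta * (depth - threshold)))`.
#' On static (non-flickering) stimuli the observer responds with probability
#' `guess_rate` (false alarms).
#'
#' @param threshold True visibility threshold as a fraction of maximal depth.
#' @param beta Psychometric slope (1/depth units); large values approximate a
#'   step function. Default 2000 gives a ~0.2 percentage-point transition.
#' @param lapse_rate Probability of missing a clearly visible flicker.
#' @param guess_rate Probability of responding to a static stimulus. The
#'   default 0.1 reflects that near-threshold detection sessions elicit
#'   frequent false alarms; with the two flicker misses available per block,
#'   it is what makes the "more than two errors" descending trigger
#'   reachable in a four-trial block.
#' @return An object of class `observer`.
#' @export
observer <- function(threshold, beta = 2000, lapse_rate = 0.02,
                     guess_rate = 0.1) {
  check_number(threshold, "threshold", 0, 1)
  check_number(beta, "beta", lower = 0, allow_zero = FALSE)
  check_number(lapse_rate, "lapse_rate", 0, 1)
  check_number(guess_rate, "guess_rate", 0, 1)
  structure(list(threshold = threshold, beta = beta,
                 lapse_rate = lapse_rate, guess_rate = guess_rate),
            class = "observer")
}

#' @export
print.observer <- function(x, ...) {
  cat(sprintf("<observer> threshold %.4f, slope %g, lapse %.3f, guess %.3f\n",
              x$threshold, x$beta, x$lapse_rate, x$guess_rate))
  invisible(x)
}

p_detect <- function(obs, depth) {
  obs$guess_rate + (1 - obs$guess_rate - obs$lapse_rate) /
    (1 + exp(-obs$beta * (depth - obs$threshold)))
}

#' Run one four-trial staircase block
#'
#' Presents, in random order, the two flickers at the given depth and two
#' static stimuli. An error is a miss on a flicker trial or a response on a
#' static trial.
#'
#' @param depth Modulation depth for the two flicker trials, in \[0, 1\].
#' @param obs An [observer()].
#' @return A data.frame with one row per stimulus: `stimulus_type`
#'   (`"flicker"`/`"static"`), `response` (logical) and `error` (logical).
#' @export
run_block <- function(depth, obs) {
  check_number(depth, "depth", 0, 1)
  stopifnot(inherits(obs, "observer"))
  stim <- sample(c("flicker", "flicker", "static", "static"))
  resp <- vapply(stim, function(s) {
    p <- if (s == "flicker") p_detect(obs, depth) else obs$guess_rate
    runif(1) < p
  }, logical(1))
  err <- ifelse(stim == "flicker", !resp, resp)
  data.frame(stimulus_type = stim, response = unname(resp),
             error = unname(err), row.names = NULL)
}

#' Two-phase staircase estimate of the visibility threshold
#'
#' Runs the descending phase from `start_depth` in steps of
#' `descending_step` until a block has more than two errors, then the
#' ascending phase in steps of `ascending_step` until both flicker trials of
#' a block are hits. Returns the periliminal depth (final ascending depth)
#' and the subliminal depth (one ascending step below, clamped at 0).
#'
#' @param obs An [observer()].
#' @param start_depth Starting depth (default 0.05, i.e. 5% of maximal depth).
#' @param descending_step Depth decrement per descending block (default
#'   0.001, i.e. 0.1 percentage points of maximal depth).
#' @param ascending_step Depth increment per ascending block (default 0.0002,
#'   i.e. 0.02 percentage points).
#' @param seed Optional integer seed for reproducibility.
#' @param max_blocks Safety cap on total block count.
#' @return An object of class `staircase_result`: a list with `periliminal`,
#'   `subliminal`, and `trace` (data.frame of block, phase, depth,
#'   stimulus_type, response, error).
#' @examples
#' r <- run_staircase(observer(threshold = 0.02), seed = 1)
#' r$periliminal
#' @export
run_staircase <- function(obs, start_depth = 0.05, descending_step = 0.001,
                          ascending_step = 0.0002, seed = NULL,
                          max_blocks = 2000L) {
  stopifnot(inherits(obs, "observer"))
  check_number(start_depth, "start_depth", lower = 0, upper = 1,
               allow_zero = FALSE)
  if (!is.null(seed)) set.seed(seed)

  depth <- start_depth
  trace <- vector("list", 0L)
  block_i <- 0L
  log_block <- function(b, phase) {
    block_i <<- block_i + 1L
    trace[[block_i]] <<- cbind(block = block_i, phase = phase,
                               depth = depth, b)
  }

  # Descending phase: stop once a completed block has > 2 errors.
  protocol_failure <- FALSE
  repeat {
    b <- run_block(depth, obs)
    log_block(b, "descending")
    if (sum(b$error) > 2L) break
    depth <- depth - descending_step
    if (depth <= 0) {
      warning("descending staircase reached depth 0 without trigger; ",
              "protocol failure")
      protocol_failure <- TRUE
      depth <- 0
      break
    }
    if (block_i >= max_blocks) stop_invalid("staircase exceeded max_blocks")
  }

  # Ascending phase: stop once both flicker trials in a block are hits
  # (static-trial responses do not affect the stop rule).
  repeat {
    depth <- min(1, depth + ascending_step)
    b <- run_block(depth, obs)
    log_block(b, "ascending")
    flick <- b[b$stimulus_type == "flicker", ]
    if (all(flick$response)) break
    if (block_i >= max_blocks) stop_invalid("staircase exceeded max_blocks")
  }

  peri <- depth
  sub <- peri - ascending_step
  if (sub < 0) {
    warning("subliminal depth clamped at 0")
    sub <- 0
  }
  structure(list(periliminal = peri, subliminal = sub,
                 protocol_failure = protocol_failure,
                 trace = do.call(rbind, trace)),
            class = "staircase_result")
}

#' @export
print.staircase_result <- function(x, ...) {
  nb <- max(x$trace$block)
  cat(sprintf(
    "<staircase_result> periliminal %.4f, subliminal %.4f (%d blocks%s)\n",
    x$periliminal, x$subliminal, nb,
    if (x$protocol_failure) ", protocol failure" else ""))
  invisible(x)
}

#' Write a staircase trace to TSV
#'
#' @param result A [run_staircase()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_staircase_trace <- function(result, path) {
  stopifnot(inherits(result, "staircase_result"))
  utils::write.table(result$trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
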