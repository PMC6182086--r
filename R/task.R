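#' Configuration of the context-dependent integration task
#'
#' The task presents noisy motion and color evidence together with a binary
#' contextual cue that tells the network which modality is relevant on the
#' current trial. Sensory inputs are piecewise-constant offsets (the signed
#' coherences `d_m`, `d_c`) plus independent zero-mean Gaussian noise at every
#' time step; context is carried by two binary channels, exactly one of which
#' is active throughout a trial.
#'
#' Two input encodings are supported. `signed_2channel` puts each modality on
#' one channel whose sign carries the feature (motion right/left, color
#' red/green), giving 4 input channels in total with the two context lines.
#' `separated_4channel` represents each feature on its own nonnegative
#' channel, ordered (motion-right, motion-left, color-red, color-green), with
#' value `baseline_input + |d|` on the favored channel and `baseline_input`
#' on its counterpart, giving 6 channels in total.
#'
#' @param coherence_levels_motion Signed motion coherence levels; must be
#'   nonempty and symmetric about zero.
#' @param coherence_levels_color Signed color coherence levels, same contract.
#' @param noise_std_motion,noise_std_color Per-step Gaussian noise sd on the
#'   sensory channels (dimensionless, default 0.04).
#' @param dt Integration step in ms.
#' @param trial_duration Trial length in ms; must be a positive multiple of
#'   `dt`.
#' @param encoding_mode `"signed_2channel"` or `"separated_4channel"`.
#' @param baseline_input Baseline offset of the separated channels.
#' @param decision_window Number of final steps over which the decision is
#'   read out (and scored, for the families that score a terminal window).
#' @param zero_coherence `"reject"` (the default: a trial whose
#'   context-relevant coherence is zero is refused, its correct answer being
#'   undefined) or `"random_target"`.
#' @param seed Optional integer seed recorded in the config.
#' @return A `task_config` object.
#' @export
task_config <- function(coherence_levels_motion = c(-0.04, -0.02, -0.01, 0.01, 0.02, 0.04),
                        coherence_levels_color = c(-0.04, -0.02, -0.01, 0.01, 0.02, 0.04),
                        noise_std_motion = 0.04,
                        noise_std_color = 0.04,
                        dt = 1,
                        trial_duration = 30,
                        encoding_mode = c("signed_2channel", "separated_4channel"),
                        baseline_input = 0.2,
                        decision_window = 1,
                        zero_coherence = c("reject", "random_target"),
                        seed = NULL) {
  encoding_mode <- match.arg(encoding_mode)
  zero_coherence <- match.arg(zero_coherence)
  sym <- function(v) {
    length(v) > 0 && isTRUE(all.equal(sort(v), sort(-v), tolerance = 1e-12))
  }
  if (!sym(coherence_levels_motion) || !sym(coherence_levels_color)) {
    stop_invalid("coherence levels must be nonempty and symmetric about zero")
  }
  if (dt <= 0) stop_invalid("dt must be > 0")
  n_steps <- trial_duration / dt
  if (trial_duration <= 0 || abs(n_steps - round(n_steps)) > 1e-9) {
    stop_invalid("trial_duration must be a positive multiple of dt")
  }
  if (noise_std_motion < 0 || noise_std_color < 0) {
    stop_invalid("noise standard deviations must be >= 0")
  }
  if (decision_window < 1 || decision_window > round(n_steps)) {
    stop_invalid("decision_window must lie in [1, trial_duration/dt]")
  }
  structure(list(
    coherence_levels_motion = coherence_levels_motion,
    coherence_levels_color = coherence_levels_color,
    noise_std_motion = noise_std_motion,
    noise_std_color = noise_std_color,
    dt = dt,
    trial_duration = trial_duration,
    n_steps = as.integer(round(n_steps)),
    encoding_mode = encoding_mode,
    baseline_input = baseline_input,
    decision_window = as.integer(decision_window),
    zero_coherence = zero_coherence,
    seed = seed
  ), class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Context-dependent integration task\n")
  cat(sprintf("  encoding: %s (%d input channels)\n", x$encoding_mode,
              n_input_channels(x)))
  cat(sprintf("  duration: %g ms, dt = %g ms (%d steps)\n",
              x$trial_duration, x$dt, x$n_steps))
  cat(sprintf("  motion coherences: %s (noise sd %g)\n",
              paste(x$coherence_levels_motion, collapse = " "), x$noise_std_motion))
  cat(sprintf("  color coherences:  %s (noise sd %g)\n",
              paste(x$coherence_levels_color, collapse = " "), x$noise_std_color))
  invisible(x)
}

n_input_channels <- function(config) {
  if (config$encoding_mode == "signed_2channel") 4L else 6L
}

#' Generate one task trial
#'
#' Builds the input time series for one trial: sensory offsets plus iid
#' Gaussian noise on every sensory channel and constant binary context lines.
#' The correct choice is the sign rule on the context-relevant coherence
#' (positive coherence -> choice 1, negative -> choice 2).
#'
#' @param config A [task_config()].
#' @param context `"motion"` or `"color"`.
#' @param d_m,d_c Signed motion / color coherence for this trial.
#' @param seed Optional integer seed for the noise draws.
#' @return A `trial` object with fields `inputs` (steps x channels matrix),
#'   `context`, `d_m`, `d_c` and `correct_choice` (`"choice1"`/`"choice2"`, or
#'   a randomly assigned label when zero relevant coherence is configured to
#'   `"random_target"`).
#' @export
make_trial <- function(config, context = c("motion", "color"),
                       d_m = NULL, d_c = NULL, seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  context <- match.arg(context)
  with_seed(seed, {
    if (is.null(d_m)) d_m <- sample(config$coherence_levels_motion, 1L)
    if (is.null(d_c)) d_c <- sample(config$coherence_levels_color, 1L)
    d_rel <- if (context == "motion") d_m else d_c
    if (d_rel == 0 && config$zero_coherence == "reject") {
      stop_invalid("context-relevant coherence is zero: correct answer undefined")
    }
    correct <- if (d_rel > 0) "choice1" else if (d_rel < 0) "choice2" else
      sample(c("choice1", "choice2"), 1L)
    tt <- config$n_steps
    inputs <- build_inputs(config, context, d_m, d_c, tt)
    structure(list(
      inputs = inputs, context = context, d_m = d_m, d_c = d_c,
      correct_choice = correct, config = config
    ), class = "trial")
  })
}

build_inputs <- function(config, context, d_m, d_c, tt) {
  ctx <- if (context == "motion") c(1, 0) else c(0, 1)
  if (config$encoding_mode == "signed_2channel") {
    u <- cbind(
      d_m + rnorm(tt, 0, config$noise_std_motion),
      d_c + rnorm(tt, 0, config$noise_std_color),
      rep(ctx[1], tt), rep(ctx[2], tt)
    )
    colnames(u) <- c("motion", "color", "ctx_motion", "ctx_color")
  } else {
    b <- config$baseline_input
    # favored channel gets baseline + |d|; counterpart stays at baseline
    # channel order: motion-right, motion-left, color-red, color-green
    mr <- b + if (d_m > 0) abs(d_m) else 0
    ml <- b + if (d_m < 0) abs(d_m) else 0
    cr <- b + if (d_c > 0) abs(d_c) else 0
    cg <- b + if (d_c < 0) abs(d_c) else 0
    u <- cbind(
      mr + rnorm(tt, 0, config$noise_std_motion),
      ml + rnorm(tt, 0, config$noise_std_motion),
      cr + rnorm(tt, 0, config$noise_std_color),
      cg + rnorm(tt, 0, config$noise_std_color),
      rep(ctx[1], tt), rep(ctx[2], tt)
    )
    colnames(u) <- c("motion_right", "motion_left", "color_red", "color_green",
                     "ctx_motion", "ctx_color")
  }
  u
}

#' Generate a batch of trials
#'
#' @param config A [task_config()].
#' @param n Number of trials (>= 1).
#' @param context_policy `"alternating"` (contexts balanced to within one
#'   trial) or `"random"`.
#' @param family Optional model-family label; when given, targets, error
#'   masks and reward schedules are attached to every trial via
#'   [target_series()].
#' @param seed Optional integer seed.
#' @return A `trial_batch` (list of trials plus the shared config).
#' @export
make_batch <- function(config, n, context_policy = c("alternating", "random"),
                       family = NULL, seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  context_policy <- match.arg(context_policy)
  if (!is.numeric(n) || n < 1) stop_invalid("n must be >= 1")
  n <- as.integer(n)
  with_seed(seed, {
    contexts <- if (context_policy == "alternating") {
      rep(c("motion", "color"), length.out = n)
    } else {
      sample(c("motion", "color"), n, replace = TRUE)
    }
    trials <- lapply(seq_len(n), function(i) {
      tr <- make_trial(config, contexts[i])
      if (!is.null(family)) {
        ts <- target_series(tr, family)
        tr$target_outputs <- ts$target_outputs
        tr$error_mask <- ts$error_mask
        tr$reward_schedule <- ts$reward_schedule
        tr$family <- family
      }
      tr
    })
    structure(list(trials = trials, n_trials = n, config = config,
                   family = family), class = "trial_batch")
  })
}

#' @export
print.trial_batch <- function(x, ...) {
  cat(sprintf("trial_batch: %d trials (%s encoding, %d steps each)\n",
              x$n_trials, x$config$encoding_mode, x$config$n_steps))
  invisible(x)
}

#' Target outputs and error mask for a trial under a model family's objective
#'
#' Each family scores different output time points. The HF family uses one
#' scalar output with target 0 at the first step and +/-1 at the last step,
#' and its error mask is true only at those two points. The pycog family uses
#' a two-channel one-hot target scored only over the final decision window.
#' The rHebb family uses a scalar +/-1 target over the decision window (the
#' reward is the negative absolute deviation from it). The pyrl family is
#' trained from rewards, not targets: the returned `reward_schedule` states
#' the reward for a correct decision (+1), an incorrect one (0), and the
#' per-step penalty for breaking fixation (-1).
#'
#' @param trial A [make_trial()] result.
#' @param family One of `"hf"`, `"pycog"`, `"pyrl"`, `"rhebb"`.
#' @return A list with `target_outputs` (steps x N_out matrix, or NULL for
#'   pyrl), `error_mask` (logical vector over steps) and `reward_schedule`
#'   (pyrl only, else NULL).
#' @export
target_series <- function(trial, family) {
  stopifnot(inherits(trial, "trial"))
  if (!family %in% c("hf", "pycog", "pyrl", "rhebb")) {
    stop_invalid("unknown model family '%s'", family)
  }
  tt <- nrow(trial$inputs)
  dw <- trial$config$decision_window
  sgn <- if (trial$correct_choice == "choice1") 1 else -1
  win <- seq.int(tt - dw + 1L, tt)
  if (family == "hf") {
    target <- matrix(0, tt, 1)
    target[tt, 1] <- sgn
    mask <- rep(FALSE, tt)
    mask[c(1L, tt)] <- TRUE
    list(target_outputs = target, error_mask = mask, reward_schedule = NULL)
  } else if (family == "pycog") {
    target <- matrix(0, tt, 2)
    target[win, if (sgn > 0) 1 else 2] <- 1
    mask <- rep(FALSE, tt)
    mask[win] <- TRUE
    list(target_outputs = target, error_mask = mask, reward_schedule = NULL)
  } else if (family == "rhebb") {
    target <- matrix(0, tt, 1)
    target[win, 1] <- sgn
    mask <- rep(FALSE, tt)
    mask[win] <- TRUE
    list(target_outputs = target, error_mask = mask, reward_schedule = NULL)
  } else { # pyrl
    mask <- rep(FALSE, tt)
    mask[tt] <- TRUE
    list(target_outputs = NULL, error_mask = mask,
         reward_schedule = list(correct = 1, incorrect = 0,
                                fixation_break = -1))
  }
}
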