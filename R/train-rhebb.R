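#' Configuration of the reward-modulated Hebbian rule
#'
#' Node-perturbation learning: sparse, large per-unit exploration kicks
#' perturb the recurrent units, every synapse accumulates an eligibility
#' trace `e[i,j] += S(r_j(t-1) * (x_i(t) - xbar_i))` with the superlinear,
#' sign-preserving function `S(x) = x^p` (default cube), and at the end of
#' each trial the recurrent weights change by `dW = eta * e * (R - Rbar)`,
#' where `R` is the trial reward (the negative mean absolute deviation of
#' the output unit from the optimal response over the decision window) and
#' `Rbar` a running average of the reward previously received under the same
#' stimulus condition.
#'
#' Two stabilizers keep desk-scale runs from destroying the network they are
#' training: the per-trial update is clipped elementwise at `max_dw` (the
#' cubed trace has a heavy tail), and the recurrent matrix relaxes toward its
#' initial state at rate `decay_to_init` per trial, which bounds the random
#' walk that reward noise would otherwise accumulate in every synapse while
#' consistent reward correlations still integrate to large changes.
#'
#' @param eta Learning rate (> 0).
#' @param superlinear_exponent Odd integer >= 3; exponent of `S`.
#' @param running_avg_tau Time constant (ms) of the exponential running
#'   average `xbar`. Short (default 5 ms), so the trace responds to the fast
#'   fluctuations the exploration kicks cause rather than to slow
#'   stimulus-driven drift.
#' @param reward_avg_scheme `"per_condition_running_mean"` (one baseline per
#'   stimulus condition - context and both signed coherences - the default)
#'   or `"global_running_mean"`.
#' @param reward_avg_rate Update rate of the reward running mean.
#' @param n_trials Training-trial budget.
#' @param max_dw Elementwise bound on one trial's weight change.
#' @param decay_to_init Per-trial relaxation rate of `W_rec` toward the
#'   initial matrix (0 disables).
#' @param kick_rate Per-unit per-step probability of an exploration kick.
#' @param kick_amp Kick amplitude: kicks are uniform on `(-kick_amp,
#'   kick_amp)` and enter the drive like the Gaussian state noise.
#' @param check_every,stop_accuracy,n_val Validation checkpoint settings
#'   (validation runs with exploration off). The returned `W_last` is the
#'   parameter snapshot with the best validation accuracy, not necessarily
#'   the last iterate: node-perturbation progress is non-monotone, and
#'   checkpoint selection is the standard way to return the learned model.
#' @return An `rhebb_config` object.
#' @export
rhebb_config <- function(eta = 0.02, superlinear_exponent = 3,
                         running_avg_tau = 5,
                         reward_avg_scheme = c("per_condition_running_mean",
                                               "global_running_mean"),
                         reward_avg_rate = 0.25, n_trials = 24000,
                         max_dw = 5e-4, decay_to_init = 1e-3,
                         kick_rate = 0.03, kick_amp = 8,
                         check_every = 500, stop_accuracy = 0.85,
                         n_val = 400) {
  if (eta <= 0) stop_invalid("eta must be > 0")
  p <- as.integer(superlinear_exponent)
  if (p < 3 || p %% 2 == 0) {
    stop_invalid("superlinear_exponent must be an odd integer >= 3")
  }
  structure(list(family = "rhebb", eta = eta, superlinear_exponent = p,
                 running_avg_tau = running_avg_tau,
                 reward_avg_scheme = match.arg(reward_avg_scheme),
                 reward_avg_rate = reward_avg_rate,
                 n_trials = as.integer(n_trials), max_dw = max_dw,
                 decay_to_init = decay_to_init,
                 kick_rate = kick_rate, kick_amp = kick_amp,
                 check_every = as.integer(check_every),
                 stop_accuracy = stop_accuracy, n_val = as.integer(n_val)),
            class = c("rhebb_config", "trainer_spec"))
}

#' Create an empty eligibility state
#'
#' @param N_rec Number of recurrent units.
#' @return An `eligibility_state` with the trace matrix `e` (zeroed at trial
#'   start), the running activity averages `x_bar`, and the reward baselines
#'   `R_bar` (a named vector, one entry per stimulus condition).
#' @export
eligibility_state <- function(N_rec) {
  structure(list(e = matrix(0, N_rec, N_rec), x_bar = rep(0, N_rec),
                 R_bar = numeric(0)),
            class = "eligibility_state")
}

#' Accumulate the Hebbian eligibility trace for one time step
#'
#' Updates the running average `x_bar` first, then increments every synapse
#' by `S(r_j_prev * (x_i - xbar_i))` where `i` indexes the postsynaptic and
#' `j` the presynaptic unit and `S(x) = x^p` is superlinear and
#' sign-preserving.
#'
#' @param state An [eligibility_state()].
#' @param r_prev Rates at the previous step (length `N_rec`).
#' @param x_now Membrane potentials at the current step.
#' @param config An [rhebb_config()].
#' @param x_bar_rate EMA rate for `x_bar`; the trainer passes
#'   `dt / running_avg_tau`.
#' @return The updated state.
#' @export
rhebb_accumulate <- function(state, r_prev, x_now, config = rhebb_config(),
                             x_bar_rate = 0.2) {
  stopifnot(inherits(state, "eligibility_state"))
  n <- length(state$x_bar)
  if (length(r_prev) != n || length(x_now) != n) {
    stop_invalid("rate/state length mismatch with eligibility state")
  }
  state$x_bar <- (1 - x_bar_rate) * state$x_bar + x_bar_rate * x_now
  fluct <- x_now - state$x_bar
  state$e <- state$e + outer(fluct, r_prev)^config$superlinear_exponent
  state
}

#' Apply the end-of-trial reward-modulated weight update
#'
#' `W_rec <- W_rec + clip(eta * e * (R - Rbar), max_dw)`, then updates the
#' reward baseline for the trial's condition. On the first encounter of a
#' condition the baseline is initialized to `R` and no weight change is
#' applied.
#'
#' @param params Network parameters.
#' @param state An [eligibility_state()] accumulated over the trial.
#' @param R Scalar trial reward.
#' @param config An [rhebb_config()].
#' @param condition Condition key for the per-condition reward baseline
#'   (ignored under the global scheme).
#' @return List with updated `params` and `state`, and the applied `delta`.
#' @export
rhebb_apply <- function(params, state, R, config = rhebb_config(),
                        condition = "global") {
  if (!is.finite(R)) stop_invalid("non-finite reward")
  key <- if (config$reward_avg_scheme == "global_running_mean") "global"
         else as.character(condition)
  if (is.na(state$R_bar[key])) {
    state$R_bar[key] <- R
    return(list(params = params, state = state,
                delta = matrix(0, nrow(state$e), ncol(state$e))))
  }
  delta <- config$eta * state$e * (R - state$R_bar[[key]])
  if (!is.null(config$max_dw)) {
    delta <- pmin(pmax(delta, -config$max_dw), config$max_dw)
  }
  params$W_rec <- params$W_rec + delta
  state$R_bar[key] <- (1 - config$reward_avg_rate) * state$R_bar[[key]] +
    config$reward_avg_rate * R
  list(params = params, state = state, delta = delta)
}

rhebb_condition_key <- function(trial) {
  paste(trial$context, trial$d_m, trial$d_c, sep = "/")
}

#' Train an rHebb network by node perturbation
#'
#' Loops over trials: resets the eligibility trace, simulates the trial with
#' exploration kicks while accumulating the trace at every step, computes the
#' reward as the negative mean absolute deviation of the output unit's rate
#' from the target over the decision window, and applies the end-of-trial
#' update followed by the relaxation toward the initial matrix. Validation
#' accuracy is evaluated with exploration off; the returned `W_last` is the
#' best-validation snapshot.
#'
#' @param params,arch Network parameters and architecture (family `"rhebb"`).
#' @param task_cfg A [task_config()].
#' @param config An [rhebb_config()].
#' @param seed Integer seed; identical seeds reproduce the run exactly.
#' @return A `training_record`.
#' @export
rhebb_train <- function(params, arch, task_cfg, config = rhebb_config(),
                        seed = 1L) {
  stopifnot(arch$family == "rhebb")
  if (arch$noise_std_rec <= 0 && config$kick_rate <= 0) {
    stop_invalid("rHebb learning needs exploration (state noise or kicks)")
  }
  W_init <- params
  W0 <- params$W_rec
  N <- arch$N_rec
  a <- arch$alpha
  p_exp <- config$superlinear_exponent
  beta <- task_cfg$dt / (config$running_avg_tau %||% 5)
  dw <- task_cfg$decision_window
  tt <- task_cfg$n_steps
  win1 <- tt - dw + 1L
  cunits <- arch$constant_input_units
  out_unit <- arch$output_unit
  lam <- config$decay_to_init %||% 0
  val_batch <- make_batch(task_cfg, config$n_val, "alternating",
                          family = "rhebb", seed = derive_seed(seed, 900001))
  R_bar <- numeric(0)
  x_bar <- rep(0, N)
  trace <- list(); converged <- FALSE
  best_acc <- -Inf; best_W <- params$W_rec
  n_done <- config$n_trials
  for (k in seq_len(config$n_trials)) {
    tr <- make_trial(task_cfg, if (k %% 2 == 1) "motion" else "color",
                     seed = derive_seed(seed, k))
    sgn <- if (tr$correct_choice == "choice1") 1 else -1
    key <- if (config$reward_avg_scheme == "global_running_mean") "global"
           else rhebb_condition_key(tr)
    with_seed(derive_seed(seed, 500000 + k), {
      x <- rep(0, N)
      r <- tanh(x)
      x[cunits] <- 1; r[cunits] <- tanh(1)
      e <- matrix(0, N, N)
      out_acc <- 0
      u <- t(tr$inputs)  # N_in x tt
      for (t in seq_len(tt)) {
        noise <- rnorm(N, 0, arch$noise_std_rec)
        if (config$kick_rate > 0) {
          noise <- noise + (runif(N) < config$kick_rate) *
            runif(N, -config$kick_amp, config$kick_amp)
        }
        r_prev <- r
        x <- as.numeric((1 - a) * x +
                          a * (params$W_rec %*% r + params$W_in %*% u[, t] +
                                 params$b_x + noise))
        x[cunits] <- 1
        # inline rhebb_accumulate semantics (running average, then trace)
        x_bar <- (1 - beta) * x_bar + beta * x
        e <- e + outer(x - x_bar, r_prev)^p_exp
        r <- tanh(x)
        if (t >= win1) out_acc <- out_acc + abs(r[out_unit] - sgn)
      }
      R <- -out_acc / dw
    })
    if (is.na(R_bar[key])) {
      R_bar[key] <- R
    } else {
      delta <- config$eta * e * (R - R_bar[[key]])
      if (!is.null(config$max_dw)) {
        delta <- pmin(pmax(delta, -config$max_dw), config$max_dw)
      }
      params$W_rec <- params$W_rec + delta
      if (lam > 0) params$W_rec <- W0 + (params$W_rec - W0) * (1 - lam)
      R_bar[key] <- (1 - config$reward_avg_rate) * R_bar[[key]] +
        config$reward_avg_rate * R
    }
    if (k %% config$check_every == 0 || k == config$n_trials) {
      acc <- accuracy(params, arch, val_batch, noise_std = 0,
                      seed = derive_seed(seed, 700000 + k))
      trace[[length(trace) + 1]] <- data.frame(iteration = k, reward = R,
                                               accuracy = acc)
      if (acc > best_acc) { best_acc <- acc; best_W <- params$W_rec }
      if (acc >= config$stop_accuracy) { converged <- TRUE; n_done <- k; break }
    }
  }
  params$W_rec <- best_W
  new_training_record("rhebb", W_init, params, do.call(rbind, trace), seed,
                      list(arch = arch, task = task_cfg, trainer = config,
                           n_trials_run = n_done, best_accuracy = best_acc),
                      converged)
}
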