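#' Specify units to inactivate during simulation
#'
#' In-silico lesion: the selected units are overridden at every step of the
#' recurrent loop, either by forcing their rate output to zero
#' (`zero_output`, used by the pycog/pyrl/rhebb families) or by clamping
#' their membrane potential to the unit's bias `b_x` (`bias_constant`, the HF
#' convention).
#'
#' @param unit_indices Integer indices of the units to clamp.
#' @param clamp_mode `"zero_output"` or `"bias_constant"`.
#' @return An `inactivation_spec` object.
#' @export
inactivation_spec <- function(unit_indices,
                              clamp_mode = c("zero_output", "bias_constant")) {
  clamp_mode <- match.arg(clamp_mode)
  unit_indices <- as.integer(unit_indices)
  structure(list(unit_indices = unit_indices, clamp_mode = clamp_mode),
            class = "inactivation_spec")
}

check_inactivation <- function(inactivation, arch) {
  if (is.null(inactivation)) return(invisible(NULL))
  stopifnot(inherits(inactivation, "inactivation_spec"))
  idx <- inactivation$unit_indices
  if (length(idx) && (min(idx) < 1 || max(idx) > arch$N_rec)) {
    stop_invalid("inactivation indices out of range [1, %d]", arch$N_rec)
  }
  if (inactivation$clamp_mode == "bias_constant" && arch$family != "hf") {
    stop_invalid("bias_constant clamping is the HF convention only")
  }
  invisible(NULL)
}

#' One Euler step of the leaky recurrent dynamics
#'
#' First-order update `x' = (1 - alpha) x + alpha (W_rec r + W_in u + b_x +
#' noise)` with `alpha = dt / tau` and `r = activation(x)`. Accepts a column
#' per trial, so `x_prev` may be a vector (one trial) or an `N_rec x B`
#' matrix.
#'
#' @param params A [init_parameters()] result.
#' @param arch The matching [architecture()].
#' @param x_prev State vector or matrix.
#' @param u_t Input vector (length `N_in`) or `N_in x B` matrix.
#' @param noise Optional additive noise of the same shape as `x_prev`
#'   (default 0, i.e. deterministic step).
#' @return The next state, same shape as `x_prev`.
#' @export
step_leaky <- function(params, arch, x_prev, u_t, noise = 0) {
  a <- arch$alpha
  r_prev <- activation_fn(arch)(x_prev)
  drive <- params$W_rec %*% r_prev + params$W_in %*% u_t + params$b_x + noise
  x_next <- (1 - a) * x_prev + a * drive
  check_finite(x_next, "recurrent state")
  x_next
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One step of the gated recurrent dynamics (pyrl families)
#'
#' Standard two-gate update with an update gate `q` and a reset gate `s`:
#' `q = sigmoid(W_q_in u + W_q_rec r + b_q)`,
#' `s = sigmoid(W_s_in u + W_s_rec r + b_s)`,
#' candidate drive `c = W_rec (s * r) + W_in u + b_x + noise`, and
#' `x' = (1 - q) * x + q * c`. With both gates forced to 1 this reduces to
#' the unleaky recurrent step `x' = W_rec r + W_in u + b_x`.
#'
#' @inheritParams step_leaky
#' @param return_gates Return the gate values alongside the state (used by
#'   the training backward pass).
#' @export
step_gated <- function(params, arch, x_prev, u_t, noise = 0,
                       return_gates = FALSE) {
  if (is.null(params$W_q_rec)) stop_invalid("gate parameters missing")
  r_prev <- activation_fn(arch)(x_prev)
  q <- sigmoid(params$W_q_in %*% u_t + params$W_q_rec %*% r_prev + params$b_q)
  s <- sigmoid(params$W_s_in %*% u_t + params$W_s_rec %*% r_prev + params$b_s)
  cand <- params$W_rec %*% (s * r_prev) + params$W_in %*% u_t + params$b_x + noise
  x_next <- (1 - q) * x_prev + q * cand
  check_finite(x_next, "recurrent state")
  if (return_gates) list(x = x_next, q = q, s = s, cand = cand, r_prev = r_prev)
  else x_next
}

apply_clamp <- function(x, r, params, arch, inactivation) {
  if (!is.null(arch$constant_input_units)) {
    # rHebb tonic-drive units: membrane potential held at a constant
    x[arch$constant_input_units, ] <- 1
    r[arch$constant_input_units, ] <- tanh(1)
  }
  if (!is.null(inactivation) && length(inactivation$unit_indices)) {
    k <- inactivation$unit_indices
    if (inactivation$clamp_mode == "zero_output") {
      r[k, ] <- 0
    } else {
      x[k, ] <- params$b_x[k]
      r[k, ] <- activation_fn(arch)(params$b_x[k])
    }
  }
  list(x = x, r = r)
}

# Batched forward simulation. inputs: T x N_in x B array. Returns final rates
# and outputs, optionally the full trajectories. Noise drawn from the current
# RNG stream (column-major, so per-trial streams are only jointly
# reproducible, which is all evaluation needs).
forward_batch <- function(params, arch, inputs, inactivation = NULL,
                          keep_states = FALSE, noise_std = NULL) {
  check_inactivation(inactivation, arch)
  dims <- dim(inputs)
  tt <- dims[1]; B <- dims[3]
  if (dims[2] != arch$N_in) stop_invalid("input width %d != N_in %d", dims[2], arch$N_in)
  N <- arch$N_rec
  sd_rec <- noise_std %||% arch$noise_std_rec
  act <- activation_fn(arch)
  x <- matrix(0, N, B)
  r <- act(x)
  cl <- apply_clamp(x, r, params, arch, inactivation)
  x <- cl$x; r <- cl$r
  xs <- if (keep_states) array(0, c(tt, N, B)) else NULL
  rs <- if (keep_states) array(0, c(tt, N, B)) else NULL
  zs <- if (!is.null(params$W_out)) array(0, c(tt, arch$N_out, B)) else NULL
  for (t in seq_len(tt)) {
    u_t <- matrix(inputs[t, , ], dims[2], B)
    noise <- if (sd_rec > 0) matrix(rnorm(N * B, 0, sd_rec), N, B) else 0
    if (arch$gated) {
      x <- step_gated(params, arch, x, u_t, noise)
    } else {
      x <- step_leaky(params, arch, x, u_t, noise)
    }
    r <- act(x)
    cl <- apply_clamp(x, r, params, arch, inactivation)
    x <- cl$x; r <- cl$r
    if (keep_states) { xs[t, , ] <- x; rs[t, , ] <- r }
    if (!is.null(zs)) zs[t, , ] <- params$W_out %*% r + params$b_z
  }
  list(x_final = x, r_final = r, x = xs, r = rs, z = zs, n_steps = tt)
}

batch_input_array <- function(batch) {
  tt <- batch$config$n_steps
  nin <- ncol(batch$trials[[1]]$inputs)
  arr <- array(0, c(tt, nin, batch$n_trials))
  for (i in seq_len(batch$n_trials)) arr[, , i] <- batch$trials[[i]]$inputs
  arr
}

#' Simulate one trial
#'
#' Runs the family's step operation over all time steps of a trial, applying
#' any inactivation clamp at every step, and decodes the choice.
#'
#' @param params,arch Network parameters and architecture.
#' @param trial A [make_trial()] result (input width must equal `N_in`).
#' @param inactivation Optional [inactivation_spec()].
#' @param seed Optional seed for the recurrent noise.
#' @param noise_std Override for the recurrent noise sd (e.g. 0 for a
#'   deterministic probe).
#' @return A `state_trajectory` with `x`, `r` (steps x N_rec), `z` (steps x
#'   N_out, or the designated unit's rate for rHebb) and the decoded
#'   `choice`.
#' @export
run_trial <- function(params, arch, trial, inactivation = NULL, seed = NULL,
                      noise_std = NULL) {
  stopifnot(inherits(trial, "trial"))
  inputs <- trial$inputs
  arr <- array(inputs, c(nrow(inputs), ncol(inputs), 1L))
  out <- with_seed(seed, forward_batch(params, arch, arr, inactivation,
                                       keep_states = TRUE,
                                       noise_std = noise_std))
  tt <- out$n_steps
  z <- if (!is.null(out$z)) {
    matrix(out$z[, , 1], tt, arch$N_out)
  } else {
    matrix(out$r[, arch$output_unit, 1], tt, 1)
  }
  traj <- structure(list(
    x = matrix(out$x[, , 1], tt, arch$N_rec),
    r = matrix(out$r[, , 1], tt, arch$N_rec),
    z = z, family = arch$family,
    decision_window = trial$config$decision_window
  ), class = "state_trajectory")
  traj$choice <- decode_choice(traj, arch$family)
  traj
}

#' Decode the behavioral choice from a trajectory
#'
#' HF and rHebb read the sign of the scalar output averaged over the decision
#' window (positive -> choice 1); pycog takes the index of the largest output
#' channel; pyrl takes the largest channel among choice 1, choice 2 and
#' "stay". Exact ties break toward the lowest channel index and are flagged
#' with attribute `tie = TRUE`.
#'
#' @param trajectory A [run_trial()] result.
#' @param family Model-family label.
#' @return `"choice1"`, `"choice2"` or (pyrl) `"stay"`.
#' @export
decode_choice <- function(trajectory, family = trajectory$family) {
  z <- trajectory$z
  dw <- trajectory$decision_window %||% 1L
  tt <- nrow(z)
  win <- seq.int(tt - dw + 1L, tt)
  zf <- colMeans(z[win, , drop = FALSE])
  if (family %in% c("hf", "rhebb")) {
    if (zf[1] == 0) {
      return(structure("choice1", tie = TRUE))
    }
    if (zf[1] > 0) "choice1" else "choice2"
  } else {
    labels <- if (family == "pycog") c("choice1", "choice2")
              else c("choice1", "choice2", "stay")
    k <- which(zf == max(zf))
    if (length(k) > 1) structure(labels[k[1]], tie = TRUE) else labels[k]
  }
}

decode_batch <- function(out, arch, decision_window = 1L) {
  tt <- out$n_steps
  win <- seq.int(tt - decision_window + 1L, tt)
  B <- ncol(out$r_final)
  if (is.null(out$z)) {
    zf <- colMeans(matrix(out$r[win, arch$output_unit, ], length(win), B))
    ifelse(zf > 0, "choice1", "choice2")
  } else {
    labels <- if (arch$N_out == 1) NULL
              else if (arch$N_out == 2) c("choice1", "choice2")
              else c("choice1", "choice2", "stay")
    zf <- matrix(0, arch$N_out, B)
    for (t in win) zf <- zf + matrix(out$z[t, , ], arch$N_out, B)
    zf <- zf / length(win)
    if (arch$N_out == 1) {
      ifelse(zf[1, ] > 0, "choice1", "choice2")
    } else {
      labels[apply(zf, 2, which.max)]
    }
  }
}

#' Fraction of correct choices on a trial batch
#'
#' Simulates every trial (with any inactivation clamp applied) and returns
#' the fraction whose decoded choice matches the trial's correct choice.
#' Zero-coherence trials are excluded from scoring.
#'
#' @param params,arch Network parameters and architecture.
#' @param batch A [make_batch()] result.
#' @param inactivation Optional [inactivation_spec()].
#' @param seed Optional seed for the recurrent noise.
#' @param noise_std Optional override of the recurrent noise sd.
#' @return Fraction correct in `[0, 1]`.
#' @export
accuracy <- function(params, arch, batch, inactivation = NULL, seed = NULL,
                     noise_std = NULL) {
  stopifnot(inherits(batch, "trial_batch"))
  rel <- vapply(batch$trials, function(tr) {
    if (tr$context == "motion") tr$d_m else tr$d_c
  }, numeric(1))
  keep <- rel != 0
  if (!any(keep)) stop_invalid("no scorable trials (all zero-coherence)")
  arr <- batch_input_array(batch)[, , keep, drop = FALSE]
  out <- with_seed(seed, forward_batch(params, arch, arr, inactivation,
                                       keep_states = is.null(params$W_out),
                                       noise_std = noise_std))
  choices <- decode_batch(out, arch, batch$config$decision_window)
  correct <- vapply(batch$trials[keep], `[[`, character(1), "correct_choice")
  mean(choices == correct)
}
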