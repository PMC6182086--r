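#' Training specification for the pyrl actor-critic family
#'
#' The policy network (gated recurrent units) selects one of three actions
#' (choice 1, choice 2, stay) at the decision step from a softmax readout and
#' is trained with the likelihood-ratio (REINFORCE) policy-gradient estimator,
#' with the baseline network's value prediction subtracted to reduce
#' variance. The baseline network receives the policy's recurrent rates and
#' action probabilities and minimizes the squared error of its
#' cumulative-reward prediction. Both networks are optimized with
#' adaptive-moment (Adam) SGD with gradient clipping, and only the synapses
#' marked plastic in each network's mask ever change.
#'
#' @param reward_values Rewards: correct decision, incorrect decision, and
#'   per-step fixation-break penalty (used only when a fixation epoch is
#'   configured).
#' @param learning_rate,baseline_learning_rate Adam step sizes.
#' @param gradient_clip_norm Global gradient-norm clip.
#' @param n_iterations Iteration budget (each iteration consumes
#'   `batch_size` trials).
#' @param batch_size Trials per gradient estimate.
#' @param entropy_bonus Coefficient of the policy-entropy bonus added to the
#'   REINFORCE surrogate; keeps the softmax policy from collapsing onto one
#'   action before the contextual strategy is found.
#' @param check_every,stop_accuracy,n_val Validation checkpoint settings.
#' @return A `pyrl_spec` object.
#' @export
pyrl_spec <- function(reward_values = list(correct = 1, incorrect = 0,
                                           fixation_break = -1),
                      learning_rate = 2e-3, baseline_learning_rate = 4e-3,
                      gradient_clip_norm = 1, n_iterations = 1200,
                      batch_size = 32, entropy_bonus = 0.01, check_every = 25,
                      stop_accuracy = 0.85, n_val = 500) {
  structure(list(family = "pyrl", reward_values = reward_values,
                 learning_rate = learning_rate,
                 baseline_learning_rate = baseline_learning_rate,
                 gradient_clip_norm = gradient_clip_norm,
                 n_iterations = as.integer(n_iterations),
                 batch_size = as.integer(batch_size),
                 entropy_bonus = entropy_bonus,
                 check_every = as.integer(check_every),
                 stop_accuracy = stop_accuracy, n_val = as.integer(n_val)),
            class = c("pyrl_spec", "trainer_spec"))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

# forward pass through a gated network keeping everything the backward pass
# needs. inputs: list over time of N_in x B matrices.
gru_forward <- function(params, arch, inputs, noise_std) {
  tt <- length(inputs)
  B <- ncol(inputs[[1]])
  N <- arch$N_rec
  act <- activation_fn(arch)
  x <- matrix(0, N, B)
  steps <- vector("list", tt)
  rs <- vector("list", tt)
  zs <- vector("list", tt)
  for (t in seq_len(tt)) {
    noise <- if (noise_std > 0) matrix(rnorm(N * B, 0, noise_std), N, B) else 0
    st <- step_gated(params, arch, x, inputs[[t]], noise, return_gates = TRUE)
    st$x_prev <- x
    x <- st$x
    steps[[t]] <- st
    rs[[t]] <- act(x)
    zs[[t]] <- params$W_out %*% rs[[t]] + params$b_z
  }
  check_finite(x, "gated forward pass")
  list(steps = steps, rs = rs, zs = zs, tt = tt, B = B)
}

# backward pass through the gated network given per-step output-error
# gradients dzs (N_out x B each, may be zero matrices).
gru_backward <- function(params, arch, inputs, fwd, dzs) {
  N <- arch$N_rec
  B <- fwd$B
  grads <- list(W_rec = matrix(0, N, N), W_in = matrix(0, N, arch$N_in),
                b_x = rep(0, N),
                W_q_in = matrix(0, N, arch$N_in), W_q_rec = matrix(0, N, N),
                b_q = rep(0, N),
                W_s_in = matrix(0, N, arch$N_in), W_s_rec = matrix(0, N, N),
                b_s = rep(0, N),
                W_out = matrix(0, arch$N_out, N), b_z = rep(0, arch$N_out))
  Wt <- t(params$W_rec); Wot <- t(params$W_out)
  Wqt <- t(params$W_q_rec); Wst <- t(params$W_s_rec)
  gcarry <- matrix(0, N, B)
  for (t in rev(seq_len(fwd$tt))) {
    st <- fwd$steps[[t]]
    phi_t <- activation_grad(arch, fwd$rs[[t]], st$x)
    g <- gcarry + phi_t * (Wot %*% dzs[[t]])
    grads$W_out <- grads$W_out + dzs[[t]] %*% t(fwd$rs[[t]])
    grads$b_z <- grads$b_z + rowSums(dzs[[t]])

    dc <- g * st$q
    dq <- g * (st$cand - st$x_prev)
    da_q <- dq * st$q * (1 - st$q)
    dsr <- Wt %*% dc
    ds <- dsr * st$r_prev
    da_s <- ds * st$s * (1 - st$s)
    dr_prev <- dsr * st$s + Wqt %*% da_q + Wst %*% da_s
    phi_prev <- activation_grad(arch, st$r_prev, st$x_prev)
    gcarry <- g * (1 - st$q) + phi_prev * dr_prev

    sr <- st$s * st$r_prev
    u_t <- inputs[[t]]
    grads$W_rec <- grads$W_rec + dc %*% t(sr)
    grads$W_in <- grads$W_in + dc %*% t(u_t)
    grads$b_x <- grads$b_x + rowSums(dc)
    grads$W_q_in <- grads$W_q_in + da_q %*% t(u_t)
    grads$W_q_rec <- grads$W_q_rec + da_q %*% t(st$r_prev)
    grads$b_q <- grads$b_q + rowSums(da_q)
    grads$W_s_in <- grads$W_s_in + da_s %*% t(u_t)
    grads$W_s_rec <- grads$W_s_rec + da_s %*% t(st$r_prev)
    grads$b_s <- grads$b_s + rowSums(da_s)
  }
  grads
}

inputs_to_list <- function(arr) {
  tt <- dim(arr)[1]
  lapply(seq_len(tt), function(t) matrix(arr[t, , ], dim(arr)[2], dim(arr)[3]))
}

#' Train a pyrl actor-critic pair
#'
#' REINFORCE with a learned baseline: every iteration, a batch of trials is
#' run through the policy network, an action is sampled from the softmax
#' policy at the decision step, the reward (+1 correct, 0 otherwise) is
#' observed, and the policy gradient `(R - v) * grad log pi(a)` is
#' backpropagated through the gated dynamics. The baseline network, fed the
#' policy's recurrent rates and action probabilities, is trained on the
#' squared error of its cumulative-reward prediction. Recurrent synapses
#' outside each network's plasticity mask are frozen exactly.
#'
#' @param policy_params,baseline_params Initial parameters from
#'   [init_parameters()].
#' @param policy_arch,baseline_arch The matching architectures
#'   (`"pyrl_policy"`, `"pyrl_baseline"`); the baseline input width must equal
#'   `N_rec + N_out` of the policy.
#' @param task_cfg A [task_config()].
#' @param spec A [pyrl_spec()].
#' @param seed Integer seed.
#' @return A list with `policy` and `baseline` training records.
#' @export
pyrl_train <- function(policy_params, baseline_params, policy_arch,
                       baseline_arch, task_cfg, spec = pyrl_spec(),
                       seed = 1L) {
  stopifnot(policy_arch$family == "pyrl_policy",
            baseline_arch$family == "pyrl_baseline")
  if (baseline_arch$N_in != policy_arch$N_rec + policy_arch$N_out) {
    stop_invalid("baseline N_in must be policy N_rec + N_out (%d), got %d",
                 policy_arch$N_rec + policy_arch$N_out, baseline_arch$N_in)
  }
  if (is.null(spec$reward_values)) stop_invalid("reward schedule absent")
  p_init <- policy_params
  b_init <- baseline_params
  rv <- spec$reward_values
  val_batch <- make_batch(task_cfg, spec$n_val, "alternating", family = "pyrl",
                          seed = derive_seed(seed, 900001))
  p_opt <- NULL; b_opt <- NULL
  trace <- list(); converged <- FALSE
  action_labels <- c("choice1", "choice2", "stay")
  for (it in seq_len(spec$n_iterations)) {
    batch <- make_batch(task_cfg, spec$batch_size, "alternating",
                        family = "pyrl", seed = derive_seed(seed, it))
    arr <- batch_input_array(batch)
    u_list <- inputs_to_list(arr)
    B <- batch$n_trials
    res <- with_seed(derive_seed(seed, 500000 + it), {
      fwd <- gru_forward(policy_params, policy_arch, u_list,
                         policy_arch$noise_std_rec)
      tt <- fwd$tt
      pis <- lapply(fwd$zs, softmax_cols)
      pi_T <- pis[[tt]]
      a_idx <- vapply(seq_len(B), function(i) {
        sample.int(policy_arch$N_out, 1L, prob = pi_T[, i])
      }, integer(1))
      correct <- vapply(batch$trials, `[[`, character(1), "correct_choice")
      R <- ifelse(action_labels[a_idx] == correct, rv$correct, rv$incorrect)

      # baseline: inputs are the policy's rates and action probabilities
      b_inputs <- lapply(seq_len(tt), function(t) rbind(fwd$rs[[t]], pis[[t]]))
      b_fwd <- gru_forward(baseline_params, baseline_arch, b_inputs,
                           baseline_arch$noise_std_rec)
      v <- do.call(rbind, lapply(b_fwd$zs, function(z) z[1, ]))  # tt x B
      adv <- R - v[tt, ]

      # policy surrogate gradient at the decision step
      onehot <- matrix(0, policy_arch$N_out, B)
      onehot[cbind(a_idx, seq_len(B))] <- 1
      dzs_p <- lapply(seq_len(tt), function(t) matrix(0, policy_arch$N_out, B))
      dz_T <- sweep(pi_T - onehot, 2, adv, `*`) / B
      if ((spec$entropy_bonus %||% 0) > 0) {
        lp <- log(pmax(pi_T, 1e-12))
        H <- -colSums(pi_T * lp)
        dz_T <- dz_T + spec$entropy_bonus * (pi_T * sweep(lp, 2, -H, `-`)) / B
      }
      dzs_p[[tt]] <- dz_T
      p_grads <- gru_backward(policy_params, policy_arch, u_list, fwd, dzs_p)

      # baseline squared-error gradient at every step (return-to-go = R)
      dzs_b <- lapply(seq_len(tt), function(t) {
        matrix(2 * (v[t, ] - R) / (tt * B), 1, B)
      })
      b_grads <- gru_backward(baseline_params, baseline_arch, b_inputs,
                              b_fwd, dzs_b)
      list(p_grads = p_grads, b_grads = b_grads, mean_R = mean(R))
    })
    res$p_grads$W_rec[!policy_params$plasticity_mask] <- 0
    res$b_grads$W_rec[!baseline_params$plasticity_mask] <- 0
    p_grads <- clip_gradients(res$p_grads, spec$gradient_clip_norm)
    b_grads <- clip_gradients(res$b_grads, spec$gradient_clip_norm)
    if (is.null(p_opt)) p_opt <- adam_state(p_grads)
    if (is.null(b_opt)) b_opt <- adam_state(b_grads)
    up <- adam_update(policy_params[names(p_grads)], p_grads, p_opt,
                      spec$learning_rate)
    policy_params[names(p_grads)] <- up$params; p_opt <- up$state
    up <- adam_update(baseline_params[names(b_grads)], b_grads, b_opt,
                      spec$baseline_learning_rate)
    baseline_params[names(b_grads)] <- up$params; b_opt <- up$state

    if (it %% spec$check_every == 0 || it == spec$n_iterations) {
      acc <- accuracy(policy_params, policy_arch, val_batch,
                      seed = derive_seed(seed, 700000 + it))
      trace[[length(trace) + 1]] <- data.frame(iteration = it,
                                               mean_reward = res$mean_R,
                                               accuracy = acc)
      if (acc >= spec$stop_accuracy) { converged <- TRUE; break }
    }
  }
  cfg <- list(arch = policy_arch, baseline_arch = baseline_arch,
              task = task_cfg, trainer = spec)
  list(
    policy = new_training_record("pyrl_policy", p_init, policy_params,
                                 do.call(rbind, trace), seed, cfg, converged),
    baseline = new_training_record("pyrl_baseline", b_init, baseline_params,
                                   NULL, seed, cfg, converged)
  )
}
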