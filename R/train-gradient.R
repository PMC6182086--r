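#' Training specification for the pycog family
#'
#' Masked-error stochastic gradient descent: the objective is the mean over
#' trials of the masked mean-squared output error plus a vanishing-gradient
#' regularizer weighted by `lambda_omega`. The Dale's-law sign constraint is
#' re-projected onto the recurrent matrix after every update.
#'
#' @param lambda_omega Weight of the vanishing-gradient regularizer.
#' @param gradient_clip_norm Global gradient-norm clip threshold.
#' @param learning_rate Step size of the optimizer.
#' @param n_iterations Iteration budget.
#' @param batch_size Trials per gradient estimate.
#' @param optimizer `"adam"` (adaptive-moment SGD, the default) or `"sgd"`.
#' @param check_every Iterations between validation checkpoints.
#' @param stop_accuracy Early-stop bar on validation accuracy.
#' @param n_val Validation-batch size.
#' @return A `pycog_loss_spec` object.
#' @export
pycog_spec <- function(lambda_omega = 0.01, gradient_clip_norm = 1,
                       learning_rate = 2e-3, n_iterations = 800,
                       batch_size = 32, optimizer = c("adam", "sgd"),
                       check_every = 25, stop_accuracy = 0.85, n_val = 500) {
  if (lambda_omega < 0) stop_invalid("lambda_omega must be >= 0")
  if (gradient_clip_norm <= 0) stop_invalid("gradient_clip_norm must be > 0")
  structure(list(family = "pycog", lambda_omega = lambda_omega,
                 gradient_clip_norm = gradient_clip_norm,
                 learning_rate = learning_rate,
                 n_iterations = as.integer(n_iterations),
                 batch_size = as.integer(batch_size),
                 optimizer = match.arg(optimizer),
                 check_every = as.integer(check_every),
                 stop_accuracy = stop_accuracy, n_val = as.integer(n_val)),
            class = c("pycog_loss_spec", "trainer_spec"))
}

#' Training specification for the HF-objective family
#'
#' The objective scores the scalar output at the first and last time points
#' of every trial against targets 0 and +/-1. The default backend minimizes
#' it by adaptive-moment gradient descent; structural damping (a penalty on
#' changes of the recurrent-rate trajectory between parameter iterates) is
#' available but off by default, and the curvature/conjugate-gradient backend
#' is not provided.
#'
#' @param lambda_R Structural-damping coefficient.
#' @param damping_enabled Whether the damping penalty enters the objective.
#' @param optimizer_backend Only `"gradient_descent"` is available.
#' @inheritParams pycog_spec
#' @return An `hf_loss_spec` object.
#' @export
hf_spec <- function(lambda_R = 0.1, damping_enabled = FALSE,
                    optimizer_backend = "gradient_descent",
                    gradient_clip_norm = 1, learning_rate = 2e-3,
                    n_iterations = 800, batch_size = 32,
                    optimizer = c("adam", "sgd"), check_every = 25,
                    stop_accuracy = 0.85, n_val = 500) {
  if (lambda_R < 0) stop_invalid("lambda_R must be >= 0")
  if (!identical(optimizer_backend, "gradient_descent")) {
    stop_invalid("only the gradient_descent backend is implemented")
  }
  structure(list(family = "hf", lambda_R = lambda_R,
                 damping_enabled = isTRUE(damping_enabled),
                 optimizer_backend = optimizer_backend,
                 gradient_clip_norm = gradient_clip_norm,
                 learning_rate = learning_rate,
                 n_iterations = as.integer(n_iterations),
                 batch_size = as.integer(batch_size),
                 optimizer = match.arg(optimizer),
                 check_every = as.integer(check_every),
                 stop_accuracy = stop_accuracy, n_val = as.integer(n_val)),
            class = c("hf_loss_spec", "trainer_spec"))
}

batch_targets <- function(batch, N_out) {
  tt <- batch$config$n_steps
  B <- batch$n_trials
  targ <- array(0, c(tt, N_out, B))
  mask <- matrix(FALSE, tt, B)
  for (i in seq_len(B)) {
    tr <- batch$trials[[i]]
    if (is.null(tr$target_outputs)) {
      stop_invalid("trial %d has no targets; build the batch with a family", i)
    }
    targ[, , i] <- tr$target_outputs
    mask[, i] <- tr$error_mask
  }
  list(targets = targ, mask = mask)
}

#' HF-family objective
#'
#' `L = 1/(2 N_trial) * sum over trials of the squared output errors at the
#' first and last time points`, optionally plus `lambda_R` times a structural
#' damping penalty (cross-entropy distance between the current recurrent-rate
#' trajectory and a frozen reference trajectory).
#'
#' @param params,arch Network parameters and architecture (family `"hf"`).
#' @param batch A batch built with `family = "hf"` (so targets and masks are
#'   attached).
#' @param spec An [hf_spec()].
#' @param noise_std Recurrent noise during the evaluation (default 0:
#'   deterministic objective).
#' @param reference_rates Optional steps x N_rec x B array of reference rates
#'   for the damping penalty.
#' @return The scalar objective; the squared-error and damping components are
#'   attached as attributes `"L"` and `"damping"`.
#' @export
hf_loss <- function(params, arch, batch, spec = hf_spec(), noise_std = 0,
                    reference_rates = NULL) {
  tm <- batch_targets(batch, arch$N_out)
  if (!all(tm$mask[1, ])) stop_invalid("HF batch must score the first time point")
  arr <- batch_input_array(batch)
  out <- forward_batch(params, arch, arr, keep_states = spec$damping_enabled,
                       noise_std = noise_std)
  B <- batch$n_trials
  err <- (out$z - tm$targets)
  msk <- array(rep(tm$mask, each = arch$N_out), dim = dim(out$z)[c(2, 1, 3)])
  msk <- aperm(msk, c(2, 1, 3))
  L <- sum((err^2) * msk) / (2 * B)
  damping <- 0
  if (spec$damping_enabled && !is.null(reference_rates)) {
    damping <- rate_cross_entropy(reference_rates, out$r) / B
  }
  structure(L + spec$lambda_R * damping, L = L, damping = damping)
}

# cross-entropy distance between two tanh-rate trajectories, mapped to (0,1)
rate_cross_entropy <- function(r_ref, r_new) {
  p <- pmin(pmax((r_ref + 1) / 2, 1e-7), 1 - 1e-7)
  q <- pmin(pmax((r_new + 1) / 2, 1e-7), 1 - 1e-7)
  -sum(p * log(q) + (1 - p) * log(1 - q)) / length(p)
}

#' pycog-family objective
#'
#' Mean over trials of the masked mean-squared output error,
#' `L_n = 1/(N_out T) * sum over channels and masked time points of
#' (z - z_target)^2`, plus `lambda_omega` times the vanishing-gradient
#' regularizer (reported as attribute `"omega"`; zero when evaluated without
#' a backward pass).
#'
#' @param params,arch Network parameters and architecture (family `"pycog"`).
#' @param batch A batch built with `family = "pycog"`.
#' @param spec A [pycog_spec()].
#' @param noise_std Recurrent noise sd during evaluation (default 0).
#' @return Scalar objective with attributes `"L"` and `"omega"`.
#' @export
pycog_loss <- function(params, arch, batch, spec = pycog_spec(),
                       noise_std = 0) {
  tm <- batch_targets(batch, arch$N_out)
  if (!any(tm$mask)) stop_invalid("error mask is false everywhere")
  g <- bptt_grad(params, arch, batch, spec, noise_std = noise_std,
                 want_grads = FALSE)
  structure(g$loss, L = g$L, omega = g$omega)
}

# masked-quadratic loss + BPTT gradients shared by the hf and pycog families.
# Returns loss, per-parameter gradients, and the vanishing-gradient
# regularizer Omega (value always; its gradient enters dW_rec via the
# constant-delta approximation when lambda_omega > 0).
bptt_grad <- function(params, arch, batch, spec, noise_std = NULL,
                      want_grads = TRUE) {
  arr <- batch_input_array(batch)
  tm <- batch_targets(batch, arch$N_out)
  tt <- dim(arr)[1]; B <- dim(arr)[3]
  N <- arch$N_rec
  a <- arch$alpha
  act <- activation_fn(arch)
  sd_rec <- noise_std %||% arch$noise_std_rec
  family <- spec$family

  xs <- vector("list", tt); rs <- vector("list", tt); zs <- vector("list", tt)
  us <- vector("list", tt)
  x <- matrix(0, N, B)
  r0 <- act(x)
  r <- r0
  for (t in seq_len(tt)) {
    u_t <- matrix(arr[t, , ], arch$N_in, B)
    noise <- if (sd_rec > 0) matrix(rnorm(N * B, 0, sd_rec), N, B) else 0
    x <- (1 - a) * x + a * (params$W_rec %*% r + params$W_in %*% u_t +
                              params$b_x + noise)
    r <- act(x)
    xs[[t]] <- x; rs[[t]] <- r; us[[t]] <- u_t
    zs[[t]] <- params$W_out %*% r + params$b_z
  }
  check_finite(x, "training forward pass")

  # per-step output-error gradients and loss
  loss <- 0
  dzs <- vector("list", tt)
  for (t in seq_len(tt)) {
    ztarg <- t(matrix(tm$targets[t, , ], arch$N_out, B))
    err <- zs[[t]] - t(ztarg)
    m <- tm$mask[t, ]
    err[, !m] <- 0
    if (family == "hf") {
      loss <- loss + sum(err^2) / (2 * B)
      dzs[[t]] <- err / B
    } else {
      loss <- loss + sum(err^2) / (arch$N_out * tt * B)
      dzs[[t]] <- 2 * err / (arch$N_out * tt * B)
    }
  }

  grads <- list(W_rec = matrix(0, N, N), W_in = matrix(0, N, arch$N_in),
                W_out = matrix(0, arch$N_out, N), b_x = rep(0, N),
                b_z = rep(0, arch$N_out))
  gnext <- matrix(0, N, B)
  omega_terms <- 0; omega_count <- 0
  lam_om <- spec$lambda_omega %||% 0
  dW_om <- if (lam_om > 0) matrix(0, N, N) else NULL
  Wt <- t(params$W_rec)
  Wot <- t(params$W_out)
  for (t in rev(seq_len(tt))) {
    phi <- activation_grad(arch, rs[[t]], xs[[t]])
    carry <- if (t < tt) {
      trans <- phi * (a * (Wt %*% gnext)) + (1 - a) * gnext
      ng <- sqrt(sum(gnext^2))
      if (ng > 1e-300) {
        ratio <- sqrt(sum(trans^2)) / ng
        omega_terms <- omega_terms + (ratio - 1)^2
        omega_count <- omega_count + 1
        if (!is.null(dW_om) && ratio > 1e-12) {
          # d(ratio)/dW_rec with the backpropagated deltas held constant
          dW_om <- dW_om + (2 * (ratio - 1)) *
            (a / (sqrt(sum(trans^2)) * ng)) * (gnext %*% t(trans * phi))
        }
      }
      trans
    } else matrix(0, N, B)
    g <- carry + phi * (Wot %*% dzs[[t]])
    if (want_grads) {
      r_prev <- if (t > 1) rs[[t - 1]] else r0
      grads$W_rec <- grads$W_rec + a * (g %*% t(r_prev))
      grads$W_in <- grads$W_in + a * (g %*% t(us[[t]]))
      grads$b_x <- grads$b_x + a * rowSums(g)
      grads$W_out <- grads$W_out + dzs[[t]] %*% t(rs[[t]])
      grads$b_z <- grads$b_z + rowSums(dzs[[t]])
    }
    gnext <- g
  }
  omega <- if (omega_count > 0) omega_terms / omega_count else 0
  if (!is.null(dW_om) && omega_count > 0 && want_grads) {
    grads$W_rec <- grads$W_rec + lam_om * (dW_om / omega_count)
  }
  list(loss = loss + lam_om * omega, L = loss, omega = omega,
       grads = if (want_grads) grads else NULL)
}

clip_gradients <- function(grads, clip_norm) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gn) && gn > clip_norm) {
    grads <- lapply(grads, function(g) g * (clip_norm / gn))
  }
  grads
}

adam_state <- function(grads) {
  list(m = lapply(grads, function(g) g * 0),
       v = lapply(grads, function(g) g * 0), t = 0)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Project the Dale's-law sign constraint onto a recurrent matrix
#'
#' Entries of excitatory presynaptic columns that became negative (and of
#' inhibitory columns that became positive) are clipped to zero; the diagonal
#' is zeroed. Idempotent.
#'
#' @param W_rec Recurrent weight matrix.
#' @param dale_signs Per-unit sign vector (+1 excitatory, -1 inhibitory).
#' @return The projected matrix.
#' @export
project_dale <- function(W_rec, dale_signs) {
  viol <- sweep(W_rec, 2, dale_signs, `*`) < 0
  W_rec[viol] <- 0
  diag(W_rec) <- 0
  W_rec
}

#' Train an HF- or pycog-family network by gradient descent
#'
#' Backpropagation through time on the family's objective, with global
#' gradient-norm clipping and (pycog) Dale's-law re-projection after every
#' update. Training stops at the iteration budget or once validation accuracy
#' reaches `spec$stop_accuracy`.
#'
#' @param params Initial [init_parameters()]; a snapshot is taken before any
#'   update.
#' @param arch The matching [architecture()].
#' @param task_cfg A [task_config()] used to generate fresh trial batches
#'   every iteration.
#' @param spec An [hf_spec()] or [pycog_spec()].
#' @param seed Integer seed; the same seed reproduces the run bit-identically.
#' @return A `training_record` with `W_init`, `W_last`, `performance_trace`
#'   (data frame of checkpoint iteration, loss and validation accuracy),
#'   `seed`, `converged`, and a config snapshot.
#' @export
sgd_train <- function(params, arch, task_cfg, spec, seed = 1L) {
  stopifnot(inherits(spec, "trainer_spec"))
  family <- spec$family
  stopifnot(arch$family == family)
  W_init <- params
  val_batch <- make_batch(task_cfg, spec$n_val, "alternating", family = family,
                          seed = derive_seed(seed, 900001))
  ref_rates <- NULL
  opt <- NULL
  trace <- list()
  converged <- FALSE
  for (it in seq_len(spec$n_iterations)) {
    batch <- make_batch(task_cfg, spec$batch_size, "alternating",
                        family = family, seed = derive_seed(seed, it))
    with_seed(derive_seed(seed, 500000 + it), {
      g <- bptt_grad(params, arch, batch, spec)
    })
    grads <- clip_gradients(g$grads, spec$gradient_clip_norm)
    if (spec$optimizer == "adam") {
      if (is.null(opt)) opt <- adam_state(grads)
      up <- adam_update(params[names(grads)], grads, opt, spec$learning_rate)
      params[names(grads)] <- up$params
      opt <- up$state
    } else {
      for (nm in names(grads)) {
        params[[nm]] <- params[[nm]] - spec$learning_rate * grads[[nm]]
      }
    }
    if (family == "pycog") {
      params$W_rec <- project_dale(params$W_rec, arch$dale_signs)
    }
    if (!is.finite(g$loss)) {
      stop_invalid("training diverged (non-finite loss) at iteration %d", it)
    }
    if (it %% spec$check_every == 0 || it == spec$n_iterations) {
      acc <- accuracy(params, arch, val_batch,
                      seed = derive_seed(seed, 700000 + it))
      trace[[length(trace) + 1]] <- data.frame(iteration = it, loss = g$loss,
                                               accuracy = acc)
      if (acc >= spec$stop_accuracy) { converged <- TRUE; break }
    }
  }
  new_training_record(family, W_init, params, do.call(rbind, trace), seed,
                      list(arch = arch, task = task_cfg, trainer = spec),
                      converged)
}

new_training_record <- function(family, W_init, W_last, trace, seed, config,
                                converged) {
  structure(list(family = family, W_init = W_init, W_last = W_last,
                 performance_trace = trace, seed = seed, config = config,
                 converged = converged),
            class = "training_record")
}

#' @export
print.training_record <- function(x, ...) {
  tr <- x$performance_trace
  final <- if (!is.null(tr) && nrow(tr)) tr$accuracy[nrow(tr)] else NA
  cat(sprintf("training_record '%s': seed %s, %s, final accuracy %.3f\n",
              x$family, format(x$seed),
              if (isTRUE(x$converged)) "converged" else "budget exhausted",
              final))
  invisible(x)
}
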