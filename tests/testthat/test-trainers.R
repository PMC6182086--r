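test_that("eligibility accumulation matches the superlinear Hebbian rule", {
  st <- eligibility_state(3)
  cfg <- rhebb_config()
  # with x_bar frozen at 0 (rate 0), r_j = 1 and x_i = 2 give e = 2^3
  st1 <- rhebb_accumulate(st, r_prev = c(1, 0, 1), x_now = c(2, 2, 2),
                          config = cfg, x_bar_rate = 0)
  expect_equal(st1$e[, 1], c(8, 8, 8))
  expect_equal(st1$e[, 2], c(0, 0, 0))  # silent presynaptic unit: unchanged
  expect_error(rhebb_accumulate(st, r_prev = c(1, 0), x_now = c(2, 2, 2)),
               "mismatch")

  # 20 random steps against a per-synapse brute-force loop on 5 units
  set.seed(14)
  n <- 5
  st <- eligibility_state(n)
  e_oracle <- matrix(0, n, n)
  xb_oracle <- rep(0, n)
  rate <- 0.2
  for (t in 1:20) {
    r_prev <- runif(n)
    x_now <- rnorm(n)
    st <- rhebb_accumulate(st, r_prev, x_now, cfg, x_bar_rate = rate)
    xb_oracle <- (1 - rate) * xb_oracle + rate * x_now
    for (i in 1:n) for (j in 1:n) {
      e_oracle[i, j] <- e_oracle[i, j] + (r_prev[j] * (x_now[i] - xb_oracle[i]))^3
    }
  }
  expect_lt(max(abs(st$e - e_oracle)), 1e-10)
})

test_that("the reward-modulated update is eta * e * (R - Rbar)", {
  n <- 2
  params <- list(W_rec = matrix(0, n, n))
  st <- eligibility_state(n)
  st$e <- matrix(8, n, n)
  st$R_bar <- c(a = 0.5)
  cfg <- rhebb_config(eta = 0.1, max_dw = NULL, reward_avg_rate = 0.25)
  up <- rhebb_apply(params, st, R = 1, config = cfg, condition = "a")
  expect_equal(up$params$W_rec, matrix(0.4, n, n))  # 0.1 * 8 * 0.5
  expect_equal(unname(up$state$R_bar["a"]), 0.625)

  # R equal to the baseline changes nothing
  up0 <- rhebb_apply(params, st, R = 0.5, config = cfg, condition = "a")
  expect_equal(up0$params$W_rec, params$W_rec)

  # sign rule: positive trace, reward below baseline -> depression
  upn <- rhebb_apply(params, st, R = 0, config = cfg, condition = "a")
  expect_true(all(upn$params$W_rec < 0))

  # unseen condition initializes the baseline without a weight change
  upi <- rhebb_apply(params, st, R = -1, config = cfg, condition = "new")
  expect_equal(upi$params$W_rec, params$W_rec)
  expect_equal(unname(upi$state$R_bar["new"]), -1)

  expect_error(rhebb_apply(params, st, R = NaN, config = cfg), "non-finite")
})

test_that("pycog loss is the masked mean-squared error plus regularizer", {
  arch <- architecture("pycog", N_rec = 10)
  p <- init_parameters(arch, seed = 1)
  cfg <- task_config(trial_duration = 6, encoding_mode = "separated_4channel",
                     noise_std_motion = 0, noise_std_color = 0)
  b <- make_batch(cfg, 3, "alternating", family = "pycog", seed = 2)

  # outputs forced to equal targets everywhere -> zero loss
  pz <- p; pz$W_rec[] <- 0; pz$W_in[] <- 0; pz$W_out[] <- 0
  for (i in seq_along(b$trials)) {
    b$trials[[i]]$target_outputs[] <- 0
  }
  l0 <- pycog_loss(pz, arch, b, pycog_spec(lambda_omega = 0), noise_std = 0)
  expect_equal(as.numeric(l0), 0)

  # single trial, single masked step, z - z* = (1, -1): L = (1 + 1) / 2
  cfg1 <- task_config(trial_duration = 1, encoding_mode = "separated_4channel",
                      noise_std_motion = 0, noise_std_color = 0)
  b1 <- make_batch(cfg1, 1, "alternating", family = "pycog", seed = 3)
  pz$b_z <- c(1, -1)
  b1$trials[[1]]$target_outputs[] <- 0
  expect_equal(as.numeric(pycog_loss(pz, arch, b1, pycog_spec(lambda_omega = 0),
                                     noise_std = 0)), 1)

  # random small batch equals an independently coded double sum
  b2 <- make_batch(cfg, 4, "alternating", family = "pycog", seed = 5)
  l <- pycog_loss(p, arch, b2, pycog_spec(lambda_omega = 0), noise_std = 0)
  oracle <- 0
  for (tr in b2$trials) {
    traj <- run_trial(p, arch, tr, noise_std = 0)
    err2 <- 0
    for (t in which(tr$error_mask)) {
      err2 <- err2 + sum((traj$z[t, ] - tr$target_outputs[t, ])^2)
    }
    oracle <- oracle + err2 / (arch$N_out * cfg$n_steps)
  }
  expect_equal(as.numeric(l), oracle / 4, tolerance = 1e-12)

  bmask <- b2
  for (i in seq_along(bmask$trials)) bmask$trials[[i]]$error_mask[] <- FALSE
  expect_error(pycog_loss(p, arch, bmask, pycog_spec()), "mask")
})

test_that("the HF objective scores the first and last time points", {
  arch <- architecture("hf", N_rec = 10)
  p <- init_parameters(arch, seed = 1)
  cfg <- task_config(trial_duration = 5, noise_std_motion = 0,
                     noise_std_color = 0)
  b <- make_batch(cfg, 1, "alternating", family = "hf", seed = 2)

  # an all-zero network with target +1 at T: loss = 1/2
  pz <- p; pz$W_rec[] <- 0; pz$W_in[] <- 0; pz$W_out[] <- 0
  b$trials[[1]]$target_outputs[5, 1] <- 1
  expect_equal(as.numeric(hf_loss(pz, arch, b, noise_std = 0)), 0.5)

  # perfect outputs give zero
  b0 <- b; b0$trials[[1]]$target_outputs[] <- 0
  expect_equal(as.numeric(hf_loss(pz, arch, b0, noise_std = 0)), 0)

  # batch of 3 random trials equals a brute-force evaluation
  b3 <- make_batch(cfg, 3, "alternating", family = "hf", seed = 4)
  l <- hf_loss(p, arch, b3, noise_std = 0)
  oracle <- 0
  for (tr in b3$trials) {
    traj <- run_trial(p, arch, tr, noise_std = 0)
    oracle <- oracle + sum((traj$z[c(1, 5), 1] - tr$target_outputs[c(1, 5), 1])^2)
  }
  expect_equal(as.numeric(l), oracle / (2 * 3), tolerance = 1e-12)
})

test_that("BPTT gradients agree with finite differences", {
  ns <- asNamespace("plasticrnn")
  for (fam in c("hf", "pycog")) {
    arch <- architecture(fam, N_rec = 7)
    p <- init_parameters(arch, seed = 3)
    cfg <- task_config(trial_duration = 6,
                       encoding_mode = if (fam == "hf") "signed_2channel"
                                       else "separated_4channel",
                       noise_std_motion = 0, noise_std_color = 0)
    b <- make_batch(cfg, 2, "alternating", family = fam, seed = 4)
    spec <- if (fam == "hf") hf_spec() else pycog_spec(lambda_omega = 0)
    g <- ns$bptt_grad(p, arch, b, spec, noise_std = 0)
    lossfun <- function(pp) ns$bptt_grad(pp, arch, b, spec, noise_std = 0,
                                         want_grads = FALSE)$loss
    eps <- 1e-5
    for (nm in c("W_rec", "W_in", "W_out", "b_x", "b_z")) {
      i <- which.max(abs(g$grads[[nm]]))
      pp <- p; pm <- p
      pp[[nm]][i] <- pp[[nm]][i] + eps
      pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      expect_lt(abs(g$grads[[nm]][i] - num) / max(abs(num), 1e-8), 1e-3)
    }
  }
})

test_that("a zero learning rate leaves the parameters untouched", {
  arch <- architecture("hf", N_rec = 12)
  p <- init_parameters(arch, seed = 2)
  rec <- sgd_train(p, arch, default_task_config("hf"),
                   hf_spec(learning_rate = 0, n_iterations = 5,
                           check_every = 5, stop_accuracy = 1.1), seed = 3)
  expect_identical(rec$W_last$W_rec, rec$W_init$W_rec)
  expect_identical(rec$W_last$W_out, rec$W_init$W_out)
})

test_that("training is reproducible from the seed", {
  arch <- architecture("hf", N_rec = 10)
  p <- init_parameters(arch, seed = 2)
  spec <- hf_spec(n_iterations = 8, check_every = 8, stop_accuracy = 1.1)
  r1 <- sgd_train(p, arch, default_task_config("hf"), spec, seed = 77)
  r2 <- sgd_train(p, arch, default_task_config("hf"), spec, seed = 77)
  expect_identical(r1$W_last, r2$W_last)
})

test_that("the Dale constraint survives pycog training updates", {
  arch <- architecture("pycog", N_rec = 20)
  p <- init_parameters(arch, seed = 4)
  rec <- sgd_train(p, arch, default_task_config("pycog"),
                   pycog_spec(n_iterations = 12, check_every = 12,
                              stop_accuracy = 1.1), seed = 5)
  exc <- which(arch$dale_signs > 0)
  inh <- which(arch$dale_signs < 0)
  expect_true(all(rec$W_last$W_rec[, exc] >= 0))
  expect_true(all(rec$W_last$W_rec[, inh] <= 0))
  expect_true(all(diag(rec$W_last$W_rec) == 0))
  # projection is idempotent
  W <- rec$W_last$W_rec
  expect_identical(project_dale(W, arch$dale_signs), W)
})

test_that("pyrl training freezes non-plastic synapses exactly", {
  arch <- architecture("pyrl_policy", N_rec = 16)
  b_arch <- architecture("pyrl_baseline", N_rec = 10, n_rec_policy = 16)
  pp <- init_parameters(arch, seed = 6)
  bp <- init_parameters(b_arch, seed = 7)
  rec <- pyrl_train(pp, bp, arch, b_arch, default_task_config("pyrl"),
                    pyrl_spec(n_iterations = 15, check_every = 15,
                              stop_accuracy = 1.1), seed = 8)
  pol <- rec$policy
  frozen <- !pp$plasticity_mask
  expect_identical(pol$W_last$W_rec[frozen], pol$W_init$W_rec[frozen])
  expect_true(any(pol$W_last$W_rec[!frozen] != pol$W_init$W_rec[!frozen]))
  bfrozen <- !bp$plasticity_mask
  expect_identical(rec$baseline$W_last$W_rec[bfrozen],
                   rec$baseline$W_init$W_rec[bfrozen])
  # dimensional contract of the baseline input
  expect_error(pyrl_train(pp, bp, arch,
                          architecture("pyrl_baseline", N_rec = 10,
                                       n_rec_policy = 12),
                          default_task_config("pyrl"), pyrl_spec(), seed = 1),
               "N_rec \\+ N_out")
})

test_that("the untrained rHebb reservoir is linearly separable", {
  # capacity control for the node-perturbation results: a ridge readout of
  # the window-averaged rates of an *untrained* network solves the task, so
  # any performance shortfall of the trained model is attributable to the
  # learning rule, not the architecture
  arch <- architecture("rhebb", N_rec = 64)
  cfg <- default_task_config("rhebb")
  p <- init_parameters(arch, seed = derive_seed(1, 101))
  featurize <- function(n, seed) {
    b <- make_batch(cfg, n, "alternating", seed = seed)
    X <- matrix(0, n, arch$N_rec)
    y <- numeric(n)
    win <- seq.int(cfg$n_steps - cfg$decision_window + 1L, cfg$n_steps)
    for (i in seq_len(n)) {
      traj <- run_trial(p, arch, b$trials[[i]], noise_std = 0)
      X[i, ] <- colMeans(traj$r[win, ])
      y[i] <- if (b$trials[[i]]$correct_choice == "choice1") 1 else -1
    }
    list(X = cbind(1, X), y = y)
  }
  tr <- featurize(400, seed = 10)
  te <- featurize(200, seed = 20)
  beta <- solve(crossprod(tr$X) + diag(1e-4, ncol(tr$X)),
                crossprod(tr$X, tr$y))
  acc <- mean(sign(te$X %*% beta) == te$y)
  expect_gt(acc, 0.9)
})

test_that("the rHebb trainer improves reward on a scaled-down run", {
  sc <- scaled_defaults("rhebb")
  res <- train_family("rhebb", N_rec = 48,
                      trainer_spec = rhebb_config(n_trials = 2500,
                                                  check_every = 250),
                      seed = 5)
  tr <- res$record$performance_trace
  expect_true(nrow(tr) >= 5)
  # validation accuracy at the best checkpoint beats the first checkpoint
  expect_gt(max(tr$accuracy), tr$accuracy[1])
  # frozen-at-best snapshot: stored weights differ from the initial ones
  expect_false(identical(res$record$W_last$W_rec, res$record$W_init$W_rec))
})
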