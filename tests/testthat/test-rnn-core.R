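test_that("architecture defaults reproduce the reference configurations", {
  hf <- architecture("hf")
  expect_equal(c(hf$N_in, hf$N_rec, hf$N_out), c(4L, 100L, 1L))
  expect_equal(hf$activation, "tanh")
  pc <- architecture("pycog")
  expect_equal(c(pc$N_in, pc$N_rec, pc$N_out), c(6L, 150L, 2L))
  expect_equal(sum(pc$dale_signs > 0), 120L)
  expect_equal(sum(pc$dale_signs < 0), 30L)
  pr <- architecture("pyrl_policy")
  expect_equal(c(pr$N_in, pr$N_rec, pr$N_out), c(6L, 100L, 3L))
  expect_equal(pr$plastic_density, 0.1)
  bl <- architecture("pyrl_baseline")
  expect_equal(bl$N_in, 103L)
  rh <- architecture("rhebb")
  expect_equal(c(rh$N_in, rh$N_rec, rh$N_out), c(4L, 200L, 1L))
  expect_equal(rh$constant_input_units, c(2L, 3L, 4L))
})

test_that("initialization has the stated moments and constraints", {
  arch <- architecture("hf")
  p <- init_parameters(arch, seed = 5)
  expect_lt(abs(sd(p$W_rec) - 0.01) / 0.01, 0.05)   # 10,000 entries

  rh <- architecture("rhebb")
  prh <- init_parameters(rh, seed = 5)
  expect_lt(abs(sd(prh$W_rec) - 0.106) / 0.106, 0.05)

  pc <- architecture("pycog")
  ppc <- init_parameters(pc, seed = 5)
  inh <- which(pc$dale_signs < 0)
  exc <- which(pc$dale_signs > 0)
  expect_true(all(ppc$W_rec[, inh] <= 0))
  expect_true(all(ppc$W_rec[, exc] >= 0))
  expect_true(all(diag(ppc$W_rec) == 0))

  pr <- architecture("pyrl_policy")
  ppr <- init_parameters(pr, seed = 5)
  expect_equal(sum(ppr$plasticity_mask), 1000L)

  expect_identical(init_parameters(arch, seed = 9), init_parameters(arch, seed = 9))
  expect_error(init_parameters(arch, init_spec = list(dist = "gaussian", mean = 0, sd = 0)),
               "sd > 0")
  expect_error(init_parameters(arch, init_spec = list(dist = "gamma", shape = -1, scale = 1)),
               "shape")
})

test_that("step_leaky implements the Euler update exactly", {
  arch <- architecture("hf", N_rec = 8, tau = 10, dt = 1)
  p <- init_parameters(arch, seed = 1)
  # fixed point at the origin with zero weights and bias
  p0 <- p
  p0$W_rec[] <- 0; p0$W_in[] <- 0; p0$b_x[] <- 0
  expect_equal(step_leaky(p0, arch, rep(0, 8), rep(0, 4)), matrix(0, 8, 1))

  # full-relaxation limit alpha = 1
  arch1 <- architecture("hf", N_rec = 8, tau = 1, dt = 1)
  x <- rnorm(8); u <- rnorm(4)
  expect_equal(step_leaky(p, arch1, x, u),
               p$W_rec %*% tanh(x) + p$W_in %*% u + p$b_x)

  # 50 random steps against an independently coded loop
  set.seed(42)
  x_pkg <- rep(0, 8)
  x_ora <- rep(0, 8)
  a <- 1 / 10
  for (t in 1:50) {
    u <- rnorm(4)
    noise <- rnorm(8, 0, 0.1)
    x_pkg <- step_leaky(p, arch, x_pkg, u, noise)
    drive <- as.numeric(p$W_rec %*% tanh(x_ora)) + as.numeric(p$W_in %*% u) +
      p$b_x + noise
    x_ora <- (1 - a) * x_ora + a * drive
    expect_lt(max(abs(as.numeric(x_pkg) - x_ora)), 1e-12)
  }
})

test_that("step_gated has correct gate semantics and matches an oracle", {
  arch <- architecture("pyrl_policy", N_rec = 6, N_in = 6)
  p <- init_parameters(arch, seed = 2)
  x <- rnorm(6); u <- rnorm(6)

  # update gate pinned to 0 freezes the state
  pz <- p; pz$W_q_in[] <- 0; pz$W_q_rec[] <- 0; pz$b_q[] <- -1e3
  expect_equal(as.numeric(step_gated(pz, arch, x, u)), x)

  # both gates pinned to 1 reduce to the unleaky recurrent step
  p1 <- p
  p1$W_q_in[] <- 0; p1$W_q_rec[] <- 0; p1$b_q[] <- 1e3
  p1$W_s_in[] <- 0; p1$W_s_rec[] <- 0; p1$b_s[] <- 1e3
  expect_equal(as.numeric(step_gated(p1, arch, x, u)),
               as.numeric(p1$W_rec %*% pmax(x, 0) + p1$W_in %*% u + p1$b_x),
               tolerance = 1e-12)

  # random step against independently coded gate equations
  sig <- function(z) 1 / (1 + exp(-z))
  r <- pmax(x, 0)
  q <- sig(as.numeric(p$W_q_in %*% u + p$W_q_rec %*% r) + p$b_q)
  s <- sig(as.numeric(p$W_s_in %*% u + p$W_s_rec %*% r) + p$b_s)
  cand <- as.numeric(p$W_rec %*% (s * r) + p$W_in %*% u) + p$b_x
  expect_lt(max(abs(as.numeric(step_gated(p, arch, x, u)) -
                      ((1 - q) * x + q * cand))), 1e-12)

  png <- p; png$W_q_rec <- NULL
  expect_error(step_gated(png, arch, x, u), "gate")
})

test_that("run_trial applies inactivation clamps and matches the no-op lesion", {
  arch <- architecture("pycog", N_rec = 20)
  p <- init_parameters(arch, seed = 3)
  cfg <- default_task_config("pycog")
  tr <- make_trial(cfg, "motion", d_m = 0.04, d_c = 0.02, seed = 4)

  base <- run_trial(p, arch, tr, seed = 9)
  noop <- run_trial(p, arch, tr, inactivation = inactivation_spec(integer(0)),
                    seed = 9)
  expect_identical(base$r, noop$r)

  les <- run_trial(p, arch, tr, inactivation = inactivation_spec(c(3, 7)), seed = 9)
  expect_true(all(les$r[, c(3, 7)] == 0))

  full <- run_trial(p, arch, tr,
                    inactivation = inactivation_spec(seq_len(20)), seed = 9)
  expect_true(all(abs(sweep(full$z, 2, p$b_z)) < 1e-12))

  expect_error(run_trial(p, arch, tr, inactivation = inactivation_spec(25)),
               "out of range")
  expect_error(inactivation_spec(1, "elsewhere"))
})

test_that("bias_constant clamping is the HF convention", {
  arch <- architecture("hf", N_rec = 10)
  p <- init_parameters(arch, seed = 1)
  p$b_x <- rnorm(10, 0, 0.5)
  cfg <- default_task_config("hf")
  tr <- make_trial(cfg, "motion", d_m = 0.04, d_c = 0.02, seed = 2)
  les <- run_trial(p, arch, tr, inactivation = inactivation_spec(4, "bias_constant"),
                   seed = 3)
  expect_true(all(abs(les$x[, 4] - p$b_x[4]) < 1e-12))
  pc <- architecture("pycog", N_rec = 10)
  expect_error(run_trial(init_parameters(pc, seed = 1), pc, tr,
                         inactivation = inactivation_spec(1, "bias_constant")),
               "HF")
})

test_that("choices are decoded by sign or argmax with flagged ties", {
  mk <- function(z, family, dw = 1) {
    structure(list(z = z, family = family, decision_window = dw),
              class = "state_trajectory")
  }
  expect_equal(decode_choice(mk(matrix(c(0.1, 0.7), 2, 1), "hf")), "choice1")
  expect_equal(decode_choice(mk(matrix(c(0.1, -0.3), 2, 1), "hf")), "choice2")
  expect_equal(decode_choice(mk(matrix(c(0.2, 0.9), 1, 2), "pycog")), "choice2")
  expect_equal(decode_choice(mk(matrix(c(0.1, 0.2, 0.9), 1, 3), "pyrl")), "stay")
  tie <- decode_choice(mk(matrix(c(0.5, 0.5), 1, 2), "pycog"))
  expect_equal(as.character(tie), "choice1")
  expect_true(attr(tie, "tie"))
})

test_that("accuracy is a mean over trials with batch decomposition", {
  arch <- architecture("pycog", N_rec = 16)
  p <- init_parameters(arch, seed = 6)
  cfg <- default_task_config("pycog")
  b <- make_batch(cfg, 40, "alternating", seed = 8)
  acc <- accuracy(p, arch, b, seed = 10, noise_std = 0)
  b1 <- b; b1$trials <- b$trials[1:20]; b1$n_trials <- 20L
  b2 <- b; b2$trials <- b$trials[21:40]; b2$n_trials <- 20L
  a1 <- accuracy(p, arch, b1, seed = 10, noise_std = 0)
  a2 <- accuracy(p, arch, b2, seed = 10, noise_std = 0)
  expect_equal(acc, (20 * a1 + 20 * a2) / 40)

  # a constant-output network is at chance on a balanced batch
  pz <- p; pz$W_out[] <- 0; pz$b_z <- c(1, 0)
  big <- make_batch(cfg, 800, "alternating", seed = 9)
  expect_lt(abs(accuracy(pz, arch, big, seed = 11, noise_std = 0) - 0.5), 0.06)
})

test_that("trajectories are deterministic given seeds", {
  arch <- architecture("hf", N_rec = 12)
  p <- init_parameters(arch, seed = 2)
  cfg <- default_task_config("hf")
  tr <- make_trial(cfg, "color", d_m = 0.02, d_c = -0.04, seed = 5)
  t1 <- run_trial(p, arch, tr, seed = 31)
  t2 <- run_trial(p, arch, tr, seed = 31)
  expect_identical(t1, t2)
  # activation-range invariants
  expect_true(all(abs(t1$r) <= 1))
  pc <- architecture("pycog", N_rec = 12)
  tpc <- run_trial(init_parameters(pc, seed = 2), pc,
                   make_trial(default_task_config("pycog"), "color", 0.02, -0.04,
                              seed = 5), seed = 31)
  expect_true(all(tpc$r >= 0))
})
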