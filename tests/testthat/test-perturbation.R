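# synthetic full-factorial sweep data with optional order effects
synth_sweep <- function(levels, orders = 3, systems, effect = 0, seed = 1) {
  set.seed(seed)
  ords <- c("descending", "ascending", "shuffled")[seq_len(orders)]
  d <- expand.grid(system = seq_len(systems),
                   sort_type = ords,
                   n_inact = seq(10, by = 10, length.out = levels),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  shift <- ifelse(d$sort_type == "descending", -effect,
                  ifelse(d$sort_type == "ascending", effect, 0))
  d$accuracy <- 0.7 + shift + rnorm(nrow(d), 0, 0.02)
  structure(list(data = d, family = "synthetic", n_systems = systems,
                 n_eval = NA), class = "inactivation_sweep")
}

test_that("two-way ANOVA degrees of freedom follow from the design", {
  a1 <- two_way_anova(synth_sweep(10, 3, 11))
  expect_equal(a1$df_factor[a1$effect == "n_inact"], 9)
  expect_equal(a1$df_factor[a1$effect == "sort_type"], 2)
  expect_equal(a1$df_factor[a1$effect == "n_inact:sort_type"], 18)
  expect_true(all(a1$df_error == 300))

  a2 <- two_way_anova(synth_sweep(12, 3, 11))
  expect_true(all(a2$df_error == 360))

  a3 <- two_way_anova(synth_sweep(10, 3, 20))
  expect_true(all(a3$df_error == 570))

  expect_error(two_way_anova(synth_sweep(5, 3, 1)), "replicates")
  d <- synth_sweep(5, 3, 4)$data
  expect_error(two_way_anova(d[d$sort_type != "shuffled" | d$n_inact != 10, ]),
               "missing cells")
})

test_that("ANOVA is calibrated under the null and invariant to system labels", {
  set.seed(5)
  Fs <- c(); ps <- c()
  for (i in 1:300) {
    sw <- synth_sweep(4, 3, 4, effect = 0, seed = 1000 + i)
    at <- two_way_anova(sw)
    Fs <- c(Fs, at$F[at$effect == "sort_type"])
    ps <- c(ps, at$p[at$effect == "sort_type"])
  }
  expect_lt(abs(mean(Fs) - 1), 0.25)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)

  sw <- synth_sweep(6, 3, 8, effect = 0.05, seed = 3)
  at1 <- two_way_anova(sw)
  perm <- sw
  perm$data$system <- ((perm$data$system + 2) %% 8) + 1
  at2 <- two_way_anova(perm)
  expect_equal(at1$F, at2$F)
  expect_equal(at1$p, at2$p)
})

test_that("Tukey post-hoc comparisons behave at both extremes", {
  # indistinguishable groups: adjusted p near 1
  sw0 <- synth_sweep(3, 3, 10, effect = 0, seed = 9)
  ph0 <- posthoc_pairwise(sw0)
  expect_gt(min(ph0$p_adj), 0.05)

  # a five-sigma separation is detected at every lesion size
  sw1 <- synth_sweep(3, 3, 10, effect = 0.1, seed = 10)
  ph1 <- posthoc_pairwise(sw1)
  da <- ph1[ph1$pair == "descending-ascending", ]
  expect_true(all(da$p_adj < 0.001))
  expect_true(all(da$diff < 0))  # descending degrades accuracy more

  # Tukey adjustment never reports less than the pairwise t-test
  d <- sw1$data[sw1$data$n_inact == 10 & sw1$data$sort_type != "shuffled", ]
  t_p <- t.test(accuracy ~ sort_type, data = d, var.equal = TRUE)$p.value
  expect_gte(da$p_adj[da$n_inact == 10] + 1e-15, t_p)
})

test_that("Kruskal-Wallis / Dunn agree with hand computations", {
  # identical duplicated groups: omnibus p ~ 1
  kd0 <- kruskal_dunn(rep(c(1, 2, 3, 4, 5), 3), rep(c("a", "b", "c"), 5))
  expect_gt(kd0$kruskal$p.value, 0.9)

  # 9-point toy example with known rank structure
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  grp <- rep(c("a", "b", "c"), each = 3)
  kd <- kruskal_dunn(vals, grp)
  # H = 12/(n(n+1)) * sum n_i (rbar_i - rbar)^2 with no ties
  H <- 12 / (9 * 10) * 3 * ((2 - 5)^2 + (5 - 5)^2 + (8 - 5)^2)
  expect_equal(unname(kd$kruskal$statistic), H)
  expect_equal(unname(kd$kruskal$statistic),
               unname(kruskal.test(vals, factor(grp))$statistic))
  # Dunn z for the extreme pair: (2 - 8) / sqrt((9*10/12) * (1/3 + 1/3))
  z_ac <- (2 - 8) / sqrt((9 * 10 / 12) * (2 / 3))
  expect_equal(kd$dunn$z[kd$dunn$pair == "a-c"], z_ac)
  expect_true(all(kd$dunn$p_adj >= kd$dunn$p))
  expect_error(kruskal_dunn(1:4, rep("a", 4)), "2 groups")
})

test_that("inactivation sweeps are reproducible and lesion the ranked units", {
  arch <- architecture("pycog", N_rec = 40)
  cfg <- default_task_config("pycog")
  recs <- lapply(1:2, function(s) {
    p <- init_parameters(arch, seed = s)
    p2 <- p
    set.seed(100 + s)
    p2$W_rec <- project_dale(p$W_rec + matrix(rnorm(1600, 0, 0.01), 40, 40),
                             arch$dale_signs)
    plasticrnn:::new_training_record("pycog", p, p2, NULL, s,
                                     list(arch = arch, task = cfg), TRUE)
  })
  sw1 <- run_inactivation_sweep(recs, arch, cfg, grid = c(10, 20, 30),
                                n_eval = 40, seed = 42)
  sw2 <- run_inactivation_sweep(recs, arch, cfg, grid = c(10, 20, 30),
                                n_eval = 40, seed = 42)
  expect_identical(sw1$data, sw2$data)
  expect_equal(nrow(sw1$data), 2 * 3 * 3)
  expect_true(all(sw1$data$accuracy >= 0 & sw1$data$accuracy <= 1))

  # the full lesion of the rankable population is order-independent
  full <- run_inactivation_sweep(recs[1], arch, cfg, grid = c(32),
                                 n_eval = 40, seed = 7)$data
  expect_equal(length(unique(full$accuracy)), 1L)

  expect_error(run_inactivation_sweep(recs, arch, cfg, grid = c(10, 200),
                                      n_eval = 10, seed = 1), "exceeds")
})

test_that("the size sweep trains per cell and tests across sizes", {
  sw <- run_size_sweep("hf", sizes = c(20, 30),
                       task_cfg = default_task_config("hf"),
                       trainer_spec = hf_spec(n_iterations = 20,
                                              check_every = 20,
                                              stop_accuracy = 1.1,
                                              n_val = 60),
                       n_seeds = 2, n_eval = 80, seed = 2)
  expect_equal(nrow(sw$data), 4)
  expect_true(all(is.finite(sw$data$accuracy)))
  expect_true(all(is.finite(sw$data$skewness)))
  expect_false(is.null(sw$accuracy_test))
  expect_true(sw$accuracy_test$kruskal$p.value >= 0 &&
                sw$accuracy_test$kruskal$p.value <= 1)
  expect_error(run_size_sweep("hf", sizes = 20,
                              task_cfg = default_task_config("hf"),
                              trainer_spec = hf_spec()), "2 sizes")
})
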