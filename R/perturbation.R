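#' Rank-ordered unit-inactivation sweep
#'
#' For each trained system, units are inactivated cumulatively in descending
#' order of their post-mean weight change (most plastic first), in ascending
#' order (least plastic first), and in a seeded shuffled order, in increments
#' of 10 units (configurable grid). Accuracy is measured on a fresh
#' evaluation batch per (system, order, n) cell with seeds derived from a
#' root seed. HF units are clamped to their bias (`bias_constant`); the other
#' families' unit outputs are set to zero.
#'
#' @param records List of `training_record`s (replicate systems of one
#'   family).
#' @param arch Architecture; defaults to the first record's.
#' @param task_cfg Task configuration for the evaluation batches; defaults to
#'   the first record's.
#' @param grid Numbers of inactivated units; default `seq(10, K, by = 10)`
#'   where K is the number of rankable units (for pycog only excitatory units
#'   are lesioned; for rHebb the grid is truncated at 100 at the reference
#'   size).
#' @param n_eval Evaluation trials per cell (default 200).
#' @param policy Analysis policy used to rank units; family default.
#' @param seed Root seed for shuffled orders and evaluation noise.
#' @return An `inactivation_sweep` object whose `data` is a tidy data frame
#'   (system, sort_type, n_inact, accuracy).
#' @export
run_inactivation_sweep <- function(records, arch = NULL, task_cfg = NULL,
                                   grid = NULL, n_eval = 200, policy = NULL,
                                   seed = 1L) {
  if (inherits(records, "training_record")) records <- list(records)
  stopifnot(length(records) >= 1)
  arch <- arch %||% records[[1]]$config$arch
  task_cfg <- task_cfg %||% records[[1]]$config$task
  clamp <- if (arch$family == "hf") "bias_constant" else "zero_output"
  rows <- list()
  for (si in seq_along(records)) {
    rec <- records[[si]]
    smry <- summarize_model(rec, arch, policy)
    rankable <- smry$ranking
    K <- length(rankable)
    g <- grid %||% seq.int(10L, min(K, if (arch$family == "rhebb") 100L else K),
                           by = 10L)
    if (max(g) > arch$N_rec) stop_invalid("grid exceeds N_rec")
    if (max(g) > K) stop_invalid("grid exceeds the %d rankable units", K)
    orders <- list(
      descending = rankable,
      ascending = rev(rankable),
      shuffled = with_seed(derive_seed(seed, 1000 + si), sample(rankable))
    )
    for (ord_name in names(orders)) {
      for (n_in in g) {
        # evaluation batches are shared across sort orders (paired design):
        # the same lesion size under different orders sees identical trials
        cell_seed <- derive_seed(seed, si * 100000 + n_in)
        batch <- make_batch(task_cfg, n_eval, "alternating",
                            family = NULL, seed = cell_seed)
        spec <- inactivation_spec(orders[[ord_name]][seq_len(n_in)], clamp)
        acc <- accuracy(rec$W_last, arch, batch, inactivation = spec,
                        seed = derive_seed(cell_seed, 1))
        rows[[length(rows) + 1]] <- data.frame(
          system = si, sort_type = ord_name, n_inact = n_in, accuracy = acc)
      }
    }
  }
  structure(list(data = do.call(rbind, rows), family = arch$family,
                 n_systems = length(records), n_eval = n_eval),
            class = "inactivation_sweep")
}

#' @export
print.inactivation_sweep <- function(x, ...) {
  cat(sprintf("inactivation_sweep '%s': %d systems, %d cells, %d trials/cell\n",
              x$family, x$n_systems, nrow(x$data), x$n_eval))
  invisible(x)
}

as_sweep_data <- function(result) {
  if (inherits(result, "inactivation_sweep")) result$data
  else if (is.data.frame(result)) result
  else stop_invalid("expected an inactivation_sweep or a data frame")
}

#' Two-way fixed-effects ANOVA of an inactivation sweep
#'
#' Accuracy ~ n_inact * sort_type with systems as replicates. Factor degrees
#' of freedom are (levels - 1) per factor and their product for the
#' interaction; the error df follows from the full-factorial design.
#'
#' @param result An [run_inactivation_sweep()] result (or its tidy data
#'   frame).
#' @return An `anova_table` data frame with rows `n_inact`, `sort_type`,
#'   `n_inact:sort_type`: `df_factor`, `df_error`, `F`, `p`.
#' @export
two_way_anova <- function(result) {
  d <- as_sweep_data(result)
  d$n_inact <- factor(d$n_inact)
  d$sort_type <- factor(d$sort_type)
  tab <- table(d$n_inact, d$sort_type)
  if (any(tab == 0)) stop_invalid("missing cells in the factorial design")
  if (any(tab < 2)) stop_invalid("need >= 2 replicates per cell")
  fit <- stats::aov(accuracy ~ n_inact * sort_type, data = d)
  s <- summary(fit)[[1]]
  rn <- trimws(rownames(s))
  df_error <- s[rn == "Residuals", "Df"]
  keep <- which(rn != "Residuals")
  out <- data.frame(
    effect = rn[keep],
    df_factor = s[keep, "Df"],
    df_error = df_error,
    F = s[keep, "F value"],
    p = s[keep, "Pr(>F)"],
    row.names = NULL
  )
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Tukey HSD pairwise comparisons of sort orders
#'
#' At each number of inactivated units, compares the sort orders pooled over
#' systems with Tukey's honestly-significant-difference test.
#'
#' @param result An [run_inactivation_sweep()] result.
#' @param method Only `"tukey_hsd"`.
#' @return Data frame: n_inact, pair, diff (first minus second group mean),
#'   lwr, upr, p_adj.
#' @export
posthoc_pairwise <- function(result, method = c("tukey_hsd")) {
  method <- match.arg(method)
  d <- as_sweep_data(result)
  if (length(unique(d$sort_type)) < 2) stop_invalid("need >= 2 sort orders")
  rows <- lapply(sort(unique(d$n_inact)), function(n_in) {
    dd <- d[d$n_inact == n_in, ]
    fit <- stats::aov(accuracy ~ sort_type, data = dd)
    tk <- stats::TukeyHSD(fit)$sort_type
    data.frame(n_inact = n_in, pair = rownames(tk), diff = tk[, "diff"],
               lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Kruskal-Wallis omnibus test with Dunn's post-hoc comparisons
#'
#' Dunn's test compares mean ranks between groups with the tie-corrected
#' normal approximation; p-values are adjusted with `p.adjust`.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @param p_adjust_method Passed to [stats::p.adjust()] (default "holm").
#' @return List with `kruskal` (the htest) and `dunn` (data frame: pair, z,
#'   p, p_adj).
#' @export
kruskal_dunn <- function(values, groups, p_adjust_method = "holm") {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_invalid("need >= 2 groups")
  kw <- stats::kruskal.test(values, groups)
  n <- length(values)
  rk <- rank(values)
  mean_rank <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / n_g[[pr[1]]] + 1 / n_g[[pr[2]]]))
    (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  dunn <- data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
                     z = z, p = p,
                     p_adj = stats::p.adjust(p, p_adjust_method))
  list(kruskal = kw, dunn = dunn)
}

#' Network-size sweep
#'
#' Trains a fresh model per (size, seed) with the family's learning rule,
#' and records final accuracy and the skewness of the post-mean weight-change
#' distribution, followed by a Kruskal-Wallis omnibus test across sizes and
#' Dunn's post-hoc comparisons.
#'
#' @param family `"hf"`, `"pycog"`, `"pyrl"` or `"rhebb"`.
#' @param sizes At least two `N_rec` values.
#' @param task_cfg Task configuration shared by all runs.
#' @param trainer_spec Trainer spec/config for the family.
#' @param n_seeds Seeds per size (default 5).
#' @param n_eval Fresh evaluation trials for the final accuracy.
#' @param seed Root seed.
#' @return A `size_sweep` object: tidy `data` (size, seed, accuracy,
#'   skewness, converged), `accuracy_test` and `skewness_test`
#'   ([kruskal_dunn()] results, NULL when all training cells failed).
#' @export
run_size_sweep <- function(family, sizes, task_cfg, trainer_spec,
                           n_seeds = 5, n_eval = 500, seed = 1L) {
  if (length(sizes) < 2) stop_invalid("need >= 2 sizes")
  rows <- list()
  for (sz in sizes) {
    for (k in seq_len(n_seeds)) {
      run_seed <- derive_seed(seed, sz * 1000 + k)
      res <- tryCatch(
        train_family(family, N_rec = sz, task_cfg = task_cfg,
                     trainer_spec = trainer_spec, seed = run_seed),
        error = function(e) NULL)
      if (is.null(res)) {
        rows[[length(rows) + 1]] <- data.frame(size = sz, seed = run_seed,
                                               accuracy = NA, skewness = NA,
                                               converged = FALSE)
        next
      }
      rec <- if (family == "pyrl") res$record$policy else res$record
      eval_batch <- make_batch(task_cfg, n_eval, "alternating",
                               seed = derive_seed(run_seed, 31))
      acc <- accuracy(rec$W_last, res$arch, eval_batch,
                      seed = derive_seed(run_seed, 32),
                      noise_std = if (family == "rhebb") 0 else NULL)
      smry <- summarize_model(rec, res$arch)
      sk <- if (inherits(smry$stats$post_mean_diff, "dist_stats"))
        smry$stats$post_mean_diff$skewness else NA
      rows[[length(rows) + 1]] <- data.frame(size = sz, seed = run_seed,
                                             accuracy = acc, skewness = sk,
                                             converged = rec$converged)
    }
  }
  d <- do.call(rbind, rows)
  ok <- stats::complete.cases(d[, c("accuracy", "skewness")])
  tests <- if (sum(ok) >= 4 && length(unique(d$size[ok])) >= 2) {
    list(accuracy = kruskal_dunn(d$accuracy[ok], d$size[ok]),
         skewness = kruskal_dunn(d$skewness[ok], d$size[ok]))
  } else list(accuracy = NULL, skewness = NULL)
  structure(list(data = d, family = family, accuracy_test = tests$accuracy,
                 skewness_test = tests$skewness),
            class = "size_sweep")
}

#' @export
print.size_sweep <- function(x, ...) {
  cat(sprintf("size_sweep '%s'\n", x$family))
  agg <- stats::aggregate(cbind(accuracy, skewness) ~ size, data = x$data,
                          FUN = mean, na.action = stats::na.omit)
  print(agg)
  if (!is.null(x$accuracy_test)) {
    cat(sprintf("  Kruskal-Wallis (accuracy): p = %.3g\n",
                x$accuracy_test$kruskal$p.value))
  }
  invisible(x)
}
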