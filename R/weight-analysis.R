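#' Build the analysis mask for a model family
#'
#' Selects which recurrent synapses enter the weight / weight-change
#' analysis. Policies: `"all"` (every recurrent synapse; the HF convention),
#' `"e_e_only"` (excitatory-to-excitatory connections; pycog),
#' `"exclude_output_and_constant"` (drops the readout unit and the
#' constant-input units both pre- and postsynaptically; rHebb, 196 of 200
#' units at the reference size), and `"plastic_only"` (only synapses marked
#' plastic; pyrl, 10% of N_rec^2 with defaults).
#'
#' @param arch An [architecture()].
#' @param policy Analysis policy label.
#' @param plasticity_mask Logical `N_rec x N_rec` matrix, required for
#'   `"plastic_only"` (taken from the trained parameters).
#' @return An `analysis_mask` with `post_units`, `pre_units`, the logical
#'   `element_mask`, and the policy label.
#' @export
build_mask <- function(arch, policy = c("all", "e_e_only",
                                        "exclude_output_and_constant",
                                        "plastic_only"),
                       plasticity_mask = NULL) {
  stopifnot(inherits(arch, "rnn_architecture"))
  policy <- match.arg(policy)
  N <- arch$N_rec
  if (policy == "e_e_only") {
    if (is.null(arch$dale_signs)) {
      stop_invalid("e_e_only requires a Dale's-law architecture (pycog)")
    }
    units <- which(arch$dale_signs > 0)
    post <- pre <- units
    em <- matrix(FALSE, N, N); em[post, pre] <- TRUE
  } else if (policy == "exclude_output_and_constant") {
    if (is.null(arch$output_unit)) {
      stop_invalid("exclude_output_and_constant requires an rHebb architecture")
    }
    units <- setdiff(seq_len(N), c(arch$output_unit, arch$constant_input_units))
    post <- pre <- units
    em <- matrix(FALSE, N, N); em[post, pre] <- TRUE
  } else if (policy == "plastic_only") {
    if (is.null(plasticity_mask)) {
      stop_invalid("plastic_only requires the plasticity mask from the parameters")
    }
    stopifnot(is.logical(plasticity_mask), all(dim(plasticity_mask) == N))
    em <- plasticity_mask
    post <- which(rowSums(em) > 0)
    pre <- which(colSums(em) > 0)
  } else {
    post <- pre <- seq_len(N)
    em <- matrix(TRUE, N, N)
  }
  structure(list(post_units = post, pre_units = pre, element_mask = em,
                 policy = policy, N_rec = N),
            class = "analysis_mask")
}

#' Signed weight-change matrix
#'
#' `W_diff = W_last - W_init`, elementwise.
#' @param W_last,W_init Same-shape matrices.
#' @return The signed difference matrix.
#' @export
weight_diff <- function(W_last, W_init) {
  if (!all(dim(W_last) == dim(W_init))) stop_invalid("shape mismatch")
  W_last - W_init
}

#' Per-postsynaptic-unit mean absolute weight
#'
#' For each included postsynaptic unit i, the mean of `|M[i, j]|` over the
#' included presynaptic units j (rows are postsynaptic, columns
#' presynaptic). Under the `plastic_only` policy the divisor is the number of
#' analyzed presynaptic entries of that row; rows with no analyzed entry are
#' dropped with a warning.
#'
#' @param M Weight or weight-change matrix.
#' @param mask An [build_mask()] result.
#' @return Named nonnegative vector, one entry per included postsynaptic
#'   unit.
#' @export
post_mean <- function(M, mask) {
  stopifnot(inherits(mask, "analysis_mask"))
  if (length(mask$pre_units) == 0) stop_invalid("empty presynaptic set")
  if (!all(dim(M) == mask$N_rec)) stop_invalid("matrix does not match mask")
  am <- abs(M) * mask$element_mask
  counts <- rowSums(mask$element_mask)[mask$post_units]
  v <- rowSums(am)[mask$post_units] / counts
  names(v) <- as.character(mask$post_units)
  if (any(counts == 0)) {
    warning("dropping post units with no analyzed presynaptic entries")
    v <- v[counts > 0]
  }
  v
}

#' Rank units by a post-mean statistic
#'
#' Descending order; exact ties break toward the lower original index.
#'
#' @param post_mean_vector Named vector from [post_mean()].
#' @return Integer unit indices, highest value first.
#' @export
rank_units <- function(post_mean_vector) {
  if (!all(is.finite(post_mean_vector))) stop_invalid("non-finite post-mean values")
  idx <- if (is.null(names(post_mean_vector))) seq_along(post_mean_vector)
         else as.integer(names(post_mean_vector))
  idx[order(-post_mean_vector, seq_along(post_mean_vector))]
}

#' Distribution statistics of a sample
#'
#' Shapiro-Wilk normality test, the D'Agostino Z-test on sample skewness, and
#' the Anscombe-Glynn Z-test on sample kurtosis (reported as excess kurtosis,
#' normal = 0). Skewness and kurtosis use the biased moment-ratio estimators
#' `g1 = m3 / m2^(3/2)` and `g2 = m4 / m2^2 - 3`.
#'
#' @param sample Numeric vector, `n >= 8`, not constant.
#' @return A `dist_stats` object: `n`, `normality_W`, `normality_p`,
#'   `skewness`, `skew_z`, `skew_p`, `kurtosis`, `kurt_z`, `kurt_p`.
#' @export
dist_stats <- function(sample) {
  sample <- as.numeric(sample)
  n <- length(sample)
  if (n < 8) stop_invalid("dist_stats requires n >= 8 (got %d)", n)
  if (diff(range(sample)) == 0) stop_invalid("undefined statistic: constant sample")
  sw <- stats::shapiro.test(if (n > 5000) sample[seq_len(5000)] else sample)
  sk <- skew_test(sample)
  ku <- kurtosis_test(sample)
  structure(list(n = n, normality_W = unname(sw$statistic),
                 normality_p = sw$p.value,
                 skewness = sk$estimate, skew_z = sk$z, skew_p = sk$p,
                 kurtosis = ku$estimate, kurt_z = ku$z, kurt_p = ku$p),
            class = "dist_stats")
}

#' @export
print.dist_stats <- function(x, ...) {
  cat(sprintf("n = %d\n", x$n))
  cat(sprintf("  normality: W = %.3f, p = %.3g\n", x$normality_W, x$normality_p))
  cat(sprintf("  skewness:  g1 = %.3f, Z = %.2f, p = %.3g\n",
              x$skewness, x$skew_z, x$skew_p))
  cat(sprintf("  kurtosis:  g2 = %.3f, Z = %.2f, p = %.3g (excess)\n",
              x$kurtosis, x$kurt_z, x$kurt_p))
  invisible(x)
}

sample_moments <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  m2 <- sum(xc^2) / n
  list(n = n, m2 = m2, m3 = sum(xc^3) / n, m4 = sum(xc^4) / n)
}

# D'Agostino (1970) transformed Z-test for sample skewness.
skew_test <- function(x) {
  mo <- sample_moments(x)
  n <- mo$n
  if (n < 8) stop_invalid("skew test requires n >= 8")
  g1 <- mo$m3 / mo$m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  if (y == 0) y <- 1
  z <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  list(estimate = g1, z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Anscombe & Glynn (1983) Z-test for sample kurtosis.
kurtosis_test <- function(x) {
  mo <- sample_moments(x)
  n <- mo$n
  if (n < 5) stop_invalid("kurtosis test requires n >= 5")
  b2 <- mo$m4 / mo$m2^2
  E <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - E) / sqrt(var_b2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  term1 <- 1 - 2 / (9 * A)
  denom <- 1 + xx * sqrt(2 / (A - 4))
  term2 <- sign(denom) * abs((1 - 2 / A) / abs(denom))^(1 / 3)
  z <- (term1 - term2) / sqrt(2 / (9 * A))
  list(estimate = b2 - 3, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Summarize the weight changes of a trained model
#'
#' Applies the analysis mask, forms the signed change matrix, computes the
#' post-mean statistics of the final weights and of the changes, ranks units
#' by the chosen post-mean, and runs the distribution tests at both the
#' post-mean (unit) level and the element (synapse) level.
#'
#' @param record A `training_record` (or planted fixture).
#' @param arch The architecture; defaults to the one stored in the record.
#' @param policy Analysis policy for [build_mask()]; defaults to the family
#'   convention (`all` for HF, `e_e_only` for pycog,
#'   `exclude_output_and_constant` for rHebb, `plastic_only` for pyrl).
#' @param rank_by `"diff"` (default) or `"last"`: which post-mean orders the
#'   unit ranking.
#' @return A `weight_change_summary`: `W_diff`, `post_mean_last`,
#'   `post_mean_diff`, `ranking`, the mask, and `stats` (a list with
#'   `post_mean_last`, `post_mean_diff` and `element_diff` [dist_stats()]
#'   entries).
#' @export
summarize_model <- function(record, arch = NULL, policy = NULL,
                            rank_by = c("diff", "last")) {
  stopifnot(inherits(record, "training_record"))
  rank_by <- match.arg(rank_by)
  arch <- arch %||% record$config$arch
  policy <- policy %||% default_policy(record$family)
  mask <- build_mask(arch, policy,
                     plasticity_mask = record$W_last$plasticity_mask)
  W_diff <- weight_diff(record$W_last$W_rec, record$W_init$W_rec)
  pml <- post_mean(record$W_last$W_rec, mask)
  pmd <- post_mean(W_diff, mask)
  ranking <- rank_units(if (rank_by == "diff") pmd else pml)
  elems <- W_diff[mask$element_mask]
  stats <- list(
    post_mean_last = try_dist_stats(pml),
    post_mean_diff = try_dist_stats(pmd),
    element_diff = try_dist_stats(elems)
  )
  structure(list(family = record$family, policy = policy, W_diff = W_diff,
                 post_mean_last = pml, post_mean_diff = pmd,
                 ranking = ranking, mask = mask, stats = stats,
                 n_elements = sum(mask$element_mask)),
            class = "weight_change_summary")
}

try_dist_stats <- function(x) {
  tryCatch(dist_stats(x), error = function(e) {
    structure(list(n = length(x), error = conditionMessage(e)),
              class = "dist_stats_unavailable")
  })
}

default_policy <- function(family) {
  switch(family,
    hf = "all",
    pycog = "e_e_only",
    pyrl_policy = , pyrl_baseline = "plastic_only",
    rhebb = "exclude_output_and_constant",
    "all")
}

#' @export
print.weight_change_summary <- function(x, ...) {
  cat(sprintf("weight_change_summary '%s' (policy %s)\n", x$family, x$policy))
  cat(sprintf("  post units: %d, analyzed synapses: %d\n",
              length(x$post_mean_diff), x$n_elements))
  s <- x$stats$post_mean_diff
  if (inherits(s, "dist_stats")) {
    cat(sprintf("  post-mean change: skew %.2f (Z = %.2f, p = %.3g)\n",
                s$skewness, s$skew_z, s$skew_p))
  }
  cat("  top units by post-mean change:",
      paste(utils::head(x$ranking, 5), collapse = " "), "\n")
  invisible(x)
}

#' Write a distribution-statistics table as CSV
#'
#' One row per analysis level, mirroring the n / normality / skewness /
#' kurtosis column layout used for reporting.
#'
#' @param summaries Named list of `weight_change_summary` objects.
#' @param path Output CSV path.
#' @param level `"post_mean_diff"`, `"post_mean_last"` or `"element_diff"`.
#' @return The data frame, invisibly.
#' @export
write_stats_csv <- function(summaries, path, level = "post_mean_diff") {
  rows <- lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]$stats[[level]]
    if (!inherits(s, "dist_stats")) {
      return(data.frame(model = nm, n = s$n, normality_p = NA, normality_W = NA,
                        skew_p = NA, skew_z = NA, skewness = NA,
                        kurt_p = NA, kurt_z = NA, kurtosis = NA))
    }
    data.frame(model = nm, n = s$n, normality_p = s$normality_p,
               normality_W = s$normality_W, skew_p = s$skew_p,
               skew_z = s$skew_z, skewness = s$skewness, kurt_p = s$kurt_p,
               kurt_z = s$kurt_z, kurtosis = s$kurtosis)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
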