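#' Synthetic weight-change fixture with planted high-plasticity units
#'
#' Emulates the row-localized weight-change structure the analysis pipeline
#' is designed to detect, without any training: `k_hot` postsynaptic rows of
#' the change matrix are drawn with a much larger Gaussian sd than the
#' background rows. Returned in `training_record` form so the whole analysis
#' stack (post-mean, ranking, distribution tests, inactivation plumbing)
#' runs on it unchanged.
#'
#' @param n Number of units (0 < k < n).
#' @param k Number of planted high-plasticity postsynaptic units (`k = 0`
#'   allowed as a null control).
#' @param sigma_bg Background change sd (> 0).
#' @param sigma_hot Planted-row change sd (> sigma_bg when k > 0).
#' @param seed Integer seed; same seed, identical fixture.
#' @return A `training_record` (also class `planted_fixture`) with
#'   `true_hot_indices` and a minimal tanh architecture in its config.
#' @export
make_planted_fixture <- function(n, k, sigma_bg = 0.01, sigma_hot = 0.1,
                                 seed = 1L) {
  if (k < 0 || k >= n) stop_invalid("need 0 <= k < n")
  if (sigma_bg <= 0) stop_invalid("sigma_bg must be > 0")
  if (k > 0 && sigma_hot <= sigma_bg) {
    stop_invalid("sigma_hot must exceed sigma_bg")
  }
  with_seed(seed, {
    W_init <- matrix(rnorm(n * n, 0, 1 / sqrt(n)), n, n)
    hot <- if (k > 0) sort(sample.int(n, k)) else integer(0)
    sds <- rep(sigma_bg, n)
    sds[hot] <- sigma_hot
    W_diff <- matrix(rnorm(n * n), n, n) * sds  # row i scaled by sds[i]
    arch <- structure(list(family = "fixture", N_in = 1L, N_rec = as.integer(n),
                           N_out = 1L, activation = "tanh", tau = 10, dt = 1,
                           alpha = 0.1, noise_std_rec = 0, dale_signs = NULL,
                           gated = FALSE),
                      class = "rnn_architecture")
    rec <- new_training_record(
      "fixture",
      W_init = list(W_rec = W_init),
      W_last = list(W_rec = W_init + W_diff),
      trace = NULL, seed = seed,
      config = list(arch = arch, sigma_bg = sigma_bg, sigma_hot = sigma_hot),
      converged = NA)
    rec$true_hot_indices <- hot
    class(rec) <- c("planted_fixture", class(rec))
    rec
  })
}

#' Tiny hand-checkable training record
#'
#' A record whose matrices are small integers, so post-mean values are exact
#' rationals for unit tests.
#'
#' @param n Number of units (<= 5).
#' @param seed Integer seed for the (unused) initial matrix jitter.
#' @return A `training_record` with `n x n` matrices.
#' @export
make_toy_record <- function(n = 3, seed = 1L) {
  if (n > 5) stop_invalid("toy records are capped at n = 5")
  W_init <- matrix(0, n, n)
  W_last <- matrix(0, n, n)
  vals <- c(1, -1, 0, 0, 0, 0, 2, 2, 2)
  W_last[seq_len(min(n * n, 9))] <-
    matrix(vals, 3, 3, byrow = TRUE)[seq_len(min(n * n, 9))]
  if (n == 3) W_last <- matrix(vals, 3, 3, byrow = TRUE)
  arch <- structure(list(family = "fixture", N_in = 1L, N_rec = as.integer(n),
                         N_out = 1L, activation = "tanh", tau = 10, dt = 1,
                         alpha = 0.1, noise_std_rec = 0, dale_signs = NULL,
                         gated = FALSE),
                    class = "rnn_architecture")
  new_training_record("fixture", list(W_rec = W_init), list(W_rec = W_last),
                      NULL, seed, list(arch = arch), NA)
}
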