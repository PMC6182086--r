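#' Recurrent network architecture for one model family
#'
#' Captures the structural description of one model instance: unit counts,
#' activation function, time constants, per-step recurrent noise, and the
#' family-specific structural constraints (Dale's-law sign vector for pycog,
#' the sparse plasticity mask density for pyrl, the designated output and
#' constant-input units for rHebb).
#'
#' Family defaults reproduce the reference configurations: HF 4/100/1 (tanh),
#' pycog 6/150/2 with 120 excitatory and 30 inhibitory units (4:1,
#' rectified-linear), pyrl policy 6/100/3 and baseline 103/100/1 (gated
#' rectified-linear units, 10% plastic recurrent synapses), rHebb 4/200/1
#' (tanh, readout from an arbitrary recurrent unit, three constant-input
#' units).
#'
#' @param family One of `"hf"`, `"pycog"`, `"pyrl_policy"`, `"pyrl_baseline"`,
#'   `"rhebb"`.
#' @param N_rec Number of recurrent units (default: the family's reference
#'   size).
#' @param N_in,N_out Input/output channel counts (defaults per family; for
#'   `pyrl_baseline` the default input width is `N_rec_policy + N_out_policy`).
#' @param tau Membrane time constant, ms.
#' @param dt Integration step, ms; must satisfy `0 < dt <= tau`.
#' @param noise_std_rec Per-step sd of the recurrent-state noise. Defaults:
#'   0.004 for HF (the stated value); 0.01 for pycog and pyrl; 0.1 for rHebb
#'   (whose main exploration signal is the trainer's sparse kicks, see
#'   [rhebb_config()]).
#' @param exc_frac Excitatory fraction for pycog (default 0.8, i.e. 4:1).
#' @param plastic_density Fraction of recurrent synapses that are plastic for
#'   the pyrl families (default 0.1).
#' @param output_unit Index of the readout unit (rHebb only, default 1).
#' @param constant_input_units Indices of units clamped to a constant drive
#'   (rHebb only, default `c(2, 3, 4)`).
#' @param n_rec_policy,n_out_policy Policy-network sizes used to derive the
#'   default baseline input width.
#' @return An `rnn_architecture` object.
#' @export
architecture <- function(family = c("hf", "pycog", "pyrl_policy",
                                    "pyrl_baseline", "rhebb"),
                         N_rec = NULL, N_in = NULL, N_out = NULL,
                         tau = 10, dt = 1, noise_std_rec = NULL,
                         exc_frac = 0.8, plastic_density = 0.1,
                         output_unit = 1L, constant_input_units = c(2L, 3L, 4L),
                         n_rec_policy = NULL, n_out_policy = 3L) {
  family <- match.arg(family)
  defaults <- list(
    hf            = list(N_in = 4L, N_rec = 100L, N_out = 1L,
                         activation = "tanh", noise = 0.004),
    pycog         = list(N_in = 6L, N_rec = 150L, N_out = 2L,
                         activation = "rectified_linear", noise = 0.01),
    pyrl_policy   = list(N_in = 6L, N_rec = 100L, N_out = 3L,
                         activation = "rectified_linear", noise = 0.01),
    pyrl_baseline = list(N_in = NA, N_rec = 100L, N_out = 1L,
                         activation = "rectified_linear", noise = 0.01),
    rhebb         = list(N_in = 4L, N_rec = 200L, N_out = 1L,
                         activation = "tanh", noise = 0.1)
  )[[family]]
  N_rec <- as.integer(N_rec %||% defaults$N_rec)
  N_out <- as.integer(N_out %||% defaults$N_out)
  if (family == "pyrl_baseline" && is.null(N_in)) {
    N_in <- as.integer((n_rec_policy %||% 100L) + n_out_policy)
  }
  N_in <- as.integer(N_in %||% defaults$N_in)
  if (dt <= 0 || dt > tau) stop_invalid("need 0 < dt <= tau")
  if (N_rec < 2 || N_in < 1 || N_out < 1) stop_invalid("invalid unit counts")

  dale_signs <- NULL
  n_exc <- NULL
  if (family == "pycog") {
    n_exc <- as.integer(round(exc_frac * N_rec))
    dale_signs <- c(rep(1, n_exc), rep(-1, N_rec - n_exc))
  }
  if (family == "rhebb") {
    output_unit <- as.integer(output_unit)
    constant_input_units <- as.integer(constant_input_units)
    idx <- c(output_unit, constant_input_units)
    if (any(idx < 1 | idx > N_rec) || anyDuplicated(idx)) {
      stop_invalid("output/constant-input unit indices invalid for N_rec = %d", N_rec)
    }
  }
  structure(list(
    family = family, N_in = N_in, N_rec = N_rec, N_out = N_out,
    activation = defaults$activation, tau = tau, dt = dt,
    alpha = dt / tau,
    noise_std_rec = noise_std_rec %||% defaults$noise,
    dale_signs = dale_signs, n_exc = n_exc,
    plastic_density = if (family %in% c("pyrl_policy", "pyrl_baseline"))
      plastic_density else NULL,
    gated = family %in% c("pyrl_policy", "pyrl_baseline"),
    output_unit = if (family == "rhebb") output_unit else NULL,
    constant_input_units = if (family == "rhebb") constant_input_units else NULL
  ), class = "rnn_architecture")
}

#' @export
print.rnn_architecture <- function(x, ...) {
  cat(sprintf("rnn_architecture '%s': N_in=%d N_rec=%d N_out=%d (%s%s)\n",
              x$family, x$N_in, x$N_rec, x$N_out, x$activation,
              if (x$gated) ", gated" else ""))
  if (!is.null(x$dale_signs)) {
    cat(sprintf("  Dale's law: %d excitatory / %d inhibitory\n",
                sum(x$dale_signs > 0), sum(x$dale_signs < 0)))
  }
  if (!is.null(x$plastic_density)) {
    cat(sprintf("  plastic recurrent synapses: %.0f%%\n", 100 * x$plastic_density))
  }
  invisible(x)
}

activation_fn <- function(arch) {
  if (arch$activation == "tanh") tanh else function(x) pmax(x, 0)
}

activation_grad <- function(arch, r, x) {
  if (arch$activation == "tanh") 1 - r * r else (x > 0) + 0
}

#' Initialize network parameters
#'
#' Draws the weight matrices of one model instance. The family defaults are:
#' HF Gaussian(0, 0.01) on every weight; rHebb Gaussian(0, 1.5 / sqrt(N_rec))
#' on the recurrent weights (0.106 at the reference size N_rec = 200); pycog
#' gamma-distributed magnitudes with the sign of each presynaptic column set
#' by the unit's Dale type, zero self-connections, and the recurrent matrix
#' rescaled to a fixed spectral radius; pyrl gamma(K = 4) magnitudes with
#' independent random sign multipliers, plus gate parameter matrices and a
#' random plasticity mask covering `plastic_density` of the recurrent
#' synapses.
#'
#' @param arch An [architecture()].
#' @param init_spec Optional override: `list(dist = "gaussian", mean, sd)`,
#'   `list(dist = "gamma", shape, scale)` (signs per Dale type or random), or
#'   `list(dist = "uniform", min, max)`.
#' @param seed Optional integer seed; identical seeds give identical
#'   parameters.
#' @return A `network_parameters` object with `W_rec`, `W_in`, `W_out`,
#'   `b_x`, `b_z`, optional gate matrices (`W_q_in`, `W_q_rec`, `b_q`,
#'   `W_s_in`, `W_s_rec`, `b_s`) and optional logical `plasticity_mask`.
#' @export
init_parameters <- function(arch, init_spec = NULL, seed = NULL) {
  stopifnot(inherits(arch, "rnn_architecture"))
  spec <- init_spec %||% default_init_spec(arch)
  validate_init_spec(spec)
  N <- arch$N_rec
  with_seed(seed, {
    draw <- function(n) draw_magnitudes(spec, n)
    p <- list()
    if (arch$family == "pycog") {
      mag <- matrix(abs(draw(N * N)), N, N)
      W <- sweep(mag, 2, arch$dale_signs, `*`)
      diag(W) <- 0
      rad <- max(Mod(eigen(W, only.values = TRUE)$values))
      if (rad > 0) W <- W * (1.2 / rad)  # fixed initial spectral radius
      p$W_rec <- W
      p$W_in <- matrix(abs(rnorm(N * arch$N_in, 0, 0.1)), N, arch$N_in)
      p$W_out <- matrix(rnorm(arch$N_out * N, 0, 0.1), arch$N_out, N)
    } else if (arch$gated) {
      signs <- matrix(sample(c(-1, 1), N * N, replace = TRUE), N, N)
      p$W_rec <- matrix(abs(draw(N * N)), N, N) * signs
      p$W_in <- matrix(rnorm(N * arch$N_in, 0, 0.1), N, arch$N_in)
      p$W_out <- matrix(rnorm(arch$N_out * N, 0, 0.1), arch$N_out, N)
      for (g in c("q", "s")) {
        p[[paste0("W_", g, "_in")]] <- matrix(rnorm(N * arch$N_in, 0, 0.1),
                                              N, arch$N_in)
        p[[paste0("W_", g, "_rec")]] <- matrix(rnorm(N * N, 0, 1 / sqrt(N)), N, N)
        p[[paste0("b_", g)]] <- rep(0, N)
      }
      k_plastic <- as.integer(round(arch$plastic_density * N * N))
      mask <- matrix(FALSE, N, N)
      mask[sample.int(N * N, k_plastic)] <- TRUE
      p$plasticity_mask <- mask
    } else { # hf, rhebb: plain Gaussian-family initialisation on all weights
      p$W_rec <- matrix(draw(N * N), N, N)
      if (arch$family == "rhebb") {
        p$W_in <- matrix(rnorm(N * arch$N_in, 0, 1), N, arch$N_in)
        p$W_out <- NULL
      } else {
        p$W_in <- matrix(draw(N * arch$N_in), N, arch$N_in)
        p$W_out <- matrix(draw(arch$N_out * N), arch$N_out, N)
      }
    }
    p$b_x <- rep(0, N)
    p$b_z <- if (is.null(p$W_out)) NULL else rep(0, arch$N_out)
    structure(p, class = "network_parameters", family = arch$family)
  })
}

default_init_spec <- function(arch) {
  switch(arch$family,
    hf = list(dist = "gaussian", mean = 0, sd = 0.01),
    rhebb = list(dist = "gaussian", mean = 0, sd = 1.5 / sqrt(arch$N_rec)),
    pycog = list(dist = "gamma", shape = 2,
                 scale = 0.5 / sqrt(arch$N_rec)),
    # signed magnitude sd = 0.15 to match the comparable-initialisation setting
    list(dist = "gamma", shape = 4, scale = 0.15 / sqrt(20))
  )
}

validate_init_spec <- function(spec) {
  if (!is.list(spec) || is.null(spec$dist)) stop_invalid("malformed init_spec")
  if (spec$dist == "gaussian" && (spec$sd %||% -1) <= 0) {
    stop_invalid("gaussian init requires sd > 0")
  }
  if (spec$dist == "gamma" &&
      ((spec$shape %||% -1) <= 0 || (spec$scale %||% -1) <= 0)) {
    stop_invalid("gamma init requires shape > 0 and scale > 0")
  }
  if (spec$dist == "uniform" && (spec$min %||% 0) >= (spec$max %||% 0)) {
    stop_invalid("uniform init requires min < max")
  }
  invisible(spec)
}

draw_magnitudes <- function(spec, n) {
  switch(spec$dist,
    gaussian = rnorm(n, spec$mean, spec$sd),
    gamma = rgamma(n, shape = spec$shape, scale = spec$scale),
    uniform = runif(n, spec$min, spec$max),
    stop_invalid("unknown init distribution '%s'", spec$dist)
  )
}
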