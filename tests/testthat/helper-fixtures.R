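# Shared helpers: small configs and a memoized store of trained records so
# the expensive training runs are shared across test files.

quick_task <- function(family) default_task_config(family)

# trainer budgets used by the test suite (the methods vignette states the
# sizes): hf/pycog stop at the 0.95 validation criterion; pyrl trains to
# convergence, where its plasticity is concentrated enough for the lesion
# contrast to be measurable; the rHebb trial budget is reduced
test_trainer_spec <- function(family) {
  switch(family,
    pyrl = pyrl_spec(n_iterations = 1500, stop_accuracy = 1.01),
    rhebb = rhebb_config(n_trials = 10000),
    scaled_defaults(family)$trainer_spec
  )
}

.record_cache <- new.env(parent = emptyenv())

trained_record <- function(family, seed) {
  key <- paste(family, seed)
  if (is.null(.record_cache[[key]])) {
    sc <- scaled_defaults(family)
    res <- train_family(family, N_rec = sc$N_rec,
                        N_rec_baseline = sc$N_rec_baseline,
                        trainer_spec = test_trainer_spec(family), seed = seed)
    rec <- if (family == "pyrl") res$record$policy else res$record
    .record_cache[[key]] <- list(record = rec, arch = res$arch)
  }
  .record_cache[[key]]
}

fresh_accuracy <- function(family, seed, n = 500) {
  tr <- trained_record(family, seed)
  batch <- make_batch(default_task_config(family), n, "alternating",
                      seed = derive_seed(seed, 777))
  accuracy(tr$record$W_last, tr$arch, batch, seed = derive_seed(seed, 778),
           noise_std = if (family == "rhebb") 0 else NULL)
}

# textbook moment-ratio estimators, kept independent of the package's code
oracle_g1 <- function(x) {
  n <- length(x); xc <- x - sum(x) / n
  (sum(xc^3) / n) / (sum(xc^2) / n)^1.5
}
oracle_g2 <- function(x) {
  n <- length(x); xc <- x - sum(x) / n
  (sum(xc^4) / n) / (sum(xc^2) / n)^2 - 3
}
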