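# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Small but full-scheme corpus for dataset-level tests.
small_corpus <- function() {
  cached("small_corpus", function() build_benchmark(n_per_class = 10, seed = 7))
}

# Fast bundle for cascade behavior tests: three low-dimensional feature
# types keep member counts small (9 + 3 + 30) without changing the decision
# machinery.
fast_bundle <- function() {
  cached("fast_bundle", function() {
    suppressWarnings(train_cascade(
      small_corpus(),
      config = list(feature_types = c("AAComposition", "AAComposition_N_C",
                                      "Dipeptide")),
      seed = 7
    ))
  })
}

# Default study conditions: full-size corpus and fully trained cascade.
default_corpus <- function() {
  cached("default_corpus", function() build_benchmark(n_per_class = 20,
                                                      seed = 2024))
}

default_bundle <- function() {
  cached("default_bundle", function() {
    suppressWarnings(train_cascade(default_corpus(), seed = 2024))
  })
}

# Tiny linearly separable two-class training set over AAComposition.
toy_training_set <- function(n_per_class = 12, seed = 3) {
  set.seed(seed)
  profile_a <- family_profile("A-rich", stats::setNames(
    c(0.6, rep(0.4 / 19, 19)), rlpcascade:::AA_ALPHABET
  ), length_range = c(60, 90))
  profile_b <- family_profile("K-rich", {
    p <- stats::setNames(rep(0.4 / 19, 20), rlpcascade:::AA_ALPHABET)
    p["K"] <- 0.6
    p["A"] <- 0.4 / 19
    p / sum(p)
  }, length_range = c(60, 90))
  records <- tibble::tibble(
    id = paste0("t", seq_len(2 * n_per_class)),
    description = "",
    residues = c(
      purrr::map_chr(seq_len(n_per_class), ~ sample_sequence(profile_a)),
      purrr::map_chr(seq_len(n_per_class), ~ sample_sequence(profile_b))
    )
  )
  list(
    X = featurize(records, "AAComposition"),
    y = rep(c("pos", "neg"), each = n_per_class),
    feature_type = "AAComposition", dataset_id = "toy", stage = "toy"
  )
}

# Independent random-walk Metropolis sampler for the Beta-Binomial
# posterior: explores p on the logit scale against the raw likelihood, never
# using the conjugate update it is meant to check.
mcmc_beta_mean <- function(x, n, alpha0 = 1, beta0 = 1, iters = 10000,
                           burnin = 2000) {
  logpost <- function(p) {
    (x + alpha0 - 1) * log(p) + (n - x + beta0 - 1) * log(1 - p)
  }
  draws <- numeric(iters)
  p <- 0.5
  for (i in seq_len(iters)) {
    z <- stats::qlogis(p) + stats::rnorm(1, 0, 0.8)
    cand <- stats::plogis(z)
    # include the logit-normal proposal Jacobian
    log_ratio <- logpost(cand) - logpost(p) +
      log(cand * (1 - cand)) - log(p * (1 - p))
    if (log(stats::runif(1)) < log_ratio) p <- cand
    draws[i] <- p
  }
  mean(draws[(burnin + 1):iters])
}

# Same idea for the Dirichlet-Multinomial posterior: Metropolis over the
# softmax parameterization of the probability simplex.
mcmc_dirichlet_mean <- function(counts, alpha0 = 1, iters = 10000,
                                burnin = 2000) {
  k <- length(counts)
  if (length(alpha0) == 1) alpha0 <- rep(alpha0, k)
  logpost <- function(theta) sum((counts + alpha0 - 1) * log(theta))
  softmax <- function(z) {
    e <- exp(z - max(z))
    e / sum(e)
  }
  # Jacobian of softmax: sum(log theta) up to a constant
  z <- rep(0, k)
  theta <- softmax(z)
  acc <- matrix(0, iters, k)
  for (i in seq_len(iters)) {
    zc <- z + stats::rnorm(k, 0, 0.4)
    tc <- softmax(zc)
    log_ratio <- logpost(tc) - logpost(theta) +
      sum(log(tc)) - sum(log(theta))
    if (log(stats::runif(1)) < log_ratio) {
      z <- zc
      theta <- tc
    }
    acc[i, ] <- theta
  }
  colMeans(acc[(burnin + 1):iters, , drop = FALSE])
}

random_protein <- function(len, alphabet = rlpcascade:::AA_ALPHABET) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
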