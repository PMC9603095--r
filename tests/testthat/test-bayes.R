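test_that("Beta-Binomial posterior follows the conjugate closed form", {
  p <- beta_binomial_posterior(rep(1, 5))
  expect_equal(p$mean, 6 / 7)
  expect_equal(p$alpha, 6)
  expect_equal(p$beta, 1)

  p <- beta_binomial_posterior(rep(0, 10))
  expect_equal(p$mean, 1 / 12)

  expect_error(beta_binomial_posterior(integer()), "Empty")
  expect_error(beta_binomial_posterior(c(1, 2)), "0/1")
})

test_that("Beta posterior mean rises with successes and converges to x/n", {
  means <- vapply(0:10, function(x) {
    beta_binomial_posterior(c(rep(1, x), rep(0, 10 - x)))$mean
  }, numeric(1))
  expect_true(all(diff(means) > 0))

  big <- beta_binomial_posterior(c(rep(1, 7000), rep(0, 3000)))
  expect_equal(big$mean, 0.7, tolerance = 0.01)
})

test_that("Dirichlet-Multinomial posterior follows the conjugate closed form", {
  p <- dirichlet_multinomial_posterior(c(a = 3, b = 0, c = 0))
  expect_equal(unname(p$mean), c(4, 1, 1) / 6)
  expect_equal(sum(p$mean), 1)

  flat <- dirichlet_multinomial_posterior(stats::setNames(rep(0, 5),
                                                          letters[1:5]))
  expect_equal(unname(flat$mean), rep(0.2, 5))

  expect_error(dirichlet_multinomial_posterior(c(a = -1, b = 2)), "Negative")
  expect_error(dirichlet_multinomial_posterior(c(a = 1)), "2 classes")
})

test_that("closed-form posteriors match an independent MCMC sampler", {
  set.seed(61)
  for (i in 1:6) {
    n <- sample(5:40, 1)
    x <- sample(0:n, 1)
    closed <- beta_binomial_posterior(c(rep(1, x), rep(0, n - x)))$mean
    expect_lt(abs(mcmc_beta_mean(x, n) - closed), 0.01)
  }
  for (i in 1:3) {
    counts <- stats::setNames(sample(0:20, 4, replace = TRUE), letters[1:4])
    closed <- dirichlet_multinomial_posterior(counts)$mean
    mc <- mcmc_dirichlet_mean(counts)
    expect_true(all(abs(mc - closed) < 0.015))
  }
})

test_that("stage votes are one per member in manifest order", {
  ts <- toy_training_set(seed = 8)
  m1 <- train_member(ts, "knn", seed = 1)
  m2 <- train_member(ts, "lda", seed = 1)
  row_pos <- ts$X[1, ]
  feature_rows <- list(AAComposition = row_pos)
  votes <- stage_vote(list(m1, m2), feature_rows, "pos")
  expect_equal(votes, c(1L, 1L))
  votes <- stage_vote(list(m1, m2), feature_rows, "neg")
  expect_equal(votes, c(0L, 0L))

  m_tri <- m1
  m_tri$feature_type <- "Tripeptide"
  expect_error(stage_vote(list(m_tri), feature_rows, "pos"), "Tripeptide")
})

test_that("subfamily votes count members per class and conserve the total", {
  ts <- toy_training_set(seed = 9)
  members <- purrr::map(1:5, ~ train_member(ts, "knn", seed = .x))
  scheme <- list(labels = c("pos", "neg"), other_label = "neg")
  counts <- subfamily_vote(members, list(AAComposition = ts$X[1, ]), scheme)
  expect_equal(sum(counts), 5)
  expect_equal(counts[["pos"]], 5L)

  bad_scheme <- list(labels = c("x", "y"), other_label = "y")
  expect_error(subfamily_vote(members, list(AAComposition = ts$X[1, ]),
                              bad_scheme),
               "outside")
})

test_that("the decision rule gates on TM, stage cutoffs and subfamily cutoff", {
  post_hi <- dirichlet_multinomial_posterior(
    stats::setNames(c(55, rep(0, 15)), paste0("C", 1:16))
  )
  post_mid <- dirichlet_multinomial_posterior(
    stats::setNames(c(25, rep(2, 15)), paste0("C", 1:16))
  )

  # TM absence vetoes everything else
  d <- decide(TRUE, FALSE, 0.99, 0.99, post_hi)
  expect_equal(d$classification, "NRLP")

  # all-pass: the argmax subfamily label
  d <- decide(TRUE, TRUE, 0.996, 0.991, post_hi)
  expect_equal(d$classification, "C1")

  # stages pass but subfamily posterior below cutoff: Undefined
  expect_lt(max(post_mid$mean), 0.7)
  d <- decide(TRUE, TRUE, 0.996, 0.991, post_mid)
  expect_equal(d$classification, "Undefined")

  # stage-1 failure (random-sequence behavior): NRLP
  d <- decide(FALSE, TRUE, 0.05, 0.85, post_hi)
  expect_equal(d$classification, "NRLP")
})

test_that("decision probability is monotone in positive evidence", {
  post_hi <- dirichlet_multinomial_posterior(
    stats::setNames(c(55, rep(0, 15)), paste0("C", 1:16))
  )
  post_lo <- dirichlet_multinomial_posterior(
    stats::setNames(rep(3, 16), paste0("C", 1:16))
  )
  grid <- expand.grid(sp = c(FALSE, TRUE), tm = c(FALSE, TRUE),
                      p1 = c(0.1, 0.9), p2 = c(0.1, 0.9),
                      hi = c(FALSE, TRUE))
  dp <- function(g) {
    decide(g$sp, g$tm, g$p1, g$p2,
           if (g$hi) post_hi else post_lo)$decision_probability
  }
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    base <- dp(g)
    for (flip in c("sp", "tm", "hi")) {
      if (!g[[flip]]) {
        g2 <- g
        g2[[flip]] <- TRUE
        expect_gte(dp(g2), base)
      }
    }
    if (g$p1 < 0.5) {
      g2 <- g
      g2$p1 <- 0.9
      expect_gte(dp(g2), base)
    }
  }
})

test_that("tidy methods expose posterior summaries", {
  td <- tidy(beta_binomial_posterior(c(1, 1, 0)))
  expect_equal(td$x, 2)
  expect_equal(td$mean, 3 / 5)
  td <- tidy(dirichlet_multinomial_posterior(c(a = 2, b = 1)))
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$mean), 1)
})
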