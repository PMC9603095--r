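#' Beta-Binomial posterior over binary ensemble votes
#'
#' Treats the member votes as n independent Bernoulli trials with success
#' probability pi and a Beta(alpha0, beta0) prior; the posterior is
#' Beta(alpha0 + x, beta0 + n - x) in closed form, with posterior mean
#' `(alpha0 + x) / (alpha0 + beta0 + n)`.
#'
#' @param votes Binary (0/1 or logical) vote vector; at least one vote.
#' @param alpha0,beta0 Beta prior hyperparameters (> 0).
#' @return An `rlp_stage_posterior`: list with `x`, `n`, `alpha0`, `beta0`,
#'   `alpha`, `beta`, `mean`.
#' @examples
#' beta_binomial_posterior(c(1, 1, 1, 1, 1))$mean  # 6/7
#' @export
beta_binomial_posterior <- function(votes, alpha0 = 1, beta0 = 1) {
  if (length(votes) == 0) stop("Empty vote vector", call. = FALSE)
  stopifnot(alpha0 > 0, beta0 > 0)
  v <- as.integer(votes)
  if (any(!v %in% c(0L, 1L))) stop("Votes must be 0/1", call. = FALSE)
  x <- sum(v)
  n <- length(v)
  structure(
    list(x = x, n = n, alpha0 = alpha0, beta0 = beta0,
         alpha = alpha0 + x, beta = beta0 + n - x,
         mean = (alpha0 + x) / (alpha0 + beta0 + n)),
    class = "rlp_stage_posterior"
  )
}

#' @export
print.rlp_stage_posterior <- function(x, ...) {
  cat(sprintf("<rlp_stage_posterior> x=%d n=%d Beta(%.2f, %.2f) mean=%.4f\n",
              x$x, x$n, x$alpha, x$beta, x$mean))
  invisible(x)
}

#' Dirichlet-Multinomial posterior over subfamily vote counts
#'
#' Treats per-class vote totals as one multinomial draw with a
#' Dirichlet(alpha0) prior; the posterior is Dirichlet(alpha0 + counts) with
#' mean `(alpha0_i + x_i) / sum_j(alpha0_j + x_j)`.
#'
#' @param counts Named non-negative integer vector, one entry per class
#'   (length >= 2).
#' @param alpha0 Prior concentration, scalar or per-class vector (default
#'   all ones).
#' @return An `rlp_subfamily_posterior`: list with `counts`, `N`, `alpha0`,
#'   `alpha`, `mean` (sums to 1).
#' @examples
#' dirichlet_multinomial_posterior(c(a = 3, b = 0, c = 0))$mean
#' @export
dirichlet_multinomial_posterior <- function(counts, alpha0 = 1) {
  if (length(counts) < 2) stop("Need at least 2 classes", call. = FALSE)
  if (any(counts < 0)) stop("Negative count", call. = FALSE)
  if (length(alpha0) == 1) alpha0 <- rep(alpha0, length(counts))
  stopifnot(length(alpha0) == length(counts), all(alpha0 > 0))
  alpha <- alpha0 + counts
  structure(
    list(counts = counts, N = sum(counts), alpha0 = alpha0, alpha = alpha,
         mean = stats::setNames(alpha / sum(alpha), names(counts))),
    class = "rlp_subfamily_posterior"
  )
}

#' @export
print.rlp_subfamily_posterior <- function(x, ...) {
  top <- which.max(x$mean)
  cat(sprintf("<rlp_subfamily_posterior> N=%d classes=%d top=%s (%.4f)\n",
              x$N, length(x$counts),
              names(x$mean)[top] %||% top, x$mean[top]))
  invisible(x)
}

#' Collect binary stage votes from ensemble members
#'
#' Each member predicts the label of one query sequence from the feature
#' vector matching its feature type; the vote is 1 when the prediction
#' equals `target_label`. Vote order follows the member list.
#'
#' @param members List of `rlp_member` models.
#' @param feature_rows Named list (by feature type) of one-row feature
#'   tibbles for the query sequence.
#' @param target_label Label counted as success (e.g. `"RLP"`).
#' @return Integer 0/1 vector, one entry per member.
#' @export
stage_vote <- function(members, feature_rows, target_label) {
  vapply(members, function(m) {
    fr <- feature_rows[[m$feature_type]]
    if (is.null(fr)) {
      stop("No feature vector of type '", m$feature_type,
           "' for member ", m$dataset_id, call. = FALSE)
    }
    as.integer(predict(m, fr)$label[1] == target_label)
  }, integer(1))
}

#' Collect subfamily vote counts from ensemble members
#'
#' @inheritParams stage_vote
#' @param scheme Class scheme ([class_scheme()]); predictions outside it
#'   error.
#' @return Named integer count vector in scheme order, summing to the number
#'   of members.
#' @export
subfamily_vote <- function(members, feature_rows, scheme) {
  labels <- vapply(members, function(m) {
    fr <- feature_rows[[m$feature_type]]
    if (is.null(fr)) {
      stop("No feature vector of type '", m$feature_type,
           "' for member ", m$dataset_id, call. = FALSE)
    }
    predict(m, fr)$label[1]
  }, character(1))
  bad <- setdiff(unique(labels), scheme$labels)
  if (length(bad)) {
    stop("Member predicted label(s) outside the class scheme: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(labels, levels = scheme$labels))
  stats::setNames(as.integer(counts), scheme$labels)
}

#' Final topology-gated decision for one sequence
#'
#' Categorical rule: the sequence is `NRLP` when it lacks a transmembrane
#' segment or fails either binary-stage cutoff; `Undefined` when the stages
#' pass but the best subfamily posterior mean is below its cutoff; otherwise
#' the argmax subfamily label. Signal-peptide absence never vetoes by itself.
#' The decision probability is the mean of a Beta posterior over the
#' weighted evidence bits (sp, tm, stage-1 pass, stage-2 pass, subfamily
#' pass); its functional form is implementation-defined.
#'
#' @param sp,tm Logical topology evidence.
#' @param p1,p2 Stage-1/stage-2 posterior means in (0, 1).
#' @param subfam_posterior `rlp_subfamily_posterior` for the query.
#' @param cutoffs List with `c1`, `c2` (binary stages) and `c3` (subfamily).
#' @param weights Evidence weights, length 5.
#' @param prior Beta prior `c(a0, b0)` for the decision probability.
#' @return An `rlp_decision`: list with `classification`,
#'   `decision_probability` and the `evidence` record.
#' @export
decide <- function(sp, tm, p1, p2, subfam_posterior,
                   cutoffs = list(c1 = 0.6, c2 = 0.6, c3 = 0.7),
                   weights = rep(1, 5), prior = c(0.5, 0.5)) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1,
            inherits(subfam_posterior, "rlp_subfamily_posterior"))
  best <- which.max(subfam_posterior$mean)
  best_mean <- subfam_posterior$mean[[best]]
  best_label <- names(subfam_posterior$mean)[best]
  pass1 <- p1 >= cutoffs$c1
  pass2 <- p2 >= cutoffs$c2
  pass3 <- best_mean >= cutoffs$c3
  classification <- if (!tm || !pass1 || !pass2) {
    "NRLP"
  } else if (!pass3) {
    "Undefined"
  } else {
    best_label
  }
  v <- as.numeric(c(sp, tm, pass1, pass2, pass3))
  a <- prior[1] + sum(weights * v)
  b <- prior[2] + sum(weights * (1 - v))
  structure(
    list(
      classification = classification,
      decision_probability = a / (a + b),
      evidence = list(sp = sp, tm = tm, stage1 = pass1, stage2 = pass2,
                      stage3 = pass3, subfamily = best_label,
                      subfamily_mean = best_mean)
    ),
    class = "rlp_decision"
  )
}

#' @export
print.rlp_decision <- function(x, ...) {
  cat(sprintf("<rlp_decision> %s (p=%.4f)\n", x$classification,
              x$decision_probability))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.rlp_stage_posterior <- function(x, ...) {
  out <- list(x = x$x, n = x$n, alpha = x$alpha, beta = x$beta,
              mean = x$mean)
  tibble::as_tibble(out)
}

#' @export
tidy.rlp_subfamily_posterior <- function(x, ...) {
  tibble::tibble(class = names(x$mean), count = as.integer(x$counts),
                 alpha = as.numeric(x$alpha), mean = as.numeric(x$mean))
}
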