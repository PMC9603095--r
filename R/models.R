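# Member-classifier registry. Each entry fits on (x matrix, y factor) and
# predicts class labels plus per-class probabilities on new rows. Fixed
# order; also the champion tie-break order.
ALGORITHM_IDS <- c("adaboost", "calibrated", "gradient_boosting", "knn",
                   "lda", "qda", "logistic_cv", "mlp")

# Drop zero-variance columns (constant features break discriminant fits on
# sparse high-dimensional encodings); remember the kept set for prediction.
# Discriminant fits additionally need columns with non-zero pooled
# within-class variance.
variance_filter <- function(x, y = NULL) {
  v <- matrixStats_colVars(x)
  if (!is.null(y)) {
    w <- rep(0, ncol(x))
    for (cl in unique(y)) {
      w <- w + matrixStats_colVars(x[y == cl, , drop = FALSE]) * sum(y == cl)
    }
    v <- pmin(v, w / nrow(x))
  }
  # discriminant fits reject within-class sd below 1e-4; keep a margin
  keep <- which(v > if (is.null(y)) 1e-12 else 4e-8)
  if (length(keep) == 0) keep <- 1L
  keep
}

matrixStats_colVars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  colSums(x^2) / n - mu^2
}

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

# --- individual algorithm backends -----------------------------------------

fit_lda <- function(x, y) {
  suppressWarnings(MASS::lda(x, grouping = y))
}
predict_lda <- function(fit, x) {
  p <- stats::predict(fit, x)
  list(label = as.character(p$class), prob = p$posterior)
}

fit_qda <- function(x, y) {
  # frequency encodings carry exact linear dependencies (rows sum to 1);
  # keep a full-rank column subset so per-class covariances invert
  qrx <- qr(scale(x, center = TRUE, scale = FALSE))
  cols <- sort(qrx$pivot[seq_len(qrx$rank)])
  list(fit = MASS::qda(x[, cols, drop = FALSE], grouping = y), cols = cols)
}
predict_qda <- function(fit, x) {
  p <- stats::predict(fit$fit, x[, fit$cols, drop = FALSE])
  list(label = as.character(p$class), prob = p$posterior)
}

fit_knn <- function(x, y, k = 5) {
  # lazy learner: store the training data
  list(x = x, y = y, k = min(k, nrow(x)))
}
predict_knn <- function(fit, x) {
  # knn resolves vote ties by randomization; pin it so prediction is pure
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(20221012L)
  pr <- class::knn(fit$x, x, fit$y, k = fit$k, prob = TRUE)
  lv <- levels(fit$y)
  win <- attr(pr, "prob")
  prob <- matrix((1 - win) / max(1, length(lv) - 1), nrow = nrow(x),
                 ncol = length(lv), dimnames = list(NULL, lv))
  prob[cbind(seq_len(nrow(x)), match(as.character(pr), lv))] <- win
  list(label = as.character(pr), prob = prob)
}

fit_logistic_cv <- function(x, y, seed) {
  fam <- if (nlevels(y) > 2) "multinomial" else "binomial"
  set.seed(seed)
  glmnet::cv.glmnet(x, y, family = fam, nfolds = 3, alpha = 0,
                    type.measure = "class")
}
predict_logistic_cv <- function(fit, x, levels) {
  pr <- stats::predict(fit, x, s = "lambda.min", type = "response")
  if (length(dim(pr)) == 3) pr <- pr[, , 1]
  if (is.null(dim(pr)) || ncol(pr) == 1) {
    pr <- cbind(1 - as.numeric(pr), as.numeric(pr))
    colnames(pr) <- levels
  }
  lab <- colnames(pr)[max.col(pr, ties.method = "first")]
  list(label = lab, prob = pr)
}

fit_mlp <- function(x, y, seed, size = 8) {
  set.seed(seed)
  utils::capture.output(
    fit <- nnet::nnet(x, class_indicator(y), size = size, softmax = TRUE,
                      maxit = 200, MaxNWts = 1e7, trace = FALSE)
  )
  list(net = fit, levels = levels(y))
}
predict_mlp <- function(fit, x) {
  pr <- stats::predict(fit$net, x)
  colnames(pr) <- fit$levels
  list(label = colnames(pr)[max.col(pr, ties.method = "first")], prob = pr)
}

class_indicator <- function(y) {
  m <- stats::model.matrix(~ y - 1)
  colnames(m) <- levels(y)
  m
}

fit_gradient_boosting <- function(x, y, seed) {
  nl <- nlevels(y)
  params <- if (nl > 2) {
    list(objective = "multi:softprob", num_class = nl, max_depth = 3,
         eta = 0.3, nthread = 1)
  } else {
    list(objective = "binary:logistic", max_depth = 3, eta = 0.3, nthread = 1)
  }
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
  booster <- xgboost::xgb.train(params = params, data = dtrain, nrounds = 30,
                                verbose = 0)
  list(booster = booster, levels = levels(y))
}
predict_gradient_boosting <- function(fit, x) {
  pr <- stats::predict(fit$booster, xgboost::xgb.DMatrix(x))
  nl <- length(fit$levels)
  if (nl > 2) {
    pr <- matrix(pr, ncol = nl, byrow = TRUE)
  } else {
    pr <- cbind(1 - pr, pr)
  }
  colnames(pr) <- fit$levels
  list(label = colnames(pr)[max.col(pr, ties.method = "first")], prob = pr)
}

# AdaBoost (SAMME) over depth-1 rpart stumps.
fit_adaboost <- function(x, y, seed, n_rounds = 40) {
  set.seed(seed)
  n <- nrow(x)
  K <- nlevels(y)
  w <- rep(1 / n, n)
  df <- data.frame(y = y, x, check.names = FALSE)
  stumps <- list()
  alphas <- numeric()
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = 0, minsplit = 2,
                                                       xval = 0))
    pred <- as.character(stats::predict(fit, df, type = "class"))
    err <- sum(w * (pred != as.character(y))) / sum(w)
    if (err >= 1 - 1 / K) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    w <- w * exp(alpha * (pred != as.character(y)))
    w <- w / sum(w)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    if (err < 1e-9) break
  }
  if (length(stumps) == 0) {    # single split never better than chance
    stumps <- list(rpart::rpart(y ~ ., data = df,
                                control = rpart::rpart.control(maxdepth = 1,
                                                               xval = 0)))
    alphas <- 1
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y),
       template = df[0, -1, drop = FALSE])
}
predict_adaboost <- function(fit, x) {
  df <- as.data.frame(x, check.names = FALSE)
  lv <- fit$levels
  score <- matrix(0, nrow(df), length(lv), dimnames = list(NULL, lv))
  for (m in seq_along(fit$stumps)) {
    pred <- as.character(stats::predict(fit$stumps[[m]], df, type = "class"))
    score[cbind(seq_len(nrow(df)), match(pred, lv))] <-
      score[cbind(seq_len(nrow(df)), match(pred, lv))] + fit$alphas[m]
  }
  list(label = lv[max.col(score, ties.method = "first")],
       prob = softmax_rows(score))
}

# Probability calibration: LDA base scores re-mapped through a one-vs-rest
# logistic (Platt) calibration layer.
fit_calibrated <- function(x, y, seed) {
  base <- fit_lda(x, y)
  raw <- stats::predict(base, x)$posterior
  lv <- levels(y)
  set.seed(seed)
  cal <- purrr::map(lv, function(cl) {
    z <- as.numeric(y == cl)
    s <- stats::qlogis(pmin(pmax(raw[, cl], 1e-6), 1 - 1e-6))
    suppressWarnings(stats::glm(z ~ s, family = stats::binomial()))
  })
  list(base = base, cal = stats::setNames(cal, lv), levels = lv)
}
predict_calibrated <- function(fit, x) {
  raw <- stats::predict(fit$base, x)$posterior
  pr <- vapply(fit$levels, function(cl) {
    s <- stats::qlogis(pmin(pmax(raw[, cl], 1e-6), 1 - 1e-6))
    as.numeric(stats::predict(fit$cal[[cl]], data.frame(s = s),
                              type = "response"))
  }, numeric(nrow(raw)))
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1,
                                     dimnames = list(NULL, fit$levels))
  pr <- pr / rowSums(pr)
  list(label = fit$levels[max.col(pr, ties.method = "first")], prob = pr)
}

# --- registry surface -------------------------------------------------------

training_matrix <- function(X) {
  if (is.matrix(X)) return(X)
  as.matrix(X[setdiff(names(X), "id")])
}

#' Train one member classifier on a training set
#'
#' Fits the requested algorithm on a training set. Zero-variance feature
#' columns are dropped before fitting (and the same columns at prediction
#' time); stochastic algorithms are seeded so repeated fits are identical.
#'
#' @param training_set An `rlp_training_set` (or a list with `X`, `y`,
#'   `feature_type`, `dataset_id`, `stage`).
#' @param algorithm_id One of `r paste(ALGORITHM_IDS, collapse = ", ")`.
#' @param seed Integer seed.
#' @return An `rlp_member` model object.
#' @export
train_member <- function(training_set, algorithm_id, seed = 1) {
  algorithm_id <- match.arg(algorithm_id, ALGORITHM_IDS)
  x <- training_matrix(training_set$X)
  y <- factor(training_set$y)
  if (nlevels(y) < 2) {
    stop("Training set is degenerate: fewer than 2 classes", call. = FALSE)
  }
  if (min(table(y)) < 2) {
    stop("Training set is degenerate: a class has fewer than 2 rows",
         call. = FALSE)
  }
  within_group <- algorithm_id %in% c("lda", "qda", "calibrated")
  keep <- variance_filter(x, if (within_group) y else NULL)
  xk <- x[, keep, drop = FALSE]
  fit <- switch(
    algorithm_id,
    adaboost = fit_adaboost(xk, y, seed),
    calibrated = fit_calibrated(xk, y, seed),
    gradient_boosting = fit_gradient_boosting(xk, y, seed),
    knn = fit_knn(xk, y),
    lda = fit_lda(xk, y),
    qda = fit_qda(xk, y),
    logistic_cv = fit_logistic_cv(xk, y, seed),
    mlp = fit_mlp(xk, y, seed)
  )
  structure(
    list(algorithm_id = algorithm_id, fit = fit, keep = keep,
         levels = levels(y), feature_type = training_set$feature_type,
         dataset_id = training_set$dataset_id, stage = training_set$stage,
         seed = seed),
    class = "rlp_member"
  )
}

#' Predict with a member classifier
#'
#' @param object An `rlp_member` from [train_member()].
#' @param new_X Feature tibble (or matrix) with the same columns the member
#'   was trained on; an `id` column is ignored.
#' @param ... Unused.
#' @return A tibble with columns `label` and one probability column per
#'   class; probabilities sum to 1 per row.
#' @export
predict.rlp_member <- function(object, new_X, ...) {
  x <- if (is.matrix(new_X)) new_X else training_matrix(new_X)
  xk <- x[, object$keep, drop = FALSE]
  out <- switch(
    object$algorithm_id,
    adaboost = predict_adaboost(object$fit, xk),
    calibrated = predict_calibrated(object$fit, xk),
    gradient_boosting = predict_gradient_boosting(object$fit, xk),
    knn = predict_knn(object$fit, xk),
    lda = predict_lda(object$fit, xk),
    qda = predict_qda(object$fit, xk),
    logistic_cv = predict_logistic_cv(object$fit, xk, object$levels),
    mlp = predict_mlp(object$fit, xk)
  )
  prob <- out$prob[, object$levels, drop = FALSE]
  dplyr::bind_cols(tibble::tibble(label = out$label), tibble::as_tibble(prob))
}

#' @export
print.rlp_member <- function(x, ...) {
  cat("<rlp_member>", x$algorithm_id, "on", x$feature_type,
      "(", x$dataset_id, ",", x$stage, ")\n")
  invisible(x)
}

# --- metrics ----------------------------------------------------------------

#' One-vs-rest confusion counts from labels
#'
#' @param truth True label vector.
#' @param predicted Predicted label vector.
#' @param classes Class order (defaults to sorted union).
#' @return Tibble with one row per class: `class`, `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted,
                             classes = sort(union(truth, predicted))) {
  purrr::map_dfr(classes, function(cl) {
    tibble::tibble(
      class = cl,
      tp = sum(truth == cl & predicted == cl),
      fp = sum(truth != cl & predicted == cl),
      tn = sum(truth != cl & predicted != cl),
      fn = sum(truth == cl & predicted != cl)
    )
  })
}

metric_or_zero <- function(num, den, name) {
  if (den == 0) {
    warning("Zero denominator for ", name, "; reporting 0")
    return(0)
  }
  num / den
}

#' Compute the classification metric suite from confusion counts
#'
#' Closed forms over one-vs-rest counts: accuracy, F1, false discovery rate,
#' Matthews correlation coefficient, precision, sensitivity and specificity.
#' Multiclass inputs (several rows) are macro-averaged by default
#' (`average = "macro"`); `"micro"` pools counts first. Zero denominators
#' yield the metric 0 with a warning.
#'
#' @param cm Confusion tibble from [confusion_counts()].
#' @param average `"macro"` or `"micro"` for multiclass inputs.
#' @return One-row tibble with columns `ACC`, `F1`, `FDR`, `MCC`,
#'   `Precision`, `Sensitivity`, `Specificity`.
#' @export
compute_metrics <- function(cm, average = c("macro", "micro")) {
  average <- match.arg(average)
  if (any(cm$tp < 0 | cm$fp < 0 | cm$tn < 0 | cm$fn < 0)) {
    stop("Negative confusion counts", call. = FALSE)
  }
  one <- function(tp, fp, tn, fn) {
    total <- tp + fp + tn + fn
    if (total == 0) stop("Empty confusion matrix", call. = FALSE)
    acc <- (tp + tn) / total
    precision <- metric_or_zero(tp, tp + fp, "precision")
    sensitivity <- metric_or_zero(tp, tp + fn, "sensitivity")
    specificity <- metric_or_zero(tn, tn + fp, "specificity")
    f1 <- if (precision + sensitivity == 0) 0 else {
      2 * precision * sensitivity / (precision + sensitivity)
    }
    fdr <- if (tp + fp == 0) 0 else fp / (fp + tp)
    mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (mcc_den == 0) {
      warning("Zero denominator for MCC; reporting 0")
      0
    } else {
      (tp * tn - fp * fn) / mcc_den
    }
    tibble::tibble(ACC = acc, F1 = f1, FDR = fdr, MCC = mcc,
                   Precision = precision, Sensitivity = sensitivity,
                   Specificity = specificity)
  }
  if (nrow(cm) == 1 || average == "micro") {
    agg <- dplyr::summarise(cm, dplyr::across(c("tp", "fp", "tn", "fn"), sum))
    if (nrow(cm) == 1) agg <- cm
    return(one(agg$tp[1], agg$fp[1], agg$tn[1], agg$fn[1]))
  }
  per <- purrr::pmap_dfr(cm[c("tp", "fp", "tn", "fn")], one)
  dplyr::summarise(per, dplyr::across(dplyr::everything(), mean))
}

# Binary confusion reduced to the positive class row (for two-class sets the
# paper's metric table is positive-class-vs-rest).
binary_or_macro_metrics <- function(truth, predicted, positive = NULL,
                                    average = "macro") {
  classes <- sort(union(truth, predicted))
  cm <- confusion_counts(truth, predicted, classes)
  if (!is.null(positive) && positive %in% cm$class && length(classes) == 2) {
    return(compute_metrics(cm[cm$class == positive, ], average = average))
  }
  compute_metrics(cm, average = average)
}

#' Cross-validate one algorithm on one training set
#'
#' Stratified k-fold cross-validation: folds are assigned with
#' [assign_folds()], SMOTE balancing (when requested) is applied to the
#' training folds only, and the pooled out-of-fold predictions yield one
#' metric row.
#'
#' @inheritParams train_member
#' @param n_folds Number of folds.
#' @param positive Label treated as the positive class for binary sets
#'   (defaults to `"RLP"` when present).
#' @param use_smote Balance training folds with [smote()] first.
#' @param average Multiclass averaging mode, `"macro"` or `"micro"`.
#' @return One-row tibble: `dataset_id`, `algorithm`, the metric suite, and
#'   the fold count used.
#' @export
cross_validate <- function(training_set, algorithm_id, n_folds = 10, seed = 1,
                           positive = NULL, use_smote = TRUE,
                           average = "macro") {
  y <- training_set$y
  if (is.null(positive) && "RLP" %in% y && length(unique(y)) == 2) {
    positive <- "RLP"
  }
  folds <- assign_folds(y, n_folds = n_folds, seed = seed)
  n_folds_used <- max(folds)
  pred <- character(length(y))
  mat <- training_matrix(training_set$X)
  for (f in seq_len(n_folds_used)) {
    tr <- folds != f
    Xtr <- mat[tr, , drop = FALSE]
    ytr <- y[tr]
    if (use_smote && length(unique(ytr)) > 1 &&
        length(unique(table(ytr))) > 1 && min(table(ytr)) >= 2) {
      bal <- smote(Xtr, ytr, seed = seed + f)
      Xtr <- bal$X
      ytr <- bal$y
    }
    sub <- list(X = Xtr, y = ytr, feature_type = training_set$feature_type,
                dataset_id = training_set$dataset_id,
                stage = training_set$stage)
    member <- train_member(sub, algorithm_id, seed = seed)
    pred[folds == f] <- predict(member, mat[folds == f, , drop = FALSE])$label
  }
  metrics <- binary_or_macro_metrics(y, pred, positive = positive,
                                     average = average)
  dplyr::bind_cols(
    tibble::tibble(dataset_id = training_set$dataset_id,
                   algorithm = algorithm_id),
    metrics,
    tibble::tibble(n_folds = n_folds_used)
  )
}

#' Select the champion algorithm for a training set
#'
#' Argmax over cross-validation MCC; ties broken by accuracy, then by the
#' fixed registry order.
#'
#' @param metric_records Tibble of [cross_validate()] rows for one set.
#' @return The winning row (one-row tibble).
#' @export
select_champion <- function(metric_records) {
  if (nrow(metric_records) == 0) stop("No candidate models", call. = FALSE)
  ord <- order(-metric_records$MCC, -metric_records$ACC,
               match(metric_records$algorithm, ALGORITHM_IDS))
  metric_records[ord[1], ]
}
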