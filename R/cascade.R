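#' Default cascade configuration
#'
#' All tunables of the pipeline in one list: feature encodings, member
#' algorithm roster, dataset multiplicities (3 negative splits, 10 subfamily
#' subsets, 500-sequence down-sampling cap), cross-validation folds, the
#' Bayesian priors, the decision cutoffs (0.6 / 0.6 / 0.7) and the topology
#' heuristic settings. `modifyList()` any subset onto the defaults.
#'
#' @return Named list of settings.
#' @export
default_config <- function() {
  list(
    feature_types = FEATURE_TYPES,
    algorithms = c("lda", "knn"),
    highdim_algorithms = "knn",
    highdim_threshold = 1000,
    n_splits = 3,
    n_subsets = 10,
    per_class_cap = 500,
    select_folds = 3,
    cv_folds = 10,
    use_smote = TRUE,
    redundancy_threshold = NULL,
    metrics_average = "macro",
    bayes = list(alpha0 = 1, beta0 = 1, dirichlet_alpha0 = 1),
    cutoffs = list(c1 = 0.6, c2 = 0.6, c3 = 0.7),
    decision_weights = rep(1, 5),
    decision_prior = c(0.5, 0.5),
    topology = list(window = 19, threshold = 1.6, min_tm_len = 15,
                    merge_gap = 5)
  )
}

merge_config <- function(config) {
  utils::modifyList(default_config(), config %||% list())
}

# Assemble the three stages' training inputs from a labeled corpus.
stage_inputs <- function(corpus, config) {
  ann <- corpus$annotations
  lab <- corpus$labels
  rlk_ids <- lab$id[lab$role == "rlk"]
  neg_ids <- lab$id[!lab$role %in% c("rlk", "rlp")]
  if (length(rlk_ids) == 0) stop("Corpus has no kinase receptors", call. = FALSE)
  positives <- purrr::map_dfr(rlk_ids, function(id) {
    rec <- corpus$records[corpus$records$id == id, ]
    a <- ann[ann$id == id, ]
    if (nrow(a) == 0 || is.na(a$kinase_start[1]) ||
        !passes_rlk_dataset_filter(a)) {
      return(NULL)
    }
    extract_stage1_positive(rec, a)
  })
  if (!is.null(config$redundancy_threshold)) {
    positives <- redundancy_filter(positives, config$redundancy_threshold)
  }
  subfam <- lab$subfamily[match(positives$id, lab$id)]
  list(
    positives = positives,
    negative_pool = corpus$records[corpus$records$id %in% neg_ids, ],
    rlk_full = corpus$records[corpus$records$id %in% rlk_ids, ],
    positives_subfam = dplyr::mutate(positives, subfamily = subfam)
  )
}

#' Build every training set of the three-stage cascade
#'
#' Stage 1 (RLP vs NRLP): the kinase-truncated receptor constructs against
#' `n_splits` disjoint negative subsets. Stage 2 (RLP vs RLK): the same
#' constructs against the full-length receptors. Stage 3 (subfamily):
#' `n_subsets` down-sampled labeled datasets. Each crossed with every
#' feature encoding: 18 + 6 + 60 sets at the defaults.
#'
#' @param corpus An `rlp_corpus` (or equivalent list with `records`,
#'   `annotations`, `labels`).
#' @param config Configuration overrides (see [default_config()]).
#' @param seed Integer seed for the random subset draws.
#' @return Named list with `stage1`, `stage2`, `stage3` lists of
#'   `rlp_training_set` objects, plus the resolved `scheme`.
#' @export
build_stage_sets <- function(corpus, config = list(), seed = 1) {
  config <- merge_config(config)
  inputs <- stage_inputs(corpus, config)
  scheme <- corpus$scheme %||% class_scheme()
  stage3_pos <- inputs$positives_subfam
  mapped <- scheme$mapping[stage3_pos$subfamily]
  stage3_pos$subfamily <- unname(
    ifelse(is.na(mapped), scheme$other_label, mapped)
  )
  list(
    stage1 = build_stage1_sets(inputs$positives, inputs$negative_pool,
                               n_splits = config$n_splits,
                               feature_types = config$feature_types,
                               seed = seed),
    stage2 = build_stage2_set(inputs$positives, inputs$rlk_full,
                              feature_types = config$feature_types),
    stage3 = build_stage3_sets(stage3_pos, scheme,
                               n_subsets = config$n_subsets,
                               per_class_cap = config$per_class_cap,
                               feature_types = config$feature_types,
                               seed = seed),
    scheme = scheme
  )
}

fit_full_member <- function(training_set, algorithm_id, config, seed) {
  X <- training_set$X
  y <- training_set$y
  if (config$use_smote && length(unique(table(y))) > 1 && min(table(y)) >= 2) {
    bal <- smote(X, y, seed = seed)
    X <- bal$X
    y <- bal$y
  }
  train_member(list(X = X, y = y, feature_type = training_set$feature_type,
                    dataset_id = training_set$dataset_id,
                    stage = training_set$stage),
               algorithm_id, seed = seed)
}

# Roster for one training set: sparse high-dimensional encodings use the
# neighbor-based roster (distance methods cope with p >> n; discriminant and
# linear fits there are both degenerate and expensive).
set_roster <- function(ts, config) {
  dim <- FEATURE_DIMS[[ts$feature_type]]
  if (!is.na(dim) && dim > config$highdim_threshold) {
    config$highdim_algorithms
  } else {
    config$algorithms
  }
}

select_and_fit <- function(sets, config, seed, n_folds) {
  members <- list()
  manifest <- list()
  for (ts in sets) {
    records <- purrr::map_dfr(set_roster(ts, config), function(alg) {
      tryCatch(
        cross_validate(ts, alg, n_folds = n_folds, seed = seed,
                       use_smote = config$use_smote,
                       average = config$metrics_average),
        error = function(e) {
          warning("Algorithm '", alg, "' failed on ", ts$dataset_id, ": ",
                  conditionMessage(e))
          NULL
        }
      )
    })
    champ <- select_champion(records)
    member <- fit_full_member(ts, champ$algorithm, config, seed)
    members[[length(members) + 1]] <- member
    manifest[[length(manifest) + 1]] <- dplyr::mutate(
      champ, stage = ts$stage, feature_type = ts$feature_type,
      .before = 1
    )
  }
  list(members = members, manifest = dplyr::bind_rows(manifest))
}

#' Train the full three-stage cascade on a labeled corpus
#'
#' Builds all training sets, cross-validates every configured algorithm on
#' each set, selects the per-set champion (best MCC, ties by accuracy then
#' registry order), and refits each champion on its full set. Champion
#' selection uses `select_folds` folds (3 by default; ranking needs fewer
#' folds than unbiased metric estimation).
#'
#' @inheritParams build_stage_sets
#' @param seed Integer seed governing all randomness.
#' @return An `rlp_bundle`: lists of fitted stage-1/2/3 members, the class
#'   scheme, the resolved config and a manifest tibble of champion metrics.
#' @export
train_cascade <- function(corpus, config = list(), seed = 1) {
  config <- merge_config(config)
  sets <- build_stage_sets(corpus, config, seed = seed)
  s1 <- select_and_fit(sets$stage1, config, seed, config$select_folds)
  s2 <- select_and_fit(sets$stage2, config, seed, config$select_folds)
  s3 <- select_and_fit(sets$stage3, config, seed, config$select_folds)
  structure(
    list(stage1 = s1$members, stage2 = s2$members, stage3 = s3$members,
         scheme = sets$scheme, config = config, seed = seed,
         manifest = dplyr::bind_rows(s1$manifest, s2$manifest, s3$manifest)),
    class = "rlp_bundle"
  )
}

#' @export
print.rlp_bundle <- function(x, ...) {
  cat("<rlp_bundle>", length(x$stage1), "stage-1,", length(x$stage2),
      "stage-2,", length(x$stage3), "stage-3 members;",
      length(x$scheme$labels), "classes\n")
  invisible(x)
}

#' @export
glance.rlp_bundle <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$manifest, .data$stage),
    n_members = dplyr::n(), mean_mcc = mean(.data$MCC),
    mean_acc = mean(.data$ACC), .groups = "drop"
  )
}

#' @export
tidy.rlp_bundle <- function(x, ...) x$manifest

#' Cross-validate every algorithm on every cascade training set
#'
#' The evaluation companion to [train_cascade()]: runs `cv_folds`-fold
#' cross-validation (10 by default) for each configured algorithm on each
#' training set and returns one metrics table per stage in the standard
#' report schema (`Data Set`, `Algorithm`, `ACC`, `F1`, `FDR`, `MCC`,
#' `Precision`, `Sensitivity`, `Specificity`).
#'
#' @inheritParams train_cascade
#' @return Named list of three tibbles: `stage1`, `stage2`, `stage3`.
#' @export
crossval_cascade <- function(corpus, config = list(), seed = 1) {
  config <- merge_config(config)
  sets <- build_stage_sets(corpus, config, seed = seed)
  run <- function(set_list) {
    purrr::map_dfr(set_list, function(ts) {
      purrr::map_dfr(set_roster(ts, config), function(alg) {
        rec <- tryCatch(
          cross_validate(ts, alg, n_folds = config$cv_folds, seed = seed,
                         use_smote = config$use_smote,
                         average = config$metrics_average),
          error = function(e) NULL
        )
        rec
      })
    }) |>
      dplyr::transmute(
        "Data Set" = .data$dataset_id, "Algorithm" = .data$algorithm,
        ACC = .data$ACC, F1 = .data$F1, FDR = .data$FDR, MCC = .data$MCC,
        Precision = .data$Precision, Sensitivity = .data$Sensitivity,
        Specificity = .data$Specificity
      )
  }
  list(stage1 = run(sets$stage1), stage2 = run(sets$stage2),
       stage3 = run(sets$stage3))
}

# Predict labels for all rows with each member once (column-bound by member
# order); returns a character matrix n_rows x n_members. `feats` must be a
# named list of numeric matrices.
member_label_matrix <- function(members, feats) {
  vapply(members, function(m) {
    predict(m, feats[[m$feature_type]])$label
  }, character(nrow(feats[[members[[1]]$feature_type]])))
}

#' Run the trained cascade on new sequences
#'
#' For each input sequence: resolve topology (external annotations win over
#' the hydropathy heuristics), compute all six encodings, collect the binary
#' stage-1 and stage-2 ensemble votes into Beta-Binomial posteriors, the
#' stage-3 subfamily votes into a Dirichlet-Multinomial posterior, and apply
#' the topology-gated decision rule. Sequences that cannot be featurized
#' (e.g. shorter than a tripeptide window) are reported as `NRLP` with a
#' warning. Output rows follow input order.
#'
#' @param records Sequence tibble ([read_fasta()]).
#' @param bundle Trained `rlp_bundle`.
#' @param annotations Optional external topology annotations
#'   ([read_annotations()]).
#' @param config Configuration overrides (cutoffs, priors, topology).
#' @return An `rlp_prediction` tibble: one row per input with topology
#'   flags, stage labels and posterior means, final `classification` and
#'   `decision_prob`.
#' @export
predict_cascade <- function(records, bundle, annotations = NULL,
                            config = list()) {
  config <- utils::modifyList(bundle$config, config)
  topo <- resolve_topology(records, annotations, config$topology)
  ok <- rep(TRUE, nrow(records))
  feats <- tryCatch(
    featurize_all(records, config$feature_types),
    error = function(e) NULL
  )
  if (is.null(feats)) {
    # at least one record fails; featurize records one by one
    ok <- vapply(seq_len(nrow(records)), function(i) {
      !inherits(tryCatch(featurize_all(records[i, ], config$feature_types),
                         error = function(e) e), "error")
    }, logical(1))
    if (any(!ok)) {
      warning("Featurization failed for ", sum(!ok),
              " record(s); reported as NRLP: ",
              paste(utils::head(records$id[!ok], 5), collapse = ", "))
    }
    feats <- featurize_all(records[ok, , drop = FALSE], config$feature_types)
  }
  feats <- purrr::map(feats, training_matrix)
  n_ok <- sum(ok)
  a0 <- config$bayes$alpha0
  b0 <- config$bayes$beta0
  d0 <- config$bayes$dirichlet_alpha0
  scheme <- bundle$scheme
  lab1 <- member_label_matrix(bundle$stage1, feats)
  lab2 <- member_label_matrix(bundle$stage2, feats)
  lab3 <- member_label_matrix(bundle$stage3, feats)
  if (n_ok == 1) {
    lab1 <- matrix(lab1, nrow = 1)
    lab2 <- matrix(lab2, nrow = 1)
    lab3 <- matrix(lab3, nrow = 1)
  }
  rows <- vector("list", nrow(records))
  j <- 0
  for (i in seq_len(nrow(records))) {
    sp <- isTRUE(topo$sp[i])
    tm <- nrow(topo$tm[[i]]) > 0
    if (!ok[i]) {
      v <- as.numeric(c(sp, tm, 0, 0, 0))
      a <- config$decision_prior[1] + sum(config$decision_weights * v)
      b <- config$decision_prior[2] + sum(config$decision_weights * (1 - v))
      rows[[i]] <- tibble::tibble(
        accession = records$id[i], sp = sp, tm = tm,
        stage1_label = "NRLP", stage1_prob = a0 / (a0 + b0),
        stage2_label = "RLK-like", stage2_prob = a0 / (a0 + b0),
        subfamily_label = "Undefined",
        subfamily_prob = 1 / length(scheme$labels),
        classification = "NRLP", decision_prob = a / (a + b)
      )
      next
    }
    j <- j + 1
    post1 <- beta_binomial_posterior(as.integer(lab1[j, ] == "RLP"), a0, b0)
    post2 <- beta_binomial_posterior(as.integer(lab2[j, ] == "RLP"), a0, b0)
    counts <- table(factor(lab3[j, ], levels = scheme$labels))
    post3 <- dirichlet_multinomial_posterior(
      stats::setNames(as.integer(counts), scheme$labels), d0
    )
    dec <- decide(sp, tm, post1$mean, post2$mean, post3,
                  cutoffs = config$cutoffs,
                  weights = config$decision_weights,
                  prior = config$decision_prior)
    best <- which.max(post3$mean)
    rows[[i]] <- tibble::tibble(
      accession = records$id[i], sp = sp, tm = tm,
      stage1_label = if (post1$mean >= config$cutoffs$c1) "RLP" else "NRLP",
      stage1_prob = post1$mean,
      stage2_label = if (post2$mean >= config$cutoffs$c2) "RLP" else "RLK-like",
      stage2_prob = post2$mean,
      subfamily_label = if (dec$evidence$stage3) {
        names(post3$mean)[best]
      } else {
        "Undefined"
      },
      subfamily_prob = post3$mean[[best]],
      classification = dec$classification,
      decision_prob = dec$decision_probability
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rlp_prediction", class(out))
  out
}

#' Plot the decision-probability profile of a prediction set
#'
#' Dot plot of per-sequence decision probabilities colored by final
#' classification, the quickest visual check that receptors and
#' non-receptors separate.
#'
#' @param object An `rlp_prediction` from [predict_cascade()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rlp_prediction <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$rank <- rank(-df$decision_prob, ties.method = "first")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$decision_prob,
                                   color = .data$classification)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "sequence (ranked)", y = "decision probability",
                  color = "classification") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot cross-validation metrics per training set
#'
#' @param object One stage's metrics tibble from [crossval_cascade()].
#' @param metric Metric column to plot (default `"MCC"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_crossval_metrics <- function(object, metric = "MCC", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data[["Data Set"]],
                                       y = .data[[metric]],
                                       fill = .data$Algorithm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
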