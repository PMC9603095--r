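# End-to-end behavior of the trained cascade, using the session-cached fast
# bundle (two feature types; the decision machinery is identical).

test_that("training produces one champion per training set with metrics", {
  bundle <- fast_bundle()
  expect_length(bundle$stage1, 3 * 3)
  expect_length(bundle$stage2, 3)
  expect_length(bundle$stage3, 3 * 10)
  expect_equal(nrow(bundle$manifest), 9 + 3 + 30)
  expect_true(all(bundle$manifest$MCC >= -1 & bundle$manifest$MCC <= 1))
  expect_true(all(bundle$manifest$algorithm %in%
                    rlpcascade:::ALGORITHM_IDS))
  g <- glance(bundle)
  expect_setequal(g$stage, c("rlp_vs_nrlp", "rlp_vs_rlk", "subfamily"))
})

test_that("receptor-like inputs pass both binary stages with their topology", {
  bundle <- fast_bundle()
  corpus <- small_corpus()
  rlp_ids <- corpus$labels$id[corpus$labels$role == "rlp"]
  sub <- corpus$records[corpus$records$id %in% rlp_ids[seq(1, 160, 16)], ]
  expect_equal(nrow(sub), 10)
  # a 30-member subfamily ensemble cannot clear the 16-class posterior at
  # 0.7 even when unanimous; test the gate at a feasible cutoff
  pred <- predict_cascade(sub, bundle, annotations = corpus$annotations,
                          config = list(cutoffs = list(c3 = 0.6)))
  expect_equal(pred$accession, sub$id)   # input order preserved
  expect_true(all(pred$sp & pred$tm))
  expect_true(all(pred$stage1_prob >= 0.6))
  expect_gte(mean(pred$stage2_prob >= 0.6), 0.8)
  # when a named subfamily is assigned it is the true one
  named <- !pred$classification %in% c("Undefined", "NRLP")
  truth <- corpus$labels$subfamily[match(pred$accession, corpus$labels$id)]
  expect_true(all(pred$classification[named] == truth[named]))
  expect_gte(sum(named), 5)
})

test_that("TM absence forces the NRLP outcome regardless of the ensembles", {
  bundle <- fast_bundle()
  corpus <- small_corpus()
  rlp_ids <- corpus$labels$id[corpus$labels$role == "rlp"]
  rec <- corpus$records[corpus$records$id == rlp_ids[1], ]
  stripped <- corpus$annotations[corpus$annotations$id == rec$id, ]
  stripped$tm <- list(tibble::tibble(start = integer(), end = integer()))
  pred <- predict_cascade(rec, bundle, annotations = stripped)
  expect_false(pred$tm)
  expect_equal(pred$classification, "NRLP")
  # while the sequence still looks receptor-like to the ensembles
  expect_gte(pred$stage1_prob, 0.6)
})

test_that("uniform-random decoys are rejected at the first stage", {
  bundle <- fast_bundle()
  set.seed(71)
  dec <- random_decoys(20)
  pred <- predict_cascade(dec, bundle)
  expect_true(all(pred$classification == "NRLP"))
  expect_true(all(pred$stage1_prob < 0.6))
})

test_that("prediction is pure: repeated runs are identical", {
  bundle <- fast_bundle()
  set.seed(72)
  dec <- random_decoys(5)
  expect_equal(predict_cascade(dec, bundle), predict_cascade(dec, bundle))
})

test_that("unfeaturizable sequences get an NRLP row and a warning", {
  bundle <- fast_bundle()
  recs <- tibble::tibble(id = c("ok", "tiny"), description = "",
                         residues = c(random_protein(250), "M"))
  expect_warning(pred <- predict_cascade(recs, bundle), "tiny")
  expect_equal(pred$accession, c("ok", "tiny"))
  expect_equal(pred$classification[2], "NRLP")
})

test_that("the prediction report round-trips through the TSV writer", {
  bundle <- fast_bundle()
  set.seed(73)
  pred <- predict_cascade(random_decoys(3), bundle)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_prediction_report(pred, out)
  tab <- readr::read_tsv(out, show_col_types = FALSE)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$Classification, pred$classification)
})

test_that("separable profiles give high stage-1 MCC; permuted labels do not", {
  corpus <- small_corpus()
  sets <- suppressWarnings(build_stage_sets(
    corpus, config = list(feature_types = "Dipeptide"), seed = 7
  ))
  ts <- sets$stage1[[1]]
  rec <- cross_validate(ts, "knn", n_folds = 5, seed = 7)
  expect_gt(rec$MCC, 0.9)

  perm <- ts
  set.seed(74)
  perm$y <- sample(perm$y)
  rec_perm <- suppressWarnings(cross_validate(perm, "knn", n_folds = 5,
                                              seed = 7))
  expect_lt(abs(rec_perm$MCC), 0.15)
})

test_that("indistinguishable profiles collapse subfamily separability", {
  # same background for every class: composition carries no class signal
  scheme <- class_scheme()
  flat <- default_family_profiles(scheme, signal = 0)
  set.seed(75)
  recs <- purrr::map_dfr(scheme$labels[1:4], function(lb) {
    tibble::tibble(
      id = paste0(gsub("[^A-Za-z]", "", lb), "_", 1:8),
      description = "",
      residues = purrr::map_chr(1:8, ~ sample_sequence(flat[[lb]]))
    )
  })
  y <- rep(scheme$labels[1:4], each = 8)
  ts <- list(X = featurize(recs, "AAComposition"), y = y,
             feature_type = "AAComposition", dataset_id = "flat",
             stage = "subfamily")
  rec <- suppressWarnings(cross_validate(ts, "knn", n_folds = 4, seed = 75))
  expect_lt(abs(rec$MCC), 0.3)
})

test_that("crossval tables mirror the report schema", {
  corpus <- small_corpus()
  cv <- suppressWarnings(crossval_cascade(
    corpus,
    config = list(feature_types = "CPAASC", cv_folds = 3,
                  n_subsets = 2),
    seed = 7
  ))
  for (tab in cv) {
    expect_equal(names(tab),
                 c("Data Set", "Algorithm", "ACC", "F1", "FDR", "MCC",
                   "Precision", "Sensitivity", "Specificity"))
    expect_gt(nrow(tab), 0)
  }
})

test_that("autoplot and tidy methods run on prediction and bundle objects", {
  bundle <- fast_bundle()
  set.seed(76)
  pred <- predict_cascade(random_decoys(4), bundle)
  p <- autoplot(pred)
  expect_s3_class(p, "ggplot")
  expect_s3_class(tidy(bundle), "tbl_df")
  p2 <- plot_crossval_metrics(
    dplyr::rename(bundle$manifest[1:4, ],
                  "Data Set" = "dataset_id", Algorithm = "algorithm")
  )
  expect_s3_class(p2, "ggplot")
})
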