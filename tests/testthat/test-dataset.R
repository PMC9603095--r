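make_rlk_record <- function(id = "r1", len = 500, kin = c(300L, 460L)) {
  rec <- tibble::tibble(id = id, description = id,
                        residues = random_protein(len))
  ann <- rlpcascade:::new_annotation(
    id, sp = TRUE, sp_cleavage = 20L,
    tm = tibble::tibble(start = 250L, end = 271L),
    kinase_start = kin[1], kinase_end = kin[2], source = "external"
  )
  list(record = rec, annotation = ann)
}

test_that("stage-1 positives are truncated just before the kinase domain", {
  set.seed(41)
  x <- make_rlk_record()
  pos <- extract_stage1_positive(x$record, x$annotation)
  expect_equal(nchar(pos$residues), 299)
  expect_equal(pos$residues, substring(x$record$residues, 1, 299))

  x <- make_rlk_record(kin = c(1L, 200L))
  expect_error(extract_stage1_positive(x$record, x$annotation), "position 1")

  x <- make_rlk_record()
  x$annotation$sp <- FALSE
  expect_error(extract_stage1_positive(x$record, x$annotation), "filter")

  x <- make_rlk_record()
  x$annotation$kinase_start <- NA_integer_
  expect_error(extract_stage1_positive(x$record, x$annotation), "kinase")
})

test_that("redundancy filter collapses near-identical sequences", {
  set.seed(42)
  base <- random_protein(80)
  other <- random_protein(80, alphabet = c("G", "P"))  # unrelated
  dup2 <- tibble::tibble(id = c("a", "b"), description = "",
                         residues = c(base, base))
  expect_equal(nrow(redundancy_filter(dup2)), 1)

  diff2 <- tibble::tibble(id = c("a", "b"), description = "",
                          residues = c(strrep("AC", 30), strrep("KR", 30)))
  expect_equal(nrow(redundancy_filter(diff2)), 2)

  many <- tibble::tibble(id = paste0("s", 1:11), description = "",
                         residues = c(rep(base, 10), other))
  kept <- redundancy_filter(many)
  expect_equal(nrow(kept), 2)
  expect_true("s11" %in% kept$id)

  # idempotent
  expect_equal(redundancy_filter(kept), kept)
})

test_that("stage-1 set construction yields n_splits x feature types disjoint sets", {
  corpus <- small_corpus()
  sets <- suppressWarnings(build_stage_sets(corpus, seed = 5))
  expect_length(sets$stage1, 18)
  expect_length(sets$stage2, 6)
  expect_length(sets$stage3, 60)

  # same positives, disjoint negatives across the three splits
  neg_ids <- purrr::map(sets$stage1[c(1, 7, 13)], function(ts) {
    ts$provenance[ts$y == "NRLP"]
  })
  expect_length(intersect(neg_ids[[1]], neg_ids[[2]]), 0)
  expect_length(intersect(neg_ids[[1]], neg_ids[[3]]), 0)

  # reproducible by seed
  sets2 <- suppressWarnings(build_stage_sets(corpus, seed = 5))
  expect_equal(sets$stage1[[1]]$provenance, sets2$stage1[[1]]$provenance)

  # positive/negative overlap is rejected
  pos <- corpus$records[1:3, ]
  expect_error(build_stage1_sets(pos, pos, feature_types = "CPAASC"),
               "share id")
})

test_that("stage-2 sets label truncated constructs against full receptors", {
  corpus <- small_corpus()
  inputs <- rlpcascade:::stage_inputs(corpus, rlpcascade:::merge_config(list()))
  sets <- build_stage2_set(inputs$positives, inputs$rlk_full,
                           feature_types = c("CPAASC", "AAComposition"))
  expect_length(sets, 2)
  expect_setequal(unique(sets[[1]]$y), c("RLP", "RLK"))
  expect_error(build_stage2_set(inputs$positives[0, ], inputs$rlk_full),
               "No positive")
})

test_that("stage-3 down-sampling caps over-represented classes only", {
  corpus <- small_corpus()
  inputs <- rlpcascade:::stage_inputs(corpus, rlpcascade:::merge_config(list()))
  pos <- inputs$positives_subfam
  sets <- build_stage3_sets(pos, corpus$scheme, n_subsets = 2,
                            per_class_cap = 6, feature_types = "CPAASC",
                            seed = 9)
  expect_length(sets, 2)
  for (ts in sets) {
    counts <- table(ts$y)
    expect_true(all(counts <= 6))
  }
  # below-cap classes pass through intact
  sets_all <- build_stage3_sets(pos, corpus$scheme, n_subsets = 1,
                                per_class_cap = 500,
                                feature_types = "CPAASC", seed = 9)
  expect_equal(nrow(sets_all[[1]]$X), nrow(pos))

  bad <- dplyr::mutate(pos, subfamily = "Not-A-Class")
  expect_error(build_stage3_sets(bad, corpus$scheme,
                                 feature_types = "CPAASC"),
               "scheme")
})

test_that("default class scheme has 15 named subfamilies plus the grouped label", {
  scheme <- class_scheme()
  expect_length(scheme$labels, 16)
  expect_equal(scheme$other_label, "Other-RLP")
  expect_true("LRR-RLP" %in% scheme$labels)
  expect_true("GDPDL-RLP" %in% scheme$labels)
})

test_that("data-driven scheme groups small subfamilies into Other-RLP", {
  counts <- c(A = 100, B = 50, C = 19, D = 5)
  scheme <- class_scheme(counts, n_named = 15, min_members = 20)
  expect_setequal(scheme$labels, c("A", "B", "Other-RLP"))
  expect_equal(unname(scheme$mapping[c("C", "D")]),
               rep("Other-RLP", 2))
})

test_that("SMOTE balances classes without touching original rows", {
  set.seed(43)
  X <- matrix(rnorm(110 * 4), ncol = 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("A", "B"), times = c(100, 10))
  out <- smote(X, y, k = 5, seed = 2)
  expect_equal(as.integer(table(out$y)), c(100L, 100L))
  expect_equal(out$X[1:110, ], X)

  # synthetic rows stay inside the minority bounding box
  synth <- out$X[111:200, ]
  mins <- apply(X[101:110, ], 2, min)
  maxs <- apply(X[101:110, ], 2, max)
  expect_true(all(t(synth) >= mins - 1e-12))
  expect_true(all(t(synth) <= maxs + 1e-12))

  # degenerate: identical minority points beget identical synthetics
  X2 <- rbind(matrix(rnorm(40), ncol = 4),
              matrix(1, nrow = 3, ncol = 4))
  y2 <- rep(c("A", "B"), times = c(10, 3))
  out2 <- smote(X2, y2, seed = 3)
  expect_true(all(out2$X[out2$y == "B", ] == 1))

  expect_error(smote(X2[1:11, ], rep(c("A", "B"), times = c(10, 1))),
               "single member")
  expect_error(smote(X, rep("A", 110)), "two classes")
})

test_that("SMOTE is reproducible by seed", {
  set.seed(44)
  X <- matrix(rnorm(60 * 3), ncol = 3)
  y <- rep(c("A", "B"), times = c(45, 15))
  expect_equal(smote(X, y, seed = 10), smote(X, y, seed = 10))
})

test_that("fold assignment stratifies within a member of parity", {
  y <- rep(c("A", "B"), each = 50)
  folds <- assign_folds(y, n_folds = 10, seed = 1)
  expect_equal(as.integer(table(folds)), rep(10L, 10))
  per_class <- table(folds, y)
  expect_true(all(per_class == 5))

  expect_equal(assign_folds(y, 10, seed = 1), assign_folds(y, 10, seed = 1))

  # unbalanced classes: fold sizes differ by at most one per class
  y2 <- rep(c("A", "B"), times = c(61, 39))
  f2 <- assign_folds(y2, n_folds = 10, seed = 2)
  tab <- table(f2, y2)
  expect_lte(diff(range(tab[, "A"])), 1)
  expect_lte(diff(range(tab[, "B"])), 1)

  expect_warning(assign_folds(rep(c("A", "B"), times = c(50, 4)), 10),
                 "reducing")
})
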