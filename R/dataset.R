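#' Extract the stage-1 positive construct from an annotated kinase receptor
#'
#' A stage-1 positive is the receptor sequence truncated just before its
#' kinase domain: ectodomain + transmembrane segment + juxtamembrane region,
#' without the kinase domain. The record must pass the single-pass topology
#' filter ([passes_rlk_dataset_filter()]) and carry a kinase annotation.
#'
#' @param record One sequence row (tibble with `id`, `residues`).
#' @param annotation The matching annotation row.
#' @return A one-row sequence tibble with the truncated residues.
#' @export
extract_stage1_positive <- function(record, annotation) {
  if (is.na(annotation$kinase_start[1])) {
    stop("Record '", record$id[1], "' has no kinase-domain annotation",
         call. = FALSE)
  }
  if (!passes_rlk_dataset_filter(annotation)) {
    stop("Record '", record$id[1],
         "' fails the SP + single-TM training filter", call. = FALSE)
  }
  ks <- annotation$kinase_start[1]
  if (ks <= 1) {
    stop("Kinase domain of '", record$id[1],
         "' starts at position 1; truncation would be empty", call. = FALSE)
  }
  tibble::tibble(
    id = record$id[1],
    description = record$description[1] %||% record$id[1],
    residues = substring(record$residues[1], 1, ks - 1)
  )
}

# Global pairwise identity: matches / alignment columns under
# match = 1, mismatch = 0, gap open -10, gap extend -1.
pair_identity <- function(a, b) {
  sub <- matrix(0, 21, 21, dimnames = list(c(AA_ALPHABET, "X"),
                                           c(AA_ALPHABET, "X")))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = sub, gapOpening = 10, gapExtension = 1,
    type = "global"
  )
  matches <- Biostrings::nmatch(aln)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  matches / cols
}

#' Remove redundant sequences by greedy identity clustering
#'
#' Iterates records by decreasing length (ties broken by id) and retains a
#' record only if its global-alignment identity to every previously retained
#' record is at most `threshold`. This reproduces the effect of CD-HIT-style
#' redundancy removal with exact alignments instead of word filters; it is
#' idempotent and deterministic.
#'
#' @param records Sequence tibble.
#' @param threshold Maximum allowed pairwise identity (default 0.85).
#' @return The retained subset of `records`, in the original row order.
#' @export
redundancy_filter <- function(records, threshold = 0.85) {
  if (nrow(records) <= 1) return(records)
  ord <- order(-nchar(records$residues), records$id)
  kept <- integer()
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (pair_identity(records$residues[i], records$residues[j]) > threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  records[sort(kept), ]
}

new_training_set <- function(stage, dataset_id, feature_type, X, y, provenance) {
  stopifnot(nrow(X) == length(y))
  structure(
    list(stage = stage, dataset_id = dataset_id, feature_type = feature_type,
         X = X, y = y, provenance = provenance),
    class = "rlp_training_set"
  )
}

#' @export
print.rlp_training_set <- function(x, ...) {
  cat("<rlp_training_set> stage:", x$stage, " id:", x$dataset_id,
      " feature:", x$feature_type, "\n  ", nrow(x$X), "rows,",
      ncol(x$X) - 1, "features; classes:",
      paste(names(table(x$y)), table(x$y), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Featurize once per feature type and slice per set; records must have ids.
featurized_lookup <- function(records, feature_types, groups) {
  featurize_all(records, feature_types, groups)
}

slice_features <- function(feat_tbl, ids) {
  feat_tbl[match(ids, feat_tbl$id), , drop = FALSE]
}

#' Build the stage-1 (RLP vs NRLP) training sets
#'
#' Pairs the same positive examples with `n_splits` disjoint random subsets
#' of the negative pool (to cover more negatives without inflating any one
#' set), then featurizes each split with every requested encoding:
#' `n_splits * length(feature_types)` training sets (18 at the defaults).
#'
#' @param positives Sequence tibble of positive examples (kinase-truncated
#'   receptor constructs).
#' @param negative_pool Sequence tibble of negatives, disjoint from the
#'   positives by id.
#' @param n_splits Number of disjoint negative subsets.
#' @param feature_types Encodings to compute.
#' @param seed Integer seed controlling the negative split.
#' @param groups Property-group table.
#' @return List of `rlp_training_set` objects.
#' @export
build_stage1_sets <- function(positives, negative_pool, n_splits = 3,
                              feature_types = FEATURE_TYPES, seed = 1,
                              groups = default_property_groups()) {
  overlap <- intersect(positives$id, negative_pool$id)
  if (length(overlap)) {
    stop("Positive and negative pools share id(s): ",
         paste(utils::head(overlap, 3), collapse = ", "), call. = FALSE)
  }
  n_pos <- nrow(positives)
  per_split <- min(n_pos, floor(nrow(negative_pool) / n_splits))
  if (per_split < n_pos) {
    warning("Negative pool supports only ", per_split,
            " negatives per split (", n_pos, " positives); proceeding.")
  }
  set.seed(seed)
  shuffled <- sample(nrow(negative_pool))
  splits <- purrr::map(seq_len(n_splits), function(s) {
    idx <- shuffled[((s - 1) * per_split + 1):(s * per_split)]
    negative_pool[idx, ]
  })
  all_records <- dplyr::bind_rows(positives, negative_pool)
  feats <- featurized_lookup(all_records, feature_types, groups)
  out <- list()
  for (s in seq_len(n_splits)) {
    ids <- c(positives$id, splits[[s]]$id)
    y <- c(rep("RLP", nrow(positives)), rep("NRLP", nrow(splits[[s]])))
    for (ft in feature_types) {
      out[[length(out) + 1]] <- new_training_set(
        stage = "rlp_vs_nrlp",
        dataset_id = paste0(ft, "_", s),
        feature_type = ft,
        X = slice_features(feats[[ft]], ids),
        y = y,
        provenance = ids
      )
    }
  }
  out
}

#' Build the stage-2 (RLP vs RLK) training sets
#'
#' The positive class is the kinase-truncated receptor constructs; the
#' negative class is the corresponding full-length kinase receptors. One
#' training set per feature type (6 at the defaults). Because the two classes
#' can share source accessions, ids are namespaced `ecto:`/`full:`.
#'
#' @param positives_ecto Truncated-construct sequence tibble.
#' @param rlk_full Full-length receptor sequence tibble.
#' @inheritParams build_stage1_sets
#' @return List of `rlp_training_set` objects.
#' @export
build_stage2_set <- function(positives_ecto, rlk_full,
                             feature_types = FEATURE_TYPES,
                             groups = default_property_groups()) {
  if (nrow(positives_ecto) == 0) stop("No positive examples", call. = FALSE)
  if (nrow(rlk_full) == 0) stop("No RLK negatives", call. = FALSE)
  pos <- dplyr::mutate(positives_ecto, id = paste0("ecto:", .data$id))
  neg <- dplyr::mutate(rlk_full, id = paste0("full:", .data$id))
  all_records <- dplyr::bind_rows(pos, neg)
  feats <- featurized_lookup(all_records, feature_types, groups)
  y <- c(rep("RLP", nrow(pos)), rep("RLK", nrow(neg)))
  purrr::map(feature_types, function(ft) {
    new_training_set(
      stage = "rlp_vs_rlk", dataset_id = ft, feature_type = ft,
      X = slice_features(feats[[ft]], all_records$id),
      y = y, provenance = all_records$id
    )
  })
}

#' Build the stage-3 (subfamily) training sets
#'
#' Produces `n_subsets` datasets in which every over-represented class
#' (more than `per_class_cap` members) is independently down-sampled to
#' `per_class_cap` sequences; smaller classes pass through intact. Each
#' subset is featurized with every encoding: `n_subsets *
#' length(feature_types)` sets (60 at the defaults).
#'
#' @param positives Sequence tibble with a `subfamily` column.
#' @param scheme Class scheme from [class_scheme()]; labels outside it error.
#' @param n_subsets Number of down-sampled datasets.
#' @param per_class_cap Down-sampling cap per class.
#' @inheritParams build_stage1_sets
#' @return List of `rlp_training_set` objects.
#' @export
build_stage3_sets <- function(positives, scheme, n_subsets = 10,
                              per_class_cap = 500,
                              feature_types = FEATURE_TYPES, seed = 1,
                              groups = default_property_groups()) {
  stopifnot("subfamily" %in% names(positives))
  unknown <- setdiff(unique(positives$subfamily), scheme$labels)
  if (length(unknown)) {
    stop("Subfamily label(s) outside the class scheme: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  feats <- featurized_lookup(positives, feature_types, groups)
  out <- list()
  set.seed(seed)
  for (s in seq_len(n_subsets)) {
    keep_idx <- unlist(purrr::map(split(seq_len(nrow(positives)),
                                        positives$subfamily), function(idx) {
      if (length(idx) > per_class_cap) sample(idx, per_class_cap) else idx
    }), use.names = FALSE)
    keep_idx <- sort(keep_idx)
    ids <- positives$id[keep_idx]
    y <- positives$subfamily[keep_idx]
    for (ft in feature_types) {
      out[[length(out) + 1]] <- new_training_set(
        stage = "subfamily", dataset_id = paste0(ft, "_", s),
        feature_type = ft,
        X = slice_features(feats[[ft]], ids), y = y, provenance = ids
      )
    }
  }
  out
}

#' Class scheme for subfamily labels
#'
#' Builds the label alphabet for stage 3. Given per-subfamily counts, the
#' `n_named` largest subfamilies become named classes and every subfamily
#' with fewer than `min_members` sequences is mapped to the grouped label
#' `"Other-RLP"`. With no arguments, returns the default scheme: the 15
#' primary receptor subfamily labels plus `"Other-RLP"`.
#'
#' @param counts Optional named integer vector of subfamily sizes.
#' @param n_named Number of named classes retained.
#' @param min_members Minimum size for a subfamily to keep its own label.
#' @return A list with elements `labels` (character), `other_label`, and
#'   `mapping` (named character vector input-label -> scheme label).
#' @export
class_scheme <- function(counts = NULL, n_named = 15, min_members = 20) {
  other <- "Other-RLP"
  if (is.null(counts)) {
    labels <- c(DEFAULT_SUBFAMILIES, other)
    mapping <- stats::setNames(DEFAULT_SUBFAMILIES, DEFAULT_SUBFAMILIES)
    return(list(labels = labels, other_label = other, mapping = mapping))
  }
  counts <- sort(counts, decreasing = TRUE)
  named <- names(counts)[seq_len(min(n_named, length(counts)))]
  named <- named[counts[named] >= min_members]
  mapping <- stats::setNames(
    ifelse(names(counts) %in% named, names(counts), other),
    names(counts)
  )
  list(labels = c(named, other), other_label = other, mapping = mapping)
}

# The 15 primary subfamily labels of the default scheme.
DEFAULT_SUBFAMILIES <- c(
  "L-Lectin-RLP", "LRR-RLP", "S-domain-RLP", "Malectin-RLP",
  "Salt-stress-response/antifungal-RLP", "WAK-RLP", "B-Lectin-RLP",
  "Unknown-RLP", "PAN-RLP", "Ethylene-responsive-RLP", "Thaumatin-RLP",
  "RCC1-RLP", "Glycosyl-hydrolases-RLP", "C-Lectin-RLP", "GDPDL-RLP"
)

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances every class up to the majority-class count by interpolating
#' synthetic rows between minority examples and their k nearest minority
#' neighbors (Euclidean distance): each synthetic row is
#' `x + u * (x_nn - x)` with `u` uniform on `[0, 1)`. Original rows are
#' never modified. `k` is reduced to `minority size - 1` when necessary.
#'
#' @param X Numeric feature matrix or tibble (an `id` column, if present, is
#'   carried along; synthetic rows get ids `smote_<class>_<i>`).
#' @param y Class label vector, length `nrow(X)`.
#' @param k Number of nearest neighbors to interpolate toward.
#' @param seed Integer seed.
#' @return List with balanced `X` (same type as input) and `y`.
#' @export
smote <- function(X, y, k = 5, seed = 1) {
  has_id <- is.data.frame(X) && "id" %in% names(X)
  ids <- if (has_id) X$id else NULL
  mat <- as.matrix(if (has_id) X[setdiff(names(X), "id")] else X)
  stopifnot(nrow(mat) == length(y))
  tab <- table(y)
  if (length(tab) < 2) stop("SMOTE needs at least two classes", call. = FALSE)
  target <- max(tab)
  set.seed(seed)
  new_rows <- list()
  new_y <- character()
  new_ids <- character()
  for (cl in names(tab)) {
    deficit <- target - tab[[cl]]
    if (deficit == 0) next
    idx <- which(y == cl)
    if (length(idx) < 2) {
      stop("Class '", cl, "' has a single member; SMOTE needs a neighbor",
           call. = FALSE)
    }
    kk <- min(k, length(idx) - 1)
    sub <- mat[idx, , drop = FALSE]
    sq <- rowSums(sub^2)
    d <- outer(sq, sq, "+") - 2 * tcrossprod(sub)  # squared Euclidean
    diag(d) <- Inf
    nn <- apply(d, 1, function(r) order(r)[seq_len(kk)], simplify = FALSE)
    base_pick <- sample(length(idx), deficit, replace = TRUE)
    for (i in seq_len(deficit)) {
      b <- base_pick[i]
      nb <- nn[[b]][sample(kk, 1)]
      u <- stats::runif(1)
      new_rows[[length(new_rows) + 1]] <- sub[b, ] + u * (sub[nb, ] - sub[b, ])
      new_y <- c(new_y, cl)
      new_ids <- c(new_ids, paste0("smote_", cl, "_", i))
    }
  }
  if (length(new_rows)) {
    add <- do.call(rbind, new_rows)
    colnames(add) <- colnames(mat)
    mat_out <- rbind(mat, add)
    y_out <- c(as.character(y), new_y)
    ids_out <- c(ids, new_ids)
  } else {
    mat_out <- mat
    y_out <- as.character(y)
    ids_out <- ids
  }
  if (has_id) {
    X_out <- dplyr::bind_cols(tibble::tibble(id = ids_out),
                              tibble::as_tibble(mat_out))
  } else if (is.data.frame(X)) {
    X_out <- tibble::as_tibble(mat_out)
  } else {
    X_out <- mat_out
  }
  list(X = X_out, y = y_out)
}

#' Assign stratified cross-validation folds
#'
#' Shuffles within each class and deals members round-robin across folds, so
#' per-fold class counts differ by at most one from perfect stratification.
#' When some class has fewer members than `n_folds`, the fold count is
#' reduced with a warning.
#'
#' @param y Class label vector.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer fold labels in `1..n_folds`, same length as `y`.
#' @export
assign_folds <- function(y, n_folds = 10, seed = 1) {
  min_class <- min(table(y))
  if (min_class < n_folds) {
    warning("Smallest class has ", min_class, " members; reducing folds to ",
            max(2, min_class))
    n_folds <- max(2, min_class)
  }
  set.seed(seed)
  folds <- integer(length(y))
  offset <- 0
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- ((seq_along(idx) - 1 + offset) %% n_folds) + 1
    offset <- offset + length(idx)  # stagger so fold sizes stay even overall
  }
  folds
}
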