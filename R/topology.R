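# Kyte-Doolittle hydropathy scale (J Mol Biol 1982, 157:105-132).
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Per-position hydropathy; X scores 0 (neutral, never drives a call).
hydropathy_profile <- function(residues) {
  vals <- KYTE_DOOLITTLE[strsplit(residues, "")[[1]]]
  vals[is.na(vals)] <- 0
  unname(vals)
}

# Sliding-window mean of the hydropathy profile, one value per window start.
window_means <- function(h, window) {
  cs <- cumsum(c(0, h))
  (cs[(window + 1):length(cs)] - cs[1:(length(cs) - window)]) / window
}

#' Predict transmembrane segments by sliding-window hydropathy
#'
#' A deterministic stand-in for dedicated transmembrane topology predictors:
#' positions covered by a sliding window (width `window`) whose mean
#' Kyte-Doolittle hydropathy exceeds `threshold` are marked, maximal marked
#' runs closer than `merge_gap` residues are merged, and runs shorter than
#' `min_len` residues are dropped.
#'
#' @param residues Protein sequence string.
#' @param window Sliding window width in residues.
#' @param threshold Mean-hydropathy cutoff for a window to count.
#' @param min_len Minimum length (residues) of a reported segment.
#' @param merge_gap Runs separated by fewer than this many residues merge.
#' @return Tibble with columns `start`, `end` (1-based inclusive);
#'   zero rows when the sequence is shorter than `window` or uniformly
#'   hydrophilic.
#' @export
predict_tm_heuristic <- function(residues, window = 19, threshold = 1.6,
                                 min_len = 15, merge_gap = 5) {
  n <- nchar(residues)
  if (n < window) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  wm <- window_means(hydropathy_profile(residues), window)
  covered <- rep(FALSE, n)
  hit <- which(wm > threshold)
  for (i in hit) covered[i:(i + window - 1)] <- TRUE
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  seg <- tibble::tibble(start = starts[runs$values], end = ends[runs$values])
  if (nrow(seg) == 0) return(seg)
  # merge runs separated by a gap < merge_gap
  merged <- seg[1, ]
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      gap <- seg$start[i] - merged$end[nrow(merged)] - 1
      if (gap < merge_gap) {
        merged$end[nrow(merged)] <- seg$end[i]
      } else {
        merged <- dplyr::bind_rows(merged, seg[i, ])
      }
    }
  }
  merged[merged$end - merged$start + 1 >= min_len, ]
}

#' Predict signal-peptide presence from the N-terminal hydrophobic core
#'
#' A deterministic stand-in for dedicated signal-peptide predictors. A signal
#' peptide is called when the first 30 residues contain a hydrophobic
#' h-region: at least `h_len` contiguous residues whose Kyte-Doolittle mean
#' exceeds `threshold`, ending before position 35 (so the region is not the
#' first transmembrane segment itself). The reported cleavage position is the
#' first small residue (A, G or S) after the h-region, when one exists.
#'
#' @param residues Protein sequence string.
#' @param threshold Mean-hydropathy cutoff for the h-region.
#' @param h_len Minimum h-region length (residues).
#' @return A list with elements `sp` (logical) and `cleavage` (integer
#'   position or `NA`).
#' @export
predict_sp_heuristic <- function(residues, threshold = 1.6, h_len = 8) {
  n <- nchar(residues)
  if (n < h_len) return(list(sp = FALSE, cleavage = NA_integer_))
  h <- hydropathy_profile(residues)
  wm <- window_means(h, h_len)
  # candidate h-region starts within residues 1..30, region must end < 35
  starts <- which(wm > threshold)
  starts <- starts[starts <= 30 & (starts + h_len - 1) < 35]
  if (length(starts) == 0) return(list(sp = FALSE, cleavage = NA_integer_))
  # h-region = first qualifying window; cleavage = first small residue after
  e <- starts[1] + h_len - 1
  tail_res <- strsplit(substring(residues, e + 1, n), "")[[1]]
  pos <- which(tail_res %in% c("A", "G", "S"))
  cleavage <- if (length(pos)) as.integer(e + pos[1]) else NA_integer_
  list(sp = TRUE, cleavage = cleavage)
}

new_annotation <- function(id, sp, sp_cleavage, tm, kinase_start = NA_integer_,
                           kinase_end = NA_integer_, source = "heuristic") {
  tibble::tibble(
    id = id, sp = sp, sp_cleavage = sp_cleavage, tm = list(tm),
    kinase_start = kinase_start, kinase_end = kinase_end, source = source
  )
}

#' Resolve sequence topology from external annotations or heuristics
#'
#' For each record, the externally supplied annotation wins when present
#' (absence of segments in an external annotation is information, not a
#' trigger for the heuristics); otherwise the built-in hydropathy heuristics
#' are applied. The `source` column records which path produced each row.
#'
#' @param records Sequence tibble from [read_fasta()].
#' @param external Optional annotation tibble from [read_annotations()].
#' @param config Optional list of heuristic settings: `window`, `threshold`,
#'   `min_tm_len`, `merge_gap`.
#' @return One annotation row per record, in record order.
#' @export
resolve_topology <- function(records, external = NULL, config = list()) {
  window <- config$window %||% 19
  threshold <- config$threshold %||% 1.6
  min_tm_len <- config$min_tm_len %||% 15
  merge_gap <- config$merge_gap %||% 5
  rows <- purrr::map2(records$id, records$residues, function(id, res) {
    if (!is.null(external) && id %in% external$id) {
      row <- external[match(id, external$id), ]
      row$source <- "external"
      return(row)
    }
    tm <- predict_tm_heuristic(res, window = window, threshold = threshold,
                               min_len = min_tm_len, merge_gap = merge_gap)
    sp <- predict_sp_heuristic(res, threshold = threshold)
    new_annotation(id, sp$sp, sp$cleavage, tm)
  })
  dplyr::bind_rows(rows)
}

#' Topology filter for training positives
#'
#' A sequence enters the positive training pool only when it carries a signal
#' peptide and exactly one transmembrane segment (the single-pass receptor
#' architecture the cascade models).
#'
#' @param annotation One annotation row (tibble).
#' @return `TRUE` or `FALSE`.
#' @export
passes_rlk_dataset_filter <- function(annotation) {
  isTRUE(annotation$sp[1]) && nrow(annotation$tm[[1]]) == 1
}
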