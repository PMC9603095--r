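#' Default side-chain chemical property groups
#'
#' Nine named residue groups used by the side-chain property encodings
#' ([cpaasc()], [cpaasc_nc()]): charge, polarity, aromaticity, aliphatic
#' character, hydrophobicity, volume, mass and conformationally special
#' residues. Groups may overlap, so a property vector need not sum to one.
#' The table is an argument everywhere it is used, so an alternative grouping
#' can be substituted without touching code.
#'
#' @return A named list of character vectors (9 groups).
#' @export
default_property_groups <- function() {
  list(
    positively_charged = c("R", "K", "H"),
    negatively_charged = c("D", "E"),
    polar_uncharged    = c("S", "T", "N", "Q"),
    aromatic           = c("F", "W", "Y"),
    nonpolar_aliphatic = c("G", "A", "V", "L", "I", "M", "P"),
    hydrophobic        = c("A", "C", "F", "I", "L", "M", "V", "W"),
    large_volume       = c("F", "I", "K", "L", "M", "R", "W", "Y"),
    large_mass         = c("F", "H", "K", "R", "W", "Y"),
    special            = c("C", "G", "P")
  )
}

FEATURE_TYPES <- c("AAComposition", "AAComposition_N_C", "Dipeptide",
                   "Tripeptide", "CPAASC", "CPAASC_N_C")

FEATURE_DIMS <- c(AAComposition = 20L, AAComposition_N_C = 40L,
                  Dipeptide = 400L, Tripeptide = 8000L,
                  CPAASC = 9L, CPAASC_N_C = 18L)

canonical_chars <- function(residues) {
  ch <- strsplit(residues, "")[[1]]
  ch[ch != "X"]
}

#' Amino acid composition (20 features)
#'
#' Frequency of each canonical residue in alphabetical order
#' `ACDEFGHIKLMNPQRSTVWY`. `X` residues are excluded from both the numerator
#' and the denominator.
#'
#' @param residues Protein sequence string with at least one canonical residue.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_composition <- function(residues) {
  ch <- canonical_chars(residues)
  if (length(ch) == 0) {
    stop("Sequence has no canonical residues", call. = FALSE)
  }
  counts <- table(factor(ch, levels = AA_ALPHABET))
  stats::setNames(as.numeric(counts) / length(ch), AA_ALPHABET)
}

#' Split a sequence into N- and C-terminal halves
#'
#' The N-terminal half takes residues `1..ceiling(L/2)` (the extra residue at
#' odd length), the C-terminal half the remainder.
#'
#' @param residues Protein sequence string of length >= 2.
#' @return List with elements `n` and `c`.
#' @export
split_nc <- function(residues) {
  n <- nchar(residues)
  if (n < 2) stop("Sequence too short to split (length < 2)", call. = FALSE)
  cut <- ceiling(n / 2)
  list(n = substring(residues, 1, cut), c = substring(residues, cut + 1, n))
}

#' N/C-terminal amino acid composition (40 features)
#'
#' Concatenation of [aa_composition()] computed on the two halves from
#' [split_nc()]; names are prefixed `N_` / `C_`.
#'
#' @inheritParams split_nc
#' @return Named numeric vector of length 40.
#' @export
aa_composition_nc <- function(residues) {
  h <- split_nc(residues)
  out <- c(aa_composition(h$n), aa_composition(h$c))
  names(out) <- c(paste0("N_", AA_ALPHABET), paste0("C_", AA_ALPHABET))
  out
}

kmer_levels <- function(k) {
  grids <- rev(rep(list(AA_ALPHABET), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

# Lexicographic k-mer name vectors, cached after first use.
.kmer_cache <- new.env(parent = emptyenv())

get_kmer_levels <- function(k) {
  key <- as.character(k)
  if (is.null(.kmer_cache[[key]])) {
    .kmer_cache[[key]] <- sort(kmer_levels(k))
  }
  .kmer_cache[[key]]
}

#' Overlapping k-mer composition (400 or 8000 features)
#'
#' Counts all overlapping k-mers (stride 1) over the canonical alphabet in
#' lexicographic order and normalizes by the number of valid windows. Windows
#' containing `X` are skipped and do not count toward the denominator.
#'
#' @param residues Protein sequence string.
#' @param k K-mer size, 2 (dipeptide) or 3 (tripeptide).
#' @return Named numeric vector of length `20^k` summing to 1.
#' @export
kmer_composition <- function(residues, k) {
  stopifnot(k %in% c(1L, 2L, 3L))  # k = 1 reduces to aa_composition
  n <- nchar(residues)
  lv <- get_kmer_levels(k)
  if (n < k) stop("Sequence shorter than k = ", k, call. = FALSE)
  kmers <- substring(residues, 1:(n - k + 1), k:n)
  kmers <- kmers[!grepl("X", kmers, fixed = TRUE)]
  if (length(kmers) == 0) {
    stop("No valid ", k, "-mer windows (all contain X)", call. = FALSE)
  }
  counts <- tabulate(match(kmers, lv), nbins = length(lv))
  stats::setNames(counts / length(kmers), lv)
}

#' Side-chain property-group composition (9 features)
#'
#' For each property group, the fraction of canonical residues belonging to
#' the group. Groups may overlap so the vector need not sum to 1; every value
#' lies in `[0, 1]`.
#'
#' @param residues Protein sequence string with at least one canonical residue.
#' @param groups Property-group table (named list of residue sets); defaults
#'   to [default_property_groups()].
#' @return Named numeric vector of length 9.
#' @export
cpaasc <- function(residues, groups = default_property_groups()) {
  ch <- canonical_chars(residues)
  if (length(ch) == 0) {
    stop("Sequence has no canonical residues", call. = FALSE)
  }
  vapply(groups, function(g) sum(ch %in% g) / length(ch), numeric(1))
}

#' N/C-terminal side-chain property composition (18 features)
#'
#' Concatenation of [cpaasc()] over the two halves from [split_nc()]; names
#' prefixed `N_` / `C_`.
#'
#' @inheritParams cpaasc
#' @return Named numeric vector of length 18.
#' @export
cpaasc_nc <- function(residues, groups = default_property_groups()) {
  h <- split_nc(residues)
  out <- c(cpaasc(h$n, groups), cpaasc(h$c, groups))
  names(out) <- c(paste0("N_", names(groups)), paste0("C_", names(groups)))
  out
}

feature_fun <- function(feature_type, groups) {
  switch(
    feature_type,
    AAComposition = aa_composition,
    AAComposition_N_C = aa_composition_nc,
    Dipeptide = function(r) kmer_composition(r, 2L),
    Tripeptide = function(r) kmer_composition(r, 3L),
    CPAASC = function(r) cpaasc(r, groups),
    CPAASC_N_C = function(r) cpaasc_nc(r, groups),
    stop("Unknown feature type: ", feature_type, call. = FALSE)
  )
}

feature_colnames <- function(feature_type, groups = default_property_groups()) {
  switch(
    feature_type,
    AAComposition = paste0("AA:", AA_ALPHABET),
    AAComposition_N_C = c(paste0("N_AA:", AA_ALPHABET), paste0("C_AA:", AA_ALPHABET)),
    Dipeptide = paste0("DI:", get_kmer_levels(2L)),
    Tripeptide = paste0("TRI:", get_kmer_levels(3L)),
    CPAASC = paste0("CP:", names(groups)),
    CPAASC_N_C = c(paste0("N_CP:", names(groups)), paste0("C_CP:", names(groups))),
    stop("Unknown feature type: ", feature_type, call. = FALSE)
  )
}

#' Featurize a set of sequence records
#'
#' Computes one of the six fixed-dimension frequency encodings for every
#' record, preserving row order. Column order is fixed per feature type.
#'
#' @param records Sequence tibble from [read_fasta()].
#' @param feature_type One of `"AAComposition"`, `"AAComposition_N_C"`,
#'   `"Dipeptide"`, `"Tripeptide"`, `"CPAASC"`, `"CPAASC_N_C"`.
#' @param groups Property-group table for the CPAASC encodings.
#' @return A tibble with an `id` column followed by the feature columns
#'   (dimension 20/40/400/8000/9/18 respectively).
#' @export
featurize <- function(records, feature_type,
                      groups = default_property_groups()) {
  feature_type <- match.arg(feature_type, FEATURE_TYPES)
  fn <- feature_fun(feature_type, groups)
  cols <- feature_colnames(feature_type, groups)
  if (nrow(records) == 0) {
    empty <- tibble::as_tibble(
      stats::setNames(rep(list(numeric()), length(cols)), cols)
    )
    return(dplyr::bind_cols(tibble::tibble(id = character()), empty))
  }
  mat <- matrix(0, nrow = nrow(records), ncol = length(cols),
                dimnames = list(NULL, cols))
  for (i in seq_len(nrow(records))) {
    v <- tryCatch(fn(records$residues[i]), error = function(e) {
      stop("Featurization (", feature_type, ") failed for record '",
           records$id[i], "': ", conditionMessage(e), call. = FALSE)
    })
    mat[i, ] <- v
  }
  dplyr::bind_cols(tibble::tibble(id = records$id), tibble::as_tibble(mat))
}

#' Featurize records with every encoding at once
#'
#' Convenience wrapper returning a named list of feature tables, one per
#' feature type, as consumed by the prediction cascade.
#'
#' @inheritParams featurize
#' @param feature_types Subset of the six encodings to compute.
#' @return Named list of feature tibbles.
#' @export
featurize_all <- function(records, feature_types = FEATURE_TYPES,
                          groups = default_property_groups()) {
  stats::setNames(
    purrr::map(feature_types, ~ featurize(records, .x, groups)),
    feature_types
  )
}
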