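#' @keywords internal
"_PACKAGE"

# Canonical amino-acid alphabet, alphabetical; X is tolerated on input but
# never contributes to any frequency denominator.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Read protein sequences from a FASTA file
#'
#' Parses a protein FASTA file into a tibble of sequence records. The record
#' id is the first whitespace-delimited token of the header; the full header
#' is kept as the description. Residues are uppercased and wrapped lines are
#' concatenated. The 20 canonical amino acids plus `X` (unknown residue) are
#' accepted; any other letter is an error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `residues`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 demo", "ACDE", "FGHI"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("Cannot parse FASTA file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(set) == 0) {
    stop("FASTA file is empty: ", path, call. = FALSE)
  }
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("Duplicate FASTA id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  residues <- toupper(as.character(set))
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "X]"), residues)
  if (any(bad)) {
    offender <- ids[which(bad)[1]]
    ch <- stringr::str_extract(
      residues[which(bad)[1]],
      paste0("[^", paste(AA_ALPHABET, collapse = ""), "X]")
    )
    stop("Illegal residue character '", ch, "' in record '", offender, "'",
         call. = FALSE)
  }
  if (any(!nzchar(residues))) {
    stop("Empty sequence in record '", ids[which(!nzchar(residues))[1]], "'",
         call. = FALSE)
  }
  tibble::tibble(id = unname(ids), description = unname(headers),
                 residues = unname(residues))
}

#' Write sequence records to a FASTA file
#'
#' Inverse of [read_fasta()]: round-tripping a record tibble through
#' `write_fasta()` and `read_fasta()` is the identity (modulo line wrapping).
#'
#' @param records Tibble with columns `id`, `residues` and optionally
#'   `description` (used as the header when present).
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(all(c("id", "residues") %in% names(records)))
  headers <- if ("description" %in% names(records) &&
                 !all(is.na(records$description))) {
    ifelse(is.na(records$description) | !nzchar(records$description),
           records$id, records$description)
  } else {
    records$id
  }
  lines <- unlist(purrr::map2(headers, records$residues, function(h, s) {
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", h), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

# Parse "start-end" into c(start, end); "" -> NULL. 1-based inclusive.
parse_interval <- function(txt, what, id) {
  txt <- trimws(txt)
  if (is.na(txt) || !nzchar(txt)) return(NULL)
  m <- regmatches(txt, regexec("^([0-9]+)-([0-9]+)$", txt))[[1]]
  if (length(m) != 3) {
    stop("Malformed ", what, " interval '", txt, "' for id '", id, "'",
         call. = FALSE)
  }
  iv <- as.integer(m[2:3])
  if (iv[2] < iv[1]) {
    stop(what, " interval end < start (", txt, ") for id '", id, "'",
         call. = FALSE)
  }
  iv
}

#' Read per-sequence topology annotations from TSV
#'
#' Ingests externally produced topology calls (e.g. reconciled output of
#' signal-peptide and transmembrane predictors) re-expressed as a TSV with
#' columns `id`, `sp` (Y/N), `tm_segments` (semicolon-separated `start-end`
#' pairs, may be empty), `kinase_domain` (`start-end` or empty). All
#' coordinates are 1-based inclusive residue indices.
#'
#' @param path Path to the annotation TSV (with header).
#' @return A tibble with columns `id`, `sp` (logical), `sp_cleavage`
#'   (integer, `NA` when unknown), `tm` (list column of tibbles with
#'   `start`, `end`), `kinase_start`, `kinase_end` (integer, `NA` when
#'   absent) and `source = "external"`.
#' @export
read_annotations <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- c("id", "sp", "tm_segments", "kinase_domain")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("Annotation TSV lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rows <- purrr::pmap(df[need], function(id, sp, tm_segments, kinase_domain) {
    sp_flag <- !is.na(sp) && toupper(trimws(sp)) == "Y"
    tm_txt <- if (is.na(tm_segments)) "" else tm_segments
    segs <- Filter(nzchar, trimws(strsplit(tm_txt, ";", fixed = TRUE)[[1]]))
    tm <- purrr::map(segs, parse_interval, what = "tm", id = id)
    tm_tbl <- if (length(tm)) {
      tibble::tibble(start = vapply(tm, `[`, integer(1), 1L),
                     end = vapply(tm, `[`, integer(1), 2L))
    } else {
      tibble::tibble(start = integer(), end = integer())
    }
    tm_tbl <- dplyr::arrange(tm_tbl, .data$start)
    kin <- parse_interval(kinase_domain, "kinase", id)
    tibble::tibble(
      id = id, sp = sp_flag, sp_cleavage = NA_integer_,
      tm = list(tm_tbl),
      kinase_start = if (is.null(kin)) NA_integer_ else kin[1],
      kinase_end = if (is.null(kin)) NA_integer_ else kin[2],
      source = "external"
    )
  })
  dplyr::bind_rows(rows)
}

#' Write per-sequence topology annotations to TSV
#'
#' Inverse of [read_annotations()]; used by the synthetic generator to emit
#' ground-truth topology alongside FASTA.
#'
#' @param annotations Annotation tibble as returned by [read_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  tm_txt <- vapply(annotations$tm, function(tbl) {
    if (nrow(tbl) == 0) "" else paste(paste0(tbl$start, "-", tbl$end), collapse = ";")
  }, character(1))
  kin_txt <- ifelse(is.na(annotations$kinase_start), "",
                    paste0(annotations$kinase_start, "-", annotations$kinase_end))
  out <- tibble::tibble(
    id = annotations$id,
    sp = ifelse(annotations$sp, "Y", "N"),
    tm_segments = tm_txt,
    kinase_domain = kin_txt
  )
  readr::write_tsv(out, path)
  invisible(path)
}

# Column order of the prediction report; fixed contract.
REPORT_COLUMNS <- c(
  "Accession", "SP", "TM",
  "RLP-NRLP", "RLP-NRLP Probability",
  "RLP-RLK", "RLP-RLK Probability",
  "RLP-Subfamily", "RLP-Subfamily Probability",
  "Classification", "Decision Probability"
)

#' Write a prediction report to TSV
#'
#' Emits one row per classified sequence with the stage labels, stage
#' posterior means, the final classification and the decision probability.
#' Probabilities are printed with 4 decimals.
#'
#' @param rows Prediction tibble as returned by [predict_cascade()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction_report <- function(rows, path) {
  out <- tibble::tibble(
    "Accession" = rows$accession,
    "SP" = ifelse(rows$sp, "Y", "N"),
    "TM" = ifelse(rows$tm, "Y", "N"),
    "RLP-NRLP" = rows$stage1_label,
    "RLP-NRLP Probability" = sprintf("%.4f", rows$stage1_prob),
    "RLP-RLK" = rows$stage2_label,
    "RLP-RLK Probability" = sprintf("%.4f", rows$stage2_prob),
    "RLP-Subfamily" = rows$subfamily_label,
    "RLP-Subfamily Probability" = sprintf("%.4f", rows$subfamily_prob),
    "Classification" = rows$classification,
    "Decision Probability" = sprintf("%.4f", rows$decision_prob)
  )
  stopifnot(identical(names(out), REPORT_COLUMNS))
  readr::write_tsv(out, path)
  invisible(path)
}
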