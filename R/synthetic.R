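# Residue pools used by the architectural blocks.
HYDROPHOBIC_CORE <- c("L", "I", "V", "F")
POLAR_POOL <- c("K", "R", "S", "T", "E", "D", "N", "Q", "G", "H", "P", "Y")

# Signature residues for the 16 default classes: the 16 canonical residues
# that are not strongly hydrophobic (so an ectodomain never mimics a
# transmembrane segment), one per class.
SIGNATURE_RESIDUES <- c("A", "C", "D", "E", "G", "H", "K", "M",
                        "N", "P", "Q", "R", "S", "T", "W", "Y")

#' Construct a family composition profile
#'
#' A family profile is the generative model for one subfamily's ectodomain:
#' a residue distribution over the 20 canonical amino acids, an optional
#' short consensus motif implanted with a per-position substitution rate,
#' and a length range.
#'
#' @param name Profile (subfamily) name.
#' @param distribution Named 20-vector of residue probabilities summing to 1.
#' @param motif Optional consensus string; `NULL` for none.
#' @param motif_sub_rate Per-position probability a motif residue is replaced
#'   by a random one.
#' @param length_range Integer `c(min, max)` sequence length.
#' @return A `family_profile` list.
#' @export
family_profile <- function(name, distribution, motif = NULL,
                           motif_sub_rate = 0.1, length_range = c(150, 400)) {
  stopifnot(length(distribution) == 20,
            abs(sum(distribution) - 1) < 1e-9,
            length_range[1] <= length_range[2])
  if (is.null(names(distribution))) names(distribution) <- AA_ALPHABET
  structure(
    list(name = name, distribution = distribution, motif = motif,
         motif_sub_rate = motif_sub_rate, length_range = length_range),
    class = "family_profile"
  )
}

#' Default family profiles for a class scheme
#'
#' One profile per subfamily label, each with a disjoint signature residue at
#' elevated frequency (`signal`) over a uniform background, plus a short
#' class-specific motif. Disjoint signatures make the subfamilies separable
#' by composition, mirroring the premise that receptor ectodomains carry the
#' subfamily signal; `signal = 0` collapses all profiles onto the background
#' (the inseparable control).
#'
#' @param scheme Class scheme from [class_scheme()].
#' @param signal Signature-residue frequency (0 for indistinguishable
#'   profiles).
#' @return Named list of `family_profile` objects.
#' @export
default_family_profiles <- function(scheme = class_scheme(), signal = 0.3) {
  labels <- scheme$labels
  sigs <- rep_len(SIGNATURE_RESIDUES, length(labels))
  stats::setNames(purrr::map(seq_along(labels), function(i) {
    sig <- sigs[i]
    p <- stats::setNames(rep((1 - signal) / 20, 20), AA_ALPHABET)
    p[sig] <- p[sig] + signal
    motif <- paste0(sig, sig, "G", sig, "P", sig)
    family_profile(labels[i], p, motif = motif)
  }), labels)
}

sample_from <- function(pool, n, prob = NULL) {
  paste(sample(pool, n, replace = TRUE, prob = prob), collapse = "")
}

#' Sample one ectodomain-like sequence from a family profile
#'
#' Length is uniform over the profile's range; residues are drawn i.i.d.
#' from the profile distribution; the motif (when present) is implanted at a
#' random position with per-position substitutions at the profile's rate.
#' Deterministic given the R random seed.
#'
#' @param profile A `family_profile`.
#' @return A residue string.
#' @export
sample_sequence <- function(profile) {
  len <- if (profile$length_range[1] == profile$length_range[2]) {
    profile$length_range[1]
  } else {
    sample(profile$length_range[1]:profile$length_range[2], 1)
  }
  seq_chars <- sample(names(profile$distribution), len, replace = TRUE,
                      prob = profile$distribution)
  if (!is.null(profile$motif) && nchar(profile$motif) <= len) {
    m <- strsplit(profile$motif, "")[[1]]
    sub <- stats::runif(length(m)) < profile$motif_sub_rate
    m[sub] <- sample(AA_ALPHABET, sum(sub), replace = TRUE)
    pos <- sample(len - length(m) + 1, 1)
    seq_chars[pos:(pos + length(m) - 1)] <- m
  }
  paste(seq_chars, collapse = "")
}

# Fixed 250-residue kinase-like consensus block: anchors canonical kinase
# motifs (glycine-rich loop, VAIK, HRD, DFG, APE) in a deterministic filler.
kinase_consensus <- function() {
  if (!is.null(.kmer_cache[["kinase"]])) return(.kmer_cache[["kinase"]])
  anchors <- c("GEGGFGKVY", "AVAIKRL", "HRDLKPEN", "DFGLARL", "APEYAMT")
  filler <- strsplit(paste0(
    "ELKDSTRSELGQVIEATNEFSDKYKIGSGGFGTVYKGELPNGTKVAVKRLSKSSGQGEREFLN",
    "EVVLLSQINHRNVVKLLGCCLETEVPLLVYEFIPNGTLFELLHGSSRGSPLSWDDRLRIAAEA"
  ), "")[[1]]
  body <- character(0)
  ai <- 1
  while (length(body) < 250) {
    body <- c(body, strsplit(anchors[((ai - 1) %% length(anchors)) + 1], "")[[1]],
              filler[seq_len(min(45, 250 - length(body)))])
    ai <- ai + 1
  }
  out <- paste(body[1:250], collapse = "")
  .kmer_cache[["kinase"]] <- out
  out
}

mutate_string <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  ch[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

# SP block: Met + positive n-region + strongly hydrophobic h-region + small
# cleavage-site residue. Returns string; cleavage index = nchar(block).
sp_block <- function() {
  h_len <- sample(10:16, 1)
  paste0("MK", sample_from(HYDROPHOBIC_CORE, h_len,
                           prob = c(0.6, 0.15, 0.15, 0.1)), "A")
}

tm_block <- function(len = 21) {
  sample_from(HYDROPHOBIC_CORE, len, prob = c(0.45, 0.25, 0.2, 0.1))
}

receptor_parts <- function(profile, with_kinase) {
  sp <- sp_block()
  ecto <- sample_sequence(profile)
  tm <- tm_block()
  tm_start <- nchar(sp) + nchar(ecto) + 1
  tm_end <- tm_start + nchar(tm) - 1
  if (with_kinase) {
    juxta <- sample_from(POLAR_POOL, sample(10:30, 1))
    kin <- mutate_string(kinase_consensus(), 0.1)
    residues <- paste0(sp, ecto, tm, juxta, kin)
    kin_start <- tm_end + nchar(juxta) + 1
    list(residues = residues, sp_cleavage = nchar(sp), tm = c(tm_start, tm_end),
         kinase = c(kin_start, kin_start + nchar(kin) - 1))
  } else {
    tail_cy <- sample_from(POLAR_POOL, sample(5:30, 1))
    residues <- paste0(sp, ecto, tm, tail_cy)
    list(residues = residues, sp_cleavage = nchar(sp), tm = c(tm_start, tm_end),
         kinase = NULL)
  }
}

#' Build one synthetic receptor-like kinase
#'
#' Concatenates signal peptide + profile-sampled ectodomain + one
#' transmembrane block + juxtamembrane linker + kinase-like block (fixed
#' 250-residue consensus with 10% substitutions), with the ground-truth
#' topology annotation.
#'
#' @param profile A `family_profile` for the ectodomain.
#' @param id Record id.
#' @return List with one-row `record` and `annotation` tibbles.
#' @export
build_rlk <- function(profile, id = profile$name) {
  p <- receptor_parts(profile, with_kinase = TRUE)
  record <- tibble::tibble(id = id, description = id, residues = p$residues)
  ann <- new_annotation(
    id, sp = TRUE, sp_cleavage = as.integer(p$sp_cleavage),
    tm = tibble::tibble(start = p$tm[1], end = p$tm[2]),
    kinase_start = as.integer(p$kinase[1]),
    kinase_end = as.integer(p$kinase[2]),
    source = "external"
  )
  list(record = record, annotation = ann)
}

#' Build one synthetic receptor-like protein
#'
#' Same architecture as [build_rlk()] minus the kinase block: signal peptide
#' + ectodomain + one transmembrane block + short cytoplasmic tail.
#'
#' @inheritParams build_rlk
#' @return List with one-row `record` and `annotation` tibbles.
#' @export
build_rlp <- function(profile, id = profile$name) {
  p <- receptor_parts(profile, with_kinase = FALSE)
  record <- tibble::tibble(id = id, description = id, residues = p$residues)
  ann <- new_annotation(
    id, sp = TRUE, sp_cleavage = as.integer(p$sp_cleavage),
    tm = tibble::tibble(start = p$tm[1], end = p$tm[2]),
    source = "external"
  )
  list(record = record, annotation = ann)
}

background_profile <- function(length_range = c(200, 600)) {
  family_profile("background", stats::setNames(rep(0.05, 20), AA_ALPHABET),
                 motif = NULL, length_range = length_range)
}

# Soluble/globular decoy (no SP, no TM), mildly polar composition.
globular_sequence <- function() {
  p <- rep(1, 20)
  names(p) <- AA_ALPHABET
  p[POLAR_POOL[POLAR_POOL %in% AA_ALPHABET]] <- 2
  p[HYDROPHOBIC_CORE] <- 0.4
  sample_sequence(family_profile("globular", p / sum(p),
                                 length_range = c(150, 500)))
}

polytopic_sequence <- function(n_tm = 3) {
  loops <- purrr::map_chr(seq_len(n_tm + 1),
                          ~ sample_from(POLAR_POOL, sample(25:60, 1)))
  tms <- purrr::map_chr(seq_len(n_tm), ~ tm_block())
  paste0(paste0(loops[seq_len(n_tm)], tms, collapse = ""), loops[n_tm + 1])
}

#' Generate uniform-random decoy sequences
#'
#' Residues drawn i.i.d. uniformly over the 20-letter alphabet; lengths
#' uniform over `length_range`. These emulate the random-sequence negative
#' control used to show the cascade does not classify noise as receptors.
#'
#' @param n Number of sequences.
#' @param length_range Integer `c(min, max)` length bounds.
#' @param prefix Id prefix.
#' @return Sequence tibble.
#' @export
random_decoys <- function(n, length_range = c(200, 600), prefix = "decoy") {
  tibble::tibble(
    id = paste0(prefix, "_", seq_len(n)),
    description = paste0(prefix, "_", seq_len(n)),
    residues = purrr::map_chr(seq_len(n), ~ sample_from(
      AA_ALPHABET, sample(length_range[1]:length_range[2], 1)))
  )
}

#' Generate a labeled synthetic benchmark corpus
#'
#' For every subfamily in the scheme, generates `n_per_class` kinase
#' receptors (RLK) and `n_per_class` kinase-less receptors (RLP) from the
#' subfamily's profile, plus four non-receptor groups: globular (no SP/TM),
#' secreted (SP only), polytopic (3 TM segments) and uniform-random decoys,
#' each of size `n_nrlp_per_group`. A pure function of its parameters and
#' `seed`.
#'
#' @param n_per_class Receptors per subfamily per architecture (>= 10).
#' @param scheme Class scheme ([class_scheme()]).
#' @param seed Integer seed.
#' @param profiles Family profiles (default [default_family_profiles()]).
#' @param n_nrlp_per_group Size of each non-receptor group; default sized so
#'   the pool supports three receptor-sized negative splits.
#' @return An `rlp_corpus`: list with `records` (sequence tibble),
#'   `annotations` (ground-truth topology) and `labels` (tibble `id`,
#'   `role`, `subfamily`).
#' @export
build_benchmark <- function(n_per_class = 20, scheme = class_scheme(),
                            seed = 1,
                            profiles = default_family_profiles(scheme),
                            n_nrlp_per_group = NULL) {
  stopifnot(n_per_class >= 10)
  if (is.null(n_nrlp_per_group)) {
    n_nrlp_per_group <- ceiling(3 * n_per_class * length(scheme$labels) / 4)
  }
  set.seed(seed)
  records <- list()
  annotations <- list()
  labels <- list()
  push <- function(record, annotation, role, subfamily) {
    records[[length(records) + 1]] <<- record
    annotations[[length(annotations) + 1]] <<- annotation
    labels[[length(labels) + 1]] <<- tibble::tibble(
      id = record$id, role = role, subfamily = subfamily
    )
  }
  safe_id <- function(label) gsub("[^A-Za-z0-9]+", "_", label)
  for (label in scheme$labels) {
    prof <- profiles[[label]]
    for (i in seq_len(n_per_class)) {
      r <- build_rlk(prof, id = paste0(safe_id(label), "_rlk_", i))
      push(r$record, r$annotation, "rlk", label)
      r <- build_rlp(prof, id = paste0(safe_id(label), "_rlp_", i))
      push(r$record, r$annotation, "rlp", label)
    }
  }
  for (i in seq_len(n_nrlp_per_group)) {
    res <- globular_sequence()
    rec <- tibble::tibble(id = paste0("nrlp_globular_", i),
                          description = paste0("nrlp_globular_", i),
                          residues = res)
    push(rec, new_annotation(rec$id, FALSE, NA_integer_,
                             tibble::tibble(start = integer(), end = integer()),
                             source = "external"),
         "nrlp_globular", NA_character_)

    sp <- sp_block()
    res <- paste0(sp, globular_sequence())
    rec <- tibble::tibble(id = paste0("nrlp_secreted_", i),
                          description = paste0("nrlp_secreted_", i),
                          residues = res)
    push(rec, new_annotation(rec$id, TRUE, as.integer(nchar(sp)),
                             tibble::tibble(start = integer(), end = integer()),
                             source = "external"),
         "nrlp_secreted", NA_character_)

    res <- polytopic_sequence(3)
    rec <- tibble::tibble(id = paste0("nrlp_polytopic_", i),
                          description = paste0("nrlp_polytopic_", i),
                          residues = res)
    tm <- predict_tm_heuristic(res)
    push(rec, new_annotation(rec$id, FALSE, NA_integer_, tm,
                             source = "external"),
         "nrlp_polytopic", NA_character_)
  }
  dec <- random_decoys(n_nrlp_per_group)
  for (i in seq_len(nrow(dec))) {
    rec <- dec[i, ]
    push(rec, new_annotation(rec$id, FALSE, NA_integer_,
                             predict_tm_heuristic(rec$residues),
                             source = "external"),
         "decoy", NA_character_)
  }
  structure(
    list(records = dplyr::bind_rows(records),
         annotations = dplyr::bind_rows(annotations),
         labels = dplyr::bind_rows(labels),
         scheme = scheme, seed = seed, n_per_class = n_per_class),
    class = "rlp_corpus"
  )
}

#' @export
print.rlp_corpus <- function(x, ...) {
  cat("<rlp_corpus>", nrow(x$records), "sequences;",
      sum(x$labels$role == "rlk"), "RLK,", sum(x$labels$role == "rlp"),
      "RLP,", sum(!x$labels$role %in% c("rlk", "rlp")), "non-receptor\n")
  invisible(x)
}

#' Write a synthetic corpus to a directory
#'
#' Emits `sequences.fasta`, `annotations.tsv` and `labels.tsv`.
#'
#' @param corpus An `rlp_corpus`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(corpus$records, file.path(dir, "sequences.fasta"))
  write_annotations(corpus$annotations, file.path(dir, "annotations.tsv"))
  readr::write_tsv(corpus$labels, file.path(dir, "labels.tsv"))
  invisible(dir)
}

#' Read a corpus written by [write_corpus()]
#'
#' @param dir Directory containing `sequences.fasta`, `annotations.tsv`,
#'   `labels.tsv`.
#' @return An `rlp_corpus` (scheme rebuilt from the labels).
#' @export
read_corpus <- function(dir) {
  records <- read_fasta(file.path(dir, "sequences.fasta"))
  annotations <- read_annotations(file.path(dir, "annotations.tsv"))
  labels <- readr::read_tsv(file.path(dir, "labels.tsv"),
                            show_col_types = FALSE)
  subfams <- unique(stats::na.omit(labels$subfamily))
  scheme <- class_scheme()
  if (!all(subfams %in% scheme$labels)) {
    counts <- table(labels$subfamily)
    scheme <- class_scheme(stats::setNames(as.integer(counts), names(counts)),
                           min_members = 1)
  }
  structure(
    list(records = records, annotations = annotations, labels = labels,
         scheme = scheme),
    class = "rlp_corpus"
  )
}
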