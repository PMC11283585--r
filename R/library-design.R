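#' Default direct-repeat sequence for crRNA array cassettes
#'
#' The 19-nt Cas12a direct repeat used as the default separator between
#' spacers when building cassette reference sequences. Real analyses should
#' supply the direct repeat of the construct actually sequenced.
#'
#' @return A single DNA string.
#' @export
default_dr_sequence <- function() "AATTTCTACTCTTGTAGAT"

#' Default complementary-overlap sequence for cassette assembly
#'
#' A synthetic 15-nt placeholder for the complementary end that joins the two
#' half-cassettes during splicing-by-overlap-extension assembly. It is used by
#' the simulators and examples; real analyses should supply the construct's
#' own overlap sequence.
#'
#' @return A single DNA string.
#' @export
default_overlap_sequence <- function() "GTCACTGGATCCGCA"

is_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  is.character(x) & !is.na(x) & grepl(pat, x)
}

gc_fraction <- function(spacer) {
  chars <- strsplit(spacer, "", fixed = TRUE)[[1]]
  mean(chars %in% c("G", "C"))
}

#' Check a spacer against the library design rules
#'
#' A spacer is admissible when it is a 20-nt A/C/G/T sequence with GC content
#' between 30% and 70% (inclusive) and, for targeting spacers, sits downstream
#' of a 5'-TTTV protospacer-adjacent motif. Violations are reported as codes,
#' never as errors, so whole candidate tables can be screened.
#'
#' @param spacer A single DNA string (the 20-nt guide).
#' @param pam_context The 4-nt PAM context (`TTTV`, V = A/C/G), or `NA` for
#'   non-targeting controls, which have no genomic PAM.
#' @param gc_bounds Inclusive lower/upper bounds on spacer GC fraction.
#' @return A character vector of violation codes (possibly empty) drawn from
#'   `"invalid_characters"`, `"length_not_20"`, `"pam_mismatch"`,
#'   `"gc_out_of_range"`.
#' @examples
#' check_spacer_rules(strrep("AC", 10), "TTTA") # character(0)
#' check_spacer_rules(strrep("AT", 10), "TTTT") # gc + pam violations
#' @export
check_spacer_rules <- function(spacer, pam_context = NA_character_,
                               gc_bounds = c(0.30, 0.70)) {
  stopifnot(length(spacer) == 1L, length(pam_context) == 1L)
  out <- character(0)
  if (!is_dna(spacer)) {
    out <- c(out, "invalid_characters")
  }
  if (is.na(spacer) || nchar(spacer) != 20L) {
    out <- c(out, "length_not_20")
  }
  if (!is.na(pam_context) && !grepl("^TTT[ACG]$", pam_context)) {
    out <- c(out, "pam_mismatch")
  }
  if (is_dna(spacer)) {
    gc <- gc_fraction(spacer)
    if (gc < gc_bounds[1] || gc > gc_bounds[2]) {
      out <- c(out, "gc_out_of_range")
    }
  }
  out
}

validate_cassette_part <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L ||
      !grepl("^[ACGT]+$", x)) {
    abort(paste0("`", what, "` must be a non-empty A/C/G/T string."))
  }
  invisible(x)
}

validate_gene_entries <- function(entries, gene_set,
                                  arg = deparse(substitute(entries))) {
  if (!is.data.frame(entries) || nrow(entries) == 0L) {
    abort(paste0("`", arg, "` must be a data frame with at least one entry."))
  }
  need <- c("name", "spacer")
  missing_cols <- setdiff(need, names(entries))
  if (length(missing_cols)) {
    abort(paste0("`", arg, "` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  entries <- tibble::as_tibble(entries)
  if (!"pam_context" %in% names(entries)) {
    entries$pam_context <- NA_character_
  }
  if ("gene_set" %in% names(entries) && !all(entries$gene_set == gene_set)) {
    abort(paste0("`", arg, "` has `gene_set` values other than '",
                 gene_set, "'."))
  }
  entries$gene_set <- gene_set
  if (anyDuplicated(entries$name)) {
    abort(paste0("Duplicate gene names in `", arg, "`."))
  }
  bad <- !is_dna(entries$spacer) | nchar(entries$spacer) != 20L
  if (any(bad)) {
    abort(paste0("Spacers must be 20-nt A/C/G/T strings; offending entries: ",
                 paste(entries$name[bad], collapse = ", ")))
  }
  if (gene_set != "control") {
    bad_pam <- is.na(entries$pam_context) |
      !grepl("^TTT[ACG]$", entries$pam_context)
    if (any(bad_pam)) {
      abort(paste0("Targeting entries need a TTTV `pam_context`; offending: ",
                   paste(entries$name[bad_pam], collapse = ", ")))
    }
  } else {
    entries$pam_context <- NA_character_
  }
  entries[, c("name", "gene_set", "spacer", "pam_context")]
}

#' Build the reference sequence of one crRNA array cassette
#'
#' The cassette layout is DR - spacer1 - DR - overlap - DR - spacer2 - DR,
#' i.e. each spacer is flanked by direct repeats and the two half-cassettes
#' are joined through the complementary overlap used during assembly.
#'
#' @param spacer1,spacer2 The two spacer sequences.
#' @param dr_sequence Direct-repeat sequence.
#' @param overlap_sequence Complementary-end sequence.
#' @return The cassette reference DNA string (vectorized over spacers).
#' @export
build_reference_sequence <- function(spacer1, spacer2,
                                     dr_sequence = default_dr_sequence(),
                                     overlap_sequence = default_overlap_sequence()) {
  validate_cassette_part(dr_sequence, "dr_sequence")
  validate_cassette_part(overlap_sequence, "overlap_sequence")
  paste0(dr_sequence, spacer1, dr_sequence, overlap_sequence,
         dr_sequence, spacer2, dr_sequence)
}

array_signature <- function(spacer1, spacer2, dr_sequence, overlap_sequence) {
  paste0(spacer1, dr_sequence, overlap_sequence, dr_sequence, spacer2)
}

new_crrna_library <- function(arrays, dr_sequence, overlap_sequence) {
  structure(arrays,
            dr_sequence = dr_sequence,
            overlap_sequence = overlap_sequence,
            class = c("crrna_library", class(tibble::tibble())))
}

#' @export
print.crrna_library <- function(x, ...) {
  cat("# crRNA array library: ", nrow(x), " arrays (",
      sum(x$category == "DKO"), " DKO / ", sum(x$category == "SKO"),
      " SKO / ", sum(x$category == "NTC_NTC"), " NTC-NTC)\n", sep = "")
  cat("# DR: ", attr(x, "dr_sequence"),
      "  overlap: ", attr(x, "overlap_sequence"), "\n", sep = "")
  NextMethod()
}

#' Direct-repeat / overlap sequence of a library
#'
#' @param design A `crrna_library` from [enumerate_arrays()].
#' @return A single DNA string.
#' @export
dr_sequence <- function(design) {
  x <- attr(design, "dr_sequence")
  if (is.null(x)) abort("`design` carries no `dr_sequence` attribute; was it built by `enumerate_arrays()`?")
  x
}

#' @rdname dr_sequence
#' @export
overlap_sequence <- function(design) {
  x <- attr(design, "overlap_sequence")
  if (is.null(x)) abort("`design` carries no `overlap_sequence` attribute; was it built by `enumerate_arrays()`?")
  x
}

#' Enumerate a dual-crRNA double-knockout library
#'
#' Builds the full combinatorial array set from gene entry tables: every
#' kinase x metabolism pair becomes a double-knockout (DKO) array with the
#' kinase spacer in position 1; every targeting gene paired with every
#' non-targeting control spacer becomes a single-knockout (SKO) array
#' (targeting spacer in position 1); and every ordered control x control pair
#' becomes an NTC-NTC array. With 15 kinase, 12 metabolism and 5 control
#' entries this yields the canonical 340-array library
#' (180 DKO + 135 SKO + 25 NTC-NTC).
#'
#' Gene entry tables need columns `name` and `spacer` (20-nt A/C/G/T);
#' targeting tables additionally need a TTTV `pam_context`. Output rows are
#' sorted lexicographically by `array_id` (`"<gene1>__<gene2>"`), so
#' enumeration is deterministic.
#'
#' @param kinase,metabolism Data frames of targeting gene entries.
#' @param controls Data frame of non-targeting control entries.
#' @param dr_sequence,overlap_sequence Cassette construction sequences; the
#'   defaults are documented placeholders intended for simulation.
#' @return A `crrna_library`: a tibble with columns `array_id`, `gene1`,
#'   `gene2`, `set1`, `set2`, `category`, `spacer1`, `spacer2`, `reference`,
#'   `signature`, carrying the DR/overlap sequences as attributes.
#' @examples
#' kin <- tibble::tibble(name = "KinA", spacer = strrep("ACGT", 5),
#'                       pam_context = "TTTA")
#' met <- tibble::tibble(name = "MetA", spacer = strrep("CATG", 5),
#'                       pam_context = "TTTC")
#' ntc <- tibble::tibble(name = "NTC1", spacer = strrep("GTCA", 5))
#' enumerate_arrays(kin, met, ntc)
#' @export
enumerate_arrays <- function(kinase, metabolism, controls,
                             dr_sequence = default_dr_sequence(),
                             overlap_sequence = default_overlap_sequence()) {
  kinase <- validate_gene_entries(kinase, "kinase")
  metabolism <- validate_gene_entries(metabolism, "metabolism")
  controls <- validate_gene_entries(controls, "control")
  validate_cassette_part(dr_sequence, "dr_sequence")
  validate_cassette_part(overlap_sequence, "overlap_sequence")

  all_names <- c(kinase$name, metabolism$name, controls$name)
  if (anyDuplicated(all_names)) {
    abort(paste0("Gene names must be unique across kinase, metabolism and ",
                 "control entries; duplicated: ",
                 paste(unique(all_names[duplicated(all_names)]), collapse = ", ")))
  }

  pair_up <- function(pos1, pos2, category) {
    grid <- tidyr::expand_grid(i = seq_len(nrow(pos1)), j = seq_len(nrow(pos2)))
    tibble::tibble(
      gene1 = pos1$name[grid$i], gene2 = pos2$name[grid$j],
      set1 = pos1$gene_set[grid$i], set2 = pos2$gene_set[grid$j],
      spacer1 = pos1$spacer[grid$i], spacer2 = pos2$spacer[grid$j],
      category = category
    )
  }

  targeting <- dplyr::bind_rows(kinase, metabolism)
  arrays <- dplyr::bind_rows(
    pair_up(kinase, metabolism, "DKO"),
    pair_up(targeting, controls, "SKO"),
    pair_up(controls, controls, "NTC_NTC")
  )
  arrays$array_id <- paste0(arrays$gene1, "__", arrays$gene2)
  arrays$reference <- build_reference_sequence(
    arrays$spacer1, arrays$spacer2, dr_sequence, overlap_sequence)
  arrays$signature <- array_signature(
    arrays$spacer1, arrays$spacer2, dr_sequence, overlap_sequence)
  arrays <- dplyr::arrange(
    arrays[, c("array_id", "gene1", "gene2", "set1", "set2", "category",
               "spacer1", "spacer2", "reference", "signature")],
    .data$array_id)

  if (anyDuplicated(arrays$array_id)) {
    abort("Array ids are not unique; gene names must not collide.")
  }
  if (anyDuplicated(arrays$reference)) {
    abort("Array reference sequences are not distinct; check spacers.")
  }
  new_crrna_library(arrays, dr_sequence, overlap_sequence)
}

#' Write / read a library design as FASTA + TSV
#'
#' `write_library()` writes `<out_prefix>.fasta` (cassette reference
#' sequences, record id = array id) and `<out_prefix>.tsv` (array metadata,
#' including the DR and overlap sequences so the design round-trips).
#' `read_library()` reconstructs the `crrna_library` and verifies that the
#' metadata and FASTA agree.
#'
#' @param design A `crrna_library`.
#' @param out_prefix Output path prefix.
#' @return `write_library()` invisibly returns the two file paths;
#'   `read_library()` returns a `crrna_library`.
#' @export
write_library <- function(design, out_prefix) {
  stopifnot(inherits(design, "crrna_library"))
  if (anyDuplicated(design$array_id)) {
    abort("Refusing to write a design with duplicate array ids.")
  }
  fasta <- paste0(out_prefix, ".fasta")
  tsv <- paste0(out_prefix, ".tsv")
  seqs <- Biostrings::DNAStringSet(setNames(design$reference, design$array_id))
  Biostrings::writeXStringSet(seqs, fasta)
  meta <- tibble::as_tibble(design)[, c("array_id", "gene1", "gene2", "set1",
                                        "set2", "category", "spacer1",
                                        "spacer2")]
  meta$dr_sequence <- dr_sequence(design)
  meta$overlap_sequence <- overlap_sequence(design)
  utils::write.table(meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' @rdname write_library
#' @export
read_library <- function(out_prefix) {
  fasta <- paste0(out_prefix, ".fasta")
  tsv <- paste0(out_prefix, ".tsv")
  meta <- tibble::as_tibble(utils::read.table(
    tsv, sep = "\t", header = TRUE, stringsAsFactors = FALSE))
  dr <- unique(meta$dr_sequence)
  ov <- unique(meta$overlap_sequence)
  if (length(dr) != 1L || length(ov) != 1L) {
    abort("Library TSV must carry a single DR and overlap sequence.")
  }
  arrays <- meta[, c("array_id", "gene1", "gene2", "set1", "set2", "category",
                     "spacer1", "spacer2")]
  arrays$reference <- build_reference_sequence(arrays$spacer1, arrays$spacer2,
                                               dr, ov)
  arrays$signature <- array_signature(arrays$spacer1, arrays$spacer2, dr, ov)
  seqs <- Biostrings::readDNAStringSet(fasta)
  fasta_ref <- setNames(as.character(seqs), names(seqs))
  if (!identical(sort(names(fasta_ref)), sort(arrays$array_id)) ||
      !all(fasta_ref[arrays$array_id] == arrays$reference)) {
    abort("FASTA and TSV disagree; library files are inconsistent.")
  }
  arrays <- dplyr::arrange(arrays, .data$array_id)
  new_crrna_library(arrays, dr, ov)
}
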