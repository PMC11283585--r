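#' Merge paired-end reads by exact suffix/prefix overlap
#'
#' Reverse-complements read 2 and joins it to read 1 at the longest exact
#' overlap between the end of read 1 and the start of the reverse-complemented
#' read 2. Amplicon reads over a fixed cassette are expected to overlap
#' perfectly, so no mismatches are tolerated, and an overlap containing `N`
#' in either read is rejected (an `N` counts as a mismatch even against
#' another `N`). Pairs whose best exact overlap is shorter than `min_overlap`
#' (default 31, i.e. strictly more than 30 bp) are returned as `NA`.
#'
#' @param read1,read2 Character vectors of equal length (A/C/G/T/N).
#' @param min_overlap Minimum qualifying overlap length in bp.
#' @return A character vector of merged fragments, `NA` where no qualifying
#'   overlap exists. Merged length is `nchar(read1) + nchar(read2) - overlap`.
#' @examples
#' frag <- strrep("ACGT", 50) # 200 nt
#' r1 <- substr(frag, 1, 150)
#' r2 <- as.character(Biostrings::reverseComplement(
#'   Biostrings::DNAString(substr(frag, 51, 200))))
#' merge_read_pairs(r1, r2) == frag
#' @export
merge_read_pairs <- function(read1, read2, min_overlap = 31L) {
  if (length(read1) != length(read2)) {
    abort("`read1` and `read2` must have the same length.")
  }
  if (length(read1) == 0L) return(character(0))
  if (any(!is_dna(read1, allow_n = TRUE)) || any(!is_dna(read2, allow_n = TRUE))) {
    abort("Reads must be non-empty strings over A/C/G/T/N.")
  }
  rc2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(read2)))
  l1 <- nchar(read1)
  l2 <- nchar(rc2)
  maxov <- pmin(l1, l2)
  merged <- rep(NA_character_, length(read1))
  pending <- which(maxov >= min_overlap)
  if (length(pending)) {
    for (len in seq(max(maxov[pending]), min_overlap)) {
      cand <- pending[maxov[pending] >= len]
      if (!length(cand)) next
      suf <- substr(read1[cand], l1[cand] - len + 1L, l1[cand])
      pre <- substr(rc2[cand], 1L, len)
      ok <- suf == pre & !grepl("N", suf, fixed = TRUE)
      hit <- cand[ok]
      if (length(hit)) {
        merged[hit] <- paste0(read1[hit], substr(rc2[hit], len + 1L, l2[hit]))
        pending <- setdiff(pending, hit)
        if (!length(pending)) break
      }
    }
  }
  merged
}

#' @rdname merge_read_pairs
#' @export
merge_read_pair <- function(read1, read2, min_overlap = 31L) {
  stopifnot(length(read1) == 1L, length(read2) == 1L)
  merge_read_pairs(read1, read2, min_overlap)
}

#' Count crRNA arrays in merged reads
#'
#' Each merged read is searched for the array signatures of the library (the
#' full inter-spacer cassette `spacer1 + DR + overlap + DR + spacer2`, an
#' exact match; spacer pairs alone could collide across SKO/NTC arrays that
#' share spacers). A read increments exactly one array when exactly one
#' signature matches; reads matching none are retried as the reverse
#' complement, and reads still matching none, or matching two or more
#' signatures, are tallied separately.
#'
#' @param reads Character vector of merged reads (`NA`s, e.g. unmerged pairs,
#'   are counted as unassigned).
#' @param design A `crrna_library`.
#' @return A tibble with columns `array_id`, `count` covering every array
#'   (zeros included), with a `qc` attribute: a tibble of
#'   `n_reads`, `n_assigned`, `n_unassigned`, `n_ambiguous`.
#' @export
count_merged_reads <- function(reads, design) {
  stopifnot(inherits(design, "crrna_library"))
  sig <- design$signature
  if (anyDuplicated(sig)) abort("Library signatures are not unique.")
  keep <- !is.na(reads)
  n_na <- sum(!keep)
  reads <- reads[keep]
  counts <- integer(nrow(design))
  n_ambig <- 0L
  n_unassigned <- n_na
  if (length(reads)) {
    subj <- Biostrings::DNAStringSet(reads)
    widths <- unique(nchar(sig))
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(sig),
                            tb.start = 1L, tb.width = min(widths))
    hits <- Biostrings::vwhichPDict(pd, subj)
    nh <- lengths(hits)
    if (any(nh == 0L)) {
      rcs <- Biostrings::reverseComplement(subj[nh == 0L])
      hits[nh == 0L] <- Biostrings::vwhichPDict(pd, rcs)
      nh <- lengths(hits)
    }
    assigned <- unlist(hits[nh == 1L], use.names = FALSE)
    counts <- tabulate(assigned, nbins = nrow(design))
    n_ambig <- sum(nh > 1L)
    n_unassigned <- n_na + sum(nh == 0L)
  }
  out <- tibble::tibble(array_id = design$array_id, count = as.integer(counts))
  attr(out, "qc") <- tibble::tibble(
    n_reads = length(reads) + n_na,
    n_assigned = sum(counts),
    n_unassigned = n_unassigned,
    n_ambiguous = n_ambig
  )
  out
}

#' Count one sample from paired FASTQ files
#'
#' Reads the pair of FASTQ files, merges mates with [merge_read_pairs()] and
#' counts arrays with [count_merged_reads()].
#'
#' @param fastq1,fastq2 Paths to the mate FASTQ files.
#' @param design A `crrna_library`.
#' @param min_overlap Minimum merge overlap (bp).
#' @return As [count_merged_reads()]; the `qc` attribute additionally reports
#'   `n_pairs` and `n_merged`.
#' @export
count_fastq_sample <- function(fastq1, fastq2, design, min_overlap = 31L) {
  r1 <- as.character(Biostrings::readDNAStringSet(fastq1, format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(fastq2, format = "fastq"))
  if (length(r1) != length(r2)) {
    abort("FASTQ mates have different read counts.")
  }
  merged <- merge_read_pairs(unname(r1), unname(r2), min_overlap = min_overlap)
  out <- count_merged_reads(merged, design)
  qc <- attr(out, "qc")
  qc$n_pairs <- length(r1)
  qc$n_merged <- sum(!is.na(merged))
  attr(out, "qc") <- qc
  out
}

#' Convert raw array counts to reads per million
#'
#' Normalizes each sample's counts to reads per million (rpm):
#' `rpm_i = count_i / sum(count) * 1e6`, so every sample column sums to one
#' million and sequencing depth differences drop out.
#'
#' @param counts A tibble with columns `array_id`, `count` and (for
#'   multi-sample tables) `sample_id`.
#' @return The input tibble with an added `rpm` column.
#' @examples
#' to_rpm(tibble::tibble(array_id = c("a", "b", "c"), count = c(1, 1, 2)))
#' @export
to_rpm <- function(counts) {
  stopifnot(is.data.frame(counts), all(c("array_id", "count") %in% names(counts)))
  counts <- tibble::as_tibble(counts)
  if (any(counts$count < 0)) abort("Counts must be non-negative.")
  grp <- if ("sample_id" %in% names(counts)) "sample_id" else character(0)
  out <- counts %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::mutate(rpm = {
      tot <- sum(.data$count)
      if (tot <= 0) {
        abort("A sample has zero total counts; rpm is undefined.")
      }
      .data$count / tot * 1e6
    }) %>%
    dplyr::ungroup()
  out
}

#' Log2 fold-change of final versus initial abundance
#'
#' Computes, per array, the fold-change `FC = (rpm_final + pc) /
#' (rpm_initial + pc)` and its log2 (`LFC`) between a final and an initial
#' sample. A pseudocount (default 1 rpm) guards against division by zero for
#' dropped-out arrays; set `pseudocount_rpm = 0` for the exact ratio. When
#' several initial samples are given their mean rpm is used as the reference
#' (e.g. the mean of day-4 replicates).
#'
#' Pseudo-replication warning: LFCs of different final samples computed
#' against the *same* initial sample share that sample's measurement error
#' and are therefore correlated; tests that treat per-sample LFCs as
#' independent observations (e.g. [synergy_by_rank_test()]) should use
#' `paired = TRUE` so each final sample has its own reference.
#'
#' @param rpm A tibble with columns `array_id`, `sample_id`, `rpm`
#'   (from [to_rpm()]).
#' @param final Character vector of final sample ids (one LFC table per id).
#' @param initial Character vector of initial (reference) sample id(s).
#' @param pseudocount_rpm Pseudocount added to both numerator and denominator.
#' @param paired If `TRUE`, `initial` must have the same length as `final`
#'   and sample `final[i]` is referenced to `initial[i]`; if `FALSE`
#'   (default) all finals share one reference, the mean rpm of `initial`.
#' @return A tibble with columns `array_id`, `sample_id` (the final sample),
#'   `fc`, `lfc`.
#' @export
compute_lfc <- function(rpm, final, initial, pseudocount_rpm = 1,
                        paired = FALSE) {
  if (paired) {
    if (length(initial) != length(final)) {
      abort("With `paired = TRUE`, `initial` must match `final` in length.")
    }
    return(purrr::map2_dfr(final, initial, function(f, i) {
      compute_lfc(rpm, f, i, pseudocount_rpm = pseudocount_rpm)
    }))
  }
  stopifnot(is.data.frame(rpm),
            all(c("array_id", "sample_id", "rpm") %in% names(rpm)))
  missing_s <- setdiff(c(final, initial), unique(rpm$sample_id))
  if (length(missing_s)) {
    abort(paste0("Sample(s) not in `rpm`: ", paste(missing_s, collapse = ", ")))
  }
  wide_ok <- function(ids) {
    sub <- rpm[rpm$sample_id %in% ids, c("array_id", "sample_id", "rpm")]
    agg <- dplyr::summarise(dplyr::group_by(sub, .data$array_id),
                            rpm = mean(.data$rpm), n = dplyr::n(),
                            .groups = "drop")
    if (length(unique(agg$n)) != 1L || unique(agg$n) != length(ids)) {
      abort("Samples do not share a common array set.")
    }
    agg[, c("array_id", "rpm")]
  }
  ref <- wide_ok(initial)
  purrr::map_dfr(final, function(fs) {
    fin <- wide_ok(fs)
    merged <- dplyr::inner_join(fin, ref, by = "array_id",
                                suffix = c("_final", "_initial"))
    if (nrow(merged) != nrow(ref)) {
      abort("Final and initial samples do not share the same array set.")
    }
    fc <- (merged$rpm_final + pseudocount_rpm) /
      (merged$rpm_initial + pseudocount_rpm)
    tibble::tibble(array_id = merged$array_id, sample_id = fs,
                   fc = fc, lfc = log2(fc))
  })
}

#' Collapse single-knockout arrays to one value per targeting gene
#'
#' Each targeting gene is represented by several SKO arrays (one per control
#' spacer in position 2); this summarizes them to a single per-gene value per
#' sample with the chosen statistic.
#'
#' @param values A tibble with columns `array_id`, `sample_id` (optional) and
#'   the value column.
#' @param design A `crrna_library`.
#' @param statistic `"mean"` (default) or `"median"`.
#' @param value_col Name of the value column (e.g. `"rpm"` or `"lfc"`).
#' @return A tibble with columns `gene`, `sample_id` (if present) and `value`.
#' @export
collapse_sko_per_gene <- function(values, design, statistic = c("mean", "median"),
                                  value_col = "rpm") {
  statistic <- match.arg(statistic)
  stopifnot(is.data.frame(values), value_col %in% names(values),
            inherits(design, "crrna_library"))
  sko <- design[design$category == "SKO", c("array_id", "gene1")]
  genes <- unique(design$gene1[design$category == "DKO" |
                                 design$category == "SKO"])
  genes <- union(genes, design$gene2[design$category == "DKO"])
  no_sko <- setdiff(genes, sko$gene1)
  if (length(no_sko)) {
    abort(paste0("Targeting gene(s) without SKO arrays: ",
                 paste(no_sko, collapse = ", ")))
  }
  fun <- if (statistic == "mean") mean else stats::median
  grp <- intersect("sample_id", names(values))
  dplyr::inner_join(tibble::as_tibble(values), sko, by = "array_id") %>%
    dplyr::rename(gene = "gene1") %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c("gene", grp)))) %>%
    dplyr::summarise(value = fun(.data[[value_col]]), .groups = "drop")
}

#' Library coverage and skew of one count column
#'
#' Coverage is the fraction of arrays detected at or above
#' `detect_threshold` reads; skew is the ratio of the 90th to the 10th
#' percentile of counts (linear-interpolation percentiles). When the 10th
#' percentile is zero the skew is undefined and returned as `NA` with
#' `skew_defined = FALSE`.
#'
#' @param counts A tibble with columns `array_id`, `count` and optionally
#'   `sample_id` (one result row per sample).
#' @param detect_threshold Minimum count for an array to count as covered.
#' @return A tibble with columns `sample_id` (if present), `coverage`,
#'   `skew`, `skew_defined`.
#' @export
coverage_and_skew <- function(counts, detect_threshold = 1L) {
  stopifnot(is.data.frame(counts), "count" %in% names(counts))
  grp <- intersect("sample_id", names(counts))
  tibble::as_tibble(counts) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::summarise(
      coverage = mean(.data$count >= detect_threshold),
      p10 = quantile(.data$count, 0.10, names = FALSE),
      p90 = quantile(.data$count, 0.90, names = FALSE),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      skew_defined = .data$p10 > 0,
      skew = ifelse(.data$skew_defined, .data$p90 / .data$p10, NA_real_)
    ) %>%
    dplyr::select(dplyr::all_of(grp), "coverage", "skew", "skew_defined")
}
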