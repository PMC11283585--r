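#' Simulate a dual-crRNA double-knockout screen
#'
#' Generates count data with the structure the interaction callers assume:
#' a plasmid library with log-normal abundance skew, cell replicates before
#' (day 4) and after (day 14) one round of in-culture selection, and tumours
#' seeded from the selected pool through a per-mouse transplantation
#' bottleneck. Per-array selection is additive on the log2 scale,
#' `s_i = f_gene1 + f_gene2 + epsilon_i` (controls contribute 0), so double
#' knockouts deviate from their single-knockout expectation exactly by the
#' planted interaction term. Selection acts once per screen interval: day-10
#' tumours carry one in vivo round from the injected pool, day-18 tumours a
#' second one. Sequencing counts are negative binomial with variance
#' `mu + dispersion * mu^2`.
#'
#' In noise-free mode (`noise = FALSE`) expected real-valued counts are
#' returned without bottleneck or sampling noise, making the enrichment
#' formulas exact: observed DKO enrichment equals `2^(f_A + f_B + epsilon)`
#' and expected enrichment equals `2^f_A + 2^f_B`.
#'
#' @param design A `crrna_library`.
#' @param fitness Named numeric vector of per-gene log2 fitness values
#'   (negative = depleting). Every targeting gene must be present; controls
#'   are fixed at 0.
#' @param interactions Optional data frame `gene_a`, `gene_b`, `epsilon` of
#'   pairwise interaction terms (DKO pairs only; default none).
#' @param dispersion Negative-binomial overdispersion (0 = Poisson).
#' @param depth Expected total reads per sample.
#' @param bottleneck Cells sampled at transplantation (`Inf` disables).
#' @param n_cell_reps,n_tumours Replicate structure (tumours per timepoint).
#' @param libskew_sdlog Log-normal sd of the initial plasmid abundance
#'   (0 = perfectly uniform library).
#' @param noise If `FALSE`, return deterministic expected counts.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return A `simulated_screen` list: `counts` (tibble `array_id`,
#'   `sample_id`, `count`), `samples` (tibble `sample_id`, `condition`,
#'   `timepoint_days`, `replicate`), `design`, `truth` (the interaction
#'   table) and `params`.
#' @export
simulate_screen <- function(design, fitness = NULL, interactions = NULL,
                            dispersion = 0.1, depth = 500 * nrow(design),
                            bottleneck = 1e5, n_cell_reps = 3, n_tumours = 6,
                            libskew_sdlog = 0.5, noise = TRUE, seed = 1L) {
  stopifnot(inherits(design, "crrna_library"), depth > 0, dispersion >= 0)
  genes <- unique(c(design$gene1[design$set1 != "control"],
                    design$gene2[design$set2 != "control"]))
  if (is.null(fitness)) fitness <- setNames(rep(0, length(genes)), genes)
  missing_f <- setdiff(genes, names(fitness))
  if (length(missing_f)) {
    abort(paste0("Missing fitness for gene(s): ",
                 paste(missing_f, collapse = ", ")))
  }
  if (is.null(interactions)) {
    interactions <- tibble::tibble(gene_a = character(0),
                                   gene_b = character(0),
                                   epsilon = numeric(0))
  }
  stopifnot(all(c("gene_a", "gene_b", "epsilon") %in% names(interactions)))
  eff <- function(gene, set) ifelse(set == "control", 0, fitness[gene])
  s <- eff(design$gene1, design$set1) + eff(design$gene2, design$set2)
  if (nrow(interactions)) {
    key <- paste0(interactions$gene_a, "__", interactions$gene_b)
    bad <- !key %in% design$array_id[design$category == "DKO"]
    if (any(bad)) {
      abort(paste0("Interaction pair(s) not DKO arrays of this design: ",
                   paste(key[bad], collapse = ", ")))
    }
    idx <- match(design$array_id, key)
    s <- s + ifelse(is.na(idx), 0, interactions$epsilon[idx])
  }
  n <- nrow(design)

  withr::with_seed(seed, {
    a <- if (libskew_sdlog > 0 && noise) rlnorm(n, 0, libskew_sdlog) else rep(1, n)
    a <- a / sum(a)
    sel <- a * 2^s
    p14 <- sel / sum(sel)

    draw <- function(p) {
      mu <- depth * p / sum(p)
      if (!noise) return(mu)
      if (dispersion > 0) rnbinom(n, mu = mu, size = 1 / dispersion)
      else rpois(n, mu)
    }
    tumour_draw <- function(rounds) {
      pool <- if (noise && is.finite(bottleneck)) {
        as.numeric(rmultinom(1, size = bottleneck, prob = p14))
      } else p14
      draw(pool * 2^(rounds * s))
    }

    cols <- list(plasmid = draw(a))
    samples <- tibble::tibble(sample_id = "plasmid", condition = "plasmid",
                              timepoint_days = 0L, replicate = 1L)
    add <- function(id, condition, day, rep_, counts) {
      cols[[id]] <<- counts
      samples <<- dplyr::bind_rows(samples, tibble::tibble(
        sample_id = id, condition = condition, timepoint_days = day,
        replicate = rep_))
    }
    for (r in seq_len(n_cell_reps)) {
      add(paste0("cell_d4_r", r), "cell", 4L, r, draw(a))
    }
    for (r in seq_len(n_cell_reps)) {
      add(paste0("cell_d14_r", r), "cell", 14L, r, draw(p14))
    }
    for (m in seq_len(n_tumours)) {
      add(paste0("tumour_d10_m", m), "tumour", 10L, m, tumour_draw(1))
    }
    for (m in seq_len(n_tumours)) {
      add(paste0("tumour_d18_m", m), "tumour", 18L, m, tumour_draw(2))
    }
    counts <- purrr::imap_dfr(cols, function(v, id) {
      tibble::tibble(array_id = design$array_id, sample_id = id, count = v)
    })
  })

  structure(list(counts = counts, samples = samples, design = design,
                 truth = tibble::as_tibble(interactions),
                 params = list(fitness = fitness, dispersion = dispersion,
                               depth = depth, bottleneck = bottleneck,
                               libskew_sdlog = libskew_sdlog, noise = noise,
                               seed = seed)),
            class = "simulated_screen")
}

#' @export
print.simulated_screen <- function(x, ...) {
  cat("# simulated double-knockout screen: ", nrow(x$design), " arrays x ",
      nrow(x$samples), " samples, ", nrow(x$truth),
      " planted interaction(s)\n", sep = "")
  invisible(x)
}

#' Sample ids of a simulated screen by condition / timepoint
#'
#' @param screen A `simulated_screen`.
#' @param condition `"plasmid"`, `"cell"` or `"tumour"`.
#' @param timepoint_days Optional day filter.
#' @return Character vector of sample ids.
#' @export
screen_samples <- function(screen, condition, timepoint_days = NULL) {
  stopifnot(inherits(screen, "simulated_screen"))
  s <- screen$samples[screen$samples$condition == condition, ]
  if (!is.null(timepoint_days)) {
    s <- s[s$timepoint_days %in% timepoint_days, ]
  }
  s$sample_id
}

#' Replicate-paired log2 fold-changes of a simulated screen
#'
#' Canonical LFC table for the rank-sum interaction model: each cell day-14
#' replicate is referenced to its own day-4 replicate and each day-18 tumour
#' to the day-10 tumour with the same index, so every reference sample is
#' used once and per-sample LFCs are independent under the null (no shared
#' reference error). One selection round separates each pair, so a planted
#' interaction `epsilon` shifts the DKO fold-change by `epsilon` log2 units
#' in every pair.
#'
#' @param screen A `simulated_screen`.
#' @param pseudocount_rpm Pseudocount (rpm) passed to [compute_lfc()].
#' @return A tibble `array_id`, `sample_id`, `fc`, `lfc` (one row per array
#'   and final sample).
#' @export
screen_lfc <- function(screen, pseudocount_rpm = 1) {
  stopifnot(inherits(screen, "simulated_screen"))
  rpm <- to_rpm(screen$counts)
  d14 <- sort(screen_samples(screen, "cell", 14))
  d4 <- sort(screen_samples(screen, "cell", 4))
  d18 <- sort(screen_samples(screen, "tumour", 18))
  d10 <- sort(screen_samples(screen, "tumour", 10))
  stopifnot(length(d14) == length(d4), length(d18) == length(d10))
  compute_lfc(rpm, final = c(d14, d18), initial = c(d4, d10),
              pseudocount_rpm = pseudocount_rpm, paired = TRUE)
}

#' Simulate paired FASTQ reads from a count column
#'
#' Emits, for every array, `count` read pairs spanning its cassette
#' reference sequence. The cassette is embedded in fixed pseudo-random
#' flanking sequence so that the fragment length is
#' `2 * read_length - target_overlap` and mates overlap by exactly
#' `target_overlap` bases; merging with [merge_read_pairs()] therefore
#' reconstructs each fragment, and counting recovers the input counts
#' exactly. Output order is a seeded shuffle; bytes are reproducible from
#' the seed.
#'
#' @param counts A tibble `array_id`, `count` (integers >= 0) covering
#'   arrays of `design`.
#' @param design A `crrna_library`.
#' @param out_prefix Path prefix for `<prefix>_R1.fastq` / `<prefix>_R2.fastq`.
#' @param read_length Read length in bp.
#' @param target_overlap Overlap between mates in the fragment (must be
#'   >= 31 to be mergeable and leave room for the cassette).
#' @param seed Integer seed.
#' @return Named character vector of the two FASTQ paths (invisibly).
#' @export
simulate_fastq <- function(counts, design, out_prefix, read_length = 150L,
                           target_overlap = 100L, seed = 1L) {
  stopifnot(inherits(design, "crrna_library"),
            is.data.frame(counts),
            all(c("array_id", "count") %in% names(counts)))
  if (!all(counts$array_id %in% design$array_id)) {
    abort("`counts` contains arrays not in `design`.")
  }
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    abort("`counts` must be non-negative integers.")
  }
  frag_len <- 2L * read_length - target_overlap
  cass_len <- max(nchar(design$reference))
  if (target_overlap < 31L) abort("`target_overlap` must be >= 31.")
  if (cass_len > 2L * read_length - 31L) {
    abort("Cassette longer than 2 * read_length - 31; pairs would not merge.")
  }
  if (frag_len < cass_len) {
    abort("Fragment too short for the cassette; lower `target_overlap`.")
  }
  withr::with_seed(seed, {
    pad <- frag_len - nchar(design$reference)
    left <- pad %/% 2L
    flank <- paste(sample(c("A", "C", "G", "T"), frag_len, replace = TRUE),
                   collapse = "")
    nfl <- rep(flank, nrow(design))
    frags <- paste0(substr(nfl, 1L, left),
                    design$reference,
                    substr(nfl, frag_len - (pad - left) + 1L, frag_len))
    stopifnot(all(nchar(frags) == frag_len))
    idx <- rep(match(counts$array_id, design$array_id), counts$count)
    if (length(idx)) idx <- sample(idx)
    r1 <- substr(frags[idx], 1L, read_length)
    r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
      substr(frags[idx], frag_len - read_length + 1L, frag_len))))
    ids <- paste0(design$array_id[idx], "_", seq_along(idx))
    f1 <- paste0(out_prefix, "_R1.fastq")
    f2 <- paste0(out_prefix, "_R2.fastq")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(setNames(r1, ids)),
                                f1, format = "fastq")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(setNames(r2, ids)),
                                f2, format = "fastq")
  })
  invisible(c(r1 = paste0(out_prefix, "_R1.fastq"),
              r2 = paste0(out_prefix, "_R2.fastq")))
}

#' Simulate an expression + survival cohort
#'
#' Generates per-gene log-normal expression, then survival times from an
#' exponential model whose log-hazard is linear in standardized log
#' expression: `log h_j = log h0 + sum beta_g z_gj + sum beta_int z_A z_B`.
#' Censoring is independent uniform on `(0, u)` with `u` solved so the
#' expected censored fraction matches `censor_fraction`.
#'
#' Note that quartile stratification on the *mean* expression of a pair is
#' symmetric in the standardized scores: a pure product interaction
#' (`beta_gene = 0`) shifts the hazards of the bottom and top quartiles
#' equally and is therefore invisible to the virtual screen; detectable
#' planted pairs combine main effects with the interaction term.
#'
#' @param genes Character vector of gene names.
#' @param n_samples Cohort size (>= 8).
#' @param beta_gene Named numeric vector of per-gene log-hazard slopes
#'   (missing genes default to 0).
#' @param beta_int Optional data frame `gene_a`, `gene_b`, `beta` of
#'   product-interaction log-hazard terms.
#' @param baseline_hazard Baseline hazard per day.
#' @param censor_fraction Expected fraction of censored samples in `[0, 1)`.
#' @param expr_meanlog,expr_sdlog Log-normal expression parameters.
#' @param seed Integer seed.
#' @return A cohort tibble: `sample_id`, `time`, `event`, one column per
#'   gene; planted effects are recorded in attribute `"truth"`.
#' @export
simulate_cohort <- function(genes, n_samples = 400L, beta_gene = NULL,
                            beta_int = NULL, baseline_hazard = 1 / 1000,
                            censor_fraction = 0.3, expr_meanlog = log(100),
                            expr_sdlog = 0.6, seed = 1L) {
  stopifnot(n_samples >= 8L, censor_fraction >= 0, censor_fraction < 1,
            length(genes) >= 1L)
  if (is.null(beta_gene)) beta_gene <- setNames(numeric(0), character(0))
  if (is.null(beta_int)) {
    beta_int <- tibble::tibble(gene_a = character(0), gene_b = character(0),
                               beta = numeric(0))
  }
  stopifnot(all(names(beta_gene) %in% genes),
            all(c(beta_int$gene_a, beta_int$gene_b) %in% genes))
  withr::with_seed(seed, {
    expr <- vapply(genes, function(g) {
      rlnorm(n_samples, meanlog = expr_meanlog, sdlog = expr_sdlog)
    }, numeric(n_samples))
    z <- scale(log(expr))
    eta <- rep(0, n_samples)
    for (g in names(beta_gene)) eta <- eta + beta_gene[[g]] * z[, g]
    if (nrow(beta_int)) {
      for (i in seq_len(nrow(beta_int))) {
        eta <- eta + beta_int$beta[i] *
          z[, beta_int$gene_a[i]] * z[, beta_int$gene_b[i]]
      }
    }
    haz <- baseline_hazard * exp(eta)
    t_event <- rexp(n_samples, rate = haz)
    if (censor_fraction > 0) {
      frac_censored <- function(u) {
        mean((1 - exp(-haz * u)) / (haz * u))
      }
      # censored prob for subject j with C~U(0,u): P(C < T)
      u <- uniroot(function(u) frac_censored(u) - censor_fraction,
                   lower = 1e-6, upper = 1e9, tol = 1e-8)$root
      c_time <- runif(n_samples, 0, u)
      event <- as.integer(t_event <= c_time)
      time <- pmin(t_event, c_time)
    } else {
      event <- rep(1L, n_samples)
      time <- t_event
    }
    cohort <- dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("s%04d", seq_len(n_samples)),
                     time = pmax(time, 1e-9), event = event),
      tibble::as_tibble(expr))
  })
  attr(cohort, "truth") <- list(beta_gene = beta_gene, beta_int = beta_int,
                                baseline_hazard = baseline_hazard,
                                censor_fraction = censor_fraction, seed = seed)
  cohort
}

#' Recovery metrics of interaction calls against simulated truth
#'
#' Compares the significant pairs of an interaction caller with the planted
#' interactions of the screen the calls were computed on.
#'
#' @param screen A `simulated_screen`.
#' @param calls An `interaction_calls` tibble (columns `gene_a`, `gene_b`,
#'   `significant`).
#' @return A one-row tibble: `n_truth`, `n_flagged`, `n_true_flagged`,
#'   `sensitivity`, `fdr` (0 when nothing is flagged).
#' @export
truth_report <- function(screen, calls) {
  stopifnot(inherits(screen, "simulated_screen"), is.data.frame(calls),
            all(c("gene_a", "gene_b", "significant") %in% names(calls)))
  dko_ids <- screen$design$array_id[screen$design$category == "DKO"]
  call_ids <- paste0(calls$gene_a, "__", calls$gene_b)
  if (!all(call_ids %in% dko_ids)) {
    abort("Calls refer to pairs outside this screen's design.")
  }
  truth <- screen$truth
  truth_ids <- paste0(truth$gene_a, "__", truth$gene_b)[truth$epsilon != 0]
  flagged <- call_ids[calls$significant]
  n_true_flagged <- length(intersect(flagged, truth_ids))
  tibble::tibble(
    n_truth = length(truth_ids),
    n_flagged = length(flagged),
    n_true_flagged = n_true_flagged,
    sensitivity = if (length(truth_ids)) n_true_flagged / length(truth_ids) else NA_real_,
    fdr = if (length(flagged)) (length(flagged) - n_true_flagged) / length(flagged) else 0
  )
}
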