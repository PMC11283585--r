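# Deterministic gene-entry tables and libraries used across tests.

random_spacers <- function(n, seed) {
  withr::with_seed(seed, {
    repeat {
      sp <- replicate(n, paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                               collapse = ""))
      if (!anyDuplicated(sp)) return(sp)
    }
  })
}

make_entries <- function(n, prefix, pam = NULL, seed = 1) {
  tibble::tibble(
    name = sprintf("%s%02d", prefix, seq_len(n)),
    spacer = random_spacers(n, seed = seed),
    pam_context = if (is.null(pam)) NA_character_ else pam
  )
}

make_library <- function(k = 15, m = 12, c = 5) {
  enumerate_arrays(
    kinase = make_entries(k, "Kin", pam = "TTTA", seed = 11),
    metabolism = make_entries(m, "Met", pam = "TTTC", seed = 22),
    controls = make_entries(c, "NTC", seed = 33)
  )
}

# the canonical 340-array screen library, built once per test run
lib340 <- make_library()

all_targeting_genes <- function(design) {
  unique(c(design$gene1[design$set1 != "control"],
           design$gene2[design$set2 != "control"]))
}

zero_fitness <- function(design) {
  g <- all_targeting_genes(design)
  stats::setNames(rep(0, length(g)), g)
}

planted_5 <- tibble::tibble(gene_a = sprintf("Kin%02d", 1:5),
                            gene_b = sprintf("Met%02d", 1:5),
                            epsilon = -2)
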