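# Independent oracles and generators used across the test files.

# Hand-written standard genetic code, independent of the Biostrings-based
# translation inside the package.
oracle_codon_table <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  codons <- sort(codons)
  aa <- c(
    AAA = "K", AAC = "N", AAG = "K", AAT = "N", ACA = "T", ACC = "T",
    ACG = "T", ACT = "T", AGA = "R", AGC = "S", AGG = "R", AGT = "S",
    ATA = "I", ATC = "I", ATG = "M", ATT = "I", CAA = "Q", CAC = "H",
    CAG = "Q", CAT = "H", CCA = "P", CCC = "P", CCG = "P", CCT = "P",
    CGA = "R", CGC = "R", CGG = "R", CGT = "R", CTA = "L", CTC = "L",
    CTG = "L", CTT = "L", GAA = "E", GAC = "D", GAG = "E", GAT = "D",
    GCA = "A", GCC = "A", GCG = "A", GCT = "A", GGA = "G", GGC = "G",
    GGG = "G", GGT = "G", GTA = "V", GTC = "V", GTG = "V", GTT = "V",
    TAA = "*", TAC = "Y", TAG = "*", TAT = "Y", TCA = "S", TCC = "S",
    TCG = "S", TCT = "S", TGA = "*", TGC = "C", TGG = "W", TGT = "C",
    TTA = "L", TTC = "F", TTG = "L", TTT = "F"
  )
  stopifnot(setequal(names(aa), codons))
  aa
})

oracle_translate <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0) return(character(0))
  codons <- substring(seq, 3 * seq_len(n) - 2, 3 * seq_len(n))
  unname(oracle_codon_table[codons])
}

# brute-force frameshift analysis: codon-by-codon comparison of the edited
# against the original translation
oracle_frameshift <- function(cds, position, ins) {
  edited <- paste0(substr(cds, 1, position), ins,
                   substr(cds, position + 1, nchar(cds)))
  ref <- oracle_translate(cds)
  alt <- oracle_translate(edited)
  n <- min(length(ref), length(alt))
  first <- NA_integer_
  for (i in seq_len(n)) {
    if (ref[i] != alt[i]) { first <- i; break }
  }
  stop_at <- NA_integer_
  if (!is.na(first)) {
    for (i in first:length(alt)) {
      if (alt[i] == "*") { stop_at <- i; break }
    }
  }
  list(is_frameshift = nchar(ins) %% 3 != 0,
       first_altered_codon = first, premature_stop_codon = stop_at)
}

random_cds <- function(n_codons) {
  body <- sample(c("A", "C", "G", "T"), 3 * (n_codons - 2), replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# random small variant table in the package layout, with per-population
# counts, for property tests
random_variant_table <- function(n, pops = c("GNOMAD_ALL", "KG_ALL"),
                                 genes = c("NPHS2", "LAMB2", "NPHS1")) {
  x <- tibble::tibble(
    gene = sample(genes, n, replace = TRUE),
    chrom = "1",
    pos = sample(1e6, n),
    rsid = sprintf("rs%07d", seq_len(n)),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = NA_character_,
    consequence = sprintf("p.Ala%dVal", seq_len(n)),
    category = "missense",
    sift = NA_real_, pph2 = NA_real_, ma = NA_real_, fathmm = NA_real_,
    condel = runif(n, 0.51, 0.95), condel_label = "D"
  )
  x$alt <- unname(vapply(x$ref,
                         function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                         character(1)))
  for (p in pops) {
    an <- sample(c(5008L, 30780L, 246000L), n, replace = TRUE)
    ac <- rbinom(n, an, 0.001)
    present <- runif(n) < 0.9
    x[[paste0("ac_", p)]] <- ifelse(present, ac, NA_integer_)
    x[[paste0("an_", p)]] <- ifelse(present, an, NA_integer_)
  }
  # guarantee every row has data somewhere
  none <- rowSums(!is.na(as.data.frame(x[paste0("ac_", pops)]))) == 0
  x[[paste0("ac_", pops[1])]][none] <- 1L
  x[[paste0("an_", pops[1])]][none] <- 5008L
  x
}
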