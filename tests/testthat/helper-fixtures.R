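# In-code fixtures shared across test files.

# One visit row of a bout table.
visitRow <- function(bout, order, species, plot = "p1", flowers = 1,
                     taxon = "honeybee") {
  data.frame(bout_id = bout, pollinator_taxon = taxon, plot_id = plot,
             visit_order = order, plant_id = paste0(species, bout, "_", order),
             species_label = species, flowers_probed = flowers)
}

# A bout table from a list of species-label sequences.
boutsFrom <- function(sequences, plot = "p1") {
  do.call(rbind, lapply(seq_along(sequences), function(b) {
    sp <- sequences[[b]]
    do.call(rbind, lapply(seq_along(sp), function(i)
      visitRow(b, i, sp[i], plot = plot)))
  }))
}

# A plot engineered to the observed plot-1 summary: 52 bouts of which 4 are
# cross-species, 70 transitions of which 5 are heterospecific.
plot1Bouts <- function() {
  seqs <- c(
    list(c("A", "B"), c("A", "B"), c("A", "B"), c("A", "B", "A")),  # 5 het
    list(c("A", "A", "A")),                                         # 2 con
    rep(list(c("A", "A")), 31),                                     # 31 con
    rep(list(c("B", "B", "B")), 16))                                # 32 con
  boutsFrom(seqs)
}

# A single-row crossing record.
crossRecord <- function(maternal = "flava", pollen = "flava",
                        treatment = "conspecific", flowers = 35,
                        fruits = 21, seeds = 33) {
  data.frame(maternal_species = maternal, pollen_species = pollen,
             treatment = treatment, flowers_pollinated = flowers,
             fruits = fruits, seeds_total = seeds)
}

# A dosage matrix with planted fixed differences between the parents.
# Loci 1..nDiag are diagnostic (parentA 0 / parentB 2, odd loci flipped);
# the rest carry a shared polymorphism.
plantedGenotypes <- function(nDiag = 5, nShared = 5, nPerPop = 4) {
  nLoci <- nDiag + nShared
  n <- 2 * nPerPop
  d <- matrix(NA_real_, nLoci, n,
              dimnames = list(sprintf("L%02d", seq_len(nLoci)),
                              c(paste0("a", seq_len(nPerPop)),
                                paste0("b", seq_len(nPerPop)))))
  for (i in seq_len(nDiag)) {
    a <- if (i %% 2 == 1) 0 else 2
    d[i, ] <- c(rep(a, nPerPop), rep(2 - a, nPerPop))
  }
  for (i in seq(nDiag + 1, length.out = nShared))
    d[i, ] <- rep(c(0, 1, 2, 1), length.out = n)
  genotypeTable(d, rep(c("parentA", "parentB"), each = nPerPop))
}

# A minimal GT-only VCF for the given loci x individuals dosage matrix.
writeTestVcf <- function(dosages, path) {
  gtOf <- function(x) c(`0` = "0/0", `1` = "0/1", `2` = "1/1")[as.character(x)]
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(dosages)), collapse = "\t"))
  for (i in seq_len(nrow(dosages))) {
    gt <- ifelse(is.na(dosages[i, ]), "./.", gtOf(dosages[i, ]))
    lines <- c(lines, paste(c("1", i, rownames(dosages)[i], "A", "T", ".",
                              "PASS", ".", "GT", gt), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}
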