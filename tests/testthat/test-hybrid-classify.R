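test_that("per-locus FST is 1 for fixed differences and 0 for shared freqs", {
  gt <- plantedGenotypes(nDiag = 3, nShared = 3, nPerPop = 5)
  fst <- perLocusFst(gt)
  expect_equal(unname(fst[1:3]), rep(1, 3))
  # shared-polymorphism loci have identical parental frequencies
  expect_equal(unname(fst[4:6]), rep(0, 3))
})

test_that("per-locus FST matches a brute-force estimator evaluation", {
  # parentA at p = 0.9, parentB at q = 0.1, ten diploids each
  d <- matrix(c(rep(2, 9), 0, rep(0, 9), 2), nrow = 1,
              dimnames = list("L1", paste0("i", 1:20)))
  gt <- genotypeTable(d, rep(c("parentA", "parentB"), each = 10))
  p <- 0.9; q <- 0.1; nA <- 20; nB <- 20
  expected <- ((p - q)^2 - p * (1 - p) / (nA - 1) - q * (1 - q) / (nB - 1)) /
    (p * (1 - q) + q * (1 - p))
  expect_equal(unname(perLocusFst(gt)), expected, tolerance = 1e-12)
})

test_that("undefined FST loci are NA and insufficient samples are skipped", {
  d <- rbind(L1 = c(0, 0, 0, 0),    # monomorphic same allele in both
             L2 = c(NA, NA, 0, 2),  # parentA all missing
             L3 = c(0, 0, 2, 2))
  colnames(d) <- paste0("i", 1:4)
  gt <- genotypeTable(d, c("parentA", "parentA", "parentB", "parentB"))
  fst <- perLocusFst(gt)
  expect_true(is.na(fst[["L1"]]))
  expect_true(is.na(fst[["L2"]]))
  expect_equal(fst[["L3"]], 1)
})

test_that("diagnostic selection keeps exactly the fixed differences", {
  gt <- plantedGenotypes(nDiag = 5, nShared = 5, nPerPop = 4)
  panel <- selectDiagnosticLoci(gt)
  expect_equal(panel$locus, sprintf("L%02d", 1:5))
  # even planted loci count parentA alleles and must be flipped
  expect_equal(panel$flip, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  oriented <- orientDosages(gt, panel)
  expect_true(all(oriented[, populations(gt) == "parentA"] == 0))
  expect_true(all(oriented[, populations(gt) == "parentB"] == 2))
})

test_that("one discordant parental genotype disqualifies a locus", {
  gt <- plantedGenotypes(nDiag = 2, nShared = 0, nPerPop = 4)
  d <- dosages(gt)
  d["L01", "a1"] <- 1  # a heterozygous parentA individual
  gt2 <- genotypeTable(d, populations(gt))
  expect_equal(selectDiagnosticLoci(gt2)$locus, "L02")
})

test_that("minimum parental sample size gates eligibility", {
  gt <- plantedGenotypes(nDiag = 2, nShared = 0, nPerPop = 4)
  d <- dosages(gt)
  d["L01", c("a1", "a2", "a3")] <- NA
  gt2 <- genotypeTable(d, populations(gt))
  expect_equal(selectDiagnosticLoci(gt2, minParentalN = 2)$locus, "L02")
  expect_equal(selectDiagnosticLoci(gt2, minParentalN = 1)$locus,
               c("L01", "L02"))
})

test_that("selection recovers planted fixed differences from simulation", {
  gt <- simulateGenotypes(c(P1 = 20, P2 = 20), nLoci = 40, epsilon = 0,
                          missingRate = 0, nFiller = 160, seed = 61)
  panel <- selectDiagnosticLoci(gt, minParentalN = 10)
  expect_equal(sort(panel$locus), sprintf("diag%03d", 1:40))
})

test_that("an empty panel warns and blocks assignment", {
  d <- matrix(rep(c(0, 1, 2, 1), 3), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("L", 1:3), paste0("i", 1:4)))
  gt <- genotypeTable(d, c("parentA", "parentA", "parentB", "parentB"))
  expect_warning(panel <- selectDiagnosticLoci(gt), "empty diagnostic panel")
  expect_equal(nrow(panel), 0)
  expect_error(assignHybridClasses(gt, panel), "refuses")
})

test_that("class genotype frequencies are the Mendelian expectations", {
  expect_equal(unname(classGenotypeFrequencies("F1")), c(0, 1, 0))
  expect_equal(unname(classGenotypeFrequencies("F2")), c(0.25, 0.5, 0.25))
  expect_equal(unname(classGenotypeFrequencies("BC1")), c(0.5, 0.5, 0))
  expect_equal(unname(classGenotypeFrequencies("BC2")), c(0, 0.5, 0.5))
  for (cls in c("P1", "P2", "F1", "F2", "BC1", "BC2"))
    expect_equal(sum(classGenotypeFrequencies(cls)), 1)
  expect_error(classGenotypeFrequencies("F3"), "unknown class")
})

test_that("an all-heterozygous individual is called F1 decisively", {
  gt <- plantedGenotypes(nDiag = 80, nShared = 0, nPerPop = 4)
  d <- cbind(dosages(gt), u1 = rep(1, 80))
  gt2 <- genotypeTable(d, c(populations(gt), "unknown"))
  panel <- selectDiagnosticLoci(gt2)
  hc <- assignHybridClasses(gt2, panel, epsilon = 0.01)
  calls <- hybridCalls(hc)
  expect_equal(calls$best_class, "F1")
  expect_gt(calls$F1, 0.999)
  expect_equal(calls$hybrid_index, 0.5)
  expect_equal(calls$interclass_heterozygosity, 1)
  # direct likelihood check: at 80 het loci the F2 log-likelihood trails
  # F1 by 80 * log((1 - eps) / (0.5 * (1 - eps) + 0.25 * eps))
  llF1 <- 80 * log(0.99)
  llF2 <- 80 * log(0.5 * 0.99 + 0.5 * 0.01 / 2)
  expect_equal(log(calls$F2 / calls$F1), llF2 - llF1, tolerance = 1e-6)
})

test_that("pure-parental dosage vectors are called P1/P2 with extreme index", {
  gt <- plantedGenotypes(nDiag = 40, nShared = 0, nPerPop = 4)
  # unknowns carrying exact parental genotypes (orientation varies by locus)
  d <- cbind(dosages(gt), u1 = dosages(gt)[, "a1"], u2 = dosages(gt)[, "b1"])
  gt2 <- genotypeTable(d, c(populations(gt), "unknown", "unknown"))
  panel <- selectDiagnosticLoci(gt2)
  calls <- hybridCalls(assignHybridClasses(gt2, panel))
  expect_equal(calls[c("u1", "u2"), "best_class"], c("P1", "P2"))
  expect_equal(calls[c("u1", "u2"), "hybrid_index"], c(0, 1))
})

test_that("posteriors sum to one and ignore locus order", {
  gt <- simulateGenotypes(seed = 62)
  panel <- selectDiagnosticLoci(gt, minParentalN = 10)
  hc <- assignHybridClasses(gt, panel)
  post <- as.matrix(hybridCalls(hc)[, c("P1", "P2", "F1", "F2",
                                        "BC1", "BC2")])
  ok <- !is.na(post[, 1])
  expect_true(all(abs(rowSums(post[ok, ]) - 1) < 1e-9))
  # permuting the panel loci leaves every posterior unchanged
  hc2 <- assignHybridClasses(gt, panel[sample(nrow(panel)), ])
  expect_equal(hybridCalls(hc2)[, 2:7], hybridCalls(hc)[, 2:7],
               tolerance = 1e-12)
})

test_that("swapping parental labels swaps P1/P2, BC1/BC2 and flips the index", {
  gt <- simulateGenotypes(c(P1 = 10, P2 = 10, F2 = 10, BC1 = 10), seed = 63,
                          nParentalRef = 10)
  pop <- populations(gt)
  swapped <- c(parentA = "parentB", parentB = "parentA",
               unknown = "unknown")[pop]
  gtSwap <- genotypeTable(dosages(gt), swapped)
  unknowns <- names(pop)[pop == "unknown"]
  a <- hybridCalls(assignHybridClasses(
    gt, selectDiagnosticLoci(gt, 5), individuals = unknowns))
  b <- hybridCalls(assignHybridClasses(
    gtSwap, selectDiagnosticLoci(gtSwap, 5), individuals = unknowns))
  expect_equal(b$P1, a$P2, tolerance = 1e-9)
  expect_equal(b$P2, a$P1, tolerance = 1e-9)
  expect_equal(b$BC1, a$BC2, tolerance = 1e-9)
  expect_equal(b$BC2, a$BC1, tolerance = 1e-9)
  expect_equal(b$F2, a$F2, tolerance = 1e-9)
  expect_equal(b$hybrid_index, 1 - a$hybrid_index, tolerance = 1e-12)
})

test_that("simulated F2 individuals show the expected index and heterozygosity", {
  gt <- simulateGenotypes(c(P1 = 20, P2 = 20, F2 = 50), nLoci = 80,
                          epsilon = 0.01, missingRate = 0, seed = 64)
  panel <- selectDiagnosticLoci(gt, minParentalN = 10)
  calls <- hybridCalls(assignHybridClasses(gt, panel))
  f2 <- calls[grepl("^F2", calls$individual), ]
  expect_true(all(f2$best_class == "F2"))
  # binomial expectations at 80 loci: index 0.5, heterozygosity 0.5
  expect_lt(abs(mean(f2$hybrid_index) - 0.5), 3 * 0.5 / sqrt(160 * 50))
  expect_lt(abs(mean(f2$interclass_heterozygosity) - 0.5),
            3 * 0.5 / sqrt(80 * 50))
})

test_that("all-missing individuals yield flagged no-calls", {
  gt <- plantedGenotypes(nDiag = 10, nShared = 0, nPerPop = 4)
  d <- cbind(dosages(gt), u1 = rep(NA_real_, 10))
  gt2 <- genotypeTable(d, c(populations(gt), "unknown"))
  calls <- hybridCalls(assignHybridClasses(gt2, selectDiagnosticLoci(gt2)))
  expect_equal(calls$best_class, "no_call")
  expect_equal(calls$n_loci_used, 0L)
  expect_true(is.na(calls$hybrid_index))
})

test_that("classifier recovers true classes on the reference simulation", {
  gt <- simulateGenotypes(c(P1 = 100, P2 = 100, F1 = 100, F2 = 100,
                            BC1 = 100, BC2 = 100), nLoci = 80,
                          epsilon = 0.01, missingRate = 0.05, seed = 65)
  panel <- selectDiagnosticLoci(gt, minParentalN = 10)
  hc <- assignHybridClasses(gt, panel, epsilon = 0.01,
                            individuals = colnames(gt))
  calls <- hybridCalls(hc)
  truth <- SummarizedExperiment::colData(gt)$true_class
  acc <- mean(calls[colnames(gt), "best_class"] == truth)
  expect_gte(acc, 0.95)
  # F1 and F2 are separable at 80 loci: no confusion either way
  expect_equal(sum(truth == "F1" & calls$best_class == "F2"), 0)
  expect_equal(sum(truth == "F2" & calls$best_class == "F1"), 0)
})

test_that("epsilon and prior inputs are validated", {
  gt <- plantedGenotypes(nDiag = 5, nShared = 0, nPerPop = 4)
  panel <- selectDiagnosticLoci(gt)
  expect_error(assignHybridClasses(gt, panel, epsilon = 0.6), "epsilon")
  expect_error(assignHybridClasses(gt, panel, prior = c(P1 = 1)), "prior")
  # a prior that zeroes a class removes it from contention
  pr <- c(P1 = 0, P2 = 1, F1 = 1, F2 = 1, BC1 = 1, BC2 = 1)
  d <- cbind(dosages(gt), u1 = dosages(gt)[, "a1"])  # a parentA-like unknown
  gt2 <- genotypeTable(d, c(populations(gt), "unknown"))
  calls <- hybridCalls(assignHybridClasses(gt2, selectDiagnosticLoci(gt2),
                                           prior = pr))
  expect_equal(calls$P1, 0)
  expect_equal(calls$best_class, "BC1")  # closest remaining class
})

test_that("VCF and dosage-matrix inputs give identical genotype tables", {
  gt <- simulateGenotypes(c(P1 = 4, P2 = 4, F2 = 4), nLoci = 8,
                          missingRate = 0.1, nParentalRef = 4, seed = 66)
  vcf <- tempfile(fileext = ".vcf")
  writeTestVcf(dosages(gt), vcf)
  tsv <- tempfile(fileext = ".tsv")
  writeDosages(gt, tsv)
  pm <- tempfile(fileext = ".txt")
  writePopmap(gt, pm)

  g1 <- readGenotypes(vcf, pm)
  g2 <- readGenotypes(tsv, pm, format = "dosage")
  expect_equal(dosages(g1), dosages(g2))
  expect_equal(populations(g1), populations(g2))
  expect_equal(unname(dosages(g1)["diag001", ]),
               unname(dosages(gt)["diag001", ]))

  pmBad <- tempfile()
  writeLines("individual\tlabel\nx\tparentA", pmBad)
  expect_error(readGenotypes(tsv, pmBad, format = "dosage"),
               "missing from the population map")
})
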