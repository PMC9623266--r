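## Diagnostic-locus selection and six-class hybrid genotype assignment.
##
## Loci fixed for alternative alleles in the two parental samples
## (Hudson FST = 1) are diagnostic: every allele copy identifies its
## parental origin. Over such a panel the six canonical classes have fixed
## Mendelian genotype frequencies, so each unknown individual gets a direct
## per-locus likelihood posterior — no MCMC needed for a fixed panel.

#' Construct a GenotypeTable
#'
#' @param dosages numeric matrix, loci (rows) × individuals (columns), of
#'   0/1/2/NA copies of the reference allele. Dimnames are used as locus
#'   and individual identifiers.
#' @param populations character vector over individuals with values
#'   `parentA`, `parentB` or `unknown`.
#' @return a [GenotypeTable-class].
#' @export
#' @examples
#' d <- matrix(c(0, 0, 2, 2, 1, 1), nrow = 1,
#'             dimnames = list("L1", paste0("ind", 1:6)))
#' genotypeTable(d, c("parentA", "parentA", "parentB", "parentB",
#'                    "unknown", "unknown"))
genotypeTable <- function(dosages, populations) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("locus", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("ind", seq_len(ncol(dosages)))
  if (length(populations) != ncol(dosages))
    stop("one population label per individual is required", call. = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosages),
    colData = S4Vectors::DataFrame(
      population = as.character(populations),
      row.names = colnames(dosages)))
  new("GenotypeTable", se)
}

#' @rdname GenotypeTable-class
#' @export
setMethod("dosages", "GenotypeTable", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname GenotypeTable-class
#' @export
setMethod("populations", "GenotypeTable", function(x)
  stats::setNames(SummarizedExperiment::colData(x)$population, colnames(x)))

#' Per-locus Hudson FST between the parental samples
#'
#' For each locus, the Hudson-style estimator on the parental reference
#' allele frequencies \eqn{p, q} with allele sample sizes \eqn{n_A, n_B}:
#' \deqn{F_{ST} = \frac{(p-q)^2 - p(1-p)/(n_A-1) - q(1-q)/(n_B-1)}
#'                     {p(1-q) + q(1-p)},}
#' clamped to \[0, 1\]. It equals 1 exactly when the two parental samples
#' are fixed for alternative alleles. Loci monomorphic in both samples
#' pooled (zero denominator) or missing in either sample are `NA`.
#'
#' @param gt a [GenotypeTable-class] with individuals labelled `parentA`
#'   and `parentB`.
#' @return named numeric over loci, in \[0, 1\] or `NA`.
#' @export
perLocusFst <- function(gt) {
  stopifnot(is(gt, "GenotypeTable"))
  pop <- populations(gt)
  d <- dosages(gt)
  dA <- d[, pop == "parentA", drop = FALSE]
  dB <- d[, pop == "parentB", drop = FALSE]
  if (ncol(dA) == 0 || ncol(dB) == 0)
    stop("both parental populations must be present", call. = FALSE)
  fstOne <- function(a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    nA <- 2 * length(a); nB <- 2 * length(b)   # allele sample sizes
    if (nA < 2 || nB < 2) return(NA_real_)
    p <- sum(a) / nA; q <- sum(b) / nB
    den <- p * (1 - q) + q * (1 - p)
    if (den == 0) return(NA_real_)             # monomorphic, same allele
    num <- (p - q)^2 - p * (1 - p) / (nA - 1) - q * (1 - q) / (nB - 1)
    min(1, max(0, num / den))
  }
  vapply(seq_len(nrow(d)), function(i) fstOne(dA[i, ], dB[i, ]),
         numeric(1), USE.NAMES = FALSE) |>
    stats::setNames(rownames(d))
}

#' Select diagnostic loci (fixed parental differences)
#'
#' A locus is diagnostic iff the two parental samples are fixed for
#' alternative alleles (per-locus FST = 1 with no sampling correction
#' needed: every parentA genotype is one homozygote, every parentB
#' genotype the other) and each parental population has at least
#' `minParentalN` called genotypes there. Orientation is recorded so that
#' after [orientDosages()] dosage 2 means two parentB-derived alleles at
#' every diagnostic locus.
#'
#' @param gt a [GenotypeTable-class].
#' @param minParentalN minimum called parental genotypes per population for
#'   a locus to be eligible (default 1).
#' @return a data.frame with columns `locus` and `flip` (logical: `TRUE`
#'   when the raw dosages count parentA alleles and must be reversed).
#'   Zero rows, with a warning, when no locus qualifies.
#' @export
selectDiagnosticLoci <- function(gt, minParentalN = 1) {
  stopifnot(is(gt, "GenotypeTable"))
  pop <- populations(gt)
  d <- dosages(gt)
  dA <- d[, pop == "parentA", drop = FALSE]
  dB <- d[, pop == "parentB", drop = FALSE]
  if (ncol(dA) == 0 || ncol(dB) == 0)
    stop("both parental populations must be present", call. = FALSE)
  pick <- lapply(seq_len(nrow(d)), function(i) {
    a <- dA[i, ][!is.na(dA[i, ])]
    b <- dB[i, ][!is.na(dB[i, ])]
    if (length(a) < minParentalN || length(b) < minParentalN) return(NULL)
    if (all(a == 0) && all(b == 2))
      data.frame(locus = rownames(d)[i], flip = FALSE)
    else if (all(a == 2) && all(b == 0))
      data.frame(locus = rownames(d)[i], flip = TRUE)
    else NULL
  })
  panel <- do.call(rbind, pick)
  if (is.null(panel)) {
    warning("empty diagnostic panel: no locus is fixed for alternative ",
            "alleles between the parental samples")
    panel <- data.frame(locus = character(0), flip = logical(0))
  }
  panel
}

#' Orient dosages to count parentB-derived alleles
#'
#' @param gt a [GenotypeTable-class].
#' @param panel a data.frame from [selectDiagnosticLoci()].
#' @return numeric matrix, panel loci × individuals, with dosage 2 = two
#'   parentB alleles everywhere.
#' @export
orientDosages <- function(gt, panel) {
  d <- dosages(gt)[panel$locus, , drop = FALSE]
  d[panel$flip, ] <- 2 - d[panel$flip, , drop = FALSE]
  d
}

#' Expected diagnostic-locus genotype frequencies per hybrid class
#'
#' Mendelian expectations for (0, 1, 2) parentB-allele dosages over a
#' diagnostic panel: P1 (1,0,0); P2 (0,0,1); F1 (0,1,0); F2 (1/4,1/2,1/4);
#' BC1 = F1 × P1 (1/2,1/2,0); BC2 = F1 × P2 (0,1/2,1/2).
#'
#' @param class one of `"P1"`, `"P2"`, `"F1"`, `"F2"`, `"BC1"`, `"BC2"`.
#' @return numeric(3): frequencies of dosage 0, 1, 2; sums to 1.
#' @export
classGenotypeFrequencies <- function(class) {
  freqs <- list(P1 = c(1, 0, 0), P2 = c(0, 0, 1), F1 = c(0, 1, 0),
                F2 = c(0.25, 0.5, 0.25), BC1 = c(0.5, 0.5, 0),
                BC2 = c(0, 0.5, 0.5))
  if (!class %in% names(freqs))
    stop("unknown class: ", class, call. = FALSE)
  stats::setNames(freqs[[class]], c("f0", "f1", "f2"))
}

#' Assign individuals to the six hybrid genotype classes
#'
#' For each individual with at least one called diagnostic genotype, the
#' per-locus likelihood of observed dosage \eqn{g} under class \eqn{k} is
#' \deqn{(1-\epsilon)\, f_g(k) + \epsilon\,(1 - f_g(k))/2,}
#' i.e. the genotype is drawn from the class frequencies with probability
#' \eqn{1-\epsilon} and mis-scored as either wrong genotype with equal
#' shares of \eqn{\epsilon}. Loci are treated as unlinked: log-likelihoods
#' accumulate across called loci, missing loci are skipped, and the
#' posterior is likelihood × prior, normalised. With \eqn{\epsilon > 0} no
#' single discordant locus can zero out a class. Also reports the hybrid
#' index (fraction of called diagnostic alleles that are parentB-derived)
#' and interclass heterozygosity (fraction of called diagnostic loci that
#' are heterozygous; expected 1.0 for F1, 0.5 for F2).
#'
#' @param gt a [GenotypeTable-class].
#' @param panel a data.frame from [selectDiagnosticLoci()]; must be
#'   non-empty.
#' @param epsilon genotyping-error rate in \[0, 0.5) (default 0.01).
#' @param prior named numeric(6) class prior (default uniform); normalised
#'   internally.
#' @param individuals which individuals to call (default: those labelled
#'   `unknown`, or all when none are).
#' @return a [HybridClassification-class]. Individuals with no called
#'   diagnostic genotype get `best_class` `"no_call"` and NA posteriors.
#' @export
assignHybridClasses <- function(gt, panel, epsilon = 0.01, prior = NULL,
                                individuals = NULL) {
  stopifnot(is(gt, "GenotypeTable"))
  if (nrow(panel) == 0)
    stop("empty diagnostic panel: assignment refuses to run", call. = FALSE)
  if (epsilon < 0 || epsilon >= 0.5)
    stop("epsilon must lie in [0, 0.5)", call. = FALSE)
  if (is.null(prior))
    prior <- stats::setNames(rep(1 / 6, 6), .hybridClasses)
  if (!identical(sort(names(prior)), sort(.hybridClasses)) ||
      any(prior < 0) || sum(prior) == 0)
    stop("prior must be a non-negative vector named by the six classes",
         call. = FALSE)
  prior <- prior[.hybridClasses] / sum(prior)
  if (is.null(individuals)) {
    pop <- populations(gt)
    individuals <- names(pop)[pop == "unknown"]
    if (length(individuals) == 0) individuals <- colnames(gt)
  }
  d <- orientDosages(gt, panel)[, individuals, drop = FALSE]

  ## 3 × 6 per-genotype log-likelihood lookup, shared across loci
  fmat <- vapply(.hybridClasses, classGenotypeFrequencies, numeric(3))
  lik <- (1 - epsilon) * fmat + epsilon * (1 - fmat) / 2
  logLik <- log(pmax(lik, .Machine$double.xmin))  # floor against underflow

  rows <- lapply(individuals, function(ind) {
    g <- d[, ind]
    called <- !is.na(g)
    n <- sum(called)
    if (n == 0) {
      post <- stats::setNames(rep(NA_real_, 6), .hybridClasses)
      return(data.frame(individual = ind, t(post), best_class = "no_call",
                        n_loci_used = 0L, hybrid_index = NA_real_,
                        interclass_heterozygosity = NA_real_))
    }
    gcalled <- g[called]
    ll <- colSums(logLik[gcalled + 1, , drop = FALSE]) + log(prior)
    post <- exp(ll - max(ll))
    post <- post / sum(post)
    data.frame(individual = ind, t(post),
               best_class = .hybridClasses[which.max(post)],
               n_loci_used = n,
               hybrid_index = sum(gcalled) / (2 * n),
               interclass_heterozygosity = mean(gcalled == 1))
  })
  calls <- S4Vectors::DataFrame(do.call(rbind, rows))
  rownames(calls) <- calls$individual
  new("HybridClassification", calls = calls, panel = panel$locus,
      epsilon = epsilon, prior = prior)
}

#' @rdname HybridClassification-class
#' @export
setMethod("hybridCalls", "HybridClassification", function(x)
  as.data.frame(x@calls))

setMethod("show", "HybridClassification", function(object) {
  cat(sprintf("HybridClassification: %d individuals, %d diagnostic loci, ",
              nrow(object@calls), length(object@panel)),
      sprintf("epsilon = %g\n", object@epsilon))
  print(table(object@calls$best_class))
})

#' Write class assignments as TSV
#'
#' @param hc a [HybridClassification-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeAssignments <- function(hc, path) {
  stopifnot(is(hc, "HybridClassification"))
  utils::write.table(hybridCalls(hc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## input readers ------------------------------------------------------------

#' Read genotypes from a dosage TSV or a VCF, with a population map
#'
#' The dosage TSV has individuals as rows and loci as columns, values
#' 0/1/2/NA, first column `individual`. A VCF is parsed for its GT field
#' only (diploid; `/` or `|` separators both accepted); dosage counts
#' copies of the ALT allele. The population map TSV has columns
#' `individual`, `label` with labels `parentA`, `parentB` or `unknown`.
#'
#' @param path genotype file (`.vcf` or dosage TSV).
#' @param popmapPath population map TSV path.
#' @param format `"auto"` (default: by file extension), `"vcf"` or
#'   `"dosage"`.
#' @return a [GenotypeTable-class].
#' @export
readGenotypes <- function(path, popmapPath,
                          format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  d <- if (format == "vcf") .readVcfDosages(path) else
    .readDosageTsv(path)
  popmap <- utils::read.table(popmapPath, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  if (!all(c("individual", "label") %in% colnames(popmap)))
    stop("population map must have columns individual, label",
         call. = FALSE)
  miss <- setdiff(colnames(d), popmap$individual)
  if (length(miss) > 0)
    stop("individuals missing from the population map: ",
         paste(miss, collapse = ", "), call. = FALSE)
  labels <- popmap$label[match(colnames(d), popmap$individual)]
  genotypeTable(d, labels)
}

.readDosageTsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(df)[1] != "individual")
    stop("dosage TSV must have 'individual' as its first column",
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$individual
  t(m)  # loci × individuals
}

.readVcfDosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gtField <- vcfR::extract.gt(v, element = "GT")
  alleles <- function(x) {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x) & grepl("^[01][/|][01]$", x)
    out[ok] <- as.numeric(substr(x[ok], 1, 1)) +
      as.numeric(substr(x[ok], 3, 3))
    out
  }
  d <- apply(gtField, 2, alleles)
  rownames(d) <- rownames(gtField)
  d
}
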