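## Generators with known ground truth for every input the pipeline reads.
## Each takes an optional `seed`; a fixed seed gives byte-identical output.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

#' Simulate pollinator foraging bouts
#'
#' Emulates mixed plots of the two species observed for pollinator
#' behavior. The first plant of a bout is drawn by plot composition; each
#' subsequent visit stays on the current species with probability
#' \eqn{c + (1-c) w_s} (where \eqn{w_s} is that species' composition
#' weight) and otherwise switches, so `constancy = 1` gives pure floral
#' constancy and `constancy = 0` composition-random foraging. Bout lengths
#' (visits) are 1 + Poisson(`meanVisits - 1`).
#'
#' @param nBouts number of bouts.
#' @param composition named numeric plot composition, e.g.
#'   `c(A = 6, B = 6)` for alternating six-and-six plots.
#' @param constancy floral-constancy parameter `c` in \[0, 1\] (default
#'   0.9, strong constancy as seen in bee-pollinated plots).
#' @param meanVisits mean plants visited per bout (default 2.5).
#' @param meanFlowers mean flowers probed per plant visit (default 2.5;
#'   flowers are 1 + Poisson(`meanFlowers - 1`)).
#' @param plotId plot label for the output.
#' @param pollinatorTaxon taxon label for the output.
#' @param seed optional integer seed.
#' @return a validated bout data.frame (see [readBouts()]).
#' @export
#' @examples
#' b <- simulateBouts(50, constancy = 1, seed = 1)
#' tallyTransitions(b)  # no heterospecific transitions at c = 1
simulateBouts <- function(nBouts, composition = c(A = 6, B = 6),
                          constancy = 0.9, meanVisits = 2.5,
                          meanFlowers = 2.5, plotId = "plot1",
                          pollinatorTaxon = "honeybee", seed = NULL) {
  if (length(composition) == 0 || sum(composition) == 0)
    stop("empty plot: composition must have plants", call. = FALSE)
  .checkProbability(constancy, "constancy")
  .withSeed(seed, {
    w <- composition / sum(composition)
    species <- names(w)
    rows <- lapply(seq_len(nBouts), function(b) {
      len <- 1L + stats::rpois(1, max(0, meanVisits - 1))
      seq_sp <- character(len)
      seq_sp[1] <- sample(species, 1, prob = w)
      for (i in seq_len(len - 1L)) {
        cur <- seq_sp[i]
        pStay <- constancy + (1 - constancy) * w[[cur]]
        seq_sp[i + 1L] <- if (stats::runif(1) < pStay) cur else
          sample(species, 1, prob = ifelse(species == cur, 0, w))
      }
      data.frame(bout_id = b, pollinator_taxon = pollinatorTaxon,
                 plot_id = plotId, visit_order = seq_len(len),
                 plant_id = paste0(seq_sp, "_",
                                   sample.int(1000, len, replace = TRUE)),
                 species_label = seq_sp,
                 flowers_probed = 1L + stats::rpois(len,
                                                    max(0, meanFlowers - 1)))
    })
    validateBouts(do.call(rbind, rows))
  })
}

#' Simulate diagnostic-panel genotypes with known true classes
#'
#' Each individual's genotype at every diagnostic locus is drawn from
#' [classGenotypeFrequencies()] of its true class, then perturbed by a
#' symmetric genotyping error (with probability `epsilon` the genotype is
#' replaced by one of the two other dosages, equally likely) and masked
#' with probability `missingRate`. Optional filler loci carry a shared
#' polymorphism (both parents at allele frequency 0.5) and are therefore
#' never diagnostic. Parental-class individuals are labelled
#' `parentA`/`parentB` up to `nParentalRef` per side (the reference
#' panels); all others are `unknown`. True classes are kept in
#' `colData(gt)$true_class`.
#'
#' @param nPerClass named integer vector of individuals per class, e.g.
#'   `c(P1 = 100, F2 = 100)`; names from P1, P2, F1, F2, BC1, BC2.
#' @param nLoci number of diagnostic loci (default 80, a realistic ddRAD
#'   diagnostic-panel size).
#' @param epsilon genotyping-error rate (default 0.01).
#' @param missingRate per-genotype missingness (default 0.05).
#' @param nFiller number of non-diagnostic filler loci (default 0).
#' @param nParentalRef individuals per parental class labelled as the
#'   reference panels (default 20).
#' @param seed optional integer seed.
#' @return a [GenotypeTable-class] with `true_class` in its `colData`.
#' @export
simulateGenotypes <- function(nPerClass = c(P1 = 20, P2 = 20, F1 = 20,
                                            F2 = 20, BC1 = 20, BC2 = 20),
                              nLoci = 80, epsilon = 0.01,
                              missingRate = 0.05, nFiller = 0,
                              nParentalRef = 20, seed = NULL) {
  if (!all(names(nPerClass) %in% .hybridClasses))
    stop("nPerClass must be named by the six classes", call. = FALSE)
  .checkProbability(c(epsilon, missingRate), "epsilon/missingRate")
  .withSeed(seed, {
    classes <- rep(names(nPerClass), nPerClass)
    n <- length(classes)
    draw <- function(cls)
      sample(0:2, nLoci, replace = TRUE,
             prob = classGenotypeFrequencies(cls))
    d <- matrix(vapply(classes, draw, numeric(nLoci)), nrow = nLoci)
    ## symmetric genotyping error: move to either other dosage
    err <- matrix(stats::runif(nLoci * n) < epsilon, nLoci, n)
    if (any(err)) {
      shift <- matrix(sample(1:2, nLoci * n, replace = TRUE), nLoci, n)
      d[err] <- (d[err] + shift[err]) %% 3
    }
    d[matrix(stats::runif(nLoci * n) < missingRate, nLoci, n)] <- NA
    rownames(d) <- sprintf("diag%03d", seq_len(nLoci))
    if (nFiller > 0) {
      filler <- matrix(stats::rbinom(nFiller * n, 2, 0.5), nFiller, n,
                       dimnames = list(sprintf("fill%03d",
                                               seq_len(nFiller)), NULL))
      d <- rbind(d, filler)
    }
    ids <- sprintf("%s_%03d", classes, stats::ave(seq_len(n), classes,
                                                  FUN = seq_along))
    colnames(d) <- ids
    pop <- rep("unknown", n)
    pop[classes == "P1"][seq_len(min(nParentalRef,
                                     sum(classes == "P1")))] <- "parentA"
    pop[classes == "P2"][seq_len(min(nParentalRef,
                                     sum(classes == "P2")))] <- "parentB"
    gt <- genotypeTable(d, pop)
    SummarizedExperiment::colData(gt)$true_class <- classes
    gt
  })
}

#' Simulate hand-pollination outcomes
#'
#' Fruits are binomial(`flowers`, `fruitProb`) per record; seeds per fruit
#' follow a Poisson truncated at `maxOvules` (default 4: the ovule number
#' per flower in this genus).
#'
#' @param treatments a data.frame with columns `maternal_species`,
#'   `pollen_species`, `treatment`, `flowers`, `fruitProb`, `seedMean`
#'   (mean seeds per fruit before truncation).
#' @param maxOvules maximum seeds per fruit (default 4).
#' @param seed optional integer seed.
#' @return a validated crossing data.frame with one row per treatment row.
#' @export
simulateCrossings <- function(treatments, maxOvules = 4, seed = NULL) {
  need <- c("maternal_species", "pollen_species", "treatment", "flowers",
            "fruitProb", "seedMean")
  if (!all(need %in% colnames(treatments)))
    stop("treatments must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  .checkProbability(treatments$fruitProb, "fruitProb")
  .withSeed(seed, {
    fruits <- stats::rbinom(nrow(treatments), treatments$flowers,
                            treatments$fruitProb)
    seeds <- vapply(seq_len(nrow(treatments)), function(i) {
      if (fruits[i] == 0) return(0)
      sum(pmin(stats::rpois(fruits[i], treatments$seedMean[i]), maxOvules))
    }, numeric(1))
    validateCrossings(data.frame(
      maternal_species = treatments$maternal_species,
      pollen_species = treatments$pollen_species,
      treatment = treatments$treatment,
      flowers_pollinated = treatments$flowers,
      fruits = fruits, seeds_total = seeds))
  })
}

#' Simulate clustered occurrence records with planted sympatry
#'
#' Each species' records form a Gaussian cluster (tangent-plane
#' approximation: km offsets converted to degrees) around its centre. A
#' fraction `overlapFraction` of the focal species' records is planted
#' within `radiusKm` of a heterospecific record, so the true geographic
#' barrier index is `1 - overlapFraction` by construction when the two
#' cluster centres are much farther apart than `radiusKm`.
#'
#' @param nFocal,nOther record counts for the focal and other species.
#' @param focalSpecies,otherSpecies species labels for the output.
#' @param centerFocal,centerOther numeric(2) `(lat, lon)` cluster centres;
#'   defaults are ~100 km apart.
#' @param dispersionKm cluster standard deviation in km (default 20).
#' @param overlapFraction fraction of focal records planted sympatric
#'   (default 0.2).
#' @param radiusKm sympatry radius (default 7).
#' @param elevationRange numeric(2); elevations are drawn uniformly in
#'   this range (default 2500–4000 m).
#' @param seed optional integer seed.
#' @return an occurrence data.frame with columns `species`, `latitude`,
#'   `longitude`, `elevation_m`.
#' @export
simulateOccurrences <- function(nFocal = 36, nOther = 58,
                                focalSpecies = "A", otherSpecies = "B",
                                centerFocal = c(27.4, 100.4),
                                centerOther = c(27.4, 101.4),
                                dispersionKm = 20, overlapFraction = 0.2,
                                radiusKm = 7,
                                elevationRange = c(2500, 4000),
                                seed = NULL) {
  .checkProbability(overlapFraction, "overlapFraction")
  .withSeed(seed, {
    kmPerDegLat <- 6371 * pi / 180
    cluster <- function(n, center) {
      dLat <- stats::rnorm(n, 0, dispersionKm) / kmPerDegLat
      dLon <- stats::rnorm(n, 0, dispersionKm) /
        (kmPerDegLat * cos(center[1] * pi / 180))
      cbind(latitude = center[1] + dLat, longitude = center[2] + dLon)
    }
    other <- cluster(nOther, centerOther)
    focal <- cluster(nFocal, centerFocal)
    nSym <- round(overlapFraction * nFocal)
    if (nSym > 0) {
      ## plant sympatric focal records right next to other-species records
      anchor <- other[sample.int(nOther, nSym, replace = TRUE), ,
                      drop = FALSE]
      jitter <- stats::runif(nSym, 0, 0.5 * radiusKm)
      theta <- stats::runif(nSym, 0, 2 * pi)
      focal[seq_len(nSym), "latitude"] <-
        anchor[, "latitude"] + jitter * sin(theta) / kmPerDegLat
      focal[seq_len(nSym), "longitude"] <- anchor[, "longitude"] +
        jitter * cos(theta) /
          (kmPerDegLat * cos(anchor[, "latitude"] * pi / 180))
    }
    df <- rbind(
      data.frame(species = focalSpecies, focal),
      data.frame(species = otherSpecies, other))
    df$elevation_m <- stats::runif(nrow(df), elevationRange[1],
                                   elevationRange[2])
    .checkOccurrences(df)
  })
}

## writers for the documented dialects -------------------------------------

#' Write tables in the dialects the readers expect
#'
#' `writeBouts()`, `writeOccurrences()` and `writeCrossings()` write the
#' comma-delimited UTF-8 files read back by [readBouts()],
#' [readOccurrences()] and [readCrossings()]; `writeDosages()` and
#' `writePopmap()` write the tab-delimited genotype inputs of
#' [readGenotypes()].
#'
#' @param x the table (for `writeDosages()`, a [GenotypeTable-class]).
#' @param path output file path.
#' @return the path, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
writeBouts <- function(x, path) {
  utils::write.csv(validateBouts(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
writeOccurrences <- function(x, path) {
  utils::write.csv(.checkOccurrences(x), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
writeCrossings <- function(x, path) {
  utils::write.csv(validateCrossings(x), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
writeDosages <- function(x, path) {
  stopifnot(is(x, "GenotypeTable"))
  df <- data.frame(individual = colnames(x), t(dosages(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @export
writePopmap <- function(x, path) {
  stopifnot(is(x, "GenotypeTable"))
  df <- data.frame(individual = colnames(x),
                   label = unname(populations(x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
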