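#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom stats setNames sd rbinom rpois runif rnorm
#' @importFrom utils read.csv write.csv read.table write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' BarrierComponent: one stage-specific reproductive-isolation statistic
#'
#' Holds a single barrier's RI value together with its life-history stage
#' label and whether it acts before or after fertilization. The raw value may
#' be negative for postzygotic barriers (heterospecific fitness exceeding
#' conspecific); the reported value is clipped at zero under the default
#' policy so that it stays on the 0 (no barrier) to 1 (complete barrier)
#' scale.
#'
#' @slot stage character stage label, e.g. `"Phenology"`.
#' @slot stageClass `"prezygotic"` or `"postzygotic"`.
#' @slot valueRaw numeric, the unclipped statistic (in \[-1, 1\]).
#' @slot value numeric, the clipped statistic (in \[0, 1\]).
#'
#' @seealso [barrierComponent()], [sequentialContributions()]
#' @export
setClass("BarrierComponent",
  representation(stage = "character", stageClass = "character",
                 valueRaw = "numeric", value = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@stageClass) != 1L ||
        !object@stageClass %in% c("prezygotic", "postzygotic"))
      msg <- c(msg, "stageClass must be 'prezygotic' or 'postzygotic'")
    if (!is.finite(object@value) || object@value < 0 || object@value > 1)
      msg <- c(msg, "value must lie in [0, 1]")
    if (is.finite(object@valueRaw) && object@valueRaw >= 0 &&
        !isTRUE(all.equal(object@value, object@valueRaw)))
      msg <- c(msg, "value must equal valueRaw when valueRaw >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' CascadeResult: sequential contributions of ordered barriers
#'
#' The result of pushing an ordered set of barrier components through the
#' sequential-contribution scheme: each stage's absolute contribution
#' \eqn{AC_n = v_n \prod_{i<n} (1 - v_i)} is the share of gene flow it blocks
#' after all earlier stages have acted, the total \eqn{T = \sum AC_n =
#' 1 - \prod (1 - v_i)}, and relative contributions \eqn{RC_n = AC_n / T}.
#'
#' @slot stages character stage labels, in life-history order.
#' @slot values numeric component values in \[0, 1\].
#' @slot absolute numeric absolute contributions.
#' @slot total numeric(1) total RI.
#' @slot relative numeric relative contributions (NA when total is 0).
#' @slot scenario character(1) free-text scenario label.
#'
#' @seealso [sequentialContributions()]
#' @export
setClass("CascadeResult",
  representation(stages = "character", values = "numeric",
                 absolute = "numeric", total = "numeric",
                 relative = "numeric", scenario = "character"),
  validity = function(object) {
    n <- length(object@values)
    msg <- NULL
    if (length(object@stages) != n || length(object@absolute) != n ||
        length(object@relative) != n)
      msg <- c(msg, "stages, values, absolute, relative must share length")
    if (n > 0 && (any(object@values < 0) || any(object@values > 1)))
      msg <- c(msg, "component values must lie in [0, 1]")
    if (n > 0 && abs(sum(object@absolute) - object@total) > 1e-9)
      msg <- c(msg, "absolute contributions must sum to the total")
    if (is.null(msg)) TRUE else msg
  })

#' TransitionTally: directed within-bout plant-to-plant transition counts
#'
#' Counts of pollinator moves between consecutively visited plants within
#' foraging bouts, split by source/destination species: `aa` and `bb` are
#' conspecific (within-species) transitions, `ab` and `ba` heterospecific.
#' Direction is preserved even though published totals usually pool ab + ba.
#'
#' @slot aa,ab,ba,bb numeric(1) non-negative counts; first letter is the
#'   source species, second the destination.
#'
#' @seealso [tallyTransitions()], [batemanIndex()]
#' @export
setClass("TransitionTally",
  representation(aa = "numeric", ab = "numeric", ba = "numeric",
                 bb = "numeric"),
  validity = function(object) {
    cnt <- c(object@aa, object@ab, object@ba, object@bb)
    if (length(cnt) != 4L || any(!is.finite(cnt)) || any(cnt < 0))
      "aa, ab, ba, bb must be single non-negative finite counts"
    else TRUE
  })

#' FlowerSeason: one species' flowering interval
#'
#' @slot species character(1) species label.
#' @slot start,end `Date`(1); `start <= end`, same calendar year.
#'
#' @seealso [flowerSeason()], [overlapDays()], [riPhenology()]
#' @export
setClass("FlowerSeason",
  representation(species = "character", start = "Date", end = "Date"),
  validity = function(object) {
    if (length(object@start) != 1L || length(object@end) != 1L)
      return("start and end must be single dates")
    if (is.na(object@start) || is.na(object@end))
      return("start and end must not be NA")
    if (object@start > object@end)
      return("start must not be after end")
    if (format(object@start, "%Y") != format(object@end, "%Y"))
      return("cross-year seasons are not supported")
    TRUE
  })

#' GenotypeTable: allele-dosage matrix with population labels
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single `"dosage"`
#' assay is a loci × individuals matrix of 0/1/2/NA copies of a designated
#' reference allele, with a `population` column in `colData` taking values
#' `parentA`, `parentB` or `unknown`. Loci are assumed unlinked.
#'
#' @seealso [genotypeTable()], [perLocusFst()], [selectDiagnosticLoci()],
#'   [assignHybridClasses()]
#' @export
setClass("GenotypeTable", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
      return("a 'dosage' assay is required")
    d <- SummarizedExperiment::assay(object, "dosage")
    if (!all(d %in% c(0, 1, 2) | is.na(d)))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
    cd <- SummarizedExperiment::colData(object)
    if (!"population" %in% colnames(cd))
      msg <- c(msg, "colData must carry a 'population' column")
    else if (!all(cd$population %in% c("parentA", "parentB", "unknown")))
      msg <- c(msg, "population labels must be parentA, parentB or unknown")
    if (is.null(msg)) TRUE else msg
  })

#' HybridClassification: per-individual genotype-class posteriors
#'
#' Result of [assignHybridClasses()]: for each individual, posterior
#' probabilities over the six canonical classes (P1, P2, F1, F2, BC1, BC2),
#' the maximum-posterior class, the number of diagnostic loci used, the
#' hybrid index (fraction of diagnostic alleles from parentB) and the
#' interclass heterozygosity (fraction of called diagnostic loci that are
#' heterozygous).
#'
#' @slot calls a [S4Vectors::DataFrame] with one row per individual.
#' @slot panel character vector of diagnostic locus names used.
#' @slot epsilon numeric(1) genotyping-error rate assumed.
#' @slot prior named numeric(6) class prior.
#'
#' @export
setClass("HybridClassification",
  representation(calls = "DataFrame", panel = "character",
                 epsilon = "numeric", prior = "numeric"),
  validity = function(object) {
    msg <- NULL
    need <- c("individual", .hybridClasses, "best_class", "n_loci_used",
              "hybrid_index", "interclass_heterozygosity")
    if (!all(need %in% colnames(object@calls)))
      msg <- c(msg, "calls is missing required columns")
    if (length(object@epsilon) != 1L || object@epsilon < 0 ||
        object@epsilon >= 0.5)
      msg <- c(msg, "epsilon must be a single value in [0, 0.5)")
    if (!identical(sort(names(object@prior)), sort(.hybridClasses)))
      msg <- c(msg, "prior must be named by the six classes")
    if (is.null(msg)) TRUE else msg
  })
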