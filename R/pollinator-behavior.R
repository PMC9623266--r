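## Foraging-bout records and the tallies derived from them.
##
## Bouts are held as a plain data.frame with one row per plant visit, in
## visit order within bout:
##   bout_id, pollinator_taxon, plot_id, visit_order, plant_id,
##   species_label (A/B/H), flowers_probed
## A bout is one pollinator's entire visit to a plot; consecutive rows of a
## bout define transitions. Transitions are never counted across bouts.

.boutCols <- c("bout_id", "pollinator_taxon", "plot_id", "visit_order",
               "plant_id", "species_label", "flowers_probed")

#' Validate a bout table
#'
#' Checks the visit-level bout schema: required columns, species labels in
#' `A`/`B`/`H`, non-empty bouts, non-negative flower counts. Rows are
#' reordered by `bout_id` then `visit_order`.
#'
#' @param bouts data.frame of visits (see Details in [readBouts()]).
#' @return the validated, reordered data.frame.
#' @export
validateBouts <- function(bouts) {
  miss <- setdiff(.boutCols, colnames(bouts))
  if (length(miss) > 0)
    stop("bout table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(bouts) == 0)
    stop("bout table has no visits", call. = FALSE)
  if (!all(bouts$species_label %in% .speciesLabels))
    stop("unknown species label: labels must be one of ",
         paste(.speciesLabels, collapse = ", "), call. = FALSE)
  .checkNonNegative(bouts$flowers_probed, "flowers_probed")
  bouts[order(bouts$bout_id, bouts$visit_order), , drop = FALSE]
}

#' Read a pollinator-observation CSV
#'
#' One row per plant visit with the strict header `bout_id,
#' pollinator_taxon, plot_id, visit_order, plant_id, species_label,
#' flowers_probed`; species labels are `A`, `B` for the two study species
#' and `H` for hybrids. UTF-8, comma-delimited.
#'
#' @param path CSV file path.
#' @return a validated bout data.frame.
#' @export
readBouts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  validateBouts(df)
}

#' Tally within-bout transitions by species pair
#'
#' Counts every consecutive plant pair within each bout, split by
#' source/destination species. Hybrid-labelled visits (`H`) are dropped
#' before tallying in the default two-species mode (so an A,H,B bout
#' contributes one A->B transition); with `strict = TRUE` their presence is
#' an error.
#'
#' @param bouts a validated bout data.frame.
#' @param strict logical; error on hybrid labels instead of excluding them.
#' @return a [TransitionTally-class].
#' @export
#' @examples
#' b <- data.frame(bout_id = 1, pollinator_taxon = "honeybee", plot_id = "p",
#'                 visit_order = 1:4, plant_id = paste0("pl", 1:4),
#'                 species_label = c("A", "A", "B", "A"), flowers_probed = 1)
#' tallyTransitions(b)  # aa=1 ab=1 ba=1
tallyTransitions <- function(bouts, strict = FALSE) {
  bouts <- validateBouts(bouts)
  if (strict && any(bouts$species_label == "H"))
    stop("hybrid-labelled visits present in strict two-species mode",
         call. = FALSE)
  bouts <- bouts[bouts$species_label != "H", , drop = FALSE]
  counts <- c(AA = 0, AB = 0, BA = 0, BB = 0)
  if (nrow(bouts) > 0) {
    from <- bouts$species_label[-nrow(bouts)]
    to <- bouts$species_label[-1]
    same <- bouts$bout_id[-nrow(bouts)] == bouts$bout_id[-1]
    key <- paste0(from[same], to[same])
    tab <- table(factor(key, levels = names(counts)))
    counts <- counts + as.numeric(tab)
  }
  transitionTally(aa = counts[["AA"]], ab = counts[["AB"]],
                  ba = counts[["BA"]], bb = counts[["BB"]])
}

#' Classify bouts as conspecific or heterospecific
#'
#' A bout is heterospecific iff its visit sequence contains at least two
#' distinct species labels; single-species bouts (including single-visit
#' bouts) are conspecific.
#'
#' @param bouts a validated bout data.frame.
#' @return named numeric: `conspecific`, `heterospecific` counts.
#' @export
classifyBouts <- function(bouts) {
  bouts <- validateBouts(bouts)
  nSpecies <- tapply(bouts$species_label, bouts$bout_id,
                     function(x) length(unique(x)))
  c(conspecific = sum(nSpecies < 2), heterospecific = sum(nSpecies >= 2))
}

#' Visit preference for one species
#'
#' Proportion of all plant visits made to the given species label; the
#' preferences over all labels present sum to 1.
#'
#' @param bouts a validated bout data.frame.
#' @param species a species label (`"A"`, `"B"` or `"H"`).
#' @return numeric(1) in \[0, 1\].
#' @export
visitPreference <- function(bouts, species) {
  bouts <- validateBouts(bouts)
  mean(bouts$species_label == species)
}

#' Flowers probed per plant visit for one species
#'
#' Mean and standard deviation of `flowers_probed` over visits to the given
#' species — the per-visit geitonogamy summary.
#'
#' @param bouts a validated bout data.frame.
#' @param species a species label.
#' @param denominator `"n-1"` (sample sd, default) or `"n"` (population sd).
#' @return named numeric: `mean`, `sd`, `n`. `sd` is 0 for a single visit.
#' @export
flowersPerPlantSummary <- function(bouts, species,
                                   denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  bouts <- validateBouts(bouts)
  x <- bouts$flowers_probed[bouts$species_label == species]
  if (length(x) == 0)
    stop("no visits to species ", species, call. = FALSE)
  s <- if (length(x) == 1) 0 else stats::sd(x)
  if (denominator == "n")
    s <- sqrt(s^2 * (length(x) - 1) / length(x))
  c(mean = mean(x), sd = s, n = length(x))
}

#' Per-plot ethological summary
#'
#' Assembles, for the bouts of a single plot, the ingredients of the
#' ethological barrier — cross-species bouts of total bouts, heterospecific
#' transitions of total transitions — plus the directed transition tally,
#' and delegates to [riEthological()] and [batemanIndex()].
#'
#' @param bouts a validated bout data.frame from one plot.
#' @return a list with elements `crossBouts`, `totalBouts`,
#'   `hetTransitions`, `totalTransitions`, `tally` (a
#'   [TransitionTally-class]), `riEthological` and `batemanIndex` (NA when
#'   undefined).
#' @export
ethologicalSummary <- function(bouts) {
  bouts <- validateBouts(bouts)
  if (length(unique(bouts$plot_id)) > 1)
    stop("bouts must come from a single plot", call. = FALSE)
  cls <- classifyBouts(bouts)
  tal <- tallyTransitions(bouts)
  het <- tal@ab + tal@ba
  tot <- tal@aa + tal@ab + tal@ba + tal@bb
  ri <- if (sum(cls) > 0 && tot > 0)
    riEthological(cls[["heterospecific"]], sum(cls), het, tot) else NA_real_
  bi <- tryCatch(batemanIndex(tal), error = function(e) NA_real_)
  list(crossBouts = cls[["heterospecific"]], totalBouts = sum(cls),
       hetTransitions = het, totalTransitions = tot, tally = tal,
       riEthological = ri, batemanIndex = bi)
}
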