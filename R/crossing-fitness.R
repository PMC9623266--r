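## Hand-pollination outcomes: fruit set, seed set, postzygotic RI.
##
## Crossing records are rows of a plain data.frame:
##   maternal_species, pollen_species, treatment, flowers_pollinated,
##   fruits, seeds_total
## treatment is one of conspecific, heterospecific, geitonogamous,
## xenogamous. RI is computed on rates, not raw counts, so unequal flower
## numbers across treatments are handled correctly.

.crossCols <- c("maternal_species", "pollen_species", "treatment",
                "flowers_pollinated", "fruits", "seeds_total")
.treatments <- c("conspecific", "heterospecific", "geitonogamous",
                 "xenogamous")

#' Validate a crossing table
#'
#' @param crossings data.frame of hand-pollination records.
#' @return the validated data.frame.
#' @export
validateCrossings <- function(crossings) {
  miss <- setdiff(.crossCols, colnames(crossings))
  if (length(miss) > 0)
    stop("crossing table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(crossings$treatment %in% .treatments))
    stop("treatment must be one of ", paste(.treatments, collapse = ", "),
         call. = FALSE)
  .checkNonNegative(crossings$flowers_pollinated, "flowers_pollinated")
  .checkNonNegative(crossings$fruits, "fruits")
  .checkNonNegative(crossings$seeds_total, "seeds_total")
  if (any(crossings$fruits > crossings$flowers_pollinated))
    stop("invalid count: fruits exceed flowers_pollinated", call. = FALSE)
  crossings
}

#' Read a crossing CSV
#'
#' Columns: `maternal_species`, `pollen_species`, `treatment`,
#' `flowers_pollinated`, `fruits`, `seeds_total`.
#'
#' @param path CSV file path.
#' @return a validated crossing data.frame.
#' @export
readCrossings <- function(path) {
  validateCrossings(utils::read.csv(path, stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8"))
}

#' Fruit set per crossing record
#'
#' `fruits / flowers_pollinated`, vectorised over records.
#'
#' @param crossings a validated crossing data.frame.
#' @return numeric vector in \[0, 1\].
#' @export
#' @examples
#' r <- data.frame(maternal_species = "H", pollen_species = "H",
#'   treatment = "geitonogamous", flowers_pollinated = 35, fruits = 17,
#'   seeds_total = 33)
#' fruitSet(r)  # 0.4857
fruitSet <- function(crossings) {
  crossings <- validateCrossings(crossings)
  if (any(crossings$flowers_pollinated == 0))
    stop("undefined rate: zero flowers pollinated", call. = FALSE)
  crossings$fruits / crossings$flowers_pollinated
}

#' Seed set per crossing record
#'
#' Default is seeds per fruit (`seeds_total / fruits`). Reported hybrid
#' seed numbers with the flower count as n behave like per-flower means, so
#' the denominator is an explicit switch: `per = "flower"` gives
#' `seeds_total / flowers_pollinated`.
#'
#' @param crossings a validated crossing data.frame.
#' @param per `"fruit"` (default) or `"flower"`.
#' @return numeric vector, seeds per chosen denominator.
#' @export
seedsPerFruit <- function(crossings, per = c("fruit", "flower")) {
  per <- match.arg(per)
  crossings <- validateCrossings(crossings)
  den <- if (per == "fruit") crossings$fruits else
    crossings$flowers_pollinated
  if (any(den == 0))
    stop("undefined rate: zero ", per, "s in a record", call. = FALSE)
  crossings$seeds_total / den
}

#' Postzygotic barrier components from a conspecific/heterospecific pair
#'
#' Computes fruit-set and seed-set rates for the two records (which must
#' share the maternal species) and delegates to [riPostzygotic()] on each
#' pair of rates, returning both barriers as [BarrierComponent-class]
#' objects. Negative raw values (heterospecific crosses outperforming
#' conspecific ones) are clipped to 0 in `riValue()` and preserved
#' unclipped in `riValueRaw()`.
#'
#' @param conspecific,heterospecific single-row crossing data.frames.
#' @param seedPer denominator for the seed rate: `"flower"` (default) or
#'   `"fruit"`.
#' @return a list with elements `fruit` and `seed`.
#' @export
postzygoticComponents <- function(conspecific, heterospecific,
                                  seedPer = c("flower", "fruit")) {
  seedPer <- match.arg(seedPer)
  conspecific <- validateCrossings(conspecific)
  heterospecific <- validateCrossings(heterospecific)
  if (nrow(conspecific) != 1L || nrow(heterospecific) != 1L)
    stop("supply exactly one record per treatment", call. = FALSE)
  if (conspecific$maternal_species != heterospecific$maternal_species)
    stop("records must share the maternal species", call. = FALSE)
  cF <- fruitSet(conspecific)
  hF <- fruitSet(heterospecific)
  cS <- seedsPerFruit(conspecific, per = seedPer)
  hS <- seedsPerFruit(heterospecific, per = seedPer)
  list(
    fruit = barrierComponent("Fruit set", "postzygotic",
                             riPostzygotic(hF, cF, clip = FALSE)),
    seed = barrierComponent("Seed production", "postzygotic",
                            riPostzygotic(hS, cS, clip = FALSE)))
}
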