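## Stage-specific reproductive-isolation statistics. All four are pure
## functions of counts or proportions; the formulas are scale-invariant, so
## S/U and H/C may be supplied as raw counts or as rates.

#' Co-occurrence barrier index
#'
#' The prezygotic barrier statistic \eqn{RI = 1 - S/(S+U)}, where `S` is the
#' degree to which some factor (space, florescence, pollinators) is shared
#' between the two species and `U` the unshared part, both from the focal
#' species' point of view. 0 means the factor is fully shared (no barrier),
#' 1 fully unshared (complete barrier).
#'
#' @param shared non-negative number `S`.
#' @param unshared non-negative number `U`; `S + U` must be positive.
#' @return numeric(1) in \[0, 1\].
#' @export
#' @examples
#' riCooccurrence(56, 20)  # 56 shared flowering days of a 76-day season
riCooccurrence <- function(shared, unshared) {
  .checkNonNegative(c(shared, unshared), "shared/unshared")
  if (shared + unshared == 0)
    stop("undefined barrier: shared + unshared must be positive",
         call. = FALSE)
  1 - shared / (shared + unshared)
}

#' Pollinator-assemblage barrier index
#'
#' Applies [riCooccurrence()] to visit counts grouped by pollinator taxon:
#' `S` is the number of visits the focal species received from taxa that
#' also visit the other species, `U` the visits from taxa unique to the
#' focal species.
#'
#' @param visitsFocal named numeric vector, visits to the focal species per
#'   pollinator taxon.
#' @param visitsOther named numeric vector, visits to the other species per
#'   pollinator taxon (only its names matter).
#' @return numeric(1) in \[0, 1\].
#' @export
#' @examples
#' castanea <- c(honeybee = 194, bumblebee = 21, anthophora = 3, eristalis = 1)
#' flava <- c(honeybee = 169, bumblebee = 7)
#' riPollinatorAssemblage(castanea, flava)  # 1 - 215/219
riPollinatorAssemblage <- function(visitsFocal, visitsOther) {
  if (is.null(names(visitsFocal)) || is.null(names(visitsOther)))
    stop("visit counts must be named by pollinator taxon", call. = FALSE)
  .checkNonNegative(visitsFocal, "visit counts")
  if (sum(visitsFocal) == 0)
    stop("undefined barrier: no visits to the focal species", call. = FALSE)
  sharedTaxa <- names(visitsFocal) %in%
    names(visitsOther)[visitsOther > 0] & visitsFocal > 0
  riCooccurrence(sum(visitsFocal[sharedTaxa]),
                 sum(visitsFocal[!sharedTaxa]))
}

#' Ethological (pollinator-behavior) barrier index
#'
#' \eqn{RI = 1 - (\mathrm{cross\ bouts}/\mathrm{total\ bouts}) \times
#' (\mathrm{heterospecific\ transitions}/\mathrm{total\ transitions})}.
#' A bout is one pollinator's entire visit to a plot; a transition is a move
#' between two plants within a bout. The index is 1 exactly when either
#' factor is zero, i.e. pollinators never carry pollen across species.
#'
#' @param crossBouts number of bouts visiting both species.
#' @param totalBouts total number of bouts (> 0).
#' @param hetTransitions number of between-species transitions.
#' @param totalTransitions total transitions (> 0).
#' @return numeric in \[0, 1\], vectorised over the counts.
#' @export
#' @examples
#' riEthological(4, 52, 5, 70)    # 0.9945
#' riEthological(8, 129, 9, 203)  # 0.9973
riEthological <- function(crossBouts, totalBouts, hetTransitions,
                          totalTransitions) {
  .checkNonNegative(c(crossBouts, totalBouts, hetTransitions,
                      totalTransitions), "bout/transition counts")
  if (any(totalBouts == 0) || any(totalTransitions == 0))
    stop("undefined barrier: zero total bouts or transitions", call. = FALSE)
  if (any(crossBouts > totalBouts) || any(hetTransitions > totalTransitions))
    stop("invalid count: part exceeds total", call. = FALSE)
  1 - (crossBouts / totalBouts) * (hetTransitions / totalTransitions)
}

#' Postzygotic barrier index
#'
#' \eqn{RI = 1 - 2H/(H+C)} with `H` and `C` the heterospecific and
#' conspecific mating success (e.g. fruit-set or seed-set rates). The raw
#' value lies in \[-1, 1\]; it is negative when heterospecific crosses
#' outperform conspecific ones, and by default such values are clipped to 0
#' for reporting (no barrier), with the raw value available via
#' `clip = FALSE`.
#'
#' @param heterospecific non-negative `H` (count or rate).
#' @param conspecific non-negative `C`; `H + C` must be positive.
#' @param clip logical; clip negative results to 0 (default `TRUE`).
#' @return numeric(1) in \[0, 1\] (clipped) or \[-1, 1\] (raw).
#' @export
#' @examples
#' riPostzygotic(0.5714, 0.60)               # 0.0244
#' riPostzygotic(0.80, 0.60, clip = FALSE)   # negative raw value
riPostzygotic <- function(heterospecific, conspecific, clip = TRUE) {
  .checkNonNegative(c(heterospecific, conspecific), "H/C")
  if (heterospecific + conspecific == 0)
    stop("undefined barrier: H + C must be positive", call. = FALSE)
  raw <- 1 - 2 * heterospecific / (heterospecific + conspecific)
  if (clip) max(0, raw) else raw
}

#' Construct a BarrierComponent
#'
#' Wraps a raw barrier value with its stage labels, applying the clipping
#' policy (negative raw values reported as 0) while preserving the raw value.
#'
#' @param stage character(1) stage label.
#' @param stageClass `"prezygotic"` or `"postzygotic"`.
#' @param valueRaw numeric(1) unclipped statistic.
#' @param clip logical; apply the clip-at-zero policy (default `TRUE`).
#' @return a [BarrierComponent-class] object.
#' @export
#' @examples
#' barrierComponent("Fruit set", "postzygotic", -0.167)
barrierComponent <- function(stage, stageClass = c("prezygotic",
                             "postzygotic"), valueRaw, clip = TRUE) {
  stageClass <- match.arg(stageClass)
  value <- if (clip) max(0, valueRaw) else valueRaw
  new("BarrierComponent", stage = as.character(stage),
      stageClass = stageClass, valueRaw = valueRaw, value = value)
}

#' Construct a TransitionTally
#'
#' @param aa,ab,ba,bb non-negative transition counts; first letter = source
#'   species, second = destination.
#' @return a [TransitionTally-class] object.
#' @export
transitionTally <- function(aa = 0, ab = 0, ba = 0, bb = 0) {
  new("TransitionTally", aa = as.numeric(aa), ab = as.numeric(ab),
      ba = as.numeric(ba), bb = as.numeric(bb))
}

.batemanCore <- function(aa, ab, ba, bb) {
  .checkNonNegative(c(aa, ab, ba, bb), "transition counts")
  con <- sqrt(aa * bb)
  het <- sqrt(ab * ba)
  if (con + het == 0)
    stop("undefined index: both within- and between-species products are 0",
         call. = FALSE)
  (con - het) / (con + het)
}

#' @rdname batemanIndex
#' @export
setMethod("batemanIndex", "TransitionTally", function(x, ab, ba, bb) {
  .batemanCore(x@aa, x@ab, x@ba, x@bb)
})

#' @rdname batemanIndex
#' @export
setMethod("batemanIndex", "numeric", function(x, ab, ba, bb) {
  .batemanCore(x, ab, ba, bb)
})

## accessors and show -------------------------------------------------------

#' @rdname BarrierComponent-class
#' @export
setMethod("stageName", "BarrierComponent", function(x) x@stage)

#' @rdname BarrierComponent-class
#' @export
setMethod("stageClass", "BarrierComponent", function(x) x@stageClass)

#' @rdname BarrierComponent-class
#' @export
setMethod("riValue", "BarrierComponent", function(x) x@value)

#' @rdname BarrierComponent-class
#' @export
setMethod("riValueRaw", "BarrierComponent", function(x) x@valueRaw)

setMethod("show", "BarrierComponent", function(object) {
  cat("BarrierComponent:", object@stage, sprintf("(%s)\n", object@stageClass))
  cat("  RI =", roundHalfUp(object@value, 4))
  if (object@valueRaw < 0)
    cat(sprintf("  (raw %s, clipped)", roundHalfUp(object@valueRaw, 4)))
  cat("\n")
})

setMethod("show", "TransitionTally", function(object) {
  cat("TransitionTally (source -> destination)\n")
  m <- matrix(c(object@aa, object@ab, object@ba, object@bb), 2, 2,
              byrow = TRUE, dimnames = list(c("A", "B"), c("A", "B")))
  print(m)
  cat("total:", sum(m), "\n")
})
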