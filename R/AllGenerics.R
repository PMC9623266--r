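#' @rdname BarrierComponent-class
#' @param object,x an object.
#' @export
setGeneric("stageName", function(x) standardGeneric("stageName"))

#' @rdname BarrierComponent-class
#' @export
setGeneric("stageClass", function(x) standardGeneric("stageClass"))

#' @rdname BarrierComponent-class
#' @export
setGeneric("riValue", function(x) standardGeneric("riValue"))

#' @rdname BarrierComponent-class
#' @export
setGeneric("riValueRaw", function(x) standardGeneric("riValueRaw"))

#' @rdname CascadeResult-class
#' @param x an object.
#' @export
setGeneric("absoluteContributions",
           function(x) standardGeneric("absoluteContributions"))

#' @rdname CascadeResult-class
#' @export
setGeneric("relativeContributions",
           function(x) standardGeneric("relativeContributions"))

#' @rdname CascadeResult-class
#' @export
setGeneric("totalRI", function(x) standardGeneric("totalRI"))

#' Bateman's floral-constancy index
#'
#' \eqn{BI = (\sqrt{aa \cdot bb} - \sqrt{ab \cdot ba}) /
#'           (\sqrt{aa \cdot bb} + \sqrt{ab \cdot ba})}
#' from the directed transition tally, where `aa`/`bb` are within-species
#' and `ab`/`ba` heterospecific transitions. Ranges from -1 (complete
#' inconstancy) through 0 (random foraging) to +1 (complete constancy).
#'
#' @param x a [TransitionTally-class] object, or the `aa` count.
#' @param ab,ba,bb counts when `x` is given as the `aa` count.
#' @return numeric(1) in \[-1, 1\].
#' @export
#' @examples
#' batemanIndex(30, 2, 3, 35)
#' batemanIndex(transitionTally(10, 0, 0, 10))  # complete constancy: +1
setGeneric("batemanIndex", function(x, ab, ba, bb)
  standardGeneric("batemanIndex"))

#' @rdname GenotypeTable-class
#' @param x an object.
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname GenotypeTable-class
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname HybridClassification-class
#' @param x an object.
#' @export
setGeneric("hybridCalls", function(x) standardGeneric("hybridCalls"))
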