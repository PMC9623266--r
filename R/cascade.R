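## Sequential combination of ordered barriers into total RI.
##
## Barriers act in life-history order: stage n can only block the gene flow
## that survived stages 1..n-1, so its absolute contribution is
##   AC_n = v_n * prod_{i<n} (1 - v_i)
## and the total T = sum AC_n = 1 - prod (1 - v_i). Relative contributions
## RC_n = AC_n / T partition T.

#' Sequential absolute and relative contributions of ordered barriers
#'
#' @param values numeric vector of component RI values in \[0, 1\], in
#'   life-history order, or a list of [BarrierComponent-class] objects
#'   (their clipped values are used).
#' @param stages optional character stage labels (taken from the components
#'   when a list is supplied).
#' @param scenario character(1) label stored with the result, e.g.
#'   `"allopatric"` or `"sympatric"`.
#' @return a [CascadeResult-class].
#' @export
#' @examples
#' ## a four-stage prezygotic cascade
#' cr <- sequentialContributions(c(0.81, 0.13, 0, 0.9945),
#'   stages = c("Geographic", "Phenology", "Pollinator assemblage",
#'              "Pollinator ethological"))
#' absoluteContributions(cr)  # 0.81 0.0247 0 0.1644
#' totalRI(cr)                # 0.9991
sequentialContributions <- function(values, stages = NULL,
                                    scenario = "allopatric") {
  if (is.list(values)) {
    if (!all(vapply(values, is, TRUE, "BarrierComponent")))
      stop("list input must contain BarrierComponent objects", call. = FALSE)
    if (is.null(stages))
      stages <- vapply(values, stageName, character(1))
    values <- vapply(values, riValue, numeric(1))
  }
  if (length(values) == 0)
    stop("at least one component is required", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("invalid component: values must lie in [0, 1]", call. = FALSE)
  if (is.null(stages))
    stages <- paste0("stage", seq_along(values))

  surviving <- cumprod(1 - values)          # gene flow remaining after stage n
  before <- c(1, surviving[-length(values)]) # ... remaining before stage n
  ac <- values * before
  total <- sum(ac)
  rc <- if (total > 0) ac / total else rep(NA_real_, length(ac))
  new("CascadeResult", stages = as.character(stages), values = values,
      absolute = ac, total = total, relative = rc,
      scenario = as.character(scenario))
}

#' @rdname CascadeResult-class
#' @export
setMethod("absoluteContributions", "CascadeResult", function(x) {
  stats::setNames(x@absolute, x@stages)
})

#' @rdname CascadeResult-class
#' @export
setMethod("relativeContributions", "CascadeResult", function(x) {
  stats::setNames(x@relative, x@stages)
})

#' @rdname CascadeResult-class
#' @export
setMethod("totalRI", "CascadeResult", function(x) x@total)

#' @rdname CascadeResult-class
#' @export
setMethod("stageName", "CascadeResult", function(x) x@stages)

#' @rdname CascadeResult-class
#' @export
setMethod("riValue", "CascadeResult", function(x) {
  stats::setNames(x@values, x@stages)
})

setMethod("show", "CascadeResult", function(object) {
  cat(sprintf("CascadeResult (%s), %d stages\n", object@scenario,
              length(object@values)))
  df <- data.frame(stage = object@stages,
                   component = roundHalfUp(object@values, 4),
                   AC = roundHalfUp(object@absolute, 4),
                   RC = roundHalfUp(object@relative, 4))
  print(df, row.names = FALSE)
  cat("Total RI:", roundHalfUp(object@total, 4), "\n")
})

#' Two-species barrier-contribution table
#'
#' Builds the standard report: one row per barrier stage with each species'
#' component value and absolute contribution under the full (allopatric)
#' cascade and under a sympatric cascade that drops the stages flagged
#' `allopatric_only` (typically the geographic stage), plus `Total` rows per
#' stage class. Prezygotic and postzygotic cascades are kept separate.
#'
#' @param components a data.frame with columns `stage`, `stage_class`
#'   (`"prezygotic"`/`"postzygotic"`), one value column per species (all in
#'   life-history order, both species sharing the ordering) and optionally
#'   `allopatric_only` (logical; default only stages named `"Geographic"`).
#' @param speciesCols character(2), names of the two value columns.
#' @param digits decimal places for display rounding (default 4).
#' @param sumRounded logical; when `TRUE`, `Total` rows are the sum of the
#'   rounded per-stage contributions rather than the rounded sum of
#'   unrounded contributions. Published tables sometimes follow the former
#'   path, so both are offered; the default is `FALSE` (round last).
#' @return a data.frame with columns stage, stage_class, per-species
#'   component values, and per-species AC columns for both scenarios;
#'   `Total` rows carry NA components.
#' @export
#' @examples
#' comp <- data.frame(
#'   stage = c("Geographic", "Phenology", "Fruit set"),
#'   stage_class = c("prezygotic", "prezygotic", "postzygotic"),
#'   flava = c(0.81, 0.13, 0), castanea = c(0.88, 0.26, 0.0244))
#' riTable(comp, speciesCols = c("flava", "castanea"))
riTable <- function(components, speciesCols, digits = 4,
                    sumRounded = FALSE) {
  need <- c("stage", "stage_class", speciesCols)
  if (!all(need %in% colnames(components)))
    stop("components must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(components$stage_class %in% c("prezygotic", "postzygotic")))
    stop("stage_class must be 'prezygotic' or 'postzygotic'", call. = FALSE)
  alloOnly <- if ("allopatric_only" %in% colnames(components))
    as.logical(components$allopatric_only)
  else components$stage == "Geographic"

  rnd <- function(x) roundHalfUp(x, digits)
  out <- NULL
  for (cls in unique(components$stage_class)) {
    sub <- components[components$stage_class == cls, , drop = FALSE]
    subAllo <- alloOnly[components$stage_class == cls]
    block <- data.frame(stage = sub$stage, stage_class = cls)
    for (sp in speciesCols)
      block[[sp]] <- rnd(sub[[sp]])
    for (sp in speciesCols) {
      cr <- sequentialContributions(sub[[sp]], sub$stage, "allopatric")
      block[[paste0("AC_", sp)]] <- rnd(cr@absolute)
    }
    for (sp in speciesCols) {
      keep <- !subAllo
      acSym <- rep(NA_real_, nrow(sub))
      if (any(keep)) {
        cr <- sequentialContributions(sub[[sp]][keep], sub$stage[keep],
                                      "sympatric")
        acSym[keep] <- cr@absolute
      }
      block[[paste0("AC_sympatric_", sp)]] <- rnd(acSym)
    }
    totalRow <- block[1, , drop = FALSE]
    totalRow$stage <- "Total"
    for (sp in speciesCols)
      totalRow[[sp]] <- NA_real_
    for (col in grep("^AC_", colnames(block), value = TRUE)) {
      vals <- block[[col]]
      totalRow[[col]] <- if (sumRounded) rnd(sum(vals, na.rm = TRUE)) else {
        ## recompute the unrounded total along the same cascade
        raw <- if (startsWith(col, "AC_sympatric_")) {
          sp <- sub("^AC_sympatric_", "", col)
          keep <- !subAllo
          if (any(keep))
            sequentialContributions(sub[[sp]][keep])@total else NA_real_
        } else {
          sp <- sub("^AC_", "", col)
          sequentialContributions(sub[[sp]])@total
        }
        rnd(raw)
      }
    }
    out <- rbind(out, block, totalRow)
  }
  rownames(out) <- NULL
  out
}

#' Format a barrier-contribution table as aligned text
#'
#' @param tab a data.frame from [riTable()].
#' @return character(1): the table rendered as aligned plain text.
#' @export
formatRITable <- function(tab) {
  fmt <- tab
  num <- vapply(fmt, is.numeric, TRUE)
  fmt[num] <- lapply(fmt[num], function(x)
    ifelse(is.na(x), "", formatC(x, format = "fg", digits = 8)))
  widths <- pmax(nchar(colnames(fmt)),
                 apply(vapply(fmt, as.character,
                              character(nrow(fmt))), 2, function(x)
                   max(nchar(x))))
  pad <- function(x, w) formatC(x, width = w + 2, flag = "-")
  lines <- paste0(mapply(pad, colnames(fmt), widths), collapse = "")
  for (i in seq_len(nrow(fmt)))
    lines <- c(lines, paste0(mapply(pad, as.character(unlist(fmt[i, ])),
                                    widths), collapse = ""))
  paste(lines, collapse = "\n")
}

#' Write a barrier-contribution table as TSV
#'
#' @param tab a data.frame from [riTable()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeRITable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
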