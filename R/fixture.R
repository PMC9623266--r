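#' Published field summaries for the S. flava / S. castanea hybrid zone
#'
#' Loads the packaged summary tables reported for the alpine
#' *Salvia flava* – *S. castanea* hybrid zone on the Qinghai-Tibet Plateau:
#' per-stage barrier component values for both species, pollinator visit
#' counts by taxon, per-plot bout/transition tallies, and the two flowering
#' seasons. These are the printed inputs from which the barrier cascade
#' and its acceptance checks are recomputed; no raw field or sequencing
#' data are included.
#'
#' Two reported values deserve care. The *S. flava* phenology component is
#' stored as its reported 0.13 even though the reported flowering dates
#' yield 0.18 under inclusive day counting (see the package vignette); and
#' the geographic component for *S. flava* is stored as the 0.81 used in
#' the contribution table rather than the 0.83 quoted in the running text.
#'
#' @return a list with elements:
#' \describe{
#'   \item{components}{data.frame for [riTable()]: `stage`, `stage_class`,
#'     `flava`, `castanea`, `allopatric_only`.}
#'   \item{visitCounts}{data.frame of visits per species × pollinator
#'     taxon.}
#'   \item{plotTallies}{data.frame of per-plot bout and transition counts
#'     for [riEthological()].}
#'   \item{seasons}{named list of [FlowerSeason-class] objects.}
#' }
#' @export
#' @examples
#' fx <- salviaFixture()
#' riTable(fx$components, speciesCols = c("flava", "castanea"))
salviaFixture <- function() {
  path <- function(f) system.file("extdata", f, package = "hybridRI",
                                  mustWork = TRUE)
  list(
    components = utils::read.csv(path("salvia_ri_components.csv"),
                                 stringsAsFactors = FALSE),
    visitCounts = utils::read.csv(path("salvia_visit_counts.csv"),
                                  stringsAsFactors = FALSE),
    plotTallies = utils::read.csv(path("salvia_plot_tallies.csv"),
                                  stringsAsFactors = FALSE),
    seasons = readSeasons(path("salvia_seasons.csv")))
}
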