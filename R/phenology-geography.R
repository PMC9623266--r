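## Flowering-season overlap and occurrence-record sympatry.

#' Construct a FlowerSeason
#'
#' @param species character(1) species label.
#' @param start,end dates (`Date` or ISO-8601 strings) within one calendar
#'   year, `start <= end`.
#' @return a [FlowerSeason-class].
#' @export
#' @examples
#' flowerSeason("castanea", "2019-08-01", "2019-10-15")
flowerSeason <- function(species, start, end) {
  new("FlowerSeason", species = as.character(species),
      start = as.Date(start), end = as.Date(end))
}

setMethod("show", "FlowerSeason", function(object) {
  cat(sprintf("FlowerSeason: %s, %s to %s (%d days)\n", object@species,
              format(object@start), format(object@end),
              as.integer(object@end - object@start) + 1L))
})

#' Season length in days, inclusive of both endpoints
#'
#' @param season a [FlowerSeason-class].
#' @return integer day count.
#' @export
seasonDays <- function(season) {
  as.integer(season@end - season@start) + 1L
}

#' Inclusive overlap of two flowering seasons, in days
#'
#' Day counting includes both endpoints: seasons sharing a single day
#' overlap by 1 day. Seasons must fall in the same calendar year.
#'
#' @param a,b [FlowerSeason-class] objects.
#' @return integer; 0 when disjoint.
#' @export
#' @examples
#' fl <- flowerSeason("flava", "2019-07-20", "2019-09-25")
#' ca <- flowerSeason("castanea", "2019-08-01", "2019-10-15")
#' overlapDays(fl, ca)  # 56
overlapDays <- function(a, b) {
  stopifnot(is(a, "FlowerSeason"), is(b, "FlowerSeason"))
  if (format(a@start, "%Y") != format(b@start, "%Y"))
    stop("unsupported range: seasons must be in the same year",
         call. = FALSE)
  lo <- max(a@start, b@start)
  hi <- min(a@end, b@end)
  max(0L, as.integer(hi - lo) + 1L)
}

#' Phenological barrier index
#'
#' [riCooccurrence()] on flowering days: `S` is the inclusive overlap with
#' the other species' season, `U` the focal species' remaining season days,
#' so `S + U` is the focal species' inclusive season length. Flowering time
#' outside the overlap is reproductively wasted on the other species, hence
#' a barrier from the focal species' point of view.
#'
#' @param focal,other [FlowerSeason-class] objects.
#' @return numeric(1) in \[0, 1\]; 0 iff the focal season lies entirely
#'   within the overlap.
#' @export
#' @examples
#' fl <- flowerSeason("flava", "2019-07-20", "2019-09-25")
#' ca <- flowerSeason("castanea", "2019-08-01", "2019-10-15")
#' riPhenology(ca, fl)  # 1 - 56/76 = 0.2632
riPhenology <- function(focal, other) {
  len <- seasonDays(focal)
  if (len <= 0)
    stop("undefined barrier: zero-length focal season", call. = FALSE)
  s <- overlapDays(focal, other)
  riCooccurrence(s, len - s)
}

#' Great-circle distance in kilometres
#'
#' Spherical haversine distance on a 6371-km-radius sphere (differences
#' from a geodesic ellipsoid are far below the 7-km sympatry threshold's
#' granularity). Vectorised over coordinates.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return numeric distance(s) in km.
#' @export
#' @examples
#' haversineKm(27, 100, 28, 100)  # ~111.19 km per degree of latitude
haversineKm <- function(lat1, lon1, lat2, lon2) {
  .checkCoords(lat1, lon1)
  .checkCoords(lat2, lon2)
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371) # km
}

.checkCoords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(abs(lat) > 90) || any(abs(lon) > 180))
    stop("invalid coordinates: |lat| <= 90 and |lon| <= 180 required",
         call. = FALSE)
  invisible(NULL)
}

.checkOccurrences <- function(records, what = "records") {
  need <- c("species", "latitude", "longitude")
  if (!all(need %in% colnames(records)))
    stop(what, " must have columns species, latitude, longitude",
         call. = FALSE)
  .checkCoords(records$latitude, records$longitude)
  if ("elevation_m" %in% colnames(records)) {
    elev <- records$elevation_m
    if (any(elev[!is.na(elev)] < 0))
      stop("elevation_m must be non-negative", call. = FALSE)
  }
  invisible(records)
}

#' Geographic barrier index under a sympatry radius
#'
#' A focal occurrence record is sympatric iff at least one heterospecific
#' record lies within `radiusKm` (default 7 km) great-circle distance;
#' the index is the allopatric fraction of focal records,
#' `1 - sympatric/total` (= [riCooccurrence()] with `S` the sympatric and
#' `U` the allopatric count).
#'
#' @param recordsFocal,recordsOther data.frames with columns `species`,
#'   `latitude`, `longitude` (decimal degrees); `recordsFocal` non-empty.
#' @param radiusKm sympatry radius in kilometres (default 7).
#' @return numeric(1) in \[0, 1\].
#' @export
riGeographic <- function(recordsFocal, recordsOther, radiusKm = 7) {
  .checkOccurrences(recordsFocal, "recordsFocal")
  .checkOccurrences(recordsOther, "recordsOther")
  if (nrow(recordsFocal) == 0)
    stop("undefined barrier: no focal records", call. = FALSE)
  if (nrow(recordsOther) == 0)
    return(1)
  sympatric <- vapply(seq_len(nrow(recordsFocal)), function(i) {
    d <- haversineKm(recordsFocal$latitude[i], recordsFocal$longitude[i],
                     recordsOther$latitude, recordsOther$longitude)
    any(d <= radiusKm)
  }, logical(1))
  riCooccurrence(sum(sympatric), sum(!sympatric))
}

#' Elevation summary of occurrence records
#'
#' @param records data.frame with an `elevation_m` column; records with
#'   missing elevation are skipped.
#' @return named numeric: `mean`, `min`, `max`, `n` over records with
#'   elevation present.
#' @export
elevationSummary <- function(records) {
  if (!"elevation_m" %in% colnames(records))
    stop("records have no elevation_m column", call. = FALSE)
  elev <- records$elevation_m[!is.na(records$elevation_m)]
  if (length(elev) == 0)
    stop("undefined summary: no records with elevation", call. = FALSE)
  c(mean = mean(elev), min = min(elev), max = max(elev), n = length(elev))
}

#' Flag exact coordinate duplicates
#'
#' De-duplication of repeated specimen records is the caller's decision;
#' this helper flags rows whose (species, latitude, longitude) repeat an
#' earlier row exactly.
#'
#' @param records an occurrence data.frame.
#' @return logical vector, `TRUE` for duplicated rows.
#' @export
flagDuplicateRecords <- function(records) {
  .checkOccurrences(records)
  duplicated(records[, c("species", "latitude", "longitude")])
}

#' Read an occurrence CSV
#'
#' Columns: `species`, `latitude`, `longitude`, optional `elevation_m`.
#'
#' @param path CSV file path.
#' @return a validated occurrence data.frame.
#' @export
readOccurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  .checkOccurrences(df)
  df
}

#' Read a flowering-season CSV
#'
#' Columns: `species`, `start_date`, `end_date` (ISO-8601).
#'
#' @param path CSV file path.
#' @return a named list of [FlowerSeason-class] objects, one per row.
#' @export
readSeasons <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("species", "start_date", "end_date")
  if (!all(need %in% colnames(df)))
    stop("season table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    flowerSeason(df$species[i], df$start_date[i], df$end_date[i]))
  stats::setNames(out, df$species)
}
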