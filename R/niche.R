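#' The 20 bioclimatic niche variables
#'
#' The 19 standard bioclimatic variables plus altitude, with their BIO codes
#' and default trait classes: altitude (A), temperature (T, BIO1-BIO11) and
#' precipitation (P, BIO12-BIO19).
#'
#' @return A data frame with columns \code{variable}, \code{code} and
#'   \code{class}.
#' @export
bioclimVariables <- function() {
  data.frame(
    variable = c("Altitude",
      "Annual Mean Temperature", "Mean Diurnal Range", "Isothermality",
      "Temperature Seasonality", "Max Temperature of Warmest Month",
      "Min Temperature of Coldest Month", "Temperature Annual Range",
      "Mean Temperature of Wettest Quarter",
      "Mean Temperature of Driest Quarter",
      "Mean Temperature of Warmest Quarter",
      "Mean Temperature of Coldest Quarter",
      "Annual Precipitation", "Precipitation of Wettest Month",
      "Precipitation of Driest Month", "Precipitation Seasonality",
      "Precipitation of Wettest Quarter", "Precipitation of Driest Quarter",
      "Precipitation of Warmest Quarter",
      "Precipitation of Coldest Quarter"),
    code = c("alt", paste0("bio", 1:19)),
    class = c("A", rep("T", 11L), rep("P", 8L)),
    row.names = NULL)
}

#' Default trait-class map
#'
#' @return Named character vector, variable name -> class letter (A/T/P),
#'   covering the 20 niche variables.
#' @export
defaultTraitClasses <- function() {
  v <- bioclimVariables()
  stats::setNames(v$class, v$variable)
}

#' Load and validate a trait-class map
#'
#' Reads a two-column CSV (\code{variable}, \code{class}) assigning each of
#' the 20 niche variables to altitude (A), temperature (T) or precipitation
#' (P).
#'
#' @param path CSV path; when \code{NULL} the packaged default is returned.
#' @return Named character vector, variable name -> class letter.
#' @export
loadTraitClasses <- function(path = NULL) {
  if (is.null(path)) return(defaultTraitClasses())
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("variable", "class") %in% names(df)))
    stop("class map must have columns 'variable' and 'class'")
  bad <- setdiff(df$class, c("A", "T", "P"))
  if (length(bad)) stop(sprintf("unknown trait class '%s'", bad[1L]))
  dup <- df$variable[duplicated(df$variable)]
  if (length(dup)) stop(sprintf("duplicate variable '%s'", dup[1L]))
  missing <- setdiff(bioclimVariables()$variable, df$variable)
  if (length(missing))
    stop(sprintf("class map is missing variable '%s'", missing[1L]))
  extra <- setdiff(df$variable, bioclimVariables()$variable)
  if (length(extra))
    stop(sprintf("unknown variable '%s' in class map", extra[1L]))
  stats::setNames(df$class, df$variable)
}

#' Build the per-haplotype niche table
#'
#' Averages each niche variable over all individuals carrying a haplotype;
#' the resulting row is the mean climatic profile of the haplotype's
#' geographic range.
#'
#' @param individuals Data frame with columns \code{individual_id},
#'   \code{lon}, \code{lat} and one column per niche variable.
#' @param membership Named character vector, individual id -> haplotype id
#'   (as in \code{membership(collapseHaplotypes(...))}).
#' @return A \linkS4class{NicheTable}; rows ordered by first appearance of
#'   each haplotype id in \code{membership}.
#' @export
buildNicheTable <- function(individuals, membership) {
  req <- c("individual_id", "lon", "lat")
  if (!all(req %in% names(individuals)))
    stop("individuals must have columns individual_id, lon, lat")
  if (anyDuplicated(individuals$individual_id))
    stop("duplicate individual_id in table")
  onlyTable <- setdiff(individuals$individual_id, names(membership))
  if (length(onlyTable))
    stop(sprintf("individual '%s' has no haplotype assignment", onlyTable[1L]))
  onlyMember <- setdiff(names(membership), individuals$individual_id)
  if (length(onlyMember))
    stop(sprintf("individual '%s' is missing from the table", onlyMember[1L]))
  if (any(abs(individuals$lon) > 180) || any(abs(individuals$lat) > 90))
    stop("coordinates outside valid longitude/latitude ranges")
  vars <- setdiff(names(individuals), req)
  if (length(vars) == 0L) stop("no niche variable columns found")
  for (v in vars) {
    bad <- which(!is.finite(individuals[[v]]))
    if (length(bad))
      stop(sprintf("missing value of '%s' for individual '%s'",
                   v, individuals$individual_id[bad[1L]]))
  }
  hap <- membership[individuals$individual_id]
  hids <- unique(unname(membership))
  m <- as.matrix(individuals[, vars, drop = FALSE])
  sums <- rowsum(m, group = hap)
  ncar <- as.integer(table(factor(hap, levels = rownames(sums))))
  means <- sums / ncar
  means <- means[hids, , drop = FALSE]
  new("NicheTable", values = means,
      nCarriers = stats::setNames(
        ncar[match(hids, rownames(sums))], hids))
}
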