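#' Published per-variable signed PSR areas for the two genera
#'
#' The printed per-variable PSR areas (two decimals) for *Calibrachoa* and
#' *Petunia* chloroplast haplotypes, shipped with the package so that the
#' class-level summaries can be recomputed without the original sequence
#' and climate data.
#'
#' @return Data frame with columns \code{variable}, \code{class},
#'   \code{calibrachoa}, \code{petunia}.
#' @export
publishedPSRAreas <- function() {
  utils::read.csv(system.file("extdata", "published_psr_areas.csv",
                              package = "psrniche", mustWork = TRUE),
                  check.names = FALSE)
}
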