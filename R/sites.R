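#' Site metadata for the 17-chronology southeast Tibetan Plateau network
#'
#' Descriptive characteristics of the published high-elevation tree-ring
#' network the package's analysis targets: site coordinates, altitude,
#' reliable time span (SSS > 0.85), replication, mean sensitivity and mean
#' segment length for 17 chronologies from four conifer species.
#'
#' @return data.frame with one row per site.
#' @export
site_network_summary <- function() {
  path <- system.file("extdata", "setp_sites.tsv", package = "ringsync")
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Species means of per-site mean segment length
#'
#' Averages the per-site mean segment lengths of [site_network_summary()]
#' within each species.
#'
#' @return named numeric vector of species means (years).
#' @export
species_segment_means <- function() {
  x <- site_network_summary()
  tapply(x$mean_segment_length, x$species, mean)
}
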