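#' Pairwise geographic distances
#'
#' Planar tables use Euclidean distance on (x, y); lon/lat tables use
#' great-circle (haversine) distance on a sphere of radius 6,371,008.8 m
#' (the IUGG mean Earth radius), via the geosphere package. Units are metres
#' in both modes.
#'
#' @param table an `indiv_table` with complete coordinates.
#' @return symmetric numeric matrix of distances (m) with zero diagonal and
#'   `id` dimnames; attribute `mode` records `"planar"` or `"geodesic"`.
#' @export
pairwise_distances <- function(table) {
  xy <- table$coords
  miss <- which(!stats::complete.cases(xy))
  if (length(miss))
    stop("missing coordinates for individual(s): ",
         paste(table$id[miss], collapse = ", "))
  if (table$coord_mode == "planar") {
    d <- as.matrix(stats::dist(xy))
    mode <- "planar"
  } else {
    n <- nrow(xy)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      d[i, j] <- d[j, i] <- geosphere::distHaversine(
        xy[i, , drop = FALSE], xy[j, , drop = FALSE], r = 6371008.8)
    }
    mode <- "geodesic"
  }
  dimnames(d) <- list(table$id, table$id)
  attr(d, "mode") <- mode
  d
}

#' Project lon/lat coordinates to a local planar frame
#'
#' Equirectangular projection about the centroid: metres east/north of the
#' mean position, suitable for plot-scale analyses (tens of hectares) where
#' planar geometry is required. Uses the same 6,371,008.8 m sphere radius as
#' [pairwise_distances()].
#'
#' @param table an `indiv_table` in `"lonlat"` mode.
#' @return the table with planar coordinates (mode `"planar"`).
#' @export
project_planar <- function(table) {
  if (table$coord_mode == "planar") return(table)
  R <- 6371008.8
  lon <- table$coords[, 1] * pi / 180
  lat <- table$coords[, 2] * pi / 180
  lat0 <- mean(lat)
  x <- R * (lon - mean(lon)) * cos(lat0)
  y <- R * (lat - lat0)
  individual_table(table$id, table$site, cbind(x, y), "planar",
                   table$geno, table$loci, dbh = table$dbh, hap = table$hap,
                   altitude = table$altitude)
}
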