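#' Georeferenced multilocus genotype table
#'
#' The central data container of the package: one row per individual with a
#' unique identifier, a site label, planar (`x`, `y`, metres) or geographic
#' (`lon`, `lat`, decimal degrees) coordinates, diameter at breast height
#' (`dbh`, cm), an optional altitude, a maternally inherited plastid haplotype
#' label, and a diploid genotype matrix over a shared locus panel.
#'
#' Genotypes are stored as an integer matrix with two adjacent columns per
#' locus; allele pairs are order-normalised (`a <= b`) so that genotype
#' equality is well defined, and missing alleles are `NA`. If either allele of
#' a locus is missing the whole locus is treated as untyped for that
#' individual.
#'
#' @param id character vector of unique individual identifiers.
#' @param site character vector of site labels (recycled if length 1).
#' @param coords two-column numeric matrix of coordinates.
#' @param coord_mode `"planar"` (metres) or `"lonlat"` (decimal degrees).
#' @param geno integer matrix, `n x 2L`, adjacent column pairs per locus.
#' @param loci character vector of `L` locus names.
#' @param dbh numeric vector of stem diameters (cm), `NA` allowed.
#' @param hap character vector of plastid haplotype labels, `NA` allowed.
#' @param altitude optional numeric vector (m).
#'
#' @return An object of class `indiv_table`: a list with elements `id`,
#'   `site`, `coords`, `coord_mode`, `dbh`, `altitude`, `hap`, `geno`, `loci`.
#' @seealso [read_individuals()], [split_size_classes()], [pairwise_distances()]
#' @export
individual_table <- function(id, site, coords, coord_mode = c("planar", "lonlat"),
                             geno, loci, dbh = NULL, hap = NULL, altitude = NULL) {
  coord_mode <- match.arg(coord_mode)
  id <- as.character(id)
  n <- length(id)
  if (anyDuplicated(id)) {
    stop("duplicated individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  site <- rep_len(as.character(site), n)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != n || ncol(coords) != 2)
    stop("coords must be an n x 2 matrix")
  colnames(coords) <- if (coord_mode == "planar") c("x", "y") else c("lon", "lat")
  loci <- as.character(loci)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != n || ncol(geno) != 2L * length(loci))
    stop("geno must have two columns per locus and one row per individual")
  # order-normalise allele pairs; propagate single-allele missingness
  for (l in seq_along(loci)) {
    a <- geno[, 2L * l - 1L]
    b <- geno[, 2L * l]
    miss <- is.na(a) | is.na(b)
    lo <- pmin(a, b); hi <- pmax(a, b)
    lo[miss] <- NA_integer_; hi[miss] <- NA_integer_
    geno[, 2L * l - 1L] <- lo
    geno[, 2L * l] <- hi
  }
  colnames(geno) <- paste0(rep(loci, each = 2L), c("_a", "_b"))
  dbh <- if (is.null(dbh)) rep(NA_real_, n) else rep_len(as.numeric(dbh), n)
  if (any(dbh < 0, na.rm = TRUE)) stop("dbh must be nonnegative")
  hap <- if (is.null(hap)) rep(NA_character_, n) else rep_len(as.character(hap), n)
  altitude <- if (is.null(altitude)) rep(NA_real_, n) else rep_len(as.numeric(altitude), n)
  structure(
    list(id = id, site = site, coords = coords, coord_mode = coord_mode,
         dbh = dbh, altitude = altitude, hap = hap, geno = geno, loci = loci),
    class = "indiv_table")
}

#' @export
print.indiv_table <- function(x, ...) {
  cat(sprintf("indiv_table: %d individuals, %d loci, %d site(s), %s coordinates\n",
              length(x$id), length(x$loci), length(unique(x$site)), x$coord_mode))
  cat(sprintf("  dbh: %d typed; plastid haplotype: %d typed (%d distinct)\n",
              sum(!is.na(x$dbh)), sum(!is.na(x$hap)),
              length(unique(stats::na.omit(x$hap)))))
  invisible(x)
}

#' Number of individuals in a table
#' @param table an `indiv_table`.
#' @return integer count.
#' @export
n_individuals <- function(table) length(table$id)

#' Subset an individual table
#'
#' @param x an `indiv_table`.
#' @param i logical, integer or character (id) index.
#' @param ... ignored.
#' @return the subsetted `indiv_table`.
#' @export
`[.indiv_table` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$id)
  individual_table(x$id[i], x$site[i], x$coords[i, , drop = FALSE],
                   x$coord_mode, x$geno[i, , drop = FALSE], x$loci,
                   dbh = x$dbh[i], hap = x$hap[i], altitude = x$altitude[i])
}

#' Combine individual tables sharing a locus panel
#' @param ... `indiv_table` objects with identical loci and coordinate mode.
#' @return a single `indiv_table`.
#' @export
bind_individuals <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1L]]) && !inherits(xs[[1L]], "indiv_table"))
    xs <- xs[[1L]]
  stopifnot(length(xs) >= 1L)
  loci <- xs[[1L]]$loci
  mode <- xs[[1L]]$coord_mode
  for (x in xs) {
    if (!identical(x$loci, loci)) stop("tables have different locus panels")
    if (!identical(x$coord_mode, mode)) stop("mixed coordinate modes")
  }
  individual_table(
    unlist(lapply(xs, `[[`, "id")), unlist(lapply(xs, `[[`, "site")),
    do.call(rbind, lapply(xs, `[[`, "coords")), mode,
    do.call(rbind, lapply(xs, `[[`, "geno")), loci,
    dbh = unlist(lapply(xs, `[[`, "dbh")),
    hap = unlist(lapply(xs, `[[`, "hap")),
    altitude = unlist(lapply(xs, `[[`, "altitude")))
}

#' Read a georeferenced genotype table from CSV
#'
#' Native dialect: a header row with columns `id`, `site`, `x`,`y` (planar
#' metres) or `lon`,`lat` (decimal degrees), `dbh`, optional `altitude`,
#' optional `hap`, then the genotype columns: either two columns per locus
#' (`locus_a`, `locus_b`) or one `a/b` column per locus. Missing alleles are
#' written as `NA` (the single missing-data sentinel); any unparseable allele
#' token is a hard error naming the row and locus.
#'
#' @param path CSV file path.
#' @param sep field separator, default `","`.
#' @return an [individual_table()].
#' @export
read_individuals <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  names(df) <- trimws(names(df))
  if (!"id" %in% names(df)) stop("missing required column: id")
  planar <- all(c("x", "y") %in% names(df))
  lonlat <- all(c("lon", "lat") %in% names(df))
  if (planar && lonlat) stop("mixed coordinate modes: both x/y and lon/lat present")
  if (!planar && !lonlat) stop("no coordinate columns found (x/y or lon/lat)")
  cmode <- if (planar) "planar" else "lonlat"
  ccols <- if (planar) c("x", "y") else c("lon", "lat")
  meta <- c("id", "site", ccols, "dbh", "altitude", "hap")
  gcols <- setdiff(names(df), meta)
  two_col <- grepl("_(a|b)$", gcols)
  if (all(two_col) && length(gcols)) {
    loci <- unique(sub("_(a|b)$", "", gcols))
    need <- c(paste0(loci, "_a"), paste0(loci, "_b"))
    if (!all(need %in% gcols)) stop("unpaired genotype columns")
    al <- lapply(loci, function(l) cbind(df[[paste0(l, "_a")]], df[[paste0(l, "_b")]]))
  } else {
    # slash dialect: one "a/b" token per locus column
    loci <- gcols
    al <- lapply(loci, function(l) {
      parts <- strsplit(df[[l]], "/", fixed = TRUE)
      bad <- lengths(parts) != 2L
      if (any(bad))
        stop(sprintf("malformed genotype '%s' at row %d, locus %s",
                     df[[l]][which(bad)[1L]], which(bad)[1L], l))
      do.call(rbind, parts)
    })
  }
  geno <- matrix(NA_integer_, nrow(df), 2L * length(loci))
  for (l in seq_along(loci)) {
    for (k in 1:2) {
      tok <- trimws(al[[l]][, k])
      tok[tok %in% c("NA", "", "-9", "0", "?")] <- NA
      val <- suppressWarnings(as.integer(tok))
      bad <- !is.na(tok) & is.na(val)
      if (any(bad))
        stop(sprintf("unparseable allele token '%s' at row %d, locus %s",
                     tok[which(bad)[1L]], which(bad)[1L], loci[l]))
      geno[, 2L * l - 2L + k] <- val
    }
  }
  num <- function(col) if (col %in% names(df)) suppressWarnings(as.numeric(df[[col]])) else NULL
  hap <- if ("hap" %in% names(df)) { h <- df$hap; h[h %in% c("NA", "")] <- NA; h } else NULL
  individual_table(
    id = df$id,
    site = if ("site" %in% names(df)) df$site else "site1",
    coords = cbind(num(ccols[1]), num(ccols[2])),
    coord_mode = cmode, geno = geno, loci = loci,
    dbh = num("dbh"), hap = hap, altitude = num("altitude"))
}

#' Write an individual table to CSV (native dialect)
#'
#' Round-trips losslessly through [read_individuals()].
#'
#' @param table an `indiv_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_individuals <- function(table, path) {
  df <- data.frame(id = table$id, site = table$site,
                   table$coords, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$dbh <- table$dbh
  if (any(!is.na(table$altitude))) df$altitude <- table$altitude
  df$hap <- table$hap
  g <- as.data.frame(table$geno)
  df <- cbind(df, g)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Export nuclear genotypes in GenePop format
#'
#' Writes one GenePop population per site with 3-digit allele codes
#' (missing = `000`), for cross-checking against legacy SGS/parentage
#' software. Allele integers must be < 1000.
#'
#' @param table an `indiv_table`.
#' @param path output file path.
#' @param title header line content.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(table, path, title = "dispkin export") {
  if (max(table$geno, na.rm = TRUE) > 999)
    stop("GenePop 3-digit export requires allele codes < 1000")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(table$loci, con)
  for (s in unique(table$site)) {
    writeLines("POP", con)
    idx <- which(table$site == s)
    for (i in idx) {
      g <- table$geno[i, ]
      g[is.na(g)] <- 0L
      codes <- sprintf("%03d%03d", g[seq(1, length(g), 2)], g[seq(2, length(g), 2)])
      writeLines(sprintf("%s ,  %s", table$id[i], paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Partition a table into size classes at a DBH threshold
#'
#' Individuals with `dbh` strictly below the threshold form the
#' seedlings-saplings-subadults class (SSS); those at or above it form the
#' adult class (ADL), following the convention that trees of DBH >= 30 cm are
#' potentially reproductive. Individuals with missing DBH are excluded from
#' the partition (and reported).
#'
#' @param table an `indiv_table`.
#' @param threshold DBH threshold in cm (default 30).
#' @return list with elements `sss`, `adl` (both `indiv_table`), `threshold`
#'   and `n_missing_dbh`.
#' @export
split_size_classes <- function(table, threshold = 30) {
  stopifnot(threshold > 0)
  if (all(is.na(table$dbh))) stop("all DBH values missing; cannot partition")
  keep <- !is.na(table$dbh)
  sss <- table[keep & table$dbh < threshold]
  adl <- table[keep & table$dbh >= threshold]
  structure(list(sss = sss, adl = adl, threshold = threshold,
                 n_missing_dbh = sum(!keep)),
            class = "size_class_partition")
}

#' @export
print.size_class_partition <- function(x, ...) {
  cat(sprintf("size classes at %.1f cm: SSS %d, ADL %d (%d missing DBH)\n",
              x$threshold, n_individuals(x$sss), n_individuals(x$adl),
              x$n_missing_dbh))
  invisible(x)
}
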