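#' Resolve mother and father by plastid haplotype
#'
#' For each assigned parent pair: if exactly one parent shares the
#' offspring's (maternally inherited) plastid haplotype and the other
#' parent's haplotype differs, the sharing parent is the mother and the other
#' the father; if both parents share it the trio is unresolved (multiple
#' matching mothers) and excluded from distance summaries; if neither shares
#' it the trio is flagged as a conflict (possible genotyping error or wrong
#' pair) and excluded. Selfed pairs (parent1 == parent2) resolve trivially.
#' Single-parent assignments and trios with missing haplotypes stay
#' unresolved.
#'
#' @param assignments a `parentage_assignment` data frame.
#' @param table an `indiv_table` with plastid haplotypes for offspring and
#'   parents.
#' @return data frame of class `role_resolved`: `offspring_id`, `mother_id`,
#'   `father_id`, `basis` (`"plastid-match"`, `"selfed"`, `"unresolved"`,
#'   `"unresolved-multiple"`, `"conflict"`).
#' @export
resolve_roles <- function(assignments, table) {
  hap <- stats::setNames(table$hap, table$id)
  n <- nrow(assignments)
  out <- data.frame(offspring_id = assignments$offspring_id,
                    mother_id = NA_character_, father_id = NA_character_,
                    basis = "unresolved", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p1 <- assignments$parent1[i]; p2 <- assignments$parent2[i]
    if (is.na(p1) || is.na(p2)) next
    if (p1 == p2) {
      out$mother_id[i] <- p1; out$father_id[i] <- p1
      out$basis[i] <- "selfed"
      next
    }
    ho <- hap[[assignments$offspring_id[i]]]
    h1 <- hap[[p1]]; h2 <- hap[[p2]]
    if (is.na(ho) || is.na(h1) || is.na(h2)) next
    m1 <- ho == h1; m2 <- ho == h2
    if (m1 && m2) out$basis[i] <- "unresolved-multiple"
    else if (!m1 && !m2) out$basis[i] <- "conflict"
    else {
      out$mother_id[i] <- if (m1) p1 else p2
      out$father_id[i] <- if (m1) p2 else p1
      out$basis[i] <- "plastid-match"
    }
  }
  class(out) <- c("role_resolved", "data.frame")
  out
}

#' Seed and pollen dispersal distances for resolved trios
#'
#' Seed distance is mother to offspring; pollen distance is father to mother
#' (the mating event); father to offspring is also emitted as an auxiliary
#' column. Trios with missing coordinates are dropped with a count.
#'
#' @param trios a [resolve_roles()] result (only resolved rows contribute).
#' @param table an `indiv_table` with coordinates for all individuals.
#' @return data frame `offspring_id`, `mother_id`, `father_id`, `site`,
#'   `seed_dist_m`, `pollen_dist_m`, `father_offspring_m`; attribute
#'   `n_dropped`.
#' @export
dispersal_distances <- function(trios, table) {
  tab <- if (table$coord_mode == "lonlat") project_planar(table) else table
  xy <- tab$coords
  rownames(xy) <- tab$id
  site <- stats::setNames(tab$site, tab$id)
  res <- trios[trios$basis %in% c("plastid-match", "selfed"), , drop = FALSE]
  ok <- res$offspring_id %in% tab$id & res$mother_id %in% tab$id &
    res$father_id %in% tab$id
  dropped <- sum(!ok)
  res <- res[ok, , drop = FALSE]
  sd_ <- sqrt(rowSums((xy[res$mother_id, , drop = FALSE] -
                         xy[res$offspring_id, , drop = FALSE])^2))
  pd_ <- sqrt(rowSums((xy[res$father_id, , drop = FALSE] -
                         xy[res$mother_id, , drop = FALSE])^2))
  fo_ <- sqrt(rowSums((xy[res$father_id, , drop = FALSE] -
                         xy[res$offspring_id, , drop = FALSE])^2))
  out <- data.frame(offspring_id = res$offspring_id,
                    mother_id = res$mother_id, father_id = res$father_id,
                    site = unname(site[res$offspring_id]),
                    seed_dist_m = unname(sd_), pollen_dist_m = unname(pd_),
                    father_offspring_m = unname(fo_),
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- dropped
  out
}

#' Percentile bootstrap confidence interval of a mean
#'
#' Non-parametric bootstrap (resampling with replacement) of the sample
#' mean; the 95% percentile interval is reported together with its
#' half-width (the "plus-minus" of report tables).
#'
#' @param values numeric vector (n >= 2 for an interval).
#' @param n_boot bootstrap iterations (default 10,000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return list `mean`, `lo`, `hi`, `half_width`, `n`, `n_boot`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 10000, seed = 1, conf = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  m <- mean(values)
  if (n < 2)
    return(list(mean = m, lo = NA_real_, hi = NA_real_,
                half_width = NA_real_, n = n, n_boot = n_boot))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  bm <- colMeans(matrix(sample(values, n * n_boot, replace = TRUE), n, n_boot))
  q <- stats::quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(mean = m, lo = q[1], hi = q[2], half_width = (q[2] - q[1]) / 2,
       n = n, n_boot = n_boot)
}

#' Per-site contemporary dispersal summary
#'
#' Mean and median seed and pollen dispersal distances per site with
#' bootstrap confidence intervals for the means.
#'
#' @param events a [dispersal_distances()] table.
#' @param n_boot bootstrap iterations.
#' @param seed RNG seed.
#' @return data frame with one row per site (plus an `overall` row when more
#'   than one site is present).
#' @export
dispersal_summary <- function(events, n_boot = 10000, seed = 1) {
  one <- function(ev, label) {
    sb <- bootstrap_mean_ci(ev$seed_dist_m, n_boot, seed)
    pb <- bootstrap_mean_ci(ev$pollen_dist_m, n_boot, seed + 1L)
    data.frame(site = label, n_events = nrow(ev),
               seed_mean_m = sb$mean, seed_ci_half = sb$half_width,
               seed_median_m = stats::median(ev$seed_dist_m),
               pollen_mean_m = pb$mean, pollen_ci_half = pb$half_width,
               pollen_median_m = stats::median(ev$pollen_dist_m),
               n_boot = n_boot, stringsAsFactors = FALSE)
  }
  sites <- unique(events$site)
  out <- do.call(rbind, lapply(sites, function(s)
    one(events[events$site == s, ], s)))
  if (length(sites) > 1) out <- rbind(out, one(events, "overall"))
  rownames(out) <- NULL
  out
}

#' Dispersal distance histogram counts
#'
#' Event counts in fixed-width distance bins (default 10 m), the plotting
#' convention for dispersal barcharts.
#'
#' @param distances numeric distances (m).
#' @param bin_width bin width (m), default 10.
#' @return data frame `lower`, `upper`, `count`.
#' @export
dispersal_histogram <- function(distances, bin_width = 10) {
  distances <- distances[!is.na(distances)]
  top <- max(distances, 0)
  breaks <- seq(0, bin_width * ceiling(top / bin_width + 1e-9), by = bin_width)
  if (length(breaks) < 2) breaks <- c(0, bin_width)
  ct <- hist(distances, breaks = breaks, plot = FALSE, right = TRUE,
             include.lowest = TRUE)$counts
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1], count = ct)
}
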