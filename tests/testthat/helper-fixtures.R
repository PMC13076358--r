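# Shared fixtures and independent brute-force oracles.

# tiny table from an explicit genotype matrix
make_table <- function(geno, xy = NULL, dbh = NULL, hap = NULL,
                       site = "s1", ids = NULL) {
  n <- nrow(geno)
  L <- ncol(geno) / 2
  if (is.null(xy)) xy <- cbind(seq_len(n), rep(0, n))
  individual_table(
    id = if (is.null(ids)) sprintf("i%03d", seq_len(n)) else ids,
    site = site, coords = xy, coord_mode = "planar",
    geno = geno, loci = sprintf("L%02d", seq_len(L)),
    dbh = dbh, hap = hap)
}

# random genotype matrix with optional missingness
random_geno <- function(n, L, k = 4, miss = 0) {
  g <- matrix(sample.int(k, 2 * n * L, replace = TRUE), n, 2 * L)
  if (miss > 0) {
    for (l in seq_len(L)) {
      drop <- runif(n) < miss
      g[drop, 2 * l - 1] <- NA
      g[drop, 2 * l] <- NA
    }
  }
  g
}

# Brute-force Loiselle kinship: literal double loop over pairs, loci, alleles.
# Deliberately written as plainly as possible, independent of the package's
# vectorised path.
brute_loiselle <- function(table, mode = "diploid") {
  n <- n_individuals(table)
  fij <- matrix(NA_real_, n, n)
  if (mode == "diploid") {
    L <- length(table$loci)
    locus_info <- lapply(seq_len(L), function(l) {
      a <- c(table$geno[, 2 * l - 1], table$geno[, 2 * l])
      a <- a[!is.na(a)]
      tb <- table(a)
      list(alleles = as.integer(names(tb)), p = as.numeric(tb) / length(a),
           nl = length(a))
    })
    indiv_freq <- function(i, l, al) {
      pair <- table$geno[i, c(2 * l - 1, 2 * l)]
      if (any(is.na(pair))) return(NA_real_)
      mean(pair == al)
    }
  } else {
    alleles <- sort(unique(na.omit(table$hap)))
    p <- as.numeric(table(factor(table$hap, levels = alleles)))
    p <- p / sum(p)
    locus_info <- list(list(alleles = alleles, p = p,
                            nl = sum(!is.na(table$hap))))
    indiv_freq <- function(i, l, al) {
      if (is.na(table$hap[i])) return(NA_real_)
      as.numeric(table$hap[i] == al)
    }
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- 0; den <- 0; any_locus <- FALSE
    for (l in seq_along(locus_info)) {
      info <- locus_info[[l]]
      if (length(info$alleles) < 2) next
      dl <- sum(info$p * (1 - info$p))
      if (dl <= 0) next
      contrib <- 0; ok <- TRUE
      for (a in seq_along(info$alleles)) {
        pi <- indiv_freq(i, l, info$alleles[a])
        pj <- indiv_freq(j, l, info$alleles[a])
        if (is.na(pi) || is.na(pj)) { ok <- FALSE; break }
        contrib <- contrib + (pi - info$p[a]) * (pj - info$p[a]) +
          info$p[a] * (1 - info$p[a]) / (info$nl - 1)
      }
      if (!ok) next
      num <- num + contrib
      den <- den + dl
      any_locus <- TRUE
    }
    if (any_locus) fij[i, j] <- fij[j, i] <- num / den
  }
  fij
}

# Brute-force Gini: literal double loop over all ordered pairs.
brute_gini <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# Brute-force rarefied allele count: mean distinct alleles over random
# subsamples of k gene copies.
brute_rarefaction <- function(counts, k, n_draws = 10000) {
  pool <- rep(seq_along(counts), counts)
  mean(replicate(n_draws, length(unique(sample(pool, k)))))
}

# Hand LOD oracle: enumerate the four ordered transmissions per locus.
# P(recorded allele | transmitted) = (1-eps)*[recorded==transmitted] + eps*p.
brute_pair_lod <- function(off, p1, p2, freq_list, eps = 0) {
  total <- 0
  for (l in seq_along(freq_list)) {
    x <- off[[l]][1]; y <- off[[l]][2]
    f <- freq_list[[l]]
    px <- if (x %in% names(f)) f[[x]] else 0
    py <- if (y %in% names(f)) f[[y]] else 0
    prob_rec <- function(rec, trans) (1 - eps) * (rec == trans) + eps *
      (if (rec %in% names(f)) f[[rec]] else 0)
    num <- 0
    for (g1 in p1[[l]]) for (g2 in p2[[l]]) {
      # each gamete equally likely (0.25 per ordered pick)
      num <- num + 0.25 * if (x == y) prob_rec(x, g1) * prob_rec(y, g2) else
        prob_rec(x, g1) * prob_rec(y, g2) + prob_rec(y, g1) * prob_rec(x, g2)
    }
    den <- if (x == y) px^2 else 2 * px * py
    total <- total + log(num) - log(den)
  }
  total
}

# Clark-Evans aggregation index: observed mean nearest-neighbour distance
# over the CSR expectation 0.5/sqrt(density).
clark_evans <- function(xy, area) {
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  mean(apply(d, 1, min)) / (0.5 / sqrt(nrow(xy) / area))
}
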