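#' Per-locus allele frequencies
#'
#' Counts are taken over non-missing gene copies only. Loci with zero typed
#' copies are flagged (`ok = FALSE`) with a warning and excluded by downstream
#' consumers.
#'
#' @param table an `indiv_table`.
#' @return an object of class `allele_freqs`: a list with one element per
#'   locus holding `alleles`, `counts`, `freq` and `n` (typed gene copies),
#'   plus attribute `loci`.
#' @export
allele_frequencies <- function(table) {
  out <- lapply(seq_along(table$loci), function(l) {
    g <- c(table$geno[, 2L * l - 1L], table$geno[, 2L * l])
    g <- g[!is.na(g)]
    if (!length(g)) return(list(alleles = integer(), counts = integer(),
                                freq = numeric(), n = 0L, ok = FALSE))
    tb <- table(g)
    list(alleles = as.integer(names(tb)), counts = as.integer(tb),
         freq = as.numeric(tb) / length(g), n = length(g), ok = TRUE)
  })
  names(out) <- table$loci
  bad <- !vapply(out, `[[`, TRUE, "ok")
  if (any(bad))
    warning("locus/loci with zero typed gene copies excluded: ",
            paste(table$loci[bad], collapse = ", "))
  structure(out, class = "allele_freqs", loci = table$loci)
}

#' Allelic richness by hypergeometric rarefaction
#'
#' Expected number of distinct alleles in a random subsample of `k` gene
#' copies: `A_R = sum_a [1 - C(n_l - n_a, k) / C(n_l, k)]` per locus. Loci
#' with fewer than `k` typed copies are skipped with a warning (they are
#' dropped from `A_R` only, not from other statistics).
#'
#' @param freqs an [allele_frequencies()] object.
#' @param k standardised number of gene copies (default 50).
#' @return list with `per_locus` (named vector, `NA` for skipped loci),
#'   `mean` over usable loci, and `k`.
#' @export
allelic_richness <- function(freqs, k = 50) {
  if (k < 2) stop("k must be >= 2")
  per <- vapply(freqs, function(f) {
    if (!f$ok || f$n < k) return(NA_real_)
    sum(1 - exp(lchoose(f$n - f$counts, k) - lchoose(f$n, k)))
  }, numeric(1))
  if (anyNA(per))
    warning(sum(is.na(per)), " locus/loci with fewer than k typed copies skipped in A_R")
  list(per_locus = per, mean = mean(per, na.rm = TRUE), k = k)
}

# per-locus observed het (simple proportion among typed individuals)
.ho_per_locus <- function(table) {
  vapply(seq_along(table$loci), function(l) {
    a <- table$geno[, 2L * l - 1L]; b <- table$geno[, 2L * l]
    t <- !is.na(a)
    if (!any(t)) return(NA_real_)
    mean(a[t] != b[t])
  }, numeric(1))
}

# per-locus unbiased expected het: n/(n-1) * (1 - sum p^2), n = gene copies
.he_per_locus <- function(freqs) {
  vapply(freqs, function(f) {
    if (!f$ok || f$n < 2) return(NA_real_)
    f$n / (f$n - 1) * (1 - sum(f$freq^2))
  }, numeric(1))
}

#' Observed and expected heterozygosity
#'
#' `H_O` is the simple proportion of heterozygous typed individuals per
#' locus; `H_E` is the small-sample unbiased gene diversity
#' `n_l/(n_l - 1) * (1 - sum p^2)` with `n_l` typed gene copies. Both are
#' averaged over usable loci.
#'
#' @param table an `indiv_table`.
#' @param freqs optional precomputed [allele_frequencies()].
#' @return list `ho`, `he` (multilocus means) and `per_locus` data frame.
#' @export
heterozygosities <- function(table, freqs = allele_frequencies(table)) {
  ho <- .ho_per_locus(table)
  he <- .he_per_locus(freqs)
  list(ho = mean(ho, na.rm = TRUE), he = mean(he, na.rm = TRUE),
       per_locus = data.frame(locus = table$loci, ho = ho, he = he))
}

#' Multilocus inbreeding coefficient with a permutation test
#'
#' `F_IS = 1 - H_O/H_E` with the multilocus ratio taken over summed per-locus
#' components (expected-heterozygosity weighting). The null distribution is
#' built by shuffling gene copies among individuals within each locus, which
#' leaves allele frequencies (hence `H_E`) unchanged; the two-sided p-value is
#' `min(1, 2*min(Pr(F* >= F), Pr(F* <= F)))` with the add-one convention.
#'
#' @param table an `indiv_table`.
#' @param n_perm number of permutations (default 10,000).
#' @param seed RNG seed.
#' @return list `fis`, `p`, `tier` (`"***"`, `"**"`, `"*"`, `"ns"`),
#'   `n_perm`, and the permuted values `fis_perm`.
#' @export
inbreeding_coefficient <- function(table, n_perm = 10000, seed = 1) {
  stopifnot(n_perm >= 1)
  freqs <- allele_frequencies(table)
  he <- .he_per_locus(freqs)
  usable <- which(!is.na(he) & he > 0)
  if (!length(usable)) stop("H_E is zero at every locus; F_IS undefined")
  ho <- .ho_per_locus(table)
  fis_of <- function(ho_l) 1 - sum(ho_l[usable]) / sum(he[usable])
  fis <- fis_of(ho)
  # gene-copy shuffling only changes H_O; vectorise per locus
  copies <- lapply(usable, function(l) {
    g <- c(table$geno[, 2L * l - 1L], table$geno[, 2L * l])
    g[!is.na(g)]
  })
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  fis_perm <- vapply(seq_len(n_perm), function(p) {
    ho_l <- ho
    for (j in seq_along(usable)) {
      g <- sample(copies[[j]])
      half <- length(g) %/% 2L
      ho_l[usable[j]] <- mean(g[seq_len(half)] != g[half + seq_len(half)])
    }
    fis_of(ho_l)
  }, numeric(1))
  p_hi <- (1 + sum(fis_perm >= fis)) / (n_perm + 1)
  p_lo <- (1 + sum(fis_perm <= fis)) / (n_perm + 1)
  p <- min(1, 2 * min(p_hi, p_lo))
  list(fis = fis, p = p, tier = significance_tier(p), n_perm = n_perm,
       fis_perm = fis_perm)
}

#' Significance tiers used in report tables
#' @param p numeric p-value(s).
#' @return character: `"***"` (< 0.001), `"**"` (< 0.01), `"*"` (< 0.05),
#'   else `"ns"`.
#' @export
significance_tier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Pairwise multilocus F_ST (Weir & Cockerham) between sites
#'
#' Weir & Cockerham's theta from per-locus, per-allele variance components,
#' summed over loci and alleles; significance per site pair by permuting
#' individuals between the two sites. Sites with fewer than 2 individuals are
#' excluded with a warning.
#'
#' @param table an `indiv_table` with >= 2 sites.
#' @param n_perm permutations per pair (default 999).
#' @param seed RNG seed.
#' @return list with symmetric matrices `fst` and `p`.
#' @export
pairwise_fst <- function(table, n_perm = 999, seed = 1) {
  sites <- unique(table$site)
  sizes <- vapply(sites, function(s) sum(table$site == s), integer(1))
  if (any(sizes < 2)) {
    warning("site(s) with < 2 individuals excluded: ",
            paste(sites[sizes < 2], collapse = ", "))
    sites <- sites[sizes >= 2]
  }
  if (length(sites) < 2) stop("need >= 2 usable sites")
  ns <- length(sites)
  fst <- matrix(NA_real_, ns, ns, dimnames = list(sites, sites))
  pmat <- fst
  diag(fst) <- 0
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    idx <- which(table$site %in% sites[c(i, j)])
    sub <- table[idx]
    grp <- sub$site == sites[i]
    obs <- .wc_theta(sub$geno, grp)
    perm <- vapply(seq_len(n_perm), function(p)
      .wc_theta(sub$geno, sample(grp)), numeric(1))
    fst[i, j] <- fst[j, i] <- obs
    pmat[i, j] <- pmat[j, i] <- (1 + sum(perm >= obs)) / (n_perm + 1)
  }
  list(fst = fst, p = pmat)
}

# Weir & Cockerham (1984) theta for two groups, multilocus ratio of sums.
# geno: n x 2L matrix; grp: logical group membership.
.wc_theta <- function(geno, grp) {
  L <- ncol(geno) %/% 2L
  r <- 2
  num <- den <- 0
  for (l in seq_len(L)) {
    a1 <- geno[, 2L * l - 1L]; a2 <- geno[, 2L * l]
    t <- !is.na(a1)
    if (sum(t & grp) < 2 || sum(t & !grp) < 2) next
    alleles <- unique(c(a1[t], a2[t]))
    if (length(alleles) < 2) next
    n_i <- c(sum(t & grp), sum(t & !grp))
    nbar <- mean(n_i)
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    for (al in alleles) {
      cnt <- (a1 == al) + (a2 == al)
      het <- (a1 == al) != (a2 == al)
      p_i <- c(sum(cnt[t & grp]), sum(cnt[t & !grp])) / (2 * n_i)
      h_i <- c(mean(het[t & grp]), mean(het[t & !grp]))
      pbar <- sum(n_i * p_i) / sum(n_i)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / sum(n_i)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                    hbar * (2 * nbar - 1) / (4 * nbar))
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Selfing-rate estimates
#'
#' Two labelled estimators: (a) the inbreeding-equilibrium transform
#' `s = 2*F_IS/(1 + F_IS)` clipped to `[0, 1]`; (b) an identity-disequilibrium
#' estimate from the multilocus g2 statistic (standardised covariance of
#' heterozygosity across locus pairs), converted to `s` via the mixed-mating
#' equilibrium relation `g2 = s/((4 - s)(1 - s))`, with a delete-one-locus
#' jackknife over loci giving a standard error and a one-sided p-value for
#' `g2 > 0` (t distribution, L-1 df). Route (b) needs >= 5 polymorphic loci;
#' the conversion uses the root of `g2*s^2 - (5*g2 + 1)*s + 4*g2 = 0` in
#' `[0, 1]`.
#'
#' @param table an `indiv_table`.
#' @param fis optional precomputed F_IS (otherwise computed without a
#'   permutation test).
#' @return list with `s_fis`, and (when computable) `g2`, `s_g2`, `g2_se`,
#'   `g2_p`, `tier`.
#' @export
selfing_rate <- function(table, fis = NULL) {
  if (is.null(fis)) {
    freqs <- allele_frequencies(table)
    he <- .he_per_locus(freqs); ho <- .ho_per_locus(table)
    u <- !is.na(he) & he > 0
    fis <- 1 - sum(ho[u]) / sum(he[u])
  }
  s_fis <- if (fis <= -1) NA_real_ else min(1, max(0, 2 * fis / (1 + fis)))
  out <- list(fis = fis, s_fis = s_fis, s_g2 = NA_real_, g2 = NA_real_,
              g2_se = NA_real_, g2_p = NA_real_, tier = NA_character_)
  # heterozygosity indicator matrix, polymorphic loci only
  L <- length(table$loci)
  H <- matrix(NA_real_, n_individuals(table), L)
  for (l in seq_len(L)) {
    a <- table$geno[, 2L * l - 1L]; b <- table$geno[, 2L * l]
    H[, l] <- ifelse(is.na(a), NA, as.numeric(a != b))
  }
  poly <- which(apply(H, 2, function(h) {
    h <- h[!is.na(h)]; length(h) > 0 && any(h > 0)
  }))
  if (length(poly) < 5) return(out)
  H <- H[, poly, drop = FALSE]
  out$g2 <- .g2_stat(H)
  out$s_g2 <- .g2_to_s(out$g2)
  jk <- vapply(seq_len(ncol(H)), function(l) .g2_stat(H[, -l, drop = FALSE]),
               numeric(1))
  Lh <- length(jk)
  out$g2_se <- sqrt((Lh - 1) / Lh * sum((jk - mean(jk))^2))
  tstat <- if (out$g2_se > 0) out$g2 / out$g2_se else Inf
  out$g2_p <- stats::pt(tstat, df = Lh - 1, lower.tail = FALSE)
  out$tier <- significance_tier(out$g2_p)
  out
}

# multilocus g2: mean within-individual cross-locus het product over its
# between-individual expectation, minus 1 (pairwise-complete over missing).
.g2_stat <- function(H) {
  Hm <- H; Hm[is.na(Hm)] <- 0
  Tm <- (!is.na(H)) * 1
  M <- crossprod(Hm)               # locus-pair sums of h_ik * h_il within i
  Np <- crossprod(Tm)              # per-pair complete-case counts
  cs <- colSums(Hm); ns <- colSums(Tm)
  # expected cross product under independence between individuals,
  # per locus pair: (sum_i h_ik)(sum_j h_jl) - sum_i h_ik h_il, over n(n-1)
  Eo <- outer(cs, cs) - M
  Nn <- outer(ns, ns) - Np
  off <- upper.tri(M)
  num <- sum(M[off] / Np[off])
  den <- sum(Eo[off] / Nn[off])
  num / den - 1
}

.g2_to_s <- function(g2) {
  if (is.na(g2) || g2 <= 0) return(0)
  disc <- (5 * g2 + 1)^2 - 16 * g2^2
  s <- ((5 * g2 + 1) - sqrt(max(disc, 0))) / (2 * g2)
  min(1, max(0, s))
}

#' Plastid haplotype diversity
#'
#' Haplotype counts, effective number of haplotypes `1/sum(p^2)`, and
#' sample-size-corrected haplotype diversity `n/(n-1) * (1 - sum p^2)`.
#'
#' @param table an `indiv_table` with plastid haplotypes.
#' @return list `n_haplotypes`, `effective_n`, `he`, `counts`, `n_typed`.
#' @export
plastid_diversity <- function(table) {
  h <- table$hap[!is.na(table$hap)]
  if (!length(h)) stop("no typed plastid haplotypes")
  tb <- table(h)
  p <- as.numeric(tb) / length(h)
  he <- if (length(h) > 1) length(h) / (length(h) - 1) * (1 - sum(p^2)) else 0
  list(n_haplotypes = length(tb), effective_n = 1 / sum(p^2), he = he,
       counts = tb, n_typed = length(h))
}

#' Diversity report for site-by-size-class groups
#'
#' Assembles the per-group diversity panel of a survey: sample size, density,
#' rarefied allelic richness, heterozygosities, F_IS with permutation tier,
#' selfing estimates and plastid haplotype diversity.
#'
#' @param table an `indiv_table` spanning one or more sites.
#' @param area_ha named vector of site areas (ha) for densities (optional).
#' @param threshold DBH size-class threshold (cm).
#' @param k rarefaction gene copies.
#' @param n_perm permutations for the F_IS test.
#' @param seed RNG seed.
#' @return data frame with one row per site x size class.
#' @export
diversity_report <- function(table, area_ha = NULL, threshold = 30, k = 50,
                             n_perm = 1000, seed = 1) {
  rows <- list()
  for (s in unique(table$site)) {
    sub <- table[table$site == s]
    parts <- split_size_classes(sub, threshold)
    for (cl in c("sss", "adl")) {
      g <- parts[[cl]]
      if (n_individuals(g) < 2) next
      freqs <- allele_frequencies(g)
      ar <- suppressWarnings(allelic_richness(freqs, k))
      het <- heterozygosities(g, freqs)
      fis <- inbreeding_coefficient(g, n_perm = n_perm, seed = seed)
      sr <- selfing_rate(g, fis = fis$fis)
      pd <- tryCatch(plastid_diversity(g), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        site = s, size_class = toupper(cl), n = n_individuals(g),
        density_ha = if (!is.null(area_ha) && s %in% names(area_ha))
          n_individuals(g) / area_ha[[s]] else NA_real_,
        a_r = ar$mean, he = het$he, ho = het$ho,
        fis = fis$fis, fis_tier = fis$tier,
        selfing_fis = sr$s_fis, selfing_g2 = sr$s_g2, g2 = sr$g2,
        g2_tier = if (is.na(sr$tier)) "ns" else sr$tier,
        hap_n = if (is.null(pd)) NA_integer_ else pd$n_haplotypes,
        hap_eff = if (is.null(pd)) NA_real_ else pd$effective_n,
        hap_he = if (is.null(pd)) NA_real_ else pd$he,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
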