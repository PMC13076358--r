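#' Pairwise Loiselle kinship matrix
#'
#' Multilocus kinship of Loiselle et al. relative to the analysed group's own
#' allele frequencies. Per locus l and allele a, with individual allele
#' frequencies `p_i` (0/0.5/1 diploid; 0/1 haploid) and reference frequency
#' `p`, the pair (i, j) contributes `(p_i - p)(p_j - p) + p(1-p)/(n_l - 1)`
#' to the numerator and `p(1-p)` to the denominator, where `n_l` is the
#' number of typed gene copies; sums run over loci jointly typed in the pair,
#' so loci are weighted by their polymorphism. Haploid mode treats the
#' plastid haplotype as a single multiallelic locus.
#'
#' @param table an `indiv_table`.
#' @param freqs optional [allele_frequencies()] computed from the same group
#'   (nuclear mode only; recomputed when `NULL`).
#' @param mode `"diploid"` (nuclear genotypes) or `"haploid"` (plastid
#'   haplotype).
#' @param min_loci minimum jointly typed loci for a pair to be defined
#'   (default 20 nuclear, 1 haploid); pairs below it are `NA`.
#' @return object of class `kinship_matrix`: list with symmetric matrix `fij`
#'   (`NA` diagonal and under-typed pairs), matrix `n_loci` of jointly typed
#'   locus counts, and `mode`.
#' @export
loiselle_kinship <- function(table, freqs = NULL,
                             mode = c("diploid", "haploid"),
                             min_loci = NULL) {
  mode <- match.arg(mode)
  n <- n_individuals(table)
  if (is.null(min_loci)) min_loci <- if (mode == "diploid") 20L else 1L
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  cnt <- matrix(0L, n, n)
  if (mode == "diploid") {
    loci <- seq_along(table$loci)
    if (is.null(freqs)) freqs <- allele_frequencies(table)
  } else {
    loci <- 1L
  }
  used <- 0L
  for (l in loci) {
    if (mode == "diploid") {
      f <- freqs[[l]]
      if (!f$ok || length(f$alleles) < 2) next
      a1 <- table$geno[, 2L * l - 1L]; a2 <- table$geno[, 2L * l]
      typed <- !is.na(a1)
      P <- (outer(a1, f$alleles, `==`) + outer(a2, f$alleles, `==`)) / 2
      P[!typed, ] <- 0
      pbar <- f$freq
      nl <- f$n
    } else {
      hap <- table$hap
      typed <- !is.na(hap)
      if (sum(typed) < 2) stop("fewer than 2 typed haplotypes")
      alleles <- sort(unique(hap[typed]))
      if (length(alleles) < 2)
        stop("haplotype locus is monomorphic; kinship undefined")
      P <- outer(hap, alleles, `==`) * 1
      P[is.na(P)] <- 0
      P[!typed, ] <- 0
      pbar <- colSums(P[typed, , drop = FALSE]) / sum(typed)
      nl <- sum(typed)
    }
    denl <- sum(pbar * (1 - pbar))
    if (denl <= 0) next
    C <- sweep(P, 2, pbar)       # deviations; rows of untyped are wrong but masked
    C[!typed, ] <- 0
    TT <- outer(typed, typed, `&`)
    num <- num + tcrossprod(C) + (denl / (nl - 1)) * TT
    den <- den + denl * TT
    cnt <- cnt + TT
    used <- used + 1L
  }
  if (used == 0L) stop("all loci monomorphic or untyped; kinship undefined")
  fij <- num / den
  min_loci <- min(min_loci, used)   # never demand more loci than are usable
  fij[cnt < min_loci] <- NA
  diag(fij) <- NA
  dimnames(fij) <- list(table$id, table$id)
  structure(list(fij = fij, n_loci = cnt, mode = mode, min_loci = min_loci),
            class = "kinship_matrix")
}

#' Sp statistic from first-class kinship and log-distance slope
#'
#' `Sp = -b_log / (1 - F_1)`, the standard scalar summary of fine-scale
#' spatial genetic structure.
#'
#' @param f1 mean kinship in the first distance class.
#' @param b_log regression slope of pairwise kinship on ln(distance).
#' @return Sp (numeric).
#' @seealso [neighborhood_size()]
#' @export
sp_statistic <- function(f1, b_log) -b_log / (1 - f1)

#' Wright's neighbourhood size
#'
#' `NS = 1/Sp`; infinite when `Sp <= 0` (no detectable structure).
#'
#' @param sp the Sp statistic.
#' @return NS (numeric, possibly `Inf`).
#' @export
neighborhood_size <- function(sp) ifelse(sp > 0, 1 / sp, Inf)

# upper-triangle pair view shared by the correlogram and slope fits
.pair_view <- function(kin, dist) {
  n <- nrow(kin$fij)
  stopifnot(nrow(dist) == n)
  ut <- which(upper.tri(kin$fij), arr.ind = TRUE)
  f <- kin$fij[ut]
  d <- dist[ut]
  keep <- !is.na(f)
  list(i = ut[keep, 1L], j = ut[keep, 2L], f = f[keep], d = d[keep])
}

# least-squares slope of f on ln(d); zero-distance pairs excluded
.slope_log <- function(f, d) {
  pos <- d > 0
  x <- log(d[pos]); y <- f[pos]
  if (length(x) < 2 || stats::var(x) == 0) return(NA_real_)
  stats::cov(x, y) / stats::var(x)
}

#' Kinship-distance autocorrelogram with permutation envelopes
#'
#' Mean pairwise kinship per distance class (half-open `(lower, upper]`
#' intervals with the given upper bounds, first class starting at 0), the
#' first-class mean `F_1`, the slope `b_log` of pairwise kinship on
#' ln(distance) over all positive-distance pairs, and the derived `Sp` and
#' neighbourhood size. The null for the envelopes and for the slope/Sp test
#' permutes individual locations (coordinates are shuffled among individuals
#' while the kinship matrix stays fixed), recomputing class means and slope
#' each time. Slope significance is two-sided.
#'
#' @param kinship a [loiselle_kinship()] result.
#' @param distances matrix from [pairwise_distances()].
#' @param breaks upper class bounds in metres
#'   (default `c(30, 60, 90, 130, 170, 220, 300, 600)`).
#' @param n_perm number of location permutations (default 10,000).
#' @param seed RNG seed.
#' @return object of class `sgs_result`: list with `classes` (data frame:
#'   `upper`, `mean_fij`, `n_pairs`, `env_lo`, `env_hi`), `f1`, `b_log`,
#'   `sp`, `ns`, `p_slope`, `tier`, `n_perm`, `n_zero_dist`, `mode`.
#' @export
autocorrelogram <- function(kinship, distances,
                            breaks = c(30, 60, 90, 130, 170, 220, 300, 600),
                            n_perm = 10000, seed = 1) {
  stopifnot(n_perm >= 1, all(diff(breaks) > 0), all(breaks > 0))
  pv <- .pair_view(kinship, distances)
  cls <- findInterval(pv$d, c(0, breaks), left.open = TRUE)
  cls[cls > length(breaks)] <- NA          # beyond last bound: no class
  nclass <- length(breaks)
  class_mean <- function(f, cl) {
    s <- tapply(f, factor(cl, levels = seq_len(nclass)), mean)
    as.numeric(s)
  }
  mean_fij <- class_mean(pv$f, cls)
  n_pairs <- as.numeric(table(factor(cls, levels = seq_len(nclass))))
  if (is.na(mean_fij[1L]) || n_pairs[1L] == 0)
    stop("empty first distance class; F_1 undefined")
  f1 <- mean_fij[1L]
  b <- .slope_log(pv$f, pv$d)
  n <- nrow(kinship$fij)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  env <- matrix(NA_real_, n_perm, nclass)
  bperm <- numeric(n_perm)
  fmat <- kinship$fij
  for (p in seq_len(n_perm)) {
    pr <- sample.int(n)
    fp <- fmat[cbind(pr[pv$i], pr[pv$j])]
    keep <- !is.na(fp)
    env[p, ] <- class_mean(fp[keep], cls[keep])
    bperm[p] <- .slope_log(fp[keep], pv$d[keep])
  }
  env_lo <- apply(env, 2, stats::quantile, probs = 0.025, na.rm = TRUE)
  env_hi <- apply(env, 2, stats::quantile, probs = 0.975, na.rm = TRUE)
  p_slope <- min(1, 2 * min(
    (1 + sum(bperm <= b, na.rm = TRUE)) / (n_perm + 1),
    (1 + sum(bperm >= b, na.rm = TRUE)) / (n_perm + 1)))
  sp <- sp_statistic(f1, b)
  structure(list(
    classes = data.frame(upper = breaks, mean_fij = mean_fij,
                         n_pairs = n_pairs, env_lo = env_lo, env_hi = env_hi),
    f1 = f1, b_log = b, sp = sp, ns = neighborhood_size(sp),
    p_slope = p_slope, tier = significance_tier(p_slope), n_perm = n_perm,
    n_zero_dist = sum(pv$d == 0), mode = kinship$mode), class = "sgs_result")
}

#' @export
print.sgs_result <- function(x, ...) {
  cat(sprintf("SGS (%s): F1 = %.4f, b_log = %.4f, Sp = %.4f%s, NS = %.1f (%d perms)\n",
              x$mode, x$f1, x$b_log, x$sp, x$tier, x$ns, x$n_perm))
  invisible(x)
}

#' Kinship on ln(distance) slope over a restricted distance range
#'
#' Least-squares slope of pairwise kinship on ln(distance) using only pairs
#' with `d_min < d <= d_max`; used by the iterative dispersal-distance
#' estimator to refit the regression over the range where the
#' isolation-by-distance approximation holds. Fewer than `min_pairs` pairs in
#' range raises a condition of class `dispkin_too_few_pairs` carrying the
#' count, which the iteration treats as non-convergence.
#'
#' @param kinship a [loiselle_kinship()] result.
#' @param distances matrix from [pairwise_distances()].
#' @param d_min,d_max range bounds in metres (`d_min < d_max`).
#' @param min_pairs minimum pairs required (default 10).
#' @return the slope (numeric).
#' @export
slope_over_range <- function(kinship, distances, d_min, d_max, min_pairs = 10) {
  stopifnot(d_min < d_max)
  pv <- .pair_view(kinship, distances)
  inr <- pv$d > d_min & pv$d <= d_max
  if (sum(inr) < min_pairs) {
    cond <- structure(
      class = c("dispkin_too_few_pairs", "error", "condition"),
      list(message = sprintf("only %d pairs in (%g, %g]; need %d",
                             sum(inr), d_min, d_max, min_pairs),
           call = sys.call(-1), count = sum(inr)))
    stop(cond)
  }
  .slope_log(pv$f[inr], pv$d[inr])
}
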