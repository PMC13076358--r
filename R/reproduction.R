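#' Per-adult reproductive success tallies
#'
#' Counts offspring per candidate adult: by role (mother/father, from
#' role-resolved trios) and in total (each concordant assignment contributes
#' one count per parental slot, so the single parent of a selfed offspring
#' gains +1 in each role and +2 in total). Adults with no assigned offspring
#' are kept at zero - every adult is a potential parent.
#'
#' @param assignments a `parentage_assignment` (pairs define totals).
#' @param trios optional [resolve_roles()] result for role counts.
#' @param adults an `indiv_table` of the candidate adults.
#' @return data frame `id`, `dbh`, `site`, `as_mother`, `as_father`, `total`.
#' @export
tally_success <- function(assignments, adults, trios = NULL) {
  out <- data.frame(id = adults$id, dbh = adults$dbh, site = adults$site,
                    as_mother = 0L, as_father = 0L, total = 0L,
                    stringsAsFactors = FALSE)
  cnt <- function(ids) {
    tb <- table(factor(ids[!is.na(ids)], levels = adults$id))
    as.integer(tb)
  }
  out$total <- cnt(assignments$parent1) + cnt(assignments$parent2)
  if (!is.null(trios)) {
    res <- trios[trios$basis %in% c("plastid-match", "selfed"), , drop = FALSE]
    out$as_mother <- cnt(res$mother_id)
    out$as_father <- cnt(res$father_id)
  }
  out
}

#' Size-fecundity regression
#'
#' Ordinary least squares of total offspring count on DBH.
#'
#' @param success a [tally_success()] table (rows with missing DBH dropped).
#' @return list `slope`, `intercept`, `r_squared`, `p` (two-sided), `n`.
#' @export
dbh_fecundity_regression <- function(success) {
  d <- success[!is.na(success$dbh), ]
  if (nrow(d) < 3) stop("need >= 3 adults with DBH")
  if (stats::var(d$dbh) == 0) stop("zero DBH variance; regression undefined")
  fit <- stats::lm(total ~ dbh, data = d)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]), n = nrow(d))
}

#' Mother-versus-father role balance test
#'
#' Paired Wilcoxon signed-rank test of per-adult offspring counts as mother
#' versus as father, over adults with at least one offspring in either role;
#' zero-difference pairs are dropped per the standard procedure (all-zero
#' differences give p = 1 with a flag).
#'
#' @param success a [tally_success()] table with role counts.
#' @return list `statistic`, `p`, `n_pairs`, `all_ties` flag.
#' @export
role_balance_test <- function(success) {
  d <- success[success$as_mother + success$as_father > 0, ]
  if (nrow(d) == 0 || all(d$as_mother == d$as_father))
    return(list(statistic = NA_real_, p = 1, n_pairs = nrow(d),
                all_ties = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(d$as_mother, d$as_father,
                                            paired = TRUE, exact = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value, n_pairs = nrow(d),
       all_ties = FALSE)
}

#' Gini index of reproductive skew
#'
#' Sample Gini index `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`, without
#' small-sample correction: 0 for perfectly even nonzero counts, (n-1)/n when
#' a single adult produces everything.
#'
#' @param counts nonnegative offspring counts, not all zero.
#' @return G in `[0, 1)`.
#' @export
gini <- function(counts) {
  stopifnot(all(counts >= 0))
  if (all(counts == 0)) stop("all counts zero; Gini undefined")
  n <- length(counts)
  x <- sort(counts)
  # identity: sum_ij |x_i - x_j| = 2 * sum_i (2i - n - 1) x_(i)
  sum((2 * seq_len(n) - n - 1) * x) / (n^2 * mean(x))
}

#' Pairwise permutation test of Gini differences between sites
#'
#' Observed statistic `|G_A - G_B|` per site pair; the null pools the two
#' sites' per-adult counts and reassigns them at the original sizes.
#' P-values use the add-one convention. Sites with fewer than 2 adults are
#' skipped.
#'
#' @param site_counts named list of per-site count vectors.
#' @param n_perm permutations (default 10,000).
#' @param seed RNG seed.
#' @return list with symmetric matrices `gini_diff` and `p`, and the
#'   per-site vector `gini`.
#' @export
gini_permutation_test <- function(site_counts, n_perm = 10000, seed = 1) {
  stopifnot(length(site_counts) >= 2)
  sites <- names(site_counts)
  g <- vapply(site_counts, gini, numeric(1))
  ns <- length(sites)
  dmat <- matrix(NA_real_, ns, ns, dimnames = list(sites, sites))
  pmat <- dmat
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    xa <- site_counts[[i]]; xb <- site_counts[[j]]
    if (length(xa) < 2 || length(xb) < 2) next
    obs <- abs(g[i] - g[j])
    pool <- c(xa, xb)
    na <- length(xa)
    null <- vapply(seq_len(n_perm), function(p) {
      idx <- sample.int(length(pool), na)
      pa <- pool[idx]; pb <- pool[-idx]
      if (all(pa == 0) || all(pb == 0)) return(NA_real_)
      abs(gini(pa) - gini(pb))
    }, numeric(1))
    null <- null[!is.na(null)]
    dmat[i, j] <- dmat[j, i] <- obs
    pmat[i, j] <- pmat[j, i] <- (1 + sum(null >= obs)) / (length(null) + 1)
  }
  list(gini = g, gini_diff = dmat, p = pmat)
}

#' Per-cluster reproductive output summary
#'
#' Offspring totals per family cluster, the share of the largest cluster,
#' and the cluster count - the family-structure view of reproductive skew.
#'
#' @param clusters a [sibship_clusters()] result.
#' @return list `per_cluster` (data frame `cluster`, `size`, `share`),
#'   `n_clusters`, `max_share`.
#' @export
cluster_summary <- function(clusters) {
  cl <- clusters$clusters
  if (nrow(cl) == 0)
    return(list(per_cluster = data.frame(cluster = integer(), size = integer(),
                                         share = numeric()),
                n_clusters = 0L, max_share = NA_real_))
  total <- sum(cl$size)
  per <- data.frame(cluster = cl$cluster, size = cl$size,
                    share = cl$size / total)
  list(per_cluster = per, n_clusters = nrow(cl), max_share = max(per$share))
}
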