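#' Genotyping-error model for parentage likelihoods
#'
#' Each recorded offspring allele is, with probability `epsilon`, a random
#' draw from the locus allele-frequency distribution instead of the truly
#' transmitted allele. Folding this into the transmission probability gives,
#' for candidate parent `c` and observed allele `x`,
#' `u_c(x) = (1 - epsilon) * T_c(x) + epsilon * p(x)`, where `T_c(x)` is the
#' Mendelian transmission probability (1, 0.5 or 0) and `p(x)` the population
#' frequency.
#'
#' @param epsilon per-allele mis-scoring rate, in `[0, 0.5)` (default 0.01).
#' @return classed list (`genotyping_error_model`).
#' @export
error_model <- function(epsilon = 0.01) {
  stopifnot(epsilon >= 0, epsilon < 0.5)
  structure(list(epsilon = epsilon), class = "genotyping_error_model")
}

# Mendelian transmission probability of allele x from each candidate:
# 0.5 per copy carried. geno: candidate matrix n x 2L; returns vector.
.transmit <- function(a1, a2, x) ((a1 == x) + (a2 == x)) / 2

# Per-offspring log-likelihood matrices over all candidate parent pairs.
# Returns list(lod = C x C symmetric matrix of pair LODs, single = length-C
# vector of single-parent LODs, n_loci_used).
.lod_matrices <- function(off_geno, cand_geno, freqs, epsilon) {
  C <- nrow(cand_geno)
  L <- length(freqs)
  pairlog <- matrix(0, C, C)
  singlelog <- numeric(C)
  denomlog <- 0
  used <- 0L
  for (l in seq_len(L)) {
    x <- off_geno[2L * l - 1L]; y <- off_geno[2L * l]
    if (is.na(x)) next
    f <- freqs[[l]]
    if (!f$ok) next
    a1 <- cand_geno[, 2L * l - 1L]; a2 <- cand_geno[, 2L * l]
    typed <- !is.na(a1)
    if (!any(typed)) next
    px <- f$freq[match(x, f$alleles)]
    py <- f$freq[match(y, f$alleles)]
    if (is.na(px)) px <- 0
    if (is.na(py)) py <- 0
    ux <- (1 - epsilon) * .transmit(a1, a2, x) + epsilon * px
    uy <- (1 - epsilon) * .transmit(a1, a2, y) + epsilon * py
    # untyped candidates transmit like a random background draw
    ux[!typed] <- px
    uy[!typed] <- py
    if (x == y) {
      num <- outer(ux, ux)
      den <- px * px
      snum <- ux * px
    } else {
      num <- outer(ux, uy) + outer(uy, ux)
      den <- 2 * px * py
      snum <- ux * py + uy * px
    }
    if (den <= 0) next                 # offspring allele absent from sample
    pairlog <- pairlog + log(num) - log(den)
    singlelog <- singlelog + log(snum) - log(den)
    used <- used + 1L
  }
  if (used == 0L) stop("no usable loci for LOD computation")
  list(lod = pairlog, single = singlelog, n_loci_used = used)
}

#' LOD score of a candidate parent pair for one offspring
#'
#' Sum over jointly typed loci of the log ratio of the offspring genotype
#' probability given Mendelian transmission from the pair (with the
#' [error_model()] folded in) over its probability under a random draw from
#' the population allele frequencies. `-Inf` signals a Mendelian exclusion
#' at `epsilon = 0`.
#'
#' @param table an `indiv_table` containing all three individuals.
#' @param offspring_id,parent1_id,parent2_id individual identifiers
#'   (`parent1_id == parent2_id` scores a selfing).
#' @param freqs optional [allele_frequencies()] (defaults to `table`'s).
#' @param error an [error_model()].
#' @return the LOD score (numeric scalar).
#' @export
pair_lod <- function(table, offspring_id, parent1_id, parent2_id,
                     freqs = allele_frequencies(table), error = error_model(0)) {
  o <- match(offspring_id, table$id)
  p1 <- match(parent1_id, table$id)
  p2 <- match(parent2_id, table$id)
  if (anyNA(c(o, p1, p2))) stop("unknown individual id")
  m <- .lod_matrices(table$geno[o, ], table$geno[c(p1, p2), , drop = FALSE],
                     freqs, error$epsilon)
  m$lod[1, 2]
}

#' Calibrate LOD-gap confidence thresholds by Monte-Carlo simulation
#'
#' Simulated offspring are generated from candidate parents drawn at
#' Hardy-Weinberg proportions from the supplied allele frequencies, with the
#' error model applied to the offspring's recorded alleles; each true parent
#' is independently present in the candidate set with probability
#' `prop_sampled`. All candidate pairs are scored, and the LOD gap `delta`
#' between the best and second-best pair is recorded together with whether
#' the best pair is the true pair. The relaxed (80%) and strict (95%)
#' thresholds are the smallest `delta` values at which the accepted
#' assignments reach that success rate.
#'
#' @param freqs an [allele_frequencies()] object.
#' @param n_sim_offspring simulated offspring (default 10,000).
#' @param n_candidates candidate parents per offspring universe (default 500).
#' @param prop_sampled probability a true parent is among the candidates
#'   (default 0.25; 0 is degenerate and an error).
#' @param error an [error_model()].
#' @param seed RNG seed.
#' @return classed list (`parentage_thresholds`): `relaxed`, `strict`,
#'   simulation parameters, and the simulated `delta`/`correct` table.
#' @export
calibrate_thresholds <- function(freqs, n_sim_offspring = 10000,
                                 n_candidates = 500, prop_sampled = 0.25,
                                 error = error_model(0.01), seed = 1) {
  if (prop_sampled <= 0)
    stop("prop_sampled = 0: no correct assignment exists; thresholds undefined")
  usable <- vapply(freqs, function(f) f$ok && length(f$alleles) > 1, TRUE)
  if (!any(usable)) stop("all loci monomorphic; calibration impossible")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  L <- length(freqs)
  eps <- error$epsilon
  draw_geno <- function(n) {
    g <- matrix(NA_integer_, n, 2L * L)
    for (l in seq_len(L)) {
      f <- freqs[[l]]
      if (!f$ok) next
      k <- length(f$alleles)
      g[, 2L * l - 1L] <- f$alleles[sample.int(k, n, TRUE, prob = f$freq)]
      g[, 2L * l] <- f$alleles[sample.int(k, n, TRUE, prob = f$freq)]
    }
    g
  }
  delta <- numeric(n_sim_offspring)
  correct <- logical(n_sim_offspring)
  for (s in seq_len(n_sim_offspring)) {
    cand <- draw_geno(n_candidates)
    mo <- 1L; fa <- 2L              # candidates 1 and 2 act as true parents
    off <- integer(2L * L)
    for (l in seq_len(L)) {
      f <- freqs[[l]]
      if (!f$ok) { off[c(2L * l - 1L, 2L * l)] <- NA_integer_; next }
      am <- cand[mo, 2L * l - 1L + (stats::runif(1) < 0.5)]
      af <- cand[fa, 2L * l - 1L + (stats::runif(1) < 0.5)]
      if (eps > 0) {
        k <- length(f$alleles)
        if (stats::runif(1) < eps) am <- f$alleles[sample.int(k, 1, prob = f$freq)]
        if (stats::runif(1) < eps) af <- f$alleles[sample.int(k, 1, prob = f$freq)]
      }
      off[2L * l - 1L] <- min(am, af); off[2L * l] <- max(am, af)
    }
    mo_in <- stats::runif(1) < prop_sampled
    fa_in <- stats::runif(1) < prop_sampled
    keep <- c(if (mo_in) mo, if (fa_in) fa, 3:n_candidates)
    cand <- cand[keep, , drop = FALSE]
    m <- .lod_matrices(off, cand, freqs, eps)
    lod <- m$lod
    lod[lower.tri(lod)] <- -Inf      # unordered pairs: keep upper + diagonal
    o <- order(lod, decreasing = TRUE)[1:2]
    best <- arrayInd(o[1], dim(lod))
    delta[s] <- lod[o[1]] - lod[o[2]]
    correct[s] <- mo_in && fa_in &&
      setequal(best[1, ], c(1L, 2L))  # true parents sit first when present
  }
  thr <- function(conf) {
    ord <- order(delta, decreasing = TRUE)
    prec <- cumsum(correct[ord]) / seq_along(ord)
    ok <- which(prec >= conf)
    if (!length(ok)) return(Inf)
    delta[ord[max(ok)]]
  }
  structure(list(relaxed = thr(0.80), strict = thr(0.95),
                 n_sim_offspring = n_sim_offspring,
                 n_candidates = n_candidates, prop_sampled = prop_sampled,
                 epsilon = eps, seed = seed,
                 sims = data.frame(delta = delta, correct = correct)),
            class = "parentage_thresholds")
}

#' @export
print.parentage_thresholds <- function(x, ...) {
  cat(sprintf("parentage thresholds (%d sims, %d candidates, %.0f%% sampled, eps=%.3g):\n",
              x$n_sim_offspring, x$n_candidates, 100 * x$prop_sampled, x$epsilon))
  cat(sprintf("  relaxed (80%%): delta >= %.3f   strict (95%%): delta >= %.3f\n",
              x$relaxed, x$strict))
  invisible(x)
}

#' Likelihood parentage assignment
#'
#' For each offspring, all candidate parent pairs (selfed pairs included) are
#' scored by joint LOD; the best pair is reported with its LOD gap `delta`
#' to the second-best pair and a confidence tier from the calibrated
#' thresholds (`strict`, `relaxed`, or `none`). Exact ties for the best pair
#' give tier `none`. When the best pair fails the relaxed threshold but the
#' best single parent passes it (LOD gap over the second-best single), a
#' single-parent assignment is reported.
#'
#' @param offspring an `indiv_table` of offspring.
#' @param candidates an `indiv_table` of candidate parents (typically the
#'   same-site adults).
#' @param thresholds a [calibrate_thresholds()] result (or list with
#'   `relaxed`/`strict`).
#' @param freqs allele frequencies of the reference population (default:
#'   offspring and candidates pooled).
#' @param error an [error_model()].
#' @return data frame of class `parentage_assignment`: `offspring_id`,
#'   `parent1`, `parent2` (`NA` for unassigned or single), `lod`, `delta`,
#'   `tier`, `method`.
#' @export
assign_likelihood <- function(offspring, candidates, thresholds,
                              freqs = NULL, error = error_model(0.01)) {
  if (is.null(freqs))
    freqs <- allele_frequencies(bind_individuals(offspring, candidates))
  C <- n_individuals(candidates)
  out <- data.frame(
    offspring_id = offspring$id, parent1 = NA_character_,
    parent2 = NA_character_, lod = NA_real_, delta = NA_real_,
    tier = "none", method = "likelihood", stringsAsFactors = FALSE)
  if (C == 0) { class(out) <- c("parentage_assignment", "data.frame"); return(out) }
  for (o in seq_len(n_individuals(offspring))) {
    m <- tryCatch(.lod_matrices(offspring$geno[o, ], candidates$geno, freqs,
                                error$epsilon), error = function(e) NULL)
    if (is.null(m)) next
    lod <- m$lod
    lod[lower.tri(lod)] <- -Inf
    ord <- order(lod, decreasing = TRUE)[1:2]
    best <- lod[ord[1]]
    if (!is.finite(best)) next
    second <- if (length(ord) > 1) lod[ord[2]] else -Inf
    delta <- best - second
    idx <- arrayInd(ord[1], dim(lod))
    tier <- if (delta == 0) "none"
    else if (delta >= thresholds$strict) "strict"
    else if (delta >= thresholds$relaxed) "relaxed"
    else "none"
    if (tier != "none") {
      out$parent1[o] <- candidates$id[idx[1, 1]]
      out$parent2[o] <- candidates$id[idx[1, 2]]
      out$lod[o] <- best; out$delta[o] <- delta; out$tier[o] <- tier
    } else if (C >= 2) {
      sv <- sort(m$single, decreasing = TRUE)
      sdelta <- sv[1] - sv[2]
      if (is.finite(sv[1]) && sdelta >= thresholds$relaxed) {
        out$parent1[o] <- candidates$id[which.max(m$single)]
        out$lod[o] <- sv[1]; out$delta[o] <- sdelta
        out$tier[o] <- if (sdelta >= thresholds$strict) "strict" else "relaxed"
      }
    }
  }
  class(out) <- c("parentage_assignment", "data.frame")
  out
}

#' Exclusion-based parentage assignment
#'
#' The second, independent assignment route: Mendelian-incompatibility
#' counting. A parent-offspring dyad mismatches at a locus when they share no
#' allele; a trio mismatches when no assignment of one transmitted allele per
#' parent explains the offspring genotype. A pair is accepted only when it is
#' the unique pair with trio mismatches `<= max_mismatch` (and each dyad
#' `<= max_mismatch`); ties leave the offspring unassigned.
#'
#' @param offspring,candidates `indiv_table`s sharing the locus panel.
#' @param max_mismatch tolerated mismatching loci (default 1).
#' @return data frame of class `parentage_assignment` with columns as in
#'   [assign_likelihood()] (`lod`/`delta` are `NA`; `method` is
#'   `"exclusion"`; accepted pairs have tier `"relaxed"`).
#' @export
assign_exclusion <- function(offspring, candidates, max_mismatch = 1) {
  C <- n_individuals(candidates)
  L <- length(offspring$loci)
  out <- data.frame(
    offspring_id = offspring$id, parent1 = NA_character_,
    parent2 = NA_character_, lod = NA_real_, delta = NA_real_,
    tier = "none", method = "exclusion", stringsAsFactors = FALSE)
  if (C == 0) { class(out) <- c("parentage_assignment", "data.frame"); return(out) }
  for (o in seq_len(n_individuals(offspring))) {
    trio <- matrix(0L, C, C)
    dyad <- integer(C)
    for (l in seq_len(L)) {
      x <- offspring$geno[o, 2L * l - 1L]; y <- offspring$geno[o, 2L * l]
      if (is.na(x)) next
      a1 <- candidates$geno[, 2L * l - 1L]; a2 <- candidates$geno[, 2L * l]
      typed <- !is.na(a1)
      cx <- (a1 == x | a2 == x) & typed
      cy <- (a1 == y | a2 == y) & typed
      dyad <- dyad + as.integer(typed & !(cx | cy))
      ok <- outer(cx, cy, `&`) | outer(cy, cx, `&`)
      ok[!typed, ] <- TRUE; ok[, !typed] <- TRUE   # untyped loci do not exclude
      trio <- trio + !ok
    }
    pairok <- trio <= max_mismatch &
      outer(dyad <= max_mismatch, dyad <= max_mismatch, `&`)
    pairok[lower.tri(pairok)] <- FALSE
    hits <- which(pairok, arr.ind = TRUE)
    if (nrow(hits) == 1L) {
      out$parent1[o] <- candidates$id[hits[1, 1]]
      out$parent2[o] <- candidates$id[hits[1, 2]]
      out$tier[o] <- "relaxed"
    }
  }
  class(out) <- c("parentage_assignment", "data.frame")
  out
}

#' Concordant merge of two assignment sets
#'
#' Keeps an offspring's parent pair only when both methods assigned the
#' identical unordered pair (both parents present in both). Per-method and
#' common assignment percentages are attached as attribute `rates`.
#'
#' @param assign_a,assign_b `parentage_assignment` data frames over the same
#'   offspring universe.
#' @return `parentage_assignment` data frame (`method = "concordant"`).
#' @export
concordant <- function(assign_a, assign_b) {
  b <- assign_b[match(assign_a$offspring_id, assign_b$offspring_id), ]
  same_pair <- function(p1, p2, q1, q2) {
    !is.na(p1) & !is.na(p2) & !is.na(q1) & !is.na(q2) &
      ((p1 == q1 & p2 == q2) | (p1 == q2 & p2 == q1))
  }
  keep <- same_pair(assign_a$parent1, assign_a$parent2, b$parent1, b$parent2)
  out <- assign_a
  out$parent1[!keep] <- NA_character_
  out$parent2[!keep] <- NA_character_
  out$tier[!keep] <- "none"
  out$lod[!keep] <- NA_real_
  out$delta[!keep] <- NA_real_
  out$method <- "concordant"
  has <- function(a) !is.na(a$parent1) & !is.na(a$parent2)
  attr(out, "rates") <- c(method_a = mean(has(assign_a)),
                          method_b = mean(has(b)), common = mean(keep))
  class(out) <- c("parentage_assignment", "data.frame")
  out
}

#' Sibship clusters from parentage assignments
#'
#' Offspring sharing at least one inferred parent are connected; clusters are
#' the connected components (half-sib families); offspring with identical
#' parent pairs form full-sib subfamilies. Clusters larger than `flag_above`
#' are flagged (the mapping convention for plotted family clusters).
#'
#' @param assignments a `parentage_assignment` with assigned pairs (rows with
#'   any assigned parent participate).
#' @param flag_above flag clusters with more than this many offspring
#'   (default 5).
#' @return list `membership` (data frame `offspring_id`, `cluster`),
#'   `clusters` (data frame `cluster`, `size`, `parents`, `flagged`), and
#'   `full_sib` (data frame `parent1`, `parent2`, `size`).
#' @export
sibship_clusters <- function(assignments, flag_above = 5) {
  a <- assignments[!is.na(assignments$parent1) | !is.na(assignments$parent2), ]
  n <- nrow(a)
  if (n == 0)
    return(list(membership = data.frame(offspring_id = character(),
                                        cluster = integer()),
                clusters = data.frame(cluster = integer(), size = integer(),
                                      parents = character(),
                                      flagged = logical()),
                full_sib = data.frame(parent1 = character(),
                                      parent2 = character(),
                                      size = integer())))
  # union-find over offspring, linked through shared parents
  par <- seq_len(n)
  find <- function(i) { while (par[i] != i) { par[i] <<- par[par[i]]; i <- par[i] }; i }
  join <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) par[rj] <<- ri }
  plist <- c(stats::setNames(seq_len(n), a$parent1),
             stats::setNames(seq_len(n), a$parent2))
  plist <- plist[!is.na(names(plist)) & names(plist) != "NA"]
  for (p in unique(names(plist))) {
    members <- plist[names(plist) == p]
    if (length(members) > 1) for (m in members[-1]) join(members[1], m)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cl <- match(roots, unique(roots))
  membership <- data.frame(offspring_id = a$offspring_id, cluster = cl,
                           stringsAsFactors = FALSE)
  clusters <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    rows <- a[cl == k, ]
    pars <- sort(unique(stats::na.omit(c(rows$parent1, rows$parent2))))
    data.frame(cluster = k, size = nrow(rows),
               parents = paste(pars, collapse = ";"),
               flagged = nrow(rows) > flag_above, stringsAsFactors = FALSE)
  }))
  both <- !is.na(a$parent1) & !is.na(a$parent2)
  fs <- if (any(both)) {
    key <- apply(cbind(pmin(a$parent1[both], a$parent2[both]),
                       pmax(a$parent1[both], a$parent2[both])), 1, paste,
                 collapse = "|")
    tb <- table(key)
    pp <- do.call(rbind, strsplit(names(tb), "|", fixed = TRUE))
    data.frame(parent1 = pp[, 1], parent2 = pp[, 2],
               size = as.integer(tb), stringsAsFactors = FALSE)
  } else data.frame(parent1 = character(), parent2 = character(),
                    size = integer())
  list(membership = membership, clusters = clusters, full_sib = fs)
}
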