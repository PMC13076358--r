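# A small deterministic trio panel used across several tests: 3 loci with
# known frequencies; parents AB x CD style configurations.
trio_table <- function() {
  # individuals: off, mom, dad, plus 3 unrelated adults
  geno <- rbind(
    c(1L, 3L,  1L, 2L,  2L, 2L),   # offspring
    c(1L, 2L,  1L, 1L,  2L, 3L),   # true mother (carries 1, 1, 2)
    c(3L, 4L,  2L, 2L,  1L, 2L),   # true father (carries 3, 2, 2)
    c(2L, 2L,  3L, 3L,  1L, 1L),
    c(4L, 4L,  3L, 4L,  3L, 3L),
    c(2L, 4L,  1L, 4L,  1L, 3L))
  make_table(geno, dbh = c(5, 50, 60, 40, 45, 55),
             hap = c("H1", "H1", "H2", "H3", "H2", "H1"),
             xy = cbind(c(0, 10, 50, 80, 120, 200), rep(0, 6)))
}

test_that("pair LOD equals the hand-computed Mendelian oracle", {
  tab <- trio_table()
  freqs <- allele_frequencies(tab)
  flist <- lapply(freqs, function(f) as.list(setNames(f$freq, f$alleles)))
  off <- list(c("1", "3"), c("1", "2"), c("2", "2"))
  mom <- list(c("1", "2"), c("1", "1"), c("2", "3"))
  dad <- list(c("3", "4"), c("2", "2"), c("1", "2"))
  for (eps in c(0, 0.01, 0.1)) {
    got <- pair_lod(tab, "i001", "i002", "i003", freqs = freqs,
                    error = error_model(eps))
    want <- brute_pair_lod(off, mom, dad, flist, eps = eps)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # true parents outscore the background at eps = 0
  expect_gt(pair_lod(tab, "i001", "i002", "i003", freqs = freqs), 0)
})

test_that("impossible transmissions give -Inf LOD and exclusion agrees", {
  tab <- trio_table()
  freqs <- allele_frequencies(tab)
  # i004 (2/2, 3/3, 1/1) cannot have produced the offspring with i005
  expect_equal(pair_lod(tab, "i001", "i004", "i005", freqs = freqs), -Inf)
  exc <- assign_exclusion(tab[1], tab[c(4, 5)], max_mismatch = 0)
  expect_true(is.na(exc$parent1[1]))
  # agreement between the two routes on impossibility (trio mismatch >= 1)
  adults <- tab[2:6]
  for (a in 1:4) for (b in (a + 1):5) {
    lod <- pair_lod(tab, "i001", adults$id[a], adults$id[b], freqs = freqs)
    exc1 <- assign_exclusion(tab[1], adults[c(a, b)], max_mismatch = 0)
    ok_pair <- !is.na(exc1$parent1[1]) ||
      # unique-pair rule can reject ties; recompute raw compatibility
      all(vapply(1:3, function(l) {
        x <- tab$geno[1, 2 * l - 1]; y <- tab$geno[1, 2 * l]
        ga <- adults$geno[a, c(2 * l - 1, 2 * l)]
        gb <- adults$geno[b, c(2 * l - 1, 2 * l)]
        (x %in% ga && y %in% gb) || (y %in% ga && x %in% gb)
      }, logical(1)))
    expect_equal(is.finite(lod), ok_pair)
  }
})

test_that("monomorphic loci are uninformative: LOD contribution zero", {
  geno <- cbind(matrix(1L, 4, 2), rbind(c(1L, 2L), c(1L, 1L), c(2L, 2L),
                                        c(1L, 2L)))
  tab <- make_table(geno)
  freqs <- allele_frequencies(tab)
  lod_mono <- pair_lod(tab, "i001", "i002", "i003", freqs = freqs)
  # same data without the monomorphic locus
  tab2 <- make_table(geno[, 3:4, drop = FALSE])
  lod2 <- pair_lod(tab2, "i001", "i002", "i003",
                   freqs = allele_frequencies(tab2))
  expect_equal(lod_mono, lod2, tolerance = 1e-12)
})

test_that("threshold calibration behaves across sampling regimes", {
  p <- sim_params(n_loci = 66, target_he = 0.5, n_generations_burnin = 0,
                  plot_width = 300, plot_height = 300, adult_density = 8)
  ad <- simulate_adults(p, seed = 51)
  freqs <- allele_frequencies(ad)
  expect_error(calibrate_thresholds(freqs, prop_sampled = 0), "undefined")
  # easy limit: everything sampled, no error; nearly all true pairs accepted
  thr <- calibrate_thresholds(freqs, n_sim_offspring = 150, n_candidates = 30,
                              prop_sampled = 1, error = error_model(0), seed = 1)
  expect_gte(mean(thr$sims$correct), 0.99)
  expect_gte(mean(thr$sims$delta >= thr$relaxed), 0.99)
  # monomorphic panel cannot be calibrated
  mono <- allele_frequencies(make_table(matrix(1L, 10, 4)))
  expect_error(suppressWarnings(calibrate_thresholds(mono)), "monomorphic")
})

test_that("calibrated thresholds are stable across seeds", {
  p <- sim_params(n_loci = 20, target_he = 0.5, n_generations_burnin = 0,
                  plot_width = 300, plot_height = 300, adult_density = 8)
  ad <- simulate_adults(p, seed = 52)
  freqs <- allele_frequencies(ad)
  t1 <- calibrate_thresholds(freqs, n_sim_offspring = 1000, n_candidates = 25,
                             prop_sampled = 0.5, error = error_model(0.02),
                             seed = 1)
  t2 <- calibrate_thresholds(freqs, n_sim_offspring = 1000, n_candidates = 25,
                             prop_sampled = 0.5, error = error_model(0.02),
                             seed = 2)
  expect_true(is.finite(t1$relaxed) && is.finite(t2$relaxed))
  expect_lt(abs(t1$relaxed - t2$relaxed) / max(t1$relaxed, 1e-9), 0.25)
})

test_that("likelihood assignment recovers simulated parent pairs", {
  p <- sim_params(n_loci = 30, target_he = 0.5, n_generations_burnin = 1,
                  plot_width = 300, plot_height = 300, adult_density = 8,
                  n_offspring = 60, immigration_rate = 0, selfing_rate = 0.02)
  s <- simulate_site(p, seed = 53)
  freqs <- allele_frequencies(s$table)
  thr <- calibrate_thresholds(freqs, n_sim_offspring = 120,
                              n_candidates = n_individuals(s$adults),
                              prop_sampled = 1, error = error_model(0), seed = 2)
  lik <- assign_likelihood(s$offspring, s$adults, thr, freqs = freqs,
                           error = error_model(0))
  m <- merge(lik, s$pedigree, by = "offspring_id")
  ok <- !is.na(m$parent1) & !is.na(m$parent2)
  truepair <- (m$parent1 == m$mother_id & m$parent2 == m$father_id) |
    (m$parent1 == m$father_id & m$parent2 == m$mother_id)
  expect_gte(mean(ok), 0.95)
  expect_gte(mean(truepair[ok]), 0.99)
  expect_true(all(m$delta[ok] >= 0))
  # empty candidate list leaves everyone unassigned
  lik0 <- assign_likelihood(s$offspring[1:3], s$adults[0], thr, freqs = freqs)
  expect_true(all(is.na(lik0$parent1)))
})

test_that("exclusion assignment applies the uniqueness and mismatch rules", {
  tab <- trio_table()
  exc <- assign_exclusion(tab[1], tab[2:6], max_mismatch = 0)
  expect_setequal(c(exc$parent1[1], exc$parent2[1]), c("i002", "i003"))
  # duplicate of the true father creates a tie: unassigned
  dup <- make_table(tab$geno[c(1, 2, 3, 3), ],
                    ids = c("i001", "i002", "i003", "i003b"))
  tie <- assign_exclusion(dup[1], dup[2:4], max_mismatch = 0)
  expect_true(is.na(tie$parent1[1]))
  # one mis-scored locus tolerated at max_mismatch = 1: a 6-locus panel where
  # only the father carries allele 3, so the true pair stays unique
  L <- 6
  geno6 <- rbind(
    matrix(c(1L, 3L), 1, 2 * L),                 # offspring, (1,3) everywhere
    matrix(c(1L, 2L), 1, 2 * L),                 # mother
    matrix(c(3L, 4L), 1, 2 * L),                 # father
    matrix(c(4L, 4L), 1, 2 * L),
    matrix(c(5L, 5L), 1, 2 * L))
  bad <- make_table(geno6)
  bad$geno[1, 1:2] <- c(2L, 2L)                  # locus 1 mis-scored
  exc0 <- assign_exclusion(bad[1], bad[2:5], max_mismatch = 0)
  expect_true(is.na(exc0$parent1[1]))
  exc1 <- assign_exclusion(bad[1], bad[2:5], max_mismatch = 1)
  expect_setequal(c(exc1$parent1[1], exc1$parent2[1]), c("i002", "i003"))
})

test_that("concordance merge keeps only identical unordered pairs", {
  a <- data.frame(offspring_id = c("o1", "o2", "o3"),
                  parent1 = c("p1", "p2", "p5"), parent2 = c("p2", "p3", "p6"),
                  lod = 1, delta = 1, tier = "relaxed", method = "likelihood",
                  stringsAsFactors = FALSE)
  b <- data.frame(offspring_id = c("o1", "o2", "o3"),
                  parent1 = c("p2", "p2", NA), parent2 = c("p1", "p4", NA),
                  lod = NA, delta = NA, tier = "relaxed", method = "exclusion",
                  stringsAsFactors = FALSE)
  m <- concordant(a, b)
  expect_equal(m$parent1[1], "p1")   # order-insensitive match
  expect_true(is.na(m$parent1[2]))   # pair disagreement
  expect_true(is.na(m$parent1[3]))   # one-sided assignment
  rates <- attr(m, "rates")
  expect_equal(unname(rates["common"]), 1 / 3)
  # identity and empty-overlap limits
  expect_equal(concordant(a, a)$parent1, a$parent1)
  bb <- b; bb$parent1 <- c("x1", "x2", "x3"); bb$parent2 <- c("y1", "y2", "y3")
  expect_true(all(is.na(concordant(a, bb)$parent1)))
})

test_that("sibship clustering forms half-sib components and full-sib families", {
  asg <- data.frame(
    offspring_id = c("o1", "o2", "o3", "o4", "o5"),
    parent1 = c("p1", "p2", "p3", "p7", "p1"),
    parent2 = c("p2", "p3", "p4", "p8", "p2"),
    lod = NA, delta = NA, tier = "relaxed", method = "concordant",
    stringsAsFactors = FALSE)
  cl <- sibship_clusters(asg, flag_above = 2)
  mem <- setNames(cl$membership$cluster, cl$membership$offspring_id)
  # o1-o2 share p2, o2-o3 share p3, o5 shares both with o1: one chain
  expect_equal(length(unique(mem[c("o1", "o2", "o3", "o5")])), 1)
  expect_false(mem["o4"] == mem["o1"])
  expect_equal(sort(cl$clusters$size), c(1, 4))
  expect_true(cl$clusters$flagged[cl$clusters$size == 4])
  expect_equal(cl$full_sib$size[cl$full_sib$parent1 == "p1"], 2)
  # invariant under offspring relabelling
  cl2 <- sibship_clusters(asg[c(3, 1, 5, 2, 4), ], flag_above = 2)
  expect_equal(sort(cl2$clusters$size), c(1, 4))
})
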