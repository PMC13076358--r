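test_that("allele frequencies count non-missing gene copies", {
  g <- rbind(c(1L, 1L), c(1L, 2L))
  f <- allele_frequencies(make_table(g))
  expect_equal(f$L01$freq, c(0.75, 0.25))
  expect_equal(f$L01$n, 4L)
  g2 <- rbind(c(1L, 1L), c(NA, NA), c(1L, 2L))
  f2 <- allele_frequencies(make_table(g2))
  expect_equal(f2$L01$n, 4L)
  g3 <- rbind(c(2L, 2L), c(2L, 2L))
  f3 <- allele_frequencies(make_table(g3))
  expect_equal(f3$L01$freq, 1)
})

test_that("rarefaction closed form matches identities and hand values", {
  # 99 copies of A and 1 of B, k = 50: 2 - C(99,50)/C(100,50) = 1.5
  g <- rbind(matrix(1L, 49, 2), c(1L, 2L))
  f <- allele_frequencies(make_table(g))
  ar <- allelic_richness(f, 50)
  expect_equal(ar$mean, 1.5)
  # k = n_l gives the observed allele count
  ar_full <- allelic_richness(f, 100)
  expect_equal(ar_full$mean, 2)
  # sample exactly the standard: monomorphic 50-copy locus
  g1 <- matrix(1L, 25, 2)
  expect_equal(allelic_richness(allele_frequencies(make_table(g1)), 50)$mean, 1)
  expect_error(allelic_richness(f, 1), ">= 2")
})

test_that("rarefaction is monotone in k and equals brute-force subsampling", {
  counts <- c(11, 6, 3)            # 3-allele toy locus, 20 copies
  g <- matrix(rep.int(1:3, counts), 10, 2)
  f <- allele_frequencies(make_table(g))
  ar_k <- vapply(2:20, function(k) allelic_richness(f, k)$mean, numeric(1))
  expect_true(all(diff(ar_k) >= -1e-12))
  expect_equal(ar_k[length(ar_k)], 3)
  set.seed(5)
  mc <- brute_rarefaction(counts, k = 8, n_draws = 10000)
  expect_equal(allelic_richness(f, 8)$mean, mc, tolerance = 0.02)
})

test_that("heterozygosities follow the unbiased formulas", {
  g <- rbind(c(1L, 2L), c(1L, 2L), c(1L, 2L))
  h <- heterozygosities(make_table(g))
  expect_equal(h$ho, 1)
  # 2 individuals AA, AB: H_O = 0.5; H_E = 4/3 * (1 - 0.625) = 0.5
  g2 <- rbind(c(1L, 1L), c(1L, 2L))
  h2 <- heterozygosities(make_table(g2))
  expect_equal(h2$ho, 0.5)
  expect_equal(h2$he, 0.5)
  # large-n limit at p = 0.5 approaches 0.5
  set.seed(6)
  g3 <- matrix(sample(1:2, 4000, replace = TRUE), 2000, 2)
  h3 <- heterozygosities(make_table(g3))
  expect_equal(h3$he, 0.5, tolerance = 0.02)
})

test_that("F_IS sign and identities behave, with a calibrated permutation null", {
  # all heterozygotes at p = 0.5: strong heterozygote excess
  g <- matrix(rep(c(1L, 2L), 30), 30, 2, byrow = TRUE)
  f <- inbreeding_coefficient(make_table(g), n_perm = 200, seed = 1)
  expect_lt(f$fis, -0.8)
  expect_lt(f$p, 0.05)
  # H_O = H_E gives F_IS = 0 (the AA,AB pair from the worked example)
  g2 <- rbind(c(1L, 1L), c(1L, 2L))
  f2 <- inbreeding_coefficient(make_table(g2), n_perm = 50, seed = 1)
  expect_equal(f2$fis, 0)
  g3 <- matrix(1L, 5, 2)
  expect_error(inbreeding_coefficient(make_table(g3)), "undefined")
})

test_that("Weir-Cockerham F_ST separates null and fixed cases", {
  set.seed(7)
  # split halves of one panmictic pool: theta near 0
  g <- random_geno(80, 6, k = 5)
  tab <- make_table(g)
  tab$site <- rep(c("a", "b"), 40)
  res <- pairwise_fst(tab, n_perm = 200, seed = 2)
  expect_lt(abs(res$fst["a", "b"]), 0.02)
  expect_gt(res$p["a", "b"], 0.05)
  # fixed alternative alleles: theta = 1
  gf <- rbind(matrix(1L, 20, 8), matrix(2L, 20, 8))
  tf <- make_table(gf)
  tf$site <- rep(c("a", "b"), each = 20)
  resf <- pairwise_fst(tf, n_perm = 50, seed = 3)
  expect_equal(resf$fst["a", "b"], 1)
  expect_lt(resf$p["a", "b"], 0.05)
})

test_that("selfing transforms follow the equilibrium algebra", {
  expect_equal(selfing_rate(make_table(rbind(c(1L, 1L), c(1L, 2L))))$s_fis, 0)
  # s = 2F/(1+F): F = 1/3 -> 0.5
  sr <- selfing_rate(make_table(random_geno(4, 2)), fis = 1 / 3)
  expect_equal(sr$s_fis, 0.5)
  sr2 <- selfing_rate(make_table(random_geno(4, 2)), fis = -0.5)
  expect_equal(sr2$s_fis, 0)     # clipped
})

test_that("g2 selfing estimator recovers the simulated rate", {
  # equilibrium mixed-mating populations; spatially unrestricted pollen
  p <- sim_params(plot_width = 600, plot_height = 500, adult_density = 10,
                  aggregation = NULL, selfing_rate = 0.3,
                  fecundity_dispersion = 0, n_generations_burnin = 8,
                  immigration_rate = 0,
                  pollen_kernel = list(scale = 1e6, shape = 1))
  est <- vapply(1:8, function(r)
    selfing_rate(simulate_adults(p, seed = 300 + r))$s_g2, numeric(1))
  expect_lt(abs(mean(est) - 0.3), 0.05)
  # and detects no identity disequilibrium without selfing
  p0 <- sim_params(plot_width = 600, plot_height = 500, adult_density = 8,
                   aggregation = NULL, selfing_rate = 0, n_generations_burnin = 0,
                   immigration_rate = 0)
  sr0 <- selfing_rate(simulate_adults(p0, seed = 77))
  expect_lt(sr0$s_g2, 0.05)
  expect_gt(sr0$g2_p, 0.01)
})

test_that("plastid diversity formulas are exact", {
  tab <- make_table(random_geno(4, 1), hap = c("H1", "H1", "H1", "H1"))
  pd <- plastid_diversity(tab)
  expect_equal(pd$effective_n, 1)
  expect_equal(pd$he, 0)
  # frequencies (0.5, 0.3, 0.2): effective number = 1/0.38
  hap <- rep(c("A", "B", "C"), c(50, 30, 20))
  tab2 <- make_table(random_geno(100, 1), hap = hap)
  pd2 <- plastid_diversity(tab2)
  expect_equal(pd2$effective_n, 1 / 0.38, tolerance = 1e-9)
  expect_equal(pd2$he, 100 / 99 * 0.62)
  # 4 equifrequent haplotypes, large n
  tab3 <- make_table(random_geno(400, 1), hap = rep(c("A", "B", "C", "D"), 100))
  expect_equal(plastid_diversity(tab3)$effective_n, 4)
  expect_equal(plastid_diversity(tab3)$he, 0.75, tolerance = 0.01)
})

test_that("diversity report assembles one row per site and size class", {
  p <- sim_params(n_loci = 6, n_offspring = 40, n_generations_burnin = 0,
                  plot_width = 300, plot_height = 300, adult_density = 8)
  s <- simulate_site(p, seed = 31)
  rep1 <- diversity_report(s$table, area_ha = c(site1 = 9), n_perm = 100, seed = 1)
  expect_equal(nrow(rep1), 2)
  expect_setequal(rep1$size_class, c("SSS", "ADL"))
  expect_true(all(rep1$he > 0 & rep1$he < 1))
  expect_true(all(rep1$a_r >= 1 | is.na(rep1$a_r)))
  expect_true(all(rep1$fis_tier %in% c("***", "**", "*", "ns")))
})
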