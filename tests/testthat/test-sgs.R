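test_that("kinship matches the brute-force double loop, with missing data", {
  set.seed(11)
  tab <- make_table(random_geno(20, 5, k = 4, miss = 0.15),
                    xy = cbind(runif(20), runif(20)))
  kin <- loiselle_kinship(tab, mode = "diploid", min_loci = 1)
  ref <- brute_loiselle(tab)
  expect_lt(max(abs(kin$fij - ref), na.rm = TRUE), 1e-12)
  expect_equal(kin$fij, t(kin$fij))
  # haploid mode against the same oracle
  tab2 <- make_table(random_geno(15, 1),
                     hap = sample(c("A", "B", "C"), 15, replace = TRUE),
                     xy = cbind(runif(15), runif(15)))
  kinh <- loiselle_kinship(tab2, mode = "haploid")
  refh <- brute_loiselle(tab2, mode = "haploid")
  expect_lt(max(abs(kinh$fij - refh), na.rm = TRUE), 1e-12)
})

test_that("kinship attains the textbook values in the large-sample limit", {
  # near-exact p = 0.5 biallelic locus with many individuals: the 1/(n-1)
  # correction is negligible and AA~AA -> 1, AA~BB -> -1, AB~AB -> 0
  n <- 1000
  g <- rbind(matrix(c(1L, 1L), n / 2, 2, byrow = TRUE),
             matrix(c(2L, 2L), n / 2, 2, byrow = TRUE))
  tab <- make_table(g)
  kin <- loiselle_kinship(tab, mode = "diploid", min_loci = 1)
  expect_equal(kin$fij[1, 2], 1, tolerance = 0.01)          # AA with AA
  expect_equal(kin$fij[1, n / 2 + 1], -1, tolerance = 0.01) # AA with BB
  # heterozygote pair at intermediate frequencies: zero allele deviations
  ghet <- rbind(c(1L, 2L), c(1L, 2L),
                matrix(c(1L, 1L), 499, 2, byrow = TRUE),
                matrix(c(2L, 2L), 499, 2, byrow = TRUE))
  kin2 <- loiselle_kinship(make_table(ghet), mode = "diploid", min_loci = 1)
  expect_equal(kin2$fij[1, 2], 0, tolerance = 0.01)
})

test_that("kinship centres near zero on panmictic data", {
  p <- sim_params(n_loci = 20, n_generations_burnin = 0, plot_width = 400,
                  plot_height = 400, adult_density = 8, aggregation = NULL)
  ad <- simulate_adults(p, seed = 12)
  kin <- loiselle_kinship(ad, mode = "diploid")
  expect_lt(abs(mean(kin$fij, na.rm = TRUE)), 0.005)
})

test_that("pairs below the joint-locus minimum are dropped", {
  g <- random_geno(6, 3, k = 4)
  g[1, ] <- NA                      # individual 1 typed nowhere
  tab <- make_table(g)
  kin <- loiselle_kinship(tab, mode = "diploid", min_loci = 2)
  expect_true(all(is.na(kin$fij[1, ])))
  expect_true(all(kin$n_loci[1, ] == 0))
})

test_that("correlogram satisfies the defining identities", {
  p <- sim_params(n_loci = 12, n_generations_burnin = 3, plot_width = 400,
                  plot_height = 400, adult_density = 10,
                  seed_kernel = list(scale = 15, shape = 1),
                  pollen_kernel = list(scale = 40, shape = 1))
  ad <- simulate_adults(p, seed = 13)
  dm <- pairwise_distances(ad)
  kin <- loiselle_kinship(ad, mode = "diploid", min_loci = 1)
  ac <- autocorrelogram(kin, dm, breaks = c(30, 60, 90, 130, 170, 220, 300, 600),
                        n_perm = 100, seed = 2)
  expect_equal(ac$sp, -ac$b_log / (1 - ac$f1))
  expect_equal(ac$ns * ac$sp, 1)
  expect_equal(ac$f1, ac$classes$mean_fij[1])
  expect_true(all(ac$classes$env_lo <= ac$classes$env_hi, na.rm = TRUE))
  expect_equal(ac$n_zero_dist, 0)
  expect_equal(sum(ac$classes$n_pairs),
               sum(dm[upper.tri(dm)] <= 600))
  # degenerate Sp cases
  expect_equal(sp_statistic(0, 0), 0)
  expect_equal(neighborhood_size(0), Inf)
})

test_that("empty first class is an error", {
  tab <- make_table(random_geno(8, 3), xy = cbind(100 * (1:8), rep(0, 8)))
  kin <- loiselle_kinship(tab, mode = "diploid", min_loci = 1)
  dm <- pairwise_distances(tab)
  expect_error(autocorrelogram(kin, dm, breaks = c(30, 600), n_perm = 10),
               "first distance class")
})

test_that("location-permutation null keeps the observed F1 inside the envelope", {
  # genotypes with no spatial signal: the observed statistic behaves like a
  # draw from its own permutation null
  set.seed(14)
  inside <- vapply(1:40, function(r) {
    tab <- make_table(random_geno(40, 10, k = 4),
                      xy = cbind(runif(40, 0, 200), runif(40, 0, 200)))
    kin <- loiselle_kinship(tab, mode = "diploid", min_loci = 1)
    dm <- pairwise_distances(tab)
    ac <- autocorrelogram(kin, dm, breaks = c(50, 100, 300), n_perm = 99,
                          seed = r)
    ac$f1 >= ac$classes$env_lo[1] && ac$f1 <= ac$classes$env_hi[1]
  }, logical(1))
  expect_gte(mean(inside), 0.85)
})

test_that("restricted-range slope honours its contracts", {
  set.seed(15)
  n <- 40
  xy <- cbind(runif(n, 0, 300), runif(n, 0, 300))
  tab <- make_table(random_geno(n, 2), xy = xy)
  dm <- pairwise_distances(tab)
  # synthetic exactly log-linear kinship: F_ij = 0.1 - 0.02 ln(d)
  kin <- loiselle_kinship(tab, mode = "diploid", min_loci = 1)
  kin$fij[] <- 0.1 - 0.02 * log(pmax(dm, 1e-12))
  diag(kin$fij) <- NA
  expect_equal(slope_over_range(kin, dm, 1, 500), -0.02, tolerance = 1e-9)
  expect_equal(slope_over_range(kin, dm, 20, 120), -0.02, tolerance = 1e-9)
  # full range reproduces the unrestricted slope for real kinship
  kin2 <- loiselle_kinship(tab, mode = "diploid", min_loci = 1)
  ac <- autocorrelogram(kin2, dm, breaks = c(100, 500), n_perm = 10, seed = 1)
  expect_equal(slope_over_range(kin2, dm, 0, max(dm) + 1), ac$b_log)
  # too few pairs: condition carries the count
  err <- tryCatch(slope_over_range(kin2, dm, 0.001, 0.002),
                  dispkin_too_few_pairs = identity)
  expect_s3_class(err, "dispkin_too_few_pairs")
  expect_equal(err$count, 0)
})

test_that("plastid SGS is stronger than nuclear SGS under short seed kernels", {
  p <- sim_params(n_loci = 16, n_generations_burnin = 6, plot_width = 400,
                  plot_height = 400, adult_density = 10, aggregation = NULL,
                  n_plastid_haplotypes = 12, target_he_plastid = 0.8,
                  seed_kernel = list(scale = 12, shape = 1),
                  pollen_kernel = list(scale = 60, shape = 1),
                  immigration_rate = 0)
  sp_n <- sp_p <- numeric(3)
  for (r in 1:3) {
    ad <- simulate_adults(p, seed = 40 + r)
    dm <- pairwise_distances(ad)
    acn <- autocorrelogram(loiselle_kinship(ad, mode = "diploid",
                                            min_loci = 12), dm,
                           n_perm = 60, seed = r)
    acp <- autocorrelogram(loiselle_kinship(ad, mode = "haploid"), dm,
                           n_perm = 60, seed = r)
    sp_n[r] <- acn$sp; sp_p[r] <- acp$sp
  }
  expect_true(all(sp_p > sp_n))
})
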