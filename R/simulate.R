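#' Parameters for the spatially explicit forward mating simulator
#'
#' The simulator emulates a closed, fully censused forest plot: adults are
#' placed by a Thomas cluster process (aggregates of trees around unobserved
#' cluster centres), genotypes are initialised at Hardy-Weinberg proportions
#' from Dirichlet-drawn allele frequencies tuned to a target gene diversity,
#' and reproduction proceeds by fecundity-weighted mother sampling, distance-
#' kernel-weighted father sampling, seed-kernel offspring placement with
#' rejection at the plot edge, Mendelian transmission of nuclear alleles and
#' strictly maternal plastid inheritance. Burn-in generations of replacement
#' reproduction let spatial genetic structure accumulate before the final
#' offspring cohort is drawn.
#'
#' Dispersal kernels belong to the exponential-power family
#' `f(d) proportional to exp(-(d/a)^b)` (b = 1 exponential, b = 2 Gaussian).
#'
#' @param plot_width,plot_height plot dimensions (m).
#' @param adult_density adults per hectare.
#' @param aggregation `NULL` for complete spatial randomness, or a list with
#'   `intensity` (cluster centres per ha) and `sigma` (cluster spread, m).
#' @param n_loci number of nuclear microsatellite loci.
#' @param allele_count_prior alleles per locus.
#' @param target_he target expected heterozygosity used to tune the Dirichlet
#'   concentration of initial allele frequencies.
#' @param n_plastid_haplotypes number of plastid haplotypes in the founding
#'   pool.
#' @param target_he_plastid target haplotype diversity of the founding
#'   plastid pool (must satisfy `(1 - he) * k > 1`; capped internally).
#' @param seed_kernel,pollen_kernel lists `list(scale, shape)` of the
#'   exponential-power dispersal kernels (m).
#' @param selfing_rate probability an offspring is selfed.
#' @param fecundity_dispersion variance-inflation of per-adult fecundity:
#'   relative fecundities are Gamma(shape = 1/dispersion) with mean 1; 0
#'   means equal fecundity.
#' @param n_offspring size of the final offspring cohort.
#' @param n_generations_burnin replacement generations before the final
#'   cohort.
#' @param immigration_rate probability the father of an offspring is an
#'   unsampled external individual.
#' @param site site label stamped on simulated individuals.
#' @return classed list of simulation parameters (`sim_params`).
#' @export
sim_params <- function(plot_width = 500, plot_height = 500,
                       adult_density = 5,
                       aggregation = list(intensity = 0.2, sigma = 40),
                       n_loci = 66, allele_count_prior = 8, target_he = 0.52,
                       n_plastid_haplotypes = 10, target_he_plastid = 0.55,
                       seed_kernel = list(scale = 25, shape = 1),
                       pollen_kernel = list(scale = 120, shape = 1),
                       selfing_rate = 0.01, fecundity_dispersion = 1,
                       n_offspring = 250, n_generations_burnin = 5,
                       immigration_rate = 0.1, site = "site1") {
  p <- as.list(environment())
  stopifnot(p$plot_width > 0, p$plot_height > 0, p$adult_density > 0,
            p$selfing_rate >= 0, p$selfing_rate <= 1,
            p$immigration_rate >= 0, p$immigration_rate <= 1,
            p$seed_kernel$scale >= 0, p$pollen_kernel$scale > 0,
            p$fecundity_dispersion >= 0)
  class(p) <- "sim_params"
  p
}

#' Sample dispersal distances from an exponential-power kernel
#'
#' Radial distances for the 2-D kernel `f(x) proportional to exp(-(r/a)^b)`:
#' `r = a * G^(1/b)` with `G ~ Gamma(shape = 2/b)`.
#'
#' @param n number of draws.
#' @param scale kernel scale `a` (m).
#' @param shape kernel shape `b`.
#' @return numeric vector of distances.
#' @export
rkernel <- function(n, scale, shape = 1) {
  if (scale == 0) return(rep(0, n))
  scale * stats::rgamma(n, shape = 2 / shape, scale = 1)^(1 / shape)
}

#' Moments of the exponential-power dispersal kernel
#'
#' Mean distance `a*gamma(3/b)/gamma(2/b)`, mean squared distance
#' `a^2*gamma(4/b)/gamma(2/b)`, axial sigma `sqrt(E[r^2]/2)` (half the mean
#' squared distance, the convention used throughout the dispersal-history
#' estimators), and the median.
#'
#' @param scale,shape kernel parameters.
#' @return list `mean`, `mean_sq`, `axial_sigma`, `median`.
#' @export
kernel_moments <- function(scale, shape = 1) {
  m1 <- scale * gamma(3 / shape) / gamma(2 / shape)
  m2 <- scale^2 * gamma(4 / shape) / gamma(2 / shape)
  med <- scale * stats::qgamma(0.5, shape = 2 / shape)^(1 / shape)
  list(mean = m1, mean_sq = m2, axial_sigma = sqrt(m2 / 2), median = med)
}

# Dirichlet concentration giving expected gene diversity he with k alleles
.dirichlet_alpha <- function(he, k) {
  stopifnot((1 - he) * k > 1)
  he / ((1 - he) * k - 1)
}

.rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  while (sum(g) == 0) g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

# positions from a Thomas process (or CSR) clipped to the plot
.sim_positions <- function(n, params) {
  w <- params$plot_width; h <- params$plot_height
  if (is.null(params$aggregation))
    return(cbind(stats::runif(n, 0, w), stats::runif(n, 0, h)))
  area_ha <- w * h / 1e4
  npar <- max(1L, stats::rpois(1, params$aggregation$intensity * area_ha))
  par_xy <- cbind(stats::runif(npar, 0, w), stats::runif(npar, 0, h))
  who <- sample.int(npar, n, replace = TRUE)
  xy <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      p <- par_xy[who[i], ] + stats::rnorm(2, 0, params$aggregation$sigma)
      if (p[1] >= 0 && p[1] <= w && p[2] >= 0 && p[2] <= h) break
    }
    if (p[1] < 0 || p[1] > w || p[2] < 0 || p[2] > h)
      p <- c(stats::runif(1, 0, w), stats::runif(1, 0, h))
    xy[i, ] <- p
  }
  xy
}

#' Simulate the adult population of a plot
#'
#' Draws the adult count from a Poisson with mean density x area, places
#' adults by the configured point process, initialises genotypes and plastid
#' haplotypes from Dirichlet-drawn founding frequencies, then applies
#' `n_generations_burnin` rounds of replacement reproduction (each generation
#' produced by [mate_and_disperse()] and promoted to adulthood) so that
#' spatial genetic structure accumulates.
#'
#' @param params a [sim_params()] object.
#' @param seed RNG seed.
#' @return an `indiv_table` of adults (all DBH >= 30 cm).
#' @export
simulate_adults <- function(params, seed = 1) {
  area_ha <- params$plot_width * params$plot_height / 1e4
  if (params$adult_density * area_ha < 2)
    stop("expected adult count < 2; enlarge plot or density")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  n <- stats::rpois(1, params$adult_density * area_ha)
  if (n < 2) n <- 2L
  xy <- .sim_positions(n, params)
  K <- params$allele_count_prior
  alpha <- .dirichlet_alpha(params$target_he, K)
  geno <- matrix(NA_integer_, n, 2L * params$n_loci)
  for (l in seq_len(params$n_loci)) {
    p <- .rdirichlet1(K, alpha)
    geno[, 2L * l - 1L] <- sample.int(K, n, replace = TRUE, prob = p)
    geno[, 2L * l] <- sample.int(K, n, replace = TRUE, prob = p)
  }
  if (params$n_plastid_haplotypes == 1L) {
    hap <- rep("H1", n)
  } else {
    he_p <- min(params$target_he_plastid,
                1 - 1.5 / params$n_plastid_haplotypes)
    hp <- .rdirichlet1(params$n_plastid_haplotypes,
                       .dirichlet_alpha(he_p, params$n_plastid_haplotypes))
    hap <- paste0("H", sample.int(params$n_plastid_haplotypes, n,
                                  replace = TRUE, prob = hp))
  }
  adults <- individual_table(
    id = sprintf("%s_A%04d", params$site, seq_len(n)),
    site = params$site, coords = xy, coord_mode = "planar",
    geno = geno, loci = sprintf("loc%02d", seq_len(params$n_loci)),
    dbh = 30 + stats::rgamma(n, shape = 1.8, scale = 18), hap = hap)
  for (g in seq_len(params$n_generations_burnin)) {
    res <- mate_and_disperse(adults, params, n_offspring = n,
                             seed = NULL, id_prefix = sprintf("B%d", g))
    off <- res$offspring
    adults <- individual_table(
      id = sprintf("%s_A%04d", params$site, seq_len(n)),
      site = params$site, coords = off$coords, coord_mode = "planar",
      geno = off$geno, loci = off$loci,
      dbh = 30 + stats::rgamma(n, shape = 1.8, scale = 18), hap = off$hap)
  }
  adults
}

#' One mating and dispersal episode
#'
#' For each offspring: a mother is sampled proportionally to relative
#' fecundity (Gamma-distributed multipliers, see [sim_params()]); with
#' probability `selfing_rate` the father is the mother, otherwise with
#' probability `immigration_rate` the father is an unsampled external
#' individual (genotype drawn from the current adult allele frequencies) and
#' otherwise a local father is sampled proportionally to fecundity times the
#' pollen-kernel weight of his distance to the mother. The offspring is
#' placed at the mother plus a seed-kernel displacement in a uniform
#' direction, resampled until it falls inside the plot; nuclear alleles are
#' transmitted Mendelian (no mutation) and the plastid haplotype is the
#' mother's. The realised seed (mother to offspring) and pollen (father to
#' mother) distances are recorded in the truth pedigree.
#'
#' @param adults an `indiv_table` of candidate parents (>= 2 individuals).
#' @param params a [sim_params()] object.
#' @param n_offspring number of offspring to produce (> 0).
#' @param seed RNG seed (`NULL` to continue the current RNG stream).
#' @param id_prefix prefix for offspring identifiers.
#' @return list `offspring` (an `indiv_table`, DBH < 30) and `pedigree`
#'   (data frame: `offspring_id`, `mother_id`, `father_id` (`"external"` for
#'   immigrant pollen), `seed_dist_m`, `pollen_dist_m`, `selfed`,
#'   `immigrant`).
#' @export
mate_and_disperse <- function(adults, params, n_offspring = params$n_offspring,
                              seed = NULL, id_prefix = "O") {
  n <- n_individuals(adults)
  if (n < 2) stop("need >= 2 adults")
  if (n_offspring <= 0) stop("n_offspring must be positive")
  if (!is.null(seed)) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
  }
  w <- params$plot_width; h <- params$plot_height
  disp <- params$fecundity_dispersion
  fec <- if (disp <= 0) rep(1, n) else
    stats::rgamma(n, shape = 1 / disp, scale = disp)
  fec[fec <= 0] <- min(fec[fec > 0], 1e-12)
  xy <- adults$coords
  dmat <- as.matrix(stats::dist(xy))
  a_p <- params$pollen_kernel$scale; b_p <- params$pollen_kernel$shape
  kw <- exp(-(dmat / a_p)^b_p)
  mom <- sample.int(n, n_offspring, replace = TRUE, prob = fec)
  selfed <- stats::runif(n_offspring) < params$selfing_rate
  immig <- !selfed & stats::runif(n_offspring) < params$immigration_rate
  dad <- integer(n_offspring)
  for (o in seq_len(n_offspring)) {
    if (selfed[o]) { dad[o] <- mom[o]; next }
    if (immig[o]) { dad[o] <- NA_integer_; next }
    wgt <- fec * kw[, mom[o]]
    wgt[mom[o]] <- 0
    if (sum(wgt) <= 0) wgt[-mom[o]] <- 1
    dad[o] <- sample.int(n, 1, prob = wgt)
  }
  # offspring placement with edge rejection
  pos <- matrix(NA_real_, n_offspring, 2)
  for (o in seq_len(n_offspring)) {
    m <- xy[mom[o], ]
    ok <- FALSE
    for (try in 1:1000) {
      r <- rkernel(1, params$seed_kernel$scale, params$seed_kernel$shape)
      th <- stats::runif(1, 0, 2 * pi)
      p <- m + r * c(cos(th), sin(th))
      if (p[1] >= 0 && p[1] <= w && p[2] >= 0 && p[2] <= h) { ok <- TRUE; break }
    }
    pos[o, ] <- if (ok) p else m
  }
  # background allele frequencies for immigrant pollen
  freqs <- allele_frequencies(adults)
  L <- length(adults$loci)
  geno <- matrix(NA_integer_, n_offspring, 2L * L)
  pick <- function(pair) if (pair[1] == pair[2]) pair[1] else
    pair[1 + (stats::runif(1) < 0.5)]
  for (o in seq_len(n_offspring)) {
    for (l in seq_len(L)) {
      ma <- adults$geno[mom[o], c(2L * l - 1L, 2L * l)]
      am <- pick(ma)
      af <- if (is.na(dad[o])) {
        f <- freqs[[l]]
        f$alleles[sample.int(length(f$alleles), 1, prob = f$freq)]
      } else pick(adults$geno[dad[o], c(2L * l - 1L, 2L * l)])
      geno[o, 2L * l - 1L] <- am
      geno[o, 2L * l] <- af
    }
  }
  seed_d <- sqrt(rowSums((pos - xy[mom, , drop = FALSE])^2))
  pollen_d <- ifelse(selfed, 0,
                     ifelse(is.na(dad), NA_real_, dmat[cbind(dad, mom)]))
  ids <- sprintf("%s_%s%04d", params$site, id_prefix, seq_len(n_offspring))
  offspring <- individual_table(
    id = ids, site = params$site, coords = pos, coord_mode = "planar",
    geno = geno, loci = adults$loci,
    dbh = pmin(29.9, 1 + stats::rgamma(n_offspring, shape = 2, scale = 6)),
    hap = adults$hap[mom])
  pedigree <- data.frame(
    offspring_id = ids, mother_id = adults$id[mom],
    father_id = ifelse(is.na(dad), "external", adults$id[ifelse(is.na(dad), 1L, dad)]),
    seed_dist_m = seed_d, pollen_dist_m = pollen_d,
    selfed = selfed, immigrant = immig, stringsAsFactors = FALSE)
  list(offspring = offspring, pedigree = pedigree)
}

#' Simulate a full site: burn-in adults plus an offspring cohort
#'
#' @param params a [sim_params()] object.
#' @param seed RNG seed.
#' @return list `table` (adults and offspring combined), `adults`,
#'   `offspring`, `pedigree` (truth), `params`.
#' @export
simulate_site <- function(params, seed = 1) {
  adults <- simulate_adults(params, seed = seed)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed + 500009L)
  res <- mate_and_disperse(adults, params, params$n_offspring, seed = NULL)
  list(table = bind_individuals(adults, res$offspring), adults = adults,
       offspring = res$offspring, pedigree = res$pedigree, params = params)
}

#' Four-site study preset
#'
#' Parameter sets emulating the design of a four-site tropical-forest survey:
#' plots of 30, 25, 38 and 17 ha; adult densities 4.1, 2.6, 3.8 and 7.9 per
#' ha; offspring cohorts of 243, 295, 237 and 282; nuclear gene diversity
#' near 0.5 at 66 loci; 5-13 plastid haplotypes per site; selfing 0.01;
#' seed-kernel medians of roughly 20-75 m and pollen-kernel medians of
#' roughly 130-290 m; and fecundity skew ranging from even to strongly
#' skewed.
#'
#' @return named list of four [sim_params()] objects.
#' @export
study_preset <- function() {
  list(
    site1 = sim_params(plot_width = 600, plot_height = 500, adult_density = 4.1,
                       n_offspring = 243, target_he = 0.57,
                       n_plastid_haplotypes = 11, target_he_plastid = 0.80,
                       seed_kernel = list(scale = 30, shape = 1),
                       pollen_kernel = list(scale = 170, shape = 1),
                       fecundity_dispersion = 0.2, immigration_rate = 0.3,
                       site = "site1"),
    site2 = sim_params(plot_width = 500, plot_height = 500, adult_density = 2.6,
                       n_offspring = 295, target_he = 0.56,
                       n_plastid_haplotypes = 9, target_he_plastid = 0.80,
                       seed_kernel = list(scale = 15, shape = 1),
                       pollen_kernel = list(scale = 112, shape = 1),
                       fecundity_dispersion = 1.5, immigration_rate = 0.1,
                       site = "site2"),
    site3 = sim_params(plot_width = 760, plot_height = 500, adult_density = 3.8,
                       n_offspring = 237, target_he = 0.57,
                       n_plastid_haplotypes = 12, target_he_plastid = 0.80,
                       seed_kernel = list(scale = 45, shape = 1),
                       pollen_kernel = list(scale = 105, shape = 1),
                       fecundity_dispersion = 0.8, immigration_rate = 0.2,
                       site = "site3"),
    site4 = sim_params(plot_width = 425, plot_height = 400, adult_density = 7.9,
                       n_offspring = 282, target_he = 0.60,
                       n_plastid_haplotypes = 18, target_he_plastid = 0.85,
                       seed_kernel = list(scale = 12, shape = 1),
                       pollen_kernel = list(scale = 79, shape = 1),
                       fecundity_dispersion = 2, immigration_rate = 0.05,
                       site = "site4"))
}

#' Simulate the four-site study fixture
#'
#' Runs [simulate_site()] for each preset (or supplied) parameter set and,
#' when `out_dir` is given, writes the native-dialect CSV fixture and the
#' truth pedigree per site plus a realised-summary CSV. Byte-identical
#' outputs for identical seeds.
#'
#' @param seed RNG seed (per-site seeds are derived from it).
#' @param params_per_site list of [sim_params()] (default [study_preset()]).
#' @param out_dir optional output directory.
#' @return named list of [simulate_site()] results, with a `summary` data
#'   frame attached as an attribute.
#' @export
simulate_study_sites <- function(seed = 1, params_per_site = study_preset(),
                                 out_dir = NULL) {
  res <- list()
  for (i in seq_along(params_per_site)) {
    p <- params_per_site[[i]]
    res[[p$site]] <- simulate_site(p, seed = seed + 7919L * i)
  }
  summ <- do.call(rbind, lapply(res, function(r) {
    freqs <- allele_frequencies(r$table)
    he <- mean(.he_per_locus(freqs), na.rm = TRUE)
    area <- r$params$plot_width * r$params$plot_height / 1e4
    data.frame(site = r$params$site, area_ha = area,
               n_adults = n_individuals(r$adults),
               n_offspring = n_individuals(r$offspring),
               adult_density_ha = n_individuals(r$adults) / area,
               total_density_ha = n_individuals(r$table) / area,
               he = he,
               n_haplotypes = length(unique(stats::na.omit(r$table$hap))),
               realized_selfing = mean(r$pedigree$selfed),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  attr(res, "summary") <- summ
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in res) {
      write_individuals(r$table, file.path(out_dir, paste0(r$params$site, ".csv")))
      utils::write.csv(r$pedigree,
                       file.path(out_dir, paste0(r$params$site, "_pedigree.csv")),
                       row.names = FALSE, quote = FALSE)
    }
    utils::write.csv(summ, file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  res
}
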