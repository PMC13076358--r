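#' Effective population density from census density
#'
#' Effective density is taken as a fraction (default 25%) of the census adult
#' density, reflecting variable age-related mortality and fertility among
#' adults (marked interannual variation in flowering limits the number of
#' adults actually reproducing in a season).
#'
#' @param census_per_ha census adult density, individuals per hectare (> 0).
#' @param fraction effective fraction in (0, 1], default 0.25.
#' @return list `per_ha` and `per_m2`.
#' @export
effective_density <- function(census_per_ha, fraction = 0.25) {
  if (!is.finite(census_per_ha) || census_per_ha <= 0)
    stop("census density must be positive")
  stopifnot(fraction > 0, fraction <= 1)
  eff <- fraction * census_per_ha
  list(per_ha = eff, per_m2 = eff / 1e4)
}

#' Axial dispersal distance from Sp under drift-dispersal equilibrium
#'
#' Inverts the isolation-by-distance approximations
#' `Sp ~ 1/(4*pi*D_e*sigma_g^2)` (nuclear, biparental) and
#' `Sp ~ 1/(2*pi*D_e*sigma_s^2)` (plastid, maternal), where `sigma` is the
#' axial dispersal distance (`sigma^2` = half the mean squared dispersal
#' distance) and `D_e` the effective density per square metre.
#'
#' @param sp the Sp statistic (> 0).
#' @param de_per_m2 effective density, individuals per m^2.
#' @param mode `"nuclear"` or `"plastid"`.
#' @return sigma in metres (`NA` when `sp <= 0`).
#' @export
sigma_from_sp <- function(sp, de_per_m2, mode = c("nuclear", "plastid")) {
  mode <- match.arg(mode)
  stopifnot(de_per_m2 > 0)
  if (!is.finite(sp) || sp <= 0) return(NA_real_)
  k <- if (mode == "nuclear") 4 else 2
  sqrt(1 / (k * pi * de_per_m2 * sp))
}

#' Iterative dispersal-distance estimation from SGS
#'
#' Starting from the full-range kinship-ln(distance) slope, `sigma` is
#' estimated by the closed-form inversion of [sigma_from_sp()], then the
#' slope is re-fit over the range `(sigma, range_mult * sigma]` (default
#' multiplier 20) and `sigma` recomputed, iterating until the relative change
#' drops below `tol`. `F_1` (first distance class, default upper bound 30 m)
#' is held fixed across iterations. Non-convergence is declared - with the
#' last `sigma` reported as censored - when the restricted range leaves the
#' sampled area (upper bound beyond the maximum pairwise distance), when
#' `Sp <= 0`, when too few pairs remain in range, or when `max_iter` is
#' reached.
#'
#' @param kinship a [loiselle_kinship()] result for the analysed group.
#' @param distances matrix from [pairwise_distances()].
#' @param de_per_m2 effective density (individuals/m^2), e.g. from
#'   [effective_density()].
#' @param mode `"nuclear"` or `"plastid"` (selects the Sp inversion).
#' @param first_class_upper upper bound of the first distance class used for
#'   `F_1` (m).
#' @param range_mult upper multiplier of the restricted regression range.
#' @param max_iter maximum iterations (default 20).
#' @param tol relative convergence tolerance on sigma (default 0.01).
#' @return list `sigma` (m; censored value when not converged, `NA` when no
#'   step produced a positive Sp), `converged`, `iterations`, `range` (last
#'   regression range), `sp`, `f1`, `b_log` (last restricted fit), `flag`
#'   (reason when not converged).
#' @export
estimate_sigma <- function(kinship, distances, de_per_m2,
                           mode = c("nuclear", "plastid"),
                           first_class_upper = 30, range_mult = 20,
                           max_iter = 20, tol = 0.01) {
  mode <- match.arg(mode)
  pv <- .pair_view(kinship, distances)
  inc <- pv$d > 0 & pv$d <= first_class_upper
  if (!any(inc)) stop("empty first distance class; F_1 undefined")
  f1 <- mean(pv$f[inc])
  dmax <- max(pv$d)
  b <- .slope_log(pv$f, pv$d)
  sp <- sp_statistic(f1, b)
  if (!is.finite(sp) || sp <= 0)
    return(list(sigma = NA_real_, converged = FALSE, iterations = 0L,
                range = c(0, dmax), sp = sp, f1 = f1, b_log = b,
                flag = "nonpositive Sp at step 0"))
  sigma <- sigma_from_sp(sp, de_per_m2, mode)
  it <- 0L; flag <- NA_character_; converged <- FALSE
  rng <- c(0, dmax)
  repeat {
    it <- it + 1L
    if (it > max_iter) { flag <- "max_iter reached"; break }
    upper <- range_mult * sigma
    if (upper > dmax) { flag <- "restricted range exceeds sampled area"; break }
    b_new <- tryCatch(
      slope_over_range(kinship, distances, sigma, upper),
      dispkin_too_few_pairs = function(e) e)
    if (inherits(b_new, "condition")) {
      flag <- sprintf("too few pairs in range (%d)", b_new$count); break
    }
    sp_new <- sp_statistic(f1, b_new)
    if (!is.finite(sp_new) || sp_new <= 0) { flag <- "nonpositive Sp"; break }
    sigma_new <- sigma_from_sp(sp_new, de_per_m2, mode)
    rng <- c(sigma, upper); b <- b_new; sp <- sp_new
    if (abs(sigma_new - sigma) / sigma < tol) {
      sigma <- sigma_new; converged <- TRUE; break
    }
    sigma <- sigma_new
  }
  list(sigma = sigma, converged = converged, iterations = it, range = rng,
       sp = sp, f1 = f1, b_log = b, flag = flag)
}

#' Decompose gene dispersal into seed and pollen components
#'
#' Under biparental nuclear inheritance and maternal seed transport,
#' `sigma_g^2 = sigma_s^2 + sigma_p^2 / 2`, so the axial pollen dispersal
#' distance is `sigma_p = sqrt(2 * (sigma_g^2 - sigma_s^2))`. When
#' `sigma_s > sigma_g` the decomposition has no real solution and `sigma_p`
#' is returned `NA` with an explanatory flag.
#'
#' @param sigma_g axial gene dispersal distance (m, nuclear SGS).
#' @param sigma_s axial seed dispersal distance (m, plastid SGS).
#' @return list `sigma_p`, `pollen_seed_ratio` (`sigma_p/sigma_s`),
#'   `seed_gene_ratio` (`sigma_s/sigma_g`), `flag`.
#' @export
decompose_pollen <- function(sigma_g, sigma_s) {
  if (is.na(sigma_g) || is.na(sigma_s))
    return(list(sigma_p = NA_real_, pollen_seed_ratio = NA_real_,
                seed_gene_ratio = NA_real_, flag = "missing input"))
  if (sigma_g < 0 || sigma_s < 0) stop("sigma values must be nonnegative")
  if (sigma_s > sigma_g)
    return(list(sigma_p = NA_real_, pollen_seed_ratio = NA_real_,
                seed_gene_ratio = sigma_s / sigma_g,
                flag = "sigma_s exceeds sigma_g; no real pollen component"))
  sigma_p <- sqrt(2 * (sigma_g^2 - sigma_s^2))
  list(sigma_p = sigma_p,
       pollen_seed_ratio = if (sigma_s > 0) sigma_p / sigma_s else NA_real_,
       seed_gene_ratio = if (sigma_g > 0) sigma_s / sigma_g else NA_real_,
       flag = NA_character_)
}

#' Historical dispersal summary for one site
#'
#' Runs the nuclear and plastid SGS-based sigma estimators for a site and
#' decomposes the pollen component, mirroring the site rows of a historical
#' dispersal table.
#'
#' @param table an `indiv_table` for a single site (analysed group).
#' @param area_ha site area in hectares (for the census adult density).
#' @param threshold adult DBH threshold (cm).
#' @param de_fraction effective-density fraction of census adult density.
#' @param ... passed to [estimate_sigma()].
#' @return list `sigma_g`, `sigma_s` (estimator results), `pollen`
#'   (decomposition), `de` (effective density).
#' @export
dispersal_history <- function(table, area_ha, threshold = 30,
                              de_fraction = 0.25, ...) {
  parts <- split_size_classes(table, threshold)
  adl <- parts$adl
  de <- effective_density(n_individuals(adl) / area_ha, de_fraction)
  dmat <- pairwise_distances(if (adl$coord_mode == "lonlat")
    project_planar(adl) else adl)
  kin_n <- loiselle_kinship(adl, mode = "diploid")
  sg <- estimate_sigma(kin_n, dmat, de$per_m2, mode = "nuclear", ...)
  ss <- tryCatch({
    kin_p <- loiselle_kinship(adl, mode = "haploid")
    estimate_sigma(kin_p, dmat, de$per_m2, mode = "plastid", ...)
  }, error = function(e) list(sigma = NA_real_, converged = FALSE,
                              flag = conditionMessage(e)))
  list(sigma_g = sg, sigma_s = ss,
       pollen = decompose_pollen(sg$sigma, ss$sigma), de = de)
}
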