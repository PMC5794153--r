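#' Pairwise kinship coefficients for dominant phenotypes
#'
#' Moment estimator of the kinship coefficient F_ij between all pairs of
#' individuals from band presence/absence phenotypes, given per-locus
#' band-allele frequencies and an assumed within-population inbreeding
#' coefficient F_IS. With q the null-allele frequency,
#' h = F_IS + (1 - F_IS) q and expected band frequency B = 1 - q h, the
#' multilocus estimator is the ratio of sums
#' \deqn{\hat F_{ij} = \sum_l (x_{il}-B_l)(x_{jl}-B_l) \,/\, \sum_l 4 p_l q_l h_l^2,}
#' whose expectation is the kinship to first order. Loci missing in either
#' member of a pair are dropped from both sums; loci with a degenerate
#' denominator (monomorphic) are excluded throughout.
#'
#' @param x a `marker_matrix` for one population.
#' @param locus_freqs per-locus frequency table for the same population
#'   (data.frame with `p_hat`, `q_hat`; see [population_freqs()]), rows in
#'   locus order of `x`.
#' @param f_is assumed inbreeding coefficient in \[0, 1).
#' @return symmetric matrix of pairwise kinship estimates with `NA`
#'   diagonal; attribute `loci_used` gives the per-pair locus counts.
#' @export
kinship_dominant <- function(x, locus_freqs, f_is = 0.19) {
  if (f_is < 0 || f_is >= 1) stop("f_is must be in [0, 1)")
  stopifnot(ncol(x) == nrow(locus_freqs))
  p <- locus_freqs$p_hat
  q <- locus_freqs$q_hat
  h <- f_is + (1 - f_is) * q
  denom <- 4 * p * q * h^2
  keep <- is.finite(denom) & denom > 1e-12
  if (!any(keep)) stop("no polymorphic loci for kinship estimation")
  m <- unclass(x)[, keep, drop = FALSE]
  B <- (1 - q * h)[keep]
  dl <- denom[keep]
  obs <- !is.na(m)
  xc <- sweep(m, 2L, B)
  xc[!obs] <- 0
  num <- tcrossprod(xc)
  den <- tcrossprod(sweep(obs * 1, 2L, sqrt(dl), `*`))
  shared <- tcrossprod(obs * 1)
  K <- num / den
  K[shared == 0L] <- NA_real_
  diag(K) <- NA_real_
  dimnames(K) <- list(rownames(x), rownames(x))
  attr(K, "loci_used") <- shared
  attr(K, "f_is") <- f_is
  K
}

#' Build distance classes for a correlogram
#'
#' Quantile-based class boundaries giving near-equal pair counts. The number
#' of classes is the largest value inside `class_range` such that every
#' class still holds at least `min_pairs` pairs; when even the lower end of
#' the range cannot be satisfied, a smaller number of classes is used and
#' the result is flagged non-conforming with a warning.
#'
#' @param geo_d symmetric distance matrix (metres) or vector of pairwise
#'   distances.
#' @param min_pairs minimum pairs per class (default 40).
#' @param class_range allowed range for the number of classes
#'   (default `c(5, 30)`).
#' @return list of class `distance_classing`: `breaks`, `n_classes`,
#'   `counts`, `mean_distance` per class, and `conforming`.
#' @export
build_distance_classes <- function(geo_d, min_pairs = 40,
                                   class_range = c(5, 30)) {
  d <- if (is.matrix(geo_d)) geo_d[lower.tri(geo_d)] else as.numeric(geo_d)
  np <- length(d)
  if (np < min_pairs)
    stop("only ", np, " pairs available (< min_pairs = ", min_pairs,
         "); lower min_pairs")
  try_nc <- function(nc) {
    br <- unique(stats::quantile(d, probs = seq(0, 1, length.out = nc + 1),
                                 names = FALSE))
    if (length(br) < 2L) return(NULL)
    cls <- findInterval(d, br, rightmost.closed = TRUE)
    cnt <- tabulate(cls, nbins = length(br) - 1L)
    if (length(cnt) == nc && all(cnt >= min_pairs)) list(br = br, cls = cls, cnt = cnt)
    else NULL
  }
  nc_hi <- min(class_range[2L], np %/% min_pairs)
  fit <- NULL
  conforming <- TRUE
  for (nc in seq(nc_hi, class_range[1L])) {
    if (nc < class_range[1L]) break
    fit <- try_nc(nc)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    conforming <- FALSE
    for (nc in seq(min(nc_hi, class_range[1L] - 1L), 1L)) {
      fit <- try_nc(nc)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) stop("could not form distance classes")
    warning("only ", length(fit$cnt), " distance class(es) hold >= ",
            min_pairs, " pairs; result flagged non-conforming")
  }
  structure(list(
    breaks = fit$br, n_classes = length(fit$cnt), counts = fit$cnt,
    mean_distance = as.numeric(tapply(d, fit$cls, mean)),
    conforming = conforming), class = "distance_classing")
}

# class index per pairwise distance under a classing (vector in, vector out)
.assign_classes <- function(d, classing) {
  cls <- findInterval(d, classing$breaks, rightmost.closed = TRUE)
  pmin(pmax(cls, 1L), classing$n_classes)
}

#' Fit the spatial genetic structure regression and correlogram
#'
#' Computes the per-distance-class mean kinship, the regression slope b_F of
#' pairwise kinship on ln(distance) over all pairs, the first-class mean
#' kinship F_1, and the Sp statistic -b_F/(1 - F_1). A permutation null is
#' built by shuffling the spatial locations among individuals; per-class
#' means and the slope are recomputed each time and the 2.5/97.5 percentiles
#' form the 95% envelope (set `alpha = 0.01` for 99%).
#'
#' Pairs at identical coordinates are excluded from the log-distance
#' regression (ln 0 undefined) but contribute to class means.
#'
#' @param kinship symmetric pairwise kinship matrix ([kinship_dominant()]).
#' @param geo_d symmetric pairwise distance matrix, same order.
#' @param classes a `distance_classing`; built automatically when `NULL`.
#' @param n_perm number of location permutations (default 10000).
#' @param seed RNG seed.
#' @param alpha two-sided envelope level (default 0.05).
#' @param max_dist optional upper distance bound (m) for the pairs entering
#'   the log-distance regression (class means are unaffected). The default
#'   `Inf` regresses over all pairs; a restricted range (classically sigma
#'   to half the study extent) is useful as a sensitivity analysis when the
#'   slope is read as -(1-F_1)/N_b, because the log-linear decay of kinship
#'   holds only over that window.
#' @return list of class `sgs_result`: `correlogram` (per class: bounds,
#'   pairs, mean distance, mean kinship, envelope, significance), `F1`,
#'   `b_F`, `b_F_envelope`, `b_F_significant`, `Sp`, `no_positive_sgs`,
#'   `n_perm`, `seed`.
#' @export
fit_sgs <- function(kinship, geo_d, classes = NULL, n_perm = 10000,
                    seed = NULL, alpha = 0.05, max_dist = Inf) {
  n <- nrow(kinship)
  stopifnot(nrow(geo_d) == n)
  if (is.null(classes)) classes <- build_distance_classes(geo_d)
  lt <- lower.tri(kinship)
  Fv <- kinship[lt]
  dv <- geo_d[lt]
  ok <- is.finite(Fv)
  stat <- function(dvec) {
    cls <- .assign_classes(dvec, classes)
    cm <- as.numeric(tapply(Fv[ok], cls[ok], mean))
    if (length(cm) < classes$n_classes) {  # guard: empty class after NA drop
      full <- rep(NA_real_, classes$n_classes)
      full[sort(unique(cls[ok]))] <- cm
      cm <- full
    }
    reg <- ok & dvec > 0 & dvec <= max_dist
    xr <- log(dvec[reg]); yr <- Fv[reg]
    b <- sum((xr - mean(xr)) * (yr - mean(yr))) / sum((xr - mean(xr))^2)
    c(b, cm)
  }
  s_obs <- stat(dv)
  b_f <- s_obs[1L]
  class_mean <- s_obs[-1L]
  f1 <- class_mean[1L]

  if (!is.null(seed)) set.seed(seed)
  perm <- matrix(NA_real_, n_perm, 1L + classes$n_classes)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n)
    perm[i, ] <- stat(geo_d[idx, idx][lt])
  }
  qs <- c(alpha / 2, 1 - alpha / 2)
  env <- apply(perm, 2L, stats::quantile, probs = qs, na.rm = TRUE)
  b_env <- env[, 1L]
  cls_env <- env[, -1L, drop = FALSE]
  sig_class <- class_mean < cls_env[1L, ] | class_mean > cls_env[2L, ]
  b_sig <- b_f < b_env[1L] || b_f > b_env[2L]
  sp <- -b_f / (1 - f1)
  no_sgs <- b_f >= 0
  if (no_sgs)
    message("b_F >= 0: no positive spatial genetic structure; Sp flagged")
  correlogram <- data.frame(
    class = seq_len(classes$n_classes),
    lower_m = classes$breaks[-length(classes$breaks)],
    upper_m = classes$breaks[-1L],
    n_pairs = classes$counts,
    mean_distance = classes$mean_distance,
    mean_kinship = class_mean,
    env_low = cls_env[1L, ], env_high = cls_env[2L, ],
    significant = sig_class)
  structure(list(
    correlogram = correlogram, F1 = f1, b_F = b_f,
    b_F_envelope = unname(b_env), b_F_significant = b_sig, Sp = sp,
    no_positive_sgs = no_sgs, alpha = alpha, n_perm = n_perm, seed = seed,
    classing = classes), class = "sgs_result")
}

#' @export
print.sgs_result <- function(x, ...) {
  cat(sprintf("SGS: F1 = %.3f  b_F = %.4f%s  Sp = %.4f (%d permutations)\n",
              x$F1, x$b_F, if (x$b_F_significant) "*" else "", x$Sp, x$n_perm))
  print(x$correlogram, digits = 3)
  invisible(x)
}

#' Sp statistic
#'
#' Intensity of fine-scale spatial genetic structure,
#' Sp = -b_F / (1 - F_1), comparable across populations and studies.
#'
#' @param F1 mean kinship in the first distance class.
#' @param b_F regression slope of kinship on ln(distance).
#' @return the Sp statistic.
#' @export
sp_statistic <- function(F1, b_F) -b_F / (1 - F1)

#' Gene-dispersal distance implied by a neighbourhood size
#'
#' Inverts N_b = 4 pi D_E sigma_g^2:
#' sigma_g = sqrt(N_b / (4 pi D_E)), with the effective density given in
#' trees per hectare and a scenario fraction applied to it
#' (1 ha = 10,000 m^2).
#'
#' @param N_b neighbourhood size (individuals).
#' @param density_per_ha effective density, trees/ha.
#' @param fraction scenario fraction of that density (default 1).
#' @return axial gene-dispersal distance in metres.
#' @export
neighbourhood_sigma <- function(N_b, density_per_ha, fraction = 1) {
  if (any(density_per_ha <= 0)) stop("density must be positive")
  sqrt(N_b / (4 * pi * fraction * density_per_ha / 1e4))
}

#' Neighbourhood size and gene-dispersal distances
#'
#' Under two-dimensional isolation by distance at drift-dispersal
#' equilibrium, Wright's neighbourhood size is N_b = 4 pi D_E sigma_g^2 and
#' is estimated from the SGS regression as N_b = (F_1 - 1)/b_F. Given a
#' census density (trees/ha) and effective-density scenarios (fractions of
#' census), the axial gene-dispersal distance follows as
#' sigma_g = sqrt(N_b / (4 pi D_E)) with D_E in trees/m^2
#' (1 ha = 10,000 m^2).
#'
#' @param F1 first-class mean kinship.
#' @param b_F regression slope on ln(distance); must be negative.
#' @param census_density_per_ha census density, trees per hectare.
#' @param scenarios fractions of census density used as effective densities
#'   (default `c(1, 1/2, 1/4, 1/10)`).
#' @param significant was b_F significantly negative? When `FALSE` the
#'   dispersal estimates are suppressed (returned as `NA`), as neighbourhood
#'   size is meaningless without detectable SGS.
#' @return list of class `dispersal_estimates`: `N_b`, and a data.frame
#'   `scenarios` with `fraction`, `D_E_per_ha`, `D_E_per_m2`, `sigma_g_m`.
#' @export
dispersal_estimates <- function(F1, b_F, census_density_per_ha,
                                scenarios = c(1, 1/2, 1/4, 1/10),
                                significant = TRUE) {
  if (census_density_per_ha <= 0) stop("census density must be positive")
  if (b_F >= 0)
    stop("b_F >= 0: neighbourhood size undefined without negative SGS slope")
  nb <- (F1 - 1) / b_F
  d_ha <- census_density_per_ha * scenarios
  d_m2 <- d_ha / 1e4
  sg <- if (significant)
    neighbourhood_sigma(nb, census_density_per_ha, scenarios)
  else rep(NA_real_, length(scenarios))
  structure(list(
    N_b = if (significant) nb else NA_real_,
    scenarios = data.frame(fraction = scenarios, D_E_per_ha = d_ha,
                           D_E_per_m2 = d_m2, sigma_g_m = sg),
    significant = significant), class = "dispersal_estimates")
}

#' @export
print.dispersal_estimates <- function(x, ...) {
  if (!x$significant) {
    cat("SGS not significant: dispersal estimates suppressed\n")
  } else {
    cat(sprintf("N_b = %.1f\n", x$N_b))
    print(x$scenarios, digits = 4)
  }
  invisible(x)
}
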