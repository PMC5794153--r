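#' Fit a non-uniform Beta prior on the null-homozygote proportion
#'
#' For dominant markers the observable per locus is the fraction of
#' individuals without the band, an estimate of z = q^2 (the null-homozygote
#' proportion under Hardy-Weinberg). A Beta(a, b) prior on z is fitted across
#' loci by the method of moments, correcting the observed across-locus
#' variance for binomial sampling noise. This is the empirical-Bayes prior of
#' Zhivotovsky-style allele-frequency estimation for dominant data.
#'
#' @param band_absence_fractions per-locus fractions m/n of band-absent
#'   individuals (polymorphic loci; values in \[0, 1\]).
#' @param sample_sizes per-locus number of typed individuals (recycled if
#'   scalar).
#' @param min_var floor for the corrected variance; at or below it the fit is
#'   degenerate and a uniform prior is returned with a warning.
#' @return list with elements `a`, `b` (class `null_prior`).
#' @export
fit_null_prior <- function(band_absence_fractions, sample_sizes,
                           min_var = 1e-8) {
  z <- band_absence_fractions
  if (any(z < 0 | z > 1)) stop("fractions must lie in [0, 1]")
  n <- rep_len(sample_sizes, length(z))
  if (length(z) < 2L) stop("need at least 2 loci to fit a prior")
  mu <- mean(z)
  v <- stats::var(z) - mean(z * (1 - z) / n)
  if (!is.finite(v) || v <= min_var || mu <= 0 || mu >= 1 ||
      v >= mu * (1 - mu)) {
    warning("degenerate across-locus variance; falling back to uniform prior")
    pr <- list(a = 1, b = 1, uniform_fallback = TRUE)
  } else {
    k <- mu * (1 - mu) / v - 1
    pr <- list(a = mu * k, b = (1 - mu) * k, uniform_fallback = FALSE)
  }
  class(pr) <- "null_prior"
  pr
}

#' Bayesian per-locus null-allele frequency estimates
#'
#' With a Beta(a, b) prior on z = q^2 and m band-absent individuals out of n,
#' the posterior of z is Beta(a + m, b + n - m). The null-allele frequency
#' estimate is the posterior mean of sqrt(z),
#' \deqn{\hat q = B(a+m+1/2,\; b+n-m) / B(a+m,\; b+n-m),}
#' evaluated in log-gamma space; its sampling variance is E\[z\] - q^2.
#'
#' @param m per-locus count of band-absent (phenotype 0) individuals.
#' @param n per-locus count of typed individuals (recycled if scalar).
#' @param prior a `null_prior` from [fit_null_prior()] (default uniform).
#' @param f_is assumed within-population inbreeding coefficient. With
#'   `f_is > 0` the null-phenotype proportion is z = q^2 + F q(1-q) and the
#'   posterior mean of q is computed by numerical quadrature (the prior is
#'   still the Beta on z).
#' @return data.frame with columns `m`, `n`, `q_hat`, `p_hat`, `var_q`,
#'   and `low_info` (TRUE where m < 3, the Lynch-Milligan small-sample flag).
#' @export
estimate_locus_freqs <- function(m, n, prior = list(a = 1, b = 1), f_is = 0) {
  n <- rep_len(n, length(m))
  if (any(n < 1 & !(n == 0 & length(m) == 1 & m == 0)))
    stop("each locus needs n >= 1 typed individuals")
  if (any(m < 0 | m > n)) stop("m must satisfy 0 <= m <= n")
  a <- prior$a; b <- prior$b
  stopifnot(a > 0, b > 0)
  A <- a + m
  B <- b + n - m
  if (f_is == 0) {
    lq <- lbeta(A + 0.5, B) - lbeta(A, B)
    q_hat <- exp(lq)
    ez <- A / (A + B)
    var_q <- pmax(ez - q_hat^2, 0)
  } else {
    if (f_is < 0 || f_is >= 1) stop("f_is must be in [0, 1)")
    est <- vapply(seq_along(m), function(i) {
      # posterior over q: prior Beta(a,b) on z(q) = q^2 + F q (1-q), with
      # Jacobian dz/dq; likelihood z^m (1-z)^(n-m)
      logpost <- function(q) {
        z <- q^2 + f_is * q * (1 - q)
        dz <- 2 * q + f_is * (1 - 2 * q)
        (a - 1) * log(z) + (b - 1) * log1p(-z) + log(dz) +
          m[i] * log(z) + (n[i] - m[i]) * log1p(-z)
      }
      qs <- seq(1e-6, 1 - 1e-6, length.out = 4001)
      lp <- logpost(qs)
      w <- exp(lp - max(lp))
      w <- w / sum(w)
      mu <- sum(w * qs)
      c(mu, sum(w * qs^2) - mu^2)
    }, numeric(2))
    q_hat <- est[1L, ]
    var_q <- est[2L, ]
  }
  data.frame(m = m, n = n, q_hat = q_hat, p_hat = 1 - q_hat, var_q = var_q,
             low_info = m < 3L)
}

# Per-population band-absence counts from a marker matrix.
.absence_counts <- function(x, pops) {
  stopifnot(nrow(x) == length(pops))
  lapply(split(seq_len(nrow(x)), pops), function(idx) {
    sub <- unclass(x)[idx, , drop = FALSE]
    list(m = colSums(sub == 0L, na.rm = TRUE), n = colSums(!is.na(sub)))
  })
}

#' Estimate per-population allele frequencies from a marker matrix
#'
#' Convenience wrapper: fits one shared null prior across loci (from pooled
#' band-absence fractions) and applies [estimate_locus_freqs()] within each
#' population.
#'
#' @param x a `marker_matrix`.
#' @param pops population label per individual (in row order of `x`).
#' @param f_is assumed inbreeding coefficient (see [estimate_locus_freqs()]).
#' @param prior optional `null_prior`; fitted from the data when `NULL`.
#' @return named list of per-population frequency data.frames
#'   (one row per locus, rownames = locus ids), with the prior attached as
#'   attribute `prior`.
#' @export
population_freqs <- function(x, pops, f_is = 0, prior = NULL) {
  cnt <- .absence_counts(x, pops)
  if (is.null(prior)) {
    # pool per-population fractions, polymorphic loci only
    fr <- unlist(lapply(cnt, function(cc) {
      f <- cc$m / cc$n
      f[f > 0 & f < 1]
    }))
    ns <- unlist(lapply(cnt, function(cc) {
      f <- cc$m / cc$n
      cc$n[f > 0 & f < 1]
    }))
    prior <- if (length(fr) >= 10) fit_null_prior(fr, ns) else list(a = 1, b = 1)
  }
  out <- lapply(cnt, function(cc) {
    lf <- estimate_locus_freqs(cc$m, cc$n, prior = prior, f_is = f_is)
    rownames(lf) <- colnames(x)
    lf
  })
  attr(out, "prior") <- prior
  out
}

#' Nei gene diversity and polymorphism summaries per population
#'
#' Per-locus diversity is the unbiased h = 2 p q n/(n-1); the population
#' H_E is its mean over loci with standard error sd/sqrt(L). PPL is the
#' percentage of loci whose minor allele frequency exceeds
#' `polymorphism_threshold`. Across populations the total diversity Ht is
#' computed from per-locus mean allele frequencies, giving the partition
#' Ht = Hw + Hb.
#'
#' @param freqs named list of per-population frequency tables from
#'   [population_freqs()].
#' @param polymorphism_threshold minor-allele-frequency cutoff for calling a
#'   locus polymorphic (default 0.05).
#' @return list with `per_population` (data.frame: pop, n_loci, PPL, H_E,
#'   SE_HE) and `overall` (Hw, Hb, Ht, mean_HE, mean_PPL).
#' @export
population_diversity <- function(freqs, polymorphism_threshold = 0.05) {
  per <- do.call(rbind, lapply(names(freqs), function(k) {
    lf <- freqs[[k]]
    nf <- pmax(lf$n, 2)
    h <- 2 * lf$p_hat * lf$q_hat * nf / (nf - 1)
    L <- length(h)
    data.frame(pop = k, n_loci = L,
               PPL = 100 * mean(pmin(lf$p_hat, lf$q_hat) > polymorphism_threshold),
               H_E = mean(h),
               SE_HE = if (L > 1) stats::sd(h) / sqrt(L) else NA_real_)
  }))
  pbar <- rowMeans(do.call(cbind, lapply(freqs, function(lf) lf$p_hat)))
  ht <- mean(2 * pbar * (1 - pbar))
  hw <- mean(per$H_E)
  list(per_population = per,
       overall = data.frame(Hw = hw, Hb = ht - hw, Ht = ht,
                            mean_HE = mean(per$H_E), mean_PPL = mean(per$PPL)))
}

#' Pairwise Nei genetic distances between populations
#'
#' Standard (1972) Nei distance for biallelic dominant loci:
#' D = -ln(Jxy / sqrt(Jx Jy)) with gene identities J accumulated from the
#' (p, q) frequency pairs across loci. The bias-corrected (1978) variant
#' replaces the within-population identities by their unbiased estimators
#' (2n J - 1)/(2n - 1).
#'
#' @param freqs named list of per-population frequency tables from
#'   [population_freqs()] (shared locus set).
#' @param variant `"1972"` (default) or `"1978"` (unbiased).
#' @return symmetric matrix of distances, zero diagonal.
#' @export
nei_distance <- function(freqs, variant = c("1972", "1978")) {
  variant <- match.arg(variant)
  pops <- names(freqs)
  k <- length(pops)
  if (k < 2) stop("need at least 2 populations")
  P <- do.call(cbind, lapply(freqs, function(lf) lf$p_hat))
  N <- do.call(cbind, lapply(freqs, function(lf) lf$n))
  D <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    jx <- mean(P[, i]^2 + (1 - P[, i])^2)
    jy <- mean(P[, j]^2 + (1 - P[, j])^2)
    jxy <- mean(P[, i] * P[, j] + (1 - P[, i]) * (1 - P[, j]))
    if (variant == "1978") {
      jx <- mean((2 * N[, i] * (P[, i]^2 + (1 - P[, i])^2) - 1) / (2 * N[, i] - 1))
      jy <- mean((2 * N[, j] * (P[, j]^2 + (1 - P[, j])^2) - 1) / (2 * N[, j] - 1))
    }
    D[i, j] <- D[j, i] <- max(-log(jxy / sqrt(jx * jy)), 0)
  }
  D
}
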