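# Squared Euclidean phenotype distances with pairwise deletion of missing
# loci, rescaled to the full locus count so pairs are comparable.
.phenotype_sqdist <- function(x) {
  m <- unclass(x)
  L <- ncol(m)
  obs <- !is.na(m)
  m0 <- m
  m0[!obs] <- 0
  # sum over shared loci of (xi - xj)^2, and shared-locus counts
  cross <- tcrossprod(m0)
  sq <- tcrossprod(m0^2, obs)
  shared <- tcrossprod(obs * 1)
  ss <- sq + t(sq) - 2 * cross
  if (any(shared[upper.tri(shared)] == 0))
    stop("some pairs share no typed locus")
  d2 <- L * ss / shared
  diag(d2) <- 0
  d2
}

# Enumerate all distinct assignments of N individuals to groups with the
# observed sizes; returns a matrix with one permuted label vector per row.
.enumerate_labelings <- function(sizes) {
  rec <- function(idx, sz) {
    if (length(sz) == 1L) return(list(list(idx)))
    out <- list()
    picks <- utils::combn(idx, sz[1L], simplify = FALSE)
    # fix the smallest index into the first remaining group only when group
    # sizes repeat? groups are labelled, so all combinations are distinct
    for (p in picks) {
      rest <- rec(setdiff(idx, p), sz[-1L])
      out <- c(out, lapply(rest, function(r) c(list(p), r)))
    }
    out
  }
  asg <- rec(seq_len(sum(sizes)), sizes)
  t(vapply(asg, function(gl) {
    lab <- integer(sum(sizes))
    for (g in seq_along(gl)) lab[gl[[g]]] <- g
    lab
  }, integer(sum(sizes))))
}

.amova_components <- function(d2, pops) {
  N <- length(pops)
  grp <- split(seq_len(N), pops)
  k <- length(grp)
  ss_tot <- sum(d2[upper.tri(d2)]) / N
  ss_w <- sum(vapply(grp, function(idx) {
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, numeric(1)))
  ss_b <- ss_tot - ss_w
  df_b <- k - 1L
  df_w <- N - k
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_w
  nk <- lengths(grp)
  n0 <- (N - sum(nk^2) / N) / df_b
  sigma_w <- ms_w
  sigma_a <- (ms_b - ms_w) / n0
  tot <- sigma_a + sigma_w
  phi <- if (tot > 0) sigma_a / tot else 0
  list(df = c(between = df_b, within = df_w),
       SSD = c(between = ss_b, within = ss_w),
       MSD = c(between = ms_b, within = ms_w),
       sigma2 = c(between = sigma_a, within = sigma_w),
       phi_st = phi)
}

#' Analysis of molecular variance (one level)
#'
#' Partitions squared Euclidean phenotype distances within and between
#' populations following the Excoffier sums-of-squares-from-distances
#' construction, with variance components from expected mean squares under
#' unequal group sizes. Significance of the fixation index Phi_ST comes from
#' permuting individuals freely among populations.
#'
#' @param x a `marker_matrix`.
#' @param pops population label per individual (row order of `x`).
#' @param n_perm number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param exhaustive if `TRUE`, enumerate every distinct assignment of
#'   individuals to groups of the observed sizes instead of sampling
#'   (feasible only for very small instances); the p-value is then the exact
#'   fraction of arrangements with Phi >= observed.
#' @return list of class `amova_result`: per-stratum `df`, `SSD`, `MSD`,
#'   variance components `sigma2`, `pct_variance`, `phi_st`, `p_value`,
#'   `n_perm`, `seed`.
#' @export
amova <- function(x, pops, n_perm = 999, seed = NULL, exhaustive = FALSE) {
  pops <- as.character(pops)
  stopifnot(nrow(x) == length(pops))
  sizes <- table(pops)
  if (any(sizes < 2)) {
    warning("excluding populations of size 1: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    keep <- pops %in% names(sizes)[sizes >= 2]
    x <- x[keep, , drop = FALSE]
    pops <- pops[keep]
  }
  if (length(unique(pops)) < 2) stop("need >= 2 populations of size >= 2")
  d2 <- .phenotype_sqdist(x)
  obs <- .amova_components(d2, pops)
  note <- NULL
  if (all(d2[upper.tri(d2)] == 0)) {
    note <- "all phenotypes identical; Phi undefined, reported as 0"
    obs$phi_st <- 0
  }
  if (exhaustive) {
    labs <- .enumerate_labelings(as.integer(table(pops)))
    lev <- sort(unique(pops))
    phis <- apply(labs, 1L, function(lb)
      .amova_components(d2, lev[lb])$phi_st)
    p <- mean(phis >= obs$phi_st - 1e-12)
    n_used <- nrow(labs)
  } else {
    if (!is.null(seed)) set.seed(seed)
    phis <- replicate(n_perm,
      .amova_components(d2, sample(pops))$phi_st)
    p <- (sum(phis >= obs$phi_st - 1e-12) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  tot <- sum(obs$sigma2)
  structure(list(
    df = obs$df, SSD = obs$SSD, MSD = obs$MSD, sigma2 = obs$sigma2,
    pct_variance = if (tot > 0) 100 * obs$sigma2 / tot else c(between = 0, within = 100),
    phi_st = obs$phi_st, p_value = p, n_perm = n_used, seed = seed,
    note = note), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (one level)\n")
  tab <- data.frame(df = x$df, SSD = round(x$SSD, 2), MSD = round(x$MSD, 2),
                    variance = round(x$sigma2, 3),
                    pct = round(x$pct_variance, 1))
  print(tab)
  cat(sprintf("Phi_ST = %.3f  p = %.4g (%d permutations)\n",
              x$phi_st, x$p_value, x$n_perm))
  invisible(x)
}

#' Wright's Fst for dominant data with a permutation G-test
#'
#' Fst is the across-population variance of estimated band-allele
#' frequencies standardized by mean-frequency heterozygosity, combined over
#' loci as a ratio of sums weighted by p(1-p). Significance comes from a
#' G statistic on the population x phenotype contingency counts (summed over
#' loci), with individuals permuted among populations.
#'
#' @param x a `marker_matrix`.
#' @param pops population label per individual.
#' @param n_perm number of permutations (default 5000).
#' @param seed RNG seed.
#' @param f_is assumed inbreeding for the frequency estimates.
#' @param exhaustive exact enumeration as in [amova()].
#' @return list of class `fst_result`: `fst`, `g_stat`, `p_value`,
#'   `n_perm`, `seed`.
#' @export
fst_g_test <- function(x, pops, n_perm = 5000, seed = NULL, f_is = 0,
                       exhaustive = FALSE) {
  pops <- as.character(pops)
  stopifnot(nrow(x) == length(pops))
  mm <- unclass(x)
  variable <- apply(mm, 2L, function(v) length(unique(v[!is.na(v)])) > 1L)
  if (!any(variable))
    stop("all loci monomorphic; Fst undefined")
  fr <- population_freqs(x, pops, f_is = f_is)
  P <- do.call(cbind, lapply(fr, function(lf) lf$p_hat))
  pbar <- rowMeans(P)
  w <- pbar * (1 - pbar)
  if (sum(w) <= 1e-12)
    stop("all loci monomorphic; Fst undefined")
  # unbiased (k-1) across-population variance; in degenerate near-fixed
  # extremes the moment ratio can exceed 1, so the report is capped there
  fst <- min(sum(apply(P, 1L, stats::var)) / sum(w), 1)

  # multilocus G: the G of each per-locus population x phenotype table,
  # summed over loci (missing cells excluded from the counts)
  m <- unclass(x)
  m1 <- (m == 1L) * 1; m1[is.na(m)] <- 0
  m0 <- (m == 0L) * 1; m0[is.na(m)] <- 0
  t1 <- colSums(m1); t0 <- colSums(m0); tt <- t1 + t0
  gstat <- function(lab) {
    O1 <- rowsum(m1, lab); O0 <- rowsum(m0, lab)
    r <- O1 + O0
    E1 <- r * rep(t1 / tt, each = nrow(O1))
    E0 <- r * rep(t0 / tt, each = nrow(O1))
    2 * (sum(O1[O1 > 0] * log(O1[O1 > 0] / E1[O1 > 0])) +
         sum(O0[O0 > 0] * log(O0[O0 > 0] / E0[O0 > 0])))
  }
  g_obs <- gstat(pops)
  if (exhaustive) {
    labs <- .enumerate_labelings(as.integer(table(pops)))
    lev <- sort(unique(pops))
    gs <- apply(labs, 1L, function(lb) gstat(lev[lb]))
    p <- mean(gs >= g_obs - 1e-9)
    n_used <- nrow(labs)
  } else {
    if (!is.null(seed)) set.seed(seed)
    gs <- replicate(n_perm, gstat(sample(pops)))
    p <- (sum(gs >= g_obs - 1e-9) + 1) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(fst = fst, g_stat = g_obs, p_value = p, n_perm = n_used,
                 seed = seed), class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Fst = %.3f  G = %.2f  p = %.4g (%d permutations)\n",
              x$fst, x$g_stat, x$p_value, x$n_perm))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower triangles, with significance from
#' permuting the rows/columns of one matrix (one-sided, r >= observed,
#' add-one correction).
#'
#' @param genetic_d,geographic_d square symmetric matrices with matching
#'   order.
#' @param n_perm number of permutations (default 9999).
#' @param seed RNG seed.
#' @return list of class `mantel_result`: `r`, `p_value`, `n_perm`, `seed`.
#' @export
mantel_test <- function(genetic_d, geographic_d, n_perm = 9999, seed = NULL) {
  genetic_d <- as.matrix(genetic_d)
  geographic_d <- as.matrix(geographic_d)
  k <- nrow(genetic_d)
  stopifnot(identical(dim(genetic_d), dim(geographic_d)), k == ncol(genetic_d))
  if (k < 4) warning("fewer than 4 populations: permutation p has very low resolution")
  lt <- lower.tri(genetic_d)
  r_obs <- stats::cor(genetic_d[lt], geographic_d[lt])
  if (!is.null(seed)) set.seed(seed)
  rs <- replicate(n_perm, {
    o <- sample.int(k)
    stats::cor(genetic_d[lt], geographic_d[o, o][lt])
  })
  p <- (sum(rs >= r_obs - 1e-12) + 1) / (n_perm + 1)
  structure(list(r = r_obs, p_value = p, n_perm = n_perm, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.3f  p = %.4g (%d permutations)\n",
              x$r, x$p_value, x$n_perm))
  invisible(x)
}
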