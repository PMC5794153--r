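# Shared fixtures and independent oracles used across test files.

# small deterministic marker matrix (values 0/1 with a few NAs)
toy_markers <- function(n = 6, L = 10, seed = 99, na_frac = 0) {
  set.seed(seed)
  m <- matrix(rbinom(n * L, 1, 0.6), n, L,
              dimnames = list(paste0("i", seq_len(n)), paste0("L", seq_len(L))))
  if (na_frac > 0) m[sample(length(m), round(na_frac * length(m)))] <- NA
  marker_matrix(m)
}

# Weir & Cockerham theta on codominant biallelic genotype counts (0/1/2),
# independent of the package's dominant-data estimator.
wc_fst_genotypes <- function(G, pops) {
  pops <- as.character(pops)
  r <- length(unique(pops))
  num <- den <- 0
  for (l in seq_len(ncol(G))) {
    g <- G[, l]
    ni <- tapply(!is.na(g), pops, sum)
    pi <- tapply(g, pops, mean, na.rm = TRUE) / 2
    hi <- tapply(g == 1, pops, mean, na.rm = TRUE)
    nbar <- mean(ni)
    pbar <- sum(ni * pi) / sum(ni)
    hbar <- sum(ni * hi) / sum(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# codominant moment kinship from true genotype counts, relative to sample
# allele frequencies (used to probe the spatial simulator's true structure)
kinship_codominant <- function(G) {
  p <- colMeans(G) / 2
  keep <- p > 0.02 & p < 0.98
  X <- sweep(G[, keep, drop = FALSE] / 2, 2, p[keep])
  tcrossprod(X) / sum(p[keep] * (1 - p[keep]))
}

# per-locus one-way ANOVA sums of squares, the independent AMOVA oracle:
# SS_total/within/between summed over loci, EMS variance components.
amova_oracle <- function(m, pops) {
  m <- unclass(m)
  pops <- as.character(pops)
  grp <- split(seq_len(nrow(m)), pops)
  N <- nrow(m); k <- length(grp)
  ss_w <- ss_t <- 0
  for (l in seq_len(ncol(m))) {
    x <- m[, l]
    ss_t <- ss_t + sum((x - mean(x))^2)
    for (idx in grp) ss_w <- ss_w + sum((x[idx] - mean(x[idx]))^2)
  }
  ss_b <- ss_t - ss_w
  ms_b <- ss_b / (k - 1); ms_w <- ss_w / (N - k)
  n0 <- (N - sum(lengths(grp)^2) / N) / (k - 1)
  sigma_a <- (ms_b - ms_w) / n0
  phi <- sigma_a / (sigma_a + ms_w)
  list(SSD = c(between = ss_b, within = ss_w),
       sigma2 = c(between = sigma_a, within = ms_w), phi_st = phi)
}

# all distinct assignments of 1:N into labelled groups of given sizes
all_labelings <- function(sizes) {
  rec <- function(idx, sz) {
    if (length(sz) == 1L) return(list(list(idx)))
    out <- list()
    for (p in utils::combn(idx, sz[1L], simplify = FALSE))
      out <- c(out, lapply(rec(setdiff(idx, p), sz[-1L]),
                           function(r) c(list(p), r)))
    out
  }
  lapply(rec(seq_len(sum(sizes)), sizes), function(gl) {
    lab <- integer(sum(sizes))
    for (g in seq_along(gl)) lab[gl[[g]]] <- g
    lab
  })
}

# simulate a panmictic "population" with random coordinates: iid phenotypes
# at given band frequencies, no spatial signal at all
panmictic_dataset <- function(n = 48, L = 150, seed = 1) {
  set.seed(seed)
  p_band <- runif(L, 0.2, 0.9)
  x <- matrix(rbinom(n * L, 1, rep(p_band, each = n)), n, L,
              dimnames = list(sprintf("i%03d", 1:n), paste0("L", 1:L)))
  st <- sample_table(data.frame(id = rownames(x), pop = "P",
                                x_m = runif(n, 0, 500), y_m = runif(n, 0, 500)))
  list(markers = marker_matrix(x), samples = st)
}
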