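#' Convert diploid band-allele counts to dominant phenotypes
#'
#' A dominant marker shows the band whenever at least one amplifiable allele
#' is present: phenotype 1 iff the band-allele count is 1 or 2.
#'
#' @param genotypes matrix of band-allele counts in \{0, 1, 2\}
#'   (individuals x loci), `NA` allowed.
#' @return a `marker_matrix` of 0/1 phenotypes.
#' @export
dominant_mask <- function(genotypes) {
  g <- as.matrix(genotypes)
  if (any(!is.na(g) & !(g %in% 0:2)))
    stop("band-allele counts must be 0, 1 or 2")
  x <- (g >= 1L) * 1L
  if (is.null(rownames(x))) rownames(x) <- paste0("ind", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("L", seq_len(ncol(x)))
  marker_matrix(x)
}

# genotype draw with inbreeding: counts of band allele per individual x locus
# P(2) = p^2 + F p q, P(1) = 2 p q (1 - F), P(0) = q^2 + F p q
.draw_genotypes <- function(p, f_is, n_ind) {
  L <- length(p)
  P2 <- p^2 + f_is * p * (1 - p)
  P1 <- 2 * p * (1 - p) * (1 - f_is)
  u <- matrix(stats::runif(n_ind * L), n_ind, L)
  g <- matrix(0L, n_ind, L)
  g[u < rep(P2 + P1, each = n_ind)] <- 1L
  g[u < rep(P2, each = n_ind)] <- 2L
  g
}

#' Simulate diverged populations of dominant markers (island model)
#'
#' Per-population band-allele frequencies follow the Balding-Nichols model:
#' Beta with mean equal to the ancestral frequency and variance
#' `theta_div * p (1 - p)`, so `theta_div` is the target Fst. Genotypes are
#' drawn with inbreeding F_IS = s/(2 - s) induced by the selfing rate `s`,
#' and converted to dominant phenotypes. Individuals receive uniform
#' coordinates inside per-population square patches laid out on a widely
#' spaced grid.
#'
#' @param n_populations number of populations.
#' @param n_individuals individuals per population (recycled).
#' @param n_loci number of dominant loci.
#' @param theta_div divergence parameter (target Fst) in \[0, 1).
#' @param selfing_rate selfing rate s in \[0, 1\]; induces
#'   F_IS = s/(2 - s).
#' @param ancestral_freqs ancestral band-allele frequencies per locus;
#'   default drawn from Uniform(0.1, 0.9).
#' @param patch_size side (m) of each population's square patch.
#' @param patch_spacing centre-to-centre distance (m) between patches.
#' @param seed RNG seed (required, for reproducible truth).
#' @return list with `markers` (`marker_matrix`), `samples`
#'   (`sample_table`), and `truth` (realized per-population allele
#'   frequencies, genotype matrix, realized F_IS, targets, seed).
#' @export
simulate_clustered <- function(n_populations = 6, n_individuals = 30,
                               n_loci = 400, theta_div = 0.1,
                               selfing_rate = 0, ancestral_freqs = NULL,
                               patch_size = 500, patch_spacing = 50000,
                               seed = 1) {
  if (theta_div < 0 || theta_div >= 1)
    stop("theta_div must be in [0, 1): theta_div = 1 gives fixed loci only")
  if (selfing_rate < 0 || selfing_rate > 1) stop("selfing rate must be in [0, 1]")
  set.seed(seed)
  n_ind <- rep_len(n_individuals, n_populations)
  if (is.null(ancestral_freqs))
    ancestral_freqs <- stats::runif(n_loci, 0.1, 0.9)
  stopifnot(length(ancestral_freqs) == n_loci)
  f_is <- selfing_rate / (2 - selfing_rate)
  pop_codes <- sprintf("P%02d", seq_len(n_populations))
  pfreq <- matrix(NA_real_, n_loci, n_populations,
                  dimnames = list(NULL, pop_codes))
  geno <- vector("list", n_populations)
  xy <- vector("list", n_populations)
  grid <- ceiling(sqrt(n_populations))
  for (k in seq_len(n_populations)) {
    p0 <- ancestral_freqs
    if (theta_div > 0) {
      sh <- (1 - theta_div) / theta_div
      pk <- stats::rbeta(n_loci, p0 * sh, (1 - p0) * sh)
    } else pk <- p0
    pfreq[, k] <- pk
    geno[[k]] <- .draw_genotypes(pk, f_is, n_ind[k])
    cx <- ((k - 1) %% grid) * patch_spacing
    cy <- ((k - 1) %/% grid) * patch_spacing
    xy[[k]] <- cbind(x_m = cx + stats::runif(n_ind[k], 0, patch_size),
                     y_m = cy + stats::runif(n_ind[k], 0, patch_size))
  }
  G <- do.call(rbind, geno)
  ids <- paste0(rep(pop_codes, n_ind), "_",
                unlist(lapply(n_ind, seq_len)))
  rownames(G) <- ids
  colnames(G) <- paste0("L", seq_len(n_loci))
  markers <- dominant_mask(G)
  samples <- sample_table(data.frame(
    id = ids, pop = rep(pop_codes, n_ind),
    x_m = do.call(rbind, xy)[, "x_m"], y_m = do.call(rbind, xy)[, "y_m"]))
  # realized inbreeding: 1 - observed het / expected het, from true genotypes
  het_obs <- mean(G == 1L)
  het_exp <- mean(2 * pfreq[, rep(seq_len(n_populations), n_ind)] *
                    (1 - pfreq[, rep(seq_len(n_populations), n_ind)]))
  truth <- list(allele_freqs = pfreq, genotypes = G,
                target_fst = theta_div, f_is_target = f_is,
                f_is_realized = 1 - het_obs / het_exp,
                ancestral_freqs = ancestral_freqs, seed = seed)
  list(markers = markers, samples = samples, truth = truth)
}

# torus axial difference
.torus_diff <- function(a, b, extent) {
  d <- abs(outer(a, b, `-`))
  pmin(d, extent - d)
}

#' Simulate isolation by distance on a torus (forward in time)
#'
#' Spatially explicit forward model of a continuous plant population:
#' N = density x area individuals live on a torus; each generation every
#' offspring picks a mother uniformly at random, is dispersed from her by an
#' axial Gaussian seed kernel (sd `sigma_s`), and receives the paternal
#' gamete from a father drawn with an axial Gaussian pollen kernel
#' (sd `sigma_p`) centred on the mother (selfing with probability
#' `selfing_rate`). After `generations` non-overlapping generations the
#' diploid genotypes are converted to dominant phenotypes, and a rectangular
#' window is sampled to mimic exhaustive sampling of a study plot.
#'
#' The axial gene-dispersal variance is sigma_g^2 = sigma_s^2 +
#' sigma_p^2/2 (pollen moves one gamete per offspring), giving the
#' theoretical neighbourhood size N_b = 4 pi D sigma_g^2 recorded in the
#' truth.
#'
#' @param extent torus side (m).
#' @param density individuals per m^2.
#' @param sigma_s,sigma_p axial seed and pollen dispersal sd (m).
#' @param generations number of generations.
#' @param n_loci number of dominant loci.
#' @param n_sample target number of sampled individuals (window sampling;
#'   all individuals if `Inf`).
#' @param selfing_rate probability an offspring is selfed.
#' @param init_freqs initial band-allele frequencies (default
#'   Uniform(0.2, 0.8)).
#' @param seed RNG seed.
#' @return list with `markers`, `samples` (single population "SIM"),
#'   and `truth` (`sigma_g2`, `N_b`, `Sp_expected` = 1/N_b, genotypes of the
#'   sample, full population size, seed).
#' @export
simulate_spatial <- function(extent = 300, density = 0.01, sigma_s = 10,
                             sigma_p = 10, generations = 100, n_loci = 300,
                             n_sample = 200, selfing_rate = 0,
                             init_freqs = NULL, seed = 1) {
  stopifnot(extent > 0, density > 0, sigma_s > 0, sigma_p > 0)
  sigma_g2 <- sigma_s^2 + sigma_p^2 / 2
  nb_theory <- 4 * pi * density * sigma_g2
  if (nb_theory < 1)
    stop("configuration gives N_b < 1 (degenerate drift); increase density or dispersal")
  set.seed(seed)
  N <- round(density * extent^2)
  if (is.null(init_freqs)) init_freqs <- stats::runif(n_loci, 0.2, 0.8)
  G <- .draw_genotypes(init_freqs, 0, N)   # band-allele counts, N x L
  pos <- cbind(stats::runif(N, 0, extent), stats::runif(N, 0, extent))
  gamete <- function(g) {
    # one allele per cell from counts {0,1,2}
    (g == 2L) + (g == 1L) * matrix(stats::rbinom(length(g), 1L, 0.5),
                                   nrow(g), ncol(g))
  }
  # Fathers are drawn with exact Gaussian log-weights via the Gumbel-max
  # trick. When the kernel is small relative to the torus, candidates are
  # restricted to the 3x3 grid-cell block around the mother (cell side >=
  # 4 sigma_p, so every parent within 4 sigma_p is included; excluded
  # parents carry < e^-8 relative weight) — O(N * block) instead of O(N^2).
  ncell <- max(1L, floor(extent / (4 * sigma_p)))
  use_grid <- ncell >= 3L
  cellsz <- extent / max(ncell, 1L)
  sample_fathers <- function(mother, pos) {
    if (!use_grid) {
      dx <- .torus_diff(pos[mother, 1L], pos[, 1L], extent)
      dy <- .torus_diff(pos[mother, 2L], pos[, 2L], extent)
      lw <- -(dx^2 + dy^2) / (2 * sigma_p^2)
      lw[cbind(seq_len(N), mother)] <- -Inf
      gum <- -log(-log(matrix(stats::runif(N * N), N, N)))
      return(max.col(lw + gum, ties.method = "first"))
    }
    cx <- pmin(floor(pos[, 1L] / cellsz), ncell - 1L)
    cy <- pmin(floor(pos[, 2L] / cellsz), ncell - 1L)
    cell <- cx + ncell * cy
    by_cell <- split(seq_len(N), cell)
    father <- integer(N)
    off_by_cell <- split(seq_len(N), cell[mother])
    for (cc in names(off_by_cell)) {
      ci <- as.integer(cc)
      bx <- ci %% ncell; by <- ci %/% ncell
      nb <- as.vector(outer((bx + -1:1) %% ncell, ((by + -1:1) %% ncell) * ncell, `+`))
      cand <- unlist(by_cell[as.character(nb)], use.names = FALSE)
      off <- off_by_cell[[cc]]
      mo <- mother[off]
      dx <- .torus_diff(pos[mo, 1L], pos[cand, 1L], extent)
      dy <- .torus_diff(pos[mo, 2L], pos[cand, 2L], extent)
      lw <- -(dx^2 + dy^2) / (2 * sigma_p^2)
      lw[outer(mo, cand, `==`)] <- -Inf    # selfing only via selfing_rate
      gum <- -log(-log(matrix(stats::runif(length(lw)), nrow(lw), ncol(lw))))
      father[off] <- cand[max.col(lw + gum, ties.method = "first")]
    }
    # a block holding no parent besides the mother (possible only at very
    # sparse settings): fall back to a dense draw for those offspring
    bad <- which(father == mother)
    for (i in bad) {
      dx <- .torus_diff(pos[mother[i], 1L], pos[, 1L], extent)
      dy <- .torus_diff(pos[mother[i], 2L], pos[, 2L], extent)
      lw <- -(dx^2 + dy^2) / (2 * sigma_p^2)
      lw[mother[i]] <- -Inf
      father[i] <- which.max(lw - log(-log(stats::runif(N))))
    }
    father
  }
  for (gen in seq_len(generations)) {
    mother <- sample.int(N, N, replace = TRUE)
    father <- sample_fathers(mother, pos)
    if (selfing_rate > 0) {
      selfed <- stats::runif(N) < selfing_rate
      father[selfed] <- mother[selfed]
    }
    G <- gamete(G[mother, , drop = FALSE]) + gamete(G[father, , drop = FALSE])
    pos <- (pos[mother, ] +
              matrix(stats::rnorm(2 * N, 0, sigma_s), N, 2L)) %% extent
  }
  # sample a window containing ~n_sample individuals (exhaustive in-plot)
  if (is.finite(n_sample) && n_sample < N) {
    side <- min(extent, extent * sqrt(n_sample / N))
    ok <- FALSE
    while (!ok) {
      inwin <- pos[, 1L] <= side & pos[, 2L] <= side
      ok <- sum(inwin) >= min(n_sample, N) * 0.5
      if (!ok) side <- min(extent, side * 1.15)
    }
    take <- which(inwin)
    if (length(take) > n_sample) take <- sort(sample(take, n_sample))
  } else take <- seq_len(N)
  Gs <- G[take, , drop = FALSE]
  rownames(Gs) <- sprintf("ind%04d", take)
  colnames(Gs) <- paste0("L", seq_len(n_loci))
  markers <- dominant_mask(Gs)
  samples <- sample_table(data.frame(
    id = rownames(Gs), pop = "SIM",
    x_m = pos[take, 1L], y_m = pos[take, 2L]))
  truth <- list(sigma_g2 = sigma_g2, N_b = nb_theory,
                Sp_expected = 1 / nb_theory, density = density,
                extent = extent, genotypes = Gs, n_population = N,
                seed = seed)
  list(markers = markers, samples = samples, truth = truth)
}
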