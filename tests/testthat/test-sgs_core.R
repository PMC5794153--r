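test_that("dominant kinship reproduces the closed-form hand example", {
  # 100 loci at p = q = 0.5, F_IS = 0; two individuals with all bands:
  # per locus (1 - 0.75)^2 / (4 * .5 * .5 * .25) -> 0.25
  L <- 100
  x <- marker_matrix(matrix(1L, 2, L, dimnames = list(c("a", "b"),
                                                      paste0("L", 1:L))))
  fr <- data.frame(p_hat = rep(0.5, L), q_hat = rep(0.5, L))
  K <- kinship_dominant(x, fr, f_is = 0)
  expect_equal(K["a", "b"], 0.25, tolerance = 1e-12)
  expect_identical(K, t(K))
  expect_true(is.na(K["a", "a"]))
})

test_that("kinship is centred on zero for unrelated individuals", {
  set.seed(51)
  n <- 120; L <- 400
  p <- runif(L, 0.2, 0.8)
  x <- dominant_mask(matrix(rbinom(n * L, 2, rep(p, each = n)), n, L))
  fr <- data.frame(p_hat = p, q_hat = 1 - p)
  K <- kinship_dominant(x, fr, f_is = 0)
  expect_lt(abs(mean(K[lower.tri(K)])), 0.005)
})

test_that("kinship estimator is calibrated against pedigree classes", {
  set.seed(52)
  L <- 1000; p <- runif(L, 0.2, 0.8)
  fr <- data.frame(p_hat = p, q_hat = 1 - p)
  geno <- function() rbinom(L, 2, p)
  gam <- function(g) (g == 2) + (g == 1) * rbinom(L, 1, 0.5)
  child <- function(g1, g2) gam(g1) + gam(g2)
  pair_pheno <- function(rel) {
    A <- geno(); B <- geno()
    gg <- switch(rel,
      unrel = list(A, B),
      po = list(A, child(A, B)),
      fs = list(child(A, B), child(A, B)),
      hs = {C <- geno(); list(child(A, B), child(A, C))})
    rbind((gg[[1]] >= 1) * 1L, (gg[[2]] >= 1) * 1L)
  }
  mean_khat <- function(rel, npair = 250) {
    mean(replicate(npair, {
      x <- pair_pheno(rel)
      dimnames(x) <- list(c("a", "b"), paste0("L", 1:L))
      kinship_dominant(marker_matrix(x), fr, f_is = 0)[2, 1]
    }))
  }
  est <- c(unrel = mean_khat("unrel"), hs = mean_khat("hs"),
           po = mean_khat("po"), fs = mean_khat("fs"))
  theta <- c(unrel = 0, hs = 0.125, po = 0.25, fs = 0.25)
  # first-order classes are recovered within 15% relative bias
  expect_lt(abs(est["hs"] - 0.125) / 0.125, 0.15)
  expect_lt(abs(est["po"] - 0.25) / 0.25, 0.15)
  expect_lt(abs(est["unrel"]), 0.02)
  # full sibs carry an identity-by-descent-2 term the first-order moment
  # estimator counts in excess; the overall calibration slope stays near 1
  expect_gt(est["fs"], 0.2)
  slope <- coef(lm(est ~ theta))[2]
  expect_lt(abs(slope - 1), 0.15)
})

test_that("kinship handles missing loci and degenerate inputs", {
  x <- toy_markers(6, 30, seed = 61)
  xm <- unclass(x)
  xm[1, ] <- NA  # individual 1 typed nowhere
  xm[2, 1:29] <- NA
  x2 <- marker_matrix(xm)
  fr <- data.frame(p_hat = runif(30, 0.3, 0.7), q_hat = NA)
  fr$q_hat <- 1 - fr$p_hat
  K <- kinship_dominant(x2, fr, f_is = 0)
  expect_true(all(is.na(K[1, ])))
  expect_true(is.finite(K[3, 4]))
  expect_equal(attr(K, "loci_used")[3, 4], 30)
  expect_error(kinship_dominant(x, fr, f_is = 1), "f_is")
  frm <- data.frame(p_hat = rep(1, 30), q_hat = rep(0, 30))
  expect_error(kinship_dominant(x, frm), "polymorphic")
})

test_that("distance classing yields near-equal classes with >= 40 pairs", {
  set.seed(71)
  d <- runif(200, 1, 1000)  # 200 pairwise distances -> 5 classes of 40
  cl <- build_distance_classes(d)
  expect_equal(cl$n_classes, 5)
  expect_equal(cl$counts, rep(40, 5))
  expect_true(cl$conforming)
  # 55 pairs (11 individuals) cannot reach the 5-class floor
  expect_warning(cl2 <- build_distance_classes(runif(55, 1, 100)),
                 "non-conforming")
  expect_false(cl2$conforming)
  expect_equal(cl2$n_classes, 1)
  expect_error(build_distance_classes(runif(20, 1, 10)), "lower min_pairs")
})

test_that("accepted classings always satisfy the pair-count constraint", {
  set.seed(72)
  for (i in 1:15) {
    n <- sample(c(60, 200, 400, 1500, 3000), 1)
    d <- switch(sample(3, 1),
                runif(n, 0, 500),
                rexp(n, 1 / 100),
                round(runif(n, 0, 50)))   # heavy ties
    d <- d + 1e-6
    cl <- suppressWarnings(build_distance_classes(d))
    expect_true(all(cl$counts >= 40))
    expect_equal(sum(cl$counts), n)
    if (cl$conforming)
      expect_true(cl$n_classes >= 5 && cl$n_classes <= 30)
  }
})

test_that("constant kinship gives zero slope and no significant classes", {
  n <- 25
  K <- matrix(0.1, n, n); diag(K) <- NA
  set.seed(73)
  xy <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  D <- as.matrix(dist(xy))
  fit <- suppressWarnings(
    fit_sgs(K, D, classes = build_distance_classes(D, min_pairs = 30,
                                                   class_range = c(5, 30)),
            n_perm = 99, seed = 1))
  expect_equal(fit$b_F, 0, tolerance = 1e-12)
  expect_false(fit$b_F_significant)
  expect_false(any(fit$correlogram$significant))
  expect_equal(fit$Sp, 0, tolerance = 1e-12)
})

test_that("Sp is stored exactly as -b_F/(1 - F_1)", {
  set.seed(74)
  pan <- panmictic_dataset(n = 30, L = 80, seed = 74)
  fr <- population_freqs(pan$markers, pan$samples$pop)[["P"]]
  K <- kinship_dominant(pan$markers, fr, f_is = 0)
  D <- pairwise_geo_distances(pan$samples)
  cl <- suppressWarnings(build_distance_classes(D))
  fit <- fit_sgs(K, D, classes = cl, n_perm = 49, seed = 2)
  expect_identical(fit$Sp, -fit$b_F / (1 - fit$F1))
  expect_equal(nrow(fit$correlogram), cl$n_classes)
  # reproducibility under a fixed seed
  fit2 <- fit_sgs(K, D, classes = cl, n_perm = 49, seed = 2)
  expect_identical(fit$correlogram, fit2$correlogram)
  expect_identical(fit$b_F_envelope, fit2$b_F_envelope)
})

test_that("co-located pairs stay in class means but leave the regression", {
  # three individuals, two at the same point: slope uses only positive
  # distances; F1 still averages over the co-located pair
  K <- matrix(NA_real_, 4, 4)
  K[lower.tri(K)] <- c(0.30, 0.10, 0.05, 0.12, 0.06, 0.02)
  K[upper.tri(K)] <- t(K)[upper.tri(K)]
  xy <- cbind(c(0, 0, 50, 400), c(0, 0, 0, 0))
  D <- as.matrix(dist(xy))
  cl <- list(breaks = c(0, 60, 400), n_classes = 2L, counts = c(4L, 2L),
             mean_distance = c(25, 383), conforming = FALSE)
  class(cl) <- "distance_classing"
  fit <- fit_sgs(K, D, classes = cl, n_perm = 19, seed = 1)
  lt <- lower.tri(D)
  pos <- D[lt] > 0
  b_hand <- coef(lm(K[lt][pos] ~ log(D[lt][pos])))[2]
  expect_equal(fit$b_F, unname(b_hand), tolerance = 1e-10)
  expect_equal(fit$F1, mean(K[lt][D[lt] < 60]))
})

test_that("dispersal estimates obey the closed-form density scaling", {
  d <- dispersal_estimates(F1 = 0.05, b_F = -0.05, census_density_per_ha = 8.19)
  expect_equal(d$N_b, (0.05 - 1) / -0.05)
  sg <- d$scenarios$sigma_g_m
  expect_equal(sg[2] / sg[1], sqrt(2), tolerance = 1e-12)
  expect_equal(sg[3] / sg[1], 2, tolerance = 1e-12)
  expect_equal(sg[4] / sg[1], sqrt(10), tolerance = 1e-12)
  expect_equal(sg[1], neighbourhood_sigma(d$N_b, 8.19), tolerance = 1e-12)
  expect_error(dispersal_estimates(0.05, 0.01, 5), "b_F >= 0")
  expect_error(dispersal_estimates(0.05, -0.01, -5), "positive")
  sup <- dispersal_estimates(0.01, -0.01, 22.05, significant = FALSE)
  expect_true(is.na(sup$N_b))
  expect_true(all(is.na(sup$scenarios$sigma_g_m)))
})
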