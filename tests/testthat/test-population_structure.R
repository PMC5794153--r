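test_that("AMOVA gives Phi_ST = 1 for maximally distinct uniform groups", {
  x <- marker_matrix(rbind(matrix(0L, 3, 20), matrix(1L, 3, 20)),
                     individual_ids = paste0("i", 1:6),
                     locus_ids = paste0("L", 1:20))
  am <- amova(x, rep(c("A", "B"), each = 3), n_perm = 99, seed = 1)
  expect_equal(am$phi_st, 1)
  expect_equal(unname(am$df), c(1, 4))
  expect_equal(sum(am$pct_variance), 100)
})

test_that("AMOVA variance components match the per-locus ANOVA oracle", {
  set.seed(21)
  for (rep in 1:4) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1); n3 <- sample(0:4, 1)
    pops <- c(rep("A", n1), rep("B", n2), if (n3 >= 2) rep("C", n3))
    n <- length(pops)
    x <- marker_matrix(matrix(rbinom(n * 30, 1, runif(30, 0.2, 0.8)), n, 30,
                              dimnames = list(paste0("i", 1:n), paste0("L", 1:30))))
    am <- amova(x, pops, n_perm = 9, seed = 1)
    orc <- amova_oracle(x, pops)
    expect_equal(unname(am$SSD), unname(orc$SSD), tolerance = 1e-9)
    expect_equal(unname(am$sigma2), unname(orc$sigma2), tolerance = 1e-9)
    expect_equal(am$phi_st, orc$phi_st, tolerance = 1e-9)
    expect_equal(sum(am$pct_variance), 100)
  }
})

test_that("exhaustive AMOVA p-value equals brute-force label enumeration", {
  set.seed(33)
  x <- marker_matrix(matrix(rbinom(7 * 25, 1, 0.5), 7, 25,
                            dimnames = list(paste0("i", 1:7), paste0("L", 1:25))))
  pops <- c("A", "A", "A", "B", "B", "B", "B")
  am <- amova(x, pops, exhaustive = TRUE)
  labs <- all_labelings(c(3, 4))
  phis <- vapply(labs, function(lb) amova_oracle(x, lb)$phi_st, numeric(1))
  p_brute <- mean(phis >= am$phi_st - 1e-12)
  expect_equal(am$p_value, p_brute)
  expect_equal(am$n_perm, length(labs))
  # sampled permutation p approaches the exhaustive value
  am2 <- amova(x, pops, n_perm = 4999, seed = 5)
  expect_lt(abs(am2$p_value - p_brute), 0.05)
})

test_that("AMOVA handles degenerate inputs as documented", {
  x <- toy_markers(5, 12)
  expect_warning(amova(x, c("A", "A", "B", "B", "C"), n_perm = 9, seed = 1),
                 "size 1")
  xid <- marker_matrix(matrix(1L, 6, 8, dimnames = list(paste0("i", 1:6),
                                                        paste0("L", 1:8))))
  am <- amova(xid, rep(c("A", "B"), 3), n_perm = 9, seed = 1)
  expect_equal(am$phi_st, 0)
  expect_match(am$note, "identical")
})

test_that("Fst and G vanish when all populations share the same data", {
  x1 <- toy_markers(8, 40, seed = 12)
  x <- marker_matrix(rbind(unclass(x1), unclass(x1)),
                     individual_ids = paste0("i", 1:16),
                     locus_ids = colnames(x1))
  f <- fst_g_test(x, rep(c("A", "B"), each = 8), n_perm = 99, seed = 1)
  expect_lt(f$fst, 1e-10)
  expect_lt(f$g_stat, 1e-10)
})

test_that("opposite fixed phenotypes give near-maximal Fst and minimal p", {
  x <- marker_matrix(rbind(matrix(1L, 15, 30), matrix(0L, 15, 30)),
                     individual_ids = paste0("i", 1:30),
                     locus_ids = paste0("L", 1:30))
  pops <- rep(c("A", "B"), each = 15)
  fs <- fst_g_test(x, pops, n_perm = 199, seed = 3)
  # Bayesian estimates never reach 0/1 exactly; the moment ratio is capped
  expect_gt(fs$fst, 0.8)
  expect_lte(fs$fst, 1)
  expect_lte(fs$p_value, 3 / 200)
  # small instance: only the observed split and its mirror attain maximal G
  x5 <- marker_matrix(unclass(x)[c(1:5, 16:20), ],
                      individual_ids = paste0("i", 1:10),
                      locus_ids = colnames(x))
  f <- fst_g_test(x5, rep(c("A", "B"), each = 5), exhaustive = TRUE)
  expect_equal(f$p_value, 2 / choose(10, 5))
  expect_gt(f$fst, 0.5)
  xmono <- marker_matrix(matrix(1L, 6, 10,
                                dimnames = list(paste0("i", 1:6),
                                                paste0("L", 1:10))))
  expect_error(fst_g_test(xmono, rep(c("A", "B"), 3), n_perm = 9),
               "monomorphic")
})

test_that("divergence simulations give concordant Phi_ST and Fst", {
  # phenotype-level Phi_ST runs somewhat above the allele-frequency Fst on
  # dominant data; the two must stay the same order of magnitude and both
  # must flag the planted structure
  sim <- simulate_clustered(n_populations = 6, n_individuals = 30,
                            n_loci = 400, theta_div = 0.2, seed = 17)
  am <- amova(sim$markers, sim$samples$pop, n_perm = 99, seed = 2)
  f <- fst_g_test(sim$markers, sim$samples$pop, n_perm = 99, seed = 2)
  expect_lt(abs(am$phi_st - f$fst), 0.15)
  expect_gt(f$fst / am$phi_st, 0.5)
  expect_lt(f$fst / am$phi_st, 2)
  expect_lte(am$p_value, 0.05)
  expect_lte(f$p_value, 0.05)
})

test_that("Mantel r equals the hand-computed Pearson correlation", {
  g <- matrix(0, 3, 3); g[lower.tri(g)] <- c(1, 2, 3); g <- g + t(g)
  h <- matrix(0, 3, 3); h[lower.tri(h)] <- c(2, 1, 5); h <- h + t(h)
  expect_warning(mt <- mantel_test(g, h, n_perm = 99, seed = 1), "resolution")
  expect_equal(mt$r, cor(c(1, 2, 3), c(2, 1, 5)))
  # proportional matrices correlate perfectly
  expect_warning(mt2 <- mantel_test(g, 3.7 * g, n_perm = 99, seed = 1))
  expect_equal(mt2$r, 1)
})

test_that("Mantel agrees with vegan and detects a planted gradient", {
  skip_if_not_installed("vegan")
  set.seed(14)
  k <- 8
  xy <- matrix(runif(2 * k), k, 2)
  geo <- as.matrix(dist(xy))
  gen <- geo + matrix(abs(rnorm(k * k, 0, 0.05)), k, k)
  gen <- (gen + t(gen)) / 2; diag(gen) <- 0
  mt <- mantel_test(gen, geo, n_perm = 999, seed = 6)
  vg <- vegan::mantel(as.dist(gen), as.dist(geo), permutations = 999)
  expect_equal(mt$r, unname(vg$statistic), tolerance = 1e-12)
  expect_lt(mt$p_value, 0.05)
})

test_that("permutation p-values are reproducible under a fixed seed", {
  sim <- simulate_clustered(n_populations = 3, n_individuals = 10,
                            n_loci = 60, theta_div = 0.05, seed = 4)
  a1 <- amova(sim$markers, sim$samples$pop, n_perm = 49, seed = 7)
  a2 <- amova(sim$markers, sim$samples$pop, n_perm = 49, seed = 7)
  expect_identical(a1$p_value, a2$p_value)
  f1 <- fst_g_test(sim$markers, sim$samples$pop, n_perm = 49, seed = 7)
  f2 <- fst_g_test(sim$markers, sim$samples$pop, n_perm = 49, seed = 7)
  expect_identical(f1$p_value, f2$p_value)
})
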