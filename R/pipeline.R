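#' Default run configuration
#'
#' Settings mirror common practice for dominant-marker SGS studies: kinship
#' under an assumed F_IS of 0.19, 10,000 SGS permutations, 5,000 for the
#' Fst G-test, 999 for AMOVA and 9,999 for the Mantel test, and dispersal
#' scenarios at census density and 1/2, 1/4, 1/10 of it.
#'
#' @param ... named overrides of the defaults.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    f_is = 0.19,
    freq_f_is = 0,                 # HWE assumed for frequency estimation
    polymorphism_threshold = 0.05,
    n_perm = list(sgs = 10000, fst = 5000, amova = 999, mantel = 9999),
    densities_per_ha = NULL,       # named: population -> trees/ha
    scenarios = c(1, 1/2, 1/4, 1/10),
    subgroups = NULL,              # named list: label -> individual ids
    min_pairs = 40,
    sgs_alpha = 0.05,
    seed = 1,
    marker_path = NULL, sample_path = NULL,
    markers = NULL, samples = NULL)
  ov <- list(...)
  for (i in seq_along(ov)) cfg[[names(ov)[i]]] <- ov[[i]]  # later wins
  if (any(unlist(cfg$n_perm) < 1)) stop("permutation counts must be positive")
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  do.call(run_config, yaml::read_yaml(path))
}

# reproducible stage seeds derived from the master seed (kept < 2^31)
.stage_seed <- function(master, stage) {
  offs <- c(freqs = 11L, amova = 23L, fst = 37L, mantel = 53L, sgs = 71L)
  (as.integer(master) * 101L + offs[[stage]]) %% 2147483587L
}

#' Run the full dominant-marker analysis
#'
#' Orchestrates the stages in order: frequency estimation, diversity
#' summaries, Nei distances, AMOVA, Fst G-test, Mantel test of isolation by
#' distance, and per-population SGS (kinship, correlogram, Sp, neighbourhood
#' size, dispersal). Each stochastic stage consumes its own seed derived
#' from the master seed, so reruns are bit-identical and stages are
#' independent.
#'
#' @param config a `run_config`; must provide data either as in-memory
#'   `markers`/`samples` or as `marker_path`/`sample_path`.
#' @return list of class `run_report` with elements `diversity`,
#'   `nei_distance`, `amova`, `fst`, `mantel`, `sgs` (per population/
#'   subgroup: `sgs_result` and `dispersal_estimates`), `freqs`,
#'   `provenance`.
#' @export
run_all <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else do.call(run_config, config)
  markers <- cfg$markers
  samples <- cfg$samples
  if (is.null(markers)) {
    if (is.null(cfg$marker_path)) stop("stage io: no marker data supplied")
    markers <- read_marker_table(cfg$marker_path)
  }
  if (is.null(samples)) {
    if (is.null(cfg$sample_path)) stop("stage io: no sample table supplied")
    samples <- read_sample_table(cfg$sample_path)
  }
  samples <- sample_table(samples)
  if (!identical(rownames(markers), samples$id))
    stop("stage io: sample ids do not match marker matrix rows")
  has_coords <- all(c("x_m", "y_m") %in% names(samples)) ||
    all(c("lat", "lon") %in% names(samples))
  if (!has_coords)
    stop("stage io: SGS requested but no coordinates available")
  samples <- project_coordinates(samples)
  pops <- samples$pop
  message("stage freqs: estimating allele frequencies (",
          length(unique(pops)), " populations, ", ncol(markers), " loci)")
  freqs <- population_freqs(markers, pops, f_is = cfg$freq_f_is)
  div <- population_diversity(freqs, cfg$polymorphism_threshold)
  neid <- nei_distance(freqs)

  message("stage structure: AMOVA / Fst / Mantel")
  am <- amova(markers, pops, n_perm = cfg$n_perm$amova,
              seed = .stage_seed(cfg$seed, "amova"))
  fst <- fst_g_test(markers, pops, n_perm = cfg$n_perm$fst,
                    seed = .stage_seed(cfg$seed, "fst"))
  cent <- do.call(rbind, lapply(split(samples[, c("x_m", "y_m")], pops), colMeans))
  geo_pop <- as.matrix(stats::dist(cent))[rownames(neid), rownames(neid)]
  man <- mantel_test(neid, geo_pop, n_perm = cfg$n_perm$mantel,
                     seed = .stage_seed(cfg$seed, "mantel"))

  units <- split(samples$id, pops)
  if (!is.null(cfg$subgroups)) units <- c(units, cfg$subgroups)
  sgs <- list()
  for (u in names(units)) {
    ids <- units[[u]]
    idx <- match(ids, samples$id)
    if (length(ids) < 3) next
    message("stage sgs: population ", u, " (", length(ids), " individuals)")
    xs <- markers[idx, , drop = FALSE]
    fr_u <- population_freqs(xs, rep(u, length(ids)),
                             f_is = cfg$freq_f_is)[[u]]
    geod <- pairwise_geo_distances(samples[idx, ])
    K <- kinship_dominant(xs, fr_u, f_is = cfg$f_is)
    cl <- tryCatch(build_distance_classes(geod, min_pairs = cfg$min_pairs),
                   error = function(e) NULL)
    if (is.null(cl)) {
      warning("stage sgs: too few pairs in ", u, "; skipped")
      next
    }
    fit <- fit_sgs(K, geod, classes = cl, n_perm = cfg$n_perm$sgs,
                   seed = .stage_seed(cfg$seed, "sgs") + match(u, names(units)),
                   alpha = cfg$sgs_alpha)
    dens <- if (!is.null(cfg$densities_per_ha) &&
                u %in% names(cfg$densities_per_ha))
      unname(unlist(cfg$densities_per_ha[u])) else NULL
    disp <- NULL
    if (fit$b_F < 0) {
      if (is.null(dens)) {
        if (fit$b_F_significant)
          stop("stage sgs: population ", u,
               " has significant SGS but no census density was configured")
      } else {
        disp <- dispersal_estimates(fit$F1, fit$b_F, dens,
                                    scenarios = cfg$scenarios,
                                    significant = fit$b_F_significant)
      }
    }
    sgs[[u]] <- list(fit = fit, dispersal = disp, n = length(ids),
                     density_per_ha = dens)
  }
  structure(list(
    diversity = div, nei_distance = neid, amova = am, fst = fst,
    mantel = man, sgs = sgs, freqs = freqs,
    provenance = list(version = as.character(utils::packageVersion("aflpsgs")),
                      seed = cfg$seed, config = unclass(cfg))),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("== diversity ==\n"); print(x$diversity$per_population, digits = 3)
  cat("== AMOVA ==\n"); print(x$amova)
  cat("== Fst ==\n"); print(x$fst)
  cat("== Mantel ==\n"); print(x$mantel)
  for (u in names(x$sgs)) {
    cat("== SGS:", u, "==\n")
    print(x$sgs[[u]]$fit)
    if (!is.null(x$sgs[[u]]$dispersal)) print(x$sgs[[u]]$dispersal)
  }
  invisible(x)
}

#' Cross-population summary means
#'
#' Unweighted arithmetic means of H_E and PPL across population rows, and of
#' Sp across the SGS rows for which Sp was computed (including any
#' subgroups).
#'
#' @param report a `run_report` from [run_all()].
#' @return named list: `mean_HE`, `mean_PPL`, `mean_Sp`, `sp_composition`.
#' @export
summarize_across_populations <- function(report) {
  per <- report$diversity$per_population
  sps <- vapply(report$sgs, function(s) s$fit$Sp, numeric(1))
  sps <- sps[is.finite(sps)]
  list(mean_HE = mean(per$H_E), mean_PPL = mean(per$PPL),
       mean_Sp = if (length(sps)) mean(sps) else NA_real_,
       sp_composition = names(sps))
}

#' Write all report tables as TSV files
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- report$provenance$seed
  paths <- character(0)
  p <- file.path(dir, "diversity.tsv")
  write_result_tsv(report$diversity$per_population, p, seed); paths <- c(paths, p)
  p <- file.path(dir, "amova.tsv")
  am <- report$amova
  write_result_tsv(data.frame(
    stratum = c("between", "within"), df = am$df, SSD = am$SSD, MSD = am$MSD,
    pct_variance = am$pct_variance,
    phi_st = c(am$phi_st, NA), p = c(am$p_value, NA)), p, seed)
  paths <- c(paths, p)
  for (u in names(report$sgs)) {
    p <- file.path(dir, paste0("correlogram_", u, ".tsv"))
    write_result_tsv(report$sgs[[u]]$fit$correlogram, p, seed)
    paths <- c(paths, p)
  }
  sgs_tab <- do.call(rbind, lapply(names(report$sgs), function(u) {
    s <- report$sgs[[u]]
    d <- s$dispersal
    sg <- if (!is.null(d)) d$scenarios$sigma_g_m else rep(NA_real_, 4)
    data.frame(pop = u, n = s$n, Sp = s$fit$Sp, F1 = s$fit$F1,
               b_F = s$fit$b_F, significant = s$fit$b_F_significant,
               N_b = if (!is.null(d)) d$N_b else NA_real_,
               D_E_per_ha = if (!is.null(s$density_per_ha)) s$density_per_ha else NA_real_,
               sigma_g_DE = sg[1], sigma_g_DE2 = sg[2], sigma_g_DE4 = sg[3],
               sigma_g_DE10 = sg[4])
  }))
  if (!is.null(sgs_tab)) {
    p <- file.path(dir, "sgs_summary.tsv")
    write_result_tsv(sgs_tab, p, seed); paths <- c(paths, p)
  }
  invisible(paths)
}
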