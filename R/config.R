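#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults emulate the study
#' design the package targets: two full-sib families segregating an XY
#' sex-determining region (SDR) on one linkage group, genotyped at 12 SDR
#' markers; a spawning group of one dam and three candidate sires genotyped
#' at 6 multi-allelic parentage markers; and a larval RNA-seq count matrix
#' in which roughly half of the truly sex-biased genes lie on the
#' sex-determining linkage group.
#'
#' @param n_families number of full-sib families.
#' @param offspring_per_family offspring per family.
#' @param n_markers_sdr number of SDR markers; must equal
#'   `length(marker_positions)`.
#' @param marker_positions strictly increasing physical positions (Mbp) of
#'   the SDR markers on the sex-determining linkage group.
#' @param sdr_interval closed interval (Mbp) containing the causal
#'   sex-determining locus; must contain at least one marker.
#' @param crossover_rate expected crossovers per meiosis on the marker
#'   region (at most one is placed per meiosis).
#' @param n_candidate_sires candidate sires in the parentage panel
#'   (exactly one is the true sire).
#' @param n_parentage_markers markers in the parentage panel.
#' @param alleles_per_marker alleles per parentage marker (>= 2; >= 3 for a
#'   well-powered panel).
#' @param n_genes genes in the simulated transcriptome.
#' @param n_lgs number of linkage groups.
#' @param genes_per_lg integer vector of gene counts per linkage group;
#'   must sum to `n_genes`.
#' @param sd_lg index (1-based) of the sex-determining linkage group.
#' @param n_de_genes number of truly sex-biased genes.
#' @param frac_de_on_sdlg fraction of truly sex-biased genes placed on the
#'   sex-determining linkage group.
#' @param n_sex_specific number of all-or-nothing sex-specific genes
#'   (a subset of the sex-biased genes).
#' @param effect_log2fc mean absolute log2 fold change of sex-biased genes.
#' @param dispersion negative-binomial dispersion (0 gives Poisson counts).
#' @param mean_library_size expected reads per sample.
#' @param dam_het_prob probability that a maternal haplotype carries the
#'   minor allele at an SDR marker (controls how often the dam is
#'   heterozygous and hence partially uninformative for paternal phasing).
#' @param seed default random seed carried with the configuration.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_families = 2L,
                       offspring_per_family = 45L,
                       n_markers_sdr = 12L,
                       marker_positions = c(0.27, 0.55, 0.96, 1.20, 1.40,
                                            1.60, 1.85, 2.10, 2.40, 2.70,
                                            3.00, 3.40),
                       sdr_interval = c(0.96, 1.85),
                       crossover_rate = 0.1,
                       n_candidate_sires = 3L,
                       n_parentage_markers = 6L,
                       alleles_per_marker = 4L,
                       n_genes = 2000L,
                       n_lgs = 23L,
                       genes_per_lg = NULL,
                       sd_lg = 8L,
                       n_de_genes = 107L,
                       frac_de_on_sdlg = 0.48,
                       n_sex_specific = 23L,
                       effect_log2fc = 2,
                       dispersion = 0.05,
                       mean_library_size = 5e5,
                       dam_het_prob = 0.15,
                       seed = 1L) {
  if (is.null(genes_per_lg)) {
    base <- n_genes %/% n_lgs
    genes_per_lg <- rep(base, n_lgs)
    genes_per_lg[seq_len(n_genes - base * n_lgs)] <-
      genes_per_lg[seq_len(n_genes - base * n_lgs)] + 1L
  }
  cfg <- list(n_families = as.integer(n_families),
              offspring_per_family = as.integer(offspring_per_family),
              n_markers_sdr = as.integer(n_markers_sdr),
              marker_positions = as.numeric(marker_positions),
              sdr_interval = as.numeric(sdr_interval),
              crossover_rate = as.numeric(crossover_rate),
              n_candidate_sires = as.integer(n_candidate_sires),
              n_parentage_markers = as.integer(n_parentage_markers),
              alleles_per_marker = as.integer(alleles_per_marker),
              n_genes = as.integer(n_genes),
              n_lgs = as.integer(n_lgs),
              genes_per_lg = as.integer(genes_per_lg),
              sd_lg = as.integer(sd_lg),
              n_de_genes = as.integer(n_de_genes),
              frac_de_on_sdlg = as.numeric(frac_de_on_sdlg),
              n_sex_specific = as.integer(n_sex_specific),
              effect_log2fc = as.numeric(effect_log2fc),
              dispersion = as.numeric(dispersion),
              mean_library_size = as.numeric(mean_library_size),
              dam_het_prob = as.numeric(dam_het_prob),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

invalid_config <- function(...) {
  stop(structure(class = c("sdrmap_invalid_config", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

validate_sim_config <- function(cfg) {
  pos_counts <- c("n_families", "offspring_per_family", "n_markers_sdr",
                  "n_candidate_sires", "n_parentage_markers",
                  "alleles_per_marker", "n_genes", "n_lgs", "sd_lg")
  for (f in pos_counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      invalid_config(f, " must be a positive count")
  for (f in c("n_de_genes", "n_sex_specific"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
      invalid_config(f, " must be a non-negative count")
  for (f in c("frac_de_on_sdlg", "dam_het_prob"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      invalid_config(f, " must lie in [0, 1]")
  if (cfg$crossover_rate < 0 || cfg$crossover_rate > 1)
    invalid_config("crossover_rate must lie in [0, 1] (at most one crossover per meiosis)")
  if (cfg$alleles_per_marker < 2L)
    invalid_config("alleles_per_marker must be >= 2")
  if (length(cfg$marker_positions) != cfg$n_markers_sdr)
    invalid_config("marker_positions must have length n_markers_sdr")
  if (any(diff(cfg$marker_positions) <= 0))
    invalid_config("marker_positions must be strictly increasing")
  if (length(cfg$sdr_interval) != 2L ||
      cfg$sdr_interval[1] >= cfg$sdr_interval[2])
    invalid_config("sdr_interval must be an increasing pair (start, end) in Mbp")
  if (length(cfg$genes_per_lg) != cfg$n_lgs)
    invalid_config("genes_per_lg must have length n_lgs")
  if (sum(cfg$genes_per_lg) != cfg$n_genes)
    invalid_config("genes_per_lg must sum to n_genes")
  if (cfg$sd_lg > cfg$n_lgs)
    invalid_config("sd_lg must index one of the n_lgs linkage groups")
  if (cfg$n_sex_specific > cfg$n_de_genes)
    invalid_config("n_sex_specific cannot exceed n_de_genes")
  if (cfg$n_de_genes > cfg$n_genes)
    invalid_config("n_de_genes cannot exceed n_genes")
  if (cfg$dispersion < 0)
    invalid_config("dispersion must be >= 0")
  if (cfg$mean_library_size <= 0 || cfg$effect_log2fc < 0)
    invalid_config("mean_library_size must be positive and effect_log2fc >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  cat("  families           :", x$n_families, "x", x$offspring_per_family,
      "offspring\n")
  cat("  SDR markers        :", x$n_markers_sdr, "spanning",
      min(x$marker_positions), "-", max(x$marker_positions), "Mbp; SDR",
      x$sdr_interval[1], "-", x$sdr_interval[2], "Mbp\n")
  cat("  crossover rate     :", x$crossover_rate, "per meiosis\n")
  cat("  parentage panel    :", x$n_parentage_markers, "markers x",
      x$alleles_per_marker, "alleles,", x$n_candidate_sires, "candidate sires\n")
  cat("  transcriptome      :", x$n_genes, "genes on", x$n_lgs,
      "LGs (SD LG index", paste0(x$sd_lg, ")"), "\n")
  cat("  sex-biased genes   :", x$n_de_genes,
      sprintf("(%.0f%% on SD LG, %d sex-specific), |log2FC| = %g",
              100 * x$frac_de_on_sdlg, x$n_sex_specific, x$effect_log2fc), "\n")
  cat("  counts             : NB dispersion", x$dispersion,
      ", mean library", format(x$mean_library_size, big.mark = ","), "\n")
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
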