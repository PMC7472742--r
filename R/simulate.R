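# Synthetic-data generators. Every generator takes an explicit seed and
# restores the caller's RNG state, so identical (config, seed) pairs are
# bit-reproducible.

#' Marker map of the simulated SDR markers
#'
#' @param config a [sim_config()].
#' @return A [marker_map()] with markers `M01`, `M02`, ... on the
#'   sex-determining linkage group (`LG<sd_lg>`).
#' @export
sim_marker_map <- function(config) {
  m <- config$n_markers_sdr
  marker_map(sprintf("M%02d", seq_len(m)),
             rep(paste0("LG", config$sd_lg), m),
             config$marker_positions)
}

# Transmit one gamete: pick hap `start` (1 or 2), optionally recombine once
# at `xo_pos` (Mbp). Returns alleles and the source haplotype per marker.
transmit_gamete <- function(hap1, hap2, positions, start, xo_pos = NA) {
  src <- rep(start, length(positions))
  if (!is.na(xo_pos)) src[positions > xo_pos] <- 3L - start
  alleles <- ifelse(src == 1L, hap1, hap2)
  list(alleles = alleles, source = src)
}

#' Simulate full-sib families segregating an XY sex-determining region
#'
#' Each family has a sire heterozygous at every SDR marker (X haplotype
#' carrying allele 1, Y haplotype allele 2 — the classic sex-associated
#' "11"/"12" pattern) and a dam whose haplotypes are drawn per marker:
#' with probability `dam_het_prob` a maternal haplotype carries a
#' maternal-specific allele 3 (as at multi-allelic microsatellite
#' markers), which keeps maternal transmissions resolvable independently
#' of the paternal ones.
#' Offspring inherit one recombined gamete from each parent; at most one
#' crossover per meiosis is placed, uniformly over the inter-marker
#' intervals, with probability `crossover_rate`. An offspring's true sex is
#' set by the paternal haplotype it carries at the causal locus (the
#' midpoint of `sdr_interval`): Y transmits male.
#'
#' @param config a [sim_config()]; the SDR interval must contain at least
#'   one marker.
#' @param seed integer seed (defaults to `config$seed`).
#' @param label_sex if `TRUE`, offspring carry their true sex as phenotype
#'   label (the genotyped-adults design); if `FALSE` they are labelled
#'   `"unknown"` (the larval design).
#' @param planted_crossovers optional data.frame with columns `family`
#'   (family index), `offspring` (offspring index within family), `parent`
#'   (`"paternal"` or `"maternal"`) and `interval` (left marker index of the
#'   inter-marker gap); overrides the random crossover draw for those
#'   meioses (the crossover is placed at the gap midpoint).
#' @return A list with elements `genotypes` (a [genotype_table()] holding
#'   parents and offspring), `map` (the [sim_marker_map()]), `phase` (the
#'   true parental haplotypes per family), and `truth` (per-offspring true
#'   sex, transmitted haplotypes and planted crossovers).
#' @export
simulate_family <- function(config, seed = config$seed, label_sex = TRUE,
                            planted_crossovers = NULL) {
  stopifnot(inherits(config, "sim_config"))
  pos <- config$marker_positions
  in_sdr <- pos >= config$sdr_interval[1] & pos <= config$sdr_interval[2]
  if (!any(in_sdr))
    invalid_config("SDR interval contains no marker; true sex transmission undefined")
  causal_pos <- mean(config$sdr_interval)
  m <- config$n_markers_sdr
  with_seed(seed, {
    ind <- list(); a1 <- list(); a2 <- list()
    phase <- list()
    truth_rows <- list(); xo_rows <- list()
    for (f in seq_len(config$n_families)) {
      fam <- paste0("F", f)
      hapX <- rep(1L, m); hapY <- rep(2L, m)
      # maternal minor allele is 3, distinct from the sire's: at markers
      # where the dam is heterozygous her transmission stays resolvable
      # independently of the paternal one (multi-allelic marker behaviour)
      hapM1 <- ifelse(stats::rbinom(m, 1L, config$dam_het_prob) == 1L, 3L, 1L)
      hapM2 <- ifelse(stats::rbinom(m, 1L, config$dam_het_prob) == 1L, 3L, 1L)
      phase[[fam]] <- list(paternal = rbind(X = hapX, Y = hapY),
                           maternal = rbind(M1 = hapM1, M2 = hapM2))
      ind[[length(ind) + 1L]] <- data.frame(
        id = c(paste0(fam, "_sire"), paste0(fam, "_dam")),
        family = fam, sex = c("male", "female"), stringsAsFactors = FALSE)
      a1[[length(a1) + 1L]] <- rbind(pmin(hapX, hapY), pmin(hapM1, hapM2))
      a2[[length(a2) + 1L]] <- rbind(pmax(hapX, hapY), pmax(hapM1, hapM2))
      for (o in seq_len(config$offspring_per_family)) {
        oid <- sprintf("%s_o%02d", fam, o)
        gam <- list()
        for (parent in c("paternal", "maternal")) {
          start <- sample(1:2, 1L)
          xo_iv <- NA_integer_
          forced <- NULL
          if (!is.null(planted_crossovers)) {
            hit <- planted_crossovers$family == f &
              planted_crossovers$offspring == o &
              planted_crossovers$parent == parent
            if (any(hit)) forced <- planted_crossovers$interval[which(hit)[1]]
          }
          if (!is.null(forced)) {
            xo_iv <- as.integer(forced)
            xo_pos <- mean(pos[xo_iv + 0:1])
          } else if (m > 1L &&
                     stats::runif(1) < config$crossover_rate) {
            xo_iv <- sample(m - 1L, 1L)
            xo_pos <- stats::runif(1, pos[xo_iv], pos[xo_iv + 1L])
          } else xo_pos <- NA
          haps <- if (parent == "paternal") phase[[fam]]$paternal
                  else phase[[fam]]$maternal
          gam[[parent]] <- transmit_gamete(haps[1, ], haps[2, ], pos,
                                           start, xo_pos)
          gam[[parent]]$start <- start
          gam[[parent]]$xo_iv <- xo_iv
          gam[[parent]]$xo_pos <- xo_pos
          if (!is.na(xo_iv))
            xo_rows[[length(xo_rows) + 1L]] <- data.frame(
              id = oid, family = fam, parent = parent,
              left_marker = xo_iv, right_marker = xo_iv + 1L,
              position_mbp = xo_pos, stringsAsFactors = FALSE)
        }
        pg <- gam$paternal; mg <- gam$maternal
        # haplotype identity carried at the causal locus decides true sex
        pat_at_causal <- if (is.na(pg$xo_pos) || causal_pos <= pg$xo_pos)
          pg$start else 3L - pg$start
        true_sex <- if (pat_at_causal == 2L) "male" else "female"
        ind[[length(ind) + 1L]] <- data.frame(
          id = oid, family = fam,
          sex = if (label_sex) true_sex else "unknown",
          stringsAsFactors = FALSE)
        a1[[length(a1) + 1L]] <- rbind(pmin(pg$alleles, mg$alleles))
        a2[[length(a2) + 1L]] <- rbind(pmax(pg$alleles, mg$alleles))
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          id = oid, family = fam, true_sex = true_sex,
          paternal_hap = c("X", "Y")[pat_at_causal],
          maternal_hap_at_seed = mg$start,
          stringsAsFactors = FALSE)
      }
    }
    gt <- genotype_table(do.call(rbind, ind), sprintf("M%02d", seq_len(m)),
                         do.call(rbind, a1), do.call(rbind, a2))
    truth <- list(
      offspring = do.call(rbind, truth_rows),
      crossovers = if (length(xo_rows)) do.call(rbind, xo_rows) else
        data.frame(id = character(), family = character(),
                   parent = character(), left_marker = integer(),
                   right_marker = integer(), position_mbp = numeric(),
                   stringsAsFactors = FALSE),
      causal_position_mbp = causal_pos)
    list(genotypes = gt, map = sim_marker_map(config), phase = phase,
         truth = truth)
  })
}

# Can (candidate allele, dam allele) explain the offspring call at a marker?
trio_compatible <- function(off, cand, dam) {
  for (x in cand) for (y in dam)
    if (min(x, y) == off[1] && max(x, y) == off[2]) return(TRUE)
  FALSE
}

duo_compatible <- function(off, cand) any(cand %in% off)

#' Simulate a parentage panel of one dam and several candidate sires
#'
#' Multi-allelic marker genotypes for a clutch of larvae, their dam, the
#' true sire and additional unrelated candidate sires drawn from population
#' allele frequencies (Dirichlet-distributed per marker). By default
#' (`informative = TRUE`) unrelated candidates are redrawn until the
#' realized panel excludes them for every offspring under the trio rule,
#' emulating a fully informative panel in which the exclusion principle
#' identifies the sire unambiguously; with `informative = FALSE` candidates
#' are plain population draws and may remain compatible by chance.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param n_offspring number of larvae (defaults to
#'   `config$offspring_per_family`; 0 yields an empty offspring table).
#' @param informative redraw unrelated candidates until excludable (see
#'   above). If a candidate cannot be made excludable within the retry
#'   budget the panel is kept and flagged `low_power` in the truth.
#' @return A list with `offspring`, `candidates` and `dam`
#'   ([genotype_table()]s on markers `P1`, `P2`, ...) and `truth` holding
#'   the true sire id, per-offspring true parent, the population allele
#'   frequencies, the analytic probability that a random unrelated
#'   candidate is excluded for a random realized offspring
#'   (`exclusion_prob`), and a `low_power` flag set when, in the realized
#'   panel, some unrelated candidate remains compatible with some
#'   offspring.
#' @export
simulate_parentage_panel <- function(config, seed = config$seed,
                                     n_offspring = config$offspring_per_family,
                                     informative = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  nm <- config$n_parentage_markers
  nk <- config$alleles_per_marker
  nc <- config$n_candidate_sires
  markers <- paste0("P", seq_len(nm))
  with_seed(seed, {
    freqs <- lapply(seq_len(nm), function(j) {
      w <- stats::rgamma(nk, 1); w / sum(w)
    })
    draw_pair <- function(j) sort(sample(nk, 2L, replace = TRUE,
                                         prob = freqs[[j]]))
    draw_geno <- function() t(vapply(seq_len(nm), draw_pair, integer(2)))
    dam_g <- draw_geno()
    sire_idx <- sample(nc, 1L)
    cand_g <- lapply(seq_len(nc), function(i) draw_geno())
    off_a1 <- matrix(NA_integer_, n_offspring, nm)
    off_a2 <- matrix(NA_integer_, n_offspring, nm)
    for (o in seq_len(n_offspring)) for (j in seq_len(nm)) {
      pa <- sample(cand_g[[sire_idx]][j, ], 1L)
      ma <- sample(dam_g[j, ], 1L)
      off_a1[o, j] <- min(pa, ma); off_a2[o, j] <- max(pa, ma)
    }
    excluded_everywhere <- function(g) {
      # TRUE when candidate g is trio-excluded (>=1 marker) for every offspring
      if (n_offspring == 0L) return(TRUE)
      for (o in seq_len(n_offspring)) {
        excl <- FALSE
        for (j in seq_len(nm))
          if (!trio_compatible(c(off_a1[o, j], off_a2[o, j]),
                               g[j, ], dam_g[j, ])) { excl <- TRUE; break }
        if (!excl) return(FALSE)
      }
      TRUE
    }
    if (informative) {
      for (i in setdiff(seq_len(nc), sire_idx)) {
        tries <- 0L
        while (!excluded_everywhere(cand_g[[i]]) && tries < 1000L) {
          cand_g[[i]] <- draw_geno()
          tries <- tries + 1L
        }
      }
    }
    # low power when, in the realized panel, some unrelated candidate
    # remains compatible with some offspring
    low_power <- !all(vapply(setdiff(seq_len(nc), sire_idx), function(i)
      excluded_everywhere(cand_g[[i]]), logical(1)))
    # analytic exclusion probability for a random HWE candidate against the
    # realized offspring (trio rule, dam known)
    excl_prob <- NA_real_
    if (n_offspring > 0L) {
      p_not_excl <- vapply(seq_len(n_offspring), function(o) {
        prod(vapply(seq_len(nm), function(j) {
          # alleles that can explain the offspring call with some dam allele
          ok_alleles <- which(vapply(seq_len(nk), function(a)
            trio_compatible(c(off_a1[o, j], off_a2[o, j]),
                            c(a, a), dam_g[j, ]), logical(1)))
          q <- sum(freqs[[j]][ok_alleles])
          1 - (1 - q)^2   # candidate carries >=1 compatible allele
        }, numeric(1)))
      }, numeric(1))
      excl_prob <- 1 - mean(p_not_excl)
    }
    mk_gt <- function(ids, sex, a1, a2)
      genotype_table(data.frame(id = ids, family = rep("P1", length(ids)),
                                sex = sex, stringsAsFactors = FALSE),
                     markers, a1, a2)
    cand_ids <- paste0("PM", seq_len(nc))
    cand_a1 <- t(vapply(cand_g, function(g) g[, 1], integer(nm)))
    cand_a2 <- t(vapply(cand_g, function(g) g[, 2], integer(nm)))
    if (nm == 1L) { cand_a1 <- matrix(cand_a1, ncol = 1L)
                    cand_a2 <- matrix(cand_a2, ncol = 1L) }
    off_ids <- if (n_offspring > 0L) sprintf("L%02d", seq_len(n_offspring))
               else character()
    list(
      offspring = mk_gt(off_ids, rep("unknown", n_offspring), off_a1, off_a2),
      candidates = mk_gt(cand_ids, rep("male", nc), cand_a1, cand_a2),
      dam = mk_gt("DAM", "female", matrix(dam_g[, 1], 1L),
                  matrix(dam_g[, 2], 1L)),
      truth = list(true_sire = cand_ids[sire_idx],
                   true_parent = stats::setNames(
                     rep(cand_ids[sire_idx], n_offspring), off_ids),
                   allele_freqs = freqs,
                   exclusion_prob = excl_prob,
                   low_power = low_power))
  })
}

#' Simulate an orthology map
#'
#' Places `n_genes` genes over `n_lgs` linkage groups according to
#' `genes_per_lg`, with uniform physical positions within each linkage
#' group.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return An [orthology_map()] with linkage groups `LG1`, ..., `LG<n_lgs>`.
#' @export
simulate_orthology <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    lgs <- rep(paste0("LG", seq_len(config$n_lgs)), config$genes_per_lg)
    pos <- unlist(lapply(config$genes_per_lg, function(k)
      sort(stats::runif(k, 0, 40))))
    orthology_map(sprintf("g%04d", seq_len(config$n_genes)), lgs, pos)
  })
}

#' Place truly sex-biased genes over linkage groups
#'
#' Draws the identity of the truly sex-biased genes: a fraction
#' `frac_de_on_sdlg` is sampled from genes on the sex-determining linkage
#' group, the remainder uniformly from genes on the other linkage groups
#' (which weights linkage groups by their gene content).
#'
#' @param ortho an [orthology_map()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return Character vector of `n_de_genes` gene ids.
#' @export
place_de_genes <- function(ortho, config, seed = config$seed) {
  sd_name <- paste0("LG", config$sd_lg)
  if (!sd_name %in% ortho$linkage_group)
    invalid_config("sex-determining linkage group ", sd_name,
                   " absent from orthology map")
  with_seed(seed, {
    on_sd <- ortho$gene_id[ortho$linkage_group == sd_name]
    off_sd <- ortho$gene_id[ortho$linkage_group != sd_name]
    n_sd <- round(config$frac_de_on_sdlg * config$n_de_genes)
    n_off <- config$n_de_genes - n_sd
    if (n_sd > length(on_sd) || n_off > length(off_sd))
      invalid_config("not enough genes to place the requested sex-biased set")
    c(sample(on_sd, n_sd), sample(off_sd, n_off))
  })
}

#' Simulate a sex-biased larval count matrix
#'
#' Counts follow a negative-binomial model with gene-wise baseline means
#' drawn log-normal, a common dispersion, and library sizes drawn uniformly
#' within 20% of `mean_library_size`. Truly sex-biased genes differ between
#' the two groups by `effect_log2fc` on the log2 scale (sign split evenly);
#' sex-specific genes have expectation zero in one group. With
#' `effect_log2fc = 0` the matrix is a pure null: the truth labels are kept
#' but all genes share one distribution across groups.
#'
#' @param assignment a [sex_group_assignment] (or data.frame with columns
#'   `id` and `group` in `"A"`/`"B"`) covering every sample.
#' @param ortho an [orthology_map()] giving gene linkage groups.
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return A list with `counts` (a [count_matrix()]) and `truth` (data.frame
#'   of sex-biased genes with linkage group, direction and sex-specific
#'   flag, plus the per-sample group labels used).
#' @export
simulate_counts <- function(assignment, ortho, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), inherits(ortho, "orthology_map"))
  if (is.data.frame(assignment) || inherits(assignment, "sex_group_assignment")) {
    asg <- as.data.frame(unclass(assignment), stringsAsFactors = FALSE)
  } else stop("assignment must be a data.frame with columns id and group")
  if (!all(c("id", "group") %in% names(asg)))
    stop("assignment must have columns id and group")
  if (any(!asg$group %in% c("A", "B")))
    stop("every sample must carry a group label in {A, B}")
  if (config$n_sex_specific > config$n_de_genes)
    invalid_config("n_sex_specific cannot exceed the number of sex-biased genes")
  if (nrow(ortho) != config$n_genes)
    invalid_config("orthology map size does not match config n_genes")
  with_seed(seed, {
    genes <- ortho$gene_id
    n_g <- length(genes); n_s <- nrow(asg)
    de <- place_de_genes(ortho, config, seed = sample.int(2^31 - 1L, 1L))
    de <- sample(de)  # shuffle before assigning directions
    up_in_A <- rep(c(TRUE, FALSE), length.out = length(de))
    ss <- if (config$n_sex_specific > 0L)
      sample(de, config$n_sex_specific) else character()
    base_mu <- stats::rlnorm(n_g, meanlog = log(150), sdlog = 1.2)
    names(base_mu) <- genes
    half <- 2^(config$effect_log2fc / 2)
    mu_A <- base_mu; mu_B <- base_mu
    if (config$effect_log2fc > 0) {
      mu_A[de[up_in_A]] <- base_mu[de[up_in_A]] * half
      mu_B[de[up_in_A]] <- base_mu[de[up_in_A]] / half
      mu_A[de[!up_in_A]] <- base_mu[de[!up_in_A]] / half
      mu_B[de[!up_in_A]] <- base_mu[de[!up_in_A]] * half
      ss_up_A <- ss[ss %in% de[up_in_A]]
      ss_up_B <- ss[ss %in% de[!up_in_A]]
      mu_B[ss_up_A] <- 0
      mu_A[ss_up_B] <- 0
    }
    libs <- stats::runif(n_s, 0.8, 1.2) * config$mean_library_size
    counts <- matrix(0L, n_g, n_s, dimnames = list(genes, asg$id))
    for (s in seq_len(n_s)) {
      mu <- (if (asg$group[s] == "A") mu_A else mu_B) *
        libs[s] / config$mean_library_size
      counts[, s] <- if (config$dispersion > 0)
        stats::rnbinom(n_g, mu = mu, size = 1 / config$dispersion)
      else stats::rpois(n_g, mu)
    }
    truth_de <- data.frame(
      gene_id = de,
      linkage_group = ortho$linkage_group[match(de, ortho$gene_id)],
      up_in = ifelse(up_in_A, "A", "B"),
      sex_specific = de %in% ss,
      stringsAsFactors = FALSE)
    list(counts = count_matrix(counts),
         truth = list(de_genes = truth_de, groups = asg,
                      library_sizes = stats::setNames(libs, asg$id)))
  })
}
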