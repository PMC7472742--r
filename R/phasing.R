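# Parental-haplotype phasing in a full-sib family.
#
# For one parent (say the sire), each marker at which that parent is
# heterozygous can reveal which of its two alleles an offspring received,
# provided the other parent's genotype makes the transmission resolvable.
# Phasing chains these per-marker transmissions into two consistent
# parental haplotypes: it seeds at the most informative marker, orients
# every other marker by majority co-segregation with the seed partition,
# and smooths each offspring's haplotype path so that a switch (candidate
# crossover) is declared only when at least `min_run` consecutive resolved
# markers support the alternative haplotype.

unphaseable <- function(msg) {
  stop(structure(class = c("sdrmap_unphaseable", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# transmitted-allele slot (1 or 2 of the parent's sorted call) for one
# offspring call; NA when ambiguous or Mendelian-inconsistent
resolve_transmission <- function(off, parent, other) {
  if (anyNA(off) || anyNA(parent)) return(NA_integer_)
  feasible <- logical(2)
  for (t in 1:2) {
    a <- parent[t]
    if (anyNA(other)) {
      feasible[t] <- a %in% off
    } else {
      for (q in other)
        if (min(a, q) == off[1] && max(a, q) == off[2]) feasible[t] <- TRUE
    }
  }
  if (sum(feasible) == 1L) which(feasible) else NA_integer_
}

# min_run-smoothed haplotype path over one offspring's resolved states
smooth_path <- function(h, min_run) {
  idx <- which(!is.na(h))
  if (!length(idx)) return(h)
  vals <- h[idx]
  out <- vals
  state <- vals[1]
  i <- 1L
  while (i <= length(vals)) {
    if (vals[i] == state) { out[i] <- state; i <- i + 1L; next }
    # candidate switch: count consecutive support for the alternative
    j <- i
    while (j <= length(vals) && vals[j] != state) j <- j + 1L
    run_len <- j - i
    if (run_len >= min_run) state <- vals[i]  # accepted crossover
    out[i:(j - 1L)] <- state                  # short blip: noise, kept on state
    i <- j
  }
  res <- h
  res[idx] <- out
  res
}

phase_one_parent <- function(gt, off_idx, parent_idx, other_idx, positions,
                             min_run) {
  m <- length(gt$markers)
  n_off <- length(off_idx)
  p1 <- gt$a1[parent_idx, ]; p2 <- gt$a2[parent_idx, ]
  o1 <- gt$a1[other_idx, ]; o2 <- gt$a2[other_idx, ]
  het <- !is.na(p1) & p1 != p2
  if (!any(het)) return(NULL)
  trans <- matrix(NA_integer_, n_off, m)
  incons <- 0L
  for (k in which(het)) for (o in seq_len(n_off)) {
    off <- c(gt$a1[off_idx[o], k], gt$a2[off_idx[o], k])
    if (anyNA(off)) next
    # Mendelian check against both parents before resolving
    explained <- FALSE
    for (a in c(p1[k], p2[k])) for (b in c(o1[k], o2[k])) {
      if (is.na(b)) { if (a %in% off) explained <- TRUE }
      else if (min(a, b) == off[1] && max(a, b) == off[2]) explained <- TRUE
    }
    if (!explained) { incons <- incons + 1L; next }  # treated as missing
    trans[o, k] <- resolve_transmission(off, c(p1[k], p2[k]),
                                        c(o1[k], o2[k]))
  }
  resolved_per_marker <- colSums(!is.na(trans))
  informative <- het & resolved_per_marker > 0L
  if (!any(informative)) return(NULL)
  # seed: most resolved offspring; prefer markers where the other parent is
  # homozygous (fully informative), then leftmost
  other_hom <- !is.na(o1) & o1 == o2
  score <- resolved_per_marker + 0.5 * other_hom
  score[!informative] <- -1
  seed_k <- which.max(score)
  orient <- rep(NA_integer_, m)  # +1: slot1 -> hap1; -1: slot1 -> hap2
  orient[seed_k] <- 1L
  seed_part <- trans[, seed_k]
  for (k in which(informative)) {
    if (k == seed_k) next
    both <- !is.na(seed_part) & !is.na(trans[, k])
    if (!any(both)) { informative[k] <- FALSE; next }
    agree <- sum(seed_part[both] == trans[, k][both])
    n_both <- sum(both)
    if (agree * 2L == n_both) { informative[k] <- FALSE; next }  # tie
    orient[k] <- if (agree * 2L > n_both) 1L else -1L
  }
  hap <- matrix(NA_integer_, n_off, m)  # haplotype id carried per marker
  for (k in which(informative))
    hap[, k] <- if (orient[k] == 1L) trans[, k] else 3L - trans[, k]
  smoothed <- t(apply(hap, 1L, smooth_path, min_run = min_run))
  if (n_off == 1L) smoothed <- matrix(smoothed, nrow = 1L)
  # haplotype allele carried by hap1/hap2 at each informative marker
  hap_alleles <- matrix(NA_integer_, 2L, m)
  for (k in which(informative)) {
    s1 <- if (orient[k] == 1L) 1L else 2L
    hap_alleles[1L, k] <- c(p1[k], p2[k])[s1]
    hap_alleles[2L, k] <- c(p1[k], p2[k])[3L - s1]
  }
  majority <- apply(smoothed, 1L, function(h) {
    v <- h[!is.na(h)]
    if (!length(v)) return(NA_integer_)
    as.integer(names(sort(table(v), decreasing = TRUE))[1])
  })
  recomb <- vapply(seq_len(n_off), function(o) {
    v <- smoothed[o, !is.na(smoothed[o, ])]
    length(unique(v)) > 1L
  }, logical(1))
  list(informative = informative, hap_alleles = hap_alleles,
       transmission = hap, smoothed = smoothed, majority = majority,
       candidate_recombinant = recomb, mendelian_inconsistencies = incons)
}

#' Phase parental haplotypes in one full-sib family
#'
#' Reconstructs the two paternal and two maternal haplotypes over the SDR
#' markers from offspring segregation and partitions the offspring into up
#' to four haplotype groups (2 paternal x 2 maternal transmissions).
#' Offspring whose transmission pattern switches parental haplotype along
#' the marker order, with at least `min_run` consecutive resolved markers
#' supporting the alternative, are flagged as candidate recombinants.
#'
#' @param genotypes a [genotype_table()] holding parents and offspring.
#' @param map a [marker_map()]; markers are analysed in map order.
#' @param family family id to phase.
#' @param sire,dam individual ids of the parents; default to
#'   `"<family>_sire"` / `"<family>_dam"` when present.
#' @param min_run minimum number of consecutive supporting markers before a
#'   haplotype switch is accepted (default 3).
#' @return An object of class `parental_phase`: marker ids and positions,
#'   per-parent phasing (`paternal`, `maternal`, each with informativeness
#'   flags, phased haplotype alleles, per-offspring transmitted-haplotype
#'   paths raw and smoothed, and candidate-recombinant flags), offspring
#'   ids, and the haplotype-group table. The maternal component is `NULL`
#'   when the dam is uninformative at every marker.
#' @export
phase_family <- function(genotypes, map, family, sire = NULL, dam = NULL,
                         min_run = 3L) {
  stopifnot(inherits(genotypes, "genotype_table"),
            inherits(map, "marker_map"))
  ids <- genotypes$individuals
  fam_idx <- which(ids$family == family)
  if (!length(fam_idx)) stop("family not found: ", family)
  if (is.null(sire)) sire <- paste0(family, "_sire")
  if (is.null(dam)) dam <- paste0(family, "_dam")
  if (!sire %in% ids$id || !dam %in% ids$id)
    stop("sire/dam not found in genotype table; pass their ids explicitly")
  ord <- map$marker_id[map$marker_id %in% genotypes$markers]
  gt <- genotypes[, ord]
  sire_i <- match(sire, gt$individuals$id)
  dam_i <- match(dam, gt$individuals$id)
  off_i <- setdiff(which(gt$individuals$family == family),
                   c(sire_i, dam_i))
  if (!length(off_i)) stop("no offspring in family ", family)
  positions <- map$position_mbp[match(ord, map$marker_id)]
  pat <- phase_one_parent(gt, off_i, sire_i, dam_i, positions, min_run)
  if (is.null(pat))
    unphaseable(paste0("unphaseable family ", family,
                       ": no paternally informative marker"))
  mat <- phase_one_parent(gt, off_i, dam_i, sire_i, positions, min_run)
  groups <- data.frame(
    id = gt$individuals$id[off_i],
    paternal_hap = pat$majority,
    maternal_hap = if (!is.null(mat)) mat$majority else NA_integer_,
    stringsAsFactors = FALSE)
  groups$haplotype_group <- paste0("P", groups$paternal_hap, "M",
                                   ifelse(is.na(groups$maternal_hap), "?",
                                          groups$maternal_hap))
  structure(list(family = family, markers = ord, positions = positions,
                 offspring = gt$individuals$id[off_i],
                 paternal = pat, maternal = mat,
                 haplotype_groups = groups, min_run = as.integer(min_run)),
            class = "parental_phase")
}

#' @export
print.parental_phase <- function(x, ...) {
  cat("parental_phase for family", x$family, "over", length(x$markers),
      "markers\n")
  cat("  paternally informative markers:", sum(x$paternal$informative), "\n")
  if (!is.null(x$maternal))
    cat("  maternally informative markers:", sum(x$maternal$informative), "\n")
  else cat("  maternal side unphaseable\n")
  tab <- table(x$haplotype_groups$haplotype_group)
  cat("  haplotype groups:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("  candidate recombinants (paternal):",
      sum(x$paternal$candidate_recombinant), "\n")
  invisible(x)
}

# haplotype carried by each offspring across the markers inside [lo, hi];
# NA when unresolved or when the path switches inside the interval
hap_at_interval <- function(comp, positions, lo, hi) {
  ks <- which(comp$informative & positions >= lo & positions <= hi)
  apply(comp$smoothed[, ks, drop = FALSE], 1L, function(h) {
    v <- unique(h[!is.na(h)])
    if (length(v) == 1L) v else NA_integer_
  })
}

#' Assign offspring into putative sex-groups
#'
#' Under the paternal (XY) scenario offspring are grouped by the paternal
#' haplotype they carry at the SDR interval; under the maternal (ZW)
#' scenario by the maternal haplotype; the random scenario is a seeded
#' negative control that permutes labels over the paternally assignable
#' offspring while preserving the paternal-scenario group sizes. Offspring
#' whose haplotype is unresolved inside the interval, or whose crossover
#' falls inside it, are unassignable (`NA` group) and should be dropped
#' downstream.
#'
#' @param phase a [phase_family()] result, or a list of them (multi-family).
#' @param scenario `"paternal"`, `"maternal"` or `"random"`.
#' @param seed integer seed, required for the random scenario.
#' @param sdr_interval optional `c(start, end)` in Mbp restricting the
#'   markers that determine the assignment; defaults to the full marker
#'   span (all informative markers).
#' @return A data.frame of class `sex_group_assignment` with columns `id`,
#'   `family`, `scenario`, `haplotype` and `group` (`"A"`/`"B"`/`NA`).
#' @export
assign_sex_groups <- function(phase, scenario = c("paternal", "maternal",
                                                  "random"),
                              seed = NULL, sdr_interval = NULL) {
  scenario <- match.arg(scenario)
  if (inherits(phase, "parental_phase")) phase <- list(phase)
  out <- lapply(phase, function(ph) {
    lo <- if (is.null(sdr_interval)) min(ph$positions) else sdr_interval[1]
    hi <- if (is.null(sdr_interval)) max(ph$positions) else sdr_interval[2]
    pat_hap <- hap_at_interval(ph$paternal, ph$positions, lo, hi)
    if (scenario == "maternal") {
      if (is.null(ph$maternal))
        unphaseable(paste0("unphaseable family ", ph$family,
                           ": no maternally informative marker"))
      hap <- hap_at_interval(ph$maternal, ph$positions, lo, hi)
    } else hap <- pat_hap
    grp <- c("A", "B")[hap]
    if (scenario == "random") {
      if (is.null(seed)) stop("random scenario requires a seed")
      assignable <- !is.na(pat_hap)
      sizes <- table(factor(c("A", "B")[pat_hap[assignable]],
                            levels = c("A", "B")))
      labels <- rep(c("A", "B"), times = sizes)
      grp <- rep(NA_character_, length(pat_hap))
      grp[assignable] <- with_seed(seed, sample(labels))
      hap <- rep(NA_integer_, length(pat_hap))
    }
    data.frame(id = ph$offspring, family = ph$family, scenario = scenario,
               haplotype = hap, group = grp, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  n_un <- sum(is.na(res$group))
  if (n_un > 0)
    message(n_un, " offspring unassignable under the ", scenario,
            " scenario (unresolved or recombinant inside the SDR interval)")
  attr(res, "seed") <- seed
  class(res) <- c("sex_group_assignment", "data.frame")
  res
}
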