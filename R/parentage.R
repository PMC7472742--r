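#' Exclusion-principle parentage testing
#'
#' Counts, for every (offspring, candidate) pair, the markers at which the
#' candidate shares no allele with the offspring and is therefore excluded
#' as a parent. When the other parent is known (`known_parent`), the trio
#' rule applies: a candidate is excluded at a marker when no choice of one
#' candidate allele plus one known-parent allele reproduces the offspring
#' call. Markers with a missing call in either member of the pair never
#' contribute; at markers where the known parent's call is missing the duo
#' (allele-sharing) rule is used instead.
#'
#' @param offspring a [genotype_table()] of offspring.
#' @param candidates a [genotype_table()] of candidate parents, genotyped
#'   on a marker panel shared with the offspring.
#' @param known_parent optional single-individual [genotype_table()] of the
#'   known other parent (e.g. the dam when testing candidate sires).
#' @param threshold minimum number of mismatching markers required to
#'   declare a candidate excluded. The default 1 is the strict exclusion
#'   principle; raising it tolerates genotyping error.
#' @return A data.frame of class `exclusion_report` with one row per
#'   (offspring, candidate): `n_markers_tested`, `exclusion_count` and
#'   `verdict` (`"excluded"`, `"compatible"`, or `"untestable"` when no
#'   marker is genotyped in both individuals).
#' @export
exclusion_counts <- function(offspring, candidates, known_parent = NULL,
                             threshold = 1L) {
  stopifnot(inherits(offspring, "genotype_table"),
            inherits(candidates, "genotype_table"), threshold >= 1L)
  markers <- intersect(offspring$markers, candidates$markers)
  if (!length(markers))
    stop("offspring and candidates share no markers")
  kp <- NULL
  if (!is.null(known_parent)) {
    stopifnot(inherits(known_parent, "genotype_table"))
    if (nrow(known_parent$individuals) != 1L)
      stop("known_parent must contain exactly one individual")
    kp <- known_parent[, intersect(markers, known_parent$markers)]
  }
  om <- match(markers, offspring$markers)
  cm <- match(markers, candidates$markers)
  rows <- list()
  for (o in seq_len(nrow(offspring$individuals))) {
    for (ci in seq_len(nrow(candidates$individuals))) {
      tested <- 0L; excl <- 0L
      for (k in seq_along(markers)) {
        off <- c(offspring$a1[o, om[k]], offspring$a2[o, om[k]])
        cand <- c(candidates$a1[ci, cm[k]], candidates$a2[ci, cm[k]])
        if (anyNA(off) || anyNA(cand)) next
        tested <- tested + 1L
        dam <- NULL
        if (!is.null(kp)) {
          kk <- match(markers[k], kp$markers)
          if (!is.na(kk) && !is.na(kp$a1[1, kk]))
            dam <- c(kp$a1[1, kk], kp$a2[1, kk])
        }
        compatible <- if (is.null(dam)) duo_compatible(off, cand)
                      else trio_compatible(off, cand, dam)
        if (!compatible) excl <- excl + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        offspring = offspring$individuals$id[o],
        candidate = candidates$individuals$id[ci],
        n_markers_tested = tested, exclusion_count = excl,
        verdict = if (tested == 0L) "untestable"
                  else if (excl >= threshold) "excluded" else "compatible",
        stringsAsFactors = FALSE)
    }
  }
  rep_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(offspring = character(), candidate = character(),
               n_markers_tested = integer(), exclusion_count = integer(),
               verdict = character(), stringsAsFactors = FALSE)
  attr(rep_df, "threshold") <- as.integer(threshold)
  class(rep_df) <- c("exclusion_report", "data.frame")
  rep_df
}

#' Assign each offspring to its single compatible candidate parent
#'
#' @param report an [exclusion_counts()] report.
#' @return A data.frame with one row per offspring: `assigned` holds the
#'   candidate id when exactly one candidate is compatible, `"ambiguous"`
#'   when several are, `"none"` when none is (untestable pairs never count
#'   as compatible).
#' @export
assign_parent <- function(report) {
  stopifnot(inherits(report, "exclusion_report"))
  out <- lapply(split(report, report$offspring), function(d) {
    comp <- d$candidate[d$verdict == "compatible"]
    data.frame(offspring = d$offspring[1],
               assigned = if (length(comp) == 1L) comp
                          else if (length(comp) > 1L) "ambiguous" else "none",
               n_compatible = length(comp), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[match(unique(report$offspring), res$offspring), , drop = FALSE]
}
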