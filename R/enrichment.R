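# Linkage-group enrichment of sex-biased genes.
#
# The relative abundance of sex-biased differentially expressed (DE) genes
# on linkage group i is
#
#     RA_i = (DE_i * G_t) / (DE_t * G_i)
#
# where DE_i is the number of sex-biased DE genes located on linkage group
# i, DE_t the total number of located sex-biased DE genes, G_i the number
# of genes on linkage group i and G_t the total gene count. RA_i = 1 means
# the linkage group carries exactly its genome-wide share of sex-biased
# genes; the linkage group harbouring the sex-determining region is
# expected to stand out by tens-fold.

#' Percentage of DE genes on the sex-determining linkage group
#'
#' @param dei DE-gene count on the linkage group.
#' @param det total (mapped) DE-gene count.
#' @return `round(100 * dei / det)`, an integer percentage.
#' @export
sd_lg_percent <- function(dei, det) as.integer(round(100 * dei / det))

#' Expected per-linkage-group share under random segregation
#'
#' @param n_lgs number of linkage groups.
#' @return `100 / n_lgs`, rounded to one decimal (percent).
#' @export
expected_null_share <- function(n_lgs) round(100 / n_lgs, 1)

#' Tag sex-specific (all-or-nothing) genes
#'
#' A gene is sex-specific when it is consistently expressed (count at least
#' `min_expr`) in every sample of one sex-group and entirely absent (zero
#' counts) in every sample of the other.
#'
#' @param counts a [count_matrix()].
#' @param assignment a [assign_sex_groups()] result (or data.frame with
#'   `id`, `group`); `NA`-group samples are dropped.
#' @param min_expr minimum count required in every expressed sample.
#' @param de optional `de_result` (or character vector of gene ids): when
#'   supplied, tagging is restricted to those genes, otherwise it is
#'   genome-wide.
#' @return A data.frame of class `sex_specific_tags` with columns
#'   `gene_id` and `expressed_group`.
#' @export
tag_sex_specific <- function(counts, assignment, min_expr = 1L, de = NULL) {
  asg <- as.data.frame(unclass(assignment), stringsAsFactors = FALSE)
  asg <- asg[!is.na(asg$group) & asg$id %in% colnames(counts), , drop = FALSE]
  x <- unclass(counts)[, asg$id, drop = FALSE]
  if (!is.null(de)) {
    ids <- if (inherits(de, "de_result") || is.data.frame(de)) de$gene_id
           else as.character(de)
    x <- x[rownames(x) %in% ids, , drop = FALSE]
  }
  A <- x[, asg$group == "A", drop = FALSE]
  B <- x[, asg$group == "B", drop = FALSE]
  on_A <- apply(A, 1L, function(r) all(r >= min_expr)) &
    apply(B, 1L, function(r) all(r == 0))
  on_B <- apply(B, 1L, function(r) all(r >= min_expr)) &
    apply(A, 1L, function(r) all(r == 0))
  res <- data.frame(
    gene_id = c(rownames(x)[on_A], rownames(x)[on_B]),
    expressed_group = c(rep("A", sum(on_A)), rep("B", sum(on_B))),
    stringsAsFactors = FALSE)
  res <- res[order(res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "min_expr") <- min_expr
  class(res) <- c("sex_specific_tags", "data.frame")
  res
}

#' Collapse transcript-level DE results to genes
#'
#' One record is kept per gene: the transcript with the smallest p-value
#' (ties broken by lexicographic transcript id) represents the gene and
#' supplies its direction and effect. Transcripts absent from the mapping
#' pass through flagged unannotated and keep their own id.
#'
#' @param de a [test_de()] result (rows are transcripts).
#' @param transcript_to_gene named character vector (names = transcript
#'   ids, values = gene ids) or data.frame with columns `transcript_id`,
#'   `gene_id`.
#' @return A `de_result`-shaped data.frame with one row per gene plus one
#'   per unannotated transcript; extra columns `transcript_id` (the
#'   representative), `n_transcripts` and `annotated`.
#' @export
collapse_transcripts <- function(de, transcript_to_gene) {
  stopifnot(is.data.frame(de))
  t2g <- if (is.data.frame(transcript_to_gene))
    stats::setNames(as.character(transcript_to_gene$gene_id),
                    transcript_to_gene$transcript_id)
  else transcript_to_gene
  d <- as.data.frame(unclass(de), stringsAsFactors = FALSE)
  d$transcript_id <- d$gene_id
  d$annotated <- d$transcript_id %in% names(t2g)
  d$gene_id <- ifelse(d$annotated, unname(t2g[d$transcript_id]),
                      d$transcript_id)
  d <- d[order(d$gene_id, d$p_value, d$transcript_id), , drop = FALSE]
  n_tr <- table(d$gene_id)
  keep <- !duplicated(d$gene_id)
  res <- d[keep, , drop = FALSE]
  res$n_transcripts <- as.integer(n_tr[res$gene_id])
  rownames(res) <- NULL
  for (a in c("alpha", "method", "dispersion", "n_samples"))
    attr(res, a) <- attr(de, a)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Per-linkage-group enrichment of sex-biased genes
#'
#' Counts the located sex-biased genes per linkage group and computes the
#' relative abundance `RA_i = DE_i * G_t / (DE_t * G_i)`. Genes absent
#' from the orthology map are reported as unmapped and excluded from the
#' located total `DE_t`.
#'
#' @param de_genes character vector of sex-biased gene ids (or a
#'   `de_result`, from which the significant genes are taken).
#' @param ortho an [orthology_map()].
#' @return A data.frame of class `enrichment_summary`, one row per linkage
#'   group with `DEi`, `Gi`, `RAi` and `percent` (= `round(100*DEi/DEt)`),
#'   plus attributes `DEt` (located total), `unmapped` and `Gt`.
#' @export
enrichment_summary <- function(de_genes, ortho) {
  stopifnot(inherits(ortho, "orthology_map"))
  if (inherits(de_genes, "de_result") || is.data.frame(de_genes))
    de_genes <- de_genes$gene_id[de_genes$significant]
  de_genes <- unique(as.character(de_genes))
  gi <- lg_totals(ortho)
  gt <- sum(gi)
  hit <- de_genes %in% ortho$gene_id
  unmapped <- sum(!hit)
  if (unmapped > 0)
    warning(unmapped, " DE gene(s) absent from the orthology map; ",
            "counted unmapped and excluded from DEt")
  mapped <- de_genes[hit]
  det <- length(mapped)
  if (det == 0L) stop("no DE gene maps to the orthology map")
  dei <- table(factor(ortho$linkage_group[match(mapped, ortho$gene_id)],
                      levels = names(gi)))
  res <- data.frame(
    linkage_group = names(gi),
    DEi = as.integer(dei),
    Gi = as.integer(gi),
    RAi = as.numeric(dei) * gt / (det * as.numeric(gi)),
    percent = sd_lg_percent(as.integer(dei), det),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  # normalization invariant: the Gi/Gt-weighted mean of RAi is exactly the
  # located fraction of DE genes (1 when all DE genes map)
  stopifnot(abs(sum(res$RAi * res$Gi / gt) - det / det) < 1e-12)
  attr(res, "DEt") <- det
  attr(res, "unmapped") <- unmapped
  attr(res, "Gt") <- gt
  class(res) <- c("enrichment_summary", "data.frame")
  res
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat("enrichment_summary: DEt =", attr(x, "DEt"), "located genes (",
      attr(x, "unmapped"), "unmapped ), Gt =", attr(x, "Gt"), "\n")
  top <- x[order(-x$RAi), ][seq_len(min(5L, nrow(x))), ]
  print.data.frame(top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Compare XY, ZW and random-control assignment scenarios
#'
#' Runs the full chain — sex-group assignment, differential expression,
#' mapping to linkage groups — under the paternal (XY), maternal (ZW) and
#' seeded random-control scenarios, and tabulates the sex-biased gene
#' counts on the sex-determining linkage group versus the others, with the
#' percentage on the SD linkage group and the paternal/maternal total
#' ratio.
#'
#' @param counts a [count_matrix()].
#' @param phase a [phase_family()] result (or list of them).
#' @param ortho an [orthology_map()].
#' @param sd_lg name of the sex-determining linkage group in `ortho`.
#' @param alpha raw p-value threshold (default 0.01).
#' @param seed seed for the random-control scenario.
#' @param sdr_interval optional SDR interval passed to
#'   [assign_sex_groups()].
#' @param ... further arguments passed to [test_de()].
#' @return A data.frame of class `scenario_table` with one row per
#'   scenario: `sd_lg_count`, `other_count`, `unmapped`, `total` (located
#'   DE genes) and `percent`; attributes `ratio`
#'   (paternal/maternal located totals, one decimal) and
#'   `expected_null_share`.
#' @export
compare_scenarios <- function(counts, phase, ortho, sd_lg, alpha = 0.01,
                              seed = 1L, sdr_interval = NULL, ...) {
  rows <- list()
  for (sc in c("paternal", "maternal", "random")) {
    asg <- assign_sex_groups(phase, sc,
                             seed = if (sc == "random") seed else NULL,
                             sdr_interval = sdr_interval)
    de <- test_de(counts, asg, alpha = alpha, ...)
    sig <- de$gene_id[de$significant]
    located <- sig[sig %in% ortho$gene_id]
    on_sd <- sum(ortho$linkage_group[match(located, ortho$gene_id)] == sd_lg)
    rows[[sc]] <- data.frame(
      scenario = sc, sd_lg_count = on_sd,
      other_count = length(located) - on_sd,
      unmapped = length(sig) - length(located),
      total = length(located),
      percent = if (length(located)) sd_lg_percent(on_sd, length(located))
                else NA_integer_,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "ratio") <- round(res$total[res$scenario == "paternal"] /
                                res$total[res$scenario == "maternal"], 1)
  attr(res, "expected_null_share") <-
    expected_null_share(length(unique(ortho$linkage_group)))
  attr(res, "sd_lg") <- sd_lg
  attr(res, "seed") <- seed
  class(res) <- c("scenario_table", "data.frame")
  res
}

#' @export
print.scenario_table <- function(x, ...) {
  cat("Sex-biased DE genes on", attr(x, "sd_lg"), "vs other linkage groups\n")
  print.data.frame(x, row.names = FALSE)
  cat("paternal/maternal total ratio:", attr(x, "ratio"),
      "| expected null share:", attr(x, "expected_null_share"), "%\n")
  invisible(x)
}
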