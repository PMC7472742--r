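#' Marker map
#'
#' A table of markers with their linkage group and physical position.
#' Positions are 1-based physical megabase-pair (Mbp) coordinates on an
#' orthologous reference map (e.g. tilapia linkage groups); intervals built
#' from them are closed at both ends. Within a linkage group positions must
#' be strictly increasing in the supplied order.
#'
#' @param marker_id character vector of unique marker identifiers.
#' @param linkage_group character vector, one linkage group per marker.
#' @param position_mbp numeric vector of non-negative physical positions (Mbp).
#' @return A `data.frame` of class `marker_map` with columns `marker_id`,
#'   `linkage_group`, `position_mbp`, sorted by linkage group and position.
#' @export
marker_map <- function(marker_id, linkage_group, position_mbp) {
  marker_id <- as.character(marker_id)
  linkage_group <- as.character(linkage_group)
  position_mbp <- as.numeric(position_mbp)
  n <- length(marker_id)
  if (length(linkage_group) != n || length(position_mbp) != n)
    stop("marker_map: columns must have equal length")
  if (anyDuplicated(marker_id))
    stop("marker_map: duplicated marker_id: ",
         paste(unique(marker_id[duplicated(marker_id)]), collapse = ", "))
  if (any(is.na(position_mbp)) || any(position_mbp < 0))
    stop("marker_map: positions must be non-negative and non-missing")
  m <- data.frame(marker_id = marker_id, linkage_group = linkage_group,
                  position_mbp = position_mbp, stringsAsFactors = FALSE)
  m <- m[order(m$linkage_group, m$position_mbp), , drop = FALSE]
  rownames(m) <- NULL
  for (lg in unique(m$linkage_group)) {
    p <- m$position_mbp[m$linkage_group == lg]
    if (any(diff(p) <= 0))
      stop("marker_map: positions within linkage group '", lg,
           "' must be strictly increasing")
  }
  class(m) <- c("marker_map", "data.frame")
  m
}

#' Genotype table
#'
#' Individuals-by-markers unphased genotype calls. Each call is an unordered
#' allele pair stored as `(min, max)`; alleles are small positive integers
#' (SNP calls "11"/"12"/"22" are the two-allele case, microsatellite calls
#' use larger allele indices). Missing calls ("ND", not determined) are `NA`
#' in both allele matrices.
#'
#' @param individuals data.frame with columns `id`, `family`, `sex`
#'   (`sex` in `"male"`, `"female"`, `"unknown"`).
#' @param markers character vector of marker ids (column order of the call
#'   matrices).
#' @param a1,a2 integer matrices (individuals x markers) holding the two
#'   alleles of each call; `NA` for missing. Pairs are normalised so that
#'   `a1 <= a2`.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(individuals, markers, a1, a2) {
  stopifnot(is.data.frame(individuals),
            all(c("id", "family", "sex") %in% names(individuals)))
  individuals$id <- as.character(individuals$id)
  individuals$family <- as.character(individuals$family)
  individuals$sex <- as.character(individuals$sex)
  if (anyDuplicated(individuals$id))
    stop("genotype_table: duplicated individual id: ",
         paste(unique(individuals$id[duplicated(individuals$id)]), collapse = ", "))
  bad <- setdiff(unique(individuals$sex), c("male", "female", "unknown"))
  if (length(bad))
    stop("genotype_table: invalid sex label(s): ", paste(bad, collapse = ", "))
  markers <- as.character(markers)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == c(nrow(individuals), length(markers))) ||
      !all(dim(a2) == dim(a1)))
    stop("genotype_table: call matrix dimensions must be individuals x markers")
  if (any(a1[!is.na(a1)] <= 0) || any(a2[!is.na(a2)] <= 0))
    stop("genotype_table: allele values must be positive integers")
  if (any(xor(is.na(a1), is.na(a2))))
    stop("genotype_table: half-missing calls are not allowed")
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  dimnames(lo) <- dimnames(hi) <- list(individuals$id, markers)
  structure(list(individuals = individuals, markers = markers,
                 a1 = lo, a2 = hi),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table: ", nrow(x$individuals), " individuals x ",
      length(x$markers), " markers (",
      sum(is.na(x$a1)), " missing calls)\n", sep = "")
  fams <- table(x$individuals$family)
  cat("families:", paste(names(fams), "(", fams, ")", sep = "", collapse = " "),
      "\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$a1)

#' Subset a genotype table by individuals and/or markers
#'
#' @param x a `genotype_table`.
#' @param i individual selector (ids, logical or integer indices).
#' @param j marker selector (ids, logical or integer indices).
#' @param ... unused.
#' @export
`[.genotype_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$a1))
  if (missing(j)) j <- seq_along(x$markers)
  if (is.character(i)) i <- match(i, x$individuals$id)
  if (is.character(j)) j <- match(j, x$markers)
  genotype_table(x$individuals[i, , drop = FALSE], x$markers[j],
                 x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE])
}

#' Orthology map of genes to linkage groups
#'
#' Gene locations on the orthologous reference linkage groups, used both to
#' place differentially expressed genes and to derive the per-linkage-group
#' gene totals \eqn{G_i} and the global total \eqn{G_t = \sum_i G_i} that
#' enter the relative-abundance statistic.
#'
#' @param gene_id character vector of unique gene identifiers.
#' @param linkage_group character vector, one linkage group per gene.
#' @param position_mbp numeric physical position (Mbp) per gene.
#' @return A `data.frame` of class `orthology_map`.
#' @export
orthology_map <- function(gene_id, linkage_group, position_mbp) {
  gene_id <- as.character(gene_id)
  linkage_group <- as.character(linkage_group)
  position_mbp <- as.numeric(position_mbp)
  n <- length(gene_id)
  if (length(linkage_group) != n || length(position_mbp) != n)
    stop("orthology_map: columns must have equal length")
  if (anyDuplicated(gene_id))
    stop("orthology_map: gene assigned more than once: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (any(is.na(linkage_group)) || any(is.na(position_mbp)) ||
      any(position_mbp < 0))
    stop("orthology_map: linkage groups and positions must be non-missing, positions >= 0")
  o <- data.frame(gene_id = gene_id, linkage_group = linkage_group,
                  position_mbp = position_mbp, stringsAsFactors = FALSE)
  class(o) <- c("orthology_map", "data.frame")
  o
}

#' Per-linkage-group gene totals
#'
#' @param ortho an `orthology_map`.
#' @return Named integer vector of gene counts per linkage group (\eqn{G_i});
#'   their sum is the global total \eqn{G_t}.
#' @export
lg_totals <- function(ortho) {
  stopifnot(inherits(ortho, "orthology_map"))
  tab <- table(ortho$linkage_group)
  structure(as.integer(tab), names = names(tab))
}

#' Count matrix
#'
#' A genes-by-samples matrix of non-negative integer read counts. Library
#' sizes are the column sums.
#'
#' @param counts numeric matrix with gene ids as rownames and sample ids as
#'   colnames; values must be non-negative integers.
#' @return An integer matrix of class `count_matrix`.
#' @export
count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count_matrix: gene (row) and sample (column) names are required")
  if (anyDuplicated(rownames(counts)))
    stop("count_matrix: duplicated gene ids")
  if (anyDuplicated(colnames(counts)))
    stop("count_matrix: duplicated sample ids")
  if (any(is.na(counts)) || any(counts < 0))
    stop("count_matrix: counts must be non-negative and non-missing")
  if (any(counts != round(counts)))
    stop("count_matrix: counts must be integers")
  storage.mode(counts) <- "integer"
  class(counts) <- c("count_matrix", class(counts))
  counts
}

#' Library sizes of a count matrix
#'
#' @param counts a `count_matrix` (or plain matrix of counts).
#' @return Named numeric vector of per-sample column sums.
#' @export
library_sizes <- function(counts) colSums(unclass(counts))
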