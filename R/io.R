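# TSV dialect shared by all readers: tab-separated, UTF-8, "#" comment lines
# ignored, "ND" = missing genotype call.

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  strsplit(lines, "\t", fixed = TRUE)
}

tsv_table <- function(path) {
  rows <- read_tsv_raw(path)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L)
    stop("ragged rows in ", path, ": line widths ",
         paste(unique(widths), collapse = ","))
  header <- rows[[1]]
  body <- rows[-1]
  cols <- lapply(seq_along(header), function(j)
    vapply(body, `[[`, character(1), j))
  names(cols) <- header
  as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
}

# Parse one genotype token. Accepts the compact two-digit convention
# ("11", "12", "22"), the general "a/b" form for multi-allelic markers,
# and "ND" for missing. Returns c(a1, a2) with NA for missing.
parse_call <- function(token, where = "") {
  token <- trimws(token)
  if (token == "ND" || token == "") return(c(NA_integer_, NA_integer_))
  if (grepl("^[0-9]+/[0-9]+$", token)) {
    ab <- as.integer(strsplit(token, "/", fixed = TRUE)[[1]])
  } else if (grepl("^[1-9][1-9]$", token)) {
    ab <- as.integer(c(substr(token, 1, 1), substr(token, 2, 2)))
  } else {
    stop("malformed allele token '", token, "'", where)
  }
  if (any(ab <= 0)) stop("malformed allele token '", token, "'", where)
  c(min(ab), max(ab))
}

format_call <- function(a1, a2) {
  out <- rep("ND", length(a1))
  ok <- !is.na(a1)
  compact <- ok & a1 <= 9 & a2 <= 9
  out[compact] <- paste0(a1[compact], a2[compact])
  gen <- ok & !compact
  out[gen] <- paste0(a1[gen], "/", a2[gen])
  out
}

#' Read a marker map from TSV
#'
#' Expects columns `marker_id`, `linkage_group`, `position_mbp`.
#'
#' @param path file path.
#' @return A [marker_map()].
#' @export
read_marker_map <- function(path) {
  d <- tsv_table(path)
  need <- c("marker_id", "linkage_group", "position_mbp")
  if (!all(need %in% names(d)))
    stop("marker map must have columns: ", paste(need, collapse = ", "))
  marker_map(d$marker_id, d$linkage_group, as.numeric(d$position_mbp))
}

#' Write a marker map to TSV
#'
#' @param map a `marker_map`.
#' @param path output file path.
#' @export
write_marker_map <- function(map, path) {
  stopifnot(inherits(map, "marker_map"))
  write_tsv_df(as.data.frame(map), path)
}

write_tsv_df <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a genotype table from TSV
#'
#' The file has columns `id`, `family`, `sex`, followed by one column per
#' marker. Calls use the compact "11"/"12"/"22" convention or "a/b" for
#' multi-allelic markers; "ND" marks a missing (not determined) call.
#' When a marker map is supplied, marker columns are reordered to map order
#' within each linkage group and markers absent from the map are rejected.
#'
#' @param path file path.
#' @param map optional [marker_map()] used to validate and order markers.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, map = NULL) {
  d <- tsv_table(path)
  meta_cols <- c("id", "family", "sex")
  if (!all(meta_cols %in% names(d)))
    stop("genotype file must have columns id, family, sex before markers")
  markers <- setdiff(names(d), meta_cols)
  if (!is.null(map)) {
    unknown <- setdiff(markers, map$marker_id)
    if (length(unknown))
      stop("marker(s) absent from map: ", paste(unknown, collapse = ", "))
    markers <- map$marker_id[map$marker_id %in% markers]
  }
  n <- nrow(d)
  a1 <- matrix(NA_integer_, n, length(markers))
  a2 <- matrix(NA_integer_, n, length(markers))
  for (j in seq_along(markers)) {
    toks <- d[[markers[j]]]
    for (i in seq_len(n)) {
      ab <- parse_call(toks[i], where = sprintf(
        " (row %d [%s], column %s)", i, d$id[i], markers[j]))
      a1[i, j] <- ab[1]; a2[i, j] <- ab[2]
    }
  }
  ind <- d[meta_cols]
  if (n == 0L) ind <- data.frame(id = character(), family = character(),
                                 sex = character(), stringsAsFactors = FALSE)
  genotype_table(ind, markers, a1, a2)
}

#' Write a genotype table to TSV
#'
#' @param gt a `genotype_table`.
#' @param path output file path.
#' @export
write_genotypes <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  d <- gt$individuals[c("id", "family", "sex")]
  for (j in seq_along(gt$markers))
    d[[gt$markers[j]]] <- format_call(gt$a1[, j], gt$a2[, j])
  write_tsv_df(d, path)
}

#' Read an orthology map from TSV
#'
#' Expects columns `gene_id`, `linkage_group`, `position_mbp`. Per-linkage
#' group gene totals are available via [lg_totals()].
#'
#' @param path file path.
#' @return An [orthology_map()].
#' @export
read_orthology <- function(path) {
  d <- tsv_table(path)
  need <- c("gene_id", "linkage_group", "position_mbp")
  if (!all(need %in% names(d)))
    stop("orthology map must have columns: ", paste(need, collapse = ", "))
  orthology_map(d$gene_id, d$linkage_group, as.numeric(d$position_mbp))
}

#' Write an orthology map to TSV
#'
#' @param ortho an `orthology_map`.
#' @param path output file path.
#' @export
write_orthology <- function(ortho, path) {
  stopifnot(inherits(ortho, "orthology_map"))
  write_tsv_df(as.data.frame(ortho), path)
}

#' Read a count matrix from TSV
#'
#' First column holds gene ids; the header line names the samples. All
#' counts must be non-negative integers; a fractional or negative token is
#' rejected.
#'
#' @param path file path.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path) {
  rows <- read_tsv_raw(path)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L)
    stop("ragged rows in ", path, ": line widths ",
         paste(unique(widths), collapse = ","))
  header <- rows[[1]]
  body <- rows[-1]
  samples <- header[-1]
  genes <- vapply(body, `[[`, character(1), 1)
  vals <- lapply(body, function(r) r[-1])
  mat <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
  for (i in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[i]]))
    bad <- is.na(v) | v < 0 | v != round(v)
    if (any(bad))
      stop("invalid count token '", vals[[i]][which(bad)[1]], "' in gene ",
           genes[i], ": counts must be non-negative integers")
    mat[i, ] <- as.integer(v)
  }
  count_matrix(mat)
}

#' Write a count matrix to TSV
#'
#' @param counts a `count_matrix`.
#' @param path output file path.
#' @export
write_counts <- function(counts, path) {
  d <- data.frame(gene_id = rownames(counts), unclass(counts),
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_df(d, path)
}

#' Write simulation ground truth as YAML
#'
#' @param truth a ground-truth list as returned by the simulators.
#' @param path output file path.
#' @export
write_ground_truth <- function(truth, path) {
  yaml::write_yaml(truth, path)
  invisible(path)
}
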