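# Recombinant-based refinement of the sex-determining interval.
#
# Within each family, phenotyped males and females define per-marker modal
# genotypes (the "sex consensus"). An individual whose genotypes flip to
# the opposite sex's consensus over a run of adjacent sex-informative
# markers evidences a crossover between its sex-determining locus and that
# run; the margins of such runs, intersected across individuals and
# families, delimit the SDR.

call_string <- function(a1, a2) ifelse(is.na(a1), NA_character_,
                                       paste0(a1, "/", a2))

modal_call <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (!length(calls)) return(list(call = NA_character_, tie = FALSE))
  tab <- sort(table(calls), decreasing = TRUE)
  tie <- length(tab) > 1L && tab[1] == tab[2]
  list(call = names(tab)[1], tie = tie)
}

#' Per-family, per-marker sex-consensus genotypes
#'
#' Computes the modal genotype among phenotyped males and among phenotyped
#' females of each family. A marker is sex-informative when both modal
#' genotypes are defined and differ; a tie within either sex makes the
#' marker uninformative. Individuals with `sex == "unknown"` are ignored.
#'
#' @param genotypes a [genotype_table()].
#' @param sexes optional named character vector overriding the sex labels
#'   in the genotype table.
#' @param map optional [marker_map()]; when given, markers are ordered by
#'   map position and physical positions are carried into downstream
#'   breakpoint coordinates (otherwise marker index is used).
#' @return An object of class `sex_consensus`: per family a data.frame with
#'   `marker_id`, `male_call`, `female_call`, `informative`.
#' @export
build_consensus <- function(genotypes, sexes = NULL, map = NULL) {
  stopifnot(inherits(genotypes, "genotype_table"))
  gt <- genotypes
  if (!is.null(map)) {
    ord <- map$marker_id[map$marker_id %in% gt$markers]
    gt <- gt[, ord]
  }
  sex <- gt$individuals$sex
  if (!is.null(sexes)) {
    hit <- gt$individuals$id %in% names(sexes)
    sex[hit] <- unname(sexes[gt$individuals$id[hit]])
  }
  positions <- if (!is.null(map))
    map$position_mbp[match(gt$markers, map$marker_id)]
  else seq_along(gt$markers)
  lgs <- if (!is.null(map))
    map$linkage_group[match(gt$markers, map$marker_id)]
  else rep("LG?", length(gt$markers))
  fams <- unique(gt$individuals$family)
  per_family <- list()
  for (fam in fams) {
    in_fam <- gt$individuals$family == fam
    males <- which(in_fam & sex == "male")
    females <- which(in_fam & sex == "female")
    if (!length(males) || !length(females))
      stop(structure(class = c("sdrmap_consensus_undefined", "error",
                               "condition"),
                     list(message = paste0("consensus undefined for family ",
                                           fam, ": only one sex phenotyped"),
                          call = sys.call(-1))))
    rows <- lapply(seq_along(gt$markers), function(k) {
      mc <- modal_call(call_string(gt$a1[males, k], gt$a2[males, k]))
      fc <- modal_call(call_string(gt$a1[females, k], gt$a2[females, k]))
      informative <- !mc$tie && !fc$tie && !is.na(mc$call) &&
        !is.na(fc$call) && mc$call != fc$call
      data.frame(marker_id = gt$markers[k], male_call = mc$call,
                 female_call = fc$call, informative = informative,
                 stringsAsFactors = FALSE)
    })
    per_family[[fam]] <- do.call(rbind, rows)
  }
  structure(list(families = per_family, markers = gt$markers,
                 positions = positions, linkage_groups = lgs,
                 sex = stats::setNames(sex, gt$individuals$id)),
            class = "sex_consensus")
}

#' Detect recombinant individuals against the sex consensus
#'
#' Scans every phenotyped individual for maximal runs of adjacent
#' sex-informative markers at which it matches the opposite sex's consensus
#' genotype. Missing calls and sex-uninformative markers neither extend nor
#' break a run; a call matching neither consensus breaks it. Runs of at
#' least `min_run` markers are reported as recombination events, with the
#' breakpoint interval on each flanked side given by the positions of the
#' last concordant and first discordant marker (`NA` on a side where the
#' run reaches the end of the scanned region).
#'
#' @param genotypes a [genotype_table()].
#' @param consensus a [build_consensus()] result on the same markers.
#' @param min_run minimum run length (default 3).
#' @return A data.frame of class `recombination_events`, one row per event:
#'   individual, family, sex, run extent (marker ids, length), flanking
#'   concordant markers and breakpoint interval bounds in map coordinates.
#' @export
detect_recombinants <- function(genotypes, consensus, min_run = 3L) {
  stopifnot(inherits(genotypes, "genotype_table"),
            inherits(consensus, "sex_consensus"), min_run >= 1L)
  gt <- genotypes[, consensus$markers]
  events <- list()
  for (i in seq_len(nrow(gt$individuals))) {
    id <- gt$individuals$id[i]
    fam <- gt$individuals$family[i]
    sex <- unname(consensus$sex[id])
    if (is.na(sex) || !sex %in% c("male", "female")) next
    cons <- consensus$families[[fam]]
    if (is.null(cons)) next
    own <- if (sex == "male") cons$male_call else cons$female_call
    opp <- if (sex == "male") cons$female_call else cons$male_call
    ks <- which(cons$informative)
    calls <- call_string(gt$a1[i, ], gt$a2[i, ])
    # status over informative markers: skip missing, break on "other"
    status <- character(0); kept <- integer(0)
    for (k in ks) {
      if (is.na(calls[k])) next           # ND: neither extends nor breaks
      st <- if (calls[k] == opp[k]) "D"
            else if (calls[k] == own[k]) "C" else "X"
      status <- c(status, st); kept <- c(kept, k)
    }
    if (!length(kept)) next
    r <- rle(status)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (s in which(r$values == "D" & r$lengths >= min_run)) {
      run_idx <- kept[starts[s]:ends[s]]
      left_flank <- if (starts[s] > 1L) kept[starts[s] - 1L] else NA_integer_
      right_flank <- if (ends[s] < length(kept)) kept[ends[s] + 1L]
                     else NA_integer_
      pos <- consensus$positions
      events[[length(events) + 1L]] <- data.frame(
        id = id, family = fam, sex = sex,
        linkage_group = consensus$linkage_groups[run_idx[1]],
        run_first_marker = consensus$markers[run_idx[1]],
        run_last_marker = consensus$markers[run_idx[length(run_idx)]],
        run_length = length(run_idx),
        flank_left_marker = ifelse(is.na(left_flank), NA_character_,
                                   consensus$markers[left_flank]),
        flank_right_marker = ifelse(is.na(right_flank), NA_character_,
                                    consensus$markers[right_flank]),
        bp_left_lo = ifelse(is.na(left_flank), NA_real_, pos[left_flank]),
        bp_left_hi = pos[run_idx[1]],
        bp_right_lo = pos[run_idx[length(run_idx)]],
        bp_right_hi = ifelse(is.na(right_flank), NA_real_, pos[right_flank]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(events)) do.call(rbind, events) else
    data.frame(id = character(), family = character(), sex = character(),
               linkage_group = character(), run_first_marker = character(),
               run_last_marker = character(), run_length = integer(),
               flank_left_marker = character(),
               flank_right_marker = character(), bp_left_lo = numeric(),
               bp_left_hi = numeric(), bp_right_lo = numeric(),
               bp_right_hi = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "span") <- range(consensus$positions)
  attr(res, "min_run") <- as.integer(min_run)
  class(res) <- c("recombination_events", "data.frame")
  res
}

# intersect a union of closed intervals (matrix with columns lo, hi) with
# another union; both may be empty (0-row)
intersect_unions <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(a[0, , drop = FALSE])
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (lo <= hi) out[[length(out) + 1L]] <- c(lo, hi)
  }
  if (!length(out)) return(a[0, , drop = FALSE])
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

#' Refine the SDR interval from recombination events
#'
#' Each event restricts the SDR to the side(s) of its breakpoint on which
#' the individual matches its own sex's consensus. The crossover lies
#' somewhere in the breakpoint gap, so the allowed region is bounded
#' conservatively at the outer margin of that gap — the position of the
#' outermost discordant marker of the run. This guarantees the causal
#' locus is never excluded by a correctly inferred event. The refined
#' interval is the intersection of the allowed regions of all events (the
#' full marker span when there are none); an empty intersection signals
#' inconsistent events.
#'
#' @param events a [detect_recombinants()] result; all events must lie on
#'   one linkage group.
#' @param map a [marker_map()] for the scanned markers.
#' @param ortho optional [orthology_map()]; when given, the number of genes
#'   inside the refined interval is reported.
#' @return An object of class `sdr_interval` with the linkage group, start
#'   and end (Mbp, closed), width, number of supporting events, marker and
#'   gene counts inside, and which sides are delimited by an event.
#' @export
refine_interval <- function(events, map, ortho = NULL) {
  stopifnot(inherits(events, "recombination_events"),
            inherits(map, "marker_map"))
  span <- attr(events, "span")
  lg <- unique(events$linkage_group)
  if (length(lg) > 1L)
    stop("events span several linkage groups: ", paste(lg, collapse = ", "))
  if (!length(lg)) lg <- unique(map$linkage_group)[1]
  allowed <- matrix(span, 1L, 2L)
  bounded <- c(left = FALSE, right = FALSE)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    segs <- list()
    if (!is.na(ev$bp_left_lo)) {            # concordant region left of run
      segs[[length(segs) + 1L]] <- c(span[1], ev$bp_left_hi)
      bounded["right"] <- TRUE              # run delimits SDR from the right
    }
    if (!is.na(ev$bp_right_hi)) {           # concordant region right of run
      segs[[length(segs) + 1L]] <- c(ev$bp_right_lo, span[2])
      bounded["left"] <- TRUE
    }
    if (!length(segs)) next                 # run covers the whole span
    allowed <- intersect_unions(allowed, do.call(rbind, segs))
  }
  if (!nrow(allowed))
    stop(structure(class = c("sdrmap_inconsistent_events", "error",
                             "condition"),
                   list(message = "inconsistent events: no region is compatible with every individual's sex",
                        call = sys.call(-1))))
  if (nrow(allowed) > 1L) {
    warning("allowed region is a union of ", nrow(allowed),
            " segments; reporting its convex hull")
  }
  start <- min(allowed[, 1]); end <- max(allowed[, 2])
  in_lg <- map$linkage_group == lg
  n_markers <- sum(in_lg & map$position_mbp >= start &
                     map$position_mbp <= end)
  n_genes <- NA_integer_
  if (!is.null(ortho))
    n_genes <- sum(ortho$linkage_group == lg & ortho$position_mbp >= start &
                     ortho$position_mbp <= end)
  structure(list(linkage_group = lg, start_mbp = start, end_mbp = end,
                 width_mbp = end - start, n_events = nrow(events),
                 n_markers = n_markers, n_genes = n_genes,
                 bounded = bounded, span = span),
            class = "sdr_interval")
}

#' @export
print.sdr_interval <- function(x, ...) {
  cat(sprintf("SDR interval: %s %.2f-%.2f Mbp (width %.2f Mbp)\n",
              x$linkage_group, x$start_mbp, x$end_mbp, x$width_mbp))
  cat("  supporting events:", x$n_events,
      "| delimited:", paste(names(x$bounded)[x$bounded], collapse = "+"),
      "\n")
  cat("  markers inside:", x$n_markers)
  if (!is.na(x$n_genes)) cat(" | genes inside:", x$n_genes)
  cat("\n")
  invisible(x)
}
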