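# Shared fixtures and independent oracles, built in code.

# A two-family genotype matrix over 15 markers reproducing the classic
# refinement structure: one male shows the female genotype pattern over the
# 4 leftmost markers, one female shows the male pattern over the 3
# rightmost markers; everyone else is fully concordant. One ND call sits
# inside the male's discordant run (must neither break nor shorten it below
# the marker count of informative discordant calls).
fig2_family <- function() {
  n_mark <- 15L
  markers <- sprintf("K%02d", seq_len(n_mark))
  pos <- seq(0.2, 3.0, length.out = n_mark)
  map <- marker_map(markers, rep("LG8", n_mark), pos)
  male_row <- rep(2L, n_mark)    # male pattern: "12" (a1=1, a2=2)
  female_row <- rep(1L, n_mark)  # female pattern: "11"
  ind <- list(); a1 <- list(); a2 <- list()
  add <- function(id, fam, sex, a2row) {
    ind[[length(ind) + 1L]] <<- data.frame(id = id, family = fam, sex = sex,
                                           stringsAsFactors = FALSE)
    a1[[length(a1) + 1L]] <<- rep(1L, n_mark)
    a2[[length(a2) + 1L]] <<- a2row
  }
  for (i in 1:4) add(paste0("A1_m", i), "A1", "male", male_row)
  for (i in 1:4) add(paste0("A1_f", i), "A1", "female", female_row)
  for (i in 1:4) add(paste0("B_m", i), "B", "male", male_row)
  for (i in 1:4) add(paste0("B_f", i), "B", "female", female_row)
  gt <- genotype_table(do.call(rbind, ind), markers,
                       do.call(rbind, a1), do.call(rbind, a2))
  # Male #4 of family A1: female pattern over the 4 leftmost markers
  gt$a2["A1_m4", 1:4] <- 1L
  # one ND inside the run
  gt$a1["A1_m4", 2] <- NA_integer_; gt$a2["A1_m4", 2] <- NA_integer_
  # Female #8 analogue (B_f4): male pattern over the 3 rightmost markers
  gt$a2["B_f4", 13:15] <- 2L
  list(genotypes = gt, map = map)
}

# Independent brute-force recombinant scan: enumerate every (individual,
# contiguous window over the informative-and-called marker subsequence),
# keep maximal all-discordant windows of length >= min_run.
brute_force_events <- function(genotypes, consensus, min_run) {
  out <- list()
  gt <- genotypes[, consensus$markers]
  for (i in seq_len(nrow(gt$individuals))) {
    id <- gt$individuals$id[i]
    fam <- gt$individuals$family[i]
    sex <- unname(consensus$sex[id])
    if (is.na(sex) || !sex %in% c("male", "female")) next
    cons <- consensus$families[[fam]]
    own <- if (sex == "male") cons$male_call else cons$female_call
    opp <- if (sex == "male") cons$female_call else cons$male_call
    calls <- ifelse(is.na(gt$a1[i, ]), NA_character_,
                    paste0(gt$a1[i, ], "/", gt$a2[i, ]))
    kept <- which(cons$informative & !is.na(calls))
    disc <- calls[kept] == opp[kept] & calls[kept] != own[kept]
    brk <- calls[kept] != opp[kept]  # concordant or "other" both break
    n <- length(kept)
    for (s in seq_len(n)) for (e in seq(s, n)) {
      if (!all(disc[s:e])) next
      maximal <- (s == 1L || !disc[s - 1L]) && (e == n || !disc[e + 1L])
      if (maximal && e - s + 1L >= min_run)
        out[[length(out) + 1L]] <- data.frame(
          id = id, first = consensus$markers[kept[s]],
          last = consensus$markers[kept[e]], len = e - s + 1L,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(id = character(), first = character(), last = character(),
               len = integer(), stringsAsFactors = FALSE)
}

# minimal assignment object for expression tests
mk_assignment <- function(n_per_group, prefix = "S") {
  structure(data.frame(id = paste0(prefix, seq_len(2 * n_per_group)),
                       family = "F1", scenario = "paternal",
                       haplotype = NA_integer_,
                       group = rep(c("A", "B"), each = n_per_group),
                       stringsAsFactors = FALSE),
            class = c("sex_group_assignment", "data.frame"))
}

# label-permutation-aware accuracy of a two-group assignment vs true sex
assignment_accuracy <- function(groups, true_sex) {
  ok <- !is.na(groups)
  acc <- mean(groups[ok] == ifelse(true_sex[ok] == "male", "A", "B"))
  max(acc, 1 - acc)
}
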