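cfg_small <- sim_config(n_families = 1, offspring_per_family = 10)

test_that("family simulation is deterministic in (config, seed)", {
  a <- simulate_family(cfg_small, seed = 7)
  b <- simulate_family(cfg_small, seed = 7)
  expect_identical(a, b)
  c <- simulate_family(cfg_small, seed = 8)
  expect_false(identical(a$genotypes$a2, c$genotypes$a2))
})

test_that("offspring genotypes are Mendelian-consistent with their parents", {
  fam <- simulate_family(sim_config(offspring_per_family = 20), seed = 3)
  gt <- fam$genotypes
  for (f in unique(gt$individuals$family)) {
    si <- match(paste0(f, "_sire"), gt$individuals$id)
    di <- match(paste0(f, "_dam"), gt$individuals$id)
    off <- setdiff(which(gt$individuals$family == f), c(si, di))
    for (o in off) for (k in seq_along(gt$markers)) {
      explained <- FALSE
      for (a in c(gt$a1[si, k], gt$a2[si, k]))
        for (b in c(gt$a1[di, k], gt$a2[di, k]))
          if (min(a, b) == gt$a1[o, k] && max(a, b) == gt$a2[o, k])
            explained <- TRUE
      expect_true(explained)
    }
  }
})

test_that("without crossovers offspring carry exactly 2 paternal and <= 2 maternal haplotypes", {
  cfg <- sim_config(n_families = 1, offspring_per_family = 12,
                    crossover_rate = 0)
  fam <- simulate_family(cfg, seed = 5)
  expect_equal(nrow(fam$truth$crossovers), 0L)
  gt <- fam$genotypes
  off <- which(!gt$individuals$id %in% c("F1_sire", "F1_dam"))
  # paternal allele at each marker: dam is known, subtract her contribution
  # using the truth phase (oracle view)
  pat <- fam$phase$F1$paternal
  hap_of <- fam$truth$offspring$paternal_hap
  expect_setequal(unique(hap_of), c("X", "Y"))
  # offspring of the same paternal haplotype and same maternal start share
  # identical transmitted paternal alleles at every marker
  for (h in c("X", "Y")) {
    ids <- fam$truth$offspring$id[hap_of == h]
    rows <- match(ids, gt$individuals$id)
    pat_row <- pat[if (h == "X") 1 else 2, ]
    for (r in rows) {
      mat_allele <- ifelse(gt$a1[r, ] == pat_row, gt$a2[r, ], gt$a1[r, ])
      expect_true(all(gt$a1[r, ] == pmin(pat_row, mat_allele) &
                        gt$a2[r, ] == pmax(pat_row, mat_allele)))
    }
  }
})

test_that("a planted crossover reproduces the opposite-sex run pattern", {
  cfg <- sim_config(n_families = 1, offspring_per_family = 10,
                    crossover_rate = 0, dam_het_prob = 0)
  pc <- data.frame(family = 1, offspring = 4, parent = "paternal",
                   interval = 4)
  fam <- simulate_family(cfg, seed = 2, planted_crossovers = pc)
  gt <- fam$genotypes
  r <- match("F1_o04", gt$individuals$id)
  sex4 <- fam$truth$offspring$true_sex[fam$truth$offspring$id == "F1_o04"]
  # with a homozygous dam, males are "12" and females "11" at every marker;
  # the crossover between markers 4 and 5 flips one flank to the opposite
  # pattern
  calls <- paste0(gt$a1[r, ], gt$a2[r, ])
  own <- if (sex4 == "male") "12" else "11"
  opp <- if (sex4 == "male") "11" else "12"
  expect_true(all(calls[1:4] == opp) || all(calls[5:12] == opp))
  expect_true(all(calls[1:4] == own) || all(calls[5:12] == own))
  expect_equal(fam$truth$crossovers$id, "F1_o04")
  expect_equal(fam$truth$crossovers$left_marker, 4L)
})

test_that("parentage panel honours Mendelian transmission and flags low power", {
  cfg <- sim_config()
  pan <- simulate_parentage_panel(cfg, seed = 11)
  sire <- pan$truth$true_sire
  si <- match(sire, pan$candidates$individuals$id)
  # brute-force allele sharing: every offspring shares >= 1 allele with the
  # true sire and with the dam at every marker
  for (o in seq_len(nrow(pan$offspring$individuals)))
    for (k in seq_along(pan$offspring$markers)) {
      off <- c(pan$offspring$a1[o, k], pan$offspring$a2[o, k])
      expect_true(any(c(pan$candidates$a1[si, k],
                        pan$candidates$a2[si, k]) %in% off))
      expect_true(any(c(pan$dam$a1[1, k], pan$dam$a2[1, k]) %in% off))
    }
  expect_false(pan$truth$low_power)
  expect_gt(pan$truth$exclusion_prob, 0.5)
  # a single biallelic marker cannot exclude reliably
  weak <- simulate_parentage_panel(
    sim_config(n_parentage_markers = 1, alleles_per_marker = 2),
    seed = 4, informative = FALSE)
  expect_true(weak$truth$low_power)
})

test_that("empty parentage panel and determinism behave", {
  cfg <- sim_config()
  p0 <- simulate_parentage_panel(cfg, seed = 9, n_offspring = 0)
  expect_equal(nrow(p0$offspring$individuals), 0L)
  expect_equal(nrow(p0$candidates$individuals), cfg$n_candidate_sires)
  expect_identical(simulate_parentage_panel(cfg, seed = 9),
                   simulate_parentage_panel(cfg, seed = 9))
})

test_that("count simulation places DE genes and honours null and boundary cases", {
  cfg <- sim_config(n_genes = 400, n_lgs = 8, sd_lg = 3, n_de_genes = 50,
                    n_sex_specific = 10)
  ortho <- simulate_orthology(cfg, seed = 6)
  asg <- mk_assignment(6)
  sim <- simulate_counts(asg, ortho, cfg, seed = 6)
  truth <- sim$truth$de_genes
  expect_equal(nrow(truth), 50L)
  expect_equal(sum(truth$sex_specific), 10L)
  expect_true(all(truth$gene_id[truth$sex_specific] %in% truth$gene_id))
  expect_equal(sum(truth$linkage_group == "LG3"), round(0.48 * 50))
  # sex-specific genes: zero in one group, expressed in the other
  for (i in which(truth$sex_specific)) {
    g <- truth$gene_id[i]
    a <- sim$counts[g, asg$group == "A"]; b <- sim$counts[g, asg$group == "B"]
    if (truth$up_in[i] == "A") expect_true(all(b == 0) && mean(a) > 0)
    else expect_true(all(a == 0) && mean(b) > 0)
  }
  # boundary: all DE genes on the SD linkage group
  cfg1 <- sim_config(n_genes = 400, n_lgs = 8, sd_lg = 3, n_de_genes = 30,
                     n_sex_specific = 0, frac_de_on_sdlg = 1)
  s1 <- simulate_counts(asg, ortho, cfg1, seed = 6)
  expect_true(all(s1$truth$de_genes$linkage_group == "LG3"))
  # null: group means indistinguishable by construction
  cfg0 <- sim_config(n_genes = 400, n_lgs = 8, sd_lg = 3, n_de_genes = 50,
                     n_sex_specific = 10, effect_log2fc = 0)
  s0 <- simulate_counts(asg, ortho, cfg0, seed = 6)
  expect_equal(nrow(s0$truth$de_genes), 50L)
  mA <- rowMeans(s0$counts[, asg$group == "A"])
  mB <- rowMeans(s0$counts[, asg$group == "B"])
  expect_lt(abs(mean(log2((mA + 1) / (mB + 1)))), 0.1)
})
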