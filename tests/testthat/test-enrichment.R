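test_that("relative abundance reduces to 1 under exact proportionality", {
  # 3 LGs with 10/20/30 genes; DE genes drawn proportionally: 1/2/3
  ortho <- orthology_map(paste0("g", 1:60),
                         rep(c("LG1", "LG2", "LG3"), c(10, 20, 30)),
                         seq(0.1, 6, by = 0.1))
  de <- c("g1", "g11", "g12", "g31", "g32", "g33")
  es <- enrichment_summary(de, ortho)
  expect_equal(es$RAi, rep(1, 3))
  expect_equal(sum(es$DEi), attr(es, "DEt"))
})

test_that("relative abundance matches direct arithmetic", {
  # DEi=51 of DEt=107 on a 1000-gene LG out of Gt=33000
  gi <- c(LG8 = 1000L, other = 32000L)
  ortho <- orthology_map(paste0("g", seq_len(33000)),
                         rep(names(gi), gi), rep(1, 33000))
  de <- c(paste0("g", 1:51), paste0("g", 1000 + 1:56))
  es <- enrichment_summary(de, ortho)
  expect_equal(es$RAi[es$linkage_group == "LG8"], 51 * 33000 / (107 * 1000),
               tolerance = 1e-12)
  expect_equal(es$percent[es$linkage_group == "LG8"], 48L)
})

test_that("unmapped DE genes are excluded from DEt and conserved in the counts", {
  ortho <- orthology_map(paste0("g", 1:40), rep(c("LG1", "LG2"), each = 20),
                         rep(1, 40))
  de <- c(paste0("g", 1:10), "novel1", "novel2")
  expect_warning(es <- enrichment_summary(de, ortho), "unmapped")
  expect_equal(attr(es, "DEt"), 10L)
  expect_equal(attr(es, "unmapped"), 2L)
  expect_equal(sum(es$DEi) + attr(es, "unmapped"), length(de))
})

test_that("the RA normalization invariant holds on random placements", {
  cfg <- sim_config()
  ortho <- simulate_orthology(cfg, seed = 71)
  gi <- lg_totals(ortho); gt <- sum(gi)
  set.seed(71)
  for (r in 1:20) {
    de <- sample(ortho$gene_id, sample(20:150, 1))
    es <- enrichment_summary(de, ortho)
    expect_lt(abs(sum(es$RAi * es$Gi / gt) - 1), 1e-12)
    expect_equal(sum(es$DEi), attr(es, "DEt"))
  }
})

test_that("sex-specific tagging applies the strict all-or-nothing rule", {
  cm <- count_matrix(matrix(
    c(5L, 7L, 6L, 0L, 0L, 0L,    # tagged, expressed in A
      5L, 0L, 6L, 0L, 0L, 0L,    # one zero sample in A -> not tagged
      0L, 0L, 0L, 3L, 9L, 4L,    # tagged, expressed in B
      5L, 7L, 6L, 1L, 0L, 0L,    # expressed in both -> not tagged
      2L, 2L, 2L, 2L, 2L, 2L),   # flat -> not tagged
    5, 6, byrow = TRUE,
    dimnames = list(paste0("g", 1:5), paste0("S", 1:6))))
  asg <- mk_assignment(3)
  tags <- tag_sex_specific(cm, asg, min_expr = 1)
  expect_equal(tags$gene_id, c("g1", "g3"))
  expect_equal(tags$expressed_group, c("A", "B"))
  # restriction to a DE set
  tags2 <- tag_sex_specific(cm, asg, min_expr = 1, de = c("g3", "g5"))
  expect_equal(tags2$gene_id, "g3")
  # raising min_expr drops inconsistently expressed genes
  tags3 <- tag_sex_specific(cm, asg, min_expr = 6)
  expect_equal(nrow(tags3), 0L)
})

test_that("simulated sex-specific genes are recovered exactly and are DE", {
  cfg <- sim_config(n_genes = 300, n_lgs = 5, sd_lg = 2, n_de_genes = 30,
                    n_sex_specific = 8, genes_per_lg = rep(60L, 5))
  ortho <- simulate_orthology(cfg, seed = 81)
  asg <- mk_assignment(8)
  sim <- simulate_counts(asg, ortho, cfg, seed = 81)
  tags <- tag_sex_specific(sim$counts, asg, min_expr = 1)
  truth_ss <- sort(sim$truth$de_genes$gene_id[sim$truth$de_genes$sex_specific])
  expect_equal(tags$gene_id, truth_ss)
  de <- test_de(sim$counts, asg)
  expect_true(all(de$significant[match(tags$gene_id, de$gene_id)]))
})

test_that("transcript collapse keeps the minimum-p representative per gene", {
  de <- test_de(count_matrix(matrix(
    c(50L, 80L, 60L, 10L, 12L, 9L,
      55L, 70L, 65L, 11L, 10L, 12L,
      20L, 22L, 19L, 21L, 20L, 22L), 3, 6, byrow = TRUE,
    dimnames = list(c("t1", "t2", "t3"), paste0("S", 1:6)))),
    mk_assignment(3), min_total = 1)
  t2g <- c(t1 = "geneA", t2 = "geneA")
  col <- collapse_transcripts(de, t2g)
  expect_equal(nrow(col), 2L)
  a <- col[col$gene_id == "geneA", ]
  expect_equal(a$p_value, min(de$p_value[de$gene_id %in% c("t1", "t2")]))
  expect_equal(a$n_transcripts, 2L)
  expect_false(col$annotated[col$gene_id == "t3"])
  # equal p-values break ties lexicographically
  de2 <- de; de2$p_value <- c(0.5, 0.5, 0.2)
  col2 <- collapse_transcripts(de2, t2g)
  expect_equal(col2$transcript_id[col2$gene_id == "geneA"], "t1")
  # 118 transcripts over 107 genes collapse to 107 records
  de3 <- de[rep(1, 118), ]
  de3$gene_id <- paste0("tr", 1:118)
  de3$p_value <- seq(0.001, 0.118, by = 0.001)
  class(de3) <- class(de)
  map3 <- stats::setNames(paste0("gene", c(1:107, 1:11)), de3$gene_id)
  col3 <- collapse_transcripts(de3, map3)
  expect_equal(nrow(col3), 107L)
  expect_equal(sum(col3$n_transcripts), 118L)
})

test_that("scenario comparison favours the paternal truth on simulated data", {
  # the paternal scenario matches the grouping the counts were generated
  # under, so it must yield the most sex-biased genes; mixed (maternal,
  # random) groupings retain only leakage through chance imbalance
  cfg <- sim_config(n_families = 1, offspring_per_family = 45,
                    crossover_rate = 0, dam_het_prob = 0.3,
                    n_genes = 600, n_lgs = 6, sd_lg = 4,
                    genes_per_lg = rep(100L, 6), n_de_genes = 40,
                    n_sex_specific = 5, frac_de_on_sdlg = 0.6)
  fam <- simulate_family(cfg, seed = 205, label_sex = FALSE)
  ph <- phase_family(fam$genotypes, fam$map, "F1")
  asg <- suppressMessages(
    assign_sex_groups(ph, "paternal", sdr_interval = cfg$sdr_interval))
  ortho <- simulate_orthology(cfg, seed = 205)
  sim <- simulate_counts(asg[!is.na(asg$group), ], ortho, cfg, seed = 305)
  tab <- suppressMessages(
    compare_scenarios(sim$counts, ph, ortho, sd_lg = "LG4",
                      seed = 405, sdr_interval = cfg$sdr_interval))
  expect_equal(tab$scenario, c("paternal", "maternal", "random"))
  pat <- tab[tab$scenario == "paternal", ]
  expect_true(pat$total > max(tab$total[-1]))
  expect_gt(pat$percent, attr(tab, "expected_null_share"))
  expect_equal(attr(tab, "ratio"), round(pat$total / tab$total[2], 1))
  expect_equal(attr(tab, "expected_null_share"), round(100 / 6, 1))
})
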