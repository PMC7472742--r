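test_that("consensus marks sex-informative markers, ties and single-sex families", {
  fx <- fig2_family()
  cons <- build_consensus(fx$genotypes, map = fx$map)
  a1 <- cons$families$A1
  expect_true(all(a1$informative))
  expect_equal(unique(a1$male_call), "1/2")
  expect_equal(unique(a1$female_call), "1/1")
  # identical calls across sexes -> uninformative
  gt <- fx$genotypes
  gt$a2[gt$individuals$family == "A1", 7] <- 1L
  c2 <- build_consensus(gt, map = fx$map)
  expect_false(c2$families$A1$informative[7])
  # a 2-2 tie among males -> uninformative
  gt2 <- fx$genotypes
  gt2$a2[c("A1_m1", "A1_m2"), 8] <- 1L
  c3 <- build_consensus(gt2, map = fx$map)
  expect_false(c3$families$A1$informative[8])
  # single-sex family
  only_m <- fx$genotypes[fx$genotypes$individuals$sex == "male", ]
  expect_error(build_consensus(only_m, map = fx$map),
               class = "sdrmap_consensus_undefined")
})

test_that("the two-family fixture yields exactly two events on opposite ends", {
  fx <- fig2_family()
  cons <- build_consensus(fx$genotypes, map = fx$map)
  ev <- detect_recombinants(fx$genotypes, cons, min_run = 3)
  expect_equal(nrow(ev), 2L)
  left <- ev[ev$id == "A1_m4", ]
  right <- ev[ev$id == "B_f4", ]
  expect_equal(left$run_first_marker, "K01")
  expect_equal(left$run_last_marker, "K04")
  expect_equal(left$run_length, 3L)  # the ND call inside the run is skipped
  expect_true(is.na(left$flank_left_marker))
  expect_equal(left$flank_right_marker, "K05")
  expect_equal(right$run_first_marker, "K13")
  expect_equal(right$run_length, 3L)
  expect_equal(right$flank_left_marker, "K12")
  iv <- refine_interval(ev, fx$map)
  span <- range(fx$map$position_mbp)
  expect_gt(iv$start_mbp, span[1])
  expect_lt(iv$end_mbp, span[2])
  expect_true(all(iv$bounded))
})

test_that("fully concordant families produce no events and no refinement", {
  fx <- fig2_family()
  gt <- fx$genotypes
  gt$a2["A1_m4", 1:4] <- 2L; gt$a1["A1_m4", 2] <- 1L; gt$a2["A1_m4", 2] <- 2L
  gt$a2["B_f4", 13:15] <- 1L
  cons <- build_consensus(gt, map = fx$map)
  ev <- detect_recombinants(gt, cons, min_run = 3)
  expect_equal(nrow(ev), 0L)
  iv <- refine_interval(ev, fx$map)
  expect_equal(c(iv$start_mbp, iv$end_mbp), range(fx$map$position_mbp))
})

test_that("detection agrees with the brute-force window scan on random families", {
  set.seed(404)
  for (rep in 1:25) {
    n_off <- sample(4:12, 1)
    m <- sample(6:15, 1)
    cfg <- sim_config(n_families = 1, offspring_per_family = n_off,
                      n_markers_sdr = m,
                      marker_positions = seq(0.2, 3.4, length.out = m),
                      crossover_rate = 0.4,
                      dam_het_prob = sample(c(0, 0.3), 1))
    fam <- simulate_family(cfg, seed = 1e6 + rep)
    # sprinkle missing calls
    gt <- fam$genotypes
    nd <- which(matrix(stats::runif(length(gt$a1)) < 0.05, nrow(gt$a1)))
    gt$a1[nd] <- NA_integer_; gt$a2[nd] <- NA_integer_
    min_run <- sample(1:3, 1)
    cons <- build_consensus(gt, map = fam$map)
    ev <- detect_recombinants(gt, cons, min_run = min_run)
    bf <- brute_force_events(gt, cons, min_run)
    key <- function(d, f, l) sort(paste(d, f, l))
    expect_identical(key(ev$id, ev$run_first_marker, ev$run_last_marker),
                     key(bf$id, bf$first, bf$last))
  }
})

test_that("planted crossovers are detected with breakpoints containing the truth", {
  cfg <- sim_config(n_families = 1, offspring_per_family = 12,
                    crossover_rate = 0, dam_het_prob = 0)
  for (iv_idx in c(2L, 6L, 10L)) {
    pc <- data.frame(family = 1, offspring = 5, parent = "paternal",
                     interval = iv_idx)
    fam <- simulate_family(cfg, seed = 300 + iv_idx,
                           planted_crossovers = pc)
    cons <- build_consensus(fam$genotypes, map = fam$map)
    ev <- detect_recombinants(fam$genotypes, cons, min_run = 1)
    ev5 <- ev[ev$id == "F1_o05", ]
    expect_equal(nrow(ev5), 1L)
    xo <- fam$truth$crossovers$position_mbp[1]
    gap <- sort(c(ev5$bp_left_lo, ev5$bp_left_hi,
                  ev5$bp_right_lo, ev5$bp_right_hi))
    expect_true(min(gap, na.rm = TRUE) <= xo && xo <= max(gap, na.rm = TRUE))
    iv <- refine_interval(ev, fam$map)
    expect_true(iv$start_mbp <= fam$truth$causal_position_mbp &&
                  fam$truth$causal_position_mbp <= iv$end_mbp)
  }
})

test_that("adding an event never widens the refined interval", {
  fx <- fig2_family()
  cons <- build_consensus(fx$genotypes, map = fx$map)
  ev <- detect_recombinants(fx$genotypes, cons, min_run = 3)
  for (i in 1:2) {
    one <- ev[i, , drop = FALSE]
    attr(one, "span") <- attr(ev, "span")
    class(one) <- class(ev)
    iv1 <- refine_interval(one, fx$map)
    iv2 <- refine_interval(ev, fx$map)
    expect_lte(iv2$width_mbp, iv1$width_mbp)
    expect_gte(iv2$start_mbp, iv1$start_mbp)
    expect_lte(iv2$end_mbp, iv1$end_mbp)
  }
})

test_that("a single one-sided event leaves the far side at the outermost marker", {
  fx <- fig2_family()
  gt <- fx$genotypes[fx$genotypes$individuals$family == "A1", ]
  cons <- build_consensus(gt, map = fx$map)
  ev <- detect_recombinants(gt, cons, min_run = 3)
  expect_equal(nrow(ev), 1L)
  iv <- refine_interval(ev, fx$map)
  expect_equal(iv$end_mbp, max(fx$map$position_mbp))
  expect_gt(iv$start_mbp, min(fx$map$position_mbp))
  expect_true(iv$bounded["left"] && !iv$bounded["right"])
})

test_that("contradictory events signal inconsistency and gene counts are reported", {
  fx <- fig2_family()
  gt <- fx$genotypes
  # extend A1_m4's discordant run through K12 (its allowed region then
  # starts at K12) while B_f4's run starts at K10 (allowed region ends at
  # K10): no position satisfies both
  gt$a1["A1_m4", 1:12] <- 1L
  gt$a2["A1_m4", 1:12] <- 1L
  gt$a2["B_f4", 10:15] <- 2L
  cons <- build_consensus(gt, map = fx$map)
  ev <- detect_recombinants(gt, cons, min_run = 3)
  expect_error(refine_interval(ev, fx$map),
               class = "sdrmap_inconsistent_events")
  # gene counting inside the interval
  cons0 <- build_consensus(fx$genotypes, map = fx$map)
  ev0 <- detect_recombinants(fx$genotypes, cons0, min_run = 3)
  ortho <- orthology_map(paste0("g", 1:6), rep("LG8", 6),
                         c(0.1, 0.7, 1.0, 1.9, 2.5, 2.95))
  iv <- refine_interval(ev0, fx$map, ortho)
  expect_equal(iv$n_genes,
               sum(ortho$position_mbp >= iv$start_mbp &
                     ortho$position_mbp <= iv$end_mbp))
})
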