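test_that("simulation is deterministic under a fixed seed", {
  des <- sim_design(n_progeny = 30, n_biparental = 10, n_female = 10,
                    n_male = 10, multilocus_fraction = 0.3)
  a <- simulate_study(des, seed = 7, n_pairs = 2, group_length_cm = 60,
                      markers_per_group = 25)
  b <- simulate_study(des, seed = 7, n_pairs = 2, group_length_cm = 60,
                      markers_per_group = 25)
  expect_identical(a$table$calls, b$table$calls)
  expect_identical(a$truth$channels, b$truth$channels)
  c2 <- simulate_study(des, seed = 8, n_pairs = 2, group_length_cm = 60,
                       markers_per_group = 25)
  expect_false(identical(a$table$calls, c2$table$calls))
})

test_that("gamete walks respect map distance", {
  set.seed(2)
  g <- sim_genome(n_pairs = 1, positions = list(c(0, 0, 10), c(0, 1000)))
  des <- sim_design(n_progeny = 10, 0, 2, 2, multilocus_fraction = 0,
                    missing_rate = 0, error_rate = 0)
  ## zero distance: identical alleles in every gamete
  gam <- simulate_gametes(g, des, "P1", n = 500)
  expect_identical(gam$LG1a[1, ], gam$LG1a[2, ])

  ## independent groups at n = 1e5: correlation within 3/sqrt(n) of zero
  gam2 <- simulate_gametes(g, des, "P1", n = 1e5)
  expect_lt(abs(cor(gam2$LG1a[1, ], gam2$LG1b[1, ])), 3 / sqrt(1e5))
  ## 1000 cM within a group behaves like free recombination too
  expect_lt(abs(cor(gam2$LG1b[1, ], gam2$LG1b[2, ])), 3 / sqrt(1e5))

  ## adjacent-interval recombination converges to kosambi_inverse(d)
  set.seed(3)
  g3 <- sim_genome(n_pairs = 1, positions = list(c(0, 10), c(0, 10)))
  gam3 <- simulate_gametes(g3, des, "P1", n = 1e5)
  rec <- mean(gam3$LG1a[1, ] != gam3$LG1a[2, ])
  r_exp <- kosambi_inverse(10)
  expect_lt(abs(rec - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / 1e5))
})

test_that("planted disequilibrium reaches the requested strength", {
  g <- sim_genome(n_pairs = 1, positions = list(c(0, 30), c(0, 30)))
  base <- list(parent = "P1", group_a = "LG1a", pos_a = 0,
               group_b = "LG1b", pos_b = 0)
  ## complete coupling: anchor-pair r2 = 1 in every replicate
  for (s in 1:5) {
    set.seed(s)
    des <- sim_design(n_progeny = 188, 0, 2, 2, multilocus_fraction = 0,
                      missing_rate = 0, error_rate = 0,
                      planted_ld = list(c(base, dprime = 1)))
    gam <- simulate_gametes(g, des, "P1")
    expect_equal(r_squared(gam$LG1a[1, ], gam$LG1b[1, ])$r2, 1)
  }
  ## monotone power: mean anchor r2 grows with |D'|
  mean_r2 <- vapply(c(0, 0.5, 0.9), function(dp) {
    vals <- vapply(1:30, function(s) {
      set.seed(1000 + s)
      des <- sim_design(n_progeny = 188, 0, 2, 2, multilocus_fraction = 0,
                        missing_rate = 0, error_rate = 0,
                        planted_ld = if (dp > 0)
                          list(c(base, dprime = dp)) else NULL)
      gam <- simulate_gametes(g, des, "P1")
      r_squared(gam$LG1a[1, ], gam$LG1b[1, ])$r2
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(mean_r2) > 0))
  ## an anchor must sit on a marker
  des_bad <- sim_design(planted_ld = list(c(base, dprime = 0.5)))
  des_bad$planted_ld[[1]]$pos_a <- 13.7
  expect_error(simulate_gametes(g, des_bad, "P1", n = 10),
               "not a marker position")
})

test_that("rendering honours class masking, marker merging and distortion", {
  ## balanced split without selection
  sim <- sim_small(51, positions = list(seq(0, 45, by = 5)),
                   n_female = 10, n_male = 2, n_progeny = 188)
  counts <- rowSums(sim$table$calls == 1L, na.rm = TRUE)
  expect_true(all(abs(counts - 94) < 4 * sqrt(188 * 0.25)))

  ## multilocus fraction 0: one locus per marker
  expect_equal(anyDuplicated(sim$truth$loci$marker_id), 0)

  ## multilocus > 0 creates shared marker ids with a/b suffixes
  set.seed(52)
  g <- sim_genome(n_pairs = 2, positions = list(seq(0, 45, by = 5)))
  des <- sim_design(n_progeny = 50, n_biparental = 8, n_female = 10,
                    n_male = 10, multilocus_fraction = 1,
                    missing_rate = 0, error_rate = 0)
  out <- render_genotype_table(simulate_gametes(g, des, "P1"),
                               simulate_gametes(g, des, "P2"), g, des)
  multi <- out$truth$loci[out$truth$loci$band_count > 1, ]
  expect_gt(nrow(multi), 0)
  expect_true(all(grepl("[ab]$", multi$locus_id)))
  ## merged loci sit on homeologous partner groups
  for (m in unique(multi$marker_id)) {
    gs <- multi$group[multi$marker_id == m]
    expect_equal(sub("[ab]$", "", gs[1]), sub("[ab]$", "", gs[2]))
    expect_false(gs[1] == gs[2])
  }

  ## viability selection shifts the allele ratio at the selected locus
  set.seed(53)
  g1 <- sim_genome(n_pairs = 1, positions = list(c(0, 20)))
  des_s <- sim_design(n_progeny = 188, 0, 2, 2, multilocus_fraction = 0,
                      missing_rate = 0, error_rate = 0,
                      distortion = data.frame(parent = "P1",
                                              group = "LG1a", pos_cm = 0,
                                              s = 0.6))
  out_s <- render_genotype_table(simulate_gametes(g1, des_s, "P1"),
                                 simulate_gametes(g1, des_s, "P2"),
                                 g1, des_s)
  al <- out_s$truth$gametes$P1$LG1a[1, ]
  expect_gt(mean(al), 0.58)      # expected 1 / (1 + (1 - s)) ~ 0.71
})

test_that("a fully randomized channel decouples from its neighbours", {
  sim <- sim_small(55, positions = list(seq(0, 45, by = 5)),
                   n_female = 10, n_male = 2)
  ids <- true_order(sim)
  ph <- sim$phased$P1
  i <- match(ids[3], rownames(ph$calls))
  set.seed(1)
  ph$calls[i, ] <- rbinom(188, 1, 0.5)      # error rate 1/2 = pure noise
  ps <- pair_stats(ph$calls)
  j <- match(ids[4], rownames(ph$calls))
  expect_lt(abs(ps$r_hat[i, j] - 0.5), 0.12)
})

test_that("planted transcript SSRs are mined back at the planted density", {
  set.seed(61)
  tx <- simulate_transcripts(n = 400, length_range = c(400, 1200),
                             density_per_bp = 1 / 4700,
                             mismatch_probs = c(1, 0, 0))
  hits <- mine_ssrs(tx$sequences, min_len = 15, max_mismatch = 0)
  total <- sum(nchar(tx$sequences))
  expect_gt(nrow(tx$truth), 30)
  expect_lt(abs(nrow(hits) / total - nrow(tx$truth) / total) /
              (nrow(tx$truth) / total), 0.10)
  ## planted tracts recovered at exact coordinates with the right motif
  key <- paste(tx$truth$seq_id, tx$truth$start, tx$truth$end)
  got <- paste(hits$seq_id, hits$start, hits$end)
  expect_gte(mean(key %in% got), 0.95)

  ## a planted sub-minimum tract is not reported
  s <- paste0(strrep("C", 30), strrep("AG", 7), strrep("C", 30))
  expect_equal(nrow(find_ssrs(s, min_len = 15)), 0)
  ## FASTA round trip
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(tx$sequences[1:3], f)
  back <- as.character(Biostrings::readDNAStringSet(f))
  expect_equal(unname(back), unname(tx$sequences[1:3]))
})

test_that("simulated reference genomes are colinear except planted changes", {
  mk <- data.frame(marker_id = sprintf("M%02d", 1:20),
                   group = rep(c("LG1a", "LG2b"), each = 10),
                   pos_cm = rep(seq(0, 45, by = 5), 2))
  ref <- simulate_reference(mk, bp_per_cm = 40000)
  expect_equal(nrow(ref$hits), 20)
  expect_equal(unique(ref$hits$chromosome[1:10]), "chr1")
  expect_equal(unique(ref$hits$chromosome[11:20]), "chr2")
  ## colinear: bp strictly increasing with cM
  expect_true(all(diff(ref$hits$start_bp[1:10]) > 0))

  ## translocation moves exactly the listed segment
  rr <- data.frame(type = "translocation", group = "LG1a", start_cm = 20,
                   end_cm = 30, dest_chrom = "chr5", dest_offset_bp = 9e6)
  ref2 <- simulate_reference(mk, rearrangements = rr)
  moved <- ref2$hits$chromosome[ref2$hits$query_id %in%
                                  mk$marker_id[mk$group == "LG1a" &
                                                 mk$pos_cm >= 20 &
                                                 mk$pos_cm <= 30]]
  expect_true(all(moved == "chr5"))

  ## decoys never outrank the true hit
  set.seed(9)
  ref3 <- simulate_reference(mk, decoy_rate = 0.5)
  bh <- best_hits(ref3$hits)
  expect_equal(bh$chromosome, ref$hits$chromosome)
})
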