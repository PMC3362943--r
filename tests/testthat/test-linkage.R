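test_that("Kosambi function matches closed forms and round-trips", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.25), 25 * log(3), tolerance = 1e-12)
  r <- seq(0.01, 0.49, by = 0.01)
  expect_lt(max(abs(kosambi_inverse(kosambi(r)) - r)), 1e-12)
  expect_equal(kosambi_inverse(0), 0)
})

test_that("two-point statistics follow the haploid testcross formulas", {
  n <- 188
  a <- rep(c(1L, 0L), length.out = n)
  ## identical vectors: R = 0, lod = n*log10(2)
  ps <- pair_stats(rbind(x = a, y = a))
  expect_equal(ps$R["x", "y"], 0)
  expect_equal(ps$lod["x", "y"], n * log10(2), tolerance = 1e-12)
  expect_equal(round(ps$lod["x", "y"], 2), 56.59)
  ## fully flipped: phase alignment gives r_hat = 0
  ps2 <- pair_stats(rbind(x = a, y = 1L - a))
  expect_equal(ps2$r_hat["x", "y"], 0)
  expect_true(ps2$flipped["x", "y"])
  ## half recombinant: r_hat = 0.5, lod = 0
  b <- c(a[1:94], 1L - a[95:188])
  ps3 <- pair_stats(rbind(x = a, y = b))
  expect_equal(ps3$r_hat["x", "y"], 0.5)
  expect_equal(ps3$lod["x", "y"], 0, tolerance = 1e-12)
  ## pairs with too few joint calls are skipped
  y4 <- a; y4[11:188] <- NA
  ps4 <- pair_stats(rbind(x = a, y = y4), n_min = 20)
  expect_true(is.na(ps4$lod["x", "y"]))
})

test_that("r_hat is nearly unbiased with RMSE near the binomial bound", {
  set.seed(31)
  n <- 188
  for (r_true in c(0.05, 0.2, 0.4)) {
    R <- rbinom(1000, n, r_true)
    r_hat <- pmin(R, n - R) / n          # phase-minimized estimate
    expect_lt(abs(mean(r_hat) - r_true), 0.01)
    rmse <- sqrt(mean((r_hat - r_true)^2))
    expect_lt(rmse, 1.2 * sqrt(r_true * (1 - r_true) / n))
  }
})

test_that("LOD-threshold grouping separates chromosomes cleanly", {
  sim <- sim_small(41, n_pairs = 1, positions = list(seq(0, 45, by = 5)),
                   n_female = 16, n_male = 2)
  ps <- pair_stats(sim$phased$P1$calls)
  grp <- group_loci(ps, lod_min = 10, rec_max = 0.4)
  expect_equal(length(grp$groups), 2)    # the two true groups
  tg <- true_group_of(names(grp$membership), sim$truth$channels, "P1")
  expect_equal(rand_index(grp$membership, tg), 1)
  ## infinite threshold: everyone alone
  grp_inf <- group_loci(ps, lod_min = Inf)
  expect_equal(lengths(grp_inf$groups), rep(1L, nrow(sim$phased$P1$loci)),
               ignore_attr = TRUE)
})

test_that("a wide marker desert may split a chromosome into contiguous parts", {
  sim <- sim_small(43, n_pairs = 1,
                   positions = list(c(0, 5, 10, 15, 70, 75, 80, 85),
                                    c(0, 50)),
                   n_female = 8, n_male = 2)
  tr <- sim$truth$channels
  tr <- tr[tr$parent == "P1" & tr$group == "LG1a", ]
  ids <- tr$locus_id[order(tr$pos_cm)]
  ps <- pair_stats(sim$phased$P1$calls)
  grp <- group_loci(ps, lod_min = 10, ids = ids)
  ## each component is contiguous in true position
  for (g in grp$groups) {
    ranks <- sort(match(g, ids))
    expect_equal(ranks, seq(min(ranks), max(ranks)))
  }
})

test_that("ordering recovers the true order and its length on clean data", {
  ok <- 0
  for (s in 1:20) {
    sim <- sim_small(s, positions = list(seq(0, 45, by = 5)),
                     n_female = 10, n_male = 2)
    ids <- true_order(sim)
    lg <- order_group(ids, pair_stats(sim$phased$P1$calls))
    ok <- ok + (identical(lg$locus_ids, ids) ||
                  identical(lg$locus_ids, rev(ids)))
  }
  expect_gte(ok / 20, 0.95)

  ## two loci at r_hat = 0.1: map length = kosambi(0.1)
  set.seed(5)
  n <- 188
  x <- rbinom(n, 1, 0.5)
  y <- x; flip <- sample(n, round(0.1 * n)); y[flip] <- 1L - y[flip]
  ps <- pair_stats(rbind(A = x, B = y))
  lg2 <- order_group(c("A", "B"), ps)
  expect_equal(max(lg2$pos_cm), kosambi(ps$r_hat["A", "B"]),
               tolerance = 1e-9)
  expect_equal(round(kosambi(0.1), 2), 10.14)

  ## single locus: zero-length map
  lg1 <- order_group("A", ps)
  expect_equal(lg1$pos_cm, 0)
})

test_that("estimated group length is close to the simulated truth", {
  lens <- vapply(1:20, function(s) {
    sim <- sim_small(s, positions = list(seq(0, 100, length.out = 20)),
                     n_female = 38, n_male = 2)
    ids <- true_order(sim)
    lg <- order_group(ids, pair_stats(sim$phased$P1$calls))
    max(lg$pos_cm)
  }, 0)
  expect_lt(abs(median(lens) - 100), 15)
})

test_that("greedy ordering reaches the exhaustive-permutation optimum", {
  for (s in c(2, 3, 4)) {
    sim <- sim_small(s, positions = list(seq(0, 42, by = 7)),
                     n_female = 12, n_male = 2)
    ids <- true_order(sim)
    if (length(ids) < 4) next
    ps <- pair_stats(sim$phased$P1$calls)
    lg <- order_group(ids, ps)
    placed <- lg$locus_ids
    idx <- match(placed, ps$ids)
    W <- ps$lod[idx, idx]; Rm <- ps$r_hat[idx, idx]
    use <- !is.na(W) & W >= 1 & !is.na(Rm) & Rm <= 0.4
    D <- matrix(NA_real_, length(idx), length(idx)); D[use] <- kosambi(Rm[use])
    Wm <- matrix(0, length(idx), length(idx)); Wm[use] <- W[use]
    perms <- combinat_perms(length(placed))
    best <- min(apply(perms, 1, function(p) {
      clovermap:::order_misfit_wls(p, D, Wm)
    }))
    got <- clovermap:::order_misfit_wls(seq_along(placed), D, Wm)
    expect_lte(got, best * 1.01 + 1e-9)
  }
})

test_that("a fully randomized locus is set aside by the jump rule", {
  sim <- sim_small(99, positions = list(seq(0, 45, by = 5)),
                   n_female = 10, n_male = 2)
  ids <- true_order(sim)
  ph <- sim$phased$P1
  set.seed(1)
  bad <- ids[2]
  ph$calls[match(bad, rownames(ph$calls)), ] <- rbinom(188, 1, 0.5)
  lg <- order_group(ids, pair_stats(ph$calls))
  expect_true(bad %in% lg$excluded)
  expect_false(bad %in% lg$locus_ids)
})

test_that("reference evidence disassembles an over-merged group", {
  set.seed(3)
  pos <- seq(0, 60, by = 2.5)
  pl <- list(list(parent = "P2", group_a = "LG1a", pos_a = 30,
                  group_b = "LG2a", pos_b = 30, dprime = 0.95),
             list(parent = "P2", group_a = "LG2a", pos_a = 30,
                  group_b = "LG3a", pos_b = 30, dprime = 0.95))
  des <- sim_design(n_progeny = 188, n_biparental = 40, n_female = 40,
                    n_male = 80, multilocus_fraction = 0.4,
                    missing_rate = 0.03, error_rate = 0.005,
                    planted_ld = pl)
  sim <- simulate_study(des, seed = 3, n_pairs = 4, positions = list(pos))
  ph <- split_parental(sim$table)
  res1 <- map_parent(ph$P1)
  ps2 <- pair_stats(ph$P2$calls)
  grp2 <- group_loci(ps2, 10, 0.4)
  ## the planted LD really over-merges three chromosomes
  big <- grp2$groups[[1]]
  tg <- true_group_of(big, sim$truth$channels, "P2")
  expect_gte(length(unique(na.omit(tg))), 3)

  mk <- unique(sim$truth$channels[sim$truth$channels$parent == "P2",
                                  c("locus_id", "group", "pos_cm")])
  mk <- merge(mk, sim$truth$loci[c("locus_id", "marker_id")])
  ref <- simulate_reference(data.frame(marker_id = mk$marker_id,
                                       group = mk$group,
                                       pos_cm = mk$pos_cm))
  d <- disassemble(big, ph$P2$loci, partner_map = res1$map,
                   hits = data.frame(marker_id = ref$hits$query_id,
                                     chromosome = ref$hits$chromosome),
                   ps = ps2)
  expect_gte(length(d$subgroups), 3)
  purity <- vapply(d$subgroups, function(g) {
    t <- table(true_group_of(g, sim$truth$channels, "P2"))
    max(t) / sum(t)
  }, 0)
  expect_true(all(purity >= 0.95))

  ## idempotence: one true chromosome stays one subgroup
  one <- grp2$groups[[which.max(vapply(grp2$groups, function(g) {
    tg <- true_group_of(g, sim$truth$channels, "P2")
    mean(tg == "LG4a", na.rm = TRUE)
  }, 0))]]
  d1 <- disassemble(one, ph$P2$loci, partner_map = res1$map,
                    hits = data.frame(marker_id = ref$hits$query_id,
                                      chromosome = ref$hits$chromosome),
                    ps = ps2)
  expect_equal(length(d1$subgroups), 1)

  ## no evidence at all is an error
  expect_error(disassemble(big, ph$P2$loci, partner_map = NULL,
                           hits = NULL, ps = ps2),
               "cannot disassemble")
})
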