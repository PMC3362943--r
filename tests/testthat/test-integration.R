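mk_map <- function(group, ids, pos, seg = "biparental", base = ids) {
  structure(data.frame(group = group, locus_id = ids, base_id = base,
                       marker_id = ids, position_cm = pos, seg_class = seg,
                       band_count = 1L, distorted = FALSE,
                       stringsAsFactors = FALSE),
            class = c("genetic_map", "data.frame"))
}

test_that("integrating identical parental maps is the identity", {
  m <- mk_map("G1", paste0("L", 1:6), seq(0, 50, by = 10))
  m2 <- m
  m2$locus_id <- paste0(m$locus_id, ".2")     # P2 channel naming
  im <- integrate_maps(m, m2)
  expect_true(all(im$meta$integrated))
  expect_equal(nrow(im$map), 6)               # anchors merged, not doubled
  expect_equal(im$map$position_cm, m$position_cm)
  expect_equal(im$map$base_id, m$base_id)
})

test_that("too few anchors triggers the documented fallback arithmetic", {
  ## 24- and 22-locus groups, 2 shared anchors, lengths 97.6 / 120.5
  p1 <- mk_map("A", c(sprintf("x%02d", 1:22), "S1", "S2"),
               c(seq(0, 97.6, length.out = 23), 97.6 / 2),
               seg = c(rep("female", 22), rep("biparental", 2)),
               base = c(sprintf("x%02d", 1:22), "S1", "S2"))
  p2 <- mk_map("B", c(sprintf("y%02d", 1:20), "S1.2", "S2.2"),
               c(seq(0, 120.5, length.out = 21), 60),
               seg = c(rep("male", 20), rep("biparental", 2)),
               base = c(sprintf("y%02d", 1:20), "S1", "S2"))
  im <- integrate_maps(p1, p2, min_anchors = 3)
  expect_false(im$meta$integrated)
  expect_true(im$meta$fallback)
  expect_equal(im$meta$n_loci, 24 + 22 - 2)             # 44
  expect_equal(im$meta$length_cm, (97.6 + 120.5) / 2)   # 109.05
  expect_true(all(is.na(im$map$position_cm)))
  st <- map_stats(im)
  expect_equal(st$per_group$n_loci, 44)
  expect_equal(st$per_group$length_cm, 109.05)
})

test_that("integration of simulated parents tracks the true positions", {
  set.seed(71)
  sim <- simulate_study(
    sim_design(n_progeny = 188, n_biparental = 14, n_female = 12,
               n_male = 12, multilocus_fraction = 0, type2_fraction = 0,
               missing_rate = 0.02, error_rate = 0.002),
    seed = 71, n_pairs = 1, positions = list(seq(0, 95, by = 5)))
  ph <- split_parental(sim$table)
  r1 <- map_parent(ph$P1)
  r2 <- map_parent(ph$P2)
  im <- integrate_maps(r1$map, r2$map)
  expect_true(any(im$meta$integrated))
  tr <- sim$truth$channels
  for (g in im$meta$group[im$meta$integrated]) {
    sub <- im$map[im$map$group == g, ]
    tp <- tr$pos_cm[match(sub$base_id, tr$locus_id)]
    rho <- abs(cor(sub$position_cm, tp, method = "spearman"))
    expect_gte(rho, 0.99)
    ## conservation: n = n1 + n2 - shared
    n1 <- sum(r1$map$group == im$correspondence$group1[
      im$correspondence$group1 == g])
    g2 <- im$meta$group2[im$meta$group == g]
    n2 <- sum(r2$map$group == g2)
    shared <- length(intersect(
      r1$map$base_id[r1$map$group == g & r1$map$seg_class == "biparental"],
      r2$map$base_id[r2$map$group == g2 &
                       r2$map$seg_class == "biparental"]))
    expect_equal(nrow(sub), n1 + n2 - shared)
  }
})

test_that("map statistics follow the length / count arithmetic", {
  m <- mk_map("G1", paste0("L", 1:5), c(0, 3, 10, 29.1, 40),
              seg = "female")
  m$distorted <- c(TRUE, FALSE, FALSE, TRUE, FALSE)
  st <- map_stats(m)
  expect_equal(st$per_group$n_loci, 5)
  expect_equal(st$per_group$length_cm, 40)
  expect_equal(st$per_group$density, 8)
  expect_equal(st$per_group$distortion_pct, 40)
  expect_equal(st$largest_gap$cm, 19.1)
  expect_equal(st$largest_gap$pair, "L3~L4")
  ## single-locus group: zero length, no gap
  st1 <- map_stats(mk_map("G2", "L9", 0, seg = "female"))
  expect_equal(st1$per_group$length_cm, 0)
  expect_true(is.na(st1$per_group$largest_gap_cm))
})

test_that("multi-locus markers are classified into the published types", {
  map <- mk_map("LG3a", c("Ma", "Mb", "N", "P1x", "Q1", "Q2"),
                c(0, 5, 10, 15, 20, 25))
  map$marker_id <- c("M", "M", "N", "P", "Q", "Q")
  map$group <- c("LG3a", "LG3b", "LG3a", "LG3a", "LG4a", "LG4a")
  map$band_count <- c(2L, 2L, 1L, 1L, 2L, 2L)
  map$seg_class <- c("female", "female", "biparental", "biparental",
                     "male", "male")
  pairing <- data.frame(group_a = c("LG3a", "LG4a"),
                        group_b = c("LG3b", "LG4b"))
  cls <- classify_multilocus(map, pairing = pairing)
  expect_equal(cls$location[cls$marker_id == "M"], "homeologous")
  expect_equal(cls$location[cls$marker_id == "Q"], "same")
  expect_true(cls$type1[cls$marker_id == "M"])
  expect_false(cls$type1[cls$marker_id == "N"])

  ## Type II: bi-parental marker on non-corresponding parental groups
  m1 <- mk_map("A", c("B1", "B2"), c(0, 10))
  m2 <- mk_map("B", c("B1.2", "B3"), c(0, 10), base = c("B1", "B3"))
  corr <- data.frame(group1 = "A", group2 = "C")  # A corresponds to C, not B
  comb <- rbind(m1, m2)
  cls2 <- classify_multilocus(comb, map1 = m1, map2 = m2,
                              correspondence = corr)
  expect_true(cls2$type2[cls2$marker_id == "B1"])
  ## and on corresponding groups it is not Type II
  corr_ok <- data.frame(group1 = "A", group2 = "B")
  cls3 <- classify_multilocus(comb, map1 = m1, map2 = m2,
                              correspondence = corr_ok)
  expect_false(cls3$type2[cls3$marker_id == "B1"])
})

test_that("homeolog pairing is recovered from shared marker names", {
  ## clear-cut counts: pair the 5-marker couple, not the 1-marker one
  map <- data.frame(
    marker_id = c(rep(sprintf("m%d", 1:5), each = 2), "z"),
    group = c(rep(c("LG1a", "LG1b"), 5), "LG2a"))
  hp <- infer_homeologs(map)
  expect_equal(hp$group_a, "LG1a")
  expect_equal(hp$group_b, "LG1b")
  expect_equal(hp$shared_markers, 5)
  ## no multi-locus markers: empty with warning
  expect_warning(hp0 <- infer_homeologs(data.frame(marker_id = "a",
                                                   group = "LG1a")),
                 "no multi-locus markers")
  expect_equal(nrow(hp0), 0)

  ## simulated duplication: inferred matching equals the genome truth
  set.seed(72)
  g <- sim_genome(n_pairs = 2, positions = list(seq(0, 45, by = 5)))
  des <- sim_design(n_progeny = 40, n_biparental = 12, n_female = 12,
                    n_male = 12, multilocus_fraction = 0.5,
                    missing_rate = 0, error_rate = 0)
  out <- render_genotype_table(simulate_gametes(g, des, "P1"),
                               simulate_gametes(g, des, "P2"), g, des)
  hp2 <- infer_homeologs(out$truth$loci)
  key <- paste(pmin(hp2$group_a, hp2$group_b),
               pmax(hp2$group_a, hp2$group_b))
  expect_true(all(key %in% c("LG1a LG1b", "LG2a LG2b")))
})
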