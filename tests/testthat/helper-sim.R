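# shared helpers for building small simulated data sets in tests

# Rand index between two partitions given as label vectors
rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  s <- sum(choose(tab, 2))
  r <- sum(choose(rowSums(tab), 2))
  c2 <- sum(choose(colSums(tab), 2))
  1 + (2 * s - r - c2) / choose(n, 2)
}

# true group of phased locus ids (P2 copies of bi-parental loci carry ".2")
true_group_of <- function(ids, truth_channels, parent) {
  tr <- truth_channels[truth_channels$parent == parent, ]
  tr$group[match(sub("\\.2$", "", ids), tr$locus_id)]
}

# small single-parent simulation: returns phased sets + truth
sim_small <- function(seed, n_pairs = 1, positions = list(seq(0, 45, by = 5)),
                      n_progeny = 188, n_biparental = 0, n_female = 10,
                      n_male = 2, ...) {
  set.seed(seed)
  g <- sim_genome(n_pairs = n_pairs, positions = positions)
  des <- sim_design(n_progeny = n_progeny, n_biparental = n_biparental,
                    n_female = n_female, n_male = n_male,
                    multilocus_fraction = 0, missing_rate = 0,
                    error_rate = 0, ...)
  gam1 <- simulate_gametes(g, des, "P1")
  gam2 <- simulate_gametes(g, des, "P2")
  out <- render_genotype_table(gam1, gam2, g, des)
  out$genome <- g
  out$phased <- split_parental(out$table)
  out
}

# loci of one true group of one parent, in true order
true_order <- function(sim, parent = "P1", group = "LG1a") {
  tr <- sim$truth$channels
  tr <- tr[tr$parent == parent & tr$group == group, ]
  tr$locus_id[order(tr$pos_cm)]
}

# a tiny genotype-table TSV fixture on disk; returns path
write_toy_genotype <- function(path, missing = "-") {
  lines <- c(
    paste(c("locus_id", "marker_id", "seg_class", "parent", "band_count",
            "p1", "p2", "p3", "p4"), collapse = "\t"),
    paste(c("L1", "M1", "female", "P1", "1", "a", "b", "a", missing),
          collapse = "\t"),
    paste(c("L2", "M2", "male", "P2", "1", "b", "b", "a", "a"),
          collapse = "\t"),
    paste(c("L3", "M3", "biparental", "P1", "1", "a", "a", "b", "b"),
          collapse = "\t"),
    paste(c("L3", "M3", "biparental", "P2", "1", "b", "a", "b", "a"),
          collapse = "\t"))
  writeLines(lines, path)
  path
}

# brute-force SSR oracle: tests every interval of the sequence against
# every primitive unit in every phase (each unit's rotations aligned as a
# full-length template; mismatch counts of all intervals via prefix
# sums), takes per-unit maximal valid intervals, then applies the same
# published overlap-resolution rule as the scanner.  Independent of the
# scanner's candidate prefilter and two-pointer machinery.
oracle_find_ssrs <- function(sequence, min_len = 15, max_mismatch = 0) {
  s <- strsplit(toupper(sequence), NULL)[[1]]
  L <- length(s)
  if (L < min_len) return(find_ssrs("", min_len, max_mismatch))
  rot_key <- function(w) min(vapply(seq_len(nchar(w)), function(i) {
    paste0(substr(w, i, nchar(w)), substr(w, 1, i - 1))
  }, ""))
  units <- character(0)
  for (u in 2:4) {
    grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), u))
    w <- apply(grid, 1, paste, collapse = "")
    units <- c(units, w[is_primitive_unit(w)])
  }
  classes <- split(units, vapply(units, rot_key, ""))
  idx_i <- row(matrix(0, L, L))
  idx_e <- col(matrix(0, L, L))
  span_ok <- idx_e - idx_i + 1 >= min_len
  cand <- list()
  for (cls in names(classes)) {
    best_mm <- matrix(Inf, L, L)
    for (w in classes[[cls]]) {       # each rotation = one phase
      wc <- strsplit(w, NULL)[[1]]
      u <- length(wc)
      tmpl <- wc[((seq_len(L) - 1) %% u) + 1]
      M <- (s != tmpl) | s == "N"
      P <- c(0, cumsum(M))
      mm <- outer(P[seq_len(L)], P[-1], function(a, b) b - a)  # mm[i,e]
      ends_ok <- outer(!M, !M, "&")
      ok <- span_ok & ends_ok & mm <= max_mismatch & idx_e >= idx_i
      best_mm[ok] <- pmin(best_mm[ok], mm[ok])
    }
    valid <- is.finite(best_mm)
    if (!any(valid)) next
    ## maximal = not contained in a valid interval of the same unit class
    grow_l <- rbind(FALSE, valid[-L, , drop = FALSE])   # valid[i-1, e]
    grow_r <- cbind(valid[, -1, drop = FALSE], FALSE)   # valid[i, e+1]
    maximal <- valid & !grow_l & !grow_r
    wh <- which(maximal, arr.ind = TRUE)
    if (nrow(wh) == 0) next
    cand[[length(cand) + 1]] <- data.frame(
      start = wh[, 1], end = wh[, 2],
      n_mismatches = best_mm[maximal],
      unit_len = nchar(cls), canonical_motif = canonical_motif(cls),
      stringsAsFactors = FALSE)
  }
  if (length(cand) == 0) return(find_ssrs("", min_len, max_mismatch))
  cand <- do.call(rbind, cand)
  o <- order(cand$start, cand$end, cand$n_mismatches, cand$canonical_motif)
  cand <- cand[o, , drop = FALSE]
  cand <- cand[!duplicated(cand[c("start", "end")]), , drop = FALSE]
  clovermap:::resolve_overlaps(cand, L, "seq")
}

# brute-force synteny chain oracle: enumerate every maximal run of
# cM-sorted anchors satisfying both gap bounds, per (group, chromosome)
oracle_chain_blocks <- function(anchors, min_anchors = 3, map_win_cm = 10,
                                ref_win_kb = 500) {
  res <- list()
  for (g in unique(anchors$group)) {
    for (ch in unique(anchors$chromosome[anchors$group == g])) {
      sub <- anchors[anchors$group == g & anchors$chromosome == ch, ]
      sub <- sub[order(sub$pos_cm, sub$bp, sub$marker_id), ]
      n <- nrow(sub)
      ok_step <- function(i) {
        sub$pos_cm[i + 1] - sub$pos_cm[i] <= map_win_cm &&
          abs(sub$bp[i + 1] - sub$bp[i]) <= ref_win_kb * 1000
      }
      i <- 1
      while (i <= n) {
        j <- i
        while (j < n && ok_step(j)) j <- j + 1
        if (j - i + 1 >= min_anchors) {
          blk <- sub[i:j, ]
          res[[length(res) + 1]] <- data.frame(
            group = g, start_cm = min(blk$pos_cm), end_cm = max(blk$pos_cm),
            chromosome = ch, n_anchors = nrow(blk),
            anchor_ids = paste(blk$marker_id, collapse = ","),
            stringsAsFactors = FALSE)
        }
        i <- j + 1
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(group = character(0), start_cm = numeric(0),
                      end_cm = numeric(0), chromosome = character(0),
                      n_anchors = integer(0), anchor_ids = character(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$group, out$chromosome, out$start_cm), , drop = FALSE]
}

## all permutations of 1..n as a matrix (small n only)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
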