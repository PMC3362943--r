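#' Define a synthetic allotetraploid genome
#'
#' The simulated species carries two subgenomes of `n_pairs` chromosomes
#' each, giving `2 * n_pairs` linkage groups arranged in homeologous
#' pairs (named e.g. LG1a/LG1b), mirroring an allotetraploid with
#' 2n = 4X = 32 that maps as 16 homeologous linkage groups.  Marker
#' positions are drawn uniformly along each group.
#'
#' @param n_pairs number of homeologous pairs (default 8).
#' @param group_length_cm length of each group in cM (scalar or vector of
#'   `2 * n_pairs`).
#' @param markers_per_group number of marker positions per group (>= 2);
#'   ignored for groups with explicit `positions`.
#' @param positions NULL for uniform-random positions, or a list of
#'   numeric vectors (recycled over groups) giving exact marker
#'   positions in cM.
#' @return object of class `sim_genome`: list with `groups` (data.frame
#'   `group`, `pair`, `partner`), `markers` (data.frame `group`, `idx`,
#'   `pos_cm`), `n_pairs`.
#' @export
sim_genome <- function(n_pairs = 8, group_length_cm = 140,
                       markers_per_group = 120, positions = NULL) {
  if (markers_per_group < 2) stop_cm("every group needs >= 2 markers")
  ng <- 2 * n_pairs
  nm <- rep(markers_per_group, length.out = ng)
  len <- rep(group_length_cm, length.out = ng)
  if (!is.null(positions)) {
    if (!is.list(positions)) positions <- list(positions)
    positions <- rep(positions, length.out = ng)
    len <- vapply(positions, max, 0)
  }
  grp <- paste0("LG", rep(seq_len(n_pairs), each = 2), c("a", "b"))
  partner <- paste0("LG", rep(seq_len(n_pairs), each = 2), c("b", "a"))
  groups <- data.frame(group = grp, pair = rep(seq_len(n_pairs), each = 2),
                       partner = partner, length_cm = len,
                       stringsAsFactors = FALSE)
  markers <- do.call(rbind, lapply(seq_len(ng), function(g) {
    pos <- if (is.null(positions)) sort(stats::runif(nm[g], 0, len[g])) else
      sort(positions[[g]])
    data.frame(group = grp[g], idx = seq_along(pos), pos_cm = pos,
               stringsAsFactors = FALSE)
  }))
  structure(list(groups = groups, markers = markers, n_pairs = n_pairs),
            class = "sim_genome")
}

#' Define a synthetic full-sib study design
#'
#' Defaults follow the white-clover study layout: 188 F1 progeny and
#' 424 / 789 / 584 loci segregating bi-parentally, from the female
#' parent only, and from the male parent only.
#'
#' @param n_progeny number of F1 progeny (default 188).
#' @param n_biparental,n_female,n_male locus counts per segregation class.
#' @param multilocus_fraction probability that a locus is merged with a
#'   same-class locus on its homeolog partner group under one marker id
#'   (multi-band, "Type I" markers).
#' @param type2_fraction probability that a bi-parental locus' male
#'   channel actually segregates from the homeolog partner group
#'   ("Type II" placements).
#' @param missing_rate per-call missing probability.
#' @param error_rate per-call symmetric mis-scoring probability.
#' @param distortion NULL or data.frame with columns `parent`, `group`,
#'   `pos_cm`, `s`: gametic viability selection of strength `s` against
#'   allele "b" at the nearest marker.
#' @param planted_ld NULL or list of lists with fields `parent`,
#'   `group_a`, `pos_a`, `group_b`, `pos_b`, `dprime`: cross-group
#'   gametic disequilibrium planted at two anchor marker positions.
#' @return object of class `sim_design`.
#' @export
sim_design <- function(n_progeny = 188, n_biparental = 424, n_female = 789,
                       n_male = 584, multilocus_fraction = 0.5,
                       type2_fraction = 0.02, missing_rate = 0.05,
                       error_rate = 0.005, distortion = NULL,
                       planted_ld = NULL) {
  if (n_progeny < 2) stop_cm("n_progeny must be >= 2")
  assert_prob(multilocus_fraction, "multilocus_fraction")
  assert_prob(type2_fraction, "type2_fraction")
  assert_prob(missing_rate, "missing_rate")
  assert_prob(error_rate, "error_rate")
  if (!is.null(distortion)) assert_prob(distortion$s, "distortion$s")
  if (!is.null(planted_ld)) {
    for (pl in planted_ld) {
      if (abs(pl$dprime) > 1) stop_cm("|D'| must be <= 1")
    }
  }
  structure(list(n_progeny = n_progeny, n_biparental = n_biparental,
                 n_female = n_female, n_male = n_male,
                 multilocus_fraction = multilocus_fraction,
                 type2_fraction = type2_fraction,
                 missing_rate = missing_rate, error_rate = error_rate,
                 distortion = distortion, planted_ld = planted_ld),
            class = "sim_design")
}

## Markov chromosome walk: alleles at ordered positions, adjacent-interval
## recombination probability r = kosambi_inverse(delta cM)
walk_group <- function(pos, n, anchor_idx = NULL, anchor_allele = NULL) {
  m <- length(pos)
  X <- matrix(0L, m, n)
  r <- kosambi_inverse(diff(pos))
  if (is.null(anchor_idx)) {
    X[1, ] <- stats::rbinom(n, 1, 0.5)
    if (m > 1) for (j in 2:m) {
      X[j, ] <- xor(X[j - 1, ], stats::rbinom(n, 1, r[j - 1])) * 1L
    }
  } else {
    X[anchor_idx, ] <- anchor_allele
    if (anchor_idx < m) for (j in (anchor_idx + 1):m) {
      X[j, ] <- xor(X[j - 1, ], stats::rbinom(n, 1, r[j - 1])) * 1L
    }
    if (anchor_idx > 1) for (j in (anchor_idx - 1):1) {
      X[j, ] <- xor(X[j + 1, ], stats::rbinom(n, 1, r[j])) * 1L
    }
  }
  X
}

anchor_index <- function(genome, group, pos_cm) {
  mk <- genome$markers[genome$markers$group == group, ]
  i <- which(abs(mk$pos_cm - pos_cm) < 1e-9)
  if (length(i) != 1) {
    stop_cm("planted LD anchor at %s cM is not a marker position of %s",
            format(pos_cm), group)
  }
  mk$idx[i]
}

#' Simulate one parent's gametes across the genome
#'
#' Each progeny receives, for every linkage group, a haploid allele
#' vector generated by a Markov chain over the ordered marker positions:
#' the allele switches between adjacent markers with probability
#' `kosambi_inverse(delta_cm)`, making simulated recombination
#' self-consistent with the Kosambi map function used in mapping.
#' Groups segregate independently, except pairs named in
#' `design$planted_ld` for this parent: there, the two anchor alleles
#' are drawn jointly with the requested gametic `D'` and the rest of
#' each chromosome is walked conditionally outward from its anchor.
#'
#' @param genome a [sim_genome].
#' @param design a [sim_design].
#' @param parent `"P1"` (female) or `"P2"` (male).
#' @param n number of gametes (default `design$n_progeny`).
#' @return named list of allele matrices (markers x gametes), one per
#'   group, with attribute `parent`.
#' @export
simulate_gametes <- function(genome, design, parent = "P1",
                             n = design$n_progeny) {
  planted <- Filter(function(p) identical(p$parent, parent),
                    design$planted_ld %||% list())
  anchored <- list()
  for (pl in planted) {
    ## sequential conditional sampling; pairs may chain (A-B then B-C)
    ia <- anchor_index(genome, pl$group_a, pl$pos_a)
    ib <- anchor_index(genome, pl$group_b, pl$pos_b)
    dp <- pl$dprime
    a <- anchored[[pl$group_a]]
    if (is.null(a)) {
      a <- list(idx = ia, allele = stats::rbinom(n, 1, 0.5))
      anchored[[pl$group_a]] <- a
    } else if (a$idx != ia) {
      stop_cm("group %s already carries a planted anchor at another position",
              pl$group_a)
    }
    if (!is.null(anchored[[pl$group_b]])) {
      stop_cm("group %s cannot be the dependent member of two planted pairs",
              pl$group_b)
    }
    same <- stats::rbinom(n, 1, (1 + dp) / 2)
    anchored[[pl$group_b]] <- list(idx = ib,
                                   allele = ifelse(same == 1, a$allele,
                                                   1L - a$allele))
  }
  out <- list()
  for (g in genome$groups$group) {
    pos <- genome$markers$pos_cm[genome$markers$group == g]
    a <- anchored[[g]]
    out[[g]] <- if (is.null(a)) walk_group(pos, n) else
      walk_group(pos, n, a$idx, a$allele)
  }
  attr(out, "parent") <- parent
  out
}

nearest_marker_idx <- function(genome, group, pos_cm) {
  mk <- genome$markers[genome$markers$group == group, ]
  mk$idx[which.min(abs(mk$pos_cm - pos_cm))]
}

#' Render simulated gametes into a genotype table with known truth
#'
#' Assigns loci of the three segregation classes to distinct marker
#' positions, applies gametic viability distortion (progeny resampled
#' with weights from the selected alleles), merges a fraction of loci
#' with a same-class partner-group locus under a shared marker id
#' (multi-band markers, locus ids suffixed "a"/"b"), optionally rewires a
#' fraction of bi-parental loci so their male channel segregates from the
#' homeolog partner group (Type II), randomizes the a/b label polarity of
#' every channel, and finally applies symmetric call error and
#' missing-at-random masking.
#'
#' @param gam1,gam2 gametes of P1 and P2 from [simulate_gametes].
#' @param genome a [sim_genome].
#' @param design a [sim_design].
#' @return list with `table` (a [genotype_table]) and `truth` (class
#'   `sim_truth`): `channels` data.frame (one row per call-vector:
#'   `locus_id`, `parent`, `group`, `idx`, `pos_cm`, `flipped`), `loci`
#'   data.frame (`locus_id`, `marker_id`, `seg_class`, `band_count`,
#'   `type2`), `gametes` (post-selection), `genome`, `design`.
#' @export
render_genotype_table <- function(gam1, gam2, genome, design) {
  mk <- genome$markers
  total <- design$n_biparental + design$n_female + design$n_male
  if (total > nrow(mk)) {
    stop_cm("design asks for %d loci but genome has only %d marker positions",
            total, nrow(mk))
  }
  n <- ncol(gam1[[1]])

  ## gametic viability selection: resample progeny by fitness weight
  if (!is.null(design$distortion) && nrow(design$distortion) > 0) {
    w <- rep(1, n)
    for (i in seq_len(nrow(design$distortion))) {
      d <- design$distortion[i, ]
      gam <- if (d$parent == "P1") gam1 else gam2
      idx <- nearest_marker_idx(genome, d$group, d$pos_cm)
      al <- gam[[d$group]][idx, ]
      w <- w * ifelse(al == 1L, 1, 1 - d$s)
    }
    keep <- sample.int(n, n, replace = TRUE, prob = w)
    gam1 <- lapply(gam1, function(X) X[, keep, drop = FALSE])
    gam2 <- lapply(gam2, function(X) X[, keep, drop = FALSE])
  }

  perm <- sample.int(nrow(mk))
  pick <- list(
    biparental = perm[seq_len(design$n_biparental)],
    female = perm[design$n_biparental + seq_len(design$n_female)],
    male = perm[design$n_biparental + design$n_female +
                  seq_len(design$n_male)])
  loci <- do.call(rbind, lapply(names(pick)[lengths(pick) > 0], function(cls) {
    data.frame(seg_class = cls, group = mk$group[pick[[cls]]],
               idx = mk$idx[pick[[cls]]], pos_cm = mk$pos_cm[pick[[cls]]],
               stringsAsFactors = FALSE)
  }))

  ## multi-band (Type I) markers: pair loci across homeolog partner groups
  partner_of <- stats::setNames(genome$groups$partner, genome$groups$group)
  loci$pair_with <- NA_integer_
  for (cls in names(pick)) {
    for (g in genome$groups$group) {
      pg <- partner_of[[g]]
      if (pg < g) next                      # handle each pair once
      ia <- which(loci$seg_class == cls & loci$group == g &
                    is.na(loci$pair_with))
      ib <- which(loci$seg_class == cls & loci$group == pg &
                    is.na(loci$pair_with))
      if (length(ia) == 0 || length(ib) == 0) next
      want <- stats::rbinom(length(ia), 1, design$multilocus_fraction) == 1
      ia <- ia[want]
      k <- min(length(ia), length(ib))
      if (k == 0) next
      ia <- ia[seq_len(k)]
      ib <- ib[sample.int(length(ib), k)]
      loci$pair_with[ia] <- ib
      loci$pair_with[ib] <- ia
    }
  }

  ## marker and locus ids
  loci$marker_id <- NA_character_
  loci$locus_id <- NA_character_
  loci$band_count <- 1L
  mcount <- 0L
  for (i in seq_len(nrow(loci))) {
    if (!is.na(loci$marker_id[i])) next
    mcount <- mcount + 1L
    mid <- sprintf("MRK%04d", mcount)
    j <- loci$pair_with[i]
    if (!is.na(j)) {
      loci$marker_id[c(i, j)] <- mid
      loci$locus_id[c(i, j)] <- paste0(mid, c("a", "b"))
      loci$band_count[c(i, j)] <- 2L
    } else {
      loci$marker_id[i] <- mid
      loci$locus_id[i] <- mid
    }
  }

  ## Type II rewiring of bi-parental male channels
  bi <- which(loci$seg_class == "biparental")
  t2 <- bi[stats::rbinom(length(bi), 1, design$type2_fraction) == 1]
  loci$type2 <- seq_len(nrow(loci)) %in% t2

  ## channel rows
  chan <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
    row <- loci[i, ]
    parents <- switch(row$seg_class, biparental = c("P1", "P2"),
                      female = "P1", male = "P2")
    do.call(rbind, lapply(parents, function(p) {
      g <- row$group; idx <- row$idx; pos <- row$pos_cm
      if (p == "P2" && row$type2) {
        g <- partner_of[[row$group]]
        idx <- nearest_marker_idx(genome, g, row$pos_cm)
        pos <- mk$pos_cm[mk$group == g & mk$idx == idx]
      }
      data.frame(locus_id = row$locus_id, parent = p, group = g, idx = idx,
                 pos_cm = pos, stringsAsFactors = FALSE)
    }))
  }))
  chan$flipped <- stats::rbinom(nrow(chan), 1, 0.5) == 1

  calls <- matrix(NA_integer_, nrow(chan), n)
  for (i in seq_len(nrow(chan))) {
    gam <- if (chan$parent[i] == "P1") gam1 else gam2
    al <- gam[[chan$group[i]]][chan$idx[i], ]
    if (chan$flipped[i]) al <- 1L - al
    calls[i, ] <- al
  }
  if (design$error_rate > 0) {
    flip <- matrix(stats::rbinom(length(calls), 1, design$error_rate),
                   nrow(calls))
    calls <- abs(calls - flip)
  }
  if (design$missing_rate > 0) {
    calls[matrix(stats::rbinom(length(calls), 1, design$missing_rate),
                 nrow(calls)) == 1] <- NA_integer_
  }

  rows <- data.frame(locus_id = chan$locus_id,
                     marker_id = loci$marker_id[match(chan$locus_id,
                                                      loci$locus_id)],
                     seg_class = loci$seg_class[match(chan$locus_id,
                                                      loci$locus_id)],
                     parent = chan$parent,
                     band_count = loci$band_count[match(chan$locus_id,
                                                        loci$locus_id)],
                     stringsAsFactors = FALSE)
  gt <- genotype_table(paste0("F1_", sprintf("%03d", seq_len(n))), rows,
                       calls)
  truth <- structure(list(channels = chan,
                          loci = loci[c("locus_id", "marker_id", "seg_class",
                                        "band_count", "type2", "group",
                                        "idx", "pos_cm")],
                          gametes = list(P1 = gam1, P2 = gam2),
                          genome = genome, design = design),
                     class = "sim_truth")
  list(table = gt, truth = truth)
}

#' One-call simulation of a study-design genotype table
#'
#' Convenience wrapper: seeds the RNG, builds the genome, simulates both
#' parents' gametes and renders the genotype table.
#'
#' @param design a [sim_design].
#' @param genome a [sim_genome], or NULL to build one with the given
#'   genome arguments.
#' @param seed RNG seed.
#' @param ... passed to [sim_genome] when `genome` is NULL.
#' @return list with `table`, `truth`, `genome`.
#' @export
simulate_study <- function(design = sim_design(), genome = NULL, seed = 1,
                           ...) {
  set.seed(seed)
  if (is.null(genome)) genome <- sim_genome(...)
  gam1 <- simulate_gametes(genome, design, "P1")
  gam2 <- simulate_gametes(genome, design, "P2")
  out <- render_genotype_table(gam1, gam2, genome, design)
  out$genome <- genome
  out
}

#' Simulate transcripts with planted SSR tracts
#'
#' Generates uniform-random nucleotide background with SSR tracts
#' planted at a chosen density: roughly one tract per `1/density_per_bp`
#' bases (Poisson per transcript).  Each planted tract draws its unit
#' length from `class_probs` (di/tri/tetra), a random primitive unit, a
#' tract length of 15-30 nt, and 0-2 interior mismatching bases with
#' probabilities `mismatch_probs`.
#'
#' @param n number of transcripts.
#' @param length_range transcript length range in nt.
#' @param density_per_bp expected planted tracts per base
#'   (default 1/4700, one per 4.7 kb).
#' @param class_probs probabilities of unit length 2/3/4.
#' @param mismatch_probs probabilities of 0/1/2 planted mismatches.
#' @return list with `sequences` (named character vector) and `truth`
#'   (data.frame `seq_id`, `start`, `end`, `unit`, `canonical_motif`,
#'   `unit_len`, `tract_len`, `n_mismatches`).
#' @export
simulate_transcripts <- function(n = 200, length_range = c(400, 1200),
                                 density_per_bp = 1 / 4700,
                                 class_probs = c(0.19, 0.698, 0.112),
                                 mismatch_probs = c(0.7, 0.2, 0.1)) {
  seqs <- character(n)
  names(seqs) <- sprintf("TR%05d", seq_len(n))
  truth <- list()
  for (i in seq_len(n)) {
    L <- sample(length_range[1]:length_range[2], 1)
    s <- sample(BASES, L, replace = TRUE)
    k <- stats::rpois(1, L * density_per_bp)
    used <- integer(0)
    for (t in seq_len(k)) {
      u <- sample(2:4, 1, prob = class_probs)
      repeat {
        unit <- paste(sample(BASES, u, replace = TRUE), collapse = "")
        if (is_primitive_unit(unit)) break
      }
      tl <- u * ceiling(sample(15:30, 1) / u)
      start <- NA
      for (try in 1:20) {
        cand <- sample(seq(25, max(25, L - tl - 25)), 1)
        if (!any((cand:(cand + tl - 1)) %in% used)) { start <- cand; break }
      }
      if (is.na(start) || start + tl - 1 > L - 24) next
      tract <- strsplit(paste(rep(unit, tl / u), collapse = ""), NULL)[[1]]
      nmm <- sample(0:2, 1, prob = mismatch_probs)
      if (nmm > 0) {
        ppos <- sample(2:(tl - 1), nmm)
        for (p in ppos) tract[p] <- sample(setdiff(BASES, tract[p]), 1)
      }
      s[start:(start + tl - 1)] <- tract
      ## break the repeat phase at both flanks so the planted coordinates
      ## are the exact maximal tract
      unit_chars <- strsplit(unit, NULL)[[1]]
      s[start - 1] <- sample(setdiff(BASES, unit_chars[u]), 1)
      s[start + tl] <- sample(setdiff(BASES, unit_chars[(tl %% u) + 1]), 1)
      used <- c(used, (start - 1):(start + tl))
      truth[[length(truth) + 1]] <-
        data.frame(seq_id = names(seqs)[i], start = start,
                   end = start + tl - 1, unit = unit,
                   canonical_motif = canonical_motif(unit), unit_len = u,
                   tract_len = tl, n_mismatches = nmm,
                   stringsAsFactors = FALSE)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(seq_id = character(0), start = integer(0), end = integer(0),
               unit = character(0), canonical_motif = character(0),
               unit_len = integer(0), tract_len = integer(0),
               n_mismatches = integer(0))
  list(sequences = seqs, truth = truth)
}

#' Write simulated transcripts to FASTA
#' @param sequences named character vector of sequences.
#' @param path output FASTA path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Simulate a colinear reference genome and its homolog hit table
#'
#' Every marker receives a reference gene whose bp position is colinear
#' with its cM position at `bp_per_cm` bases per centimorgan on the
#' reference chromosome of its homeologous pair (both homeologs of pair
#' k map to chromosome k), except for listed rearrangements.  Optional
#' hit noise adds wrong-chromosome decoy hits with lower bitscore and
#' removes hits for a fraction of markers.
#'
#' @param markers data.frame with columns `marker_id`, `group`, `pos_cm`
#'   (one row per marker; e.g. derived from a `sim_truth` or a map).
#' @param bp_per_cm physical-to-genetic scale (default 40000 bp/cM).
#' @param rearrangements NULL or data.frame with columns `type`
#'   (`"translocation"` or `"inversion"`), `group`, `start_cm`, `end_cm`,
#'   and for translocations `dest_chrom`, `dest_offset_bp`.
#' @param decoy_rate fraction of markers receiving an extra
#'   wrong-chromosome hit with worse bitscore.
#' @param miss_rate fraction of markers with no hit at all.
#' @return list with `hits` (a `hit_table` data.frame) and `truth`
#'   (data.frame `marker_id`, `chromosome`, `start_bp`).
#' @export
simulate_reference <- function(markers, bp_per_cm = 40000,
                               rearrangements = NULL, decoy_rate = 0,
                               miss_rate = 0) {
  pair <- as.integer(sub("^LG(\\d+)[ab]$", "\\1", markers$group))
  if (anyNA(pair)) stop_cm("group names must look like LG<k>a / LG<k>b")
  chrom <- paste0("chr", pair)
  bp <- round(markers$pos_cm * bp_per_cm) + 1
  if (!is.null(rearrangements)) {
    for (i in seq_len(nrow(rearrangements))) {
      rr <- rearrangements[i, ]
      hit <- markers$group == rr$group & markers$pos_cm >= rr$start_cm &
        markers$pos_cm <= rr$end_cm
      if (rr$type == "translocation") {
        chrom[hit] <- rr$dest_chrom
        bp[hit] <- round(rr$dest_offset_bp +
                           (markers$pos_cm[hit] - rr$start_cm) * bp_per_cm) + 1
      } else if (rr$type == "inversion") {
        bp[hit] <- round((rr$end_cm - (markers$pos_cm[hit] - rr$start_cm)) *
                           bp_per_cm) + 1
      } else {
        stop_cm("unknown rearrangement type '%s'", rr$type)
      }
    }
  }
  truth <- data.frame(marker_id = markers$marker_id, chromosome = chrom,
                      start_bp = as.integer(bp), stringsAsFactors = FALSE)
  hits <- data.frame(query_id = markers$marker_id,
                     reference_id = paste0("gene_", markers$marker_id),
                     chromosome = chrom, start_bp = as.integer(bp),
                     end_bp = as.integer(bp + 999), evalue = 1e-50,
                     bitscore = 200, stringsAsFactors = FALSE)
  nmk <- nrow(markers)
  if (decoy_rate > 0) {
    pickd <- which(stats::rbinom(nmk, 1, decoy_rate) == 1)
    if (length(pickd) > 0) {
      all_chr <- unique(chrom)
      dec <- hits[pickd, , drop = FALSE]
      dec$chromosome <- vapply(dec$chromosome, function(cc) {
        alt <- setdiff(all_chr, cc)
        if (length(alt) == 0) cc else sample(alt, 1)
      }, "")
      dec$start_bp <- as.integer(round(stats::runif(nrow(dec), 1, max(bp))))
      dec$end_bp <- dec$start_bp + 999L
      dec$bitscore <- 100
      dec$evalue <- 1e-30
      dec$reference_id <- paste0("decoy_", dec$query_id)
      hits <- rbind(hits, dec)
    }
  }
  if (miss_rate > 0) {
    drop <- markers$marker_id[stats::rbinom(nmk, 1, miss_rate) == 1]
    hits <- hits[!(hits$query_id %in% drop), , drop = FALSE]
  }
  rownames(hits) <- NULL
  class(hits) <- c("hit_table", "data.frame")
  list(hits = hits, truth = truth)
}
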