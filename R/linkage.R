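#' Kosambi mapping function
#'
#' Converts a recombination fraction to additive map distance in
#' centimorgans, `d = 25 * ln((1 + 2r) / (1 - 2r))`, which accounts for
#' moderate crossover interference.  `kosambi_inverse()` is the exact
#' inverse, `r = 0.5 * tanh(d / 50)`.
#'
#' @param r recombination fraction(s); values are clamped to `[0, 0.5)`.
#' @param cm map distance(s) in cM (nonnegative).
#' @return `kosambi()`: distance in cM; `kosambi_inverse()`: recombination
#'   fraction in `[0, 0.5)`.
#' @examples
#' kosambi(0.25)            # 25 * log(3) ~ 27.465
#' kosambi_inverse(27.465)  # ~0.25
#' @export
kosambi <- function(r) {
  r <- pmin(pmax(r, 0), 0.5 - 1e-12)
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambi_inverse <- function(cm) {
  cm <- pmax(cm, 0)
  pmin(pmax(0.5 * tanh(cm / 50), 0), 0.5 - 1e-12)
}

#' Two-point recombination and LOD statistics for a haploid locus set
#'
#' Computes, for every pair of loci in a phased (gametic, "HAP1"-style)
#' call matrix, the number of informative progeny, the phase-minimized
#' recombinant count, the recombination fraction estimate `r_hat = R / n`
#' (with `R <= n - R`, i.e. the allele labelling of each locus is aligned
#' to minimize mismatches), and the two-point LOD score
#' `R*log10(2r) + (n-R)*log10(2(1-r))` with the `r = 0` limit
#' `n*log10(2)`.
#'
#' @param calls integer/numeric matrix, loci in rows (rownames = locus
#'   ids), progeny in columns; entries 1 ("a"), 0 ("b") or `NA` (missing).
#' @param n_min minimum number of jointly informative progeny; pairs below
#'   it get `NA` statistics.
#' @return An object of class `pair_stats`: a list with locus `ids` and
#'   square matrices `n`, `R`, `r_hat`, `lod`, and logical `flipped`
#'   (TRUE where the minimizing phase reverses the labels of locus j
#'   relative to locus i).
#' @export
pair_stats <- function(calls, n_min = 20) {
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("L", seq_len(nrow(calls)))
  }
  ids <- rownames(calls)
  A <- (calls == 1); A[is.na(A)] <- FALSE; A <- A * 1
  B <- (calls == 0); B[is.na(B)] <- FALSE; B <- B * 1
  n11 <- tcrossprod(A)
  n00 <- tcrossprod(B)
  n10 <- tcrossprod(A, B)
  n01 <- t(n10)
  M <- n10 + n01                       # mismatches in the as-coded phase
  n <- n11 + n00 + M
  R <- pmin(M, n - M)
  flipped <- M > n - M
  r_hat <- ifelse(n > 0, R / n, NA_real_)
  lod <- matrix(NA_real_, nrow(calls), nrow(calls))
  ok <- n > 0
  r0 <- r_hat[ok] == 0
  lodv <- numeric(sum(ok))
  lodv[r0] <- n[ok][r0] * log10(2)
  if (any(!r0)) {
    rr <- r_hat[ok][!r0]
    lodv[!r0] <- R[ok][!r0] * log10(2 * rr) +
      (n[ok][!r0] - R[ok][!r0]) * log10(2 * (1 - rr))
  }
  lod[ok] <- lodv
  low <- n < n_min
  r_hat[low] <- NA_real_
  lod[low] <- NA_real_
  diag(r_hat) <- 0; diag(lod) <- NA_real_
  dimnames(n) <- dimnames(R) <- dimnames(r_hat) <-
    dimnames(lod) <- dimnames(flipped) <- list(ids, ids)
  structure(list(ids = ids, n = n, R = R, r_hat = r_hat, lod = lod,
                 flipped = flipped),
            class = "pair_stats")
}

#' Partition loci into linkage groups by LOD threshold
#'
#' Single-linkage grouping: loci are connected when their two-point LOD is
#' at least `lod_min` and the recombination estimate at most `rec_max`;
#' linkage groups are the connected components of this graph, mirroring
#' threshold-based grouping in standard mapping software.
#'
#' @param ps a [pair_stats] object.
#' @param lod_min LOD threshold for declaring linkage (default 10).
#' @param rec_max maximum recombination fraction for an edge (default 0.4).
#' @param ids optional subset of locus ids to partition.
#' @return list with `groups` (list of locus-id vectors, largest first)
#'   and `membership` (named integer vector).
#' @export
group_loci <- function(ps, lod_min = 10, rec_max = 0.4, ids = NULL) {
  ids <- ids %||% ps$ids
  idx <- match(ids, ps$ids)
  if (anyNA(idx)) stop_cm("unknown locus ids in 'ids'")
  adj <- ps$lod[idx, idx, drop = FALSE] >= lod_min &
    ps$r_hat[idx, idx, drop = FALSE] <= rec_max
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  if (is.finite(lod_min)) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
  } else {
    comp <- seq_along(ids)
  }
  names(comp) <- ids
  groups <- split(ids, comp)
  groups <- groups[order(-lengths(groups), vapply(groups, min, ""))]
  names(groups) <- NULL
  member <- rep(seq_along(groups), lengths(groups))
  names(member) <- unlist(groups)
  list(groups = groups, membership = member[ids])
}

## positions implied by chaining adjacent-pair Kosambi distances; used as
## the cheap position estimate during order search
chain_positions <- function(ord_idx, D, d_fallback) {
  k <- length(ord_idx)
  if (k == 1) return(0)
  d <- D[cbind(ord_idx[-k], ord_idx[-1])]
  d[is.na(d)] <- d_fallback
  cumsum(c(0, d))
}

## LOD-weighted normalized misfit of an order at given positions;
## max_span limits which pairs contribute residuals (Inf = all pairs)
misfit_at <- function(p, ord_idx, D, W, max_span = Inf) {
  Ds <- D[ord_idx, ord_idx, drop = FALSE]
  Ws <- W[ord_idx, ord_idx, drop = FALSE]
  use <- upper.tri(Ds) & !is.na(Ds) & Ws > 0
  if (is.finite(max_span)) {
    k <- length(ord_idx)
    use <- use & abs(outer(seq_len(k), seq_len(k), "-")) <= max_span
  }
  if (!any(use)) return(0)
  dm <- abs(outer(p, p, "-"))
  sum(Ws[use] * (dm[use] - Ds[use])^2) / sum(Ws[use])
}

## cheap surrogate misfit (positions chained from adjacent distances);
## used to rank candidate insertions and ripple permutations
order_misfit <- function(ord_idx, D, W, d_fallback) {
  misfit_at(chain_positions(ord_idx, D, d_fallback), ord_idx, D, W)
}

## reference misfit (positions from the weighted least-squares fit),
## over all informative pairs; reported and used by the ordering oracle
order_misfit_wls <- function(ord_idx, D, W) {
  misfit_at(wls_positions(ord_idx, D, W), ord_idx, D, W)
}

## goodness-of-fit statistic for the jump rule: residuals of the pairs the
## position fit actually models (span <= 2); long pairs carry a systematic
## Markov-vs-Kosambi offset that would otherwise inflate every addition
jump_misfit <- function(ord_idx, D, W) {
  misfit_at(wls_positions(ord_idx, D, W), ord_idx, D, W, max_span = 2)
}

## exhaustive permutation of every sliding window of 3; single sweep,
## repeated until no improvement (at most maxit sweeps)
ripple3 <- function(ord_idx, D, W, d_fallback, maxit = 3) {
  k <- length(ord_idx)
  if (k < 3) return(ord_idx)
  perms <- matrix(c(1,2,3, 1,3,2, 2,1,3, 2,3,1, 3,1,2, 3,2,1),
                  ncol = 3, byrow = TRUE)
  best <- order_misfit(ord_idx, D, W, d_fallback)
  for (it in seq_len(maxit)) {
    improved <- FALSE
    for (w in seq_len(k - 2)) {
      win <- w:(w + 2)
      for (p in 2:6) {
        cand <- ord_idx
        cand[win] <- ord_idx[win][perms[p, ]]
        m <- order_misfit(cand, D, W, d_fallback)
        if (m < best - 1e-12) {
          ord_idx <- cand
          best <- m
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  ord_idx
}

## weighted least-squares interval lengths on a fixed order.  Only pairs
## spanning at most `span` intervals enter the fit: under a Markov meiosis
## model the Kosambi distance is additive only locally, so long-range
## pairwise distances systematically understate map distance and would
## compress the map if fitted.
wls_positions <- function(ord_idx, D, W, span = 2L) {
  k <- length(ord_idx)
  if (k == 1) return(0)
  m <- k - 1
  M <- matrix(0, m, m)
  v <- numeric(m)
  Ds <- D[ord_idx, ord_idx, drop = FALSE]
  Ws <- W[ord_idx, ord_idx, drop = FALSE]
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):min(k, i + span)) {
      w <- Ws[i, j]; d <- Ds[i, j]
      if (is.na(d) || w <= 0) next
      iv <- i:(j - 1)
      M[iv, iv] <- M[iv, iv] + w
      v[iv] <- v[iv] + w * d
    }
  }
  covered <- diag(M) > 0
  g <- rep(NA_real_, m)
  if (any(covered)) {
    Mr <- M[covered, covered, drop = FALSE]
    diag(Mr) <- diag(Mr) + 1e-8
    g[covered] <- solve(Mr, v[covered])
  }
  ## intervals with no covering pair: fall back to chained adjacent distance
  if (any(!covered)) {
    d_adj <- Ds[cbind(seq_len(m), seq_len(m) + 1)]
    g[!covered] <- ifelse(is.na(d_adj[!covered]), kosambi(0.4), d_adj[!covered])
  }
  cumsum(c(0, pmax(g, 0)))
}

#' Order the loci of one linkage group and assign cM positions
#'
#' Regression-style ordering: the highest-LOD pair seeds the order; the
#' remaining loci are added in decreasing informativeness (summed LOD to
#' already-placed loci), each inserted at the slot minimizing the
#' LOD-weighted least-squares misfit between map distances and pairwise
#' Kosambi distances (only pairs with `lod >= lod_order_min` and
#' `r_hat <= rec_max` contribute).  After every addition each sliding
#' window of three loci is exhaustively permuted (ripple).  A locus whose
#' best insertion raises the normalized misfit by more than `jump` is set
#' aside and retried once after all other loci are placed (the "third
#' round").  Final positions come from a weighted least-squares fit of
#' interval lengths on the final order, anchored at 0; orientation puts
#' the lexicographically smaller terminal locus at 0.
#'
#' @param ids locus ids forming one linkage group.
#' @param ps a [pair_stats] object covering those loci.
#' @param jump goodness-of-fit jump threshold for setting a locus aside
#'   (default 5.0).
#' @param lod_order_min minimum LOD for a pair to inform ordering
#'   (default 1.0).
#' @param rec_max maximum recombination fraction for an informative pair
#'   (default 0.4).
#' @param group_id optional label stored on the result.
#' @return An object of class `linkage_group`: list with `group_id`,
#'   `locus_ids` (final order), `pos_cm`, `excluded` (unplaceable loci),
#'   and `misfit` (final normalized misfit).
#' @export
order_group <- function(ids, ps, jump = 5.0, lod_order_min = 1.0,
                        rec_max = 0.4, group_id = NA_character_) {
  idx <- match(ids, ps$ids)
  if (anyNA(idx)) stop_cm("unknown locus ids in 'ids'")
  k <- length(idx)
  if (k == 1) {
    return(structure(list(group_id = group_id, locus_ids = ids, pos_cm = 0,
                          excluded = character(0), misfit = 0),
                     class = "linkage_group"))
  }
  W <- ps$lod[idx, idx, drop = FALSE]
  Rm <- ps$r_hat[idx, idx, drop = FALSE]
  use <- !is.na(W) & W >= lod_order_min & !is.na(Rm) & Rm <= rec_max
  D <- matrix(NA_real_, k, k)
  D[use] <- kosambi(Rm[use])
  Wm <- matrix(0, k, k)
  Wm[use] <- W[use]
  d_fb <- kosambi(rec_max)

  ## seed: highest-LOD usable pair
  if (!any(use)) {
    ## nothing informative: emit input order with fallback spacing
    pos <- seq(0, by = d_fb, length.out = k)
    return(structure(list(group_id = group_id, locus_ids = ids,
                          pos_cm = pos, excluded = character(0),
                          misfit = NA_real_),
                     class = "linkage_group"))
  }
  seed <- which(Wm == max(Wm), arr.ind = TRUE)[1, ]
  ord <- as.integer(seed)
  placed <- rep(FALSE, k)
  placed[ord] <- TRUE
  aside <- integer(0)
  cur_misfit <- jump_misfit(ord, D, Wm)

  add_one <- function(ord, cand, cur_misfit, allow_jump) {
    ## returns list(ord, misfit, placed flag); cur_misfit on the jump scale
    slots <- length(ord) + 1
    cheap <- vapply(seq_len(slots), function(s) {
      order_misfit(append(ord, cand, after = s - 1), D, Wm, d_fb)
    }, 0)
    ## evaluate the few best-ranked slots under the exact LS objective
    top <- order(cheap)[seq_len(min(3, slots))]
    best_m <- Inf; best_ord <- NULL
    for (s in top) {
      trial <- append(ord, cand, after = s - 1)
      m <- jump_misfit(trial, D, Wm)
      if (m < best_m) { best_m <- m; best_ord <- trial }
    }
    if (allow_jump && best_m - cur_misfit > jump) {
      return(list(ord = ord, misfit = cur_misfit, placed = FALSE))
    }
    best_ord <- ripple3(best_ord, D, Wm, d_fb)
    list(ord = best_ord, misfit = jump_misfit(best_ord, D, Wm),
         placed = TRUE)
  }

  round_pass <- function(ord, cur_misfit, pool, allow_jump) {
    aside_local <- integer(0)
    while (length(pool) > 0) {
      info <- vapply(pool, function(i) {
        w <- Wm[i, ord]
        sum(w[w > 0])
      }, 0)
      nxt <- pool[which.max(info)]
      pool <- setdiff(pool, nxt)
      if (info[which.max(info)] <= 0) {      # no usable link yet
        aside_local <- c(aside_local, nxt)
        next
      }
      res <- add_one(ord, nxt, cur_misfit, allow_jump)
      if (res$placed) {
        ord <- res$ord
        cur_misfit <- res$misfit
      } else {
        aside_local <- c(aside_local, nxt)
      }
    }
    list(ord = ord, misfit = cur_misfit, aside = aside_local)
  }

  pool <- which(!placed)
  r1 <- round_pass(ord, cur_misfit, pool, allow_jump = TRUE)
  ## third round: retry set-aside loci once (jump rule still applies)
  r2 <- round_pass(r1$ord, r1$misfit, r1$aside, allow_jump = TRUE)
  ord <- r2$ord

  ## orientation: lexicographically smallest terminal locus at position 0
  if (ids[ord[length(ord)]] < ids[ord[1]]) ord <- rev(ord)
  pos <- wls_positions(ord, D, Wm)
  structure(list(group_id = group_id,
                 locus_ids = ids[ord],
                 pos_cm = pos,
                 excluded = ids[r2$aside],
                 misfit = order_misfit_wls(ord, D, Wm)),
            class = "linkage_group")
}

#' Mosaicism score of an ordered locus set
#'
#' Mean per-progeny fraction of allele switches between adjacent loci
#' (after two-point phase alignment).  Correctly ordered single
#' chromosomes give low scores; over-merged groups mixing several
#' chromosomes give scores near 0.5, mimicking the mosaic graphical
#' genotypes used to flag a suspect group.
#'
#' @param calls phased call matrix (loci x progeny) in map order.
#' @param ps [pair_stats] for phase alignment.
#' @return a single numeric score in `[0, 0.5]`ish.
#' @export
mosaicism_score <- function(calls, ps) {
  ids <- rownames(calls)
  idx <- match(ids, ps$ids)
  if (nrow(calls) < 2) return(0)
  sw <- vapply(seq_len(nrow(calls) - 1), function(i) {
    ps$r_hat[idx[i], idx[i + 1]]
  }, 0)
  mean(sw, na.rm = TRUE)
}

#' Disassemble an over-merged linkage group using reference evidence
#'
#' Reassigns each locus of a suspect group using, in order of precedence:
#' (1) the linkage group on the other parent's map that carries a locus of
#' the same marker; (2) the reference chromosome of the marker's best
#' homolog hit, translated to partner-map groups by majority vote over
#' loci carrying both kinds of evidence; (3) highest mean LOD linkage to
#' the already-labelled subgroups.  Each subgroup is then re-validated by
#' LOD-threshold grouping.
#'
#' @param suspect_ids locus ids of the suspect group.
#' @param loci_meta data.frame with columns `locus_id`, `marker_id` for at
#'   least the suspect loci.
#' @param partner_map data.frame with columns `locus_id`, `marker_id`,
#'   `group` describing the other parent's map (may be NULL).
#' @param hits data.frame with columns `marker_id`, `chromosome` of
#'   best homolog hits (may be NULL).
#' @param ps [pair_stats] covering the suspect loci.
#' @param lod_min LOD threshold for re-validation (default 10).
#' @param rec_max maximum recombination fraction for re-validation edges.
#' @return list with `subgroups` (named list of locus-id vectors),
#'   `evidence` (per-locus data.frame with the assignment and its source),
#'   `unresolved` (locus ids with no evidence), and `validation`
#'   (per-subgroup number of LOD-connected components).
#' @export
disassemble <- function(suspect_ids, loci_meta, partner_map = NULL,
                        hits = NULL, ps, lod_min = 10, rec_max = 0.4) {
  meta <- loci_meta[match(suspect_ids, loci_meta$locus_id), , drop = FALSE]
  if (anyNA(meta$locus_id)) stop_cm("loci_meta is missing some suspect loci")

  partner_grp <- rep(NA_character_, length(suspect_ids))
  if (!is.null(partner_map) && nrow(partner_map) > 0) {
    ## marker-level evidence: majority partner group of the marker's loci
    pg <- tapply(as.character(partner_map$group), partner_map$marker_id,
                 function(g) names(sort(table(g), decreasing = TRUE))[1])
    partner_grp <- unname(pg[meta$marker_id])
    ## locus-level evidence is stronger: a bi-parental bridge locus maps
    ## on the partner map itself (matched through base_id when present)
    if ("base_id" %in% names(meta) && "base_id" %in% names(partner_map)) {
      j <- match(meta$base_id, partner_map$base_id)
      partner_grp <- ifelse(is.na(j), partner_grp,
                            as.character(partner_map$group)[j])
    }
  }
  ref_chr <- rep(NA_character_, length(suspect_ids))
  if (!is.null(hits) && nrow(hits) > 0) {
    hc <- tapply(as.character(hits$chromosome), hits$marker_id,
                 function(x) x[1])
    ref_chr <- unname(hc[meta$marker_id])
  }
  if (all(is.na(partner_grp)) && all(is.na(ref_chr))) {
    stop_cm("cannot disassemble without reference information")
  }

  assigned <- partner_grp
  source <- ifelse(!is.na(partner_grp), "partner_map", NA_character_)
  conflicts <- which(!is.na(partner_grp) & !is.na(ref_chr))

  ## chromosome -> partner-group dictionary by majority vote
  both <- !is.na(partner_grp) & !is.na(ref_chr)
  chr2grp <- character(0)
  if (any(both)) {
    chr2grp <- tapply(partner_grp[both], ref_chr[both],
                      function(g) names(sort(table(g), decreasing = TRUE))[1])
  }
  need_chr <- is.na(assigned) & !is.na(ref_chr)
  mapped <- unname(chr2grp[ref_chr[need_chr]])
  lab <- ifelse(is.na(mapped), paste0("chr:", ref_chr[need_chr]), mapped)
  assigned[need_chr] <- lab
  source[need_chr] <- "reference_hit"

  ## linkage rescue for the rest
  idx <- match(suspect_ids, ps$ids)
  lodm <- ps$lod[idx, idx, drop = FALSE]
  lodm[is.na(lodm)] <- 0
  rest <- which(is.na(assigned))
  labs <- unique(assigned[!is.na(assigned)])
  unresolved <- character(0)
  for (i in rest) {
    means <- vapply(labs, function(g) {
      mean(lodm[i, which(assigned == g)])
    }, 0)
    if (length(means) > 0 && max(means) > 0) {
      assigned[i] <- labs[which.max(means)]
      source[i] <- "linkage"
    } else {
      unresolved <- c(unresolved, suspect_ids[i])
      source[i] <- "unresolved"
    }
  }

  ok <- !is.na(assigned)
  subgroups <- split(suspect_ids[ok], assigned[ok])
  validation <- vapply(subgroups, function(g) {
    if (length(g) < 2) return(1L)
    length(group_loci(ps, lod_min = lod_min, rec_max = rec_max,
                      ids = g)$groups)
  }, 1L)
  evidence <- data.frame(locus_id = suspect_ids,
                         marker_id = meta$marker_id,
                         partner_group = partner_grp,
                         ref_chromosome = ref_chr,
                         assigned = assigned,
                         source = source,
                         conflict = seq_along(suspect_ids) %in% conflicts &
                           !is.na(partner_grp) & !is.na(ref_chr),
                         stringsAsFactors = FALSE)
  list(subgroups = subgroups, evidence = evidence,
       unresolved = unresolved, validation = validation)
}
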