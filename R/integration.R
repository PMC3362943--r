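#' Assemble a genetic map data.frame from ordered linkage groups
#'
#' @param groups list of `linkage_group` objects (see [order_group]).
#' @param phased a `phased_set` (see [split_parental]) supplying locus
#'   metadata.
#' @return data.frame of class `genetic_map`: `group`, `locus_id`,
#'   `base_id`, `marker_id`, `position_cm`, `seg_class`, `distorted`.
#' @export
assemble_map <- function(groups, phased) {
  df <- do.call(rbind, lapply(groups, function(lg) {
    data.frame(group = lg$group_id, locus_id = lg$locus_ids,
               position_cm = lg$pos_cm, stringsAsFactors = FALSE)
  }))
  i <- match(df$locus_id, phased$loci$locus_id)
  df$base_id <- phased$loci$base_id[i]
  df$marker_id <- phased$loci$marker_id[i]
  df$seg_class <- phased$loci$seg_class[i]
  df$band_count <- phased$loci$band_count[i]
  df$distorted <- phased$loci$distorted[i]
  class(df) <- c("genetic_map", "data.frame")
  df
}

## piecewise-linear transform through (x_anchor, y_anchor), linear slope-1
## extension beyond the terminal anchors
pwl_transform <- function(x, xa, ya) {
  o <- order(xa)
  xa <- xa[o]; ya <- cummax(ya[o])          # enforce monotone consensus
  ## collapse duplicated anchor x
  keep <- !duplicated(xa)
  xa <- xa[keep]; ya <- ya[keep]
  if (length(xa) == 1) return(x - xa + ya)
  y <- stats::approx(xa, ya, xout = x, rule = 1)$y
  lo <- x < xa[1]; hi <- x > xa[length(xa)]
  y[lo] <- ya[1] + (x[lo] - xa[1])
  y[hi] <- ya[length(ya)] + (x[hi] - xa[length(xa)])
  y
}

#' Integrate two parental-specific maps through shared bi-parental loci
#'
#' Group correspondence is established from shared bi-parental locus
#' `base_id`s (greedy, by descending shared-anchor count).  When a group
#' pair shares at least `min_anchors` anchors, each parental scale is
#' rescaled by monotone piecewise-linear interpolation through the mean
#' anchor positions (after orienting the second map: it is flipped when
#' anchor positions correlate negatively), non-anchor loci are placed at
#' their transformed positions, and anchor-order conflicts between the
#' parents are resolved by the (weighted) mean position.  Group pairs
#' with fewer shared anchors are not integrated; they carry the fallback
#' statistics `n = n1 + n2 - n_shared` and
#' `length = mean(length1, length2)`.  Groups with no correspondent are
#' passed through unchanged with a warning.
#'
#' @param map1,map2 `genetic_map` data.frames (see [assemble_map]) for
#'   parents P1 and P2.
#' @param min_anchors minimum shared bi-parental loci for true
#'   integration (default 3).
#' @return object of class `integrated_map`: list with `map` (combined
#'   data.frame; fallback groups have `NA` positions) and `meta`
#'   (per-group data.frame: `group`, `group2`, `n_anchors`, `integrated`,
#'   `fallback`, `n_loci`, `length_cm`).
#' @export
integrate_maps <- function(map1, map2, min_anchors = 3) {
  bi1 <- map1[map1$seg_class == "biparental", , drop = FALSE]
  bi2 <- map2[map2$seg_class == "biparental", , drop = FALSE]
  shared <- intersect(bi1$base_id, bi2$base_id)
  tab <- table(bi1$group[match(shared, bi1$base_id)],
               bi2$group[match(shared, bi2$base_id)])

  ## greedy 1-1 correspondence by shared-anchor count
  corr <- data.frame(group1 = character(0), group2 = character(0),
                     n_anchors = integer(0), stringsAsFactors = FALSE)
  if (length(tab) > 0) {
    tt <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(tt) <- c("group1", "group2", "n")
    tt <- tt[tt$n > 0, , drop = FALSE]
    tt <- tt[order(-tt$n, tt$group1, tt$group2), , drop = FALSE]
    for (i in seq_len(nrow(tt))) {
      if (tt$group1[i] %in% corr$group1 || tt$group2[i] %in% corr$group2)
        next
      corr <- rbind(corr, data.frame(group1 = tt$group1[i],
                                     group2 = tt$group2[i],
                                     n_anchors = tt$n[i]))
    }
  }

  out_rows <- list()
  meta <- list()
  glen <- function(m, g) {
    p <- m$position_cm[m$group == g]
    if (length(p) == 0) 0 else max(p)
  }
  for (g1 in unique(map1$group)) {
    m1 <- map1[map1$group == g1, , drop = FALSE]
    ci <- match(g1, corr$group1)
    if (is.na(ci)) {
      warn_cm("group %s has no corresponding group on the other map; passed through", g1)
      m1$origin <- ifelse(m1$seg_class == "biparental", "biparental", "P1")
      out_rows[[g1]] <- m1
      meta[[g1]] <- data.frame(group = g1, group2 = NA_character_,
                               n_anchors = 0L, integrated = FALSE,
                               fallback = FALSE, n_loci = nrow(m1),
                               length_cm = glen(map1, g1))
      next
    }
    g2 <- corr$group2[ci]
    m2 <- map2[map2$group == g2, , drop = FALSE]
    anchors <- intersect(m1$base_id[m1$seg_class == "biparental"],
                         m2$base_id[m2$seg_class == "biparental"])
    a1 <- m1$position_cm[match(anchors, m1$base_id)]
    a2 <- m2$position_cm[match(anchors, m2$base_id)]
    if (length(anchors) >= 2 && stats::cor(a1, a2) < 0) {
      m2$position_cm <- max(m2$position_cm) - m2$position_cm
      a2 <- m2$position_cm[match(anchors, m2$base_id)]
    }
    if (length(anchors) >= min_anchors) {
      cons <- (a1 + a2) / 2
      p1 <- pwl_transform(m1$position_cm, a1, cons)
      p2 <- pwl_transform(m2$position_cm, a2, cons)
      m1$position_cm <- p1
      m2$position_cm <- p2
      ## anchors appear once, at the mean of their transformed positions
      am1 <- match(anchors, m1$base_id)
      am2 <- match(anchors, m2$base_id)
      m1$position_cm[am1] <- (p1[am1] + p2[am2]) / 2
      m2 <- m2[-am2, , drop = FALSE]
      m1$origin <- ifelse(m1$seg_class == "biparental", "biparental", "P1")
      m2$origin <- ifelse(m2$seg_class == "biparental", "biparental", "P2")
      comb <- rbind(m1, m2)
      comb$group <- g1
      comb <- comb[order(comb$position_cm, comb$locus_id), , drop = FALSE]
      comb$position_cm <- comb$position_cm - min(comb$position_cm)
      out_rows[[g1]] <- comb
      meta[[g1]] <- data.frame(group = g1, group2 = g2,
                               n_anchors = length(anchors),
                               integrated = TRUE, fallback = FALSE,
                               n_loci = nrow(comb),
                               length_cm = max(comb$position_cm))
    } else {
      ## fallback: not integrated
      m1$origin <- ifelse(m1$seg_class == "biparental", "biparental", "P1")
      m2$origin <- ifelse(m2$seg_class == "biparental", "biparental", "P2")
      m2 <- m2[!(m2$base_id %in% anchors), , drop = FALSE]
      comb <- rbind(m1, m2)
      comb$group <- g1
      comb$position_cm <- NA_real_
      out_rows[[g1]] <- comb
      meta[[g1]] <- data.frame(group = g1, group2 = g2,
                               n_anchors = length(anchors),
                               integrated = FALSE, fallback = TRUE,
                               n_loci = nrow(m1) + nrow(m2),
                               length_cm = mean(c(glen(map1, g1),
                                                  glen(map2, g2))))
    }
  }
  map <- do.call(rbind, out_rows)
  rownames(map) <- NULL
  structure(list(map = map, meta = do.call(rbind, meta),
                 correspondence = corr),
            class = "integrated_map")
}

#' @export
print.integrated_map <- function(x, ...) {
  cat(sprintf("integrated_map: %d loci on %d groups (%d integrated, %d fallback)\n",
              nrow(x$map), nrow(x$meta), sum(x$meta$integrated),
              sum(x$meta$fallback)))
  invisible(x)
}

#' Per-group and total map statistics
#'
#' Number of loci, map length, locus density (`length / n`, the average
#' spacing between loci), segregation distortion percentage, and the
#' largest gap between adjacent loci.  Totals sum lengths and locus
#' counts; total density and distortion are count-weighted.  For
#' non-integrated fallback groups the supplied `meta` length/count are
#' used and no gap is reported.
#'
#' @param map a `genetic_map` data.frame or an `integrated_map`.
#' @param meta optional per-group meta data.frame (from
#'   [integrate_maps]); taken automatically from an `integrated_map`.
#' @return list with `per_group` (data.frame) and `total` (one-row
#'   data.frame), plus `largest_gap` (list: group, locus pair, cM).
#' @export
map_stats <- function(map, meta = NULL) {
  if (inherits(map, "integrated_map")) {
    meta <- map$meta
    map <- map$map
  }
  per <- do.call(rbind, lapply(unique(map$group), function(g) {
    sub <- map[map$group == g, , drop = FALSE]
    mrow <- if (!is.null(meta)) meta[meta$group == g, , drop = FALSE] else
      NULL
    fallback <- !is.null(mrow) && nrow(mrow) == 1 && isTRUE(mrow$fallback)
    if (fallback) {
      n <- mrow$n_loci
      len <- mrow$length_cm
      gap <- NA_real_; gap_pair <- NA_character_
    } else {
      sub <- sub[order(sub$position_cm), , drop = FALSE]
      n <- nrow(sub)
      len <- if (n > 0) max(sub$position_cm) else 0
      if (n > 1) {
        d <- diff(sub$position_cm)
        j <- which.max(d)
        gap <- d[j]
        gap_pair <- paste(sub$locus_id[j], sub$locus_id[j + 1], sep = "~")
      } else {
        gap <- NA_real_; gap_pair <- NA_character_
      }
    }
    dist_pct <- 100 * mean(sub$distorted, na.rm = TRUE)
    data.frame(group = g, n_loci = n, length_cm = len,
               density = if (n > 0) len / n else NA_real_,
               distortion_pct = dist_pct, largest_gap_cm = gap,
               largest_gap_pair = gap_pair, stringsAsFactors = FALSE)
  }))
  n_tot <- sum(per$n_loci)
  len_tot <- sum(per$length_cm)
  dist_tot <- 100 * mean(map$distorted, na.rm = TRUE)
  total <- data.frame(group = "Total", n_loci = n_tot, length_cm = len_tot,
                      density = if (n_tot > 0) len_tot / n_tot else NA_real_,
                      distortion_pct = dist_tot, stringsAsFactors = FALSE)
  gi <- which.max(per$largest_gap_cm)
  largest_gap <- if (length(gi) == 1 && !all(is.na(per$largest_gap_cm))) {
    list(group = per$group[gi], pair = per$largest_gap_pair[gi],
         cm = per$largest_gap_cm[gi])
  } else NULL
  list(per_group = per, total = total, largest_gap = largest_gap)
}

#' Classify multi-locus markers (Type I / Type II; same / homeologous /
#' other placement)
#'
#' Type I markers produce multiple loci through multiple observed bands
#' (`band_count > 1`).  Type II markers are bi-parental markers whose P1
#' and P2 placements fall on non-corresponding linkage groups.  For
#' markers with several mapped loci, the location class is `same` when
#' all loci share one group, `homeologous` when they span exactly one
#' homeologous pair, `other` otherwise.
#'
#' @param map combined map data.frame with `locus_id`, `marker_id`,
#'   `group`, `band_count` (joined in if absent), `seg_class`.
#' @param map1,map2 parental maps (for the Type II check), may be NULL.
#' @param correspondence data.frame `group1`, `group2` from
#'   [integrate_maps] (for Type II), may be NULL.
#' @param pairing data.frame `group_a`, `group_b` of homeologous pairs
#'   (e.g. from [infer_homeologs]), may be NULL.
#' @return data.frame per marker: `marker_id`, `n_loci`, `type1`,
#'   `type2`, `location`.
#' @export
classify_multilocus <- function(map, map1 = NULL, map2 = NULL,
                                correspondence = NULL, pairing = NULL) {
  homeo_key <- character(0)
  if (!is.null(pairing) && nrow(pairing) > 0) {
    homeo_key <- c(paste(pairing$group_a, pairing$group_b),
                   paste(pairing$group_b, pairing$group_a))
  }
  res <- lapply(split(seq_len(nrow(map)), map$marker_id), function(ii) {
    sub <- map[ii, , drop = FALSE]
    groups <- unique(sub$group)
    type1 <- any(sub$band_count > 1, na.rm = TRUE)
    type2 <- FALSE
    if (!is.null(map1) && !is.null(map2) && !is.null(correspondence)) {
      bib <- unique(sub$base_id[sub$seg_class == "biparental"])
      for (b in bib) {
        g1 <- map1$group[match(b, map1$base_id)]
        g2 <- map2$group[match(b, map2$base_id)]
        if (!is.na(g1) && !is.na(g2)) {
          expect2 <- correspondence$group2[match(g1, correspondence$group1)]
          if (!is.na(expect2) && expect2 != g2) type2 <- TRUE
        }
      }
    }
    location <- if (length(groups) == 1) {
      if (nrow(sub) > 1) "same" else "single"
    } else if (length(groups) == 2 &&
               paste(groups[1], groups[2]) %in% homeo_key) {
      "homeologous"
    } else {
      "other"
    }
    data.frame(marker_id = sub$marker_id[1], n_loci = nrow(sub),
               type1 = type1, type2 = type2, location = location,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Infer homeologous group pairing from multi-locus marker names
#'
#' Counts, for every pair of linkage groups, the markers with loci on
#' both, and greedily builds a maximum-weight perfect matching (largest
#' shared-marker counts first; ties broken lexicographically).
#'
#' @param map map data.frame with `marker_id` and `group`.
#' @return data.frame `group_a`, `group_b`, `shared_markers`; empty (with
#'   a warning) when no marker spans two groups.
#' @export
infer_homeologs <- function(map) {
  cnt <- list()
  for (m in unique(map$marker_id)) {
    g <- sort(unique(map$group[map$marker_id == m]))
    if (length(g) < 2) next
    for (i in seq_len(length(g) - 1)) {
      for (j in (i + 1):length(g)) {
        key <- paste(g[i], g[j], sep = "\t")
        cnt[[key]] <- (cnt[[key]] %||% 0L) + 1L
      }
    }
  }
  if (length(cnt) == 0) {
    warn_cm("no multi-locus markers; homeolog pairing is empty")
    return(data.frame(group_a = character(0), group_b = character(0),
                      shared_markers = integer(0)))
  }
  df <- data.frame(do.call(rbind, strsplit(names(cnt), "\t")),
                   shared_markers = unlist(cnt), stringsAsFactors = FALSE)
  names(df)[1:2] <- c("group_a", "group_b")
  df <- df[order(-df$shared_markers, df$group_a, df$group_b), , drop = FALSE]
  used <- character(0)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (df$group_a[i] %in% used || df$group_b[i] %in% used) next
    keep[i] <- TRUE
    used <- c(used, df$group_a[i], df$group_b[i])
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
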