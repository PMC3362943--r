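#' Grid-sample loci along a genetic map
#'
#' For every grid point 0, `step_cm`, 2*`step_cm`, ... along each linkage
#' group, picks the nearest locus not already chosen (deterministic:
#' ties go to the smaller position, then the lexicographically smaller
#' locus id), approximating "one locus about every `step_cm` cM".
#'
#' @param map `genetic_map` data.frame (`group`, `locus_id`,
#'   `position_cm`).
#' @param step_cm grid step in cM (default 5).
#' @return character vector of selected locus ids.
#' @export
sample_grid <- function(map, step_cm = 5) {
  unlist(lapply(unique(map$group), function(g) {
    sub <- map[map$group == g & !is.na(map$position_cm), , drop = FALSE]
    if (nrow(sub) == 0) return(character(0))
    sub <- sub[order(sub$position_cm, sub$locus_id), , drop = FALSE]
    pts <- seq(0, max(sub$position_cm), by = step_cm)
    chosen <- character(0)
    for (p in pts) {
      free <- !(sub$locus_id %in% chosen)
      if (!any(free)) break
      d <- abs(sub$position_cm - p)
      d[!free] <- Inf
      chosen <- c(chosen, sub$locus_id[which.min(d)])
    }
    chosen
  }), use.names = FALSE)
}

#' Gametic r-squared between two phased loci
#'
#' Over the progeny informative at both loci, with haplotype counts
#' `f11, f10, f01, f00` and allele margins, `r2 = (f11*f00 - f10*f01)^2 /
#' (p1*p0*q1*q0)` -- the squared Pearson correlation of the 0/1 allele
#' codes, invariant to a/b relabelling of either locus.  Undefined
#' (returned `NA`) when either locus is monomorphic among the shared
#' informative progeny.
#'
#' @param x,y integer call vectors (1/0/NA) of equal length.
#' @return list with `r2`, `n` (informative progeny).
#' @export
r_squared <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  f11 <- sum(x == 1 & y == 1); f10 <- sum(x == 1 & y == 0)
  f01 <- sum(x == 0 & y == 1); f00 <- sum(x == 0 & y == 0)
  p1 <- f11 + f10; p0 <- f01 + f00
  q1 <- f11 + f01; q0 <- f10 + f00
  if (p1 == 0 || p0 == 0 || q1 == 0 || q0 == 0) {
    return(list(r2 = NA_real_, n = n))
  }
  list(r2 = (f11 * f00 - f10 * f01)^2 / (p1 * p0 * q1 * q0), n = n)
}

## all-pairs r2 over a call matrix (loci x progeny), via joint counts
r2_matrix <- function(calls) {
  A <- (calls == 1); A[is.na(A)] <- FALSE; A <- A * 1
  B <- (calls == 0); B[is.na(B)] <- FALSE; B <- B * 1
  f11 <- tcrossprod(A); f00 <- tcrossprod(B)
  f10 <- tcrossprod(A, B); f01 <- t(f10)
  p1 <- f11 + f10; p0 <- f01 + f00
  q1 <- f11 + f01; q0 <- f10 + f00
  denom <- p1 * p0 * q1 * q0
  r2 <- (f11 * f00 - f10 * f01)^2 / ifelse(denom > 0, denom, NA_real_)
  list(r2 = r2, n = f11 + f10 + f01 + f00)
}

#' Scan a parental map for linkage disequilibrium within and across
#' linkage groups
#'
#' Grid-samples loci (about every `step_cm` cM), computes gametic
#' r-squared for every sampled pair, lists cross-group pairs exceeding
#' `r2_min`, and summarizes `step_cm`-sized map bins by their number of
#' high-LD cross-group partners.  Pairs with fewer than `n_min` jointly
#' informative progeny are skipped.
#'
#' @param map `genetic_map` data.frame for one parent.
#' @param phased matching `phased_set` (for the call vectors).
#' @param step_cm sampling grid in cM (default 5).
#' @param r2_min threshold for reporting cross-group LD (default 0.5).
#' @param n_min minimum informative progeny per pair (default 30).
#' @return object of class `ld_scan`: list with `pairs` (all sampled
#'   pairs: `locus_i`, `locus_j`, `group_i`, `group_j`, `r2`, `n`,
#'   `cross_group`), `cross_hits` (cross-group pairs with
#'   `r2 > r2_min`), `regions` (per-group bins with cross-group partner
#'   counts, high-LD bins first), `matrix` (r2 matrix of sampled loci in
#'   map order) and `sampled` (locus ids).
#' @export
ld_scan <- function(map, phased, step_cm = 5, r2_min = 0.5, n_min = 30) {
  sel <- sample_grid(map, step_cm = step_cm)
  sub <- map[match(sel, map$locus_id), , drop = FALSE]
  sub <- sub[order(sub$group, sub$position_cm, sub$locus_id), , drop = FALSE]
  calls <- phased$calls[match(sub$locus_id, rownames(phased$calls)), ,
                        drop = FALSE]
  rs <- r2_matrix(calls)
  r2 <- rs$r2; nm <- rs$n
  k <- nrow(sub)
  ut <- which(upper.tri(r2), arr.ind = TRUE)
  pairs <- data.frame(locus_i = sub$locus_id[ut[, 1]],
                      locus_j = sub$locus_id[ut[, 2]],
                      group_i = sub$group[ut[, 1]],
                      group_j = sub$group[ut[, 2]],
                      pos_i = sub$position_cm[ut[, 1]],
                      pos_j = sub$position_cm[ut[, 2]],
                      r2 = r2[ut], n = nm[ut],
                      stringsAsFactors = FALSE)
  skipped <- pairs$n < n_min
  pairs$r2[skipped] <- NA_real_
  pairs$cross_group <- pairs$group_i != pairs$group_j
  cross_hits <- pairs[pairs$cross_group & !is.na(pairs$r2) &
                        pairs$r2 > r2_min, , drop = FALSE]
  ## regions: per-group bins of step_cm, counting high-LD cross partners
  bins <- list()
  if (nrow(cross_hits) > 0) {
    ends <- rbind(
      data.frame(group = cross_hits$group_i, pos = cross_hits$pos_i),
      data.frame(group = cross_hits$group_j, pos = cross_hits$pos_j))
    ends$bin <- floor(ends$pos / step_cm)
    agg <- stats::aggregate(list(n_partners = rep(1, nrow(ends))),
                            by = list(group = ends$group, bin = ends$bin),
                            FUN = sum)
    agg$start_cm <- agg$bin * step_cm
    agg$end_cm <- (agg$bin + 1) * step_cm
    bins <- agg[order(-agg$n_partners, agg$group, agg$start_cm),
                c("group", "start_cm", "end_cm", "n_partners")]
    rownames(bins) <- NULL
  } else {
    bins <- data.frame(group = character(0), start_cm = numeric(0),
                       end_cm = numeric(0), n_partners = integer(0))
  }
  rownames(r2) <- colnames(r2) <- sub$locus_id
  structure(list(pairs = pairs, cross_hits = cross_hits, regions = bins,
                 matrix = r2, sampled = sub$locus_id,
                 n_skipped = sum(skipped)),
            class = "ld_scan")
}

#' @export
print.ld_scan <- function(x, ...) {
  cat(sprintf("ld_scan: %d sampled loci, %d pairs (%d skipped), %d cross-group pairs above threshold\n",
              length(x$sampled), nrow(x$pairs), x$n_skipped,
              nrow(x$cross_hits)))
  invisible(x)
}

#' Write the sampled r-squared matrix as plain text (for heatmap
#' rendering)
#' @param scan an `ld_scan` object.
#' @param path output path.
#' @export
write_ld_matrix <- function(scan, path) {
  utils::write.table(round(scan$matrix, 6), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
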