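#' Build map-to-genome homolog anchors
#'
#' Filters a hit table at `evalue_max`, keeps the best hit per marker
#' (highest bitscore; ties by smallest E-value then lexicographic
#' reference id), and joins it to the map positions of that marker's
#' loci.  Markers without a passing hit are dropped (count reported via
#' a message-free attribute `n_unanchored`).
#'
#' @param map `genetic_map` data.frame (`marker_id`, `group`,
#'   `position_cm`, `locus_id`).
#' @param hits `hit_table` data.frame; `query_id` is matched against
#'   `marker_id`.
#' @param evalue_max E-value cutoff (default 1e-10).
#' @return data.frame of anchors: `marker_id`, `locus_id`, `group`,
#'   `pos_cm`, `chromosome`, `bp`.
#' @export
build_anchors <- function(map, hits, evalue_max = 1e-10) {
  h <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  h <- best_hits(h)
  i <- match(map$marker_id, h$query_id)
  out <- data.frame(marker_id = map$marker_id, locus_id = map$locus_id,
                    group = map$group, pos_cm = map$position_cm,
                    chromosome = h$chromosome[i],
                    bp = h$start_bp[i], stringsAsFactors = FALSE)
  n_unanchored <- sum(is.na(out$chromosome))
  if (n_unanchored == nrow(out) && nrow(out) > 0) {
    warn_cm("no marker has a passing homolog hit")
  }
  out <- out[!is.na(out$chromosome) & !is.na(out$pos_cm), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unanchored") <- n_unanchored
  out
}

#' Chain anchors into synteny blocks
#'
#' Within each (linkage group, reference chromosome) cell, anchors
#' sorted by map position are chained into maximal runs in which every
#' consecutive pair lies within `map_win_cm` centimorgans on the map AND
#' within `ref_win_kb` kilobases on the chromosome; runs with at least
#' `min_anchors` anchors become synteny blocks.  Block orientation is
#' the sign of the Spearman correlation between cM and bp inside the
#' block (`mixed` when |rho| < 0.5).
#'
#' @param anchors data.frame from [build_anchors].
#' @param min_anchors minimum anchors per block (default 3).
#' @param map_win_cm maximum consecutive-anchor gap on the map
#'   (default 10 cM).
#' @param ref_win_kb maximum consecutive-anchor gap on the reference
#'   (default 500 kb).
#' @return data.frame of blocks: `group`, `start_cm`, `end_cm`,
#'   `chromosome`, `start_bp`, `end_bp`, `n_anchors`, `orientation`,
#'   `anchor_ids` (comma-joined marker ids).
#' @export
chain_blocks <- function(anchors, min_anchors = 3, map_win_cm = 10,
                         ref_win_kb = 500) {
  empty <- data.frame(group = character(0), start_cm = numeric(0),
                      end_cm = numeric(0), chromosome = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_anchors = integer(0), orientation = character(0),
                      anchor_ids = character(0), stringsAsFactors = FALSE)
  if (nrow(anchors) == 0) return(empty)
  out <- list()
  for (key in unique(paste(anchors$group, anchors$chromosome, sep = "\r"))) {
    gc <- strsplit(key, "\r")[[1]]
    sub <- anchors[anchors$group == gc[1] & anchors$chromosome == gc[2], ,
                   drop = FALSE]
    sub <- sub[order(sub$pos_cm, sub$bp, sub$marker_id), , drop = FALSE]
    if (nrow(sub) == 0) next
    brk <- c(FALSE, diff(sub$pos_cm) > map_win_cm |
               abs(diff(sub$bp)) > ref_win_kb * 1000)
    run <- cumsum(brk)
    for (r in unique(run)) {
      blk <- sub[run == r, , drop = FALSE]
      if (nrow(blk) < min_anchors) next
      rho <- suppressWarnings(stats::cor(blk$pos_cm, blk$bp,
                                         method = "spearman"))
      orientation <- if (is.na(rho) || abs(rho) < 0.5) "mixed" else
        if (rho > 0) "+" else "-"
      out[[length(out) + 1]] <-
        data.frame(group = gc[1], start_cm = min(blk$pos_cm),
                   end_cm = max(blk$pos_cm), chromosome = gc[2],
                   start_bp = min(blk$bp), end_bp = max(blk$bp),
                   n_anchors = nrow(blk), orientation = orientation,
                   anchor_ids = paste(blk$marker_id, collapse = ","),
                   stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  out <- do.call(rbind, out)
  out <- out[order(out$group, out$chromosome, out$start_cm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map-to-chromosome colinearity summary
#'
#' Per linkage group: anchor counts per reference chromosome, the
#' percentage of the group's mapped loci anchored to the dominant
#' chromosome, and the cM / bp coverage of its synteny blocks.
#'
#' @param anchors data.frame from [build_anchors].
#' @param blocks data.frame from [chain_blocks].
#' @param map optional map data.frame to supply total mapped-locus
#'   counts per group (defaults to anchor counts).
#' @return data.frame per group: `group`, `n_loci`, `n_anchors`,
#'   `dominant_chromosome`, `n_dominant`, `pct_dominant`,
#'   `block_cov_cm`, `block_cov_bp`.
#' @export
colinearity_summary <- function(anchors, blocks, map = NULL) {
  groups <- if (!is.null(map)) unique(map$group) else unique(anchors$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- anchors[anchors$group == g, , drop = FALSE]
    n_loci <- if (!is.null(map)) sum(map$group == g) else nrow(sub)
    if (nrow(sub) == 0) {
      return(data.frame(group = g, n_loci = n_loci, n_anchors = 0L,
                        dominant_chromosome = NA_character_,
                        n_dominant = 0L, pct_dominant = 0,
                        block_cov_cm = 0, block_cov_bp = 0,
                        stringsAsFactors = FALSE))
    }
    tab <- sort(table(sub$chromosome), decreasing = TRUE)
    bl <- blocks[blocks$group == g, , drop = FALSE]
    data.frame(group = g, n_loci = n_loci, n_anchors = nrow(sub),
               dominant_chromosome = names(tab)[1],
               n_dominant = as.integer(tab[1]),
               pct_dominant = round_half_up(100 * tab[1] / n_loci, 0),
               block_cov_cm = sum(bl$end_cm - bl$start_cm),
               block_cov_bp = sum(bl$end_bp - bl$start_bp),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
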