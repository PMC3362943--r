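BASES <- c("A", "C", "G", "T")

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(s, NULL), function(x) paste(rev(x), collapse = ""), ""))
}

rotations <- function(unit) {
  u <- nchar(unit)
  vapply(seq_len(u), function(i) {
    paste0(substr(unit, i, u), substr(unit, 1, i - 1))
  }, "")
}

#' Canonical SSR motif class
#'
#' The canonical class of a repeat unit is the lexicographically smallest
#' string among all rotations of the unit and all rotations of its
#' reverse complement, so that e.g. GA, TC, CT and AG all collapse to the
#' class "AG".  This is the strand- and phase-collapsed labelling used in
#' published SSR frequency tables.
#'
#' @param unit character vector of repeat units (over ACGT).
#' @return character vector of canonical motifs.
#' @export
canonical_motif <- function(unit) {
  vapply(unit, function(w) {
    min(c(rotations(w), rotations(revcomp_chr(w))))
  }, "", USE.NAMES = FALSE)
}

#' Is a repeat unit primitive (not a repetition of a shorter unit)?
#' @param unit character vector of units.
#' @return logical vector.
#' @export
is_primitive_unit <- function(unit) {
  vapply(unit, function(w) {
    u <- nchar(w)
    for (d in seq_len(u - 1)) {
      if (u %% d == 0 &&
          w == paste(rep(substr(w, 1, d), u / d), collapse = "")) {
        return(FALSE)
      }
    }
    TRUE
  }, TRUE, USE.NAMES = FALSE)
}

## all maximal windows for one unit template aligned at sequence phase 1:
## windows [i, e] with M[i]=M[e]=0, <= k mismatches, length >= min_len
unit_windows <- function(M, k, min_len) {
  L <- length(M)
  match_pos <- which(!M)
  if (length(match_pos) == 0) return(NULL)
  q <- which(M)
  i <- match_pos
  if (length(q) == 0) {
    f <- rep(L, length(i))
  } else {
    nbefore <- findInterval(i - 1L, q)       # mismatches strictly before i
    lim <- nbefore + k + 1L                  # index of the (k+1)-th mismatch
    f <- ifelse(lim > length(q), L, q[pmin(lim, length(q))] - 1L)
  }
  e <- match_pos[findInterval(f, match_pos)]
  len <- e - i + 1L
  keep <- len >= min_len
  if (!any(keep)) return(NULL)
  i <- i[keep]; e <- e[keep]
  first <- !duplicated(e)                    # smallest start per reach
  i <- i[first]; e <- e[first]
  P <- cumsum(M)
  mism <- P[e] - ifelse(i > 1, P[i - 1], 0)
  data.frame(start = i, end = e, n_mismatches = mism)
}

## candidate repeat units actually present in the sequence: any valid
## tract of length >= min_len with <= k mismatches contains a perfect
## segment of length >= ceil((min_len - k) / (k + 1)), i.e. a run of
## u-periodicity; harvest units from those runs
candidate_units <- function(si, s_chr, u, min_len, k) {
  L <- length(si)
  if (L < u + 1) return(character(0))
  minseg <- ceiling((min_len - k) / (k + 1))
  need <- max(1L, minseg - u)
  P <- si[seq_len(L - u)] == si[(u + 1):L] & si[seq_len(L - u)] > 0
  if (need > 1) {
    run <- stats::filter(as.numeric(P), rep(1, need), sides = 1)
    starts <- which(!is.na(run) & run == need) - need + 1L
  } else {
    starts <- which(P)
  }
  starts <- starts[starts + u - 1 <= L]
  if (length(starts) == 0) return(character(0))
  units <- unique(substring(s_chr, starts, starts + u - 1L))
  units <- units[!grepl("[^ACGT]", units)]
  units <- unique(unlist(lapply(units, rotations)))
  units[is_primitive_unit(units)]
}

#' Find SSR tracts, allowing mismatches
#'
#' Scans a nucleotide sequence for maximal tracts of length at least
#' `min_len` whose Hamming distance to some phase of a primitive di-,
#' tri-, or tetra-nucleotide repeat is at most `max_mismatch` (no
#' indels).  Tracts must start and end on a base matching the repeat
#' template; `N` never matches.  Overlapping candidates are resolved
#' greedily: the longest tract wins, ties go to fewer mismatches, then to
#' the leftmost start.  Each reported hit carries the minimal mismatch
#' count over all unit/phase alignments achieving its interval, and the
#' strand/phase-collapsed [canonical_motif] class.
#'
#' @param sequence a single character string over A/C/G/T/N.
#' @param min_len minimum tract length in nt (default 15).
#' @param max_mismatch maximum number of mismatched bases (0, 1 or 2).
#' @param seq_id identifier stored in the output.
#' @return data.frame with columns `seq_id`, `start`, `end` (1-based
#'   inclusive), `unit_len`, `canonical_motif`, `tract_len`,
#'   `n_mismatches`, ordered by `start`.
#' @export
find_ssrs <- function(sequence, min_len = 15, max_mismatch = 0,
                      seq_id = "seq") {
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), unit_len = integer(0),
                      canonical_motif = character(0), tract_len = integer(0),
                      n_mismatches = integer(0), stringsAsFactors = FALSE)
  s <- toupper(sequence)
  L <- nchar(s)
  if (L < min_len) return(empty)
  si <- match(strsplit(s, NULL)[[1]], BASES)
  si[is.na(si)] <- 0L
  cand <- list()
  for (u in 2:4) {
    units <- candidate_units(si, s, u, min_len, max_mismatch)
    for (w in units) {
      wi <- match(strsplit(w, NULL)[[1]], BASES)
      tmpl <- wi[((seq_len(L) - 1L) %% u) + 1L]
      M <- si != tmpl | si == 0L
      ## windows maximal at every mismatch budget up to the cap, so a
      ## perfect core nested in a mismatch-extended window stays
      ## available if the larger window loses the overlap resolution
      for (k in 0:max_mismatch) {
        win <- unit_windows(M, k, min_len)
        if (is.null(win)) next
        win$unit_len <- u
        win$canonical_motif <- canonical_motif(w)
        cand[[length(cand) + 1L]] <- win
      }
    }
  }
  if (length(cand) == 0) return(empty)
  cand <- do.call(rbind, cand)
  ## same interval reachable via several units: keep minimal mismatches,
  ## tie-broken by lexicographic motif
  o <- order(cand$start, cand$end, cand$n_mismatches, cand$canonical_motif)
  cand <- cand[o, , drop = FALSE]
  cand <- cand[!duplicated(cand[c("start", "end")]), , drop = FALSE]
  resolve_overlaps(cand, L, seq_id)
}

## greedy overlap resolution: longest, then fewest mismatches, then leftmost
resolve_overlaps <- function(cand, L, seq_id) {
  cand$tract_len <- cand$end - cand$start + 1L
  o <- order(-cand$tract_len, cand$n_mismatches, cand$start,
             cand$canonical_motif)
  cand <- cand[o, , drop = FALSE]
  covered <- logical(L)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:cand$end[i]
    if (!any(covered[span])) {
      keep[i] <- TRUE
      covered[span] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  data.frame(seq_id = seq_id, start = out$start, end = out$end,
             unit_len = out$unit_len, canonical_motif = out$canonical_motif,
             tract_len = out$tract_len,
             n_mismatches = as.integer(out$n_mismatches),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mine SSRs across a sequence set
#'
#' Applies [find_ssrs] to every sequence of a FASTA file, a
#' `Biostrings::DNAStringSet`, or a named character vector, and
#' optionally annotates marker-design feasibility.
#'
#' @param x FASTA path, `DNAStringSet`, or named character vector.
#' @param min_len,max_mismatch see [find_ssrs].
#' @param flag if TRUE, add the [flag_designable] annotation.
#' @param amplicon,min_flank passed to [flag_designable].
#' @return data.frame of hits across sequences; attribute `total_bases`
#'   holds the summed input length.
#' @export
mine_ssrs <- function(x, min_len = 15, max_mismatch = 0, flag = TRUE,
                      amplicon = c(90, 300), min_flank = 20) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (inherits(x, "DNAStringSet")) {
    seqs <- as.character(x)
  } else {
    seqs <- x
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  hits <- do.call(rbind, lapply(names(seqs), function(id) {
    find_ssrs(seqs[[id]], min_len = min_len, max_mismatch = max_mismatch,
              seq_id = id)
  }))
  if (flag && nrow(hits) > 0) {
    hits <- flag_designable(hits, nchar(seqs), amplicon = amplicon,
                            min_flank = min_flank)
  }
  attr(hits, "total_bases") <- sum(nchar(seqs))
  hits
}

#' Flag SSR tracts on which a marker could be designed
#'
#' A tract is designable when at least `min_flank` non-SSR bases exist on
#' each side within the sequence and some amplicon length `A` with
#' `amplicon[1] <= A <= amplicon[2]` can contain the tract plus both
#' minimal flanks inside the sequence.
#'
#' @param hits data.frame from [find_ssrs]/[mine_ssrs].
#' @param seq_lengths named vector of sequence lengths (names = seq ids).
#' @param amplicon allowed amplified-fragment size range in bp.
#' @param min_flank minimal flank on each side in bp.
#' @return `hits` with a logical `designable` column added.
#' @export
flag_designable <- function(hits, seq_lengths, amplicon = c(90, 300),
                            min_flank = 20) {
  sl <- seq_lengths[hits$seq_id]
  left <- hits$start - 1
  right <- sl - hits$end
  amin <- pmax(hits$tract_len + 2 * min_flank, amplicon[1])
  amax <- pmin(sl, amplicon[2])
  hits$designable <- left >= min_flank & right >= min_flank & amin <= amax
  hits
}

#' Summarize SSR hits into a motif frequency report
#'
#' Builds the per-motif and per-unit-class frequency table: counts,
#' percentages of all identified SSRs, overall density (input bp per
#' SSR), and -- when design information is available -- counts of
#' designable tracts by mismatch class with their within-class and
#' overall shares.  Either raw `hits` or a precomputed `counts` table
#' (columns `motif`, `unit_len`, `n`, and optionally `designed_m0`,
#' `designed_m1`, `designed_m2`) can be supplied.
#'
#' @param hits data.frame from [mine_ssrs] (with `designable` and
#'   `n_mismatches` columns for design counts), or NULL.
#' @param counts precomputed per-motif count table, or NULL.
#' @param total_bases total input length in bp (for density).
#' @return object of class `motif_report`: list with `motifs` (per-motif
#'   table), `classes` (per-unit-length totals), `n_total`, `density_bp`
#'   (NA with `density_defined = FALSE` when there are no hits),
#'   `n_designed_total`.
#' @export
summarize_motifs <- function(hits = NULL, counts = NULL, total_bases = NA) {
  if (is.null(counts)) {
    stopifnot(!is.null(hits))
    if (nrow(hits) == 0) {
      counts <- data.frame(motif = character(0), unit_len = integer(0),
                           n = integer(0), designed_m0 = integer(0),
                           designed_m1 = integer(0), designed_m2 = integer(0))
    } else {
      key <- split(seq_len(nrow(hits)), hits$canonical_motif)
      counts <- data.frame(
        motif = names(key),
        unit_len = vapply(key, function(i) hits$unit_len[i[1]], 1L),
        n = lengths(key), stringsAsFactors = FALSE)
      des <- if ("designable" %in% names(hits)) hits$designable else
        rep(FALSE, nrow(hits))
      for (k in 0:2) {
        counts[[paste0("designed_m", k)]] <- vapply(key, function(i) {
          sum(des[i] & hits$n_mismatches[i] == k, na.rm = TRUE)
        }, 0L)
      }
      rownames(counts) <- NULL
    }
  }
  counts <- as.data.frame(counts, stringsAsFactors = FALSE)
  has_design <- all(c("designed_m0", "designed_m1", "designed_m2") %in%
                      names(counts))
  if (has_design) {
    counts$designed_total <- counts$designed_m0 + counts$designed_m1 +
      counts$designed_m2
  }
  n_total <- sum(counts$n)
  counts$pct <- if (n_total > 0) 100 * counts$n / n_total else
    rep(NA_real_, nrow(counts))
  classes <- do.call(rbind, lapply(sort(unique(counts$unit_len)), function(u) {
    sub <- counts[counts$unit_len == u, , drop = FALSE]
    data.frame(unit_len = u, n = sum(sub$n),
               pct = if (n_total > 0) 100 * sum(sub$n) / n_total else NA_real_,
               designed_n = if (has_design) sum(sub$designed_total) else
                 NA_integer_)
  }))
  n_designed <- if (has_design) sum(counts$designed_total) else NA_integer_
  if (has_design && n_designed > 0) {
    classes$designed_pct <- 100 * classes$designed_n / n_designed
    counts$designed_pct_within_class <- 100 * counts$designed_total /
      classes$designed_n[match(counts$unit_len, classes$unit_len)]
  }
  density <- if (n_total > 0 && !is.na(total_bases)) total_bases / n_total
             else NA_real_
  structure(list(motifs = counts, classes = classes, n_total = n_total,
                 density_bp = density,
                 density_defined = n_total > 0 && !is.na(total_bases),
                 n_designed_total = n_designed,
                 total_bases = total_bases),
            class = "motif_report")
}

#' @export
print.motif_report <- function(x, ...) {
  cat(sprintf("motif_report: %d SSRs", x$n_total))
  if (x$density_defined) {
    cat(sprintf(", one per %.1f kb", x$density_bp / 1000))
  }
  cat("\n")
  cls <- x$classes
  for (i in seq_len(nrow(cls))) {
    cat(sprintf("  %d-mer: %d (%.1f%%)", cls$unit_len[i], cls$n[i],
                round_half_up(cls$pct[i], 1)))
    if (!is.na(cls$designed_n[i])) {
      cat(sprintf(", %d designable", cls$designed_n[i]))
    }
    cat("\n")
  }
  invisible(x)
}
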