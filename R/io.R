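#' Construct a locus-by-progeny genotype table
#'
#' Container for segregation data of a full-sib F1 family scored in the
#' two-way pseudo-testcross design.  Each locus row belongs to a
#' segregation class: `biparental` loci are heterozygous in both parents
#' and carry one call vector per parental meiosis channel (two rows,
#' `parent` P1 and P2); `female` loci segregate only from parent P1 and
#' `male` loci only from parent P2 (one row each).
#'
#' @param progeny_ids character vector of progeny identifiers.
#' @param rows data.frame with columns `locus_id`, `marker_id`,
#'   `seg_class` (one of `biparental`, `female`, `male`), `parent`
#'   (`P1`/`P2`), `band_count` (integer >= 1).
#' @param calls integer matrix (`nrow(rows)` x `length(progeny_ids)`);
#'   1 = allele "a", 0 = allele "b", `NA` = missing.
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(progeny_ids, rows, calls) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  need <- c("locus_id", "marker_id", "seg_class", "parent", "band_count")
  miss <- setdiff(need, names(rows))
  if (length(miss) > 0) stop_cm("rows is missing columns: %s",
                                paste(miss, collapse = ", "))
  if (!all(rows$seg_class %in% c("biparental", "female", "male"))) {
    stop_cm("seg_class must be biparental/female/male")
  }
  if (!all(rows$parent %in% c("P1", "P2"))) stop_cm("parent must be P1 or P2")
  key <- paste(rows$locus_id, rows$parent)
  if (anyDuplicated(key)) {
    stop_cm("duplicate locus id: %s",
            rows$locus_id[duplicated(key)][1])
  }
  for (lid in unique(rows$locus_id)) {
    sub <- rows[rows$locus_id == lid, ]
    cls <- unique(sub$seg_class)
    if (length(cls) != 1) stop_cm("locus %s has inconsistent seg_class", lid)
    expect <- switch(cls, biparental = c("P1", "P2"),
                     female = "P1", male = "P2")
    if (!setequal(sub$parent, expect)) {
      stop_cm("locus %s (%s) must have channel(s) %s", lid, cls,
              paste(expect, collapse = "+"))
    }
  }
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(rows) || ncol(calls) != length(progeny_ids)) {
    stop_cm("calls must be %d x %d", nrow(rows), length(progeny_ids))
  }
  if (!all(calls %in% c(0L, 1L, NA))) stop_cm("calls must be 0/1/NA")
  rownames(calls) <- paste(rows$locus_id, rows$parent, sep = "|")
  structure(list(progeny_ids = as.character(progeny_ids),
                 rows = rows, calls = calls),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d loci (%d call rows) x %d progeny\n",
              length(unique(x$rows$locus_id)), nrow(x$rows),
              length(x$progeny_ids)))
  cat("  seg classes:",
      paste(sprintf("%s=%d", names(tb <- table(
        x$rows$seg_class[!duplicated(x$rows$locus_id)])), tb),
        collapse = ", "), "\n")
  invisible(x)
}

#' Read a genotype table from TSV/CSV
#'
#' Expects a header `locus_id marker_id seg_class parent [band_count]`
#' followed by one column per progeny; calls are `a`, `b`, or a missing
#' symbol.  Tab- and comma-delimited files are auto-detected.
#'
#' @param path file path.
#' @param missing_symbols character vector of symbols normalized to the
#'   missing sentinel (`NA`).
#' @return a [genotype_table].
#' @export
read_genotype_table <- function(path, missing_symbols = c("-", "—", ".",
                                                          "NA", "")) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  meta_cols <- intersect(c("locus_id", "marker_id", "seg_class", "parent",
                           "band_count"), names(df))
  if (!all(c("locus_id", "marker_id", "seg_class", "parent") %in% meta_cols)) {
    stop_cm("genotype table must have locus_id/marker_id/seg_class/parent columns")
  }
  progeny <- setdiff(names(df), meta_cols)
  if (length(progeny) == 0) stop_cm("no progeny columns found")
  rows <- df[meta_cols]
  if (!"band_count" %in% names(rows)) rows$band_count <- 1L
  rows$band_count <- as.integer(rows$band_count)
  key <- paste(rows$locus_id, rows$parent)
  if (anyDuplicated(key)) {
    stop_cm("duplicate locus id: %s", rows$locus_id[duplicated(key)][1])
  }
  raw <- as.matrix(df[progeny])
  calls <- matrix(NA_integer_, nrow(raw), ncol(raw))
  calls[raw == "a"] <- 1L
  calls[raw == "b"] <- 0L
  bad <- matrix(!(raw %in% c("a", "b", missing_symbols)), nrow(raw))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop_cm("unknown call symbol '%s' at locus %s, progeny column '%s'",
            raw[w[1], w[2]], rows$locus_id[w[1]], progeny[w[2]])
  }
  genotype_table(progeny, rows, calls)
}

#' Write a genotype table to TSV
#'
#' @param gt a [genotype_table].
#' @param path output path.
#' @param missing_symbol symbol written for missing calls (default `-`).
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gt, path, missing_symbol = "-") {
  sym <- matrix(missing_symbol, nrow(gt$calls), ncol(gt$calls))
  sym[gt$calls == 1L] <- "a"
  sym[gt$calls == 0L] <- "b"
  colnames(sym) <- gt$progeny_ids
  out <- cbind(gt$rows[c("locus_id", "marker_id", "seg_class", "parent",
                         "band_count")], as.data.frame(sym, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BLAST-tabular homolog hit table
#'
#' Accepts the plain 12-column tabular dialect (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`; the
#' subject id then doubles as the chromosome and `sstart`/`send` give the
#' position) or a 15-column extension with explicit `chromosome start_bp
#' end_bp` appended.  Records with `evalue > evalue_max` are dropped.
#'
#' @param path file path (tab-separated, no header; `#` comments allowed).
#' @param evalue_max E-value cutoff (default `Inf`).
#' @return data.frame of class `hit_table` with columns `query_id`,
#'   `reference_id`, `chromosome`, `start_bp`, `end_bp`, `evalue`,
#'   `bitscore`.
#' @export
read_hit_table <- function(path, evalue_max = Inf) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) {
    out <- data.frame(query_id = character(0), reference_id = character(0),
                      chromosome = character(0), start_bp = integer(0),
                      end_bp = integer(0), evalue = numeric(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("hit_table", "data.frame")
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != 12 & nf < 15)
  if (length(bad) > 0) {
    stop_cm("unparseable hit-table row at line %d (found %d fields)",
            lineno[bad[1]], nf[bad[1]])
  }
  get <- function(i) vapply(parts, `[[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(get(i)))
    if (anyNA(v)) {
      stop_cm("unparseable %s at line %d", what, lineno[which(is.na(v))[1]])
    }
    v
  }
  ext <- nf >= 15
  evalue <- num(11, "evalue")
  bitscore <- num(12, "bitscore")
  sstart <- num(9, "sstart"); send <- num(10, "send")
  chrom <- get(2)
  start_bp <- pmin(sstart, send)
  end_bp <- pmax(sstart, send)
  if (any(ext)) {
    chrom[ext] <- vapply(parts[ext], `[[`, "", 13)
    start_bp[ext] <- as.numeric(vapply(parts[ext], `[[`, "", 14))
    end_bp[ext] <- as.numeric(vapply(parts[ext], `[[`, "", 15))
    if (anyNA(start_bp) || anyNA(end_bp)) {
      stop_cm("unparseable extended coordinates near line %d",
              lineno[which(is.na(start_bp) | is.na(end_bp))[1]])
    }
  }
  out <- data.frame(query_id = get(1), reference_id = get(2),
                    chromosome = chrom, start_bp = as.integer(start_bp),
                    end_bp = as.integer(end_bp), evalue = evalue,
                    bitscore = bitscore, stringsAsFactors = FALSE)
  out <- out[out$evalue <= evalue_max, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Reduce a hit table to one best hit per query
#'
#' Best = maximum bitscore; ties broken by smallest E-value, then by
#' lexicographically smallest reference id.
#'
#' @param hits a `hit_table` data.frame (see [read_hit_table]).
#' @return `hit_table` with one row per `query_id`.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  o <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$reference_id)
  h <- hits[o, , drop = FALSE]
  h <- h[!duplicated(h$query_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Write / read a genetic map as TSV
#'
#' Columns: `group`, `locus_id`, `position_cm`, `seg_class`,
#' `distorted_flag`, plus `marker_id` and `base_id` when available.
#'
#' @param map data.frame with at least `group`, `locus_id`, `position_cm`.
#' @param path file path.
#' @return `path` (write) or the map data.frame (read).
#' @export
write_map <- function(map, path) {
  cols <- intersect(c("group", "locus_id", "position_cm", "seg_class",
                      "distorted_flag", "marker_id", "base_id"), names(map))
  utils::write.table(map[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write synteny links in a Circos-style text format
#'
#' One line per block: `lg start_cm end_cm chrom start_bp end_bp`.
#'
#' @param blocks data.frame of synteny blocks (see [chain_blocks]).
#' @param path file path.
#' @export
write_synteny_links <- function(blocks, path) {
  lines <- sprintf("%s %g %g %s %d %d", blocks$group, blocks$start_cm,
                   blocks$end_cm, blocks$chromosome,
                   as.integer(blocks$start_bp), as.integer(blocks$end_bp))
  writeLines(lines, path)
  invisible(path)
}
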