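#' Split a genotype table into the two parental-specific haploid sets
#'
#' In the two-way pseudo-testcross strategy every heterozygous locus of a
#' parent segregates 1:1 among the F1 progeny, so each parental meiosis
#' can be analysed as a haploid ("HAP1") data set.  Female-specific loci
#' go to the P1 set, male-specific loci to the P2 set, and bi-parental
#' loci contribute one phased locus to EACH set (these shared loci later
#' bridge the two maps during integration: both copies carry the same
#' `base_id`, the P2 copy's `locus_id` is suffixed ".2").
#'
#' Loci with no informative call, or with fewer than
#' `min_informative_frac` of progeny scored, are excluded with a warning.
#'
#' @param gt a [genotype_table].
#' @param min_informative_frac minimum fraction of non-missing progeny
#'   for a channel to enter mapping (default 0.2).
#' @param alpha significance level for the segregation distortion test.
#' @return list with elements `P1` and `P2`, each a `phased_set`: list of
#'   `loci` (data.frame `locus_id`, `base_id`, `marker_id`, `parent`,
#'   `seg_class`, `band_count`, `n_informative`, `chi2`, `p_value`,
#'   `distorted`, `untestable`) and `calls` (loci x progeny matrix).
#' @export
split_parental <- function(gt, min_informative_frac = 0.2, alpha = 0.05) {
  out <- list()
  for (p in c("P1", "P2")) {
    sel <- which(gt$rows$parent == p)
    rows <- gt$rows[sel, , drop = FALSE]
    calls <- gt$calls[sel, , drop = FALSE]
    inf <- rowSums(!is.na(calls))
    drop <- inf < max(1, min_informative_frac * length(gt$progeny_ids))
    if (any(drop)) {
      warn_cm("%s: excluding %d locus/loci with <%d%% informative progeny",
              p, sum(drop), round(100 * min_informative_frac))
      rows <- rows[!drop, , drop = FALSE]
      calls <- calls[!drop, , drop = FALSE]
    }
    base_id <- rows$locus_id
    locus_id <- if (nrow(rows) == 0) character(0) else
      ifelse(rows$seg_class == "biparental" & p == "P2",
             paste0(base_id, ".2"), base_id)
    dist <- test_distortion(calls, alpha = alpha)
    loci <- data.frame(locus_id = locus_id, base_id = base_id,
                       marker_id = rows$marker_id,
                       parent = rep(p, nrow(rows)),
                       seg_class = rows$seg_class,
                       band_count = rows$band_count,
                       n_informative = rowSums(!is.na(calls)),
                       chi2 = dist$chi2, p_value = dist$p,
                       distorted = dist$distorted,
                       untestable = dist$untestable,
                       stringsAsFactors = FALSE)
    rownames(calls) <- locus_id
    out[[p]] <- structure(list(loci = loci, calls = calls,
                               progeny_ids = gt$progeny_ids),
                          class = "phased_set")
  }
  out
}

#' @export
print.phased_set <- function(x, ...) {
  cat(sprintf("phased_set (%s): %d loci x %d progeny, %.1f%% distorted\n",
              x$loci$parent[1] %||% "?", nrow(x$loci),
              length(x$progeny_ids),
              100 * mean(x$loci$distorted, na.rm = TRUE)))
  invisible(x)
}

#' Chi-square test of segregation distortion against 1:1
#'
#' For a testcross locus with `n_a` and `n_b` informative calls the
#' statistic is `(n_a - n_b)^2 / (n_a + n_b)` on 1 df (no continuity
#' correction).  A locus is distorted when `p < alpha`.  Loci with zero
#' informative calls are flagged untestable.
#'
#' @param calls integer vector or matrix (loci x progeny) of 1/0/NA calls.
#' @param alpha significance level (default 0.05).
#' @return list with vectors `chi2`, `p`, `distorted`, `untestable`.
#' @export
test_distortion <- function(calls, alpha = 0.05) {
  if (is.vector(calls)) calls <- matrix(calls, nrow = 1)
  na_ <- rowSums(calls == 1L, na.rm = TRUE)
  nb <- rowSums(calls == 0L, na.rm = TRUE)
  n <- na_ + nb
  untestable <- n == 0
  chi2 <- ifelse(untestable, NA_real_, (na_ - nb)^2 / pmax(n, 1))
  p <- ifelse(untestable, NA_real_,
              stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  list(chi2 = chi2, p = p,
       distorted = ifelse(untestable, NA, p < alpha),
       untestable = untestable)
}

#' Marker polymorphism and mapping summary
#'
#' Per marker source: number screened, number polymorphic, polymorphic
#' ratio (%), and -- when mapped counts are given -- mapped markers,
#' mapped loci, and average loci per marker.  Ratios are rounded half-up
#' to one decimal, matching standard reporting; a source with zero
#' screened markers gets an undefined (NA) ratio.
#'
#' @param screened data.frame with columns `source`, `n_screened`,
#'   `n_polymorphic`, and optionally `n_mapped_markers`, `n_mapped_loci`.
#' @return data.frame with `ratio_pct` and `loci_per_marker` columns
#'   added, plus a `Total` row.
#' @export
summarize_polymorphism <- function(screened) {
  df <- as.data.frame(screened, stringsAsFactors = FALSE)
  tot <- data.frame(source = "Total",
                    n_screened = sum(df$n_screened),
                    n_polymorphic = sum(df$n_polymorphic))
  for (col in c("n_mapped_markers", "n_mapped_loci")) {
    if (col %in% names(df)) tot[[col]] <- sum(df[[col]])
  }
  df <- rbind(df, tot[names(df)])
  df$ratio_pct <- ifelse(df$n_screened > 0,
                         round_half_up(100 * df$n_polymorphic /
                                         df$n_screened, 1), NA_real_)
  if (all(c("n_mapped_markers", "n_mapped_loci") %in% names(df))) {
    df$loci_per_marker <- ifelse(df$n_mapped_markers > 0,
                                 round_half_up(df$n_mapped_loci /
                                                 df$n_mapped_markers, 1),
                                 NA_real_)
  }
  df
}
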