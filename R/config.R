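#' Pipeline configuration
#'
#' Collects every threshold of the mapping pipeline with its published
#' default: LOD grouping threshold 10, maximum recombination fraction 0.4,
#' goodness-of-fit jump 5.0, ordering LOD >= 1.0, LD grid step 5 cM with
#' r-squared threshold 0.5, synteny chaining (>= 3 anchors within 10 cM /
#' 500 kb gaps), SSR minimum tract length 15 nt with amplicons of
#' 90-300 bp, homolog E-value cutoffs (1e-20 nucleotide, 1e-10
#' translated), and the distortion test level alpha = 0.05.
#'
#' @param ... named overrides of any default; unknown names are an error.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    lod_group = 10,
    rec_max = 0.4,
    jump = 5.0,
    lod_order_min = 1.0,
    pair_n_min = 20,
    min_informative_frac = 0.2,
    suspect_flag_fraction = 0.25,
    ld_grid_cm = 5,
    ld_r2_min = 0.5,
    ld_n_min = 30,
    synteny_min_anchors = 3,
    synteny_map_win_cm = 10,
    synteny_ref_win_kb = 500,
    ssr_min_len = 15,
    ssr_max_mismatch = 2,
    amplicon_min = 90,
    amplicon_max = 300,
    min_flank = 20,
    evalue_nucl = 1e-20,
    evalue_prot = 1e-10,
    integrate_min_anchors = 3,
    alpha = 0.05,
    seed = 1L,
    genotype_path = NULL,
    hit_table_path = NULL,
    fasta_path = NULL,
    missing_symbols = c("-", "—", ".", "NA", "")
  )
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0) stop_cm("unknown config fields: %s",
                                 paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips losslessly: `read_config(write_config(cfg, f))` equals
#' `cfg`.
#'
#' @param cfg a [pipeline_config].
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw[!vapply(raw, is.null, TRUE)])
  for (nm in names(raw)) if (is.null(raw[[nm]])) cfg[nm] <- list(NULL)
  cfg
}
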