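#' Build one parental-specific map from a phased locus set
#'
#' Two-point statistics, LOD-threshold grouping, optional reference-
#' guided disassembly of a suspect (over-merged) group, ordering of each
#' group, and assembly into a `genetic_map`.  A group is flagged suspect
#' when it holds more than `suspect_flag_fraction` of all loci AND
#' partner-map or homolog-hit evidence is available to disassemble it.
#'
#' @param phased a `phased_set` from [split_parental].
#' @param cfg a [pipeline_config].
#' @param partner_map optional `genetic_map` of the other parent (used
#'   for disassembly evidence).
#' @param hits optional best-hit table with `marker_id`/`query_id` and
#'   `chromosome` columns (disassembly evidence).
#' @return list with `map` (a `genetic_map`), `groups` (list of
#'   `linkage_group`), `pairstats`, `grouping`, and `disassembly` (NULL
#'   unless a suspect group was disassembled).
#' @export
map_parent <- function(phased, cfg = pipeline_config(), partner_map = NULL,
                       hits = NULL) {
  ps <- pair_stats(phased$calls, n_min = cfg$pair_n_min)
  grp <- group_loci(ps, lod_min = cfg$lod_group, rec_max = cfg$rec_max)
  groups <- grp$groups
  total <- length(ps$ids)
  disres <- NULL
  sizes <- lengths(groups)
  suspect <- which(sizes > cfg$suspect_flag_fraction * total)
  if (length(suspect) > 0 && (!is.null(partner_map) || !is.null(hits))) {
    s <- suspect[1]
    hh <- NULL
    if (!is.null(hits)) {
      hh <- data.frame(marker_id = hits$query_id %||% hits$marker_id,
                       chromosome = hits$chromosome,
                       stringsAsFactors = FALSE)
    }
    disres <- disassemble(groups[[s]], phased$loci, partner_map = partner_map,
                          hits = hh, ps = ps, lod_min = cfg$lod_group,
                          rec_max = cfg$rec_max)
    groups <- c(groups[-s], unname(disres$subgroups))
    groups <- groups[order(-lengths(groups))]
  }
  ordered <- lapply(seq_along(groups), function(i) {
    order_group(groups[[i]], ps, jump = cfg$jump,
                lod_order_min = cfg$lod_order_min, rec_max = cfg$rec_max,
                group_id = sprintf("G%02d", i))
  })
  list(map = assemble_map(ordered, phased), groups = ordered,
       pairstats = ps, grouping = grp, disassembly = disres)
}

log_stage <- function(con, stage, ...) {
  msg <- sprintf(...)
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full mapping pipeline
#'
#' Reads the genotype table named in the configuration, splits it into
#' parental channels, builds both parental maps (with reference-guided
#' disassembly of an over-merged male-parent group when evidence is
#' available), integrates them, computes map statistics, scans both
#' parental maps for within- and cross-group LD, and, when a homolog
#' hit table is configured, builds anchors and synteny blocks.  All
#' outputs are TSV/text files under `outdir`; record counts per stage go
#' to `pipeline.log` (timings are only echoed to the console so reruns
#' with the same seed and config are byte-identical).
#'
#' @param cfg a [pipeline_config]; `genotype_path` must be set.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(cfg, outdir) {
  if (is.null(cfg$genotype_path)) {
    stop_cm("configuration error: genotype_path is not set")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  logf <- file.path(outdir, "pipeline.log")
  con <- file(logf, open = "wt")
  on.exit(close(con), add = TRUE)
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop_cm("stage '%s' failed: %s", stage, conditionMessage(e))
    })
    message(sprintf("[%s] done in %.1f s", stage,
                    proc.time()[["elapsed"]] - t0))
    res
  }

  gt <- run_stage("read", read_genotype_table(cfg$genotype_path,
                                              cfg$missing_symbols))
  log_stage(con, "read", "%d call rows x %d progeny", nrow(gt$rows),
            length(gt$progeny_ids))

  phased <- run_stage("split", split_parental(
    gt, min_informative_frac = cfg$min_informative_frac,
    alpha = cfg$alpha))
  log_stage(con, "split", "P1=%d loci, P2=%d loci",
            nrow(phased$P1$loci), nrow(phased$P2$loci))

  hits <- NULL
  if (!is.null(cfg$hit_table_path)) {
    hits <- run_stage("hits", best_hits(
      read_hit_table(cfg$hit_table_path, evalue_max = cfg$evalue_prot)))
    log_stage(con, "hits", "%d best hits", nrow(hits))
  }

  res1 <- run_stage("map_P1", map_parent(phased$P1, cfg, hits = NULL))
  log_stage(con, "map_P1", "%d groups, %d mapped loci",
            length(res1$groups), nrow(res1$map))
  res2 <- run_stage("map_P2", map_parent(phased$P2, cfg,
                                         partner_map = res1$map,
                                         hits = hits))
  log_stage(con, "map_P2", "%d groups, %d mapped loci%s",
            length(res2$groups), nrow(res2$map),
            if (is.null(res2$disassembly)) "" else
              sprintf(" (suspect group disassembled into %d subgroups)",
                      length(res2$disassembly$subgroups)))
  write_map(stats_cols(res1$map), file.path(outdir, "map_P1.tsv"))
  write_map(stats_cols(res2$map), file.path(outdir, "map_P2.tsv"))

  integ <- run_stage("integrate",
                     integrate_maps(res1$map, res2$map,
                                    min_anchors = cfg$integrate_min_anchors))
  log_stage(con, "integrate", "%d loci, %d/%d groups integrated",
            nrow(integ$map), sum(integ$meta$integrated), nrow(integ$meta))
  write_map(stats_cols(integ$map), file.path(outdir, "map_integrated.tsv"))

  st <- run_stage("stats", map_stats(integ))
  utils::write.table(st$per_group, file.path(outdir, "map_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(st$total, file.path(outdir, "map_stats_total.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage(con, "stats", "total %d loci, %.1f cM", st$total$n_loci,
            st$total$length_cm)

  ld <- run_stage("ld", lapply(
    list(P1 = list(map = res1$map, ph = phased$P1),
         P2 = list(map = res2$map, ph = phased$P2)),
    function(x) ld_scan(x$map, x$ph, step_cm = cfg$ld_grid_cm,
                        r2_min = cfg$ld_r2_min, n_min = cfg$ld_n_min)))
  for (p in names(ld)) {
    utils::write.table(ld[[p]]$pairs,
                       file.path(outdir, sprintf("ld_pairs_%s.tsv", p)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ld[[p]]$regions,
                       file.path(outdir, sprintf("ld_regions_%s.tsv", p)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_ld_matrix(ld[[p]], file.path(outdir,
                                       sprintf("ld_matrix_%s.tsv", p)))
    log_stage(con, "ld", "%s: %d sampled loci, %d cross-group pairs > %.2f",
              p, length(ld[[p]]$sampled), nrow(ld[[p]]$cross_hits),
              cfg$ld_r2_min)
  }

  syn <- NULL
  if (!is.null(hits)) {
    syn <- run_stage("synteny", {
      anchors <- build_anchors(res1$map, hits, evalue_max = cfg$evalue_prot)
      blocks <- chain_blocks(anchors,
                             min_anchors = cfg$synteny_min_anchors,
                             map_win_cm = cfg$synteny_map_win_cm,
                             ref_win_kb = cfg$synteny_ref_win_kb)
      list(anchors = anchors, blocks = blocks,
           summary = colinearity_summary(anchors, blocks, res1$map))
    })
    utils::write.table(syn$anchors, file.path(outdir, "anchors.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(syn$blocks, file.path(outdir, "synteny_blocks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(syn$summary,
                       file.path(outdir, "colinearity_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_synteny_links(syn$blocks, file.path(outdir, "synteny_links.txt"))
    log_stage(con, "synteny", "%d anchors, %d blocks", nrow(syn$anchors),
              nrow(syn$blocks))
  }

  invisible(list(genotypes = gt, phased = phased, map_P1 = res1,
                 map_P2 = res2, integrated = integ, stats = st, ld = ld,
                 synteny = syn))
}

## writable column view of a map (rename position for the TSV contract)
stats_cols <- function(map) {
  out <- map
  names(out)[names(out) == "distorted"] <- "distorted_flag"
  out
}
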