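#' Default pipeline configuration
#'
#' Collects every stage threshold (each anchored to its module default) plus
#' the simulator configurations for simulation mode.
#'
#' @param seed master seed; every stage derives a named substream from it
#' @param alpha FDR threshold for differential methylation
#' @param window promoter half-width in bp
#' @param top_fraction,bottom_fraction classifier fractions
#' @param min_samples_detected,min_coverage site filter
#' @param hypo_threshold hypomethylation bound
#' @param min_fc,max_p DE filter
#' @param coord_base coverage-file coordinate dialect (0 or 1)
#' @param behavior a [behavior_sim_config()] (simulation mode)
#' @param methylome a [methyl_sim_config()] (simulation mode)
#' @return a list of class `run_config`
#' @export
run_config <- function(seed = 1, alpha = 0.05, window = 2000,
                       top_fraction = 0.25, bottom_fraction = 0.40,
                       min_samples_detected = 7, min_coverage = 5,
                       hypo_threshold = 0.3, min_fc = 2, max_p = 0.05,
                       coord_base = 1,
                       behavior = NULL, methylome = NULL) {
  check_fraction(alpha, "alpha")
  check_positive(window, "window")
  check_fraction(top_fraction, "top_fraction")
  check_fraction(bottom_fraction, "bottom_fraction")
  if (top_fraction + bottom_fraction > 1)
    stop_config("top_fraction + bottom_fraction", "must not exceed 1")
  check_positive(min_samples_detected, "min_samples_detected")
  check_positive(min_coverage, "min_coverage")
  check_fraction(hypo_threshold, "hypo_threshold")
  check_positive(min_fc, "min_fc")
  check_fraction(max_p, "max_p")
  if (!coord_base %in% c(0, 1)) stop_config("coord_base", "must be 0 or 1")
  if (is.null(behavior)) behavior <- behavior_sim_config(seed = seed)
  if (is.null(methylome)) {
    gm <- simulate_gene_model(seed = seed)
    methylome <- methyl_sim_config(seed = seed, gene_model = gm)
  }
  behavior$seed <- seed
  methylome$seed <- seed
  structure(list(seed = seed, alpha = alpha, window = window,
                 top_fraction = top_fraction,
                 bottom_fraction = bottom_fraction,
                 min_samples_detected = min_samples_detected,
                 min_coverage = min_coverage,
                 hypo_threshold = hypo_threshold,
                 min_fc = min_fc, max_p = max_p, coord_base = coord_base,
                 behavior = behavior, methylome = methylome),
            class = "run_config")
}

#' Run the full synthetic-data pipeline
#'
#' Chains simulate -> score/classify -> filter -> DMC (F0, F1) -> maintained
#' differences -> hypomethylation and promoter enrichment -> metagene & MDS
#' -> DE overlap, and reports stage counts plus recovery metrics against the
#' simulator's ground truth. Identical config and seed give an identical
#' report.
#'
#' @param cfg a [run_config()]
#' @param out_dir optional directory; when given, all stage outputs are
#'   written (CSV/TSV/BED/JSON) and re-readable by the package's own readers
#' @return a list of class `transmeth_report` with elements behavior,
#'   methylome, integration and summary (the machine-readable stage counts)
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  gm <- cfg$methylome$gene_model
  if (is.null(gm)) gm <- simulate_gene_model(seed = cfg$seed)

  beh <- simulate_behavior_cohort(cfg$behavior)
  scores <- score_cohort(beh$sessions)
  scores <- classify_cohort(scores, cfg$top_fraction, cfg$bottom_fraction)
  bp_addict <- scores$break_point[scores$label == "Addict"]
  bp_non <- scores$break_point[scores$label == "Non-addict"]
  bp_test <- rank_sum_test(bp_addict, bp_non)

  sim <- simulate_methyl_matrix(cfg$methylome)
  m_all <- sim$matrix
  m <- filter_sites(m_all, cfg$min_samples_detected, cfg$min_coverage)
  f0 <- dmc_test(m, "F0", alpha = cfg$alpha)
  f1 <- dmc_test(m, "F1", alpha = cfg$alpha)
  maintained <- maintained_differences(f0, f1)

  truth <- sim$truth[match(site_keys(m), sim$truth$site), ]
  true_maint <- truth$site[truth$maintained]
  tp <- sum(maintained %in% true_maint)
  sens <- if (length(true_maint)) tp / length(true_maint) else NA_real_
  fdp <- if (length(maintained))
    (length(maintained) - tp) / length(maintained) else 0

  hypo <- hypo_flag(m, cfg$hypo_threshold)
  is_maint <- site_keys(m) %in% maintained
  hy_ok <- !is.na(hypo)
  hypo_enr <- if (any(is_maint & hy_ok))
    enrichment(sum(hypo[is_maint & hy_ok]), sum(!hypo[is_maint & hy_ok]),
               sum(hypo[!is_maint & hy_ok]), sum(!hypo[!is_maint & hy_ok]))
  else NULL

  ann <- annotate_sites(m, gm, window = cfg$window)
  is_prom <- ann$element == "promoter"
  prom_enr <- if (any(is_maint))
    enrichment(sum(is_prom & is_maint), sum(!is_prom & is_maint),
               sum(is_prom & !is_maint), sum(!is_prom & !is_maint))
  else NULL

  profile <- metagene_profile(m, gm)
  mds <- mds_embedding(m)

  maint_genes <- sort(unique(ann$gene_id[is_maint & is_prom]))
  de <- simulate_de_table(gm$genes$gene_id, affected_genes = maint_genes,
                          seed = cfg$seed)
  de_genes <- filter_de(de, cfg$min_fc, cfg$max_p)
  overlap <- overlap_enrichment(maint_genes, de_genes,
                                intersect(gm$genes$gene_id, de$gene_id))

  summary <- list(
    seed = cfg$seed,
    thresholds = cfg[c("alpha", "window", "top_fraction", "bottom_fraction",
                       "min_samples_detected", "min_coverage",
                       "hypo_threshold", "min_fc", "max_p", "coord_base")],
    n_animals = nrow(scores),
    n_addict = sum(scores$label == "Addict"),
    n_nonaddict = sum(scores$label == "Non-addict"),
    breakpoint_ranksum_p = bp_test$p.value,
    sites_in = nrow(m_all$sites),
    sites_filtered = nrow(m$sites),
    dmc_f0 = sum(f0$significant),
    dmc_f1 = sum(f1$significant),
    maintained = length(maintained),
    maintained_sensitivity = sens,
    maintained_fdp = fdp,
    hypo_pct_maintained = 100 * mean(hypo[is_maint & hy_ok]),
    hypo_pct_background = 100 * mean(hypo[!is_maint & hy_ok]),
    promoter_pct_maintained = 100 * mean(is_prom[is_maint]),
    promoter_pct_background = 100 * mean(is_prom[!is_maint]),
    hypo_or = if (!is.null(hypo_enr)) hypo_enr$odds_ratio else NA_real_,
    promoter_or = if (!is.null(prom_enr)) prom_enr$odds_ratio else NA_real_,
    promoter_or_ci = if (!is.null(prom_enr)) prom_enr$ci95 else
      c(NA_real_, NA_real_),
    n_maintained_promoter_genes = length(maint_genes),
    n_de_genes = length(de_genes),
    overlap_genes = overlap$overlap_size,
    overlap_p = overlap$hypergeometric_p
  )

  report <- structure(list(
    behavior = list(sessions = beh$sessions, animals = beh$animals,
                    scores = scores, breakpoint_test = bp_test),
    methylome = list(matrix = m, truth = sim$truth, dmc_f0 = f0, dmc_f1 = f1,
                     maintained = maintained, hypo = hypo,
                     hypo_enrichment = hypo_enr,
                     promoter_enrichment = prom_enr,
                     annotation = ann, profile = profile, mds = mds,
                     gene_model = gm),
    integration = list(de = de, de_genes = de_genes, overlap = overlap),
    summary = summary
  ), class = "transmeth_report")

  if (!is.null(out_dir)) write_report(report, out_dir, cfg)
  report
}

#' @export
print.transmeth_report <- function(x, ...) {
  s <- x$summary
  cat("transmeth pipeline report\n")
  cat(sprintf("  cohort: %d animals -> %d Addict / %d Non-addict (break-point rank-sum p = %.2g)\n",
              s$n_animals, s$n_addict, s$n_nonaddict, s$breakpoint_ranksum_p))
  cat(sprintf("  CpG sites: %d simulated, %d pass filter\n",
              s$sites_in, s$sites_filtered))
  cat(sprintf("  DMCs: %d (F0), %d (F1); maintained: %d (sensitivity %.2f, FDP %.2f)\n",
              s$dmc_f0, s$dmc_f1, s$maintained,
              s$maintained_sensitivity, s$maintained_fdp))
  cat(sprintf("  enrichment: hypomethylation OR %.2f, promoter OR %.2f\n",
              s$hypo_or, s$promoter_or))
  cat(sprintf("  integration: %d DE genes, %d overlap maintained promoters (p = %.2g)\n",
              s$n_de_genes, s$overlap_genes, s$overlap_p))
  invisible(x)
}

write_report <- function(report, out_dir, cfg) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$behavior$sessions,
                   file.path(out_dir, "sessions.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$behavior$scores),
                   file.path(out_dir, "cohort_scores.csv"), row.names = FALSE)
  write_coverage_tables(report$methylome$matrix,
                        file.path(out_dir, "coverage"),
                        coord_base = cfg$coord_base)
  utils::write.csv(report$methylome$matrix$samples,
                   file.path(out_dir, "sample_metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(report$methylome$truth,
                   file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  write_dmc_table(report$methylome$dmc_f0, file.path(out_dir, "dmc_F0.tsv"))
  write_dmc_table(report$methylome$dmc_f1, file.path(out_dir, "dmc_F1.tsv"))
  write_sites_bed(report$methylome$maintained,
                  file.path(out_dir, "maintained.bed"))
  utils::write.table(report$methylome$profile,
                     file.path(out_dir, "metagene_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mds <- report$methylome$mds
  utils::write.csv(data.frame(sample_id = rownames(mds), mds),
                   file.path(out_dir, "mds_coordinates.csv"),
                   row.names = FALSE)
  utils::write.csv(report$integration$de, file.path(out_dir, "de_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write a DMC table as TSV
#' @param x a `dmc_table`
#' @param path output file
#' @export
write_dmc_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a DMC table written by [write_dmc_table()]
#' @param path input file
#' @return a `dmc_table`
#' @export
read_dmc_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  class(d) <- c("dmc_table", "data.frame")
  d
}

#' Write site keys as a BED file (0-based half-open)
#' @param sites character vector of "chrom:pos" keys (pos 0-based)
#' @param path output file
#' @export
write_sites_bed <- function(sites, path) {
  if (length(sites)) {
    chrom <- sub(":.*$", "", sites)
    pos <- as.integer(sub("^.*:", "", sites))
    d <- data.frame(chrom = chrom, start = pos, end = pos + 1L)
    d <- d[order(d$chrom, d$start), ]
  } else {
    d <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0))
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of CpG sites back into site keys
#' @param path BED file (0-based half-open)
#' @return character vector of "chrom:pos" keys
#' @export
read_sites_bed <- function(path) {
  if (file.size(path) == 0) return(character(0))
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  paste0(d[[1]], ":", d[[2]])
}
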