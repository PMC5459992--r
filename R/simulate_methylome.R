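METHYL_GROUPS <- c("Saline-F0", "Addict-F0", "Non-addict-F0",
                   "Addict-F1", "Non-addict-F1")

#' Configuration for the RRBS-like methylation simulator
#'
#' Emulates the sperm RRBS design: 16 samples in five groups (Saline F0,
#' Addict/Non-addict F0, Addict/Non-addict F1), bimodal CpG baseline
#' methylation, negative-binomial coverage, beta-binomial methylated counts,
#' a global demethylation shift in the cocaine-exposed F0 groups, a per-site
#' generational drift separating F1 from F0 methylomes, and a planted set of
#' phenotype-associated CpGs of which a fraction is maintained into F1.
#'
#' @param n_sites number of CpG sites
#' @param samples_per_group named integer vector over the five groups
#'   Saline-F0, Addict-F0, Non-addict-F0, Addict-F1, Non-addict-F1
#' @param weight_hypo mixture weight of the hypomethylated baseline component
#' @param beta_hypo,beta_hyper shape pairs of the two Beta baseline components
#' @param coverage_mean,coverage_dispersion negative-binomial coverage
#'   parameters (mean reads per site per sample, NB size)
#' @param global_demethylation_shift logit-scale shift (<= 0) applied to all
#'   sites of cocaine-exposed F0 samples (Addict-F0, Non-addict-F0)
#' @param generation_effect_sd SD of the per-site logit-scale N(0, sd)
#'   generational offset applied to all F1 samples (emulates germline
#'   epigenetic drift between generations; 0 disables it)
#' @param n_planted_dmcs number of phenotype-associated CpGs planted
#' @param planted_effect logit-scale Addict-vs-Non-addict shift at planted
#'   sites (sign drawn per site)
#' @param maintenance_fraction fraction of planted CpGs whose effect persists
#'   in F1
#' @param overdispersion beta-binomial intra-sample correlation in [0, 1)
#' @param gene_model optional `gene_model`; when given, site placement is
#'   promoter-aware (see `promoter_site_fraction`)
#' @param promoter_site_fraction fraction of sites placed inside promoter
#'   windows when a gene model is supplied
#' @param planted_promoter_fraction fraction of planted sites drawn from
#'   promoter-resident sites when a gene model is supplied
#' @param promoter_window half-width of the promoter window around the TSS
#' @param seed master seed; methylome draws use the "methylome" substream
#' @return a validated list of class `methyl_sim_config`
#' @export
methyl_sim_config <- function(
    n_sites = 10000,
    samples_per_group = c("Saline-F0" = 4, "Addict-F0" = 3,
                          "Non-addict-F0" = 3, "Addict-F1" = 3,
                          "Non-addict-F1" = 3),
    weight_hypo = 0.6, beta_hypo = c(0.5, 10), beta_hyper = c(10, 0.5),
    coverage_mean = 30, coverage_dispersion = 5,
    global_demethylation_shift = -0.3, generation_effect_sd = 0.3,
    n_planted_dmcs = 200, planted_effect = 1.5, maintenance_fraction = 0.8,
    overdispersion = 0.05, gene_model = NULL,
    promoter_site_fraction = 0.35, planted_promoter_fraction = 0.8,
    promoter_window = 2000, seed = 1) {
  check_positive(n_sites, "n_sites")
  miss <- setdiff(METHYL_GROUPS, names(samples_per_group))
  if (length(miss))
    stop_config("samples_per_group",
                paste("is missing required groups:",
                      paste(miss, collapse = ", ")))
  if (any(samples_per_group < 1))
    stop_config("samples_per_group", "must have >= 1 sample per group")
  if (weight_hypo <= 0 || weight_hypo >= 1)
    stop_config("weight_hypo", "must lie in (0, 1)")
  check_positive(coverage_mean, "coverage_mean")
  check_positive(coverage_dispersion, "coverage_dispersion")
  if (global_demethylation_shift > 0)
    stop_config("global_demethylation_shift", "must be <= 0")
  check_nonneg(generation_effect_sd, "generation_effect_sd")
  check_nonneg(n_planted_dmcs, "n_planted_dmcs")
  if (n_planted_dmcs > n_sites)
    stop_config("n_planted_dmcs", "must not exceed n_sites")
  check_fraction(maintenance_fraction, "maintenance_fraction")
  if (overdispersion < 0 || overdispersion >= 1)
    stop_config("overdispersion", "must lie in [0, 1)")
  check_fraction(promoter_site_fraction, "promoter_site_fraction")
  check_fraction(planted_promoter_fraction, "planted_promoter_fraction")
  structure(list(
    n_sites = as.integer(n_sites),
    samples_per_group = samples_per_group[METHYL_GROUPS],
    weight_hypo = weight_hypo, beta_hypo = beta_hypo,
    beta_hyper = beta_hyper, coverage_mean = coverage_mean,
    coverage_dispersion = coverage_dispersion,
    global_demethylation_shift = global_demethylation_shift,
    generation_effect_sd = generation_effect_sd,
    n_planted_dmcs = as.integer(n_planted_dmcs),
    planted_effect = planted_effect,
    maintenance_fraction = maintenance_fraction,
    overdispersion = overdispersion, gene_model = gene_model,
    promoter_site_fraction = promoter_site_fraction,
    planted_promoter_fraction = planted_promoter_fraction,
    promoter_window = promoter_window, seed = seed
  ), class = "methyl_sim_config")
}

rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(stats::rbinom(n, size, prob))
  a <- prob * (1 / rho - 1)
  b <- (1 - prob) * (1 / rho - 1)
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

#' Simulate an RRBS-like methylation matrix with planted effects
#'
#' Per site s a baseline methylation probability pi_s is drawn from the
#' bimodal Beta mixture. Per sample, logit(pi_s) is shifted by the global
#' demethylation term (cocaine-exposed F0 groups), a per-site generational
#' drift (all F1 samples), and by the planted Addict effect (Addict groups,
#' planted sites; F1 only for maintained sites). Coverage is negative
#' binomial; methylated counts are beta-binomial.
#'
#' @param cfg a [methyl_sim_config()]
#' @return list with `matrix` (a [methyl_matrix()]) and `truth` (data.frame:
#'   site, chrom, pos, baseline, planted, maintained, sign)
#' @export
simulate_methyl_matrix <- function(cfg = methyl_sim_config()) {
  stopifnot(inherits(cfg, "methyl_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(cfg$seed, "methylome"))

  ns <- cfg$n_sites
  pos <- sim_site_positions(cfg)
  sites <- data.frame(chrom = "chr1", pos = pos$pos)

  hypo <- stats::runif(ns) < cfg$weight_hypo
  pi0 <- ifelse(hypo,
                stats::rbeta(ns, cfg$beta_hypo[1], cfg$beta_hypo[2]),
                stats::rbeta(ns, cfg$beta_hyper[1], cfg$beta_hyper[2]))
  pi0 <- pmin(pmax(pi0, 1e-4), 1 - 1e-4)

  npl <- cfg$n_planted_dmcs
  planted <- sim_planted_sites(cfg, pos$in_promoter)
  n_maint <- round(cfg$maintenance_fraction * npl)
  maintained <- planted[seq_len(n_maint)]
  sgn <- integer(ns)
  if (npl > 0) sgn[planted] <- sample(c(-1L, 1L), npl, replace = TRUE)

  gen_drift <- if (cfg$generation_effect_sd > 0)
    stats::rnorm(ns, 0, cfg$generation_effect_sd) else numeric(ns)

  groups <- rep(names(cfg$samples_per_group), cfg$samples_per_group)
  n_samp <- length(groups)
  sample_id <- sprintf("S%02d_%s", seq_len(n_samp), gsub("-", "", groups))
  pheno <- sub("-F[01]$", "", groups)
  gen <- sub("^.*-", "", groups)

  eff_f0 <- numeric(ns); eff_f0[planted] <- sgn[planted] * cfg$planted_effect
  eff_f1 <- numeric(ns)
  if (n_maint > 0)
    eff_f1[maintained] <- sgn[maintained] * cfg$planted_effect

  l0 <- logit(pi0)
  meth <- total <- matrix(0L, ns, n_samp)
  for (j in seq_len(n_samp)) {
    l <- l0
    if (gen[j] == "F0" && pheno[j] != "Saline")
      l <- l + cfg$global_demethylation_shift
    if (gen[j] == "F1") l <- l + gen_drift
    if (pheno[j] == "Addict")
      l <- l + (if (gen[j] == "F0") eff_f0 else eff_f1)
    pij <- expit(l)
    cov <- stats::rnbinom(ns, size = cfg$coverage_dispersion,
                          mu = cfg$coverage_mean)
    meth[, j] <- as.integer(rbetabinom(ns, cov, pij, cfg$overdispersion))
    total[, j] <- as.integer(cov)
  }

  samples <- data.frame(sample_id = sample_id, generation = gen,
                        phenotype = pheno, stringsAsFactors = FALSE)
  m <- methyl_matrix(sites, meth, total, samples)
  # methyl_matrix() sorts sites by (chrom, pos); carry truth in matrix order
  key_in <- paste0(sites$chrom, ":", sites$pos)
  ord <- match(site_keys(m), key_in)
  truth <- data.frame(
    site = site_keys(m),
    chrom = m$sites$chrom, pos = m$sites$pos,
    baseline = pi0[ord],
    planted = seq_len(ns)[ord] %in% planted,
    maintained = seq_len(ns)[ord] %in% maintained,
    sign = sgn[ord],
    stringsAsFactors = FALSE
  )
  list(matrix = m, truth = truth)
}

sim_site_positions <- function(cfg) {
  ns <- cfg$n_sites
  span <- max(200L * ns, 2000000L)
  if (is.null(cfg$gene_model)) {
    pos <- sort(sample.int(span, ns))
    return(list(pos = pos, in_promoter = rep(FALSE, ns)))
  }
  gm <- cfg$gene_model
  w <- cfg$promoter_window
  tss <- gm$genes$tss
  lo <- pmax(0L, tss - w); hi <- tss + w
  n_prom <- round(cfg$promoter_site_fraction * ns)
  gidx <- sample.int(length(tss), n_prom, replace = TRUE)
  prom_pos <- lo[gidx] + sample.int(2L * w + 1L, n_prom, replace = TRUE) - 1L
  # non-promoter sites: rejection-sample positions outside every window
  out_pos <- integer(0)
  need <- ns - n_prom
  while (length(out_pos) < need) {
    cand <- sample.int(span, 2L * need)
    inside <- rep(FALSE, length(cand))
    for (g in seq_along(tss))
      inside <- inside | (cand >= lo[g] & cand <= hi[g])
    out_pos <- c(out_pos, cand[!inside])
  }
  out_pos <- out_pos[seq_len(need)]
  pos <- c(prom_pos, out_pos)
  in_prom <- c(rep(TRUE, n_prom), rep(FALSE, need))
  dup <- duplicated(pos)
  while (any(dup)) {
    pos[dup] <- pos[dup] + sample.int(7L, sum(dup), replace = TRUE)
    dup <- duplicated(pos)
  }
  list(pos = pos, in_promoter = in_prom)
}

sim_planted_sites <- function(cfg, in_promoter) {
  npl <- cfg$n_planted_dmcs
  if (npl == 0) return(integer(0))
  if (is.null(cfg$gene_model) || !any(in_promoter))
    return(sample.int(cfg$n_sites, npl))
  n_from_prom <- min(round(cfg$planted_promoter_fraction * npl),
                     sum(in_promoter))
  prom_idx <- which(in_promoter)
  other_idx <- which(!in_promoter)
  c(sample(prom_idx, n_from_prom),
    sample(other_idx, npl - n_from_prom))
}

#' Simulate a differential-expression results table
#'
#' Companion generator for the integration stage: given a gene universe and a
#' set of genes whose promoters carry maintained methylation differences,
#' produces a DE table in which affected genes are preferentially
#' differentially expressed (fold change >= 2 at small p, direction up in
#' Non-addict).
#'
#' @param gene_ids character vector, the gene universe
#' @param affected_genes genes with maintained promoter methylation
#' @param de_rate_affected,de_rate_background probability of a gene being
#'   truly differentially expressed in each stratum
#' @param seed master seed; draws use the "expression" substream
#' @return data.frame gene_id, fold_change, p_value
#' @export
simulate_de_table <- function(gene_ids, affected_genes = character(0),
                              de_rate_affected = 0.5,
                              de_rate_background = 0.05, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, "expression"))
  n <- length(gene_ids)
  affected <- gene_ids %in% affected_genes
  rate <- ifelse(affected, de_rate_affected, de_rate_background)
  is_de <- stats::runif(n) < rate
  fc <- ifelse(is_de, 2 * exp(stats::rexp(n, 2)),
               exp(stats::rnorm(n, 0, 0.2)))
  p <- ifelse(is_de, stats::runif(n, 0, 0.01), stats::runif(n))
  data.frame(gene_id = gene_ids, fold_change = fc, p_value = p,
             stringsAsFactors = FALSE)
}
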