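#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Conditional on the margins, sums the hypergeometric probabilities of all
#' tables whose probability does not exceed that of the observed table
#' (with the conventional relative tolerance for probabilities that tie up
#' to rounding). Vectorised over tables.
#'
#' @param a,b,c,d cell counts: rows are meth/unmeth, columns the two groups,
#'   i.e. the table is rbind(c(a, b), c(c, d))
#' @return two-sided p-values
#' @export
fisher_p2x2 <- function(a, b, c, d) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative", call. = FALSE)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m1 <- a[i] + c[i]          # column 1 total (group A reads)
    m2 <- b[i] + d[i]          # column 2 total
    k <- a[i] + b[i]           # methylated margin
    if (m1 == 0 || m2 == 0 || k + c[i] + d[i] == 0) { p[i] <- 1; next }
    x <- max(0, k - m2):min(k, m1)
    probs <- stats::dhyper(x, m1, m2, k)
    pobs <- stats::dhyper(a[i], m1, m2, k)
    p[i] <- min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
  }
  p
}

#' Per-CpG differential methylation between Addict and Non-addict
#'
#' Pools methylated/total counts across samples within each phenotype of the
#' requested generation and applies a two-sided Fisher exact test per site,
#' with Benjamini-Hochberg correction across all tested sites. Sites with
#' zero pooled coverage in either phenotype are excluded and counted in the
#' `skipped` attribute. When the between-sample variance of methylation
#' levels exceeds three times its binomial expectation a caveat about
#' overdispersion relative to the pooled-count model is emitted.
#'
#' @param m a filtered `methyl_matrix`
#' @param generation "F0" or "F1"
#' @param alpha FDR threshold for the significant flag (default 0.05)
#' @param use_raw_p flag significance on raw p < alpha instead of q <= alpha
#' @return a `dmc_table` data.frame: site, chrom, pos, level_A, level_N,
#'   diff, p, q, direction, significant; attribute `skipped` holds excluded
#'   site keys
#' @export
dmc_test <- function(m, generation = c("F0", "F1"), alpha = 0.05,
                     use_raw_p = FALSE) {
  generation <- match.arg(generation)
  selA <- m$samples$generation == generation & m$samples$phenotype == "Addict"
  selN <- m$samples$generation == generation &
    m$samples$phenotype == "Non-addict"
  if (!any(selA) || !any(selN))
    stop(sprintf("generation %s lacks Addict or Non-addict samples",
                 generation), call. = FALSE)
  methA <- rowSums(m$meth[, selA, drop = FALSE])
  totA <- rowSums(m$total[, selA, drop = FALSE])
  methN <- rowSums(m$meth[, selN, drop = FALSE])
  totN <- rowSums(m$total[, selN, drop = FALSE])
  ok <- totA > 0 & totN > 0
  check_overdispersion_caveat(m, selA | selN)

  lev_A <- methA[ok] / totA[ok]
  lev_N <- methN[ok] / totN[ok]
  p <- fisher_p2x2(methA[ok], methN[ok],
                   totA[ok] - methA[ok], totN[ok] - methN[ok])
  q <- bh_adjust(p)
  out <- data.frame(
    site = site_keys(m)[ok],
    chrom = m$sites$chrom[ok], pos = m$sites$pos[ok],
    level_A = lev_A, level_N = lev_N, diff = lev_A - lev_N,
    p = p, q = q, direction = sign(lev_A - lev_N),
    significant = if (use_raw_p) p < alpha else q <= alpha,
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- site_keys(m)[!ok]
  attr(out, "generation") <- generation
  attr(out, "alpha") <- alpha
  class(out) <- c("dmc_table", "data.frame")
  out
}

check_overdispersion_caveat <- function(m, sel) {
  lev <- methyl_levels(m)[, sel, drop = FALSE]
  tot <- m$total[, sel, drop = FALSE]
  mu <- rowMeans(lev, na.rm = TRUE)
  v_obs <- apply(lev, 1, stats::var, na.rm = TRUE)
  v_bin <- mu * (1 - mu) / rowMeans(ifelse(tot > 0, tot, NA), na.rm = TRUE)
  r <- stats::median(v_obs / v_bin, na.rm = TRUE)
  if (is.finite(r) && r > 3)
    message(sprintf(
      paste0("overdispersion caveat: between-sample variance of methylation ",
             "levels is %.1fx the binomial expectation; pooled-count p-values ",
             "are anticonservative"), r))
  invisible(r)
}

#' @export
print.dmc_table <- function(x, ...) {
  cat(sprintf("DMC table (%s): %d sites tested, %d significant at FDR <= %g",
              attr(x, "generation") %||% "?", nrow(x),
              sum(x$significant), attr(x, "alpha") %||% 0.05))
  ns <- length(attr(x, "skipped"))
  if (ns) cat(sprintf(" (%d sites skipped: zero pooled coverage)", ns))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x)[order(x$p), ], 6),
                   digits = 3, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Maintained methylation differences across generations
#'
#' Sites significant in both the F0 and F1 tables with the same direction of
#' the Addict-minus-Non-addict difference.
#'
#' @param f0,f1 `dmc_table`s from the same filtered site universe
#' @return character vector of site keys ("chrom:pos")
#' @export
maintained_differences <- function(f0, f1) {
  s0 <- f0[f0$significant & f0$direction != 0, c("site", "direction")]
  s1 <- f1[f1$significant & f1$direction != 0, c("site", "direction")]
  common <- merge(s0, s1, by = "site", suffixes = c("_f0", "_f1"))
  sort(common$site[common$direction_f0 == common$direction_f1])
}

#' Hypomethylation flag per site
#'
#' TRUE when the maximum per-sample methylation fraction over covered samples
#' is at most `threshold` (inclusive). Sites covered in no sample get NA and
#' are excluded from enrichment denominators.
#'
#' @param m a `methyl_matrix`
#' @param threshold inclusive upper bound on the site maximum (default 0.3)
#' @return named logical vector over sites (NA where never covered)
#' @export
hypo_flag <- function(m, threshold = 0.3) {
  lev <- methyl_levels(m)
  mx <- suppressWarnings(apply(lev, 1, max, na.rm = TRUE))
  out <- ifelse(is.infinite(mx), NA, mx <= threshold)
  names(out) <- site_keys(m)
  out
}

#' Odds-ratio enrichment of a 2x2 table
#'
#' OR = ad/bc with the Haldane-Anscombe +0.5 correction applied to every cell
#' when any cell is zero; 95% CI from the log-OR Wald interval on the
#' (corrected) cells; two-sided Fisher exact p attached.
#'
#' @param a,b,c,d cell counts, table rbind(c(a, b), c(c, d))
#' @return an `enrichment_result`: table, odds_ratio, ci95, fisher_p
#' @export
enrichment <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) stop("counts must be non-negative", call. = FALSE)
  if (all(cells == 0)) stop("all-zero table", call. = FALSE)
  fp <- fisher_p2x2(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- cells["a"] * cells["d"] / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  structure(list(table = matrix(c(a, b, c, d), 2, byrow = TRUE),
                 odds_ratio = unname(or), ci95 = unname(ci),
                 fisher_p = fp),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("odds ratio %.4g (95%% CI %.4g-%.4g), Fisher p = %.3g\n",
              x$odds_ratio, x$ci95[1], x$ci95[2], x$fisher_p))
  print(x$table)
  invisible(x)
}
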