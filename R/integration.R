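#' Filter a differential-expression table
#'
#' Keeps genes passing the fold-change and p-value thresholds. Fold change is
#' the linear Non-addict / Addict expression ratio; `direction = "up"`
#' (higher in Non-addict) keeps fold_change >= min_fc, "down" keeps
#' fold_change <= 1/min_fc, "both" keeps either. The p cut is strict
#' (p < max_p), the fold-change cut inclusive, matching the usual
#' "fold change >= 2, P < 0.05" reading.
#'
#' @param de data.frame: gene_id, fold_change (> 0), p_value
#' @param min_fc minimum fold change (default 2)
#' @param max_p exclusive p-value bound (default 0.05)
#' @param direction "up" (default), "down" or "both"
#' @return character vector of gene ids
#' @export
filter_de <- function(de, min_fc = 2, max_p = 0.05,
                      direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  miss <- setdiff(c("gene_id", "fold_change", "p_value"), names(de))
  if (length(miss))
    stop("DE table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(de) == 0) return(character(0))
  if (any(!is.finite(de$fold_change)) || any(de$fold_change <= 0))
    stop("fold_change must be strictly positive", call. = FALSE)
  check_positive(min_fc, "min_fc")
  keep_dir <- switch(direction,
                     up = de$fold_change >= min_fc,
                     down = de$fold_change <= 1 / min_fc,
                     both = de$fold_change >= min_fc |
                       de$fold_change <= 1 / min_fc)
  sort(unique(de$gene_id[keep_dir & de$p_value < max_p]))
}

#' Overlap of methylation-affected and differentially expressed genes
#'
#' Upper-tail hypergeometric test of observing at least the realised overlap
#' when |de_genes| genes are drawn from the universe containing |meth_genes|
#' successes.
#'
#' @param meth_genes genes with maintained promoter methylation differences
#' @param de_genes differentially expressed genes
#' @param universe the gene universe; both sets must be subsets of it
#' @return list of class `overlap_result`: universe_size, set_meth_size,
#'   set_de_size, overlap_size, overlap_genes, hypergeometric_p
#' @export
overlap_enrichment <- function(meth_genes, de_genes, universe) {
  meth_genes <- unique(meth_genes); de_genes <- unique(de_genes)
  universe <- unique(universe)
  out_m <- setdiff(meth_genes, universe)
  out_d <- setdiff(de_genes, universe)
  if (length(out_m) || length(out_d))
    stop("genes outside the universe: ",
         paste(utils::head(c(out_m, out_d), 10), collapse = ", "),
         call. = FALSE)
  ov <- intersect(meth_genes, de_genes)
  k <- length(ov)
  p <- stats::phyper(k - 1, length(meth_genes),
                     length(universe) - length(meth_genes),
                     length(de_genes), lower.tail = FALSE)
  structure(list(universe_size = length(universe),
                 set_meth_size = length(meth_genes),
                 set_de_size = length(de_genes),
                 overlap_size = k,
                 overlap_genes = sort(ov),
                 hypergeometric_p = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "%d of %d DE genes overlap %d methylation-affected genes (universe %d)\n",
    x$overlap_size, x$set_de_size, x$set_meth_size, x$universe_size))
  cat(sprintf("upper-tail hypergeometric p = %.3g\n", x$hypergeometric_p))
  invisible(x)
}
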