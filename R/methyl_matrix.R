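#' Construct a CpG methylation count matrix
#'
#' The central container of the methylome stages: an ordered site table plus
#' parallel matrices of methylated and total read counts (sites x samples)
#' and per-sample metadata. Positions are 0-based internally; conversion from
#' 1-based inputs happens once at the I/O boundary.
#'
#' @param sites data.frame with columns chrom, pos (0-based CpG position)
#' @param meth,total integer matrices, rows = sites, cols = samples
#' @param samples data.frame with columns sample_id, generation ("F0"/"F1"),
#'   phenotype ("Saline"/"Addict"/"Non-addict")
#' @return an object of class `methyl_matrix`
#' @export
methyl_matrix <- function(sites, meth, total, samples) {
  stopifnot(is.data.frame(sites), all(c("chrom", "pos") %in% names(sites)))
  stopifnot(is.matrix(meth), is.matrix(total),
            all(dim(meth) == dim(total)),
            nrow(meth) == nrow(sites), ncol(meth) == nrow(samples))
  miss <- setdiff(c("sample_id", "generation", "phenotype"), names(samples))
  if (length(miss))
    stop("sample metadata is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("sample ids must be unique", call. = FALSE)
  if (any(meth > total))
    stop("count_meth exceeds count_total", call. = FALSE)
  if (any(meth < 0) || any(total < 0))
    stop("counts must be non-negative", call. = FALSE)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  meth <- meth[ord, , drop = FALSE]
  total <- total[ord, , drop = FALSE]
  if (anyDuplicated(paste(sites$chrom, sites$pos)))
    stop("duplicated CpG site", call. = FALSE)
  rownames(sites) <- NULL
  key <- paste0(sites$chrom, ":", sites$pos)
  dimnames(meth) <- dimnames(total) <- list(key, samples$sample_id)
  structure(list(sites = sites, meth = meth, total = total,
                 samples = samples),
            class = "methyl_matrix")
}

#' @export
print.methyl_matrix <- function(x, ...) {
  cat(sprintf("methyl_matrix: %d CpG sites x %d samples\n",
              nrow(x$sites), nrow(x$samples)))
  tab <- table(paste(x$samples$phenotype, x$samples$generation, sep = "-"))
  cat("samples per group:\n")
  print(tab)
  cov <- x$total[x$total > 0]
  if (length(cov))
    cat(sprintf("median coverage at covered entries: %.0f\n",
                stats::median(cov)))
  invisible(x)
}

#' @export
dim.methyl_matrix <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Per-sample methylation fractions
#'
#' @param m a `methyl_matrix`
#' @return matrix of meth/total with NA where coverage is 0
#' @export
methyl_levels <- function(m) {
  lev <- m$meth / m$total
  lev[m$total == 0] <- NA_real_
  lev
}

site_keys <- function(m) paste0(m$sites$chrom, ":", m$sites$pos)

#' Read bismark-style coverage files into a methyl_matrix
#'
#' Each file holds one sample as TSV without header: chrom, start, end,
#' percent methylation, count methylated, count unmethylated. The site
#' universe is the union across samples; a site absent from a sample gets
#' coverage 0 there.
#'
#' @param paths character vector of coverage file paths
#' @param metadata data.frame with sample_id (matching `names(paths)` or file
#'   base names), generation, phenotype
#' @param coord_base 1 (default, bismark convention) or 0; starts are
#'   converted to 0-based internal positions
#' @return a `methyl_matrix`
#' @export
read_coverage_tables <- function(paths, metadata, coord_base = 1) {
  if (!coord_base %in% c(0, 1)) stop_config("coord_base", "must be 0 or 1")
  ids <- names(paths)
  if (is.null(ids)) ids <- sub("\\.[^.]*$", "", basename(paths))
  miss <- setdiff(ids, metadata$sample_id)
  if (length(miss))
    stop("metadata does not cover samples: ", paste(miss, collapse = ", "),
         call. = FALSE)
  per <- lapply(seq_along(paths), function(i) {
    d <- utils::read.table(paths[i], sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "pct",
                                         "count_meth", "count_unmeth"))
    if (any(d$count_meth < 0) || any(d$count_unmeth < 0))
      stop(sprintf("%s: negative counts", paths[i]), call. = FALSE)
    bad <- which(abs(d$pct - 100 * d$count_meth /
                       pmax(1, d$count_meth + d$count_unmeth)) > 1 &
                   (d$count_meth + d$count_unmeth) > 0)
    if (length(bad))
      stop(sprintf("%s: line %d: percent methylation inconsistent with counts",
                   paths[i], bad[1]), call. = FALSE)
    d$pos <- d$start - coord_base
    if (anyDuplicated(paste(d$chrom, d$pos)))
      stop(sprintf("%s: duplicated site within file", paths[i]),
           call. = FALSE)
    d
  })
  all_sites <- unique(do.call(rbind, lapply(per, function(d)
    d[, c("chrom", "pos")])))
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), , drop = FALSE]
  key <- paste0(all_sites$chrom, ":", all_sites$pos)
  meth <- total <- matrix(0L, nrow(all_sites), length(paths))
  for (i in seq_along(per)) {
    d <- per[[i]]
    idx <- match(paste0(d$chrom, ":", d$pos), key)
    meth[idx, i] <- as.integer(d$count_meth)
    total[idx, i] <- as.integer(d$count_meth + d$count_unmeth)
  }
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  rownames(md) <- NULL
  methyl_matrix(all_sites, meth, total, md)
}

#' Write a methyl_matrix as one coverage file per sample
#'
#' Inverse of [read_coverage_tables()]; rows with zero coverage are omitted
#' (a sample "detects" only its covered sites).
#'
#' @param m a `methyl_matrix`
#' @param dir output directory (created if needed)
#' @param coord_base 1 (default) or 0
#' @return named vector of file paths, invisibly
#' @export
write_coverage_tables <- function(m, dir, coord_base = 1) {
  if (!coord_base %in% c(0, 1)) stop_config("coord_base", "must be 0 or 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(m$samples))
  names(paths) <- m$samples$sample_id
  for (j in seq_len(nrow(m$samples))) {
    keep <- m$total[, j] > 0
    d <- data.frame(
      chrom = m$sites$chrom[keep],
      start = m$sites$pos[keep] + coord_base,
      end = m$sites$pos[keep] + 1,
      pct = round(100 * m$meth[keep, j] / m$total[keep, j], 6),
      count_meth = m$meth[keep, j],
      count_unmeth = m$total[keep, j] - m$meth[keep, j]
    )
    p <- file.path(dir, paste0(m$samples$sample_id[j], ".cov"))
    utils::write.table(d, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    paths[j] <- p
  }
  invisible(paths)
}

#' Filter CpG sites by detection breadth and coverage depth
#'
#' Retains sites with at least `min_samples_detected` samples at coverage
#' `>= min_coverage`. Defaults encode detection in strictly more than 6
#' samples at >= 5x. Idempotent.
#'
#' @param m a `methyl_matrix`
#' @param min_samples_detected minimum number of qualifying samples (default 7)
#' @param min_coverage minimum reads for a sample to count as detecting a
#'   site (default 5)
#' @return the filtered `methyl_matrix`
#' @export
filter_sites <- function(m, min_samples_detected = 7, min_coverage = 5) {
  if (min_samples_detected < 1) stop_config("min_samples_detected", "must be >= 1")
  if (min_coverage < 1) stop_config("min_coverage", "must be >= 1")
  keep <- rowSums(m$total >= min_coverage) >= min_samples_detected
  subset_sites(m, keep)
}

subset_sites <- function(m, keep) {
  out <- m
  out$sites <- m$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$meth <- m$meth[keep, , drop = FALSE]
  out$total <- m$total[keep, , drop = FALSE]
  out
}
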