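#' Metagene methylation profile
#'
#' Average methylation of CpG sites along a normalised gene axis: a
#' fixed-width upstream flank before the TSS, the gene body rescaled to
#' [0, 1], and a fixed-width downstream flank after the TES, each split into
#' `n_bins` bins. Minus-strand genes are reversed so the axis always runs
#' TSS to TES. Site levels are pooled read counts per sample group
#' (phenotype-generation); a bin containing no site is NA, never zero.
#'
#' @param m a `methyl_matrix`
#' @param gm a `gene_model`
#' @param n_bins bins per zone (default 20)
#' @param flank flank width in bp (default 2000)
#' @return data.frame: group, zone ("upstream"/"body"/"downstream"), bin
#'   (1..n_bins within zone), x (global axis position), mean_level, n_sites
#' @export
metagene_profile <- function(m, gm, n_bins = 20, flank = 2000) {
  if (n_bins < 1) stop_config("n_bins", "must be >= 1")
  if (nrow(gm$genes) == 0) stop("gene model is empty", call. = FALSE)
  g <- gm$genes
  short <- (g$end - g$start) < n_bins
  if (any(short)) {
    message(sprintf("%d gene(s) shorter than one bin per bp skipped",
                    sum(short)))
    g <- g[!short, , drop = FALSE]
  }
  sgr <- GenomicRanges::GRanges(m$sites$chrom,
                                IRanges::IRanges(m$sites$pos + 1L, width = 1L))
  wgr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(pmax(1L, g$start + 1L - flank), g$end + flank))
  hits <- GenomicRanges::findOverlaps(sgr, wgr)
  si <- S4Vectors::queryHits(hits); gi <- S4Vectors::subjectHits(hits)

  pos <- m$sites$pos[si]
  gs <- g$start[gi]; ge <- g$end[gi]; plus <- g$strand[gi] == "+"
  # signed position along the gene axis: negative upstream of TSS, 0..1 body,
  # >1 downstream of TES (units of flank bp outside the body)
  rel <- ifelse(plus,
                ifelse(pos < gs, (pos - gs) / flank,
                       ifelse(pos >= ge, 1 + (pos - ge + 1) / flank,
                              (pos - gs) / (ge - gs))),
                ifelse(pos >= ge, (ge - 1 - pos) / flank,
                       ifelse(pos < gs, 1 + (gs - pos) / flank,
                              (ge - 1 - pos) / (ge - gs))))
  inside <- rel >= -1 & rel <= 2
  si <- si[inside]; rel <- rel[inside]
  zone <- ifelse(rel < 0, "upstream", ifelse(rel <= 1, "body", "downstream"))
  binof <- function(u) pmin(n_bins, pmax(1L, 1L + as.integer(floor(u * n_bins))))
  bin <- integer(length(rel))
  bin[zone == "upstream"] <- binof(rel[zone == "upstream"] + 1)
  bin[zone == "body"] <- binof(rel[zone == "body"])
  bin[zone == "downstream"] <- binof(rel[zone == "downstream"] - 1)

  grp <- paste(m$samples$phenotype, m$samples$generation, sep = "-")
  zones <- c("upstream", "body", "downstream")
  res <- list()
  for (gname in unique(grp)) {
    sel <- grp == gname
    pm <- rowSums(m$meth[, sel, drop = FALSE])
    pt <- rowSums(m$total[, sel, drop = FALSE])
    lev <- ifelse(pt > 0, pm / pt, NA_real_)
    lv <- lev[si]
    keyz <- factor(zone, zones)
    for (z in zones) {
      zi <- keyz == z
      mlev <- tapply(lv[zi], factor(bin[zi], seq_len(n_bins)),
                     mean, na.rm = TRUE)
      nsite <- tapply(!is.na(lv[zi]), factor(bin[zi], seq_len(n_bins)),
                      sum)
      res[[length(res) + 1L]] <- data.frame(
        group = gname, zone = z, bin = seq_len(n_bins),
        x = (match(z, zones) - 1) + (seq_len(n_bins) - 0.5) / n_bins,
        mean_level = as.numeric(mlev),
        n_sites = ifelse(is.na(as.integer(nsite)), 0L, as.integer(nsite)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  out$mean_level[is.nan(out$mean_level)] <- NA_real_
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Classical MDS embedding of samples
#'
#' Torgerson metric scaling of Euclidean distances between per-sample
#' methylation-level vectors. Sites covered in every sample are used by
#' default; `impute = "mean"` instead fills missing levels with the site
#' mean. Coordinates are centred at the origin; each dimension's sign is
#' fixed so its first nonzero coordinate is positive.
#'
#' @param m a `methyl_matrix`
#' @param dims number of dimensions (default 2)
#' @param impute "complete" (default) or "mean"
#' @return matrix samples x dims with rownames = sample ids; attribute
#'   `n_sites_used` and `eig` (eigenvalues)
#' @export
mds_embedding <- function(m, dims = 2, impute = c("complete", "mean")) {
  impute <- match.arg(impute)
  ns <- nrow(m$samples)
  if (ns < dims + 1)
    stop("need at least dims + 1 samples", call. = FALSE)
  lev <- methyl_levels(m)
  if (impute == "complete") {
    keep <- rowSums(is.na(lev)) == 0
    lev <- lev[keep, , drop = FALSE]
  } else {
    rm <- rowMeans(lev, na.rm = TRUE)
    idx <- which(is.na(lev), arr.ind = TRUE)
    if (nrow(idx)) lev[idx] <- rm[idx[, 1]]
    lev <- lev[!is.na(rowMeans(lev)), , drop = FALSE]
  }
  if (nrow(lev) < dims)
    stop(sprintf("degenerate input: only %d usable sites for %d dimensions",
                 nrow(lev), dims), call. = FALSE)
  d <- stats::dist(t(lev))
  fit <- stats::cmdscale(d, k = dims, eig = TRUE)
  coords <- fit$points
  coords <- sweep(coords, 2, colMeans(coords))
  for (k in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, k]) > 1e-12)
    if (length(nz) && coords[nz[1], k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- m$samples$sample_id
  colnames(coords) <- paste0("dim", seq_len(dims))
  attr(coords, "n_sites_used") <- nrow(lev)
  attr(coords, "eig") <- fit$eig
  coords
}
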