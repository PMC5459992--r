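#' Construct a gene model
#'
#' Internal coordinates are 0-based half-open. The TSS is strand-aware: the
#' interval start for + genes and the last base (end - 1) for - genes; the
#' TES is the opposite extremity.
#'
#' @param genes data.frame: gene_id, chrom, strand ("+"/"-"), start, end
#'   (0-based half-open gene extent)
#' @param exons data.frame: gene_id, chrom, start, end (0-based half-open),
#'   each block within its gene extent
#' @return an object of class `gene_model`
#' @export
gene_model <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)))
  stopifnot(all(c("gene_id", "start", "end") %in% names(exons)))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  if (any(genes$end <= genes$start))
    stop("gene end must exceed start", call. = FALSE)
  ex <- merge(exons, genes[, c("gene_id", "start", "end")],
              by = "gene_id", suffixes = c("", "_gene"))
  if (any(ex$start < ex$start_gene | ex$end > ex$end_gene))
    stop("exon blocks must lie within their gene extent", call. = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tes <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  rownames(genes) <- NULL
  structure(list(genes = genes,
                 exons = exons[, c("gene_id", "start", "end")]),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %d genes, %d exon blocks on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons),
              length(unique(x$genes$chrom))))
  invisible(x)
}

#' Read a gene model from BED12 or GTF
#'
#' @param path file path
#' @param format "auto" (by extension), "bed12" or "gtf"
#' @return a `gene_model`
#' @export
read_gene_model <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  if (format == "bed12") {
    gr <- rtracklayer::import(path, format = "BED")
    genes <- data.frame(
      gene_id = as.character(gr$name),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    )
    bl <- rtracklayer::blocks(gr)
    nb <- S4Vectors::elementNROWS(bl)
    flat <- unlist(bl, use.names = FALSE)
    exons <- data.frame(
      gene_id = rep(genes$gene_id, nb),
      start = GenomicRanges::start(flat) - 1L,
      end = GenomicRanges::end(flat),
      stringsAsFactors = FALSE
    )
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    gid <- as.character(gr$gene_id)
    exons <- data.frame(
      gene_id = gid,
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    )
    sp <- split(seq_along(gr), gid)
    genes <- do.call(rbind, lapply(names(sp), function(g) {
      i <- sp[[g]]
      data.frame(gene_id = g,
                 chrom = as.character(GenomicRanges::seqnames(gr))[i[1]],
                 strand = as.character(GenomicRanges::strand(gr))[i[1]],
                 start = min(GenomicRanges::start(gr)[i]) - 1L,
                 end = max(GenomicRanges::end(gr)[i]),
                 stringsAsFactors = FALSE)
    }))
  }
  gene_model(genes, exons)
}

#' Simulate a compact gene model
#'
#' Random non-overlapping genes on one chromosome with 1-8 exon blocks each;
#' used to exercise annotation, metagene and integration stages against known
#' structure.
#'
#' @param n_genes number of genes
#' @param chrom chromosome name
#' @param span chromosome length in bp
#' @param seed master seed; draws use the "genemodel" substream
#' @return a `gene_model`
#' @export
simulate_gene_model <- function(n_genes = 80, chrom = "chr1", span = 2000000,
                                seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(seed, "genemodel"))
  slot <- floor(span / n_genes)
  if (slot < 6000) stop("span too small for n_genes", call. = FALSE)
  genes <- exons <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    len <- sample(2000:min(20000, slot - 4100), 1)
    start <- (g - 1L) * slot + sample.int(slot - len - 4001L, 1) + 2000L
    end <- start + len
    strand <- sample(c("+", "-"), 1)
    nex <- sample(1:8, 1)
    cuts <- sort(sample(seq(start, end - 50, by = 25), 2 * nex))
    ex <- data.frame(gene_id = sprintf("G%03d", g),
                     start = cuts[seq(1, 2 * nex, 2)],
                     end = cuts[seq(2, 2 * nex, 2)] + 25L)
    ex$end <- pmin(ex$end, end)
    genes[[g]] <- data.frame(gene_id = sprintf("G%03d", g), chrom = chrom,
                             strand = strand, start = start, end = end,
                             stringsAsFactors = FALSE)
    exons[[g]] <- ex
  }
  gene_model(do.call(rbind, genes), do.call(rbind, exons))
}

#' Annotate CpG sites to genomic elements
#'
#' Assigns each site to promoter (within +/- `window` bp of a strand-aware
#' TSS, closed interval), exon, intron or intergenic, with precedence
#' promoter > exon > intron. A site within several promoter windows is
#' resolved to the gene with the nearest TSS. Sites on chromosomes absent
#' from the gene model are intergenic (with one warning).
#'
#' @param sites data.frame with columns chrom, pos (0-based), or a
#'   `methyl_matrix`
#' @param gm a `gene_model`
#' @param window promoter half-width in bp (default 2000)
#' @return data.frame: site, chrom, pos, element, gene_id (NA when
#'   intergenic)
#' @export
annotate_sites <- function(sites, gm, window = 2000) {
  if (inherits(sites, "methyl_matrix")) sites <- sites$sites
  n <- nrow(sites)
  out <- data.frame(site = paste0(sites$chrom, ":", sites$pos),
                    chrom = sites$chrom, pos = sites$pos,
                    element = rep("intergenic", n),
                    gene_id = NA_character_,
                    stringsAsFactors = FALSE)
  if (n == 0 || nrow(gm$genes) == 0) return(out)
  known <- sites$chrom %in% gm$genes$chrom
  if (any(!known))
    warning("sites on chromosomes absent from the gene model ",
            "were annotated as intergenic", call. = FALSE)
  if (!any(known)) return(out)
  # overlaps run on known-chromosome sites only; indices map back via `kidx`
  kidx <- which(known)
  sites <- sites[known, , drop = FALSE]
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos + 1L, width = 1L))
  g <- gm$genes
  # closed promoter window [tss - w, tss + w] in 0-based coords
  pgr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(pmax(1L, g$tss + 1L - window),
                              g$tss + 1L + window))
  ph <- GenomicRanges::findOverlaps(sgr, pgr)
  if (length(ph)) {
    qh <- S4Vectors::queryHits(ph); sh <- S4Vectors::subjectHits(ph)
    dist <- abs(sites$pos[qh] - g$tss[sh])
    best <- tapply(seq_along(qh), qh, function(ii) ii[which.min(dist[ii])])
    qi <- kidx[as.integer(names(best))]; bi <- unlist(best)
    out$element[qi] <- "promoter"
    out$gene_id[qi] <- g$gene_id[sh[bi]]
  }
  egr <- GenomicRanges::GRanges(
    g$chrom[match(gm$exons$gene_id, g$gene_id)],
    IRanges::IRanges(gm$exons$start + 1L, gm$exons$end))
  todo <- out$element[kidx] == "intergenic"
  eh <- GenomicRanges::findOverlaps(sgr[todo], egr)
  if (length(eh)) {
    qi <- kidx[which(todo)][S4Vectors::queryHits(eh)]
    out$element[qi] <- "exon"
    out$gene_id[qi] <- gm$exons$gene_id[S4Vectors::subjectHits(eh)]
  }
  bgr <- GenomicRanges::GRanges(g$chrom,
                                IRanges::IRanges(g$start + 1L, g$end))
  todo <- out$element[kidx] == "intergenic"
  bh <- GenomicRanges::findOverlaps(sgr[todo], bgr)
  if (length(bh)) {
    qi <- kidx[which(todo)][S4Vectors::queryHits(bh)]
    out$element[qi] <- "intron"
    out$gene_id[qi] <- g$gene_id[S4Vectors::subjectHits(bh)]
  }
  out
}
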