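test_that("coverage tables round-trip through write and read", {
  cfg <- methyl_sim_config(n_sites = 200, seed = 8)
  m <- simulate_methyl_matrix(cfg)$matrix
  dir <- withr::local_tempdir()
  paths <- write_coverage_tables(m, dir)
  m2 <- read_coverage_tables(paths, m$samples)
  # sites never covered anywhere are not representable in coverage files
  covered <- rowSums(m$total) > 0
  expect_equal(m2$sites, m$sites[covered, ], ignore_attr = TRUE)
  expect_equal(unname(m2$meth), unname(m$meth[covered, ]))
  expect_equal(unname(m2$total), unname(m$total[covered, ]))
})

test_that("coverage reader interprets rows and rejects malformed input", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "s1.cov"); f2 <- file.path(dir, "s2.cov")
  writeLines("chr1\t100\t101\t50.0\t5\t5", f1)
  writeLines("chr2\t900\t901\t100.0\t7\t0", f2)
  md <- data.frame(sample_id = c("s1", "s2"),
                   generation = "F0", phenotype = "Addict")
  m <- read_coverage_tables(c(f1, f2), md)
  expect_equal(nrow(m$sites), 2)        # union of disjoint site sets
  expect_equal(m$sites$pos, c(99, 899)) # 1-based starts -> 0-based internal
  expect_equal(unname(m$meth["chr1:99", ]), c(5L, 0L))
  expect_equal(unname(m$total["chr1:99", ]), c(10L, 0L))
  expect_equal(methyl_levels(m)["chr1:99", "s1"], 0.5)

  writeLines(c("chr1\t100\t101\t50.0\t5\t5", "chr1\t100\t101\t20.0\t1\t4"),
             f1)
  expect_error(read_coverage_tables(c(f1, f2), md), "duplicated site")
  writeLines("chr1\t100\t101\t90.0\t5\t5", f1)
  expect_error(read_coverage_tables(c(f1, f2), md), "inconsistent")
  writeLines("chr1\t100\t101\t50.0\t5\t5", f1)
  expect_error(read_coverage_tables(c(f1, f2), md[1, ]), "does not cover")
})

test_that("site filter honours the detection-breadth boundary", {
  # 16 samples; site 1 covered >=5x in 7 samples, site 2 in 6, site 3 in 16
  lev <- matrix(0.5, 3, 16)
  m <- toy_matrix(lev, total = 10, generation = study_layout()$generation,
                  phenotype = study_layout()$phenotype)
  m$total[1, 8:16] <- 4L; m$meth[1, 8:16] <- 2L
  m$total[2, 7:16] <- 4L; m$meth[2, 7:16] <- 2L
  f <- filter_sites(m, min_samples_detected = 7, min_coverage = 5)
  expect_equal(f$sites$pos, m$sites$pos[c(1, 3)])
  # idempotence and subset property
  f2 <- filter_sites(f, 7, 5)
  expect_identical(f2$sites, f$sites)
  expect_true(all(paste(f$sites$chrom, f$sites$pos) %in%
                    paste(m$sites$chrom, m$sites$pos)))
  # fully permissive filter keeps every site with any coverage
  expect_equal(nrow(filter_sites(m, 1, 1)$sites), 3)
})

test_that("per-site Fisher p-values agree with the enumeration oracle", {
  expect_equal(fisher_p2x2(9, 1, 1, 9), 202 / 184756, tolerance = 1e-12)
  expect_equal(fisher_p2x2(5, 5, 5, 5), 1)
  set.seed(41)
  for (rep in 1:200) {
    n <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, runif(4)))
    p <- fisher_p2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p, fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the brute-force definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(43)
  for (rep in 1:50) {
    p <- runif(sample(1:100, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("dmc_test pools counts per phenotype and flags FDR significance", {
  gen <- c("F0", "F0"); phe <- c("Addict", "Non-addict")
  lev <- rbind(c(0.9, 0.1),  # 9/10 vs 1/10
               c(0.5, 0.5),
               c(NA, 0.5))   # zero coverage in Addict -> skipped
  m <- toy_matrix(lev, total = 10, generation = gen, phenotype = phe)
  tab <- dmc_test(m, "F0", alpha = 0.05)
  expect_equal(nrow(tab), 2)
  expect_equal(attr(tab, "skipped"), "chr1:300")
  i1 <- which(tab$site == "chr1:100")
  expect_equal(tab$p[i1], 202 / 184756, tolerance = 1e-12)
  expect_equal(tab$level_A[i1], 0.9)
  expect_equal(tab$level_N[i1], 0.1)
  expect_equal(tab$direction[i1], 1)
  i2 <- which(tab$site == "chr1:200")
  expect_equal(tab$p[i2], 1)
  expect_equal(tab$q, bh_oracle(tab$p), tolerance = 1e-12)
  expect_error(dmc_test(m, "F1"), "lacks")
})

test_that("maintained differences require significance in both generations with equal direction", {
  mk <- function(site, direction, significant) {
    d <- data.frame(site = site, direction = direction,
                    significant = significant)
    class(d) <- c("dmc_table", "data.frame"); d
  }
  f0 <- mk(c("chr1:1", "chr1:2", "chr1:3", "chr1:4"),
           c(1, 1, -1, 1), c(TRUE, TRUE, TRUE, FALSE))
  f1 <- mk(c("chr1:1", "chr1:2", "chr1:3", "chr1:4"),
           c(1, -1, -1, 1), c(TRUE, TRUE, TRUE, TRUE))
  out <- maintained_differences(f0, f1)
  expect_equal(out, c("chr1:1", "chr1:3"))  # direction-consistent only
  expect_lte(length(out), min(sum(f0$significant), sum(f1$significant)))
})

test_that("hypomethylation flag uses an inclusive 0.3 bound over covered samples", {
  lev <- rbind(c(0.1, 0.2, 0.30),
               c(0.1, 0.31, 0.2),
               c(0, NA, NA),
               c(NA, NA, NA))
  m <- toy_matrix(lev, total = 100,
                  generation = rep("F0", 3),
                  phenotype = rep("Addict", 3))
  h <- hypo_flag(m, threshold = 0.3)
  expect_equal(unname(h), c(TRUE, FALSE, TRUE, NA))
})

test_that("enrichment odds ratios, Wald CIs and symmetry", {
  e <- enrichment(10, 10, 10, 10)
  expect_equal(e$odds_ratio, 1)
  expect_true(e$ci95[1] < 1 && e$ci95[2] > 1)

  e2 <- enrichment(20, 10, 30, 60)
  expect_equal(e2$odds_ratio, 4)
  expect_equal(e2$ci95, c(1.66491, 9.61012), tolerance = 1e-4)
  expect_true(e2$ci95[1] <= e2$odds_ratio && e2$odds_ratio <= e2$ci95[2])

  e3 <- enrichment(30, 60, 20, 10)  # swapped rows
  expect_equal(e3$odds_ratio, 1 / e2$odds_ratio, tolerance = 1e-12)

  e4 <- enrichment(5, 0, 3, 7)      # Haldane correction engages
  expect_equal(e4$odds_ratio, 5.5 * 7.5 / (0.5 * 3.5))
  expect_error(enrichment(0, 0, 0, 0), "all-zero")
})

test_that("metagene profile is flat under uniform methylation and reports empty bins as NA", {
  gm <- gene_model(
    genes = data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                       start = 10000L, end = 20000L),
    exons = data.frame(gene_id = "g1", start = 10000L, end = 20000L))
  pos <- as.integer(seq(8000, 22000, by = 120))
  lev <- matrix(0.8, length(pos), 2)
  m <- toy_matrix(lev, total = 10, generation = c("F0", "F0"),
                  phenotype = c("Saline", "Saline"), pos = pos)
  pr <- metagene_profile(m, gm, n_bins = 10)
  expect_equal(unique(pr$group), "Saline-F0")
  expect_true(all(abs(pr$mean_level - 0.8) < 1e-12, na.rm = TRUE))
  expect_false(any(is.na(pr$mean_level[pr$n_sites > 0])))

  # remove every site of one upstream bin: reported NA, not zero
  drop <- pos >= 8000 & pos < 8200
  m2 <- toy_matrix(lev[!drop, , drop = FALSE], total = 10,
                   generation = c("F0", "F0"),
                   phenotype = c("Saline", "Saline"), pos = pos[!drop])
  pr2 <- metagene_profile(m2, gm, n_bins = 10)
  first_up <- pr2$zone == "upstream" & pr2$bin == 1
  expect_true(is.na(pr2$mean_level[first_up]))
  expect_equal(pr2$n_sites[first_up], 0L)
})

test_that("metagene profile reverses minus-strand genes", {
  mkgm <- function(strand) gene_model(
    genes = data.frame(gene_id = "g1", chrom = "chr1", strand = strand,
                       start = 10000L, end = 20000L),
    exons = data.frame(gene_id = "g1", start = 10000L, end = 20000L))
  pos <- as.integer(seq(8000, 22000, by = 50))
  # methylation rises linearly with genomic coordinate
  lev <- matrix((pos - 8000) / 14000, ncol = 1)
  m <- toy_matrix(lev, total = 1000, generation = "F0", phenotype = "Saline",
                  pos = pos)
  fwd <- metagene_profile(m, mkgm("+"), n_bins = 10)
  rev <- metagene_profile(m, mkgm("-"), n_bins = 10)
  expect_true(all(diff(fwd$mean_level[fwd$zone == "body"]) > 0))
  expect_true(all(diff(rev$mean_level[rev$zone == "body"]) < 0))
  # upstream of the minus-strand TSS lies at high genomic coordinates
  expect_gt(mean(rev$mean_level[rev$zone == "upstream"]),
            mean(rev$mean_level[rev$zone == "downstream"]))
})

test_that("classical MDS reproduces planar distances and handles duplicates", {
  # three level vectors with pairwise Euclidean distances 3, 4, 5
  lev <- matrix(0, 41, 3)
  lev[1:25, 2] <- 0.6
  lev[26:41, 3] <- 1.0
  m <- toy_matrix(lev, total = 10, generation = rep("F0", 3),
                  phenotype = c("Saline", "Addict", "Non-addict"))
  xy <- mds_embedding(m, dims = 2)
  d <- as.matrix(dist(xy))
  expect_equal(d["S01", "S02"], 3, tolerance = 1e-9)
  expect_equal(d["S01", "S03"], 4, tolerance = 1e-9)
  expect_equal(d["S02", "S03"], 5, tolerance = 1e-9)
  expect_equal(colMeans(xy), c(dim1 = 0, dim2 = 0), tolerance = 1e-12)

  lev4 <- cbind(lev, lev[, 2])
  m4 <- toy_matrix(lev4, total = 10, generation = rep("F0", 4),
                   phenotype = c("Saline", "Addict", "Non-addict", "Addict"))
  xy4 <- mds_embedding(m4, dims = 2)
  expect_equal(unname(xy4["S02", ]), unname(xy4["S04", ]), tolerance = 1e-9)
})

test_that("MDS uses complete-case sites by default and errors when degenerate", {
  lev <- rbind(c(0.2, 0.4, 0.6), c(NA, 0.5, 0.5), c(0.8, 0.2, 0.1))
  m <- toy_matrix(lev, total = 10, generation = rep("F0", 3),
                  phenotype = rep("Addict", 3))
  xy <- mds_embedding(m, dims = 2)
  expect_equal(attr(xy, "n_sites_used"), 2)
  xym <- mds_embedding(m, dims = 2, impute = "mean")
  expect_equal(attr(xym, "n_sites_used"), 3)

  lev1 <- matrix(c(0.2, 0.4, 0.6), 1)
  m1 <- toy_matrix(lev1, total = 10, generation = rep("F0", 3),
                   phenotype = rep("Addict", 3))
  expect_error(mds_embedding(m1, dims = 2), "degenerate")
  expect_error(mds_embedding(m, dims = 3), "dims \\+ 1|at least")
})

test_that("the pooled exact test is calibrated under its own binomial model", {
  # with no extra-binomial variation, a null methylome yields (essentially)
  # no FDR discoveries
  for (s in 1:2) {
    cfg <- methyl_sim_config(n_sites = 10000, n_planted_dmcs = 0,
                             overdispersion = 0, seed = 300 + s)
    m <- filter_sites(simulate_methyl_matrix(cfg)$matrix)
    expect_lte(sum(dmc_test(m, "F0")$significant), 10)  # <= 0.1% of sites
  }
})

test_that("promoter-biased planted sites produce promoter enrichment with CI above 1", {
  hits <- 0
  for (s in 1:10) {
    gm <- simulate_gene_model(n_genes = 80, seed = s)
    cfg <- methyl_sim_config(n_sites = 4000, n_planted_dmcs = 200,
                             planted_effect = 2.5, coverage_mean = 60,
                             gene_model = gm,
                             promoter_site_fraction = 0.35,
                             planted_promoter_fraction = 0.8, seed = s)
    sim <- simulate_methyl_matrix(cfg)
    m <- filter_sites(sim$matrix)
    mt <- maintained_differences(dmc_test(m, "F0"), dmc_test(m, "F1"))
    ann <- annotate_sites(m, gm)
    is_m <- ann$site %in% mt
    is_p <- ann$element == "promoter"
    e <- enrichment(sum(is_p & is_m), sum(!is_p & is_m),
                    sum(is_p & !is_m), sum(!is_p & !is_m))
    hits <- hits + (e$odds_ratio > 1 && e$ci95[1] > 1)
  }
  expect_gte(hits, 9)
})
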