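test_that("CpG counts follow the geometric-gap expectation", {
  spec <- genome_spec(chrom_lengths = c(chr1 = 1e5),
                      cpg_spacing_mean = 100, cgi_count = 0,
                      n_genes = 2, seed = 11)
  g <- simulate_genome(spec)
  n <- nrow(g$cpg_map)
  expect_gt(n, 1000 - 4 * sqrt(1000))
  expect_lt(n, 1000 + 4 * sqrt(1000))
  expect_true(all(g$cpg_map$pos >= 1 & g$cpg_map$pos <= 1e5 - 1))
  expect_true(all(diff(g$cpg_map$pos) >= 2))
})

test_that("genome generation is deterministic and respects empty cases", {
  spec <- genome_spec(chrom_lengths = c(chr1 = 2e5), cgi_count = 0,
                      n_genes = 3, seed = 5)
  g1 <- simulate_genome(spec)
  g2 <- simulate_genome(spec)
  expect_identical(g1$cpg_map, g2$cpg_map)
  expect_identical(g1$genes, g2$genes)
  expect_equal(nrow(g1$cgi), 0)
})

test_that("island CpG density is at least five-fold background", {
  spec <- genome_spec(chrom_lengths = c(chr1 = 1e6), cgi_count = 10,
                      cgi_length_bp = 1000, n_genes = 2, seed = 3)
  g <- simulate_genome(spec)
  in_cgi <- !is.na(methylfate:::interval_index(g$cpg_map$chrom,
                                               g$cpg_map$pos, g$cgi))
  cgi_bp <- sum(g$cgi$end - g$cgi$start)
  dens_cgi <- sum(in_cgi) / cgi_bp
  dens_bg <- sum(!in_cgi) / (1e6 - cgi_bp)
  expect_gte(dens_cgi, 5 * dens_bg)
})

test_that("invalid genome specs are rejected", {
  expect_error(genome_spec(chrom_lengths = c(chr1 = 1500),
                           cgi_length_bp = 1000, cgi_count = 2),
               "shorter than")
  expect_error(genome_spec(chrom_lengths = c(1e5)), "named")
})

test_that("plant_features keeps exact bookkeeping", {
  g <- simulate_genome(genome_spec(chrom_lengths = c(chr1 = 1e6,
                                                     chr2 = 1e6,
                                                     chrX = 3e5,
                                                     chrY = 1e5),
                                   cgi_count = 60, seed = 2))
  tr <- plant_features(g, dmr_n = 10, pmd_n = 3,
                       pmd_length_bp = c(5e4, 1e5), seed = 4)
  feats <- tr$features
  dmrs <- dplyr::filter(feats, kind == "gamete_dmr")
  expect_equal(nrow(dmrs), 20)
  expect_equal(sum(dmrs$origin == "maternal"), 10)
  pmds <- dplyr::filter(feats, kind == "pmd")
  expect_equal(nrow(pmds), 3)
  # pmds pairwise disjoint
  for (i in seq_len(nrow(pmds))) {
    for (j in seq_len(nrow(pmds))[-i]) {
      same <- pmds$chrom[i] == pmds$chrom[j]
      expect_false(same && pmds$start[i] < pmds$end[j] &&
                     pmds$end[i] > pmds$start[j])
    }
  }
  expect_false(anyDuplicated(feats$feature_id) > 0)
  # no xi features when disabled
  tr0 <- plant_features(g, dmr_n = 2, pmd_n = 0, xi_fraction = 0,
                        seed = 4)
  expect_equal(sum(tr0$features$kind == "xi_block"), 0)
})

test_that("every planted feature contains a CpG and DMRs avoid PMDs", {
  tr <- acc_study()$truth
  g <- acc_study()$genome
  feats <- tr$features
  hits <- vapply(seq_len(nrow(feats)), function(i) {
    any(g$cpg_map$chrom == feats$chrom[i] &
          g$cpg_map$pos > feats$start[i] &
          g$cpg_map$pos <= feats$end[i])
  }, logical(1))
  expect_true(all(hits))
  dmr <- dplyr::filter(feats, kind == "gamete_dmr")
  pmd <- dplyr::filter(feats, kind == "pmd")
  expect_false(any(methylfate:::overlaps_any(dmr$chrom, dmr$start,
                                             dmr$end, pmd)))
})

test_that("simulated samples hit their target mean methylation", {
  study <- acc_study()
  sperm <- summarize_calls(filter_coverage(acc_calls()$sperm, 5))
  expect_equal(sperm$mean_meth, 0.77, tolerance = 0.015)
  oocyte <- summarize_calls(filter_coverage(acc_calls()$oocyte, 5))
  expect_equal(oocyte$mean_meth, 0.65, tolerance = 0.015)
})

test_that("pooled mean converges to the target at deep coverage", {
  spec <- genome_spec(chrom_lengths = c(chr1 = 1e6), cgi_count = 10,
                      n_genes = 2, seed = 9)
  g <- simulate_genome(spec)
  samp <- sample_spec("deep", 0.65, coverage_mean = 50,
                      conversion_error = 0)
  tr <- plant_features(g, samples = samp, dmr_n = 0, pmd_n = 0,
                       xi_fraction = 0, escapee_n = 0, seed = 9)
  calls <- destrand(simulate_sample(g, tr, samp, seed = 10)$calls)
  expect_equal(summarize_calls(calls)$mean_meth, 0.65,
               tolerance = 0.005)
})

test_that("degenerate sampling cases behave exactly", {
  spec <- genome_spec(chrom_lengths = c(chr1 = 5e4), cgi_count = 0,
                      n_genes = 1, seed = 1)
  g <- simulate_genome(spec)
  samp <- sample_spec("zero", 0, conversion_error = 0,
                      beta_dispersion = Inf)
  tr <- plant_features(g, samples = samp, dmr_n = 0, pmd_n = 0,
                       xi_fraction = 0, escapee_n = 0, seed = 1)
  s <- simulate_sample(g, tr, samp, seed = 2)
  expect_true(all(s$calls$n_meth == 0))
})

test_that("strand split conserves coverage per CpG", {
  s <- acc_study()$samples$sperm
  by_site <- dplyr::group_by(s$calls,
                             chrom, cpg = ifelse(strand == "-", pos - 1L,
                                                 pos))
  tot <- dplyr::summarise(by_site, cov = sum(n_meth + n_unmeth),
                          n = dplyr::n(), .groups = "drop")
  expect_true(all(tot$n == 2))
  # destranded coverage equals the stranded total
  d <- destrand(s$calls)
  expect_identical(sum(d$n_meth) + sum(d$n_unmeth),
                   sum(s$calls$n_meth) + sum(s$calls$n_unmeth))
})

test_that("sample simulation and study writing are byte-deterministic", {
  spec <- genome_spec(chrom_lengths = c(chr1 = 1e5, chrX = 5e4,
                                        chrY = 2e4),
                      cgi_count = 4, n_genes = 6, seed = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  samples <- default_sample_specs()[c(1, 2, 4), ]
  simulate_study(spec, samples = samples, seed = 77, outdir = d1,
                 dmr_n = 2, pmd_n = 0)
  simulate_study(spec, samples = samples, seed = 77, outdir = d2,
                 dmr_n = 2, pmd_n = 0)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("X/pseudo-Y count simulation matches its sampling model", {
  tr <- acc_study()$truth
  xy_f <- simulate_xy_counts(tr, "oocyte", noise_frac = 0, seed = 1)
  expect_identical(xy_f$y_reads, 0L)
  ys <- vapply(1:50, function(i) {
    simulate_xy_counts(tr, "sperm", lambda_y = 500, seed = i)$y_reads
  }, integer(1))
  expect_true(all(ys >= 400 & ys <= 600))
  xy_p <- simulate_xy_counts(tr, "E3.5", seed = 2)
  expect_identical(xy_p$sex_true, "pooled")
})

test_that("the truth ledger lists every feature exactly once on disk", {
  tr <- acc_study()$truth
  path <- withr::local_tempfile()
  write_truth(tr, path)
  lines <- readLines(path)
  expect_identical(lines[1], "# methylfate_truth v1")
  body <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  expect_equal(nrow(body), nrow(tr$features))
  expect_false(anyDuplicated(body$feature_id) > 0)
})
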