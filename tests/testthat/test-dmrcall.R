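test_that("tiling partitions chromosomes with a clipped final tile", {
  tg <- tile_genome(c(chr1 = 250), 100)
  expect_identical(tg$start, c(0L, 100L, 200L))
  expect_identical(tg$end, c(100L, 200L, 250L))
  # every destranded site maps to exactly one tile
  a <- make_calls("chr1", c(1, 100, 101, 199, 249), rep(2, 5), rep(2, 5))
  tiles <- tile_counts(a, a, min_reads = 0, min_cpg = 0,
                       chrom_lengths = c(chr1 = 250))
  expect_identical(sum(tiles$n_cpg), nrow(a))
  # pos 100 is in [0,100) (1-based pos -> 0-based 99), pos 101 in
  # [100,200)
  expect_identical(tiles$n_cpg[tiles$start == 0], 2L)
})

test_that("tiles need minimum reads in both conditions and one CpG", {
  a <- make_calls("chr1", 50, 2, 1)   # cov 3
  b <- make_calls("chr1", 50, 1, 1)   # cov 2
  expect_equal(nrow(tile_counts(a, b)), 0)
  expect_equal(nrow(tile_counts(b, a)), 0)
  b3 <- make_calls("chr1", 50, 2, 1)
  expect_equal(nrow(tile_counts(a, b3)), 1)
  expect_error(tile_counts(a, b3, tile_bp = 0), "tile_bp")
})

test_that("the exact test reproduces hand-enumerable cases", {
  expect_equal(exact_meth_test(2, 0, 0, 2), 1 / 3, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(exact_meth_test(5, 5, 5, 5), 1, ignore_attr = TRUE)
  p0 <- exact_meth_test(0, 0, 3, 2)
  expect_equal(as.numeric(p0), 1)
  expect_equal(attr(p0, "n_zero_margin"), 1)
  expect_error(exact_meth_test(-1, 2, 3, 4), "non-negative")
})

test_that("the exact test agrees with stats::fisher.test", {
  withr::local_seed(4)
  for (i in 1:100) {
    N <- sample(4:60, 1)
    ca <- sample(1:(N - 1), 1); K <- sample(1:(N - 1), 1)
    a <- sample(max(0, ca - (N - K)):min(ca, K), 1)
    u <- ca - a; b <- K - a; v <- (N - ca) - b
    p_ref <- stats::fisher.test(matrix(c(a, u, b, v), 2,
                                       byrow = TRUE))$p.value
    expect_equal(as.numeric(exact_meth_test(a, u, b, v)), p_ref,
                 tolerance = 1e-7)
  }
})

test_that("BH adjustment matches the hand-applied step-up", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.123), 0.123)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  # NA excluded from m: only two tests
  expect_equal(adjust_fdr(c(0.02, NA, 0.04)), c(0.04, NA, 0.04))
  # permutation invariance and rank monotonicity
  withr::local_seed(8)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(adjust_fdr(p)[perm], adjust_fdr(p[perm]))
  q <- adjust_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q >= p & q <= 1))
})

test_that("DMR thresholds act exactly as printed and monotonically", {
  tiles <- tibble::tibble(
    chrom = "chr1", start = c(0L, 100L, 200L), end = c(100L, 200L, 300L),
    n_cpg = 2L, meth_a = c(17L, 17L, 10L), cov_a = 20L,
    meth_b = c(0L, 0L, 10L), cov_b = 20L,
    meth_pct_a = c(85, 85, 50), meth_pct_b = c(0, 0, 50),
    diff = c(85, 85, 0), p = c(1e-6, 1e-6, 1), q = c(0.001, 0.02, 1))
  d <- call_dmrs(tiles)
  expect_equal(nrow(d), 1)
  expect_identical(d$label, "sperm_specific")
  expect_identical(d$start, 0L)
  # permissive thresholds return every tile; raising difference never
  # adds calls
  expect_equal(nrow(call_dmrs(tiles, difference = 0, qvalue = 1.01)), 3)
  tt <- acc_tiles()
  n80 <- nrow(call_dmrs(tt, difference = 80))
  n90 <- nrow(call_dmrs(tt, difference = 90))
  expect_lte(n90, n80)
})

test_that("annotation follows CGI > promoter > intragenic > intergenic", {
  genes <- tibble::tibble(chrom = "chr1", start = 1000L, end = 5000L,
                          name = "g1", score = 0, strand = "+")
  cgi <- tibble::tibble(chrom = "chr1", start = 2000L, end = 2500L)
  dmrs <- tibble::tibble(chrom = "chr1",
                         start = c(2100L, 3000L, 9000L, 500L),
                         end = c(2200L, 3100L, 9100L, 600L))
  ann <- annotate_dmrs(dmrs, genes = genes, cgi = cgi)
  expect_identical(ann$feature_class,
                   c("CGI", "intragenic", "intergenic", "promoter"))
  bad <- tibble::tibble(chrom = "chr1", start = 10L, end = 10L)
  expect_error(annotate_dmrs(dmrs, genes = bad), "end <= start")
})

test_that("merging bridges small gaps but never labels", {
  tiles <- tibble::tibble(
    chrom = "chr1", start = c(0L, 100L, 500L, 900L),
    end = c(100L, 200L, 600L, 1000L),
    label = c("sperm_specific", "sperm_specific", "oocyte_specific",
              "sperm_specific"),
    n_cpg = 2L, meth_a = 10L, cov_a = 12L, meth_b = 1L, cov_b = 12L,
    meth_pct_a = 83.3, meth_pct_b = 8.3, diff = 75, q = 1e-4)
  m <- merge_dmrs(tiles, max_gap = 300)
  expect_equal(nrow(m), 3)
  first <- dplyr::filter(m, start == 0)
  expect_identical(first$end, 200L)
  expect_identical(first$n_tiles, 2L)
  expect_identical(first$cov_a, 24L)
})

test_that("site-level testing reports stability against change", {
  a <- make_calls("chr1", 1:50 * 10, rep(6, 50), rep(4, 50))
  d <- diff_sites(a, a)
  expect_equal(d$fraction_stable, 1)
  b <- make_calls("chr2", 1:10, rep(6, 10), rep(4, 10))
  expect_error(diff_sites(a, b), "no shared sites")
})

test_that("a planted global methylation drop is powerfully detected", {
  spec <- genome_spec(chrom_lengths = c(chr1 = 3e5), cgi_count = 0,
                      n_genes = 2, seed = 31)
  g <- simulate_genome(spec)
  samples <- dplyr::bind_rows(
    sample_spec("high", 0.77, coverage_mean = 20, beta_dispersion = Inf,
                conversion_error = 0),
    sample_spec("low", 0.16, coverage_mean = 20, beta_dispersion = Inf,
                conversion_error = 0))
  tr <- plant_features(g, samples = samples, dmr_n = 0, pmd_n = 0,
                       xi_fraction = 0, escapee_n = 0, seed = 31)
  a <- destrand(simulate_sample(g, tr, samples[1, ], seed = 32)$calls)
  b <- destrand(simulate_sample(g, tr, samples[2, ], seed = 33)$calls)
  d <- diff_sites(a, b, min_cov = 5)
  expect_lt(d$fraction_stable, 0.5)
})

test_that("meta-profiles recover flat and carved landscapes", {
  pos <- seq(10, 19990, by = 25)
  calls <- make_calls("chr1", pos, rep(7, length(pos)),
                      rep(3, length(pos)))
  iv <- tibble::tibble(chrom = "chr1", start = c(5000L, 12000L),
                       end = c(7000L, 14000L), strand = c("+", "-"))
  prof <- meta_profile(calls, iv)
  expect_true(all(abs(prof$mean_meth - 0.7) < 1e-9, na.rm = TRUE))
  expect_error(meta_profile(calls, iv[0, ]), "at least one interval")
  # hypomethylated bodies on a high background give a U-shape
  body <- pos >= 5000 & pos < 7000 | pos >= 12000 & pos < 14000
  carved <- make_calls("chr1", pos,
                       ifelse(body, 1, 8), ifelse(body, 9, 2))
  prof2 <- meta_profile(carved, iv)
  expect_true(all(prof2$mean_meth[prof2$zone == "body"] < 0.2))
  expect_true(all(prof2$mean_meth[prof2$zone != "body"] > 0.7,
                  na.rm = TRUE))
})

test_that("minus-strand intervals are read 5' to 3'", {
  pos <- seq(10, 4990, by = 20)
  # gradient rising with coordinate
  m <- as.integer(round(9 * (pos / 5000)))
  calls <- make_calls("chr1", pos, m, 9L - m)
  plus <- tibble::tibble(chrom = "chr1", start = 1000L, end = 4000L,
                         strand = "+")
  minus <- dplyr::mutate(plus, strand = "-")
  p_plus <- meta_profile(calls, plus, flank = 500)
  p_minus <- meta_profile(calls, minus, flank = 500)
  body_p <- p_plus$mean_meth[p_plus$zone == "body"]
  body_m <- p_minus$mean_meth[p_minus$zone == "body"]
  expect_equal(body_m, rev(body_p))
})
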