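test_that("stage methylation pools counts and respects the read floor", {
  dmrs <- tibble::tibble(chrom = "chr1", start = c(0L, 200L),
                         end = c(100L, 300L))
  st <- list(
    E3.5 = make_calls("chr1", c(10, 50, 250), c(3, 2, 2), c(3, 2, 2)),
    brain = make_calls("chr1", c(10, 250), c(1, 5), c(1, 0)))
  m <- stage_methylation(dmrs, st, stage_min_reads = 3)
  expect_equal(m$meth_E3.5, c(50, 50))
  expect_true(is.na(m$meth_brain[1]))  # 2 reads < 3
  expect_equal(m$meth_brain[2], 100)
  expect_warning(
    stage_methylation(dmrs, list(liver = make_calls(character(0),
                                                    integer(0),
                                                    integer(0),
                                                    integer(0)))),
    "empty")
})

test_that("fate classification follows the printed intermediate rules", {
  mk <- function(e35, ed, te, br, li, sp) {
    tibble::tibble(chrom = "chr1", start = 0L, end = 100L,
                   meth_E3.5 = e35, `meth_E7.5_ED` = ed,
                   `meth_E7.5_TE` = te, meth_brain = br,
                   meth_liver = li, meth_spleen = sp)
  }
  expect_identical(classify_fates(mk(50, 50, 50, 50, 48, 55))$fate,
                   "lifelong")
  expect_identical(classify_fates(mk(50, 85, 45, 80, 80, 80))$fate,
                   "TE_retained")
  expect_identical(classify_fates(mk(75, 50, 50, 50, 50, 50))$fate,
                   "not_established")
  expect_identical(classify_fates(mk(50, 50, 85, 85, 85, 85))$fate,
                   "ED_retained")
  expect_identical(classify_fates(mk(50, 85, 85, 85, 85, 85))$fate,
                   "transient_embryonic")
  # inclusive band edges
  expect_identical(classify_fates(mk(40, 60, 85, 85, 85, 85))$fate,
                   "ED_retained")
  # a missing stage falsifies the clause it gates
  expect_identical(classify_fates(mk(50, NA, 50, 50, 50, 50))$fate,
                   "TE_retained")
  expect_identical(classify_fates(mk(NA, 50, 50, 50, 50, 50))$fate,
                   "not_established")
  # joint lineage retention is its own column
  both <- classify_fates(mk(50, 50, 50, 85, 85, 85))
  expect_identical(both$fate, "ED_retained")
  expect_true(both$retained_both_lineages)
})

test_that("fate labels partition and widen monotonically", {
  withr::local_seed(5)
  n <- 300
  grid <- tibble::tibble(
    chrom = "chr1", start = seq_len(n) * 100L,
    end = seq_len(n) * 100L + 50L,
    meth_E3.5 = runif(n, 0, 100), `meth_E7.5_ED` = runif(n, 0, 100),
    `meth_E7.5_TE` = runif(n, 0, 100), meth_brain = runif(n, 0, 100),
    meth_liver = runif(n, 0, 100), meth_spleen = runif(n, 0, 100))
  f1 <- classify_fates(grid)
  expect_true(all(f1$fate %in% c("not_established", "lifelong",
                                 "ED_retained", "TE_retained",
                                 "transient_embryonic")))
  f2 <- classify_fates(grid, intermediate = c(30, 70))
  was_lifelong <- f1$fate == "lifelong"
  expect_true(all(f2$fate[was_lifelong] == "lifelong"))
})

test_that("classification is exact on analytic stage means", {
  truth <- fate_study()$truth
  dmr <- dplyr::filter(truth$features, kind == "gamete_dmr")
  eff <- function(s) {
    100 * vapply(dmr$effect, function(e) unname(e[[s]]), numeric(1))
  }
  analytic <- tibble::tibble(
    chrom = dmr$chrom, start = dmr$start, end = dmr$end,
    meth_E3.5 = eff("E3.5"), `meth_E7.5_ED` = eff("E7.5_ED"),
    `meth_E7.5_TE` = eff("E7.5_TE"), meth_brain = eff("brain"),
    meth_liver = eff("liver"), meth_spleen = eff("spleen"))
  called <- classify_fates(analytic)$fate
  planted <- ifelse(dmr$fate == "transient", "transient_embryonic",
                    dmr$fate)
  expect_identical(called, planted)
})

test_that("nearest-gene assignment uses half-open gaps and tie rules", {
  genes <- tibble::tibble(chrom = "chr1",
                          start = c(2000L, 5000L), end = c(3000L, 6000L),
                          name = c("gA", "gB"))
  iv <- tibble::tibble(chrom = "chr1", start = 1000L, end = 1100L)
  ng <- nearest_gene(iv, genes)
  expect_identical(ng$nearest_gene, "gA")
  expect_equal(ng$distance_bp, 900)
  inside <- nearest_gene(tibble::tibble(chrom = "chr1", start = 2500L,
                                        end = 2600L), genes)
  expect_equal(inside$distance_bp, 0)
  # equidistant: smaller start coordinate wins
  tie_genes <- tibble::tibble(chrom = "chr1",
                              start = c(3000L, 1000L),
                              end = c(3500L, 1500L),
                              name = c("late", "early"))
  tie <- nearest_gene(tibble::tibble(chrom = "chr1", start = 2000L,
                                     end = 2500L), tie_genes)
  expect_identical(tie$nearest_gene, "early")
  # no gene on the chromosome: unassigned
  off <- nearest_gene(tibble::tibble(chrom = "chr9", start = 1L,
                                     end = 2L), genes)
  expect_true(is.na(off$nearest_gene))
})

test_that("track_fates excludes X by default and maps origin from labels", {
  dmrs <- tibble::tibble(chrom = c("chr1", "chrX"),
                         start = c(0L, 0L), end = c(100L, 100L),
                         label = c("oocyte_specific", "sperm_specific"))
  st <- list(E3.5 = make_calls("chr1", 10, 5, 5),
             `E7.5_ED` = make_calls("chr1", 10, 5, 5),
             `E7.5_TE` = make_calls("chr1", 10, 5, 5),
             brain = make_calls("chr1", 10, 5, 5),
             liver = make_calls("chr1", 10, 5, 5),
             spleen = make_calls("chr1", 10, 5, 5))
  f <- track_fates(dmrs, st)
  expect_equal(nrow(f), 1)
  expect_identical(f$origin, "maternal")
  expect_identical(f$fate, "lifelong")
})

test_that("fate reports count by origin and handle edge cases", {
  recs <- tibble::tibble(
    fate = c("lifelong", "lifelong", "transient_embryonic"),
    origin = c("maternal", "maternal", "paternal"))
  r <- fate_report(recs)
  expect_equal(r$n, 3)
  expect_equal(r$prop_maternal_lifelong, 1)
  expect_equal(sum(r$counts$n), 3)
  r0 <- fate_report(recs[0, ])
  expect_equal(r0$n, 0)
  expect_true(is.nan(r0$prop_maternal_lifelong))
})
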