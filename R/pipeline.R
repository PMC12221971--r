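#' Run the demonstration pipeline end to end
#'
#' Simulates a compact developmental-methylome study, writes its call
#' files, then runs every analysis stage from those files: destranding and
#' pooling, gamete tile testing and DMR calling with annotation, fate
#' tracking across stages with nearest genes, methylome segmentation and
#' PMD flagging for the two E7.5 lineages, embryo sexing, and
#' allele-specific X analysis. All outputs are written as TSV under
#' `outdir`; the run is fully determined by `seed` (identical seeds give
#' byte-identical files).
#'
#' @param outdir Output directory.
#' @param seed Integer seed.
#' @param spec Genome specification (default: a compact 2.55 Mb genome so
#'   the demo runs in seconds).
#' @param dmr_n Planted gamete DMRs per origin.
#' @param pmd_n Planted trophectoderm PMDs.
#' @return Invisibly, a list with the main result objects (`dmrs`,
#'   `fates`, `report`, `segments_te`, `segments_ed`, `sex_calls`,
#'   `allele_x`).
#' @export
run_demo <- function(outdir, seed = 1729,
                     spec = genome_spec(chrom_lengths = c(chr1 = 1.2e6,
                                                          chr2 = 1e6,
                                                          chrX = 3e5,
                                                          chrY = 5e4),
                                        cgi_count = 60, n_genes = 40),
                     dmr_n = 15, pmd_n = 2) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  simdir <- file.path(outdir, "sim")
  samples <- dplyr::bind_rows(
    default_sample_specs(),
    sample_spec("adult_f", 0.70, role = "adult", sex = "female"),
    sample_spec("adult_m", 0.70, role = "adult", sex = "male"))
  study <- simulate_study(spec, samples = samples, seed = seed,
                          outdir = simdir,
                          dmr_n = dmr_n, pmd_n = pmd_n,
                          fate_counts = c(transient = 6, ED_retained = 3,
                                          TE_retained = 3, lifelong = 3))

  # ingest from the written files, as a real analysis would
  calls <- purrr::map(names(study$samples), function(nm) {
    read_calls(file.path(simdir, paste0(nm, ".CpG_report.txt")),
               "cytosine_report") %>%
      destrand()
  })
  names(calls) <- names(study$samples)
  filt <- purrr::map(calls, filter_coverage, min_cov = 5)

  summaries <- purrr::map2(filt, names(filt),
                           ~ summarize_calls(.x, sample = .y)) %>%
    bind_rows() %>%
    select(-"hist")
  readr::write_tsv(summaries, file.path(outdir, "sample_summaries.tsv"),
                   progress = FALSE)

  tiles <- tile_counts(calls$sperm, calls$oocyte,
                       chrom_lengths = spec$chrom_lengths) %>%
    test_tiles()
  dmrs <- call_dmrs(tiles) %>%
    annotate_dmrs(genes = study$genome$genes, cgi = study$genome$cgi)
  readr::write_tsv(dmrs, file.path(outdir, "gamete_dmrs.tsv"),
                   progress = FALSE)

  stages <- calls[c("E3.5", "E7.5_ED", "E7.5_TE", "brain", "liver",
                    "spleen")]
  fates <- track_fates(merge_dmrs(dmrs), stages,
                       genes = study$genome$genes)
  readr::write_tsv(as_tibble(fates), file.path(outdir, "dmr_fates.tsv"),
                   progress = FALSE)
  report <- fate_report(fates)
  readr::write_tsv(report$counts, file.path(outdir, "fate_counts.tsv"),
                   progress = FALSE)

  seg_in <- function(nm) {
    shared <- semi_join(filt[[nm]],
                        filt[[setdiff(c("E7.5_ED", "E7.5_TE"), nm)]],
                        by = c("chrom", "pos"))
    set_destranded(shared)
  }
  segments_te <- segment_methylome(seg_in("E7.5_TE")) %>% flag_pmds()
  segments_ed <- segment_methylome(seg_in("E7.5_ED")) %>% flag_pmds()
  readr::write_tsv(as_tibble(segments_te),
                   file.path(outdir, "segments_TE.tsv"), progress = FALSE)
  readr::write_tsv(as_tibble(segments_ed),
                   file.path(outdir, "segments_ED.tsv"), progress = FALSE)

  sex_calls <- infer_sex(study$xy)
  readr::write_tsv(sex_calls, file.path(outdir, "sex_calls.tsv"),
                   progress = FALSE)

  female <- names(study$samples)[study$specs$sex == "female" &
                                   study$specs$role == "adult"][1]
  allele_x <- allele_compare(study$samples[[female]]$maternal,
                             study$samples[[female]]$paternal)
  readr::write_tsv(select(allele_x, -"hist_maternal", -"hist_paternal"),
                   file.path(outdir, "allele_x.tsv"), progress = FALSE)

  invisible(list(dmrs = dmrs, fates = fates, report = report,
                 segments_te = segments_te, segments_ed = segments_ed,
                 sex_calls = sex_calls, allele_x = allele_x,
                 summaries = summaries))
}
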