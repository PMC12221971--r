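#' Infer embryo sex from X and pseudo-Y read counts
#'
#' Sex is called from pseudo-Y reads per million library reads (y-CPM):
#' male libraries carry abundant Y-gene reads, females only a mismapping
#' trickle. The decision threshold `tau_cpm` is estimated per batch as the
#' arithmetic midpoint of the two cluster means obtained by splitting the
#' sorted y-CPM values at their largest gap (>= 4 samples; otherwise a
#' fixed default of 1 CPM). Calls inside the guard band around the
#' threshold are returned as `ambiguous` - in particular, sex-mixed pooled
#' libraries, whose y-CPM sits near half the male level, are flagged
#' rather than classified.
#'
#' @param counts Tibble with `sample`, `x_reads`, `y_reads`,
#'   `total_reads` (e.g. [simulate_xy_counts()] output).
#' @param tau_cpm Decision threshold in y-CPM; `NULL` (default) estimates
#'   it from the batch.
#' @param guard Half-width of the ambiguity band as a fraction of
#'   `tau_cpm`: male requires `y_cpm >= tau * (1 + guard)`, female
#'   `y_cpm <= tau * (1 - guard)`.
#' @return `counts` with `y_cpm`, `tau_cpm` and `sex_call` columns.
#' @export
infer_sex <- function(counts, tau_cpm = NULL, guard = 0.45) {
  if (any(counts$total_reads <= 0)) abort("total_reads must be > 0")
  y_cpm <- counts$y_reads / counts$total_reads * 1e6
  if (is.null(tau_cpm)) {
    tau_cpm <- if (length(y_cpm) >= 4) {
      s <- sort(y_cpm)
      cut <- which.max(diff(s))
      (mean(s[seq_len(cut)]) + mean(s[(cut + 1):length(s)])) / 2
    } else 1.0
  }
  counts %>%
    mutate(y_cpm = y_cpm, tau_cpm = tau_cpm,
           sex_call = case_when(
             y_cpm >= tau_cpm * (1 + guard) ~ "male",
             y_cpm <= tau_cpm * (1 - guard) ~ "female",
             TRUE ~ "ambiguous"
           ))
}

meth_hist <- function(frac) {
  bin <- pmin(floor(100 * frac / 10), 9)
  tibble(bin_lo = seq(0, 90, 10), bin_hi = seq(10, 100, 10),
         n = as.integer(tabulate(bin + 1, nbins = 10)))
}

#' Per-chromosome-group methylation distributions
#'
#' Splits a (destranded, filtered) call table into autosomes and the X
#' chromosome and reports per-group site counts, unweighted mean
#' methylation, and 10-point-bin histograms. Group means are identical to
#' [summarize_calls()] restricted to the same site sets.
#'
#' @param calls Destranded call table (conventionally filtered >= 5x).
#' @param x_chrom X chromosome name (default `"chrX"`).
#' @param exclude Chromosomes dropped entirely (default `"chrY"`).
#' @return Tibble `group`, `n_sites`, `mean_meth`, `hist` (list-column).
#'   Groups with zero sites are flagged with a warning and `NA` mean.
#' @export
chrom_distributions <- function(calls, x_chrom = "chrX",
                                exclude = "chrY") {
  assert_destranded(calls)
  x <- filter(calls, !.data$chrom %in% exclude)
  frac <- meth_fraction(x)
  grp <- if_else(x$chrom == x_chrom, "X", "autosomes")
  purrr::map(c("autosomes", "X"), function(g) {
    f <- frac[grp == g]
    if (length(f) == 0) {
      warn(paste0("chromosome group '", g, "' has zero sites"))
      return(tibble(group = g, n_sites = 0L, mean_meth = NA_real_,
                    hist = list(meth_hist(numeric(0)))))
    }
    tibble(group = g, n_sites = length(f), mean_meth = mean(f),
           hist = list(meth_hist(f)))
  }) %>% bind_rows()
}

#' Female-to-male X methylation ratio
#'
#' Ratio of the female sample's mean X methylation to the male's, on each
#' sample's own filtered sites. Imprinted X inactivation with a
#' hypomethylated inactive X drives this ratio below 1 (toward one half
#' as Xi methylation approaches zero, since the female X is an equal
#' Xa/Xi mixture).
#'
#' @param calls_female,calls_male Destranded, filtered call tables.
#' @param x_chrom X chromosome name.
#' @return Scalar ratio.
#' @export
female_male_x_ratio <- function(calls_female, calls_male,
                                x_chrom = "chrX") {
  mean_x <- function(calls) {
    x <- filter(calls, .data$chrom == x_chrom)
    if (nrow(x) == 0) abort("no X-chromosome sites")
    mean(meth_fraction(x))
  }
  mean_x(calls_female) / mean_x(calls_male)
}

#' Compare maternal and paternal allele methylation
#'
#' Filters each allele-labelled call table to `min_cov`, then reports
#' per-chromosome-group (autosomes vs X) allele means, histograms, and
#' the paternal-minus-maternal mean difference. The X group isolates
#' imprinted-XCI hypomethylation of the silenced paternal X.
#'
#' @param calls_maternal,calls_paternal Destranded allele call tables
#'   (errors when empty).
#' @param min_cov Per-site minimum coverage per allele (default 5).
#' @param x_chrom,exclude Chromosome grouping as in
#'   [chrom_distributions()].
#' @return Tibble `group`, `n_maternal`, `n_paternal`, `mean_maternal`,
#'   `mean_paternal`, `mean_diff` (paternal - maternal), `hist_maternal`,
#'   `hist_paternal`.
#' @export
allele_compare <- function(calls_maternal, calls_paternal, min_cov = 5,
                           x_chrom = "chrX", exclude = "chrY") {
  if (nrow(calls_maternal) == 0 || nrow(calls_paternal) == 0) {
    abort("empty allele call table")
  }
  prep <- function(calls) {
    x <- filter_coverage(calls, min_cov) %>%
      filter(!.data$chrom %in% exclude)
    mutate(x, frac = meth_fraction(x),
           group = if_else(.data$chrom == x_chrom, "X", "autosomes"))
  }
  m <- prep(calls_maternal)
  p <- prep(calls_paternal)
  purrr::map(c("autosomes", "X"), function(g) {
    fm <- m$frac[m$group == g]
    fp <- p$frac[p$group == g]
    tibble(group = g, n_maternal = length(fm), n_paternal = length(fp),
           mean_maternal = if (length(fm)) mean(fm) else NA_real_,
           mean_paternal = if (length(fp)) mean(fp) else NA_real_,
           mean_diff = (if (length(fp)) mean(fp) else NA_real_) -
             (if (length(fm)) mean(fm) else NA_real_),
           hist_maternal = list(meth_hist(fm)),
           hist_paternal = list(meth_hist(fp)))
  }) %>% bind_rows()
}

#' Classify genes as transcriptionally active or inactive
#'
#' Active if TPM exceeds `active_gt` (default > 5), inactive if TPM is at
#' most `inactive_le` (default <= 1); genes in between are excluded
#' (category `NA`).
#'
#' @param expression Tibble with `gene` and `tpm`.
#' @param active_gt,inactive_le Thresholds.
#' @return `expression` with a `category` column.
#' @export
classify_gene_activity <- function(expression, active_gt = 5,
                                   inactive_le = 1) {
  if (any(expression$tpm < 0)) abort("negative TPM")
  mutate(expression, category = case_when(
    .data$tpm > active_gt ~ "active",
    .data$tpm <= inactive_le ~ "inactive",
    TRUE ~ NA_character_
  ))
}

#' Pooled methylation level of genomic regions
#'
#' For each region, sums methylated and total reads over its CpG sites
#' and reports the pooled-count methylation percentage; regions whose
#' pooled coverage is below `min_reads` get a missing value. Used for
#' gene bodies, promoters and intergenic controls (e.g. active versus
#' inactive oocyte genes).
#'
#' @param calls Destranded call table (conventionally filtered to >= 3
#'   reads per site for this analysis).
#' @param regions Tibble `chrom`, `start`, `end` with optional `name`
#'   (regions may overlap).
#' @param min_reads Minimum pooled reads per region (default 3).
#' @return `regions` with `n_cpg`, `meth_pct` columns.
#' @export
gene_region_methylation <- function(calls, regions, min_reads = 3) {
  assert_destranded(calls)
  regions <- as_tibble(regions)
  if (nrow(regions) == 0) {
    return(mutate(regions, n_cpg = integer(0), meth_pct = numeric(0)))
  }
  res <- purrr::map(seq_len(nrow(regions)), function(i) {
    sel <- calls$chrom == regions$chrom[i] &
      calls$pos > regions$start[i] & calls$pos <= regions$end[i]
    cov <- sum(calls$n_meth[sel] + calls$n_unmeth[sel])
    tibble(n_cpg = sum(sel),
           meth_pct = if (cov >= min_reads) {
             100 * sum(calls$n_meth[sel]) / cov
           } else NA_real_)
  }) %>% bind_rows()
  bind_cols(regions, res)
}

#' Allele methylation at XCI escapees versus subject genes
#'
#' Restricts to expressed genes (FPKM above `fpkm_gt`), joins externally
#' supplied escapee/subject labels, and summarizes per-allele methylation
#' by group. Escapees are expected to match the active allele on both
#' alleles; subject genes to be hypomethylated on the silenced paternal
#' allele.
#'
#' @param gene_meth Tibble with `gene`, `allele` (`maternal`/`paternal`)
#'   and `meth_pct` (e.g. from [gene_region_methylation()] run per
#'   allele).
#' @param escape_list Tibble with `gene` and `status`
#'   (`escapee`/`subject`). Labels for genes absent from `gene_meth` are
#'   skipped with a warning; an empty list yields a single unlabelled
#'   group with a warning.
#' @param expression Tibble with `gene` and `fpkm`.
#' @param fpkm_gt Expression threshold (exclusive, default 1).
#' @return Tibble `status`, `allele`, `n_genes`, `mean_meth`,
#'   `median_meth`.
#' @export
escapee_methylation <- function(gene_meth, escape_list, expression,
                                fpkm_gt = 1) {
  expressed <- filter(expression, .data$fpkm > fpkm_gt)$gene
  x <- filter(gene_meth, .data$gene %in% expressed, !is.na(.data$meth_pct))
  if (is.null(escape_list) || nrow(escape_list) == 0) {
    warn("empty escape-gene list: returning a single unlabelled group")
    x$status <- "unlabelled"
  } else {
    unknown <- setdiff(escape_list$gene, gene_meth$gene)
    if (length(unknown) > 0) {
      warn(paste0("escape labels for unknown genes skipped: ",
                  paste(unknown, collapse = ", ")))
    }
    x <- inner_join(x, select(escape_list, "gene", "status"), by = "gene")
  }
  x %>%
    group_by(.data$status, .data$allele) %>%
    summarise(n_genes = n(), mean_meth = mean(.data$meth_pct),
              median_meth = median(.data$meth_pct), .groups = "drop")
}

#' X-to-autosome expression ratio
#'
#' Median TPM of X-linked genes over median TPM of autosomal genes,
#' after removing genes expressed below `tpm_ge`. Invariant to rescaling
#' all TPMs by a constant.
#'
#' @param expression Tibble with `gene`, `tpm` and `chrom` (or supply
#'   `gene_chrom_map`).
#' @param gene_chrom_map Optional tibble `gene`, `chrom`.
#' @param tpm_ge Inclusive minimum TPM (default 1).
#' @param x_chrom,exclude X chromosome name / chromosomes dropped.
#' @return Scalar ratio.
#' @export
xa_ratio <- function(expression, gene_chrom_map = NULL, tpm_ge = 1,
                     x_chrom = "chrX", exclude = "chrY") {
  x <- as_tibble(expression)
  if (!"chrom" %in% names(x)) {
    if (is.null(gene_chrom_map)) abort("need chrom or gene_chrom_map")
    x <- inner_join(x, gene_chrom_map, by = "gene")
  }
  x <- filter(x, .data$tpm >= tpm_ge, !.data$chrom %in% exclude)
  x_tpm <- x$tpm[x$chrom == x_chrom]
  a_tpm <- x$tpm[x$chrom != x_chrom]
  if (length(x_tpm) == 0) abort("no X-linked genes pass the filter")
  if (length(a_tpm) == 0) abort("no autosomal genes pass the filter")
  median(x_tpm) / median(a_tpm)
}
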