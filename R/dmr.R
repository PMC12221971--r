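#' Fixed-width tiling of a chromosome set
#'
#' Tiles are laid from coordinate 0 in non-overlapping `tile_bp` windows
#' (0-based half-open); the final partial window is included.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param tile_bp Tile width in bp (conventionally 100).
#' @return Tibble `chrom`, `start`, `end`.
#' @export
#' @examples
#' tile_genome(c(chr1 = 250), 100)
tile_genome <- function(chrom_lengths, tile_bp = 100) {
  if (tile_bp <= 0) abort("tile_bp must be > 0")
  purrr::map(names(chrom_lengths), function(chr) {
    len <- chrom_lengths[[chr]]
    starts <- seq(0, len - 1, by = tile_bp)
    tibble(chrom = chr, start = as.integer(starts),
           end = as.integer(pmin(starts + tile_bp, len)))
  }) %>% bind_rows()
}

#' Pooled per-tile counts for a two-condition comparison
#'
#' Lays fixed `tile_bp` windows from coordinate 0 and sums destranded read
#' counts per condition within each tile. A tile is retained only if its
#' summed coverage reaches `min_reads` in *both* conditions and it
#' contains at least `min_cpg` CpG sites (union of the two conditions).
#' Tile methylation per condition is the pooled-count percentage, and
#' `diff` is condition A minus condition B in percentage points.
#'
#' @param calls_a,calls_b Destranded, pooled call tables (A is the first
#'   condition; the sign convention of `diff` follows it).
#' @param tile_bp Tile width (default 100 bp).
#' @param min_reads Minimum summed coverage per condition per tile
#'   (default 3).
#' @param min_cpg Minimum CpG sites per tile (default 1).
#' @param chrom_lengths Optional named lengths used to clip the final
#'   partial tile's `end`.
#' @return Tibble `chrom`, `start`, `end`, `n_cpg`, `meth_a`, `cov_a`,
#'   `meth_b`, `cov_b`, `meth_pct_a`, `meth_pct_b`, `diff`.
#' @export
tile_counts <- function(calls_a, calls_b, tile_bp = 100, min_reads = 3,
                        min_cpg = 1, chrom_lengths = NULL) {
  if (tile_bp <= 0) abort("tile_bp must be > 0")
  assert_destranded(calls_a, "calls_a")
  assert_destranded(calls_b, "calls_b")
  a <- select(calls_a, "chrom", "pos", ma = "n_meth", ua = "n_unmeth")
  b <- select(calls_b, "chrom", "pos", mb = "n_meth", ub = "n_unmeth")
  joint <- dplyr::full_join(a, b, by = c("chrom", "pos")) %>%
    mutate(dplyr::across(c("ma", "ua", "mb", "ub"),
                         ~ dplyr::coalesce(.x, 0L)))
  tiles <- joint %>%
    mutate(start = as.integer((.data$pos - 1) %/% tile_bp) * as.integer(tile_bp)) %>%
    group_by(.data$chrom, .data$start) %>%
    summarise(n_cpg = n(),
              meth_a = sum(.data$ma), cov_a = sum(.data$ma + .data$ua),
              meth_b = sum(.data$mb), cov_b = sum(.data$mb + .data$ub),
              .groups = "drop") %>%
    mutate(end = .data$start + as.integer(tile_bp))
  if (!is.null(chrom_lengths)) {
    tiles <- mutate(tiles, end = pmin(
      .data$end, as.integer(chrom_lengths[.data$chrom])))
  }
  tiles %>%
    filter(.data$cov_a >= min_reads, .data$cov_b >= min_reads,
           .data$n_cpg >= min_cpg) %>%
    mutate(meth_pct_a = 100 * .data$meth_a / .data$cov_a,
           meth_pct_b = 100 * .data$meth_b / .data$cov_b,
           diff = .data$meth_pct_a - .data$meth_pct_b) %>%
    select("chrom", "start", "end", "n_cpg", "meth_a", "cov_a", "meth_b",
           "cov_b", "meth_pct_a", "meth_pct_b", "diff") %>%
    arrange(.data$chrom, .data$start)
}

#' Two-sided exact test on pooled 2x2 methylation counts
#'
#' For each table `[[a_meth, a_unmeth], [b_meth, b_unmeth]]`, the p-value
#' is the sum of hypergeometric point probabilities (margins fixed) of all
#' tables whose probability does not exceed that of the observed table
#' (comparison tolerance 1e-12). A table with a zero margin (no reads in a
#' condition, or all reads one way) carries no information against the
#' null and returns p = 1 by convention; the number of such tables is
#' recorded in the `"n_zero_margin"` attribute.
#'
#' @param a_meth,a_unmeth,b_meth,b_unmeth Non-negative integer vectors
#'   (recycled to a common length).
#' @return Numeric vector of two-sided p-values.
#' @export
#' @examples
#' exact_meth_test(2, 0, 0, 2)  # 1/3
exact_meth_test <- function(a_meth, a_unmeth, b_meth, b_unmeth) {
  n <- max(length(a_meth), length(a_unmeth), length(b_meth),
           length(b_unmeth))
  am <- rep_len(a_meth, n); au <- rep_len(a_unmeth, n)
  bm <- rep_len(b_meth, n); bu <- rep_len(b_unmeth, n)
  if (any(c(am, au, bm, bu) < 0, na.rm = TRUE)) {
    abort("counts must be non-negative")
  }
  p <- vapply(seq_len(n), function(i) {
    if (anyNA(c(am[i], au[i], bm[i], bu[i]))) return(NA_real_)
    cov_a <- am[i] + au[i]; cov_b <- bm[i] + bu[i]
    K <- am[i] + bm[i]; N <- cov_a + cov_b
    if (cov_a == 0 || cov_b == 0 || K == 0 || K == N) return(1)
    k <- max(0, cov_a - (N - K)):min(cov_a, K)
    d <- dhyper(k, K, N - K, cov_a)
    d_obs <- dhyper(am[i], K, N - K, cov_a)
    min(1, sum(d[d <= d_obs * (1 + 1e-12)]))
  }, numeric(1))
  zero <- (am + au == 0) | (bm + bu == 0) | (am + bm == 0) |
    (au + bu == 0)
  attr(p, "n_zero_margin") <- sum(zero, na.rm = TRUE)
  p
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values `q_(i) = min_{j >= i}(p_(j) * m / j)` capped at 1,
#' computed via [stats::p.adjust()]. `NA`/`NaN` p-values are propagated
#' and excluded from the number of tests `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, order-aligned with `p`.
#' @export
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
adjust_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Test tiles for differential methylation
#'
#' Applies the two-sided exact count test to each tile's pooled counts and
#' attaches Benjamini-Hochberg q-values.
#'
#' @param tiles A [tile_counts()] table.
#' @return The table with `p` and `q` columns, classed `tile_test`. The
#'   test and FDR method names and the `diff = A - B` sign convention are
#'   recorded in attributes (`"method"`, `"fdr_method"`, `"convention"`).
#' @export
test_tiles <- function(tiles) {
  p <- exact_meth_test(tiles$meth_a, tiles$cov_a - tiles$meth_a,
                       tiles$meth_b, tiles$cov_b - tiles$meth_b)
  out <- mutate(tiles, p = as.numeric(p), q = adjust_fdr(as.numeric(p)))
  class(out) <- c("tile_test", class(out))
  attr(out, "method") <- "two-sided Fisher exact on pooled counts"
  attr(out, "fdr_method") <- "BH"
  attr(out, "convention") <- "diff = condition A - condition B"
  out
}

#' Call differentially methylated regions from tested tiles
#'
#' A tile is a DMR when `|diff|` reaches the difference threshold *and*
#' its q-value is below the significance threshold. The conventional
#' gamete screen uses `difference = 80` and `qvalue = 0.01`. Positive
#' `diff` (A-high) tiles get `label_a`, negative get `label_b`.
#'
#' @param tiles A [test_tiles()] result.
#' @param difference Minimum absolute methylation difference in
#'   percentage points.
#' @param qvalue q-value threshold (exclusive).
#' @param label_a,label_b Labels for A-high / B-high DMRs (defaults follow
#'   the sperm-vs-oocyte convention with A = sperm).
#' @return Tibble of DMR tiles with a `label` column.
#' @export
call_dmrs <- function(tiles, difference = 80, qvalue = 0.01,
                      label_a = "sperm_specific",
                      label_b = "oocyte_specific") {
  out <- tiles %>%
    filter(abs(.data$diff) >= difference, .data$q < qvalue) %>%
    mutate(label = if_else(.data$diff > 0, label_a, label_b))
  as_tibble(out)
}

#' Merge adjacent same-label DMR tiles into regions
#'
#' Significant tiles belonging to one differentially methylated locus are
#' contiguous (or nearly so, when an interior tile narrowly misses a
#' threshold); merging them yields region-level records whose pooled
#' counts are far deeper than any single 100-bp tile - the right substrate
#' for downstream fate tracking.
#'
#' @param dmrs A [call_dmrs()] result.
#' @param max_gap Maximum bp gap bridged between tiles of the same label
#'   (default 300, i.e. up to three consecutive sub-threshold interior
#'   tiles; the merged region's pooled counts include their sites).
#' @return Region-level tibble with summed counts, recomputed methylation
#'   percentages and `diff`, `n_tiles`, and the minimum tile `q`.
#' @export
merge_dmrs <- function(dmrs, max_gap = 300) {
  if (nrow(dmrs) == 0) return(as_tibble(dmrs))
  x <- arrange(as_tibble(dmrs), .data$chrom, .data$label, .data$start)
  new_run <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)] |
                 x$label[-1] != x$label[-nrow(x)] |
                 x$start[-1] - x$end[-nrow(x)] > max_gap)
  x$run <- cumsum(new_run)
  x %>%
    group_by(.data$run) %>%
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end), label = .data$label[1],
              n_tiles = n(), n_cpg = sum(.data$n_cpg),
              meth_a = sum(.data$meth_a), cov_a = sum(.data$cov_a),
              meth_b = sum(.data$meth_b), cov_b = sum(.data$cov_b),
              q = min(.data$q), .groups = "drop") %>%
    mutate(meth_pct_a = 100 * .data$meth_a / .data$cov_a,
           meth_pct_b = 100 * .data$meth_b / .data$cov_b,
           diff = .data$meth_pct_a - .data$meth_pct_b) %>%
    select("chrom", "start", "end", "label", "n_tiles", "n_cpg",
           "meth_a", "cov_a", "meth_b", "cov_b", "meth_pct_a",
           "meth_pct_b", "diff", "q") %>%
    arrange(.data$chrom, .data$start)
}

overlaps_any <- function(chrom, start, end, iv) {
  out <- rep(FALSE, length(chrom))
  if (nrow(iv) == 0) return(out)
  for (chr in unique(chrom)) {
    j <- iv$chrom == chr
    if (!any(j)) next
    s2 <- iv$start[j]; e2 <- iv$end[j]
    sel <- which(chrom == chr)
    out[sel] <- vapply(sel, function(i) {
      any(s2 < end[i] & e2 > start[i])
    }, logical(1))
  }
  out
}

#' Derive promoter intervals from gene bodies
#'
#' The 1 kb upstream of each TSS, strand-aware, clipped at chromosome
#' bounds when lengths are supplied.
#'
#' @param genes BED-style gene tibble with `strand`.
#' @param upstream_bp Promoter extent upstream of the TSS.
#' @param chrom_lengths Optional named chromosome lengths for clipping.
#' @return BED-style promoter tibble.
#' @export
promoters_from_genes <- function(genes, upstream_bp = 1000,
                                 chrom_lengths = NULL) {
  out <- genes %>%
    mutate(
      p_start = if_else(.data$strand == "+",
                        pmax(.data$start - as.integer(upstream_bp), 0L),
                        .data$end),
      p_end = if_else(.data$strand == "+", .data$start,
                      .data$end + as.integer(upstream_bp)),
      start = .data$p_start, end = .data$p_end
    ) %>%
    select(-"p_start", -"p_end")
  if (!is.null(chrom_lengths)) {
    out <- mutate(out, end = pmin(
      .data$end, as.integer(chrom_lengths[.data$chrom])))
  }
  filter(out, .data$end > .data$start)
}

#' Assign each DMR a genomic feature class
#'
#' Classes are assigned by overlap (>= 1 bp, half-open arithmetic) with
#' fixed precedence CGI > promoter > intragenic > intergenic. If promoters
#' are not supplied they are derived from genes ([promoters_from_genes()]).
#'
#' @param dmrs DMR tibble (`chrom`, `start`, `end`).
#' @param genes,promoters,cgi BED-style annotation tibbles (any may be
#'   `NULL`/empty).
#' @return `dmrs` with a `feature_class` column.
#' @export
annotate_dmrs <- function(dmrs, genes = NULL, promoters = NULL,
                          cgi = NULL) {
  empty <- tibble(chrom = character(), start = integer(), end = integer())
  genes <- genes %||% empty
  cgi <- cgi %||% empty
  if (is.null(promoters)) {
    promoters <- if (nrow(genes) > 0 && "strand" %in% names(genes)) {
      promoters_from_genes(genes)
    } else empty
  }
  if (any(genes$end <= genes$start) || any(cgi$end <= cgi$start) ||
      any(promoters$end <= promoters$start)) {
    abort("annotation interval with end <= start")
  }
  dmrs %>%
    mutate(
      in_cgi = overlaps_any(.data$chrom, .data$start, .data$end, cgi),
      in_prom = overlaps_any(.data$chrom, .data$start, .data$end,
                             promoters),
      in_gene = overlaps_any(.data$chrom, .data$start, .data$end, genes),
      feature_class = case_when(
        in_cgi ~ "CGI",
        in_prom ~ "promoter",
        in_gene ~ "intragenic",
        TRUE ~ "intergenic"
      )
    ) %>%
    select(-"in_cgi", -"in_prom", -"in_gene")
}

#' Per-site differential methylation between two conditions
#'
#' Runs the two-sided exact count test at every CpG site shared by both
#' filtered tables, adjusts with Benjamini-Hochberg, and reports the
#' fraction of captured sites whose methylation did not change
#' significantly (q >= alpha) - the site-level stability measure.
#'
#' @param calls_a,calls_b Destranded call tables.
#' @param alpha Significance level on q (default 0.05).
#' @param min_cov Per-site minimum coverage in each condition (default 5).
#' @return A list of class `site_diff`: `sites` (tibble with per-site
#'   counts, `p`, `q`), `fraction_stable`, `alpha`, `min_cov`.
#' @export
diff_sites <- function(calls_a, calls_b, alpha = 0.05, min_cov = 5) {
  a <- filter_coverage(calls_a, min_cov)
  b <- filter_coverage(calls_b, min_cov)
  shared <- inner_join(
    select(a, "chrom", "pos", ma = "n_meth", ua = "n_unmeth"),
    select(b, "chrom", "pos", mb = "n_meth", ub = "n_unmeth"),
    by = c("chrom", "pos")
  )
  if (nrow(shared) == 0) abort("no shared sites between conditions")
  p <- exact_meth_test(shared$ma, shared$ua, shared$mb, shared$ub)
  sites <- mutate(shared, p = as.numeric(p), q = adjust_fdr(as.numeric(p)))
  structure(list(sites = sites,
                 fraction_stable = mean(sites$q >= alpha),
                 alpha = alpha, min_cov = min_cov),
            class = "site_diff")
}

#' @export
print.site_diff <- function(x, ...) {
  cat("Per-site differential methylation\n")
  cat("  shared sites:", nrow(x$sites), "(min coverage", x$min_cov, ")\n")
  cat(sprintf("  stable fraction (q >= %.3g): %.4f\n", x$alpha,
              x$fraction_stable))
  invisible(x)
}

#' Scaled meta-profile of methylation over a set of intervals
#'
#' Each interval body is rescaled to a fixed number of bins and flanked by
#' fixed-width bins (the scale-regions profile used for feature classes
#' such as repeat families). Per-bin values are the mean per-site
#' methylation of the CpGs falling in the bin, averaged across intervals;
#' minus-strand intervals are reversed so profiles read 5' to 3'.
#'
#' @param calls Destranded call table.
#' @param intervals Stranded BED-style tibble (error when empty).
#' @param body_bins Number of bins the body is scaled to (default 20).
#' @param flank Flank extent in bp (default 1000).
#' @param bin_bp Flank bin width (default 50).
#' @return A tibble of class `meta_profile`: `bin`, `zone` (`upstream` /
#'   `body` / `downstream`), `position` (bin midpoint label), `mean_meth`,
#'   `n_intervals`.
#' @export
meta_profile <- function(calls, intervals, body_bins = 20, flank = 1000,
                         bin_bp = 50) {
  assert_destranded(calls)
  if (is.null(intervals) || nrow(intervals) == 0) {
    abort("meta_profile requires at least one interval")
  }
  if (!"strand" %in% names(intervals)) intervals$strand <- "+"
  nf <- as.integer(ceiling(flank / bin_bp))
  total_bins <- 2L * nf + body_bins
  frac <- meth_fraction(calls)
  per_interval <- purrr::map(seq_len(nrow(intervals)), function(i) {
    chr <- intervals$chrom[i]
    s <- intervals$start[i]; e <- intervals$end[i]
    sel <- calls$chrom == chr & (calls$pos - 1) >= (s - flank) &
      (calls$pos - 1) < (e + flank)
    if (!any(sel)) return(NULL)
    pos0 <- calls$pos[sel] - 1
    m <- frac[sel]
    bin <- integer(length(pos0))
    up <- pos0 < s
    body <- pos0 >= s & pos0 < e
    down <- pos0 >= e
    bin[up] <- pmin(nf, (pos0[up] - (s - flank)) %/% bin_bp + 1)
    body_len <- e - s
    bin[body] <- if (body_len < bin_bp) {
      nf + 1L  # interval shorter than one bin: single body bin
    } else {
      nf + pmin(body_bins,
                floor((pos0[body] - s) / body_len * body_bins) + 1)
    }
    bin[down] <- nf + body_bins + pmin(nf, (pos0[down] - e) %/% bin_bp + 1)
    if (intervals$strand[i] == "-") bin <- total_bins + 1L - bin
    tibble(bin = bin, m = m) %>%
      group_by(.data$bin) %>%
      summarise(m = mean(.data$m), .groups = "drop")
  }) %>% purrr::compact() %>% bind_rows()
  out <- per_interval %>%
    group_by(.data$bin) %>%
    summarise(mean_meth = mean(.data$m), n_intervals = n(),
              .groups = "drop") %>%
    dplyr::right_join(tibble(bin = seq_len(total_bins)), by = "bin") %>%
    arrange(.data$bin) %>%
    mutate(zone = case_when(
      .data$bin <= nf ~ "upstream",
      .data$bin <= nf + body_bins ~ "body",
      TRUE ~ "downstream"
    ))
  class(out) <- c("meta_profile", class(out))
  attr(out, "body_bins") <- body_bins
  attr(out, "flank") <- flank
  attr(out, "bin_bp") <- bin_bp
  out
}
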