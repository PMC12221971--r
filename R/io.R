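#' Read a per-cytosine methylation call table
#'
#' Imports bisulfite CpG methylation calls from either of the two standard
#' per-cytosine text dialects:
#'
#' * `"cytosine_report"`: one row per strand per cytosine, tab-separated
#'   columns `chrom`, 1-based `pos`, `strand` (`+`/`-`), `n_meth`,
#'   `n_unmeth`, `context`, `trinucleotide`.
#' * `"coverage"`: destranded rows `chrom`, 1-based `start`, 1-based `end`,
#'   percent methylation, `n_meth`, `n_unmeth`. Rows are treated as already
#'   destranded.
#'
#' @param path Path to the call file.
#' @param dialect One of `"cytosine_report"` or `"coverage"`.
#' @param context Sequence context to retain (`"CpG"` by default); use
#'   `"all"` to keep every row.
#' @return A tibble with columns `chrom`, `pos`, `strand`, `n_meth`,
#'   `n_unmeth`, `context` (and `trinucleotide` for cytosine reports). An
#'   empty file yields an empty table.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("chr1\t100\t+\t3\t2\tCpG\tCGA",
#'              "chr1\t101\t-\t1\t4\tCpG\tCGT"), f)
#' read_calls(f, "cytosine_report")
read_calls <- function(path, dialect = c("cytosine_report", "coverage"),
                       context = "CpG") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (file.size(path) == 0) {
    return(empty_calls(destranded = dialect == "coverage"))
  }
  if (dialect == "cytosine_report") {
    x <- readr::read_tsv(
      path,
      col_names = c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                    "context", "trinucleotide"),
      col_types = readr::cols(
        chrom = readr::col_character(), pos = readr::col_double(),
        strand = readr::col_character(), n_meth = readr::col_double(),
        n_unmeth = readr::col_double(), context = readr::col_character(),
        trinucleotide = readr::col_character()
      ),
      progress = FALSE
    )
    validate_call_rows(x, path)
    bad_strand <- which(!x$strand %in% c("+", "-"))
    if (length(bad_strand) > 0) {
      abort(paste0("unknown strand symbol at line ", bad_strand[1],
                   " of ", path))
    }
    if (!identical(context, "all")) x <- filter(x, .data$context == !!context)
    mutate(x, n_meth = as.integer(.data$n_meth),
           n_unmeth = as.integer(.data$n_unmeth), pos = as.integer(.data$pos))
  } else {
    x <- readr::read_tsv(
      path,
      col_names = c("chrom", "start", "end", "meth_pct", "n_meth", "n_unmeth"),
      col_types = readr::cols(
        chrom = readr::col_character(), start = readr::col_double(),
        end = readr::col_double(), meth_pct = readr::col_double(),
        n_meth = readr::col_double(), n_unmeth = readr::col_double()
      ),
      progress = FALSE
    )
    validate_call_rows(x, path)
    out <- tibble(
      chrom = x$chrom, pos = as.integer(x$start), strand = "+",
      n_meth = as.integer(x$n_meth), n_unmeth = as.integer(x$n_unmeth),
      context = "CpG"
    )
    set_destranded(out)
  }
}

validate_call_rows <- function(x, path) {
  num <- intersect(c("pos", "start", "end", "n_meth", "n_unmeth"), names(x))
  for (col in num) {
    bad <- which(is.na(x[[col]]) | x[[col]] < 0)
    if (length(bad) > 0) {
      abort(paste0("malformed row at line ", bad[1], " of ", path,
                   " (column ", col, ")"))
    }
  }
  invisible(x)
}

empty_calls <- function(destranded = FALSE) {
  out <- tibble(chrom = character(), pos = integer(), strand = character(),
                n_meth = integer(), n_unmeth = integer(),
                context = character())
  if (destranded) out <- set_destranded(out)
  out
}

#' Write a call table to disk
#'
#' @param calls A call-table tibble.
#' @param path Output path.
#' @param dialect `"cytosine_report"` (per-strand rows, 7 columns) or
#'   `"coverage"` (destranded rows with a percent-methylation column).
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path,
                        dialect = c("cytosine_report", "coverage")) {
  dialect <- match.arg(dialect)
  if (dialect == "cytosine_report") {
    tri <- if ("trinucleotide" %in% names(calls)) calls$trinucleotide else "CGN"
    out <- tibble(c1 = calls$chrom, c2 = calls$pos, c3 = calls$strand,
                  c4 = calls$n_meth, c5 = calls$n_unmeth,
                  c6 = calls$context, c7 = tri)
  } else {
    cov <- calls$n_meth + calls$n_unmeth
    pct <- if_else(cov > 0, 100 * calls$n_meth / cov, 0)
    out <- tibble(c1 = calls$chrom, c2 = calls$pos, c3 = calls$pos,
                  c4 = round(pct, 6), c5 = calls$n_meth,
                  c6 = calls$n_unmeth)
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

set_destranded <- function(calls) {
  attr(calls, "destranded") <- TRUE
  calls
}

#' Test whether a call table is destranded
#'
#' A table is destranded if produced by [destrand()] (or read from the
#' coverage dialect), or if it contains no minus-strand rows.
#'
#' @param calls A call-table tibble.
#' @return Logical scalar.
#' @export
is_destranded <- function(calls) {
  isTRUE(attr(calls, "destranded")) || !any(calls$strand == "-")
}

assert_destranded <- function(calls, what = "calls") {
  if (!is_destranded(calls)) {
    abort(paste0(what, " must be destranded (see destrand())"))
  }
  invisible(calls)
}

#' Merge strand-resolved CpG calls into per-dinucleotide records
#'
#' A CpG dinucleotide is read on both strands: the plus-strand cytosine at
#' position `i` and the minus-strand cytosine at `i + 1`. Destranding merges
#' the minus-strand record into the plus-strand coordinate by summing
#' counts. Orphan minus-strand records (no plus partner) are re-coordinated
#' to `i - 1`; a minus-strand record at position 1 has no admissible partner
#' position and is kept in place with a message.
#'
#' Total methylated and unmethylated counts are conserved exactly.
#'
#' @param calls A strand-resolved CpG call table.
#' @return A destranded call table (all rows `+`, positions are CpG starts).
#' @export
#' @examples
#' x <- tibble::tibble(chrom = "chr1", pos = c(100L, 101L),
#'                     strand = c("+", "-"), n_meth = c(3L, 1L),
#'                     n_unmeth = c(2L, 4L), context = "CpG")
#' destrand(x)
destrand <- function(calls) {
  x <- filter(calls, .data$context == "CpG")
  stuck <- x$strand == "-" & x$pos <= 1
  if (any(stuck)) {
    inform(paste0(sum(stuck), " minus-strand record(s) at position <= 1 ",
                  "have no partner position; kept in place"))
  }
  x <- mutate(x, pos = if_else(.data$strand == "-" & .data$pos > 1,
                               .data$pos - 1L, .data$pos))
  out <- x %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(n_meth = sum(.data$n_meth), n_unmeth = sum(.data$n_unmeth),
              .groups = "drop") %>%
    mutate(strand = "+", context = "CpG") %>%
    select("chrom", "pos", "strand", "n_meth", "n_unmeth", "context") %>%
    arrange(.data$chrom, .data$pos)
  set_destranded(out)
}

#' Pool destranded call tables by summing counts per site
#'
#' Sites present in only some tables are kept (union of site sets); counts
#' at shared sites are summed.
#'
#' @param ... Destranded call tables, or a single list of them.
#' @return A destranded call table.
#' @export
pool_calls <- function(...) {
  tables <- list(...)
  if (length(tables) == 1 && is.list(tables[[1]]) &&
      !is.data.frame(tables[[1]])) {
    tables <- tables[[1]]
  }
  if (length(tables) == 0) abort("no tables to pool")
  for (t in tables) assert_destranded(t, "every pooled table")
  out <- bind_rows(tables) %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(n_meth = sum(.data$n_meth), n_unmeth = sum(.data$n_unmeth),
              .groups = "drop") %>%
    mutate(strand = "+", context = "CpG") %>%
    select("chrom", "pos", "strand", "n_meth", "n_unmeth", "context") %>%
    arrange(.data$chrom, .data$pos)
  set_destranded(out)
}

#' Filter call tables to a minimum read coverage
#'
#' @param calls A destranded call table.
#' @param min_cov Minimum coverage (methylated + unmethylated reads); sites
#'   below it are dropped. The conventional analysis filter is 5 reads.
#' @return The filtered table; the number of removed sites is stored in the
#'   `"n_removed"` attribute.
#' @export
filter_coverage <- function(calls, min_cov = 5) {
  assert_destranded(calls)
  keep <- (calls$n_meth + calls$n_unmeth) >= min_cov
  out <- set_destranded(calls[keep, , drop = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-site methylation fraction
#'
#' @param calls A call table.
#' @return Numeric vector `n_meth / (n_meth + n_unmeth)` (NaN where
#'   coverage is zero).
#' @export
meth_fraction <- function(calls) {
  calls$n_meth / (calls$n_meth + calls$n_unmeth)
}

#' Summarize a filtered, destranded call table
#'
#' Computes the unweighted per-site mean methylation, a histogram of
#' per-site methylation over ten 10-percentage-point bins (right-open
#' except the last, so fully methylated sites land in the 90-100 bin), and
#' optionally the fraction of genome CpGs captured at >= 1x and >= 5x.
#'
#' @param calls A destranded call table.
#' @param genome_cpg_total Optional total number of CpG dinucleotides in
#'   the genome, for capture fractions.
#' @param sample Optional sample label carried into the output.
#' @return A one-row tibble with `sample`, `n_sites`, `mean_meth`,
#'   `capture_1x`, `capture_5x` and a list-column `hist` (tibble with
#'   `bin_lo`, `bin_hi`, `n`).
#' @export
summarize_calls <- function(calls, genome_cpg_total = NULL, sample = NA_character_) {
  assert_destranded(calls)
  # uncaptured (zero-coverage) sites carry no methylation estimate
  calls <- calls[calls$n_meth + calls$n_unmeth > 0, , drop = FALSE]
  n_sites <- nrow(calls)
  if (n_sites == 0) {
    warn("empty call table: mean methylation undefined")
    return(tibble(sample = sample, n_sites = 0L, mean_meth = NA_real_,
                  capture_1x = NA_real_, capture_5x = NA_real_,
                  hist = list(tibble(bin_lo = seq(0, 90, 10),
                                     bin_hi = seq(10, 100, 10),
                                     n = rep(0L, 10)))))
  }
  frac <- meth_fraction(calls)
  pct <- 100 * frac
  bin <- pmin(floor(pct / 10), 9)
  hist_tbl <- tibble(bin_lo = seq(0, 90, 10), bin_hi = seq(10, 100, 10),
                     n = as.integer(tabulate(bin + 1, nbins = 10)))
  cov <- calls$n_meth + calls$n_unmeth
  tibble(
    sample = sample,
    n_sites = n_sites,
    mean_meth = mean(frac),
    capture_1x = if (is.null(genome_cpg_total)) NA_real_ else
      sum(cov >= 1) / genome_cpg_total,
    capture_5x = if (is.null(genome_cpg_total)) NA_real_ else
      sum(cov >= 5) / genome_cpg_total,
    hist = list(hist_tbl)
  )
}

#' Read and write BED6 interval files
#'
#' Intervals are 0-based half-open. Rows with `end <= start` are rejected.
#'
#' @param path File path.
#' @return `read_bed()`: a tibble with `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (file.size(path) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double(), strand = character()))
  }
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), name = readr::col_character(),
      score = readr::col_double(), strand = readr::col_character()
    ),
    progress = FALSE
  )
  bad <- which(x$end <= x$start)
  if (length(bad) > 0) {
    abort(paste0("interval with end <= start at line ", bad[1], " of ", path))
  }
  mutate(x, start = as.integer(.data$start), end = as.integer(.data$end))
}

#' @rdname read_bed
#' @param intervals A tibble with at least `chrom`, `start`, `end`; `name`,
#'   `score` and `strand` default to `"."`, 0 and `"+"`.
#' @export
write_bed <- function(intervals, path) {
  out <- tibble(
    chrom = intervals$chrom,
    start = intervals$start,
    end = intervals$end,
    name = if ("name" %in% names(intervals)) intervals$name else ".",
    score = if ("score" %in% names(intervals)) intervals$score else 0,
    strand = if ("strand" %in% names(intervals)) intervals$strand else "+"
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
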