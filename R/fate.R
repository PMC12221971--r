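#' Pooled methylation of DMR intervals across developmental stages
#'
#' For every DMR and every stage call table, sums methylated and total
#' reads over the CpG sites inside the DMR interval and reports the
#' pooled-count methylation percentage. Stages whose summed coverage in a
#' DMR falls below `stage_min_reads` are marked missing (`NA`), mirroring
#' the read-minimum used when tiling gametes.
#'
#' @param dmrs DMR tibble (`chrom`, `start`, `end`; any extra columns are
#'   carried through).
#' @param stages Named list of destranded (pooled) call tables, e.g.
#'   `list(E3.5 = ..., E7.5_ED = ..., E7.5_TE = ..., brain = ...,
#'   liver = ..., spleen = ...)`.
#' @param stage_min_reads Minimum pooled reads per DMR per stage
#'   (default 3).
#' @return `dmrs` with one `meth_<stage>` percentage column per stage.
#' @export
stage_methylation <- function(dmrs, stages, stage_min_reads = 3) {
  stopifnot(is.list(stages), !is.null(names(stages)))
  out <- as_tibble(dmrs)
  iv <- select(out, "chrom", "start", "end")
  for (nm in names(stages)) {
    calls <- stages[[nm]]
    col <- paste0("meth_", nm)
    if (is.null(calls) || nrow(calls) == 0) {
      warn(paste0("stage '", nm, "' has an empty call table; all missing"))
      out[[col]] <- NA_real_
      next
    }
    assert_destranded(calls, paste0("stage '", nm, "'"))
    idx <- interval_index(calls$chrom, calls$pos, iv)
    hit <- !is.na(idx)
    meth <- tapply(calls$n_meth[hit], idx[hit], sum)
    cov <- tapply(calls$n_meth[hit] + calls$n_unmeth[hit], idx[hit], sum)
    m <- rep(NA_real_, nrow(out)); cv <- rep(0, nrow(out))
    m[as.integer(names(meth))] <- meth
    cv[as.integer(names(cov))] <- cov
    out[[col]] <- if_else(cv >= stage_min_reads, 100 * m / cv, NA_real_)
  }
  out
}

is_intermediate <- function(x, lo, hi) {
  !is.na(x) & x >= lo & x <= hi
}

#' Classify the developmental fate of gamete DMRs
#'
#' A gamete DMR whose one-allele mark survives fertilization shows
#' intermediate (diploid ~50%) methylation. Classification on the stage
#' columns produced by [stage_methylation()], with the intermediate band
#' inclusive at both bounds:
#'
#' * `not_established`: E3.5 not intermediate (regardless of later
#'   stages).
#' * `lifelong`: intermediate at E3.5, E7.5 embryonic disc, and all of
#'   brain, liver and spleen - the candidate imprint class.
#' * `ED_retained` / `TE_retained`: intermediate at E3.5 and the
#'   respective E7.5 lineage (ED takes precedence; joint retention is
#'   reported in `retained_both_lineages`).
#' * `transient_embryonic`: intermediate at E3.5 only.
#'
#' A missing stage value makes the clause it gates evaluate false.
#'
#' @param stage_meth Output of [stage_methylation()].
#' @param intermediate Inclusive percentage band (default `c(40, 60)`).
#' @param stage_e35,stage_ed,stage_te Stage labels for E3.5 and the E7.5
#'   lineages.
#' @param stage_adults Adult tissue labels (all must be intermediate for
#'   `lifelong`).
#' @return `stage_meth` with `fate` and `retained_both_lineages` columns.
#' @export
classify_fates <- function(stage_meth, intermediate = c(40, 60),
                           stage_e35 = "E3.5", stage_ed = "E7.5_ED",
                           stage_te = "E7.5_TE",
                           stage_adults = c("brain", "liver", "spleen")) {
  lo <- intermediate[1]; hi <- intermediate[2]
  if (lo >= hi) abort("intermediate band must satisfy lo < hi")
  col <- function(s) stage_meth[[paste0("meth_", s)]]
  need <- c(stage_e35, stage_ed, stage_te, stage_adults)
  missing_cols <- need[!paste0("meth_", need) %in% names(stage_meth)]
  if (length(missing_cols) > 0) {
    abort(paste0("missing stage columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  i35 <- is_intermediate(col(stage_e35), lo, hi)
  ied <- is_intermediate(col(stage_ed), lo, hi)
  ite <- is_intermediate(col(stage_te), lo, hi)
  iad <- purrr::map(stage_adults, ~ is_intermediate(col(.x), lo, hi)) %>%
    purrr::reduce(`&`)
  stage_meth %>%
    mutate(
      fate = case_when(
        !i35 ~ "not_established",
        ied & iad ~ "lifelong",
        ied ~ "ED_retained",
        ite ~ "TE_retained",
        TRUE ~ "transient_embryonic"
      ),
      retained_both_lineages = i35 & ied & ite
    )
}

#' Nearest gene to each interval
#'
#' Half-open interval gap on the same chromosome; overlap means distance
#' 0. Ties are broken by the smaller gene start coordinate, then
#' lexicographic gene id. Intervals on gene-less chromosomes are flagged
#' unassigned (`NA`).
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @param genes BED-style gene tibble with `name`.
#' @return `intervals` with `nearest_gene` and `distance_bp` columns.
#' @export
nearest_gene <- function(intervals, genes) {
  res <- purrr::map(seq_len(nrow(intervals)), function(i) {
    g <- genes[genes$chrom == intervals$chrom[i], ]
    if (nrow(g) == 0) {
      return(tibble(nearest_gene = NA_character_,
                    distance_bp = NA_real_))
    }
    s <- intervals$start[i]; e <- intervals$end[i]
    gap <- pmax(0, pmax(g$start - e, s - g$end))
    g <- mutate(g, gap = gap) %>%
      arrange(.data$gap, .data$start, .data$name)
    tibble(nearest_gene = g$name[1], distance_bp = g$gap[1])
  }) %>% bind_rows()
  bind_cols(as_tibble(intervals), res)
}

#' Track gamete DMRs through development
#'
#' End-to-end fate tracker: computes per-stage methylation of each gamete
#' DMR, classifies fates, assigns parental origin from the gamete
#' methylation sign, and annotates the nearest gene. The X chromosome is
#' excluded by default because sex-mixed embryo pools confound X
#' methylation.
#'
#' @param dmrs [call_dmrs()] output (or any interval BED-like tibble; a
#'   `label` column of `sperm_specific`/`oocyte_specific` sets origin).
#' @param stages Named list of destranded stage call tables.
#' @param genes Optional gene tibble for nearest-gene annotation.
#' @param intermediate Inclusive intermediate band (percent).
#' @param stage_min_reads Per-DMR per-stage read minimum.
#' @param exclude_x Drop `chrX` DMRs before tracking (default TRUE).
#' @param ... Stage-label arguments passed to [classify_fates()].
#' @return A tibble of DMR fate records classed `dmr_fates`.
#' @export
track_fates <- function(dmrs, stages, genes = NULL,
                        intermediate = c(40, 60), stage_min_reads = 3,
                        exclude_x = TRUE, ...) {
  x <- as_tibble(dmrs)
  if (exclude_x) x <- filter(x, .data$chrom != "chrX")
  if ("label" %in% names(x)) {
    x <- mutate(x, origin = case_when(
      .data$label == "oocyte_specific" ~ "maternal",
      .data$label == "sperm_specific" ~ "paternal",
      TRUE ~ NA_character_
    ))
  }
  out <- stage_methylation(x, stages, stage_min_reads = stage_min_reads) %>%
    classify_fates(intermediate = intermediate, ...)
  if (!is.null(genes)) out <- nearest_gene(out, genes)
  class(out) <- c("dmr_fates", class(out))
  out
}

#' Summarize fate classifications by parental origin
#'
#' @param records A classified fate table ([track_fates()] or
#'   [classify_fates()] output with an `origin` column).
#' @return A list of class `fate_report`: `counts` (fate x origin
#'   contingency tibble), `n`, and `prop_maternal_lifelong` (proportion of
#'   life-long DMRs of maternal origin; `NaN` when none).
#' @export
fate_report <- function(records) {
  x <- as_tibble(records)
  if (nrow(x) == 0) {
    return(structure(list(counts = tibble(fate = character(),
                                          origin = character(),
                                          n = integer()),
                          n = 0L, prop_maternal_lifelong = NaN),
                     class = "fate_report"))
  }
  if (!"origin" %in% names(x)) x$origin <- NA_character_
  counts <- x %>%
    count(.data$fate, .data$origin, name = "n") %>%
    arrange(.data$fate, .data$origin)
  ll <- filter(x, .data$fate == "lifelong")
  structure(list(counts = counts, n = nrow(x),
                 prop_maternal_lifelong =
                   mean(ll$origin == "maternal")),
            class = "fate_report")
}

#' @export
print.fate_report <- function(x, ...) {
  cat("Gamete DMR fate report (", x$n, " DMRs)\n", sep = "")
  print(tidyr::pivot_wider(x$counts, names_from = "origin",
                           values_from = "n", values_fill = 0L))
  cat(sprintf("proportion maternal among life-long: %.3f\n",
              x$prop_maternal_lifelong))
  invisible(x)
}
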