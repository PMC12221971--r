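#' Segment a methylome into contiguous stretches of similar methylation
#'
#' Per chromosome, the ordered per-site methylation fractions are split by
#' greedy recursive binary segmentation: each candidate split is the one
#' that maximally reduces the within-segment sum of squared error, and it
#' is accepted only when both children keep at least `min_seg` CpGs and
#' the split lowers a Gaussian BIC (two extra parameters per accepted
#' change point). Segment mean methylation values are then clustered into
#' at most `max_classes` classes by a 1-D Gaussian mixture (G chosen by
#' BIC), and adjacent segments of the same class are merged
#' (neighbour joining). Classes are indexed in increasing order of class
#' mean.
#'
#' The caller supplies an already filtered, destranded table (the
#' conventional analysis keeps sites with >= 5 reads in every compared
#' sample). Large assembly gaps are *not* split automatically; pass
#' `max_gap` (e.g. 10000) to impose segment breaks at inter-CpG gaps
#' larger than that many bp.
#'
#' @param calls Destranded, filtered call table for one sample.
#' @param min_seg Minimum CpGs per segment (default 5). Chromosomes with
#'   fewer sites become a single segment flagged `short`.
#' @param max_classes Maximum number of methylation classes (default 3).
#' @param max_gap Optional bp gap above which a break is imposed
#'   (default `NULL`, off).
#' @return A tibble of class `meth_segmentation`: `chrom`, `start`, `end`
#'   (first to last CpG dinucleotide, 0-based half-open), `n_cpg`,
#'   `mean_meth`, `seg_class`, `short`. Attributes record the parameters
#'   and the fitted class means.
#' @export
segment_methylome <- function(calls, min_seg = 5, max_classes = 3,
                              max_gap = NULL) {
  assert_destranded(calls)
  if (nrow(calls) == 0) abort("cannot segment an empty call table")
  x <- arrange(calls, .data$chrom, .data$pos)
  frac <- meth_fraction(x)

  seg_site <- integer(nrow(x))  # per-site segment id
  short_flag <- logical(0)
  block_of <- integer(0)        # per-segment block id (gap/chrom breaks)
  next_id <- 0L
  block_id <- 0L
  for (chr in unique(x$chrom)) {
    sel <- which(x$chrom == chr)
    m <- frac[sel]
    blocks <- list(seq_along(m))
    if (!is.null(max_gap) && length(sel) > 1) {
      gaps <- diff(x$pos[sel])
      cuts <- which(gaps > max_gap)
      bounds <- c(0, cuts, length(m))
      blocks <- purrr::map2(head(bounds, -1) + 1, tail(bounds, -1), seq)
    }
    for (blk in blocks) {
      block_id <- block_id + 1L
      bm <- m[blk]
      if (length(bm) < 2 * min_seg) {
        next_id <- next_id + 1L
        seg_site[sel[blk]] <- next_id
        short_flag[next_id] <- length(bm) < min_seg
        block_of[next_id] <- block_id
        next
      }
      cp <- binseg_changepoints(bm, min_seg)
      bounds <- c(0L, cp, length(bm))
      for (j in seq_len(length(bounds) - 1)) {
        next_id <- next_id + 1L
        seg_site[sel[blk][(bounds[j] + 1):bounds[j + 1]]] <- next_id
        short_flag[next_id] <- FALSE
        block_of[next_id] <- block_id
      }
    }
  }

  seg <- tibble(chrom = x$chrom, pos = x$pos, m = frac, id = seg_site) %>%
    group_by(.data$chrom, .data$id) %>%
    summarise(start = min(.data$pos) - 1L, end = max(.data$pos) + 1L,
              n_cpg = n(), mean_meth = mean(.data$m), .groups = "drop") %>%
    arrange(.data$chrom, .data$start)
  seg$short <- short_flag[seg$id]
  seg$block <- block_of[seg$id]

  seg$seg_class <- classify_segment_means(seg$mean_meth, max_classes)

  # join same-class neighbours (never across gap/chromosome breaks)
  run <- cumsum(c(TRUE, seg$seg_class[-1] != seg$seg_class[-nrow(seg)] |
                    seg$block[-1] != seg$block[-nrow(seg)]))
  site_run <- run[match(seg_site, seg$id)]
  joined <- tibble(chrom = x$chrom, pos = x$pos, m = frac,
                   run = site_run) %>%
    group_by(.data$chrom, .data$run) %>%
    summarise(start = min(.data$pos) - 1L, end = max(.data$pos) + 1L,
              n_cpg = n(), mean_meth = mean(.data$m), .groups = "drop") %>%
    arrange(.data$chrom, .data$start)
  joined$seg_class <- seg$seg_class[match(joined$run, run)]
  short_by_run <- tapply(seg$short, run, any)
  joined$short <- as.logical(unname(short_by_run[as.character(joined$run)]))
  out <- select(joined, "chrom", "start", "end", "n_cpg", "mean_meth",
                "seg_class", "short")

  class_means <- tapply(rep(out$mean_meth, out$n_cpg),
                        rep(out$seg_class, out$n_cpg), mean)
  class(out) <- c("meth_segmentation", class(out))
  attr(out, "params") <- list(min_seg = min_seg, max_classes = max_classes,
                              max_gap = max_gap)
  attr(out, "n_classes") <- length(unique(out$seg_class))
  attr(out, "class_means") <- class_means
  out
}

# greedy binary segmentation; returns sorted change points (index of last
# site of the left child)
binseg_changepoints <- function(m, min_seg) {
  n <- length(m)
  S <- cumsum(m); S2 <- cumsum(m^2)
  sse <- function(a, b) {
    s <- S[b] - if (a > 1) S[a - 1] else 0
    s2 <- S2[b] - if (a > 1) S2[a - 1] else 0
    max(s2 - s^2 / (b - a + 1), 0)
  }
  eps <- 1e-12
  cps <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    a <- seg[1]; b <- seg[2]
    len <- b - a + 1
    if (len < 2 * min_seg) next
    cand <- (a + min_seg - 1):(b - min_seg)
    rss <- vapply(cand, function(s) sse(a, s) + sse(s + 1, b), numeric(1))
    s_best <- cand[which.min(rss)]
    rss0 <- sse(a, b); rss1 <- min(rss)
    # Gaussian BIC-type acceptance; the 4 log(n) penalty charges the two
    # extra parameters plus the max-over-candidates split selection
    if (len * log((rss1 + eps) / len) + 4 * log(len) <
        len * log((rss0 + eps) / len)) {
      cps <- c(cps, s_best)
      stack <- c(stack, list(c(a, s_best)), list(c(s_best + 1L, b)))
    }
  }
  cps <- sort(cps)
  # coordinate-descent refinement: re-optimize each boundary between its
  # neighbours (greedy first splits can land one site off the joint
  # SSE optimum)
  if (length(cps) > 0) {
    for (pass in 1:10) {
      changed <- FALSE
      bounds <- c(0L, cps, n)
      for (j in seq_along(cps)) {
        a <- bounds[j] + 1L; b <- bounds[j + 2]
        cand <- (a + min_seg - 1):(b - min_seg)
        rss <- vapply(cand, function(s) sse(a, s) + sse(s + 1, b),
                      numeric(1))
        s_best <- cand[which.min(rss)]
        if (s_best != cps[j]) {
          cps[j] <- s_best
          bounds <- c(0L, cps, n)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  cps
}

classify_segment_means <- function(means, max_classes) {
  u <- sort(unique(round(means, 10)))
  if (length(u) == 1 || length(means) == 1) {
    return(rep(1L, length(means)))
  }
  if (length(u) == 2) {
    return(as.integer(match(round(means, 10), u)))
  }
  g_max <- min(max_classes, length(u))
  fit <- tryCatch({
    bic <- suppressWarnings(
      mclust::mclustBIC(means, G = 1:g_max, modelNames = c("E", "V"),
                        verbose = FALSE))
    suppressWarnings(mclust::Mclust(means, x = bic, verbose = FALSE))
  }, error = function(e) NULL)
  cl <- if (!is.null(fit) && !is.null(fit$classification)) {
    fit$classification
  } else {
    kmeans(means, centers = min(g_max, length(means) - 1),
           nstart = 5)$cluster
  }
  # relabel so class index increases with class mean
  ord <- order(tapply(means, cl, mean))
  as.integer(match(cl, ord))
}

#' Flag partially methylated domains among segments
#'
#' A segment is a PMD candidate when it is long and its mean methylation
#' is intermediate - the disordered-methylation signature of
#' trophectoderm/placental methylomes. The length and band thresholds are
#' package defaults, not published constants.
#'
#' @param segments A [segment_methylome()] result.
#' @param min_len_bp Minimum segment length (default 100 kb).
#' @param mid_lo,mid_hi Inclusive intermediate methylation band
#'   (fractions; default 0.3-0.7).
#' @return `segments` with an `is_pmd` column.
#' @export
flag_pmds <- function(segments, min_len_bp = 1e5, mid_lo = 0.3,
                      mid_hi = 0.7) {
  out <- mutate(as_tibble(segments),
                is_pmd = (.data$end - .data$start) >= min_len_bp &
                  .data$mean_meth >= mid_lo & .data$mean_meth <= mid_hi)
  class(out) <- c("meth_segmentation", class(out))
  for (at in c("params", "n_classes", "class_means")) {
    attr(out, at) <- attr(segments, at)
  }
  attr(out, "pmd_thresholds") <- list(min_len_bp = min_len_bp,
                                      mid_lo = mid_lo, mid_hi = mid_hi)
  out
}

#' Compare segmentations of two samples
#'
#' Both segmentations must have been produced with identical parameters.
#' Returns the per-segment (length, methylation, class) arrays of both
#' samples plus each sample's PMD genome fraction (PMD bp over segmented
#' bp; 0 when `is_pmd` has not been flagged).
#'
#' @param segments_a,segments_b [segment_methylome()] (optionally
#'   [flag_pmds()]-annotated) results.
#' @param names Sample labels for the two inputs.
#' @return A list of class `segment_comparison`: `segments` (long tibble
#'   with `sample`, `chrom`, `start`, `end`, `length_bp`, `mean_meth`,
#'   `seg_class`, `is_pmd`) and `summary` (per-sample `n_segments`,
#'   `pmd_fraction`).
#' @export
segment_compare <- function(segments_a, segments_b,
                            names = c("A", "B")) {
  pa <- attr(segments_a, "params"); pb <- attr(segments_b, "params")
  if (!identical(pa[c("min_seg", "max_classes", "max_gap")],
                 pb[c("min_seg", "max_classes", "max_gap")])) {
    abort("segmentations were produced with different parameters")
  }
  one <- function(s, nm) {
    s <- as_tibble(s)
    if (!"is_pmd" %in% names(s)) s$is_pmd <- FALSE
    mutate(s, sample = nm, length_bp = .data$end - .data$start) %>%
      select("sample", "chrom", "start", "end", "length_bp", "mean_meth",
             "seg_class", "is_pmd")
  }
  segs <- bind_rows(one(segments_a, names[1]), one(segments_b, names[2]))
  summary <- segs %>%
    group_by(.data$sample) %>%
    summarise(n_segments = n(),
              pmd_fraction = sum(.data$length_bp[.data$is_pmd]) /
                sum(.data$length_bp),
              .groups = "drop")
  structure(list(segments = segs, summary = summary),
            class = "segment_comparison")
}

#' Jaccard index between two interval sets
#'
#' Intersection over union of total covered bp (intervals are 0-based
#' half-open; overlapping intervals within a set are merged first). Used
#' to score recovery of planted domains.
#'
#' @param a,b Interval tibbles (`chrom`, `start`, `end`).
#' @return Scalar in `[0, 1]` (`NaN` when both sets are empty).
#' @export
interval_jaccard <- function(a, b) {
  merge_set <- function(x) {
    x <- arrange(as_tibble(x), .data$chrom, .data$start)
    if (nrow(x) == 0) return(x)
    keep <- list(); cur <- x[1, ]
    for (i in seq_len(nrow(x))[-1]) {
      if (x$chrom[i] == cur$chrom && x$start[i] <= cur$end) {
        cur$end <- max(cur$end, x$end[i])
      } else {
        keep[[length(keep) + 1]] <- cur; cur <- x[i, ]
      }
    }
    keep[[length(keep) + 1]] <- cur
    bind_rows(keep)
  }
  a <- merge_set(select(as_tibble(a), "chrom", "start", "end"))
  b <- merge_set(select(as_tibble(b), "chrom", "start", "end"))
  len <- function(x) sum(x$end - x$start)
  inter <- 0
  for (i in seq_len(nrow(a))) {
    j <- b$chrom == a$chrom[i]
    if (!any(j)) next
    inter <- inter + sum(pmax(0, pmin(b$end[j], a$end[i]) -
                                pmax(b$start[j], a$start[i])))
  }
  union_len <- len(a) + len(b) - inter
  inter / union_len
}
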