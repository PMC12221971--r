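# shared fixtures: built once per run, cached in an environment

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# quick destranded call-table constructor
make_calls <- function(chrom, pos, n_meth, n_unmeth) {
  out <- tibble::tibble(chrom = chrom, pos = as.integer(pos),
                        strand = "+", n_meth = as.integer(n_meth),
                        n_unmeth = as.integer(n_unmeth), context = "CpG")
  methylfate:::set_destranded(out)
}

# the main synthetic study: 5 Mb genome, 50 gamete DMRs per origin,
# 3 trophectoderm PMDs, Xi block with escapees, plus a 0.70-global adult
# male/female pair
acc_study <- function(seed = 1729) {
  cached(paste0("acc", seed), {
    samples <- dplyr::bind_rows(
      default_sample_specs(),
      sample_spec("adult_f", 0.70, role = "adult", sex = "female"),
      sample_spec("adult_m", 0.70, role = "adult", sex = "male")
    )
    simulate_study(samples = samples, seed = seed, dmr_n = 50, pmd_n = 3)
  })
}

acc_calls <- function(seed = 1729) {
  cached(paste0("acc_calls", seed), {
    lapply(acc_study(seed)$samples, function(s) destrand(s$calls))
  })
}

acc_tiles <- function(seed = 1729) {
  cached(paste0("acc_tiles", seed), {
    calls <- acc_calls(seed)
    spec <- acc_study(seed)$genome$spec
    test_tiles(tile_counts(calls$sperm, calls$oocyte,
                           chrom_lengths = spec$chrom_lengths))
  })
}

# fate-focused study: 25 planted DMRs per fate per origin (200 total)
fate_study <- function(seed = 1729) {
  cached(paste0("fate", seed), {
    spec <- genome_spec(chrom_lengths = c(chr1 = 3e6, chr2 = 3e6,
                                          chr3 = 3e6),
                        cgi_count = 450, n_genes = 60, seed = seed)
    samples <- dplyr::filter(
      default_sample_specs(),
      name %in% c("sperm", "oocyte", "E3.5", "E7.5_ED", "E7.5_TE",
                  "brain", "liver", "spleen"))
    simulate_study(spec, samples = samples, seed = seed, dmr_n = 100,
                   fate_counts = c(transient = 25, ED_retained = 25,
                                   TE_retained = 25, lifelong = 25),
                   pmd_n = 0, xi_fraction = 0, escapee_n = 0)
  })
}

# X-inactivation study: uniform planted 0.70 (maternal/active) vs 0.35
# (paternal/inactive) X, no escapees
xi_study <- function(seed = 1729) {
  cached(paste0("xi", seed), {
    spec <- genome_spec(chrom_lengths = c(chr1 = 1e6, chrX = 8e5,
                                          chrY = 1e5),
                        cgi_count = 30, n_genes = 20, seed = seed)
    samples <- dplyr::bind_rows(
      sample_spec("adult_f", 0.70, role = "adult", sex = "female"),
      sample_spec("adult_m", 0.70, role = "adult", sex = "male"))
    simulate_study(spec, samples = samples, seed = seed, dmr_n = 5,
                   pmd_n = 0, escapee_n = 0)
  })
}

# independent exact-test oracle: enumerate all tables with the observed
# margins via log-factorials
oracle_fisher_p <- function(a, u, b, v) {
  ca <- a + u; cb <- b + v; K <- a + b; N <- ca + cb
  if (ca == 0 || cb == 0 || K == 0 || K == N) return(1)
  ks <- max(0, ca - (N - K)):min(ca, K)
  lp <- vapply(ks, function(k) {
    lfactorial(K) + lfactorial(N - K) + lfactorial(ca) + lfactorial(cb) -
      lfactorial(N) - lfactorial(k) - lfactorial(K - k) -
      lfactorial(ca - k) - lfactorial(cb - (K - k))
  }, numeric(1))
  pr <- exp(lp)
  sum(pr[pr <= pr[ks == a] * (1 + 1e-12)])
}

# exhaustive SSE change-point oracles
oracle_sse <- function(x) if (length(x) < 1) 0 else sum((x - mean(x))^2)

oracle_best_split1 <- function(x, min_seg) {
  n <- length(x)
  cand <- min_seg:(n - min_seg)
  cand[which.min(vapply(cand, function(s) {
    oracle_sse(x[1:s]) + oracle_sse(x[(s + 1):n])
  }, numeric(1)))]
}

oracle_best_split2 <- function(x, min_seg) {
  n <- length(x)
  best <- NULL; bv <- Inf
  for (s in min_seg:(n - 2 * min_seg)) {
    for (t in (s + min_seg):(n - min_seg)) {
      v <- oracle_sse(x[1:s]) + oracle_sse(x[(s + 1):t]) +
        oracle_sse(x[(t + 1):n])
      if (v < bv) { bv <- v; best <- c(s, t) }
    }
  }
  best
}

# map called regions back to planted DMRs: best-overlap fate per planted
# feature
planted_fate_calls <- function(fates, truth_dmr) {
  vapply(seq_len(nrow(truth_dmr)), function(i) {
    j <- which(fates$chrom == truth_dmr$chrom[i] &
                 fates$start < truth_dmr$end[i] &
                 fates$end > truth_dmr$start[i])
    if (length(j) == 0) return(NA_character_)
    ov <- pmin(fates$end[j], truth_dmr$end[i]) -
      pmax(fates$start[j], truth_dmr$start[i])
    fates$fate[j[which.max(ov)]]
  }, character(1))
}
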