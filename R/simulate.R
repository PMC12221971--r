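#' Specify a synthetic genome
#'
#' Defines the skeleton for the methylome simulator: chromosome set, mean
#' CpG spacing (geometric inter-site gaps), and CpG-island blocks in which
#' CpGs are densified.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths in bp.
#'   The default provides two autosomes plus `chrX` and `chrY` (5 Mb
#'   total). Sex-linked analyses require `chrX`/`chrY` to be present.
#' @param cpg_spacing_mean Mean distance in bp between background CpG
#'   starts (minimum gap 2, so dinucleotides never overlap).
#' @param cgi_count Number of CpG-island blocks to place (CpGs densified
#'   to at least 5x the background density).
#' @param cgi_length_bp Length of each CpG-island block.
#' @param n_genes Number of toy genes placed uniformly (non-overlapping,
#'   random strand); promoters are the 1 kb upstream of each TSS.
#' @param gene_length_bp Length of each toy gene.
#' @param seed Integer RNG seed (default 1729).
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(chrom_lengths = c(chr1 = 2e6, chr2 = 2e6,
                                          chrX = 8e5, chrY = 2e5),
                        cpg_spacing_mean = 100,
                        cgi_count = 160, cgi_length_bp = 1000,
                        n_genes = 80, gene_length_bp = 5000,
                        seed = 1729) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    abort("chrom_lengths must be a named vector")
  }
  if (any(chrom_lengths < 2)) abort("chromosome lengths must be >= 2 bp")
  if (cpg_spacing_mean < 3) abort("cpg_spacing_mean must be >= 3")
  if (cgi_count > 0 && any(chrom_lengths < 2 * cgi_length_bp)) {
    abort(paste0("chromosome shorter than 2 x cgi_length_bp: ",
                 paste(names(chrom_lengths)[chrom_lengths < 2 * cgi_length_bp],
                       collapse = ", ")))
  }
  structure(list(chrom_lengths = chrom_lengths,
                 cpg_spacing_mean = cpg_spacing_mean,
                 cgi_count = cgi_count, cgi_length_bp = cgi_length_bp,
                 n_genes = n_genes, gene_length_bp = gene_length_bp,
                 seed = seed),
            class = "genome_spec")
}

# geometric-gap CpG walk: gaps are 2 + Geom(1/(mean-2)), so E[gap] = mean
# and dinucleotides never overlap
rcpg_positions <- function(len, spacing) {
  prob <- 1 / max(spacing - 2, 1)
  pos <- integer(0)
  at <- 0
  repeat {
    n_draw <- max(ceiling((len - at) / spacing * 1.4), 50)
    gaps <- 2 + rgeom(n_draw, prob)
    new <- at + cumsum(gaps)
    pos <- c(pos, new[new <= len - 1])
    if (length(new) == 0 || max(new) > len - 1) break
    at <- max(new)
  }
  pos[pos >= 1 & pos <= len - 1]
}

place_intervals <- function(chrom_lengths, n, len_lo, len_hi = len_lo,
                            existing = NULL, max_tries = 200) {
  # uniform non-overlapping placement proportional to chromosome length
  if (n == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  chroms <- names(chrom_lengths)
  placed <- existing %||%
    tibble(chrom = character(), start = integer(), end = integer())
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      chr <- base::sample(chroms, 1, prob = chrom_lengths)
      len <- if (len_hi > len_lo) {
        as.integer(round(runif(1, len_lo, len_hi)))
      } else as.integer(len_lo)
      if (chrom_lengths[[chr]] <= len + 2) next
      start <- as.integer(floor(runif(1, 0, chrom_lengths[[chr]] - len)))
      end <- start + len
      clash <- placed$chrom == chr & placed$start < end & placed$end > start
      if (!any(clash)) {
        out[[i]] <- tibble(chrom = chr, start = start, end = end)
        placed <- bind_rows(placed, out[[i]])
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(paste0("could not place interval ", i, " of ", n,
                   " without overlap; most saturated chromosome: ",
                   names(which.max(table(placed$chrom)))))
    }
  }
  bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a genome skeleton: CpG map and toy annotations
#'
#' Generates per-chromosome CpG positions from a geometric-gap process,
#' CpG-island blocks with densified CpGs, and a toy gene annotation with
#' promoters defined as the 1 kb upstream of each TSS (strand-aware).
#' Genes on `chrY` double as the pseudo-Y interval set used for embryo
#' sexing.
#'
#' @param spec A [genome_spec()].
#' @return An object of class `sim_genome`: a list with `spec`, `cpg_map`
#'   (tibble `chrom`, 1-based `pos`), and BED-style (0-based half-open)
#'   tibbles `genes`, `promoters`, `cgi`, `pseudo_y`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::local_seed(spec$seed)
  lens <- spec$chrom_lengths
  # islands go on autosomes: keeps the sex chromosomes' allele-level
  # ground truth uniform for the X-inactivation analyses
  auto <- setdiff(names(lens), c("chrX", "chrY"))
  cgi_lens <- if (length(auto) > 0) lens[auto] else lens
  cgi <- place_intervals(cgi_lens, spec$cgi_count, spec$cgi_length_bp) %>%
    arrange(.data$chrom, .data$start)
  dense_spacing <- max(3, spec$cpg_spacing_mean / 8)
  cpg <- purrr::map(names(lens), function(chr) {
    bg <- rcpg_positions(lens[[chr]], spec$cpg_spacing_mean)
    ci <- filter(cgi, .data$chrom == chr)
    dense <- unlist(purrr::map2(ci$start, ci$end, function(s, e) {
      s + rcpg_positions(e - s, dense_spacing)
    }))
    # background sites inside islands are replaced by the dense draw
    if (nrow(ci) > 0) {
      in_cgi <- !is.na(interval_index(rep(chr, length(bg)), bg, ci))
      bg <- bg[!in_cgi]
    }
    pos <- sort(unique(c(bg, dense)))
    if (length(pos) > 1) pos <- pos[c(TRUE, diff(pos) >= 2)]
    tibble(chrom = chr, pos = as.integer(pos))
  }) %>% bind_rows()
  genes <- place_intervals(lens, spec$n_genes, spec$gene_length_bp,
                           existing = NULL) %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(name = paste0("gene", row_number()), score = 0,
           strand = base::sample(c("+", "-"), n(), replace = TRUE))
  promoters <- genes %>%
    mutate(
      p_start = if_else(.data$strand == "+",
                        pmax(.data$start - 1000L, 0L), .data$end),
      p_end = if_else(.data$strand == "+", .data$start,
                      pmin(.data$end + 1000L,
                           as.integer(lens[.data$chrom]))),
      start = .data$p_start, end = .data$p_end,
      name = paste0(.data$name, "_prom")
    ) %>%
    filter(.data$end > .data$start) %>%
    select("chrom", "start", "end", "name", "score", "strand")
  cgi <- mutate(cgi, name = paste0("cgi", row_number()), score = 0,
                strand = "+")
  structure(list(spec = spec, cpg_map = cpg, genes = genes,
                 promoters = promoters, cgi = cgi,
                 pseudo_y = filter(genes, .data$chrom == "chrY")),
            class = "sim_genome")
}

# index (or NA) of the non-overlapping 0-based half-open interval covering
# each 1-based position
interval_index <- function(chrom, pos, intervals) {
  out <- rep(NA_integer_, length(pos))
  if (nrow(intervals) == 0 || length(pos) == 0) return(out)
  intervals <- mutate(intervals, .row = row_number())
  for (chr in unique(chrom)) {
    iv <- intervals[intervals$chrom == chr, ]
    if (nrow(iv) == 0) next
    iv <- iv[order(iv$start), ]
    sel <- which(chrom == chr)
    idx <- findInterval(pos[sel] - 1, iv$start)
    hit <- idx > 0 & (pos[sel] - 1) < iv$end[pmax(idx, 1)]
    out[sel[hit]] <- iv$.row[idx[hit]]
  }
  out
}

#' Default sample panel for the developmental-methylome simulation
#'
#' One row per sample condition: gametes, the embryonic stage series, the
#' E7.5 embryonic-disc and trophectoderm lineages, and adult tissues.
#' Global methylation means follow the published developmental trajectory
#' (sperm 0.77, oocyte 0.65, E1.5 0.625, E4.5 0.64, E5.5 0.54, E6.5 0.45,
#' E7.5 0.49, brain 0.72, liver 0.69, spleen 0.55); E3.5 (0.63) and the
#' E7.5 lineage backgrounds (0.75) are interpolated/free choices described
#' in the package vignette. Embryo pools are sex-mixed (`"pooled"`);
#' adult tissues default to male so their recovered genome means sit on
#' the trajectory (a planted inactive-X block lowers female genome means)
#' - X analyses use dedicated sexed pairs added via [sample_spec()].
#'
#' @param coverage_mean Poisson mean read depth per CpG.
#' @param beta_dispersion Beta concentration of per-CpG latent noise
#'   (`Inf` = no latent noise).
#' @param conversion_error Probability an unmethylated C reads methylated.
#' @return A tibble of sample specifications with roles used when planting
#'   features (`gamete`, `embryo`, `lineage_ED`, `lineage_TE`, `adult`).
#' @export
default_sample_specs <- function(coverage_mean = 10, beta_dispersion = 100,
                                 conversion_error = 0.005) {
  tibble(
    name = c("sperm", "oocyte", "E1.5", "E3.5", "E4.5", "E5.5", "E6.5",
             "E7.5", "E7.5_ED", "E7.5_TE", "brain", "liver", "spleen"),
    global_meth_mean = c(0.77, 0.65, 0.625, 0.63, 0.64, 0.54, 0.45,
                         0.49, 0.75, 0.75, 0.72, 0.69, 0.55),
    role = c("gamete", "gamete", "embryo", "embryo", "embryo", "embryo",
             "embryo", "embryo", "lineage_ED", "lineage_TE", "adult",
             "adult", "adult"),
    sex = c("male", "female", "pooled", "pooled", "pooled", "pooled",
            "pooled", "pooled", "pooled", "pooled", "male", "male",
            "male"),
    coverage_mean = coverage_mean,
    beta_dispersion = beta_dispersion,
    conversion_error = conversion_error
  )
}

#' Specify a single simulated sample
#'
#' @param name Sample label.
#' @param global_meth_mean Target genome-wide mean methylation in `[0,1]`.
#' @param role One of `gamete`, `embryo`, `lineage_ED`, `lineage_TE`,
#'   `adult` (controls which planted-feature effects apply).
#' @param sex `male`, `female` or `pooled`.
#' @param coverage_mean Poisson mean read depth per CpG (> 0).
#' @param beta_dispersion Beta concentration (`Inf` disables latent noise).
#' @param conversion_error In `[0, 0.05)`.
#' @return A one-row sample-spec tibble.
#' @export
sample_spec <- function(name, global_meth_mean, role = "adult",
                        sex = "pooled", coverage_mean = 10,
                        beta_dispersion = 100, conversion_error = 0.005) {
  if (global_meth_mean < 0 || global_meth_mean > 1) {
    abort("global_meth_mean must be in [0, 1]")
  }
  if (coverage_mean <= 0) abort("coverage_mean must be > 0")
  if (conversion_error < 0 || conversion_error >= 0.05) {
    abort("conversion_error must be in [0, 0.05)")
  }
  tibble(name = name, global_meth_mean = global_meth_mean, role = role,
         sex = sex, coverage_mean = coverage_mean,
         beta_dispersion = beta_dispersion,
         conversion_error = conversion_error)
}

fate_effect <- function(fate, stage_role, mid, resolved) {
  # methylation target of a gamete DMR in a post-fertilization sample
  retained <- switch(fate,
    transient = stage_role == "embryo",
    ED_retained = stage_role %in% c("embryo", "lineage_ED"),
    TE_retained = stage_role %in% c("embryo", "lineage_TE"),
    lifelong = TRUE,
    FALSE
  )
  if (retained) mid else resolved
}

#' Plant ground-truth features into a simulated genome
#'
#' Places gamete DMRs (on autosomal CpG-island blocks, where germline DMRs
#' reside in vivo), partially methylated domains (for the trophectoderm
#' lineage), an inactive-X hypomethylation block with escapee exceptions,
#' and records every feature with its per-sample methylation targets in a
#' truth ledger.
#'
#' Gamete DMR targets default to 0.85 on the methylated gamete and 0.05 on
#' the other; every post-fertilization sample in which the mark is retained
#' gets the mid-level mean of the two parental targets (0.45, the diploid
#' one-allele signature), and 0.85 where the mark has resolved.
#'
#' @param genome A [simulate_genome()] result.
#' @param samples Sample-spec tibble (default [default_sample_specs()]).
#' @param dmr_n Number of gamete DMRs per parental origin.
#' @param fate_counts Named integer vector allocating each origin's DMRs to
#'   fates `transient`, `ED_retained`, `TE_retained`, `lifelong`; recycled
#'   proportionally if it does not sum to `dmr_n`.
#' @param pmd_n Number of partially methylated domains (trophectoderm).
#' @param pmd_length_bp Length range for PMDs.
#' @param pmd_level PMD methylation target.
#' @param xi_fraction Fraction of `chrX` covered by the inactive-X
#'   hypomethylation block (0 disables it).
#' @param xi_level Inactive-X (paternal-allele) methylation target.
#' @param escapee_n Number of X genes escaping inactivation (their Xi
#'   methylation matches the active allele).
#' @param meth_high,meth_low Gamete DMR targets for the methylated and
#'   unmethylated gamete.
#' @param cgi_level Methylation target forced at CpG islands.
#' @param seed Integer RNG seed.
#' @return An object of class `sim_truth`: list with `features` (tibble
#'   `kind`, `chrom`, `start`, `end`, `origin`, `fate`, list-column
#'   `effect` of per-sample targets), `sample_sexes`, and `params`.
#' @export
plant_features <- function(genome, samples = default_sample_specs(),
                           dmr_n = 50,
                           fate_counts = c(transient = 0.5,
                                           ED_retained = 0.2,
                                           TE_retained = 0.2,
                                           lifelong = 0.1),
                           pmd_n = 3, pmd_length_bp = c(1e5, 3e5),
                           pmd_level = 0.45,
                           xi_fraction = 1, xi_level = 0.35,
                           escapee_n = 4,
                           meth_high = 0.85, meth_low = 0.05,
                           cgi_level = 0.05, seed = 1729) {
  stopifnot(inherits(genome, "sim_genome"))
  withr::local_seed(seed)
  lens <- genome$spec$chrom_lengths
  autosomes <- setdiff(names(lens), c("chrX", "chrY"))
  mid <- (meth_high + meth_low) / 2
  roles <- setNames(samples$role, samples$name)

  # --- PMDs first (trophectoderm lineage only), away from each other
  te_samples <- samples$name[samples$role == "lineage_TE"]
  pmd_iv <- place_intervals(lens[autosomes], pmd_n,
                            pmd_length_bp[1], pmd_length_bp[2])

  # --- gamete DMRs: sample autosomal CpG islands outside PMDs without
  # replacement (keeps domain-level and island-level truth disjoint)
  auto_cgi <- filter(genome$cgi, .data$chrom %in% autosomes)
  in_pmd <- overlaps_any(auto_cgi$chrom, auto_cgi$start, auto_cgi$end,
                         pmd_iv)
  auto_cgi <- auto_cgi[!in_pmd, ]
  need <- 2 * dmr_n
  if (nrow(auto_cgi) < need) {
    abort(paste0("cannot place ", need, " gamete DMRs: only ",
                 nrow(auto_cgi),
                 " autosomal CpG-island blocks available outside PMDs"))
  }
  fates <- rep(names(fate_counts),
               times = round_to_total(fate_counts, dmr_n))
  dmr_rows <- auto_cgi[base::sample.int(nrow(auto_cgi), need), ]
  dmrs <- purrr::map(seq_len(need), function(i) {
    origin <- if (i <= dmr_n) "maternal" else "paternal"
    fate <- fates[((i - 1) %% dmr_n) + 1]
    gam_hi <- if (origin == "maternal") "oocyte" else "sperm"
    gam_lo <- if (origin == "maternal") "sperm" else "oocyte"
    eff <- purrr::map_dbl(samples$name, function(s) {
      r <- roles[[s]]
      if (s == gam_hi) meth_high
      else if (s == gam_lo) meth_low
      else if (r == "gamete") meth_low
      else fate_effect(fate, r, mid, meth_high)
    })
    tibble(kind = "gamete_dmr", chrom = dmr_rows$chrom[i],
           start = dmr_rows$start[i], end = dmr_rows$end[i],
           origin = origin, fate = fate,
           effect = list(setNames(eff, samples$name)))
  }) %>% bind_rows()

  pmds <- pmd_iv %>%
    mutate(kind = "pmd", origin = "none", fate = "none",
           effect = purrr::map(seq_len(n()), function(i) {
             setNames(rep(pmd_level, length(te_samples)), te_samples)
           }))

  # --- inactive-X block and escapees
  xi <- NULL
  escapees <- NULL
  if (xi_fraction > 0 && "chrX" %in% names(lens)) {
    xi_end <- as.integer(round(xi_fraction * lens[["chrX"]]))
    xi <- tibble(kind = "xi_block", chrom = "chrX", start = 0L,
                 end = xi_end, origin = "paternal", fate = "none",
                 effect = list(setNames(xi_level, "xi")))
    x_genes <- filter(genome$genes, .data$chrom == "chrX",
                      .data$end <= xi_end)
    if (escapee_n > 0 && nrow(x_genes) > 0) {
      pick <- x_genes[base::sample.int(nrow(x_genes),
                                       min(escapee_n, nrow(x_genes))), ]
      escapees <- tibble(kind = "escapee", chrom = pick$chrom,
                         start = pick$start, end = pick$end,
                         origin = "none", fate = "none",
                         effect = purrr::map(seq_len(nrow(pick)),
                                             ~ setNames(numeric(0),
                                                        character(0))))
      escapees$gene <- pick$name
    }
  }

  cgi_feat <- genome$cgi %>%
    select("chrom", "start", "end") %>%
    mutate(kind = "cgi", origin = "none", fate = "none",
           effect = purrr::map(seq_len(n()),
                               ~ setNames(numeric(0), character(0))))

  features <- bind_rows(dmrs, pmds, xi, escapees, cgi_feat) %>%
    mutate(feature_id = paste0(.data$kind, "_", row_number())) %>%
    select("feature_id", "kind", "chrom", "start", "end", "origin",
           "fate", dplyr::any_of("gene"), "effect")

  # every planted interval must contain at least one CpG
  hit <- purrr::pmap_lgl(
    list(features$chrom, features$start, features$end),
    function(chr, s, e) {
      any(genome$cpg_map$chrom == chr & genome$cpg_map$pos > s &
            genome$cpg_map$pos <= e)
    })
  if (!all(hit)) {
    abort(paste0("planted feature without a CpG: ",
                 paste(features$feature_id[!hit], collapse = ", ")))
  }

  structure(list(
    features = features,
    sample_sexes = setNames(samples$sex, samples$name),
    params = list(meth_high = meth_high, meth_low = meth_low, mid = mid,
                  cgi_level = cgi_level, pmd_level = pmd_level,
                  xi_level = xi_level, seed = seed)
  ), class = "sim_truth")
}

round_to_total <- function(props, total) {
  # largest-remainder allocation of `total` among named proportions/counts
  w <- props / sum(props)
  base_n <- floor(w * total)
  rem <- total - sum(base_n)
  if (rem > 0) {
    extra <- order(w * total - base_n, decreasing = TRUE)[seq_len(rem)]
    base_n[extra] <- base_n[extra] + 1
  }
  as.integer(base_n)
}

rbeta_disp <- function(n, mu, theta) {
  # Beta(mu*theta, (1-mu)*theta); theta = Inf or boundary mu degenerates
  out <- mu
  draw <- is.finite(theta) & mu > 0 & mu < 1
  if (length(mu) == 1) {
    if (draw) return(rbeta(n, mu * theta, (1 - mu) * theta))
    return(rep(mu, n))
  }
  out[draw] <- rbeta(sum(draw), mu[draw] * theta, (1 - mu[draw]) * theta)
  out
}

#' Simulate one sample's methylation calls
#'
#' Per CpG: the regional target is the sample's global mean, overridden at
#' CpG islands (forced low) and inside planted features; a latent
#' methylation probability is drawn from a Beta centred on the target;
#' coverage is Poisson and split equally between the two alleles (binomial
#' thinning); methylated counts are binomial at the allele's latent
#' probability adjusted for bisulfite conversion error
#' (`p' = p + (1 - p) * error`). In female samples, X-chromosome calls are
#' an equal mixture of the active (maternal) and inactive (paternal)
#' allele; males carry a single, maternal X and no paternal-X records.
#' Combined counts are split across strands binomially.
#'
#' @param genome A [simulate_genome()] result.
#' @param truth A [plant_features()] truth ledger.
#' @param sample One row of a sample-spec tibble (see [sample_spec()]).
#' @param seed Integer RNG seed.
#' @return An object of class `sim_sample`: list with `calls` (stranded
#'   cytosine-report-style table, two rows per CpG), `maternal` and
#'   `paternal` (destranded allele call tables), and `sample` (the spec
#'   row).
#' @export
simulate_sample <- function(genome, truth, sample, seed = 1729) {
  stopifnot(inherits(genome, "sim_genome"), inherits(truth, "sim_truth"))
  if (!sample$name %in% names(truth$sample_sexes)) {
    abort(paste0("sample not in truth ledger: ", sample$name))
  }
  withr::local_seed(seed)
  sex <- sample$sex
  cpg <- genome$cpg_map
  if (sex == "female") cpg <- filter(cpg, .data$chrom != "chrY")
  n <- nrow(cpg)
  p <- truth$params

  # regional targets: global -> CGI forcing -> feature overrides
  target <- rep(sample$global_meth_mean, n)
  overridden <- rep(FALSE, n)
  cgi_iv <- filter(truth$features, .data$kind == "cgi")
  in_cgi <- !is.na(interval_index(cpg$chrom, cpg$pos, cgi_iv))
  target[in_cgi] <- p$cgi_level
  overridden <- overridden | in_cgi
  tgt_m <- target
  tgt_p <- target
  for (kind in c("pmd", "gamete_dmr")) {
    fs <- filter(truth$features, .data$kind == !!kind)
    if (nrow(fs) == 0) next
    eff_val <- purrr::map_dbl(fs$effect, function(e) {
      if (sample$name %in% names(e)) unname(e[[sample$name]]) else NA_real_
    })
    idx <- interval_index(cpg$chrom, cpg$pos, fs)
    hit <- which(!is.na(idx) & !is.na(eff_val[pmax(idx, 1)]))
    if (length(hit) == 0) next
    e <- eff_val[idx[hit]]
    target[hit] <- e
    overridden[hit] <- TRUE
    if (kind == "gamete_dmr") {
      # retained one-allele marks: alleles carry the parental states
      is_mid <- abs(e - p$mid) < 1e-9
      orig <- fs$origin[idx[hit]]
      tm <- e; tp <- e
      tm[is_mid] <- if_else(orig[is_mid] == "maternal",
                            p$meth_high, p$meth_low)
      tp[is_mid] <- if_else(orig[is_mid] == "maternal",
                            p$meth_low, p$meth_high)
      tgt_m[hit] <- tm; tgt_p[hit] <- tp
    } else {
      tgt_m[hit] <- e; tgt_p[hit] <- e
    }
  }
  # background compensation, per chromosome: the non-overridden target is
  # raised (or lowered) so each chromosome's mean target equals
  # global_meth_mean; the genome-wide mean then matches it too
  for (chr in unique(cpg$chrom)) {
    on_chr <- cpg$chrom == chr
    ov <- overridden & on_chr
    bg <- !overridden & on_chr
    if (!any(bg) || !any(ov)) next
    b <- (sample$global_meth_mean * sum(on_chr) - sum(target[ov])) /
      sum(bg)
    b <- min(max(b, 0), 1)
    target[bg] <- b
    tgt_m[bg] <- b
    tgt_p[bg] <- b
  }

  # inactive X: paternal allele hypomethylated in females, except
  # escapees; gametes are exempt (germline X is not in the somatic
  # inactive state)
  if (sex == "female" && !identical(sample$role, "gamete")) {
    xi <- filter(truth$features, .data$kind == "xi_block")
    if (nrow(xi) > 0) {
      in_xi <- !is.na(interval_index(cpg$chrom, cpg$pos, xi))
      esc <- filter(truth$features, .data$kind == "escapee")
      in_esc <- if (nrow(esc) > 0) {
        !is.na(interval_index(cpg$chrom, cpg$pos, esc))
      } else rep(FALSE, n)
      tgt_p[in_xi & !in_esc] <- p$xi_level
    }
  }

  cov <- rpois(n, sample$coverage_mean)
  on_x <- cpg$chrom == "chrX"
  cov_m <- rbinom(n, cov, 0.5)
  if (sex == "male") cov_m[on_x] <- cov[on_x]  # single maternal X
  cov_p <- cov - cov_m

  theta <- sample$beta_dispersion
  eps <- sample$conversion_error
  pm <- rbeta_disp(n, tgt_m, theta); pm <- pm + (1 - pm) * eps
  pp <- rbeta_disp(n, tgt_p, theta); pp <- pp + (1 - pp) * eps
  meth_m <- rbinom(n, cov_m, pm)
  meth_p <- rbinom(n, cov_p, pp)
  meth <- meth_m + meth_p
  unmeth <- cov - meth

  # strand split of the combined counts
  plus_meth <- rbinom(n, meth, 0.5)
  plus_unmeth <- rbinom(n, unmeth, 0.5)
  calls <- bind_rows(
    tibble(chrom = cpg$chrom, pos = cpg$pos, strand = "+",
           n_meth = plus_meth, n_unmeth = plus_unmeth),
    tibble(chrom = cpg$chrom, pos = cpg$pos + 1L, strand = "-",
           n_meth = meth - plus_meth, n_unmeth = unmeth - plus_unmeth)
  ) %>%
    mutate(context = "CpG", trinucleotide = "CGN") %>%
    arrange(.data$chrom, .data$pos, .data$strand)

  allele_tbl <- function(cv, mt) {
    keep <- cv > 0
    out <- tibble(chrom = cpg$chrom[keep], pos = cpg$pos[keep],
                  strand = "+", n_meth = mt[keep],
                  n_unmeth = cv[keep] - mt[keep], context = "CpG")
    set_destranded(out)
  }
  pat <- allele_tbl(cov_p, meth_p)
  if (sex == "male") pat <- set_destranded(filter(pat, .data$chrom != "chrX"))
  structure(list(calls = calls,
                 maternal = allele_tbl(cov_m, meth_m),
                 paternal = pat,
                 sample = sample),
            class = "sim_sample")
}

#' Simulate X and pseudo-Y read counts for embryo sexing
#'
#' Males draw pseudo-Y reads at the full rate, females at a small
#' mismapping rate, and sex-mixed pools at half the male rate; female X
#' counts are doubled (two copies).
#'
#' @param truth A [plant_features()] truth ledger.
#' @param sample Sample name (must be in the truth ledger) .
#' @param lambda_x,lambda_y Poisson means for X / pseudo-Y reads in a male
#'   library.
#' @param noise_frac Female pseudo-Y rate as a fraction of `lambda_y`
#'   (read mismapping).
#' @param total_reads Library size.
#' @param seed Integer RNG seed.
#' @return One-row tibble: `sample`, `sex_true`, `x_reads`, `y_reads`,
#'   `total_reads`.
#' @export
simulate_xy_counts <- function(truth, sample, lambda_x = 10000,
                               lambda_y = 2000, noise_frac = 0.01,
                               total_reads = 1e6, seed = 1729) {
  if (!sample %in% names(truth$sample_sexes)) {
    abort(paste0("sample not in truth ledger: ", sample))
  }
  withr::local_seed(seed)
  sex <- unname(truth$sample_sexes[[sample]])
  lam <- switch(sex,
    male = c(x = lambda_x, y = lambda_y),
    female = c(x = 2 * lambda_x, y = noise_frac * lambda_y),
    pooled = c(x = 1.5 * lambda_x, y = 0.5 * lambda_y),
    abort(paste0("unknown sex: ", sex))
  )
  tibble(sample = sample, sex_true = sex,
         x_reads = rpois(1, lam[["x"]]),
         y_reads = if (lam[["y"]] == 0) 0L else rpois(1, lam[["y"]]),
         total_reads = as.integer(total_reads))
}

#' Simulate a gene-expression table
#'
#' Log-normal TPMs with an optional multiplicative shift applied to
#' X-linked genes (emulating X-to-autosome expression imbalance).
#'
#' @param genes Gene tibble (`chrom`, `name`).
#' @param x_shift Multiplier applied to `chrX` gene TPMs.
#' @param meanlog,sdlog Log-normal parameters.
#' @param seed Integer RNG seed.
#' @return Tibble `gene`, `chrom`, `tpm`.
#' @export
simulate_expression <- function(genes, x_shift = 1, meanlog = 2,
                                sdlog = 1, seed = 1729) {
  withr::local_seed(seed)
  tpm <- rlnorm(nrow(genes), meanlog, sdlog)
  tpm[genes$chrom == "chrX"] <- tpm[genes$chrom == "chrX"] * x_shift
  tibble(gene = genes$name, chrom = genes$chrom, tpm = tpm)
}

#' Simulate a full developmental-methylome study
#'
#' Convenience wrapper: genome, truth ledger, one call set per sample, and
#' X/pseudo-Y sexing counts, all driven by a single seed. Optionally writes
#' every artefact to `outdir` (cytosine reports, allele coverage files,
#' annotation BEDs, truth TSV) with deterministic bytes.
#'
#' @param spec A [genome_spec()].
#' @param samples Sample-spec tibble.
#' @param seed Integer master seed; per-sample seeds are derived from it.
#' @param outdir Optional output directory.
#' @param ... Passed to [plant_features()].
#' @return A list of class `sim_study`: `genome`, `truth`, `samples`
#'   (named list of `sim_sample`), `xy` (sexing counts tibble), `specs`.
#' @export
simulate_study <- function(spec = genome_spec(),
                           samples = default_sample_specs(),
                           seed = 1729, outdir = NULL, ...) {
  spec$seed <- seed
  genome <- simulate_genome(spec)
  truth <- plant_features(genome, samples = samples, seed = seed + 1, ...)
  sims <- purrr::map(seq_len(nrow(samples)), function(i) {
    simulate_sample(genome, truth, samples[i, ], seed = seed + 100 + i)
  })
  names(sims) <- samples$name
  xy <- purrr::map2(samples$name, seq_len(nrow(samples)), function(s, i) {
    simulate_xy_counts(truth, s, seed = seed + 500 + i)
  }) %>% bind_rows()
  study <- structure(list(genome = genome, truth = truth, samples = sims,
                          xy = xy, specs = samples, seed = seed),
                     class = "sim_study")
  if (!is.null(outdir)) write_study(study, outdir)
  study
}

#' Write a simulated study to disk
#'
#' @param study A [simulate_study()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(study$samples)) {
    s <- study$samples[[nm]]
    write_calls(s$calls, file.path(outdir, paste0(nm, ".CpG_report.txt")),
                "cytosine_report")
    write_calls(s$maternal, file.path(outdir, paste0(nm, ".maternal.cov")),
                "coverage")
    write_calls(s$paternal, file.path(outdir, paste0(nm, ".paternal.cov")),
                "coverage")
  }
  write_bed(study$genome$genes, file.path(outdir, "genes.bed"))
  write_bed(study$genome$promoters, file.path(outdir, "promoters.bed"))
  write_bed(study$genome$cgi, file.path(outdir, "cgi.bed"))
  write_bed(study$genome$pseudo_y, file.path(outdir, "pseudo_y.bed"))
  readr::write_tsv(study$xy, file.path(outdir, "xy_counts.tsv"),
                   progress = FALSE)
  write_truth(study$truth, file.path(outdir, "truth.tsv"))
  invisible(outdir)
}

#' Write / read the planted-feature truth ledger
#'
#' TSV with a versioned header comment; the `effect` list-column is
#' serialized as `sample=value` pairs.
#'
#' @param truth A `sim_truth`.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  eff <- purrr::map_chr(truth$features$effect, function(e) {
    if (length(e) == 0) return(".")
    paste0(names(e), "=", signif(e, 8), collapse = ";")
  })
  tab <- truth$features %>%
    select(-"effect") %>%
    mutate(effect = eff)
  hdr <- c("# methylfate_truth v1",
           paste0("# seed=", truth$params$seed),
           paste0("# sexes=", paste0(names(truth$sample_sexes), "=",
                                     truth$sample_sexes, collapse = ";")))
  writeLines(hdr, path)
  suppressWarnings(
    readr::write_tsv(tab, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  )
  invisible(path)
}
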