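#' Tidy and glance methods
#'
#' broom-style accessors for the package's result objects: `tidy()`
#' returns the per-unit table as a plain tibble, `glance()` a one-row
#' summary.
#'
#' @param x A `tile_test`, `site_diff`, `meth_segmentation`,
#'   `fate_report` or `segment_comparison` object.
#' @param ... Unused.
#' @return A tibble.
#' @name methylfate-tidiers
NULL

#' @rdname methylfate-tidiers
#' @export
tidy.tile_test <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "tile_test")
  as_tibble(out)
}

#' @rdname methylfate-tidiers
#' @export
glance.tile_test <- function(x, ...) {
  tibble(n_tiles = nrow(x),
         n_q_lt_0.01 = sum(x$q < 0.01, na.rm = TRUE),
         method = attr(x, "method") %||% NA_character_,
         fdr_method = attr(x, "fdr_method") %||% NA_character_)
}

#' @rdname methylfate-tidiers
#' @export
tidy.site_diff <- function(x, ...) as_tibble(x$sites)

#' @rdname methylfate-tidiers
#' @export
glance.site_diff <- function(x, ...) {
  tibble(n_sites = nrow(x$sites), fraction_stable = x$fraction_stable,
         alpha = x$alpha, min_cov = x$min_cov)
}

#' @rdname methylfate-tidiers
#' @export
tidy.meth_segmentation <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "meth_segmentation")
  as_tibble(out)
}

#' @rdname methylfate-tidiers
#' @export
glance.meth_segmentation <- function(x, ...) {
  tibble(n_segments = nrow(x),
         n_classes = attr(x, "n_classes") %||% NA_integer_,
         median_n_cpg = median(x$n_cpg),
         n_pmd = if ("is_pmd" %in% names(x)) sum(x$is_pmd) else
           NA_integer_)
}

#' @rdname methylfate-tidiers
#' @export
tidy.fate_report <- function(x, ...) as_tibble(x$counts)

#' @rdname methylfate-tidiers
#' @export
glance.fate_report <- function(x, ...) {
  tibble(n_dmrs = x$n,
         prop_maternal_lifelong = x$prop_maternal_lifelong)
}

#' @rdname methylfate-tidiers
#' @export
tidy.segment_comparison <- function(x, ...) as_tibble(x$segments)

#' @rdname methylfate-tidiers
#' @export
glance.segment_comparison <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "sample",
                     values_from = c("n_segments", "pmd_fraction"))
}
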