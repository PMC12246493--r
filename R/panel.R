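#' Phased genotype panel
#'
#' The panel is the container shared by the screening, LD and phylogeny
#' stages: a phased haplotype matrix (one row per haplotype, two per sample)
#' over polarized bi-allelic sites, with per-sample group labels. Codes are
#' 0 = ancestral, 1 = derived, `NA` = missing call.
#'
#' @param sites Tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`,
#'   `ancestral`, `derived`, `consequence`, `gene` (one row per site,
#'   positions ascending).
#' @param haplotypes Integer matrix, `2 * nrow(samples)` rows by
#'   `nrow(sites)` columns, values in `{0, 1, NA}`. Rows are ordered two per
#'   sample, in sample order.
#' @param samples Tibble with columns `sample_id`, `group` (one of
#'   `"AFRICAN"`, `"NEANDERTAL"`, `"DENISOVAN"`, `"MODERN"`) and
#'   `population` (non-`NA` for modern samples).
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(sites, haplotypes, samples) {
  stopifnot(is.data.frame(sites), is.matrix(haplotypes), is.data.frame(samples))
  need <- c("chrom", "pos", "id", "ref", "alt", "ancestral", "derived",
            "consequence", "gene")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    stop("samples needs columns sample_id, group", call. = FALSE)
  }
  if (!all(samples$group %in% c("AFRICAN", "NEANDERTAL", "DENISOVAN", "MODERN"))) {
    stop("unknown group label", call. = FALSE)
  }
  if (nrow(haplotypes) != 2 * nrow(samples)) {
    stop("haplotype matrix must have 2 rows per sample", call. = FALSE)
  }
  if (ncol(haplotypes) != nrow(sites)) {
    stop("haplotype matrix columns must match sites", call. = FALSE)
  }
  if (!all(haplotypes %in% c(0L, 1L, NA))) {
    stop("haplotype codes must be 0, 1 or NA", call. = FALSE)
  }
  if (is.unsorted(sites$pos)) stop("site positions must be ascending", call. = FALSE)
  if (anyDuplicated(sites$id)) stop("site ids must be unique", call. = FALSE)
  if (!("population" %in% names(samples))) samples$population <- NA_character_
  rownames(haplotypes) <- paste0(rep(samples$sample_id, each = 2), "_h", 1:2)
  structure(
    list(sites = tibble::as_tibble(sites),
         haplotypes = haplotypes,
         samples = tibble::as_tibble(samples)),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  grp <- table(x$samples$group)
  cat(sprintf("<genotype_panel> %d sites x %d samples (%d haplotypes)\n",
              nrow(x$sites), nrow(x$samples), nrow(x$haplotypes)))
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Extract haplotype rows for selected sample groups
#'
#' @param panel A [genotype_panel].
#' @param groups Character vector of group labels; default all.
#' @param populations Optional modern population filter.
#' @return Integer matrix of haplotypes (rows) by sites (columns).
#' @export
panel_haplotypes <- function(panel, groups = NULL, populations = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  keep <- rep(TRUE, nrow(panel$samples))
  if (!is.null(groups)) keep <- keep & panel$samples$group %in% groups
  if (!is.null(populations)) {
    keep <- keep & !is.na(panel$samples$population) &
      panel$samples$population %in% populations
  }
  rows <- rep(keep, each = 2)
  panel$haplotypes[rows, , drop = FALSE]
}

#' Diploid genotypes (derived-allele dosage) for selected samples
#'
#' @inheritParams panel_haplotypes
#' @return Integer matrix samples x sites, values 0/1/2 or `NA` when either
#'   haplotype is missing.
#' @export
panel_genotypes <- function(panel, groups = NULL, populations = NULL) {
  h <- panel_haplotypes(panel, groups, populations)
  n <- nrow(h) / 2
  g <- h[seq(1, 2 * n, by = 2), , drop = FALSE] +
    h[seq(2, 2 * n, by = 2), , drop = FALSE]
  rownames(g) <- sub("_h1$", "", rownames(h)[seq(1, 2 * n, by = 2)])
  g
}
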