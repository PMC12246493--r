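#' Polarize raw variant records against ancestral alleles
#'
#' Assigns the derived allele as the non-ancestral allele among ref/alt.
#' Records whose ancestral allele is unknown or matches neither observed
#' allele are flagged unpolarizable and excluded from screening downstream.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt` and `ancestral` (`NA` = unknown ancestral state).
#' @return The input as a tibble with columns `derived` and `unpolarizable`
#'   appended.
#' @examples
#' polarize_variants(tibble::tibble(
#'   chrom = "chr1", pos = c(100, 200, 300), id = c("v1", "v2", "v3"),
#'   ref = "A", alt = "T", ancestral = c("A", "T", "C")))
#' @export
polarize_variants <- function(variants) {
  stopifnot(all(c("chrom", "pos", "id", "ref", "alt", "ancestral") %in%
                  names(variants)))
  if (any(variants$ref == variants$alt, na.rm = TRUE)) {
    stop("malformed record: ref equals alt", call. = FALSE)
  }
  variants |>
    tibble::as_tibble() |>
    dplyr::mutate(
      unpolarizable = is.na(.data$ancestral) |
        (.data$ancestral != .data$ref & .data$ancestral != .data$alt),
      derived = dplyr::case_when(
        .data$unpolarizable ~ NA_character_,
        .data$ancestral == .data$ref ~ .data$alt,
        TRUE ~ .data$ref
      )
    )
}

#' Screening filter configuration
#'
#' The archaic-specific screen retains variants whose ancestral allele is
#' fixed among African haplotypes, whose derived allele is homozygous in all
#' (non-missing) Neandertal genomes, optionally absent from the Denisovan,
#' with a consequence in the whitelist and gene in the target set. The
#' Denisovan rule defaults off for the basic screen and should be enabled
#' for archaic-specificity ranking sets.
#'
#' @param african_fixed_ancestral Require zero derived alleles over all
#'   African haplotypes.
#' @param neandertal_hom_derived Require every Neandertal sample with a
#'   non-missing call to be homozygous derived.
#' @param denisovan_absent Require no derived allele in the Denisovan.
#' @param consequences Consequence whitelist (default `"missense"`).
#' @param genes Gene-symbol set; `NULL` disables the gene filter.
#' @param min_neandertal_obs Minimum Neandertal samples with non-missing
#'   calls (default 3).
#' @return A list of class `screen_filters`.
#' @export
screen_filters <- function(african_fixed_ancestral = TRUE,
                           neandertal_hom_derived = TRUE,
                           denisovan_absent = FALSE,
                           consequences = "missense",
                           genes = NULL,
                           min_neandertal_obs = 3) {
  stopifnot(is.logical(african_fixed_ancestral),
            is.logical(neandertal_hom_derived),
            is.logical(denisovan_absent),
            min_neandertal_obs >= 0)
  structure(list(african_fixed_ancestral = african_fixed_ancestral,
                 neandertal_hom_derived = neandertal_hom_derived,
                 denisovan_absent = denisovan_absent,
                 consequences = consequences, genes = genes,
                 min_neandertal_obs = min_neandertal_obs),
            class = "screen_filters")
}

#' Screen a panel for archaic-specific derived variants
#'
#' Applies every enabled filter in [screen_filters()] to each site of the
#' panel and returns the qualifying sites in input order.
#'
#' @param panel A [genotype_panel].
#' @param filters A [screen_filters] configuration.
#' @param variant_ids Optional subset of site ids to screen (default all
#'   sites); an id absent from the panel is an error.
#' @return Tibble of qualifying sites (same columns as `panel$sites`).
#' @export
screen_variants <- function(panel, filters = screen_filters(),
                            variant_ids = NULL) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(filters, "screen_filters"))
  if (!any(panel$samples$group == "AFRICAN") ||
      !any(panel$samples$group == "NEANDERTAL")) {
    stop("panel needs at least one African and one Neandertal sample",
         call. = FALSE)
  }
  sites <- panel$sites
  if (!is.null(variant_ids)) {
    missing_ids <- setdiff(variant_ids, sites$id)
    if (length(missing_ids)) {
      stop("variant(s) absent from panel: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
  }
  afr <- panel_haplotypes(panel, "AFRICAN")
  nea <- panel_genotypes(panel, "NEANDERTAL")
  den <- if (any(panel$samples$group == "DENISOVAN")) {
    panel_genotypes(panel, "DENISOVAN")
  } else NULL

  pass <- rep(TRUE, nrow(sites))
  if (!is.null(variant_ids)) pass <- sites$id %in% variant_ids
  if (filters$african_fixed_ancestral) {
    pass <- pass & colSums(afr == 1, na.rm = TRUE) == 0
  }
  if (filters$neandertal_hom_derived) {
    n_obs <- colSums(!is.na(nea))
    all_hom <- colSums(nea == 2, na.rm = TRUE) == n_obs
    pass <- pass & n_obs >= filters$min_neandertal_obs & all_hom
  }
  if (filters$denisovan_absent && !is.null(den)) {
    pass <- pass & colSums(den >= 1, na.rm = TRUE) == 0
  }
  if (!is.null(filters$consequences)) {
    pass <- pass & sites$consequence %in% filters$consequences
  }
  if (!is.null(filters$genes) && length(filters$genes)) {
    pass <- pass & !is.na(sites$gene) & sites$gene %in% filters$genes
  }
  sites[pass, , drop = FALSE]
}

#' Rank screened candidates by an impact-score table
#'
#' Orders candidates by descending score. Candidates without a score are
#' placed last and flagged; score ties keep input order and are reported as
#' tied.
#'
#' @param candidates Tibble with an `id` column (e.g. output of
#'   [screen_variants()]).
#' @param scores Named numeric vector or two-column data frame (`id`,
#'   `score`) mapping variant ids to impact scores (e.g. REVEL).
#' @return The candidates with `score`, `rank`, `tied` and `unscored`
#'   columns, ordered by descending score.
#' @export
rank_candidates <- function(candidates, scores) {
  stopifnot("id" %in% names(candidates))
  if (is.data.frame(scores)) {
    stopifnot(all(c("id", "score") %in% names(scores)))
    scores <- stats::setNames(scores$score, scores$id)
  }
  out <- candidates |>
    tibble::as_tibble() |>
    dplyr::mutate(
      score = unname(scores[.data$id]),
      unscored = is.na(.data$score),
      .input_order = dplyr::row_number()
    ) |>
    dplyr::arrange(.data$unscored, dplyr::desc(.data$score), .data$.input_order)
  if (nrow(out) == 0) {
    return(dplyr::mutate(dplyr::select(out, -".input_order"),
                         rank = integer(0), tied = logical(0)))
  }
  out |>
    dplyr::mutate(
      rank = dplyr::row_number(),
      tied = !.data$unscored &
        (duplicated(.data$score) | duplicated(.data$score, fromLast = TRUE))
    ) |>
    dplyr::select(-".input_order")
}
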