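#' Write a genotype panel as VCF plus a sample-group TSV
#'
#' Emits a minimal VCFv4.2 with phased `GT` calls (`.` for missing alleles)
#' and an `AA` INFO field carrying the ancestral allele, plus a side TSV
#' mapping `sample_id` to `group` and `population`. Consequence and gene
#' annotations go into the INFO field as `CSQ` and `GENE`.
#'
#' @param panel A [genotype_panel].
#' @param vcf_path,groups_path Output paths.
#' @return Invisibly, the VCF path.
#' @export
write_panel_vcf <- function(panel, vcf_path, groups_path) {
  stopifnot(inherits(panel, "genotype_panel"))
  s <- panel$sites
  samples <- panel$samples$sample_id
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  # translate ancestral/derived coding back to ref/alt allele indices
  alt_is_derived <- s$derived == s$alt
  gt_rows <- vapply(seq_len(nrow(s)), function(j) {
    h <- panel$haplotypes[, j]
    allele <- ifelse(is.na(h), ".",
                     ifelse(h == 1L,
                            ifelse(alt_is_derived[j], "1", "0"),
                            ifelse(alt_is_derived[j], "0", "1")))
    paste(allele[seq(1, length(h), 2)], allele[seq(2, length(h), 2)],
          sep = "|", collapse = "\t")
  }, character(1))
  info <- sprintf("AA=%s;CSQ=%s;GENE=%s", s$ancestral, s$consequence,
                  ifelse(is.na(s$gene), ".", s$gene))
  body <- paste(s$chrom, s$pos, s$id, s$ref, s$alt, ".", "PASS", info, "GT",
                gt_rows, sep = "\t")
  writeLines(c(header, body), vcf_path)
  utils::write.table(panel$samples, groups_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(vcf_path)
}

#' Write / read a recombination map as 3-column TSV
#'
#' Columns: `chrom`, `pos`, `cM` (cumulative centimorgans).
#'
#' @param map Map tibble as from [sim_recomb_map()].
#' @param path File path.
#' @return `write_recomb_map()` the path invisibly; [read_recomb_map()] the
#'   validated tibble.
#' @export
write_recomb_map <- function(map, path) {
  stopifnot(all(c("chrom", "pos", "cM") %in% names(map)))
  utils::write.table(map[, c("chrom", "pos", "cM")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recomb_map
#' @export
read_recomb_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("chrom", "pos", "cM"), names(df))
  if (length(miss)) stop("map TSV lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.unsorted(df$pos, strictly = TRUE)) {
    stop("map positions must be strictly ascending", call. = FALSE)
  }
  if (is.unsorted(df$cM)) stop("cumulative cM must be non-decreasing",
                               call. = FALSE)
  tibble::as_tibble(df)
}

#' Write / read a kinetic plate as long-format CSV
#'
#' Columns: `well`, `enzyme`, `substrate_mM`, `replicate`, `time_s`,
#' `A340`.
#'
#' @param plate Long plate tibble as from [sim_kinetic_plate()].
#' @param path File path.
#' @return `write_plate_csv()` the path invisibly; [read_plate_csv()] the
#'   validated tibble.
#' @export
write_plate_csv <- function(plate, path) {
  need <- c("well", "enzyme", "substrate_mM", "replicate", "time_s", "A340")
  stopifnot(all(need %in% names(plate)))
  utils::write.csv(plate[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "enzyme", "substrate_mM", "replicate", "time_s", "A340")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plate CSV lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tibble::as_tibble(df)
}

#' Write / read athlete genotype-count studies as TSV
#'
#' Columns: `study`, `discipline`, `category`, `a_CC`, `a_CT`, `a_TT`,
#' `c_CC`, `c_CT`, `c_TT`.
#'
#' @param studies Study tibble as from [sim_athlete_studies()].
#' @param path File path.
#' @return `write_studies_tsv()` the path invisibly; [read_studies_tsv()]
#'   the validated tibble.
#' @export
write_studies_tsv <- function(studies, path) {
  need <- c("study", "discipline", "category", "a_CC", "a_CT", "a_TT",
            "c_CC", "c_CT", "c_TT")
  stopifnot(all(need %in% names(studies)))
  utils::write.table(studies[, need], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_studies_tsv
#' @export
read_studies_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("study", "discipline", "category", "a_CC", "a_CT", "a_TT",
            "c_CC", "c_CT", "c_TT")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("studies TSV lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tibble::as_tibble(df)
}
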