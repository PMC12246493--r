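#' Genomic interval
#'
#' A one-row tibble describing a 1-based genomic interval. The length
#' convention used throughout the package is `length_bp = end - start`,
#' matching how haplotype extents are conventionally reported from their
#' printed endpoint coordinates.
#'
#' @param chrom Chromosome name, e.g. `"chr1"`.
#' @param start,end 1-based positions with `start <= end`.
#' @return A tibble with columns `chrom`, `start`, `end`, `length_bp`.
#' @examples
#' genomic_interval("chr1", 114371932, 114812153)
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start < 1 || end < start) {
    stop("invalid interval: need 1 <= start <= end", call. = FALSE)
  }
  tibble::tibble(chrom = chrom, start = start, end = end,
                 length_bp = end - start)
}

#' Pairwise linkage disequilibrium r-squared between two haplotype vectors
#'
#' Computes the haplotype (phased) r^2 statistic
#' \deqn{r^2 = D^2 / (p_A(1-p_A)\,p_B(1-p_B)), \quad D = f_{AB} - p_A p_B}
#' on two equal-length 0/1 vectors, one entry per haplotype. Archaic samples
#' should never enter this computation; it is defined on modern phased
#' haplotypes only.
#'
#' @param hap_a,hap_b Integer/numeric 0/1 vectors of equal length >= 2,
#'   no missing values (drop missing haplotypes pairwise upstream).
#' @return A single value in \[0, 1\], or `NA_real_` with a warning when
#'   either site is monomorphic (r^2 undefined).
#' @examples
#' ld_r2(c(1, 1, 0, 0, 0), c(1, 1, 0, 0, 1))
#' @export
ld_r2 <- function(hap_a, hap_b) {
  if (length(hap_a) != length(hap_b)) {
    stop("haplotype vectors must have equal length", call. = FALSE)
  }
  if (length(hap_a) < 2) stop("need at least 2 haplotypes", call. = FALSE)
  if (anyNA(hap_a) || anyNA(hap_b)) {
    stop("missing values not allowed; drop missing haplotypes first",
         call. = FALSE)
  }
  if (!all(hap_a %in% c(0, 1)) || !all(hap_b %in% c(0, 1))) {
    stop("haplotype vectors must be coded 0/1", call. = FALSE)
  }
  p_a <- mean(hap_a)
  p_b <- mean(hap_b)
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    warning("monomorphic site: r^2 undefined, returning NA", call. = FALSE)
    return(NA_real_)
  }
  d <- mean(hap_a == 1 & hap_b == 1) - p_a * p_b
  d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
}

#' Delimit the haplotype around a focal variant by LD threshold
#'
#' Computes r^2 between the focal site and every other site over the panel's
#' modern haplotypes, and returns the genomic interval spanning the sites
#' that satisfy the threshold (the focal site is always included). With
#' `threshold = 1` and mode `"ge"` this delimits the core haplotype in
#' perfect LD with the focal allele; with `threshold = 0.8` the extended
#' haplotype.
#'
#' @param panel A [genotype_panel] object.
#' @param focal_id Variant id of the focal site (e.g. an rsID).
#' @param threshold r^2 threshold in \[0, 1\].
#' @param mode `"ge"` (default) keeps sites with `r^2 >= threshold` (up to a
#'   1e-9 floating tolerance, so `ge 1.0` captures exact perfect proxies);
#'   `"gt"` keeps strict exceedance.
#' @return An object of class `haplotype_extent`: a list with `interval`
#'   (a [genomic_interval] tibble) and `r2` (per-site tibble: `pos`, `id`,
#'   `r2`, `included`). `tidy()` returns the per-site table.
#' @export
haplotype_extent <- function(panel, focal_id, threshold = 0.8,
                             mode = c("ge", "gt")) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "genotype_panel"))
  sites <- panel$sites
  k <- match(focal_id, sites$id)
  if (is.na(k)) stop("focal variant '", focal_id, "' not in panel", call. = FALSE)
  modern <- panel_haplotypes(panel, groups = "MODERN")
  focal_vec <- modern[, k]
  if (length(unique(focal_vec[!is.na(focal_vec)])) < 2) {
    stop("focal variant is monomorphic among modern haplotypes", call. = FALSE)
  }
  r2 <- vapply(seq_len(ncol(modern)), function(j) {
    ok <- !is.na(modern[, k]) & !is.na(modern[, j])
    if (sum(ok) < 2) return(NA_real_)
    suppressWarnings(ld_r2(modern[ok, k], modern[ok, j]))
  }, numeric(1))
  tol <- 1e-9
  included <- if (mode == "ge") !is.na(r2) & r2 >= threshold - tol
              else !is.na(r2) & r2 > threshold + tol
  included[k] <- TRUE
  span <- range(sites$pos[included])
  out <- list(
    interval = genomic_interval(sites$chrom[k], span[1], span[2]),
    r2 = tibble::tibble(pos = sites$pos, id = sites$id, r2 = r2,
                        included = included),
    focal_id = focal_id, threshold = threshold, mode = mode
  )
  class(out) <- "haplotype_extent"
  out
}

#' @export
print.haplotype_extent <- function(x, ...) {
  iv <- x$interval
  cat(sprintf("<haplotype_extent> %s:%s-%s (%s bp), r^2 %s %s with %s; %d/%d sites\n",
              iv$chrom, format(iv$start, big.mark = ","),
              format(iv$end, big.mark = ","),
              format(iv$length_bp, big.mark = ","),
              if (x$mode == "ge") ">=" else ">", x$threshold,
              x$focal_id, sum(x$r2$included), nrow(x$r2)))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.haplotype_extent <- function(x, ...) x$r2

#' Genetic length of an interval on a recombination map
#'
#' Linearly interpolates the cumulative centimorgan coordinate at the
#' interval endpoints and returns the difference. Endpoints outside the map
#' range are an error: silent extrapolation would corrupt the downstream
#' survival test.
#'
#' @param interval A [genomic_interval] tibble (one row).
#' @param map A recombination map tibble with columns `pos` (strictly
#'   ascending) and `cM` (non-decreasing cumulative centimorgans), as
#'   produced by [sim_recomb_map()] or [read_recomb_map()].
#' @return Genetic length in centimorgans (>= 0).
#' @examples
#' map <- tibble::tibble(pos = c(114300000, 114900000), cM = c(0, 0.10))
#' genetic_length(genomic_interval("chr1", 114371932, 114812153), map)
#' @export
genetic_length <- function(interval, map) {
  stopifnot(is.data.frame(interval), nrow(interval) == 1,
            is.data.frame(map), all(c("pos", "cM") %in% names(map)))
  if (is.unsorted(map$pos, strictly = TRUE)) {
    stop("map positions must be strictly ascending", call. = FALSE)
  }
  if (is.unsorted(map$cM)) {
    stop("cumulative cM must be non-decreasing", call. = FALSE)
  }
  if (interval$start < min(map$pos) || interval$end > max(map$pos)) {
    stop("interval endpoint outside map range; no extrapolation", call. = FALSE)
  }
  cm <- stats::approx(map$pos, map$cM, xout = c(interval$start, interval$end),
                      method = "linear", ties = "ordered")$y
  cm[2] - cm[1]
}

#' Gamma survival test for incomplete lineage sorting
#'
#' Tests whether a haplotype shared between Neandertals and modern humans is
#' too long (in genetic map units) to be a remnant of the common ancestral
#' population rather than the product of admixture. Under incomplete lineage
#' sorting, recombination whittles a shared ancestral tract down over the
#' total branch length `T = 2 t_div - t_admix` generations separating the
#' two observations, so the expected shared-tract length is `L = 100/T` cM.
#' Conditioning on observing the tract on both branches, the tract length
#' follows a Gamma distribution with shape 2 and rate `1/L` per cM, and the
#' reported p is its upper-tail probability at the observed length, with
#' closed form `p = exp(-r m) (1 + r m)`.
#'
#' @param m_cM Observed genetic length of the shared haplotype, centimorgans.
#' @param t_div_gen Generations since the Neandertal/modern-human common
#'   ancestor (default 21,500).
#' @param t_admix_gen Generations since archaic admixture (default 2,000).
#' @return A one-row tibble: `m_cM`, `t_div_gen`, `t_admix_gen`,
#'   `T_total_gen`, `L_cM`, `rate_per_cM`, `shape`, `p`.
#' @examples
#' ils_test(0.063) # rate 410 per cM, p ~ 1.6e-10
#' @export
ils_test <- function(m_cM, t_div_gen = 21500, t_admix_gen = 2000) {
  stopifnot(length(m_cM) == 1, is.finite(m_cM))
  if (m_cM < 0) stop("m_cM must be >= 0", call. = FALSE)
  if (!(t_div_gen > t_admix_gen && t_admix_gen >= 0)) {
    stop("need t_div_gen > t_admix_gen >= 0", call. = FALSE)
  }
  T_total <- 2 * t_div_gen - t_admix_gen
  if (T_total <= 0) stop("non-positive total branch length", call. = FALSE)
  rate <- T_total / 100 # per cM
  p <- stats::pgamma(m_cM, shape = 2, rate = rate, lower.tail = FALSE)
  tibble::tibble(
    m_cM = m_cM, t_div_gen = t_div_gen, t_admix_gen = t_admix_gen,
    T_total_gen = T_total, L_cM = 100 / T_total, rate_per_cM = rate,
    shape = 2, p = p
  )
}

#' LD decay plot around a focal variant
#'
#' @param object A `haplotype_extent` object.
#' @param ... Unused.
#' @return A ggplot: per-site r^2 against position, the retained haplotype
#'   interval shaded.
#' @export
autoplot.haplotype_extent <- function(object, ...) {
  df <- object$r2[!is.na(object$r2$r2), ]
  iv <- object$interval
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$r2)) +
    ggplot2::annotate("rect", xmin = iv$start, xmax = iv$end,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$included)) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = sprintf("position (%s)", iv$chrom),
                  y = expression(r^2),
                  colour = "in haplotype") +
    ggplot2::theme_minimal()
}
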