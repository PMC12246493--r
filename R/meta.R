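#' Apply the study inclusion rules
#'
#' Retains studies with at least `min_athletes` athletes and a clear
#' endurance/power classification; every dropped study is logged with the
#' violated rule.
#'
#' @param studies Tibble with columns `study`, `category` and genotype
#'   counts `a_CC`, `a_CT`, `a_TT` (athletes); `n_athletes` is derived from
#'   the counts if absent.
#' @param min_athletes Minimum athlete count (default 20).
#' @return The input with logical `retained` and character
#'   `exclusion_reason` columns appended.
#' @export
filter_studies <- function(studies, min_athletes = 20) {
  stopifnot(all(c("study", "category") %in% names(studies)))
  out <- tibble::as_tibble(studies)
  if (!"n_athletes" %in% names(out)) {
    stopifnot(all(c("a_CC", "a_CT", "a_TT") %in% names(out)))
    out$n_athletes <- out$a_CC + out$a_CT + out$a_TT
  }
  out |>
    dplyr::mutate(
      exclusion_reason = dplyr::case_when(
        .data$n_athletes < min_athletes ~ sprintf("n<%d", min_athletes),
        !.data$category %in% c("endurance", "power") ~ "unclassified",
        TRUE ~ NA_character_
      ),
      retained = is.na(.data$exclusion_reason)
    )
}

#' Sainte-Lague (highest averages, odd divisors) integer apportionment
#'
#' Distributes `total` integer units across bins proportionally to
#' `weights` using the divisor sequence 1, 3, 5, ...: units are awarded one
#' at a time to the bin with the highest current average
#' `weight / (2 * allocated + 1)`. Ties are broken by the larger weight,
#' then by the lower bin index.
#'
#' @param total Non-negative integer to distribute.
#' @param weights Non-negative weights, at least one positive when
#'   `total > 0`.
#' @return Integer allocation vector summing to `total`.
#' @examples
#' sainte_lague_allocate(7, c(5, 3, 1)) # 4 2 1
#' @export
sainte_lague_allocate <- function(total, weights) {
  stopifnot(total >= 0, all(weights >= 0))
  total <- as.integer(total)
  alloc <- integer(length(weights))
  if (total == 0) return(alloc)
  if (all(weights == 0)) {
    stop("cannot allocate a positive total over all-zero weights",
         call. = FALSE)
  }
  for (i in seq_len(total)) {
    avg <- weights / (2 * alloc + 1)
    top <- which(avg == max(avg))
    if (length(top) > 1) top <- top[weights[top] == max(weights[top])]
    alloc[top[1]] <- alloc[top[1]] + 1L
  }
  alloc
}

#' Split pooled study controls across disciplines
#'
#' When one study contributes athletes to several disciplines but a single
#' pooled control group, reusing the controls in every discipline would
#' inflate the meta-analysis. Each control genotype class (CC, CT, TT) is
#' therefore apportioned independently across the disciplines with
#' [sainte_lague_allocate()], weighted by the study's athletes per
#' discipline, preserving integer counts and approximate allele
#' frequencies.
#'
#' @param controls Named vector or one-row data frame with `c_CC`, `c_CT`,
#'   `c_TT`: the pooled control genotype counts.
#' @param athletes_per_discipline Named numeric vector: athletes per
#'   discipline (the apportionment weights).
#' @return Tibble with one row per discipline: `discipline`, `c_CC`,
#'   `c_CT`, `c_TT`; each genotype column sums to the pooled count.
#' @export
split_controls <- function(controls, athletes_per_discipline) {
  if (is.data.frame(controls)) {
    controls <- c(c_CC = controls$c_CC[1], c_CT = controls$c_CT[1],
                  c_TT = controls$c_TT[1])
  }
  stopifnot(all(c("c_CC", "c_CT", "c_TT") %in% names(controls)),
            length(athletes_per_discipline) >= 1)
  if (all(athletes_per_discipline == 0)) {
    stop("zero athletes in all disciplines", call. = FALSE)
  }
  w <- as.numeric(athletes_per_discipline)
  tibble::tibble(
    discipline = names(athletes_per_discipline) %||%
      paste0("D", seq_along(w)),
    c_CC = sainte_lague_allocate(controls[["c_CC"]], w),
    c_CT = sainte_lague_allocate(controls[["c_CT"]], w),
    c_TT = sainte_lague_allocate(controls[["c_TT"]], w)
  )
}

#' Per-study odds ratio for athlete status
#'
#' Collapses the genotype counts to a 2x2 table under the chosen genetic
#' model (carrier: CT+TT vs CC; allele: T vs C allele counts) and computes
#' the log odds ratio with Woolf standard error `sqrt(sum(1/cell))`,
#' numerically identical to single-covariate logistic regression. When any
#' cell is zero the Haldane-Anscombe 0.5 correction is added to all four
#' cells and flagged.
#'
#' @param counts One-row data frame (or named vector) with `a_CC`, `a_CT`,
#'   `a_TT`, `c_CC`, `c_CT`, `c_TT`.
#' @param model `"carrier"` (default, dominant contrast) or `"allele"`.
#' @return One-row tibble: `logOR`, `std.error`, `OR`, `conf.low`,
#'   `conf.high`, `p`, `weight`, `zero_cell`.
#' @export
study_odds_ratio <- function(counts, model = c("carrier", "allele")) {
  model <- match.arg(model)
  g <- if (is.data.frame(counts)) as.list(counts[1, ]) else as.list(counts)
  need <- c("a_CC", "a_CT", "a_TT", "c_CC", "c_CT", "c_TT")
  stopifnot(all(need %in% names(g)))
  if (model == "carrier") {
    a <- g$a_CT + g$a_TT; b <- g$a_CC
    c_ <- g$c_CT + g$c_TT; d <- g$c_CC
  } else {
    a <- g$a_CT + 2 * g$a_TT; b <- 2 * g$a_CC + g$a_CT
    c_ <- g$c_CT + 2 * g$c_TT; d <- 2 * g$c_CC + g$c_CT
  }
  if (a + b == 0 || c_ + d == 0) {
    stop("empty margin: no athletes or no controls", call. = FALSE)
  }
  zero <- any(c(a, b, c_, d) == 0)
  if (zero) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  log_or <- log(a * d / (b * c_))
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  zmult <- 1.959964
  tibble::tibble(
    logOR = log_or, std.error = se, OR = exp(log_or),
    conf.low = exp(log_or - zmult * se),
    conf.high = exp(log_or + zmult * se),
    p = 2 * stats::pnorm(-abs(log_or / se)),
    weight = 1 / se^2, zero_cell = zero
  )
}

#' Fixed-effect inverse-variance pooling of study effects
#'
#' Pools log odds ratios assuming one common effect:
#' `pooled logOR = sum(w_i logOR_i) / sum(w_i)` with `w_i = 1/SE_i^2` and
#' `pooled SE = 1/sqrt(sum(w_i))`. Cochran's Q and I-squared are reported
#' as heterogeneity descriptions only; they play no role in the model.
#'
#' @param estimates Tibble with columns `logOR` and `std.error` (e.g. rows
#'   of [study_odds_ratio()] output), one per study stratum.
#' @param category Optional category label carried into the result.
#' @return An object of class `meta_result`; `tidy()` returns the per-study
#'   rows plus the pooled row, `glance()` the pooled summary.
#' @export
pool_fixed_effect <- function(estimates, category = NA_character_) {
  stopifnot(all(c("logOR", "std.error") %in% names(estimates)),
            nrow(estimates) >= 1)
  if (any(estimates$std.error <= 0)) stop("non-positive SE", call. = FALSE)
  w <- 1 / estimates$std.error^2
  pooled_log <- sum(w * estimates$logOR) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  q <- sum(w * (estimates$logOR - pooled_log)^2)
  k <- nrow(estimates)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) else 0
  zmult <- 1.959964
  pooled <- tibble::tibble(
    logOR = pooled_log, std.error = pooled_se, OR = exp(pooled_log),
    conf.low = exp(pooled_log - zmult * pooled_se),
    conf.high = exp(pooled_log + zmult * pooled_se),
    p = 2 * stats::pnorm(-abs(pooled_log / pooled_se)),
    Q = q, I2 = i2, n_strata = k
  )
  structure(list(category = category, pooled = pooled,
                 studies = tibble::as_tibble(estimates)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("<meta_result>%s pooled OR = %.3f (95%% CI %.3f-%.3f), p = %.3g; Q = %.2f, I2 = %.0f%% (%d strata)\n",
              if (is.na(x$category)) "" else paste0(" [", x$category, "]"),
              p$OR, p$conf.low, p$conf.high, p$p, p$Q, 100 * p$I2,
              p$n_strata))
  invisible(x)
}

#' @export
tidy.meta_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$studies, pooled = FALSE),
    dplyr::mutate(x$pooled[, intersect(names(x$pooled), names(x$studies))],
                  study = "pooled", pooled = TRUE)
  )
}

#' @export
glance.meta_result <- function(x, ...) {
  dplyr::mutate(x$pooled, category = x$category, .before = 1)
}

#' Forest plot of a meta-analysis result
#'
#' @param object A `meta_result`.
#' @param ... Unused.
#' @return A ggplot forest plot: per-study odds ratios with 95% CIs, point
#'   size proportional to inverse-variance weight, pooled estimate at the
#'   bottom.
#' @export
autoplot.meta_result <- function(object, ...) {
  df <- tidy.meta_result(object)
  if (!"study" %in% names(df)) df$study <- paste0("stratum ", seq_len(nrow(df)))
  df$study[df$pooled] <- "Pooled"
  df$study <- factor(df$study, levels = rev(unique(df$study)))
  if (!"weight" %in% names(df)) df$weight <- 1 / df$std.error^2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$OR, y = .data$study)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight,
                                     shape = .data$pooled)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18),
                                guide = "none") +
    ggplot2::scale_size_area(guide = "none") +
    ggplot2::labs(x = "odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Run the athlete-status meta-analysis pipeline
#'
#' Applies the inclusion rules, splits pooled controls of multi-discipline
#' studies via Sainte-Lague apportionment, computes one odds ratio per
#' study-discipline stratum, and pools strata within each sport category
#' with a fixed-effect model. A study appearing in several rows is assumed
#' to contribute one pooled control group (identical control counts on each
#' row).
#'
#' @param studies Tibble with one row per study-discipline: `study`,
#'   `discipline`, `category`, `a_CC`, `a_CT`, `a_TT`, `c_CC`, `c_CT`,
#'   `c_TT`.
#' @param model Genetic model passed to [study_odds_ratio()].
#' @param min_athletes Inclusion threshold (default 20; applied per study
#'   over all its disciplines).
#' @param by_study If `TRUE`, aggregate a multi-discipline study's strata
#'   into one per-study estimate (fixed-effect within study) before pooling
#'   across studies; default pools per discipline-study stratum.
#' @return Named list of `meta_result`, one per category present; empty
#'   categories give a warning and are omitted.
#' @export
run_meta <- function(studies, model = c("carrier", "allele"),
                     min_athletes = 20, by_study = FALSE) {
  model <- match.arg(model)
  need <- c("study", "discipline", "category", "a_CC", "a_CT", "a_TT",
            "c_CC", "c_CT", "c_TT")
  miss <- setdiff(need, names(studies))
  if (length(miss)) stop("studies table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  per_study <- studies |>
    dplyr::group_by(.data$study) |>
    dplyr::summarise(category = .data$category[1],
                     n_athletes = sum(.data$a_CC + .data$a_CT + .data$a_TT),
                     .groups = "drop")
  flt <- filter_studies(per_study, min_athletes = min_athletes)
  kept <- flt$study[flt$retained]
  rows <- studies |> dplyr::filter(.data$study %in% kept)

  strata <- rows |>
    dplyr::group_by(.data$study) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) > 1) {
        ctrl <- unique(d[, c("c_CC", "c_CT", "c_TT")])
        if (nrow(ctrl) != 1) {
          stop("multi-discipline study '", key$study,
               "' has inconsistent pooled control counts", call. = FALSE)
        }
        ath <- stats::setNames(d$a_CC + d$a_CT + d$a_TT, d$discipline)
        splt <- split_controls(ctrl, ath)
        d <- d |>
          dplyr::select(-"c_CC", -"c_CT", -"c_TT") |>
          dplyr::left_join(splt, by = "discipline")
      }
      d
    }) |>
    dplyr::ungroup()

  est <- dplyr::bind_rows(lapply(seq_len(nrow(strata)), function(i) {
    row <- strata[i, ]
    dplyr::bind_cols(row[, c("study", "discipline", "category")],
                     study_odds_ratio(row, model = model))
  }))

  if (by_study) {
    est <- est |>
      dplyr::group_by(.data$study, .data$category) |>
      dplyr::group_modify(function(d, key) {
        if (nrow(d) == 1) return(dplyr::select(d, -dplyr::any_of("study")))
        pooled <- pool_fixed_effect(d)$pooled
        tibble::tibble(discipline = "combined",
                       logOR = pooled$logOR, std.error = pooled$std.error,
                       OR = pooled$OR, conf.low = pooled$conf.low,
                       conf.high = pooled$conf.high, p = pooled$p,
                       weight = 1 / pooled$std.error^2, zero_cell = NA)
      }) |>
      dplyr::ungroup()
  }

  cats <- if (nrow(est)) unique(est$category) else character(0)
  out <- lapply(cats, function(cat) {
    pool_fixed_effect(est[est$category == cat, ], category = cat)
  })
  names(out) <- cats
  empty <- setdiff(c("endurance", "power"), cats)
  if (length(empty) && length(intersect(studies$category, empty))) {
    warning("no retained studies in category: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  out
}
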