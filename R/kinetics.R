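#' Substrate-inhibition velocity
#'
#' Canonical substrate-inhibition model
#' \deqn{v = \frac{V_{max} [S]}{K_m + [S](1 + [S]/K_i)}}
#' where `Vmax` is the maximum velocity in the absence of inhibition, `Km`
#' the Michaelis-Menten constant and `Ki` the dissociation constant for
#' substrate binding in the inhibitory state. Velocity rises to a unique
#' interior maximum at `S = sqrt(Km * Ki)` and declines beyond it; the
#' Michaelis-Menten model is the `Ki -> Inf` limit.
#'
#' @param S Substrate concentration, mM (vectorized, >= 0).
#' @param Vmax,Km,Ki Positive kinetic parameters (Vmax in
#'   umol min^-1 mg^-1, Km and Ki in mM).
#' @return Velocity in the units of `Vmax`.
#' @examples
#' si_velocity(1, Vmax = 24.96, Km = 0.61, Ki = 8.68)
#' @export
si_velocity <- function(S, Vmax, Km, Ki) {
  if (any(S < 0)) stop("negative substrate concentration", call. = FALSE)
  if (any(c(Vmax, Km, Ki) <= 0)) stop("parameters must be > 0", call. = FALSE)
  Vmax * S / (Km + S * (1 + S / Ki))
}

#' Slope of the linear kinetic range of an absorbance trace
#'
#' Ordinary least-squares slope of A340 against time (in minutes) over the
#' assay's linear window.
#'
#' @param trace Data frame with columns `time_s` and `A340`.
#' @param window Linear window in minutes, `c(start, end)`.
#' @param blank_slope Optional blank (zero-substrate) slope to subtract,
#'   in A340 per minute.
#' @return One-row tibble: `slope_per_min`, `intercept`, `r_squared`,
#'   `n_points`.
#' @export
linear_velocity <- function(trace, window = c(0, 5), blank_slope = 0) {
  stopifnot(all(c("time_s", "A340") %in% names(trace)))
  t_min <- trace$time_s / 60
  keep <- t_min >= window[1] & t_min <= window[2]
  if (sum(keep) < 3) stop("fewer than 3 points in the linear window",
                          call. = FALSE)
  fit <- stats::lm(A340 ~ t_min, data = data.frame(A340 = trace$A340[keep],
                                                   t_min = t_min[keep]))
  tss <- sum((trace$A340[keep] - mean(trace$A340[keep]))^2)
  rss <- sum(stats::residuals(fit)^2)
  tibble::tibble(
    slope_per_min = unname(stats::coef(fit)[2]) - blank_slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    n_points = sum(keep)
  )
}

#' Beer-Lambert conversion of an absorbance change to NADH concentration
#'
#' @param delta_A340 Absorbance change at 340 nm.
#' @param epsilon340 NADH extinction coefficient, M^-1 cm^-1.
#' @param path_cm Optical path length, cm.
#' @return Concentration in mol per litre.
#' @examples
#' absorbance_to_concentration(0.1) # 2.593e-5 M
#' @export
absorbance_to_concentration <- function(delta_A340, epsilon340 = 6220,
                                        path_cm = 0.62) {
  if (epsilon340 <= 0 || path_cm <= 0) {
    stop("extinction coefficient and path length must be positive",
         call. = FALSE)
  }
  delta_A340 / (epsilon340 * path_cm)
}

#' Specific activity from an absorbance slope
#'
#' Converts an A340 slope (per minute) to a specific activity in
#' umol min^-1 mg^-1, assuming one NADH produced per deaminated AMP
#' (the coupled IMP dehydrogenase assay).
#'
#' @param slope_per_min Absorbance change per minute.
#' @param assay An [assay_params] object.
#' @return Specific activity, umol min^-1 mg^-1 protein.
#' @export
specific_activity <- function(slope_per_min, assay = assay_params()) {
  stopifnot(inherits(assay, "assay_params"))
  if (assay$protein_mg <= 0) stop("zero protein mass", call. = FALSE)
  c_per_min <- absorbance_to_concentration(slope_per_min, assay$epsilon340,
                                           assay$path_cm) # mol L^-1 min^-1
  c_per_min * (assay$volume_uL * 1e-6) * 1e6 / assay$protein_mg
}

# inverse of specific_activity: expected A340 slope for a given activity
activity_to_slope <- function(activity, assay = assay_params()) {
  activity * assay$protein_mg / ((assay$volume_uL * 1e-6) * 1e6) *
    assay$epsilon340 * assay$path_cm
}

#' Per-well velocities from a long-format plate table
#'
#' Fits the linear window of each well's trace and converts the slope to a
#' specific activity, yielding the velocity points that enter kinetic fits.
#'
#' @param plate Long tibble with columns `well`, `enzyme`, `substrate_mM`,
#'   `replicate`, `time_s`, `A340` (as produced by [sim_kinetic_plate()] or
#'   [read_plate_csv()]).
#' @param assay An [assay_params] object (its `linear_window_min` defines
#'   the fitted range).
#' @param blank_subtract If `TRUE`, subtract the mean zero-substrate slope
#'   per enzyme before converting.
#' @return Tibble of velocity points: `enzyme`, `substrate_mM`, `replicate`,
#'   `well`, `slope_per_min`, `v` (umol min^-1 mg^-1).
#' @export
plate_velocities <- function(plate, assay = assay_params(),
                             blank_subtract = FALSE) {
  need <- c("well", "enzyme", "substrate_mM", "replicate", "time_s", "A340")
  miss <- setdiff(need, names(plate))
  if (length(miss)) stop("plate lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  slopes <- plate |>
    dplyr::group_by(.data$enzyme, .data$substrate_mM, .data$replicate,
                    .data$well) |>
    dplyr::group_modify(~ linear_velocity(.x, window = assay$linear_window_min)) |>
    dplyr::ungroup()
  if (blank_subtract) {
    blanks <- slopes |>
      dplyr::filter(.data$substrate_mM == 0) |>
      dplyr::group_by(.data$enzyme) |>
      dplyr::summarise(blank = mean(.data$slope_per_min), .groups = "drop")
    slopes <- slopes |>
      dplyr::left_join(blanks, by = "enzyme") |>
      dplyr::mutate(slope_per_min = .data$slope_per_min -
                      dplyr::coalesce(.data$blank, 0)) |>
      dplyr::select(-"blank")
  }
  slopes |>
    dplyr::mutate(v = specific_activity(.data$slope_per_min, assay)) |>
    dplyr::select("enzyme", "substrate_mM", "replicate", "well",
                  "slope_per_min", "v")
}

# starting values per the documented initialization rule
.si_start <- function(S, v) {
  vmax0 <- 1.2 * max(v)
  rising <- order(S)
  half <- which(v[rising] >= max(v) / 2)
  km0 <- if (length(half)) S[rising][half[1]] else stats::median(S)
  km0 <- max(km0, 1e-3)
  c(Vmax = vmax0, Km = km0, Ki = max(S))
}

#' Fit the substrate-inhibition model to velocity points
#'
#' Nonlinear least squares (Levenberg-Marquardt) of velocity against
#' substrate concentration. Standard errors come from the Jacobian-based
#' covariance at the optimum, 95% confidence intervals from the t
#' distribution with `n - k` degrees of freedom. Up to five jittered
#' restarts are attempted before declaring non-convergence. A warning is
#' emitted when the fitted `Ki` runs away above the sampled substrate range
#' (Michaelis-Menten-like data cannot pin the inhibition constant).
#'
#' @param points Data frame with columns `substrate_mM` and `v` (points at
#'   zero substrate are dropped from the fit; at least 4 distinct positive
#'   substrate levels required).
#' @return An object of class `si_fit`; see [tidy.si_fit()] and
#'   [glance.si_fit()].
#' @export
fit_si <- function(points) {
  stopifnot(all(c("substrate_mM", "v") %in% names(points)))
  pts <- points[points$substrate_mM > 0, , drop = FALSE]
  S <- pts$substrate_mM
  v <- pts$v
  if (length(unique(S)) < 4) {
    stop("need at least 4 distinct positive substrate levels", call. = FALSE)
  }
  mean_by_S <- tapply(v, S, mean)
  if (names(which.max(mean_by_S)) == as.character(max(S))) {
    warning("no substrate level above the apparent velocity peak; ",
            "Ki is weakly identified", call. = FALSE)
  }
  start <- .si_start(S, v)
  jitter_factors <- list(c(1, 1, 1), c(1, 0.5, 2), c(2, 2, 0.5),
                         c(0.5, 1, 4), c(1.5, 0.25, 1), c(0.8, 4, 0.25))
  fit <- NULL
  for (jf in jitter_factors) {
    st <- start * jf
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ Vmax * S / (Km + S * (1 + S / Ki)),
        data = data.frame(S = S, v = v),
        start = as.list(st),
        lower = c(Vmax = 1e-9, Km = 1e-9, Ki = 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("substrate-inhibition fit failed to converge after restarts",
         call. = FALSE)
  }
  est <- stats::coef(fit)
  n <- length(v)
  k <- 3L
  ss <- sum(stats::residuals(fit)^2)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, 3))
  names(se) <- names(est)
  tcrit <- stats::qt(0.975, df = n - k)
  if (est[["Ki"]] > 100 * max(S)) {
    warning("fitted Ki far above the sampled substrate range; ",
            "data carry little evidence of substrate inhibition",
            call. = FALSE)
  }
  structure(list(
    coef = est, se = se,
    ci = cbind(lower = est - tcrit * se, upper = est + tcrit * se),
    vcov = tryCatch(stats::vcov(fit), error = function(e) NULL),
    ss = ss, n = n, k = k, aicc = aicc_ls(ss, n, k),
    data = tibble::tibble(substrate_mM = S, v = v,
                          fitted = stats::fitted(fit)),
    nls = fit
  ), class = "si_fit")
}

#' @export
print.si_fit <- function(x, ...) {
  cat("<si_fit> substrate-inhibition model, n =", x$n, "\n")
  print(round(cbind(estimate = x$coef, se = x$se, x$ci), 4))
  cat(sprintf("  SS = %.4g, AICc = %.3f\n", x$ss, x$aicc))
  invisible(x)
}

#' Tidy a substrate-inhibition fit
#'
#' @param x An `si_fit` object.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.si_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                 std.error = unname(x$se),
                 conf.low = unname(x$ci[, "lower"]),
                 conf.high = unname(x$ci[, "upper"]))
}

#' One-row fit summary
#'
#' @param x An `si_fit` object.
#' @param ... Unused.
#' @return Tibble with `n`, `k`, `ss`, `sigma`, `AICc`.
#' @export
glance.si_fit <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, ss = x$ss,
                 sigma = sqrt(x$ss / (x$n - x$k)), AICc = x$aicc)
}

#' @export
autoplot.si_fit <- function(object, ...) {
  grid <- tibble::tibble(
    substrate_mM = seq(min(object$data$substrate_mM) / 2,
                       max(object$data$substrate_mM), length.out = 200))
  grid$v <- si_velocity(grid$substrate_mM, object$coef[["Vmax"]],
                        object$coef[["Km"]], object$coef[["Ki"]])
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$substrate_mM, y = .data$v)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "[S] (mM)",
                  y = expression(v ~ (mu * mol ~ min^-1 ~ mg^-1))) +
    ggplot2::theme_minimal()
}

# all 8 subsets of {Vmax, Km, Ki}
.sharing_patterns <- function() {
  pars <- c("Vmax", "Km", "Ki")
  unlist(lapply(0:3, function(m) utils::combn(pars, m, simplify = FALSE)),
         recursive = FALSE)
}

.pattern_label <- function(shared) {
  if (!length(shared)) "none" else paste(shared, collapse = "+")
}

#' Joint two-enzyme fit with a shared-parameter pattern
#'
#' Fits both enzymes' velocity points in a single least-squares problem in
#' which the parameters named in `shared` are tied across enzymes and the
#' rest are duplicated, giving `k = 6 - |shared|` free parameters.
#'
#' @param points Data frame with columns `enzyme` (exactly two levels),
#'   `substrate_mM`, `v`.
#' @param shared Character subset of `c("Vmax", "Km", "Ki")` to tie.
#' @return An object of class `si_global_fit` with per-enzyme estimates,
#'   pooled residual SS and AICc.
#' @export
global_fit <- function(points, shared = character(0)) {
  stopifnot(all(c("enzyme", "substrate_mM", "v") %in% names(points)),
            all(shared %in% c("Vmax", "Km", "Ki")))
  shared <- unique(shared)
  enz <- unique(points$enzyme)
  if (length(enz) != 2) stop("need exactly two enzymes", call. = FALSE)
  pts <- points[points$substrate_mM > 0, , drop = FALSE]
  d1 <- pts[pts$enzyme == enz[1], ]
  d2 <- pts[pts$enzyme == enz[2], ]

  pars <- c("Vmax", "Km", "Ki")
  free <- setdiff(pars, shared)
  # parameter vector layout: shared params once, free params per enzyme
  par_names <- c(shared, as.vector(outer(free, c(".1", ".2"), paste0)))
  s1 <- .si_start(d1$substrate_mM, d1$v)
  s2 <- .si_start(d2$substrate_mM, d2$v)
  # refine heuristic starts with per-dataset fits when they converge
  r1 <- tryCatch(suppressWarnings(fit_si(d1)$coef), error = function(e) s1)
  r2 <- tryCatch(suppressWarnings(fit_si(d2)$coef), error = function(e) s2)
  make_start <- function(a, b) {
    nm1 <- if (length(free)) paste0(free, ".1") else character(0)
    nm2 <- if (length(free)) paste0(free, ".2") else character(0)
    st <- c((a[shared] + b[shared]) / 2,
            stats::setNames(a[free], nm1),
            stats::setNames(b[free], nm2))
    names(st) <- par_names
    st
  }
  starts <- list(make_start(r1, r2), make_start(s1, s2),
                 make_start(r1, r2) * 0.5, make_start(r1, r2) * 2)

  unpack <- function(p, which_enz) {
    vapply(pars, function(nm) {
      if (nm %in% shared) p[[nm]] else p[[paste0(nm, ".", which_enz)]]
    }, numeric(1))
  }
  resid_fn <- function(p) {
    p <- stats::setNames(as.numeric(p), par_names)
    q1 <- unpack(p, 1)
    q2 <- unpack(p, 2)
    c(d1$v - si_velocity(d1$substrate_mM, q1[["Vmax"]], q1[["Km"]], q1[["Ki"]]),
      d2$v - si_velocity(d2$substrate_mM, q2[["Vmax"]], q2[["Km"]], q2[["Ki"]]))
  }
  out <- NULL
  for (st in starts) {
    cand <- tryCatch(
      minpack.lm::nls.lm(
        par = st, fn = resid_fn,
        lower = rep(1e-9, length(st)),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(cand) || cand$info == 0 || !all(is.finite(cand$par))) next
    if (is.null(out) || sum(cand$fvec^2) < sum(out$fvec^2)) out <- cand
  }
  if (is.null(out)) stop("global fit failed to converge", call. = FALSE)
  p <- stats::setNames(as.numeric(out$par), par_names)
  n <- nrow(d1) + nrow(d2)
  k <- length(par_names)
  ss <- sum(out$fvec^2)
  covm <- tryCatch({
    sigma2 <- ss / (n - k)
    sigma2 * solve(out$hessian)
  }, error = function(e) NULL)
  se <- if (!is.null(covm)) sqrt(pmax(diag(covm), 0)) else
    rep(NA_real_, length(p))
  names(se) <- par_names
  per_enzyme <- dplyr::bind_rows(lapply(1:2, function(i) {
    q <- unpack(p, i)
    qse <- vapply(pars, function(nm) {
      key <- if (nm %in% shared) nm else paste0(nm, ".", i)
      se[[key]]
    }, numeric(1))
    tibble::tibble(enzyme = enz[i], term = pars, estimate = unname(q),
                   std.error = unname(qse), shared = pars %in% shared)
  }))
  structure(list(
    enzymes = enz, shared = shared, label = .pattern_label(shared),
    par = p, se = se, per_enzyme = per_enzyme,
    ss = ss, n = n, k = k, aicc = aicc_ls(ss, n, k)
  ), class = "si_global_fit")
}

#' @export
print.si_global_fit <- function(x, ...) {
  cat(sprintf("<si_global_fit> shared: %s | k = %d, n = %d, SS = %.4g, AICc = %.3f\n",
              x$label, x$k, x$n, x$ss, x$aicc))
  print(as.data.frame(x$per_enzyme))
  invisible(x)
}

#' @export
tidy.si_global_fit <- function(x, ...) x$per_enzyme

#' @export
glance.si_global_fit <- function(x, ...) {
  tibble::tibble(shared = x$label, n = x$n, k = x$k, ss = x$ss, AICc = x$aicc)
}

#' Rank all shared-parameter patterns by AICc
#'
#' Fits all 8 subsets of `{Vmax, Km, Ki}` as shared between the two enzymes
#' and ranks them by AICc; ties are broken toward more sharing (fewer free
#' parameters). Patterns whose fit fails are retained in the table with a
#' flag rather than an error.
#'
#' @param points As in [global_fit()].
#' @return An object of class `sharing_selection`: `table` (tibble: pattern
#'   label, `n_shared`, `k`, `ss`, `AICc`, `dAICc`, `failed`, ranked) and
#'   `fits` (named list of `si_global_fit`).
#' @export
select_sharing <- function(points) {
  patterns <- .sharing_patterns()
  fits <- lapply(patterns, function(sh) {
    tryCatch(global_fit(points, shared = sh), error = function(e) e)
  })
  labels <- vapply(patterns, .pattern_label, character(1))
  names(fits) <- labels
  tab <- purrr::map2_dfr(fits, patterns, function(f, sh) {
    if (inherits(f, "error")) {
      tibble::tibble(pattern = .pattern_label(sh), n_shared = length(sh),
                     k = 6L - length(sh), ss = NA_real_, AICc = NA_real_,
                     failed = TRUE)
    } else {
      tibble::tibble(pattern = f$label, n_shared = length(sh), k = f$k,
                     ss = f$ss, AICc = f$aicc, failed = FALSE)
    }
  })
  tab <- tab |>
    dplyr::arrange(.data$failed, .data$AICc, .data$k) |>
    dplyr::mutate(dAICc = .data$AICc - .data$AICc[1])
  structure(list(table = tab, fits = fits), class = "sharing_selection")
}

#' @export
print.sharing_selection <- function(x, ...) {
  cat("<sharing_selection> AICc ranking of shared-parameter patterns\n")
  print(as.data.frame(x$table))
  invisible(x)
}

#' @export
tidy.sharing_selection <- function(x, ...) x$table

#' Extra-sum-of-squares F test between two enzymes
#'
#' Compares the nested all-shared fit (one curve for both enzymes, k = 3)
#' against the all-separate fit (k = 6):
#' \deqn{F = \frac{(SS_{shared} - SS_{sep})/(df_{shared} - df_{sep})}{SS_{sep}/df_{sep}}}
#' with p from the F distribution. A significant p means the two enzymes'
#' kinetics differ.
#'
#' @param points As in [global_fit()].
#' @return One-row tibble: `F`, `df1`, `df2`, `p`, `ss_shared`,
#'   `ss_separate`.
#' @export
compare_enzymes <- function(points) {
  f_shared <- global_fit(points, shared = c("Vmax", "Km", "Ki"))
  f_sep <- global_fit(points, shared = character(0))
  df_sh <- f_shared$n - f_shared$k
  df_sep <- f_sep$n - f_sep$k
  ss_sh <- f_shared$ss
  ss_sep <- f_sep$ss
  if (ss_sep > ss_sh * (1 + 1e-8)) {
    stop("numerical-fit error: separate fit worse than shared fit",
         call. = FALSE)
  }
  Fstat <- max(0, ((ss_sh - ss_sep) / (df_sh - df_sep)) / (ss_sep / df_sep))
  tibble::tibble(
    F = Fstat, df1 = df_sh - df_sep, df2 = df_sep,
    p = stats::pf(Fstat, df_sh - df_sep, df_sep, lower.tail = FALSE),
    ss_shared = ss_sh, ss_separate = ss_sep
  )
}

#' Unpaired two-sample t test with degenerate-case conventions
#'
#' Pooled-variance Student t by default (Welch available). Two groups with
#' zero variance and equal means give p = 1 by convention; zero variance
#' with unequal means gives p = 0 with a warning.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return One-row tibble: `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
two_sample_ttest <- function(group_a, group_b,
                             variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  df0 <- length(group_a) + length(group_b) - 2
  if (va == 0 && vb == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(tibble::tibble(t = 0, df = df0, p = 1,
                            mean_a = mean(group_a), mean_b = mean(group_b)))
    }
    warning("zero variance in both groups with unequal means", call. = FALSE)
    return(tibble::tibble(t = sign(mean(group_a) - mean(group_b)) * Inf,
                          df = df0, p = 0,
                          mean_a = mean(group_a), mean_b = mean(group_b)))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = variant == "pooled")
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 mean_a = mean(group_a), mean_b = mean(group_b))
}
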