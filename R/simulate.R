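#' Scenario for a synthetic genotype panel
#'
#' Describes the population structure and planted signal of a simulated
#' phased panel: an African group in which qualifying variants are fixed
#' ancestral, three Neandertal and one Denisovan genome, modern populations
#' of which a fraction of haplotypes carry an introgressed archaic tract of
#' a given genetic length around the focal variant, decoy variants that each
#' violate one screening filter, and neutral background sites. Group sizes
#' default to the screening design this package emulates: 661 African
#' genomes, 3 Neandertals, 1 Denisovan.
#'
#' @param n_african,n_neandertal,n_denisovan Diploid sample counts.
#' @param n_modern Named integer vector: samples per modern population.
#' @param region A [genomic_interval] tibble.
#' @param focal_pos,focal_id Position and id of the planted qualifying
#'   missense variant.
#' @param focal_gene Gene symbol assigned to the focal variant.
#' @param n_background Neutral sites with a common allele frequency across
#'   groups.
#' @param n_tract_sites Archaic-like marker sites inside the introgressed
#'   tract (derived in Neandertals and carrier haplotypes only).
#' @param n_decoys Sites violating exactly one enabled screening filter each.
#' @param introgressed_fraction Proportion of modern haplotypes carrying the
#'   archaic tract (at least one carrier is planted whenever the fraction is
#'   positive).
#' @param tract_genetic_length Genetic length of the planted tract, cM.
#' @param mean_rate_cM_per_Mb Mean recombination rate of the generated map.
#' @param archaic_missing_rate Missing-call rate at archaic genomes on
#'   non-planted sites (exercises imputation rules downstream).
#' @param archaic_het_rate Heterozygosity rate of archaic genomes at
#'   background sites (exercises the phylogeny exclusion rule).
#' @param filters A [screen_filters] object; decoy violations are drawn from
#'   the filters enabled here, so the truth table is exact for this
#'   configuration.
#' @return A validated list of class `panel_scenario`.
#' @export
panel_scenario <- function(n_african = 661, n_neandertal = 3, n_denisovan = 1,
                           n_modern = c(EUR_A = 20, EUR_B = 20, SAS = 20,
                                        AMR = 20, EAS = 20),
                           region = genomic_interval("chr1", 114371932, 114812153),
                           focal_pos = 114679616, focal_id = "rs34526199",
                           focal_gene = "AMPD1",
                           n_background = 40, n_tract_sites = 30, n_decoys = 10,
                           introgressed_fraction = 0.05,
                           tract_genetic_length = 0.063,
                           mean_rate_cM_per_Mb = 0.16,
                           archaic_missing_rate = 0, archaic_het_rate = 0.05,
                           filters = screen_filters(denisovan_absent = TRUE)) {
  stopifnot(n_african >= 1, n_neandertal >= 1, n_denisovan >= 0,
            all(n_modern >= 0), sum(n_modern) >= 1,
            n_background >= 0, n_tract_sites >= 0, n_decoys >= 0,
            introgressed_fraction >= 0, introgressed_fraction <= 1,
            tract_genetic_length >= 0, mean_rate_cM_per_Mb > 0,
            archaic_missing_rate >= 0, archaic_missing_rate <= 1,
            archaic_het_rate >= 0, archaic_het_rate <= 1)
  if (is.null(names(n_modern))) names(n_modern) <- paste0("POP", seq_along(n_modern))
  if (focal_pos < region$start || focal_pos > region$end) {
    stop("focal position outside region", call. = FALSE)
  }
  structure(as.list(environment()), class = "panel_scenario")
}

#' Simulate a phased genotype panel with a planted introgressed haplotype
#'
#' Generates a [genotype_panel] whose planted qualifying variant is
#' ancestral-fixed in the African group, homozygous derived in every
#' Neandertal, absent from the Denisovan, and carried by a fixed fraction of
#' modern haplotypes together with a tract of derived archaic-like marker
#' alleles spanning the requested genetic length on the generated
#' recombination map. Decoy variants each violate one enabled screening
#' filter; background sites share a common allele frequency across groups.
#'
#' @param scenario A [panel_scenario].
#' @param seed Integer seed; identical seeds give identical panels.
#' @return A list of class `panel_sim`: `panel` (the [genotype_panel]),
#'   `truth` (tibble of planted qualifying variants), `map` (recombination
#'   map tibble), `carriers` (haplotype row names carrying the tract),
#'   `tract` (the tract [genomic_interval]), `scenario`.
#' @export
sim_genotype_panel <- function(scenario = panel_scenario(), seed) {
  stopifnot(inherits(scenario, "panel_scenario"))
  with_seed(seed, {
    sc <- scenario
    map <- sim_recomb_map(sc$region, sc$mean_rate_cM_per_Mb,
                          n_knots = 8, seed = sample.int(2^31 - 1, 1))
    total_cM <- max(map$cM)
    if (sc$tract_genetic_length > total_cM) {
      stop("introgressed tract longer than the region's genetic length",
           call. = FALSE)
    }

    # physical tract interval: invert the cumulative map around the focal site
    cm_at <- function(pos) stats::approx(map$pos, map$cM, pos, ties = "ordered")$y
    pos_at <- function(cm) stats::approx(map$cM, map$pos, cm, ties = "ordered")$y
    cm0 <- cm_at(sc$focal_pos)
    half <- sc$tract_genetic_length / 2
    lo <- cm0 - half
    hi <- cm0 + half
    if (lo < 0) { hi <- hi - lo; lo <- 0 }
    if (hi > total_cM) { lo <- lo - (hi - total_cM); hi <- total_cM }
    tract <- genomic_interval(sc$region$chrom, round(pos_at(lo)), round(pos_at(hi)))

    samples <- tibble::tibble(
      sample_id = c(sprintf("AFR%03d", seq_len(sc$n_african)),
                    sprintf("NEA%d", seq_len(sc$n_neandertal)),
                    if (sc$n_denisovan > 0) sprintf("DEN%d", seq_len(sc$n_denisovan)),
                    unlist(lapply(names(sc$n_modern), function(p)
                      sprintf("%s%03d", p, seq_len(sc$n_modern[[p]]))))),
      group = c(rep("AFRICAN", sc$n_african),
                rep("NEANDERTAL", sc$n_neandertal),
                rep("DENISOVAN", sc$n_denisovan),
                rep("MODERN", sum(sc$n_modern))),
      population = c(rep(NA_character_, sc$n_african + sc$n_neandertal +
                           sc$n_denisovan),
                     rep(names(sc$n_modern), sc$n_modern))
    )
    is_afr <- rep(samples$group == "AFRICAN", each = 2)
    is_nea <- rep(samples$group == "NEANDERTAL", each = 2)
    is_den <- rep(samples$group == "DENISOVAN", each = 2)
    is_mod <- rep(samples$group == "MODERN", each = 2)
    H <- 2 * nrow(samples)
    h_mod <- sum(is_mod)

    n_car <- round(sc$introgressed_fraction * h_mod)
    if (sc$introgressed_fraction > 0 && n_car == 0) n_car <- 1
    carrier_idx <- sort(sample(which(is_mod), n_car))

    # site roles and positions
    decoy_pool <- c(
      if (sc$filters$african_fixed_ancestral) "african",
      if (sc$filters$neandertal_hom_derived) c("nea_het", "nea_anc"),
      if (sc$filters$denisovan_absent) "denisovan",
      "consequence"
    )
    roles <- c("focal",
               rep("tract", sc$n_tract_sites),
               if (sc$n_decoys > 0) sample(decoy_pool, sc$n_decoys, replace = TRUE),
               rep("background", sc$n_background))
    n_sites <- length(roles)
    pool <- setdiff(seq(sc$region$start, sc$region$end), sc$focal_pos)
    pos_tract <- sort(sample(pool[pool >= tract$start & pool <= tract$end],
                             sc$n_tract_sites))
    pos_other <- sort(sample(setdiff(pool, pos_tract),
                             n_sites - 1 - sc$n_tract_sites))
    pos <- c(sc$focal_pos, pos_tract, pos_other)
    ord <- order(pos)
    pos <- pos[ord]
    roles <- roles[ord]

    nucs <- c("A", "C", "G", "T")
    ref <- sample(nucs, n_sites, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(nucs, r), 1), character(1))
    anc_is_ref <- stats::runif(n_sites) < 0.8
    ancestral <- ifelse(anc_is_ref, ref, alt)
    derived <- ifelse(anc_is_ref, alt, ref)

    consequence <- rep("intergenic", n_sites)
    gene <- rep(NA_character_, n_sites)
    X <- matrix(0L, nrow = H, ncol = n_sites)

    draw_freq <- function(idx, f) stats::rbinom(length(idx), 1, f)
    for (j in seq_len(n_sites)) {
      role <- roles[j]
      if (role == "background") {
        f <- stats::runif(1, 0.05, 0.95)
        X[is_afr | is_mod, j] <- stats::rbinom(sum(is_afr | is_mod), 1, f)
        # archaic genomes: mostly homozygous, occasionally heterozygous
        arch <- which(rep(samples$group %in% c("NEANDERTAL", "DENISOVAN"),
                          each = 2))
        for (s in seq(1, length(arch), by = 2)) {
          if (stats::runif(1) < sc$archaic_het_rate) {
            X[arch[s], j] <- 1L; X[arch[s + 1], j] <- 0L
          } else {
            X[arch[c(s, s + 1)], j] <- stats::rbinom(1, 1, f)
          }
        }
      } else if (role == "tract" || role == "focal") {
        X[is_nea, j] <- 1L
        X[carrier_idx, j] <- 1L
        if (role == "focal") {
          consequence[j] <- "missense"
          gene[j] <- sc$focal_gene
        }
      } else { # decoys: qualifying pattern except for one violated rule
        consequence[j] <- "missense"
        gene[j] <- sc$focal_gene
        X[is_nea, j] <- 1L
        X[is_mod, j] <- draw_freq(which(is_mod), stats::runif(1, 0, 0.3))
        if (role == "african") {
          f <- stats::runif(1, 0.01, 0.2)
          v <- draw_freq(which(is_afr), f)
          if (sum(v) == 0) v[1] <- 1L
          X[is_afr, j] <- v
        } else if (role == "nea_het") {
          X[which(is_nea)[1], j] <- 0L
        } else if (role == "nea_anc") {
          k <- which(is_nea)[1:2]
          X[k, j] <- 0L
        } else if (role == "denisovan") {
          X[is_den, j] <- 1L
        } else if (role == "consequence") {
          consequence[j] <- "synonymous"
        }
      }
    }

    # optional missing calls in archaics, only at non-planted sites
    if (sc$archaic_missing_rate > 0) {
      arch_rows <- which(is_nea | is_den)
      bg_cols <- which(roles == "background")
      for (r in arch_rows) {
        drop <- bg_cols[stats::runif(length(bg_cols)) < sc$archaic_missing_rate]
        X[r, drop] <- NA
      }
    }

    sites <- tibble::tibble(
      chrom = sc$region$chrom, pos = pos,
      id = ifelse(roles == "focal", sc$focal_id,
                  sprintf("site_%09d", pos)),
      ref = ref, alt = alt, ancestral = ancestral, derived = derived,
      consequence = consequence, gene = gene, role = roles
    )
    panel <- genotype_panel(sites[, setdiff(names(sites), "role")], X, samples)
    truth <- sites[sites$role == "focal", ]
    structure(list(panel = panel, truth = truth, map = map,
                   carriers = rownames(panel$haplotypes)[carrier_idx],
                   tract = tract, roles = roles, scenario = sc),
              class = "panel_sim")
  })
}

#' Simulate a recombination map over a region
#'
#' Draws random knot positions and segment-wise rates, rescaled so the mean
#' rate over the region equals `mean_rate_cM_per_Mb` exactly. With two knots
#' the map is linear at that rate.
#'
#' @param region A [genomic_interval] tibble of positive length.
#' @param mean_rate_cM_per_Mb Mean recombination rate, cM per Mb.
#' @param n_knots Number of map knots (>= 2), endpoints included.
#' @param seed Integer seed.
#' @return Tibble with columns `chrom`, `pos` (strictly ascending) and `cM`
#'   (non-decreasing cumulative centimorgans, 0 at the region start).
#' @export
sim_recomb_map <- function(region, mean_rate_cM_per_Mb = 1, n_knots = 10,
                           seed = 1) {
  stopifnot(is.data.frame(region), nrow(region) == 1, n_knots >= 2)
  if (region$length_bp <= 0) stop("region of zero length", call. = FALSE)
  with_seed(seed, {
    inner <- if (n_knots > 2) {
      sort(sample(seq(region$start + 1, region$end - 1), n_knots - 2))
    } else integer(0)
    pos <- c(region$start, inner, region$end)
    seg <- diff(pos)
    rate <- stats::rlnorm(length(seg), meanlog = 0, sdlog = 0.6)
    inc <- rate * seg
    total <- mean_rate_cM_per_Mb * region$length_bp / 1e6
    inc <- inc * total / sum(inc)
    tibble::tibble(chrom = region$chrom, pos = pos, cM = c(0, cumsum(inc)))
  })
}

#' Assay parameters for the NADH-coupled AMP deaminase assay
#'
#' AMP deamination is followed through IMP dehydrogenase: each deaminated
#' AMP reduces one NAD+ to NADH, monitored at 340 nm. Beer-Lambert converts
#' the absorbance slope to a NADH production rate using the NADH extinction
#' coefficient and the plate's empirical path length.
#'
#' @param epsilon340 NADH extinction coefficient, M^-1 cm^-1 (default 6220).
#' @param path_cm Optical path length, cm (default 0.62, empirical for a
#'   round-bottom 96-well plate at the assay volume).
#' @param volume_uL Reaction volume, microlitres (default 215: 200 buffer +
#'   5 protein + 10 substrate).
#' @param protein_mg Protein per reaction, mg (default 4e-4, i.e. 0.4 ug).
#' @param linear_window_min Start and end of the linear kinetic range,
#'   minutes (default 0-5, the recombinant-protein window; muscle extracts
#'   use 40-60).
#' @return A list of class `assay_params`.
#' @export
assay_params <- function(epsilon340 = 6220, path_cm = 0.62, volume_uL = 215,
                         protein_mg = 4e-4, linear_window_min = c(0, 5)) {
  stopifnot(epsilon340 > 0, path_cm > 0, volume_uL > 0, protein_mg > 0,
            length(linear_window_min) == 2,
            linear_window_min[1] < linear_window_min[2])
  structure(list(epsilon340 = epsilon340, path_cm = path_cm,
                 volume_uL = volume_uL, protein_mg = protein_mg,
                 linear_window_min = linear_window_min),
            class = "assay_params")
}

#' Scenario for a simulated kinetic plate
#'
#' @param enzymes Tibble with columns `enzyme`, `Vmax` (umol min^-1 mg^-1),
#'   `Km` (mM), `Ki` (mM): the true substrate-inhibition parameters per
#'   enzyme. Defaults to the modern/Neandertal AMPD1 pair with a shared Ki.
#' @param substrate_mM Substrate series (default 0 to 5 mM, seven non-zero
#'   levels).
#' @param n_replicates Wells per enzyme and substrate level.
#' @param noise_sd Homoscedastic Gaussian noise on absorbance readings.
#' @param assay An [assay_params] object.
#' @param times_s Reading times in seconds (default every 20 s over 10 min).
#' @param a340_start Baseline absorbance at time zero.
#' @return A list of class `kinetic_scenario`.
#' @export
kinetic_scenario <- function(enzymes = tibble::tibble(
                               enzyme = c("modern", "neandertal"),
                               Vmax = c(24.96, 19.21),
                               Km = c(0.61, 0.91),
                               Ki = c(8.68, 8.68)),
                             substrate_mM = c(0, 0.1, 0.25, 0.5, 1, 2, 3, 5),
                             n_replicates = 4, noise_sd = 0.005,
                             assay = assay_params(),
                             times_s = seq(0, 600, by = 20),
                             a340_start = 0.05) {
  stopifnot(all(c("enzyme", "Vmax", "Km", "Ki") %in% names(enzymes)),
            all(enzymes$Vmax > 0), all(enzymes$Km > 0), all(enzymes$Ki > 0),
            n_replicates >= 1, noise_sd >= 0, inherits(assay, "assay_params"))
  if (any(substrate_mM < 0)) stop("negative substrate concentration", call. = FALSE)
  structure(as.list(environment()), class = "kinetic_scenario")
}

#' Simulate plate-reader absorbance traces from the substrate-inhibition model
#'
#' For each well the true velocity at its substrate concentration is
#' computed from the substrate-inhibition model, converted to an absorbance
#' slope through Beer-Lambert and the assay geometry, and a linear trace
#' plus Gaussian noise is emitted.
#'
#' @param scenario A [kinetic_scenario].
#' @param seed Integer seed.
#' @return A list of class `plate_sim`: `plate` (long tibble: `well`,
#'   `enzyme`, `substrate_mM`, `replicate`, `time_s`, `A340`), `truth`
#'   (per-well true velocity and slope), `scenario`.
#' @export
sim_kinetic_plate <- function(scenario = kinetic_scenario(), seed) {
  stopifnot(inherits(scenario, "kinetic_scenario"))
  with_seed(seed, {
    sc <- scenario
    design <- tidyr::expand_grid(
      enzyme = sc$enzymes$enzyme,
      substrate_mM = sc$substrate_mM,
      replicate = seq_len(sc$n_replicates)
    ) |>
      dplyr::left_join(sc$enzymes, by = "enzyme") |>
      dplyr::mutate(
        well = sprintf("W%03d", dplyr::row_number()),
        v_true = si_velocity(.data$substrate_mM, .data$Vmax, .data$Km, .data$Ki),
        slope_true = activity_to_slope(.data$v_true, sc$assay)
      )
    plate <- design |>
      dplyr::select("well", "enzyme", "substrate_mM", "replicate", "slope_true") |>
      tidyr::expand_grid(time_s = sc$times_s) |>
      dplyr::mutate(
        A340 = sc$a340_start + .data$slope_true * .data$time_s / 60 +
          stats::rnorm(dplyr::n(), 0, sc$noise_sd)
      ) |>
      dplyr::select(-"slope_true")
    structure(list(plate = plate,
                   truth = design[, c("well", "enzyme", "substrate_mM",
                                      "replicate", "Vmax", "Km", "Ki",
                                      "v_true", "slope_true")],
                   scenario = sc),
              class = "plate_sim")
  })
}

#' Scenario for simulated athlete genotype studies
#'
#' The default design mirrors a seven-study meta-analysis of 1208 elite
#' athletes and 1537 sedentary controls split between endurance and power
#' disciplines. Control carriers are drawn binomially at
#' `control_carrier_freq`; athlete carriers at the odds implied by
#' `true_carrier_OR`; carriers are split into heterozygous/homozygous
#' genotype classes under Hardy-Weinberg at the allele frequency implied by
#' the carrier frequency.
#'
#' @param studies Tibble with columns `study`, `discipline`, `category`,
#'   `n_athletes`, `n_controls`.
#' @param control_carrier_freq Carrier (CT+TT) frequency among controls.
#' @param true_carrier_OR True carrier odds ratio, athletes vs controls.
#' @return A list of class `meta_scenario`.
#' @export
meta_scenario <- function(studies = tibble::tibble(
                            study = paste0("S", 1:7),
                            discipline = c("distance_running", "cycling",
                                           "triathlon", "rowing", "sprint",
                                           "weightlifting", "throwing"),
                            category = c(rep("endurance", 4), rep("power", 3)),
                            n_athletes = c(200, 180, 176, 150, 200, 170, 132),
                            n_controls = c(230, 200, 185, 170, 270, 250, 232)),
                          control_carrier_freq = 0.25,
                          true_carrier_OR = 0.5) {
  stopifnot(all(c("study", "discipline", "category", "n_athletes",
                  "n_controls") %in% names(studies)),
            control_carrier_freq >= 0, control_carrier_freq <= 1,
            true_carrier_OR > 0)
  structure(list(studies = studies,
                 control_carrier_freq = control_carrier_freq,
                 true_carrier_OR = true_carrier_OR),
            class = "meta_scenario")
}

# split carrier counts into het/hom classes under Hardy-Weinberg at the
# allele frequency implied by the carrier frequency f: q = 1 - sqrt(1 - f),
# so P(hom | carrier) = q / (2 - q)
.split_carriers <- function(n_carriers, carrier_freq) {
  if (n_carriers == 0 || carrier_freq <= 0) return(c(het = 0L, hom = 0L))
  q <- 1 - sqrt(max(0, 1 - carrier_freq))
  p_hom <- q / (2 - q)
  hom <- stats::rbinom(1, n_carriers, p_hom)
  c(het = n_carriers - hom, hom = hom)
}

#' Simulate athlete/control genotype count tables
#'
#' @param scenario A [meta_scenario].
#' @param seed Integer seed.
#' @return A list of class `studies_sim`: `studies` (tibble: `study`,
#'   `discipline`, `category`, `a_CC`, `a_CT`, `a_TT`, `c_CC`, `c_CT`,
#'   `c_TT`), `true_carrier_OR`, `scenario`.
#' @export
sim_athlete_studies <- function(scenario = meta_scenario(), seed) {
  stopifnot(inherits(scenario, "meta_scenario"))
  with_seed(seed, {
    sc <- scenario
    if (any(sc$studies$n_controls == 0)) {
      warning("study with zero controls: downstream allocation will fail",
              call. = FALSE)
    }
    p_c <- sc$control_carrier_freq
    odds_a <- sc$true_carrier_OR * p_c / (1 - p_c)
    p_a <- odds_a / (1 + odds_a)
    rows <- purrr::pmap(sc$studies, function(study, discipline, category,
                                             n_athletes, n_controls) {
      ac <- stats::rbinom(1, n_athletes, p_a)
      cc <- stats::rbinom(1, n_controls, p_c)
      a_split <- .split_carriers(ac, p_a)
      c_split <- .split_carriers(cc, p_c)
      tibble::tibble(study = study, discipline = discipline,
                     category = category,
                     a_CC = n_athletes - ac, a_CT = a_split[["het"]],
                     a_TT = a_split[["hom"]],
                     c_CC = n_controls - cc, c_CT = c_split[["het"]],
                     c_TT = c_split[["hom"]])
    })
    structure(list(studies = dplyr::bind_rows(rows),
                   true_carrier_OR = sc$true_carrier_OR, scenario = sc),
              class = "studies_sim")
  })
}
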