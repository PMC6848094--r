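#' Group-level flux truths for the default synthetic cohort
#'
#' Mean absolute fluxes (umol/min/gww), oxygen consumption, glycogen
#' contribution to the lactate/pyruvate pool and liver weights per group,
#' with the dispersions used for per-liver lognormal variation. Relative
#' model parameters are derived as `f_acetyl_labeled = V_PDH / V_TCA`,
#' `y_pc = V_PC / V_TCA`, `y_pyc = V_PyC / V_TCA`,
#' `f_pyr_medium = 1 - glycogen fraction`.
#'
#' @return data frame with one row per group
#' @export
group_flux_truths <- function() {
  g <- data.frame(
    group = c("lean-control", "lean-DKO", "DIO-control", "DIO-DKO"),
    diet = c("lean", "lean", "DIO", "DIO"),
    genotype = c("control", "DKO", "control", "DKO"),
    v_tca = c(0.41, 0.62, 0.37, 0.64),
    sd_v_tca = c(0.06, 0.13, 0.11, 0.23),
    mvo2 = c(1.16, 1.79, 1.01, 1.73),
    sd_mvo2 = c(0.18, 0.36, 0.29, 0.62),
    v_pdh = c(0.20, 0.46, 0.03, 0.12),
    sd_v_pdh = c(0.04, 0.07, 0.01, 0.07),
    v_pc = c(1.14, 1.78, 1.12, 1.99),
    sd_v_pc = c(0.23, 0.47, 0.50, 0.90),
    v_pyc = c(0.76, 1.33, 0.69, 1.22),
    sd_v_pyc = c(0.16, 0.31, 0.32, 0.60),
    glycogen_pct = c(81.40, 78.72, 76.80, 70.93),
    sd_glycogen_pct = c(7.59, 4.42, 9.34, 7.17),
    liver_weight = c(1.51, 1.58, 3.81, 2.10),
    sd_liver_weight = c(0.28, 0.46, 0.44, 0.58),
    sd_cycling_degree = c(0.09, 0.01, 0.04, 0.07)
  )
  g$f_acetyl_labeled <- g$v_pdh / g$v_tca
  g$y_pc <- g$v_pc / g$v_tca
  g$y_pyc <- g$v_pyc / g$v_tca
  g$r_cyc <- g$y_pyc / g$y_pc
  g$f_pyr_medium <- 1 - g$glycogen_pct / 100
  # per-liver CVs: total dispersion decomposed into a shared V_TCA factor
  # and a residual on the relative parameter (floor 0.05)
  cv <- function(sd, mean) sd / mean
  resid_cv <- function(cv_tot, cv_tca) sqrt(pmax(cv_tot^2 - cv_tca^2, 0.0025))
  g$cv_v_tca <- cv(g$sd_v_tca, g$v_tca)
  g$cv_f_acetyl <- resid_cv(cv(g$sd_v_pdh, g$v_pdh), g$cv_v_tca)
  g$cv_y_pc <- resid_cv(cv(g$sd_v_pc, g$v_pc), g$cv_v_tca)
  g$cv_r_cyc <- cv(g$sd_cycling_degree, g$y_pyc / (g$y_pc + g$f_acetyl_labeled))
  g$cv_mvo2_resid <- resid_cv(cv(g$sd_mvo2, g$mvo2), g$cv_v_tca)
  g
}

#' Specification of a synthetic perfused-liver cohort
#'
#' Emulates the study conditions: livers perfused with 1.5 mM [U-13C]lactate
#' + 0.15 mM [U-13C]pyruvate, four groups (lean/DIO x control/DKO) of four
#' livers, glutamate C2/C3/C4 and lactate C2 multiplet tables with
#' measurement noise, oxygen data reproducing the group MVO2 means, and
#' hyperpolarized acquisitions of 50 spectra every 2 s with 20-degree
#' pulses.
#'
#' @param n_per_group livers per group (default 4)
#' @param noise_sd Gaussian SD added to each multiplet component fraction
#' @param hp_noise_sd per-point noise of rendered HP spectra
#' @param jitter if `TRUE`, per-liver lognormal variation of the truth
#'   fluxes with the group CVs of [group_flux_truths()]; if `FALSE`, every
#'   liver sits exactly at the group mean
#' @param seed master seed; each generator derives its own stream by a
#'   fixed offset so adding generators never perturbs existing outputs
#' @param groups subset of groups to generate
#' @param truths truth table, default [group_flux_truths()]
#' @export
cohort_spec <- function(n_per_group = 4, noise_sd = 0.01, hp_noise_sd = 0.005,
                        jitter = TRUE, seed = 1,
                        groups = c("lean-control", "lean-DKO",
                                   "DIO-control", "DIO-DKO"),
                        truths = group_flux_truths()) {
  stopifnot(n_per_group >= 1, noise_sd >= 0)
  structure(list(n_per_group = n_per_group, noise_sd = noise_sd,
                 hp_noise_sd = hp_noise_sd, jitter = jitter, seed = seed,
                 groups = groups, truths = truths[truths$group %in% groups, ]),
            class = "cohort_spec")
}

# draw the per-liver truth parameters for every liver of the cohort
draw_liver_truths <- function(spec) {
  tr <- spec$truths
  rows <- list()
  for (gi in seq_len(nrow(tr))) {
    g <- tr[gi, ]
    for (i in seq_len(spec$n_per_group)) {
      if (spec$jitter) {
        v_tca <- rlnorm_cv(1, g$v_tca, g$cv_v_tca)
        f_lab <- clip(rlnorm_cv(1, g$f_acetyl_labeled, g$cv_f_acetyl), 0.005, 0.95)
        y_pc <- rlnorm_cv(1, g$y_pc, g$cv_y_pc)
        r <- clip(rlnorm_cv(1, g$r_cyc, g$cv_r_cyc), 0.01, 0.99)
        f_med <- clip(1 - stats::rnorm(1, g$glycogen_pct, g$sd_glycogen_pct) / 100,
                      0.02, 0.9)
        mvo2 <- g$mvo2 * (v_tca / g$v_tca) * rlnorm_cv(1, 1, g$cv_mvo2_resid)
        weight <- rlnorm_cv(1, g$liver_weight, g$sd_liver_weight / g$liver_weight)
      } else {
        v_tca <- g$v_tca; f_lab <- g$f_acetyl_labeled; y_pc <- g$y_pc
        r <- g$r_cyc; f_med <- g$f_pyr_medium; mvo2 <- g$mvo2
        weight <- g$liver_weight
      }
      rows[[length(rows) + 1]] <- data.frame(
        liver_id = sprintf("%s_%d", g$group, i), group = g$group,
        diet = g$diet, genotype = g$genotype,
        f_acetyl_labeled = f_lab, f_pyr_medium = f_med,
        y_pc = y_pc, y_pyc = r * y_pc, v_tca = v_tca, mvo2 = mvo2,
        v_pdh = f_lab * v_tca, v_pc = y_pc * v_tca, v_pyc = r * y_pc * v_tca,
        liver_weight = weight
      )
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic multiplet dataset
#'
#' Forward-predicts glutamate C2/C3/C4 and lactate C2 multiplet fractions
#' per liver from the per-liver truth fluxes, adds Gaussian measurement
#' noise, clips to \[0, 1\] and renormalizes each carbon. Deterministic under
#' a fixed seed.
#'
#' @param spec a `cohort_spec`
#' @param network network model
#' @return list with `table` (the multiplet table: `liver_id`, `group`,
#'   `carbon`, `component`, `fraction`, `sd`) and `truth` (per-liver ground
#'   truth record)
#' @export
generate_multiplet_dataset <- function(spec, network = build_liver_network()) {
  withr::with_seed(spec$seed + 11L, {
    truth <- draw_liver_truths(spec)
    tab <- list()
    for (i in seq_len(nrow(truth))) {
      fl <- relative_fluxes(f_acetyl_labeled = truth$f_acetyl_labeled[i],
                            f_pyr_medium = truth$f_pyr_medium[i],
                            y_pc = truth$y_pc[i], y_pyc = truth$y_pyc[i],
                            dilution_mode = "acetyl")
      pred <- predict_multiplets(fl, network)
      for (cb in names(pred)) {
        fr <- pred[[cb]]
        if (spec$noise_sd > 0) {
          fr <- fr + stats::rnorm(length(fr), 0, spec$noise_sd)
          fr <- clip(fr, 0, 1)
          fr <- fr / sum(fr)
        }
        tab[[length(tab) + 1]] <- data.frame(
          liver_id = truth$liver_id[i], group = truth$group[i],
          carbon = cb, component = names(fr), fraction = unname(fr),
          sd = max(spec$noise_sd, 0.005))
      }
    }
    list(table = do.call(rbind, tab), truth = truth)
  })
}

#' Generate synthetic perfusion records
#'
#' Draws per-liver oxygen consumption around the group means (tied to the
#' same liver-level V_TCA factor as the multiplet truths when a truth table
#' is supplied) and inverts the MVO2 formula into afferent/efferent pO2 at a
#' weight-proportional perfusate flow, so that [oxygen_consumption()]
#' recovers the generated values exactly.
#'
#' @param spec a `cohort_spec`
#' @param truth optional per-liver truth table from
#'   [generate_multiplet_dataset()]; if omitted, a fresh one is drawn
#' @param pO2_afferent afferent oxygen tension (mmHg, 95% O2 equilibration)
#' @param o2_solubility umol/mL/mmHg
#' @param flow_per_g perfusate flow per gram of liver (mL/min/g)
#' @return data frame of perfusion records plus the generated `mvo2`
#' @export
generate_perfusion_records <- function(spec, truth = NULL, pO2_afferent = 600,
                                       o2_solubility = 0.00135,
                                       flow_per_g = 16 / 3) {
  if (is.null(truth)) {
    truth <- withr::with_seed(spec$seed + 22L, draw_liver_truths(spec))
  }
  flow <- flow_per_g * truth$liver_weight
  dpo2 <- truth$mvo2 * truth$liver_weight / (o2_solubility * flow)
  if (any(dpo2 >= pO2_afferent)) stop("oxygen demand exceeds afferent supply")
  data.frame(liver_id = truth$liver_id, group = truth$group,
             pO2_afferent = pO2_afferent, pO2_efferent = pO2_afferent - dpo2,
             flow = flow, liver_weight = truth$liver_weight,
             o2_solubility = o2_solubility, mvo2 = truth$mvo2)
}

# Per-group hyperpolarized exchange rates (1/s). The bicarbonate rate scales
# with the group's PDH flux; lactate exchange is faster in the fat-loaded
# (DIO) livers as a redox proxy; alanine follows the observed lean/DIO
# crossover; the malate C1 -> C4 scrambling is slow so C1 stays above C4.
hp_group_rates <- function() {
  tr <- group_flux_truths()
  data.frame(
    group = tr$group,
    k_pyr_bic = 0.004 * tr$v_pdh / 0.20,
    k_pyr_lac = c(0.020, 0.019, 0.032, 0.027),
    k_pyr_ala = c(0.012, 0.008, 0.008, 0.012),
    k_pyr_mal1 = c(0.0012, 0.0016, 0.0012, 0.0016),
    k_pyr_asp1 = 0.0008,
    k_mal1_mal4 = 0.02,
    k_asp1_asp4 = 0.02
  )
}

#' Generate a synthetic hyperpolarized dataset
#'
#' One simulated [1-13C]pyruvate time series per liver under the default
#' acquisition scheme (50 spectra, 2 s apart, 20-degree pulses), with
#' group-specific exchange rates (see `hepflux:::hp_group_rates`) and
#' per-liver lognormal rate variation (CV 0.10).
#'
#' @param spec a `cohort_spec`
#' @param scheme acquisition scheme
#' @param rate_cv per-liver lognormal CV on each rate (0 when
#'   `spec$jitter` is `FALSE`)
#' @return list with `series` (named list of `hp_timeseries`) and `truth`
#'   (per-liver rates)
#' @export
generate_hp_dataset <- function(spec, scheme = acquisition_scheme(),
                                rate_cv = 0.10) {
  rates <- hp_group_rates()
  rates <- rates[rates$group %in% spec$groups, ]
  if (!spec$jitter) rate_cv <- 0
  withr::with_seed(spec$seed + 33L, {
    series <- list()
    truth <- list()
    rate_names <- setdiff(names(rates), "group")
    for (gi in seq_len(nrow(rates))) {
      for (i in seq_len(spec$n_per_group)) {
        id <- sprintf("%s_%d", rates$group[gi], i)
        kv <- vapply(rate_names, function(rn) {
          rlnorm_cv(1, rates[[rn]][gi], rate_cv)
        }, numeric(1))
        model <- exchange_model(
          k_pyr_lac = kv[["k_pyr_lac"]], k_pyr_ala = kv[["k_pyr_ala"]],
          k_pyr_bic = kv[["k_pyr_bic"]], k_pyr_mal1 = kv[["k_pyr_mal1"]],
          k_pyr_asp1 = kv[["k_pyr_asp1"]], k_mal1_mal4 = kv[["k_mal1_mal4"]],
          k_asp1_asp4 = kv[["k_asp1_asp4"]],
          bolus = list(dose = 1, duration = 5, hydrate_fraction = 0.08))
        series[[id]] <- simulate_hp_timeseries(
          model, scheme, noise_sd = spec$hp_noise_sd,
          seed = spec$seed + 33L + 101L * (gi * spec$n_per_group + i))
        truth[[id]] <- data.frame(liver_id = id, group = rates$group[gi],
                                  t(kv))
      }
    }
    list(series = series, truth = do.call(rbind, truth))
  })
}

#' Named isotopomer fixtures from the labeling scheme
#'
#' The exact species traced through the network diagrams: the PDH product,
#' the first- and second-turn glutamate isotopomers, the two PC-derived OAA
#' isotopomers and the lactate species returned by pyruvate cycling after
#' zero, one and two TCA turns. Used as oracles in tests.
#'
#' @return named list of `iso_dist`
#' @export
fixture_paper_patterns <- function() {
  list(
    "[1,2-13C2]acetyl-CoA" = iso_species(2, c(1, 2), "acetyl_coa"),
    "[4,5-13C2]glutamate" = iso_species(5, c(4, 5), "glutamate"),
    "[3,4,5-13C3]glutamate" = iso_species(5, c(3, 4, 5), "glutamate"),
    "[1,2,4,5-13C4]glutamate" = iso_species(5, c(1, 2, 4, 5), "glutamate"),
    "[1,2,3-13C3]OAA" = iso_species(4, c(1, 2, 3), "oaa"),
    "[2,3,4-13C3]OAA" = iso_species(4, c(2, 3, 4), "oaa"),
    "[2,3-13C2]lactate" = iso_species(3, c(2, 3), "lactate"),
    "[1,2-13C2]lactate" = iso_species(3, c(1, 2), "lactate"),
    "[3-13C]lactate" = iso_species(3, 3, "lactate"),
    "[1-13C]lactate" = iso_species(3, 1, "lactate"),
    "[2-13C]lactate" = iso_species(3, 2, "lactate"),
    "[U-13C]pyruvate" = iso_species(3, c(1, 2, 3), "pyruvate")
  )
}
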