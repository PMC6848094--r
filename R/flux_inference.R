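#' Forward-predict NMR multiplet fractions from relative fluxes
#'
#' Solves the steady-state isotopomer balance and reads off the multiplet
#' fractions of the observed carbons (glutamate C2/C3/C4 and lactate C2).
#'
#' @param fluxes a `relative_fluxes` object
#' @param network network model, default [build_liver_network()]
#' @param carbons observed carbons to report
#' @param tol solver tolerance
#' @param init optional solver warm start
#' @return named list of component vectors (class `multiplet_prediction`)
#'   with attributes `enrichment` (positional enrichment of each observed
#'   carbon) and `f_acetyl_labeled_effective`
#' @export
predict_multiplets <- function(fluxes, network = build_liver_network(),
                               carbons = c("glu_C2", "glu_C3", "glu_C4", "lac_C2"),
                               tol = 1e-10, init = NULL) {
  ss <- solve_steady_state(network, fluxes, tol = tol, init = init)
  reg <- observed_carbon_registry()
  out <- list()
  enr <- numeric(0)
  for (cb in carbons) {
    dist <- if (startsWith(cb, "glu")) ss$glutamate else ss$lactate
    enr[cb] <- positional_enrichment(dist, reg[[cb]]$obs)
    out[[cb]] <- if (enr[cb] > 1e-12) multiplet_fractions(dist, cb) else NULL
  }
  attr(out, "enrichment") <- enr
  attr(out, "f_acetyl_labeled_effective") <-
    attr(ss, "f_acetyl_labeled_effective")
  attr(out, "steady_state") <- ss
  class(out) <- "multiplet_prediction"
  out
}

# flatten a prediction into the (carbon, component) rows of a table
flatten_prediction <- function(pred, rows) {
  vapply(seq_len(nrow(rows)), function(i) {
    comp <- pred[[rows$carbon[i]]]
    if (is.null(comp)) return(NA_real_)
    unname(comp[rows$component[i]])
  }, numeric(1))
}

#' Fit relative fluxes to a measured multiplet table
#'
#' SD-weighted nonlinear least squares between predicted and measured
#' multiplet fractions for one liver, minimized by bounded
#' Levenberg-Marquardt with seeded multi-starts. Pyruvate cycling is
#' parameterized as `y_pyc = r_cyc * y_pc` with `r_cyc` in \[0, 1\] so the
#' steady-state constraint `y_pyc <= y_pc` is honored by box bounds.
#'
#' @param data data frame with columns `carbon`, `component`, `fraction`,
#'   `sd` for a single liver (extra columns ignored)
#' @param dilution_mode `"acetyl"` (default) or `"pyruvate"`; decides whether
#'   the free enrichment parameter is `f_acetyl_labeled` or
#'   `f_acetyl_unlabeled_fat`
#' @param carbons observed carbons entering the objective; default all
#'   carbons present in `data`
#' @param n_starts number of seeded multi-start points (default 20)
#' @param seed RNG seed for the start points
#' @param fit_scramble if `TRUE`, the fumarase scrambling extent is a fifth
#'   free parameter; otherwise it is fixed at `scramble`
#' @param scramble fixed scrambling extent when not fitted
#' @param fixed named list of parameters to freeze at given values
#'   (e.g. `list(y_pc = 0)` for a nested-model comparison)
#' @param sd_floor lower bound on measurement SDs used in the weights
#' @param bounds named list overriding default box bounds
#' @param network network model
#' @return a `fit_result`: fluxes (point estimates as `relative_fluxes`),
#'   `residual` (weighted SSQ), `stderr`, `n_starts_converged`,
#'   `f_pdh_frac` (effective [1,2-13C2] acetyl fraction)
#' @export
fit_relative_fluxes <- function(data,
                                dilution_mode = c("acetyl", "pyruvate"),
                                carbons = NULL,
                                n_starts = 20, seed = 1,
                                fit_scramble = FALSE, scramble = 1,
                                fixed = list(),
                                sd_floor = 0.005,
                                bounds = list(),
                                network = build_liver_network()) {
  dilution_mode <- match.arg(dilution_mode)
  if (!all(c("carbon", "component", "fraction") %in% names(data))) {
    schema_error("multiplet data needs columns carbon, component, fraction")
  }
  if (is.null(data$sd)) data$sd <- sd_floor
  carbons <- carbons %||% intersect(names(observed_carbon_registry()),
                                    unique(data$carbon))
  rows <- data[data$carbon %in% carbons, c("carbon", "component", "fraction", "sd")]
  if (nrow(rows) == 0) schema_error("no usable multiplet rows for the requested carbons")
  w <- 1 / pmax(rows$sd, sd_floor)

  enr_name <- if (dilution_mode == "acetyl") "f_acetyl_labeled" else "f_acetyl_unlabeled_fat"
  par_lo <- c(1e-3, 1e-3, 0, 0)
  par_hi <- c(1, 1, 5, 1)
  names(par_lo) <- names(par_hi) <- c(enr_name, "f_pyr_medium", "y_pc", "r_cyc")
  if (fit_scramble) {
    par_lo <- c(par_lo, scramble = 0)
    par_hi <- c(par_hi, scramble = 1)
  }
  for (nm in names(bounds)) {
    par_lo[nm] <- bounds[[nm]][1]
    par_hi[nm] <- bounds[[nm]][2]
  }
  fixed <- unlist(fixed)
  free_names <- setdiff(names(par_lo), names(fixed))
  if (nrow(rows) < length(free_names)) {
    schema_error("fewer multiplet components than free parameters")
  }

  warm <- new.env(parent = emptyenv())
  make_fluxes <- function(par) {
    p <- c(par, fixed)
    args <- list(f_pyr_medium = unname(p["f_pyr_medium"]),
                 y_pc = unname(p["y_pc"]),
                 y_pyc = unname(p["r_cyc"] * p["y_pc"]),
                 scramble = if ("scramble" %in% names(p))
                   unname(p[["scramble"]]) else scramble,
                 dilution_mode = dilution_mode)
    args[[enr_name]] <- unname(p[enr_name])
    do.call(relative_fluxes, args)
  }
  resid_fn <- function(par) {
    names(par) <- free_names
    fl <- make_fluxes(par)
    pred <- predict_multiplets(fl, network, carbons = carbons,
                               tol = 1e-10, init = warm$ss)
    warm$ss <- lapply(attr(pred, "steady_state"), function(d) d$fractions)
    ph <- flatten_prediction(pred, rows)
    ph[is.na(ph)] <- 0
    w * (ph - rows$fraction)
  }

  default_start <- c(0.5, 0.25, 2, 0.5, if (fit_scramble) 0.8)
  names(default_start) <- names(par_lo)
  starts <- list(default_start[free_names])
  if (n_starts > 1) {
    extra <- withr::with_seed(seed, {
      lapply(seq_len(n_starts - 1), function(i) {
        stats::setNames(stats::runif(length(free_names),
                                     par_lo[free_names], par_hi[free_names]),
                        free_names)
      })
    })
    starts <- c(starts, extra)
  }

  fits <- lapply(starts, function(p0) {
    tryCatch(
      minpack.lm::nls.lm(par = p0, lower = par_lo[free_names],
                         upper = par_hi[free_names], fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ptol = 1e-10, ftol = 1e-10)),
      error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("all optimization starts failed")
  ssq <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  ypyc <- vapply(fits, function(f) {
    p <- c(f$par, fixed)
    unname(p["r_cyc"] * p["y_pc"])
  }, numeric(1))
  # best residual; ties (within 1e-8) broken toward the smaller y_pyc
  ord <- order(round(ssq - min(ssq), 8) > 1e-8, ssq, ypyc)
  best <- fits[[ord[1]]]
  best_ssq <- sum(best$fvec^2)
  n_conv <- sum(ssq <= best_ssq + 1e-6)

  par <- best$par
  names(par) <- free_names
  fl <- make_fluxes(par)
  pred <- predict_multiplets(fl, network, carbons = carbons)
  stderr <- rep(NA_real_, length(free_names))
  names(stderr) <- free_names
  dof <- nrow(rows) - length(free_names)
  if (dof > 0) {
    h <- try(solve(best$hessian) * best_ssq / dof, silent = TRUE)
    if (!inherits(h, "try-error")) stderr <- sqrt(pmax(diag(h), 0))
  }
  structure(list(fluxes = fl, par = par, residual = best_ssq,
                 stderr = stderr, n_starts_converged = n_conv,
                 f_pdh_frac = attr(pred, "f_acetyl_labeled_effective"),
                 prediction = pred, dilution_mode = dilution_mode,
                 carbons = carbons),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Relative-flux fit (", x$dilution_mode, " dilution)\n", sep = "")
  est <- c(x$par, y_pyc = unname(x$fluxes$y_pyc),
           f_pdh_frac = unname(x$f_pdh_frac))
  print(round(est, 4))
  cat("weighted SSQ:", format(x$residual, digits = 4),
      " starts at optimum:", x$n_starts_converged, "\n")
  invisible(x)
}

#' Hepatic oxygen consumption from a perfusion record
#'
#' MVO2 = (afferent pO2 - efferent pO2) x O2 solubility x flow / liver
#' weight, in umol/min per gram wet weight.
#'
#' @param rec list or data frame with fields `pO2_afferent`, `pO2_efferent`
#'   (mmHg), `flow` (mL/min), `liver_weight` (g) and optionally
#'   `o2_solubility` (umol/mL/mmHg, default 0.00135 for saline at 37 C)
#' @return MVO2 in umol/min/gww (vectorized over data-frame rows)
#' @export
oxygen_consumption <- function(rec) {
  sol <- rec$o2_solubility %||% 0.00135
  if (any(rec$flow <= 0) || any(rec$liver_weight <= 0)) {
    stop("flow and liver weight must be positive")
  }
  if (any(rec$pO2_afferent < rec$pO2_efferent) || any(rec$pO2_efferent < 0)) {
    stop("pO2 values must satisfy afferent >= efferent >= 0")
  }
  (rec$pO2_afferent - rec$pO2_efferent) * sol * rec$flow / rec$liver_weight
}

#' TCA cycle flux from oxygen consumption
#'
#' Solves `mvo2 = c_turn * V_TCA + c_pdh * V_PDH + c_fat * V_fat` for V_TCA,
#' with V_PDH and V_fat written as fitted fractions of the acetyl-CoA supply
#' times V_TCA. Default O2 stoichiometry: 2 O2 per TCA turn, 0.5 per
#' PDH-derived acetyl unit and 0.875 per beta-oxidation-derived acetyl unit
#' (palmitate bookkeeping); all three are configurable, not constants.
#'
#' @param mvo2 oxygen consumption (umol/min/gww, > 0)
#' @param fit a `fit_result`, or any list with an `f_pdh_frac` field giving
#'   the pyruvate-derived (labeled) acetyl fraction
#' @param stoich named coefficients `c_turn`, `c_pdh`, `c_fat`
#' @return V_TCA (umol/min/gww)
#' @export
tca_flux_from_mvo2 <- function(mvo2, fit,
                               stoich = c(c_turn = 2, c_pdh = 0.5, c_fat = 0.875)) {
  if (any(mvo2 <= 0)) stop("mvo2 must be positive")
  fp <- if (is.numeric(fit)) fit else fit$f_pdh_frac
  denom <- stoich[["c_turn"]] + stoich[["c_pdh"]] * fp +
    stoich[["c_fat"]] * (1 - fp)
  v <- mvo2 / denom
  if (any(v <= 0)) stop("nonpositive V_TCA solution")
  unname(v)
}

#' Absolute fluxes from a fit and V_TCA
#'
#' Relative flux estimates are scaled into umol/min/gww by multiplying with
#' the citrate-synthase (TCA) flux.
#'
#' @param fit a `fit_result` (or a list with `f_pdh_frac` and a `fluxes`
#'   element carrying `y_pc`, `y_pyc`)
#' @param v_tca TCA cycle flux (umol/min/gww, > 0)
#' @param mvo2 optional oxygen consumption stored alongside
#' @return an `absolute_fluxes` list: `v_tca`, `v_pdh`, `v_pc`, `v_pyc`,
#'   `mvo2`
#' @export
absolute_fluxes <- function(fit, v_tca, mvo2 = NA_real_) {
  if (v_tca <= 0) stop("v_tca must be positive")
  structure(list(v_tca = v_tca,
                 v_pdh = fit$f_pdh_frac * v_tca,
                 v_pc = fit$fluxes$y_pc * v_tca,
                 v_pyc = fit$fluxes$y_pyc * v_tca,
                 mvo2 = mvo2),
            class = "absolute_fluxes")
}

#' Degree of pyruvate cycling
#'
#' `V_PyC / (V_PC + V_PDH)`. Invariant to the V_TCA scale.
#'
#' @param f an `absolute_fluxes` object or any list with `v_pyc`, `v_pc`,
#'   `v_pdh`
#' @export
cycling_degree <- function(f) {
  denom <- f$v_pc + f$v_pdh
  if (denom <= 0) stop("v_pc + v_pdh must be positive")
  f$v_pyc / denom
}

#' Lactate C2 pyruvate-cycling index
#'
#' Ratio of lactate C2 enrichment attributable to pyruvate cycling (the D12
#' and D23 doublets) to total C2 enrichment.
#'
#' @param lac_c2 named fractions with components `S`, `D12`, `D23`, `Q`
#' @export
lactate_cycling_index <- function(lac_c2) {
  tot <- sum(lac_c2[c("S", "D12", "D23", "Q")], na.rm = TRUE)
  if (tot <= 0) stop("all-zero lactate C2 components")
  unname((lac_c2[["D12"]] + lac_c2[["D23"]]) / tot)
}

#' Unlabeled (glycogen) contribution to the lactate/pyruvate pool
#'
#' With the medium as the only labeled carbon source, the fraction of the
#' tissue lactate/pyruvate pool arising from unlabeled glycogenolysis is
#' `1 - lactate_enrichment / medium_enrichment`.
#'
#' @param lactate_enrichment measured fractional 13C enrichment of tissue
#'   lactate (0 < value <= medium_enrichment)
#' @param medium_enrichment enrichment of the medium substrates (default
#'   0.99, commercial [U-13C] purity)
#' @export
partition_unlabeled_sources <- function(lactate_enrichment,
                                        medium_enrichment = 0.99) {
  if (any(lactate_enrichment <= 0) || any(medium_enrichment > 1) ||
      any(lactate_enrichment > medium_enrichment)) {
    stop("need 0 < lactate_enrichment <= medium_enrichment <= 1")
  }
  1 - lactate_enrichment / medium_enrichment
}
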