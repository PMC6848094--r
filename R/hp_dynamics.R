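#' Acquisition scheme for hyperpolarized 13C spectroscopy
#'
#' @param flip_angle excitation flip angle in degrees (0 < angle < 90)
#' @param repetition_time seconds between acquisitions
#' @param n_spectra number of acquisitions
#' @param spectral_points points of the rendered ppm axis
#' @param linewidth_hz full width at half maximum of the Lorentzian lines
#' @param freq_mhz 13C carrier frequency (for Hz -> ppm conversion)
#' @param ppm_range two-element ppm window
#' @export
acquisition_scheme <- function(flip_angle = 20, repetition_time = 2,
                               n_spectra = 50, spectral_points = 16384,
                               linewidth_hz = 1.5, freq_mhz = 100.6,
                               ppm_range = c(155, 190)) {
  stopifnot(flip_angle > 0, flip_angle < 90, n_spectra >= 1,
            repetition_time > 0)
  structure(list(flip_angle = flip_angle, repetition_time = repetition_time,
                 n_spectra = n_spectra, spectral_points = spectral_points,
                 linewidth_hz = linewidth_hz, freq_mhz = freq_mhz,
                 ppm_range = ppm_range),
            class = "acquisition_scheme")
}

#' First-order exchange model for hyperpolarized [1-13C]pyruvate
#'
#' Chemical shifts default to the product resonances observed in perfused
#' liver (bicarbonate 160.9, aspartate C1 175.3, alanine C1 176.5,
#' aspartate C4 178.3, malate C4 180.3, malate C1 181.5, lactate C1 183.1
#' ppm); pyruvate (171.0) and pyruvate-hydrate (179.5) are literature
#' conventions. Exchange is unidirectional (pyruvate to products) on the
#' hyperpolarized timescale; malate C1 -> malate C4 and aspartate C1 ->
#' aspartate C4 model the slow fumarase scrambling of the C1 label into C4.
#'
#' @param k_pyr_lac,k_pyr_ala,k_pyr_bic,k_pyr_mal1,k_pyr_asp1 first-order
#'   conversion rates out of pyruvate (1/s)
#' @param k_mal1_mal4,k_asp1_asp4 scrambling rates (1/s)
#' @param t1 per-metabolite longitudinal relaxation times (s); a scalar is
#'   recycled (default 30 s, typical of carboxyl carbons)
#' @param shifts named chemical shifts (ppm), overriding the defaults
#' @param bolus list with `dose` (arbitrary magnetization units),
#'   `duration` (s of linear-ramp inflow; 0 = instantaneous bolus) and
#'   `hydrate_fraction` (impurity fraction of the dose arriving as
#'   pyruvate-hydrate)
#' @export
exchange_model <- function(k_pyr_lac = 0, k_pyr_ala = 0, k_pyr_bic = 0,
                           k_pyr_mal1 = 0, k_pyr_asp1 = 0,
                           k_mal1_mal4 = 0, k_asp1_asp4 = 0,
                           t1 = 30, shifts = NULL,
                           bolus = list(dose = 1, duration = 5,
                                        hydrate_fraction = 0)) {
  mets <- c("pyruvate", "pyruvate_hydrate", "bicarbonate", "aspartate_C1",
            "alanine", "aspartate_C4", "malate_C4", "malate_C1", "lactate")
  def_shifts <- c(pyruvate = 171.0, pyruvate_hydrate = 179.5,
                  bicarbonate = 160.9, aspartate_C1 = 175.3, alanine = 176.5,
                  aspartate_C4 = 178.3, malate_C4 = 180.3, malate_C1 = 181.5,
                  lactate = 183.1)
  if (!is.null(shifts)) def_shifts[names(shifts)] <- shifts
  rates <- c(k_pyr_lac = k_pyr_lac, k_pyr_ala = k_pyr_ala,
             k_pyr_bic = k_pyr_bic, k_pyr_mal1 = k_pyr_mal1,
             k_pyr_asp1 = k_pyr_asp1, k_mal1_mal4 = k_mal1_mal4,
             k_asp1_asp4 = k_asp1_asp4)
  if (any(rates < 0)) stop("conversion rates must be non-negative")
  t1 <- if (length(t1) == 1) stats::setNames(rep(t1, length(mets)), mets) else t1
  if (any(t1 <= 0)) stop("T1 values must be positive")
  bolus$dose <- bolus$dose %||% 1
  bolus$duration <- bolus$duration %||% 5
  bolus$hydrate_fraction <- bolus$hydrate_fraction %||% 0
  structure(list(metabolites = mets, shifts = def_shifts, rates = rates,
                 t1 = t1, bolus = bolus),
            class = "exchange_model")
}

# rate matrix A: dM/dt = A M (T1 loss on the diagonal, unidirectional flows)
exchange_rate_matrix <- function(model) {
  mets <- model$metabolites
  A <- matrix(0, length(mets), length(mets), dimnames = list(mets, mets))
  edges <- list(c("pyruvate", "lactate", "k_pyr_lac"),
                c("pyruvate", "alanine", "k_pyr_ala"),
                c("pyruvate", "bicarbonate", "k_pyr_bic"),
                c("pyruvate", "malate_C1", "k_pyr_mal1"),
                c("pyruvate", "aspartate_C1", "k_pyr_asp1"),
                c("malate_C1", "malate_C4", "k_mal1_mal4"),
                c("aspartate_C1", "aspartate_C4", "k_asp1_asp4"))
  for (e in edges) {
    k <- model$rates[[e[3]]]
    A[e[2], e[1]] <- A[e[2], e[1]] + k
    A[e[1], e[1]] <- A[e[1], e[1]] - k
  }
  diag(A) <- diag(A) - 1 / model$t1[mets]
  A
}

#' Simulate a hyperpolarized 13C time series
#'
#' Longitudinal magnetizations evolve by unidirectional first-order exchange
#' with T1 loss between pulses; each excitation reads out
#' `sin(flip) * M` and depletes the stores by `cos(flip)`. Spectra are
#' rendered as Lorentzian lines at the metabolite shifts with seeded
#' Gaussian noise.
#'
#' @param model an `exchange_model`
#' @param scheme an `acquisition_scheme`
#' @param noise_sd per-point Gaussian noise SD added to the spectra
#' @param seed RNG seed for the noise
#' @param render_spectra if `FALSE`, only peak-area time courses are stored
#' @return an `hp_timeseries`: `time` (s), `areas` (acquisition x
#'   metabolite), `spectra`, `ppm`, plus the scheme and model
#' @export
simulate_hp_timeseries <- function(model, scheme = acquisition_scheme(),
                                   noise_sd = 0, seed = NULL,
                                   render_spectra = TRUE) {
  mets <- model$metabolites
  A <- exchange_rate_matrix(model)
  TR <- scheme$repetition_time
  flip <- scheme$flip_angle * pi / 180
  n <- scheme$n_spectra
  E_TR <- as.matrix(Matrix::expm(A * TR))

  dose <- model$bolus$dose
  hf <- model$bolus$hydrate_fraction
  dur <- model$bolus$duration
  inflow <- stats::setNames(numeric(length(mets)), mets)
  inflow["pyruvate"] <- 1 - hf
  inflow["pyruvate_hydrate"] <- hf

  M <- stats::setNames(numeric(length(mets)), mets)
  if (dur <= 0) M <- M + dose * inflow

  dt <- 0.02
  E_dt <- if (dur > 0) as.matrix(Matrix::expm(A * dt)) else NULL
  ramp_rate <- function(t) {           # linear ramp peaking at `dur`, total = dose
    if (t < 0 || t >= dur) 0 else 2 * dose * t / dur^2
  }

  time <- (seq_len(n) - 1) * TR
  areas <- matrix(0, n, length(mets), dimnames = list(NULL, mets))
  for (i in seq_len(n)) {
    areas[i, ] <- sin(flip) * M
    M <- cos(flip) * M
    t0 <- time[i]
    if (t0 < dur) {
      steps <- round(TR / dt)
      for (s in seq_len(steps)) {
        tm <- t0 + (s - 0.5) * dt
        M <- drop(E_dt %*% M) + ramp_rate(tm) * dt * inflow
      }
      names(M) <- mets
    } else {
      M <- drop(E_TR %*% M)
      names(M) <- mets
    }
  }

  spectra <- NULL
  ppm <- NULL
  if (render_spectra) {
    ppm <- seq(scheme$ppm_range[1], scheme$ppm_range[2],
               length.out = scheme$spectral_points)
    hw <- (scheme$linewidth_hz / 2) / scheme$freq_mhz   # half width, ppm
    basis <- vapply(mets, function(m) {
      (hw / pi) / ((ppm - model$shifts[[m]])^2 + hw^2)
    }, numeric(length(ppm)))
    spectra <- areas %*% t(basis)
    if (noise_sd > 0) {
      noise <- withr::with_seed(seed %||% 1, {
        matrix(stats::rnorm(length(spectra), 0, noise_sd), nrow = n)
      })
      spectra <- spectra + noise
    }
  }
  structure(list(time = time, areas = areas, spectra = spectra, ppm = ppm,
                 scheme = scheme, model = model),
            class = "hp_timeseries")
}

#' Sum spectra across acquisitions
#'
#' Pointwise sum of all acquired spectra, as used to display and quantify
#' the experiment (e.g. 50 free-induction decays summed over 100 s).
#'
#' @param series an `hp_timeseries` with rendered spectra, or a matrix of
#'   spectra (acquisitions in rows)
#' @param ppm ppm axis when `series` is a bare matrix
#' @return data frame with columns `ppm`, `intensity`
#' @export
sum_spectra <- function(series, ppm = NULL) {
  if (inherits(series, "hp_timeseries")) {
    if (is.null(series$spectra)) stop("series has no rendered spectra")
    ppm <- series$ppm
    series <- series$spectra
  }
  if (is.null(dim(series))) series <- matrix(series, nrow = 1)
  data.frame(ppm = ppm, intensity = colSums(series))
}

#' Default integration windows for the liver HP resonances
#'
#' +/- 0.5 ppm around each assigned shift; the aspartate C4, malate C4 and
#' pyruvate-hydrate windows are narrowed to +/- 0.4 ppm to keep neighboring
#' windows disjoint.
#'
#' @param model an `exchange_model`
#' @param half_width default window half width (ppm)
#' @param narrow named overrides of the half width
#' @export
default_peak_windows <- function(model, half_width = 0.5,
                                 narrow = c(aspartate_C4 = 0.4,
                                            malate_C4 = 0.4,
                                            pyruvate_hydrate = 0.4)) {
  hw <- stats::setNames(rep(half_width, length(model$metabolites)),
                        model$metabolites)
  hw[names(narrow)] <- narrow
  out <- lapply(model$metabolites, function(m) {
    model$shifts[[m]] + c(-1, 1) * hw[[m]]
  })
  stats::setNames(out, model$metabolites)
}

#' Integrate peak areas from a spectrum
#'
#' Trapezoidal integration of the spectrum within each (non-overlapping)
#' window.
#'
#' @param spectrum data frame with columns `ppm`, `intensity`
#' @param windows named list of `c(low, high)` ppm windows
#' @return named numeric vector of areas
#' @export
integrate_peaks <- function(spectrum, windows) {
  wm <- do.call(rbind, windows)
  ord <- order(wm[, 1])
  if (any(wm[ord, 1][-1] < wm[ord, 2][-length(ord)] - 1e-12)) {
    stop("integration windows overlap")
  }
  vapply(windows, function(w) {
    sel <- spectrum$ppm >= w[1] & spectrum$ppm <= w[2]
    if (sum(sel) < 2) return(0)
    pracma::trapz(spectrum$ppm[sel], spectrum$intensity[sel])
  }, numeric(1))
}

#' Normalized metabolite fractions and bicarbonate/lactate ratio
#'
#' Areas are normalized to the total of all 13C signals, excluding
#' pyruvate-hydrate, which is an impurity of the polarized preparation.
#'
#' @param areas named numeric vector of peak areas
#' @param exclude metabolites excluded from the total (default the hydrate)
#' @return list with `fractions` (summing to 1) and
#'   `bicarbonate_lactate_ratio`
#' @export
normalize_fractions <- function(areas, exclude = "pyruvate_hydrate") {
  keep <- setdiff(names(areas), exclude)
  tot <- sum(areas[keep])
  if (tot <= 0) stop("total non-hydrate area must be positive")
  fr <- areas[keep] / tot
  list(fractions = fr,
       bicarbonate_lactate_ratio =
         unname(areas[["bicarbonate"]] / areas[["lactate"]]))
}
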