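test_that("forward prediction hits the limiting multiplet patterns", {
  pm <- predict_multiplets(relative_fluxes(f_acetyl_labeled = 1,
                                           f_pyr_medium = 1,
                                           medium_enrichment = 1))
  expect_equal(pm$glu_C4[["Q"]], 1, tolerance = 1e-9)
  # without cycling, tissue lactate is just medium [U-13C]: pure quartet
  pm0 <- predict_multiplets(relative_fluxes(f_acetyl_labeled = 0.6,
                                            f_pyr_medium = 0.3, y_pc = 2,
                                            y_pyc = 0))
  expect_equal(pm0$lac_C2[["Q"]], 1, tolerance = 1e-9)
  # cycling puts label back as D12/D23 doublets
  pm1 <- predict_multiplets(relative_fluxes(f_acetyl_labeled = 0.6,
                                            f_pyr_medium = 0.3, y_pc = 2,
                                            y_pyc = 1.5))
  expect_gt(pm1$lac_C2[["D12"]], 0.01)
  expect_gt(pm1$lac_C2[["D23"]], 0.01)
})

test_that("noiseless fits recover the generating fluxes (round trip)", {
  truth <- relative_fluxes(f_acetyl_labeled = 0.6, f_pyr_medium = 0.2,
                           y_pc = 2.8, y_pyc = 1.9)
  tab <- prediction_table(truth)
  fit <- fit_relative_fluxes(tab, n_starts = 8, seed = 1)
  expect_equal(fit$par[["f_acetyl_labeled"]], 0.6, tolerance = 1e-4)
  expect_equal(fit$par[["f_pyr_medium"]], 0.2, tolerance = 1e-4)
  expect_equal(fit$fluxes$y_pc, 2.8, tolerance = 1e-4)
  expect_equal(fit$fluxes$y_pyc, 1.9, tolerance = 1e-4)
  expect_lt(fit$residual, 1e-8)
  expect_gt(fit$n_starts_converged, 1)
  # local optimality: perturbing any parameter raises the residual
  obj <- function(f, fm, ypc, ypyc) {
    pred <- predict_multiplets(relative_fluxes(
      f_acetyl_labeled = f, f_pyr_medium = fm, y_pc = ypc, y_pyc = ypyc))
    ph <- unlist(pred[unique(tab$carbon)])
    sum(((ph - tab$fraction) / tab$sd)^2)
  }
  base <- obj(0.6, 0.2, 2.8, 1.9)
  expect_lt(base, obj(0.65, 0.2, 2.8, 1.9))
  expect_lt(base, obj(0.6, 0.25, 2.8, 1.9))
  expect_lt(base, obj(0.6, 0.2, 3.1, 1.9))
  expect_lt(base, obj(0.6, 0.2, 2.8, 1.6))
})

test_that("freezing anaplerosis at zero worsens the fit to cycling data", {
  truth <- relative_fluxes(f_acetyl_labeled = 0.6, f_pyr_medium = 0.2,
                           y_pc = 2.8, y_pyc = 1.9)
  tab <- prediction_table(truth)
  free <- fit_relative_fluxes(tab, n_starts = 4, seed = 2)
  frozen <- fit_relative_fluxes(tab, n_starts = 4, seed = 2,
                                fixed = list(y_pc = 0))
  expect_gt(frozen$residual, free$residual + 1)
})

test_that("oxygen consumption follows the Fick arithmetic", {
  rec <- list(pO2_afferent = 500, pO2_efferent = 200, flow = 8,
              liver_weight = 1.5, o2_solubility = 0.00135)
  expect_equal(oxygen_consumption(rec), 2.16, tolerance = 1e-12)
  rec2 <- rec; rec2$liver_weight <- 3
  expect_equal(oxygen_consumption(rec2), 1.08, tolerance = 1e-12)
  rec3 <- rec; rec3$pO2_efferent <- rec3$pO2_afferent
  expect_equal(oxygen_consumption(rec3), 0)
  expect_error(oxygen_consumption(list(pO2_afferent = 100, pO2_efferent = 200,
                                       flow = 8, liver_weight = 1)))
  expect_error(oxygen_consumption(list(pO2_afferent = 300, pO2_efferent = 200,
                                       flow = -1, liver_weight = 1)))
})

test_that("V_TCA scaling from MVO2 matches the closed forms", {
  fit <- list(f_pdh_frac = 1)  # all-carbohydrate limit
  expect_equal(tca_flux_from_mvo2(2.5, fit), 2.5 / 2.5, tolerance = 1e-12)
  expect_equal(tca_flux_from_mvo2(1.7, fit,
                                  stoich = c(c_turn = 1, c_pdh = 0, c_fat = 0)),
               1.7)
  # lean-control-like supply: consistent with the printed V_TCA within 15%
  v <- tca_flux_from_mvo2(1.16, list(f_pdh_frac = 0.20 / 0.41))
  expect_lt(abs(v - 0.41) / 0.41, 0.15)
})

test_that("absolute fluxes scale linearly with V_TCA", {
  fit <- list(f_pdh_frac = 0.49,
              fluxes = list(y_pc = 1.0, y_pyc = 0.6))
  af <- absolute_fluxes(fit, 0.41)
  expect_equal(af$v_pc, 0.41)
  expect_equal(af$v_pyc, 0.6 * 0.41)
  fit0 <- list(f_pdh_frac = 0, fluxes = list(y_pc = 0, y_pyc = 0))
  af0 <- absolute_fluxes(fit0, 1)
  expect_equal(af0$v_pdh + af0$v_pc + af0$v_pyc, 0)
  # cycling degree is a ratio of relative fluxes: invariant to the scale
  fit2 <- list(f_pdh_frac = 0.49, fluxes = list(y_pc = 2.78, y_pyc = 1.85))
  expect_equal(cycling_degree(absolute_fluxes(fit2, 0.41)),
               cycling_degree(absolute_fluxes(fit2, 4.1)),
               tolerance = 1e-12)
  expect_equal(cycling_degree(list(v_pyc = 0, v_pc = 1, v_pdh = 1)), 0)
  expect_error(cycling_degree(list(v_pyc = 1, v_pc = 0, v_pdh = 0)))
})

test_that("lactate cycling index is the doublet share and grows with y_pyc", {
  expect_equal(lactate_cycling_index(c(S = 0.2, D12 = 0.1, D23 = 0.2, Q = 0.5)),
               0.3, tolerance = 1e-12)
  expect_equal(lactate_cycling_index(c(S = 0, D12 = 0, D23 = 0, Q = 1)), 0)
  expect_error(lactate_cycling_index(c(S = 0, D12 = 0, D23 = 0, Q = 0)))
  idx <- vapply(c(0.3, 0.9, 1.5, 2.1), function(ypyc) {
    pm <- predict_multiplets(relative_fluxes(f_acetyl_labeled = 0.5,
                                             f_pyr_medium = 0.2,
                                             y_pc = 2.8, y_pyc = ypyc))
    lactate_cycling_index(pm$lac_C2)
  }, numeric(1))
  expect_true(all(diff(idx) > 0))
})

test_that("unlabeled-source partition inverts the enrichment dilution", {
  expect_equal(partition_unlabeled_sources(0.9, 0.9), 0)
  expect_equal(partition_unlabeled_sources(0.45, 0.9), 0.5)
  expect_error(partition_unlabeled_sources(0.95, 0.9))
  # model round trip with cycling off: 75% glycogen-derived pyruvate
  fl <- relative_fluxes(f_acetyl_labeled = 0.5, f_pyr_medium = 0.25, y_pc = 2,
                        y_pyc = 0)
  ss <- solve_steady_state(build_liver_network(), fl)
  enr <- positional_enrichment(ss$lactate, 2)
  expect_equal(partition_unlabeled_sources(enr, 0.99), 0.75, tolerance = 1e-9)
})
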