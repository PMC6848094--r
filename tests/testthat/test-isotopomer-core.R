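net <- build_liver_network()
fx <- fixture_paper_patterns()

test_that("carbon maps reproduce the canonical labeling products", {
  upyr <- fx[["[U-13C]pyruvate"]]
  # PDH decarboxylation of [U-13C]pyruvate -> [1,2-13C2]acetyl-CoA
  expect_dist_equal(apply_atom_map(upyr, net$maps$pdh),
                    fx[["[1,2-13C2]acetyl-CoA"]])
  # PC carboxylation with unlabeled CO2 -> [1,2,3-13C3]OAA
  oaa <- apply_atom_map(upyr, net$maps$pc)
  expect_dist_equal(oaa, fx[["[1,2,3-13C3]OAA"]])
  # complete fumarase symmetrization -> equal parts [1,2,3] and [2,3,4]
  expect_dist_equal(iso_mix(list(oaa, reverse_carbons(oaa)), c(0.5, 0.5)),
                    iso_mix(fx[c("[1,2,3-13C3]OAA", "[2,3,4-13C3]OAA")],
                            c(0.5, 0.5)))
  # decarboxylation of [2,3,4-13C3]OAA regenerates [2,3-13C2]pyruvate/lactate
  pyr <- apply_atom_map(fx[["[2,3,4-13C3]OAA"]], net$maps$pyruvate_cycling)
  expect_dist_equal(apply_atom_map(pyr, net$maps$ldh),
                    fx[["[2,3-13C2]lactate"]])
  # [4,5-13C2]aKG through KGDH/succinate -> equal [1,2] and [3,4] OAA
  o <- apply_atom_map(iso_species(5, c(4, 5)), net$maps$akgdh_succinate)
  expect_equal(o$fractions[[4]], 0.5)   # bits 1,2 -> [1,2-13C2]
  expect_equal(o$fractions[[13]], 0.5)  # bits 3,4 -> [3,4-13C2]
})

test_that("atom-map application mixes pools independently and conserves label", {
  # all-unlabeled sources give an all-unlabeled product
  u <- apply_atom_map(list(iso_unlabeled(4), iso_unlabeled(2)),
                      net$maps$citrate_synthase)
  expect_dist_equal(u, iso_unlabeled(5))
  # expected 13C count in product + released CO2 equals that of the sources
  withr::with_seed(42, {
    for (rep in 1:10) {
      doaa <- iso_dist(prop.table(stats::runif(16)))
      dac <- iso_dist(prop.table(stats::runif(4)))
      kg <- apply_atom_map(list(doaa, dac), net$maps$citrate_synthase)
      lhs <- sum(vapply(1:5, function(c) positional_enrichment(kg, c), 1)) +
        positional_enrichment(doaa, 1)  # OAA C1 released at IDH
      rhs <- sum(vapply(1:4, function(c) positional_enrichment(doaa, c), 1)) +
        sum(vapply(1:2, function(c) positional_enrichment(dac, c), 1))
      expect_equal(lhs, rhs, tolerance = 1e-12)
      expect_equal(sum(kg$fractions), 1, tolerance = 1e-9)
    }
  })
  # a distribution symmetric under carbon reversal is unchanged by the
  # 50/50 succinate branch beyond the deterministic carbon shift
  sym <- iso_mix(list(iso_species(5, c(2, 3)), iso_species(5, c(4, 5))),
                 c(0.5, 0.5))
  out <- apply_atom_map(sym, net$maps$akgdh_succinate)
  expect_dist_equal(out, reverse_carbons(out))
  # dimension mismatch is an error
  expect_error(apply_atom_map(iso_unlabeled(4), net$maps$pdh))
})

test_that("positional enrichment is the labeled-state marginal", {
  expect_equal(positional_enrichment(iso_unlabeled(3), 2), 0)
  expect_equal(positional_enrichment(iso_species(3, 1), 1), 1)
  half <- iso_mix(fx[c("[1,2,3-13C3]OAA", "[2,3,4-13C3]OAA")], c(0.5, 0.5))
  expect_equal(positional_enrichment(half, 1), 0.5)
  expect_equal(positional_enrichment(half, 2), 1)
  expect_error(positional_enrichment(iso_unlabeled(3), 4), "out of range")
})

test_that("multiplet classification follows the J-coupling neighbor logic", {
  m <- multiplet_fractions(fx[["[4,5-13C2]glutamate"]], "glu_C4")
  expect_equal(m, c(S = 0, D34 = 0, D45 = 1, Q = 0))
  m <- multiplet_fractions(fx[["[3,4,5-13C3]glutamate"]], "glu_C4")
  expect_equal(m[["Q"]], 1)
  uglu <- iso_species(5, 1:5)
  expect_equal(multiplet_fractions(uglu, "glu_C4")[["Q"]], 1)
  expect_equal(multiplet_fractions(uglu, "glu_C3")[["T"]], 1)
  expect_equal(multiplet_fractions(uglu, "glu_C2")[["Q"]], 1)
  # glutamate C3 pools the two one-neighbor doublets into D
  d <- multiplet_fractions(iso_species(5, c(3, 4)), "glu_C3")
  expect_equal(d[["D"]], 1)
  expect_equal(multiplet_fractions(fx[["[2,3-13C2]lactate"]], "lac_C2"),
               c(S = 0, D12 = 0, D23 = 1, Q = 0))
  expect_error(multiplet_fractions(iso_unlabeled(5), "glu_C4"),
               "zero enrichment")
})

test_that("multiplet components always sum to 1 at positive enrichment", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      d <- iso_dist(prop.table(stats::runif(32)))
      for (cb in c("glu_C2", "glu_C3", "glu_C4")) {
        expect_equal(sum(multiplet_fractions(d, cb)), 1, tolerance = 1e-9)
      }
    }
  })
})

test_that("natural-abundance background raises enrichment by ~1.1% per carbon", {
  d <- add_natural_abundance(iso_unlabeled(3))
  expect_equal(positional_enrichment(d, 1), 0.011, tolerance = 1e-12)
  expect_equal(sum(d$fractions), 1, tolerance = 1e-12)
  # already-labeled carbons are untouched
  d2 <- add_natural_abundance(iso_species(3, 2))
  expect_equal(positional_enrichment(d2, 2), 1)
})

test_that("network JSON serialization round-trips and stays functional", {
  txt <- network_to_json(net)
  net2 <- network_from_json(txt)
  expect_equal(names(net2$maps), names(net$maps))
  up <- fx[["[U-13C]pyruvate"]]
  expect_dist_equal(apply_atom_map(up, net2$maps$pdh),
                    apply_atom_map(up, net$maps$pdh))
  fl <- relative_fluxes(f_acetyl_labeled = 0.5, f_pyr_medium = 0.3,
                        y_pc = 2, y_pyc = 1)
  expect_equal(solve_steady_state(net2, fl)$glutamate$fractions,
               solve_steady_state(net, fl)$glutamate$fractions,
               tolerance = 1e-9)
})
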