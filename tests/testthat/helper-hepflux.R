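# Build a single-liver multiplet table from a forward prediction,
# optionally with seeded Gaussian noise (renormalized per carbon).
prediction_table <- function(fluxes, sd = 0.01, noise = FALSE, seed = 1,
                             liver_id = "L1", group = "lean-control") {
  pred <- predict_multiplets(fluxes)
  rows <- do.call(rbind, lapply(names(pred), function(cb) {
    data.frame(liver_id = liver_id, group = group, carbon = cb,
               component = names(pred[[cb]]),
               fraction = unname(pred[[cb]]), sd = sd)
  }))
  if (noise) {
    rows <- withr::with_seed(seed, {
      for (cb in unique(rows$carbon)) {
        i <- rows$carbon == cb
        f <- rows$fraction[i] + stats::rnorm(sum(i), 0, sd)
        f <- pmin(pmax(f, 0), 1)
        rows$fraction[i] <- f / sum(f)
      }
      rows
    })
  }
  rows
}

expect_dist_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$fractions, b$fractions, tolerance = tol)
}
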