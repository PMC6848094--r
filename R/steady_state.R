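#' Relative fluxes driving the steady-state isotopomer model
#'
#' All fluxes are dimensionless, expressed per unit citrate-synthase flux.
#'
#' Acetyl-CoA inflow is a three-way mixture: a fraction `f_acetyl_labeled` of
#' [1,2-13C2] units formed from medium-derived [U-13C]pyruvate, a fraction
#' `f_acetyl_unlabeled_fat` of unlabeled units (beta-oxidation and any other
#' endogenous acetyl source), and - when the two do not sum to 1 - the
#' remainder drawn through PDH from the mixed tissue pyruvate pool. The two
#' dilution modes differ only in which parameters are free:
#' \describe{
#'   \item{`"acetyl"` (default)}{unlabeled carbohydrate (glycogenolysis) is
#'     accounted at the acetyl-CoA node: `f_acetyl_labeled` is the labeled
#'     acetyl fraction and `f_acetyl_unlabeled_fat` defaults to its
#'     complement.}
#'   \item{`"pyruvate"`}{glycogen dilution happens in the pyruvate pool:
#'     acetyl-CoA is `1 - f_acetyl_unlabeled_fat` PDH product of the mixed
#'     pyruvate pool plus unlabeled fat.}
#' }
#'
#' @param f_acetyl_labeled fraction of acetyl-CoA inflow arriving as
#'   [1,2-13C2] units, in \[0, 1\]
#' @param f_acetyl_unlabeled_fat fraction of acetyl-CoA inflow that is
#'   unlabeled (fat/endogenous), in \[0, 1\]
#' @param f_pyr_medium fraction of the non-recycled pyruvate inflow coming
#'   from medium [U-13C]lactate/pyruvate (the rest is unlabeled
#'   glycogenolysis), in \[0, 1\]
#' @param y_pc pyruvate-carboxylase flux per unit citrate-synthase flux (>= 0)
#' @param y_pyc pyruvate-cycling flux per unit citrate-synthase flux
#'   (0 <= y_pyc <= y_pc; the balance `y_pc - y_pyc` leaves as cataplerosis)
#' @param scramble extent of fumarase scrambling applied to PC-derived
#'   four-carbon units, in \[0, 1\] (1 = complete symmetrization, the
#'   steady-state extract default)
#' @param dilution_mode `"acetyl"` or `"pyruvate"` (see Details)
#' @param medium_enrichment isotopic purity of the medium [U-13C] substrates
#' @export
relative_fluxes <- function(f_acetyl_labeled = NULL,
                            f_acetyl_unlabeled_fat = NULL,
                            f_pyr_medium = 1,
                            y_pc = 0, y_pyc = 0,
                            scramble = 1,
                            dilution_mode = c("acetyl", "pyruvate"),
                            medium_enrichment = 0.99) {
  dilution_mode <- match.arg(dilution_mode)
  if (dilution_mode == "acetyl") {
    if (is.null(f_acetyl_labeled)) f_acetyl_labeled <- 0.5
    if (is.null(f_acetyl_unlabeled_fat)) {
      f_acetyl_unlabeled_fat <- 1 - f_acetyl_labeled
    }
  } else {
    if (is.null(f_acetyl_unlabeled_fat)) f_acetyl_unlabeled_fat <- 0.5
    if (is.null(f_acetyl_labeled)) f_acetyl_labeled <- 0
  }
  chk01 <- function(x, nm) {
    if (x < -1e-9 || x > 1 + 1e-9) stop(nm, " must be in [0, 1]")
    min(max(x, 0), 1)
  }
  f_acetyl_labeled <- chk01(f_acetyl_labeled, "f_acetyl_labeled")
  f_acetyl_unlabeled_fat <- chk01(f_acetyl_unlabeled_fat, "f_acetyl_unlabeled_fat")
  f_pyr_medium <- chk01(f_pyr_medium, "f_pyr_medium")
  scramble <- chk01(scramble, "scramble")
  if (f_acetyl_labeled + f_acetyl_unlabeled_fat > 1 + 1e-9) {
    stop("f_acetyl_labeled + f_acetyl_unlabeled_fat must not exceed 1")
  }
  if (y_pc < 0 || y_pyc < 0) stop("relative fluxes must be non-negative")
  if (y_pyc > y_pc + 1e-9) {
    stop("y_pyc must not exceed y_pc (cataplerotic OAA efflux y_pc - y_pyc >= 0)")
  }
  structure(list(f_acetyl_labeled = f_acetyl_labeled,
                 f_acetyl_unlabeled_fat = f_acetyl_unlabeled_fat,
                 f_pyr_medium = f_pyr_medium,
                 y_pc = y_pc, y_pyc = min(y_pyc, y_pc),
                 scramble = scramble, dilution_mode = dilution_mode,
                 medium_enrichment = medium_enrichment),
            class = "relative_fluxes")
}

#' Solve the steady-state label-balance equations
#'
#' Finds the fixed point of the isotopomer balance: each pool's distribution
#' equals the flux-weighted mixture of its inflow maps. Pools are updated by
#' successive substitution in a fixed order (pyruvate, acetyl-CoA, OAA,
#' alpha-ketoglutarate) until the largest absolute change over all states
#' drops below `tol`. Glutamate mirrors alpha-ketoglutarate and tissue
#' lactate mirrors the mixed pyruvate pool (rapid exchange).
#'
#' @param network a `network_model` (typically [build_liver_network()])
#' @param fluxes a `relative_fluxes` object
#' @param tol convergence tolerance (max-norm), default 1e-10
#' @param max_iter iteration cap
#' @param init optional list of starting fraction vectors (warm start)
#' @return list of `iso_dist` per pool (class `steady_state`), with
#'   attributes `iterations` and `f_acetyl_labeled_effective` (the fraction
#'   of acetyl-CoA that is [1,2-13C2], the quantity scaled into V_PDH)
#' @export
solve_steady_state <- function(network, fluxes, tol = 1e-10,
                               max_iter = 10000, init = NULL) {
  stopifnot(inherits(fluxes, "relative_fluxes"), tol > 0)
  ops <- network$operators
  M_pdh <- ops$pdh; M_pc <- ops$pc; M_cs <- ops$citrate_synthase
  M_succ <- ops$akgdh_succinate; M_cyc <- ops$pyruvate_cycling

  e <- fluxes$medium_enrichment
  med <- numeric(8); med[1] <- 1 - e; med[8] <- e
  unl3 <- c(1, numeric(7))
  f_lab <- fluxes$f_acetyl_labeled
  f_fat <- fluxes$f_acetyl_unlabeled_fat
  rem <- max(0, 1 - f_lab - f_fat)
  ac_fixed <- numeric(4)
  ac_fixed[1] <- ac_fixed[1] + f_fat
  ac_fixed[4] <- ac_fixed[4] + f_lab   # [1,2-13C2] acetyl state (bits 1+2)
  v_pdh_rel <- 1 - f_fat
  y_pc <- fluxes$y_pc; y_pyc <- fluxes$y_pyc
  f_nonrec <- v_pdh_rel + y_pc - y_pyc
  pyr_fresh <- fluxes$f_pyr_medium * med + (1 - fluxes$f_pyr_medium) * unl3
  rev16 <- carbon_reversal_perm(4)
  s_half <- fluxes$scramble / 2

  pyr <- init$pyruvate %||% unl3
  ac <- init$acetyl_coa %||% c(1, numeric(3))
  oaa <- init$oaa %||% c(1, numeric(15))
  kg <- init$akg %||% c(1, numeric(31))

  for (iter in seq_len(max_iter)) {
    pyr_new <- if (y_pyc + f_nonrec > 1e-12) {
      (y_pyc * drop(M_cyc %*% oaa) + f_nonrec * pyr_fresh) / (y_pyc + f_nonrec)
    } else pyr_fresh
    ac_new <- ac_fixed + rem * drop(M_pdh %*% pyr_new)
    pc_u <- drop(M_pc %*% pyr_new)
    pc_s <- (1 - s_half) * pc_u + s_half * pc_u[rev16]
    oaa_new <- (y_pc * pc_s + drop(M_succ %*% kg)) / (1 + y_pc)
    kg_new <- drop(M_cs %*% kronecker(oaa_new, ac_new))
    delta <- max(max(abs(pyr_new - pyr)), max(abs(ac_new - ac)),
                 max(abs(oaa_new - oaa)), max(abs(kg_new - kg)))
    pyr <- pyr_new; ac <- ac_new; oaa <- oaa_new; kg <- kg_new
    if (delta < tol) break
  }
  if (delta >= tol) {
    stop(structure(class = c("hepflux_convergence_error", "error", "condition"),
                   list(message = "steady-state solver did not converge",
                        call = sys.call())))
  }
  # fraction of acetyl-CoA that is [1,2-13C2]
  f_eff <- ac[4]
  out <- list(
    pyruvate = iso_dist(pyr, "pyruvate"),
    lactate = iso_dist(pyr, "lactate"),
    acetyl_coa = iso_dist(ac, "acetyl_coa"),
    oaa = iso_dist(oaa, "oaa"),
    akg = iso_dist(kg, "akg"),
    glutamate = iso_dist(kg, "glutamate")
  )
  attr(out, "iterations") <- iter
  attr(out, "f_acetyl_labeled_effective") <- f_eff
  attr(out, "fluxes") <- fluxes
  class(out) <- "steady_state"
  out
}

#' Brute-force turn-by-turn labeling oracle
#'
#' Independent reference computation: propagates every isotopomer state
#' explicitly, turn by turn, from an unlabeled start, using hand-coded
#' carbon fates (integer bit operations) rather than the atom-map operator
#' machinery behind [solve_steady_state()]. Converges to the steady-state
#' solution as `n_turns` grows. Intended for testing.
#'
#' @param network a `network_model` (pool sizes only; the carbon fates are
#'   hard-coded here on purpose)
#' @param fluxes a `relative_fluxes` object
#' @param n_turns number of explicit cycle applications (>= 1)
#' @return list of `iso_dist` per pool
#' @export
enumerate_oracle <- function(network, fluxes, n_turns) {
  stopifnot(n_turns >= 1)
  bit <- function(s, c) bitwAnd(s, bitwShiftL(1L, c - 1L)) > 0
  e <- fluxes$medium_enrichment
  f_lab <- fluxes$f_acetyl_labeled
  f_fat <- fluxes$f_acetyl_unlabeled_fat
  rem <- max(0, 1 - f_lab - f_fat)
  v_pdh <- 1 - f_fat
  y_pc <- fluxes$y_pc; y_pyc <- fluxes$y_pyc
  f_nonrec <- v_pdh + y_pc - y_pyc
  fm <- fluxes$f_pyr_medium
  scr <- fluxes$scramble

  pyr <- c(1, numeric(7)); ac <- c(1, numeric(3))
  oaa <- c(1, numeric(15)); kg <- c(1, numeric(31))
  fresh <- numeric(8); fresh[1] <- (1 - fm) + fm * (1 - e); fresh[8] <- fm * e

  for (turn in seq_len(n_turns)) {
    # pyruvate: cycling return keeps OAA C1..C3, drops C4
    ret <- numeric(8)
    for (o in 0:15) {
      s <- 0L
      if (bit(o, 1)) s <- s + 1L
      if (bit(o, 2)) s <- s + 2L
      if (bit(o, 3)) s <- s + 4L
      ret[s + 1] <- ret[s + 1] + oaa[o + 1]
    }
    pyr <- if (y_pyc + f_nonrec > 1e-12) {
      (y_pyc * ret + f_nonrec * fresh) / (y_pyc + f_nonrec)
    } else fresh
    # acetyl-CoA: direct [1,2-13C2] + fat + PDH of pyruvate (C2 -> C1, C3 -> C2)
    pdh <- numeric(4)
    for (p in 0:7) {
      s <- 0L
      if (bit(p, 2)) s <- s + 1L
      if (bit(p, 3)) s <- s + 2L
      pdh[s + 1] <- pdh[s + 1] + pyr[p + 1]
    }
    ac <- rem * pdh
    ac[1] <- ac[1] + f_fat
    ac[4] <- ac[4] + f_lab
    # OAA: PC product (pyr C1..C3 -> OAA C1..C3, C4 unlabeled), scrambled,
    # plus the succinate return from alpha-ketoglutarate
    pc <- numeric(16)
    for (p in 0:7) pc[p + 1] <- pc[p + 1] + pyr[p + 1]  # bits align, C4 = 0
    pcs <- numeric(16)
    for (o in 0:15) {
      r <- 0L  # reverse 4 bits
      if (bit(o, 1)) r <- r + 8L
      if (bit(o, 2)) r <- r + 4L
      if (bit(o, 3)) r <- r + 2L
      if (bit(o, 4)) r <- r + 1L
      pcs[o + 1] <- (1 - scr / 2) * pc[o + 1] + (scr / 2) * pc[r + 1]
    }
    succ <- numeric(16)
    for (k in 0:31) {
      a <- 0L  # forward: OAA C1..C4 <- KG C2..C5
      if (bit(k, 2)) a <- a + 1L
      if (bit(k, 3)) a <- a + 2L
      if (bit(k, 4)) a <- a + 4L
      if (bit(k, 5)) a <- a + 8L
      b <- 0L  # reversed: OAA C1..C4 <- KG C5..C2
      if (bit(k, 5)) b <- b + 1L
      if (bit(k, 4)) b <- b + 2L
      if (bit(k, 3)) b <- b + 4L
      if (bit(k, 2)) b <- b + 8L
      succ[a + 1] <- succ[a + 1] + 0.5 * kg[k + 1]
      succ[b + 1] <- succ[b + 1] + 0.5 * kg[k + 1]
    }
    oaa <- (y_pc * pcs + succ) / (1 + y_pc)
    # alpha-KG: OAA C4,C3,C2 -> C1,C2,C3; acetyl C2,C1 -> C4,C5; OAA C1 out
    kg <- numeric(32)
    for (o in 0:15) {
      if (oaa[o + 1] == 0) next
      base <- 0L
      if (bit(o, 4)) base <- base + 1L
      if (bit(o, 3)) base <- base + 2L
      if (bit(o, 2)) base <- base + 4L
      for (a in 0:3) {
        s <- base
        if (bit(a, 2)) s <- s + 8L
        if (bit(a, 1)) s <- s + 16L
        kg[s + 1] <- kg[s + 1] + oaa[o + 1] * ac[a + 1]
      }
    }
  }
  list(
    pyruvate = iso_dist(pyr, "pyruvate"),
    lactate = iso_dist(pyr, "lactate"),
    acetyl_coa = iso_dist(ac, "acetyl_coa"),
    oaa = iso_dist(oaa, "oaa"),
    akg = iso_dist(kg, "akg"),
    glutamate = iso_dist(kg, "glutamate")
  )
}
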