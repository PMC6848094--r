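#' Isotopomer distributions
#'
#' An isotopomer distribution is a probability vector over all `2^n` labeling
#' states of an n-carbon pool. State `s` (0-based) has carbon `c` labeled
#' when bit `c - 1` of `s` is set, so the vector element `s + 1` is the
#' fraction of molecules carrying exactly that 13C pattern. The all-unlabeled
#' state is element 1 and the uniformly labeled ([U-13C]) state is the last
#' element.
#'
#' @param fractions numeric vector of length `2^n`, non-negative, summing to
#'   1 (within 1e-9).
#' @param pool optional pool name carried along for display.
#' @return an object of class `iso_dist`.
#' @export
iso_dist <- function(fractions, pool = NULL) {
  n <- as.integer(round(log2(length(fractions))))
  if (length(fractions) != 2^n || n < 0) {
    stop("fractions must have length 2^n for some n >= 0")
  }
  fractions <- as.numeric(fractions)
  if (any(fractions < -1e-9)) stop("isotopomer fractions must be non-negative")
  fractions[fractions < 0] <- 0
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("isotopomer fractions must sum to 1 (within 1e-9)")
  }
  structure(list(pool = pool, n_carbons = n, fractions = fractions),
            class = "iso_dist")
}

#' @export
print.iso_dist <- function(x, digits = 4, ...) {
  cat("Isotopomer distribution", if (!is.null(x$pool)) paste0("(", x$pool, ")"),
      "-", x$n_carbons, "carbons\n")
  nz <- which(x$fractions > 1e-12)
  lab <- vapply(nz - 1L, function(s) {
    bits <- which(bitwAnd(s, 2^(seq_len(x$n_carbons) - 1)) > 0)
    if (length(bits) == 0) "unlabeled" else paste0("[", paste(bits, collapse = ","), "-13C]")
  }, character(1))
  print(stats::setNames(round(x$fractions[nz], digits), lab))
  invisible(x)
}

#' All-unlabeled distribution for an n-carbon pool
#' @param n number of carbons
#' @param pool optional pool name
#' @export
iso_unlabeled <- function(n, pool = NULL) {
  f <- numeric(2^n)
  f[1] <- 1
  iso_dist(f, pool)
}

#' Pure single-isotopomer distribution
#'
#' @param n number of carbons
#' @param labeled integer vector of labeled carbon positions (1-based)
#' @param pool optional pool name
#' @export
iso_species <- function(n, labeled = integer(0), pool = NULL) {
  if (length(labeled) && (any(labeled < 1) || any(labeled > n))) {
    stop("labeled carbon index out of range")
  }
  f <- numeric(2^n)
  f[sum(2^(unique(labeled) - 1)) + 1] <- 1
  iso_dist(f, pool)
}

#' Mixture of isotopomer distributions
#' @param dists list of `iso_dist` over the same pool size
#' @param weights mixture weights (normalized internally)
#' @export
iso_mix <- function(dists, weights) {
  stopifnot(length(dists) == length(weights), length(dists) >= 1)
  n <- dists[[1]]$n_carbons
  if (!all(vapply(dists, function(d) d$n_carbons, 1L) == n)) {
    stop("all mixture components must have the same number of carbons")
  }
  w <- weights / sum(weights)
  f <- Reduce(`+`, Map(function(d, wi) wi * d$fractions, dists, w))
  iso_dist(f, dists[[1]]$pool)
}

#' Positional (fractional) enrichment of one carbon
#'
#' Marginal probability that the given carbon position carries 13C.
#'
#' @param dist an `iso_dist`
#' @param carbon carbon index (1-based)
#' @return fraction in \[0, 1\]
#' @export
positional_enrichment <- function(dist, carbon) {
  stopifnot(inherits(dist, "iso_dist"))
  if (carbon < 1 || carbon > dist$n_carbons) stop("carbon index out of range")
  s <- seq_len(2^dist$n_carbons) - 1L
  sum(dist$fractions[bitwAnd(s, 2^(carbon - 1)) > 0])
}

# Permutation reversing carbon order (C1 <-> Cn, C2 <-> Cn-1, ...) on state
# indices; used for fumarase/succinate symmetrization.
carbon_reversal_perm <- function(n) {
  s <- seq_len(2^n) - 1L
  out <- integer(2^n)
  for (i in seq_along(s)) {
    v <- 0L
    for (c in seq_len(n)) {
      if (bitwAnd(s[i], 2^(c - 1)) > 0) v <- v + 2^(n - c)
    }
    out[i] <- v + 1L
  }
  out
}

#' Reverse the carbon order of a distribution
#' @param dist an `iso_dist`
#' @export
reverse_carbons <- function(dist) {
  perm <- carbon_reversal_perm(dist$n_carbons)
  iso_dist(dist$fractions[perm], dist$pool)
}

#' Add natural-abundance 13C background
#'
#' Each unlabeled carbon is flipped to labeled independently with probability
#' `p` (1.1% by default). Off by default throughout the package: multiplet
#' fractions at tracer-level enrichments are insensitive to it.
#'
#' @param dist an `iso_dist`
#' @param p per-carbon natural-abundance probability
#' @export
add_natural_abundance <- function(dist, p = 0.011) {
  f <- dist$fractions
  n <- dist$n_carbons
  s <- seq_len(2^n) - 1L
  for (c in seq_len(n)) {
    bit <- 2^(c - 1)
    unl <- bitwAnd(s, bit) == 0
    moved <- f[unl] * p
    f[unl] <- f[unl] - moved
    f[which(unl) + bit] <- f[which(unl) + bit] + moved
  }
  iso_dist(f, dist$pool)
}

# Registry of observed carbons: pool size, observed position, J-coupled
# neighbors, and the component name for each neighbor-labeling pattern
# (names follow the spectroscopic convention: S singlet, Dxy doublet from
# the Jxy coupling, T triplet = degenerate doublet of doublets, Q quartet).
observed_carbon_registry <- function() {
  list(
    glu_C4 = list(n = 5, obs = 4, nb = c(3, 5),
                  comp = c(none = "S", lo = "D34", hi = "D45", both = "Q")),
    glu_C3 = list(n = 5, obs = 3, nb = c(2, 4),
                  comp = c(none = "S", lo = "D", hi = "D", both = "T")),
    glu_C2 = list(n = 5, obs = 2, nb = c(1, 3),
                  comp = c(none = "S", lo = "D12", hi = "D23", both = "Q")),
    lac_C2 = list(n = 3, obs = 2, nb = c(1, 3),
                  comp = c(none = "S", lo = "D12", hi = "D23", both = "Q"))
  )
}

#' 13C multiplet fractions of an observed carbon
#'
#' Classifies the isotopomers in which the observed carbon is labeled by the
#' labeling state of its one-bond neighbors, giving the fractional areas of
#' the singlet/doublet/triplet/quartet components of that carbon's resonance
#' (conditioned on the observed carbon being 13C). For glutamate C3 the two
#' single-neighbor doublets are pooled into one `D` component, as they are
#' in typical spectral fitting.
#'
#' @param dist an `iso_dist` of the right pool size (5 carbons for glutamate,
#'   3 for lactate)
#' @param carbon one of `"glu_C4"`, `"glu_C3"`, `"glu_C2"`, `"lac_C2"`
#' @return named numeric vector of component fractions summing to 1
#' @export
multiplet_fractions <- function(dist, carbon) {
  reg <- observed_carbon_registry()
  if (!carbon %in% names(reg)) stop("unknown observed carbon: ", carbon)
  cfg <- reg[[carbon]]
  if (dist$n_carbons != cfg$n) {
    stop(carbon, " requires a ", cfg$n, "-carbon distribution")
  }
  s <- seq_len(2^cfg$n) - 1L
  obs_on <- bitwAnd(s, 2^(cfg$obs - 1)) > 0
  enr <- sum(dist$fractions[obs_on])
  if (enr <= 1e-12) {
    stop("observed carbon has zero enrichment; multiplet undefined")
  }
  lo_on <- bitwAnd(s, 2^(cfg$nb[1] - 1)) > 0
  hi_on <- bitwAnd(s, 2^(cfg$nb[2] - 1)) > 0
  comp_names <- unique(unname(cfg$comp))
  out <- stats::setNames(numeric(length(comp_names)), comp_names)
  key <- ifelse(lo_on & hi_on, "both", ifelse(lo_on, "lo", ifelse(hi_on, "hi", "none")))
  f <- dist$fractions
  for (k in c("none", "lo", "hi", "both")) {
    sel <- obs_on & key == k
    out[cfg$comp[[k]]] <- out[cfg$comp[[k]]] + sum(f[sel])
  }
  out / enr
}
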