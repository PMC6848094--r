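#' Carbon pools and atom maps
#'
#' A `NetworkModel` is a set of carbon pools plus carbon-atom transition
#' maps. Each map tells, for every product carbon, which source-pool carbon
#' it derives from (or that it enters from an unlabeled inflow such as CO2
#' fixed by pyruvate carboxylase), which source carbons leave as CO2, and -
#' for reactions passing through a symmetric intermediate - a set of
#' alternative mappings with branch probabilities.
#'
#' @param name pool name (unique within a network)
#' @param n_carbons number of carbons (>= 1)
#' @export
carbon_pool <- function(name, n_carbons) {
  stopifnot(is.character(name), length(name) == 1, n_carbons >= 1)
  structure(list(name = name, n_carbons = as.integer(n_carbons)),
            class = "carbon_pool")
}

#' Define a carbon-atom transition map
#'
#' @param name reaction name
#' @param source_pools character vector of source pool names (ordered)
#' @param product_pool product pool name
#' @param n_product number of product carbons
#' @param branches list of branches; each branch is
#'   `list(weight =, origin = list(...))` where `origin` has one entry per
#'   product carbon: either `c(source_pool_index, source_carbon)` or `NULL`
#'   for an unlabeled inflow. Branch weights must sum to 1.
#' @param released list of `c(source_pool_index, source_carbon)` carbons
#'   leaving as CO2 (common to all branches).
#' @export
atom_map <- function(name, source_pools, product_pool, n_product,
                     branches, released = list()) {
  w <- vapply(branches, function(b) b$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) stop("branch weights must sum to 1")
  for (b in branches) {
    if (length(b$origin) != n_product) {
      stop("each branch must give one origin per product carbon")
    }
  }
  for (r in released) {
    for (b in branches) {
      for (o in b$origin) {
        if (!is.null(o) && o[1] == r[1] && o[2] == r[2]) {
          stop("released carbon is also mapped to a product carbon")
        }
      }
    }
  }
  structure(list(name = name, source_pools = source_pools,
                 product_pool = product_pool, n_product = as.integer(n_product),
                 branches = branches, released = released),
            class = "atom_map")
}

#' Assemble a network model
#' @param pools list of `carbon_pool`
#' @param maps list of `atom_map`
#' @export
network_model <- function(pools, maps) {
  nm <- vapply(pools, function(p) p$name, character(1))
  if (anyDuplicated(nm)) stop("pool names must be unique")
  names(pools) <- nm
  names(maps) <- vapply(maps, function(m) m$name, character(1))
  for (m in maps) {
    if (!all(m$source_pools %in% nm) || !(m$product_pool %in% nm)) {
      stop("map ", m$name, " references unknown pools")
    }
  }
  maps <- lapply(maps, function(m) {
    m$n_source <- vapply(m$source_pools, function(p) pools[[p]]$n_carbons, 1L)
    m
  })
  net <- structure(list(pools = pools, maps = maps), class = "network_model")
  net$operators <- lapply(maps, function(m) map_matrix(m, m$n_source))
  net
}

# Dense linear operator for a map: product-state distribution =
# M %*% joint-source-state vector, where the joint vector over k sources is
# kronecker(d1, ..., dk) (independent-pool mixing).
map_matrix <- function(map, n_src) {
  sizes <- 2^n_src
  total <- prod(sizes)
  np <- map$n_product
  M <- matrix(0, nrow = 2^np, ncol = total)
  # kronecker index: j-1 = ((s1 * n2) + s2) * n3 + ... (first source slowest)
  for (j in seq_len(total) - 1L) {
    st <- integer(length(sizes))
    rem <- j
    for (k in rev(seq_along(sizes))) {
      st[k] <- rem %% sizes[k]
      rem <- rem %/% sizes[k]
    }
    for (b in map$branches) {
      prod_state <- 0L
      for (c in seq_len(np)) {
        o <- b$origin[[c]]
        if (!is.null(o) && bitwAnd(st[o[1]], 2^(o[2] - 1)) > 0) {
          prod_state <- prod_state + 2^(c - 1)
        }
      }
      M[prod_state + 1L, j + 1L] <- M[prod_state + 1L, j + 1L] + b$weight
    }
  }
  M
}

#' Apply an atom map to source distributions
#'
#' Sources mix independently (the joint state probability is the product of
#' the marginals across distinct source pools); branch alternatives are
#' averaged with their weights. Label is conserved: the expected number of
#' 13C atoms in the product plus released CO2 equals that of the sources
#' whenever every source carbon is either mapped or released.
#'
#' @param sources a single `iso_dist` or a list with one `iso_dist` per
#'   source pool, in the order of `map$source_pools`
#' @param map an `atom_map`
#' @return the product `iso_dist`
#' @export
apply_atom_map <- function(sources, map) {
  if (inherits(sources, "iso_dist")) sources <- list(sources)
  if (length(sources) != length(map$source_pools)) {
    stop("map expects ", length(map$source_pools), " source distribution(s)")
  }
  n_src <- vapply(sources, function(d) d$n_carbons, 1L)
  if (!is.null(map$n_source) && !all(n_src == map$n_source)) {
    stop("dimension mismatch: map ", map$name, " expects source sizes (",
         paste(map$n_source, collapse = ", "), "), got (",
         paste(n_src, collapse = ", "), ")")
  }
  M <- map_matrix(map, n_src)
  joint <- Reduce(kronecker, lapply(sources, function(d) d$fractions))
  iso_dist(drop(M %*% joint), map$product_pool)
}

#' The hepatic carbon-transition network
#'
#' Pools: pyruvate (3C), lactate (3C), acetyl-CoA (2C), a combined
#' OAA/malate/aspartate pool (4C), alpha-ketoglutarate (5C), glutamate (5C),
#' CO2 (1C). Maps:
#' \itemize{
#'   \item `pdh`: pyruvate C2 -> acetyl-CoA C1, C3 -> C2; C1 released as CO2.
#'   \item `pc`: pyruvate C1..C3 -> OAA C1..C3; OAA C4 from unlabeled CO2.
#'   \item `citrate_synthase`: OAA C4,C3,C2 -> aKG C1,C2,C3 and acetyl-CoA
#'     C2,C1 -> aKG C4,C5; OAA C1 released (isocitrate dehydrogenase).
#'   \item `akgdh_succinate`: aKG C2..C5 -> OAA C1..C4 with a 50/50 branch
#'     reversing the order (symmetric succinate/fumarate); aKG C1 released.
#'   \item `pyruvate_cycling`: OAA C1..C3 -> pyruvate C1..C3; OAA C4
#'     released. The same carbon fate describes both the PEPCK/pyruvate
#'     kinase and the malic-enzyme routes.
#'   \item `ldh`: pyruvate <-> lactate identity exchange.
#'   \item `glu_exchange`: aKG <-> glutamate identity exchange.
#' }
#' @return a `network_model`
#' @export
build_liver_network <- function() {
  pools <- list(
    carbon_pool("pyruvate", 3), carbon_pool("lactate", 3),
    carbon_pool("acetyl_coa", 2), carbon_pool("oaa", 4),
    carbon_pool("akg", 5), carbon_pool("glutamate", 5),
    carbon_pool("co2", 1)
  )
  br <- function(weight, ...) list(weight = weight, origin = list(...))
  maps <- list(
    atom_map("pdh", "pyruvate", "acetyl_coa", 2,
             branches = list(br(1, c(1, 2), c(1, 3))),
             released = list(c(1, 1))),
    atom_map("pc", "pyruvate", "oaa", 4,
             branches = list(br(1, c(1, 1), c(1, 2), c(1, 3), NULL))),
    atom_map("citrate_synthase", c("oaa", "acetyl_coa"), "akg", 5,
             branches = list(br(1, c(1, 4), c(1, 3), c(1, 2), c(2, 2), c(2, 1))),
             released = list(c(1, 1))),
    atom_map("akgdh_succinate", "akg", "oaa", 4,
             branches = list(
               br(0.5, c(1, 2), c(1, 3), c(1, 4), c(1, 5)),
               br(0.5, c(1, 5), c(1, 4), c(1, 3), c(1, 2))
             ),
             released = list(c(1, 1))),
    atom_map("pyruvate_cycling", "oaa", "pyruvate", 3,
             branches = list(br(1, c(1, 1), c(1, 2), c(1, 3))),
             released = list(c(1, 4))),
    atom_map("ldh", "pyruvate", "lactate", 3,
             branches = list(br(1, c(1, 1), c(1, 2), c(1, 3)))),
    atom_map("glu_exchange", "akg", "glutamate", 5,
             branches = list(br(1, c(1, 1), c(1, 2), c(1, 3), c(1, 4), c(1, 5))))
  )
  network_model(pools, maps)
}

#' Serialize a network model to JSON
#' @param network a `network_model`
#' @param path optional file path; if `NULL` the JSON string is returned
#' @export
network_to_json <- function(network, path = NULL) {
  enc <- list(
    pools = lapply(unname(network$pools), function(p) {
      list(name = p$name, n_carbons = p$n_carbons)
    }),
    maps = lapply(unname(network$maps), function(m) {
      list(name = m$name, source_pools = as.list(m$source_pools),
           product_pool = m$product_pool, n_product = m$n_product,
           branches = lapply(m$branches, function(b) {
             list(weight = b$weight,
                  origin = lapply(b$origin, function(o) {
                    if (is.null(o)) "unlabeled-inflow" else as.list(o)
                  }))
           }),
           released = lapply(m$released, as.list))
    })
  )
  txt <- jsonlite::toJSON(enc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a network model from JSON
#' @param path file path or JSON string produced by [network_to_json()]
#' @export
network_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  pools <- lapply(x$pools, function(p) carbon_pool(p$name, p$n_carbons))
  maps <- lapply(x$maps, function(m) {
    atom_map(m$name, unlist(m$source_pools), m$product_pool, m$n_product,
             branches = lapply(m$branches, function(b) {
               list(weight = b$weight,
                    origin = lapply(b$origin, function(o) {
                      if (identical(o, "unlabeled-inflow")) NULL else unlist(o)
                    }))
             }),
             released = lapply(m$released, unlist))
  })
  network_model(pools, maps)
}
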