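#' Read and write multiplet tables
#'
#' CSV dialect: UTF-8, comma-separated, mandatory header, decimal point.
#' Columns: `liver_id`, `group`, `carbon`, `component`, `fraction`, `sd`.
#'
#' @param path CSV file path
#' @return data frame
#' @export
read_multiplet_table <- function(path) {
  if (!file.exists(path)) schema_error(paste("file not found:", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("liver_id", "group", "carbon", "component", "fraction", "sd")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    schema_error(paste("multiplet table missing column(s):",
                       paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0) schema_error("multiplet table has no rows")
  bad <- which(!is.finite(x$fraction) | x$fraction < 0 | x$fraction > 1)
  if (length(bad)) {
    schema_error(paste0("fraction out of [0,1] at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  known <- names(observed_carbon_registry())
  bad <- which(!x$carbon %in% known)
  if (length(bad)) {
    schema_error(paste0("unknown carbon '", x$carbon[bad[1]], "' at row ", bad[1]))
  }
  x
}

#' @rdname read_multiplet_table
#' @param table multiplet table data frame
#' @export
write_multiplet_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read and write perfusion records
#'
#' Columns: `liver_id`, `group`, `pO2_afferent`, `pO2_efferent`, `flow`,
#' `liver_weight`, optional `o2_solubility`.
#' @param path CSV file path
#' @export
read_perfusion_records <- function(path) {
  if (!file.exists(path)) schema_error(paste("file not found:", path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("liver_id", "group", "pO2_afferent", "pO2_efferent",
            "flow", "liver_weight")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    schema_error(paste("perfusion table missing column(s):",
                       paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0) schema_error("perfusion table has no rows")
  bad <- which(x$pO2_afferent < x$pO2_efferent | x$pO2_efferent < 0 |
                 x$flow <= 0 | x$liver_weight <= 0)
  if (length(bad)) {
    schema_error(paste0("invalid perfusion values at row(s) ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  x
}

#' @rdname read_perfusion_records
#' @param records perfusion record data frame
#' @export
write_perfusion_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read and write hyperpolarized time series as tidy CSV
#'
#' Long format with columns `time`, `metabolite`, `area`.
#' @param series an `hp_timeseries` (writer) or CSV path (reader)
#' @param path CSV file path
#' @export
write_hp_timeseries <- function(series, path) {
  df <- data.frame(
    time = rep(series$time, times = ncol(series$areas)),
    metabolite = rep(colnames(series$areas), each = nrow(series$areas)),
    area = as.vector(series$areas))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hp_timeseries
#' @export
read_hp_timeseries <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "metabolite", "area")
  if (!all(need %in% names(x))) {
    schema_error("hp time series needs columns time, metabolite, area")
  }
  time <- sort(unique(x$time))
  mets <- unique(x$metabolite)
  areas <- matrix(0, length(time), length(mets), dimnames = list(NULL, mets))
  for (m in mets) {
    xi <- x[x$metabolite == m, ]
    areas[match(xi$time, time), m] <- xi$area
  }
  structure(list(time = time, areas = areas, spectra = NULL, ppm = NULL,
                 scheme = NULL, model = NULL), class = "hp_timeseries")
}

#' @rdname write_hp_timeseries
#' @param spectrum data frame with `ppm`, `intensity`
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(spectrum[, c("ppm", "intensity")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hp_timeseries
#' @export
read_spectrum <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ppm", "intensity") %in% names(x))) {
    schema_error("spectrum needs columns ppm, intensity")
  }
  x
}

#' Significance stars
#'
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#' @param p p-value(s)
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("")
    if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

#' Group comparisons
#'
#' Welch's unequal-variance t-test for two-group comparisons (knockout vs
#' control) or ordinary one-way ANOVA with Tukey HSD post hoc across
#' several groups.
#'
#' @param values numeric vector
#' @param groups group labels, same length
#' @param test `"welch"` (exactly two groups) or `"anova_tukey"`
#' @return data frame with `comparison`, `statistic`, `p_value`, `stars`;
#'   for ANOVA the first row is the omnibus F test followed by the Tukey
#'   pairwise contrasts
#' @export
compare_groups <- function(values, groups, test = c("welch", "anova_tukey")) {
  test <- match.arg(test)
  groups <- factor(groups)
  if (any(table(groups) < 2)) stop("need at least 2 values per group")
  if (test == "welch") {
    if (nlevels(groups) != 2) stop("welch test requires exactly 2 groups")
    tt <- stats::t.test(values ~ groups, var.equal = FALSE)
    out <- data.frame(comparison = paste(levels(groups), collapse = " vs "),
                      statistic = unname(tt$statistic),
                      p_value = tt$p.value)
  } else {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$groups
    out <- rbind(
      data.frame(comparison = "ANOVA (omnibus)",
                 statistic = an$`F value`[1], p_value = an$`Pr(>F)`[1]),
      data.frame(comparison = rownames(tk),
                 statistic = tk[, "diff"], p_value = tk[, "p adj"]))
  }
  out$stars <- significance_stars(out$p_value)
  rownames(out) <- NULL
  out
}

#' Run the full flux-analysis pipeline
#'
#' Orchestrates the analysis in the order of the wet-lab workflow: read the
#' multiplet and perfusion tables, fit relative fluxes per liver, convert
#' oxygen consumption to V_TCA, scale into absolute fluxes, compute the
#' cycling indices, and test group differences (Welch DKO vs control within
#' each diet; ANOVA + Tukey across all groups).
#'
#' @param config list (or path to a JSON file) with fields:
#'   `multiplet_csv`, `perfusion_csv` (paths) or `multiplet_table`,
#'   `perfusion_records` (in-memory data frames); `output_dir` (optional;
#'   reports written when given); `dilution_mode`; `stoich` (named c_turn,
#'   c_pdh, c_fat); `n_starts`; `seed`; `medium_enrichment`; `verbose`
#' @return (invisibly) list with `per_liver`, `group_summary`,
#'   `group_tests`, `config`
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  cfg <- utils::modifyList(
    list(dilution_mode = "acetyl",
         stoich = c(c_turn = 2, c_pdh = 0.5, c_fat = 0.875),
         n_starts = 20, seed = 1, medium_enrichment = 0.99,
         output_dir = NULL, verbose = FALSE),
    config)
  tab <- cfg$multiplet_table %||% read_multiplet_table(cfg$multiplet_csv)
  perf <- cfg$perfusion_records %||% read_perfusion_records(cfg$perfusion_csv)
  if (nrow(tab) == 0) schema_error("multiplet table has no rows")
  say <- function(...) if (isTRUE(cfg$verbose)) message(...)
  say("pipeline: dilution_mode=", cfg$dilution_mode,
      " n_starts=", cfg$n_starts, " seed=", cfg$seed)

  network <- build_liver_network()
  livers <- unique(tab$liver_id)
  res <- list()
  for (li in seq_along(livers)) {
    id <- livers[li]
    sub <- tab[tab$liver_id == id, ]
    fit <- fit_relative_fluxes(sub, dilution_mode = cfg$dilution_mode,
                               n_starts = cfg$n_starts,
                               seed = cfg$seed + li, network = network)
    rec <- perf[perf$liver_id == id, ]
    if (nrow(rec) != 1) {
      schema_error(paste0("perfusion record missing or duplicated for liver ", id))
    }
    mvo2 <- oxygen_consumption(rec)
    v_tca <- tca_flux_from_mvo2(mvo2, fit, stoich = cfg$stoich)
    af <- absolute_fluxes(fit, v_tca, mvo2 = mvo2)
    lac <- sub[sub$carbon == "lac_C2", ]
    lac_index <- if (nrow(lac)) {
      lactate_cycling_index(stats::setNames(lac$fraction, lac$component))
    } else NA_real_
    res[[li]] <- data.frame(
      liver_id = id, group = sub$group[1],
      f_acetyl_labeled = fit$f_pdh_frac,
      f_pyr_medium = fit$fluxes$f_pyr_medium,
      y_pc = fit$fluxes$y_pc, y_pyc = fit$fluxes$y_pyc,
      residual = fit$residual, n_starts_converged = fit$n_starts_converged,
      mvo2 = mvo2, v_tca = v_tca, v_pdh = af$v_pdh, v_pc = af$v_pc,
      v_pyc = af$v_pyc, cycling_degree = cycling_degree(af),
      lactate_cycling_index = lac_index,
      glycogen_fraction = 1 - fit$fluxes$f_pyr_medium)
    say("fitted ", id, ": ssq=", signif(fit$residual, 3))
  }
  per_liver <- do.call(rbind, res)

  metrics <- c("mvo2", "v_tca", "v_pdh", "v_pc", "v_pyc", "cycling_degree")
  agg <- stats::aggregate(per_liver[metrics], by = list(group = per_liver$group),
                          function(x) c(mean = mean(x), sd = stats::sd(x)))
  group_summary <- do.call(data.frame, agg)

  tests <- list()
  grp <- per_liver$group
  diets <- unique(sub("-(control|DKO)$", "", grp))
  for (metric in metrics) {
    for (d in diets) {
      pair <- c(paste0(d, "-control"), paste0(d, "-DKO"))
      sel <- grp %in% pair
      if (length(unique(grp[sel])) == 2 && all(table(grp[sel]) >= 2)) {
        ct <- tryCatch(compare_groups(per_liver[[metric]][sel], grp[sel],
                                      "welch"),
                       error = function(e) {
                         data.frame(comparison = paste(sort(unique(grp[sel])),
                                                       collapse = " vs "),
                                    statistic = NA_real_, p_value = NA_real_,
                                    stars = "")
                       })
        ct$metric <- metric
        tests[[length(tests) + 1]] <- ct
      }
    }
    if (length(unique(grp)) > 2 && all(table(grp) >= 2)) {
      ct <- tryCatch(compare_groups(per_liver[[metric]], grp, "anova_tukey"),
                     error = function(e) NULL)
      if (!is.null(ct)) {
        ct$metric <- metric
        tests[[length(tests) + 1]] <- ct
      }
    }
  }
  group_tests <- if (length(tests)) do.call(rbind, tests) else NULL

  out <- list(per_liver = per_liver, group_summary = group_summary,
              group_tests = group_tests,
              config = cfg[c("dilution_mode", "stoich", "n_starts", "seed",
                             "medium_enrichment")])
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_liver, file.path(cfg$output_dir, "per_liver_fluxes.csv"),
                     row.names = FALSE)
    utils::write.csv(group_summary, file.path(cfg$output_dir, "group_summary.csv"),
                     row.names = FALSE)
    if (!is.null(group_tests)) {
      utils::write.csv(group_tests, file.path(cfg$output_dir, "group_tests.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(out[c("per_liver", "group_summary", "group_tests",
                               "config")],
                         file.path(cfg$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(out)
}
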