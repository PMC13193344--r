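# End-to-end orchestration: curves -> per-leaf traits -> population means
# -> comparative models -> tidy outputs with a JSON metadata sidecar.

#' Default pipeline configuration
#'
#' @param seed integer seed driving every stochastic stage.
#' @param out_dir output directory (created if needed).
#' @param n_replicates leaves per population for the simulated study.
#' @param aggregate `"population_means"` (replicates are averaged once, in
#'   a dedicated stage, before comparative modelling) or `"none"`.
#' @param pv a [pv_fit_config()].
#' @param models character vector of `response ~ predictor` formulas run
#'   through PGLS on the population-mean trait table; defaults to the
#'   standard anatomy-hydraulics set plus climate PC1 models.
#' @param asr_traits traits reconstructed on the tree.
#' @param alpha significance level for the letter displays.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("leafhydro_run_"),
                            n_replicates = 3,
                            aggregate = c("population_means", "none"),
                            pv = pv_fit_config(),
                            models = c("K_leaf ~ VLA2",
                                       "Psi_leaf ~ VLA2",
                                       "g_sat ~ VLA2",
                                       "C_bulk ~ BSA_per_width",
                                       "C_bulk ~ LT",
                                       "Psi_leaf ~ BSA_per_width",
                                       "Psi_TLP ~ BSA_per_width",
                                       "g_sat ~ K_leaf",
                                       "g_sat ~ C_bulk",
                                       "K_leaf ~ PC1",
                                       "C_bulk ~ PC1",
                                       "Psi_leaf ~ PC1"),
                            asr_traits = c("C_bulk", "K_leaf", "VLA2"),
                            alpha = 0.05) {
  aggregate <- match.arg(aggregate)
  structure(list(seed = seed, out_dir = out_dir,
                 n_replicates = n_replicates, aggregate = aggregate,
                 pv = pv, models = models, asr_traits = asr_traits,
                 alpha = alpha),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar fields of [pipeline_config()] can be overridden from YAML;
#' unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  raw <- yaml::read_yaml(path)
  allowed <- c("seed", "out_dir", "n_replicates", "aggregate", "models",
               "asr_traits", "alpha")
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}

stage_msg <- function(quiet, ...) if (!quiet) message("[leafhydro] ", ...)

#' Run the full analysis pipeline on a (simulated or supplied) study
#'
#' Stages: (1) per-leaf PV parameters; (2) light-response fits for
#' assimilation and conductance; (3) evaporative-flux K_leaf; (4) anatomy
#' traits and photosynthetic-type classification; (5) aggregation of
#' replicates to population means; (6) Kruskal-Wallis tests with compact
#' letter displays per trait across groups; (7) climate PCA and extraction
#' of PC1; (8) PGLS models for each configured trait ~ predictor pair;
#' (9) Brownian-motion ancestral states for the configured traits.  Every
#' intermediate is written as tidy CSV under `config$out_dir`, plus a JSON
#' run-metadata sidecar; outputs are a pure function of (inputs, config,
#' seed).
#'
#' @param config a [pipeline_config()].
#' @param study optional study list as produced by [simulate_study()]; by
#'   default one is simulated from `config$seed`.
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with the population trait table, model fits,
#'   letter displays, PCA, ASR results and the output directory.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(study)) {
    stage_msg(quiet, "simulating study (seed ", config$seed, ")")
    study <- simulate_study(seed = config$seed,
                            n_replicates = config$n_replicates)
  }

  fail <- function(stage, e, ctx = "")
    stop("pipeline stage '", stage, "' failed", if (nzchar(ctx))
      paste0(" [", ctx, "]"), ": ", conditionMessage(e), call. = FALSE)

  # --- stage: PV parameters per leaf -------------------------------------
  stage_msg(quiet, "PV parameters for ", length(study$pv_curves), " leaves")
  pv_tab <- tryCatch({
    tabs <- lapply(names(study$pv_curves), function(key) {
      obs <- study$pv_curves[[key]]
      cfg <- config$pv
      fl <- attr(obs, "psi_floor")
      if (!is.null(fl)) cfg$psi_floor <- min(cfg$psi_floor, fl)
      res <- derive_pv_parameters(obs, cfg)
      data.frame(leaf_id = key,
                 population = sub("_leaf\\d+$", "", key),
                 psi_tlp = res$psi_tlp, psi_ft = res$psi_ft,
                 rwc_tlp = res$rwc_tlp, awf = res$awf,
                 epsilon = res$epsilon, c_bulk = res$c_bulk,
                 r2_osmotic = res$r2_osmotic)
    })
    do.call(rbind, tabs)
  }, error = function(e) fail("pv_parameters", e))
  utils::write.csv(pv_tab, file.path(config$out_dir, "pv_params.csv"),
                   row.names = FALSE, quote = FALSE)

  # --- stage: light-response fits ----------------------------------------
  stage_msg(quiet, "light-response fits")
  light_tab <- tryCatch({
    rows <- lapply(names(study$light_assim), function(key) {
      fa <- fit_nonrectangular_hyperbola(study$light_assim[[key]])
      fg <- fit_nonrectangular_hyperbola(study$light_cond[[key]])
      data.frame(leaf_id = key,
                 population = sub("_leaf\\d+$", "", key),
                 A_sat = fa$sat, phi = fa$phi, theta = fa$theta,
                 R_d = fa$offset, rmse_A = fa$rmse,
                 g_sat = fg$sat, phi0 = fg$phi, theta0 = fg$theta,
                 g_0 = fg$offset, rmse_g = fg$rmse)
    })
    do.call(rbind, rows)
  }, error = function(e) fail("light_response", e))
  utils::write.csv(light_tab, file.path(config$out_dir, "light_fits.csv"),
                   row.names = FALSE, quote = FALSE)

  # --- stage: K_leaf ------------------------------------------------------
  stage_msg(quiet, "evaporative-flux K_leaf")
  kleaf_tab <- tryCatch(
    data.frame(leaf_id = study$spots$id, population = study$spots$population,
               K_leaf = compute_kleaf(study$spots$E, study$spots$psi_stem,
                                      study$spots$psi_leaf),
               Psi_leaf = study$spots$psi_leaf),
    error = function(e) fail("kleaf", e))
  utils::write.csv(kleaf_tab, file.path(config$out_dir, "kleaf.csv"),
                   row.names = FALSE, quote = FALSE)

  # --- stage: anatomy -----------------------------------------------------
  stage_msg(quiet, "anatomy traits")
  anat_tab <- tryCatch(
    do.call(rbind, lapply(study$anatomy, anatomy_traits)),
    error = function(e) fail("anatomy", e))
  utils::write.csv(anat_tab, file.path(config$out_dir, "anatomy.csv"),
                   row.names = FALSE, quote = FALSE)

  # --- stage: aggregate to population means ------------------------------
  stage_msg(quiet, "aggregating to population means")
  agg <- function(df, cols) {
    out <- stats::aggregate(df[cols], list(population = df$population), mean)
    rownames(out) <- out$population
    out$population <- NULL
    out
  }
  pv_mean <- agg(pv_tab, c("psi_tlp", "psi_ft", "rwc_tlp", "awf",
                           "epsilon", "c_bulk"))
  light_mean <- agg(light_tab, c("A_sat", "g_sat"))
  kleaf_mean <- agg(kleaf_tab, c("K_leaf", "Psi_leaf"))
  pops <- rownames(study$populations)
  traits <- data.frame(
    row.names = pops,
    group = study$populations$group,
    type = classify_photosynthetic_type(study$populations$d13c),
    Psi_TLP = pv_mean[pops, "psi_tlp"],
    Psi_FT = pv_mean[pops, "psi_ft"],
    RWC_TLP = pv_mean[pops, "rwc_tlp"],
    AWF = pv_mean[pops, "awf"],
    epsilon = pv_mean[pops, "epsilon"],
    C_bulk = pv_mean[pops, "c_bulk"],
    A_sat = light_mean[pops, "A_sat"],
    g_sat = light_mean[pops, "g_sat"],
    K_leaf = kleaf_mean[pops, "K_leaf"],
    Psi_leaf = kleaf_mean[pops, "Psi_leaf"],
    VLA2 = anat_tab[pops, "minor_vla"],
    major_VLA = anat_tab[pops, "major_vla"],
    BSA_per_width = anat_tab[pops, "bsa_per_width"],
    LT = anat_tab[pops, "leaf_thickness"],
    d13c = anat_tab[pops, "d13c"])

  # --- stage: climate PCA -------------------------------------------------
  stage_msg(quiet, "climate PCA")
  pca <- tryCatch(climate_pca(study$climate),
                  error = function(e) fail("climate_pca", e))
  traits$PC1 <- pca$scores[pops, 1]
  traits$PC2 <- pca$scores[pops, 2]
  utils::write.csv(
    data.frame(component = seq_along(pca$prop_var),
               prop_var = pca$prop_var),
    file.path(config$out_dir, "pca_variance.csv"), row.names = FALSE,
    quote = FALSE)
  utils::write.csv(cbind(population = rownames(pca$scores),
                         as.data.frame(pca$scores)),
                   file.path(config$out_dir, "pca_scores.csv"),
                   row.names = FALSE, quote = FALSE)

  write_trait_table(traits, file.path(config$out_dir, "trait_table.csv"),
                    metadata = list(seed = config$seed,
                                    n_replicates = config$n_replicates,
                                    aggregate = config$aggregate))

  # --- stage: group comparisons ------------------------------------------
  stage_msg(quiet, "Kruskal-Wallis + letter displays")
  kw_traits <- c("RWC_TLP", "AWF", "epsilon", "Psi_TLP", "Psi_FT",
                 "C_bulk", "K_leaf")
  letters_tab <- do.call(rbind, lapply(kw_traits, function(tr) {
    per_leaf <- switch(tr,
      K_leaf = stats::setNames(kleaf_tab$K_leaf, kleaf_tab$population),
      RWC_TLP = stats::setNames(pv_tab$rwc_tlp, pv_tab$population),
      AWF = stats::setNames(pv_tab$awf, pv_tab$population),
      epsilon = stats::setNames(pv_tab$epsilon, pv_tab$population),
      Psi_TLP = stats::setNames(pv_tab$psi_tlp, pv_tab$population),
      Psi_FT = stats::setNames(pv_tab$psi_ft, pv_tab$population),
      C_bulk = stats::setNames(pv_tab$c_bulk, pv_tab$population))
    grp <- study$populations[names(per_leaf), "group"]
    kw <- kruskal_wallis(as.numeric(per_leaf), g = grp)
    cld <- compact_letter_display(as.numeric(per_leaf), g = grp,
                                  alpha = config$alpha)
    data.frame(trait = tr, group = names(cld), letters = unname(cld),
               H = kw$H, p = kw$p_value)
  }))
  utils::write.csv(letters_tab, file.path(config$out_dir, "letters.csv"),
                   row.names = FALSE, quote = FALSE)

  # --- stage: PGLS --------------------------------------------------------
  stage_msg(quiet, "PGLS models (", length(config$models), ")")
  pgls_rows <- lapply(config$models, function(fm) {
    fit <- tryCatch(
      suppressWarnings(pgls_fit(stats::as.formula(fm), traits, study$tree)),
      error = function(e) fail("pgls", e, fm))
    slope_row <- which(rownames(fit$coefficients) != "(Intercept)")[1]
    data.frame(model = fm, lambda = fit$lambda,
               slope = fit$coefficients$estimate[slope_row],
               slope_p = fit$coefficients$p[slope_row],
               r2 = fit$r2, adj_r2 = fit$adj_r2, n = fit$n)
  })
  pgls_tab <- do.call(rbind, pgls_rows)
  utils::write.csv(pgls_tab, file.path(config$out_dir, "pgls_fits.csv"),
                   row.names = FALSE, quote = FALSE)

  # --- stage: ancestral states -------------------------------------------
  stage_msg(quiet, "ancestral state reconstruction")
  asr_list <- lapply(config$asr_traits, function(tr) {
    x <- stats::setNames(traits[[tr]], rownames(traits))
    res <- tryCatch(ancestral_states_bm(study$tree, x),
                    error = function(e) fail("asr", e, tr))
    utils::write.csv(res$states,
                     file.path(config$out_dir, paste0("asr_", tr, ".csv")),
                     row.names = FALSE, quote = FALSE)
    res
  })
  names(asr_list) <- config$asr_traits

  # --- run metadata -------------------------------------------------------
  summary <- list(
    package = "leafhydro",
    version = as.character(utils::packageVersion("leafhydro")),
    seed = config$seed,
    n_populations = nrow(study$populations),
    n_replicates = config$n_replicates,
    models = config$models,
    asr_traits = config$asr_traits,
    outputs = list.files(config$out_dir))
  jsonlite::write_json(summary, file.path(config$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(traits = traits, pv = pv_tab, light = light_tab,
                 kleaf = kleaf_tab, anatomy = anat_tab, letters = letters_tab,
                 pgls = pgls_tab, pca = pca, asr = asr_list,
                 out_dir = config$out_dir))
}
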