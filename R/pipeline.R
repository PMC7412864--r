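# End-to-end orchestration: simulate (or load) -> validate -> standardize ->
# cluster -> PLS -> component selection -> correlation profiles ->
# diffusion fits -> uptake and GAG statistics, with a reproducibility
# manifest. Each stage consumes a sub-seed derived from the master seed by a
# fixed counter scheme, so any stage can be re-run in isolation.

#' Build a pipeline run configuration
#'
#' Either point the pipeline at existing CSV inputs (`descriptors_csv`,
#' `responses_csv`, `traces_csv`, `gag_csv`) or let it simulate a study
#' bundle (`simulate = TRUE`, the default) with [write_study_bundle()].
#'
#' @param out_dir Output directory for result files and the manifest.
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @param simulate Simulate inputs when file paths are absent (default TRUE).
#' @param sim_config A [library_sim_config()] used when simulating.
#' @param descriptors_csv,responses_csv,traces_csv,gag_csv Optional input
#'   paths; when given they are used instead of simulation.
#' @param scale Standardize descriptors before distances/PLS (default TRUE).
#' @param max_components Maximum PLS components to fit (default 10).
#' @param variance_threshold Cumulative X-variance threshold for component
#'   selection (default 0.80).
#' @param alpha Significance level for uptake flags and post hoc tests
#'   (default 0.05).
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = TRUE,
                       sim_config = library_sim_config(),
                       descriptors_csv = NULL, responses_csv = NULL,
                       traces_csv = NULL, gag_csv = NULL,
                       scale = TRUE, max_components = 10L,
                       variance_threshold = 0.80, alpha = 0.05) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), simulate = simulate,
              sim_config = sim_config, descriptors_csv = descriptors_csv,
              responses_csv = responses_csv, traces_csv = traces_csv,
              gag_csv = gag_csv, scale = scale,
              max_components = as.integer(max_components),
              variance_threshold = variance_threshold, alpha = alpha)
  if (!simulate) {
    files <- c(descriptors = descriptors_csv, responses = responses_csv)
    if (is.null(descriptors_csv)) {
      stop("config lacks both a descriptors file and a simulation block")
    }
    if (is.null(responses_csv)) {
      stop("config lacks both a responses file and a simulation block")
    }
    miss <- files[!file.exists(unlist(files))]
    if (length(miss)) stop("missing input file(s): ",
                           paste(unlist(miss), collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()]
#'   (with `sim_config` as a nested map of [library_sim_config()] arguments).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim_config)) {
    y$sim_config <- do.call(library_sim_config, y$sim_config)
  }
  do.call(run_config, y)
}

# documented sub-seed scheme: stage k of master seed s uses s * 1000 + k
# (masters are expected small; kept far below .Machine$integer.max)
stage_seed <- function(master, k) as.integer(master %% 1000000L) * 1000L + k

#' Run the full chemometric analysis pipeline
#'
#' Sequences every stage of the screening analysis and writes all result
#' files plus a JSON reproducibility manifest (input hashes, config, key
#' outputs). Deterministic under a fixed master seed; a failure in any stage
#' aborts with a stage-labelled error.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (list; also written to
#'   `out_dir/manifest.json`).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  log_line <- function(...) message(sprintf(...))
  outputs <- character()
  key <- list()

  # -- inputs --------------------------------------------------------------
  inputs <- stage("inputs", {
    if (config$simulate && is.null(config$descriptors_csv)) {
      paths <- write_study_bundle(file.path(config$out_dir, "inputs"),
                                  config = config$sim_config,
                                  seed = stage_seed(config$seed, 1L))
      as.list(paths)
    } else {
      list(descriptors = config$descriptors_csv,
           responses = config$responses_csv,
           traces = config$traces_csv, gag = config$gag_csv)
    }
  })
  tbl <- stage("load", read_descriptor_table(inputs$descriptors))
  responses <- stage("load", utils::read.csv(inputs$responses))
  log_line("inputs: %d polymers x %d descriptors", nrow(tbl$values),
           ncol(tbl$values))

  # -- validation + standardization ---------------------------------------
  report <- stage("validate", validate_library(tbl))
  std <- stage("standardize", {
    if (config$scale) standardize_descriptors(tbl) else NULL
  })

  # -- clustering ----------------------------------------------------------
  clust <- stage("clustering", {
    d <- manhattan_distances(if (config$scale) std else tbl,
                             scale = config$scale)
    tree <- cluster_polymers(d)
    f_newick <- file.path(config$out_dir, "cluster_tree.nwk")
    f_merges <- file.path(config$out_dir, "cluster_merges.csv")
    tree_to_newick(tree, f_newick)
    write_merge_table(tree, f_merges)
    outputs <- c(outputs, f_newick, f_merges)
    tree
  })
  log_line("clustering: %d merges, max height %.3g", nrow(clust$merges),
           max(clust$merges$height))

  # -- PLS -----------------------------------------------------------------
  pls <- stage("pls", {
    x <- if (config$scale) std$z_values else tbl$values
    y <- log(as.matrix(responses[, c("e1", "e2")]))
    H <- min(config$max_components, nrow(x) - 1L, ncol(x))
    model <- fit_pls(x, y, ncomp = H, max_iter = 10000L)
    scree <- rmse_scree(model)
    sel <- suppressWarnings(
      select_components(scree, model$r2x_cum,
                        threshold = config$variance_threshold))
    f_var <- file.path(config$out_dir, "pls_variance.csv")
    f_load <- file.path(config$out_dir, "pls_loading_map.csv")
    f_model <- file.path(config$out_dir, "pls_model.json")
    utils::write.csv(variance_tables(model), f_var, row.names = FALSE)
    utils::write.csv(loading_map(model), f_load, row.names = FALSE)
    write_pls_model(model, f_model)
    # per-end-cap importance profiles at the selected component count
    f_imp <- file.path(config$out_dir, "pls_importance.csv")
    imp <- do.call(rbind, lapply(c("e1", "e2"), function(ec) {
      m1 <- fit_pls(x, y[, ec, drop = FALSE],
                    ncomp = min(sel$h_selected, nrow(x) - 1L, ncol(x)))
      cbind(endcap = ec,
            variable_response_correlations(m1, h = m1$ncomp))
    }))
    utils::write.csv(imp, f_imp, row.names = FALSE)
    outputs <- c(outputs, f_var, f_load, f_model, f_imp)
    list(model = model, scree = scree, selection = sel)
  })
  log_line("pls: h_selected = %d (elbow), h_variance = %s, Y-R2 cum = %.3f",
           pls$selection$h_selected,
           ifelse(is.na(pls$selection$h_variance), "none",
                  pls$selection$h_variance),
           pls$model$r2y_cum[pls$selection$h_selected])

  # -- diffusion -----------------------------------------------------------
  diffusion <- stage("diffusion", {
    if (is.null(inputs$traces)) NULL else {
      f_fits <- file.path(config$out_dir, "diffusion_fits.csv")
      fits <- fit_diffusion_table(inputs$traces, path = f_fits)
      outputs <- c(outputs, f_fits)
      fits
    }
  })
  if (!is.null(diffusion)) {
    key$mean_D_mm2_per_min <- mean(diffusion$D_mm2_per_min)
    log_line("diffusion: %d fits, mean D = %.3g mm^2/min", nrow(diffusion),
             key$mean_D_mm2_per_min)
  }

  # -- uptake statistics ---------------------------------------------------
  uptake <- stage("uptake", {
    if (is.null(inputs$uptake)) NULL else {
    u <- utils::read.csv(inputs$uptake)
    keys <- unique(u[, c("polymer_id", "endcap", "time_min")])
    res <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
      g <- merge(u, keys[i, , drop = FALSE])
      r <- uptake_ratio(g$uptake_ug_per_mg[g$arm == "conjugate"],
                        g$uptake_ug_per_mg[g$arm == "reference"])
      data.frame(keys[i, , drop = FALSE], ratio = r$ratio,
                 direction = r$direction, p_one_tailed = r$p_one_tailed)
    }))
    flags <- flag_significant_uptake(res, alpha = config$alpha)
    f_upt <- file.path(config$out_dir, "uptake_ratios.csv")
    utils::write.csv(flags, f_upt, row.names = FALSE)
    outputs <- c(outputs, f_upt)
    flags
    }
  })
  if (!is.null(uptake)) {
    key$n_significant_uptake <- sum(uptake$significant)
    key$max_uptake_ratio <- max(uptake$ratio)
    log_line("uptake: %d/%d polymer x time cells significant, max ratio %.3g",
             key$n_significant_uptake, nrow(uptake), key$max_uptake_ratio)
  }

  # -- GAG efficacy --------------------------------------------------------
  gag <- stage("gag", {
    if (is.null(inputs$gag)) NULL else {
    g <- utils::read.csv(inputs$gag)
    cv <- gag_cumulative_variation(g)
    last_day <- max(cv$per_sample$day)
    final <- cv$per_sample[cv$per_sample$day == last_day, ]
    av <- one_way_anova(final$variation_pct, final$group)
    tk <- tukey_hsd(final$variation_pct, final$group)
    f_gag <- file.path(config$out_dir, "gag_variation.csv")
    f_tukey <- file.path(config$out_dir, "gag_tukey.csv")
    utils::write.csv(cv$summary, f_gag, row.names = FALSE)
    utils::write.csv(tk, f_tukey, row.names = FALSE)
    outputs <- c(outputs, f_gag, f_tukey)
    list(variation = cv, anova = av, tukey = tk, day = last_day)
    }
  })
  if (!is.null(gag)) {
    key$gag_anova_p_final_day <- gag$anova$p
    log_line("gag: day %d ANOVA F = %.3g (p = %.3g)", gag$day, gag$anova$F,
             key$gag_anova_p_final_day)
  }

  # -- manifest ------------------------------------------------------------
  manifest <- list(
    package = "pbaescreen",
    version = as.character(utils::packageVersion("pbaescreen")),
    seed = config$seed,
    config = list(scale = config$scale,
                  max_components = config$max_components,
                  variance_threshold = config$variance_threshold,
                  alpha = config$alpha,
                  simulate = config$simulate,
                  sim_config = if (config$simulate) {
                    unclass(config$sim_config)
                  } else NULL),
    inputs = lapply(Filter(Negate(is.null), inputs), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    validation = list(missing = nrow(report$missing),
                      constant = length(report$constant_columns),
                      high_correlation_pairs = nrow(report$high_correlations)),
    key_outputs = c(list(
      h_selected = pls$selection$h_selected,
      h_variance = pls$selection$h_variance,
      r2y_cum_selected = pls$model$r2y_cum[pls$selection$h_selected]),
      key),
    output_files = lapply(outputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  f_manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  log_line("manifest written to %s", f_manifest)
  invisible(manifest)
}
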