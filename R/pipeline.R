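# Configuration and end-to-end orchestration: one config drives
# simulate -> mind -> gradient -> contrast -> spatial -> pls -> enrich ->
# importance, writing headered delimited text plus a JSON manifest with file
# hashes so two runs from the same config are verifiably identical.

#' Build a pipeline configuration
#'
#' Returns the complete parameter set for [run_pipeline()]. Defaults give a
#' small synthetic study (68 regions, 12 cases + 12 controls, 500 genes,
#' 500 spins) that runs end-to-end on one CPU in a few minutes; the
#' morphometric parameters (k = 1 neighbour, top-10% row threshold,
#' alpha = 0.5) are the standard MIND-gradient settings. Stage seeds are
#' derived deterministically from `seed`.
#'
#' @param out_dir Output directory.
#' @param seed Master integer seed.
#' @param regions_per_hemisphere,n_cases,n_controls Cohort dimensions.
#' @param effect_regions,effect_size Planted group effect (vertex level).
#' @param n_genes,loading_fraction,expression_noise_sd Expression generator.
#' @param k KL neighbour order; `fraction` row-threshold fraction; `alpha`
#'   diffusion normalization; `n_gradients` embedding components.
#' @param n_spins,n_boot,pls_components,n_null Statistical stage sizes.
#' @param stages Character vector of stages to run (dependencies are the
#'   caller's responsibility; later stages read earlier stages' outputs from
#'   memory, so skipping an upstream stage marks its dependents stale).
#' @return A `pipeline_config` list; round-trips losslessly through YAML via
#'   [write_pipeline_config()] / [read_pipeline_config()].
#' @export
pipeline_config <- function(out_dir = tempfile("mindgrad-run-"),
                            seed = 1L,
                            regions_per_hemisphere = 34L,
                            n_cases = 12L, n_controls = 12L,
                            effect_regions = c(3L, 4L),
                            effect_size = 1.0,
                            n_genes = 500L,
                            loading_fraction = 0.3,
                            expression_noise_sd = 0.5,
                            k = 1L, fraction = 0.1, alpha = 0.5,
                            n_gradients = 10L,
                            n_spins = 500L, n_boot = 500L,
                            pls_components = 10L, n_null = 500L,
                            stages = c("simulate", "mind", "gradient",
                                       "contrast", "spatial", "pls",
                                       "enrich", "importance")) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    regions_per_hemisphere = as.integer(regions_per_hemisphere),
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    effect_regions = as.integer(effect_regions),
    effect_size = effect_size,
    n_genes = as.integer(n_genes),
    loading_fraction = loading_fraction,
    expression_noise_sd = expression_noise_sd,
    k = as.integer(k), fraction = fraction, alpha = alpha,
    n_gradients = as.integer(n_gradients),
    n_spins = as.integer(n_spins), n_boot = as.integer(n_boot),
    pls_components = as.integer(pls_components),
    n_null = as.integer(n_null),
    stages = stages,
    # explicit per-stage seeds, all derived from the master seed
    seeds = list(parcellation = as.integer(seed),
                 cohort = as.integer(seed) + 1000L,
                 annotation = as.integer(seed) + 2000L,
                 expression = as.integer(seed) + 3000L,
                 spins = as.integer(seed) + 4000L,
                 bootstrap = as.integer(seed) + 5000L,
                 null_draws = as.integer(seed) + 6000L)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#' @param config A `pipeline_config`.
#' @param path File path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$effect_regions <- as.integer(cfg$effect_regions)
  int_fields <- c("seed", "regions_per_hemisphere", "n_cases", "n_controls",
                  "n_genes", "k", "n_gradients", "n_spins", "n_boot",
                  "pls_components", "n_null")
  for (f in int_fields) cfg[[f]] <- as.integer(cfg[[f]])
  cfg$seeds <- lapply(cfg$seeds, as.integer)
  class(cfg) <- "pipeline_config"
  cfg
}

write_matrix_csv <- function(M, path) {
  df <- tibble::as_tibble(M, rownames = "region_id")
  readr::write_csv(df, path)
  path
}

#' Run the full synthetic study end-to-end
#'
#' Executes the configured stages in order, writes every result as headered
#' delimited text under `config$out_dir`, and returns (and writes) a JSON
#' manifest recording stage parameters, seeds, and an md5 hash of every
#' output file. Identical configs produce identical manifests.
#'
#' @param config A `pipeline_config`.
#' @param verbose Print stage progress.
#' @return The manifest, invisibly (list with `parameters`, `stages`,
#'   `files` incl. md5 hashes).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  files <- character()
  note <- function(p) { files <<- c(files, p); p }
  ran <- character()
  state <- new.env(parent = emptyenv())

  stage_on <- function(s) s %in% config$stages
  need <- function(s, dep) {
    if (!exists(dep, envir = state)) {
      abort(sprintf("stage '%s' failed: upstream stage output '%s' missing (stage skipped or stale)",
                    s, dep), class = "mindgrad_stage_error")
    }
    get(dep, envir = state)
  }

  if (stage_on("simulate")) {
    say("simulate: R = %d, %d + %d subjects, %d genes",
        2 * config$regions_per_hemisphere, config$n_cases, config$n_controls,
        config$n_genes)
    parc <- generate_parcellation(config$regions_per_hemisphere,
                                  seed = config$seeds$parcellation)
    cohort <- generate_cohort(parc, config$n_cases, config$n_controls,
                              effect_regions = config$effect_regions,
                              effect_size = config$effect_size,
                              seed = config$seeds$cohort)
    panel <- generate_annotation_panel(parc, seed = config$seeds$annotation)
    left <- parc[parc$hemisphere == "L", ]
    axis_map <- generate_annotation_map(parc, smoothness = 0.5,
                                        seed = config$seeds$annotation + 500L)
    expr <- generate_expression(
      parc, config$n_genes,
      target_map = axis_map$value[parc$hemisphere == "L"],
      loading_fraction = config$loading_fraction,
      noise_sd = config$expression_noise_sd,
      seed = config$seeds$expression)
    assign("parc", parc, state); assign("cohort", cohort, state)
    assign("panel", panel, state); assign("expr", expr, state)
    assign("axis_map", axis_map, state)
    readr::write_csv(parc, out("parcellation.csv"))
    note(out("parcellation.csv"))
    readr::write_csv(cohort$covariates, out("covariates.csv"))
    note(out("covariates.csv"))
    readr::write_csv(cohort$vertices, out("vertices.csv"))
    note(out("vertices.csv"))
    readr::write_csv(panel$info, out("panel_info.csv"))
    note(out("panel_info.csv"))
    note(write_matrix_csv(panel$values, out("panel_values.csv")))
    readr::write_csv(expr$genes, out("gene_classes.csv"))
    note(out("gene_classes.csv"))
    note(write_matrix_csv(expr$expression, out("expression.tsv")))
    ran <- c(ran, "simulate")
  }

  if (stage_on("mind")) {
    parc <- need("mind", "parc"); cohort <- need("mind", "cohort")
    say("mind: k = %d", config$k)
    minds <- build_cohort_mind(cohort$vertices, parc, k = config$k)
    assign("minds", minds, state)
    for (sid in names(minds)) {
      note(write_matrix_csv(minds[[sid]]$values,
                            out(sprintf("mind_%s.csv", sid))))
    }
    ran <- c(ran, "mind")
  }

  if (stage_on("gradient")) {
    minds <- need("gradient", "minds")
    say("gradient: fraction = %.2f, alpha = %.2f, %d components",
        config$fraction, config$alpha, config$n_gradients)
    grads <- fit_cohort_gradients(minds, fraction = config$fraction,
                                  alpha = config$alpha,
                                  n_components = config$n_gradients)
    assign("grads", grads, state)
    note(write_matrix_csv(grads$gradient1, out("gradient1.csv")))
    note(write_matrix_csv(grads$template$components, out("template.csv")))
    readr::write_csv(
      tibble::tibble(component = seq_along(grads$template$variance_explained),
                     variance_explained = grads$template$variance_explained),
      out("template_variance.csv"))
    note(out("template_variance.csv"))
    ran <- c(ran, "gradient")
  }

  if (stage_on("contrast")) {
    grads <- need("contrast", "grads"); cohort <- need("contrast", "cohort")
    parc <- need("contrast", "parc")
    say("contrast: covariate GLM + BH-FDR")
    contrast <- fit_region_glm(grads$gradient1, cohort$covariates)
    by_network <- aggregate_by_label(grads$gradient1, cohort$covariates,
                                     parc, "network")
    by_class <- aggregate_by_label(grads$gradient1, cohort$covariates,
                                   parc, "class")
    grp <- cohort$covariates$group
    ks <- distribution_test(rowMeans(grads$gradient1[grp == "case", , drop = FALSE]),
                            rowMeans(grads$gradient1[grp == "control", , drop = FALSE]))
    assign("contrast", contrast, state)
    readr::write_csv(contrast, out("contrast.csv")); note(out("contrast.csv"))
    readr::write_csv(by_network, out("contrast_network.csv"))
    note(out("contrast_network.csv"))
    readr::write_csv(by_class, out("contrast_class.csv"))
    note(out("contrast_class.csv"))
    readr::write_csv(ks, out("distribution_test.csv"))
    note(out("distribution_test.csv"))
    ran <- c(ran, "contrast")
  }

  if (stage_on("spatial")) {
    parc <- need("spatial", "parc"); contrast <- need("spatial", "contrast")
    panel <- need("spatial", "panel"); grads <- need("spatial", "grads")
    cohort <- need("spatial", "cohort")
    say("spatial: %d spins", config$n_spins)
    ens <- build_spin_ensemble(parc, config$n_spins, config$seeds$spins)
    assign("ens", ens, state)
    pc <- panel_correlations(contrast, panel, ens)
    ei <- ei_ratio(panel)
    ctrl_mean <- colMeans(grads$gradient1[cohort$covariates$group == "control", ,
                                          drop = FALSE])
    ref <- tmap_vs_reference(contrast, ctrl_mean, ens)
    assign("ei", ei, state)
    readr::write_csv(pc, out("panel_correlations.csv"))
    note(out("panel_correlations.csv"))
    readr::write_csv(ei, out("ei_ratio.csv")); note(out("ei_ratio.csv"))
    readr::write_csv(ref, out("tmap_vs_control_mean.csv"))
    note(out("tmap_vs_control_mean.csv"))
    ran <- c(ran, "spatial")
  }

  if (stage_on("pls")) {
    parc <- need("pls", "parc"); contrast <- need("pls", "contrast")
    expr <- need("pls", "expr"); ens <- need("pls", "ens")
    say("pls: %d components, %d bootstraps", config$pls_components,
        config$n_boot)
    left_ids <- parc$region_id[parc$hemisphere == "L"]
    ens_left <- subset_spin_ensemble(ens, left_ids)
    t_left <- contrast$t[match(left_ids, contrast$region_id)]
    pls <- decode_pls(expr$expression, t_left, ens_left,
                      n_components = config$pls_components,
                      n_boot = config$n_boot,
                      seed = config$seeds$bootstrap)
    score_cor <- score_target_correlation(pls, t_left, ens_left)
    assign("pls", pls, state); assign("left_ids", left_ids, state)
    assign("ens_left", ens_left, state); assign("t_left", t_left, state)
    readr::write_csv(pls$predictors, out("pls_predictors.csv"))
    note(out("pls_predictors.csv"))
    note(write_matrix_csv(pls$region_scores, out("pls_scores.csv")))
    jsonlite::write_json(
      list(variance_explained = pls$variance_explained_y,
           p_spin_component1 = pls$p_spin_component1,
           score_tmap_r = score_cor$r, score_tmap_p_spin = score_cor$p_spin),
      out("pls_summary.json"), auto_unbox = TRUE, digits = NA)
    note(out("pls_summary.json"))
    pos <- pls$predictors$predictor[pls$predictors$significant &
                                      pls$predictors$direction == "positive"]
    neg <- pls$predictors$predictor[pls$predictors$significant &
                                      pls$predictors$direction == "negative"]
    writeLines(pos, out("pls1_positive.txt")); note(out("pls1_positive.txt"))
    writeLines(neg, out("pls1_negative.txt")); note(out("pls1_negative.txt"))
    ran <- c(ran, "pls")
  }

  if (stage_on("enrich")) {
    pls <- need("enrich", "pls"); expr <- need("enrich", "expr")
    say("enrich: %d null draws", config$n_null)
    sig_pos <- pls$predictors$predictor[pls$predictors$significant &
                                          pls$predictors$direction == "positive"]
    if (!length(sig_pos)) {
      sig_pos <- pls$predictors$predictor[order(-pls$predictors$z)[1:10]]
    }
    enr <- null_ratio_enrichment(sig_pos, expr$genes, expr$genes$gene_id,
                                 n_null = config$n_null,
                                 seed = config$seeds$null_draws)
    readr::write_csv(enr, out("enrichment.csv")); note(out("enrichment.csv"))
    ran <- c(ran, "enrich")
  }

  if (stage_on("importance")) {
    pls <- need("importance", "pls"); panel <- need("importance", "panel")
    ei <- need("importance", "ei"); parc <- need("importance", "parc")
    ens_left <- need("importance", "ens_left")
    t_left <- need("importance", "t_left")
    say("importance: exact LMG, %d bootstraps", config$n_boot)
    left <- parc$hemisphere == "L"
    predictors <- cbind(
      pls1_score = pls$region_scores[, 1],
      map_a = panel$values[left, 1],
      map_b = panel$values[left, 9],
      ei_ratio = ei$value[left]
    )
    imp <- fit_importance(t_left, predictors, ensemble = ens_left,
                          n_boot = config$n_boot,
                          seed = config$seeds$bootstrap + 1L)
    readr::write_csv(imp$shares, out("importance_shares.csv"))
    note(out("importance_shares.csv"))
    jsonlite::write_json(
      list(r2 = imp$r2, adjusted_r2 = imp$adjusted_r2,
           p_spin_fit = imp$p_spin_fit),
      out("importance_summary.json"), auto_unbox = TRUE, digits = NA)
    note(out("importance_summary.json"))
    ran <- c(ran, "importance")
  }

  files <- unique(files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mindgrad")),
    parameters = unclass(config)[setdiff(names(unclass(config)),
                                         c("out_dir", "stages"))],
    stages_run = ran,
    stale = setdiff(c("simulate", "mind", "gradient", "contrast", "spatial",
                      "pls", "enrich", "importance"), ran),
    files = lapply(setNames(nm = basename(files)), function(f) {
      list(md5 = unname(tools::md5sum(file.path(config$out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
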