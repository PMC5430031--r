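#' Run the full SSM analysis pipeline
#'
#' Orchestrates simulate (or load) -> decompose -> select -> bootstrap ->
#' inference, writing every stage's artifacts under `out_dir` and a JSON
#' reproducibility manifest (config snapshot, seeds, per-stage wall clock,
#' content hashes of every output, selected components, headline statistics).
#'
#' A single master seed governs the run; per-stage seeds are derived from it
#' deterministically.  With `resume = TRUE`, a stage whose output files
#' already exist is not recomputed: its artifacts are loaded from disk, so
#' deleting a downstream stage's outputs and rerunning regenerates only that
#' stage.
#'
#' @param config a named list, or path to a YAML file, with optional
#'   elements `seed` (master seed, default 1), `simulate` (overrides passed
#'   to [synthetic_config()]), `inputs` (instead of `simulate`: list with
#'   `images` (vector of NIfTI paths or a directory), `mask`, `covariates`,
#'   optional `schema`), `select` (`k_max`, `max_subset`, `use_aicc`),
#'   `bootstrap` (`n_iterations`, `z_crit`, `z_cap`, `fixed_subset`), and
#'   `inference` (`wmh_floor_cc`).
#' @param out_dir output directory.
#' @param resume reuse existing stage outputs (default `TRUE`).
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly, as a list.  Side effects: files under
#'   `out_dir/data`, `out_dir/decomposition`, `out_dir/pattern`,
#'   `out_dir/bootstrap`, `out_dir/inference`, plus `manifest.json`.
#' @export
run_ssm_pipeline <- function(config = list(), out_dir, resume = TRUE,
                             quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  say <- function(...) if (!quiet) message(...)
  master_seed <- as.integer(config$seed %||% 1L)
  sel_cfg <- utils::modifyList(list(k_max = 8L, max_subset = 4L,
                                    use_aicc = FALSE), config$select %||% list())
  boot_cfg <- utils::modifyList(list(n_iterations = 500L, z_crit = 2,
                                     z_cap = 50, fixed_subset = NULL),
                                config$bootstrap %||% list())
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (f in c(if (!is.null(inp$mask)) inp$mask, inp$covariates))
      if (!file.exists(f)) stop("input does not exist: ", f)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_time <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    stage_time[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # ---- stage: data (simulate or load) --------------------------------------
  data_dir <- file.path(out_dir, "data")
  dataset <- timed("data", {
    if (!is.null(config$inputs)) {
      inp <- config$inputs
      imgs <- inp$images
      if (length(imgs) == 1L && dir.exists(imgs))
        imgs <- sort(list.files(imgs, pattern = "\\.nii(\\.gz)?$",
                                full.names = TRUE))
      gmv <- load_gmv_dataset(imgs, inp$mask)
      cov <- load_covariates(inp$covariates, inp$schema)
      cov <- add_derived_covariates(
        cov, wmh_floor_cc = config$inference$wmh_floor_cc)
      say("data: loaded ", nrow(gmv$data), " subjects")
      list(gmv = gmv, covariates = cov)
    } else {
      cov_path <- file.path(data_dir, "covariates.csv")
      if (resume && file.exists(cov_path) &&
          file.exists(file.path(data_dir, "mask.nii.gz"))) {
        say("data: reusing ", data_dir)
        imgs <- sort(list.files(data_dir, pattern = "_gmv\\.nii\\.gz$",
                                full.names = TRUE))
        gmv <- load_gmv_dataset(imgs, file.path(data_dir, "mask.nii.gz"),
                                subject_ids = sub("_gmv\\.nii\\.gz$", "",
                                                  basename(imgs)))
        cov <- add_derived_covariates(
          load_covariates(cov_path),
          wmh_floor_cc = config$inference$wmh_floor_cc)
        list(gmv = gmv, covariates = cov)
      } else {
        sim_args <- config$simulate %||% list()
        if (is.null(sim_args$seed)) sim_args$seed <- master_seed
        ds <- simulate_cohort(do.call(synthetic_config, sim_args))
        paths <- write_dataset(ds, data_dir)
        say("data: simulated ", ds$config$n_subjects, " subjects (seed ",
            ds$config$seed, ")")
        # downstream stages consume the written artifacts, so a fresh run
        # and a resumed run see bit-identical inputs
        gmv <- load_gmv_dataset(paths$images, paths$mask,
                                subject_ids = ds$gmv$subject_ids)
        cov <- add_derived_covariates(
          load_covariates(paths$covariates),
          wmh_floor_cc = config$inference$wmh_floor_cc)
        list(gmv = gmv, covariates = cov, truth = ds)
      }
    }
  })
  gmv <- dataset$gmv
  cov <- dataset$covariates

  # ---- stage: decompose + select ------------------------------------------
  pat_dir <- file.path(out_dir, "pattern")
  dec_dir <- file.path(out_dir, "decomposition")
  fit <- timed("select", {
    fit <- ssm_pattern(gmv, cov, k_max = sel_cfg$k_max,
                       max_subset = sel_cfg$max_subset,
                       use_aicc = sel_cfg$use_aicc)
    if (!(resume && file.exists(file.path(pat_dir, "pattern.yaml")))) {
      dir.create(dec_dir, showWarnings = FALSE)
      dir.create(pat_dir, showWarnings = FALSE)
      dec <- fit$decomposition
      for (k in seq_len(min(sel_cfg$k_max, nrow(dec$loadings))))
        save_voxel_map(dec$loadings[k, ], gmv,
                       file.path(dec_dir, sprintf("loading_%02d.nii.gz", k)))
      utils::write.csv(
        data.frame(id = gmv$subject_ids, dec$ssf,
                   check.names = FALSE),
        file.path(dec_dir, "ssf.csv"), row.names = FALSE)
      yaml::write_yaml(list(eigenvalues = dec$eigenvalues,
                            var_fraction = dec$var_fraction,
                            grand_mean = dec$grand_mean),
                       file.path(dec_dir, "manifest.yaml"))
      save_voxel_map(fit$pattern_weights, gmv,
                     file.path(pat_dir, "pattern.nii.gz"))
      utils::write.csv(data.frame(id = gmv$subject_ids,
                                  score = fit$subject_scores,
                                  log_wmh = fit$y),
                       file.path(pat_dir, "subject_scores.csv"),
                       row.names = FALSE)
      yaml::write_yaml(list(selected = fit$selected,
                            betas = as.list(fit$betas),
                            r = fit$r, r2 = fit$r2, adj_r2 = fit$adj_r2,
                            r2_components = fit$r2_components,
                            aic = fit$aic, n = fit$n, k = fit$k),
                       file.path(pat_dir, "pattern.yaml"))
    }
    say("select: components {", paste(fit$selected, collapse = ","),
        "}, adj R^2 = ", round(fit$adj_r2, 3))
    fit
  })

  # ---- stage: bootstrap ----------------------------------------------------
  boot_dir <- file.path(out_dir, "bootstrap")
  zmap_path <- file.path(boot_dir, "zmap.nii.gz")
  zmap <- timed("bootstrap", {
    if (resume && file.exists(zmap_path)) {
      say("bootstrap: reusing ", boot_dir)
      z <- load_voxel_map(zmap_path, gmv)
      masks <- threshold_zmap(z, boot_cfg$z_crit)
      list(z = z, pos_mask = masks$pos_mask, neg_mask = masks$neg_mask,
           reused = TRUE)
    } else {
      dir.create(boot_dir, showWarnings = FALSE)
      zm <- bootstrap_zmap(gmv, cov$log_wmh, cov$tiv_cc,
                           n_iterations = boot_cfg$n_iterations,
                           seed = master_seed + 1L,
                           z_crit = boot_cfg$z_crit, z_cap = boot_cfg$z_cap,
                           k_max = sel_cfg$k_max,
                           max_subset = sel_cfg$max_subset,
                           use_aicc = sel_cfg$use_aicc,
                           fixed_subset = boot_cfg$fixed_subset)
      save_voxel_map(zm$z, gmv, zmap_path)
      save_voxel_map(as.numeric(zm$pos_mask), gmv,
                     file.path(boot_dir, "pos_mask.nii.gz"))
      save_voxel_map(as.numeric(zm$neg_mask), gmv,
                     file.path(boot_dir, "neg_mask.nii.gz"))
      utils::write.csv(zm$log, file.path(boot_dir, "iterations.csv"),
                       row.names = FALSE)
      say("bootstrap: ", zm$n_iterations, " iterations, ",
          sum(zm$pos_mask), " pos / ", sum(zm$neg_mask), " neg voxels")
      zm
    }
  })

  # ---- stage: inference ----------------------------------------------------
  inf_dir <- file.path(out_dir, "inference")
  infer <- timed("inference", {
    dir.create(inf_dir, showWarnings = FALSE)
    an <- ancova_group_effect(fit$subject_scores, cov$bp_group,
                              cov[, c("age", "sex", "low_education", "gc_z")])
    tr <- ordinal_trend_test(fit$subject_scores, cov$bp_group,
                             cov[, c("age", "low_education")])
    cg <- cognition_associations(fit$subject_scores, cov)
    rows <- rbind(
      data.frame(effect = "bp_group_F", estimate = an$f_stat,
                 p = an$p, p_corrected = NA_real_, adj_r2 = an$adj_r2),
      data.frame(effect = "bp_trend_B", estimate = tr$beta,
                 p = tr$p, p_corrected = NA_real_, adj_r2 = tr$adj_r2),
      data.frame(effect = paste0("cognition_", cg$domain, "_B"),
                 estimate = cg$beta, p = cg$p, p_corrected = cg$p_corrected,
                 adj_r2 = cg$adj_r2))
    utils::write.csv(rows, file.path(inf_dir, "results.csv"),
                     row.names = FALSE)
    utils::write.csv(an$contrasts, file.path(inf_dir, "contrasts.csv"),
                     row.names = FALSE)
    rpt <- c(
      "SSM WMH~GMV pattern analysis",
      sprintf("Selected components: {%s}; R = %.3f, adj R^2 = %.3f",
              paste(fit$selected, collapse = ","), fit$r, fit$adj_r2),
      sprintf("BP group ANCOVA: F = %.3f (dof %d, %d), p = %.4g",
              an$f_stat, an$dof[1], an$dof[2], an$p),
      sprintf("Ordinal BP trend: B = %.3f, adj R^2 = %.3f, p = %.4g",
              tr$beta, tr$adj_r2, tr$p),
      "Cognition (B, p, corrected p):",
      sprintf("  %-10s B = %+.3f, p = %.4g, corrected p = %.4g",
              cg$domain, cg$beta, cg$p, cg$p_corrected))
    writeLines(rpt, file.path(inf_dir, "report.txt"))
    say(paste(rpt[2:4], collapse = "\n"))
    list(ancova = an, trend = tr, cognition = cg)
  })

  # ---- manifest ------------------------------------------------------------
  outputs <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  outputs <- outputs[basename(outputs) != "manifest.json"]
  hashes <- as.list(tools::md5sum(outputs))
  names(hashes) <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1",
                                        out_dir), "/?"), "", names(hashes))
  manifest <- list(
    package_version = as.character(utils::packageVersion("ssmpattern")),
    master_seed = master_seed,
    config = config,
    stages = stage_time,
    selected_components = fit$selected,
    headline = list(
      r = fit$r, adj_r2 = fit$adj_r2, aic = fit$aic,
      ancova_f = infer$ancova$f_stat, ancova_p = infer$ancova$p,
      trend_b = infer$trend$beta, trend_p = infer$trend$p,
      pos_voxels = sum(zmap$pos_mask), neg_voxels = sum(zmap$neg_mask)),
    outputs = hashes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
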