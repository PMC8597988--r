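#' Experiment configuration
#'
#' One JSON-serialisable configuration drives a full experiment: cohort
#' generation, classifier training, matching sweeps, ROC, defense and
#' adversarial-training evaluation. Every stage's seed is derived
#' deterministically from the single master seed by stage name, so adding a
#' stage never perturbs earlier stages' randomness.
#'
#' @param n_individuals cohort size.
#' @param master_seed master seed all stage seeds derive from.
#' @param image_size c(height, width).
#' @param render_noise_sd render-time pixel noise sd.
#' @param confusion_level simulated classifier error (used by the image-free
#'   fast path in sweeps when `use_images = FALSE`).
#' @param train_epochs classifier training iterations.
#' @param k_values integer vector of top-k values to sweep.
#' @param population_sizes integer vector of gallery sizes.
#' @param replicates subsample replicates per size.
#' @param defense_epsilons numeric vector of defense budgets.
#' @param defense_steps PGD iterations for the defense stage.
#' @param robust_epsilon adversarial-training budget.
#' @param robust_passes adversarial-training passes.
#' @param eval_epsilons attack budgets for robustness evaluation.
#' @param train_fraction train split fraction for adversarial training.
#' @param use_images run the image pipeline (TRUE) or the image-free noisy
#'   prediction simulator for the matching stages.
#' @param smoothing_alpha pseudo-count for conditional-table fitting.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(n_individuals = 60, master_seed = 1,
                              image_size = c(32, 32), render_noise_sd = 0.05,
                              confusion_level = 0.1, train_epochs = 300,
                              k_values = c(1, 5),
                              population_sizes = c(10, 20, 40),
                              replicates = 10,
                              defense_epsilons = c(0.001, 0.01, 0.05),
                              defense_steps = 60,
                              robust_epsilon = 0.01, robust_passes = 5,
                              eval_epsilons = c(0, 0.001, 0.01, 0.025),
                              train_fraction = 0.6,
                              use_images = TRUE,
                              smoothing_alpha = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "experiment_config")
}

#' Read / write an experiment configuration as JSON
#'
#' Round-trips losslessly: reading a written config reproduces it exactly.
#'
#' @param path file path.
#' @export
write_experiment_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_experiment_config
#' @param config an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(experiment_config, x)
}

#' Run a full linkage-risk experiment
#'
#' Pipeline: generate a synthetic cohort; fit conditional tables; (with
#' images) render images, train the classifier ensemble, predict; score all
#' image-genome pairs; sweep top-k success over population sizes against
#' random and true-phenotype baselines; compute pooled ROC/AUC in both
#' threshold modes; defend every image at each defense epsilon and re-score;
#' adversarially train at the configured budget and evaluate robustness.
#' All outputs are written as CSVs plus a provenance manifest (config, seeds,
#' package version) into `out_dir`.
#'
#' @param config an `experiment_config`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory report tables (`risk`,
#'   `roc`, `defense`, `robustness`) and the manifest.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  seed <- config$master_seed
  log_stage <- function(...) message("[phenolink] ", ...)

  stage <- "simulate"
  result <- tryCatch({
    log_stage("simulate: cohort of ", config$n_individuals)
    spec <- generator_spec(
      n_individuals = config$n_individuals,
      image_size = config$image_size,
      render_noise_sd = config$render_noise_sd,
      confusion_level = config$confusion_level,
      seed = derive_seed(seed, "cohort")
    )
    cohort <- generate_cohort(spec)
    schema <- spec$schema

    stage <- "fit"
    model <- fit_conditional_tables(cohort$genomes, cohort$profiles, schema,
                                    smoothing_alpha = config$smoothing_alpha)

    stage <- "predict"
    if (config$use_images) {
      images <- render_images(cohort$profiles, spec)
      ensemble <- train_reference_classifiers(
        images, cohort$profiles, schema,
        epochs = config$train_epochs, seed = derive_seed(seed, "train"))
      preds <- predict_all(ensemble, images, schema)
    } else {
      images <- NULL
      ensemble <- NULL
      preds <- simulate_noisy_predictions(
        cohort$profiles, config$confusion_level, schema,
        seed = derive_seed(seed, "noisy"))
    }

    stage <- "match"
    m <- build_score_matrix(preds, cohort$genomes, model, schema)

    stage <- "sweep"
    risk <- list()
    for (k in config$k_values) {
      risk[[length(risk) + 1L]] <- population_sweep(
        m, config$population_sizes, k, config$replicates,
        seed = derive_seed(seed, paste0("sweep_k", k)), mode = "predicted")
      risk[[length(risk) + 1L]] <- baseline_upper_bound(
        cohort$profiles, cohort$genomes, model, schema, k,
        config$population_sizes, config$replicates,
        seed = derive_seed(seed, paste0("sweep_k", k)))
      risk[[length(risk) + 1L]] <- baseline_random(
        config$population_sizes, k, seed = derive_seed(seed, "random"))
    }
    risk <- do.call(rbind, risk)
    write_risk_report(risk, file.path(out_dir, "risk_curves.csv"))

    stage <- "roc"
    roc_tau <- roc_and_auc(m, mode = "tau")
    roc_k <- roc_and_auc(m, mode = "k")
    roc_df <- rbind(
      cbind(mode = "tau", roc_tau$roc, auc = roc_tau$auc),
      cbind(mode = "k", roc_k$roc, auc = roc_k$auc)
    )
    utils::write.csv(roc_df, file.path(out_dir, "roc.csv"), row.names = FALSE)

    stage <- "defend"
    defense <- NULL
    if (config$use_images) {
      rows <- list()
      for (eps in config$defense_epsilons) {
        cfg <- perturbation_config(eps, steps = config$defense_steps,
                                   seed = derive_seed(seed, paste0("def", eps)))
        def <- defend_images(images, cohort$genomes, ensemble, model, schema,
                             cfg)
        dimgs <- lapply(seq_along(def), function(i) {
          im <- def[[i]]$perturbed_image
          im$image_id <- images[[i]]$image_id
          im
        })
        dm <- build_score_matrix(predict_all(ensemble, dimgs, schema),
                                 cohort$genomes, model, schema)
        for (k in config$k_values) {
          rows[[length(rows) + 1L]] <- data.frame(
            mode = "defended", population_size = config$n_individuals,
            k_or_tau = k, metric = paste0("top_k_success_eps_", eps),
            value = top_k_success(dm, k), n_replicates = 1L, seed = seed)
        }
      }
      for (k in config$k_values) {
        rows[[length(rows) + 1L]] <- data.frame(
          mode = "undefended", population_size = config$n_individuals,
          k_or_tau = k, metric = "top_k_success_eps_0",
          value = top_k_success(m, k), n_replicates = 1L, seed = seed)
      }
      defense <- do.call(rbind, rows)
      write_risk_report(defense, file.path(out_dir, "defense.csv"))
    }

    stage <- "advtrain"
    robustness <- NULL
    if (config$use_images && config$robust_passes > 0) {
      split <- train_test_split(config$n_individuals, config$train_fraction,
                                seed = derive_seed(seed, "split"))
      rcfg <- robust_train_config(config$robust_epsilon,
                                  passes = config$robust_passes,
                                  train_fraction = config$train_fraction,
                                  seed = derive_seed(seed, "advtrain"))
      robust <- adversarial_train(
        ensemble, images[split$train], cohort$genomes[split$train],
        cohort$profiles[split$train], model, schema, rcfg)
      stage <- "evalrobust"
      robustness <- evaluate_robustness(
        robust, ensemble, images[split$test], cohort$genomes[split$test],
        cohort$profiles[split$test], model, schema,
        eval_epsilons = config$eval_epsilons, k = config$k_values[1],
        seed = derive_seed(seed, "evalrobust"))
      write_risk_report(robustness, file.path(out_dir, "robustness.csv"))
    }

    stage <- "manifest"
    manifest <- list(
      config = unclass(config),
      config_hash = config_hash(config),
      package_version = as.character(utils::packageVersion("phenolink")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      stage_seeds = list(
        cohort = derive_seed(seed, "cohort"),
        train = derive_seed(seed, "train"),
        advtrain = derive_seed(seed, "advtrain")
      )
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(risk = risk, roc = roc_df, defense = defense,
         robustness = robustness, manifest = manifest)
  }, error = function(e) {
    stop("experiment failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

# stable content hash of a config (serialisation-based, no external deps)
config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (code in utf8ToInt(as.character(json))) h <- (h * 33 + code) %% 2^31
  sprintf("%08x", as.integer(h))
}
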