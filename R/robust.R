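#' Adversarial training configuration
#'
#' @param epsilon_train perturbation budget used to generate training
#'   perturbations.
#' @param passes passes over the perturbed data (default 5).
#' @param train_fraction train split fraction in (0, 1) (default 0.6).
#' @param seed integer seed.
#' @param attack_steps PGD iterations when generating training
#'   perturbations.
#' @param epochs_per_pass classifier gradient iterations per pass.
#' @param loss `"defense"`: perturbations minimise the image-to-true-genome
#'   defense objective (the attack being defended against); or
#'   `"cross_entropy"`: per-classifier misprediction perturbations.
#' @param mix_ratio fraction of clean inputs mixed into each pass's
#'   training batch (0 = train purely on perturbed inputs).
#' @return an object of class `robust_train_config`.
#' @export
robust_train_config <- function(epsilon_train, passes = 5,
                                train_fraction = 0.6, seed = 1,
                                attack_steps = 50, epochs_per_pass = 50,
                                loss = c("defense", "cross_entropy"),
                                mix_ratio = 0) {
  loss <- match.arg(loss)
  stopifnot(passes >= 0, train_fraction > 0, train_fraction < 1,
            mix_ratio >= 0, mix_ratio <= 1)
  structure(
    list(epsilon_train = epsilon_train, passes = as.integer(passes),
         train_fraction = train_fraction, seed = as.integer(seed),
         attack_steps = as.integer(attack_steps),
         epochs_per_pass = as.integer(epochs_per_pass),
         loss = loss, mix_ratio = mix_ratio),
    class = "robust_train_config"
  )
}

# perturb one training image against the current ensemble
adv_example <- function(image, genome, label, ensemble, model, schema,
                        config, seed) {
  pc <- perturbation_config(config$epsilon_train,
                            steps = config$attack_steps,
                            init = "random", seed = seed)
  if (config$loss == "defense") {
    craft_defense_perturbation(image, genome, ensemble, model, schema,
                               pc)$perturbed_image
  } else {
    x0 <- as.vector(image$pixels)
    res <- pgd_minimize(x0, pc, function(x) {
      value <- 0; grad <- numeric(length(x0))
      for (p in schema$phenotypes) {
        clf <- ensemble$classifiers[[p]]
        g <- clf_predict(clf, x)
        ti <- match(label$values[[p]], clf$domain)
        dlogits <- -g; dlogits[ti] <- dlogits[ti] + 1
        value <- value + log(max(g[ti], 1e-20))
        grad <- grad + clf_input_grad(clf, x, dlogits)
      }
      list(value = value, grad = grad)
    })
    defense_result(image, res, pc)$perturbed_image
  }
}

#' Adversarially train the classifier ensemble
#'
#' Hardens the phenotype classifiers against the perturbation defense by
#' iterated retraining on perturbed inputs: each pass regenerates
#' perturbations (random starting points in the epsilon box) against the
#' current ensemble — by default by minimising the image-to-true-genome
#' defense objective, since the attack being countered targets the matching
#' score, not the individual classifiers — then runs a training epoch with
#' those perturbed images in place of the originals (`mix_ratio` of clean
#' inputs can be mixed back in). Paired genome-image data are therefore
#' required. Five passes is the default.
#'
#' @param ensemble starting `classifier_ensemble`.
#' @param images,genomes,labels aligned training lists (`image_tensor`,
#'   `genome`, `phenotype_profile`).
#' @param model a `conditional_model`.
#' @param schema a `phenotype_schema`.
#' @param config a `robust_train_config`.
#' @return the hardened `classifier_ensemble` (input returned unchanged when
#'   `passes = 0`), with the training ids recorded in `$train_ids`.
#' @export
adversarial_train <- function(ensemble, images, genomes, labels, model,
                              schema = model$schema, config) {
  stopifnot(length(images) == length(genomes),
            length(images) == length(labels))
  ensemble$train_ids <- vapply(images, function(im) im$image_id, character(1))
  if (config$passes == 0L) return(ensemble)
  dims <- ensemble$dims
  X_clean <- t(vapply(images, function(im) as.vector(im$pixels),
                      numeric(prod(dims))))
  for (pass in seq_len(config$passes)) {
    perturbed <- lapply(seq_along(images), function(i) {
      adv_example(images[[i]], genomes[[i]], labels[[i]], ensemble, model,
                  schema, config,
                  seed = derive_seed(config$seed, sprintf("adv_p%d_i%d", pass, i)))
    })
    X <- t(vapply(perturbed, function(im) as.vector(im$pixels),
                  numeric(prod(dims))))
    if (config$mix_ratio > 0) {
      set.seed(derive_seed(config$seed, paste0("mix", pass)))
      n_clean <- round(config$mix_ratio * nrow(X_clean))
      pick <- sample(nrow(X_clean), n_clean)
      X <- rbind(X, X_clean[pick, , drop = FALSE])
      y_extra <- pick
    } else {
      y_extra <- integer(0)
    }
    for (p in schema$phenotypes) {
      clf <- ensemble$classifiers[[p]]
      yi <- match(vapply(labels, function(l) l$values[[p]], character(1)),
                  clf$domain)
      yi_all <- c(yi, yi[y_extra])
      ensemble$classifiers[[p]] <-
        adam_fit_softmax(clf, X, yi_all, rep(1, length(yi_all)),
                         config$epochs_per_pass, lr = 0.05)
    }
  }
  ensemble
}

#' Evaluate matching robustness of a hardened ensemble
#'
#' For each evaluation epsilon (0 = clean inputs), defends the held-out test
#' images at that budget against the target ensemble, recomputes predictions
#' and the score matrix against the test genomes, and reports top-k matching
#' success — for the robust ensemble and, when supplied, the clean ensemble
#' under the same attack. Train/test overlap is rejected.
#'
#' @param robust_ensemble hardened `classifier_ensemble` (with `$train_ids`).
#' @param clean_ensemble optional baseline ensemble evaluated identically.
#' @param test_images,test_genomes,test_labels aligned held-out lists.
#' @param model a `conditional_model`.
#' @param schema a `phenotype_schema`.
#' @param eval_epsilons numeric vector of attack budgets (include 0 for the
#'   clean-input row).
#' @param k top-k parameter.
#' @param seed integer seed for the defense PGD.
#' @param attack_steps PGD iterations at evaluation time.
#' @return risk-report rows: mode `"robust"` / `"clean_model"`, with
#'   `k_or_tau` = k, one row per (model, epsilon); `population_size` is the
#'   test-set size.
#' @export
evaluate_robustness <- function(robust_ensemble, clean_ensemble = NULL,
                                test_images, test_genomes, test_labels,
                                model, schema = model$schema,
                                eval_epsilons = c(0, 0.001, 0.01, 0.025),
                                k = 1, seed = 1, attack_steps = 50) {
  test_ids <- vapply(test_images, function(im) im$image_id, character(1))
  overlap <- intersect(robust_ensemble$train_ids %||% character(0), test_ids)
  if (length(overlap)) {
    stop("train/test split overlaps: ", paste(overlap, collapse = ", "))
  }
  ensembles <- list(robust = robust_ensemble)
  if (!is.null(clean_ensemble)) ensembles$clean_model <- clean_ensemble
  rows <- list()
  for (mode in names(ensembles)) {
    ens <- ensembles[[mode]]
    for (eps in eval_epsilons) {
      imgs <- if (eps > 0) {
        cfg <- perturbation_config(eps, steps = attack_steps,
                                   seed = derive_seed(seed, paste0(mode, eps)))
        lapply(defend_images(test_images, test_genomes, ens, model, schema,
                             cfg),
               function(r) r$perturbed_image)
      } else test_images
      # keep probe ids aligned with genome ids for the truth mapping
      for (i in seq_along(imgs)) imgs[[i]]$image_id <- test_ids[i]
      preds <- predict_all(ens, imgs, schema)
      m <- build_score_matrix(preds, test_genomes, model, schema)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, population_size = length(test_genomes),
        k_or_tau = k, metric = paste0("top_k_success_eps_", eps),
        value = top_k_success(m, k), n_replicates = 1L, seed = seed)
    }
  }
  do.call(rbind, rows)
}

#' Split paired data into train and test partitions
#'
#' @param n number of pairs.
#' @param train_fraction fraction assigned to training.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test` (disjoint).
#' @export
train_test_split <- function(n, train_fraction = 0.6, seed = 1) {
  set.seed(derive_seed(seed, "split"))
  train <- sort(sample(n, round(train_fraction * n)))
  list(train = train, test = setdiff(seq_len(n), train))
}
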