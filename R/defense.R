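#' Perturbation configuration
#'
#' Settings for the projected-gradient-descent perturbation search: the
#' l-infinity budget epsilon (in normalised [0,1] pixel units), iteration
#' count, step size, initialisation and seed.
#'
#' @param epsilon max per-pixel perturbation, in [0, 1].
#' @param steps PGD iterations (>= 0).
#' @param step_size gradient step scale; defaults to `epsilon / 10`.
#' @param init `"zero"` (start at the original image) or `"random"`
#'   (uniform in the epsilon box).
#' @param seed integer seed (used by random init).
#' @return an object of class `perturbation_config`.
#' @export
perturbation_config <- function(epsilon, steps = 100,
                                step_size = epsilon / 10,
                                init = c("zero", "random"), seed = 1) {
  init <- match.arg(init)
  stopifnot(epsilon >= 0, epsilon <= 1)
  if (steps < 0) stop("steps must be >= 0")
  structure(
    list(epsilon = epsilon, steps = as.integer(steps),
         step_size = step_size, init = init, seed = as.integer(seed)),
    class = "perturbation_config"
  )
}

#' Privacy-defense objective for an image and its true genome
#'
#' The surrogate the defender minimises. The matching score depends on the
#' classifiers only through the discontinuous argmax variant, so the
#' predicted probabilities are brought in through their logarithms:
#' \deqn{\sum_p \sum_{v_p} \log g_p(v_p, x)\; \log P(v_p \mid y_j)}
#' with `P` floored at the model's `prob_floor` and `g` floored at `g_floor`
#' inside the log. This double-log form is the default
#' (`form = "log_log"`); the expected-log-likelihood alternative
#' \eqn{\sum_p \sum_{v_p} g_p(v_p, x) \log P(v_p \mid y_j)} is available as
#' `form = "expected_loglik"`. Both are differentiable with respect to the
#' pixels.
#'
#' @param image an `image_tensor`.
#' @param genome the image's true `genome`.
#' @param ensemble a `classifier_ensemble`.
#' @param model a `conditional_model`.
#' @param schema a `phenotype_schema` (defaults to the model's).
#' @param form `"log_log"` (default) or `"expected_loglik"`.
#' @param g_floor floor inside `log g` for numerical stability.
#' @return a scalar objective value.
#' @export
defense_objective <- function(image, genome, ensemble, model,
                              schema = model$schema,
                              form = c("log_log", "expected_loglik"),
                              g_floor = 1e-20) {
  form <- match.arg(form)
  x <- as.vector(image$pixels)
  obj_from_x(x, genome, ensemble, model, schema, form, g_floor)$value
}

# objective value and gradient w.r.t. flattened pixels at x
obj_from_x <- function(x, genome, ensemble, model, schema, form, g_floor) {
  value <- 0
  grad <- numeric(length(x))
  for (p in schema$phenotypes) {
    clf <- ensemble$classifiers[[p]]
    cvec <- log(pmax(phenotype_prob_vector(p, genome, model, schema),
                     model$prob_floor))
    g <- clf_predict(clf, x)
    if (form == "log_log") {
      value <- value + sum(log(pmax(g, g_floor)) * cvec)
      dlogits <- cvec - sum(cvec) * g
    } else {
      value <- value + sum(g * cvec)
      dlogits <- g * (cvec - sum(cvec * g))
    }
    grad <- grad + clf_input_grad(clf, x, dlogits)
  }
  list(value = value, grad = grad)
}

# shared PGD driver: minimises objective(x) over delta in the epsilon box,
# keeping x0 + delta in [0,1]; Adam steps; returns the best iterate seen
pgd_minimize <- function(x0, config, objective_fn) {
  eps_box <- config$epsilon
  if (config$init == "random" && eps_box > 0) {
    set.seed(config$seed)
    delta <- stats::runif(length(x0), -eps_box, eps_box)
    delta <- clip01(x0 + delta) - x0
  } else {
    delta <- numeric(length(x0))
  }
  ob0 <- objective_fn(x0 + delta)
  best_delta <- delta
  best_val <- ob0$value
  trace <- numeric(config$steps + 1L)
  trace[1L] <- ob0$value
  m <- numeric(length(x0)); v <- m
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  g <- ob0$grad
  if (config$steps > 0 && eps_box > 0) {
    for (t in seq_len(config$steps)) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      step <- config$step_size * (m / (1 - beta1^t)) /
        (sqrt(v / (1 - beta2^t)) + adam_eps)
      delta <- delta - step
      delta <- pmin(pmax(delta, -eps_box), eps_box)   # noise box
      delta <- clip01(x0 + delta) - x0                # valid pixel range
      ob <- objective_fn(x0 + delta)
      trace[t + 1L] <- ob$value
      g <- ob$grad
      if (ob$value < best_val) {
        best_val <- ob$value
        best_delta <- delta
      }
    }
  } else {
    trace <- trace[1L]
  }
  list(delta = best_delta, value = best_val, initial = trace[1L],
       trace = trace)
}

#' Craft a privacy-defense perturbation for an image
#'
#' Projected gradient descent on the defense objective: starting from the
#' original image (delta = 0 unless `init = "random"`), takes adaptive-moment
#' gradient steps on delta and, after every step, clips the noise to
#' [-epsilon, epsilon] and the perturbed pixels to [0, 1]. Returns the best
#' iterate by objective, so the final objective never exceeds the initial
#' one.
#'
#' @inheritParams defense_objective
#' @param config a `perturbation_config`.
#' @return an object of class `defense_result`: `perturbed_image`, `delta`
#'   (array like the pixels), `objective_trace`, `initial_objective`,
#'   `final_objective`.
#' @export
craft_defense_perturbation <- function(image, genome, ensemble, model,
                                       schema = model$schema, config,
                                       form = c("log_log", "expected_loglik"),
                                       g_floor = 1e-20) {
  form <- match.arg(form)
  x0 <- as.vector(image$pixels)
  res <- pgd_minimize(x0, config, function(x) {
    obj_from_x(x, genome, ensemble, model, schema, form, g_floor)
  })
  defense_result(image, res, config)
}

defense_result <- function(image, res, config) {
  dims <- dim(image$pixels)
  perturbed <- array(clip01(as.vector(image$pixels) + res$delta), dim = dims)
  structure(
    list(
      perturbed_image = image_tensor(perturbed, paste0(image$image_id, "_def")),
      delta = array(res$delta, dim = dims),
      objective_trace = res$trace,
      initial_objective = res$initial,
      final_objective = res$value,
      config = config
    ),
    class = "defense_result"
  )
}

#' @export
print.defense_result <- function(x, ...) {
  cat(sprintf(
    "defense_result: eps = %g, steps = %d, objective %.4f -> %.4f, max|delta| = %.4g\n",
    x$config$epsilon, x$config$steps, x$initial_objective,
    x$final_objective, max(abs(x$delta))
  ))
  invisible(x)
}

#' Single-phenotype targeted perturbation (baseline)
#'
#' The conventional misclassification attack used as a comparison point for
#' the tailored defense: PGD that pushes one chosen classifier (typically
#' sex, the most informative phenotype) away from its current argmax by
#' minimising the log-probability of that variant, under the same box
#' projections.
#'
#' @param image an `image_tensor`.
#' @param target_phenotype phenotype whose prediction is attacked.
#' @param ensemble a `classifier_ensemble`.
#' @param schema a `phenotype_schema`.
#' @param config a `perturbation_config`.
#' @param g_floor floor inside the log.
#' @return a `defense_result` (objective = log g of the original argmax).
#' @export
targeted_phenotype_perturbation <- function(image, target_phenotype, ensemble,
                                            schema, config, g_floor = 1e-20) {
  if (!target_phenotype %in% schema$phenotypes) {
    stop("unknown phenotype '", target_phenotype, "'")
  }
  clf <- ensemble$classifiers[[target_phenotype]]
  x0 <- as.vector(image$pixels)
  t_idx <- argmax_first(clf_predict(clf, x0))
  res <- pgd_minimize(x0, config, function(x) {
    g <- clf_predict(clf, x)
    dlogits <- -g
    dlogits[t_idx] <- dlogits[t_idx] + 1
    list(value = log(max(g[t_idx], g_floor)),
         grad = clf_input_grad(clf, x, dlogits))
  })
  defense_result(image, res, config)
}

#' Defend a whole image set against its true genomes
#'
#' Convenience wrapper: crafts one defense perturbation per image (against
#' the paired genome) and returns the perturbed images.
#'
#' @param images list of `image_tensor`.
#' @param genomes aligned list of the images' true `genome` objects.
#' @inheritParams craft_defense_perturbation
#' @return list of `defense_result`.
#' @export
defend_images <- function(images, genomes, ensemble, model,
                          schema = model$schema, config,
                          form = c("log_log", "expected_loglik")) {
  form <- match.arg(form)
  stopifnot(length(images) == length(genomes))
  lapply(seq_along(images), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("defend", i))
    craft_defense_perturbation(images[[i]], genomes[[i]], ensemble, model,
                               schema, cfg, form = form)
  })
}
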