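#' Image tensor
#'
#' A height x width x channels array of pixel intensities in [0, 1] plus an
#' id. All images in an experiment share one fixed size.
#'
#' @param pixels numeric array (h, w, c) with values in [0, 1].
#' @param image_id character id.
#' @return an object of class `image_tensor`.
#' @export
image_tensor <- function(pixels, image_id) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  if (any(pixels < 0) || any(pixels > 1)) {
    stop("pixel values must lie in [0, 1]")
  }
  structure(list(pixels = pixels, image_id = image_id),
            class = "image_tensor")
}

#' Read / write an image as PNG, normalised to [0, 1]
#'
#' @param path PNG file path.
#' @param image_id id to attach (defaults to the file name).
#' @return `read_image_png` returns an `image_tensor` with 3 channels
#'   (grayscale is replicated, alpha dropped).
#' @export
read_image_png <- function(path, image_id = basename(path)) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  image_tensor(clip01(px), image_id)
}

#' @rdname read_image_png
#' @param image an `image_tensor`.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image$pixels, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Classifier contract
#
# A phenotype classifier is any object implementing:
#   clf_predict(clf, x)            -> named softmax probability vector over
#                                     the phenotype's variant domain
#   clf_input_grad(clf, x, dlogits)-> gradient w.r.t. the flattened pixel
#                                     vector x of sum(dlogits * logits(x))
# (x is the flattened pixel vector). Any differentiable model — including an
# externally trained deep network wrapped in R — can be plugged into the
# defense and adversarial-training machinery by providing these two methods.
# ---------------------------------------------------------------------------

#' @export
clf_predict <- function(clf, x) UseMethod("clf_predict")

#' @export
clf_input_grad <- function(clf, x, dlogits) UseMethod("clf_input_grad")

#' @export
clf_predict.linear_softmax_classifier <- function(clf, x) {
  stats::setNames(softmax(as.vector(clf$W %*% x) + clf$b), clf$domain)
}

#' @export
clf_input_grad.linear_softmax_classifier <- function(clf, x, dlogits) {
  as.vector(crossprod(clf$W, dlogits))
}

new_linear_classifier <- function(phenotype, domain, n_features, sd = 1e-3) {
  structure(
    list(
      phenotype = phenotype, domain = domain,
      W = matrix(stats::rnorm(length(domain) * n_features, sd = sd),
                 nrow = length(domain)),
      b = stats::rnorm(length(domain), sd = sd)
    ),
    class = "linear_softmax_classifier"
  )
}

#' Train the reference phenotype classifier ensemble
#'
#' Fits one multinomial-logistic (linear softmax) classifier per phenotype on
#' flattened pixels, by full-batch cross-entropy descent with adaptive
#' first/second-moment (Adam-style) steps. The model is deliberately simple:
#' the synthetic images encode each phenotype in dedicated pixel regions, so
#' a linear decision surface recovers them, while remaining exactly
#' differentiable for the perturbation machinery. The ensemble satisfies the
#' pluggable-classifier contract (`clf_predict` / `clf_input_grad`), so a
#' deep face model can substitute for it unchanged downstream.
#'
#' @param train_images list of `image_tensor` (identical dimensions).
#' @param labels list of `phenotype_profile` aligned by position with
#'   `train_images`.
#' @param schema a `phenotype_schema`.
#' @param epochs full-batch gradient iterations (0 returns the seeded
#'   near-uniform initialisation).
#' @param seed integer seed; training is deterministic given seed and data.
#' @param lr Adam step size.
#' @param class_weights weight classes inversely to frequency (default off).
#' @return an object of class `classifier_ensemble` with one classifier per
#'   phenotype and the common image dims.
#' @export
train_reference_classifiers <- function(train_images, labels, schema,
                                        epochs = 300, seed = 1, lr = 0.05,
                                        class_weights = FALSE) {
  stopifnot(length(train_images) == length(labels), epochs >= 0)
  dims <- dim(train_images[[1]]$pixels)
  X <- t(vapply(train_images, function(im) as.vector(im$pixels),
                numeric(prod(dims))))
  classifiers <- list()
  for (p in schema$phenotypes) {
    dom <- schema$variant_domain[[p]]
    y <- vapply(labels, function(l) l$values[[p]], character(1))
    if (epochs > 0 && length(unique(y)) < 2L) {
      stop("phenotype '", p, "' has a single class in the training data")
    }
    yi <- match(y, dom)
    set.seed(derive_seed(seed, paste0("clf_", p)))
    clf <- new_linear_classifier(p, dom, ncol(X))
    w_obs <- if (class_weights) {
      freq <- tabulate(yi, nbins = length(dom))
      (1 / pmax(freq, 1))[yi] * length(yi) / length(dom)
    } else rep(1, length(yi))
    clf <- adam_fit_softmax(clf, X, yi, w_obs, epochs, lr)
    classifiers[[p]] <- clf
  }
  structure(list(classifiers = classifiers, dims = dims),
            class = "classifier_ensemble")
}

# full-batch Adam on weighted multinomial cross-entropy
adam_fit_softmax <- function(clf, X, yi, w_obs, epochs, lr,
                             beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  n <- nrow(X); C <- length(clf$domain)
  Y <- matrix(0, n, C); Y[cbind(seq_len(n), yi)] <- 1
  mW <- matrix(0, C, ncol(X)); vW <- mW
  mb <- numeric(C); vb <- mb
  for (t in seq_len(epochs)) {
    logits <- X %*% t(clf$W) + matrix(clf$b, n, C, byrow = TRUE)
    logits <- logits - apply(logits, 1, max)
    P <- exp(logits); P <- P / rowSums(P)
    G <- (P - Y) * w_obs / n        # d loss / d logits
    gW <- t(G) %*% X
    gb <- colSums(G)
    mW <- beta1 * mW + (1 - beta1) * gW; vW <- beta2 * vW + (1 - beta2) * gW^2
    mb <- beta1 * mb + (1 - beta1) * gb; vb <- beta2 * vb + (1 - beta2) * gb^2
    corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
    clf$W <- clf$W - lr * (mW / corr1) / (sqrt(vW / corr2) + eps)
    clf$b <- clf$b - lr * (mb / corr1) / (sqrt(vb / corr2) + eps)
  }
  clf
}

#' Predict phenotype distributions for one image
#'
#' Runs every classifier in the ensemble on the image and packages the
#' softmax outputs plus their argmax variants as a `prediction_set`. Pure:
#' no state is read or mutated beyond the arguments.
#'
#' @param ensemble a `classifier_ensemble`.
#' @param image an `image_tensor` matching the ensemble's dimensions.
#' @param schema a `phenotype_schema`.
#' @return a `prediction_set`.
#' @export
predict_distributions <- function(ensemble, image, schema) {
  if (!identical(dim(image$pixels), as.integer(ensemble$dims)) &&
      !identical(dim(image$pixels), ensemble$dims)) {
    stop("image dimensions ", paste(dim(image$pixels), collapse = "x"),
         " do not match ensemble dimensions ",
         paste(ensemble$dims, collapse = "x"))
  }
  x <- as.vector(image$pixels)
  dists <- lapply(schema$phenotypes, function(p) {
    clf_predict(ensemble$classifiers[[p]], x)
  })
  names(dists) <- schema$phenotypes
  prediction_set(image$image_id, dists)
}

#' Batch prediction helper
#'
#' @param images list of `image_tensor`.
#' @inheritParams predict_distributions
#' @return list of `prediction_set`.
#' @export
predict_all <- function(ensemble, images, schema) {
  lapply(images, predict_distributions, ensemble = ensemble, schema = schema)
}

#' Held-out accuracy of an ensemble per phenotype
#'
#' @param ensemble a `classifier_ensemble`.
#' @param images list of `image_tensor`.
#' @param labels aligned list of `phenotype_profile`.
#' @param schema a `phenotype_schema`.
#' @return named numeric vector of per-phenotype argmax accuracies.
#' @export
classifier_accuracy <- function(ensemble, images, labels, schema) {
  preds <- predict_all(ensemble, images, schema)
  vapply(schema$phenotypes, function(p) {
    mean(vapply(seq_along(images), function(i) {
      preds[[i]]$argmax_variants[[p]] == labels[[i]]$values[[p]]
    }, logical(1)))
  }, numeric(1))
}

#' Save / load an ensemble checkpoint
#'
#' Single-file checkpoint (R serialisation) holding all classifier
#' parameters and dimensions.
#'
#' @param path checkpoint file path.
#' @export
save_ensemble <- function(ensemble, path) {
  saveRDS(ensemble, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @param ensemble a `classifier_ensemble`.
#' @export
load_ensemble <- function(path) {
  readRDS(path)
}

#' @export
print.classifier_ensemble <- function(x, ...) {
  cat(sprintf(
    "classifier_ensemble: %s on %s images\n",
    paste(names(x$classifiers), collapse = ", "),
    paste(x$dims, collapse = "x")
  ))
  invisible(x)
}
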