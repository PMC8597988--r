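#' Top-k matching success
#'
#' Fraction of probe images whose true genome's score is among the k largest
#' in the image's row. Ties are broken deterministically by genome list order
#' (earlier genomes win); `ties = "expected"` instead reports the expected
#' success under uniformly random tie-breaking, i.e. the fraction of the tied
#' block that fits into the remaining top-k slots.
#'
#' @param matrix a `score_matrix` with truth.
#' @param k number of top-scored genomes an attacker may claim, `1 <= k <= N`.
#' @param ties `"deterministic"` (default) or `"expected"`.
#' @return success fraction in [0, 1].
#' @export
top_k_success <- function(matrix, k, ties = c("deterministic", "expected")) {
  ties <- match.arg(ties)
  if (is.null(matrix$truth)) stop("score matrix has no truth mapping")
  n <- length(matrix$genome_ids)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  probes <- names(matrix$truth)
  succ <- vapply(probes, function(im) {
    row <- matrix$scores[im, ]
    jt <- match(matrix$truth[[im]], matrix$genome_ids)
    s <- row[jt]
    n_above <- sum(row > s)
    if (ties == "deterministic") {
      rank_det <- n_above + sum(row == s & seq_len(n) < jt) + 1
      as.numeric(rank_det <= k)
    } else {
      t <- sum(row == s)  # tied block incl. the true genome
      max(0, min(k - n_above, t)) / t
    }
  }, numeric(1))
  mean(succ)
}

#' Random score matrix (the no-information null)
#'
#' I.i.d. uniform scores on a (shifted-negative) scale; the analytic top-k
#' success rate of this null is k/N, the random-matching lower bound.
#'
#' @param n_images,n_genomes dimensions; by default truth is the identity
#'   mapping on shared ids (requires `n_images <= n_genomes`).
#' @param seed integer seed.
#' @return a `score_matrix` with identity truth on the probe ids.
#' @export
random_score_matrix <- function(n_images, n_genomes, seed) {
  stopifnot(n_images <= n_genomes)
  set.seed(seed)
  ids <- sprintf("ind%03d", seq_len(n_genomes))
  m <- matrix(stats::runif(n_images * n_genomes) - 1,
              nrow = n_images, ncol = n_genomes)
  score_matrix(ids[seq_len(n_images)], ids, m,
               truth = stats::setNames(ids[seq_len(n_images)], ids[seq_len(n_images)]))
}

#' Matching success as a function of population size
#'
#' For each requested population size s, repeatedly subsamples a
#' subpopulation of s individuals and recomputes top-k success of their probe
#' images against exactly those individuals' genomes. Each probe's true
#' genome is therefore always present — matching success is defined under
#' the assumption that the true match is in the gallery. Subsampling is
#' independent across sizes and replicates, and reproducible from the seed.
#'
#' @param matrix a `score_matrix` with truth.
#' @param sizes integer vector of population sizes (each `<=` total genomes).
#' @param k top-k parameter (each size must be `>= k`).
#' @param replicates subsample replicates per size.
#' @param seed integer seed.
#' @param mode label recorded in the report rows (e.g. "predicted",
#'   "true_phenotype", "random").
#' @return a data.frame with columns mode, population_size, k_or_tau,
#'   metric, value, n_replicates, seed (the tidy risk-report layout).
#' @export
population_sweep <- function(matrix, sizes, k, replicates = 20, seed = 1,
                             mode = "predicted") {
  if (is.null(matrix$truth)) stop("score matrix has no truth mapping")
  stopifnot(replicates >= 1)
  if (any(sizes > length(matrix$truth))) {
    stop("population size exceeds available true pairs")
  }
  if (any(sizes < k)) stop("population size below k")
  rows <- lapply(sizes, function(s) {
    set.seed(derive_seed(seed, paste0("sweep", s)))
    vals <- vapply(seq_len(replicates), function(r) {
      sub <- subsample_matrix(matrix, s)
      top_k_success(sub, k)
    }, numeric(1))
    data.frame(mode = mode, population_size = s, k_or_tau = k,
               metric = "top_k_success", value = mean(vals),
               n_replicates = replicates, seed = seed)
  })
  do.call(rbind, rows)
}

# subsample a subpopulation of s true pairs: the probe images of the chosen
# individuals matched against exactly those individuals' genomes, so every
# probe's true genome is present by construction
subsample_matrix <- function(matrix, s) {
  probes <- names(matrix$truth)
  pick <- sort(sample(length(probes), s))
  rows <- probes[pick]
  keep <- match(matrix$truth[rows], matrix$genome_ids)
  score_matrix(rows, matrix$genome_ids[keep],
               matrix$scores[rows, keep, drop = FALSE],
               truth = matrix$truth[rows])
}

#' True-phenotype upper-bound sweep
#'
#' Identical protocol to the predicted-phenotype sweep, but the attacker
#' scores with the individuals' actual phenotypes instead of classifier
#' argmax predictions — the performance ceiling of any image-based attack
#' that observes these phenotypes.
#'
#' @param truth_phenotypes list of `phenotype_profile` objects for the probes.
#' @param genomes list of `genome` objects.
#' @param model a `conditional_model`.
#' @param schema a `phenotype_schema`.
#' @inheritParams population_sweep
#' @return risk-report rows (see [population_sweep()]), mode "true_phenotype".
#' @export
baseline_upper_bound <- function(truth_phenotypes, genomes, model,
                                 schema = model$schema, k = 1,
                                 sizes, replicates = 20, seed = 1) {
  preds <- predictions_from_truth(truth_phenotypes, schema)
  m <- build_score_matrix(preds, genomes, model, schema)
  population_sweep(m, sizes, k, replicates, seed, mode = "true_phenotype")
}

#' Random lower-bound sweep rows
#'
#' The analytic random-matching rate k/s for each size; reported in the same
#' tidy layout for plotting beside the empirical curves.
#'
#' @inheritParams population_sweep
#' @export
baseline_random <- function(sizes, k, seed = 1) {
  data.frame(mode = "random", population_size = sizes, k_or_tau = k,
             metric = "top_k_success", value = k / sizes,
             n_replicates = 0L, seed = seed)
}

#' ROC curve and AUC for match-versus-nonmatch prediction
#'
#' Treats every image-genome pair as a binary instance (positive = true
#' pair), pooled across images. In mode `"tau"` a pair is declared a match
#' when its log-likelihood score is at least a threshold tau, swept over all
#' distinct scores; in mode `"k"` a pair is a match when it lies in the
#' image's top k, swept over k = 0..N (0 and N anchor the curve at (0,0) and
#' (1,1)). AUC is the trapezoidal integral over the sorted ROC points.
#' `macro = TRUE` averages per-image ROC curves (mode "tau" only) instead of
#' pooling.
#'
#' @param matrix a `score_matrix` with truth.
#' @param mode `"tau"` (score threshold, default) or `"k"` (rank threshold).
#' @param macro per-image macro-averaging flag.
#' @return list with `roc` (data.frame fpr, tpr, threshold) and `auc`.
#' @export
roc_and_auc <- function(matrix, mode = c("tau", "k"), macro = FALSE) {
  mode <- match.arg(mode)
  if (is.null(matrix$truth)) stop("score matrix has no truth mapping")
  probes <- names(matrix$truth)
  n <- length(matrix$genome_ids)
  if (mode == "tau") {
    if (macro) {
      grids <- lapply(probes, function(im) {
        labels <- matrix$genome_ids == matrix$truth[[im]]
        roc_points(matrix$scores[im, ], labels)
      })
      # average TPR over a common FPR grid
      fpr_grid <- sort(unique(unlist(lapply(grids, function(g) g$fpr))))
      tpr <- rowMeans(vapply(grids, function(g) {
        stats::approx(g$fpr, g$tpr, xout = fpr_grid, ties = max,
                      yleft = 0, yright = 1)$y
      }, numeric(length(fpr_grid))))
      roc <- data.frame(fpr = fpr_grid, tpr = tpr, threshold = NA_real_)
    } else {
      scores <- as.vector(matrix$scores[probes, , drop = FALSE])
      labels <- as.vector(vapply(matrix$genome_ids, function(g) {
        matrix$truth[probes] == g
      }, logical(length(probes))))
      roc <- roc_points(scores, labels)
    }
  } else {
    # rank-threshold sweep: per image, predicted positives are its top-k pairs
    ranks <- t(vapply(probes, function(im) {
      row <- matrix$scores[im, ]
      rank_det <- rank(-row, ties.method = "first")
      rank_det
    }, numeric(n)))
    true_rank <- vapply(seq_along(probes), function(i) {
      ranks[i, match(matrix$truth[[probes[i]]], matrix$genome_ids)]
    }, numeric(1))
    n_pos <- length(probes)
    n_neg <- length(probes) * (n - 1)
    pts <- lapply(0:n, function(k) {
      tp <- sum(true_rank <= k)
      fp <- n_pos * k - tp
      data.frame(fpr = fp / n_neg, tpr = tp / n_pos, threshold = k)
    })
    roc <- do.call(rbind, pts)
  }
  roc <- roc[order(roc$fpr, roc$tpr), ]
  list(roc = roc, auc = trapezoid_auc(roc$fpr, roc$tpr))
}

# ROC over a score threshold: predicted positive iff score >= tau
roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  scores <- scores[o]; labels <- labels[o]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  # step only at distinct score values
  keep <- !duplicated(scores, fromLast = TRUE) | seq_along(scores) == length(scores)
  tp <- cumsum(labels)[keep]
  fp <- cumsum(!labels)[keep]
  data.frame(
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos),
    threshold = c(Inf, scores[keep])
  )
}

trapezoid_auc <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Write risk-report rows as CSV
#'
#' @param report data.frame in the tidy risk-report layout.
#' @param path file path.
#' @export
write_risk_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
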