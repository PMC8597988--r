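#' Classifier prediction set for one image
#'
#' Holds, for one image, the per-phenotype predicted probability
#' distributions over variant domains and the most-likely (argmax) variant of
#' each, which is what the matching score consumes. Ties in the argmax are
#' broken by domain order.
#'
#' @param image_id character id.
#' @param distributions named list, phenotype -> named probability vector
#'   over the phenotype's variant domain (each summing to 1 within 1e-6).
#' @return an object of class `prediction_set`.
#' @export
prediction_set <- function(image_id, distributions) {
  stopifnot(is.character(image_id), length(image_id) == 1L)
  argmax <- character(length(distributions))
  names(argmax) <- names(distributions)
  for (p in names(distributions)) {
    d <- distributions[[p]]
    if (abs(sum(d) - 1) > 1e-6) {
      stop("distribution for '", p, "' does not sum to 1")
    }
    argmax[[p]] <- names(d)[argmax_first(d)]
  }
  structure(
    list(image_id = image_id, distributions = distributions,
         argmax_variants = argmax),
    class = "prediction_set"
  )
}

#' Build prediction sets directly from known phenotypes
#'
#' One-hot "predictions" from ground-truth profiles; this is the
#' true-phenotype upper-bound attacker, which knows every observable
#' phenotype exactly.
#'
#' @param profiles list of `phenotype_profile` objects.
#' @param schema a `phenotype_schema`.
#' @return list of `prediction_set` objects.
#' @export
predictions_from_truth <- function(profiles, schema) {
  lapply(profiles, function(pr) {
    dists <- lapply(schema$phenotypes, function(p) {
      dom <- schema$variant_domain[[p]]
      d <- stats::setNames(rep(0, length(dom)), dom)
      d[[pr$values[[p]]]] <- 1
      d
    })
    names(dists) <- schema$phenotypes
    prediction_set(pr$individual_id, dists)
  })
}

#' Log-likelihood matching score for one image-genome pair
#'
#' The naive-Bayes matching score
#' \deqn{p_{ij} = \sum_{p \in \{sex, hair, skin, eye\}} \log P(z_{i,p} \mid y_j)}
#' where \eqn{z_{i,p}} is the image's most-likely predicted variant for
#' phenotype \eqn{p} and each \eqn{P(z \mid y)} is the product of per-SNP
#' empirical conditionals. Probabilities are floored at the model's
#' `prob_floor` before taking logs (natural log), so scores are always
#' finite and nonpositive.
#'
#' @param predictions a `prediction_set` covering all schema phenotypes.
#' @param genome a `genome`.
#' @param model a `conditional_model`.
#' @param schema a `phenotype_schema` (defaults to the model's).
#' @return a single nonpositive log-likelihood.
#' @export
score_pair <- function(predictions, genome, model, schema = model$schema) {
  missing <- setdiff(schema$phenotypes, names(predictions$argmax_variants))
  if (length(missing)) {
    stop("predictions missing phenotypes: ", paste(missing, collapse = ", "))
  }
  s <- 0
  for (p in schema$phenotypes) {
    pr <- phenotype_prob_given_genome(predictions$argmax_variants[[p]], p,
                                      genome, model, schema)
    s <- s + log(max(pr, model$prob_floor))
  }
  s
}

#' Score matrix over all image-genome pairs
#'
#' @param predictions list of `prediction_set` objects (rows).
#' @param genomes list of `genome` objects (columns).
#' @param model a `conditional_model`.
#' @param schema a `phenotype_schema` (defaults to the model's).
#' @param truth optional named character vector image_id -> genome_id giving
#'   the correct match; defaults to identity of shared ids when every image
#'   id is also a genome id.
#' @return an object of class `score_matrix` with fields `image_ids`,
#'   `genome_ids`, `scores` (images x genomes matrix of log-likelihoods) and
#'   `truth`.
#' @export
build_score_matrix <- function(predictions, genomes, model,
                               schema = model$schema, truth = NULL) {
  stopifnot(length(predictions) > 0L, length(genomes) > 0L)
  image_ids <- vapply(predictions, function(p) p$image_id, character(1))
  genome_ids <- vapply(genomes, function(g) g$individual_id, character(1))
  if (anyDuplicated(image_ids)) stop("duplicate image ids")
  if (anyDuplicated(genome_ids)) stop("duplicate genome ids")

  # precompute per-genome log P(v|y) vectors once per phenotype
  logp <- lapply(genomes, function(g) {
    lapply(schema$phenotypes, function(p) {
      v <- phenotype_prob_vector(p, g, model, schema)
      log(pmax(v, model$prob_floor))
    }) |> stats::setNames(schema$phenotypes)
  })
  scores <- matrix(0, nrow = length(predictions), ncol = length(genomes),
                   dimnames = list(image_ids, genome_ids))
  for (i in seq_along(predictions)) {
    z <- predictions[[i]]$argmax_variants
    for (j in seq_along(genomes)) {
      s <- 0
      for (p in schema$phenotypes) s <- s + logp[[j]][[p]][[z[[p]]]]
      scores[i, j] <- s
    }
  }
  if (is.null(truth) && all(image_ids %in% genome_ids)) {
    truth <- stats::setNames(image_ids, image_ids)
  }
  score_matrix(image_ids, genome_ids, scores, truth)
}

#' @rdname build_score_matrix
#' @param image_ids,genome_ids ordered id vectors.
#' @param scores dense matrix of finite log-likelihood scores.
#' @export
score_matrix <- function(image_ids, genome_ids, scores, truth = NULL) {
  stopifnot(nrow(scores) == length(image_ids),
            ncol(scores) == length(genome_ids),
            all(is.finite(scores)))
  if (!is.null(truth)) {
    bad <- setdiff(names(truth), image_ids)
    if (length(bad)) stop("truth refers to unknown image ids: ",
                          paste(bad, collapse = ", "))
    if (!all(truth %in% genome_ids)) stop("truth refers to unknown genome ids")
  }
  dimnames(scores) <- list(image_ids, genome_ids)
  structure(
    list(image_ids = image_ids, genome_ids = genome_ids,
         scores = scores, truth = truth),
    class = "score_matrix"
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf(
    "score_matrix: %d images x %d genomes%s\n",
    length(x$image_ids), length(x$genome_ids),
    if (is.null(x$truth)) "" else sprintf(" (%d truth pairs)", length(x$truth))
  ))
  invisible(x)
}

#' Read / write a score matrix as TSV
#'
#' Rows are images, columns genomes; the first column holds image ids. Truth
#' is not serialised.
#'
#' @param path file path.
#' @export
write_score_matrix_tsv <- function(matrix, path) {
  df <- data.frame(image_id = matrix$image_ids,
                   matrix$scores, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_matrix_tsv
#' @param matrix a `score_matrix`.
#' @param truth optional truth mapping to attach.
#' @export
read_score_matrix_tsv <- function(path, truth = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  score_matrix(as.character(df$image_id), colnames(m), m, truth = truth)
}
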