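#' Fit empirical phenotype-given-genotype conditional tables
#'
#' For every (phenotype, SNP) pair in the schema, estimates the distribution
#' of phenotype variants conditional on each diploid genotype observed in the
#' fitting cohort, with additive (Laplace) smoothing:
#' \deqn{P(v \mid g) = \frac{n_{v,g} + \alpha}{n_g + \alpha\,|D_p|}}
#' where \eqn{n_{v,g}} counts individuals with genotype \eqn{g} and variant
#' \eqn{v}, and \eqn{|D_p|} is the size of the phenotype's variant domain.
#' Genotypes never observed during fitting are served the uniform
#' distribution at query time. Individuals missing a genotype at a SNP do not
#' contribute to that SNP's counts.
#'
#' The default \eqn{\alpha = 1} guards the log-space matching score against
#' unseen (genotype, variant) cells; \eqn{\alpha = 0} reproduces raw
#' empirical frequencies.
#'
#' @param cohort_genomes list of `genome` objects.
#' @param cohort_phenotypes list of `phenotype_profile` objects, aligned with
#'   the genomes by `individual_id` (order-free).
#' @param schema a `phenotype_schema`.
#' @param smoothing_alpha nonnegative pseudo-count (default 1).
#' @param prob_floor positive floor applied to probabilities at
#'   log-conversion time only, never to the stored tables (default 1e-12).
#' @return an object of class `conditional_model` with fields `tables`
#'   (`tables[[phenotype]][[rsID]][[genotype]]` = named probability vector
#'   over the variant domain), `smoothing_alpha`, `prob_floor`, `schema`.
#' @export
#' @examples
#' sc <- default_schema(snp_map = list(sex = "rs1", hair = "rs1",
#'                                     skin = "rs1", eye = "rs1"))
#' gs <- lapply(1:4, function(i) genome(paste0("i", i), c(rs1 = "AA")))
#' ps <- lapply(1:4, function(i)
#'   phenotype_profile(paste0("i", i),
#'     c(sex = "F", hair = "brown", skin = "pale", eye = "blue")))
#' m <- fit_conditional_tables(gs, ps, sc, smoothing_alpha = 0)
#' m$tables$eye$rs1$AA["blue"]  # 1
fit_conditional_tables <- function(cohort_genomes, cohort_phenotypes, schema,
                                   smoothing_alpha = 1, prob_floor = 1e-12) {
  stopifnot(inherits(schema, "phenotype_schema"),
            smoothing_alpha >= 0, prob_floor > 0)
  if (length(cohort_genomes) == 0L || length(cohort_phenotypes) == 0L) {
    stop("fitting cohort is empty")
  }
  gid <- vapply(cohort_genomes, function(g) g$individual_id, character(1))
  pid <- vapply(cohort_phenotypes, function(p) p$individual_id, character(1))
  only_g <- setdiff(gid, pid)
  only_p <- setdiff(pid, gid)
  if (length(only_g) || length(only_p)) {
    stop("cohorts not aligned; unmatched ids: ",
         paste(c(only_g, only_p), collapse = ", "))
  }
  prof_by_id <- stats::setNames(cohort_phenotypes, pid)

  tables <- list()
  for (p in schema$phenotypes) {
    dom <- schema$variant_domain[[p]]
    tables[[p]] <- list()
    for (snp in schema$snp_map[[p]]) {
      counts <- list()  # genotype -> named count vector over dom
      for (g in cohort_genomes) {
        gt <- g$genotypes[[snp]] %||% NA_character_
        if (is.na(gt)) next
        v <- prof_by_id[[g$individual_id]]$values[[p]]
        if (!v %in% dom) {
          stop("phenotype value '", v, "' of ", g$individual_id,
               " not in the ", p, " domain")
        }
        if (is.null(counts[[gt]])) {
          counts[[gt]] <- stats::setNames(numeric(length(dom)), dom)
        }
        counts[[gt]][v] <- counts[[gt]][v] + 1
      }
      tables[[p]][[snp]] <- lapply(counts, function(cnt) {
        (cnt + smoothing_alpha) / (sum(cnt) + smoothing_alpha * length(dom))
      })
    }
  }
  structure(
    list(tables = tables, smoothing_alpha = smoothing_alpha,
         prob_floor = prob_floor, schema = schema),
    class = "conditional_model"
  )
}

#' @export
print.conditional_model <- function(x, ...) {
  n_cells <- sum(vapply(x$tables, function(tp)
    sum(vapply(tp, length, integer(1))), integer(1)))
  cat(sprintf(
    "conditional_model: %d phenotypes, %d (SNP, genotype) cells, alpha = %g\n",
    length(x$tables), n_cells, x$smoothing_alpha
  ))
  invisible(x)
}

# per-SNP conditional lookup; unseen genotypes get the uniform distribution
snp_conditional <- function(model, phenotype, snp, genotype) {
  dom <- model$schema$variant_domain[[phenotype]]
  tab <- model$tables[[phenotype]][[snp]]
  if (is.null(tab)) stop("SNP '", snp, "' not fitted for phenotype '", phenotype, "'")
  entry <- tab[[genotype]]
  if (is.null(entry)) {
    entry <- stats::setNames(rep(1 / length(dom), length(dom)), dom)
  }
  entry
}

#' Probability of a phenotype variant given a genome
#'
#' Computes \eqn{P(v_p \mid y)} as the product, over the phenotype's relevant
#' SNPs, of the per-SNP empirical conditional evaluated at the genome's
#' genotype. A SNP missing from the genome contributes a neutral factor of 1
#' (alternatively a uniform `1/|domain|` factor via
#' `missing_policy = "uniform"`). With `normalize = TRUE` the products are
#' renormalised across the variant domain — a diagnostic mode only; the
#' matching score uses raw products.
#'
#' @param variant variant label (must be in the phenotype's domain).
#' @param phenotype phenotype name.
#' @param genome a `genome`.
#' @param model a `conditional_model`.
#' @param schema a `phenotype_schema` (defaults to the model's).
#' @param missing_policy `"skip"` (default) or `"uniform"`.
#' @param normalize renormalise across variants (default `FALSE`).
#' @return probability in (0, 1].
#' @export
phenotype_prob_given_genome <- function(variant, phenotype, genome, model,
                                        schema = model$schema,
                                        missing_policy = c("skip", "uniform"),
                                        normalize = FALSE) {
  missing_policy <- match.arg(missing_policy)
  v <- phenotype_prob_vector(phenotype, genome, model, schema, missing_policy)
  if (!variant %in% names(v)) {
    stop("variant '", variant, "' not in the ", phenotype, " domain")
  }
  if (normalize) v <- v / sum(v)
  unname(v[[variant]])
}

# full vector of products over relevant SNPs, one entry per variant
phenotype_prob_vector <- function(phenotype, genome, model,
                                  schema = model$schema,
                                  missing_policy = "skip") {
  if (!phenotype %in% schema$phenotypes) stop("unknown phenotype '", phenotype, "'")
  snps <- schema$snp_map[[phenotype]]
  if (length(snps) == 0L) {
    stop("phenotype '", phenotype, "' has no relevant SNPs configured; cannot score")
  }
  dom <- schema$variant_domain[[phenotype]]
  out <- stats::setNames(rep(1, length(dom)), dom)
  for (snp in snps) {
    gt <- genome$genotypes[[snp]] %||% NA_character_
    if (is.na(gt)) {
      if (missing_policy == "uniform") out <- out / length(dom)
      next  # "skip": neutral factor
    }
    out <- out * snp_conditional(model, phenotype, snp, gt)[dom]
  }
  out
}
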