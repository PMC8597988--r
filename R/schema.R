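#' Phenotype schema: visible traits, their variant domains, and relevant SNPs
#'
#' A `phenotype_schema` names the visible phenotypes used for linkage, the
#' closed set of variant labels each can take, and the SNPs (rsIDs) that
#' inform each phenotype. The matching score treats each phenotype's
#' variant-given-genome probability as a product of per-SNP conditionals over
#' exactly these SNPs.
#'
#' @param phenotypes character vector of phenotype names, in scoring order.
#' @param variant_domain named list, one character vector of variant labels
#'   per phenotype.
#' @param snp_map named list, one character vector of rsIDs per phenotype.
#' @return an object of class `phenotype_schema`.
#' @export
phenotype_schema <- function(phenotypes, variant_domain, snp_map) {
  stopifnot(is.character(phenotypes), length(phenotypes) >= 1L)
  if (!setequal(names(variant_domain), phenotypes) ||
      !setequal(names(snp_map), phenotypes)) {
    stop("variant_domain and snp_map must be named by exactly the phenotypes")
  }
  for (p in phenotypes) {
    dom <- variant_domain[[p]]
    if (length(dom) == 0L || anyDuplicated(dom)) {
      stop("variant domain for '", p, "' must be non-empty and duplicate-free")
    }
  }
  structure(
    list(
      phenotypes = phenotypes,
      variant_domain = variant_domain[phenotypes],
      snp_map = snp_map[phenotypes]
    ),
    class = "phenotype_schema"
  )
}

#' Default four-phenotype schema
#'
#' The standard schema for face-visible traits: sex in \{F, M\}, eye colour in
#' \{blue, brown, intermediate\}, hair colour in \{black, blonde, brown\} and
#' skin colour in \{pale, intermediate, dark\}. The published SNP panel behind
#' the original study is not public, so the default SNP map is a small
#' synthetic biallelic panel (2-4 SNPs per phenotype) matched to the cohort
#' generator; substitute a real panel via `snp_map`.
#'
#' @param snp_map optional named list of rsID vectors to override the
#'   synthetic default panel.
#' @return a `phenotype_schema`.
#' @export
#' @examples
#' sc <- default_schema()
#' sc$variant_domain$sex     # "F" "M"
default_schema <- function(snp_map = NULL) {
  if (is.null(snp_map)) {
    snp_map <- list(
      sex  = c("rs1001", "rs1002"),
      hair = c("rs2001", "rs2002", "rs2003"),
      skin = c("rs3001", "rs3002"),
      eye  = c("rs4001", "rs4002", "rs4003")
    )
  }
  phenotype_schema(
    phenotypes = c("sex", "hair", "skin", "eye"),
    variant_domain = list(
      sex  = c("F", "M"),
      hair = c("black", "blonde", "brown"),
      skin = c("pale", "intermediate", "dark"),
      eye  = c("blue", "brown", "intermediate")
    ),
    snp_map = snp_map
  )
}

#' Read / write a schema as JSON
#'
#' @param path file path.
#' @return `read_schema_json` returns a `phenotype_schema`;
#'   `write_schema_json` returns `path` invisibly.
#' @export
read_schema_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  phenotype_schema(
    phenotypes = as.character(x$phenotypes),
    variant_domain = lapply(x$variant_domain, as.character),
    snp_map = lapply(x$snp_map, as.character)
  )
}

#' @rdname read_schema_json
#' @param schema a `phenotype_schema`.
#' @export
write_schema_json <- function(schema, path) {
  stopifnot(inherits(schema, "phenotype_schema"))
  jsonlite::write_json(
    list(
      phenotypes = schema$phenotypes,
      variant_domain = schema$variant_domain,
      snp_map = schema$snp_map
    ),
    path,
    auto_unbox = FALSE, pretty = TRUE
  )
  invisible(path)
}

#' @export
print.phenotype_schema <- function(x, ...) {
  cat("phenotype_schema with", length(x$phenotypes), "phenotypes\n")
  for (p in x$phenotypes) {
    cat(sprintf(
      "  %-5s {%s}  SNPs: %s\n", p,
      paste(x$variant_domain[[p]], collapse = ", "),
      paste(x$snp_map[[p]], collapse = ", ")
    ))
  }
  invisible(x)
}

all_schema_snps <- function(schema) {
  unique(unlist(schema$snp_map, use.names = FALSE))
}
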