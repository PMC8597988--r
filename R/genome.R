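#' Genomes and phenotype profiles
#'
#' A `genome` holds one individual's unordered diploid genotypes over a SNP
#' panel. Allele pairs are canonicalised to sorted order at construction, so
#' "AG" and "GA" compare equal; input is assumed to be on a consistent
#' strand. Missing genotypes are stored as `NA` (never dropped), written as
#' `--` in TSV.
#'
#' @param individual_id character id.
#' @param genotypes named character vector, rsID -> two-letter genotype from
#'   \{A,C,G,T\}, or `NA`/`"--"` for missing.
#' @return an object of class `genome`.
#' @export
#' @examples
#' g <- genome("id1", c(rs1001 = "GA", rs2001 = "--"))
#' g$genotypes[["rs1001"]]  # "AG"
genome <- function(individual_id, genotypes) {
  stopifnot(is.character(individual_id), length(individual_id) == 1L)
  genotypes <- vapply(genotypes, canonical_genotype, character(1))
  structure(
    list(individual_id = individual_id, genotypes = genotypes),
    class = "genome"
  )
}

canonical_genotype <- function(g) {
  if (is.na(g) || identical(g, "--") || !nzchar(g)) return(NA_character_)
  alleles <- strsplit(g, "")[[1]]
  if (length(alleles) != 2L || !all(alleles %in% c("A", "C", "G", "T"))) {
    stop("invalid genotype '", g, "': expected two characters from {A,C,G,T} or '--'")
  }
  paste(sort(alleles), collapse = "")
}

#' @rdname genome
#' @param values named character vector, phenotype -> variant label.
#' @param schema optional `phenotype_schema`; when given, values are checked
#'   against the variant domains.
#' @export
phenotype_profile <- function(individual_id, values, schema = NULL) {
  stopifnot(is.character(individual_id), length(individual_id) == 1L)
  values <- unlist(values)
  if (!is.null(schema)) {
    for (p in names(values)) {
      if (!p %in% schema$phenotypes) stop("unknown phenotype '", p, "'")
      if (!values[[p]] %in% schema$variant_domain[[p]]) {
        stop("value '", values[[p]], "' not in the ", p, " domain")
      }
    }
  }
  structure(
    list(individual_id = individual_id, values = values),
    class = "phenotype_profile"
  )
}

#' @export
print.genome <- function(x, ...) {
  n_miss <- sum(is.na(x$genotypes))
  cat(sprintf(
    "genome %s: %d SNPs (%d missing)\n",
    x$individual_id, length(x$genotypes), n_miss
  ))
  invisible(x)
}

#' @export
print.phenotype_profile <- function(x, ...) {
  cat(sprintf(
    "phenotype_profile %s: %s\n", x$individual_id,
    paste(names(x$values), x$values, sep = "=", collapse = ", ")
  ))
  invisible(x)
}

#' Read and write genotype tables as TSV
#'
#' Layout: header `individual_id<TAB>rs...<TAB>rs...`, one row per
#' individual, cells two-letter genotypes or `--` for missing.
#'
#' @param path file path.
#' @return `read_genomes_tsv` returns a list of `genome` objects.
#' @export
read_genomes_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (!"individual_id" %in% names(df)) stop("missing 'individual_id' column")
  snps <- setdiff(names(df), "individual_id")
  lapply(seq_len(nrow(df)), function(i) {
    genome(df$individual_id[i],
           stats::setNames(as.character(df[i, snps]), snps))
  })
}

#' @rdname read_genomes_tsv
#' @param genomes list of `genome` objects.
#' @export
write_genomes_tsv <- function(genomes, path) {
  snps <- unique(unlist(lapply(genomes, function(g) names(g$genotypes))))
  rows <- lapply(genomes, function(g) {
    gt <- g$genotypes[snps]
    gt[is.na(gt)] <- "--"
    c(g$individual_id, unname(gt))
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("individual_id", snps)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write phenotype profiles as TSV
#'
#' Layout: `individual_id<TAB>sex<TAB>hair<TAB>skin<TAB>eye` (column set
#' follows the schema's phenotypes when writing).
#'
#' @param path file path.
#' @param schema optional `phenotype_schema` for domain validation.
#' @return `read_profiles_tsv` returns a list of `phenotype_profile` objects.
#' @export
read_profiles_tsv <- function(path, schema = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (!"individual_id" %in% names(df)) stop("missing 'individual_id' column")
  phen <- setdiff(names(df), "individual_id")
  lapply(seq_len(nrow(df)), function(i) {
    phenotype_profile(df$individual_id[i],
                      stats::setNames(as.character(df[i, phen]), phen),
                      schema = schema)
  })
}

#' @rdname read_profiles_tsv
#' @param profiles list of `phenotype_profile` objects.
#' @export
write_profiles_tsv <- function(profiles, path) {
  phen <- names(profiles[[1]]$values)
  rows <- lapply(profiles, function(p) c(p$individual_id, unname(p$values[phen])))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("individual_id", phen)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimal VCF genotype reader
#'
#' Extracts diploid genotypes from a VCF's GT field, resolving allele indices
#' against REF/ALT (multi-allelic sites accepted). Sample columns become
#' individuals; the ID column supplies rsIDs. Everything beyond GT is
#' ignored. Half-missing or fully missing calls (`./.`, `.|1`) map to
#' missing. Requires the vcfR package.
#'
#' @param path VCF file path (plain or bgzipped).
#' @return list of `genome` objects, one per sample.
#' @export
read_genomes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_genomes_vcf requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  lapply(samples, function(s) {
    calls <- vapply(seq_along(ids), function(i) {
      gt_to_pair(gt[i, s], ref[i], alt[i])
    }, character(1))
    genome(s, stats::setNames(calls, ids))
  })
}

gt_to_pair <- function(call, ref, alt) {
  if (is.na(call)) return(NA_character_)
  idx <- strsplit(call, "[/|]")[[1]]
  if (length(idx) != 2L || any(idx == ".")) return(NA_character_)
  alleles <- c(ref, strsplit(alt, ",")[[1]])
  pair <- alleles[as.integer(idx) + 1L]
  if (any(is.na(pair)) || any(nchar(pair) != 1L)) return(NA_character_)
  paste(sort(pair), collapse = "")
}
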