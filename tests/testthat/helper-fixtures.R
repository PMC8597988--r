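# shared fixtures: tiny schemas and cohorts built in code

# one SNP per phenotype; with product combination this makes the generating
# conditionals directly identifiable from (genotype, phenotype) counts
single_snp_schema <- function() {
  default_schema(snp_map = list(sex = "rs1001", hair = "rs2001",
                                skin = "rs3001", eye = "rs4001"))
}

# cohort where every individual shares one genotype at one SNP, with chosen
# eye colours; used for direct hand-counted conditionals
handmade_cohort <- function(eyes, genotype = "AA", snp = "rs4001") {
  ids <- paste0("h", seq_along(eyes))
  genomes <- lapply(ids, function(id) {
    genome(id, stats::setNames(c("AA", "AA", "AA", genotype),
                               c("rs1001", "rs2001", "rs3001", snp)))
  })
  profiles <- lapply(seq_along(ids), function(i) {
    phenotype_profile(ids[i], c(sex = "F", hair = "brown", skin = "pale",
                                eye = eyes[i]))
  })
  list(genomes = genomes, profiles = profiles)
}

# standard small synthetic world for matching tests
small_world <- function(n = 20, seed = 7, noise = 0.05, ...) {
  spec <- generator_spec(n_individuals = n, seed = seed,
                         render_noise_sd = noise, ...)
  cohort <- generate_cohort(spec)
  model <- fit_conditional_tables(cohort$genomes, cohort$profiles,
                                  spec$schema)
  list(spec = spec, schema = spec$schema, genomes = cohort$genomes,
       profiles = cohort$profiles, model = model)
}

# independent brute-force conditional estimator: plain counting over raw
# records, never touching fit_conditional_tables internals
oracle_conditional <- function(genomes, profiles, phenotype, snp, genotype,
                               domain, alpha) {
  counts <- stats::setNames(rep(0, length(domain)), domain)
  for (i in seq_along(genomes)) {
    gt <- genomes[[i]]$genotypes[[snp]]
    if (is.na(gt) || gt != genotype) next
    v <- profiles[[i]]$values[[phenotype]]
    counts[v] <- counts[v] + 1
  }
  (counts + alpha) / (sum(counts) + alpha * length(domain))
}

# independent score oracle: explicit loops over phenotypes and SNPs with
# brute-force counting, log flooring applied at the end
oracle_score <- function(pred, genome, genomes, profiles, schema, alpha,
                         prob_floor = 1e-12) {
  total <- 0
  for (p in schema$phenotypes) {
    dom <- schema$variant_domain[[p]]
    z <- pred$argmax_variants[[p]]
    prob <- 1
    for (snp in schema$snp_map[[p]]) {
      gt <- genome$genotypes[[snp]]
      if (is.na(gt)) next
      seen <- any(vapply(genomes, function(g) {
        !is.na(g$genotypes[[snp]]) && g$genotypes[[snp]] == gt
      }, logical(1)))
      prob <- prob * if (seen) {
        oracle_conditional(genomes, profiles, p, snp, gt, dom, alpha)[[z]]
      } else 1 / length(dom)
    }
    total <- total + log(max(prob, prob_floor))
  }
  total
}

# rank of the true genome in a score row, ties broken by genome order
oracle_rank <- function(row, true_idx) {
  r <- 0
  for (j in seq_along(row)) {
    if (row[j] > row[true_idx] || (row[j] == row[true_idx] && j < true_idx)) {
      r <- r + 1
    }
  }
  r + 1
}
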