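test_that("generator spec validates probabilities and requires a seed", {
  expect_error(generator_spec(10), "seed")
  sc <- default_schema()
  snps <- c("rs1001", "rs1002", "rs2001", "rs2002", "rs2003",
            "rs3001", "rs3002", "rs4001", "rs4002", "rs4003")
  freq1 <- stats::setNames(rep(0.5, 10), snps)
  freq1["rs1001"] <- 1.0
  expect_error(generator_spec(10, schema = sc, allele_freq = freq1, seed = 1),
               "strictly inside")
  bad_tabs <- default_generating_tables(sc, stats::setNames(
    rep(list(c("A", "G")), 10), snps))
  bad_tabs$sex$rs1001$AA <- c(F = 0.7, M = 0.7)
  expect_error(generator_spec(10, schema = sc, generating_tables = bad_tabs,
                              seed = 1),
               "sum to 1")
})

test_that("cohorts are pure functions of the spec and seed", {
  spec <- generator_spec(n_individuals = 30, seed = 11)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  c2 <- generate_cohort(generator_spec(n_individuals = 30, seed = 12))
  expect_false(identical(a$genomes, c2$genomes))
  # rendered images and simulated predictions are equally reproducible
  expect_identical(render_images(a$profiles[1:3], spec),
                   render_images(a$profiles[1:3], spec))
  expect_identical(
    simulate_noisy_predictions(a$profiles, 0.3, spec$schema, seed = 4),
    simulate_noisy_predictions(a$profiles, 0.3, spec$schema, seed = 4)
  )
})

test_that("genotype draws follow Hardy-Weinberg proportions", {
  sc <- single_snp_schema()
  freq <- stats::setNames(rep(0.3, 4), unlist(sc$snp_map))
  spec <- generator_spec(n_individuals = 4000, schema = sc,
                         allele_freq = freq, seed = 17)
  co <- generate_cohort(spec)
  gts <- vapply(co$genomes, function(g) g$genotypes[["rs1001"]], character(1))
  p <- 0.3
  expected <- c(AA = p^2, AG = 2 * p * (1 - p), GG = (1 - p)^2)
  for (gt in names(expected)) {
    se <- sqrt(expected[gt] * (1 - expected[gt]) / 4000)
    expect_lt(abs(mean(gts == gt) - expected[gt]), 4 * se)
  }
})

test_that("sampled phenotypes reproduce the generating conditionals", {
  # one SNP per phenotype: the sampling conditional IS the generating table
  sc <- single_snp_schema()
  spec <- generator_spec(n_individuals = 5000, schema = sc, seed = 23)
  co <- generate_cohort(spec)
  for (p in sc$phenotypes) {
    snp <- sc$snp_map[[p]]
    gts <- vapply(co$genomes, function(g) g$genotypes[[snp]], character(1))
    vals <- vapply(co$profiles, function(pr) pr$values[[p]], character(1))
    for (gt in unique(gts)) {
      sel <- gts == gt
      if (sum(sel) < 200) next
      emp <- vapply(sc$variant_domain[[p]],
                    function(v) mean(vals[sel] == v), numeric(1))
      gen <- spec$generating_tables[[p]][[snp]][[gt]]
      se <- sqrt(gen * (1 - gen) / sum(sel))
      expect_true(all(abs(emp - gen) < 4 * se + 1e-3),
                  info = paste(p, gt))
    }
  }
})

test_that("near-monomorphic SNPs leave rare genotypes to the smoothing fallback", {
  sc <- single_snp_schema()
  freq <- stats::setNames(rep(0.999, 4), unlist(sc$snp_map))
  spec <- generator_spec(n_individuals = 200, schema = sc,
                         allele_freq = freq, seed = 29)
  co <- generate_cohort(spec)
  m <- fit_conditional_tables(co$genomes, co$profiles, sc)
  # GG essentially never observed: the model serves the uniform distribution
  g_rare <- genome("rare", stats::setNames(rep("GG", 4), unlist(sc$snp_map)))
  pv <- phenolink:::phenotype_prob_vector("eye", g_rare, m)
  if (is.null(m$tables$eye$rs4001$GG)) {
    expect_equal(unname(pv), rep(1 / 3, 3))
  } else {
    expect_equal(sum(pv), 1, tolerance = 1e-9)
  }
})

test_that("ideal genotype assignment maximises the phenotype likelihood", {
  sc <- single_snp_schema()
  w <- small_world(n = 60, seed = 37, schema = sc)
  profile <- w$profiles[[1]]
  pick <- assign_genotype_ideal(profile, w$genomes, w$profiles, w$model)
  # exhaustive oracle over the matching pool
  phen <- names(profile$values)
  match_idx <- which(vapply(w$profiles, function(pp) {
    all(pp$values[phen] == profile$values[phen])
  }, logical(1)))
  liks <- vapply(match_idx, function(j) {
    prod(vapply(sc$phenotypes, function(p) {
      phenotype_prob_given_genome(profile$values[[p]], p, w$genomes[[j]],
                                  w$model)
    }, numeric(1)))
  }, numeric(1))
  best_lik <- prod(vapply(sc$phenotypes, function(p) {
    phenotype_prob_given_genome(profile$values[[p]], p, pick, w$model)
  }, numeric(1)))
  expect_equal(best_lik, max(liks))
  # the returned genome's owner shares the profile's phenotypes
  owner <- w$profiles[[match(pick$individual_id,
                             vapply(w$genomes, `[[`, "", "individual_id"))]]
  expect_identical(owner$values[phen], profile$values[phen])
  # single candidate is returned regardless of likelihood
  one <- assign_genotype_ideal(w$profiles[[2]], w$genomes[2], w$profiles[2],
                               w$model)
  expect_identical(one$individual_id, w$genomes[[2]]$individual_id)
  # no candidate errors
  stranger <- phenotype_profile("x", c(sex = "F", hair = "black",
                                       skin = "dark", eye = "blue"))
  expect_error(assign_genotype_ideal(stranger, w$genomes[2], w$profiles[2],
                                     w$model),
               "no genome")
})

test_that("realistic genotype assignment draws uniformly from the matching pool", {
  sc <- single_snp_schema()
  w <- small_world(n = 40, seed = 43, schema = sc)
  # pick the profile with the largest matching pool so uniformity is testable
  keys <- vapply(w$profiles, function(p) paste(p$values, collapse = "|"),
                 character(1))
  profile <- w$profiles[[match(names(which.max(table(keys))), keys)]]
  phen <- names(profile$values)
  match_ids <- vapply(w$genomes, `[[`, "", "individual_id")[
    vapply(w$profiles, function(pp) all(pp$values[phen] == profile$values[phen]),
           logical(1))]
  draws <- vapply(1:10000, function(s) {
    assign_genotype_realistic(profile, w$genomes, w$profiles,
                              seed = s)$individual_id
  }, character(1))
  expect_true(all(draws %in% match_ids))
  p_exp <- 1 / length(match_ids)
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  for (id in match_ids) {
    expect_lt(abs(mean(draws == id) - p_exp), 4 * se)
  }
  expect_identical(
    assign_genotype_realistic(profile, w$genomes, w$profiles, seed = 3),
    assign_genotype_realistic(profile, w$genomes, w$profiles, seed = 3)
  )
})

test_that("rendered images stay in range and encode phenotypes exactly at zero noise", {
  sc <- default_schema()
  spec <- generator_spec(n_individuals = 25, seed = 47, render_noise_sd = 0)
  co <- generate_cohort(spec)
  imgs <- render_images(co$profiles, spec)
  for (im in imgs) {
    expect_true(all(im$pixels >= 0 & im$pixels <= 1))
  }
  # rule-based decoder recovers every phenotype
  for (i in seq_along(imgs)) {
    expect_identical(decode_image(imgs[[i]], sc)$values[sc$phenotypes],
                     co$profiles[[i]]$values[sc$phenotypes])
  }
  # identical phenotypes give identical images at zero noise
  same <- which(duplicated(vapply(co$profiles, function(p)
    paste(p$values, collapse = "|"), character(1))) |
    duplicated(vapply(co$profiles, function(p)
      paste(p$values, collapse = "|"), character(1)), fromLast = TRUE))
  if (length(same) >= 2) {
    key <- vapply(co$profiles, function(p) paste(p$values, collapse = "|"),
                  character(1))
    pair <- which(key == key[same[1]])[1:2]
    expect_equal(imgs[[pair[1]]]$pixels, imgs[[pair[2]]]$pixels)
  }
  # noisy renders remain clipped
  specn <- generator_spec(n_individuals = 5, seed = 47, render_noise_sd = 0.3)
  con <- generate_cohort(specn)
  for (im in render_images(con$profiles, specn)) {
    expect_true(all(im$pixels >= 0 & im$pixels <= 1))
  }
})

test_that("simulated predictions hit the configured confusion level", {
  sc <- default_schema()
  spec <- generator_spec(n_individuals = 10000, seed = 53)
  co <- generate_cohort(spec)
  # confusion 0 reproduces the truth exactly
  p0 <- simulate_noisy_predictions(co$profiles[1:50], 0, sc, seed = 1)
  for (i in 1:50) {
    expect_identical(p0[[i]]$argmax_variants[sc$phenotypes],
                     stats::setNames(co$profiles[[i]]$values[sc$phenotypes],
                                     sc$phenotypes))
  }
  # confusion 1 on a two-variant phenotype forces an error every time
  p1 <- simulate_noisy_predictions(co$profiles[1:200], 1, sc, seed = 2)
  sex_acc <- mean(vapply(1:200, function(i) {
    p1[[i]]$argmax_variants[["sex"]] == co$profiles[[i]]$values[["sex"]]
  }, logical(1)))
  expect_equal(sex_acc, 0)
  # empirical confusion matches the configured rate
  conf <- 0.25
  pn <- simulate_noisy_predictions(co$profiles, conf, sc, seed = 3)
  err <- mean(vapply(seq_along(pn), function(i) {
    pn[[i]]$argmax_variants[["eye"]] != co$profiles[[i]]$values[["eye"]]
  }, logical(1)))
  se <- sqrt(conf * (1 - conf) / 10000)
  expect_lt(abs(err - conf), 3 * se)
})

test_that("the vote combination rule is available and changes sampling", {
  sc <- default_schema()
  sp_prod <- generator_spec(n_individuals = 300, seed = 59, combine = "product")
  sp_vote <- generator_spec(n_individuals = 300, seed = 59, combine = "vote")
  a <- generate_cohort(sp_prod)
  b <- generate_cohort(sp_vote)
  expect_identical(
    vapply(a$genomes, `[[`, "", "individual_id"),
    vapply(b$genomes, `[[`, "", "individual_id")
  )
  vals_a <- vapply(a$profiles, function(p) paste(p$values, collapse = "|"),
                   character(1))
  vals_b <- vapply(b$profiles, function(p) paste(p$values, collapse = "|"),
                   character(1))
  expect_false(identical(vals_a, vals_b))
})
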