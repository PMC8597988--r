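test_that("default schema carries the four visible phenotypes and domains", {
  sc <- default_schema()
  expect_identical(sc$phenotypes, c("sex", "hair", "skin", "eye"))
  expect_identical(sc$variant_domain$sex, c("F", "M"))
  expect_identical(sc$variant_domain$eye, c("blue", "brown", "intermediate"))
  expect_identical(sc$variant_domain$hair, c("black", "blonde", "brown"))
  expect_identical(sc$variant_domain$skin, c("pale", "intermediate", "dark"))
  expect_true(all(lengths(sc$snp_map) >= 1))
})

test_that("schema validation rejects malformed domains", {
  expect_error(
    phenotype_schema("sex", list(sex = c("F", "F")), list(sex = "rs1")),
    "duplicate-free"
  )
  expect_error(
    phenotype_schema("sex", list(sex = character(0)), list(sex = "rs1")),
    "non-empty"
  )
})

test_that("single-class degenerate fit gives probability one without smoothing", {
  co <- handmade_cohort(rep("blue", 4))
  m <- fit_conditional_tables(co$genomes, co$profiles, single_snp_schema(),
                              smoothing_alpha = 0)
  tab <- m$tables$eye$rs4001$AA
  expect_equal(unname(tab["blue"]), 1)
  expect_equal(unname(tab["brown"]), 0)
  expect_equal(unname(tab["intermediate"]), 0)
})

test_that("smoothed counts match hand arithmetic on the six-individual toy cohort", {
  eyes <- c("blue", "blue", "brown", "brown", "brown", "intermediate")
  gts <- c("AA", "AA", "AA", "AG", "AG", "AG")
  ids <- paste0("t", 1:6)
  genomes <- lapply(1:6, function(i) {
    genome(ids[i], c(rs1001 = "AA", rs2001 = "AA", rs3001 = "AA",
                     rs4001 = gts[i]))
  })
  profiles <- lapply(1:6, function(i) {
    phenotype_profile(ids[i], c(sex = "F", hair = "brown", skin = "pale",
                                eye = eyes[i]))
  })
  m <- fit_conditional_tables(genomes, profiles, single_snp_schema(),
                              smoothing_alpha = 1)
  # 2 blue of 3 AA, alpha = 1, domain size 3: (2+1)/(3+3)
  expect_equal(unname(m$tables$eye$rs4001$AA["blue"]), 0.5)
  # every cell equals the independent brute-force counter
  for (gt in c("AA", "AG")) {
    expect_equal(
      m$tables$eye$rs4001[[gt]],
      oracle_conditional(genomes, profiles, "eye", "rs4001", gt,
                         c("blue", "brown", "intermediate"), alpha = 1)
    )
  }
})

test_that("fitted tables equal brute-force counting on random cohorts", {
  sc <- default_schema()
  for (alpha in c(0, 1, 2.5)) {
    w <- small_world(n = 50, seed = 31 + alpha)
    m <- fit_conditional_tables(w$genomes, w$profiles, sc,
                                smoothing_alpha = alpha)
    for (p in sc$phenotypes) {
      for (snp in sc$snp_map[[p]]) {
        for (gt in names(m$tables[[p]][[snp]])) {
          expect_equal(
            m$tables[[p]][[snp]][[gt]],
            oracle_conditional(w$genomes, w$profiles, p, snp, gt,
                               sc$variant_domain[[p]], alpha),
            tolerance = 1e-12
          )
        }
      }
    }
  }
})

test_that("stored probability vectors are simplex points with smoothing floor", {
  w <- small_world(n = 60, seed = 5)
  m <- w$model  # alpha = 1 default
  for (p in names(m$tables)) {
    dom_size <- length(m$schema$variant_domain[[p]])
    for (snp in names(m$tables[[p]])) {
      for (entry in m$tables[[p]][[snp]]) {
        expect_equal(sum(entry), 1, tolerance = 1e-9)
        # minimum achievable mass under alpha = 1 given the largest cell count
        expect_true(all(entry >= 1 / (60 + dom_size)))
      }
    }
  }
})

test_that("fit rejects empty and misaligned cohorts, naming the stray id", {
  co <- handmade_cohort(c("blue", "brown"))
  expect_error(fit_conditional_tables(list(), list(), single_snp_schema()),
               "empty")
  expect_error(
    fit_conditional_tables(co$genomes[1], co$profiles, single_snp_schema()),
    "h2"
  )
})

test_that("unseen genotypes are served the uniform distribution", {
  co <- handmade_cohort(rep("blue", 4), genotype = "AA")
  m <- fit_conditional_tables(co$genomes, co$profiles, single_snp_schema())
  g_new <- genome("new", c(rs1001 = "AA", rs2001 = "AA", rs3001 = "AA",
                           rs4001 = "GG"))
  for (v in c("blue", "brown", "intermediate")) {
    expect_equal(phenotype_prob_given_genome(v, "eye", g_new, m), 1 / 3)
  }
})

test_that("variant probability is the product over relevant SNPs", {
  # two relevant eye SNPs with conditionals 0.5 and 0.2 (alpha = 0)
  sc <- default_schema(snp_map = list(sex = "rs1001", hair = "rs2001",
                                      skin = "rs3001",
                                      eye = c("rs4001", "rs4002")))
  ids <- paste0("i", 1:10)
  eyes <- c(rep("blue", 2), rep("brown", 8))
  genomes <- lapply(1:10, function(i) {
    # rs4001 AA for first 4 (2 blue of 4 -> 0.5); rs4002 AA for all
    # (2 blue of 10 -> 0.2)
    genome(ids[i], c(rs1001 = "AA", rs2001 = "AA", rs3001 = "AA",
                     rs4001 = if (i <= 4) "AA" else "GG", rs4002 = "AA"))
  })
  profiles <- lapply(1:10, function(i) {
    phenotype_profile(ids[i], c(sex = "F", hair = "brown", skin = "pale",
                                eye = eyes[i]))
  })
  m <- fit_conditional_tables(genomes, profiles, sc, smoothing_alpha = 0)
  g <- genomes[[1]]
  expect_equal(phenotype_prob_given_genome("blue", "eye", g, m), 0.5 * 0.2)
  # looped multiplication oracle
  loop <- 1
  for (snp in sc$snp_map$eye) {
    loop <- loop * oracle_conditional(genomes, profiles, "eye", snp,
                                      g$genotypes[[snp]],
                                      sc$variant_domain$eye, 0)[["blue"]]
  }
  expect_equal(phenotype_prob_given_genome("blue", "eye", g, m), loop)
  # single relevant SNP returns the table entry unchanged
  expect_equal(phenotype_prob_given_genome("brown", "hair", g, m),
               unname(m$tables$hair$rs2001$AA["brown"]))
})

test_that("missing genotypes contribute a neutral factor (or uniform by policy)", {
  sc <- default_schema(snp_map = list(sex = "rs1001", hair = "rs2001",
                                      skin = "rs3001",
                                      eye = c("rs4001", "rs4002")))
  co <- handmade_cohort(rep("blue", 4))
  genomes <- lapply(co$genomes, function(g) {
    genome(g$individual_id, c(g$genotypes, rs4002 = "AA"))
  })
  m <- fit_conditional_tables(genomes, co$profiles, sc)
  g_partial <- genome("p1", c(rs1001 = "AA", rs2001 = "AA", rs3001 = "AA",
                              rs4001 = "--", rs4002 = "AA"))
  expect_equal(
    phenotype_prob_given_genome("blue", "eye", g_partial, m),
    unname(m$tables$eye$rs4002$AA["blue"])
  )
  expect_equal(
    phenotype_prob_given_genome("blue", "eye", g_partial, m,
                                missing_policy = "uniform"),
    unname(m$tables$eye$rs4002$AA["blue"]) / 3
  )
})

test_that("scoring is invariant to SNP order in the map and errors without SNPs", {
  sc1 <- default_schema(snp_map = list(sex = "rs1001", hair = "rs2001",
                                       skin = "rs3001",
                                       eye = c("rs4001", "rs4002")))
  sc2 <- default_schema(snp_map = list(sex = "rs1001", hair = "rs2001",
                                       skin = "rs3001",
                                       eye = c("rs4002", "rs4001")))
  co <- handmade_cohort(c("blue", "brown", "blue", "intermediate"))
  genomes <- lapply(co$genomes, function(g) {
    genome(g$individual_id, c(g$genotypes, rs4002 = "AG"))
  })
  m1 <- fit_conditional_tables(genomes, co$profiles, sc1)
  m2 <- fit_conditional_tables(genomes, co$profiles, sc2)
  expect_equal(
    phenotype_prob_given_genome("blue", "eye", genomes[[1]], m1),
    phenotype_prob_given_genome("blue", "eye", genomes[[1]], m2)
  )
  sc_empty <- phenotype_schema(
    c("sex", "eye"),
    list(sex = c("F", "M"), eye = c("blue", "brown")),
    list(sex = "rs1001", eye = character(0))
  )
  m_e <- fit_conditional_tables(co$genomes, co$profiles, sc_empty)
  expect_error(
    phenotype_prob_given_genome("blue", "eye", co$genomes[[1]], m_e),
    "no relevant SNPs"
  )
})

test_that("fitted tables converge to the generating conditionals with cohort size", {
  sc <- single_snp_schema()
  errs <- vapply(c(50, 500, 5000), function(n) {
    spec <- generator_spec(n_individuals = n, schema = sc, seed = 41)
    co <- generate_cohort(spec)
    m <- fit_conditional_tables(co$genomes, co$profiles, sc)
    worst <- 0
    for (p in sc$phenotypes) {
      snp <- sc$snp_map[[p]]
      for (gt in names(m$tables[[p]][[snp]])) {
        gen <- spec$generating_tables[[p]][[snp]][[gt]]
        worst <- max(worst, max(abs(m$tables[[p]][[snp]][[gt]] - gen)))
      }
    }
    worst
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.02)
})
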