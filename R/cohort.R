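#' Synthetic cohort generator specification
#'
#' Bundles everything needed to generate a genotype-phenotype-image cohort
#' with known generating distributions: the schema, per-SNP allele
#' frequencies, the genotype-conditional variant tables the phenotypes are
#' drawn from, image geometry and noise, simulated classifier confusion, and
#' the mandatory seed.
#'
#' @param n_individuals cohort size.
#' @param schema a `phenotype_schema`.
#' @param allele_freq named numeric vector, rsID -> frequency of the first
#'   allele, strictly inside (0, 1); defaults to 0.5 everywhere.
#' @param alleles named list, rsID -> the two allele letters (default
#'   c("A", "G") for every SNP).
#' @param generating_tables nested list
#'   `[[phenotype]][[rsID]][[genotype]]` -> named probability vector over the
#'   variant domain; defaults to [default_generating_tables()].
#' @param combine `"product"`: phenotypes are drawn from the renormalised
#'   product of per-SNP conditionals (the same combination rule the matching
#'   score assumes, so parameter-recovery experiments are well specified);
#'   `"vote"`: a deliberately misspecified alternative where each SNP votes
#'   an independently drawn variant and the modal vote wins.
#' @param image_size c(height, width) of rendered images.
#' @param render_noise_sd Gaussian pixel noise added at render time.
#' @param confusion_level probability that the simulated classifier's argmax
#'   is a (uniform) wrong variant.
#' @param seed integer seed (mandatory).
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(n_individuals, schema = default_schema(),
                           allele_freq = NULL, alleles = NULL,
                           generating_tables = NULL,
                           combine = c("product", "vote"),
                           image_size = c(32, 32),
                           render_noise_sd = 0.05,
                           confusion_level = 0.1,
                           seed) {
  combine <- match.arg(combine)
  if (missing(seed)) stop("generator_spec requires an explicit seed")
  snps <- all_schema_snps(schema)
  if (is.null(allele_freq)) {
    allele_freq <- stats::setNames(rep(0.5, length(snps)), snps)
  }
  if (any(allele_freq <= 0) || any(allele_freq >= 1)) {
    stop("allele frequencies must lie strictly inside (0, 1)")
  }
  if (is.null(alleles)) {
    alleles <- stats::setNames(rep(list(c("A", "G")), length(snps)), snps)
  }
  if (is.null(generating_tables)) {
    generating_tables <- default_generating_tables(schema, alleles)
  }
  for (p in names(generating_tables)) {
    for (snp in names(generating_tables[[p]])) {
      for (gt in names(generating_tables[[p]][[snp]])) {
        v <- generating_tables[[p]][[snp]][[gt]]
        if (abs(sum(v) - 1) > 1e-9) {
          stop("generating table (", p, ", ", snp, ", ", gt,
               ") does not sum to 1")
        }
      }
    }
  }
  structure(
    list(n_individuals = n_individuals, schema = schema,
         allele_freq = allele_freq, alleles = alleles,
         generating_tables = generating_tables, combine = combine,
         image_size = image_size, render_noise_sd = render_noise_sd,
         confusion_level = confusion_level, seed = as.integer(seed)),
    class = "generator_spec"
  )
}

#' Default genotype-conditional generating tables
#'
#' For each (phenotype, SNP), maps the three biallelic genotypes to a
#' variant distribution peaked along the allele dosage: dosage 0 favours the
#' first variant, dosage 2 the last, heterozygotes the middle (or an even
#' split for two-variant domains). `strength` is the peak probability mass.
#'
#' @param schema a `phenotype_schema`.
#' @param alleles named list, rsID -> the two allele letters.
#' @param strength peak mass, in (1/|domain|, 1].
#' @return nested list in the `generating_tables` layout.
#' @export
default_generating_tables <- function(schema, alleles, strength = 0.85) {
  tabs <- list()
  for (p in schema$phenotypes) {
    dom <- schema$variant_domain[[p]]
    C <- length(dom)
    tabs[[p]] <- list()
    for (snp in schema$snp_map[[p]]) {
      al <- sort(alleles[[snp]])
      gts <- c(paste0(al[1], al[1]), paste0(al[1], al[2]), paste0(al[2], al[2]))
      entries <- lapply(0:2, function(dosage) {
        v <- stats::setNames(rep((1 - strength) / max(C - 1, 1), C), dom)
        if (C == 2 && dosage == 1) {
          v[] <- 0.5
        } else {
          peak <- 1 + round(dosage * (C - 1) / 2)
          v[peak] <- strength
        }
        v / sum(v)
      })
      tabs[[p]][[snp]] <- stats::setNames(entries, gts)
    }
  }
  tabs
}

#' Generate a synthetic genotype-phenotype cohort
#'
#' Genotypes are sampled per SNP under Hardy-Weinberg equilibrium from the
#' allele frequencies (two independent allele draws, canonicalised).
#' Phenotypes are then sampled from the genotype-conditional generating
#' tables, combined across each phenotype's SNPs by the spec's `combine`
#' rule. Fully reproducible from the spec's seed.
#'
#' @param spec a `generator_spec`.
#' @return list with elements `genomes` (list of `genome`) and `profiles`
#'   (list of `phenotype_profile`), aligned by position and id.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  schema <- spec$schema
  snps <- all_schema_snps(schema)
  set.seed(derive_seed(spec$seed, "cohort"))
  ids <- sprintf("syn%05d", seq_len(spec$n_individuals))
  genomes <- vector("list", spec$n_individuals)
  profiles <- vector("list", spec$n_individuals)
  for (i in seq_len(spec$n_individuals)) {
    gts <- vapply(snps, function(snp) {
      al <- spec$alleles[[snp]]
      f <- spec$allele_freq[[snp]]
      draw <- sample(al, 2, replace = TRUE, prob = c(f, 1 - f))
      paste(sort(draw), collapse = "")
    }, character(1))
    values <- vapply(schema$phenotypes, function(p) {
      dom <- schema$variant_domain[[p]]
      tabs <- spec$generating_tables[[p]]
      if (spec$combine == "product") {
        w <- stats::setNames(rep(1, length(dom)), dom)
        for (snp in schema$snp_map[[p]]) w <- w * tabs[[snp]][[gts[[snp]]]][dom]
        sample(dom, 1, prob = w / sum(w))
      } else {
        votes <- vapply(schema$snp_map[[p]], function(snp) {
          sample(dom, 1, prob = tabs[[snp]][[gts[[snp]]]][dom])
        }, character(1))
        tab <- table(factor(votes, levels = dom))
        dom[argmax_first(as.numeric(tab))]
      }
    }, character(1))
    genomes[[i]] <- genome(ids[i], gts)
    profiles[[i]] <- phenotype_profile(ids[i], values, schema = schema)
  }
  list(genomes = genomes, profiles = profiles)
}

# pool genomes whose owners report exactly the profile's phenotypes
matching_pool <- function(profile, pool, pool_profiles) {
  stopifnot(length(pool) == length(pool_profiles))
  phen <- names(profile$values)
  keep <- vapply(pool_profiles, function(pp) {
    all(pp$values[phen] == profile$values[phen])
  }, logical(1))
  which(keep)
}

#' Idealised genotype assignment for a phenotype profile
#'
#' Among pool genomes whose owners share all the profile's phenotypes,
#' returns the one maximising the product over phenotypes of
#' \eqn{P(\text{profile}_p \mid y)} under the fitted conditional model — the
#' most representative genotype for that phenotype combination. Ties break
#' deterministically by individual id.
#'
#' @param profile a `phenotype_profile` to find a genome for.
#' @param pool list of candidate `genome` objects.
#' @param pool_profiles aligned list of the pool owners' profiles.
#' @param model a `conditional_model`.
#' @param schema a `phenotype_schema`.
#' @return a `genome` from the pool.
#' @export
assign_genotype_ideal <- function(profile, pool, pool_profiles, model,
                                  schema = model$schema) {
  idx <- matching_pool(profile, pool, pool_profiles)
  if (length(idx) == 0L) {
    stop("no genome in the pool matches the phenotypes of ",
         profile$individual_id)
  }
  lik <- vapply(idx, function(j) {
    prod(vapply(schema$phenotypes, function(p) {
      phenotype_prob_given_genome(profile$values[[p]], p, pool[[j]],
                                  model, schema)
    }, numeric(1)))
  }, numeric(1))
  ids <- vapply(pool[idx], function(g) g$individual_id, character(1))
  best <- idx[order(-lik, ids)][1L]
  pool[[best]]
}

#' Realistic genotype assignment: an empirical draw
#'
#' Uniform seeded draw among the phenotype-matching pool genomes, emulating
#' assignment according to the empirical distribution of genotypes among
#' individuals with those phenotypes.
#'
#' @inheritParams assign_genotype_ideal
#' @param seed integer seed.
#' @return a `genome` from the pool.
#' @export
assign_genotype_realistic <- function(profile, pool, pool_profiles, seed) {
  idx <- matching_pool(profile, pool, pool_profiles)
  if (length(idx) == 0L) {
    stop("no genome in the pool matches the phenotypes of ",
         profile$individual_id)
  }
  set.seed(seed)
  pool[[idx[sample.int(length(idx), 1L)]]]
}

# renderer geometry and encoding strength. Phenotypes are encoded as small
# channel offsets (+-.render_contrast) on a fixed base face, not as saturated
# patch colours: visible-trait signal in real photographs is subtle, and the
# perturbation experiments only make sense when an l-inf budget comparable to
# the encoding contrast can alter what a classifier reads off the image.
.render_base <- c(0.50, 0.45, 0.40)
.render_contrast <- 0.06

render_regions <- function(h, w) {
  band <- (floor(3 * h / 4) + 1):h
  mid_r <- band[ceiling(length(band) / 2)]
  mid_c <- floor(w / 2)
  half <- max(1, floor(w / 16))
  list(
    hair = list(rows = 1:max(1, floor(h / 4)), cols = 1:w),
    eye  = list(rows = (floor(h / 4) + 1):floor(h / 2),
                cols = (floor(w / 4) + 1):floor(3 * w / 4)),
    skin = list(rows = (floor(h / 2) + 1):floor(3 * h / 4), cols = 1:w),
    band = band,
    vbar = list(rows = band, cols = (mid_c - half):(mid_c + half)),
    hbar = list(rows = max(band[1], mid_r - 1):min(h, mid_r + 1), cols = 1:w)
  )
}

# variant -> RGB offset: k-th variant raises the k-th channel by the contrast
variant_offset <- function(variant, domain) {
  off <- c(0, 0, 0)
  off[match(variant, domain)] <- .render_contrast
  off
}

#' Render phenotype-encoding images
#'
#' Deterministic synthetic "faces" on a fixed base colour: the skin variant
#' tints the mid-face strip (and background), the hair variant the top band,
#' the eye variant a central patch — each variant raising one colour channel
#' by a small fixed contrast — and sex is a low-contrast shape cue in the
#' bottom band (vertical bar for M, horizontal for F). Seeded Gaussian noise
#' of sd `render_noise_sd` is added and pixels are clipped to [0, 1]. With
#' zero noise, identical phenotypes give identical images. The encoding
#' contrast is deliberately small (0.06) so that, as with real photographs,
#' phenotype evidence in pixels is of the same order as the perturbation
#' budgets under study; the images emulate only that phenotypes are readable
#' from pixels, not face photography itself.
#'
#' @param profiles list of `phenotype_profile`.
#' @param spec a `generator_spec` (image size, noise sd, seed).
#' @return list of `image_tensor`.
#' @export
render_images <- function(profiles, spec) {
  h <- spec$image_size[1]; w <- spec$image_size[2]
  reg <- render_regions(h, w)
  lapply(profiles, function(pr) {
    px <- array(rep(.render_base, each = h * w), dim = c(h, w, 3))
    add <- function(rows, cols, off) {
      for (ch in 1:3) px[rows, cols, ch] <<- px[rows, cols, ch] + off[ch]
    }
    add(1:h, 1:w,
        variant_offset(pr$values[["skin"]], spec$schema$variant_domain$skin))
    add(reg$hair$rows, reg$hair$cols,
        variant_offset(pr$values[["hair"]], spec$schema$variant_domain$hair))
    add(reg$eye$rows, reg$eye$cols,
        variant_offset(pr$values[["eye"]], spec$schema$variant_domain$eye))
    if (pr$values[["sex"]] == "M") {
      add(reg$vbar$rows, reg$vbar$cols, rep(.render_contrast, 3))
    } else {
      add(reg$hbar$rows, reg$hbar$cols, rep(.render_contrast, 3))
    }
    if (spec$render_noise_sd > 0) {
      set.seed(derive_seed(spec$seed, paste0("img_", pr$individual_id)))
      px <- px + stats::rnorm(length(px), sd = spec$render_noise_sd)
    }
    image_tensor(array(clip01(px), dim = c(h, w, 3)), pr$individual_id)
  })
}

#' Rule-based image decoder (oracle)
#'
#' Recovers the encoded phenotypes from a rendered image without any
#' learning: per region, the channel with the largest mean offset above the
#' base colour names the variant; the sex shape cue is read by comparing
#' vertical-bar and horizontal-bar brightness. Used to verify that rendered
#' images carry their phenotypes (exact at zero render noise).
#'
#' @param image an `image_tensor` from [render_images()].
#' @param schema a `phenotype_schema`.
#' @return a `phenotype_profile`.
#' @export
decode_image <- function(image, schema) {
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  reg <- render_regions(h, w)
  mean_col <- function(rows, cols) {
    vapply(1:3, function(ch) mean(px[rows, cols, ch]), numeric(1))
  }
  # skin offset is global, so subtract the skin strip's colour from regions
  # that stack their own offset on top of it
  skin_col <- mean_col(reg$skin$rows, reg$skin$cols)
  pick <- function(col, domain) domain[argmax_first(col)]
  vals <- c(
    hair = pick(mean_col(reg$hair$rows, reg$hair$cols) - skin_col,
                schema$variant_domain$hair),
    skin = pick(skin_col - .render_base, schema$variant_domain$skin),
    eye = pick(mean_col(reg$eye$rows, reg$eye$cols) - skin_col,
               schema$variant_domain$eye)
  )
  vcells <- setdiff(reg$vbar$rows, reg$hbar$rows)
  v_bright <- mean(px[vcells, reg$vbar$cols, ])
  h_bright <- mean(px[reg$hbar$rows, setdiff(1:w, reg$vbar$cols), ])
  vals[["sex"]] <- if (v_bright > h_bright) "M" else "F"
  phenotype_profile(image$image_id, vals[schema$phenotypes], schema = schema)
}

#' Simulate noisy classifier predictions directly from phenotypes
#'
#' Bypasses images entirely for fast matching experiments: per phenotype,
#' the simulated argmax equals the true variant with probability
#' `1 - confusion_level`, otherwise a uniformly chosen wrong variant. The
#' returned distribution puts `sharpness` mass on the argmax and spreads the
#' rest uniformly.
#'
#' @param profiles list of `phenotype_profile`.
#' @param confusion_level per-phenotype error probability in [0, 1].
#' @param schema a `phenotype_schema`.
#' @param seed integer seed.
#' @param sharpness argmax mass of the emitted distribution (> 1/|domain|).
#' @return list of `prediction_set`.
#' @export
simulate_noisy_predictions <- function(profiles, confusion_level, schema,
                                       seed, sharpness = 0.8) {
  stopifnot(confusion_level >= 0, confusion_level <= 1)
  set.seed(derive_seed(seed, "noisy_predictions"))
  lapply(profiles, function(pr) {
    dists <- lapply(schema$phenotypes, function(p) {
      dom <- schema$variant_domain[[p]]
      truth <- pr$values[[p]]
      z <- if (stats::runif(1) < confusion_level && length(dom) > 1L) {
        sample(setdiff(dom, truth), 1)
      } else truth
      d <- stats::setNames(rep((1 - sharpness) / (length(dom) - 1), length(dom)),
                           dom)
      d[[z]] <- sharpness
      d
    })
    names(dists) <- schema$phenotypes
    prediction_set(pr$individual_id, dists)
  })
}
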