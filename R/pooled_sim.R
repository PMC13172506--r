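# Synthetic-data generator: proband calls and pooled-parent read counts
# under controlled inheritance scenarios. All randomness flows from one
# explicit seed so outputs are reproducible bit-for-bit on one platform.

SCENARIOS <- c("de_novo", "maternal", "paternal", "biparental",
               "comp_het", "hemizygous_maternal", "homozygous_biallelic")

#' Simulation configuration
#'
#' Describes one simulated cohort of trios with pooled parents. Defaults
#' emulate the study conditions of the pooled design: pools of 8 parents
#' sequenced to the depth returned by [required_pool_depth()], probands at
#' 100X, a per-read error rate of 1e-3, and equimolar pooling.
#'
#' @param n_trios Number of trios.
#' @param pool_size Parents per pool (default 8).
#' @param pool_depth Mean reads per pooled site (default
#'   `required_pool_depth(pool_size)`).
#' @param proband_depth Mean reads per proband site (default 100).
#' @param error_rate Per-read probability that a read reports the wrong
#'   allele (default 0.001).
#' @param overdispersion Nonnegative scalar controlling unequal sample
#'   representation in the pool; 0 means equimolar. Positive values draw
#'   per-sample pool weights from a symmetric Dirichlet with concentration
#'   `1 / overdispersion`, so larger values give more unequal pipetting.
#' @param scenario_mix Named nonnegative proportions over the inheritance
#'   scenarios `de_novo`, `maternal`, `paternal`, `biparental`, `comp_het`,
#'   `hemizygous_maternal`, `homozygous_biallelic`; must sum to 1.
#' @param variants_per_trio Variants simulated per trio (default 6; a
#'   `comp_het` draw counts as one and emits two variants in one gene).
#' @param poisson_depth If `TRUE` (default) per-site depths are Poisson
#'   around the configured means; `FALSE` fixes them exactly, for exact
#'   tests.
#' @param seed Integer seed for all draws.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_trios = 10L,
                       pool_size = 8L,
                       pool_depth = NULL,
                       proband_depth = 100L,
                       error_rate = 0.001,
                       overdispersion = 0,
                       scenario_mix = c(de_novo = 0.3, maternal = 0.2,
                                        paternal = 0.2, biparental = 0.15,
                                        comp_het = 0.05,
                                        hemizygous_maternal = 0.05,
                                        homozygous_biallelic = 0.05),
                       variants_per_trio = 6L,
                       poisson_depth = TRUE,
                       seed = 1L) {
  n_trios <- assert_count(n_trios, "n_trios")
  pool_size <- assert_count(pool_size, "pool_size")
  if (is.null(pool_depth)) pool_depth <- required_pool_depth(pool_size)
  pool_depth <- assert_count(pool_depth, "pool_depth")
  proband_depth <- assert_count(proband_depth, "proband_depth")
  variants_per_trio <- assert_count(variants_per_trio, "variants_per_trio")
  stopifnot(is.numeric(error_rate), length(error_rate) == 1,
            error_rate >= 0, error_rate <= 1,
            is.numeric(overdispersion), length(overdispersion) == 1,
            overdispersion >= 0)
  unknown <- setdiff(names(scenario_mix), SCENARIOS)
  if (length(unknown)) {
    stop("unknown scenario(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  mix <- scenario_mix[SCENARIOS]
  names(mix) <- SCENARIOS
  mix[is.na(mix)] <- 0
  if (any(mix < 0)) stop("scenario_mix proportions must be nonnegative", call. = FALSE)
  if (abs(sum(mix) - 1) > 1e-9) {
    stop("scenario_mix proportions must sum to 1", call. = FALSE)
  }
  if (mix[["comp_het"]] > 0 && pool_size < 1) {
    stop("comp_het scenarios require pool_size >= 1", call. = FALSE)
  }
  structure(
    list(n_trios = n_trios, pool_size = pool_size, pool_depth = pool_depth,
         proband_depth = proband_depth, error_rate = error_rate,
         overdispersion = overdispersion, scenario_mix = mix,
         variants_per_trio = variants_per_trio,
         poisson_depth = isTRUE(poisson_depth),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# run code under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# symmetric Dirichlet draw via normalized gammas
rdirichlet1 <- function(n, alpha) {
  g <- stats::rgamma(n, shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, n)  # degenerate underflow guard
  g / sum(g)
}

# allele-share weights of a pool: 2 slots per sample, sample weights split
# equally across a sample's two alleles
pool_allele_weights <- function(pool_size, overdispersion) {
  if (overdispersion <= 0) {
    rep(1 / (2 * pool_size), 2 * pool_size)
  } else {
    w <- rdirichlet1(pool_size, 1 / overdispersion)
    rep(w / 2, each = 2)
  }
}

#' Simulate the read evidence for one site in one parental pool
#'
#' `k_carrier_alleles` of the pool's `2 * pool_size` alleles carry the
#' alternate allele, so the expected alternate fraction is
#' `k / (2 * pool_size)` under equimolar pooling. Reads are drawn
#' binomially at that fraction, perturbed symmetrically by the sequencing
#' error rate (non-carrier reads convert to alternate at `error_rate`,
#' carrier reads away at the same rate) and, when `overdispersion > 0`, by
#' Dirichlet-distributed per-sample representation.
#'
#' @param k_carrier_alleles Number of alternate alleles present in the pool,
#'   in `[0, 2 * pool_size]`. A heterozygous singleton carrier is k = 1.
#' @param pool_size Individuals in the pool.
#' @param depth Reads sampled at the site (> 0).
#' @param error_rate Per-read conversion probability.
#' @param overdispersion See [sim_config()].
#' @param pool_id `"maternal"` or `"paternal"` label carried on the result.
#' @return A [pool_observation()] with `source = "simulated"`.
#' @export
simulate_pool_reads <- function(k_carrier_alleles, pool_size, depth,
                                error_rate = 0, overdispersion = 0,
                                pool_id = "maternal") {
  stopifnot(length(k_carrier_alleles) == 1, k_carrier_alleles >= 0,
            k_carrier_alleles <= 2 * pool_size)
  depth <- assert_count(depth, "depth")
  w <- pool_allele_weights(pool_size, overdispersion)
  k <- as.integer(round(k_carrier_alleles))
  p_true <- if (k == 0) 0 else sum(w[seq_len(k)])
  p_obs <- p_true * (1 - error_rate) + (1 - p_true) * error_rate
  alt <- stats::rbinom(1, depth, p_obs)
  pool_observation(pool_id = pool_id, depth = depth, alt_reads = alt,
                   source = "simulated")
}

# scenario -> true carrier-allele counts and proband genotype
scenario_truth <- function(scenario) {
  switch(scenario,
    de_novo              = list(k_m = 0L, k_p = 0L, genotype = "het"),
    maternal             = list(k_m = 1L, k_p = 0L, genotype = "het"),
    paternal             = list(k_m = 0L, k_p = 1L, genotype = "het"),
    biparental           = list(k_m = 1L, k_p = 1L, genotype = "het"),
    hemizygous_maternal  = list(k_m = 1L, k_p = 0L, genotype = "hemi"),
    homozygous_biallelic = list(k_m = 1L, k_p = 1L, genotype = "hom"),
    stop("unknown scenario: ", scenario, call. = FALSE)
  )
}

rdepth <- function(n, mean_depth, poisson) {
  if (poisson) pmax(1L, stats::rpois(n, mean_depth)) else rep(as.integer(mean_depth), n)
}

# draw proband alt reads given genotype fraction and error rate
proband_alt <- function(depth, gt_frac, error_rate) {
  p <- gt_frac * (1 - error_rate) + (1 - gt_frac) * error_rate
  stats::rbinom(length(depth), depth, p)
}

gt_fraction <- function(genotype) {
  c(het = 0.5, hom = 1, hemi = 1)[[genotype]]
}

#' Simulate a cohort of trios with pooled parents
#'
#' Generates, per trio, proband variant calls and per-site read counts in
#' the maternal and paternal pools under inheritance scenarios drawn from
#' `scenario_mix`, together with the ground-truth table and annotation /
#' gene tables sufficient to exercise the downstream classifier and
#' prioritization cascade. A `comp_het` draw emits two variants in one
#' gene, one carried only in the maternal pool and one only in the paternal
#' pool; `hemizygous_maternal` emits an X-chromosome variant in a male
#' proband, carried by one mother and absent from the paternal pool.
#'
#' Deterministic for a fixed `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `pooled_cohort` with tibbles `probands`,
#'   `maternal_counts`, `paternal_counts`, `truth`, `annotations`, `genes`,
#'   and the `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  rows <- list()
  gene_counter <- 0L
  for (t in seq_len(config$n_trios)) {
    n_draw <- config$variants_per_trio
    scen <- sample(SCENARIOS, n_draw, replace = TRUE,
                   prob = config$scenario_mix)
    sex <- if (any(scen == "hemizygous_maternal")) "male" else {
      sample(c("male", "female"), 1)
    }
    vi <- 0L
    for (s in scen) {
      gene_counter <- gene_counter + 1L
      gene <- sprintf("GENE%04d", gene_counter)
      if (s == "comp_het") {
        for (sub in c("maternal", "paternal")) {
          vi <- vi + 1L
          rows[[length(rows) + 1L]] <- variant_row(t, vi, sub, gene, sex,
                                                   comp_het = TRUE)
        }
      } else {
        vi <- vi + 1L
        rows[[length(rows) + 1L]] <- variant_row(t, vi, s, gene, sex,
                                                 comp_het = FALSE)
      }
    }
  }
  truth <- dplyr::bind_rows(rows)
  truth$variant_id <- sprintf("T%03d_V%03d", truth$trio_id, truth$var_idx)

  n <- nrow(truth)
  # proband read evidence
  pdp <- rdepth(n, config$proband_depth, config$poisson_depth)
  gt_frac <- vapply(truth$genotype, gt_fraction, numeric(1))
  palt <- proband_alt(pdp, gt_frac, config$error_rate)
  probands <- tibble::tibble(
    trio_id = truth$trio_id, variant_id = truth$variant_id, sex = truth$sex,
    chrom = truth$chrom, pos = truth$pos, ref = truth$ref, alt = truth$alt,
    gene = truth$gene, genotype = truth$genotype,
    depth = pdp, alt_reads = palt, vaf = ifelse(pdp > 0, palt / pdp, NA_real_)
  )

  # pooled read evidence; under overdispersion, per-sample weights are drawn
  # once per pool so that poorly represented individuals fail consistently
  pool_counts <- function(k_col) {
    w_by_trio <- lapply(seq_len(config$n_trios), function(i) {
      pool_allele_weights(config$pool_size, config$overdispersion)
    })
    dp <- rdepth(n, config$pool_depth, config$poisson_depth)
    alt_reads <- integer(n)
    for (i in seq_len(n)) {
      k <- truth[[k_col]][i]
      w <- w_by_trio[[truth$trio_id[i]]]
      # carrier allele slot(s) chosen at random among samples
      p_true <- if (k == 0) 0 else {
        slots <- sample(seq_along(w), k)
        sum(w[slots])
      }
      p_obs <- p_true * (1 - config$error_rate) +
        (1 - p_true) * config$error_rate
      alt_reads[i] <- stats::rbinom(1, dp[i], p_obs)
    }
    tibble::tibble(
      trio_id = truth$trio_id, chrom = truth$chrom, pos = truth$pos,
      ref = truth$ref, alt = truth$alt, depth = dp, alt_count = alt_reads
    )
  }
  maternal_counts <- pool_counts("k_maternal")
  paternal_counts <- pool_counts("k_paternal")

  ann <- simulate_annotations(truth)

  structure(
    list(probands = probands, maternal_counts = maternal_counts,
         paternal_counts = paternal_counts,
         truth = dplyr::select(truth, -"var_idx"),
         annotations = ann$annotations, genes = ann$genes, config = config),
    class = "pooled_cohort"
  )
}

# one truth row; comp_het members are passed as their transmitting parent
variant_row <- function(trio_id, var_idx, scenario, gene, sex, comp_het) {
  tr <- scenario_truth(scenario)
  on_x <- scenario == "hemizygous_maternal"
  chrom <- if (on_x) "chrX" else paste0("chr", sample(1:22, 1))
  scenario_label <- if (comp_het) "comp_het" else scenario
  transmitting <- if (comp_het) scenario else NA_character_
  ref <- sample(c("A", "C", "G", "T"), 1)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  tibble::tibble(
    trio_id = trio_id, var_idx = var_idx,
    scenario = scenario_label, transmitting = transmitting,
    gene = gene, sex = sex, chrom = chrom,
    pos = sample.int(5e7, 1), ref = ref, alt = alt,
    genotype = tr$genotype, k_maternal = tr$k_m, k_paternal = tr$k_p
  )
}

# annotation and gene tables consistent with each scenario's clinical story
simulate_annotations <- function(truth) {
  n <- nrow(truth)
  causal <- truth$scenario %in% c("de_novo", "comp_het",
                                  "hemizygous_maternal",
                                  "homozygous_biallelic")
  consequence <- ifelse(causal,
                        sample(c("missense", "lof"), n, replace = TRUE),
                        sample(c("missense", "synonymous", "other"), n,
                               replace = TRUE, prob = c(0.4, 0.3, 0.3)))
  annotations <- tibble::tibble(
    variant_id = truth$variant_id,
    gene = truth$gene,
    consequence = consequence,
    gnomad_ac = ifelse(causal, sample(0:1, n, replace = TRUE),
                       sample(0:500, n, replace = TRUE)),
    clinvar = ifelse(causal, "none",
                     sample(c("none", "VUS", "LB", "B"), n, replace = TRUE,
                            prob = c(0.7, 0.1, 0.1, 0.1))),
    cadd = ifelse(causal, stats::runif(n, 23, 40), stats::runif(n, 0, 22)),
    revel = ifelse(consequence == "missense",
                   ifelse(causal, stats::runif(n, 0.6, 1), stats::runif(n, 0, 0.5)),
                   NA_real_),
    alphamissense = ifelse(consequence == "missense",
                           ifelse(causal, stats::runif(n, 0.65, 1),
                                  stats::runif(n, 0, 0.55)),
                           NA_real_),
    sift = ifelse(consequence == "missense",
                  ifelse(causal, 0, stats::runif(n, 0.05, 1)), NA_real_),
    spliceai = ifelse(consequence %in% c("synonymous", "splice_region"),
                      stats::runif(n, 0, 0.5), NA_real_),
    phylop = stats::runif(n, -2, 10)
  )
  annotations$gnomad_af <- annotations$gnomad_ac / 1.6e6

  gene_tbl <- dplyr::distinct(
    tibble::tibble(gene = truth$gene, scenario = truth$scenario,
                   chrom = truth$chrom),
    .data$gene, .keep_all = TRUE
  )
  ng <- nrow(gene_tbl)
  moi <- ifelse(gene_tbl$chrom == "chrX", "XL",
                ifelse(gene_tbl$scenario %in% c("comp_het", "homozygous_biallelic"),
                       "AR",
                       ifelse(gene_tbl$scenario == "de_novo", "AD", "unknown")))
  in_panel <- moi != "unknown" & stats::runif(ng) < 0.5
  genes <- tibble::tibble(
    gene = gene_tbl$gene,
    moi = moi,
    in_panel = in_panel,
    domino = ifelse(moi == "AD", stats::runif(ng, 0.6, 1),
                    ifelse(moi == "AR", stats::runif(ng, 0, 0.59),
                           stats::runif(ng, 0, 1))),
    pli = stats::runif(ng),
    pnull = stats::runif(ng),
    loeuf = stats::runif(ng, 0.1, 2),
    mis_z = stats::rnorm(ng, 0, 2)
  )
  list(annotations = annotations, genes = genes)
}

#' Simulate the singleton ultra-rare validation experiment
#'
#' Emulates the validation design in which ultra-rare variants known from
#' individual parental exomes are looked up in the pools: each variant is
#' carried heterozygously by exactly one individual in exactly one pool
#' (k = 1 singleton), so its expected pool VAF is
#' `expected_allelic_balance(pool_size)`.
#'
#' Under overdispersion, per-sample pool weights are drawn once per pool
#' and each variant is assigned a carrier individual at random, so
#' under-represented individuals miss detection consistently across their
#' variants.
#'
#' @param n_variants Number of singleton variants.
#' @param pool_size Individuals per pool (default 10, the validation pool
#'   format).
#' @param depth Mean pool depth (default `required_pool_depth(pool_size)`).
#' @param error_rate,overdispersion,poisson_depth See [sim_config()].
#' @param seed Integer seed.
#' @return Tibble with `variant_id`, `pool_id`, `carrier`, `depth`,
#'   `alt_count`, `vaf`.
#' @export
simulate_singleton_validation <- function(n_variants, pool_size = 10L,
                                          depth = NULL, error_rate = 0.001,
                                          overdispersion = 0,
                                          poisson_depth = TRUE, seed = 1L) {
  n_variants <- assert_count(n_variants, "n_variants")
  pool_size <- assert_count(pool_size, "pool_size")
  if (is.null(depth)) depth <- required_pool_depth(pool_size)
  depth <- assert_count(depth, "depth")
  with_seed(seed, {
    # per-sample weights fixed per pool; carrier drawn per variant
    w <- list(maternal = pool_allele_weights(pool_size, overdispersion),
              paternal = pool_allele_weights(pool_size, overdispersion))
    pool_id <- sample(c("maternal", "paternal"), n_variants, replace = TRUE)
    carrier <- sample.int(pool_size, n_variants, replace = TRUE)
    dp <- rdepth(n_variants, depth, poisson_depth)
    alt <- integer(n_variants)
    for (i in seq_len(n_variants)) {
      # the carrier is heterozygous: one of their two allele slots
      p_true <- w[[pool_id[i]]][2 * carrier[i] - 1]
      p_obs <- p_true * (1 - error_rate) + (1 - p_true) * error_rate
      alt[i] <- stats::rbinom(1, dp[i], p_obs)
    }
    tibble::tibble(
      variant_id = sprintf("S%05d", seq_len(n_variants)),
      pool_id = pool_id, carrier = carrier, depth = dp, alt_count = alt,
      vaf = ifelse(dp > 0, alt / dp, 0)
    )
  })
}
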