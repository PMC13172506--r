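test_that("frequency filter applies MOI-specific cutoffs with ClinVar overrides", {
  ad <- list(moi = "AD"); ar <- list(moi = "AR")
  # benign veto beats frequency
  expect_false(frequency_filter(list(clinvar = "B", gnomad_ac = 0), ad)$keep)
  expect_false(frequency_filter(list(clinvar = "LB", gnomad_ac = 0), ar)$keep)
  # pathogenic bypass beats frequency
  res <- frequency_filter(list(clinvar = "P", gnomad_af = 0.02, gnomad_ac = 9000), ar)
  expect_true(res$keep)
  expect_identical(res$reason, "clinvar_pathogenic")
  # dominant context: AC < 5 strict
  expect_true(frequency_filter(list(clinvar = "none", gnomad_ac = 4, gnomad_af = 0), ad)$keep)
  expect_false(frequency_filter(list(clinvar = "none", gnomad_ac = 5, gnomad_af = 0), ad)$keep)
  # recessive context: AF < 0.1%
  expect_true(frequency_filter(list(clinvar = "none", gnomad_ac = 100, gnomad_af = 0.0009), ar)$keep)
  expect_false(frequency_filter(list(clinvar = "none", gnomad_ac = 100, gnomad_af = 0.001), ar)$keep)
  # missing gnomAD entry is treated as absent
  expect_true(frequency_filter(list(clinvar = "none"), ad)$keep)
  expect_true(frequency_filter(list(clinvar = NA, gnomad_ac = NA, gnomad_af = NA), ar)$keep)
})

test_that("ClinVar overrides dominate every other field combination", {
  withr::with_seed(50, {
    for (i in 1:50) {
      v <- list(gnomad_ac = sample(0:10000, 1), gnomad_af = runif(1))
      g <- list(moi = sample(c("AD", "AR", "XL", "unknown"), 1))
      expect_false(frequency_filter(c(v, clinvar = sample(c("B", "LB"), 1)), g)$keep)
      expect_true(frequency_filter(c(v, clinvar = sample(c("P", "LP"), 1)), g)$keep)
    }
  })
})

test_that("frequency filter is monotone in frequency", {
  g <- list(moi = "AD")
  acs <- 0:10
  keeps <- vapply(acs, function(ac) {
    frequency_filter(list(clinvar = "none", gnomad_ac = ac, gnomad_af = 0), g)$keep
  }, logical(1))
  expect_true(all(diff(as.integer(keeps)) <= 0))  # keep never reappears
  g <- list(moi = "AR")
  afs <- seq(0, 0.005, by = 0.0005)
  keeps <- vapply(afs, function(af) {
    frequency_filter(list(clinvar = "none", gnomad_ac = 0, gnomad_af = af), g)$keep
  }, logical(1))
  expect_true(all(diff(as.integer(keeps)) <= 0))
})

test_that("in-silico prioritization combines predictor verdicts", {
  # unanimously deleterious missense: prioritized under every mode
  ccr7 <- list(consequence = "missense", cadd = 26.8, revel = 0.7,
               alphamissense = 0.73, sift = 0)
  for (mode in c("majority", "all_of", "any_of")) {
    expect_true(insilico_prioritize(ccr7, mode = mode)$prioritized,
                info = mode)
  }
  # splicing at exactly 0.6: inclusive threshold
  spl <- list(consequence = "splice_region", spliceai = 0.6)
  expect_true(insilico_prioritize(spl)$prioritized)
  expect_false(insilico_prioritize(
    list(consequence = "synonymous", spliceai = 0.59))$prioritized)
  # missense with no scores: vacuous evidence never prioritizes
  none <- insilico_prioritize(list(consequence = "missense"))
  expect_false(none$prioritized)
  expect_identical(none$flags, "no_evidence")
  # LoF prioritized without missense predictors
  expect_true(insilico_prioritize(list(consequence = "lof"))$prioritized)
  # majority over available predictors only
  two_of_three <- list(consequence = "missense", cadd = 30, revel = 0.9,
                       alphamissense = 0.1)
  expect_true(insilico_prioritize(two_of_three, mode = "majority")$prioritized)
  expect_false(insilico_prioritize(two_of_three, mode = "all_of")$prioritized)
  one_of_three <- list(consequence = "missense", cadd = 30, revel = 0.1,
                       alphamissense = 0.1)
  expect_false(insilico_prioritize(one_of_three, mode = "majority")$prioritized)
  expect_true(insilico_prioritize(one_of_three, mode = "any_of")$prioritized)
})

test_that("candidate gene evidence flags follow the constraint thresholds", {
  med1 <- candidate_gene_evidence(
    v = list(gnomad_ac = 0),
    g = list(domino = 0.9, pli = 1, pnull = NA, loeuf = NA, mis_z = NA))
  expect_setequal(med1$flags, c("domino_dominant", "pli_high",
                                "gnomad_absent_or_singleton"))
  angptl2 <- candidate_gene_evidence(
    v = list(gnomad_ac = 2),
    g = list(domino = 0.22, pli = 0.01))
  expect_false("domino_dominant" %in% angptl2$flags)
  expect_false("pli_high" %in% angptl2$flags)
  empty <- candidate_gene_evidence(g = list())
  expect_identical(empty$n_flags, 0L)
  expect_length(empty$flags, 0)
  # boundary behavior
  expect_true("domino_dominant" %in%
                candidate_gene_evidence(g = list(domino = 0.6))$flags)
  expect_false("misz_constrained" %in%
                 candidate_gene_evidence(g = list(mis_z = 3.09))$flags)
  expect_true("loeuf_constrained" %in%
                candidate_gene_evidence(g = list(loeuf = 0.59))$flags)
})

test_that("reportable selection implements the three criteria", {
  genes <- tibble::tibble(
    gene = c("KNOWN_AD", "CAND_DOM", "KNOWN_AR", "CAND_REC", "KNOWN_XL"),
    moi = c("AD", "unknown", "AR", "unknown", "XL"),
    in_panel = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    domino = c(NA, 0.9, NA, 0.22, NA))
  variants <- tibble::tibble(
    variant_id = sprintf("v%d", 1:7),
    gene = c("KNOWN_AD", "CAND_DOM", "KNOWN_AR", "CAND_REC",
             "KNOWN_XL", "KNOWN_AR", "KNOWN_AR"),
    genotype = c("het", "het", "hom", "hom", "hemi", "het", "het"),
    status = c("de_novo", "de_novo", NA, NA, "maternal",
               "maternal", "paternal"),
    gnomad_ac = 0L)
  rep_tbl <- select_reportable(variants, genes)
  expect_identical(
    rep_tbl$criterion[rep_tbl$variant_id == "v1"], "denovo_AD_XL")
  expect_identical(rep_tbl$tier[rep_tbl$variant_id == "v1"], "known_gene")
  expect_identical(
    rep_tbl$criterion[rep_tbl$variant_id == "v2"],
    "denovo_candidate_dominant")
  expect_identical(
    rep_tbl$criterion[rep_tbl$variant_id == "v3"], "biallelic_AR")
  expect_identical(
    rep_tbl$criterion[rep_tbl$variant_id == "v4"],
    "biallelic_candidate_recessive")
  expect_identical(
    rep_tbl$criterion[rep_tbl$variant_id == "v5"], "hemizygous_XL")
  # in-trans comp-het pair in a known AR gene
  pair <- rep_tbl[rep_tbl$variant_id == "v6,v7", ]
  expect_identical(pair$criterion, "biallelic_AR")
  expect_identical(pair$tier, "known_gene")
})

test_that("in-cis and biparental pairs are not reportable as comp-het", {
  genes <- tibble::tibble(gene = "AR1", moi = "AR", in_panel = TRUE,
                          domino = NA_real_)
  cis <- tibble::tibble(
    variant_id = c("a", "b"), gene = "AR1", genotype = "het",
    status = c("maternal", "maternal"), gnomad_ac = 0L)
  expect_identical(nrow(select_reportable(cis, genes)), 0L)
  bip <- dplyr::mutate(cis, status = c("maternal", "biparental"))
  expect_identical(nrow(select_reportable(bip, genes)), 0L)
})

test_that("reportable selection matches the row-by-row oracle on 1000 variants", {
  sim <- random_annotated_variants(1000, seed = 61)
  got <- select_reportable(sim$variants, sim$genes)
  want <- oracle_reportable(sim$variants, sim$genes)
  key <- function(df) {
    sort(paste(df$gene, df$variant_id, df$criterion, df$tier, sep = "|"))
  }
  expect_identical(key(got), key(want))
  expect_gt(nrow(want), 0)  # the property is not vacuous
})

test_that("full cascade keeps pathogenic bypass ahead of in-silico screen", {
  genes <- tibble::tibble(gene = "G1", moi = "AR", in_panel = TRUE,
                          domino = NA_real_)
  variants <- tibble::tibble(
    variant_id = "v1", gene = "G1", genotype = "hom", status = NA_character_,
    gnomad_ac = 5000L, gnomad_af = 0.01, clinvar = "P",
    consequence = "missense", cadd = 1, revel = 0.01, alphamissense = 0.01,
    sift = 1, spliceai = NA_real_)
  res <- prioritize_snvs(variants, genes)
  expect_identical(nrow(res$reportable), 1L)
  expect_identical(res$reportable$criterion, "biallelic_AR")
  # same variant without the ClinVar assertion is filtered on frequency
  variants$clinvar <- "none"
  res2 <- prioritize_snvs(variants, genes)
  expect_identical(nrow(res2$reportable), 0L)
  expect_identical(res2$dropped$filter_reason, "gnomad_af_too_high")
})
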