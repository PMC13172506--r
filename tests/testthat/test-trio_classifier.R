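test_that("proband QC thresholds are inclusive", {
  v <- function(vaf, dp) {
    proband_variant("chr1", 100L, "A", "T", depth = dp,
                    alt_reads = round(vaf * dp), genotype = "het")
  }
  expect_true(qc_proband_variant(v(0.30, 20L)))
  expect_false(qc_proband_variant(v(0.29, 200L)))
  expect_false(qc_proband_variant(v(0.50, 19L)))
  expect_true(qc_proband_variant(v(0.50, 200L)))
})

test_that("pool presence threshold is inclusive at 1% and flags no coverage", {
  # 1/172 = 0.58%: the highest pool VAF ever seen for a confirmed de novo
  expect_identical(
    pool_presence(pool_observation("maternal", 172L, 1L, "recount")),
    "absent")
  # 1/180 = 0.56%: the documented inherited false negative — still absent
  expect_identical(
    pool_presence(pool_observation("maternal", 180L, 1L, "recount")),
    "absent")
  expect_identical(
    pool_presence(pool_observation("maternal", 100L, 2L, "recount")),
    "present")
  expect_identical(
    pool_presence(pool_observation("maternal", 400L, 4L, "recount")),
    "present")  # exactly 1%
  expect_identical(
    pool_presence(pool_observation("maternal", 0L, 0L, "recount")),
    "insufficient")
  # degenerate threshold 0: any site with >= 1 alt read is present
  for (alt in 1:5) {
    expect_identical(
      pool_presence(pool_observation("maternal", 100L, alt), threshold = 0),
      "present")
  }
})

test_that("recount lookup returns exact arithmetic and coverage signals", {
  counts <- tibble::tibble(
    chrom = c("chr1", "chr1"), pos = c(100L, 200L), ref = c("A", "C"),
    alt = c("T", "G"), depth = c(320L, 150L), alt_count = c(3L, 0L))
  obs <- recount_pool_vaf(counts, "chr1", 100, "A", "T")
  expect_equal(obs$vaf, 0.009375)
  expect_identical(obs$source, "recount")
  expect_identical(pool_presence(obs), "absent")
  # missing site: insufficient coverage, never silently absent
  miss <- recount_pool_vaf(counts, "chr9", 999, "A", "T")
  expect_identical(miss$depth, 0L)
  expect_identical(pool_presence(miss), "insufficient")
  # duplicate rows name the site
  dup <- dplyr::bind_rows(counts, counts[1, ])
  expect_error(recount_pool_vaf(dup, "chr1", 100, "A", "T"),
               "duplicate.*chr1:100")
})

test_that("classification matches the hand-enumerated truth table", {
  states <- c("present", "absent", "insufficient")
  # autosomes: all sexes and genotypes behave identically
  tt <- autosomal_truth_table()
  for (sex in c("male", "female", "unknown")) {
    for (i in seq_len(nrow(tt))) {
      call <- classify_inheritance(
        het_variant("chr7", sex = sex),
        obs_of(tt$maternal[i], "maternal"),
        obs_of(tt$paternal[i], "paternal"))
      expect_identical(call$status, tt$status[i],
                       info = sprintf("autosome %s/%s sex=%s",
                                      tt$maternal[i], tt$paternal[i], sex))
    }
  }
  # female X het: autosomal table applies
  for (i in seq_len(nrow(tt))) {
    call <- classify_inheritance(
      het_variant("chrX", sex = "female"),
      obs_of(tt$maternal[i], "maternal"),
      obs_of(tt$paternal[i], "paternal"))
    expect_identical(call$status, tt$status[i],
                     info = sprintf("female X %s/%s", tt$maternal[i],
                                    tt$paternal[i]))
  }
  # male X hemizygous: maternal pool decides, paternal non-informative
  mx <- male_x_hemi_truth_table()
  for (i in seq_len(nrow(mx))) {
    call <- classify_inheritance(
      het_variant("chrX", sex = "male", genotype = "hemi"),
      obs_of(mx$maternal[i], "maternal"),
      obs_of(mx$paternal[i], "paternal"))
    expect_identical(call$status, mx$status[i],
                     info = sprintf("male X hemi %s/%s", mx$maternal[i],
                                    mx$paternal[i]))
    expect_true("paternal_pool_non_informative" %in% call$flags)
  }
  # unknown sex on X is undetermined with an explanatory flag
  for (m in states) {
    call <- classify_inheritance(
      het_variant("chrX", sex = "unknown"),
      obs_of(m, "maternal"), obs_of("absent", "paternal"))
    expect_identical(call$status, "undetermined")
    expect_true("sex_required_for_chrX" %in% call$flags)
  }
  # chrY and mitochondrial contigs pass through undetermined
  for (chrom in c("chrY", "chrM", "MT")) {
    call <- classify_inheritance(
      het_variant(chrom, sex = "male"),
      obs_of("present", "maternal"), obs_of("absent", "paternal"))
    expect_identical(call$status, "undetermined")
    expect_true("contig_not_supported" %in% call$flags)
  }
})

test_that("the documented false-negative mode is reproduced", {
  # an inherited variant at 0.56% pool VAF (1/180 reads) falls below the
  # 1% threshold and is called de novo: the method's known limitation
  call <- classify_inheritance(
    het_variant("chr2", sex = "female"),
    pool_observation("maternal", 180L, 1L, "recount"),
    pool_observation("paternal", 200L, 0L, "recount"))
  expect_identical(call$status, "de_novo")
})

test_that("raising the threshold never converts de novo to inherited", {
  withr::with_seed(40, {
    for (rep in 1:60) {
      m <- pool_observation("maternal", 400L, sample(0:30, 1))
      p <- pool_observation("paternal", 400L, sample(0:30, 1))
      v <- het_variant("chr3")
      t1 <- sort(runif(2, 0, 0.1))
      lo <- classify_inheritance(v, m, p, threshold = t1[1])$status
      hi <- classify_inheritance(v, m, p, threshold = t1[2])$status
      if (lo == "de_novo") expect_identical(hi, "de_novo")
    }
  })
})

test_that("compound-het phasing follows parental origin", {
  mk <- function(status) {
    structure(list(chrom = "chr1", pos = 1L, ref = "A", alt = "T",
                   status = status, maternal_present = status == "maternal",
                   paternal_present = status == "paternal",
                   evidence = list(), flags = character()),
              class = "inheritance_call")
  }
  # maternal + paternal: one in-trans pair
  ph <- phase_compound_hets(list(mk("maternal"), mk("paternal")))
  expect_identical(ph$phase, "in_trans")
  # same origin: in cis
  ph <- phase_compound_hets(list(mk("maternal"), mk("maternal")))
  expect_identical(ph$phase, "in_cis")
  # enumeration over all status pairs against a literal oracle
  statuses <- c("de_novo", "maternal", "paternal", "biparental",
                "undetermined")
  expected_phase <- function(a, b) {
    uni <- c("maternal", "paternal")
    if (a %in% uni && b %in% uni && a != b) "in_trans"
    else if (a %in% uni && b %in% uni) "in_cis"
    else "unphaseable"
  }
  for (a in statuses) {
    for (b in statuses) {
      ph <- phase_compound_hets(list(mk(a), mk(b)))
      expect_identical(ph$phase, expected_phase(a, b),
                       info = paste(a, b))
    }
  }
  # biparental member carries its reason
  ph <- phase_compound_hets(list(mk("maternal"), mk("biparental")))
  expect_identical(ph$reason, "carrier in both pools")
})

test_that("cohort driver drops QC failures and joins pools by site", {
  probands <- tibble::tibble(
    trio_id = 1L, variant_id = c("v1", "v2"), sex = "female",
    chrom = "chr1", pos = c(100L, 200L), ref = "A", alt = "T",
    gene = "G1", genotype = "het",
    depth = c(100L, 100L), alt_reads = c(50L, 10L))  # v2 fails VAF QC
  counts <- tibble::tibble(
    trio_id = 1L, chrom = "chr1", pos = c(100L, 200L), ref = "A", alt = "T",
    depth = 400L, alt_count = c(8L, 0L))
  empty <- dplyr::mutate(counts, alt_count = 0L)
  out <- classify_cohort(probands, counts, empty)
  expect_identical(nrow(out), 1L)
  expect_identical(out$variant_id, "v1")
  expect_identical(out$status, "maternal")
  expect_equal(out$maternal_vaf, 0.02)
})
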