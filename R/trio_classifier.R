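# Inheritance classification of proband variants from pooled-parent
# read evidence, plus compound-heterozygote phasing.

#' One normalized biallelic proband variant call
#'
#' @param chrom Contig name, kept verbatim.
#' @param pos 1-based position.
#' @param ref,alt Alleles after biallelic decomposition and
#'   left-normalization.
#' @param depth Read depth (DP).
#' @param alt_reads Reads supporting the alternate allele.
#' @param genotype One of `"het"`, `"hom_alt"`, `"hemi"`.
#' @param sex Proband sex: `"male"`, `"female"`, or `"unknown"`.
#' @return An object of class `proband_variant` with a computed `vaf`.
#' @export
proband_variant <- function(chrom, pos, ref, alt, depth, alt_reads,
                            genotype = c("het", "hom_alt", "hemi"),
                            sex = c("unknown", "male", "female")) {
  genotype <- match.arg(genotype)
  sex <- match.arg(sex)
  pos <- assert_count(pos, "pos")
  depth <- assert_count(depth, "depth")
  if (!is.numeric(alt_reads) || alt_reads < 0 || alt_reads > depth) {
    stop("`alt_reads` must be in [0, depth]", call. = FALSE)
  }
  structure(
    list(chrom = as.character(chrom), pos = pos, ref = as.character(ref),
         alt = as.character(alt), depth = depth,
         alt_reads = as.integer(alt_reads),
         vaf = alt_reads / depth, genotype = genotype, sex = sex),
    class = "proband_variant"
  )
}

#' Per-site read evidence from one parental pool
#'
#' `depth = 0` encodes a site with no usable pool coverage (including sites
#' missing from a recount table); its presence status is "insufficient",
#' never "absent".
#'
#' @param pool_id `"maternal"` or `"paternal"`.
#' @param depth Reads at the site (>= 0).
#' @param alt_reads Alternate-supporting reads, `0 <= alt_reads <= depth`.
#' @param source Where the counts came from: `"caller"` (pool VCF),
#'   `"recount"` (pileup recount table), or `"simulated"`.
#' @return An object of class `pool_observation`.
#' @export
pool_observation <- function(pool_id = c("maternal", "paternal"),
                             depth, alt_reads,
                             source = c("caller", "recount", "simulated")) {
  pool_id <- match.arg(pool_id)
  source <- match.arg(source)
  if (!is.numeric(depth) || length(depth) != 1 || is.na(depth) || depth < 0) {
    stop("`depth` must be a single nonnegative number", call. = FALSE)
  }
  depth <- as.integer(depth)
  if (!is.numeric(alt_reads) || alt_reads < 0 || alt_reads > depth) {
    if (depth == 0 && alt_reads == 0) {
      # fine: explicit no-coverage observation
    } else {
      stop("`alt_reads` must be in [0, depth]", call. = FALSE)
    }
  }
  structure(
    list(pool_id = pool_id, depth = depth, alt_reads = as.integer(alt_reads),
         vaf = if (depth > 0) alt_reads / depth else NA_real_,
         source = source),
    class = "pool_observation"
  )
}

#' Proband variant quality filter
#'
#' Retains calls with variant allele fraction at or above `min_vaf` and
#' depth at or above `min_dp` (both bounds inclusive). The defaults,
#' VAF >= 0.3 and DP >= 20, are the thresholds under which a germline
#' heterozygous call is considered reliable for the trio analysis.
#'
#' @param v A [proband_variant()].
#' @param min_vaf Minimum VAF (default 0.3).
#' @param min_dp Minimum depth (default 20).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
qc_proband_variant <- function(v, min_vaf = 0.3, min_dp = 20L) {
  stopifnot(inherits(v, "proband_variant"))
  v$vaf >= min_vaf && v$depth >= min_dp
}

#' Presence of a proband variant in a parental pool
#'
#' A variant is present in a pool when its pool VAF reaches the detection
#' threshold (default 1%, inclusive). Below the threshold it is absent:
#' reads at sub-threshold VAF are indistinguishable from sequencing error
#' at pooled depth. A pool with zero depth at the site cannot support
#' either conclusion and returns `"insufficient"`.
#'
#' @param obs A [pool_observation()].
#' @param threshold Pool VAF presence threshold (default 0.01).
#' @return `"present"`, `"absent"`, or `"insufficient"`.
#' @export
pool_presence <- function(obs, threshold = 0.01) {
  stopifnot(inherits(obs, "pool_observation"))
  if (obs$depth == 0) return("insufficient")
  if (obs$vaf >= threshold) "present" else "absent"
}

#' Look up pool read counts for a site in a recount table
#'
#' The recount table plays the role of a systematic pileup review of the
#' pooled alignments: per-site raw depth and alternate read counts,
#' independent of what the pool's variant caller chose to emit. Sites
#' missing from the table become zero-depth observations (insufficient
#' coverage), never silent absences.
#'
#' @param counts A counts table from [read_counts_table()] (columns `chrom`,
#'   `pos`, `ref`, `alt`, `depth`, `alt_count`).
#' @param chrom,pos,ref,alt Site key.
#' @param pool_id Pool label for the resulting observation.
#' @return A [pool_observation()] with `source = "recount"`.
#' @export
recount_pool_vaf <- function(counts, chrom, pos, ref, alt,
                             pool_id = c("maternal", "paternal")) {
  pool_id <- match.arg(pool_id)
  stopifnot(is.data.frame(counts))
  hit <- counts[counts$chrom == chrom & counts$pos == pos &
                  counts$ref == ref & counts$alt == alt, , drop = FALSE]
  if (nrow(hit) > 1) {
    stop(sprintf("duplicate recount rows for site %s:%d %s>%s",
                 chrom, pos, ref, alt), call. = FALSE)
  }
  if (nrow(hit) == 0) {
    return(pool_observation(pool_id, depth = 0L, alt_reads = 0L,
                            source = "recount"))
  }
  pool_observation(pool_id, depth = hit$depth, alt_reads = hit$alt_count,
                   source = "recount")
}

#' Classify the inheritance of one proband variant
#'
#' Combines presence calls from the maternal and paternal pools:
#'
#' * autosomes (and female X): absent/absent is de novo, present/absent is
#'   maternal, absent/present is paternal, present/present is biparental;
#' * chrX, male proband, hemizygous variant: the paternal pool is not
#'   informative (fathers do not transmit an X to sons), so the call rests
#'   on the maternal pool alone — present means maternal, absent means
#'   de novo; the paternal observation is recorded but unused;
#' * chrY and mitochondrial contigs: undetermined (not handled by the
#'   pooling design);
#' * any pool with insufficient coverage that the decision needs makes the
#'   call undetermined, never silently de novo.
#'
#' @param v A [proband_variant()] that passed [qc_proband_variant()].
#' @param maternal,paternal [pool_observation()]s at the variant site.
#' @param threshold Pool presence threshold, see [pool_presence()].
#' @return A list of class `inheritance_call` with `status` in
#'   `{de_novo, maternal, paternal, biparental, undetermined}`,
#'   presence booleans, the raw evidence, and character `flags`.
#' @export
classify_inheritance <- function(v, maternal, paternal, threshold = 0.01) {
  stopifnot(inherits(v, "proband_variant"),
            inherits(maternal, "pool_observation"),
            inherits(paternal, "pool_observation"))
  m <- pool_presence(maternal, threshold)
  p <- pool_presence(paternal, threshold)
  flags <- character()
  chrom <- normalize_chrom(v$chrom)

  if (chrom %in% c("Y", "MT")) {
    status <- "undetermined"
    flags <- c(flags, "contig_not_supported")
  } else if (chrom == "X" && v$sex == "unknown") {
    status <- "undetermined"
    flags <- c(flags, "sex_required_for_chrX")
  } else if (chrom == "X" && v$sex == "male" && v$genotype == "hemi") {
    # maternal pool decides; paternal X not transmitted to sons
    status <- switch(m,
      present = "maternal",
      absent = "de_novo",
      insufficient = "undetermined"
    )
    if (m == "insufficient") flags <- c(flags, "insufficient_maternal_coverage")
    flags <- c(flags, "paternal_pool_non_informative")
  } else {
    if (m == "insufficient" || p == "insufficient") {
      status <- "undetermined"
      if (m == "insufficient") flags <- c(flags, "insufficient_maternal_coverage")
      if (p == "insufficient") flags <- c(flags, "insufficient_paternal_coverage")
    } else {
      status <- if (m == "present" && p == "present") "biparental"
      else if (m == "present") "maternal"
      else if (p == "present") "paternal"
      else "de_novo"
    }
  }
  structure(
    list(
      chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      status = status,
      maternal_present = identical(m, "present"),
      paternal_present = identical(p, "present"),
      evidence = list(maternal = maternal, paternal = paternal),
      flags = flags
    ),
    class = "inheritance_call"
  )
}

#' @export
print.inheritance_call <- function(x, ...) {
  cat(sprintf("<inheritance_call> %s:%d %s>%s — %s (maternal VAF %s, paternal VAF %s)\n",
              x$chrom, x$pos, x$ref, x$alt, x$status,
              fmt_vaf(x$evidence$maternal), fmt_vaf(x$evidence$paternal)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

fmt_vaf <- function(obs) {
  if (obs$depth == 0) "no coverage" else sprintf("%.4f", obs$vaf)
}

normalize_chrom <- function(chrom) {
  c0 <- sub("^chr", "", chrom, ignore.case = TRUE)
  if (toupper(c0) %in% c("M", "MT")) return("MT")
  toupper(c0)
}

#' Phase candidate compound heterozygotes within one gene
#'
#' Two heterozygous variants in one gene are a compound heterozygote only
#' if they lie on opposite haplotypes (in trans), which the pooled design
#' infers from opposite parental origin: one variant present only in the
#' maternal pool and the other only in the paternal pool. Pairs where
#' either member is biparental (carrier in both pools, phase unknowable
#' from pools) or undetermined are reported as unphaseable with a reason.
#'
#' @param calls List of `inheritance_call` objects for heterozygous proband
#'   variants sharing one gene.
#' @return Tibble with one row per variant pair: `i`, `j` (indices into
#'   `calls`), `phase` (`"in_trans"`, `"in_cis"`, `"unphaseable"`), and
#'   `reason`.
#' @export
phase_compound_hets <- function(calls) {
  stopifnot(is.list(calls), all(vapply(calls, inherits, logical(1),
                                       "inheritance_call")))
  n <- length(calls)
  if (n < 2) {
    return(tibble::tibble(i = integer(), j = integer(),
                          phase = character(), reason = character()))
  }
  pairs <- utils::combn(n, 2)
  res <- apply(pairs, 2, function(ij) {
    a <- calls[[ij[1]]]$status
    b <- calls[[ij[2]]]$status
    uni <- c("maternal", "paternal")
    if (a %in% uni && b %in% uni && a != b) {
      c(phase = "in_trans", reason = "opposite parental origin")
    } else if (a %in% uni && b %in% uni && a == b) {
      c(phase = "in_cis", reason = sprintf("both %s", a))
    } else if ("biparental" %in% c(a, b)) {
      c(phase = "unphaseable", reason = "carrier in both pools")
    } else if ("undetermined" %in% c(a, b)) {
      c(phase = "unphaseable", reason = "undetermined inheritance")
    } else {
      # at least one de novo: not an inherited pair
      c(phase = "unphaseable", reason = "de novo member")
    }
  })
  tibble::tibble(
    i = pairs[1, ], j = pairs[2, ],
    phase = unname(res["phase", ]), reason = unname(res["reason", ])
  )
}

#' Classify every QC-passing variant of a cohort table
#'
#' Vectorized driver over per-trio tables: joins each proband variant to
#' its maternal and paternal pool counts by site and classifies it.
#'
#' @param probands Tibble with columns `trio_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `depth`, `alt_reads`, `genotype`, `sex` (as produced by
#'   [simulate_cohort()] or [read_proband_vcf()] plus a sex column).
#' @param maternal_counts,paternal_counts Count tables with columns
#'   `trio_id` (optional if single-trio), `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_count`.
#' @param threshold Pool presence threshold.
#' @param min_vaf,min_dp Proband QC thresholds, see [qc_proband_variant()].
#' @return Tibble with one row per QC-passing variant: key columns,
#'   `status`, `maternal_vaf`, `maternal_dp`, `paternal_vaf`,
#'   `paternal_dp`, `flags` (comma-joined).
#' @export
classify_cohort <- function(probands, maternal_counts, paternal_counts,
                            threshold = 0.01, min_vaf = 0.3, min_dp = 20L) {
  stopifnot(is.data.frame(probands))
  if (!"trio_id" %in% names(probands)) probands$trio_id <- 1L
  for (nm in c("maternal_counts", "paternal_counts")) {
    tbl <- get(nm)
    if (!"trio_id" %in% names(tbl)) {
      tbl$trio_id <- 1L
      assign(nm, tbl)
    }
  }
  out <- vector("list", nrow(probands))
  kept <- logical(nrow(probands))
  for (i in seq_len(nrow(probands))) {
    row <- probands[i, ]
    gt <- if (row$genotype == "hom") "hom_alt" else row$genotype
    v <- proband_variant(row$chrom, row$pos, row$ref, row$alt,
                         depth = row$depth, alt_reads = row$alt_reads,
                         genotype = gt, sex = row$sex)
    if (!qc_proband_variant(v, min_vaf, min_dp)) next
    kept[i] <- TRUE
    m <- lookup_pool(maternal_counts, row, "maternal")
    p <- lookup_pool(paternal_counts, row, "paternal")
    call <- classify_inheritance(v, m, p, threshold)
    out[[i]] <- tibble::tibble(
      trio_id = row$trio_id,
      variant_id = if ("variant_id" %in% names(row)) row$variant_id else NA_character_,
      chrom = row$chrom, pos = row$pos, ref = row$ref, alt = row$alt,
      gene = if ("gene" %in% names(row)) row$gene else NA_character_,
      genotype = row$genotype,
      status = call$status,
      maternal_vaf = if (m$depth > 0) m$vaf else NA_real_,
      maternal_dp = m$depth,
      paternal_vaf = if (p$depth > 0) p$vaf else NA_real_,
      paternal_dp = p$depth,
      flags = paste(call$flags, collapse = ",")
    )
  }
  dplyr::bind_rows(out[kept])
}

lookup_pool <- function(counts, row, pool_id) {
  sub <- counts[counts$trio_id == row$trio_id, , drop = FALSE]
  recount_pool_vaf(sub, row$chrom, row$pos, row$ref, row$alt,
                   pool_id = pool_id)
}
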