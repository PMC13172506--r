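# Independent oracles and fixture builders shared across tests.
# Oracles are written as literal enumerations / row-by-row re-derivations,
# deliberately not sharing code paths with the package's rules engines.

# --- observations -----------------------------------------------------------

obs_present <- function(pool_id = "maternal") {
  pool_observation(pool_id, depth = 100L, alt_reads = 5L, source = "recount")
}
obs_absent <- function(pool_id = "maternal") {
  pool_observation(pool_id, depth = 100L, alt_reads = 0L, source = "recount")
}
obs_insufficient <- function(pool_id = "maternal") {
  pool_observation(pool_id, depth = 0L, alt_reads = 0L, source = "recount")
}
obs_of <- function(kind, pool_id) {
  switch(kind,
         present = obs_present(pool_id),
         absent = obs_absent(pool_id),
         insufficient = obs_insufficient(pool_id))
}

het_variant <- function(chrom = "chr1", sex = "unknown", genotype = "het") {
  proband_variant(chrom, 1000L, "A", "T", depth = 100L, alt_reads = 50L,
                  genotype = genotype, sex = sex)
}

# --- hand-enumerated truth table for inheritance classification -------------
# Literal expected statuses for every cell of
# {present, absent, insufficient}^2 x context.

autosomal_truth_table <- function() {
  tibble::tribble(
    ~maternal,      ~paternal,      ~status,
    "absent",       "absent",       "de_novo",
    "present",      "absent",       "maternal",
    "absent",       "present",      "paternal",
    "present",      "present",      "biparental",
    "insufficient", "absent",       "undetermined",
    "insufficient", "present",      "undetermined",
    "insufficient", "insufficient", "undetermined",
    "absent",       "insufficient", "undetermined",
    "present",      "insufficient", "undetermined"
  )
}

male_x_hemi_truth_table <- function() {
  # paternal pool never informative: expand each maternal state over all
  # paternal states with the same expected status
  base <- tibble::tribble(
    ~maternal,      ~status,
    "present",      "maternal",
    "absent",       "de_novo",
    "insufficient", "undetermined"
  )
  tidyr::crossing(base, paternal = c("present", "absent", "insufficient"))
}

# --- row-by-row oracle for the three reportable criteria --------------------
# Re-derives every reportable call for a variant table with plain logical
# expressions, independent of select_reportable()'s grouping engine.

oracle_reportable <- function(variants, genes) {
  gene_of <- function(sym) {
    hit <- genes[genes$gene == sym, ]
    if (nrow(hit) == 0) {
      list(moi = "unknown", in_panel = FALSE, domino = NA_real_)
    } else {
      list(moi = if (is.na(hit$moi[1])) "unknown" else hit$moi[1],
           in_panel = isTRUE(hit$in_panel[1]),
           domino = hit$domino[1])
    }
  }
  rows <- list()
  push <- function(gene, vid, criterion, tier) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene = gene, variant_id = vid, criterion = criterion, tier = tier,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    g <- gene_of(v$gene)
    st <- if (is.na(v$status)) "unknown" else v$status
    known_dom <- g$in_panel && g$moi %in% c("AD", "XL")
    cand_dom <- !is.na(g$domino) && g$domino >= 0.6
    if (st == "de_novo" && v$genotype %in% c("het", "hemi")) {
      if (known_dom) push(v$gene, v$variant_id, "denovo_AD_XL", "known_gene")
      else if (cand_dom) push(v$gene, v$variant_id,
                              "denovo_candidate_dominant", "candidate_gene")
    }
    if (v$genotype == "hemi" && g$moi == "XL" && st != "de_novo") {
      push(v$gene, v$variant_id, "hemizygous_XL",
           if (g$in_panel) "known_gene" else "candidate_gene")
    }
    if (v$genotype == "hom") {
      if (g$in_panel && g$moi == "AR") {
        push(v$gene, v$variant_id, "biallelic_AR", "known_gene")
      } else if (!is.na(g$domino) && g$domino < 0.6) {
        push(v$gene, v$variant_id, "biallelic_candidate_recessive",
             "candidate_gene")
      } else if (is.na(g$domino) && g$moi == "unknown") {
        push(v$gene, v$variant_id, "biallelic_candidate_recessive",
             "candidate_gene")
      }
    }
  }
  # compound hets: ordered scan over all pairs within a gene
  for (sym in unique(variants$gene)) {
    vv <- variants[variants$gene == sym & variants$genotype == "het" &
                     !is.na(variants$status), ]
    if (nrow(vv) < 2) next
    g <- gene_of(sym)
    for (a in seq_len(nrow(vv) - 1)) {
      for (b in (a + 1):nrow(vv)) {
        sa <- vv$status[a]; sb <- vv$status[b]
        trans <- (sa == "maternal" && sb == "paternal") ||
          (sa == "paternal" && sb == "maternal")
        if (!trans) next
        vid <- paste(vv$variant_id[c(a, b)], collapse = ",")
        if (g$in_panel && g$moi == "AR") {
          push(sym, vid, "biallelic_AR", "known_gene")
        } else if (!is.na(g$domino) && g$domino < 0.6) {
          push(sym, vid, "biallelic_candidate_recessive", "candidate_gene")
        } else if (is.na(g$domino) && g$moi == "unknown") {
          push(sym, vid, "biallelic_candidate_recessive", "candidate_gene")
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(), variant_id = character(),
                      criterion = character(), tier = character()))
  }
  do.call(rbind, rows)
}

# random annotated-variant table for the oracle-equivalence property
random_annotated_variants <- function(n, seed) {
  withr::with_seed(seed, {
    gene_pool <- sprintf("G%03d", 1:40)
    genes <- tibble::tibble(
      gene = gene_pool,
      moi = sample(c("AD", "AR", "XL", "unknown"), 40, replace = TRUE),
      in_panel = sample(c(TRUE, FALSE), 40, replace = TRUE),
      domino = ifelse(runif(40) < 0.25, NA_real_, runif(40)),
      pli = runif(40), pnull = runif(40), loeuf = runif(40, 0.1, 2),
      mis_z = rnorm(40)
    )
    variants <- tibble::tibble(
      variant_id = sprintf("V%04d", seq_len(n)),
      gene = sample(gene_pool, n, replace = TRUE),
      genotype = sample(c("het", "hom", "hemi"), n, replace = TRUE,
                        prob = c(0.7, 0.2, 0.1)),
      status = sample(c("de_novo", "maternal", "paternal", "biparental",
                        "undetermined", NA), n, replace = TRUE),
      gnomad_ac = sample(0:3, n, replace = TRUE)
    )
    list(variants = variants, genes = genes)
  })
}

# --- CNV fixtures -----------------------------------------------------------

cnv_call <- function(chrom = "chr1", start = 1000L, end = 5000L,
                     svtype = "DEL", callers = "ExomeDepth,Convading",
                     run_recurrence = 1L, genes = "PANEL1",
                     hi_score = 10, ts_score = 10, min_loeuf = 1.0,
                     contained_in_population_event = FALSE,
                     affects_coding = TRUE, phenotype_match = TRUE) {
  tibble::tibble(chrom = chrom, start = start, end = end, svtype = svtype,
                 callers = callers, run_recurrence = run_recurrence,
                 genes = genes, hi_score = hi_score, ts_score = ts_score,
                 min_loeuf = min_loeuf,
                 contained_in_population_event = contained_in_population_event,
                 affects_coding = affects_coding,
                 phenotype_match = phenotype_match)
}

# independent single-rule checks for the cascade order-independence property
cnv_rule_violations <- function(row, panel) {
  genes <- strsplit(row$genes, ",")[[1]]
  callers <- strsplit(row$callers, ",")[[1]]
  v <- character()
  if (!any(trimws(genes) %in% panel)) v <- c(v, "not_in_panel")
  if (row$run_recurrence > 1) v <- c(v, "run_recurrent")
  if (length(callers) <= 1) v <- c(v, "single_caller")
  if (!is.na(row$min_loeuf) && row$min_loeuf < 0.6) v <- c(v, "loeuf")
  if (row$svtype == "DEL") {
    if (!is.na(row$hi_score) && row$hi_score >= 40) v <- c(v, "haploinsufficiency")
    if (isTRUE(row$contained_in_population_event)) v <- c(v, "population_deletion")
  } else {
    if (!is.na(row$ts_score) && row$ts_score >= 40) v <- c(v, "triplosensitivity")
    if (isTRUE(row$contained_in_population_event)) v <- c(v, "population_duplication")
  }
  v
}

# --- printed de novo candidate distribution fixture -------------------------
# 27 apparently de novo proband variants with pooled evidence: 15 with no
# pool reads, 5 below the 1% threshold (one at 1/180 = 0.56%, the
# documented inherited false negative), 7 between 1% and 5%.

denovo_candidate_fixture <- function() {
  below <- list(c(1L, 180L), c(1L, 172L), c(2L, 400L), c(3L, 350L),
                c(1L, 150L))  # VAFs 0.56%..0.86%
  within <- list(c(4L, 400L), c(5L, 400L), c(8L, 400L), c(10L, 400L),
                 c(12L, 400L), c(16L, 400L), c(20L, 400L))  # 1%..5%
  rows <- list()
  add <- function(p_alt, p_depth) {
    i <- length(rows) + 1L
    rows[[i]] <<- tibble::tibble(
      trio_id = 1L, variant_id = sprintf("DN%02d", i),
      chrom = "chr2", pos = 1000L + i, ref = "A", alt = "G",
      gene = sprintf("GENE%02d", i), genotype = "het", sex = "female",
      depth = 100L, alt_reads = 50L,
      pool_alt = p_alt, pool_depth = p_depth)
  }
  for (i in 1:15) add(0L, 400L)
  for (x in below) add(x[1], x[2])
  for (x in within) add(x[1], x[2])
  dplyr::bind_rows(rows)
}
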