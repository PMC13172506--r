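# Mode-of-inheritance aware SNV filtering cascade and candidate-gene
# evidence assessment.

#' Population-frequency filter with ClinVar overrides
#'
#' ClinVar benign / likely benign variants are dropped regardless of
#' frequency; pathogenic / likely pathogenic variants are kept regardless
#' of frequency. Otherwise the cutoff depends on the gene's mode of
#' inheritance: for dominant and X-linked contexts a variant is kept only
#' when its total gnomAD allele count is below 5; for recessive contexts
#' when its gnomAD allele frequency is below 0.1%. Genes with unknown MOI
#' use the recessive (more permissive) cutoff. A variant missing from
#' gnomAD counts as AC = 0, AF = 0.
#'
#' @param v One annotated variant: a named list or one-row data frame with
#'   `gnomad_ac`, `gnomad_af`, `clinvar` (one of `"P"`, `"LP"`, `"VUS"`,
#'   `"LB"`, `"B"`, `"none"`; `NA` treated as `"none"`).
#' @param g Gene info: named list or one-row data frame with `moi` (one of
#'   `"AD"`, `"AR"`, `"XL"`, `"unknown"`).
#' @param max_ac Dominant/X-linked allele-count cutoff (exclusive, default 5).
#' @param max_af Recessive allele-frequency cutoff (exclusive, default 0.001).
#' @return List with `keep` (logical) and `reason` (character).
#' @export
frequency_filter <- function(v, g, max_ac = 5L, max_af = 0.001) {
  v <- as.list(v); g <- as.list(g)
  clinvar <- v$clinvar %||% "none"
  if (is.na(clinvar)) clinvar <- "none"
  if (clinvar %in% c("B", "LB")) {
    return(list(keep = FALSE, reason = "clinvar_benign"))
  }
  if (clinvar %in% c("P", "LP")) {
    return(list(keep = TRUE, reason = "clinvar_pathogenic"))
  }
  ac <- v$gnomad_ac %||% 0L
  af <- v$gnomad_af %||% 0
  if (is.null(ac) || is.na(ac)) ac <- 0L
  if (is.null(af) || is.na(af)) af <- 0
  moi <- g$moi %||% "unknown"
  if (is.na(moi)) moi <- "unknown"
  if (moi %in% c("AD", "XL")) {
    if (ac < max_ac) list(keep = TRUE, reason = "rare_dominant_context")
    else list(keep = FALSE, reason = "gnomad_ac_too_high")
  } else {
    if (af < max_af) list(keep = TRUE, reason = "rare_recessive_context")
    else list(keep = FALSE, reason = "gnomad_af_too_high")
  }
}

#' In-silico pathogenicity prioritization
#'
#' Missense variants are scored against four predictors — CADD > 20,
#' REVEL > 0.5, AlphaMissense > 0.6, SIFT < 0.01 — and the per-predictor
#' verdicts are combined by `mode`: `"majority"` (default) requires a
#' strict majority of the predictors with scores available, `"all_of"`
#' requires every available predictor to agree, `"any_of"` requires one.
#' Loss-of-function variants (stopgain, frameshift, canonical splice) are
#' prioritized without missense predictors. Synonymous and splice-region
#' variants use SpliceAI >= 0.6. A missense variant with no available
#' predictor is not prioritized and flagged `"no_evidence"`.
#'
#' @param v One annotated variant: named list or one-row data frame with
#'   `consequence` (`"missense"`, `"lof"`, `"synonymous"`,
#'   `"splice_region"`, `"other"`) and scores `cadd`, `revel`,
#'   `alphamissense`, `sift`, `spliceai` (any may be `NA` / absent).
#' @param mode Combination rule for missense predictors.
#' @param thresholds Named list overriding the predictor cutoffs
#'   (`cadd`, `revel`, `alphamissense`, `sift`, `spliceai`).
#' @return List with `prioritized` (logical), `verdicts` (named logical,
#'   `NA` where a score is missing), and `flags`.
#' @export
insilico_prioritize <- function(v, mode = c("majority", "all_of", "any_of"),
                                thresholds = list()) {
  mode <- match.arg(mode)
  v <- as.list(v)
  th <- utils::modifyList(
    list(cadd = 20, revel = 0.5, alphamissense = 0.6, sift = 0.01,
         spliceai = 0.6),
    thresholds
  )
  sc <- function(name) {
    x <- v[[name]]
    if (is.null(x) || length(x) == 0 || is.na(x)) NA_real_ else as.numeric(x)
  }
  consequence <- v$consequence %||% "other"
  flags <- character()

  if (consequence == "lof") {
    return(list(prioritized = TRUE,
                verdicts = c(lof = TRUE), flags = "lof_prioritized"))
  }
  if (consequence %in% c("synonymous", "splice_region", "other")) {
    s <- sc("spliceai")
    verdicts <- c(spliceai = if (is.na(s)) NA else s >= th$spliceai)
    prioritized <- isTRUE(verdicts[["spliceai"]])
    if (is.na(s)) flags <- "no_evidence"
    return(list(prioritized = prioritized, verdicts = verdicts,
                flags = flags))
  }
  # missense
  verdicts <- c(
    cadd = { x <- sc("cadd"); if (is.na(x)) NA else x > th$cadd },
    revel = { x <- sc("revel"); if (is.na(x)) NA else x > th$revel },
    alphamissense = { x <- sc("alphamissense"); if (is.na(x)) NA else x > th$alphamissense },
    sift = { x <- sc("sift"); if (is.na(x)) NA else x < th$sift }
  )
  avail <- verdicts[!is.na(verdicts)]
  if (length(avail) == 0) {
    return(list(prioritized = FALSE, verdicts = verdicts,
                flags = "no_evidence"))
  }
  prioritized <- switch(mode,
    majority = sum(avail) * 2 > length(avail),
    all_of = all(avail),
    any_of = any(avail)
  )
  list(prioritized = prioritized, verdicts = verdicts, flags = flags)
}

#' Gene-level candidate evidence flags
#'
#' No composite cutoff is applied; the flags and their count are returned
#' for ranking and interpretation only. Constraint flags follow the usual
#' gnomAD conventions: pLI > 0.9, pNull < 0.1, LOEUF < 0.6, missense
#' Z > 3.09; a Domino score >= 0.6 marks a likely dominant-acting gene;
#' absence or singleton status in gnomAD (AC <= 1) marks extreme rarity.
#'
#' @param v Annotated variant (for `gnomad_ac`); may be `NULL`.
#' @param g Gene info with any of `domino`, `pli`, `pnull`, `loeuf`,
#'   `mis_z`; missing fields simply contribute no flag.
#' @return List with `flags` (character vector of satisfied flags) and
#'   `n_flags`.
#' @export
candidate_gene_evidence <- function(v = NULL, g) {
  g <- as.list(g)
  v <- if (is.null(v)) list() else as.list(v)
  num <- function(lst, name) {
    x <- lst[[name]]
    if (is.null(x) || length(x) == 0 || is.na(x)) NA_real_ else as.numeric(x)
  }
  checks <- c(
    domino_dominant = isTRUE(num(g, "domino") >= 0.6),
    pli_high = isTRUE(num(g, "pli") > 0.9),
    pnull_low = isTRUE(num(g, "pnull") < 0.1),
    loeuf_constrained = isTRUE(num(g, "loeuf") < 0.6),
    misz_constrained = isTRUE(num(g, "mis_z") > 3.09),
    gnomad_absent_or_singleton = isTRUE(num(v, "gnomad_ac") <= 1)
  )
  list(flags = names(checks)[checks], n_flags = sum(checks))
}

#' Select reportable variants under the three inheritance criteria
#'
#' Applies the reporting criteria that partition on zygosity, inheritance
#' and gene evidence:
#'
#' 1. apparently de novo variants in known dominant (AD) or X-linked genes,
#'    or in candidate genes with a Domino score >= 0.6;
#' 2. hemizygous variants in X-linked genes;
#' 3. homozygous or compound-heterozygous (in-trans) variants in known
#'    recessive (AR) genes, or in candidate genes with a Domino score
#'    < 0.6.
#'
#' A gene is "known" for a criterion when it is in the panel with the
#' matching MOI (`tier = "known_gene"`), otherwise it is assessed as a
#' candidate (`tier = "candidate_gene"`). Compound heterozygotes require a
#' valid in-trans pair: one member maternal and the other paternal (see
#' [phase_compound_hets()]); pairs involving biparental or undetermined
#' members are not reportable. Genes with unknown MOI and no Domino score
#' fall to the recessive branch for homozygous/comp-het variants only and
#' carry a `"no_moi_evidence"` flag.
#'
#' @param variants Tibble with one row per variant: `variant_id`, `gene`,
#'   `genotype` (`"het"`, `"hom"`, `"hemi"`), `status` (inheritance:
#'   `"de_novo"`, `"maternal"`, `"paternal"`, `"biparental"`,
#'   `"undetermined"`, or `NA` for unknown), plus annotation columns
#'   (`gnomad_ac` used for evidence flags).
#' @param genes Tibble of gene info: `gene`, `moi`, `in_panel`, `domino`,
#'   `pli`, `pnull`, `loeuf`, `mis_z` (all but `gene` optional).
#' @return Tibble with one row per reportable call: `gene`, `variant_id`
#'   (comma-joined for pairs), `criterion`, `tier`, `evidence_flags`,
#'   `n_evidence_flags`.
#' @export
select_reportable <- function(variants, genes) {
  stopifnot(is.data.frame(variants), is.data.frame(genes))
  out <- list()
  for (gsym in unique(variants$gene)) {
    vg <- variants[variants$gene == gsym, , drop = FALSE]
    g <- genes[genes$gene == gsym, , drop = FALSE]
    g <- if (nrow(g)) as.list(g[1, ]) else list(gene = gsym, moi = "unknown",
                                                in_panel = FALSE)
    out[[length(out) + 1L]] <- reportable_for_gene(vg, g)
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    return(tibble::tibble(gene = character(), variant_id = character(),
                          criterion = character(), tier = character(),
                          evidence_flags = character(),
                          n_evidence_flags = integer()))
  }
  res
}

reportable_for_gene <- function(vg, g) {
  moi <- g$moi %||% "unknown"
  if (is.null(moi) || is.na(moi)) moi <- "unknown"
  in_panel <- isTRUE(g$in_panel)
  domino <- g$domino
  domino <- if (is.null(domino) || length(domino) == 0 || is.na(domino)) NA_real_ else as.numeric(domino)
  calls <- list()
  add <- function(rows, criterion, tier, extra_flags = character()) {
    ev <- candidate_gene_evidence(as.list(rows[1, ]), g)
    calls[[length(calls) + 1L]] <<- tibble::tibble(
      gene = g$gene,
      variant_id = paste(rows$variant_id, collapse = ","),
      criterion = criterion, tier = tier,
      evidence_flags = paste(c(ev$flags, extra_flags), collapse = ","),
      n_evidence_flags = ev$n_flags
    )
  }

  for (i in seq_len(nrow(vg))) {
    row <- vg[i, , drop = FALSE]
    status <- row$status
    if (is.na(status)) status <- "unknown"
    # criterion 1: de novo, dominant context
    if (status == "de_novo" && row$genotype %in% c("het", "hemi")) {
      if (in_panel && moi %in% c("AD", "XL")) {
        add(row, "denovo_AD_XL", "known_gene")
      } else if (!is.na(domino) && domino >= 0.6) {
        add(row, "denovo_candidate_dominant", "candidate_gene")
      }
    }
    # criterion 2: hemizygous in an X-linked gene, regardless of Domino
    if (row$genotype == "hemi" && moi == "XL" && status != "de_novo") {
      add(row, "hemizygous_XL",
          if (in_panel) "known_gene" else "candidate_gene")
    }
    # criterion 3a: homozygous, recessive context
    if (row$genotype == "hom") {
      if (in_panel && moi == "AR") {
        add(row, "biallelic_AR", "known_gene")
      } else if (!is.na(domino) && domino < 0.6) {
        add(row, "biallelic_candidate_recessive", "candidate_gene")
      } else if (is.na(domino) && moi == "unknown") {
        add(row, "biallelic_candidate_recessive", "candidate_gene",
            extra_flags = "no_moi_evidence")
      }
    }
  }

  # criterion 3b: compound heterozygotes — valid in-trans pairs only
  hets <- vg[vg$genotype == "het" & !is.na(vg$status), , drop = FALSE]
  if (nrow(hets) >= 2) {
    idx <- utils::combn(nrow(hets), 2)
    for (k in seq_len(ncol(idx))) {
      a <- hets[idx[1, k], , drop = FALSE]
      b <- hets[idx[2, k], , drop = FALSE]
      in_trans <- (a$status == "maternal" && b$status == "paternal") ||
        (a$status == "paternal" && b$status == "maternal")
      if (!in_trans) next
      pair <- rbind(a, b)
      if (in_panel && moi == "AR") {
        add(pair, "biallelic_AR", "known_gene")
      } else if (!is.na(domino) && domino < 0.6) {
        add(pair, "biallelic_candidate_recessive", "candidate_gene")
      } else if (is.na(domino) && moi == "unknown") {
        add(pair, "biallelic_candidate_recessive", "candidate_gene",
            extra_flags = "no_moi_evidence")
      }
    }
  }
  dplyr::bind_rows(calls)
}

#' Full SNV prioritization cascade
#'
#' Applies, in order, the population-frequency filter (with ClinVar
#' overrides), the in-silico prioritization, and the reportable-call
#' selection, over a joined variant table. ClinVar pathogenic variants
#' bypass the in-silico screen.
#'
#' @param variants Annotated variant tibble (see [select_reportable()] for
#'   the required columns, plus `gnomad_af`, `clinvar`, `consequence` and
#'   the predictor scores).
#' @param genes Gene info tibble.
#' @param mode In-silico combination rule, see [insilico_prioritize()].
#' @return List with `reportable` (tibble from [select_reportable()]),
#'   `filtered` (the surviving variant tibble, with `filter_reason` and
#'   `prioritized` columns), and `dropped` (tibble of dropped variants with
#'   reasons).
#' @export
prioritize_snvs <- function(variants, genes, mode = "majority") {
  stopifnot(is.data.frame(variants), is.data.frame(genes))
  gmap <- split(genes, genes$gene)
  keep <- logical(nrow(variants))
  reason <- character(nrow(variants))
  prio <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    row <- as.list(variants[i, ])
    g <- gmap[[row$gene]]
    g <- if (is.null(g)) list(moi = "unknown") else as.list(g[1, ])
    ff <- frequency_filter(row, g)
    reason[i] <- ff$reason
    if (!ff$keep) next
    if (ff$reason == "clinvar_pathogenic") {
      keep[i] <- TRUE; prio[i] <- TRUE
      next
    }
    ip <- insilico_prioritize(row, mode = mode)
    prio[i] <- ip$prioritized
    keep[i] <- ip$prioritized
    if (!ip$prioritized) reason[i] <- "not_prioritized_in_silico"
  }
  filtered <- variants[keep, , drop = FALSE]
  filtered$filter_reason <- reason[keep]
  filtered$prioritized <- prio[keep]
  dropped <- variants[!keep, , drop = FALSE]
  dropped$filter_reason <- reason[!keep]
  reportable <- select_reportable(filtered, genes)
  list(reportable = reportable, filtered = filtered, dropped = dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
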