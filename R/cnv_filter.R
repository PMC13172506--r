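# Solo-exome CNV filtering cascade and prioritization.
#
# Calls arrive annotated (overlapped genes, caller provenance, run
# recurrence, dosage-sensitivity scores); this module only applies the
# filter cascade and the deterministic ranking.

#' Filter a table of CNV calls
#'
#' Applies the cascade, in order, recording for every dropped call the
#' first rule it failed:
#'
#' 1. `panel` — at least one overlapped gene must be in the diagnostic
#'    panel;
#' 2. `run_recurrence` — calls seen in more than one individual of the
#'    same sequencing run are technical artifacts;
#' 3. `single_caller` — calls supported by only one caller are dropped;
#' 4. `loeuf` — LOEUF rule, see `loeuf_rule` below;
#' 5. dosage sensitivity — deletions are kept only with a
#'    haploinsufficiency score `HI < 40` and dropped when fully contained
#'    in a benign population deletion; duplications analogously with the
#'    triplosensitivity score `TS < 40` and benign population
#'    duplications.
#'
#' `loeuf_rule` controls a rule whose published wording ("LOEUF < 0.6,
#' indicative of low functional impact, excluded") inverts the usual LOEUF
#' semantics (low LOEUF = constrained): `"literal"` (default) excludes
#' calls whose minimum per-gene LOEUF is below 0.6 exactly as worded and
#' emits a warning documenting the discrepancy; `"semantic"` excludes
#' calls whose minimum LOEUF is >= 0.6 (i.e. keeps constrained genes);
#' `"off"` disables the rule. Gene-level scores aggregate across
#' multi-gene calls by minimum (the most constrained gene governs).
#'
#' @param calls Tibble with one row per CNV call: `chrom`, `start`, `end`
#'   (1-based inclusive), `svtype` (`"DEL"`/`"DUP"`), `callers`
#'   (comma-separated caller names or list-column), `run_recurrence`
#'   (distinct individuals in the run with an overlapping same-type call,
#'   including this one), `genes` (comma-separated symbols or list-column),
#'   `hi_score`, `ts_score` (percentiles, `NA` allowed), `min_loeuf`
#'   (minimum LOEUF over overlapped genes, `NA` allowed),
#'   `contained_in_population_event` (logical), `affects_coding`,
#'   `phenotype_match` (logical, used by [prioritize_cnvs()]).
#' @param panel Character vector of panel gene symbols.
#' @param loeuf_rule `"literal"`, `"semantic"`, or `"off"`.
#' @param max_run_recurrence Maximum individuals per run (default 1: only
#'   the index case).
#' @param hi_cutoff,ts_cutoff Dosage-sensitivity keep-cutoffs (default 40,
#'   exclusive: kept when score < cutoff).
#' @return The input tibble with added columns `status`
#'   (`"retained"`/`"dropped"`) and `drop_reason` (`NA` when retained).
#' @export
filter_cnvs <- function(calls, panel, loeuf_rule = c("literal", "semantic", "off"),
                        max_run_recurrence = 1L, hi_cutoff = 40, ts_cutoff = 40) {
  loeuf_rule <- match.arg(loeuf_rule)
  stopifnot(is.data.frame(calls))
  if (nrow(calls)) {
    bad <- which(calls$start > calls$end)
    if (length(bad)) {
      stop("malformed interval(s) with start > end at row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (!all(calls$svtype %in% c("DEL", "DUP"))) {
      stop("svtype must be 'DEL' or 'DUP'", call. = FALSE)
    }
  }
  if (loeuf_rule == "literal" && nrow(calls)) {
    warning(paste(
      "loeuf_rule = 'literal' excludes calls with min LOEUF < 0.6 as",
      "published; note that low LOEUF normally marks CONSTRAINED genes —",
      "use loeuf_rule = 'semantic' to exclude unconstrained genes instead."
    ), call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, ]
    gene_list <- split_multi(row$genes)
    caller_list <- split_multi(row$callers)
    reason[i] <- first_failure(
      row, gene_list, caller_list, panel, loeuf_rule,
      max_run_recurrence, hi_cutoff, ts_cutoff
    )
  }
  calls$status <- ifelse(is.na(reason), "retained", "dropped")
  calls$drop_reason <- reason
  calls
}

split_multi <- function(x) {
  if (is.list(x)) return(x[[1]])
  if (is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(as.character(x), ",")[[1]])
}

first_failure <- function(row, genes, callers, panel, loeuf_rule,
                          max_run_recurrence, hi_cutoff, ts_cutoff) {
  if (!any(genes %in% panel)) return("not_in_panel")
  if (!is.na(row$run_recurrence) && row$run_recurrence > max_run_recurrence) {
    return("run_recurrent")
  }
  if (length(callers) <= 1) return("single_caller")
  ml <- row$min_loeuf
  if (loeuf_rule == "literal" && !is.na(ml) && ml < 0.6) return("loeuf")
  if (loeuf_rule == "semantic" && !is.na(ml) && ml >= 0.6) return("loeuf")
  if (row$svtype == "DEL") {
    if (!is.na(row$hi_score) && row$hi_score >= hi_cutoff) {
      return("haploinsufficiency")
    }
    if (isTRUE(row$contained_in_population_event)) {
      return("population_deletion")
    }
  } else {
    if (!is.na(row$ts_score) && row$ts_score >= ts_cutoff) {
      return("triplosensitivity")
    }
    if (isTRUE(row$contained_in_population_event)) {
      return("population_duplication")
    }
  }
  NA_character_
}

#' Rank retained CNV calls
#'
#' Stable deterministic ranking of the retained calls: more callers first,
#' then coding-region calls, then calls matching the patient's phenotype,
#' with shorter spans breaking remaining ties; equal keys preserve input
#' order.
#'
#' @param retained Tibble of retained calls (rows of [filter_cnvs()]
#'   output with `status == "retained"`, or any table with the same
#'   columns).
#' @return The input tibble sorted, with a `rank` column added.
#' @export
prioritize_cnvs <- function(retained) {
  stopifnot(is.data.frame(retained))
  if (!nrow(retained)) {
    retained$rank <- integer()
    return(retained)
  }
  n_callers <- vapply(seq_len(nrow(retained)), function(i) {
    length(split_multi(retained$callers[i]))
  }, integer(1))
  span <- retained$end - retained$start + 1
  ord <- order(-n_callers,
               -as.integer(isTRUE_vec(retained$affects_coding)),
               -as.integer(isTRUE_vec(retained$phenotype_match)),
               span,
               seq_len(nrow(retained)))  # explicit stability
  out <- retained[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
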