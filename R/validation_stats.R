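# Statistics used to optimize and validate the pooling strategy and to
# summarize diagnostic-workflow outcomes.

#' Sensitivity of pooled detection
#'
#' `100 * TP / (TP + FN)`, reported to two decimals (half-up). True
#' positives are variants known from individual sequencing that the pool
#' detects at the presence threshold; false negatives are those it misses.
#'
#' @param true_positive,false_negative Nonnegative counts, not both zero.
#' @return Percentage rounded to 2 decimals.
#' @examples
#' sensitivity(1091, 36)  # 96.81
#' @export
sensitivity <- function(true_positive, false_negative) {
  stopifnot(is.numeric(true_positive), is.numeric(false_negative),
            true_positive >= 0, false_negative >= 0)
  if (true_positive + false_negative == 0) {
    stop("sensitivity undefined: no positive truth calls", call. = FALSE)
  }
  round_half_up(100 * true_positive / (true_positive + false_negative), 2)
}

#' Pool VAF as a printed percentage
#'
#' @param alt,depth Read counts, `depth > 0`.
#' @return Percentage `100 * alt / depth` rounded to 2 decimals (half-up).
#' @examples
#' vaf_percent(1, 172)  # 0.58
#' vaf_percent(1, 180)  # 0.56
#' @export
vaf_percent <- function(alt, depth) {
  stopifnot(is.numeric(alt), is.numeric(depth))
  if (any(depth <= 0)) stop("depth must be positive", call. = FALSE)
  round_half_up(100 * alt / depth, 2)
}

# round() banker-rounds; printed percentages use arithmetic half-up
round_half_up <- function(x, digits) {
  floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
}

#' Breakdown of pooled detection by VAF bin
#'
#' Partitions per-variant pool VAFs into the detection bins used to
#' characterize the pooling limit of detection. The default bins are
#' contiguous half-open intervals labelled after the conventional
#' reporting ranges: detected at the threshold (`>= 1%`), just below
#' (`0.55–1%`), trace reads (`> 0 – 0.55%`), and `no reads`. Detected
#' variants are those in the top bin; sensitivity is computed from the
#' detected/not-detected split via [sensitivity()].
#'
#' @param vafs Numeric vector of pool VAFs (fractions in `[0, 1]`).
#' @param threshold Detection threshold as a fraction (default 0.01).
#' @param bin_edges Increasing numeric vector of inner edges (fractions)
#'   splitting the sub-threshold range; default `c(0.0055)` giving the
#'   bins above. Custom edges must be strictly increasing and below the
#'   threshold.
#' @return List with `counts` (named integer vector, top bin first),
#'   `detected`, `not_detected`, and `sensitivity_pct`.
#' @export
detection_breakdown <- function(vafs, threshold = 0.01, bin_edges = 0.0055) {
  stopifnot(is.numeric(vafs), all(vafs >= 0), all(vafs <= 1))
  bin_edges <- sort(unique(bin_edges))
  if (any(bin_edges <= 0) || any(bin_edges >= threshold)) {
    stop("bin_edges must lie strictly between 0 and the threshold",
         call. = FALSE)
  }
  edges <- c(0, bin_edges, threshold)
  ints <- cbind(lower = edges[-length(edges)], upper = edges[-1])
  int_labels <- apply(ints, 1, function(e) {
    sprintf("(%s%%, %s%%)", format_pct(e[["lower"]]), format_pct(e[["upper"]]))
  })
  counts <- integer(2 + nrow(ints))
  names(counts) <- c(sprintf(">=%s%%", format_pct(threshold)),
                     rev(int_labels), "no_reads")
  counts[1] <- sum(vafs >= threshold)
  counts[length(counts)] <- sum(vafs == 0)
  for (r in seq_len(nrow(ints))) {
    # half-open (lower, upper]; excludes exact zero already counted
    in_bin <- vafs > ints[r, "lower"] & vafs <= ints[r, "upper"] &
      vafs < threshold & vafs > 0
    counts[1 + nrow(ints) - r + 1] <- sum(in_bin)
  }
  detected <- counts[[1]]
  not_detected <- length(vafs) - detected
  list(counts = counts, detected = detected, not_detected = not_detected,
       sensitivity_pct = if (length(vafs)) sensitivity(detected, not_detected) else NA_real_)
}

format_pct <- function(x) {
  out <- format(100 * x, trim = TRUE, scientific = FALSE)
  out <- ifelse(grepl("\\.", out), sub("\\.?0+$", "", out), out)
  out
}

#' Test observed pool allelic balance against its expectation
#'
#' Wilcoxon signed-rank test of the per-variant pool VAFs against the
#' expected allelic balance of a singleton heterozygote
#' (`1 / (2 * pool size)`). Differences of exactly zero are dropped (the
#' signed-rank convention); the exact null distribution is used for up to
#' 25 nonzero differences and the normal approximation with continuity
#' correction beyond that.
#'
#' @param vafs Numeric vector of pool VAFs (>= 5 observations).
#' @param expected Expected allelic balance, in (0, 0.5].
#' @return List with `median`, `expected`, `statistic`, `p_value`,
#'   `n_nonzero`, and `degenerate` (`TRUE` when every VAF equals the
#'   expectation exactly, in which case `p_value = 1`).
#' @export
allelic_balance_test <- function(vafs, expected) {
  stopifnot(is.numeric(vafs), length(vafs) >= 5,
            is.numeric(expected), length(expected) == 1,
            expected > 0, expected <= 0.5)
  # round differences to 9 decimals so binary representation error cannot
  # break the symmetry of |d| ranks (VAFs are ratios of read counts; real
  # differences are never that small)
  d <- round(vafs - expected, 9)
  nz <- sum(d != 0)
  if (nz == 0) {
    return(list(median = stats::median(vafs), expected = expected,
                statistic = NA_real_, p_value = 1, n_nonzero = 0L,
                degenerate = TRUE))
  }
  wt <- suppressWarnings(stats::wilcox.test(
    d, mu = 0, alternative = "two.sided",
    exact = nz <= 25, correct = TRUE
  ))
  list(median = stats::median(vafs), expected = expected,
       statistic = unname(wt$statistic), p_value = wt$p.value,
       n_nonzero = as.integer(nz), degenerate = FALSE)
}

#' Diagnostic-yield summary of a patient cohort
#'
#' Recomputes every percentage from raw counts. Solo-phase outcomes use
#' all patients as denominator; trio-phase outcomes use the patients that
#' entered the trio phase. Overall rows (per outcome across phases) use
#' all patients.
#'
#' @param outcomes Tibble with one row per patient per phase: `patient_id`,
#'   `phase` (`"solo_wes"` or `"trio_pooled"`), `outcome` (one of
#'   `"diagnosed_known_gene"`, `"candidate_gene"`, `"candidate_cnv"`,
#'   `"unsolved"`).
#' @return Tibble with `phase`, `outcome`, `n`, `denominator`, `percent`
#'   (2 decimals, half-up); phase `"overall"` rows aggregate
#'   `diagnosed_known_gene` and `candidate_gene` across phases.
#' @export
yield_summary <- function(outcomes) {
  stopifnot(is.data.frame(outcomes))
  if (!nrow(outcomes)) {
    return(tibble::tibble(phase = character(), outcome = character(),
                          n = integer(), denominator = integer(),
                          percent = numeric()))
  }
  stopifnot(all(c("patient_id", "phase", "outcome") %in% names(outcomes)))
  n_all <- length(unique(outcomes$patient_id))
  n_trio <- length(unique(outcomes$patient_id[outcomes$phase == "trio_pooled"]))
  denom <- function(phase) {
    switch(phase, solo_wes = n_all, trio_pooled = n_trio, overall = n_all)
  }
  per_phase <- dplyr::count(outcomes, .data$phase, .data$outcome, name = "n")
  per_phase$denominator <- unname(vapply(per_phase$phase, denom, numeric(1)))
  overall <- dplyr::count(
    outcomes[outcomes$outcome != "unsolved", , drop = FALSE],
    .data$outcome, name = "n"
  )
  if (nrow(overall)) {
    overall$phase <- "overall"
    overall$denominator <- n_all
    per_phase <- dplyr::bind_rows(per_phase,
                                  overall[, c("phase", "outcome", "n",
                                              "denominator")])
  }
  per_phase$percent <- ifelse(
    per_phase$denominator > 0,
    round_half_up(100 * per_phase$n / per_phase$denominator, 2), NA_real_
  )
  tibble::as_tibble(per_phase)
}
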