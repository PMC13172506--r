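# Closed-form design mathematics for pooled parental sequencing.

#' Specification of one parental DNA pool
#'
#' A pool combines equimolar DNA from `n_samples` parents and is sequenced as
#' a single library. Design depth targets `reads_per_het_allele` reads for
#' each allele of a heterozygous variant carried by one pooled individual.
#'
#' @param n_samples Number of individuals combined in the pool (>= 1).
#' @param reads_per_het_allele Target reads supporting one heterozygous
#'   allele (default 20, the conventional clinical floor).
#' @return An object of class `pool_spec`.
#' @examples
#' pool_spec(10)
#' @export
pool_spec <- function(n_samples, reads_per_het_allele = 20L) {
  n_samples <- assert_count(n_samples, "n_samples")
  reads_per_het_allele <- assert_count(reads_per_het_allele, "reads_per_het_allele")
  structure(
    list(n_samples = n_samples, reads_per_het_allele = reads_per_het_allele),
    class = "pool_spec"
  )
}

#' @export
print.pool_spec <- function(x, ...) {
  cat(sprintf(
    "<pool_spec> %d samples, %d reads per heterozygous allele (target depth %dX)\n",
    x$n_samples, x$reads_per_het_allele, required_pool_depth(x)
  ))
  invisible(x)
}

#' Required mean sequencing depth for a parental pool
#'
#' Each of the `n` pooled individuals contributes two alleles, and a
#' heterozygous singleton variant occupies one of the `2n` allele shares of
#' the pool. To see at least `reads_per_het_allele` reads for that allele on
#' average, the pool must be sequenced to
#' `n_samples * 2 * reads_per_het_allele` mean depth.
#'
#' The value is an exact integer target; rounding up to lane or flow-cell
#' granularity is the sequencing facility's concern.
#'
#' @param spec A [pool_spec()], or a bare sample count (the default 20
#'   reads/allele is then used).
#' @return Integer mean target depth.
#' @examples
#' required_pool_depth(pool_spec(10))  # 400
#' required_pool_depth(8)              # 320
#' @export
required_pool_depth <- function(spec) {
  if (!inherits(spec, "pool_spec")) spec <- pool_spec(spec)
  as.integer(spec$n_samples * 2L * spec$reads_per_het_allele)
}

#' Expected allelic balance of a pool singleton
#'
#' The expected variant allele fraction of a variant carried heterozygously
#' by exactly one of `n_samples` pooled individuals: one alternate allele
#' among `2 * n_samples` pooled alleles, i.e. `1 / (2 * n_samples)`.
#'
#' @param n_samples Number of individuals in the pool (>= 1).
#' @return Fraction in (0, 0.5].
#' @examples
#' expected_allelic_balance(10)  # 0.05
#' @export
expected_allelic_balance <- function(n_samples) {
  n_samples <- assert_count(n_samples, "n_samples")
  1 / (2 * n_samples)
}

#' Cost model for a pooled trio
#'
#' One pooled-WES run costs `pooled_multiplier` standard-WES units (the
#' elevated depth makes the pooled library more expensive to sequence than a
#' standard exome), and its cost amortizes over the `pool_size` parents it
#' contains. A pooled trio then costs one standard proband exome plus each
#' parent's share of one pool.
#'
#' @param pooled_multiplier Ratio of one pooled-WES run cost to one standard
#'   WES run cost (default 1.28, i.e. 28% more expensive).
#' @param pool_size Parents per pool (default 8).
#' @param standard_wes_unit_cost Cost of one standard WES in arbitrary
#'   currency units (default 1).
#' @return An object of class `cost_model`.
#' @export
cost_model <- function(pooled_multiplier = 1.28, pool_size = 8L,
                       standard_wes_unit_cost = 1) {
  if (!is.numeric(pooled_multiplier) || length(pooled_multiplier) != 1 ||
      is.na(pooled_multiplier) || pooled_multiplier <= 0) {
    stop("`pooled_multiplier` must be a single positive number", call. = FALSE)
  }
  pool_size <- assert_count(pool_size, "pool_size")
  if (!is.numeric(standard_wes_unit_cost) || length(standard_wes_unit_cost) != 1 ||
      is.na(standard_wes_unit_cost) || standard_wes_unit_cost <= 0) {
    stop("`standard_wes_unit_cost` must be a single positive number", call. = FALSE)
  }
  structure(
    list(pooled_multiplier = pooled_multiplier, pool_size = pool_size,
         standard_wes_unit_cost = standard_wes_unit_cost),
    class = "cost_model"
  )
}

#' Per-trio cost reduction of the pooled design
#'
#' A standard trio sequences three individual exomes (3 units). The pooled
#' trio sequences the proband individually (1 unit) plus each parent's share
#' of one pooled run: `pooled_multiplier / pool_size` units per parent, two
#' parents per trio. The reduction is
#' `1 - (1 + 2 * pooled_multiplier / pool_size) / 3`.
#'
#' With the defaults (pooled run 28% dearer than standard WES, 8 parents per
#' pool) the reduction is exactly 56%.
#'
#' @param model A [cost_model()].
#' @return Fraction in `[0, 1)` of the standard trio cost saved.
#' @examples
#' trio_cost_reduction(cost_model())                   # 0.56
#' trio_cost_reduction(cost_model(1.28, pool_size = 10))
#' @export
trio_cost_reduction <- function(model = cost_model()) {
  if (!inherits(model, "cost_model")) {
    stop("`model` must be a cost_model object", call. = FALSE)
  }
  u <- model$standard_wes_unit_cost
  pooled_trio <- u + 2 * model$pooled_multiplier * u / model$pool_size
  1 - pooled_trio / (3 * u)
}

#' Summarize a pool design
#'
#' Convenience wrapper returning depth, expected allelic balance, and
#' per-trio cost reduction for one design in a single-row tibble.
#'
#' @inheritParams pool_spec
#' @param pooled_multiplier Passed to [cost_model()].
#' @return A one-row tibble with columns `n_samples`,
#'   `reads_per_het_allele`, `required_depth`, `expected_allelic_balance`,
#'   `cost_reduction`.
#' @export
pool_design_summary <- function(n_samples, reads_per_het_allele = 20L,
                                pooled_multiplier = 1.28) {
  spec <- pool_spec(n_samples, reads_per_het_allele)
  tibble::tibble(
    n_samples = spec$n_samples,
    reads_per_het_allele = spec$reads_per_het_allele,
    required_depth = required_pool_depth(spec),
    expected_allelic_balance = expected_allelic_balance(spec$n_samples),
    cost_reduction = trio_cost_reduction(
      cost_model(pooled_multiplier, pool_size = spec$n_samples)
    )
  )
}

# single positive integer, coerced
assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 ||
      abs(x - round(x)) > 1e-8) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
  as.integer(round(x))
}
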