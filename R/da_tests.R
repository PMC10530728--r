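# Reference differential-abundance tests: rare-taxon filter, additive
# log-ratio transform, Wilcoxon rank-sum, Benjamini-Hochberg.

#' Filter rare taxa by presence fraction
#'
#' Keeps taxon `j` when the fraction of samples with a non-zero count is at
#' least `presence_fraction`. The 20% cutoff is the stringent filter
#' recommended for compositional analyses; 10% is the laxer filter several
#' methods apply by default.
#'
#' @param counts `n` x `J` non-negative count matrix.
#' @param presence_fraction Scalar in (0, 1].
#' @return Integer vector of kept taxon indices.
#' @export
filter_rare_taxa <- function(counts, presence_fraction = 0.2) {
  stopifnot(is.matrix(counts), presence_fraction > 0,
            presence_fraction <= 1)
  presence <- colMeans(counts > 0)
  kept <- which(presence >= presence_fraction)
  if (length(kept) == 0L) {
    stop("no taxa pass the ", presence_fraction, " presence filter")
  }
  kept
}

#' Additive log-ratio transform with pseudocounts
#'
#' Returns `log(counts[, j] + pseudocount) - log(counts[, ref] +
#' pseudocount)` for every taxon `j` other than the reference. A
#' pseudocount of 0.5 or 1 is added to every count (including the
#' reference) to accommodate zeros.
#'
#' @param counts `n` x `J` count matrix.
#' @param pseudocount Positive constant added to all counts.
#' @param reference Column index of the reference taxon.
#' @return `n` x `(J-1)` matrix; column names follow `counts` with the
#'   reference column dropped.
#' @export
alr_transform <- function(counts, pseudocount = 0.5, reference) {
  stopifnot(is.matrix(counts), pseudocount > 0,
            length(reference) == 1L, reference >= 1,
            reference <= ncol(counts))
  lc <- log(counts + pseudocount)
  (lc - lc[, reference])[, -reference, drop = FALSE]
}

#' Choose the alr reference taxon
#'
#' Among kept taxa that are null (non-causal — known in simulated data),
#' returns the one with the largest mean relative abundance in the dataset.
#' Ties are broken by the lowest column index.
#'
#' @param counts `n` x `J` count matrix.
#' @param null_taxa Integer indices of null taxa; `NULL` means all taxa.
#' @param kept Integer indices of taxa passing the rare-taxon filter.
#' @return Column index of the reference taxon.
#' @export
choose_reference_taxon <- function(counts, null_taxa = NULL,
                                   kept = seq_len(ncol(counts))) {
  candidates <- if (is.null(null_taxa)) kept else intersect(kept, null_taxa)
  if (length(candidates) == 0L) stop("no null taxa available as reference")
  rel <- counts / rowSums(counts)
  mean_rel <- colMeans(rel[, candidates, drop = FALSE])
  candidates[which.max(mean_rel)]  # which.max takes the first maximum
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration is used when the smaller group has at most
#' `exact_limit` observations and the data are tie-free; otherwise the
#' normal approximation with mid-ranks, tie-corrected variance and
#' continuity correction. Values constant across all samples give `p = 1`
#' by convention.
#'
#' @param values Numeric vector of per-sample observations.
#' @param groups Binary group labels (two levels, both present).
#' @param exact_limit Largest minimum group size for the exact path.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(values, groups, exact_limit = 10L) {
  g <- unique(groups)
  if (length(g) != 2L) stop("`groups` must contain exactly two levels")
  x <- values[groups == g[1L]]
  y <- values[groups == g[2L]]
  if (length(unique(values)) == 1L) return(1)
  exact <- min(length(x), length(y)) <= exact_limit &&
    !anyDuplicated(values)
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment: with order statistics `p(1) <= ... <=
#' p(m)`, `q(k) = min_{l >= k} p(l) m / l`, capped at 1 and mapped back to
#' the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Differential-abundance test result
#'
#' Container for per-taxon p/q-values of one method on one dataset, with
#' the detected set at the nominal level.
#'
#' @param taxon_ids Integer indices (or names) of the tested taxa.
#' @param p_values,q_values Per-taxon p-values and BH q-values.
#' @param method_name Method label.
#' @param level Nominal FDR level; taxa with `q <= level` are detected.
#' @param reference Optional reference-taxon index (excluded from testing).
#' @return An object of class `da_result`.
#' @export
da_result <- function(taxon_ids, p_values, q_values, method_name,
                      level = 0.2, reference = NULL) {
  stopifnot(length(taxon_ids) == length(p_values),
            length(p_values) == length(q_values))
  if (any(q_values < p_values - 1e-12, na.rm = TRUE)) {
    stop("q-values must dominate p-values")
  }
  if (any(q_values > 1 + 1e-12, na.rm = TRUE)) stop("q-values must be <= 1")
  detected <- taxon_ids[!is.na(q_values) & q_values <= level]
  structure(list(taxon_ids = taxon_ids, p_values = p_values,
                 q_values = q_values, detected = detected,
                 method_name = method_name, level = level,
                 reference = reference),
            class = "da_result")
}

#' @export
print.da_result <- function(x, ...) {
  cat(sprintf("%s: %d taxa tested, %d detected at q <= %s\n",
              x$method_name, length(x$taxon_ids), length(x$detected),
              format(x$level)))
  invisible(x)
}

#' Wilcoxon test on alr-transformed counts
#'
#' The bundled reference procedure: filter rare taxa, pick the most
#' abundant kept null taxon as the alr reference, transform all counts with
#' a pseudocount (0.5 for "wilcox-alr-half", 1 for "wilcox-alr-one"), run a
#' two-sided Wilcoxon rank-sum test of each alr coordinate against the
#' binary trait, and adjust by Benjamini-Hochberg. The reference taxon
#' itself is not tested.
#'
#' @param dataset A `sim_dataset` (or any list with `counts`, `trait` and
#'   `beta1` elements; `beta1` identifies the null taxa).
#' @param pseudocount Pseudocount added to all counts (0.5 or 1 in the
#'   named variants).
#' @param presence_fraction Rare-taxon filter threshold.
#' @param level Nominal FDR level for detection.
#' @return A [da_result()].
#' @export
run_wilcox_alr <- function(dataset, pseudocount = 0.5,
                           presence_fraction = 0.2, level = 0.2) {
  counts <- dataset$counts
  trait <- dataset$trait
  if (length(unique(trait)) != 2L) {
    stop("the Wilcoxon alr test requires a binary trait")
  }
  null_taxa <- if (!is.null(dataset$beta1)) {
    which(dataset$beta1 == 0)
  } else {
    setdiff(seq_len(ncol(counts)), dataset$causal_set)
  }
  kept <- filter_rare_taxa(counts, presence_fraction)
  ref <- choose_reference_taxon(counts, null_taxa, kept)
  alr <- alr_transform(counts[, kept, drop = FALSE], pseudocount,
                       reference = match(ref, kept))
  p <- apply(alr, 2L, wilcoxon_rank_sum, groups = trait)
  q <- bh_adjust(p)
  name <- if (isTRUE(all.equal(pseudocount, 0.5))) {
    "wilcox-alr-half"
  } else if (isTRUE(all.equal(pseudocount, 1))) {
    "wilcox-alr-one"
  } else {
    sprintf("wilcox-alr-c%g", pseudocount)
  }
  da_result(taxon_ids = setdiff(kept, ref), p_values = unname(p),
            q_values = unname(q), method_name = name, level = level,
            reference = ref)
}
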