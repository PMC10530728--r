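# Study designs: causal/confounder taxon sets, traits, effect vectors.

#' Select the causal taxon set
#'
#' Two schemes are supported:
#' * `"M1"`: 20 taxa sampled uniformly without replacement from the taxa
#'   whose mean relative abundance exceeds `threshold` (default 0.005),
#'   excluding the single most abundant taxon.
#' * `"M2"`: the five most abundant taxa.
#'
#' @param profile A [community_profile()].
#' @param scheme `"M1"` or `"M2"`.
#' @param threshold Mean-abundance floor for the M1 pool.
#' @param m1_size,m2_size Causal-set sizes (defaults 20 and 5).
#' @return Integer vector of taxon indices.
#' @export
select_causal_taxa <- function(profile, scheme = c("M1", "M2"),
                               threshold = 0.005, m1_size = 20L,
                               m2_size = 5L) {
  scheme <- match.arg(scheme)
  pi_bar <- profile$pi_bar
  if (scheme == "M2") {
    if (length(pi_bar) < m2_size) stop("fewer than ", m2_size, " taxa")
    return(order(pi_bar, decreasing = TRUE)[seq_len(m2_size)])
  }
  pool <- setdiff(which(pi_bar > threshold), which.max(pi_bar))
  if (length(pool) < m1_size) {
    stop("M1 pool has only ", length(pool), " taxa above ", threshold,
         " (need ", m1_size, ")")
  }
  sort(sample(pool, m1_size))
}

#' Select the confounder-associated taxon set
#'
#' The confounder is associated with a mix of causal and null taxa: 10 + 10
#' under scheme `"M1"`, 2 + 3 under `"M2"`.
#'
#' @param causal_set Integer indices of causal taxa.
#' @param null_pool Integer indices of null taxa to sample from.
#' @param scheme `"M1"` or `"M2"`.
#' @return Integer vector of taxon indices.
#' @export
select_confounder_taxa <- function(causal_set, null_pool,
                                   scheme = c("M1", "M2")) {
  scheme <- match.arg(scheme)
  n_causal <- if (scheme == "M1") 10L else 2L
  n_null <- if (scheme == "M1") 10L else 3L
  if (length(causal_set) < n_causal) stop("causal pool too small")
  if (length(null_pool) < n_null) stop("null pool too small")
  sort(c(sample(causal_set, n_causal), sample(null_pool, n_null)))
}

#' Draw trait and confounder values
#'
#' Binary traits assign exactly half of the samples to each group, in random
#' order; continuous traits are i.i.d. Uniform(-1, 1). A binary confounder,
#' available only with binary traits, is Bernoulli with success probability
#' `p0` in the `T = 0` group and `p1` in the `T = 1` group.
#'
#' @param n Sample count (even for binary traits).
#' @param trait_type `"binary"` or `"continuous"`.
#' @param confounded Draw a confounder? (binary traits only)
#' @param p0,p1 Confounder probabilities given `T = 0` / `T = 1`.
#' @return List with components `trait` and `confounder` (`NULL` when not
#'   confounded).
#' @export
draw_traits <- function(n, trait_type = c("binary", "continuous"),
                        confounded = FALSE, p0 = 0.2, p1 = 0.8) {
  trait_type <- match.arg(trait_type)
  if (trait_type == "continuous") {
    if (confounded) {
      stop("a confounder is only supported with a binary trait")
    }
    return(list(trait = stats::runif(n, -1, 1), confounder = NULL))
  }
  if (n %% 2L != 0L) stop("`n` must be even for a binary trait")
  trait <- sample(rep(c(0L, 1L), each = n %/% 2L))
  confounder <- NULL
  if (confounded) {
    if (any(c(p0, p1) < 0) || any(c(p0, p1) > 1)) stop("probabilities must be in [0,1]")
    confounder <- stats::rbinom(n, 1L, ifelse(trait == 1L, p1, p0))
  }
  list(trait = trait, confounder = confounder)
}

#' Build per-taxon effect-size vectors
#'
#' Expands a causal set with a common trait effect `beta` and an optional
#' confounder-associated set with effects `beta_confounder` into full-length
#' log-fold-change vectors `beta1` (trait) and `beta2` (confounder), zero
#' off the respective sets. When `beta_confounder` is `NULL`, confounder
#' effects default to magnitude `beta` with alternating signs across the
#' confounder set.
#'
#' @param J Number of taxa.
#' @param causal_set Integer indices of trait-associated taxa.
#' @param beta Common log-fold trait effect on causal taxa.
#' @param confounder_set Integer indices of confounder-associated taxa.
#' @param beta_confounder Per-taxon confounder effects (recycled to the
#'   length of `confounder_set`), or `NULL` for the alternating default.
#' @return List with `beta1`, `beta2`, `causal_set`, `confounder_set`.
#' @export
effect_spec <- function(J, causal_set = integer(0), beta = 0,
                        confounder_set = integer(0), beta_confounder = NULL) {
  beta1 <- numeric(J)
  beta1[causal_set] <- beta
  beta2 <- numeric(J)
  if (length(confounder_set) > 0L) {
    if (is.null(beta_confounder)) {
      beta_confounder <- beta * (-1)^(seq_along(confounder_set) - 1L)
    }
    beta2[confounder_set] <- rep_len(beta_confounder, length(confounder_set))
  }
  list(beta1 = beta1, beta2 = beta2,
       causal_set = as.integer(causal_set),
       confounder_set = as.integer(confounder_set))
}
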