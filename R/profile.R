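# Community profiles: mean relative abundances plus Dirichlet overdispersion.

#' Community profile
#'
#' Bundles a mean relative-abundance vector `pi_bar` with the Dirichlet
#' overdispersion `theta_dm` used to draw per-sample baseline compositions.
#' Under the parameterization used here, `Var(pi_j) = pi_bar_j (1 -
#' pi_bar_j) theta_dm`, i.e. the concentration vector is
#' `pi_bar * (1 - theta_dm) / theta_dm`.
#'
#' @param pi_bar Non-negative vector summing to 1.
#' @param overdispersion Scalar in (0, 1); default 0.02, typical of
#'   upper-respiratory-tract profiles fitted by Dirichlet-Multinomial.
#' @return An object of class `community_profile`.
#' @export
community_profile <- function(pi_bar, overdispersion = 0.02) {
  pi_bar <- as.numeric(pi_bar)
  if (any(!is.finite(pi_bar)) || any(pi_bar < 0)) {
    stop("`pi_bar` entries must be finite and non-negative")
  }
  if (abs(sum(pi_bar) - 1) > 1e-6) {
    stop("`pi_bar` must sum to 1 (got ", format(sum(pi_bar)), ")")
  }
  if (length(overdispersion) != 1L || overdispersion <= 0 || overdispersion >= 1) {
    stop("`overdispersion` must lie strictly between 0 and 1")
  }
  # keep the entries bitwise as supplied (pinned values stay exact);
  # downstream consumers tolerate the sub-1e-6 departure from unit sum
  structure(list(pi_bar = pi_bar, overdispersion = overdispersion),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  cat("Community profile:", length(x$pi_bar), "taxa, overdispersion",
      format(x$overdispersion), "\n")
  cat("  top mean abundances:",
      paste(format(utils::head(sort(x$pi_bar, decreasing = TRUE), 5L),
                   digits = 3), collapse = ", "), "\n")
  invisible(x)
}

#' Synthesize a heavy-tailed mean-abundance profile
#'
#' Generates a synthetic stand-in for an empirical mean relative-abundance
#' vector: a sorted (non-increasing), normalized, log-normal-tailed profile.
#' Optionally the leading entries are pinned to given values exactly, with
#' the tail rescaled to fill the remaining mass; this is how the bundled
#' profiles reproduce the five dominant mean abundances (0.105, 0.062,
#' 0.054, 0.050, 0.049) of the upper-respiratory-tract community that the
#' default simulations emulate.
#'
#' @param J Number of taxa.
#' @param pinned_top Optional numeric vector of leading mean abundances,
#'   summing to less than 1.
#' @param overdispersion Passed to [community_profile()].
#' @param sdlog Log-scale sd of the tail draws (default 2; larger values give
#'   heavier tails and more rare taxa).
#' @return A [community_profile()].
#' @export
#' @examples
#' set.seed(1)
#' prof <- synthesize_mean_abundances(100,
#'   pinned_top = c(0.105, 0.062, 0.054, 0.050, 0.049))
#' head(prof$pi_bar)
synthesize_mean_abundances <- function(J, pinned_top = NULL,
                                       overdispersion = 0.02, sdlog = 2) {
  if (length(J) != 1L || J < 1 || J != round(J)) stop("`J` must be a positive integer")
  k <- length(pinned_top)
  if (k >= J) stop("`pinned_top` must be shorter than `J`")
  if (k > 0L) {
    pinned_top <- as.numeric(pinned_top)
    if (any(pinned_top <= 0)) stop("pinned abundances must be positive")
    if (any(diff(pinned_top) > 0)) stop("`pinned_top` must be non-increasing")
    if (sum(pinned_top) >= 1) stop("`pinned_top` must sum to less than 1")
  }
  remainder <- 1 - sum(pinned_top)
  jt <- J - k
  tail_raw <- sort(stats::rlnorm(jt, meanlog = 0, sdlog = sdlog),
                   decreasing = TRUE)
  tail <- tail_raw * remainder / sum(tail_raw)
  if (k > 0L) {
    cap <- pinned_top[k]
    u <- remainder / jt  # uniform tail with the same mass
    if (u > cap) {
      stop("cannot keep the profile non-increasing: remaining mass ",
           format(remainder), " spread over ", jt,
           " taxa exceeds the smallest pinned abundance")
    }
    if (tail[1L] > cap) {
      # shrink toward the uniform tail just enough to respect the cap;
      # a convex combination preserves both the total mass and the ordering
      lambda <- (cap - u) / (tail[1L] - u)
      tail <- pmin(lambda * tail + (1 - lambda) * u, cap)
    }
  }
  community_profile(c(pinned_top, tail), overdispersion)
}

#' Draw baseline relative abundances from the Dirichlet model
#'
#' Each sample's baseline composition is an independent Dirichlet draw with
#' mean `pi_bar` and overdispersion `theta_dm`, implemented via normalized
#' gamma variates with shape `pi_bar * (1 - theta_dm) / theta_dm`.
#'
#' @param profile A [community_profile()].
#' @param n Number of samples.
#' @return An `n` x `J` matrix whose rows sum to 1.
#' @export
draw_baseline_abundances <- function(profile, n) {
  stopifnot(inherits(profile, "community_profile"), n >= 1)
  pi_bar <- profile$pi_bar
  th <- profile$overdispersion
  J <- length(pi_bar)
  alpha <- pi_bar * (1 - th) / th
  g <- matrix(stats::rgamma(n * J, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Method-of-moments overdispersion estimate
#'
#' Pools per-taxon moment estimates of the Dirichlet overdispersion: with
#' per-taxon sample mean `m_j` and variance `v_j` of the relative
#' abundances, the estimate is `sum_j v_j / sum_j m_j (1 - m_j)`, i.e. the
#' per-taxon ratios `v_j / (m_j (1 - m_j))` weighted by `m_j (1 - m_j)`.
#'
#' @param Pi An `n` x `J` matrix of relative abundances (rows sum to 1).
#' @return Scalar overdispersion estimate.
#' @export
estimate_overdispersion <- function(Pi) {
  stopifnot(is.matrix(Pi), nrow(Pi) >= 2L)
  m <- colMeans(Pi)
  v <- apply(Pi, 2L, stats::var)
  sum(v) / sum(m * (1 - m))
}
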