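# Experimental-bias model.
#
# Observed relative abundances follow a log-linear perturbation of the true
# composition: log p_ij = log pi_ij + gamma_j + sum_{j' != j} theta_jj' pi_ij'
# + alpha_i, where gamma_j is the taxon-specific main-effect bias, theta_jj'
# the taxon-taxon interaction bias, and alpha_i the per-sample normalization.
# Interaction biases are generated relative to the main effects as
#   theta_jj' = -sign(gamma_j') * phi * epsilon_jj' * |gamma_j|,
# with phi a common magnitude and epsilon_jj' a non-negative, unit-mean
# error term.

.scenarios <- c("S-nondiff", "S-diff-causal", "S-diff-half")

#' Draw taxon-specific main-effect biases
#'
#' Main-effect biases `gamma[j]` are independent draws from a zero-mean
#' normal on the log scale, so `exp(gamma[j])` is the multiplicative
#' measurement-bias fold change of taxon `j`. The default standard deviation
#' of 0.8 puts ~95% of fold changes between 0.2 and 5.
#'
#' @param J Number of taxa (positive integer).
#' @param sigma_gamma Standard deviation of the log-scale biases (default 0.8).
#' @return Numeric vector of length `J`.
#' @export
#' @examples
#' set.seed(1)
#' gamma <- draw_main_biases(10)
#' range(exp(gamma))
draw_main_biases <- function(J, sigma_gamma = 0.8) {
  if (length(J) != 1L || !is.finite(J) || J < 1 || J != round(J)) {
    stop("`J` must be a positive integer")
  }
  if (length(sigma_gamma) != 1L || !is.finite(sigma_gamma) || sigma_gamma < 0) {
    stop("`sigma_gamma` must be a non-negative scalar")
  }
  stats::rnorm(J, mean = 0, sd = sigma_gamma)
}

#' Draw the interaction error-term matrix
#'
#' Generates the J x J matrix of non-negative, unit-mean error terms
#' `epsilon[j, j']` that modulate interaction biases. The half-scale values
#' `epsilon/2` are drawn from N(0.5, normal_sd^2) (unimodal, modest spread)
#' or Beta(0.5, 0.5) (bimodal at 0 and 1, larger spread) row by row:
#'
#' * `"S-nondiff"`: every row uses the normal distribution.
#' * `"S-diff-causal"`: rows in `causal_set` use the beta distribution (a
#'   trait-related difference in error spread), all other rows the normal.
#' * `"S-diff-half"`: rows in `half_set` (a random half of the taxa) use the
#'   beta distribution; the variation is large but unrelated to the trait.
#'
#' Normal draws are clamped at zero to respect the non-negativity of
#' `epsilon`; the clamped mass is ~3e-7 at the default sd. When `base_seed`
#' is supplied, each row is drawn from its own sub-stream keyed by
#' (`base_seed`, row), so switching a subset of rows to the beta distribution
#' leaves the draws of all other rows untouched — this is what couples the
#' "S-nondiff" and "S-diff-causal" scenarios at null taxa.
#'
#' @param J Number of taxa.
#' @param scenario One of `"S-nondiff"`, `"S-diff-causal"`, `"S-diff-half"`.
#' @param causal_set Integer taxon indices; required for `"S-diff-causal"`.
#' @param half_set Integer taxon indices; required for `"S-diff-half"`.
#' @param normal_sd Standard deviation of the half-scale normal (default 0.1).
#' @param beta_shape Length-2 shape parameters of the half-scale beta
#'   (default `c(0.5, 0.5)`).
#' @param base_seed Optional integer; when given, row `j` is drawn under
#'   `mix_seed(base_seed, "eps", j)`.
#' @return A `J` x `J` numeric matrix with non-negative entries and
#'   (population) mean one. Diagonal entries are drawn but never used: the
#'   interaction matrix zeroes them.
#' @export
draw_epsilon <- function(J, scenario = .scenarios, causal_set = NULL,
                         half_set = NULL, normal_sd = 0.1,
                         beta_shape = c(0.5, 0.5), base_seed = NULL) {
  scenario <- match.arg(scenario)
  if (length(J) != 1L || J < 1 || J != round(J)) stop("`J` must be a positive integer")
  if (normal_sd < 0) stop("`normal_sd` must be non-negative")
  beta_rows <- rep(FALSE, J)
  if (scenario == "S-diff-causal") {
    if (is.null(causal_set) || length(causal_set) == 0L) {
      stop("scenario \"S-diff-causal\" requires a non-empty `causal_set`")
    }
    beta_rows[causal_set] <- TRUE
  } else if (scenario == "S-diff-half") {
    if (is.null(half_set) || length(half_set) == 0L) {
      stop("scenario \"S-diff-half\" requires a non-empty `half_set`")
    }
    beta_rows[half_set] <- TRUE
  }
  eps <- matrix(0, J, J)
  draw_row <- function(j) {
    half <- if (beta_rows[j]) {
      stats::rbeta(J, beta_shape[1L], beta_shape[2L])
    } else {
      stats::rnorm(J, mean = 0.5, sd = normal_sd)
    }
    pmax(2 * half, 0)
  }
  for (j in seq_len(J)) {
    eps[j, ] <- if (is.null(base_seed)) {
      draw_row(j)
    } else {
      with_rng_seed(mix_seed(base_seed, "eps", j), draw_row(j))
    }
  }
  eps
}

#' Build the taxon-taxon interaction-bias matrix
#'
#' Computes `theta[j, j'] = -sign(gamma[j']) * phi * epsilon[j, j'] *
#' |gamma[j]|` for `j != j'` and zero on the diagonal. The sign opposition
#' means a taxon measured above its true abundance depresses the measured
#' abundances of the others, as expected when a roughly constant total number
#' of amplicons is sequenced. `sign(0)` is 0, so a taxon with no main-effect
#' bias induces no interaction bias; rows with `gamma[j] == 0` are
#' identically zero. The matrix is not symmetric in general.
#'
#' @param gamma Main-effect bias vector (length `J`).
#' @param phi Non-negative interaction magnitude; 0 disables interactions.
#' @param epsilon `J` x `J` error matrix from [draw_epsilon()].
#' @return A `J` x `J` matrix `theta` with zero diagonal.
#' @export
#' @examples
#' build_interaction_matrix(c(1, -1), phi = 1, epsilon = matrix(1, 2, 2))
build_interaction_matrix <- function(gamma, phi, epsilon) {
  if (length(phi) != 1L || !is.finite(phi) || phi < 0) {
    stop("`phi` must be a non-negative scalar")
  }
  J <- length(gamma)
  if (!is.matrix(epsilon) || any(dim(epsilon) != J)) {
    stop("`epsilon` must be a ", J, " x ", J, " matrix")
  }
  theta <- -phi * (abs(gamma) %o% sign(gamma)) * epsilon
  diag(theta) <- 0
  theta
}

#' Per-sample interaction-bias field
#'
#' The total interaction contribution to taxon `j`'s log bias in sample `i`
#' is `eta[i, j] = sum_{j' != j} theta[j, j'] * Pi[i, j']`, a weighting of
#' the interaction matrix by the sample's true composition. Because
#' contributions carry both signs, `eta` averages to approximately zero per
#' taxon, while its variance grows with `|gamma[j]|` at fixed `phi`.
#'
#' @param theta Interaction matrix from [build_interaction_matrix()].
#' @param Pi `n` x `J` matrix of true relative abundances; rows must sum to 1.
#' @param tol Tolerance on row sums of `Pi` (default 1e-6).
#' @return An `n` x `J` matrix of log-scale interaction biases.
#' @export
interaction_bias_field <- function(theta, Pi, tol = 1e-6) {
  if (!is.matrix(Pi)) Pi <- matrix(Pi, nrow = 1L)
  J <- ncol(Pi)
  if (!is.matrix(theta) || any(dim(theta) != J)) {
    stop("`theta` must be a ", J, " x ", J, " matrix")
  }
  rs <- rowSums(Pi)
  if (any(abs(rs - 1) > tol)) {
    stop("rows of `Pi` must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  }
  # diagonal of theta is zero, so the full product equals the j' != j sum
  Pi %*% t(theta)
}

#' Convert presence-model interaction ratios to an abundance-scale magnitude
#'
#' In a presence-based interaction model the interaction term for taxon `j'`
#' is a constant whenever the taxon is present; in the relative-abundance
#' model used here the corresponding term is `theta[j, j'] * pi[i, j']`. A
#' mean absolute interaction-to-main-effect ratio estimated on the presence
#' scale therefore converts to the abundance-scale magnitude `phi` by
#' dividing by the typical relative abundance of the interacting taxa. For
#' mock communities with three equally abundant taxa (`pi = 1/3`), a
#' presence-scale ratio of 0.204 gives `phi = 0.612`.
#'
#' @param mean_abs_ratio Mean of the absolute presence-scale
#'   interaction-to-main-effect ratios (positive scalar).
#' @param mean_relative_abundance Typical relative abundance of an
#'   interacting taxon (positive scalar).
#' @return The abundance-scale interaction magnitude `phi`.
#' @export
#' @examples
#' phi_from_presence_ratios(0.204, 1 / 3)
phi_from_presence_ratios <- function(mean_abs_ratio, mean_relative_abundance) {
  if (length(mean_abs_ratio) != 1L || !is.finite(mean_abs_ratio) ||
      mean_abs_ratio <= 0) {
    stop("`mean_abs_ratio` must be a positive scalar")
  }
  if (length(mean_relative_abundance) != 1L ||
      !is.finite(mean_relative_abundance) || mean_relative_abundance <= 0) {
    stop("`mean_relative_abundance` must be a positive scalar")
  }
  mean_abs_ratio / mean_relative_abundance
}
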