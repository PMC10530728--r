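# True and observed (bias-distorted) relative abundances.

#' True relative abundances after trait/confounder spike-in
#'
#' Applies an exponential tilt to the baseline compositions: taxon `j` in
#' sample `i` is multiplied by `exp(beta1[j] T_i + beta2[j] C_i)` and each
#' row renormalized. Effects therefore act on absolute abundances; observed
#' relative abundances of all taxa shift through the normalization.
#'
#' @param Pi0 `n` x `J` baseline relative abundances (rows sum to 1).
#' @param effects Output of [effect_spec()].
#' @param trait Length-`n` trait vector.
#' @param confounder Optional length-`n` confounder vector.
#' @return `n` x `J` matrix of true relative abundances.
#' @export
true_abundances <- function(Pi0, effects, trait, confounder = NULL) {
  stopifnot(is.matrix(Pi0), length(trait) == nrow(Pi0))
  logtilt <- outer(trait, effects$beta1)
  if (!is.null(confounder)) {
    logtilt <- logtilt + outer(confounder, effects$beta2)
  }
  if (all(logtilt == 0)) return(Pi0)  # null tilt is the identity, bitwise
  w <- Pi0 * exp(logtilt)
  w / rowSums(w)
}

#' Expected observed relative abundances under experimental bias
#'
#' Multiplies the spiked baseline by the bias factor
#' `exp(gamma[j] + eta[i, j])`, where `eta` is the interaction-bias field
#' computed from `theta` and the true (post-spike) composition `Pi`, and
#' renormalizes. With `gamma = 0` and `theta = 0` the observed abundances
#' equal the true ones.
#'
#' @param Pi0 `n` x `J` baseline relative abundances.
#' @param Pi `n` x `J` true relative abundances from [true_abundances()] on
#'   the same inputs.
#' @param gamma Main-effect bias vector.
#' @param theta Interaction matrix (or `NULL` for none).
#' @param effects Output of [effect_spec()].
#' @param trait,confounder Covariate vectors as in [true_abundances()].
#' @return List with `P` (`n` x `J` expected observed abundances, rows sum
#'   to 1), `log_norm` (length-`n` log normalizing denominators; the
#'   sample-specific normalization factor up to sign), and `eta` (the
#'   interaction-bias field).
#' @export
observed_abundances <- function(Pi0, Pi, gamma, theta, effects, trait,
                                confounder = NULL) {
  stopifnot(is.matrix(Pi0), all(dim(Pi0) == dim(Pi)),
            length(gamma) == ncol(Pi0))
  eta <- if (is.null(theta)) {
    matrix(0, nrow(Pi0), ncol(Pi0))
  } else {
    interaction_bias_field(theta, Pi)
  }
  logw <- sweep(eta, 2L, gamma, "+") + outer(trait, effects$beta1)
  if (!is.null(confounder)) {
    logw <- logw + outer(confounder, effects$beta2)
  }
  if (all(logw == 0)) {
    # no distortion at all: observed equals baseline bitwise
    return(list(P = Pi0, log_norm = rep(0, nrow(Pi0)), eta = eta))
  }
  w <- Pi0 * exp(logw)
  denom <- rowSums(w)
  list(P = w / denom, log_norm = log(denom), eta = eta)
}
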