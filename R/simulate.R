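# Replicate simulation: configuration object and the end-to-end generator.

#' Simulation configuration
#'
#' Collects all parameters of one simulation condition. Defaults reproduce
#' the reference study conditions: 856 taxa, 100 samples, binary trait,
#' main-effect bias sd 0.8, Dirichlet overdispersion 0.02, library sizes
#' N(10000, (10000/3)^2) truncated at 2000, and a heavy-tailed synthetic
#' mean-abundance profile whose top five entries are pinned to 0.105,
#' 0.062, 0.054, 0.050 and 0.049.
#'
#' @param J Number of taxa.
#' @param n Number of samples (even for binary traits).
#' @param trait_type `"binary"` or `"continuous"`.
#' @param confounded Include a binary confounder (binary traits only)?
#' @param scheme Causal-set scheme, `"M1"` or `"M2"` (see
#'   [select_causal_taxa()]).
#' @param beta Common trait log-fold effect on causal taxa.
#' @param beta_confounder Confounder effects (see [effect_spec()]).
#' @param sigma_gamma Main-effect bias sd; 0 disables main-effect bias.
#' @param phi Interaction-bias magnitude; 0 disables interactions.
#' @param scenario Interaction error scenario (see [draw_epsilon()]).
#' @param overdispersion Dirichlet overdispersion in (0, 1).
#' @param pi_bar Optional explicit mean-abundance vector (otherwise a
#'   synthetic profile is generated; see [synthesize_mean_abundances()]).
#' @param pinned_top Leading mean abundances for the synthetic profile.
#' @param lib_mean,lib_sd,lib_min Library-size model (see
#'   [draw_library_sizes()]).
#' @param causal_set,confounder_set Optional explicit taxon sets; when
#'   `NULL` they are drawn from the replicate's seed.
#' @param fixed_bias When `TRUE`, the bias structure (`gamma`, `epsilon`) is
#'   drawn from `bias_seed` instead of the replicate seed, holding it fixed
#'   across replicates.
#' @param bias_seed Integer seed for `fixed_bias` mode.
#' @param epsilon_normal_sd Half-scale normal sd of the interaction errors.
#' @param epsilon_beta_params Length-2 beta shapes of the interaction errors.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(J = 856L, n = 100L,
                       trait_type = c("binary", "continuous"),
                       confounded = FALSE,
                       scheme = c("M1", "M2"),
                       beta = 0, beta_confounder = NULL,
                       sigma_gamma = 0.8, phi = 0,
                       scenario = c("S-nondiff", "S-diff-causal",
                                    "S-diff-half"),
                       overdispersion = 0.02,
                       pi_bar = NULL,
                       pinned_top = c(0.105, 0.062, 0.054, 0.050, 0.049),
                       lib_mean = 10000, lib_sd = 10000 / 3,
                       lib_min = 2000,
                       causal_set = NULL, confounder_set = NULL,
                       fixed_bias = FALSE, bias_seed = NULL,
                       epsilon_normal_sd = 0.1,
                       epsilon_beta_params = c(0.5, 0.5)) {
  cfg <- list(J = as.integer(J), n = as.integer(n),
              trait_type = match.arg(trait_type),
              confounded = isTRUE(confounded),
              scheme = match.arg(scheme),
              beta = beta, beta_confounder = beta_confounder,
              sigma_gamma = sigma_gamma, phi = phi,
              scenario = match.arg(scenario),
              overdispersion = overdispersion,
              pi_bar = pi_bar, pinned_top = pinned_top,
              lib_mean = lib_mean, lib_sd = lib_sd, lib_min = lib_min,
              causal_set = causal_set, confounder_set = confounder_set,
              fixed_bias = isTRUE(fixed_bias), bias_seed = bias_seed,
              epsilon_normal_sd = epsilon_normal_sd,
              epsilon_beta_params = epsilon_beta_params)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (J < 2L) stop("`J` must be at least 2")
    if (n < 2L) stop("`n` must be at least 2")
    if (trait_type == "binary" && n %% 2L != 0L) {
      stop("`n` must be even for a binary trait")
    }
    if (trait_type == "continuous" && confounded) {
      stop("a confounder is only supported with a binary trait")
    }
    if (!is.finite(phi) || phi < 0) stop("`phi` must be non-negative")
    if (sigma_gamma < 0) stop("`sigma_gamma` must be non-negative")
    if (overdispersion <= 0 || overdispersion >= 1) {
      stop("`overdispersion` must lie strictly between 0 and 1")
    }
    if (lib_min <= 0 || lib_mean <= lib_min) {
      stop("library-size model requires 0 < lib_min < lib_mean")
    }
    if (!is.null(pi_bar) && length(pi_bar) != J) {
      stop("`pi_bar` must have length `J`")
    }
    if (fixed_bias && is.null(bias_seed)) {
      stop("`fixed_bias = TRUE` requires `bias_seed`")
    }
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration:\n")
  cat(sprintf("  J = %d taxa, n = %d samples, trait %s%s, scheme %s\n",
              x$J, x$n, x$trait_type,
              if (x$confounded) " + confounder" else "", x$scheme))
  cat(sprintf("  beta = %s, sigma_gamma = %s, phi = %s, scenario %s\n",
              format(x$beta), format(x$sigma_gamma), format(x$phi),
              x$scenario))
  invisible(x)
}

#' Simulate one replicate dataset
#'
#' Deterministic function of `(config, seed)`: generates the community
#' profile (unless supplied), the causal and confounder taxon sets (unless
#' supplied), baseline compositions, trait/confounder values, the bias
#' structure, expected observed abundances, library sizes and multinomial
#' read counts. Every component draws from its own sub-stream derived via
#' [mix_seed()], so e.g. changing the interaction scenario never perturbs
#' the baseline or trait draws.
#'
#' @param config A [sim_config()] (or a list coercible to one).
#' @param seed Integer replicate seed.
#' @return An object of class `sim_dataset` with elements `counts`, `Pi0`,
#'   `Pi`, `P`, `log_norm`, `eta`, `library_sizes`, `trait`, `confounder`,
#'   `causal_set`, `confounder_set`, `gamma`, `beta1`, `beta2`, `pi_bar`,
#'   `half_set`, `replicate_seed` and `config`.
#' @export
#' @examples
#' ds <- simulate_replicate(sim_config(J = 30, n = 20, beta = 1,
#'                                     scheme = "M2"), seed = 1)
#' rowSums(ds$counts)[1:3]
simulate_replicate <- function(config, seed) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  seed <- as.integer(seed)

  profile <- if (is.null(config$pi_bar)) {
    with_rng_seed(mix_seed(seed, "profile"),
                  synthesize_mean_abundances(config$J, config$pinned_top,
                                             config$overdispersion))
  } else {
    community_profile(config$pi_bar, config$overdispersion)
  }

  causal_set <- config$causal_set
  if (is.null(causal_set)) {
    causal_set <- with_rng_seed(mix_seed(seed, "causal"),
                                select_causal_taxa(profile, config$scheme))
  }
  confounder_set <- config$confounder_set
  if (config$confounded && is.null(confounder_set)) {
    null_pool <- setdiff(seq_len(config$J), causal_set)
    confounder_set <- with_rng_seed(
      mix_seed(seed, "confounder"),
      select_confounder_taxa(causal_set, null_pool, config$scheme))
  }

  effects <- effect_spec(config$J, causal_set, config$beta,
                         confounder_set %||% integer(0),
                         config$beta_confounder)

  # Bias structure: from the replicate seed by default, or from a dedicated
  # seed when the bias configuration is held fixed across replicates.
  bias_base <- if (config$fixed_bias) as.integer(config$bias_seed) else seed
  gamma <- with_rng_seed(mix_seed(bias_base, "gamma"),
                         draw_main_biases(config$J, config$sigma_gamma))
  half_set <- NULL
  if (config$scenario == "S-diff-half") {
    half_set <- with_rng_seed(mix_seed(seed, "half"),
                              sort(sample(config$J, config$J %/% 2L)))
  }
  theta <- NULL
  if (config$phi > 0) {
    eps <- draw_epsilon(config$J, config$scenario, causal_set, half_set,
                        normal_sd = config$epsilon_normal_sd,
                        beta_shape = config$epsilon_beta_params,
                        base_seed = mix_seed(bias_base, "epsilon"))
    theta <- build_interaction_matrix(gamma, config$phi, eps)
  }

  Pi0 <- with_rng_seed(mix_seed(seed, "baseline"),
                       draw_baseline_abundances(profile, config$n))
  tr <- with_rng_seed(mix_seed(seed, "traits"),
                      draw_traits(config$n, config$trait_type,
                                  config$confounded))
  Pi <- true_abundances(Pi0, effects, tr$trait, tr$confounder)
  obs <- observed_abundances(Pi0, Pi, gamma, theta, effects, tr$trait,
                             tr$confounder)
  libs <- with_rng_seed(mix_seed(seed, "libsize"),
                        draw_library_sizes(config$n, config$lib_mean,
                                           config$lib_sd, config$lib_min))
  counts <- with_rng_seed(mix_seed(seed, "counts"),
                          draw_counts(obs$P, libs))

  taxon_ids <- sprintf("T%04d", seq_len(config$J))
  sample_ids <- sprintf("S%04d", seq_len(config$n))
  dimnames(counts) <- list(sample_ids, taxon_ids)

  structure(list(counts = counts, Pi0 = Pi0, Pi = Pi, P = obs$P,
                 log_norm = obs$log_norm, eta = obs$eta,
                 library_sizes = libs, trait = tr$trait,
                 confounder = tr$confounder,
                 causal_set = as.integer(causal_set),
                 confounder_set = as.integer(confounder_set %||% integer(0)),
                 gamma = gamma, beta1 = effects$beta1,
                 beta2 = effects$beta2,
                 pi_bar = profile$pi_bar, half_set = half_set,
                 replicate_seed = seed, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d samples x %d taxa (seed %d)\n",
              nrow(x$counts), ncol(x$counts), x$replicate_seed))
  cat(sprintf("  causal taxa: %d, confounder-associated: %d\n",
              length(x$causal_set), length(x$confounder_set)))
  cat(sprintf("  library sizes: %d-%d, total reads %.0f\n",
              min(x$library_sizes), max(x$library_sizes), sum(x$counts)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
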