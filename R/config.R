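# YAML run configuration: simulation + grid parameters with defaults.

#' Default run configuration
#'
#' The full set of tunable parameters with their default (reference-study)
#' values: simulation parameters as in [sim_config()] plus grid-level
#' settings (`phi_values`, `beta_values`, `scenarios`, `replicates`,
#' `methods`, `level`, `presence_fraction`, `base_seed`).
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(J = 856L, n = 100L, trait_type = "binary", confounded = FALSE,
       scheme = "M1", beta = 0, beta_confounder = NULL,
       sigma_gamma = 0.8, phi = 0, scenario = "S-nondiff",
       overdispersion = 0.02,
       pinned_top = c(0.105, 0.062, 0.054, 0.050, 0.049),
       pi_bar = NULL, pi_bar_file = NULL,
       lib_mean = 10000, lib_sd = 10000 / 3, lib_min = 2000,
       epsilon_normal_sd = 0.1, epsilon_beta_params = c(0.5, 0.5),
       phi_values = c(0, 0.612, 1, 2, 4),
       beta_values = c(0, 0.25, 0.5, 1, 1.5, 2),
       scenarios = "S-nondiff", replicates = 200L,
       methods = "wilcox-alr-half", level = 0.2,
       presence_fraction = 0.2, base_seed = 1L)
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file of parameter overrides, merges it over
#' [default_config()], rejects unknown keys, and validates every
#' type-level invariant. An empty file yields the defaults. A
#' `pi_bar_file` key names a plain-text file with one mean relative
#' abundance per line, standing in for an empirical profile.
#'
#' @param path YAML file path.
#' @return A validated named list of parameters.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("configuration must be a YAML mapping")
  # YAML 1.1 reads a bare key `n` as boolean FALSE; restore it
  names(user)[names(user) == "FALSE"] <- "n"
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(user)] <- user
  if (!is.null(cfg$pi_bar_file)) {
    pi_bar <- scan(cfg$pi_bar_file, what = numeric(), quiet = TRUE)
    cfg$pi_bar <- pi_bar / sum(pi_bar)
    cfg$J <- length(pi_bar)
  }
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  # delegate the simulation-level invariants to sim_config()
  sim_config(J = cfg$J, n = cfg$n, trait_type = cfg$trait_type,
             confounded = cfg$confounded, scheme = cfg$scheme,
             beta = cfg$beta, beta_confounder = cfg$beta_confounder,
             sigma_gamma = cfg$sigma_gamma, phi = cfg$phi,
             scenario = cfg$scenario,
             overdispersion = cfg$overdispersion, pi_bar = cfg$pi_bar,
             pinned_top = cfg$pinned_top, lib_mean = cfg$lib_mean,
             lib_sd = cfg$lib_sd, lib_min = cfg$lib_min,
             epsilon_normal_sd = cfg$epsilon_normal_sd,
             epsilon_beta_params = cfg$epsilon_beta_params)
  if (any(cfg$phi_values < 0)) stop("`phi_values` must be non-negative")
  if (cfg$replicates < 1L) stop("`replicates` must be at least 1")
  if (cfg$level <= 0 || cfg$level > 1) stop("`level` must be in (0, 1]")
  if (cfg$presence_fraction <= 0 || cfg$presence_fraction > 1) {
    stop("`presence_fraction` must be in (0, 1]")
  }
  invisible(cfg)
}

#' Save a run configuration to YAML
#'
#' Inverse of [load_config()] up to default suppression: only keys are
#' written, so `load_config(save_config(cfg, f))` reproduces `cfg`.
#'
#' @param config Named list of parameters.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(Filter(Negate(is.null), config), path)
  invisible(path)
}
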