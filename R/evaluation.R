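# Replicate grids: empirical FDR and sensitivity across
# (scenario, phi, beta) cells, plus interaction-bias diagnostics.

utils::globalVariables(".data")  # tidy-eval pronoun used in plot_eval()

#' False discovery proportion and sensitivity of one detected set
#'
#' `fdp = |detected \ causal| / |detected|` (0 when nothing is detected);
#' `sensitivity = |detected intersect causal| / |causal|`, `NA` when there
#' are no causal taxa (the global null, where sensitivity is undefined).
#'
#' @param detected Detected taxon indices (subset of `tested`).
#' @param causal Truly causal taxon indices.
#' @param tested Tested taxon indices.
#' @return Named list with `fdp` and `sensitivity`.
#' @export
#' @examples
#' fdp_and_sensitivity(c(1, 2, 3), causal = 1, tested = 1:10)
fdp_and_sensitivity <- function(detected, causal, tested) {
  if (length(setdiff(detected, tested)) > 0L) {
    stop("`detected` must be a subset of `tested`")
  }
  fdp <- if (length(detected) == 0L) 0 else {
    length(setdiff(detected, causal)) / length(detected)
  }
  sens <- if (length(causal) == 0L) NA_real_ else {
    length(intersect(detected, causal)) / length(causal)
  }
  list(fdp = fdp, sensitivity = sens)
}

#' Experiment grid definition
#'
#' A grid of simulation cells (scenario x phi x beta) evaluated with one or
#' more registered methods over replicate datasets. The community profile
#' and, within each cell, the causal/confounder sets are held fixed across
#' replicates (drawn once from the cell seed), so FDR and sensitivity vary
#' only through sampling noise. Replicate `r` of a cell uses the seed
#' `mix_seed(cell_seed, "rep", r)` and can be regenerated in isolation.
#'
#' @param phi_values Interaction magnitudes (default `c(0, 0.612, 1, 2, 4)`).
#' @param beta_values Trait effect sizes; include 0 for the global null
#'   (default `c(0, 0.25, 0.5, 1, 1.5, 2)`).
#' @param scenarios Subset of the three interaction scenarios.
#' @param scheme Causal-set scheme, `"M1"` or `"M2"`.
#' @param replicates Replicates per cell (default desk-scale 200; the
#'   reference studies use 1000).
#' @param base_seed Integer master seed.
#' @param methods Registered method names (see [register_da_method()]).
#' @param level Nominal FDR level (default 0.20).
#' @param presence_fraction Rare-taxon filter passed to each method.
#' @param J,n,trait_type,confounded,sigma_gamma,overdispersion,pinned_top,pi_bar
#'   Simulation parameters shared by all cells (see [sim_config()]).
#' @param redraw_causal_per_replicate Redraw the causal set every replicate
#'   instead of once per cell?
#' @return An object of class `experiment_grid`.
#' @export
experiment_grid <- function(phi_values = c(0, 0.612, 1, 2, 4),
                            beta_values = c(0, 0.25, 0.5, 1, 1.5, 2),
                            scenarios = "S-nondiff",
                            scheme = c("M1", "M2"),
                            replicates = 200L, base_seed = 1L,
                            methods = "wilcox-alr-half",
                            level = 0.2, presence_fraction = 0.2,
                            J = 856L, n = 100L,
                            trait_type = "binary", confounded = FALSE,
                            sigma_gamma = 0.8, overdispersion = 0.02,
                            pinned_top = c(0.105, 0.062, 0.054, 0.050,
                                           0.049),
                            pi_bar = NULL,
                            redraw_causal_per_replicate = FALSE) {
  scheme <- match.arg(scheme)
  if (replicates < 1L) stop("`replicates` must be at least 1")
  if (any(phi_values < 0)) stop("`phi_values` must be non-negative")
  stopifnot(all(scenarios %in% c("S-nondiff", "S-diff-causal",
                                 "S-diff-half")))
  for (m in methods) get_da_method(m)  # fail fast on unknown methods
  structure(list(phi_values = phi_values, beta_values = beta_values,
                 scenarios = scenarios, scheme = scheme,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed), methods = methods,
                 level = level, presence_fraction = presence_fraction,
                 J = as.integer(J), n = as.integer(n),
                 trait_type = trait_type, confounded = confounded,
                 sigma_gamma = sigma_gamma,
                 overdispersion = overdispersion,
                 pinned_top = pinned_top, pi_bar = pi_bar,
                 redraw_causal_per_replicate =
                   isTRUE(redraw_causal_per_replicate)),
            class = "experiment_grid")
}

#' Run an experiment grid
#'
#' For every cell and replicate, simulates a dataset, applies every
#' requested method, and records the false discovery proportion and
#' sensitivity against the truly differential taxa (`beta1 != 0`; empty at
#' `beta = 0`). Empirical FDR is the mean FDP over replicates (FDP 0 when
#' nothing is detected); sensitivity is the mean per-replicate sensitivity,
#' `NA` for global-null cells. Method failures on individual replicates are
#' caught, counted and excluded.
#'
#' @param grid An [experiment_grid()].
#' @param verbose Print per-cell progress?
#' @return An object of class `eval_summary`: a long-format data frame with
#'   one row per (scenario, scheme, phi, beta, method) cell and columns
#'   `empirical_fdr`, `sensitivity`, `mean_detected`, `n_replicates_used`,
#'   `n_failed`, plus the grid as an attribute.
#' @export
run_grid <- function(grid, verbose = FALSE) {
  stopifnot(inherits(grid, "experiment_grid"))
  profile <- if (is.null(grid$pi_bar)) {
    with_rng_seed(mix_seed(grid$base_seed, "profile"),
                  synthesize_mean_abundances(grid$J, grid$pinned_top,
                                             grid$overdispersion))
  } else {
    community_profile(grid$pi_bar, grid$overdispersion)
  }
  cells <- expand.grid(scenario = grid$scenarios, phi = grid$phi_values,
                       beta = grid$beta_values,
                       stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells) * length(grid$methods))
  ri <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    cell_seed <- mix_seed(grid$base_seed, cell$scenario,
                          format(cell$phi, digits = 15),
                          format(cell$beta, digits = 15))
    causal_set <- NULL
    confounder_set <- NULL
    if (!grid$redraw_causal_per_replicate) {
      causal_set <- with_rng_seed(mix_seed(cell_seed, "causal"),
                                  select_causal_taxa(profile, grid$scheme))
      if (grid$confounded) {
        null_pool <- setdiff(seq_len(grid$J), causal_set)
        confounder_set <- with_rng_seed(
          mix_seed(cell_seed, "confounder"),
          select_confounder_taxa(causal_set, null_pool, grid$scheme))
      }
    }
    cfg <- sim_config(J = grid$J, n = grid$n,
                      trait_type = grid$trait_type,
                      confounded = grid$confounded, scheme = grid$scheme,
                      beta = cell$beta, sigma_gamma = grid$sigma_gamma,
                      phi = cell$phi, scenario = cell$scenario,
                      overdispersion = grid$overdispersion,
                      pi_bar = profile$pi_bar,
                      causal_set = causal_set,
                      confounder_set = confounder_set)
    stats_env <- lapply(grid$methods, function(m) {
      list(fdp = numeric(0), sens = numeric(0), det = numeric(0),
           failed = 0L)
    })
    names(stats_env) <- grid$methods
    for (r in seq_len(grid$replicates)) {
      ds <- simulate_replicate(cfg, mix_seed(cell_seed, "rep", r))
      truly_causal <- which(ds$beta1 != 0)
      for (m in grid$methods) {
        res <- tryCatch(get_da_method(m)(ds, grid$level,
                                         grid$presence_fraction),
                        error = function(e) e)
        if (inherits(res, "error")) {
          stats_env[[m]]$failed <- stats_env[[m]]$failed + 1L
          warning("method ", m, " failed on replicate ", r, " of cell ",
                  ci, ": ", conditionMessage(res), call. = FALSE)
          next
        }
        # sensitivity denominator is ALL truly causal taxa: a causal taxon
        # removed by the filter counts as missed
        fs <- fdp_and_sensitivity(res$detected, truly_causal,
                                  res$taxon_ids)
        stats_env[[m]]$fdp <- c(stats_env[[m]]$fdp, fs$fdp)
        stats_env[[m]]$sens <- c(stats_env[[m]]$sens, fs$sensitivity)
        stats_env[[m]]$det <- c(stats_env[[m]]$det, length(res$detected))
      }
    }
    for (m in grid$methods) {
      s <- stats_env[[m]]
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        scenario = cell$scenario, scheme = grid$scheme,
        phi = cell$phi, beta = cell$beta, method = m,
        filter = grid$presence_fraction, level = grid$level,
        empirical_fdr = if (length(s$fdp)) mean(s$fdp) else NA_real_,
        sensitivity = if (all(is.na(s$sens))) NA_real_ else
          mean(s$sens, na.rm = TRUE),
        mean_detected = if (length(s$det)) mean(s$det) else NA_real_,
        n_replicates_used = length(s$fdp), n_failed = s$failed,
        stringsAsFactors = FALSE)
    }
    if (verbose) {
      message(sprintf("cell %d/%d done (%s, phi=%g, beta=%g)", ci,
                      nrow(cells), cell$scenario, cell$phi, cell$beta))
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  attr(out, "grid") <- grid
  class(out) <- c("eval_summary", "data.frame")
  out
}

#' Flatten an evaluation summary to a plain long-format table
#'
#' Validates that rows are unique on (scenario, scheme, phi, beta, method,
#' filter) and returns a plain data frame suitable for writing to TSV.
#'
#' @param summary An `eval_summary` from [run_grid()].
#' @return A plain `data.frame`.
#' @export
summarize_to_table <- function(summary) {
  stopifnot(inherits(summary, "data.frame"), nrow(summary) >= 1L)
  key <- summary[, c("scenario", "scheme", "phi", "beta", "method",
                     "filter")]
  if (anyDuplicated(key)) stop("duplicate grid cells in summary")
  out <- as.data.frame(summary)
  attr(out, "grid") <- NULL
  class(out) <- "data.frame"
  out
}

#' Interaction-bias field diagnostics
#'
#' Pools the interaction-bias field `eta` over the samples of one or more
#' simulated datasets and summarizes it per taxon. The per-taxon mean is
#' expected to sit near zero (contributions of both signs average out),
#' while the variance grows with the main-effect bias magnitude `|gamma|`
#' at a given `phi`.
#'
#' @param datasets A `sim_dataset` or a list of them (generated with
#'   interactions on, and sharing a bias structure if `abs_gamma` is to be
#'   meaningful across datasets).
#' @return Data frame with columns `taxon`, `mean_eta`, `var_eta`,
#'   `abs_gamma`.
#' @export
eta_diagnostics <- function(datasets) {
  if (inherits(datasets, "sim_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L)
  eta <- do.call(rbind, lapply(datasets, `[[`, "eta"))
  abs_gamma <- rowMeans(vapply(datasets, function(d) abs(d$gamma),
                               numeric(ncol(eta))))
  data.frame(taxon = seq_len(ncol(eta)),
             mean_eta = colMeans(eta),
             var_eta = apply(eta, 2L, stats::var),
             abs_gamma = abs_gamma)
}

#' Plot an evaluation summary
#'
#' FDR and sensitivity against the effect size, one panel per interaction
#' magnitude, one line per method. Requires ggplot2.
#'
#' @param summary An `eval_summary` from [run_grid()].
#' @param metric `"empirical_fdr"` or `"sensitivity"`.
#' @return A ggplot object.
#' @export
plot_eval <- function(summary, metric = c("empirical_fdr",
                                          "sensitivity")) {
  metric <- match.arg(metric)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_eval() requires the ggplot2 package")
  }
  df <- summarize_to_table(summary)
  lv <- unique(df$level)[1L]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$beta,
                                        y = .data[[metric]],
                                        colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_grid(scenario ~ phi,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "effect size beta", y = metric) +
    ggplot2::theme_bw()
  if (metric == "empirical_fdr") {
    p <- p + ggplot2::geom_hline(yintercept = lv, linetype = "dotted")
  }
  p
}
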