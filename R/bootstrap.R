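#' Parametric bootstrap of a diversification statistic under a neutral
#' character model
#'
#' Fits an Mk2 model to the observed states, simulates `n_reps` neutral
#' binary characters on the fixed tree (root state fixed to the
#' reconstructed ancestral state, not resampled), evaluates a statistic on
#' each replicate, and returns the one-sided empirical p-value: the
#' proportion of simulated values greater than or equal to the observed
#' value. Replicates on which the statistic is undefined (e.g. a simulated
#' character with no informative richness contrasts) are dropped and
#' counted; more than 20% undefined aborts the run.
#'
#' Two rate presets mirror the two described uses: `"mk2-fitted"` simulates
#' at the free two-rate MLE (diversification-test nulls), and
#' `"mk2-equal-rates"` at the constrained equal-rate MLE (transition-rate
#' test nulls).
#'
#' @param tree a `phylo` object.
#' @param states tip states (data.frame or named vector; unknowns pruned).
#' @param statistic a function `(tree, tip_states) -> numeric scalar`; see
#'   [stat_macrocaic_F()], [stat_bisse_dll()], [stat_mk2_dll()],
#'   [stat_mk2_pp()].
#' @param n_reps number of simulated replicates (the reference analysis
#'   used 1000).
#' @param seed integer seed; replicate `i` uses stream `seed + i`, so
#'   results are independent of execution order.
#' @param rate_model `"mk2-fitted"` or `"mk2-equal-rates"`.
#' @param root_state root state for the simulations; default `NULL`
#'   reconstructs it (argmax marginal at the root under the fitted model).
#' @param add_one use the `(k + 1) / (n + 1)` corrected p-value instead of
#'   the plain proportion (recommended, but off by default to follow the
#'   reference procedure).
#' @param root_prior root prior for the Mk2 fit and reconstruction.
#' @param states_column column used when `states` is a data.frame.
#' @return an object of class `bootstrap_outcome`: list with `observed`,
#'   `null_values`, `p_value`, `n_reps`, `n_dropped`, `seed`,
#'   `statistic_name`, `rate_model`, `rates` (simulation rates), and
#'   `root_state`.
#' @export
parametric_bootstrap <- function(tree, states, statistic, n_reps = 1000L,
                                 seed = 1L,
                                 rate_model = c("mk2-fitted",
                                                "mk2-equal-rates"),
                                 root_state = NULL, add_one = FALSE,
                                 root_prior = "obs",
                                 states_column = "state") {
  rate_model <- match.arg(rate_model)
  if (is.data.frame(states)) {
    pk <- prune_to_known(tree, states, states_column)
    tree <- pk$tree
    states <- setNames(pk$tip_states, tree$tip.label)
  } else {
    states <- .resolve_states(tree, states, allow_unknown = TRUE)
    if (anyNA(states)) {
      keep <- tree$tip.label[!is.na(states)]
      tree <- prune_to_taxa(tree, keep)
      states <- setNames(states[!is.na(states)][match(tree$tip.label, keep)],
                         tree$tip.label)
    } else names(states) <- tree$tip.label
  }
  fit <- fit_mk2(tree, states, constrain_equal = rate_model == "mk2-equal-rates",
                 root_prior = root_prior)
  if (is.null(root_state)) {
    asr <- marginal_asr_mk2(tree, states, fit$model)
    root_state <- if (asr[1L, "p_TSD"] >= asr[1L, "p_GSD"]) 1L else 0L
  }
  observed <- statistic(tree, states)
  if (!is.finite(observed)) stop("statistic undefined on the observed data")
  null_values <- rep(NA_real_, n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(seed + i)
    sim <- simulate_binary_character(tree, fit$model$q_GT, fit$model$q_TG,
                                     root_state = root_state)
    v <- tryCatch(suppressWarnings(statistic(tree, sim$tip_states)),
                  error = function(e) NA_real_)
    null_values[i] <- if (is.null(v) || !is.finite(v)) NA_real_ else v
  }
  ok <- !is.na(null_values)
  if (sum(!ok) > 0.2 * n_reps)
    stop("statistic failed on ", sum(!ok), " of ", n_reps, " replicates")
  nv <- null_values[ok]
  p <- if (add_one) (1 + sum(nv >= observed)) / (1 + length(nv))
       else mean(nv >= observed)
  structure(list(observed = observed, null_values = null_values,
                 p_value = p, n_reps = n_reps, n_dropped = sum(!ok),
                 seed = seed,
                 statistic_name = attr(statistic, "name") %||% "statistic",
                 rate_model = rate_model,
                 rates = c(q_GT = fit$model$q_GT, q_TG = fit$model$q_TG),
                 root_state = root_state, add_one = add_one),
            class = "bootstrap_outcome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bootstrap statistic: MacroCAIC F
#'
#' @param richness tip richness table (or named vector); `NULL` = 1 per tip.
#' @param mns minimal clade size for a contrast to enter the regression.
#' @return a statistic function for [parametric_bootstrap()].
#' @export
stat_macrocaic_F <- function(richness = NULL, mns = 10L) {
  f <- function(tree, tip_states) {
    r <- macrocaic_regression(compute_contrasts(tree, tip_states, richness),
                              mns)
    if (!r$computable) return(NA_real_)
    r$F_stat
  }
  attr(f, "name") <- paste0("macrocaic-F-mns", mns)
  f
}

#' Bootstrap statistic: BiSSE diversification delta log-likelihood
#'
#' The first evaluation (the observed data) runs the full multi-start fit
#' and caches the null-model MLEs; later evaluations (the simulated
#' replicates, which share the tree) start the optimizer from those
#' estimates. The cache depends only on the observed data, so replicate
#' results remain independent of execution order.
#'
#' @param sampling_fraction sampling fraction passed to the BiSSE fits.
#' @param nstart,rtol,atol fitting controls for the replicate evaluations
#'   (see [fit_bisse_diversification_test()]).
#' @param ... further arguments to [fit_bisse_diversification_test()].
#' @return a statistic function for [parametric_bootstrap()].
#' @export
stat_bisse_dll <- function(sampling_fraction = 1, nstart = 0L,
                           rtol = 1e-7, atol = 1e-9, ...) {
  init <- NULL
  f <- function(tree, tip_states) {
    if (is.null(init)) {
      fit <- fit_bisse_diversification_test(tree, tip_states,
                                            sampling_fraction = sampling_fraction,
                                            nstart = 2L, rtol = rtol,
                                            atol = atol, ...)
      m <- fit$fit_null$model
      init <<- c(m$lambda_G, m$mu_G, m$q_GT, m$q_TG)
      return(fit$delta_ll)
    }
    fit_bisse_diversification_test(tree, tip_states,
                                   sampling_fraction = sampling_fraction,
                                   nstart = nstart, init = init,
                                   rtol = rtol, atol = atol, ...)$delta_ll
  }
  attr(f, "name") <- "bisse-dll"
  f
}

#' Bootstrap statistic: Mk2 asymmetry delta log-likelihood
#'
#' @param ... further arguments to [mk2_asymmetry_test()].
#' @return a statistic function for [parametric_bootstrap()].
#' @export
stat_mk2_dll <- function(...) {
  f <- function(tree, tip_states) {
    cmp <- mk2_asymmetry_test(tree, tip_states, ...)$comparison
    cmp$loglik_alt - cmp$loglik_null
  }
  attr(f, "name") <- "mk2-dll"
  f
}

#' Bootstrap statistic: Mk2 MCMC posterior probability that q_TG > q_GT
#'
#' The MCMC chain inside the statistic is seeded deterministically from the
#' enclosing bootstrap replicate's RNG stream.
#'
#' @param prior_mean,n_steps,burn_in MCMC settings (see [mk2_mcmc()]).
#' @return a statistic function for [parametric_bootstrap()].
#' @export
stat_mk2_pp <- function(prior_mean = 0.1, n_steps = 2000L, burn_in = 0.25) {
  f <- function(tree, tip_states) {
    tr <- mk2_mcmc(tree, tip_states, prior_mean = prior_mean,
                   n_steps = n_steps, burn_in = burn_in)
    posterior_prob_asymmetry(tr)$pp
  }
  attr(f, "name") <- "mk2-pp"
  f
}
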