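#' Run the full SDM macro-evolution pipeline
#'
#' Orchestrates the study-shaped analysis on one data set: prune to
#' known-state taxa, Mk2 transition-rate tests (ML + LRT, MCMC posterior
#' probability), BiSSE transition-rate test with sampling fraction,
#' marginal ancestral-state reconstruction, MacroCAIC richness contrasts
#' across MNS cutoffs with parametric-bootstrap p-values, the BiSSE
#' diversification test with its bootstrap p-value, and regime-dependent
#' lifespan models (BM1/BM2/OU1/OUM) over the reconstruction-painted tree.
#'
#' @param tree a `phylo` object, or path to a Newick file.
#' @param states tip-state data.frame (or path to a TSV).
#' @param lifespan optional tip-value data.frame of lifespans in years (or
#'   path); enables the trait-model stage.
#' @param richness optional tip richness table (or path); defaults to 1 per
#'   tip for MacroCAIC.
#' @param states_column `"state"` (primary) or `"alt_state"` (alternative
#'   SDM assignment).
#' @param sampling_fraction BiSSE skeletal-tree sampling fraction.
#' @param mns MNS cutoffs for MacroCAIC.
#' @param n_boot parametric-bootstrap replicates (reference setting: 1000).
#' @param mcmc_steps,mcmc_burn_in,mcmc_prior_mean MCMC settings (reference:
#'   2000 steps, 25% burn-in, exponential prior mean 0.1).
#' @param root_prior root prior for all likelihoods.
#' @param seed integer seed controlling the MCMC and all bootstrap streams.
#' @param outdir optional directory; when given, the result tables are
#'   written as TSV files together with a run log recording every setting.
#' @return list with elements `transition_rates` (one row per analysis:
#'   ML, MCMC, BiSSE, with rate estimates, significance and bootstrap p),
#'   `macrocaic` (one row per MNS cutoff), `diversification` (BiSSE test +
#'   bootstrap p), `asr` (node marginal tables plus root state),
#'   `trait_models` (per-model log-likelihoods, rates and optima plus the
#'   fits), `config`, and `n_tips_used`.
#' @export
run_pipeline <- function(tree, states, lifespan = NULL, richness = NULL,
                         states_column = "state", sampling_fraction = 1,
                         mns = c(10L, 20L, 30L, 40L), n_boot = 1000L,
                         mcmc_steps = 2000L, mcmc_burn_in = 0.25,
                         mcmc_prior_mean = 0.1, root_prior = "obs",
                         seed = 1L, outdir = NULL) {
  if (is.character(tree)) tree <- read_newick(file = tree)
  if (is.character(states)) states <- read_state_table(states)
  if (is.character(lifespan)) lifespan <- read_value_table(lifespan)
  if (is.character(richness)) richness <- read_value_table(richness,
                                                           integer = TRUE)
  config <- list(states_column = states_column,
                 sampling_fraction = sampling_fraction, mns = mns,
                 n_boot = n_boot, mcmc_steps = mcmc_steps,
                 mcmc_burn_in = mcmc_burn_in,
                 mcmc_prior_mean = mcmc_prior_mean, root_prior = root_prior,
                 seed = seed)
  pk <- prune_to_known(tree, states, states_column)
  tr <- pk$tree
  s <- setNames(pk$tip_states, tr$tip.label)

  # --- transition rates: ML + LRT, MCMC PP, BiSSE, with bootstrap p ------
  ml <- mk2_asymmetry_test(tr, s, root_prior = root_prior)
  trace <- mk2_mcmc(tr, s, prior_mean = mcmc_prior_mean, n_steps = mcmc_steps,
                    burn_in = mcmc_burn_in, seed = seed,
                    root_prior = root_prior)
  pp <- posterior_prob_asymmetry(trace)
  bt <- fit_bisse_transition_test(tr, s, sampling_fraction = sampling_fraction,
                                  root_prior = root_prior)
  boot_dll <- parametric_bootstrap(tr, s, stat_mk2_dll(root_prior = root_prior),
                                   n_reps = n_boot, seed = seed,
                                   rate_model = "mk2-equal-rates",
                                   root_prior = root_prior)
  boot_pp <- parametric_bootstrap(
    tr, s, stat_mk2_pp(prior_mean = mcmc_prior_mean,
                       n_steps = max(200L, mcmc_steps %/% 4L)),
    n_reps = max(20L, n_boot %/% 10L), seed = seed,
    rate_model = "mk2-equal-rates", root_prior = root_prior)
  transition_rates <- data.frame(
    analysis = c("Maximum likelihood", "MCMC", "BiSSE"),
    q_GT = c(ml$fit_free$model$q_GT, mean(trace$q_GT), bt$fit_free$model$q_GT),
    q_TG = c(ml$fit_free$model$q_TG, mean(trace$q_TG), bt$fit_free$model$q_TG),
    significance = c(ml$comparison$p_value, pp$pp, bt$comparison$p_value),
    simulation_p = c(boot_dll$p_value, boot_pp$p_value, NA_real_)
  )

  # --- ancestral states --------------------------------------------------
  asr <- marginal_asr_mk2(tr, s, ml$fit_free$model)
  root_state <- if (asr[1L, "p_TSD"] >= asr[1L, "p_GSD"]) 1L else 0L
  asr_bisse <- marginal_asr_bisse(tr, s, bt$fit_equal$model)

  # --- MacroCAIC + bootstrap p per MNS -----------------------------------
  mc <- macrocaic(tr, s, richness, mns = mns)
  mc$simulation_p <- NA_real_
  for (j in seq_along(mns)) {
    if (!is.na(mc$F_stat[j])) {
      b <- tryCatch(
        parametric_bootstrap(tr, s, stat_macrocaic_F(richness, mns[j]),
                             n_reps = n_boot, seed = seed + 1000L * j,
                             rate_model = "mk2-fitted",
                             root_state = root_state,
                             root_prior = root_prior),
        error = function(e) NULL)
      if (!is.null(b)) mc$simulation_p[j] <- b$p_value
    }
  }

  # --- BiSSE diversification test + bootstrap ----------------------------
  div <- fit_bisse_diversification_test(tr, s,
                                        sampling_fraction = sampling_fraction,
                                        root_prior = root_prior)
  boot_div <- tryCatch(
    parametric_bootstrap(tr, s, stat_bisse_dll(sampling_fraction),
                         n_reps = n_boot, seed = seed + 5000L,
                         rate_model = "mk2-fitted", root_state = root_state,
                         root_prior = root_prior),
    error = function(e) NULL)
  diversification <- list(test = div,
                          simulation_p = if (is.null(boot_div)) NA_real_
                                         else boot_div$p_value)

  # --- lifespan trait models over the painted tree -----------------------
  trait <- NULL
  if (!is.null(lifespan)) {
    have <- intersect(tr$tip.label, normalize_species_names(lifespan$species))
    if (length(have) >= 10L) {
      tr2 <- prune_to_taxa(tr, have)
      s2 <- s[tr2$tip.label]
      asr2 <- marginal_asr_mk2(tr2, s2, ml$fit_free$model)
      paint <- paint_regimes(asr2, s2, tr2)
      fits <- lapply(c("BM1", "BM2", "OU1", "OUM"), function(m)
        fit_trait_model(tr2, lifespan, paint, m, log_transform = TRUE))
      names(fits) <- c("BM1", "BM2", "OU1", "OUM")
      cmp <- compare_trait_models(fits$BM1, fits$BM2, fits$OU1, fits$OUM)
      trait <- list(
        fits = fits, comparison = cmp,
        table = data.frame(
          loglik_BM1 = fits$BM1$loglik, loglik_BM2 = fits$BM2$loglik,
          bm_p_value = cmp$lrt_bm$p_value,
          sigma2_GSD = fits$BM2$sigma2[["GSD"]],
          sigma2_TSD = fits$BM2$sigma2[["TSD"]],
          loglik_OU1 = fits$OU1$loglik, loglik_OUM = fits$OUM$loglik,
          ou_p_value = cmp$lrt_ou$p_value,
          optimum_GSD = exp(fits$OUM$theta[["GSD"]]),
          optimum_TSD = exp(fits$OUM$theta[["TSD"]])))
    }
  }

  out <- list(transition_rates = transition_rates, macrocaic = mc,
              diversification = diversification,
              asr = list(mk2 = asr, bisse = asr_bisse,
                         root_state = root_state,
                         root_state_label = .STATE_LEVELS[root_state + 1L]),
              trait_models = trait, config = config,
              n_tips_used = ape::Ntip(tr))
  if (!is.null(outdir)) .write_pipeline_outputs(out, outdir)
  out
}

.write_pipeline_outputs <- function(out, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stamp <- function(d) {
    d$seed <- out$config$seed
    d
  }
  write_table_tsv(stamp(out$transition_rates),
                  file.path(outdir, "transition_rates.tsv"))
  write_table_tsv(stamp(out$macrocaic), file.path(outdir, "macrocaic.tsv"))
  asr_tab <- data.frame(node = rownames(out$asr$mk2),
                        p_GSD = out$asr$mk2[, 1L], p_TSD = out$asr$mk2[, 2L])
  write_table_tsv(stamp(asr_tab), file.path(outdir, "asr_mk2.tsv"))
  if (!is.null(out$trait_models))
    write_table_tsv(stamp(out$trait_models$table),
                    file.path(outdir, "trait_models.tsv"))
  log <- c(
    "sdmdiv run log",
    paste0("n_tips_used: ", out$n_tips_used),
    paste0("root_state: ", out$asr$root_state_label),
    paste0("diversification_delta_ll: ",
           format(out$diversification$test$delta_ll)),
    paste0("diversification_simulation_p: ",
           format(out$diversification$simulation_p)),
    vapply(names(out$config), function(k)
      paste0(k, ": ", paste(format(out$config[[k]]), collapse = ",")),
      character(1L)))
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}
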