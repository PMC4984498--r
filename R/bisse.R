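#' Construct a BiSSE model
#'
#' Binary-state speciation and extinction model: state-dependent speciation
#' (`lambda`), extinction (`mu`) and transition (`q`) rates, plus per-state
#' sampling fractions for the skeletal-tree correction (the fraction of the
#' clade's species present in the tree; it enters through the initial
#' conditions of the extinction ODE).
#'
#' @param lambda_G,lambda_T speciation rates of GSD (state 0) and TSD
#'   (state 1) lineages.
#' @param mu_G,mu_T extinction rates.
#' @param q_GT,q_TG transition rates GSD -> TSD and TSD -> GSD.
#' @param f_G,f_T sampling fractions in (0, 1].
#' @param condition_on_survival condition the likelihood on survival of the
#'   two crown lineages (default `TRUE`, the convention of the software
#'   family this model comes from).
#' @param root_prior,root_state as in [mk2_model()].
#' @return an object of class `bisse_model`.
#' @export
bisse_model <- function(lambda_G, lambda_T, mu_G, mu_T, q_GT, q_TG,
                        f_G = 1, f_T = 1, condition_on_survival = TRUE,
                        root_prior = "obs", root_state = 1L) {
  pars <- c(lambda_G, lambda_T, mu_G, mu_T, q_GT, q_TG)
  stopifnot(all(is.finite(pars)), all(pars >= 0),
            f_G > 0, f_G <= 1, f_T > 0, f_T <= 1)
  structure(list(lambda_G = lambda_G, lambda_T = lambda_T,
                 mu_G = mu_G, mu_T = mu_T, q_GT = q_GT, q_TG = q_TG,
                 f_G = f_G, f_T = f_T,
                 condition_on_survival = isTRUE(condition_on_survival),
                 root_prior = match.arg(root_prior,
                   c("obs", "flat", "stationary", "fixed")),
                 root_state = as.integer(root_state)),
            class = "bisse_model")
}

.bisse_par_vec <- function(model) {
  c(model$lambda_G, model$lambda_T, model$mu_G, model$mu_T,
    model$q_GT, model$q_TG)
}

#' BiSSE log-likelihood
#'
#' Branch-wise numerical integration of the coupled extinction/data ODE
#' system (adaptive Dormand-Prince 5(4), rtol 1e-8 / atol 1e-10, extinction
#' probabilities clamped to `[0,1]` against round-off), with per-node
#' rescaling of the data partials and speciation-rate multiplication at
#' every internal node. The root combines the two state partials according
#' to the model's root prior; with `condition_on_survival` the likelihood is
#' divided by the prior-weighted `lambda (1 - E)^2` term.
#'
#' @param tree an ultrametric `phylo` object.
#' @param states tip states (data.frame or named vector), all known.
#' @param model a [bisse_model()].
#' @param rtol,atol relative/absolute tolerances of the adaptive ODE
#'   integrator.
#' @return the log-likelihood (scalar).
#' @export
bisse_loglik <- function(tree, states, model, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "bisse_model"))
  pr <- .tree_prep(tree)
  s <- .resolve_states(tree, states)
  s <- s[match(pr$tip.label, tree$tip.label)]
  ll <- .bisse_loglik_cpp(pr$edge, pr$el, pr$ntip, s, .bisse_par_vec(model),
                          model$f_G, model$f_T, model$condition_on_survival,
                          .root_prior_code(model$root_prior), model$root_state,
                          0L, 0L, rtol, atol)
  if (is.nan(ll)) stop("BiSSE ODE integration failed (non-finite values)")
  ll
}

# Generic multi-start ML driver over a log-parameterized BiSSE submodel.
# `build` maps the free log-parameter vector to the 6-vector
# (la0, la1, mu0, mu1, q01, q10).
.bisse_ml <- function(pr, s, build, starts, f, cond_surv, rp, root_state,
                      rtol = 1e-8, atol = 1e-10) {
  nll <- function(x) {
    p <- build(exp(x))
    v <- -.bisse_loglik_cpp(pr$edge, pr$el, pr$ntip, s, p, f[1L], f[2L],
                            cond_surv, rp, root_state, 0L, 0L, rtol, atol)
    if (!is.finite(v)) 1e10 else v
  }
  lb <- log(1e-9); ub <- log(20)
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- try(optim(pmin(pmax(log(starts[k, ]), lb), ub), nll,
                     method = "L-BFGS-B", lower = lb, upper = ub,
                     control = list(maxit = 500L, factr = 1e9)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("BiSSE optimization failed from every start")
  list(par = exp(best$par), loglik = -best$value,
       convergence = best$convergence)
}

# Data-driven starting values: Yule lambda, small mu, parsimony-ish q.
.bisse_starts <- function(pr, s, nstart = 2L) {
  la <- max((pr$ntip - 2) / sum(pr$el), 1e-4)
  q0 <- max(.fitch_changes(pr, s), 0.5) / sum(pr$el)
  out <- rbind(c(la, la / 20, q0, q0),
               c(la / 2, la / 4, q0 * 5, q0 * 5))
  out[seq_len(min(nstart, 2L)), , drop = FALSE]
}

#' BiSSE transition-rate asymmetry test
#'
#' Fits BiSSE with speciation and extinction rates constrained equal across
#' states (`lambda_G = lambda_T`, `mu_G = mu_T`) and compares free
#' transition rates against `q_GT = q_TG` with a one-df LRT, accounting for
#' the sampling fraction of species present in the tree (a single fraction
#' applied to both states).
#'
#' @inheritParams bisse_loglik
#' @param sampling_fraction fraction of the clade's species present in the
#'   tree, in (0, 1].
#' @param condition_on_survival,root_prior,root_state as in [bisse_model()].
#' @param states_column column used when `states` is a data.frame.
#' @param nstart number of optimizer starts (deterministic, data-driven).
#' @param rtol,atol ODE integrator tolerances used during fitting.
#' @return list with `fit_free`, `fit_equal` (each a [bisse_model()] plus
#'   `loglik`), and `comparison` from [lrt()].
#' @export
fit_bisse_transition_test <- function(tree, states, sampling_fraction = 1,
                                      condition_on_survival = TRUE,
                                      root_prior = "obs", root_state = 1L,
                                      states_column = "state", nstart = 2L,
                                      rtol = 1e-8, atol = 1e-10) {
  stopifnot(sampling_fraction > 0, sampling_fraction <= 1)
  if (is.data.frame(states)) {
    pk <- prune_to_known(tree, states, states_column)
    tree <- pk$tree; states <- pk$tip_states
  }
  pr <- .tree_prep(tree)
  s <- .resolve_states(tree, states)
  s <- s[match(pr$tip.label, tree$tip.label)]
  rp <- .root_prior_code(root_prior)
  f <- rep(sampling_fraction, 2L)
  st <- .bisse_starts(pr, s, nstart)
  # equal q first: (lambda, mu, q)
  st_eq <- cbind(st[, 1:2, drop = FALSE], sqrt(st[, 3L] * st[, 4L]))
  eq <- .bisse_ml(pr, s, function(p) c(p[1L], p[1L], p[2L], p[2L], p[3L], p[3L]),
                  st_eq, f, condition_on_survival, rp, root_state, rtol, atol)
  # free q: (lambda, mu, q01, q10), warm-started from the constrained optimum
  st_free <- rbind(c(eq$par[1:2], eq$par[3L], eq$par[3L]), st)
  free <- .bisse_ml(pr, s, function(p) c(p[1L], p[1L], p[2L], p[2L], p[3L], p[4L]),
                    st_free, f, condition_on_survival, rp, root_state,
                    rtol, atol)
  free$loglik <- max(free$loglik, eq$loglik)  # guard optimizer jitter
  mk_mod <- function(p) bisse_model(p[1L], p[2L], p[3L], p[4L], p[5L], p[6L],
                                    f[1L], f[2L], condition_on_survival,
                                    root_prior, root_state)
  list(
    fit_free = list(model = mk_mod(c(free$par[1L], free$par[1L], free$par[2L],
                                     free$par[2L], free$par[3L], free$par[4L])),
                    loglik = free$loglik, df = 4L),
    fit_equal = list(model = mk_mod(c(eq$par[1L], eq$par[1L], eq$par[2L],
                                      eq$par[2L], eq$par[3L], eq$par[3L])),
                     loglik = eq$loglik, df = 3L),
    comparison = lrt(eq$loglik, free$loglik, df = 1L)
  )
}

#' BiSSE state-dependent diversification test
#'
#' Compares a null model with state-independent speciation and extinction
#' (`lambda_G = lambda_T`, `mu_G = mu_T`, free transition rates) against an
#' alternative with state-dependent speciation (and optionally extinction).
#' The log-likelihood difference is the statistic fed to the parametric
#' bootstrap harness.
#'
#' @inheritParams fit_bisse_transition_test
#' @param free_mu also free the extinction rates in the alternative model
#'   (default `FALSE`: state-dependent speciation only, df = 1).
#' @param init optional extra starting point for the null optimization, as
#'   `c(lambda, mu, q_GT, q_TG)` (e.g. MLEs from a previous fit on the same
#'   tree); with `nstart = 0` it is the only start.
#' @param rtol,atol ODE integrator tolerances used during fitting.
#' @return list with `fit_null`, `fit_alt`, `delta_ll`
#'   (= loglik_alt - loglik_null), and `comparison` from [lrt()].
#' @export
fit_bisse_diversification_test <- function(tree, states, sampling_fraction = 1,
                                           free_mu = FALSE,
                                           condition_on_survival = TRUE,
                                           root_prior = "obs", root_state = 1L,
                                           states_column = "state",
                                           nstart = 2L, init = NULL,
                                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(sampling_fraction > 0, sampling_fraction <= 1)
  if (is.data.frame(states)) {
    pk <- prune_to_known(tree, states, states_column)
    tree <- pk$tree; states <- pk$tip_states
  }
  pr <- .tree_prep(tree)
  s <- .resolve_states(tree, states)
  s <- s[match(pr$tip.label, tree$tip.label)]
  rp <- .root_prior_code(root_prior)
  f <- rep(sampling_fraction, 2L)
  st <- .bisse_starts(pr, s, nstart)
  if (!is.null(init)) st <- rbind(matrix(init, nrow = 1L), st)
  if (nrow(st) == 0L) stop("no starting values: give `init` or nstart >= 1")
  null <- .bisse_ml(pr, s, function(p) c(p[1L], p[1L], p[2L], p[2L], p[3L], p[4L]),
                    st, f, condition_on_survival, rp, root_state, rtol, atol)
  if (free_mu) {
    st_alt <- rbind(
      c(null$par[1L], null$par[1L], null$par[2L], null$par[2L],
        null$par[3L], null$par[4L]),
      cbind(st[, 1L], st[, 1L], st[, 2L], st[, 2L], st[, 3L], st[, 4L]))
    alt <- .bisse_ml(pr, s, function(p) p, st_alt, f, condition_on_survival,
                     rp, root_state, rtol, atol)
    alt_par <- alt$par
    df_alt <- 6L
  } else {
    st_alt <- rbind(
      c(null$par[1L], null$par[1L], null$par[2L], null$par[3L], null$par[4L]),
      cbind(st[, 1L], st[, 1L], st[, 2L], st[, 3L], st[, 4L]))
    alt <- .bisse_ml(pr, s,
                     function(p) c(p[1L], p[2L], p[3L], p[3L], p[4L], p[5L]),
                     st_alt, f, condition_on_survival, rp, root_state,
                     rtol, atol)
    alt_par <- c(alt$par[1L], alt$par[2L], alt$par[3L], alt$par[3L],
                 alt$par[4L], alt$par[5L])
    df_alt <- 5L
  }
  mk_mod <- function(p) bisse_model(p[1L], p[2L], p[3L], p[4L], p[5L], p[6L],
                                    f[1L], f[2L], condition_on_survival,
                                    root_prior, root_state)
  ll_alt <- max(alt$loglik, null$loglik)  # guard optimizer jitter at nesting
  list(
    fit_null = list(model = mk_mod(c(null$par[1L], null$par[1L], null$par[2L],
                                     null$par[2L], null$par[3L], null$par[4L])),
                    loglik = null$loglik, df = 4L),
    fit_alt = list(model = mk_mod(alt_par), loglik = ll_alt, df = df_alt),
    delta_ll = ll_alt - null$loglik,
    comparison = lrt(null$loglik, ll_alt, df = df_alt - 4L)
  )
}

#' Marginal ancestral-state reconstruction under BiSSE
#'
#' Node marginals computed by clamping each internal node to each state and
#' recomputing the full BiSSE likelihood; rows are renormalized to sum
#' to 1. With state-independent speciation/extinction, vanishing extinction
#' and full sampling this converges to the Mk2 marginals.
#'
#' @inheritParams bisse_loglik
#' @return matrix as in [marginal_asr_mk2()].
#' @export
marginal_asr_bisse <- function(tree, states, model) {
  stopifnot(inherits(model, "bisse_model"))
  pr <- .tree_prep(tree)
  s <- .resolve_states(tree, states)
  s <- s[match(pr$tip.label, tree$tip.label)]
  m <- .bisse_marginal_cpp(pr$edge, pr$el, pr$ntip, s, .bisse_par_vec(model),
                           model$f_G, model$f_T, model$condition_on_survival,
                           .root_prior_code(model$root_prior),
                           model$root_state)
  dimnames(m) <- list(as.character(pr$ntip + seq_len(pr$ntip - 1L)),
                      c("p_GSD", "p_TSD"))
  m
}

#' Fit a pure-birth (Yule) model to a tree
#'
#' Closed-form maximum likelihood for the constant-rate pure-birth process
#' on a crown tree conditioned on survival of the two root lineages: the
#' log-likelihood kernel is `(n - 2) log(lambda) - lambda * X` with `X` the
#' sum of all branch lengths, maximized at `lambda = (n - 2) / X`. This is
#' the `mu = 0`, single-state, fully sampled limit of the BiSSE likelihood
#' used in this package.
#'
#' @param tree a `phylo` object.
#' @return list with `lambda`, `loglik` (kernel value at the MLE) and `n`.
#' @export
fit_yule <- function(tree) {
  n <- ape::Ntip(tree)
  X <- sum(tree$edge.length)
  lambda <- (n - 2) / X
  list(lambda = lambda, loglik = (n - 2) * log(lambda) - lambda * X, n = n)
}
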