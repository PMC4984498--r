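#' Construct a two-state Markov (Mk2) model
#'
#' @param q_GT transition rate GSD -> TSD (state 0 -> 1), per lineage per
#'   unit time.
#' @param q_TG transition rate TSD -> GSD (state 1 -> 0).
#' @param root_prior how the root state is handled in the likelihood:
#'   `"obs"` (weights proportional to each state's root partial likelihood,
#'   the FitzJohn weighting; default), `"flat"`, `"stationary"`, or
#'   `"fixed"` (see `root_state`).
#' @param root_state root state for `root_prior = "fixed"` (0 = GSD,
#'   1 = TSD).
#' @return an object of class `mk2_model`.
#' @export
mk2_model <- function(q_GT, q_TG, root_prior = "obs", root_state = 1L) {
  stopifnot(q_GT >= 0, q_TG >= 0, is.finite(q_GT), is.finite(q_TG))
  structure(list(q_GT = q_GT, q_TG = q_TG,
                 root_prior = match.arg(root_prior,
                   c("obs", "flat", "stationary", "fixed")),
                 root_state = as.integer(root_state)),
            class = "mk2_model")
}

# Postorder bundle consumed by the C++ pruning kernels.
.tree_prep <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  storage.mode(edge) <- "integer"
  list(edge = edge, el = tr$edge.length, ntip = ape::Ntip(tr),
       tip.label = tr$tip.label)
}

# States argument: tip-state data.frame, or named/plain vector along tips.
.resolve_states <- function(tree, states, column = "state",
                            allow_unknown = FALSE) {
  if (is.data.frame(states)) {
    s <- align_states(tree, states, column)
  } else if (!is.null(names(states))) {
    i <- match(normalize_species_names(tree$tip.label),
               normalize_species_names(names(states)))
    s <- as.integer(states)[i]
  } else {
    if (length(states) != ape::Ntip(tree))
      stop("unnamed state vector must have one entry per tip")
    s <- as.integer(states)
  }
  if (!allow_unknown && anyNA(s))
    stop("unknown tip states present; prune first (see prune_to_known)")
  if (any(!is.na(s) & !(s %in% 0:1))) stop("states must be 0, 1 or NA")
  s
}

#' Mk2 log-likelihood by Felsenstein pruning
#'
#' Closed-form 2x2 branch transition probabilities (no matrix exponential
#' needed for two states) combined tip-to-root, with per-node rescaling.
#'
#' @param tree a `phylo` object.
#' @param states tip states (tip-state data.frame or named vector;
#'   0 = GSD, 1 = TSD). All tips must have a known state.
#' @param model an [mk2_model()].
#' @return the log-likelihood (scalar).
#' @export
mk2_loglik <- function(tree, states, model) {
  stopifnot(inherits(model, "mk2_model"))
  pr <- .tree_prep(tree)
  s <- .resolve_states(tree, states)
  s <- s[match(pr$tip.label, tree$tip.label)]
  .mk2_loglik_cpp(pr$edge, pr$el, pr$ntip, s, model$q_GT, model$q_TG,
                  .root_prior_code(model$root_prior), model$root_state)
}

# Fitch parsimony change count: cheap data-driven optimizer start.
.fitch_changes <- function(pr, s) {
  nmax <- max(pr$edge)
  set <- matrix(FALSE, nmax, 2L)
  set[cbind(seq_len(pr$ntip), s + 1L)] <- TRUE
  seen <- logical(nmax)
  changes <- 0L
  for (i in seq_len(nrow(pr$edge))) {
    par <- pr$edge[i, 1L]; ch <- pr$edge[i, 2L]
    if (!seen[par]) {
      set[par, ] <- set[ch, ]
      seen[par] <- TRUE
    } else {
      inter <- set[par, ] & set[ch, ]
      if (any(inter)) set[par, ] <- inter
      else { set[par, ] <- set[par, ] | set[ch, ]; changes <- changes + 1L }
    }
  }
  changes
}

#' Fit the Mk2 model by maximum likelihood
#'
#' Bounded L-BFGS-B optimization on log rates with multiple starts: a fixed
#' log-spaced grid across `[1e-7, 10]` plus a parsimony-informed start
#' (Fitch change count divided by total branch length). The multi-start grid
#' is deterministic so fitting consumes no random numbers. Tips with unknown
#' state are pruned before fitting.
#'
#' @param tree a `phylo` object.
#' @param states tip states (data.frame or named vector; unknowns allowed,
#'   they are pruned).
#' @param constrain_equal force `q_GT = q_TG` (the null model of the
#'   asymmetry test).
#' @param root_prior,root_state as in [mk2_model()].
#' @param states_column `"state"` or `"alt_state"` when `states` is a
#'   data.frame.
#' @return list with `model` (the fitted [mk2_model()]), `loglik`, `df`
#'   (number of free rate parameters) and `convergence`.
#' @export
fit_mk2 <- function(tree, states, constrain_equal = FALSE,
                    root_prior = "obs", root_state = 1L,
                    states_column = "state") {
  if (is.data.frame(states)) {
    pk <- prune_to_known(tree, states, states_column)
    tree <- pk$tree; s_full <- pk$tip_states
  } else {
    s_full <- .resolve_states(tree, states, allow_unknown = TRUE)
    if (anyNA(s_full)) {
      keep <- tree$tip.label[!is.na(s_full)]
      tree <- prune_to_taxa(tree, keep)
      s_full <- s_full[!is.na(s_full)][match(tree$tip.label, keep)]
    }
  }
  if (min(table(factor(s_full, levels = 0:1))) < 2L)
    warning("fewer than 2 tips in one state; rate estimates may sit on a bound")
  pr <- .tree_prep(tree)
  s <- s_full[match(pr$tip.label, tree$tip.label)]
  rp <- .root_prior_code(root_prior)
  lb <- log(1e-9); ub <- log(10)
  nll <- if (constrain_equal) {
    function(x) {
      v <- -.mk2_loglik_cpp(pr$edge, pr$el, pr$ntip, s, exp(x[1L]), exp(x[1L]),
                            rp, root_state)
      if (!is.finite(v)) 1e10 else v
    }
  } else {
    function(x) {
      v <- -.mk2_loglik_cpp(pr$edge, pr$el, pr$ntip, s, exp(x[1L]), exp(x[2L]),
                            rp, root_state)
      if (!is.finite(v)) 1e10 else v
    }
  }
  grid <- log(c(1e-4, 1e-3, 1e-2, 1e-1, 1))
  q_pars <- max(.fitch_changes(pr, s), 0.5) / sum(pr$el)
  starts <- unique(c(log(min(max(q_pars, 1e-7), 10)), grid))
  npar <- if (constrain_equal) 1L else 2L
  best <- NULL
  for (st in starts) {
    fit <- try(optim(rep(st, npar), nll, method = "L-BFGS-B",
                     lower = lb, upper = ub,
                     control = list(maxit = 500L)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("Mk2 optimization failed from every start")
  q <- exp(best$par)
  if (constrain_equal) q <- c(q, q)
  list(model = mk2_model(q[1L], q[2L], root_prior, root_state),
       loglik = -best$value,
       df = npar,
       convergence = best$convergence)
}

#' Likelihood-ratio test of two nested models
#'
#' @param loglik_null,loglik_alt log-likelihoods of the nested (null) and
#'   nesting (alternative) model.
#' @param df difference in free parameters (>= 1).
#' @param tol tolerance by which `loglik_alt` may fall below `loglik_null`
#'   before the function errors (signals optimizer failure).
#' @return list with `loglik_null`, `loglik_alt`, `df`, `lrt_stat`
#'   (= 2 * deltaLL, truncated at 0), and `p_value` from the chi-square
#'   upper tail.
#' @export
lrt <- function(loglik_null, loglik_alt, df = 1L, tol = 1e-4) {
  if (df < 1L) stop("df must be >= 1")
  if (loglik_alt < loglik_null - tol)
    stop("alternative log-likelihood below null by more than `tol`: ",
         "optimizer failure?")
  stat <- max(0, 2 * (loglik_alt - loglik_null))
  list(loglik_null = loglik_null, loglik_alt = loglik_alt, df = as.integer(df),
       lrt_stat = stat, p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Mk2 transition-rate asymmetry test (ML + LRT)
#'
#' Fits the free two-rate and the constrained equal-rate Mk2 models and
#' compares them with a one-degree-of-freedom likelihood-ratio test.
#'
#' @inheritParams fit_mk2
#' @return list with `fit_free`, `fit_equal`, and `comparison` (from
#'   [lrt()]).
#' @export
mk2_asymmetry_test <- function(tree, states, root_prior = "obs",
                               root_state = 1L, states_column = "state") {
  free <- fit_mk2(tree, states, constrain_equal = FALSE,
                  root_prior = root_prior, root_state = root_state,
                  states_column = states_column)
  eq <- fit_mk2(tree, states, constrain_equal = TRUE,
                root_prior = root_prior, root_state = root_state,
                states_column = states_column)
  list(fit_free = free, fit_equal = eq,
       comparison = lrt(eq$loglik, free$loglik, df = 1L))
}

#' Posterior sampling of Mk2 transition rates by slice-sampling MCMC
#'
#' Samples `(q_GT, q_TG)` from the posterior proportional to the Mk2
#' likelihood times independent exponential priors. Each step updates the
#' two rates in a fixed scan order (`q_GT` then `q_TG`) with a univariate
#' slice sampler on the log-rate scale (step-out width 1.0); the exponential
#' prior and the log-scale Jacobian are part of the target.
#'
#' @inheritParams fit_mk2
#' @param prior_mean mean of the exponential prior on each rate (default
#'   0.1).
#' @param n_steps total MCMC steps (default 2000).
#' @param burn_in fraction of initial steps discarded (default 0.25).
#' @param seed optional integer seed.
#' @param init initial `(q_GT, q_TG)`; defaults to the prior mean.
#' @return a `data.frame` of retained samples (`q_GT`, `q_TG`, `loglik`)
#'   with attributes `prior_mean`, `n_steps`, `burn_in`, `seed`.
#' @export
mk2_mcmc <- function(tree, states, prior_mean = 0.1, n_steps = 2000L,
                     burn_in = 0.25, seed = NULL, root_prior = "obs",
                     root_state = 1L, states_column = "state",
                     init = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(states)) {
    pk <- prune_to_known(tree, states, states_column)
    tree <- pk$tree
    states <- pk$tip_states
  }
  pr <- .tree_prep(tree)
  s <- .resolve_states(tree, states)
  s <- s[match(pr$tip.label, tree$tip.label)]
  rp <- .root_prior_code(root_prior)
  rate <- 1 / prior_mean
  lb <- log(1e-10); ub <- log(100)
  logpost <- function(x) {
    if (any(x < lb) || any(x > ub)) return(-Inf)
    q <- exp(x)
    ll <- .mk2_loglik_cpp(pr$edge, pr$el, pr$ntip, s, q[1L], q[2L],
                          rp, root_state)
    if (!is.finite(ll)) return(-Inf)
    ll + sum(dexp(q, rate, log = TRUE)) + sum(x)
  }
  x <- log(if (is.null(init)) rep(prior_mean, 2L) else init)
  f <- logpost(x)
  w <- 1.0
  keep_from <- floor(n_steps * burn_in) + 1L
  out <- matrix(NA_real_, n_steps, 3L)
  for (step in seq_len(n_steps)) {
    for (j in 1:2) {
      y <- f - rexp(1L)
      L <- x; R <- x
      L[j] <- x[j] - w * runif(1L)
      R[j] <- L[j] + w
      m <- 0L
      while (logpost(L) > y && m < 50L) { L[j] <- L[j] - w; m <- m + 1L }
      m <- 0L
      while (logpost(R) > y && m < 50L) { R[j] <- R[j] + w; m <- m + 1L }
      repeat {
        xn <- x
        xn[j] <- runif(1L, L[j], R[j])
        fn <- logpost(xn)
        if (fn > y) { x <- xn; f <- fn; break }
        if (xn[j] < x[j]) L[j] <- xn[j] else R[j] <- xn[j]
        if (R[j] - L[j] < 1e-12) break
      }
    }
    out[step, ] <- c(exp(x), f - sum(dexp(exp(x), rate, log = TRUE)) - sum(x))
  }
  trace <- data.frame(q_GT = out[keep_from:n_steps, 1L],
                      q_TG = out[keep_from:n_steps, 2L],
                      loglik = out[keep_from:n_steps, 3L])
  attr(trace, "prior_mean") <- prior_mean
  attr(trace, "n_steps") <- n_steps
  attr(trace, "burn_in") <- burn_in
  attr(trace, "seed") <- seed
  class(trace) <- c("mk2_mcmc", "data.frame")
  trace
}

#' Posterior probability that q_TG exceeds q_GT
#'
#' The fraction of retained MCMC samples with `q_TG > q_GT`. Values above
#' 0.975 or below 0.025 flag a significant rate asymmetry.
#'
#' @param trace an MCMC trace from [mk2_mcmc()] (or any data.frame with
#'   columns `q_GT`, `q_TG`).
#' @return list with `pp` and `significant`.
#' @export
posterior_prob_asymmetry <- function(trace) {
  if (nrow(trace) == 0L) stop("empty MCMC trace")
  pp <- mean(trace$q_TG > trace$q_GT)
  list(pp = pp, significant = pp > 0.975 || pp < 0.025)
}

#' Marginal ancestral-state reconstruction under Mk2
#'
#' Per internal node, the marginal posterior probability of each state given
#' all tip data, computed by clamping the node to each state in turn and
#' re-running the pruning pass (exactly equivalent to the down-pass x
#' up-pass formulation, and exact).
#'
#' @inheritParams mk2_loglik
#' @return matrix with one row per internal node (rownames are ape node
#'   ids, the first row is the root) and columns `p_GSD`, `p_TSD`; rows sum
#'   to 1.
#' @export
marginal_asr_mk2 <- function(tree, states, model) {
  stopifnot(inherits(model, "mk2_model"))
  pr <- .tree_prep(tree)
  s <- .resolve_states(tree, states)
  s <- s[match(pr$tip.label, tree$tip.label)]
  m <- .mk2_marginal_cpp(pr$edge, pr$el, pr$ntip, s, model$q_GT, model$q_TG,
                         .root_prior_code(model$root_prior), model$root_state)
  dimnames(m) <- list(as.character(pr$ntip + seq_len(pr$ntip - 1L)),
                      c("p_GSD", "p_TSD"))
  m
}
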