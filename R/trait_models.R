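#' Paint tree branches with character-state regimes from an ancestral
#' reconstruction
#'
#' Each node takes the state with the larger marginal probability; exact
#' ties are broken toward the parent's regime (a root tie goes to TSD, the
#' ancestral state in the systems this package targets). Each branch then
#' carries the regime of its child node, so a regime shift is placed on the
#' branch along which the reconstruction changes state.
#'
#' @param asr marginal reconstruction matrix from [marginal_asr_mk2()] or
#'   [marginal_asr_bisse()] (rows = internal nodes in ape id order).
#' @param states tip states (data.frame or named vector), all known.
#' @param tree the `phylo` object the reconstruction was computed on.
#' @return an object of class `regime_painting`: list with `node_regime`
#'   (integer regime per node id, tips included) and `provenance`.
#' @export
paint_regimes <- function(asr, states, tree) {
  pr <- .tree_prep(tree)
  s <- .resolve_states(tree, states)
  s <- s[match(pr$tip.label, tree$tip.label)]
  ntip <- pr$ntip
  nmax <- max(pr$edge)
  if (nrow(asr) != ntip - 1L)
    stop("reconstruction does not cover every internal node")
  node_regime <- rep(NA_integer_, nmax)
  node_regime[seq_len(ntip)] <- s
  p_tsd <- asr[, "p_TSD"]
  root <- pr$edge[nrow(pr$edge), 1L]
  tie <- abs(p_tsd - 0.5) < 1e-12
  node_regime[root] <- if (tie[1L]) 1L else as.integer(p_tsd[1L] > 0.5)
  # preorder: parents before children, so parent regime is known at a tie
  for (i in rev(seq_len(nrow(pr$edge)))) {
    ch <- pr$edge[i, 2L]
    if (ch <= ntip) next
    k <- ch - ntip
    node_regime[ch] <- if (tie[k]) node_regime[pr$edge[i, 1L]]
                       else as.integer(p_tsd[k] > 0.5)
  }
  structure(list(node_regime = node_regime, provenance = "asr-max-marginal"),
            class = "regime_painting")
}

# ---------------------------------------------------------------------------
# Shared machinery: regime-split shared-path matrices V_G / V_T, node depths,
# and root-to-tip regime weight functions for the OU mean.
# ---------------------------------------------------------------------------
.trait_struct <- function(tree, painting = NULL) {
  pr <- .tree_prep(tree)
  ntip <- pr$ntip
  nmax <- max(pr$edge)
  depth <- node_depths(tree)
  # depth is indexed by ape node id; ids agree across reorderings
  Tbar <- mean(depth[seq_len(ntip)])
  edge_regime <- if (is.null(painting)) rep(0L, nrow(pr$edge))
                 else painting$node_regime[pr$edge[, 2L]]
  root <- pr$edge[nrow(pr$edge), 1L]
  root_regime <- if (is.null(painting)) 0L else painting$node_regime[root]
  # descendant tips per node (postorder accumulation)
  desc <- vector("list", nmax)
  for (i in seq_len(ntip)) desc[[i]] <- i
  V <- array(0, c(ntip, ntip, 2L))
  for (i in seq_len(nrow(pr$edge))) {
    par <- pr$edge[i, 1L]; ch <- pr$edge[i, 2L]
    tips <- desc[[ch]]
    V[tips, tips, edge_regime[i] + 1L] <-
      V[tips, tips, edge_regime[i] + 1L] + pr$el[i]
    desc[[par]] <- c(desc[[par]], tips)
  }
  parent <- integer(nmax)
  edge_of <- integer(nmax)
  for (i in seq_len(nrow(pr$edge))) {
    parent[pr$edge[i, 2L]] <- pr$edge[i, 1L]
    edge_of[pr$edge[i, 2L]] <- i
  }
  list(pr = pr, ntip = ntip, depth = depth, T = Tbar,
       V_G = V[, , 1L], V_T = V[, , 2L],
       edge_regime = edge_regime, root = root, root_regime = root_regime,
       parent = parent, edge_of = edge_of,
       tip.label = pr$tip.label)
}

# OU regime-weight design matrix at pull strength alpha: row i gives the
# weight of each regime's optimum in E[y_i]; rows sum to 1 (the root term
# exp(-alpha T) is assigned to the root regime).
.ou_weights <- function(st, alpha) {
  n <- st$ntip
  W <- matrix(0, n, 2L)
  Tt <- st$T
  for (i in seq_len(n)) {
    node <- i
    while (node != st$root) {
      e <- st$edge_of[node]
      t1 <- st$depth[node]
      t0 <- st$depth[st$parent[node]]
      W[i, st$edge_regime[e] + 1L] <- W[i, st$edge_regime[e] + 1L] +
        exp(-alpha * (Tt - t1)) - exp(-alpha * (Tt - t0))
      node <- st$parent[node]
    }
    W[i, st$root_regime + 1L] <- W[i, st$root_regime + 1L] + exp(-alpha * Tt)
  }
  W
}

# OU covariance kernel (unit sigma2), fixed root value:
# C_ij = exp(-alpha d_ij) (1 - exp(-2 alpha t_mrca)) / (2 alpha).
.ou_kernel <- function(st, alpha) {
  ta <- st$V_G + st$V_T                      # shared path length = mrca depth
  d <- 2 * (st$T - ta)
  diag(d) <- 0
  exp(-alpha * d) * (-expm1(-2 * alpha * ta)) / (2 * alpha)
}

# Profiled Gaussian log-likelihood: y ~ N(X beta, sigma2 * C) with beta and
# sigma2 at their conditional ML. Returns loglik and the profiled estimates.
.gls_profile <- function(y, X, C) {
  n <- length(y)
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) return(list(loglik = -Inf))
  logdet <- 2 * sum(log(diag(R)))
  Xi <- backsolve(R, X, transpose = TRUE)
  yi <- backsolve(R, y, transpose = TRUE)
  XtX <- crossprod(Xi)
  beta <- tryCatch(solve(XtX, crossprod(Xi, yi)), error = function(e) NULL)
  if (is.null(beta)) return(list(loglik = -Inf))
  r <- yi - Xi %*% beta
  s2 <- sum(r^2) / n
  if (s2 <= 0) return(list(loglik = -Inf))
  ll <- -0.5 * (n * log(2 * pi * s2) + logdet + n)
  list(loglik = ll, beta = drop(beta), sigma2 = s2)
}

.resolve_values <- function(tree, values, log_transform = FALSE) {
  if (is.data.frame(values)) {
    i <- match(normalize_species_names(tree$tip.label),
               normalize_species_names(values$species))
    if (anyNA(i)) stop("values missing for some tips")
    v <- values$value[i]
  } else {
    i <- match(normalize_species_names(tree$tip.label),
               normalize_species_names(names(values)))
    if (anyNA(i)) stop("values missing for some tips")
    v <- as.numeric(values)[i]
  }
  if (log_transform) {
    if (any(v <= 0)) stop("cannot log-transform non-positive values")
    v <- log(v)
  }
  setNames(v, tree$tip.label)
}

#' Fit a regime-dependent model of continuous trait evolution
#'
#' Exact Gaussian likelihoods over the tip covariance implied by the painted
#' tree:
#'
#' * `BM1` -- single-rate Brownian motion (free root value, one rate);
#' * `BM2` -- Brownian motion with a separate rate per regime;
#' * `OU1` -- single-optimum Ornstein-Uhlenbeck (fixed-root covariance,
#'   shared pull `alpha` and rate `sigma2`);
#' * `OUM` -- OU with a distinct optimum per regime, shared `alpha` and
#'   `sigma2`; tip expectations weight each optimum by the regime history
#'   along the root-to-tip path (exponential decay), with the root's weight
#'   assigned to the root regime's optimum.
#'
#' The root value and `sigma2` (and the optima) are profiled analytically;
#' only the BM2 rate ratio and the OU pull strength are optimized
#' numerically (coarse log-grid then local refinement). The trait is
#' assumed already on log scale unless `log_transform = TRUE`.
#'
#' @param tree an ultrametric `phylo` object (required for OU models).
#' @param values tip values (data.frame `species`/`value` or named vector).
#' @param painting a [paint_regimes()] object (required for BM2/OUM).
#' @param model one of `"BM1"`, `"BM2"`, `"OU1"`, `"OUM"`.
#' @param log_transform natural-log-transform the values first (use for
#'   lifespans in years).
#' @return an object of class `trait_model_fit`: list with `model`,
#'   `sigma2` (named per regime where applicable), `alpha`, `theta`
#'   (optima, input scale), `root_value`, `loglik`, `k`, `AIC`, `n`, and a
#'   data `fingerprint` used by [compare_trait_models()].
#' @export
fit_trait_model <- function(tree, values, painting = NULL,
                            model = c("BM1", "BM2", "OU1", "OUM"),
                            log_transform = FALSE) {
  model <- match.arg(model)
  if (model %in% c("BM2", "OUM") && is.null(painting))
    stop("two-regime models need a `painting`")
  if (model %in% c("OU1", "OUM") && !validate_ultrametric(tree, 1e-6)$ok)
    stop("OU models require an ultrametric tree")
  y <- .resolve_values(tree, values, log_transform)
  st <- .trait_struct(tree, painting)
  y <- y[st$tip.label]
  n <- st$ntip
  V <- st$V_G + st$V_T
  one <- matrix(1, n, 1L)
  out <- switch(model,
    BM1 = {
      g <- .gls_profile(y, one, V)
      list(sigma2 = g$sigma2, alpha = NA_real_, theta = NA_real_,
           root_value = g$beta, loglik = g$loglik, k = 2L)
    },
    BM2 = {
      obj <- function(rho) -.gls_profile(y, one, st$V_G + exp(rho) * st$V_T)$loglik
      grid <- seq(-8, 8, length.out = 17L)
      vals <- vapply(grid, obj, 0)
      i <- which.min(vals)
      o <- optimize(obj, c(grid[max(1L, i - 1L)], grid[min(17L, i + 1L)]))
      rho <- o$minimum
      g <- .gls_profile(y, one, st$V_G + exp(rho) * st$V_T)
      list(sigma2 = c(GSD = g$sigma2, TSD = g$sigma2 * exp(rho)),
           alpha = NA_real_, theta = NA_real_, root_value = g$beta,
           loglik = g$loglik, k = 3L)
    },
    OU1 = .fit_ou(y, st, two_theta = FALSE),
    OUM = .fit_ou(y, st, two_theta = TRUE)
  )
  structure(c(list(model = model), out,
              list(AIC = 2 * out$k - 2 * out$loglik, n = n,
                   fingerprint = c(n, sum(y), sum(y^2)))),
            class = "trait_model_fit")
}

.fit_ou <- function(y, st, two_theta) {
  n <- st$ntip
  ll_at <- function(la) {
    a <- exp(la)
    X <- if (two_theta) .ou_weights(st, a) else matrix(1, n, 1L)
    if (two_theta && any(colSums(abs(X)) < 1e-10))
      X <- X[, colSums(abs(X)) >= 1e-10, drop = FALSE]  # single-regime tree
    .gls_profile(y, X, .ou_kernel(st, a))
  }
  lo <- log(1e-3 / st$T); hi <- log(50 / st$T)
  grid <- seq(lo, hi, length.out = 21L)
  vals <- vapply(grid, function(la) -ll_at(la)$loglik, 0)
  i <- which.min(vals)
  o <- optimize(function(la) -ll_at(la)$loglik,
                c(grid[max(1L, i - 1L)], grid[min(21L, i + 1L)]))
  a <- exp(o$minimum)
  g <- ll_at(o$minimum)
  theta <- if (two_theta) {
    th <- g$beta
    if (length(th) == 1L) th <- rep(th, 2L)
    c(GSD = th[1L], TSD = th[2L])
  } else c(optimum = unname(g$beta))
  list(sigma2 = g$sigma2, alpha = a, theta = theta,
       root_value = unname(theta[st$root_regime + 1L]),
       loglik = g$loglik, k = if (two_theta) 4L else 3L)
}

#' Evaluate a regime trait model's log-likelihood at given parameters
#'
#' Direct evaluation (no fitting); used for nesting identities and limit
#' checks.
#'
#' @inheritParams fit_trait_model
#' @param pars list with `sigma2` (length 1 or 2 as c(GSD, TSD)), and for
#'   OU models `alpha` and `theta` (length 1 or 2), and for BM models
#'   `root_value`.
#' @return the log-likelihood.
#' @export
trait_model_loglik <- function(tree, values, painting = NULL,
                               model = c("BM1", "BM2", "OU1", "OUM"),
                               pars, log_transform = FALSE) {
  model <- match.arg(model)
  y <- .resolve_values(tree, values, log_transform)
  st <- .trait_struct(tree, painting)
  y <- y[st$tip.label]
  n <- st$ntip
  if (model %in% c("BM1", "BM2")) {
    s2 <- rep_len(pars$sigma2, 2L)
    C <- s2[1L] * st$V_G + s2[2L] * st$V_T
    mu <- rep(pars$root_value, n)
  } else {
    a <- pars$alpha
    theta <- rep_len(pars$theta, 2L)
    C <- pars$sigma2 * .ou_kernel(st, a)
    W <- .ou_weights(st, a)
    mu <- drop(W %*% theta)
  }
  R <- chol(C)
  r <- backsolve(R, y - mu, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(r^2))
}

#' Compare the four trait models
#'
#' Likelihood-ratio tests of the two nested pairs (BM1 vs BM2 and OU1 vs
#' OUM, one df each) and an AIC ranking across all four fits, which must
#' come from identical data.
#'
#' @param bm1,bm2,ou1,oum fits from [fit_trait_model()].
#' @return list with `lrt_bm`, `lrt_ou` (from [lrt()]), `aic` (data.frame
#'   ranked by AIC), and `best` (model name with the lowest AIC).
#' @export
compare_trait_models <- function(bm1, bm2, ou1, oum) {
  fits <- list(BM1 = bm1, BM2 = bm2, OU1 = ou1, OUM = oum)
  for (nm in names(fits))
    if (fits[[nm]]$model != nm) stop("fit order must be BM1, BM2, OU1, OUM")
  fp <- vapply(fits, function(f) f$fingerprint, numeric(3L))
  if (max(abs(fp - fp[, 1L])) > 1e-8)
    stop("fits were not computed on identical data")
  aic <- data.frame(model = names(fits),
                    loglik = vapply(fits, function(f) f$loglik, 0),
                    k = vapply(fits, function(f) f$k, 0L),
                    AIC = vapply(fits, function(f) f$AIC, 0))
  aic <- aic[order(aic$AIC), ]
  aic$delta_aic <- aic$AIC - aic$AIC[1L]
  list(lrt_bm = lrt(bm1$loglik, bm2$loglik, df = 1L, tol = 1e-3),
       lrt_ou = lrt(ou1$loglik, oum$loglik, df = 1L, tol = 1e-3),
       aic = aic, best = aic$model[1L])
}
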