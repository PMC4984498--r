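#' Species-richness contrasts for a binary predictor (MacroCAIC)
#'
#' At every internal node whose daughter clades differ in (reconstructed)
#' predictor value, computes a richness response contrast -- the log ratio
#' of summed clade richness, oriented toward the daughter with the higher
#' predictor value -- and the standard phylogenetically independent contrast
#' of the predictor. Internal predictor values and branch-length adjustments
#' follow the Felsenstein contrasts down-pass.
#'
#' @param tree a `phylo` object.
#' @param states tip states (data.frame or named vector), all known; the
#'   binary predictor (0 = GSD, 1 = TSD).
#' @param richness optional tip-value data.frame (or named vector) of clade
#'   richness counts per tip; defaults to 1 per tip (tip counts of the tree
#'   itself).
#' @return a `data.frame` with one row per internal node: `node`, daughter
#'   clade sizes `n1`/`n2` (richness-weighted), `clade_size` (their sum),
#'   `predictor_contrast` (>= 0 by orientation), `response_contrast`
#'   (`log(N_hi / N_lo)`), `informative` (daughters differ in predictor),
#'   and MNS eligibility flags `mns10`, `mns20`, `mns30`, `mns40`.
#' @export
compute_contrasts <- function(tree, states, richness = NULL) {
  pr <- .tree_prep(tree)
  s <- .resolve_states(tree, states)
  s <- s[match(pr$tip.label, tree$tip.label)]
  ntip <- pr$ntip
  rich <- rep(1, ntip)
  if (!is.null(richness)) {
    if (is.data.frame(richness)) {
      i <- match(normalize_species_names(pr$tip.label),
                 normalize_species_names(richness$species))
      if (anyNA(i)) stop("richness missing for some tips")
      rich <- richness$value[i]
    } else {
      i <- match(normalize_species_names(pr$tip.label),
                 normalize_species_names(names(richness)))
      if (anyNA(i)) stop("richness missing for some tips")
      rich <- as.numeric(richness)[i]
    }
  }
  if (any(rich <= 0)) stop("richness must be strictly positive")
  nmax <- max(pr$edge)
  x <- numeric(nmax); x[seq_len(ntip)] <- s
  vadj <- numeric(nmax)                 # accumulated contrast variance
  N <- numeric(nmax); N[seq_len(ntip)] <- rich
  ch_val <- matrix(NA_real_, nmax, 2L)  # per-parent daughter summaries
  ch_v <- matrix(NA_real_, nmax, 2L)
  ch_N <- matrix(NA_real_, nmax, 2L)
  ch_n <- integer(nmax)
  for (i in seq_len(nrow(pr$edge))) {
    par <- pr$edge[i, 1L]; ch <- pr$edge[i, 2L]
    k <- ch_n[par] + 1L
    ch_val[par, k] <- x[ch]
    ch_v[par, k] <- pr$el[i] + vadj[ch]
    ch_N[par, k] <- N[ch]
    ch_n[par] <- k
    if (k == 2L) {  # both daughters seen: finalize the node
      va <- ch_v[par, 1L]; vb <- ch_v[par, 2L]
      if (va + vb > 0) {
        x[par] <- (ch_val[par, 1L] / va + ch_val[par, 2L] / vb) /
                  (1 / va + 1 / vb)
        vadj[par] <- va * vb / (va + vb)
      } else {  # zero-length resolution: equal weights, no extra variance
        x[par] <- mean(ch_val[par, 1:2])
        vadj[par] <- 0
      }
      N[par] <- sum(ch_N[par, 1:2])
    }
  }
  nodes <- (ntip + 1L):nmax
  out <- data.frame(node = nodes, n1 = ch_N[nodes, 1L], n2 = ch_N[nodes, 2L])
  out$clade_size <- out$n1 + out$n2
  dx <- ch_val[nodes, 1L] - ch_val[nodes, 2L]
  vsum <- ch_v[nodes, 1L] + ch_v[nodes, 2L]
  hi_first <- dx >= 0
  n_hi <- ifelse(hi_first, out$n1, out$n2)
  n_lo <- ifelse(hi_first, out$n2, out$n1)
  out$predictor_contrast <- abs(dx) / sqrt(pmax(vsum, .Machine$double.eps))
  out$response_contrast <- log(n_hi / n_lo)
  out$informative <- abs(dx) > 1e-12
  for (m in c(10L, 20L, 30L, 40L))
    out[[paste0("mns", m)]] <- out$clade_size >= m
  out
}

#' Through-origin regression of richness contrasts on predictor contrasts
#'
#' Ordinary least squares through the origin (the contrast convention: the
#' orientation of each contrast is arbitrary, so the fit must be invariant
#' to sign flips) of the response contrasts on the predictor contrasts,
#' restricted to informative contrasts whose clade holds at least `mns`
#' species. The F statistic of this regression feeds the parametric
#' bootstrap harness. With k contrasts the F test has (1, k - 1) degrees of
#' freedom.
#'
#' @param contrasts a contrast table from [compute_contrasts()].
#' @param mns minimal number of species a node's clade must contain.
#' @param through_origin set `FALSE` for an intercept model (non-standard;
#'   for diagnostics only).
#' @return list with `computable`, `n` (contrasts used), `r2` (adjusted
#'   R-squared, as conventionally reported for this method), `slope`,
#'   `F_stat`, `p_value`.
#' @export
macrocaic_regression <- function(contrasts, mns = 10L, through_origin = TRUE) {
  d <- contrasts[contrasts$informative & contrasts$clade_size >= mns &
                 is.finite(contrasts$predictor_contrast) &
                 is.finite(contrasts$response_contrast), , drop = FALSE]
  if (nrow(d) < 2L) {
    return(list(computable = FALSE, n = nrow(d), r2 = NA_real_,
                slope = NA_real_, F_stat = NA_real_, p_value = NA_real_))
  }
  fit <- if (through_origin) {
    lm(response_contrast ~ 0 + predictor_contrast, data = d)
  } else {
    lm(response_contrast ~ predictor_contrast, data = d)
  }
  sm <- summary(fit)
  fs <- sm$fstatistic
  list(computable = TRUE, n = nrow(d), r2 = sm$adj.r.squared,
       slope = unname(coef(fit)[["predictor_contrast"]]),
       F_stat = unname(fs[1L]),
       p_value = unname(pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE)))
}

#' MacroCAIC analysis across MNS cutoffs
#'
#' Convenience wrapper: computes the contrast table once (pruning to
#' known-state tips) and fits the through-origin regression at each minimal
#' clade size cutoff.
#'
#' @inheritParams compute_contrasts
#' @param mns integer vector of MNS cutoffs (default `c(10, 20, 30, 40)`).
#' @param states_column column used when `states` is a data.frame.
#' @return a `data.frame` with columns `mns`, `n`, `r2`, `slope`, `F_stat`,
#'   `p_value`.
#' @export
macrocaic <- function(tree, states, richness = NULL,
                      mns = c(10L, 20L, 30L, 40L), states_column = "state") {
  if (is.data.frame(states)) {
    pk <- prune_to_known(tree, states, states_column)
    tree <- pk$tree; states <- pk$tip_states
  }
  tab <- compute_contrasts(tree, states, richness)
  rows <- lapply(mns, function(m) {
    r <- macrocaic_regression(tab, m)
    data.frame(mns = m, n = r$n, r2 = r$r2, slope = r$slope,
               F_stat = r$F_stat, p_value = r$p_value)
  })
  do.call(rbind, rows)
}
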