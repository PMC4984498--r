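test_that("Mk2 likelihood agrees with brute-force oracles", {
  # zero rates, uniform tips, fixed matching root: P(data) = 1
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(mk2_loglik(tr, c(A = 1, B = 1, C = 1),
                          mk2_model(0, 0, "fixed", root_state = 1L)), 0)
  # cherry against the matrix-exponential closed computation
  cherry <- read_newick("(A:1,B:1);")
  P <- oracle_pmat(0.5, 0.5, 1)
  brute <- 0.5 * P[1L, 1L]^2 + 0.5 * P[2L, 1L]^2
  expect_equal(mk2_loglik(cherry, c(A = 0, B = 0),
                          mk2_model(0.5, 0.5, "flat")),
               log(brute), tolerance = 1e-12)
  # enumeration oracle on random 5-tip trees and random rates
  set.seed(31)
  for (rep in 1:5) {
    tr5 <- simulate_bd_tree(5)
    s5 <- setNames(rbinom(5, 1, 0.5), tr5$tip.label)
    q <- runif(2, 0.01, 1)
    expect_equal(mk2_loglik(tr5, s5, mk2_model(q[1], q[2], "fixed",
                                               root_state = 1L)),
                 oracle_mk2_loglik(tr5, s5, q[1], q[2], "fixed", 1L),
                 tolerance = 1e-10)
    expect_equal(mk2_loglik(tr5, s5, mk2_model(q[1], q[2], "flat")),
                 oracle_mk2_loglik(tr5, s5, q[1], q[2], "flat"),
                 tolerance = 1e-10)
  }
})

test_that("Mk2 likelihood is invariant to zero-length polytomy resolutions", {
  a <- read_newick("((A:1,B:1):0,C:1);")   # resolution 1 of a 3-tip star
  b <- read_newick("((A:1,C:1):0,B:1);")   # resolution 2
  star <- read_newick("(A:1,B:1,C:1);")    # resolved deterministically
  s <- c(A = 0, B = 1, C = 1)
  m <- mk2_model(0.3, 0.6, "obs")
  ll <- vapply(list(a, b, star), function(t) mk2_loglik(t, s, m), 0)
  expect_equal(ll[1L], ll[2L], tolerance = 1e-12)
  expect_equal(ll[1L], ll[3L], tolerance = 1e-12)
})

test_that("likelihood conservation over all tip patterns with a fixed root", {
  tr <- simulate_bd_tree(6, seed = 33)
  m <- mk2_model(0.23, 0.71, "fixed", root_state = 0L)
  tot <- sum(vapply(0:63, function(i) {
    s <- setNames(as.integer(intToBits(i))[1:6], tr$tip.label)
    exp(mk2_loglik(tr, s, m))
  }, 0))
  expect_equal(tot, 1, tolerance = 1e-10)
})

test_that("ML fitting respects nesting and boundary behavior", {
  fx <- make_fixture("lizard-like", n_tips = 200, seed = 35)
  s <- setNames(fx$truth$tip_states, fx$tree$tip.label)
  free <- fit_mk2(fx$tree, s)
  eq <- fit_mk2(fx$tree, s, constrain_equal = TRUE)
  expect_gte(free$loglik, eq$loglik - 1e-6)
  expect_equal(eq$model$q_GT, eq$model$q_TG)
  # strong simulated asymmetry is recovered in direction
  expect_gt(free$model$q_TG, free$model$q_GT)

  # all tips in one state: rate out of the observed state pins to the bound
  tr <- simulate_bd_tree(30, seed = 36)
  mono <- setNames(rep(1L, 30), tr$tip.label)
  expect_warning(fit_one <- fit_mk2(tr, mono), "fewer than 2")
  expect_lt(fit_one$model$q_TG, 1e-6)

  # unknown states are pruned before fitting
  s_na <- s
  s_na[1:40] <- NA
  fit_na <- fit_mk2(fx$tree, s_na)
  expect_true(is.finite(fit_na$loglik))
})

test_that("the LRT reproduces chi-square tail probabilities", {
  expect_equal(lrt(-10, -10, 1)$p_value, 1)
  expect_equal(lrt(0, 3.841459 / 2, 1)$p_value, 0.05, tolerance = 1e-4)
  expect_equal(lrt(0, 0.05, 2)$p_value, pchisq(0.1, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(lrt(0, 0.05, 2)$p_value, 0.9512294, tolerance = 1e-6)
  expect_error(lrt(-5, -6, 1), "optimizer failure")
})

test_that("cross-check against an independent Mk implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_bd_tree(40, seed = 37)
  ch <- simulate_binary_character(tr, 0.05, 0.12, root_state = 1L, seed = 38)
  s <- ch$tip_states
  sf <- setNames(factor(ifelse(s == 0, "GSD", "TSD")), names(s))
  fm <- phytools::fitMk(tr, sf, model = "ARD", pi = "equal")
  # fitMk rates are ordered (q10, q01); same likelihood at the same rates
  expect_equal(mk2_loglik(tr, s, mk2_model(fm$rates[2L], fm$rates[1L], "flat")),
               unclass(logLik(fm))[1L], tolerance = 1e-6,
               ignore_attr = TRUE)
  mine <- fit_mk2(tr, s, root_prior = "flat")
  expect_equal(mine$loglik, unclass(logLik(fm))[1L], tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(mine$model$q_GT, unname(fm$rates[2L]), tolerance = 0.02)
  expect_equal(mine$model$q_TG, unname(fm$rates[1L]), tolerance = 0.02)
})

test_that("slice-sampling MCMC is reproducible and recovers the prior", {
  # near-zero branch lengths carry almost no information: posterior ~ prior
  tr <- read_newick("(A:0.01,B:0.01);")
  tra <- mk2_mcmc(tr, c(A = 1, B = 1), seed = 41)
  expect_equal(nrow(tra), 1500L)  # 2000 steps minus 25% burn-in
  expect_true(all(tra$q_GT > 0 & tra$q_TG > 0))
  expect_lt(abs(mean(tra$q_GT) - 0.1), 0.03)
  expect_lt(abs(mean(tra$q_TG) - 0.1), 0.03)
  trb <- mk2_mcmc(tr, c(A = 1, B = 1), seed = 41)
  expect_identical(tra, trb)
})

test_that("MCMC credible intervals cover generating rates", {
  set.seed(43)
  hits <- 0L
  n_cov <- 12L
  for (r in seq_len(n_cov)) {
    tr <- simulate_bd_tree(150, lambda = 0.1)
    ch <- simulate_binary_character(tr, 0.03, 0.08, root_state = 1L)
    trace <- mk2_mcmc(tr, ch$tip_states, n_steps = 1200L)
    ci_gt <- quantile(trace$q_GT, c(0.025, 0.975))
    ci_tg <- quantile(trace$q_TG, c(0.025, 0.975))
    hits <- hits + (ci_gt[1L] <= 0.03 && 0.03 <= ci_gt[2L] &&
                    ci_tg[1L] <= 0.08 && 0.08 <= ci_tg[2L])
  }
  expect_gte(hits / n_cov, 0.75)
})

test_that("posterior asymmetry probability follows the significance rule", {
  up <- data.frame(q_GT = rep(0.01, 100), q_TG = rep(0.2, 100))
  expect_equal(posterior_prob_asymmetry(up)$pp, 1)
  expect_true(posterior_prob_asymmetry(up)$significant)
  mid <- data.frame(q_GT = c(rep(0.2, 97), rep(0.01, 3)),
                    q_TG = c(rep(0.01, 97), rep(0.2, 3)))
  expect_equal(posterior_prob_asymmetry(mid)$pp, 0.03)
  expect_false(posterior_prob_asymmetry(mid)$significant)
  expect_error(posterior_prob_asymmetry(up[0, ]), "empty")
})

test_that("marginal reconstruction matches enumeration and symmetry", {
  # zero rates: every node certainly in the tips' shared state
  tr <- read_newick("((A:1,B:1):1,C:2);")
  asr0 <- marginal_asr_mk2(tr, c(A = 1, B = 1, C = 1), mk2_model(0, 0, "obs"))
  expect_equal(unname(asr0[, "p_TSD"]), c(1, 1))
  expect_equal(rowSums(asr0), c(`4` = 1, `5` = 1), tolerance = 1e-10)

  # 3-tip exhaustive oracle (fixed root)
  s3 <- c(A = 0, B = 1, C = 1)
  m <- mk2_model(0.4, 0.7, "fixed", root_state = 1L)
  asr <- marginal_asr_mk2(tr, s3, m)
  oracle <- oracle_mk2_marginal(tr, s3, 0.4, 0.7, root_state = 1L)
  # fixed root: root row is degenerate at the fixed state
  expect_equal(unname(asr[1L, ]), c(0, 1), tolerance = 1e-10)
  expect_equal(unname(asr[2L, ]), unname(oracle["5", ]), tolerance = 1e-10)
  # flat-root oracle, all nodes
  m2 <- mk2_model(0.4, 0.7, "flat")
  asr2 <- marginal_asr_mk2(tr, s3, m2)
  oracle2 <- oracle_mk2_marginal(tr, s3, 0.4, 0.7, flat_root = TRUE)
  expect_equal(unname(asr2), unname(oracle2), tolerance = 1e-10)

  # symmetric cherry with opposite tips: root exactly (1/2, 1/2)
  cherry <- read_newick("(A:1,B:1);")
  asrc <- marginal_asr_mk2(cherry, c(A = 0, B = 1),
                           mk2_model(0.3, 0.3, "flat"))
  expect_equal(unname(asrc[1L, ]), c(0.5, 0.5), tolerance = 1e-12)
})
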