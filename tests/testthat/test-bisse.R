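test_that("BiSSE reduces to the Yule closed form", {
  tr <- simulate_bd_tree(20, lambda = 0.12, seed = 51)
  n <- 20L
  X <- sum(tr$edge.length)
  ones <- setNames(rep(1L, n), tr$tip.label)
  for (la in c(0.05, 0.1, 0.2)) {
    m <- bisse_model(la, la, 0, 0, 0, 0)
    expect_equal(bisse_loglik(tr, ones, m, rtol = 1e-10, atol = 1e-12),
                 (n - 2) * log(la) - la * X, tolerance = 1e-8)
  }
  # and the closed-form Yule MLE agrees with ape's
  expect_equal(fit_yule(tr)$lambda, ape::yule(tr)$lambda, tolerance = 1e-10)
})

test_that("branch integration keeps E in [0,1] and D non-negative", {
  # full sampling: E starts at exactly 0
  y <- sdmdiv:::.bisse_branch_cpp(c(0, 0, 1, 0), 8,
                                  c(0.2, 0.1, 0.05, 0.1, 0.3, 0.2))
  expect_true(all(y[1:2] >= 0 & y[1:2] <= 1))
  expect_true(all(y[3:4] >= 0))
  set.seed(52)
  for (rep in 1:10) {
    pars <- runif(6, 0, 0.5)
    f <- runif(1, 0.2, 1)
    y <- sdmdiv:::.bisse_branch_cpp(c(1 - f, 1 - f, f, 0), runif(1, 0.1, 30),
                                    pars)
    expect_true(all(y[1:2] >= 0 & y[1:2] <= 1))
    expect_true(all(y[3:4] >= 0))
  }
})

test_that("BiSSE factorizes into Yule x Mk2 as extinction vanishes", {
  tr <- simulate_bd_tree(10, seed = 53)
  ch <- simulate_binary_character(tr, 0.1, 0.2, seed = 54)
  la <- 0.1
  m <- bisse_model(la, la, 1e-7, 1e-7, 0.1, 0.2)
  ll_b <- bisse_loglik(tr, ch$tip_states, m)
  ll_m <- mk2_loglik(tr, ch$tip_states, mk2_model(0.1, 0.2, "obs"))
  ll_y <- (10 - 2) * log(la) - la * sum(tr$edge.length)
  expect_equal(ll_b, ll_m + ll_y, tolerance = 1e-4)
})

test_that("likelihood is invariant to swapping state labels with parameters", {
  tr <- simulate_bd_tree(15, seed = 55)
  ch <- simulate_binary_character(tr, 0.15, 0.25, seed = 56)
  m <- bisse_model(0.1, 0.2, 0.03, 0.05, 0.1, 0.2, f_G = 0.6, f_T = 0.8,
                   root_prior = "flat")
  m_swap <- bisse_model(0.2, 0.1, 0.05, 0.03, 0.2, 0.1, f_G = 0.8, f_T = 0.6,
                        root_prior = "flat")
  expect_equal(bisse_loglik(tr, 1L - ch$tip_states, m_swap),
               bisse_loglik(tr, ch$tip_states, m), tolerance = 1e-9)
})

test_that("constrained BiSSE transition-rate test recovers asymmetry", {
  fx <- make_fixture("lizard-like", n_tips = 250, seed = 57)
  s <- setNames(fx$truth$tip_states, fx$tree$tip.label)
  res <- fit_bisse_transition_test(fx$tree, s)
  expect_gte(res$comparison$loglik_alt, res$comparison$loglik_null - 1e-6)
  expect_gt(res$fit_free$model$q_TG, res$fit_free$model$q_GT)
  expect_lt(res$comparison$p_value, 0.05)
  # constrained models share lambda and mu across states by construction
  expect_equal(res$fit_free$model$lambda_G, res$fit_free$model$lambda_T)
  expect_equal(res$fit_free$model$mu_G, res$fit_free$model$mu_T)
})

test_that("diversification test emits a non-negative delta log-likelihood", {
  tr <- simulate_bd_tree(60, seed = 58)
  ch <- simulate_binary_character(tr, 0.05, 0.08, seed = 59)
  res <- fit_bisse_diversification_test(tr, ch$tip_states, nstart = 1)
  expect_gte(res$delta_ll, 0)
  expect_equal(res$comparison$df, 1L)
  expect_true(res$comparison$p_value >= 0 && res$comparison$p_value <= 1)
})

test_that("state-dependent speciation is detected when truly present", {
  # two sister clades grown at a 4x speciation ratio, states tracking the
  # clades: the state-dependent-lambda alternative should win decisively
  scale_to <- function(tr, h) {
    tr$edge.length <- tr$edge.length * h / max(sdmdiv:::node_depths(tr))
    tr
  }
  fast <- scale_to(simulate_bd_tree(250, lambda = 0.3, seed = 60), 10)
  slow <- scale_to(simulate_bd_tree(6, lambda = 0.15, seed = 61), 10)
  slow$tip.label <- paste0("s", seq_len(6))
  glued <- read_newick(paste0(
    "(", sub(";$", "", write_newick(fast)), ":1,",
    sub(";$", "", write_newick(slow)), ":1);"))
  s <- setNames(c(rep(1L, 250), rep(0L, 6)),
                c(fast$tip.label, slow$tip.label))
  res <- fit_bisse_diversification_test(glued, s, nstart = 1)
  expect_gt(res$fit_alt$model$lambda_T, res$fit_alt$model$lambda_G)
  expect_lt(res$comparison$p_value, 0.05)

  # and on a neutral character the two lambda MLEs stay close
  tr <- simulate_bd_tree(150, seed = 62)
  ch <- simulate_binary_character(tr, 0.04, 0.06, seed = 63)
  neut <- fit_bisse_diversification_test(tr, ch$tip_states, nstart = 1)
  la <- c(neut$fit_alt$model$lambda_G, neut$fit_alt$model$lambda_T)
  expect_lt(abs(diff(la)) / mean(la), 0.5)
})

test_that("BiSSE marginals converge to Mk2 marginals and sum to one", {
  tr <- simulate_bd_tree(8, seed = 62)
  ones <- setNames(rep(1L, 8), tr$tip.label)
  m0 <- bisse_model(0.1, 0.1, 0, 0, 0, 0)
  asr0 <- marginal_asr_bisse(tr, ones, m0)
  expect_equal(unname(asr0[, "p_TSD"]), rep(1, 7))

  ch <- simulate_binary_character(tr, 0.1, 0.2, seed = 63)
  mb <- bisse_model(0.1, 0.1, 1e-7, 1e-7, 0.1, 0.2)
  ab <- marginal_asr_bisse(tr, ch$tip_states, mb)
  am <- marginal_asr_mk2(tr, ch$tip_states, mk2_model(0.1, 0.2, "obs"))
  expect_equal(unname(ab), unname(am), tolerance = 1e-4)
  expect_equal(unname(rowSums(ab)), rep(1, 7), tolerance = 1e-8)
})
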