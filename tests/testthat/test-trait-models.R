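test_that("regime painting follows argmax and tie rules", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  s <- c(A = 1, B = 1, C = 0)
  asr <- matrix(c(0.9, 0.5, 0.1, 0.5), 2L, 2L,
                dimnames = list(c("4", "5"), c("p_GSD", "p_TSD")))
  # root (node 4) is GSD-leaning; node 5 ties and takes the parent's regime
  p <- paint_regimes(asr, s, tr)
  expect_equal(p$node_regime[4L], 0L)
  expect_equal(p$node_regime[5L], 0L)
  expect_equal(p$node_regime[1:3], c(1L, 1L, 0L))
  # root tie goes to TSD
  asr2 <- asr
  asr2[1L, ] <- c(0.5, 0.5)
  p2 <- paint_regimes(asr2, s, tr)
  expect_equal(p2$node_regime[4L], 1L)
  expect_equal(p2$node_regime[5L], 1L)  # tie inherits the (TSD) root
  # certain reconstruction: every branch TSD
  asr3 <- asr
  asr3[, "p_TSD"] <- 1
  asr3[, "p_GSD"] <- 0
  expect_true(all(paint_regimes(asr3, c(A = 1, B = 1, C = 1),
                                tr)$node_regime == 1L))
})

test_that("painting from a fitted reconstruction recovers the true history", {
  set.seed(91)
  acc <- replicate(6, {
    fx <- make_fixture("turtle-like")
    s <- setNames(fx$truth$tip_states, fx$tree$tip.label)
    m <- fit_mk2(fx$tree, s)$model
    p <- paint_regimes(marginal_asr_mk2(fx$tree, s, m), s, fx$tree)
    mean(p$node_regime == fx$truth$painting$node_regime)
  })
  expect_gte(mean(acc), 0.9)
})

test_that("nesting identities hold exactly and OU tends to BM as alpha -> 0", {
  fx <- make_fixture("turtle-like", seed = 92)
  tr <- fx$tree
  paint <- fx$truth$painting
  y <- setNames(log(fx$lifespan$value), fx$lifespan$species)
  ll_bm1 <- trait_model_loglik(tr, y, NULL, "BM1",
                               list(sigma2 = 0.04, root_value = 3.3))
  ll_bm2 <- trait_model_loglik(tr, y, paint, "BM2",
                               list(sigma2 = c(0.04, 0.04), root_value = 3.3))
  expect_equal(ll_bm1, ll_bm2, tolerance = 1e-12)
  ll_ou1 <- trait_model_loglik(tr, y, paint, "OU1",
                               list(sigma2 = 0.03, alpha = 0.1, theta = 3.4))
  ll_oum <- trait_model_loglik(tr, y, paint, "OUM",
                               list(sigma2 = 0.03, alpha = 0.1,
                                    theta = c(3.4, 3.4)))
  expect_equal(ll_ou1, ll_oum, tolerance = 1e-12)
  ll_lim <- trait_model_loglik(tr, y, NULL, "OU1",
                               list(sigma2 = 0.04, alpha = 1e-7, theta = 3.3))
  expect_equal(ll_lim, ll_bm1, tolerance = 1e-3)

  # fitted versions of the same identities
  f_bm1 <- fit_trait_model(tr, y, NULL, "BM1")
  f_bm2 <- fit_trait_model(tr, y, paint, "BM2")
  f_ou1 <- fit_trait_model(tr, y, paint, "OU1")
  f_oum <- fit_trait_model(tr, y, paint, "OUM")
  expect_gte(f_bm2$loglik, f_bm1$loglik - 1e-6)
  expect_gte(f_oum$loglik, f_ou1$loglik - 1e-6)
  cmp <- compare_trait_models(f_bm1, f_bm2, f_ou1, f_oum)
  expect_equal(cmp$lrt_bm$df, 1L)
  expect_equal(cmp$lrt_ou$df, 1L)
  expect_equal(nrow(cmp$aic), 4L)
  expect_equal(cmp$aic$AIC, 2 * cmp$aic$k - 2 * cmp$aic$loglik)
  # at equal log-likelihood the extra parameter costs exactly 2 AIC units
  expect_equal(f_oum$AIC + 2 * (f_oum$loglik - f_ou1$loglik),
               f_ou1$AIC + 2)
})

test_that("likelihood is invariant to label swaps with paired parameters", {
  fx <- make_fixture("turtle-like", seed = 93)
  tr <- fx$tree
  paint <- fx$truth$painting
  y <- setNames(log(fx$lifespan$value), fx$lifespan$species)
  swap <- paint
  swap$node_regime <- 1L - paint$node_regime
  ll <- trait_model_loglik(tr, y, paint, "OUM",
                           list(sigma2 = 0.03, alpha = 0.1,
                                theta = c(3.1, 3.6)))
  ll_sw <- trait_model_loglik(tr, y, swap, "OUM",
                              list(sigma2 = 0.03, alpha = 0.1,
                                   theta = c(3.6, 3.1)))
  expect_equal(ll, ll_sw, tolerance = 1e-10)
  ll_bm <- trait_model_loglik(tr, y, paint, "BM2",
                              list(sigma2 = c(0.02, 0.08), root_value = 3.3))
  ll_bm_sw <- trait_model_loglik(tr, y, swap, "BM2",
                                 list(sigma2 = c(0.08, 0.02),
                                      root_value = 3.3))
  expect_equal(ll_bm, ll_bm_sw, tolerance = 1e-10)
})

test_that("model selection behaves sanely under generating models", {
  # data simulated under BM1: extra-parameter models win rarely
  set.seed(94)
  rejections <- replicate(10, {
    fx <- make_fixture("turtle-like", n_tips = 60)
    y <- simulate_regime_trait(fx$tree, NULL,
                               list(model = "BM1", sigma2 = 0.05,
                                    root_value = 3))
    f1 <- fit_trait_model(fx$tree, y, NULL, "BM1")
    f2 <- fit_trait_model(fx$tree, y, fx$truth$painting, "BM2")
    lrt(f1$loglik, f2$loglik, 1L, tol = 1e-3)$p_value < 0.05
  })
  expect_lte(mean(rejections), 0.3)
  # data simulated under OUM with well-separated optima: OUM wins the AIC
  set.seed(95)
  wins <- replicate(8, {
    fx <- make_fixture("turtle-like", n_tips = 90)
    y <- simulate_regime_trait(fx$tree, fx$truth$painting,
                               list(model = "OUM", sigma2 = 0.03, alpha = 0.3,
                                    theta = c(2.5, 4)))
    fits <- lapply(c("BM1", "BM2", "OU1", "OUM"), function(m)
      fit_trait_model(fx$tree, y, fx$truth$painting, m))
    compare_trait_models(fits[[1]], fits[[2]], fits[[3]], fits[[4]])$best
  })
  expect_gte(mean(wins == "OUM"), 0.6)
})

test_that("OU fitting refuses non-ultrametric trees; BM2 needs a painting", {
  y <- c(A = 1, B = 2, C = 1.5)
  expect_error(fit_trait_model(nonultra_tree(), y, NULL, "OU1"),
               "ultrametric")
  expect_error(fit_trait_model(nonultra_tree(), y, NULL, "BM2"), "painting")
})
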