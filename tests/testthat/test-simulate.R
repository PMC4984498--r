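test_that("birth-death simulator returns conditioned, ultrametric trees", {
  tr <- simulate_bd_tree(2, seed = 1)
  expect_equal(ape::Ntip(tr), 2L)
  expect_true(validate_ultrametric(tr)$ok)

  tr <- simulate_bd_tree(100, lambda = 0.1, mu = 0, seed = 2)
  expect_equal(ape::Ntip(tr), 100L)
  expect_equal(tr$Nnode, 99L)
  expect_equal(nrow(tr$edge), 198L)
  expect_true(validate_ultrametric(tr, 1e-9)$ok)

  # with extinction: still exactly n extant tips after pruning
  tre <- simulate_bd_tree(60, lambda = 0.2, mu = 0.1, seed = 3)
  expect_equal(ape::Ntip(tre), 60L)
  expect_true(validate_ultrametric(tre, 1e-9)$ok)

  expect_identical(write_newick(simulate_bd_tree(50, seed = 9)),
                   write_newick(simulate_bd_tree(50, seed = 9)))
})

test_that("pure-birth internode waiting times are exponential with rate k*lambda", {
  set.seed(13)
  pool <- numeric(0)
  for (r in 1:30) {
    tr <- simulate_bd_tree(40, lambda = 0.1)
    bt <- sort(ape::branching.times(tr), decreasing = TRUE)
    iv <- -diff(c(bt, 0))                  # intervals while 2..n lineages
    pool <- c(pool, iv * (2:(length(iv) + 1L)) * 0.1)
  }
  expect_gt(ks.test(pool, "pexp", 1)$p.value, 0.01)
})

test_that("binary character simulation matches the analytic transition law", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  ch <- simulate_binary_character(tr, 0, 0, root_state = 1L, seed = 1)
  expect_true(all(ch$tip_states == 1L))
  expect_equal(ch$n_changes, 0L)

  # tip states equal the end of the recorded change history
  ch2 <- simulate_binary_character(tr, 0.5, 0.3, root_state = 0L, seed = 2)
  expect_equal(unname(ch2$edge_states),
               unname(ch2$node_states[ch2$edge_order[, 2L]]))

  # single branch: flip frequency matches the matrix exponential
  set.seed(3)
  cherry <- read_newick("(A:1.7,B:0.0001);")
  p01 <- oracle_pmat(0.3, 0.5, 1.7)[1L, 2L]
  flips <- replicate(3000, simulate_binary_character(
    cherry, 0.3, 0.5, root_state = 0L)$tip_states[["A"]])
  expect_lt(abs(mean(flips) - p01), 4 * sqrt(p01 * (1 - p01) / 3000))

  # long branch: stationary frequency q01 / (q01 + q10)
  set.seed(4)
  lb <- read_newick("(A:200,B:200);")
  st <- replicate(2500, simulate_binary_character(
    lb, 0.15, 0.35, root_state = 1L)$tip_states[["A"]])
  expect_lt(abs(mean(st) - 0.3), 4 * sqrt(0.3 * 0.7 / 2500))
})

test_that("tip-pattern distribution matches the pruning likelihood", {
  tr4 <- read_newick("((A:1,B:1):0.5,(C:0.7,D:0.7):0.8);")
  expected <- vapply(0:15, function(i) {
    s <- setNames(as.integer(intToBits(i))[1:4], c("A", "B", "C", "D"))
    exp(mk2_loglik(tr4, s, mk2_model(0.4, 0.25, "fixed", root_state = 1L)))
  }, 0)
  expect_equal(sum(expected), 1, tolerance = 1e-10)
  set.seed(5)
  N <- 8000
  pat <- replicate(N, sum(simulate_binary_character(
    tr4, 0.4, 0.25, root_state = 1L)$tip_states[c("A", "B", "C", "D")] *
      c(1, 2, 4, 8)))
  obs <- tabulate(pat + 1L, 16L)
  expect_gt(suppressWarnings(chisq.test(obs, p = expected)$p.value), 0.001)
})

test_that("regime trait simulation follows the stated conditional laws", {
  tr <- read_newick("(A:2,B:2);")
  # degenerate: no noise, no pull
  x <- simulate_regime_trait(tr, NULL,
                             list(model = "BM1", sigma2 = 0, root_value = 3),
                             seed = 1)
  expect_equal(unname(x), c(3, 3))
  # BM cherry: tip difference ~ Normal(0, 2 sigma2 t)
  set.seed(2)
  d <- replicate(1500, diff(simulate_regime_trait(
    tr, NULL, list(model = "BM1", sigma2 = 0.5, root_value = 0))))
  expect_gt(ks.test(d / sqrt(2 * 0.5 * 2), "pnorm")$p.value, 0.01)
  # strong OU pull: tip means approach the regime optimum
  set.seed(3)
  xs <- replicate(400, simulate_regime_trait(
    tr, NULL, list(model = "OU1", sigma2 = 0.1, alpha = 5, theta = 7))[["A"]])
  expect_lt(abs(mean(xs) - 7), 0.05)
  expect_lt(abs(var(xs) - 0.1 / 10), 0.005)
  # OU refuses non-ultrametric trees
  expect_error(simulate_regime_trait(nonultra_tree(), NULL,
               list(model = "OU1", sigma2 = 0.1, alpha = 1, theta = 0)),
               "ultrametric")
})

test_that("fixtures hit the target state frequencies and masking", {
  set.seed(6)
  gsd_frac <- replicate(8, {
    fx <- make_fixture("lizard-like", n_tips = 300)
    mean(fx$truth$tip_states == 0L)
  })
  expect_gte(mean(gsd_frac >= 0.7 & gsd_frac <= 0.95), 0.75)
  set.seed(7)
  tsd_frac <- replicate(8, {
    fx <- make_fixture("turtle-like", n_tips = 87)
    mean(fx$truth$tip_states == 1L)
  })
  expect_gte(mean(tsd_frac >= 0.6 & tsd_frac <= 0.95), 0.75)

  fx <- make_fixture("turtle-like", seed = 8, mask_fraction = 0)
  expect_false(anyNA(fx$states$state))
  fx2 <- make_fixture("turtle-like", seed = 8, mask_fraction = 0.25)
  expect_equal(sum(is.na(fx2$states$state)), round(0.25 * 87))
  # lifespan optima ordering is built in
  expect_gt(fx2$truth$trait_model$theta[["TSD"]],
            fx2$truth$trait_model$theta[["GSD"]])
  # fixture directory round-trips through the package readers
  d <- tempfile()
  write_fixture(fx2, d)
  tr <- read_newick(file = file.path(d, "tree.nwk"))
  st <- read_state_table(file.path(d, "states.tsv"))
  expect_equal(sort(tr$tip.label), sort(st$species))
  expect_equal(sum(is.na(st$state)), sum(is.na(fx2$states$state)))
})
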