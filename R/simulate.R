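#' Simulate a constant-rate birth-death tree with a fixed number of tips
#'
#' Forward-time simulation at speciation rate `lambda` and extinction rate
#' `mu`, run until `n_tips` lineages are alive, then extended by the waiting
#' time to the next event (so the simulated present falls strictly between
#' events and pendant branches have positive length). Extinct lineages are
#' pruned. If the whole tree dies before reaching `n_tips` the simulation is
#' retried up to `max_retries` times.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param lambda speciation rate per lineage per unit time (> 0).
#' @param mu extinction rate (>= 0).
#' @param seed optional integer seed (`set.seed`); `NULL` uses the current
#'   RNG stream.
#' @param max_retries retry cap for whole-tree extinction.
#' @return an ultrametric, bifurcating `phylo` object with `n_tips` tips
#'   labelled `t1..tn`.
#' @export
simulate_bd_tree <- function(n_tips, lambda = 0.1, mu = 0, seed = NULL,
                             max_retries = 100L) {
  stopifnot(n_tips >= 2L, lambda > 0, mu >= 0)
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_retries)) {
    res <- .bd_forward(n_tips, lambda, mu)
    if (!is.null(res)) return(.lineages_to_phylo(res))
  }
  stop("whole-tree extinction in every attempt (", max_retries, " retries)")
}

# One forward pass; NULL on total extinction before n_tips lineages co-exist.
.bd_forward <- function(n_tips, lambda, mu) {
  cap <- 4L * n_tips + 8L
  parent <- integer(cap); t0 <- numeric(cap); t1 <- numeric(cap)
  status <- integer(cap)  # 0 alive, 1 split, 2 dead
  ch1 <- integer(cap); ch2 <- integer(cap)
  # virtual root lineage 0 is implicit; start from the two crown lineages
  parent[1:2] <- 0L; t0[1:2] <- 0; n_lin <- 2L
  alive <- c(1L, 2L); n_alive <- 2L
  t <- 0
  rate_tot <- lambda + mu
  repeat {
    if (n_alive == 0L) return(NULL)
    if (n_alive == n_tips) {
      t <- t + rexp(1L, n_alive * rate_tot)  # extend to just before next event
      break
    }
    t <- t + rexp(1L, n_alive * rate_tot)
    i <- sample.int(n_alive, 1L)
    lin <- alive[i]
    if (runif(1L) < lambda / rate_tot) {
      if (n_lin + 2L > cap) {  # grow storage
        cap <- cap * 2L
        length(parent) <- cap; length(t0) <- cap; length(t1) <- cap
        length(status) <- cap; length(ch1) <- cap; length(ch2) <- cap
        status[is.na(status)] <- 0L
      }
      t1[lin] <- t; status[lin] <- 1L
      a <- n_lin + 1L; b <- n_lin + 2L
      parent[a] <- lin; parent[b] <- lin
      t0[a] <- t; t0[b] <- t
      status[a] <- 0L; status[b] <- 0L
      ch1[lin] <- a; ch2[lin] <- b
      alive[i] <- a
      n_alive <- n_alive + 1L
      alive[n_alive] <- b
      n_lin <- b
    } else {
      t1[lin] <- t; status[lin] <- 2L
      alive[i] <- alive[n_alive]
      n_alive <- n_alive - 1L
    }
  }
  extant <- alive[seq_len(n_alive)]
  t1[extant] <- t
  list(parent = parent[seq_len(n_lin)], t0 = t0[seq_len(n_lin)],
       t1 = t1[seq_len(n_lin)], status = status[seq_len(n_lin)],
       ch1 = ch1[seq_len(n_lin)], ch2 = ch2[seq_len(n_lin)])
}

# Convert the lineage records to phylo, pruning extinct lineages and merging
# pass-through spans. Children always have larger ids than parents, so a
# reverse-id sweep computes "has extant descendant" bottom-up.
.lineages_to_phylo <- function(L) {
  n_lin <- length(L$parent)
  useful <- L$status == 0L
  for (id in n_lin:1) {
    if (L$status[id] == 1L)
      useful[id] <- useful[L$ch1[id]] || useful[L$ch2[id]]
  }
  # resolve a lineage: follow single-useful-child chains; returns c(end, t0)
  resolve <- function(id) {
    start <- L$t0[id]
    repeat {
      if (L$status[id] == 0L) return(c(id, start))
      u1 <- useful[L$ch1[id]]; u2 <- useful[L$ch2[id]]
      if (u1 && u2) return(c(id, start))
      id <- if (u1) L$ch1[id] else L$ch2[id]
    }
  }
  # find crown start: virtual root splits into lineages 1, 2
  if (useful[1L] && useful[2L]) {
    top <- c(1L, 2L)
  } else {
    r <- resolve(if (useful[1L]) 1L else 2L)
    stopifnot(L$status[r[1L]] == 1L)
    top <- c(L$ch1[r[1L]], L$ch2[r[1L]])
  }
  n_tip <- sum(L$status == 0L & useful)
  n_node <- n_tip - 1L
  edge <- matrix(0L, 2L * n_tip - 2L, 2L)
  elen <- numeric(2L * n_tip - 2L)
  next_tip <- 0L; next_int <- n_tip + 1L; next_edge <- 0L
  # explicit stack of (parent-node-id, lineage-id, span-start)
  stack_par <- integer(2L * n_tip); stack_lin <- integer(2L * n_tip)
  stack_t0 <- numeric(2L * n_tip)
  root_id <- next_int; next_int <- next_int + 1L
  sp <- 2L
  r1 <- resolve(top[1L]); r2 <- resolve(top[2L])
  stack_par[1L] <- root_id; stack_lin[1L] <- r1[1L]; stack_t0[1L] <- r1[2L]
  stack_par[2L] <- root_id; stack_lin[2L] <- r2[1L]; stack_t0[2L] <- r2[2L]
  while (sp > 0L) {
    par <- stack_par[sp]; lin <- stack_lin[sp]; start <- stack_t0[sp]
    sp <- sp - 1L
    if (L$status[lin] == 0L) {
      next_tip <- next_tip + 1L
      node <- next_tip
    } else {
      node <- next_int; next_int <- next_int + 1L
    }
    next_edge <- next_edge + 1L
    edge[next_edge, ] <- c(par, node)
    elen[next_edge] <- L$t1[lin] - start
    if (L$status[lin] == 1L) {
      ra <- resolve(L$ch1[lin]); rb <- resolve(L$ch2[lin])
      sp <- sp + 1L
      stack_par[sp] <- node; stack_lin[sp] <- ra[1L]; stack_t0[sp] <- ra[2L]
      sp <- sp + 1L
      stack_par[sp] <- node; stack_lin[sp] <- rb[1L]; stack_t0[sp] <- rb[2L]
    }
  }
  tr <- list(edge = edge, edge.length = elen,
             tip.label = paste0("t", seq_len(n_tip)), Nnode = n_node)
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

#' Simulate a binary character along a tree
#'
#' Exact stochastic simulation of a two-state continuous-time Markov chain
#' (exponential waiting times between flips along each branch). The full
#' change history and true node states are retained so ancestral-state
#' reconstructions and the pruning likelihood can be cross-validated against
#' the generating process.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param q01 instantaneous rate 0 -> 1 (GSD -> TSD).
#' @param q10 instantaneous rate 1 -> 0 (TSD -> GSD).
#' @param root_state state at the root (0 or 1).
#' @param seed optional integer seed.
#' @return list with `tip_states` (named integer vector along tip labels),
#'   `node_states` (states of all nodes, indexed by node id),
#'   `edge_states` (state at the child end of each edge, i.e. the true
#'   branch regime under the child-side convention), `n_changes`, and
#'   `history` (data.frame of individual changes: edge, time along edge,
#'   from, to).
#' @export
simulate_binary_character <- function(tree, q01, q10, root_state = 1L,
                                      seed = NULL) {
  stopifnot(q01 >= 0, q10 >= 0, root_state %in% 0:1)
  if (!is.null(seed)) set.seed(seed)
  tree_po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nmax <- max(tree_po$edge)
  node_state <- rep(NA_integer_, nmax)
  root <- tree_po$edge[nrow(tree_po$edge), 1L]
  node_state[root] <- as.integer(root_state)
  rates <- c(q01, q10)  # indexed by current state + 1
  hist_edge <- integer(0); hist_time <- numeric(0)
  hist_from <- integer(0); hist_to <- integer(0)
  # preorder = reverse postorder: parent state known before child visited
  ord <- rev(seq_len(nrow(tree_po$edge)))
  for (i in ord) {
    par <- tree_po$edge[i, 1L]; ch <- tree_po$edge[i, 2L]
    len <- tree_po$edge.length[i]
    s <- node_state[par]
    t <- 0
    repeat {
      r <- rates[s + 1L]
      if (r <= 0) break
      t <- t + rexp(1L, r)
      if (t >= len) break
      hist_edge <- c(hist_edge, i); hist_time <- c(hist_time, t)
      hist_from <- c(hist_from, s); hist_to <- c(hist_to, 1L - s)
      s <- 1L - s
    }
    node_state[ch] <- s
  }
  tips <- setNames(node_state[seq_len(ntip)], tree_po$tip.label)
  list(tip_states = tips,
       node_states = node_state,
       edge_states = node_state[tree_po$edge[, 2L]],
       edge_order = tree_po$edge,
       n_changes = length(hist_edge),
       history = data.frame(edge = hist_edge, time = hist_time,
                            from = hist_from, to = hist_to))
}

#' Simulate a continuous trait under a regime-dependent BM or OU process
#'
#' Branch-by-branch exact simulation: under Brownian motion the increment on
#' a branch of length `l` in regime `r` is Normal(0, sigma2_r * l); under
#' Ornstein-Uhlenbeck the transition toward the regime optimum `theta_r` uses
#' the exact conditional mean and variance.
#'
#' @param tree an ultrametric `phylo` object (ultrametricity enforced for OU
#'   models).
#' @param painting a regime painting as from [paint_regimes()], or `NULL`
#'   for single-regime models.
#' @param model list describing the generating model, with elements
#'   `model` (`"BM1"`, `"BM2"`, `"OU1"`, `"OUM"`), `sigma2` (length 1, or 2
#'   ordered as c(GSD, TSD)), `alpha` (OU only), `theta` (OU only; length 1
#'   or 2 as c(GSD, TSD)), and optional `root_value` (defaults to the root
#'   regime's `theta` under OU and to 0 under BM).
#' @param seed optional integer seed.
#' @return named numeric vector of tip values (same scale as `theta`).
#' @export
simulate_regime_trait <- function(tree, painting = NULL, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mtype <- match.arg(model$model, c("BM1", "BM2", "OU1", "OUM"))
  is_ou <- mtype %in% c("OU1", "OUM")
  if (is_ou && !validate_ultrametric(tree, 1e-6)$ok)
    stop("OU simulation requires an ultrametric tree")
  tree_po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nmax <- max(tree_po$edge)
  two_regime <- mtype %in% c("BM2", "OUM")
  if (two_regime && is.null(painting))
    stop("two-regime models need a `painting`")
  edge_regime <- if (is.null(painting)) rep(0L, nrow(tree_po$edge))
                 else .painting_for_edges(painting, tree_po)
  sigma2 <- rep_len(model$sigma2, 2L)
  alpha <- if (is_ou) model$alpha else 0
  theta <- if (is_ou) rep_len(model$theta, 2L) else c(0, 0)
  root <- tree_po$edge[nrow(tree_po$edge), 1L]
  root_regime <- if (is.null(painting)) 0L else painting$node_regime[root]
  x <- numeric(nmax)
  x[root] <- if (!is.null(model$root_value)) model$root_value
             else if (is_ou) theta[root_regime + 1L] else 0
  for (i in rev(seq_len(nrow(tree_po$edge)))) {
    par <- tree_po$edge[i, 1L]; ch <- tree_po$edge[i, 2L]
    l <- tree_po$edge.length[i]
    r <- edge_regime[i] + 1L
    if (is_ou && alpha > 0) {
      m <- theta[r] + (x[par] - theta[r]) * exp(-alpha * l)
      v <- sigma2[r] * (-expm1(-2 * alpha * l)) / (2 * alpha)
    } else {
      m <- x[par]
      v <- sigma2[r] * l
    }
    x[ch] <- rnorm(1L, m, sqrt(v))
  }
  setNames(x[seq_len(ntip)], tree_po$tip.label)
}

# Map a painting (edge regimes stored against a reference edge matrix) onto a
# possibly reordered edge matrix of the same tree.
.painting_for_edges <- function(painting, tree_po) {
  painting$node_regime[tree_po$edge[, 2L]]
}

#' Generate a self-contained turtle-like or lizard-like synthetic data set
#'
#' Builds a pure-birth tree plus binary sex-determining-mechanism states,
#' lifespans, and per-tip clade richness with the statistical structure of
#' the two empirical systems this package targets:
#'
#' * `"turtle-like"`: near-equal, slow transition rates, TSD root, and an
#'   expected TSD tip share near 78%; lifespan evolves under a two-optimum
#'   OU process with the TSD optimum (35.9 y) above the GSD optimum
#'   (22.6 y).
#' * `"lizard-like"`: strongly asymmetric rates (TSD -> GSD much faster than
#'   GSD -> TSD), TSD root, expected GSD tip share near 86%, and close
#'   lifespan optima (7.9 vs 10.1 y).
#'
#' Transition rates were calibrated analytically from the two-state
#' transition probability at the expected crown age of a pure-birth tree at
#' `lambda = 0.1`, to hit the target tip-state frequencies in expectation.
#' A fraction of tip states can be masked as unknown, uniformly at random.
#'
#' @param profile `"turtle-like"` or `"lizard-like"`.
#' @param n_tips number of tips (>= 20; defaults: 87 turtle-like, 300
#'   lizard-like).
#' @param seed integer seed (required for reproducibility).
#' @param mask_fraction fraction of tip states set to unknown (default 0).
#' @return list with `tree`, `states` (tip-state data.frame), `lifespan`
#'   (tip-value data.frame, years), `richness` (tip-value data.frame,
#'   counts), and `truth` (generating parameters, true node states and true
#'   branch painting).
#' @export
make_fixture <- function(profile = c("turtle-like", "lizard-like"),
                         n_tips = NULL, seed = NULL, mask_fraction = 0) {
  profile <- match.arg(profile)
  stopifnot(mask_fraction >= 0, mask_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  if (profile == "turtle-like") {
    if (is.null(n_tips)) n_tips <- 87L
    q01 <- 0.006; q10 <- 0.006
    theta <- log(c(GSD = 22.6204, TSD = 35.8875))
  } else {
    if (is.null(n_tips)) n_tips <- 300L
    q01 <- 0.002; q10 <- 0.04
    theta <- log(c(GSD = 7.9104, TSD = 10.0869))
  }
  stopifnot(n_tips >= 20L)
  lambda <- 0.1
  tree <- simulate_bd_tree(n_tips, lambda = lambda, mu = 0)
  char <- simulate_binary_character(tree, q01, q10, root_state = 1L)
  truth_painting <- .painting_from_history(tree, char)
  ou <- list(model = "OUM", sigma2 = 0.03, alpha = 0.1, theta = theta)
  logspan <- simulate_regime_trait(tree, truth_painting, ou)
  states <- char$tip_states[tree$tip.label]
  masked <- states
  if (mask_fraction > 0) {
    idx <- sample.int(n_tips, round(mask_fraction * n_tips))
    masked[idx] <- NA_integer_
  }
  richness <- 1L + rnbinom(n_tips, size = 0.7, mu = 9)
  list(
    tree = tree,
    states = state_table(masked),
    lifespan = data.frame(species = tree$tip.label,
                          value = exp(logspan[tree$tip.label]),
                          stringsAsFactors = FALSE),
    richness = data.frame(species = tree$tip.label, value = richness,
                          stringsAsFactors = FALSE),
    truth = list(lambda = lambda, q01 = q01, q10 = q10, root_state = 1L,
                 trait_model = ou, node_states = char$node_states,
                 painting = truth_painting, tip_states = states,
                 mask_fraction = mask_fraction)
  )
}

# A regime painting object from a simulated character's true node states.
.painting_from_history <- function(tree, char) {
  structure(list(node_regime = char$node_states,
                 provenance = "true-history"),
            class = "regime_painting")
}

#' Write a fixture to a directory as Newick + TSV files
#'
#' Emits `tree.nwk`, `states.tsv`, `lifespan.tsv`, `richness.tsv` in the
#' same formats the readers in this package accept.
#'
#' @param fixture list as returned by [make_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(fixture$tree, file.path(dir, "tree.nwk"))
  st <- fixture$states
  st$state <- ifelse(is.na(st$state), "unknown", .STATE_LEVELS[st$state + 1L])
  st$alt_state <- ifelse(is.na(st$alt_state), "unknown",
                         .STATE_LEVELS[st$alt_state + 1L])
  write_table_tsv(st, file.path(dir, "states.tsv"))
  write_table_tsv(fixture$lifespan, file.path(dir, "lifespan.tsv"))
  write_table_tsv(fixture$richness, file.path(dir, "richness.tsv"))
  invisible(dir)
}
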