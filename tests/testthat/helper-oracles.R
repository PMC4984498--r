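# Independent oracles used across tests. These deliberately avoid the
# package's own closed forms: transition probabilities come from a true
# matrix exponential (Matrix::expm) and likelihoods from exhaustive
# enumeration of ancestral-state assignments.

oracle_pmat <- function(q01, q10, t) {
  Q <- matrix(c(-q01, q01, q10, -q10), 2L, byrow = TRUE)
  as.matrix(Matrix::expm(Q * t))
}

# Joint-enumeration Mk2 likelihood: sum over every assignment of states to
# internal nodes of the product of branch transition probabilities.
oracle_mk2_loglik <- function(tree, tip_states, q01, q10,
                              root_prior = c("fixed", "flat"),
                              root_state = 1L) {
  root_prior <- match.arg(root_prior)
  pr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(pr)
  nmax <- max(pr$edge)
  s <- tip_states[pr$tip.label]
  Plist <- lapply(pr$edge.length, function(t) oracle_pmat(q01, q10, t))
  internal <- (ntip + 1L):nmax
  root <- pr$edge[nrow(pr$edge), 1L]
  tot <- 0
  for (i in 0:(2^length(internal) - 1L)) {
    st <- integer(nmax)
    st[seq_len(ntip)] <- s
    st[internal] <- as.integer(intToBits(i))[seq_along(internal)]
    w <- if (root_prior == "fixed") as.numeric(st[root] == root_state) else 0.5
    if (w == 0) next
    p <- w
    for (e in seq_len(nrow(pr$edge)))
      p <- p * Plist[[e]][st[pr$edge[e, 1L]] + 1L, st[pr$edge[e, 2L]] + 1L]
    tot <- tot + p
  }
  log(tot)
}

# Exhaustive marginal ancestral reconstruction by enumeration (fixed or flat
# root), normalized per internal node.
oracle_mk2_marginal <- function(tree, tip_states, q01, q10, root_state = 1L,
                                flat_root = FALSE) {
  pr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(pr)
  nmax <- max(pr$edge)
  s <- tip_states[pr$tip.label]
  Plist <- lapply(pr$edge.length, function(t) oracle_pmat(q01, q10, t))
  internal <- (ntip + 1L):nmax
  root <- pr$edge[nrow(pr$edge), 1L]
  post <- matrix(0, length(internal), 2L,
                 dimnames = list(as.character(internal), NULL))
  for (i in 0:(2^length(internal) - 1L)) {
    st <- integer(nmax)
    st[seq_len(ntip)] <- s
    st[internal] <- as.integer(intToBits(i))[seq_along(internal)]
    if (!flat_root && st[root] != root_state) next
    p <- 1
    for (e in seq_len(nrow(pr$edge)))
      p <- p * Plist[[e]][st[pr$edge[e, 1L]] + 1L, st[pr$edge[e, 2L]] + 1L]
    for (k in seq_along(internal))
      post[k, st[internal[k]] + 1L] <- post[k, st[internal[k]] + 1L] + p
  }
  sweep(post, 1L, rowSums(post), "/")
}

# A small deterministic non-ultrametric tree for error-path tests.
nonultra_tree <- function() read_newick("((A:1,B:2):1,C:2);")
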