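# Independent oracles, kept deliberately naive.

# All is_a path lengths from the root to a term, by exhaustive path
# enumeration over the raw edge list.
oracle_path_lengths <- function(dag, term, root = "GO:0003674") {
  isa <- dag$edges[dag$edges$relation == "is_a", , drop = FALSE]
  walk <- function(id) {
    if (id == root) return(0L)
    ps <- isa$parent[isa$child == id]
    if (!length(ps)) return(integer(0))
    unlist(lapply(ps, function(p) walk(p) + 1L))
  }
  sort(unique(walk(term)))
}

# One-sided hypergeometric upper tail P(X >= x) by full enumeration of
# the probability mass (no phyper, no fisher.test).
oracle_hyper_tail <- function(x, M, K, k) {
  # M successes in a universe of K, draw k, observe >= x successes
  probs <- vapply(0:k, function(i)
    choose(M, i) * choose(K - M, k - i) / choose(K, k), numeric(1))
  sum(probs[(x + 1):(k + 1)])
}

# Exhaustive enumeration of all unrooted binary topologies on the rows
# of m, with the optimum length (Farris evaluation reused only for
# scoring; topology generation is independent of the search code).
oracle_exhaustive_optimum <- function(m) {
  n <- nrow(m)
  X <- m; storage.mode(X) <- "integer"
  trees <- list(gocensus:::utree_triplet(1:3, n, rownames(m), n + 1L))
  if (n > 3L) for (t in 4:n) {
    nxt <- list()
    for (ut in trees) {
      for (k in seq_len(nrow(ut$edge))) {
        e <- ut$edge
        a <- e[k, 1L]; b <- e[k, 2L]
        w <- max(gocensus:::utree_nodes(ut)) + 1L
        e2 <- rbind(e[-k, , drop = FALSE], c(a, w), c(w, b), c(w, t))
        nxt[[length(nxt) + 1L]] <- gocensus:::new_utree(e2, n, rownames(m))
      }
    }
    trees <- nxt
  }
  lens <- vapply(trees, function(u) sum(gocensus:::farris_down(u, X)$len),
                 numeric(1))
  list(optimum = min(lens), n_topologies = length(trees))
}

# Star-tree (single ancestral state) minimum for an ordered character by
# brute force over all candidate ancestral states.
oracle_star_length <- function(x) {
  min(vapply(0:max(x), function(a) sum(abs(x - a)), numeric(1)))
}

random_state_matrix <- function(n, k, smax = 31) {
  m <- matrix(sample(0:smax, n * k, replace = TRUE), n, k)
  rownames(m) <- paste0("t", seq_len(n))
  storage.mode(m) <- "integer"
  m
}
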