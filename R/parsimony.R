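#' Minimal tree length under Wagner (linearly ordered) parsimony
#'
#' Computes the minimum number of steps required by a set of linearly
#' ordered multistate characters on a fixed unrooted topology, using the
#' Farris interval down-pass. A change between states `i` and `j` costs
#' `|i - j|`; the result is independent of where the computation roots the
#' tree.
#'
#' @param tree an unrooted or rooted binary tree (`ape::phylo`); rooted
#'   trees are unrooted first (length is rooting-invariant).
#' @param m integer matrix of character states (taxa in rows, characters in
#'   columns); rownames must match the tip labels.
#' @param per_character if `TRUE`, return the per-character step vector
#'   instead of the total.
#' @return total tree length in steps (or a per-character vector).
#' @seealso [sankoff_length()] for the independent dynamic-programming
#'   oracle, [heuristic_search()] to search topologies.
#' @export
wagner_length <- function(tree, m, per_character = FALSE) {
  ut <- as_utree(tree)
  X <- states_for_utree(ut, m)
  check_states(X)
  if (ut$ntip == 2L) {
    len <- abs(X[1L, ] - X[2L, ])
  } else {
    len <- farris_down(ut, X)$len
  }
  if (per_character) len else sum(len)
}

#' Tree length by generalized Sankoff dynamic programming
#'
#' Independent oracle for [wagner_length()]: evaluates the same additive
#' cost (`c(i, j) = |i - j|`) by full dynamic programming over all states
#' at every internal node. Slower, but makes no use of interval algebra,
#' so agreement between the two is a meaningful check.
#'
#' @inheritParams wagner_length
#' @return total tree length in steps (or a per-character vector).
#' @export
sankoff_length <- function(tree, m, per_character = FALSE) {
  ut <- as_utree(tree)
  X <- states_for_utree(ut, m)
  check_states(X)
  if (ut$ntip == 2L) {
    len <- abs(X[1L, ] - X[2L, ])
    return(if (per_character) len else sum(len))
  }
  ori <- utree_orient(ut)
  smax <- max(X)
  states <- 0:smax
  costmat <- abs(outer(states, states, "-"))
  len <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    C <- matrix(Inf, max(ori$present), smax + 1L)
    for (t in ori$tips) {
      C[t, ] <- Inf
      C[t, X[t, j] + 1L] <- 0
    }
    for (v in ori$postorder) {
      if (v <= ut$ntip) next
      acc <- numeric(smax + 1L)
      for (ch in ori$children[[v]]) {
        acc <- acc + apply(costmat + rep(C[ch, ], each = smax + 1L), 1L, min)
      }
      C[v, ] <- acc
    }
    top <- ori$children[[ori$anchor]]
    len[j] <- min(C[top, ] + abs(states - X[ori$anchor, j]))
  }
  if (per_character) len else sum(len)
}

check_states <- function(X) {
  if (any(is.na(X)) || any(X < 0))
    stop("character states must be non-negative integers")
  invisible(X)
}

as_utree <- function(tree) {
  if (inherits(tree, "utree")) return(tree)
  if (inherits(tree, "phylo")) return(utree_from_phylo(tree))
  stop("tree must be an ape::phylo object")
}

# --- stepwise addition ------------------------------------------------------

stepwise_addition_utree <- function(m, order) {
  n <- nrow(m)
  labels <- rownames(m)
  X <- m
  storage.mode(X) <- "integer"
  next_id <- n + 1L
  ut <- utree_triplet(order[1:3], n, labels, next_id)
  next_id <- next_id + 1L
  if (n > 3L) for (t in order[4:n]) {
    ei <- farris_edge_intervals(ut, X)
    xt <- X[t, ]
    best_cost <- Inf; best_v <- NA_integer_
    for (v in ei$edge_nodes) {
      cost <- sum(interval_point_gap(ei$flo[v, ], ei$fhi[v, ], xt))
      if (cost < best_cost) { best_cost <- cost; best_v <- v }
    }
    ut <- utree_attach_tip(ut, best_v, ei$ori$parent[best_v], t, next_id)
    next_id <- next_id + 1L
  }
  ut
}

# --- TBR --------------------------------------------------------------------

# Split the tree at edge row k; returns the two components as utrees (single
# tips are returned as the tip id) plus the ids of suppressed internal
# endpoints, reusable as junction nodes on reattachment.
utree_split <- function(ut, k) {
  a <- ut$edge[k, 1L]; b <- ut$edge[k, 2L]
  rest <- ut$edge[-k, , drop = FALSE]
  comp_of <- function(start) {
    seen <- start
    repeat {
      hit <- rest[, 1L] %in% seen | rest[, 2L] %in% seen
      nodes <- unique(c(seen, as.vector(rest[hit, ])))
      if (length(nodes) == length(seen)) break
      seen <- nodes
    }
    seen
  }
  make_comp <- function(x) {
    nodes <- comp_of(x)
    sub <- rest[rest[, 1L] %in% nodes & rest[, 2L] %in% nodes, , drop = FALSE]
    if (nrow(sub) == 0L) return(list(tip = x, junction = NA_integer_))
    # suppress the split endpoint x (now degree 2)
    touch <- which(sub[, 1L] == x | sub[, 2L] == x)
    nb <- setdiff(as.vector(sub[touch, ]), x)
    sub <- sub[-touch, , drop = FALSE]
    sub <- rbind(sub, nb)
    list(tree = new_utree(sub, ut$ntip, ut$labels), junction = x)
  }
  list(A = make_comp(a), B = make_comp(b))
}

# Attachment descriptors for one side of a bisection: the per-edge fold
# intervals (or the tip's point states), the side's unrooted length and the
# bookkeeping needed to rebuild.
side_points <- function(comp, X) {
  if (!is.null(comp$tip)) {
    xt <- X[comp$tip, ]
    return(list(single = TRUE, tip = comp$tip, len = 0,
                flo = matrix(xt, 1L), fhi = matrix(xt, 1L),
                nodes = NA_integer_, parents = NA_integer_))
  }
  tr <- comp$tree
  if (nrow(tr$edge) == 1L) {
    v1 <- tr$edge[1L, 1L]; v2 <- tr$edge[1L, 2L]
    lo <- pmin(X[v1, ], X[v2, ]); hi <- pmax(X[v1, ], X[v2, ])
    return(list(single = FALSE, tree = tr, len = sum(hi - lo),
                flo = matrix(lo, 1L), fhi = matrix(hi, 1L),
                nodes = v2, parents = v1, junction = comp$junction))
  }
  ei <- farris_edge_intervals(tr, X)
  list(single = FALSE, tree = tr, len = ei$total,
       flo = ei$flo[ei$edge_nodes, , drop = FALSE],
       fhi = ei$fhi[ei$edge_nodes, , drop = FALSE],
       nodes = ei$edge_nodes, parents = ei$ori$parent[ei$edge_nodes],
       junction = comp$junction)
}

# One full TBR sweep; returns the best strictly-improving neighbour, or, if
# collect_equal, also all distinct neighbours matching `target_len`.
tbr_scan <- function(ut, X, current_len, collect_equal = FALSE,
                     target_len = current_len) {
  best_len <- current_len
  best <- NULL
  equal_trees <- list()
  for (k in seq_len(nrow(ut$edge))) {
    sp <- utree_split(ut, k)
    A <- side_points(sp$A, X)
    B <- side_points(sp$B, X)
    base <- A$len + B$len
    if (base > best_len && !collect_equal) next
    for (i in seq_len(nrow(A$flo))) {
      gaps <- interval_gap(A$flo[i, ], A$fhi[i, ],
                           t(B$flo), t(B$fhi))
      # gaps is a matrix [nchar x nB] when nB > 1; sum per attachment
      if (is.matrix(gaps)) cost <- colSums(gaps) else cost <- sum(gaps)
      lens <- base + cost
      hits <- which(lens < best_len |
                    (collect_equal & lens == target_len))
      for (jj in hits) {
        newt <- tbr_reconnect(ut, A, B, i, jj)
        L <- base + cost[jj]
        if (L < best_len) {
          best_len <- L; best <- newt
          if (!collect_equal) next
        }
        if (collect_equal && L == target_len)
          equal_trees[[length(equal_trees) + 1L]] <- newt
      }
    }
  }
  list(len = best_len, tree = best, equal = equal_trees)
}

# Rebuild the tree for attachment i (side A) x j (side B), reusing the
# suppressed junction ids.
tbr_reconnect <- function(ut, A, B, i, j) {
  insert_side <- function(S, idx, junction_pool) {
    if (S$single) return(list(edges = NULL, port = S$tip, pool = junction_pool))
    v <- S$nodes[idx]; p <- S$parents[idx]
    w <- junction_pool[1L]
    e <- S$tree$edge
    kk <- which((e[, 1L] == v & e[, 2L] == p) | (e[, 2L] == v & e[, 1L] == p))[1L]
    e <- e[-kk, , drop = FALSE]
    e <- rbind(e, c(p, w), c(w, v))
    list(edges = e, port = w, pool = junction_pool[-1L])
  }
  pool <- c(if (!A$single) A$junction, if (!B$single) B$junction)
  ra <- insert_side(A, i, pool)
  rb <- insert_side(B, j, ra$pool)
  edges <- rbind(ra$edges, rb$edges, c(ra$port, rb$port))
  new_utree(edges, ut$ntip, ut$labels)
}

#' Heuristic maximum-parsimony search (stepwise addition + TBR)
#'
#' Random-addition-sequence stepwise addition followed by tree
#' bisection-reconnection (TBR) branch swapping to a local optimum, under
#' Wagner ordered-character costs. All distinct minimal-length trees found
#' across replicates (including equal-length TBR neighbours of the optima)
#' are returned. Deterministic given `seed`.
#'
#' @param m taxa-by-characters integer state matrix with rownames.
#' @param n_addseq number of random addition sequences.
#' @param seed master seed; replicate `r` uses stream `seed + r`.
#' @param collect_ties also sweep the final plateau for equal-length
#'   neighbours of the best trees (one round).
#' @return an object of class `mp_search`: list with `trees` (a
#'   `multiPhylo` of distinct optimal unrooted trees), `length` (steps),
#'   and `consensus` (strict consensus, `phylo`).
#' @export
heuristic_search <- function(m, n_addseq = 10, seed = NULL,
                             collect_ties = TRUE) {
  n <- nrow(m)
  if (is.null(rownames(m))) stop("state matrix must have rownames")
  X <- m; storage.mode(X) <- "integer"
  check_states(X)
  if (n < 2L) stop("need at least 2 taxa")
  if (n < 4L) {
    ut <- if (n == 2L) new_utree(cbind(1L, 2L), 2L, rownames(m))
          else utree_triplet(1:3, 3L, rownames(m), 4L)
    return(finish_search(list(ut), wagner_length(ut, m), m))
  }
  best_len <- Inf
  found <- list()   # canonical -> utree
  for (r in seq_len(n_addseq)) {
    if (!is.null(seed)) set.seed(seed + r)
    ord <- sample.int(n)
    ut <- stepwise_addition_utree(X, ord)
    len <- sum(farris_down(ut, X)$len)
    repeat {
      sc <- tbr_scan(ut, X, len)
      if (sc$len < len) { ut <- sc$tree; len <- sc$len } else break
    }
    if (len < best_len) { best_len <- len; found <- list() }
    if (len == best_len) found[[utree_canonical(ut)]] <- ut
  }
  if (collect_ties) {
    frontier <- found
    for (ut in frontier) {
      sc <- tbr_scan(ut, X, best_len, collect_equal = TRUE,
                     target_len = best_len)
      for (eq in sc$equal) {
        key <- utree_canonical(eq)
        if (is.null(found[[key]])) found[[key]] <- eq
      }
    }
  }
  finish_search(found[order(names(found))], best_len, m)
}

finish_search <- function(utrees, len, m) {
  utrees <- unname(utrees)
  phylos <- lapply(utrees, utree_to_phylo)
  class(phylos) <- "multiPhylo"
  cons <- if (length(phylos) > 1L) ape::consensus(phylos) else phylos[[1L]]
  structure(list(trees = phylos, utrees = utrees, length = len,
                 n_trees = length(utrees), consensus = cons),
            class = "mp_search")
}

#' @export
print.mp_search <- function(x, ...) {
  cat(sprintf("Maximum-parsimony search: %d optimal tree(s), length %d steps\n",
              x$n_trees, as.integer(x$length)))
  invisible(x)
}

# --- Lundberg rooting -------------------------------------------------------

#' Root a most-parsimonious tree by the Lundberg method
#'
#' A hypothetical ancestor with the given character states is attached, in
#' turn, to every edge of the unrooted tree; the attachment adding the
#' fewest steps wins, and the root is placed at that junction (the
#' hypothetical ancestor itself is not kept in the reported tree). For
#' trees of functions the conventional ancestor is the per-character
#' maximum observed state (most abundant = oldest); for trees of organisms
#' it is the all-zero vector.
#'
#' @param tree unrooted binary `phylo` (or `mp_search`, in which case the
#'   first tree in canonical order is rooted).
#' @param m taxa-by-characters state matrix with rownames.
#' @param ancestor `"max"`, `"zero"`, or an explicit integer vector of
#'   per-character ancestral states.
#' @return a list with `tree` (rooted `phylo`), `attachment_cost` (steps
#'   added by the best attachment), `rooted_length`, `tied_edges` (number
#'   of equally optimal root positions; ties resolved by the lowest edge
#'   index in the canonical post-order edge enumeration) and
#'   `root_bipartition` (tip labels on one side of the root).
#' @export
lundberg_root <- function(tree, m, ancestor = c("max", "zero")) {
  if (inherits(tree, "mp_search")) tree <- tree$trees[[1L]]
  ut <- as_utree(tree)
  X <- states_for_utree(ut, m)
  check_states(X)
  if (is.character(ancestor)) {
    ancestor <- match.arg(ancestor)
    anc <- switch(ancestor,
                  max = apply(X, 2L, max),
                  zero = integer(ncol(X)))
  } else {
    if (length(ancestor) != ncol(m))
      stop("ancestor vector length must equal the number of characters")
    anc <- as.integer(ancestor)
  }
  ei <- farris_edge_intervals(ut, X)
  costs <- vapply(ei$edge_nodes, function(v)
    sum(interval_point_gap(ei$flo[v, ], ei$fhi[v, ], anc)), numeric(1))
  best <- min(costs)
  ties <- which(costs == best)
  v <- ei$edge_nodes[ties[1L]]      # canonical post-order tie-break
  rooted <- utree_to_phylo(ut, root_child = v, root_parent = ei$ori$parent[v])
  side <- sort(utree_clade_tips(ut, v, ei$ori))
  all_tips <- sort(utree_nodes(ut)[utree_nodes(ut) <= ut$ntip])
  other <- setdiff(all_tips, side)
  if (length(other) < length(side) ||
      (length(other) == length(side) && min(other) < min(side)))
    side <- other
  list(tree = rooted,
       attachment_cost = best,
       unrooted_length = ei$total,
       rooted_length = ei$total + best,
       tied_edges = length(ties),
       root_bipartition = ut$labels[side])
}

utree_clade_tips <- function(ut, v, ori) {
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (x <= ut$ntip) out <- c(out, x)
    else stack <- c(stack, ori$children[[x]])
  }
  out
}

# --- fit indices ------------------------------------------------------------

#' Consistency, retention and homoplasy indices
#'
#' Per-character and ensemble fit of linearly ordered characters to a
#' topology. For an ordered character, the minimum conceivable steps is its
#' state range; the maximum is the star-tree length (sum of absolute
#' deviations from the character's median state); observed steps come from
#' the Farris pass on the tree. CI = sum(min)/sum(obs),
#' RI = (sum(max) - sum(obs)) / (sum(max) - sum(min)), ensemble
#' HI = 1 - CI; per-character HI = 1 - min/obs (0 where obs = 0).
#'
#' @inheritParams wagner_length
#' @return list with `per_character` data.frame (min, max, obs, ci, ri, hi)
#'   and ensemble `CI`, `RI`, `HI`, `length`.
#' @export
fit_indices <- function(tree, m) {
  ut <- as_utree(tree)
  X <- states_for_utree(ut, m)
  obs <- wagner_length(ut, X, per_character = TRUE)
  minst <- apply(X, 2L, function(x) max(x) - min(x))
  maxst <- apply(X, 2L, function(x) sum(abs(x - stats::median(x))))
  # star-tree length of an ordered character is minimised at the median;
  # with an even number of taxa any value in the median interval ties.
  ci_c <- ifelse(obs > 0, minst / obs, NA_real_)
  hi_c <- ifelse(obs > 0, 1 - minst / obs, 0)
  ri_c <- ifelse(maxst > minst, (maxst - obs) / (maxst - minst), NA_real_)
  tot_obs <- sum(obs); tot_min <- sum(minst); tot_max <- sum(maxst)
  CI <- if (tot_obs > 0) tot_min / tot_obs else 1
  RI <- if (tot_max > tot_min) (tot_max - tot_obs) / (tot_max - tot_min)
        else NA_real_
  list(per_character = data.frame(
         character = colnames(X) %||% seq_len(ncol(X)),
         min_steps = minst, max_steps = maxst, obs_steps = obs,
         ci = ci_c, ri = ri_c, hi = hi_c, row.names = NULL),
       CI = CI, RI = RI, HI = 1 - CI, length = tot_obs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- bootstrap --------------------------------------------------------------

#' Non-parametric bootstrap support for tree bipartitions
#'
#' Characters are resampled with replacement; each replicate is analysed
#' with the same heuristic search, and a bipartition of the reference tree
#' is counted as recovered when it appears in the strict consensus of the
#' replicate's optimal trees. Replicate `r` draws from RNG stream
#' `seed + 1000 + r`, so replicates are order-independent.
#'
#' @param tree reference unrooted tree (`phylo` or `mp_search`).
#' @param m taxa-by-characters state matrix with rownames.
#' @param n_reps number of bootstrap replicates.
#' @param seed master seed.
#' @param n_addseq addition sequences per replicate search.
#' @return data.frame with one row per internal bipartition of the
#'   reference tree: the smaller tip set, support %, and a majority flag.
#' @export
bootstrap_support <- function(tree, m, n_reps = 100, seed = 1,
                              n_addseq = 2) {
  if (inherits(tree, "mp_search")) tree <- tree$trees[[1L]]
  ut <- as_utree(tree)
  # reference bipartition keys use tip ids in *matrix* order
  ref_ut <- relabel_to_matrix_order(ut, m)
  ref <- utree_bipartitions(ref_ut)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  counts <- setNames(numeric(length(ref)), ref)
  for (r in seq_len(n_reps)) {
    set.seed(seed + 1000L + r)
    idx <- sample.int(ncol(m), replace = TRUE)
    mb <- m[, idx, drop = FALSE]
    res <- heuristic_search(mb, n_addseq = n_addseq, seed = seed + 2000L + r,
                            collect_ties = TRUE)
    reps <- lapply(res$utrees, function(u)
      utree_bipartitions(relabel_to_matrix_order(u, m)))
    common <- Reduce(intersect, reps)
    hit <- ref %in% common
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_reps
  tipsets <- lapply(strsplit(names(counts), ".", fixed = TRUE),
                    function(ix) rownames(m)[as.integer(ix)])
  data.frame(bipartition = names(counts),
             tips = vapply(tipsets, paste, character(1), collapse = ","),
             support = unname(support),
             majority = unname(support > 50),
             row.names = NULL)
}

#' Write bootstrap support onto a tree's internal node labels
#'
#' Matches each internal node's bipartition against a
#' [bootstrap_support()] table and stores the support percentage as the
#' node label, the conventional way to carry BS values in newick.
#'
#' @param tree a rooted or unrooted `phylo`.
#' @param bs data.frame from [bootstrap_support()].
#' @param m the state matrix the support was computed on (its row order
#'   defines the bipartition keys).
#' @return the tree with `node.label` set ("" where no match, e.g. the
#'   root).
#' @export
annotate_bootstrap <- function(tree, bs, m) {
  n <- length(tree$tip.label)
  idx <- match(tree$tip.label, rownames(m))
  if (anyNA(idx)) stop("tree tips missing from the state matrix")
  phy <- stats::reorder(tree)
  labels <- character(phy$Nnode)
  all_ids <- seq_len(n)
  for (node in (n + 1L):(n + phy$Nnode)) {
    tips <- idx[tip_descendants(phy, node)]
    if (length(tips) < 2L || length(tips) > n - 2L) next
    key1 <- paste(sort(tips), collapse = ".")
    key2 <- paste(sort(setdiff(all_ids, tips)), collapse = ".")
    hit <- match(c(key1, key2), bs$bipartition)
    hit <- hit[!is.na(hit)][1]
    if (!is.na(hit)) labels[node - n] <- format(bs$support[hit])
  }
  phy$node.label <- labels
  phy
}

tip_descendants <- function(phy, node) {
  n <- length(phy$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= n) out <- c(out, v)
    else stack <- c(stack, phy$edge[phy$edge[, 1L] == v, 2L])
  }
  out
}

# Map a utree's tip ids onto the ordering of a reference matrix, so that
# bipartition keys are comparable across searches on resampled matrices.
relabel_to_matrix_order <- function(ut, m) {
  idx <- match(ut$labels, rownames(m))
  e <- ut$edge
  tipmask <- e <= ut$ntip
  e[tipmask] <- idx[e[tipmask]]
  new_utree(e, ut$ntip, rownames(m))
}
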