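# Internal machinery for unrooted binary trees and Farris interval passes.
#
# A "utree" is a minimal unrooted binary tree: tips are node ids 1..ntip,
# internal nodes are ids > ntip (each of degree 3), edges is a 2-column
# integer matrix. For ntip = 3 there is a single internal node; for
# ntip = 2 a single edge. Character data are integer matrices with one row
# per tip id and one column per character (states 0..31, cost |i - j|).

new_utree <- function(edge, ntip, labels = NULL) {
  storage.mode(edge) <- "integer"
  if (is.null(labels)) labels <- paste0("t", seq_len(ntip))
  structure(list(edge = edge, ntip = as.integer(ntip), labels = labels),
            class = "utree")
}

utree_nodes <- function(ut) sort(unique(as.vector(ut$edge)))

utree_adjacency <- function(ut) {
  nmax <- max(ut$edge)
  adj <- vector("list", nmax)
  for (i in seq_len(nrow(ut$edge))) {
    a <- ut$edge[i, 1L]; b <- ut$edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Orient the tree away from an anchor tip ("rooted at a leaf"): every node
# except the anchor gets a parent, internal nodes get exactly two children.
# Returns parent vector, children list, a postorder over non-anchor nodes,
# and the anchor tip id. Edge k of the orientation is identified with its
# child node (all nodes except the anchor), giving the 2*ntip - 3 edges.
utree_orient <- function(ut, anchor = NULL) {
  adj <- utree_adjacency(ut)
  present <- utree_nodes(ut)
  tips <- present[present <= ut$ntip]
  if (is.null(anchor)) anchor <- min(tips)
  nmax <- max(present)
  parent <- integer(nmax)
  order <- integer(0)
  # iterative DFS from the anchor
  stack <- anchor
  visited <- logical(nmax)
  visit_order <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    visited[v] <- TRUE
    visit_order <- c(visit_order, v)
    for (w in adj[[v]]) if (!visited[w]) {
      parent[w] <- v
      stack <- c(stack, w)
    }
  }
  postorder <- rev(visit_order)            # children before parents
  children <- vector("list", nmax)
  for (v in setdiff(present, anchor)) {
    p <- parent[v]
    children[[p]] <- c(children[[p]], v)
  }
  list(parent = parent, children = children,
       postorder = postorder[postorder != anchor],
       preorder = visit_order[visit_order != anchor],
       anchor = anchor, present = present, tips = tips)
}

# Fold two interval sets (vectorised over characters).
# Returns lo, hi of the folded interval and the non-negative gap cost.
interval_fold <- function(lo1, hi1, lo2, hi2) {
  il <- pmax(lo1, lo2); ih <- pmin(hi1, hi2)
  ov <- il <= ih
  gap <- pmax(0L, il - ih)
  list(lo = ifelse(ov, il, ih), hi = ifelse(ov, ih, il), cost = gap)
}

# Distance from interval [lo, hi] to point x (vectorised).
interval_point_gap <- function(lo, hi, x) pmax(0L, pmax(lo - x, x - hi))

interval_gap <- function(lo1, hi1, lo2, hi2) {
  pmax(0L, pmax(lo1 - hi2, lo2 - hi1))
}

# Farris down-pass on the leaf-anchored orientation. X is [>=ntip, nchar]
# (rows indexed by tip id). Returns per-character minimal length and the
# downward interval of every node (rows indexed by node id).
farris_down <- function(ut, X, ori = NULL) {
  if (is.null(ori)) ori <- utree_orient(ut)
  nchar_ <- ncol(X)
  nmax <- max(ori$present)
  lo <- matrix(0L, nmax, nchar_); hi <- matrix(0L, nmax, nchar_)
  for (t in ori$tips) { lo[t, ] <- X[t, ]; hi[t, ] <- X[t, ] }
  len <- numeric(nchar_)
  for (v in ori$postorder) {
    if (v <= ut$ntip) next
    ch <- ori$children[[v]]
    f <- interval_fold(lo[ch[1L], ], hi[ch[1L], ], lo[ch[2L], ], hi[ch[2L], ])
    lo[v, ] <- f$lo; hi[v, ] <- f$hi
    len <- len + f$cost
  }
  top <- ori$children[[ori$anchor]]
  len <- len + interval_point_gap(lo[top, ], hi[top, ], X[ori$anchor, ])
  list(len = len, lo = lo, hi = hi, ori = ori)
}

# Per-edge fold intervals: for every edge (identified by its child node v in
# the anchored orientation) the interval of the fold between the subtree
# below v and the rest of the tree. Used for stepwise addition, TBR
# reattachment scans and Lundberg rooting.
farris_edge_intervals <- function(ut, X) {
  ori <- utree_orient(ut)
  dn <- farris_down(ut, X, ori)
  nchar_ <- ncol(X)
  nmax <- max(ori$present)
  ulo <- matrix(0L, nmax, nchar_); uhi <- matrix(0L, nmax, nchar_)
  # upward interval seen from the parent side of each node
  top <- ori$children[[ori$anchor]]
  ulo[top, ] <- X[ori$anchor, ]; uhi[top, ] <- X[ori$anchor, ]
  for (v in ori$preorder) {
    if (v <= ut$ntip) next
    ch <- ori$children[[v]]
    f1 <- interval_fold(ulo[v, ], uhi[v, ], dn$lo[ch[2L], ], dn$hi[ch[2L], ])
    ulo[ch[1L], ] <- f1$lo; uhi[ch[1L], ] <- f1$hi
    f2 <- interval_fold(ulo[v, ], uhi[v, ], dn$lo[ch[1L], ], dn$hi[ch[1L], ])
    ulo[ch[2L], ] <- f2$lo; uhi[ch[2L], ] <- f2$hi
  }
  edge_nodes <- setdiff(c(ori$postorder), ori$anchor)
  flo <- matrix(0L, nmax, nchar_); fhi <- matrix(0L, nmax, nchar_)
  for (v in edge_nodes) {
    f <- interval_fold(dn$lo[v, ], dn$hi[v, ], ulo[v, ], uhi[v, ])
    flo[v, ] <- f$lo; fhi[v, ] <- f$hi
  }
  list(len = dn$len, total = sum(dn$len), flo = flo, fhi = fhi,
       edge_nodes = edge_nodes, ori = ori)
}

# --- tree editing -----------------------------------------------------------

# Attach tip `t` (id <= ntip) onto the edge identified by child node v of the
# anchored orientation; `next_id` supplies the id of the new internal node.
utree_attach_tip <- function(ut, v, parent_of_v, t, next_id) {
  e <- ut$edge
  k <- which((e[, 1L] == v & e[, 2L] == parent_of_v) |
             (e[, 2L] == v & e[, 1L] == parent_of_v))[1L]
  e <- e[-k, , drop = FALSE]
  e <- rbind(e, c(parent_of_v, next_id), c(next_id, v), c(next_id, t))
  new_utree(e, ut$ntip, ut$labels)
}

# The unique unrooted tree on three tips.
utree_triplet <- function(tips, ntip, labels, internal_id) {
  e <- cbind(rep(internal_id, 3L), tips)
  new_utree(e, ntip, labels)
}

# --- canonical form / bipartitions -----------------------------------------

# Canonical newick-like string of the unrooted topology (labels by tip id),
# used to deduplicate co-optimal trees deterministically.
utree_canonical <- function(ut) {
  ori <- utree_orient(ut, anchor = min(utree_nodes(ut)[utree_nodes(ut) <= ut$ntip]))
  rec <- function(v) {
    if (v <= ut$ntip) return(sprintf("%d", v))
    parts <- sort(vapply(ori$children[[v]], rec, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  top <- ori$children[[ori$anchor]]
  paste0("(", ori$anchor, ",", rec(top), ")")
}

# Non-trivial bipartitions as canonical keys: for each internal edge, the
# tip set on the side away from the smallest tip, sorted.
utree_bipartitions <- function(ut) {
  ori <- utree_orient(ut)
  tipsets <- vector("list", max(ori$present))
  for (v in ori$postorder) {
    if (v <= ut$ntip) tipsets[[v]] <- v
    else tipsets[[v]] <- sort(unlist(tipsets[ori$children[[v]]]))
  }
  keys <- character(0)
  ntips_present <- length(ori$tips)
  for (v in ori$postorder) {
    if (v <= ut$ntip) next
    s <- tipsets[[v]]
    if (length(s) >= 2L && length(s) <= ntips_present - 2L)
      keys <- c(keys, paste(s, collapse = "."))
  }
  unique(keys)
}

# --- conversions ------------------------------------------------------------

# Rooted ape::phylo from a utree plus a root position on the edge whose
# orientation child is `v` (parent `p`). If v/p are NULL the tree is
# exported unrooted (basal trichotomy), as ape represents unrooted trees.
utree_to_phylo <- function(ut, root_child = NULL, root_parent = NULL) {
  adj <- utree_adjacency(ut)
  present <- utree_nodes(ut)
  tips <- present[present <= ut$ntip]
  n <- length(tips)
  tip_new <- integer(max(present))
  tip_new[tips] <- seq_len(n)
  if (!is.null(root_child)) {
    root_kids <- c(root_child, root_parent)
    blocked <- rbind(c(root_child, root_parent), c(root_parent, root_child))
  } else {
    start <- present[present > ut$ntip][1L]
    if (is.na(start)) {  # two-tip tree
      phy <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                  tip.label = ut$labels[tips], Nnode = 1L)
      class(phy) <- "phylo"
      return(phy)
    }
    root_kids <- adj[[start]]
    blocked <- cbind(start, root_kids)   # start node IS the root
  }
  new_id <- n + 1L
  node_new <- integer(max(present))
  edges <- matrix(integer(0), 0, 2)
  # BFS assigning ids; virtual root gets n+1
  assign_id <- function(v) {
    if (v <= ut$ntip) return(tip_new[v])
    if (node_new[v] == 0L) { new_id <<- new_id + 1L; node_new[v] <<- new_id }
    node_new[v]
  }
  if (!is.null(root_child)) {
    root_id <- n + 1L
    queue <- list(list(node = root_child, par = root_parent, par_id = root_id),
                  list(node = root_parent, par = root_child, par_id = root_id))
  } else {
    start <- present[present > ut$ntip][1L]
    node_new[start] <- n + 1L
    queue <- lapply(adj[[start]], function(w)
      list(node = w, par = start, par_id = n + 1L))
  }
  while (length(queue)) {
    item <- queue[[1L]]; queue <- queue[-1L]
    vid <- assign_id(item$node)
    edges <- rbind(edges, c(item$par_id, vid))
    if (item$node > ut$ntip) {
      for (w in adj[[item$node]]) if (w != item$par) {
        queue <- c(queue, list(list(node = w, par = item$node, par_id = vid)))
      }
    }
  }
  phy <- list(edge = edges, tip.label = ut$labels[tips],
              Nnode = max(edges) - n)
  class(phy) <- "phylo"
  stats::reorder(phy)
}

# utree from an ape::phylo (rooted trees are unrooted first).
utree_from_phylo <- function(phy) {
  if (length(phy$tip.label) == 2L)
    return(new_utree(cbind(1L, 2L), 2L, phy$tip.label))
  phy <- ape::unroot(phy)
  if (!ape::is.binary(phy) && length(phy$tip.label) > 3L)
    stop("tree must be binary (fully resolved)")
  new_utree(phy$edge, length(phy$tip.label), phy$tip.label)
}

# Character matrix rows indexed by tip id for a given utree/taxon order:
# takes a taxa-by-characters matrix with rownames and returns rows ordered
# to match tip ids (label i -> tip id i).
states_for_utree <- function(ut, m) {
  if (is.null(rownames(m))) stop("state matrix must have rownames")
  idx <- match(ut$labels, rownames(m))
  if (anyNA(idx))
    stop("taxa missing from state matrix: ",
         paste(ut$labels[is.na(idx)], collapse = ", "))
  X <- m[idx, , drop = FALSE]
  storage.mode(X) <- "integer"
  rownames(X) <- ut$labels
  X
}
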