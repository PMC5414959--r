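#' Relative node-distance age of every leaf on a rooted tree
#'
#' A leaf's depth is the number of internal nodes on its root-to-leaf
#' path, the root itself excluded (equivalently, path edge count minus
#' one); nd scales depth by the maximum leaf depth so the most basal leaf
#' reads 0 and the deepest 1. The divisor is configurable: the historical
#' description "total number of taxa" is available, but printed timeline
#' values are only consistent with the max-depth divisor, the default.
#'
#' @param tree a rooted `phylo`.
#' @param divisor `"max_depth"` (default) or `"n_taxa"`.
#' @return named numeric vector of nd values (full precision), one per
#'   leaf.
#' @export
node_distance <- function(tree, divisor = c("max_depth", "n_taxa")) {
  divisor <- match.arg(divisor)
  if (!inherits(tree, "phylo")) stop("tree must be an ape::phylo object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  n <- length(tree$tip.label)
  phy <- stats::reorder(tree)               # cladewise: parents first
  depth_edges <- numeric(max(phy$edge))
  for (i in seq_len(nrow(phy$edge)))
    depth_edges[phy$edge[i, 2L]] <- depth_edges[phy$edge[i, 1L]] + 1
  depth <- depth_edges[seq_len(n)] - 1      # internal nodes below the root
  div <- switch(divisor,
                max_depth = max(depth),
                n_taxa = n)
  nd <- if (div > 0) depth / div else rep(0, n)
  names(nd) <- tree$tip.label
  nd
}

#' Distribution index f: fraction of genomes encoding each taxon
#'
#' `f(t) = |{G : g(t, G) > 0}| / |genomes in scope|`. An f of 0 means the
#' taxon is absent from every sampled genome; 1 means universal presence.
#'
#' @param m an `abundance_matrix` (or a plain taxa x genomes matrix).
#' @param genomes optional genome-id subset (e.g. one superkingdom).
#' @return named numeric vector in `[0, 1]`.
#' @export
distribution_index <- function(m, genomes = NULL) {
  g <- if (inherits(m, "abundance_matrix")) m$g else m
  if (!is.null(genomes)) {
    missing <- setdiff(genomes, colnames(g))
    if (length(missing))
      stop("unknown genomes: ", paste(missing, collapse = ", "))
    g <- g[, genomes, drop = FALSE]
  }
  if (ncol(g) == 0L) stop("empty genome scope")
  rowMeans(g > 0)
}

#' Superkingdom Venn group of every taxon
#'
#' Concatenates, in the fixed order A, B, E, the superkingdom letters
#' whose genomes contain the taxon (g > 0 in at least one genome). Taxa
#' absent from every genome get `NA` and are listed separately.
#'
#' @param m an `abundance_matrix`.
#' @param meta genome metadata (genome, superkingdom with values
#'   A/B/E); defaults to the metadata attached to `m`.
#' @return list with `group` (named character vector: "A".."ABE" or NA)
#'   and `absent` (taxa found in no genome).
#' @export
venn_group <- function(m, meta = NULL) {
  g <- if (inherits(m, "abundance_matrix")) m$g else m
  if (is.null(meta) && inherits(m, "abundance_matrix")) meta <- m$meta
  if (is.null(meta)) stop("genome metadata required")
  sk <- meta$superkingdom[match(colnames(g), meta$genome)]
  if (anyNA(sk))
    stop("genomes without superkingdom labels: ",
         paste(colnames(g)[is.na(sk)], collapse = ", "))
  if (!all(sk %in% c("A", "B", "E")))
    stop("superkingdom labels must be A, B or E")
  grp <- apply(g > 0, 1L, function(present) {
    letters_in <- sort(unique(sk[present]))
    if (!length(letters_in)) NA_character_
    else paste(letters_in, collapse = "")
  })
  list(group = grp, absent = names(grp)[is.na(grp)])
}

#' Genealogical sorting index of a leaf group
#'
#' Measures how exclusively a group of leaves is sorted on a rooted tree:
#' `gs = (k - 1) / sum over union nodes of (children - 1)`, where the
#' union nodes are the internal nodes on the paths from the group's
#' leaves to their most recent common ancestor. The index is 1 exactly
#' when the group is monophyletic and decreases as members disperse. The
#' permutation p-value is the fraction of equal-sized leaf groups scoring
#' at least as high: exact by full enumeration when `choose(n, k)` is
#' small, otherwise Monte Carlo with `n_perm` draws.
#'
#' @param tree rooted `phylo`.
#' @param group character vector of tip labels (size >= 2), or `"all"`.
#' @param n_perm Monte Carlo permutations when exhaustive enumeration is
#'   too large.
#' @param seed RNG seed for Monte Carlo permutation.
#' @param exact_limit enumerate exhaustively when `choose(n, k)` is at
#'   most this.
#' @return list with `gsi`, `p`, `method` ("exact" or "sampled").
#' @export
gsi <- function(tree, group, n_perm = 10000, seed = 1,
                exact_limit = 200000) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tips <- tree$tip.label
  if (identical(group, "all")) group <- tips
  if (!all(group %in% tips))
    stop("group contains labels not in the tree")
  k <- length(group)
  if (k < 2L) stop("group size must be >= 2")
  n <- length(tips)
  phy <- stats::reorder(tree)
  parent <- integer(max(phy$edge))
  nkids <- integer(max(phy$edge))
  for (i in seq_len(nrow(phy$edge))) {
    parent[phy$edge[i, 2L]] <- phy$edge[i, 1L]
    nkids[phy$edge[i, 1L]] <- nkids[phy$edge[i, 1L]] + 1L
  }
  root <- n + 1L
  gs_of <- function(tip_ids) {
    # walk each leaf up; union nodes are those reached by >= 1 leaf and
    # at or below the MRCA (the shallowest node reached by all leaves)
    count <- integer(length(parent))
    for (t in tip_ids) {
      v <- parent[t]
      while (v != 0L) {
        count[v] <- count[v] + 1L
        v <- parent[v]
      }
    }
    kk <- length(tip_ids)
    mrca <- root
    # MRCA: deepest node with count == kk; walk from one leaf upward
    v <- parent[tip_ids[1L]]
    while (v != 0L) {
      if (count[v] == kk) { mrca <- v; break }
      v <- parent[v]
    }
    # union nodes: counted nodes that are descendants-or-equal of mrca;
    # equivalently, drop the strict ancestors of the mrca
    v <- parent[mrca]
    while (v != 0L) { count[v] <- 0L; v <- parent[v] }
    u <- which(count > 0L)
    (kk - 1) / sum(nkids[u] - 1L)
  }
  obs <- gs_of(match(group, tips))
  if (choose(n, k) <= exact_limit) {
    combos <- utils::combn(n, k)
    vals <- apply(combos, 2L, gs_of)
    p <- mean(vals >= obs - 1e-12)
    method <- "exact"
  } else {
    set.seed(seed)
    vals <- replicate(n_perm, gs_of(sample.int(n, k)))
    p <- (1 + sum(vals >= obs - 1e-12)) / (n_perm + 1)
    method <- "sampled"
  }
  list(gsi = obs, p = p, method = method)
}

#' Assemble the evolutionary timeline of a rooted tree of functions
#'
#' Combines node-distance ages, distribution indices, Venn superkingdom
#' groups and (optionally) level-1 category membership into one table,
#' mirroring the per-term timeline layout.
#'
#' @param tree rooted `phylo` whose tips are the matrix taxa.
#' @param m an `abundance_matrix` over the same taxa.
#' @param meta genome metadata (defaults to `m$meta`).
#' @param level1_map optional named list: level-1 category id ->
#'   terminal/taxon ids, used to attach categories.
#' @param digits optional presentation rounding for nd (2 for levels 1-2,
#'   4 for level 3 is conventional); `NULL` keeps full precision.
#' @return a `timeline` data.frame: taxon, nd, f, venn, level1.
#' @export
build_timeline <- function(tree, m, meta = NULL, level1_map = NULL,
                           digits = NULL) {
  nd <- node_distance(tree)
  f <- distribution_index(m)
  vg <- venn_group(m, meta)
  taxa <- names(nd)
  f <- f[taxa]; grp <- vg$group[taxa]
  lvl1 <- rep(NA_character_, length(taxa))
  if (!is.null(level1_map)) {
    lvl1 <- vapply(taxa, function(tx) {
      hits <- names(level1_map)[vapply(level1_map, function(s)
        tx %in% s, FALSE)]
      if (length(hits)) paste(sort(hits), collapse = ",") else NA_character_
    }, character(1))
  }
  out <- data.frame(taxon = taxa,
                    nd = if (is.null(digits)) unname(nd)
                         else round(unname(nd), digits),
                    f = unname(f),
                    venn = unname(grp),
                    level1 = unname(lvl1),
                    row.names = NULL)
  class(out) <- c("timeline", "data.frame")
  out
}

#' Write a timeline table as TSV
#' @param timeline a `timeline` data.frame.
#' @param path output file.
#' @export
write_timeline <- function(timeline, path) {
  utils::write.table(timeline, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Age-binned counts of taxa per level-1 category
#'
#' Counts taxa in nd bins (half-open `[lo, hi)`, last bin closed) for
#' each level-1 functional category. A taxon belonging to several
#' categories is counted once per category; such taxa are flagged.
#'
#' @param timeline a `timeline` with non-NA `level1`.
#' @param bins bin edges over nd; default `c(0, 0.4, 0.6, 1)` - the three
#'   conventional age bins.
#' @return list with `table` (bins x categories count matrix),
#'   `multi_category` (taxa in more than one category).
#' @export
age_histogram <- function(timeline, bins = c(0, 0.4, 0.6, 1)) {
  nd <- timeline$nd
  if (any(nd < 0 | nd > 1)) stop("nd values must lie in [0, 1]")
  cats <- strsplit(timeline$level1, ",", fixed = TRUE)
  if (any(vapply(cats, function(x) length(x) == 0L || all(is.na(x)), FALSE)))
    stop("every taxon needs at least one level-1 category")
  nb <- length(bins) - 1L
  bin_of <- function(x) {
    b <- findInterval(x, bins, rightmost.closed = TRUE)
    pmin(pmax(b, 1L), nb)
  }
  bin_labels <- paste0("[", bins[-length(bins)], ",", bins[-1L],
                       c(rep(")", nb - 1L), "]"))
  all_cats <- sort(unique(unlist(cats)))
  tab <- matrix(0L, nb, length(all_cats),
                dimnames = list(bin_labels, all_cats))
  for (i in seq_along(nd)) {
    b <- bin_of(nd[i])
    for (cc in cats[[i]]) tab[b, cc] <- tab[b, cc] + 1L
  }
  list(table = tab,
       multi_category = timeline$taxon[lengths(cats) > 1L])
}

#' Cumulative accumulation of taxa along the timeline
#'
#' Step curves of distinct-taxon counts by nd at each analysed level,
#' plus ordinary least-squares fits of each deeper level's cumulative
#' count against the level-1 cumulative count evaluated on the shared nd
#' grid (slope > 1 means the deeper level accumulates terms faster).
#'
#' @param timelines named list of `timeline` data.frames, e.g.
#'   `list("1" = tl1, "2" = tl2, "3" = tl3)`; the first is the reference.
#' @return list with `curves` (per level data.frame nd, cumulative) and
#'   `fits` (per non-reference level: slope, intercept, r2; `NA` when
#'   fewer than 3 grid points).
#' @export
accumulation_curve <- function(timelines) {
  stopifnot(length(timelines) >= 1L)
  for (tl in timelines)
    if (any(tl$nd < 0 | tl$nd > 1)) stop("nd values must lie in [0, 1]")
  curves <- lapply(timelines, function(tl) {
    nd <- sort(tl$nd)
    ux <- unique(nd)
    data.frame(nd = ux,
               cumulative = vapply(ux, function(v) sum(nd <= v), 0L))
  })
  grid <- sort(unique(unlist(lapply(timelines, function(tl) tl$nd))))
  cum_at <- function(tl) vapply(grid, function(v) sum(tl$nd <= v), 0L)
  ref <- cum_at(timelines[[1L]])
  fits <- list()
  for (nm in names(timelines)[-1L]) {
    y <- cum_at(timelines[[nm]])
    if (length(grid) < 3L) {
      fits[[nm]] <- list(slope = NA_real_, intercept = NA_real_,
                         r2 = NA_real_)
    } else {
      fit <- stats::lm(y ~ ref)
      fits[[nm]] <- list(slope = unname(stats::coef(fit)[2L]),
                         intercept = unname(stats::coef(fit)[1L]),
                         r2 = summary(fit)$r.squared)
    }
  }
  list(curves = curves, fits = fits)
}
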