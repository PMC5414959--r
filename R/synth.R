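# Synthetic GO DAGs and functionomes with known ground truth. The
# generative model embodies the assumptions the census pipeline relies
# on: older functions have had more time to spread across genomes and to
# grow in per-genome abundance, so birth rank should be recoverable from
# a rooted tree of functions.

#' Simulation parameters
#'
#' @param n_terms number of terminal molecular-function terms.
#' @param n_genomes named vector of genomes per superkingdom (A, B, E).
#' @param n_level1,n_level2,n_level3 internal DAG layer sizes.
#' @param multi_parent_p probability a non-terminal/terminal term gets a
#'   second is_a parent (possibly at a different depth).
#' @param non_isa_p probability a level-2 term hangs by part_of (or
#'   regulates) instead of is_a, exercising the relation filter.
#' @param lambda abundance growth rate: a term of birth rank r in a
#'   genome carries `1 + Poisson(lambda * (T - r) / T)` gene copies, so
#'   expected abundance decreases with rank (T = n_terms).
#' @param loss_p per-genome probability that a vertically inherited term
#'   is independently lost.
#' @param hgt_rate per-term probability of being horizontally mobile: a
#'   mobile term's genes scatter into genomes regardless of lineage.
#' @param htp_label probability a horizontally transferred gene is
#'   labelled as an HTP.
#' @param seed master seed; all generator output is a deterministic
#'   function of (params, seed).
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_terms = 40, n_genomes = c(A = 10, B = 10, E = 10),
                       n_level1 = 6, n_level2 = 12, n_level3 = 18,
                       multi_parent_p = 0.15, non_isa_p = 0.1,
                       lambda = 5, loss_p = 0.05,
                       hgt_rate = 0, htp_label = 0.9, seed = 1) {
  p <- list(n_terms = n_terms, n_genomes = n_genomes,
            n_level1 = n_level1, n_level2 = n_level2, n_level3 = n_level3,
            multi_parent_p = multi_parent_p, non_isa_p = non_isa_p,
            lambda = lambda, loss_p = loss_p,
            hgt_rate = hgt_rate, htp_label = htp_label, seed = seed)
  probs <- c(multi_parent_p, non_isa_p, loss_p, hgt_rate, htp_label)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_terms < 1 || any(n_genomes < 1)) stop("counts must be >= 1")
  if (n_level1 < 2) stop("need at least 2 level-1 terms")
  class(p) <- "sim_params"
  p
}

pick1 <- function(x) x[sample.int(length(x), 1L)]

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(if (had) assign(".Random.seed", old, envir = .GlobalEnv)
          else if (exists(".Random.seed", envir = .GlobalEnv,
                          inherits = FALSE))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

syn_id <- function(i) sprintf("GO:%07d", 1000000L + i)

#' Generate a synthetic molecular-function DAG (and its OBO text)
#'
#' Builds a rooted DAG with three internal layers and a terminal layer:
#' configurable multi-parent terms (so level sets can have size > 1), a
#' fraction of part_of edges (to exercise the is_a-only relation filter),
#' and a childless shallow term (to exercise promotion of childless
#' parents). Byte-identical output for a fixed seed.
#'
#' @param p a `sim_params`.
#' @return list with `obo` (character vector of OBO lines), `dag`
#'   (parsed `go_dag`), `terminals` (terminal term ids), `layers` (term
#'   ids per layer).
#' @export
generate_dag <- function(p) {
  with_seed(p$seed, {
    i <- 0L
    nid <- function() { i <<- i + 1L; syn_id(i) }
    root <- "GO:0003674"
    l1 <- replicate(p$n_level1, nid())
    l2 <- replicate(p$n_level2, nid())
    l3 <- replicate(p$n_level3, nid())
    tt <- replicate(p$n_terms, nid())
    edges <- data.frame(child = character(0), parent = character(0),
                        relation = character(0))
    add <- function(child, parent, relation = "is_a")
      edges <<- rbind(edges, data.frame(child = child, parent = parent,
                                        relation = relation))
    # the last level-1 term stays childless (promotion case)
    childless <- l1[p$n_level1]
    for (t in l1) add(t, root)
    fertile_l1 <- setdiff(l1, childless)
    for (t in l2) {
      rel <- if (stats::runif(1) < p$non_isa_p) "part_of" else "is_a"
      add(t, pick1(fertile_l1), rel)
      if (rel == "is_a" && stats::runif(1) < p$multi_parent_p)
        add(t, pick1(setdiff(fertile_l1, edges$parent[edges$child == t])))
    }
    l2_isa <- unique(edges$child[edges$child %in% l2 &
                                 edges$relation == "is_a"])
    for (t in l3) {
      add(t, pick1(l2_isa))
      if (stats::runif(1) < p$multi_parent_p)
        add(t, pick1(fertile_l1))  # cross-depth parent: level set {2, 3}
    }
    for (t in tt) {
      add(t, pick1(l3))
      if (stats::runif(1) < p$multi_parent_p)
        add(t, pick1(l3[l3 != edges$parent[edges$child == t][1L]]))
    }
    obo <- c("format-version: 1.2", "ontology: synthetic-go", "")
    stanza <- function(id, name, eds) {
      body <- c("[Term]", paste0("id: ", id), paste0("name: ", name),
                "namespace: molecular_function")
      for (k in seq_len(nrow(eds))) {
        body <- c(body,
                  if (eds$relation[k] == "is_a")
                    paste0("is_a: ", eds$parent[k])
                  else paste0("relationship: ", eds$relation[k], " ",
                              eds$parent[k]))
      }
      c(body, "")
    }
    obo <- c(obo, stanza(root, "molecular_function",
                         edges[0, , drop = FALSE]))
    all_terms <- c(l1, l2, l3, tt)
    depth_name <- c(rep("broad", length(l1)), rep("mid", length(l2)),
                    rep("narrow", length(l3)), rep("terminal", length(tt)))
    for (k in seq_along(all_terms)) {
      id <- all_terms[k]
      obo <- c(obo, stanza(id, sprintf("synthetic %s activity %d",
                                       depth_name[k], k),
                           edges[edges$child == id, , drop = FALSE]))
    }
    list(obo = obo, dag = parse_obo(obo), terminals = tt,
         layers = list(level1 = l1, level2 = l2, level3 = l3,
                       terminal = tt, childless_level1 = childless))
  })
}

# Birth lineages along the stem line of descent of a fixed genome
# lineage tree of shape ((A),(B,E)) with a pectinate eukaryal crown:
# ALL > BE > E > nested eukaryal subclades > a single genome. New
# functions arise on the diversifying stem, so presence sets are nested
# by birth rank (Weston-generality polarization: the taxic distribution
# of a younger state is a subset of an older one). Archaea and Bacteria
# then derive their repertoires by loss, never by lineage-specific
# ancient births.
lineage_nodes <- function(n_genomes) {
  gA <- paste0("A", seq_len(n_genomes[["A"]]))
  gB <- paste0("B", seq_len(n_genomes[["B"]]))
  gE <- paste0("E", seq_len(n_genomes[["E"]]))
  nE <- length(gE)
  crown_sizes <- unique(pmax(1L, rev(round(nE * c(1, 0.8, 0.6, 0.4, 0.2, 1 / nE)))))
  crown_sizes <- sort(crown_sizes, decreasing = TRUE)
  nodes <- c(list(ALL = c(gA, gB, gE), BE = c(gB, gE)),
             setNames(lapply(crown_sizes, function(k) gE[seq_len(k)]),
                      paste0("E", crown_sizes)))
  nodes
}

#' Generate synthetic functionomes (GAF annotations) with ground truth
#'
#' Terminal terms are born in rank order along a fixed 3-superkingdom
#' lineage tree: a term is present in the genomes descending from its
#' birth lineage, minus independent losses; per-genome copy number is
#' `1 + Poisson(lambda * (T - rank) / T)`, so expected abundance
#' decreases with birth rank. With `hgt_rate > 0` a fraction of terms is
#' horizontally mobile: their genes scatter across lineages and are
#' labelled HTP with probability `htp_label`.
#'
#' @param dag_out result of [generate_dag()] (or a list with `terminals`).
#' @param p a `sim_params`.
#' @return list with `annotations` (`annotation_set`), `gaf` (named list
#'   of per-genome GAF line vectors), `meta` (genome metadata
#'   data.frame), `htp_genes`, `truth` (birth_rank, birth_node,
#'   mobile_terms, events, presence matrix).
#' @export
generate_functionomes <- function(dag_out, p) {
  terminals <- dag_out$terminals
  T_ <- length(terminals)
  with_seed(p$seed + 1L, {
    nodes <- lineage_nodes(p$n_genomes)
    genomes <- nodes$ALL
    meta <- data.frame(
      genome = genomes,
      superkingdom = substr(genomes, 1L, 1L),
      lifestyle = "free-living")
    # birth node per rank: contiguous rank blocks walk the node list
    node_idx <- pmin(length(nodes),
                     1L + ((seq_len(T_) - 1L) * length(nodes)) %/% T_)
    birth_node <- names(nodes)[node_idx]
    mobile <- stats::runif(T_) < p$hgt_rate
    presence <- matrix(FALSE, T_, length(genomes),
                       dimnames = list(terminals, genomes))
    events <- list()
    for (r in seq_len(T_)) {
      native <- nodes[[birth_node[r]]]
      if (mobile[r]) {
        carriers <- genomes[stats::runif(length(genomes)) < 0.4]
        if (!length(carriers)) carriers <- pick1(genomes)
        for (g in setdiff(carriers, native))
          events[[length(events) + 1L]] <-
            data.frame(term = terminals[r], donor = birth_node[r],
                       recipient = g)
      } else {
        kept <- stats::runif(length(native)) >= p$loss_p
        carriers <- native[kept]
      }
      presence[r, carriers] <- TRUE
    }
    rows <- list()
    htp <- character(0)
    for (r in seq_len(T_)) {
      mean_copies <- p$lambda * (T_ - r) / T_
      for (g in genomes[presence[r, ]]) {
        ncop <- 1L + stats::rpois(1L, mean_copies)
        ids <- sprintf("g_%s_t%03d_%02d", g, r, seq_len(ncop))
        if (mobile[r]) {
          is_htp <- stats::runif(ncop) < p$htp_label
          htp <- c(htp, ids[is_htp])
        }
        rows[[length(rows) + 1L]] <-
          data.frame(genome = g, gene = ids, term = terminals[r],
                     evidence = "IEA", qualifier = "enables")
      }
    }
    ann <- do.call(rbind, rows)
    rownames(ann) <- NULL
    class(ann) <- c("annotation_set", "data.frame")
    gaf <- lapply(setNames(genomes, genomes), function(g) {
      a <- ann[ann$genome == g, , drop = FALSE]
      c("!gaf-version: 2.2",
        sprintf(paste(c("SYNT", "%s", "%s", "enables", "%s", "SYNT:0000001",
                        "IEA", "", "F", "synthetic gene product", "",
                        "protein", "taxon:%d", "20091101", "SYNT", "", ""),
                      collapse = "\t"),
                a$gene, a$gene, a$term, match(g, genomes)))
    })
    truth <- list(
      birth_rank = setNames(seq_len(T_), terminals),
      birth_node = setNames(birth_node, terminals),
      mobile_terms = terminals[mobile],
      events = if (length(events)) do.call(rbind, events)
               else data.frame(term = character(0), donor = character(0),
                               recipient = character(0)),
      presence = presence)
    list(annotations = ann, gaf = gaf, meta = meta,
         htp_genes = unique(htp), truth = truth)
  })
}

#' Write a simulated dataset to disk (OBO, per-genome GAF, metadata, HTP)
#' @param dag_out result of [generate_dag()].
#' @param fx result of [generate_functionomes()].
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(dag_out, fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(dag_out$obo, file.path(dir, "ontology.obo"))
  for (g in names(fx$gaf))
    writeLines(fx$gaf[[g]], file.path(dir, paste0(g, ".gaf")))
  utils::write.table(fx$meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(fx$htp_genes, file.path(dir, "htp_genes.txt"))
  invisible(dir)
}

#' Rank agreement between true birth order and reconstructed ages
#'
#' Spearman correlation between ground-truth birth ranks and the nd ages
#' of the same taxa, with the correlation test's p-value (exact for small
#' n without ties).
#'
#' @param truth ground-truth list from [generate_functionomes()] (or a
#'   named rank vector).
#' @param timeline a `timeline` data.frame, or a named nd vector.
#' @return list with `rho`, `p`, `n`.
#' @export
evaluate_recovery <- function(truth, timeline) {
  ranks <- if (is.list(truth) && !is.null(truth$birth_rank))
    truth$birth_rank else truth
  nd <- if (is.data.frame(timeline))
    setNames(timeline$nd, timeline$taxon) else timeline
  shared <- intersect(names(ranks), names(nd))
  if (!length(shared)) stop("no shared taxa between truth and timeline")
  if (length(shared) < length(nd))
    warning("timeline taxa missing from truth: ",
            length(nd) - length(shared))
  ct <- suppressWarnings(
    stats::cor.test(ranks[shared], nd[shared], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Homoplasy-free ladder character matrix
#'
#' Taxa t1..tn on a perfect pectinate (caterpillar) history: character
#' class c (c = 1..n-1) takes state `step` for taxa with index > c and 0
#' otherwise, replicated `reps` times. Every class is compatible with the
#' single caterpillar topology; taxon tn carries the per-character
#' maximum state (the oldest taxon under the max-state ancestor
#' polarization).
#'
#' @param n_taxa number of taxa (>= 4).
#' @param reps copies of each character class.
#' @param step state difference per class.
#' @return integer matrix with rownames t1..tn.
#' @export
ladder_matrix <- function(n_taxa, reps = 20, step = 1) {
  stopifnot(n_taxa >= 4)
  cls <- seq_len(n_taxa - 1L)
  m <- sapply(rep(cls, each = reps), function(cc)
    as.integer(step * (seq_len(n_taxa) > cc)))
  rownames(m) <- paste0("t", seq_len(n_taxa))
  colnames(m) <- paste0("c", rep(cls, each = reps), "_", seq_len(reps))
  m
}
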