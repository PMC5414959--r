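#' Build the multi-level GO term network annotated with nd ages
#'
#' Nodes are the analysed taxa at levels 1, 2, 3 and (optionally) the
#' terminal terms, each carrying its level's nd age. Edges connect
#' adjacent levels only: a deeper node is linked to a shallower one when
#' it is an is_a descendant within the selection mappings; terminal nodes
#' link to the level-3 taxa whose constituencies contain them. Self-links
#' of promoted childless terms are not counted.
#'
#' @param timelines named list of `timeline` data.frames keyed
#'   `"1"`, `"2"`, `"3"` and optionally `"terminal"` (an empty or absent
#'   terminal timeline restricts the network to levels 1-3).
#' @param dag a `go_dag`.
#' @param mappings named list of `terminal_mapping`s keyed `"1"`, `"2"`,
#'   `"3"`.
#' @return a `go_network`: `nodes` (term, level, nd) and `edges`
#'   (from, to, level_from, level_to) data.frames; rows sorted by nd.
#' @export
build_network <- function(timelines, dag, mappings) {
  lev_names <- intersect(c("1", "2", "3", "terminal"), names(timelines))
  nodes <- do.call(rbind, lapply(lev_names, function(nm) {
    tl <- timelines[[nm]]
    if (is.null(tl) || nrow(tl) == 0L) return(NULL)
    if (any(is.na(tl$nd)))
      stop("taxa missing an nd age at level ", nm, ": ",
           paste(tl$taxon[is.na(tl$nd)], collapse = ", "))
    data.frame(term = tl$taxon, level = nm, nd = tl$nd)
  }))
  kids <- isa_children_map(dag)
  edges <- list()
  pairs <- list(c("1", "2"), c("2", "3"))
  for (pr in pairs) {
    up <- nodes$term[nodes$level == pr[1L]]
    dn <- nodes$term[nodes$level == pr[2L]]
    if (!length(up) || !length(dn)) next
    for (u in up) {
      desc <- setdiff(isa_descendants(kids, u), u)
      hit <- intersect(desc, dn)
      if (length(hit))
        edges[[length(edges) + 1L]] <-
          data.frame(from = u, to = hit,
                     level_from = pr[1L], level_to = pr[2L])
    }
  }
  terms_term <- nodes$term[nodes$level == "terminal"]
  if (length(terms_term) && !is.null(mappings[["3"]])) {
    cons <- mappings[["3"]]$taxa
    for (u in intersect(names(cons), nodes$term[nodes$level == "3"])) {
      hit <- setdiff(intersect(cons[[u]], terms_term), u)
      if (length(hit))
        edges[[length(edges) + 1L]] <-
          data.frame(from = u, to = hit,
                     level_from = "3", level_to = "terminal")
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(from = character(0), to = character(0),
                           level_from = character(0),
                           level_to = character(0))
  nodes <- nodes[order(nodes$nd, nodes$term), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "go_network")
}

#' @export
print.go_network <- function(x, ...) {
  lv <- table(x$nodes$level)
  cat(sprintf("GO network: %d nodes (%s), %d edges\n",
              nrow(x$nodes),
              paste(sprintf("level %s: %d", names(lv), lv), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Hub terms of a network level
#'
#' Nodes at the given level with at least `min_links` links to the next
#' deeper level, sorted by nd ascending (ties by term id). Conventional
#' thresholds: 6 for level 2 (hubs against level 3) and 30 for level 3
#' (hubs against terminals), both configurable.
#'
#' @param net a `go_network`.
#' @param level `"1"`, `"2"` or `"3"`.
#' @param min_links minimum link count; default 6 for level 2, 30 for
#'   level 3, 1 otherwise.
#' @return data.frame: term, links, nd.
#' @export
hub_terms <- function(net, level, min_links = NULL) {
  level <- as.character(level)
  if (!level %in% net$nodes$level) stop("level ", level, " not in network")
  if (is.null(min_links))
    min_links <- switch(level, "2" = 6L, "3" = 30L, 1L)
  e <- net$edges[net$edges$level_from == level, , drop = FALSE]
  cnt <- table(e$from)
  terms <- names(cnt)[cnt >= min_links]
  if (!length(terms))
    return(data.frame(term = character(0), links = integer(0),
                      nd = numeric(0)))
  nd <- net$nodes$nd[match(terms, net$nodes$term)]
  out <- data.frame(term = terms, links = as.integer(cnt[terms]), nd = nd)
  out <- out[order(out$nd, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a network as a Pajek .net file
#' @param net a `go_network`.
#' @param path output file.
#' @export
write_pajek <- function(net, path) {
  ids <- seq_len(nrow(net$nodes))
  names(ids) <- net$nodes$term
  out <- c(sprintf("*Vertices %d", nrow(net$nodes)),
           sprintf('%d "%s" %.4f', ids, net$nodes$term, net$nodes$nd),
           "*Edges",
           if (nrow(net$edges))
             sprintf("%d %d", ids[net$edges$from], ids[net$edges$to]))
  writeLines(out, path)
  invisible(path)
}

#' Write a network edge list as TSV (u, v, levels, nd_u, nd_v)
#' @param net a `go_network`.
#' @param path output file.
#' @export
write_network_tsv <- function(net, path) {
  e <- net$edges
  nd <- setNames(net$nodes$nd, net$nodes$term)
  d <- data.frame(u = e$from, v = e$to,
                  level_u = e$level_from, level_v = e$level_to,
                  nd_u = unname(nd[e$from]), nd_v = unname(nd[e$to]))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
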