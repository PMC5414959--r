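#' Parse a Gene Ontology OBO 1.2 file
#'
#' Reads `[Term]` stanzas, keeping `is_a` and `relationship:` edges with
#' their relation type. `regulates`, `positively_regulates` and
#' `negatively_regulates` are collapsed to the relation `"regulates"`.
#' Obsolete terms are flagged and carry no outgoing edges; `alt_id`s are
#' recorded so annotations can be resolved to canonical accessions.
#'
#' @param x path to an OBO file, or a character vector of OBO lines.
#' @param namespace_root accession expected as the molecular_function
#'   root; its absence (while molecular_function terms exist) is a
#'   structural error.
#' @return an object of class `go_dag`: `terms` (data.frame id, name,
#'   namespace, obsolete), `edges` (data.frame child, parent, relation),
#'   `alt` (named vector alt id -> canonical id), `root`.
#' @export
parse_obo <- function(x, namespace_root = "GO:0003674") {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x) else unlist(strsplit(x, "\n", fixed = TRUE))
  in_term <- FALSE
  terms <- list(); edges <- list(); alt <- character(0)
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    if (is.na(cur$id)) stop("OBO [Term] stanza without id (near line ",
                            cur$line, ")")
    terms[[cur$id]] <<- cur
    if (!cur$obsolete) for (e in cur$edges)
      edges[[length(edges) + 1L]] <<- e
    for (a in cur$alt) alt[[a]] <<- cur$id
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "!")) next
    if (startsWith(ln, "[")) {
      flush()
      in_term <- identical(ln, "[Term]")
      cur <- if (in_term)
        list(id = NA_character_, name = NA_character_,
             namespace = NA_character_, obsolete = FALSE,
             edges = list(), alt = character(0), line = i)
      next
    }
    if (!in_term) next
    kv <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1L]]
    if (length(kv) != 3L)
      stop("malformed OBO line ", i, ": ", ln)
    key <- kv[2L]; val <- kv[3L]
    val <- sub("\\s*!.*$", "", val)  # strip trailing comments
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (key == "alt_id") cur$alt <- c(cur$alt, val)
    else if (key == "is_a")
      cur$edges <- c(cur$edges, list(c(child = NA, parent = val,
                                       relation = "is_a")))
    else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) < 2L) stop("malformed relationship at line ", i)
      rel <- parts[1L]
      if (rel %in% c("regulates", "positively_regulates",
                     "negatively_regulates")) rel <- "regulates"
      cur$edges <- c(cur$edges, list(c(child = NA, parent = parts[2L],
                                       relation = rel)))
    }
    # other keys (def, synonym, xref, ...) are ignored
  }
  flush()
  term_df <- data.frame(
    id = vapply(terms, `[[`, "", "id"),
    name = vapply(terms, `[[`, "", "name"),
    namespace = vapply(terms, `[[`, "", "namespace"),
    obsolete = vapply(terms, `[[`, FALSE, "obsolete"),
    row.names = NULL)
  edge_df <- if (length(edges)) {
    child_ids <- rep(names(terms),
                     vapply(terms, function(t)
                       if (t$obsolete) 0L else length(t$edges), 0L))
    data.frame(child = child_ids,
               parent = vapply(edges, `[[`, "", "parent"),
               relation = vapply(edges, `[[`, "", "relation"),
               row.names = NULL)
  } else data.frame(child = character(0), parent = character(0),
                    relation = character(0))
  if (any(term_df$namespace == "molecular_function", na.rm = TRUE) &&
      !namespace_root %in% term_df$id)
    stop("molecular_function root ", namespace_root, " missing from ontology")
  isa <- edge_df[edge_df$relation == "is_a", , drop = FALSE]
  if (nrow(isa)) {
    g <- igraph::graph_from_data_frame(isa[, c("child", "parent")],
                                       directed = TRUE)
    if (!igraph::is_dag(g)) stop("is_a subgraph contains a cycle")
  }
  structure(list(terms = term_df, edges = edge_df, alt = alt,
                 root = namespace_root),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("GO DAG: %d terms (%d obsolete), %d edges (%d is_a)\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges),
              sum(x$edges$relation == "is_a")))
  invisible(x)
}

isa_edges <- function(dag) {
  dag$edges[dag$edges$relation == "is_a", c("child", "parent"), drop = FALSE]
}

#' Hierarchy levels of every term (all is_a path lengths from the root)
#'
#' A term's level set contains the length of every distinct is_a path from
#' the namespace root down to it (the root has level 0); multi-parent
#' terms can hold several levels at once. Terms with no is_a route to the
#' root (e.g. part_of-only children) get an empty set.
#'
#' @param dag a `go_dag`.
#' @param max_depth path lengths above this are not enumerated (bounds the
#'   cost on pathological ontologies).
#' @return named list: term id -> sorted integer vector of levels.
#' @export
term_levels <- function(dag, max_depth = 20L) {
  isa <- isa_edges(dag)
  ids <- dag$terms$id[!dag$terms$obsolete]
  lv <- setNames(vector("list", length(ids)), ids)
  lv[[dag$root]] <- 0L
  if (nrow(isa)) {
    g <- igraph::graph_from_data_frame(isa, directed = TRUE,
                                       vertices = unique(c(ids, isa$parent)))
    ord <- igraph::topo_sort(g, mode = "in")$name  # parents before children
    parents_of <- split(isa$parent, isa$child)
    for (id in ord) {
      ps <- parents_of[[id]]
      if (is.null(ps)) next
      got <- sort(unique(unlist(lv[ps], use.names = FALSE) + 1L))
      lv[[id]] <- got[got <= max_depth]
    }
  }
  lapply(lv, function(v) if (is.null(v)) integer(0) else as.integer(v))
}

isa_children_map <- function(dag) {
  isa <- isa_edges(dag)
  split(isa$child, isa$parent)
}

# All is_a descendants of `id`, including itself.
isa_descendants <- function(children_map, id) {
  out <- character(0)
  stack <- id
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    kids <- children_map[[v]]
    if (!is.null(kids)) stack <- c(stack, kids)
  }
  unique(out)
}

#' Select the taxa analysed at a hierarchy level
#'
#' Applies the four taxon-selection rules, in order: (i) a childless term
#' whose levels all lie above (shallower than) `L` is promoted to be its
#' own taxon at `L`; (ii) terms reachable only through part_of/regulates
#' relations hold no level and are excluded (their terminals are reported
#' as unmapped); (iii) a taxon with several parents at the level appears
#' once; (iv) a term holding several levels is retained at each of them.
#' A taxon is kept only when at least one terminal term (from `terminals`)
#' is reachable from it by is_a descent - itself included.
#'
#' @param dag a `go_dag`.
#' @param terminals character vector of terminal term ids (terms directly
#'   assigned to gene products).
#' @param L hierarchy level, one of 1, 2, 3.
#' @param levels optional precomputed [term_levels()] result.
#' @return an object of class `terminal_mapping`: `level`, `taxa` (named
#'   list taxon id -> terminal ids), `provenance` (named vector, "level"
#'   or "promoted"), `unmapped` (terminals under no taxon).
#' @export
select_level_taxa <- function(dag, terminals, L, levels = NULL) {
  if (!L %in% 1:3) stop("L must be 1, 2 or 3")
  if (is.null(levels)) levels <- term_levels(dag)
  terminals <- unique(resolve_ids(dag, terminals))
  kids <- isa_children_map(dag)
  has_child <- names(kids)
  candidates <- names(levels)[vapply(levels, function(v) L %in% v, FALSE)]
  candidates <- setdiff(candidates, dag$root)
  promoted <- names(levels)[vapply(levels, function(v)
    length(v) > 0L && all(v < L) && min(v) >= 1L, FALSE)]
  promoted <- setdiff(promoted[!promoted %in% has_child], candidates)
  prov <- c(setNames(rep("level", length(candidates)), candidates),
            setNames(rep("promoted", length(promoted)), promoted))
  taxa <- list()
  for (tx in names(prov)) {
    cons <- intersect(isa_descendants(kids, tx), terminals)
    if (length(cons)) taxa[[tx]] <- sort(cons)
  }
  prov <- prov[names(taxa)]
  covered <- unique(unlist(taxa, use.names = FALSE))
  structure(list(level = as.integer(L), taxa = taxa, provenance = prov,
                 unmapped = sort(setdiff(terminals, covered))),
            class = "terminal_mapping")
}

#' @export
print.terminal_mapping <- function(x, ...) {
  cat(sprintf("Level-%d terminal mapping: %d taxa (%d promoted), %d unmapped terminals\n",
              x$level, length(x$taxa), sum(x$provenance == "promoted"),
              length(x$unmapped)))
  invisible(x)
}

resolve_ids <- function(dag, ids) {
  hit <- ids %in% names(dag$alt)
  ids[hit] <- dag$alt[ids[hit]]
  ids
}

#' Restrict a terminal mapping to the terminals of an annotation set
#'
#' Each taxon's constituency is intersected with the terminals actually
#' annotated; annotations to unknown or obsolete accessions are skipped
#' with a warning and counted in the attached report. Terminals reachable
#' from several taxa stay in every constituency (many-to-many preserved).
#'
#' @param dag a `go_dag`.
#' @param mapping a `terminal_mapping` from [select_level_taxa()].
#' @param annotations an `annotation_set` (see [parse_gaf()]) or a
#'   character vector of terminal term ids.
#' @return a `terminal_mapping` restricted to annotated terminals, with a
#'   `report` element (n_annotated, n_unknown, unknown ids).
#' @export
map_terminals <- function(dag, mapping, annotations) {
  ids <- if (is.data.frame(annotations)) unique(annotations$term)
         else unique(as.character(annotations))
  ids <- resolve_ids(dag, ids)
  known <- dag$terms$id[!dag$terms$obsolete]
  unknown <- setdiff(ids, known)
  if (length(unknown))
    warning(length(unknown), " annotation term(s) unknown or obsolete; skipped")
  ids <- intersect(ids, known)
  taxa <- lapply(mapping$taxa, intersect, ids)
  taxa <- taxa[lengths(taxa) > 0L]
  covered <- unique(unlist(taxa, use.names = FALSE))
  structure(list(level = mapping$level, taxa = taxa,
                 provenance = mapping$provenance[names(taxa)],
                 unmapped = sort(setdiff(ids, covered)),
                 report = list(n_annotated = length(ids),
                               n_unknown = length(unknown),
                               unknown = unknown)),
            class = "terminal_mapping")
}

#' Write a terminal mapping as 3-column TSV (taxon, level, terminal)
#' @param mapping a `terminal_mapping`.
#' @param path output file.
#' @export
write_terminal_mapping <- function(mapping, path) {
  rows <- data.frame(
    taxon = rep(names(mapping$taxa), lengths(mapping$taxa)),
    level = mapping$level,
    terminal = unlist(mapping$taxa, use.names = FALSE))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a terminal mapping written by [write_terminal_mapping()]
#' @param path TSV file (taxon, level, terminal).
#' @export
read_terminal_mapping <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  taxa <- split(d$terminal, d$taxon)
  structure(list(level = unique(d$level)[1L],
                 taxa = lapply(taxa, sort),
                 provenance = setNames(rep("level", length(taxa)),
                                       names(taxa)),
                 unmapped = character(0)),
            class = "terminal_mapping")
}
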