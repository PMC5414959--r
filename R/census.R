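# The 32-state alphabet used for ordered characters (PAUP*-compatible).
GO_SYMBOLS <- strsplit("0123456789ABCDEFGHIJKLMNOPQRSTUV", "")[[1]]

#' Parse a GAF 2.x annotation file
#'
#' Retains molecular_function rows (aspect column `"F"`), drops rows whose
#' qualifier contains `NOT`, and collapses duplicate (genome, gene, term)
#' triples (annotations differing only in evidence code count once).
#'
#' @param x path to a GAF file, or a character vector of GAF lines.
#' @param genome genome identifier for the records; default is the first
#'   taxon token of column 13.
#' @return an `annotation_set`: data.frame with columns genome, gene,
#'   term, evidence, qualifier; attribute `n_dropped_not` counts
#'   NOT-qualified rows removed.
#' @export
parse_gaf <- function(x, genome = NULL) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    readLines(x) else unlist(strsplit(x, "\n", fixed = TRUE))
  body <- which(!startsWith(lines, "!") & nzchar(trimws(lines)))
  rows <- strsplit(lines[body], "\t", fixed = TRUE)
  # the last GAF columns (annotation extension, gene product form) are
  # routinely empty; strsplit drops trailing empty fields, so pad
  rows <- lapply(rows, function(r)
    if (length(r) %in% 15:16) c(r, rep("", 17L - length(r))) else r)
  bad <- which(lengths(rows) != 17L)
  if (length(bad))
    stop("GAF line ", body[bad[1L]], " has ", lengths(rows)[bad[1L]],
         " columns (expected 17)")
  if (!length(rows)) {
    out <- data.frame(genome = character(0), gene = character(0),
                      term = character(0), evidence = character(0),
                      qualifier = character(0))
    class(out) <- c("annotation_set", "data.frame")
    return(out)
  }
  m <- do.call(rbind, rows)
  keep_f <- m[, 9L] == "F"
  is_not <- grepl("NOT", m[, 4L], fixed = TRUE)
  keep <- keep_f & !is_not
  gm <- if (is.null(genome)) sub("\\|.*$", "", m[keep, 13L]) else genome
  out <- data.frame(genome = gm,
                    gene = m[keep, 2L],
                    term = m[keep, 5L],
                    evidence = m[keep, 7L],
                    qualifier = m[keep, 4L],
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("genome", "gene", "term")]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_not") <- sum(keep_f & is_not)
  class(out) <- c("annotation_set", "data.frame")
  out
}

#' Read a directory of per-genome GAF files
#' @param dir directory containing `*.gaf` files; each file's basename
#'   (without extension) becomes the genome id.
#' @param pattern filename pattern.
#' @return a combined `annotation_set`.
#' @export
read_annotation_dir <- function(dir, pattern = "\\.gaf$") {
  files <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (!length(files)) stop("no GAF files found in ", dir)
  sets <- lapply(files, function(f)
    parse_gaf(f, genome = sub("\\.gaf$", "", basename(f))))
  out <- do.call(rbind, lapply(sets, as.data.frame))
  out <- out[!duplicated(out[, c("genome", "gene", "term")]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("annotation_set", "data.frame")
  out
}

#' Genomic-abundance matrix of GO taxa
#'
#' The census: cell (taxon, genome) counts the distinct gene products of
#' the genome annotated to any terminal term in the taxon's constituency.
#' A gene with two terminal annotations under one taxon counts once for
#' that taxon; a gene under terminals of two different taxa counts once in
#' each (the DAG's many-to-many structure is preserved).
#'
#' @param ann an `annotation_set`.
#' @param mapping a `terminal_mapping`, or `NULL` for terminal identity
#'   (each terminal term is its own taxon).
#' @param meta genome metadata data.frame (genome, superkingdom,
#'   lifestyle); required if `free_living_only`. Every genome present in
#'   `ann` must have a row.
#' @param free_living_only drop genomes whose lifestyle is not
#'   "free-living".
#' @return an `abundance_matrix`: list with `g` (integer taxa x genomes
#'   matrix), `g_max`, `meta`.
#' @export
build_matrix <- function(ann, mapping = NULL, meta = NULL,
                         free_living_only = FALSE) {
  ann <- as.data.frame(ann)
  if (!is.null(meta)) {
    missing <- setdiff(unique(ann$genome), meta$genome)
    if (length(missing))
      stop("genomes without metadata: ", paste(missing, collapse = ", "))
    if (free_living_only) {
      keep <- meta$genome[meta$lifestyle == "free-living"]
      ann <- ann[ann$genome %in% keep, , drop = FALSE]
      meta <- meta[meta$genome %in% keep, , drop = FALSE]
    }
  } else if (free_living_only) {
    stop("free_living_only requires metadata")
  }
  genomes <- sort(unique(ann$genome))
  if (is.null(mapping)) {
    taxa <- sort(unique(ann$term))
    constituents <- setNames(as.list(taxa), taxa)
  } else {
    constituents <- mapping$taxa
    taxa <- names(constituents)
  }
  g <- matrix(0L, length(taxa), length(genomes),
              dimnames = list(taxa, genomes))
  by_term <- split(seq_len(nrow(ann)), ann$term)
  for (tx in taxa) {
    idx <- unlist(by_term[constituents[[tx]]], use.names = FALSE)
    if (!length(idx)) next
    tab <- table(ann$genome[idx][!duplicated(ann[idx, c("genome", "gene")])])
    g[tx, names(tab)] <- as.integer(tab)
  }
  structure(list(g = g, g_max = max(g), meta = meta),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("Abundance matrix: %d taxa x %d genomes, g_max = %d\n",
              nrow(x$g), ncol(x$g), x$g_max))
  invisible(x)
}

#' Remove terminal terms enriched in horizontally transferred proteins
#'
#' For each terminal term, a one-sided hypergeometric (Fisher exact) test
#' of HTP membership among the term's gene products against all other gene
#' products; terms with p below `alpha` are removed from the annotation
#' set. No multiple-testing correction is applied (raw p-values, matching
#' the conventional raw `P < 0.05` screen for this filter).
#'
#' @param ann an `annotation_set`.
#' @param htp_genes character vector of horizontally-transferred gene ids;
#'   ids absent from the annotations are warned about.
#' @param alpha significance level in (0, 1).
#' @return list with `removed` (term ids), `annotations` (filtered
#'   `annotation_set`), `p_values` (named per-term vector).
#' @export
hgt_enrichment_filter <- function(ann, htp_genes, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  ann_df <- as.data.frame(ann)
  genes <- unique(ann_df$gene)
  htp_genes <- unique(htp_genes)
  stray <- setdiff(htp_genes, genes)
  if (length(stray))
    warning(length(stray), " HTP gene id(s) absent from the annotations")
  htp <- intersect(htp_genes, genes)
  K <- length(genes); M <- length(htp)
  terms <- unique(ann_df$term)
  p <- setNames(rep(1, length(terms)), terms)
  if (M > 0L) {
    gene_sets <- lapply(split(ann_df$gene, ann_df$term), unique)
    for (tm in terms) {
      gs <- gene_sets[[tm]]
      k <- length(gs); x <- sum(gs %in% htp)
      # P(X >= x) with X ~ Hypergeom(M, K - M, k)
      p[tm] <- stats::phyper(x - 1L, M, K - M, k, lower.tail = FALSE)
    }
  }
  removed <- names(p)[p < alpha]
  kept <- ann_df[!ann_df$term %in% removed, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("annotation_set", "data.frame")
  list(removed = removed, annotations = kept, p_values = p)
}

# Round half away from zero (so 0.5 -> 1); plain round() would go to even.
round_half_up <- function(x) floor(x + 0.5)

#' Normalize and encode abundances as 32 ordered states
#'
#' Applies the log-scale normalization
#' `state = Round( ln(g + 1) / ln(g_max + 1) * 31 )` with half-up
#' rounding, mapping every count into the ordered states 0..31 and the
#' alphanumeric symbols 0-9, A-V. `g_max` is the matrix-wide maximum, so
#' `g = 0` encodes to state 0 and `g = g_max` to state 31; encoding is
#' monotone in g.
#'
#' @param m an `abundance_matrix` (all-zero matrices are an error: the
#'   scale is undefined).
#' @return an `encoded_matrix`: list with `states` (integer matrix),
#'   `symbols` (character matrix), `alphabet`, `g_max`, `meta`.
#' @export
normalize_encode <- function(m) {
  g <- if (inherits(m, "abundance_matrix")) m$g else m
  if (any(g < 0)) stop("abundances must be non-negative")
  gmax <- max(g)
  if (gmax < 1) stop("all-zero matrix: g_max undefined for scaling")
  states <- round_half_up(log(g + 1) / log(gmax + 1) * 31)
  storage.mode(states) <- "integer"
  symbols <- matrix(GO_SYMBOLS[states + 1L], nrow(g), ncol(g),
                    dimnames = dimnames(g))
  structure(list(states = states, symbols = symbols,
                 alphabet = GO_SYMBOLS, g_max = gmax,
                 meta = if (inherits(m, "abundance_matrix")) m$meta),
            class = "encoded_matrix")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat(sprintf("Encoded matrix: %d x %d, states 0..31 (g_max = %d)\n",
              nrow(x$states), ncol(x$states), x$g_max))
  invisible(x)
}

sanitize_taxon_names <- function(x) {
  out <- gsub("[^A-Za-z0-9_.]", "_", x)
  if (anyDuplicated(out))
    stop("taxa names collide after sanitization: ",
         paste(out[duplicated(out)], collapse = ", "))
  out
}

#' Write an encoded matrix as a NEXUS ordered-character file
#'
#' Emits a DATA block with `SYMBOLS="0~9A~V"` and an ASSUMPTIONS block
#' declaring every character ordered (Wagner), the layout expected by
#' parsimony software. Orientation `"tof"` writes GO taxa as rows
#' (genomes are the characters); `"tol"` writes the transpose.
#'
#' @param e an `encoded_matrix`.
#' @param path output file.
#' @param orientation `"tof"` (rows = matrix rows) or `"tol"` (transpose).
#' @export
write_character_matrix <- function(e, path, orientation = c("tof", "tol")) {
  orientation <- match.arg(orientation)
  s <- e$symbols
  if (orientation == "tol") s <- t(s)
  taxa <- sanitize_taxon_names(rownames(s))
  width <- max(nchar(taxa)) + 2L
  out <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(s), ncol(s)),
    "  FORMAT SYMBOLS=\"0~9A~V\" MISSING=? GAP=-;",
    "  MATRIX",
    sprintf("    %-*s%s", width, taxa, apply(s, 1L, paste, collapse = "")),
    "  ;",
    "END;",
    "BEGIN ASSUMPTIONS;",
    "  OPTIONS DEFTYPE=ORD;",
    sprintf("  TYPESET * wagner = ORD: 1-%d;", ncol(s)),
    "END;")
  writeLines(out, path)
  invisible(path)
}

#' Read a NEXUS character matrix written by [write_character_matrix()]
#' @param path NEXUS file.
#' @return integer state matrix (taxa x characters) with rownames.
#' @export
read_character_matrix <- function(path) {
  lines <- readLines(path)
  i0 <- grep("^\\s*MATRIX\\s*$", lines)[1L]
  if (is.na(i0)) stop("no MATRIX block found in ", path)
  i1 <- i0 + which(grepl("^\\s*;\\s*$", lines[(i0 + 1L):length(lines)]))[1L]
  rows <- trimws(lines[(i0 + 1L):(i1 - 1L)])
  rows <- rows[nzchar(rows)]
  parts <- strsplit(rows, "\\s+")
  taxa <- vapply(parts, `[[`, "", 1L)
  seqs <- vapply(parts, `[[`, "", 2L)
  states <- do.call(rbind, lapply(strsplit(seqs, ""), function(ch)
    match(ch, GO_SYMBOLS) - 1L))
  rownames(states) <- taxa
  storage.mode(states) <- "integer"
  states
}
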