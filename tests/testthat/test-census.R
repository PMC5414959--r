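test_that("parse_gaf keeps F-aspect rows, drops NOT, collapses duplicates", {
  ann <- parse_gaf(toy_gaf(), genome = "g1")
  expect_s3_class(ann, "annotation_set")
  expect_equal(nrow(ann), 2L)               # gene1 deduped, gene2 NOT, gene4 P
  expect_setequal(ann$gene, c("gene1", "gene3"))
  expect_equal(attr(ann, "n_dropped_not"), 1L)
  expect_error(parse_gaf(c("!h", "a\tb\tc")), "columns")
})

test_that("build_matrix counts distinct gene products per taxon", {
  ann <- data.frame(
    genome = c("G1", "G1", "G1", "G1", "G2"),
    gene = c("p1", "p2", "p3", "p1", "p1"),
    term = c("T1", "T1", "T1", "T2", "T1"),
    evidence = "IEA", qualifier = "enables")
  meta <- data.frame(genome = c("G1", "G2"), superkingdom = c("B", "E"),
                     lifestyle = "free-living")
  # terminal identity: 3 distinct genes on T1 in G1
  m0 <- build_matrix(ann, meta = meta)
  expect_equal(m0$g["T1", "G1"], 3L)
  # two terminals under one taxon: a shared gene counts once
  map1 <- structure(list(level = 1L, taxa = list(TX = c("T1", "T2")),
                         provenance = c(TX = "level"),
                         unmapped = character(0)),
                    class = "terminal_mapping")
  m1 <- build_matrix(ann, mapping = map1, meta = meta)
  expect_equal(m1$g["TX", "G1"], 3L)        # p1 under T1 and T2 counts once
  # one terminal under two taxa counts in each
  map2 <- structure(list(level = 1L,
                         taxa = list(TA = "T1", TB = c("T1", "T2")),
                         provenance = c(TA = "level", TB = "level"),
                         unmapped = character(0)),
                    class = "terminal_mapping")
  m2 <- build_matrix(ann, mapping = map2, meta = meta)
  expect_equal(m2$g["TA", "G1"], 3L)
  expect_equal(m2$g["TB", "G1"], 3L)
  expect_error(build_matrix(ann, meta = meta[1, ]), "without metadata")
})

test_that("free-living filter drops parasitic genomes", {
  ann <- data.frame(genome = c("G1", "G2"), gene = c("p1", "p2"),
                    term = "T1", evidence = "IEA", qualifier = "enables")
  meta <- data.frame(genome = c("G1", "G2"),
                     superkingdom = c("B", "B"),
                     lifestyle = c("free-living", "obligate-parasitic"))
  m <- build_matrix(ann, meta = meta, free_living_only = TRUE)
  expect_equal(colnames(m$g), "G1")
})

test_that("HGT enrichment filter matches the exact hypergeometric tail", {
  # term X: 10 genes, all HTP; background 100 genes with 10 HTP total
  genes_x <- paste0("h", 1:10)
  genes_bg <- paste0("b", 1:90)
  ann <- data.frame(genome = "G1",
                    gene = c(genes_x, genes_bg),
                    term = c(rep("X", 10), rep("BG", 90)),
                    evidence = "IEA", qualifier = "enables")
  res <- hgt_enrichment_filter(ann, genes_x, alpha = 0.05)
  expect_true("X" %in% res$removed)
  expect_lt(res$p_values[["X"]], 0.001)
  expect_equal(res$p_values[["X"]],
               oracle_hyper_tail(10, 10, 100, 10), tolerance = 1e-12)
  # term with no HTP genes: one-sided p >= 0.5, kept
  expect_gte(res$p_values[["BG"]], 0.5)
  expect_false("BG" %in% res$removed)
  # empty HTP set removes nothing
  res0 <- hgt_enrichment_filter(ann, character(0), alpha = 0.05)
  expect_length(res0$removed, 0L)
  expect_error(hgt_enrichment_filter(ann, genes_x, alpha = 1.5), "alpha")
  expect_warning(hgt_enrichment_filter(ann, c(genes_x, "ghost"), 0.05),
                 "absent")
})

test_that("filter removes a term iff its exact tail p < alpha (small instances)", {
  set.seed(11)
  for (rep in 1:20) {
    ng <- sample(10:50, 1)
    genes <- paste0("g", seq_len(ng))
    ann <- data.frame(genome = "G1", gene = genes,
                      term = sample(c("T1", "T2", "T3"), ng, replace = TRUE),
                      evidence = "IEA", qualifier = "enables")
    htp <- sample(genes, sample.int(ng, 1))
    res <- hgt_enrichment_filter(ann, htp, alpha = 0.05)
    for (tm in unique(ann$term)) {
      gs <- unique(ann$gene[ann$term == tm])
      p_oracle <- oracle_hyper_tail(sum(gs %in% htp), length(htp), ng,
                                    length(gs))
      expect_equal(res$p_values[[tm]], p_oracle, tolerance = 1e-10)
      expect_equal(tm %in% res$removed, p_oracle < 0.05)
    }
  }
})

test_that("normalize_encode reproduces the 32-state formula", {
  g <- matrix(c(0L, 7L, 100L, 3L), 2, 2,
              dimnames = list(c("T1", "T2"), c("G1", "G2")))
  m <- structure(list(g = g, g_max = 100L, meta = NULL),
                 class = "abundance_matrix")
  e <- normalize_encode(m)
  expect_equal(e$states["T1", "G1"], 0L)                 # g = 0
  expect_equal(e$states["T1", "G2"], 31L)                # g = g_max
  expect_equal(e$symbols["T1", "G2"], "V")
  # g = 7, g_max = 100: ln(8)/ln(101)*31 = 13.967 -> 14 -> "E"
  expect_equal(e$states["T2", "G1"], 14L)
  expect_equal(e$symbols["T2", "G1"], "E")
  expect_error(normalize_encode(matrix(0L, 2, 2)), "all-zero")
})

test_that("encoding is monotone, in range, half-up rounded", {
  expect_equal(gocensus:::round_half_up(c(0.5, 1.5, 2.4, 2.6)),
               c(1, 2, 2, 3))
  set.seed(3)
  for (i in 1:20) {
    g <- matrix(rpois(30, sample(c(2, 50, 800), 1)), 5, 6,
                dimnames = list(paste0("t", 1:5), paste0("g", 1:6)))
    if (max(g) < 1) next
    e <- normalize_encode(g)
    expect_true(all(e$states >= 0L & e$states <= 31L))
    o <- order(g)
    expect_true(all(diff(e$states[o]) >= 0L))            # monotone in g
    expect_equal(e$states[which.max(g)], 31L)
  }
  expect_length(unique(GO_SYMBOLS <- gocensus:::GO_SYMBOLS), 32L)
})

test_that("NEXUS character matrices round-trip with letter symbols", {
  g <- matrix(c(0L, 5L, 31L, 12L, 1L, 31L), 3, 2,
              dimnames = list(c("tax one", "tax_two", "tax3"),
                              c("G1", "G2")))
  e <- normalize_encode(g)
  f <- tempfile(fileext = ".nex")
  write_character_matrix(e, f, orientation = "tof")
  txt <- readLines(f)
  expect_true(any(grepl("SYMBOLS=\"0~9A~V\"", txt)))
  expect_true(any(grepl("DEFTYPE=ORD", txt)))
  expect_true(any(grepl("V", txt[grep("tax", txt)])))    # state 31 prints V
  back <- read_character_matrix(f)
  expect_equal(unname(back), unname(e$states))
  expect_equal(rownames(back), c("tax_one", "tax_two", "tax3"))
  # transposed orientation
  f2 <- tempfile(fileext = ".nex")
  write_character_matrix(e, f2, orientation = "tol")
  expect_equal(unname(read_character_matrix(f2)), unname(t(e$states)))
  # 2 taxa x 1 character dimensions line
  e1 <- normalize_encode(matrix(c(1L, 4L), 2, 1,
                                dimnames = list(c("a", "b"), "G1")))
  f3 <- tempfile(fileext = ".nex")
  write_character_matrix(e1, f3)
  expect_true(any(grepl("NTAX=2 NCHAR=1", readLines(f3))))
  # name collisions after sanitization are refused
  gbad <- matrix(1:2, 2, 1, dimnames = list(c("a b", "a_b"), "G1"))
  expect_error(write_character_matrix(normalize_encode(gbad), tempfile()),
               "collide")
})
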