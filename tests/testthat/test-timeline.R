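test_that("node_distance counts internal nodes, scaled by max depth", {
  # caterpillar of 6 leaves: depths 0,1,2,3,4,4
  tr <- ape::read.tree(text = "(a,(b,(c,(d,(e,f)))));")
  nd <- node_distance(tr)
  expect_equal(unname(nd[c("a", "b", "c", "d", "e", "f")]),
               c(0, 1, 2, 3, 4, 4) / 4)
  expect_equal(min(nd), 0)
  expect_equal(max(nd), 1)
  # printed-precision conventions from the timeline tables
  big <- ape::stree(16, type = "left")       # max depth 14
  ndb <- node_distance(big)
  expect_equal(round(sort(unique(ndb))[2], 2), 0.07)   # depth 1 of 14
  expect_error(node_distance(ape::unroot(tr)), "rooted")
  # n_taxa divisor stays available
  ndt <- node_distance(tr, divisor = "n_taxa")
  expect_equal(max(ndt), 4 / 6)
})

test_that("nd is monotone along root-to-leaf paths and permutation-stable", {
  set.seed(8)
  for (i in 1:10) {
    tr <- ape::rtree(8)
    nd <- node_distance(tr)
    expect_gte(min(nd), 0)
    expect_equal(max(nd), 1)
    tr2 <- ape::rotateConstr(tr, sample(tr$tip.label))
    expect_equal(node_distance(tr2)[names(nd)], nd)
    # monotone along any root-to-leaf path: a leaf is never shallower
    # than the nd implied by its ancestors' depths; check via cherries
    # sharing equal depth
    phy <- stats::reorder(tr)
    dep <- numeric(max(phy$edge))
    for (k in seq_len(nrow(phy$edge)))
      dep[phy$edge[k, 2]] <- dep[phy$edge[k, 1]] + 1
    leafdep <- dep[seq_len(8)] - 1
    expect_equal(unname(nd[tr$tip.label]), leafdep / max(leafdep))
  }
  # a leaf attached at the root split (the basal taxon) reads exactly 0
  bas <- ape::read.tree(text = "(x,((a,b),(c,d)));")
  expect_equal(unname(node_distance(bas)["x"]), 0)
})

test_that("distribution index is presence over scope", {
  g <- matrix(c(1L, 0L, 2L, 0L, 0L, 3L,
                5L, 5L, 5L, 5L, 5L, 5L), 2, 6, byrow = TRUE,
              dimnames = list(c("T1", "T2"), paste0("G", 1:6)))
  f <- distribution_index(g)
  expect_equal(unname(f), c(3 / 6, 1))
  # absent taxon
  g0 <- rbind(g, T3 = 0L)
  expect_equal(unname(distribution_index(g0)["T3"]), 0)
  # per-superkingdom scope
  expect_equal(unname(distribution_index(g, genomes = c("G1", "G3"))["T1"]), 1)
  expect_error(distribution_index(g[, 0, drop = FALSE]), "empty")
  # 3 of 12 synthetic genomes
  g12 <- matrix(0L, 1, 12, dimnames = list("T", paste0("G", 1:12)))
  g12[1, 1:3] <- 1L
  expect_equal(unname(distribution_index(g12)), 0.25)
})

test_that("venn groups concatenate superkingdom letters in A,B,E order", {
  meta <- data.frame(genome = paste0("G", 1:6),
                     superkingdom = c("A", "A", "B", "B", "E", "E"),
                     lifestyle = "free-living")
  g <- matrix(0L, 4, 6, dimnames = list(c("T1", "T2", "T3", "T4"),
                                        meta$genome))
  g["T1", ] <- 1L                      # everywhere -> ABE
  g["T2", 5:6] <- 1L                   # only Eukarya -> E
  g["T3", 3:5] <- 1L                   # Bacteria + Eukarya -> BE
  vg <- venn_group(g, meta)
  expect_equal(unname(vg$group[c("T1", "T2", "T3")]), c("ABE", "E", "BE"))
  expect_true(is.na(vg$group["T4"]))
  expect_equal(vg$absent, "T4")
  # removing a superkingdom never adds letters
  keep <- meta$genome[meta$superkingdom != "A"]
  vg2 <- venn_group(g[, keep], meta[meta$genome %in% keep, ])
  for (tx in c("T1", "T2", "T3")) {
    if (is.na(vg2$group[tx])) next
    expect_true(all(strsplit(vg2$group[tx], "")[[1]] %in%
                    strsplit(vg$group[tx], "")[[1]]))
  }
})

test_that("gsi is 1 iff monophyletic and p comes from full enumeration", {
  tr <- seven_leaf_trees()[[1]]        # (((a,b),(c,d)),((e,f),g));
  mono <- gsi(tr, c("a", "b"))
  expect_equal(mono$gsi, 1)
  expect_equal(mono$method, "exact")
  non <- gsi(tr, c("a", "e"))
  expect_lt(non$gsi, 1)
  # group = all leaves is 1 by convention
  expect_equal(gsi(tr, "all")$gsi, 1)
  # two leaves at opposite ends of an 8-leaf ladder
  lad <- ape::read.tree(text = "(a,(b,(c,(d,(e,(f,(g,h)))))));")
  far <- gsi(lad, c("a", "h"))
  expect_lt(far$gsi, 0.5)
  # exact p: fraction of equal-size groups with gsi >= observed
  vals <- apply(utils::combn(lad$tip.label, 2), 2,
                function(g) gsi(lad, g)$gsi)
  expect_equal(far$p, mean(vals >= far$gsi))
  expect_error(gsi(tr, c("a", "zz")), "not in the tree")
  expect_error(gsi(tr, "a"), "size")
})

test_that("age histogram follows half-open bin conventions", {
  tl <- data.frame(taxon = paste0("T", 1:5),
                   nd = c(0, 0.4, 0.5, 0.6, 1),
                   f = 1, venn = "ABE",
                   level1 = c("c1", "c1", "c2", "c2", "c1,c2"))
  h <- age_histogram(tl)
  expect_equal(sum(h$table), 6L)                 # multi-category counted twice
  expect_equal(h$multi_category, "T5")
  expect_equal(unname(h$table["[0.4,0.6)", "c1"]), 1L)   # nd = 0.4 in middle
  expect_equal(unname(h$table["[0.6,1]", "c1"]), 1L)     # the multi taxon
  expect_equal(unname(h$table["[0,0.4)", "c1"]), 1L)
  # all taxa at nd 0 land in the first bin
  tl0 <- transform(tl, nd = 0)
  expect_equal(sum(age_histogram(tl0)$table[1, ]), 6L)
  expect_error(age_histogram(transform(tl, nd = nd + 1)), "0, 1")
})

test_that("accumulation curves step correctly and recover a 3:1 ratio", {
  tl1 <- data.frame(taxon = paste0("A", 1:5), nd = seq(0, 1, length.out = 5))
  # duplicated nd values appear as one step of height 2
  tld <- data.frame(taxon = c("X1", "X2"), nd = c(0.5, 0.5))
  cv <- accumulation_curve(list("1" = tld))
  expect_equal(nrow(cv$curves[["1"]]), 1L)
  expect_equal(cv$curves[["1"]]$cumulative, 2L)
  # uniform spacing: cumulative is linear in rank
  cu <- accumulation_curve(list("1" = tl1))$curves[["1"]]
  expect_equal(cu$cumulative, 1:5)
  # constructed two-level timeline with an exact 3:1 birth ratio
  nd1 <- seq(0.1, 1, by = 0.1)
  tlA <- data.frame(taxon = paste0("a", seq_along(nd1)), nd = nd1)
  nd2 <- rep(nd1, each = 3)
  tlB <- data.frame(taxon = paste0("b", seq_along(nd2)), nd = nd2)
  ac <- suppressWarnings(accumulation_curve(list("1" = tlA, "2" = tlB)))
  expect_equal(ac$fits[["2"]]$slope, 3, tolerance = 1e-8)
  expect_equal(ac$fits[["2"]]$r2, 1, tolerance = 1e-8)
  # fewer than 3 grid points: slope omitted
  ac2 <- accumulation_curve(list("1" = tld, "2" = tld))
  expect_true(is.na(ac2$fits[["2"]]$slope))
})

test_that("build_timeline assembles nd, f, venn and level-1 categories", {
  meta <- data.frame(genome = c("G1", "G2", "G3"),
                     superkingdom = c("A", "B", "E"),
                     lifestyle = "free-living")
  g <- matrix(c(3L, 2L, 1L,
                0L, 1L, 1L,
                0L, 0L, 1L), 3, 3, byrow = TRUE,
              dimnames = list(c("T1", "T2", "T3"), meta$genome))
  am <- structure(list(g = g, g_max = 3L, meta = meta),
                  class = "abundance_matrix")
  tr <- ape::read.tree(text = "(T1,(T2,T3));")
  tl <- build_timeline(tr, am, level1_map = list(c1 = c("T1", "T2"),
                                                 c2 = c("T2", "T3")))
  expect_equal(tl$nd[tl$taxon == "T1"], 0)
  expect_equal(tl$venn[tl$taxon == "T2"], "BE")
  expect_equal(tl$f[tl$taxon == "T3"], 1 / 3)
  expect_equal(tl$level1[tl$taxon == "T2"], "c1,c2")
  f <- tempfile(fileext = ".tsv")
  write_timeline(tl, f)
  expect_equal(utils::read.delim(f)$taxon, tl$taxon)
})
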