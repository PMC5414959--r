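test_that("wagner_length matches its worked examples", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  m <- matrix(c(0L, 2L, 1L, 3L), 4, 1,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  expect_equal(wagner_length(tr, m), 4)
  # constant character: zero steps on any topology
  expect_equal(wagner_length(tr, matrix(5L, 4, 1,
    dimnames = list(c("A", "B", "C", "D"), NULL))), 0)
  # 3-leaf star, states 0/1/5: sum of deviations from the median
  tr3 <- ape::read.tree(text = "(A,B,C);")
  m3 <- matrix(c(0L, 1L, 5L), 3, 1, dimnames = list(c("A", "B", "C"), NULL))
  expect_equal(wagner_length(tr3, m3), 5)
  # two-leaf tree: forced |3 - 9|
  tr2 <- ape::read.tree(text = "(A,B);")
  m2 <- matrix(c(3L, 9L), 2, 1, dimnames = list(c("A", "B"), NULL))
  expect_equal(sankoff_length(tr2, m2), 6)
  expect_error(wagner_length(tr, m3), "missing")
})

test_that("wagner and sankoff lengths agree on random instances", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    m <- random_state_matrix(n, sample(2:5, 1))
    rownames(m) <- tr$tip.label
    expect_equal(wagner_length(tr, m), sankoff_length(tr, m), info = i)
  }
})

test_that("tree length is invariant to re-rooting and leaf permutation", {
  set.seed(5)
  for (i in 1:20) {
    tr <- ape::rtree(7, rooted = FALSE)
    m <- random_state_matrix(7, 4)
    rownames(m) <- tr$tip.label
    L <- wagner_length(tr, m)
    rerooted <- ape::root(tr, outgroup = sample(tr$tip.label, 1),
                          resolve.root = TRUE)
    expect_equal(wagner_length(rerooted, m), L)
    perm <- sample(nrow(m))
    expect_equal(wagner_length(tr, m[perm, , drop = FALSE]), L)
  }
})

test_that("an independent sankoff implementation (phangorn) agrees", {
  skip_if_not_installed("phangorn")
  set.seed(9)
  for (i in 1:10) {
    n <- 6
    smax <- 5
    tr <- ape::rtree(n, rooted = FALSE)
    m <- random_state_matrix(n, 4, smax = smax)
    rownames(m) <- tr$tip.label
    dat <- phangorn::phyDat(matrix(as.character(m), n,
                                   dimnames = dimnames(m)),
                            type = "USER", levels = as.character(0:smax))
    cost <- abs(outer(0:smax, 0:smax, "-"))
    dimnames(cost) <- list(0:smax, 0:smax)
    expect_equal(wagner_length(tr, m),
                 as.numeric(phangorn::parsimony(tr, dat, method = "sankoff",
                                                cost = cost)))
  }
})

test_that("heuristic search attains the exhaustive optimum (n <= 7)", {
  set.seed(21)
  for (i in 1:12) {
    n <- sample(5:7, 1)
    m <- random_state_matrix(n, sample(3:5, 1), smax = 10)
    opt <- oracle_exhaustive_optimum(m)
    hs <- heuristic_search(m, n_addseq = 4, seed = i)
    expect_equal(hs$length, opt$optimum, info = i)
  }
})

test_that("search recovers a ladder topology exactly, with TL = sum of ranges", {
  m <- ladder_matrix(6, reps = 3, step = 2)
  hs <- heuristic_search(m, n_addseq = 3, seed = 1)
  expect_equal(hs$length, sum(apply(m, 2, max) - apply(m, 2, min)))
  expect_equal(hs$n_trees, 1L)
  truth <- ape::read.tree(text = "(t1,(t2,(t3,(t4,(t5,t6)))));")
  expect_equal(ape::dist.topo(ape::unroot(truth), hs$trees[[1]]
               )[[1]], 0)
  fi <- fit_indices(hs$trees[[1]], m)
  expect_equal(fi$CI, 1)
  expect_equal(fi$RI, 1)
  expect_equal(fi$HI, 0)
})

test_that("duplicate taxa form a zero-length pendant pair", {
  m <- random_state_matrix(5, 4, smax = 8)
  m <- rbind(m, dup = m["t1", ])
  rownames(m)[6] <- "t6"
  hs <- heuristic_search(m, n_addseq = 3, seed = 2)
  # t1 and t6 identical: grouping them adds no steps over 5-taxon optimum
  opt5 <- oracle_exhaustive_optimum(m[1:5, , drop = FALSE])
  expect_equal(hs$length, opt5$optimum)
})

test_that("searches on < 4 taxa return the unique topology", {
  m <- random_state_matrix(3, 3)
  hs <- heuristic_search(m, seed = 1)
  expect_equal(hs$n_trees, 1L)
  expect_equal(hs$length, sum(apply(m, 2, oracle_star_length)))
})

test_that("lundberg rooting scans every edge and is length-consistent", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:7, 1)
    m <- random_state_matrix(n, 4, smax = 12)
    hs <- heuristic_search(m, n_addseq = 3, seed = i)
    lr <- lundberg_root(hs, m, ancestor = "max")
    expect_gte(lr$attachment_cost, 0)
    expect_equal(lr$rooted_length, lr$unrooted_length + lr$attachment_cost)
    expect_true(ape::is.rooted(lr$tree))
    # exhaustive attachment oracle: append the ancestor as a real taxon,
    # shifting internal node ids to make room for the new tip id n + 1
    anc <- apply(m, 2, max)
    ut <- hs$utrees[[1]]
    e <- ut$edge; e[e > n] <- e[e > n] + 1L
    ut_shift <- gocensus:::new_utree(e, n + 1L, c(ut$labels, "ANC"))
    m_aug <- rbind(m, ANC = anc)
    best_direct <- Inf
    for (k in seq_len(nrow(e))) {
      w <- max(e) + 1L
      e2 <- rbind(e[-k, , drop = FALSE],
                  c(e[k, 1L], w), c(w, e[k, 2L]), c(w, n + 1L))
      ut2 <- gocensus:::new_utree(e2, n + 1L, c(ut$labels, "ANC"))
      best_direct <- min(best_direct, wagner_length(ut2, m_aug))
    }
    expect_equal(lr$rooted_length, best_direct)
  }
})

test_that("lundberg with the max ancestor roots a ladder at the oldest taxon", {
  m <- ladder_matrix(7, reps = 4)
  hs <- heuristic_search(m, n_addseq = 3, seed = 1)
  lr <- lundberg_root(hs, m, ancestor = "max")
  expect_equal(lr$root_bipartition, "t7")   # the all-max taxon is basal
  expect_equal(lr$attachment_cost, 0)
  # tol mode: an all-zero taxon present -> root adjacent to it
  lr0 <- lundberg_root(hs, m, ancestor = "zero")
  expect_equal(lr0$root_bipartition, "t1")  # the all-zero taxon
  # fully symmetric 4-taxon matrix (constant characters): every edge is
  # an equally parsimonious root position and the ties are reported
  msym <- matrix(1L, 4, 2, dimnames = list(paste0("s", 1:4), NULL))
  hs4 <- heuristic_search(msym, n_addseq = 2, seed = 1)
  lr4 <- lundberg_root(hs4$trees[[1]], msym, ancestor = "max")
  expect_equal(lr4$tied_edges, 5L)
  expect_error(lundberg_root(hs, m, ancestor = c(1L, 2L)), "length")
})

test_that("fit indices match hand-enumerated values and aggregate identity", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  m <- matrix(c(0L, 2L, 1L, 3L), 4, 1,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  fi <- fit_indices(tr, m)
  expect_equal(fi$per_character$min_steps, 3)
  expect_equal(fi$per_character$max_steps, 4)
  expect_equal(fi$per_character$obs_steps, 4)
  expect_equal(fi$CI, 0.75)
  expect_equal(fi$RI, 0)
  expect_equal(fi$HI, 0.25)
  # star-tree maxima agree with brute force over ancestral states
  set.seed(41)
  m2 <- random_state_matrix(6, 5, smax = 9)
  tr2 <- ape::rtree(6, rooted = FALSE); rownames(m2) <- tr2$tip.label
  fi2 <- fit_indices(tr2, m2)
  expect_equal(fi2$per_character$max_steps,
               apply(m2, 2, oracle_star_length))
  # ensemble indices are the step-weighted aggregation of per-character ones
  pc <- fi2$per_character
  expect_equal(fi2$CI, sum(pc$min_steps) / sum(pc$obs_steps))
  expect_equal(fi2$RI, (sum(pc$max_steps) - sum(pc$obs_steps)) /
                        (sum(pc$max_steps) - sum(pc$min_steps)))
  # homoplasy-free ladder character: ci = ri = 1, hi = 0
  ml <- ladder_matrix(5, reps = 1)
  trl <- ape::read.tree(text = "(t1,(t2,(t3,(t4,t5))));")
  fil <- fit_indices(trl, ml)
  expect_true(all(fil$per_character$ci == 1))
  expect_true(all(fil$per_character$hi == 0))
  expect_equal(fil$RI, 1)
})

test_that("bootstrap support is reproducible and saturates on clean data", {
  # 20 identical perfectly tree-like characters -> every bipartition 100%
  m <- ladder_matrix(5, reps = 20)[, seq(1, 80, by = 4)]
  hs <- heuristic_search(m, n_addseq = 2, seed = 1)
  bs <- bootstrap_support(hs, m, n_reps = 30, seed = 7, n_addseq = 2)
  expect_true(all(bs$support == 100))
  expect_true(all(bs$majority))
  bs2 <- bootstrap_support(hs, m, n_reps = 30, seed = 7, n_addseq = 2)
  expect_identical(bs, bs2)                  # seed-fixed reproducibility
  expect_error(bootstrap_support(hs, m, n_reps = 0), "n_reps")
})

test_that("a single character supports only its own bipartitions", {
  # one character splitting {t1,t2} from {t3,t4,t5}
  m <- matrix(c(0L, 0L, 4L, 4L, 4L), 5, 1,
              dimnames = list(paste0("t", 1:5), NULL))
  hs <- heuristic_search(m, n_addseq = 4, seed = 3)
  bs <- bootstrap_support(hs$trees[[1]], m, n_reps = 20, seed = 5,
                          n_addseq = 2)
  implied <- bs$support[bs$tips %in% c("t1,t2", "t3,t4,t5")]
  others <- bs$support[!bs$tips %in% c("t1,t2", "t3,t4,t5")]
  expect_true(all(implied == 100))
  if (length(others)) expect_true(all(others == 0))
})
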