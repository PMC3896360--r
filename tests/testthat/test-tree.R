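cvec <- function(id, scores) {
  structure(list(K = 5L, species_id = id, scores = scores,
                 p = NULL, p0 = NULL),
            class = "composition_vector")
}

test_that("cosine distance handles identical, orthogonal and zero vectors", {
  a <- cvec("a", c(AAAAA = 1, VVVVV = 2))
  expect_equal(as.numeric(cosine_distance(a, a)), 0)
  expect_equal(attr(cosine_distance(a, a), "cosine"), 1)

  b <- cvec("b", c(LLLLL = 1))
  d <- cosine_distance(a, b)
  expect_equal(as.numeric(d), 0.5)
  expect_equal(attr(d, "cosine"), 0)

  ## all-zero after projection onto a foreign key set
  ks <- keyset("SSSSS")
  expect_equal(as.numeric(cosine_distance(a, b, keys = ks)), 0.5)

  b4 <- b
  b4$K <- 4L
  expect_error(cosine_distance(a, b4), "K mismatch")
})

test_that("sparse cosine distances match the dense oracle", {
  set.seed(41)
  pool <- enumerate_strings(c("A", "V", "L"), 5)
  for (i in 1:20) {
    sa <- sample(pool, sample(5:40, 1))
    sb <- sample(pool, sample(5:40, 1))
    a <- cvec("a", stats::setNames(stats::rnorm(length(sa)), sa))
    b <- cvec("b", stats::setNames(stats::rnorm(length(sb)), sb))
    da <- db <- rep(0, length(pool))
    names(da) <- names(db) <- pool
    da[names(a$scores)] <- a$scores
    db[names(b$scores)] <- b$scores
    expect_equal(as.numeric(cosine_distance(a, b)),
                 dense_cosine_distance(da, db), tolerance = 1e-12)
  }
})

test_that("distance matrices are symmetric with the expected degeneracies", {
  a <- cvec("a", c(AAAAA = 1))
  b <- cvec("b", c(VVVVV = 1))
  c_ <- cvec("c", c(LLLLL = 1))
  dm <- distance_matrix(list(a, b, c_))
  expect_equal(unname(dm[upper.tri(dm)]), rep(0.5, 3))

  dup <- distance_matrix(list(a, cvec("a2", a$scores)))
  expect_equal(dup["a", "a2"], 0)
})

test_that("NJ solves the 3-taxon closed form and additive matrices exactly", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  ## closed form: la = (dab + dac - dbc)/2 etc.
  lens <- tr$edge.length[match(1:3, tr$edge[, 2])]
  expect_equal(sort(lens), sort(c(1, 2, 3)))

  ## additive 4-taxon matrix built from a known tree: exact recovery of
  ## topology and branch lengths (path metric reproduced)
  t4 <- ape::read.tree(text = "((a:1,b:2):0.7,(c:1.5,d:0.5):0.3);")
  d4 <- ape::cophenetic.phylo(t4)
  r4 <- nj_tree(d4)
  expect_equal(topology_similarity(r4, t4), 100, ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(r4)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-10)

  ## ultrametric 5-taxon case agrees with the single-linkage topology
  t5 <- ape::read.tree(text = "(((a:1,b:1):1,c:2):2,(d:3,e:3):1);")
  d5 <- ape::cophenetic.phylo(t5)
  r5 <- nj_tree(d5)
  hc <- stats::hclust(stats::as.dist(d5), method = "single")
  hc_tree <- ape::as.phylo(hc)
  expect_equal(topology_similarity(r5, hc_tree), 100, ignore_attr = TRUE)

  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers random additive trees (property)", {
  set.seed(42)
  for (i in 1:20) {
    case <- random_additive_case(sample(4:8, 1))
    tr <- nj_tree(case$dm)
    expect_equal(topology_similarity(tr, case$tree), 100, ignore_attr = TRUE)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("gene draws have the resampling distribution and reproducibility", {
  d1 <- bootstrap_gene_draws(paste0("g", 1:13), 50, seed = 7)
  d2 <- bootstrap_gene_draws(paste0("g", 1:13), 50, seed = 7)
  expect_identical(d1, d2)
  expect_true(all(lengths(d1) == 13))
  expect_true(all(unlist(d1) %in% paste0("g", 1:13)))
  expect_error(bootstrap_gene_draws(character(0), 10), "empty gene universe")
})

test_that("bootstrap replicates are seeded, reproducible and well-formed", {
  sim <- fixture("twoclade-minimal")
  b1 <- bootstrap_trees(sim$proteomes, n_replicates = 5, seed = 9)
  b2 <- bootstrap_trees(sim$proteomes, n_replicates = 5, seed = 9)
  expect_identical(lapply(b1, ape::write.tree), lapply(b2, ape::write.tree))
  expect_true(all(vapply(b1, function(t)
    setequal(t$tip.label, names(sim$proteomes)), FALSE)))

  ## single-gene universe: every draw is that gene, so each replicate tree
  ## equals the full-data tree
  single <- lapply(sim$proteomes, function(p) {
    p$proteins <- p$proteins["g1"]
    p
  })
  full <- nj_tree(distance_matrix(cv_matrix(single, K = 5)))
  rep1 <- bootstrap_trees(single, n_replicates = 1, seed = 3)
  expect_equal(topology_similarity(rep1[[1]], full), 100, ignore_attr = TRUE)
})

test_that("support values count matching bipartitions", {
  main <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,(e:1,f:1):1);")
  all100 <- consensus_support(main, list(main, main))
  expect_equal(setdiff(unique(all100$node.label), ""), "100")

  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1,f:1);")
  all0 <- consensus_support(main, list(star, star))
  expect_equal(setdiff(unique(all0$node.label), ""), "0")

  ## 4 taxa, 3 replicates of which 2 contain the main internal edge
  m4 <- ape::read.tree(text = "((a:1,b:1):1,c:1,d:1);")
  alt <- ape::read.tree(text = "((a:1,c:1):1,b:1,d:1);")
  s <- consensus_support(m4, list(m4, m4, alt))
  expect_true("66.7" %in% s$node.label)

  ## supports do not depend on replicate order
  s2 <- consensus_support(m4, list(alt, m4, m4))
  expect_equal(s$node.label, s2$node.label)
})

test_that("topology similarity agrees with brute-force bipartitions and RF", {
  t1 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  t2 <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1);")
  expect_equal(topology_similarity(t1, t1), 100, ignore_attr = TRUE)
  s <- topology_similarity(t1, t2)
  expect_equal(as.numeric(s), 0)
  expect_equal(attr(s, "rf"), 2L)
  expect_error(topology_similarity(t1, ape::rtree(5)), "leaf sets")

  ## two identical stars have no internal edges but identical topology
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_equal(topology_similarity(star, star), 100, ignore_attr = TRUE)

  set.seed(43)
  for (i in 1:10) {
    ta <- ape::rtree(8)
    tb <- ape::rtree(8)
    tb$tip.label <- sample(ta$tip.label)
    ba <- brute_bipartitions(ta)
    bb <- brute_bipartitions(tb)
    shared <- length(intersect(ba, bb))
    s <- topology_similarity(ta, tb)
    expect_equal(as.numeric(s),
                 100 * shared / max(length(ba), length(bb)))
    expect_equal(attr(s, "rf"),
                 as.integer(phangorn::RF.dist(ape::unroot(ta),
                                              ape::unroot(tb))))
  }
})
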