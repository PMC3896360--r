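make_cv <- function(id, scores) {
  structure(list(K = nchar(names(scores))[1], species_id = id,
                 scores = scores, p = rep(NA_real_, length(scores)),
                 p0 = rep(NA_real_, length(scores))),
            class = "composition_vector")
}

test_that("variance profile follows the population convention", {
  r1 <- make_cv("a", c(AAAAA = 0))
  r2 <- make_cv("b", c(AAAAA = 1))
  vp <- variance_profile(list(r1, r2))
  expect_equal(unname(vp$variances["AAAAA"]), 0.25)

  same <- variance_profile(list(r2, r2, r2))
  expect_equal(same$v_max, 0)
  expect_error(variance_profile(list(r1)), "at least 2")
})

test_that("sparse variances match a dense recomputation", {
  set.seed(21)
  keys <- replicate(30, paste(sample(c("A", "V", "L"), 5, TRUE), collapse = ""))
  keys <- unique(keys)
  rows <- lapply(1:5, function(i) {
    sel <- sample(keys, sample(3:length(keys), 1))
    make_cv(paste0("s", i), stats::setNames(stats::rnorm(length(sel)), sel))
  })
  vp <- variance_profile(rows)
  dense <- sapply(keys, function(k)
    vapply(rows, function(r) if (k %in% names(r$scores)) r$scores[[k]] else 0, 0))
  ref <- apply(dense, 2, function(col) mean(col^2) - mean(col)^2)
  ref <- ref[ref > 0 | names(ref) %in% names(vp$variances)]
  expect_equal(vp$variances[order(names(vp$variances))],
               ref[order(names(ref))], tolerance = 1e-12)
})

test_that("critical point is the stated fraction of the maximum variance", {
  vp <- structure(list(K = 5L,
                       variances = c(a = 10, b = 0.5, c = 0.2),
                       n_species = 4L, v_max = 10, reduction = 0.9,
                       critical_value = 1),
                  class = "variance_profile")
  expect_equal(critical_point(vp), 1)
  expect_equal(critical_point(vp, reduction = 0.8), 2)

  vp0 <- vp
  vp0$variances[] <- 0
  vp0$v_max <- 0
  expect_equal(critical_point(vp0), 0)

  ## linear scaling
  vp2 <- vp
  vp2$variances <- vp$variances * 7
  vp2$v_max <- vp$v_max * 7
  expect_equal(critical_point(vp2), 7 * critical_point(vp))
})

test_that("key selection is strict and convention-invariant", {
  r <- list(make_cv("a", c(AAAAA = 0, VVVVV = 0, LLLLL = 0)),
            make_cv("b", c(AAAAA = 6.3, VVVVV = 1.4, LLLLL = 0.9)))
  vp <- variance_profile(r)
  ks <- select_keys(vp)
  expect_equal(ks$strings, "AAAAA")   # only the dominant-variance string

  ## identical species: empty set (strict inequality at 0)
  ident <- variance_profile(list(r[[2]], r[[2]]))
  expect_length(select_keys(ident)$strings, 0)

  ## uniform N/(N-1) rescaling (sample-variance convention) cannot change
  ## the selection
  vp_sample <- vp
  n <- vp$n_species
  vp_sample$variances <- vp$variances * n / (n - 1)
  vp_sample$v_max <- vp$v_max * n / (n - 1)
  vp_sample$critical_value <- (1 - vp$reduction) * vp_sample$v_max
  expect_equal(select_keys(vp_sample)$strings, ks$strings)

  ## uniform rescaling of all CV rows leaves the selection unchanged
  r_scaled <- lapply(r, function(x) { x$scores <- 3.7 * x$scores; x })
  expect_equal(select_keys(variance_profile(r_scaled))$strings, ks$strings)
})

test_that("group extraction degenerates to plain selection and handles ties", {
  sim <- fixture("twoclade-minimal")
  cvs <- cv_matrix(sim$proteomes, K = 5)
  whole <- select_keys(variance_profile(cvs))
  one <- extract_group_keys(sim$proteomes, n_subgroups = 1, seed = 4,
                            cvs = cvs)
  expect_equal(one$strings, whole$strings)

  ident <- lapply(1:4, function(i) {
    p <- sim$proteomes[[1]]
    p$species_id <- paste0("dup", i)
    p
  })
  expect_length(extract_group_keys(ident, n_subgroups = 2, seed = 1)$strings, 0)
  expect_error(extract_group_keys(ident[1:3], n_subgroups = 2, seed = 1),
               "at least 4")
})

test_that("engineered discriminative strings survive subgroup intersection", {
  sim <- fixture("small4x5")
  cvs <- cv_matrix(sim$proteomes, K = 5)
  broad <- extract_group_keys(sim$proteomes, n_subgroups = 2, seed = 11,
                              cvs = cvs)
  expect_true(all(sim$truth$motifs$motif %in% broad$strings))
})

test_that("broad extraction converges and nests core within broad", {
  sim <- fixture("twoclade-minimal")
  cvs <- cv_matrix(sim$proteomes, K = 5)

  one <- extract_broad_keys(sim$proteomes, group_size = 8, n_subgroups = 2,
                            max_reps = 1, seed = 5, cvs = cvs)
  expect_equal(one$core$strings, one$broad$strings)

  ## a pool of identical species yields empty key groups, so the second
  ## repetition is trivially contained and extraction stops there
  dup_pool <- lapply(1:8, function(i) {
    p <- sim$proteomes[[1]]
    p$species_id <- paste0("dup", i)
    p
  })
  dup <- extract_broad_keys(dup_pool, group_size = 8, n_subgroups = 2,
                            max_reps = 10, seed = 5)
  expect_equal(length(dup$groups), 2L)
  expect_equal(dup$containment[2], 1)
  expect_length(dup$broad$strings, 0)

  rep2 <- extract_broad_keys(sim$proteomes, group_size = 8, n_subgroups = 2,
                             max_reps = 5, seed = 5, cvs = cvs)
  expect_true(all(rep2$core$strings %in% rep2$broad$strings))
  for (g in rep2$groups) {
    expect_true(all(rep2$core$strings %in% g$strings))
    expect_true(all(g$strings %in% rep2$broad$strings))
  }
  expect_error(extract_broad_keys(sim$proteomes, group_size = 3,
                                  n_subgroups = 2), "at least")
})

test_that("taxon-specific extraction unions subtaxa with the broad set", {
  sim <- fixture("twoclade-minimal")
  pro <- sim$proteomes
  cvs <- cv_matrix(pro, K = 5)
  phyla <- sim$truth$phyla

  ## one subtaxon, no broad set: equals the group extraction of the subtaxon
  p1 <- pro[phyla == "P01"]
  alone <- extract_specific_keys(p1, subtaxa = rep("x", 4),
                                 cvs = cvs[phyla == "P01"], seed = 2)
  grp <- extract_group_keys(p1, n_subgroups = 2,
                            cvs = cvs[phyla == "P01"],
                            seed = with_seed(2, sample.int(.Machine$integer.max, 1)))
  expect_equal(alone$strings, grp$strings)

  ## a broad set disjoint from the subtaxon keys adds its full size
  fake_broad <- keyset(c("WWWWW", "YYYYY"), label = "fake")
  both <- extract_specific_keys(p1, subtaxa = rep("x", 4), broad = fake_broad,
                                cvs = cvs[phyla == "P01"], seed = 2)
  expect_length(both$strings, length(alone$strings) + 2L)

  ## undersized subtaxa are skipped with a warning
  expect_warning(
    extract_specific_keys(pro[1:3], subtaxa = c("a", "a", "b"),
                          cvs = cvs[1:3], seed = 2),
    "skipped")
})

test_that("global union behaves like a set union", {
  a <- keyset(c("AAAAA", "VVVVV"), label = "a")
  b <- keyset(c("LLLLL"), label = "b")
  g <- global_keys(list(a, b))
  expect_length(g$strings, 3)
  expect_equal(global_keys(list(a, b), broad = keyset(character(0), K = 5))$strings,
               g$strings)
  expect_equal(global_keys(list(g, g))$strings, g$strings)
  expect_error(global_keys(list(a, keyset("AAA", label = "k3"))), "same K")
})
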