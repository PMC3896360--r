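test_that("window conservativity reproduces the scale endpoints", {
  aln <- aa_alignment(c(a = "MKVLAMKVLA", b = "MKVLAMKVLA", c = "MKVLAMKVLA"))
  prof <- conservativity_profile(aln)
  expect_true(all(prof$scores == 15))

  ## all rows pairwise distinct in every window
  aln2 <- aa_alignment(c(a = "AAAAA", b = "VVVVV", c = "LLLLL"))
  expect_true(all(conservativity_profile(aln2)$scores == 0))

  ## n = 3 with two identical rows: m = 2, round(15 * 1/2) = 8
  aln3 <- aa_alignment(c(a = "MKVLA", b = "MKVLA", c = "LLLLL"))
  expect_equal(unname(conservativity_profile(aln3)$scores), 8L)

  expect_error(conservativity_profile(aa_alignment(c(a = "MK", b = "MK"))),
               "shorter than window")
})

test_that("conservativity is row-permutation invariant and duplication-monotone", {
  set.seed(61)
  rows <- vapply(1:4, function(i)
    paste(sample(c("A", "V", "L", "S"), 30, TRUE), collapse = ""), "")
  names(rows) <- paste0("r", 1:4)
  p1 <- conservativity_profile(aa_alignment(rows))
  p2 <- conservativity_profile(aa_alignment(rows[c(3, 1, 4, 2)]))
  expect_equal(p1$scores, p2$scores)

  ## duplicating a row can only raise the majority multiplicity
  dup <- c(rows, r5 = unname(rows[1]))
  p3 <- conservativity_profile(aa_alignment(dup))
  ## compare on the shared 0..15 scale: both use scale 15 but different n;
  ## duplication must not lower the most-frequent-segment multiplicity
  m1 <- 1 + round(p1$scores / 15 * (4 - 1))
  m3 <- 1 + round(p3$scores / 15 * (5 - 1))
  expect_true(all(m3 >= m1))
})

test_that("gaps are ordinary symbols inside windows", {
  aln <- aa_alignment(c(a = "MK-LA", b = "MK-LA", c = "MKVLA"))
  ## identical gap placement still counts as agreement
  expect_equal(unname(conservativity_profile(aln)$scores), 8L)
})

test_that("key mapping produces exact overlap-aware coverage", {
  expect_equal(map_keys("MKVLA", keyset("MKVLA")), rep(1L, 5))
  ## two overlapping occurrences (starts 1 and 2); positions 2-5 sit under
  ## both, the ends under one, so total mass is K * occurrences = 10
  expect_equal(map_keys("AAAAAA", keyset("AAAAA")),
               c(1L, 2L, 2L, 2L, 2L, 1L))
  expect_equal(map_keys("MKV", keyset("MKVLA")), rep(0L, 3))

  ## gapped row: matching on residues, coverage on alignment columns
  cov <- map_keys("MK-VLAM", keyset("KVLAM"))
  expect_equal(cov, c(0L, 1L, 0L, 1L, 1L, 1L, 1L))

  ## random sequences against the naive all-positions scan
  set.seed(62)
  pool <- enumerate_strings(c("A", "V", "L"), 3)
  ks3 <- keyset(sample(pool, 8))
  for (i in 1:10) {
    s <- paste(sample(c("A", "V", "L"), 40, TRUE), collapse = "")
    cov <- map_keys(s, ks3)
    ref <- integer(40)
    for (j in 1:38) {
      if (substr(s, j, j + 2) %in% ks3$strings)
        ref[j:(j + 2)] <- ref[j:(j + 2)] + 1L
    }
    expect_equal(cov, ref)
    ## coverage mass equals K times the number of occurrences
    occ <- sum(vapply(1:38, function(j)
      substr(s, j, j + 2) %in% ks3$strings, FALSE))
    expect_equal(sum(cov), 3L * occ)
  }
})

test_that("accumulation regions are maximal qualifying runs", {
  expect_equal(nrow(accumulation_regions(list(rep(0L, 20)))), 0)

  cov <- rep(0L, 20)
  cov[8:13] <- 2L
  reg <- accumulation_regions(list(cov))
  expect_equal(reg$start, 8)
  expect_equal(reg$end, 13)
  expect_equal(reg$hit_density, 2)

  ## runs shorter than min_len are dropped
  cov2 <- rep(0L, 20)
  cov2[3:5] <- 1L
  expect_equal(nrow(accumulation_regions(list(cov2), min_len = 5)), 0)

  ## nesting: regions at a higher threshold sit inside lower-threshold ones
  set.seed(63)
  covs <- lapply(1:3, function(i) as.integer(stats::rpois(200, 0.7)))
  r1 <- accumulation_regions(covs, min_total = 1)
  r2 <- accumulation_regions(covs, min_total = 2)
  for (i in seq_len(nrow(r2))) {
    inside <- any(r1$start <= r2$start[i] & r1$end >= r2$end[i])
    expect_true(inside)
  }
  expect_error(accumulation_regions(list(1:3, 1:4)), "equal length")
})

test_that("overlap summary contrasts regions against background", {
  aln <- aa_alignment(c(a = "MKVLAMKVLAVVVVVVVVVV",
                        b = "MKVLAMKVLASTSTGAGAGA",
                        c = "MKVLAMKVLAGGGGGTTTTT"))
  prof <- conservativity_profile(aln)
  ## a region inside the fully conserved first half
  reg <- data.frame(start = 1, end = 10, hit_density = 1)
  ov <- overlap_summary(reg, prof)
  expect_equal(ov$region_conserved_frac, 1)
  expect_lt(ov$background_conserved_frac, 1)

  none <- accumulation_regions(list(rep(0L, 20)))
  ov2 <- overlap_summary(none, prof)
  expect_true(is.na(ov2$region_conserved_frac))
  expect_equal(ov2$n_region_cols, 0)
})

test_that("keys concentrate in engineered conserved blocks (fixture)", {
  sim <- fixture("vertebrate-like10x2")
  pro <- sim$proteomes
  keys <- extract_group_keys(pro, n_subgroups = 2, seed = 3)
  expect_gt(length(keys$strings), 0)

  genes <- vapply(pro[[1]]$proteins, nchar, 0L)
  off <- cumsum(c(0, genes[-length(genes)]))
  names(off) <- names(genes)
  bl <- sim$truth$conserved_blocks
  block_cols <- unlist(lapply(seq_len(nrow(bl)), function(i)
    (off[bl$gene[i]] + bl$start[i]):(off[bl$gene[i]] + bl$end[i])))

  rows <- vapply(pro, function(p) paste(p$proteins, collapse = ""), "")
  covs <- lapply(rows, map_keys, keys = keys)
  total <- Reduce(`+`, covs)
  expect_gte(sum(total[block_cols]) / sum(total), 0.70)

  prof <- conservativity_profile(aa_alignment(rows, labels = names(pro)))
  reg <- accumulation_regions(covs)
  ov <- overlap_summary(reg, prof)
  expect_gt(ov$region_conserved_frac, ov$background_conserved_frac)
})
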