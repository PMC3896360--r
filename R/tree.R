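#' Cosine distance between two composition vectors
#'
#' `C(A, B)` is the cosine of the angle between the two sparse score vectors
#' over the union of their supports and `D = (1 - C) / 2`, which lies in
#' \[0, 1\]. When a key set is given both vectors are first projected onto
#' it (absent strings count 0). If either projected vector is all-zero, `C`
#' is defined as 0 so that `D = 0.5`.
#'
#' @param a,b [composition_vector] objects with the same `K`.
#' @param keys Optional [keyset] to project onto.
#' @return The distance `D(A, B)`; the cosine is attached as
#'   `attr(, "cosine")`.
#' @export
cosine_distance <- function(a, b, keys = NULL) {
  if (a$K != b$K) stop("K mismatch: ", a$K, " vs ", b$K)
  va <- a$scores
  vb <- b$scores
  if (!is.null(keys)) {
    if (keys$K != a$K) stop("key set K mismatch")
    va <- va[names(va) %in% keys$strings]
    vb <- vb[names(vb) %in% keys$strings]
  }
  na <- sqrt(sum(va^2))
  nb <- sqrt(sum(vb^2))
  C <- if (na == 0 || nb == 0) 0 else {
    common <- intersect(names(va), names(vb))
    sum(va[common] * vb[common]) / (na * nb)
  }
  C <- min(1, max(-1, C))
  structure((1 - C) / 2, cosine = C)
}

#' Pairwise cosine-distance matrix
#'
#' @param rows List of [composition_vector] rows (see [cv_matrix]).
#' @param keys Optional [keyset]; distances are computed on the projected
#'   vectors.
#' @return Labeled symmetric matrix with zero diagonal.
#' @export
distance_matrix <- function(rows, keys = NULL) {
  ids <- unname(vapply(rows, `[[`, "", "species_id"))
  n <- length(rows)
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- cosine_distance(rows[[i]], rows[[j]], keys = keys)
    dm[i, j] <- dm[j, i] <- as.numeric(d)
  }
  dm
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou--Nei neighbor joining (via [ape::nj]). Negative branch lengths,
#' which NJ can produce on non-additive input, are set to zero with the
#' deficit transferred to the sibling branch so path lengths through the
#' parent are preserved.
#'
#' @param dm Labeled symmetric distance matrix (or `dist`), at least 3 taxa.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  dm <- validate_distance_matrix(dm)
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 taxa")
  tree <- ape::nj(stats::as.dist(dm))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1L]
    sib <- setdiff(which(tree$edge[, 1L] == parent), e)
    if (length(sib)) {
      s <- sib[which.min(tree$edge[sib, 2L])]
      tree$edge.length[s] <- tree$edge.length[s] + deficit
    }
  }
  tree
}

#' Joint gene-family bootstrap draws
#'
#' One bootstrap replicate draws `G` gene families with replacement from the
#' `G`-family universe; the same draw is applied to every species so the
#' composition vectors stay comparable (a locus bootstrap). Some genes are
#' drawn repeatedly while others are skipped.
#'
#' @param genes Character vector: the gene-family universe.
#' @param n_replicates Number of replicates (default 100).
#' @param seed Integer seed.
#' @return A list of character vectors, one draw (length `G`) per replicate.
#' @export
bootstrap_gene_draws <- function(genes, n_replicates = 100, seed = NULL) {
  genes <- unique(genes)
  if (!length(genes)) stop("empty gene universe")
  stopifnot(n_replicates >= 1)
  with_seed(seed,
            lapply(seq_len(n_replicates),
                   function(i) sample(genes, length(genes), replace = TRUE)))
}

#' Bootstrap replicate trees by gene-family resampling
#'
#' For each replicate, gene families are drawn with replacement
#' ([bootstrap_gene_draws]); counts, composition vectors, distances and the
#' NJ tree are rebuilt from the drawn families (a gene drawn twice counts
#' twice; species missing a drawn gene simply contribute nothing for it).
#' Fully reproducible given `seed`.
#'
#' @param proteomes List of [proteome] objects.
#' @param n_replicates Number of replicates (default 100).
#' @param K String length (default 5).
#' @param keys Optional [keyset] for projected distances.
#' @param seed Integer seed.
#' @return List of [ape::phylo] trees, with the draws attached as
#'   `attr(, "draws")`.
#' @export
bootstrap_trees <- function(proteomes, n_replicates = 100, K = 5,
                            keys = NULL, seed = NULL) {
  K <- as.integer(K)
  ids <- vapply(proteomes, `[[`, "", "species_id")
  genes <- unique(unlist(lapply(proteomes, function(p) names(p$proteins))))
  genes <- genes[order_genes(genes)]
  draws <- bootstrap_gene_draws(genes, n_replicates, seed = seed)
  ## per-species per-gene counts at the three orders; counts never span
  ## proteins, so replicate counts are sums over the drawn families.
  per_gene <- lapply(proteomes, function(p) {
    lapply(p$proteins, function(s)
      lapply(c(K, K - 1L, K - 2L), function(k)
        tryCatch(count_kstrings(s, k), error = function(e) NULL)))
  })
  names(per_gene) <- ids
  sum_counts <- function(lst, k) {
    lst <- Filter(Negate(is.null), lst)
    if (!length(lst)) return(NULL)
    v <- unlist(unname(lapply(lst, `[[`, "counts")))
    agg <- rowsum(v, names(v))
    counts <- as.integer(agg)
    names(counts) <- rownames(agg)
    structure(list(K = k, counts = counts, total_windows = sum(counts)),
              class = "kstring_counts")
  }
  strings <- if (!is.null(keys)) keys$strings
  trees <- lapply(draws, function(drawn) {
    rows <- lapply(ids, function(id) {
      ## each drawn copy counts: a gene drawn twice contributes twice
      gl <- per_gene[[id]][drawn[drawn %in% names(per_gene[[id]])]]
      cK <- sum_counts(lapply(gl, `[[`, 1L), K)
      cK1 <- sum_counts(lapply(gl, `[[`, 2L), K - 1L)
      cK2 <- sum_counts(lapply(gl, `[[`, 3L), K - 2L)
      if (is.null(cK) || is.null(cK1) || is.null(cK2))
        stop("replicate draw left species '", id, "' with no countable windows")
      cv_from_counts(cK, cK1, cK2, species_id = id, strings = strings)
    })
    nj_tree(distance_matrix(rows, keys = keys))
  })
  attr(trees, "draws") <- draws
  trees
}

## Canonical non-trivial bipartitions of an unrooted tree, as strings.
## Each internal edge splits the leaves in two; the side not containing the
## alphabetically first leaf is sorted and collapsed to one string.
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  first <- tips[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (first %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2L && length(side) <= length(labs) - 2L)
      out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

#' Annotate a tree with bootstrap support values
#'
#' Each internal edge of the main tree receives the percentage of replicate
#' trees containing the same leaf bipartition, stored in `node.label`
#' (rounded to one decimal).
#'
#' @param main The full-data [ape::phylo] tree.
#' @param replicates List of replicate trees on the same leaf set.
#' @return `main` with `node.label` set to support percentages (the root
#'   label is empty).
#' @export
consensus_support <- function(main, replicates) {
  stopifnot(inherits(main, "phylo"), length(replicates) >= 1L)
  main <- ape::unroot(main)
  rep_bips <- lapply(replicates, tree_bipartitions)
  tips <- sort(main$tip.label)
  first <- tips[1L]
  pp <- ape::prop.part(main)
  labs <- attr(pp, "labels")
  nlab <- character(main$Nnode)
  for (i in seq_along(pp)) {
    side <- labs[pp[[i]]]
    if (first %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L || length(side) > length(labs) - 2L) {
      nlab[i] <- ""
      next
    }
    key <- paste(sort(side), collapse = "|")
    pct <- 100 * mean(vapply(rep_bips, function(b) key %in% b, FALSE))
    nlab[i] <- format(round(pct, 1))
  }
  main$node.label <- nlab
  main
}

#' Majority-rule consensus of bootstrap trees
#'
#' @param replicates List of [ape::phylo] trees on the same leaf set.
#' @param p Proportion for a clade to be retained (default 0.5).
#' @return An [ape::phylo] consensus tree.
#' @export
consensus_tree <- function(replicates, p = 0.5) {
  ape::consensus(replicates, p = p)
}

#' Topological similarity of two trees
#'
#' Shared-bipartition percentage:
#' `100 * |shared non-trivial bipartitions| / max(|B1|, |B2|)`, which is 100
#' exactly when the topologies are identical. The raw Robinson--Foulds
#' distance `|B1| + |B2| - 2 |shared|` is attached as `attr(, "rf")`.
#' Two trees with no internal edges at all (stars) count as identical.
#'
#' @param t1,t2 [ape::phylo] trees on the same leaf set.
#' @return Similarity percentage in \[0, 100\].
#' @export
topology_similarity <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  shared <- length(intersect(b1, b2))
  denom <- max(length(b1), length(b2))
  sim <- if (denom == 0) 100 else 100 * shared / denom
  structure(sim, rf = length(b1) + length(b2) - 2L * shared)
}
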