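## Independent brute-force oracles. These deliberately use the slowest,
## most literal formulations (explicit loops, full enumeration over small
## alphabets) and never call the package's counting/CV code paths.

## O(L * K) literal sliding-window count.
naive_count <- function(seqs, K) {
  acc <- list()
  for (s in seqs) {
    n <- nchar(s)
    if (n < K) next
    for (i in seq_len(n - K + 1)) {
      w <- substr(s, i, i + K - 1)
      acc[[w]] <- (if (is.null(acc[[w]])) 0L else acc[[w]]) + 1L
    }
  }
  unlist(acc)
}

naive_total_windows <- function(seqs, K) {
  sum(pmax(nchar(seqs) - K + 1, 0))
}

## Literal evaluation of the (K-2)-Markov background for one string.
naive_p0 <- function(seqs, K, s) {
  cnt <- function(k, w) {
    v <- naive_count(seqs, k)
    if (is.null(v) || is.na(v[w]) || !w %in% names(v)) 0 else unname(v[w])
  }
  pre <- substr(s, 1, K - 1)
  suf <- substr(s, 2, K)
  core <- substr(s, 2, K - 1)
  core_n <- cnt(K - 2, core)
  if (core_n == 0) return(0)
  (cnt(K - 1, pre) / naive_total_windows(seqs, K - 1)) *
    (cnt(K - 1, suf) / naive_total_windows(seqs, K - 1)) /
    (core_n / naive_total_windows(seqs, K - 2))
}

naive_p <- function(seqs, K, s) {
  v <- naive_count(seqs, K)
  n <- if (!is.null(v) && s %in% names(v)) unname(v[s]) else 0
  n / naive_total_windows(seqs, K)
}

naive_score <- function(seqs, K, s) {
  p0 <- naive_p0(seqs, K, s)
  if (p0 == 0) return(0)
  (naive_p(seqs, K, s) - p0) / p0
}

## All strings of length K over an explicit alphabet (full enumeration;
## keep the alphabet small).
enumerate_strings <- function(alphabet, K) {
  grid <- do.call(expand.grid, c(rep(list(alphabet), K),
                                 stringsAsFactors = FALSE))
  apply(grid, 1, paste, collapse = "")
}

## Dense score vector of one proteome over an enumerated string universe.
dense_scores <- function(seqs, K, universe) {
  vapply(universe, function(s) naive_score(seqs, K, s), 0)
}

random_proteome <- function(id, alphabet = c("A", "V", "L", "S"),
                            n_prot = sample(1:5, 1),
                            len_range = c(10, 50)) {
  prot <- vapply(seq_len(n_prot), function(i)
    paste(sample(alphabet, sample(len_range[1]:len_range[2], 1),
                 replace = TRUE), collapse = ""), "")
  names(prot) <- paste0("g", seq_len(n_prot))
  proteome(id, prot)
}

## Cosine distance evaluated on dense vectors.
dense_cosine_distance <- function(x, y) {
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0.5)
  (1 - sum(x * y) / (nx * ny)) / 2
}

## Random tree with strictly positive branch lengths and its additive
## (cophenetic) distance matrix.
random_additive_case <- function(n) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

## Literal bipartition enumeration: for every internal edge, split the tip
## set by connectivity after deleting the edge (graph traversal on the
## edge list, no ape partition helpers).
brute_bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  edges <- tree$edge
  out <- character(0)
  adj <- split(rep(seq_len(nrow(edges)), 2), c(edges[, 1], edges[, 2]))
  for (e in seq_len(nrow(edges))) {
    if (edges[e, 2] <= nt) next              # pendant edge: trivial split
    ## collect tips reachable from the child node without crossing edge e
    seen <- integer(0)
    stack <- edges[e, 2]
    while (length(stack)) {
      v <- stack[1]
      stack <- stack[-1]
      if (v %in% seen) next
      seen <- c(seen, v)
      inc <- setdiff(unlist(adj[as.character(v)]), e)
      for (e2 in inc) stack <- c(stack, setdiff(edges[e2, ], v))
    }
    side <- sort(tree$tip.label[intersect(seen, seq_len(nt))])
    if (length(side) >= 2 && length(side) <= nt - 2) {
      other <- sort(setdiff(tree$tip.label, side))
      if (sort(tree$tip.label)[1] %in% side) side <- other
      out <- c(out, paste(side, collapse = "|"))
    }
  }
  unique(out)
}
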