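#' @keywords internal
"_PACKAGE"

## Canonical 20-letter amino-acid alphabet; everything downstream (counting,
## Markov background, key selection) lives in this 20^K space.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Ambiguity codes and stop that cannot match any K-string over the canonical
## alphabet; they are stripped (with a message) rather than remapped.
AA_AMBIGUOUS <- c("B", "Z", "J", "X", "*")

## Metazoan mitochondrial protein-coding gene vocabulary, in the fixed order
## used for all deterministic output. Unknown genes sort after these.
MT_GENE_ORDER <- c("atp6", "atp8", "cox1", "cox2", "cox3",
                   "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
                   "cob")

## Approximate residue frequencies of metazoan mitochondrial proteins
## (hydrophobic-rich, membrane-spanning bias). Used by the simulator's root
## draw so that K-string sparsity behaves like real input.
MT_AA_FREQS <- c(A = 0.070, C = 0.010, D = 0.020, E = 0.025, F = 0.065,
                 G = 0.060, H = 0.020, I = 0.085, K = 0.030, L = 0.150,
                 M = 0.055, N = 0.040, P = 0.045, Q = 0.020, R = 0.020,
                 S = 0.075, T = 0.070, V = 0.060, W = 0.030, Y = 0.050)

#' Size of the K-string feature space
#'
#' Number of distinct length-`K` strings over the amino-acid alphabet,
#' i.e. `20^K` (3,200,000 for the default `K = 5`).
#'
#' @param K String length (positive integer).
#' @param alphabet_size Alphabet size; 20 for proteins.
#' @return A number.
#' @examples
#' kstring_space_size(5)
#' @export
kstring_space_size <- function(K = 5, alphabet_size = 20L) {
  stopifnot(K >= 1, alphabet_size >= 1)
  alphabet_size^K
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Order gene names by the canonical mitochondrial order, unknown names last,
## lexicographically.
order_genes <- function(genes) {
  idx <- match(genes, MT_GENE_ORDER)
  idx[is.na(idx)] <- length(MT_GENE_ORDER) + 1L
  order(idx, genes)
}
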