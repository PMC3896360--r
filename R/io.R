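#' Write a distance matrix in PHYLIP square format
#'
#' Relaxed PHYLIP dialect: a count line, then one whitespace-delimited row per
#' taxon with the full (untruncated) label first.
#'
#' @param dm Square symmetric numeric matrix with zero diagonal and labels in
#'   `rownames`.
#' @param path Output file.
#' @param digits Significant digits to print.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, digits = 10L) {
  dm <- validate_distance_matrix(dm)
  lines <- c(format(nrow(dm)),
             vapply(seq_len(nrow(dm)), function(i) {
               paste(c(rownames(dm)[i],
                       formatC(dm[i, ], format = "g", digits = digits)),
                     collapse = " ")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path Path written by [write_distance_matrix] (or any relaxed PHYLIP
#'   square matrix with full, whitespace-free labels).
#' @return Labeled symmetric matrix.
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) != n + 1L)
    stop("malformed PHYLIP matrix: expected ", n, " rows")
  toks <- strsplit(trimws(lines[-1L]), "\\s+")
  labs <- vapply(toks, `[[`, "", 1L)
  vals <- t(vapply(toks, function(z) as.numeric(z[-1L]), numeric(n)))
  dimnames(vals) <- list(labs, labs)
  validate_distance_matrix(vals)
}

validate_distance_matrix <- function(dm, tol = 1e-8) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("distance matrix must be square")
  if (is.null(rownames(dm))) stop("distance matrix must be labeled")
  if (max(abs(dm - t(dm))) > tol) stop("distance matrix is not symmetric")
  if (any(abs(diag(dm)) > tol)) stop("distance matrix diagonal must be zero")
  if (any(dm < -tol)) stop("distances must be non-negative")
  colnames(dm) <- rownames(dm)
  dm
}

#' Read an aligned FASTA file
#'
#' All rows must have equal length; the alphabet is amino acids plus `-`.
#'
#' @param path Aligned FASTA file.
#' @return An object of class `"aa_alignment"`: a list with `labels` and a
#'   character vector `rows` (one gapped sequence per label).
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  aa_alignment(as.character(ss), labels = sub("\\s.*$", "", names(ss)))
}

#' Construct an alignment from gapped sequences
#'
#' @param rows Character vector of equal-length gapped sequences.
#' @param labels Row labels (species ids).
#' @return An object of class `"aa_alignment"`.
#' @export
aa_alignment <- function(rows, labels = names(rows)) {
  force(labels)
  rows <- toupper(unname(rows))
  if (length(rows) < 2L) stop("alignment needs at least 2 rows")
  if (length(unique(nchar(rows))) != 1L)
    stop("ragged alignment: rows have unequal lengths")
  if (is.null(labels) || anyDuplicated(labels))
    stop("alignment rows must have unique labels")
  structure(list(labels = labels, rows = rows,
                 n = length(rows), L = nchar(rows[1L])),
            class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("Amino-acid alignment: ", x$n, " rows x ", x$L, " columns\n", sep = "")
  invisible(x)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln An `"aa_alignment"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  writeLines(as.vector(rbind(paste0(">", aln$labels), aln$rows)), path)
  invisible(path)
}

#' Write a tree in Newick format
#'
#' Support values (stored as `node.label`) are rendered as internal node
#' labels when `with_support = TRUE`.
#'
#' @param tree An [ape::phylo] object.
#' @param path Output file.
#' @param with_support Keep internal node labels in the output.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, with_support = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (!with_support) tree$node.label <- NULL
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Write a key set to a plain-text file
#'
#' One K-string per line; `#`-prefixed header lines carry the label, K and
#' provenance.
#'
#' @param ks A [keyset].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_keyset <- function(ks, path) {
  stopifnot(inherits(ks, "keyset"))
  prov <- if (length(ks$provenance))
    paste0("# provenance: ",
           paste(names(ks$provenance),
                 vapply(ks$provenance, function(z) paste(format(z), collapse = ","), ""),
                 sep = "=", collapse = "; "))
  writeLines(c(paste0("# label: ", ks$label),
               paste0("# K: ", ks$K),
               prov,
               ks$strings), path)
  invisible(path)
}

#' Read a key set written by [write_keyset]
#'
#' @param path Input file.
#' @return A [keyset].
#' @export
read_keyset <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  strings <- lines[!startsWith(lines, "#") & nzchar(lines)]
  lab <- sub("^# label:\\s*", "", hdr[startsWith(hdr, "# label:")])
  K <- as.integer(sub("^# K:\\s*", "", hdr[startsWith(hdr, "# K:")]))
  if (!length(K) || is.na(K)) K <- if (length(strings)) nchar(strings[1L]) else 5L
  keyset(strings, K = K, label = if (length(lab)) lab else "imported",
         provenance = list(file = path))
}

#' Export a composition vector as TSV
#'
#' Columns: `kstring`, `p` (observed frequency), `p0` (Markov background),
#' `score`.
#'
#' @param cv A [composition_vector].
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_cv_tsv <- function(cv, path) {
  stopifnot(inherits(cv, "composition_vector"))
  tab <- data.frame(kstring = names(cv$scores), p = cv$p, p0 = cv$p0,
                    score = unname(cv$scores))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
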