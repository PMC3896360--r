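#' Pairwise key-set sharing and bias table
#'
#' Summarizes a collection of key sets the way published phylum tables do:
#' the diagonal holds each group's key-set size, the upper triangle the
#' number of strings shared by each pair, and the lower triangle the bias
#' percentage `100 * (1 - shared / |column set|)` -- the fraction of the
#' column group's keys absent from the row group -- rounded to one decimal.
#'
#' @param sets List of at least two [keyset] objects with the same `K`.
#' @return An object of class `"sharing_table"`: `labels`, integer `sizes`,
#'   integer matrix `shared` (upper triangle), numeric matrix `bias` (lower
#'   triangle; `NA` where the column set is empty).
#' @export
sharing_table <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 key sets")
  Ks <- vapply(sets, `[[`, 0L, "K")
  if (length(unique(Ks)) != 1L) stop("all key sets must share the same K")
  labels <- vapply(sets, `[[`, "", "label")
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  n <- length(sets)
  sizes <- vapply(sets, function(s) length(s$strings), 0L)
  shared <- matrix(NA_integer_, n, n, dimnames = list(labels, labels))
  bias <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sh <- length(intersect(sets[[i]]$strings, sets[[j]]$strings))
    shared[i, j] <- sh
    ## bias cell at (row j, column i): normalized by column group i's size
    bias[j, i] <- if (sizes[i] > 0) round(100 * (1 - sh / sizes[i]), 1) else NA_real_
  }
  new_sharing_table(labels, sizes, shared, bias)
}

new_sharing_table <- function(labels, sizes, shared, bias) {
  names(sizes) <- labels
  structure(list(labels = labels, sizes = sizes, shared = shared, bias = bias),
            class = "sharing_table")
}

#' @export
print.sharing_table <- function(x, digits = 1, ...) {
  n <- length(x$labels)
  m <- matrix("", n, n, dimnames = list(x$labels, x$labels))
  diag(m) <- format(x$sizes)
  m[upper.tri(m)] <- format(x$shared[upper.tri(x$shared)])
  m[lower.tri(m)] <- formatC(x$bias[lower.tri(x$bias)], format = "f",
                             digits = digits)
  cat("Key-string sharing table (diagonal: set size; upper: shared count;",
      "lower: bias %)\n")
  print(m, quote = FALSE, right = TRUE)
  invisible(x)
}

#' Summary statistics of a sharing table
#'
#' Minimum, maximum and mean of the diagonal set sizes, of the
#' upper-triangle shared counts, and of the lower-triangle (rounded) bias
#' percentages.
#'
#' @param st A [sharing_table].
#' @return A list with numeric triples `sizes`, `shared`, `bias`, each of
#'   the form `c(min, max, mean)`.
#' @export
summarize_sharing <- function(st) {
  stopifnot(inherits(st, "sharing_table"))
  tri <- function(v) c(min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE),
                       mean = mean(v, na.rm = TRUE))
  list(sizes = tri(as.numeric(st$sizes)),
       shared = tri(st$shared[upper.tri(st$shared)]),
       bias = tri(st$bias[lower.tri(st$bias)]))
}

#' Read a sharing table from TSV
#'
#' Expects the published layout: a header row of group labels, then one row
#' per group (`label`, then `n` cells) holding the set size on the diagonal,
#' shared counts above it and bias percentages below it.
#'
#' @param path TSV file.
#' @return A [sharing_table].
#' @export
read_sharing_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m)) stop("sharing table must be square")
  labels <- rownames(m)
  shared <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  bias <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  shared[upper.tri(shared)] <- as.integer(m[upper.tri(m)])
  bias[lower.tri(bias)] <- m[lower.tri(m)]
  new_sharing_table(labels, as.integer(diag(m)), shared, bias)
}

#' Write a sharing table as TSV
#'
#' @param st A [sharing_table].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sharing_table <- function(st, path) {
  n <- length(st$labels)
  m <- matrix(NA_real_, n, n, dimnames = list(st$labels, st$labels))
  diag(m) <- st$sizes
  m[upper.tri(m)] <- st$shared[upper.tri(st$shared)]
  m[lower.tri(m)] <- st$bias[lower.tri(st$bias)]
  utils::write.table(cbind(data.frame(group = st$labels), as.data.frame(m)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
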