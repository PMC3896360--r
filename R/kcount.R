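#' Count K-strings in a proteome
#'
#' Slides a window of length `K` with step 1 within each protein
#' independently; windows never span two proteins.
#'
#' @param x A [proteome], or a character vector of sequences.
#' @param K String length (1--7 by default convention; the counting itself
#'   accepts any `K >= 1`).
#' @return An object of class `"kstring_counts"`: list with `K`, a named
#'   integer vector `counts`, and `total_windows`.
#' @examples
#' count_kstrings(proteome("sp1", c(g1 = "AAAAAA")), K = 5)
#' @export
count_kstrings <- function(x, K) {
  seqs <- if (inherits(x, "proteome")) x$proteins else x
  stopifnot(is.character(seqs), K >= 1)
  K <- as.integer(K)
  windows <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < K) return(character(0))
    substring(s, 1:(n - K + 1L), K:n)
  }), use.names = FALSE)
  if (!length(windows))
    stop("no countable windows: all proteins shorter than K = ", K)
  tab <- table(windows)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(list(K = K, counts = counts,
                 total_windows = length(windows)),
            class = "kstring_counts")
}

#' @export
print.kstring_counts <- function(x, ...) {
  cat("K-string counts: K = ", x$K, ", ", length(x$counts),
      " distinct strings over ", x$total_windows, " windows\n", sep = "")
  invisible(x)
}

#' Markov-expected frequency of a K-string
#'
#' The (K-2)-order Markov background predicts
#' `p0(s) = p(prefix) * p(suffix) / p(core)` where prefix and suffix are the
#' two (K-1)-substrings of `s` and core is the central (K-2)-substring; each
#' `p` is the corresponding count divided by its own total window count.
#' Returns 0 when the core is unseen.
#'
#' @param cK,cK1,cK2 `"kstring_counts"` at orders K, K-1 and K-2 on the same
#'   proteome.
#' @param s Character vector of K-strings.
#' @return Numeric vector of background frequencies `p0(s)`.
#' @export
markov_expected <- function(cK, cK1, cK2, s) {
  stopifnot(inherits(cK, "kstring_counts"), cK1$K == cK$K - 1L, cK2$K == cK$K - 2L)
  K <- cK$K
  if (any(nchar(s) != K)) stop("all strings must have length K = ", K)
  pre <- substr(s, 1L, K - 1L)
  suf <- substr(s, 2L, K)
  core <- substr(s, 2L, K - 1L)
  p_pre <- unname(cK1$counts[pre]) / cK1$total_windows
  p_suf <- unname(cK1$counts[suf]) / cK1$total_windows
  p_core <- unname(cK2$counts[core]) / cK2$total_windows
  p0 <- p_pre * p_suf / p_core
  p0[is.na(p0) | !is.finite(p0)] <- 0
  p0
}

## Build the composition vector from precomputed counts at orders K, K-1, K-2.
## Support = every string with p > 0 or p0 > 0; if `strings` is given, the
## vector is restricted to those strings (used for key-set projection in the
## bootstrap hot path).
cv_from_counts <- function(cK, cK1, cK2, species_id = NA_character_,
                           strings = NULL) {
  K <- cK$K
  if (is.null(strings)) {
    ## candidates with p0 > 0: overlapping pairs of observed (K-1)-strings.
    ## An observed K-string always has observed parts, so this also covers
    ## all strings with p > 0.
    u <- names(cK1$counts)
    u_core <- substr(u, 2L, K - 1L)          # (K-2)-suffix of a prefix
    v_core <- substr(u, 1L, K - 2L)          # (K-2)-prefix of a suffix
    v_by_core <- split(seq_along(u), v_core)
    u_by_core <- split(seq_along(u), u_core)
    cores <- intersect(names(u_by_core), names(v_by_core))
    pieces <- lapply(cores, function(cr) {
      ui <- u_by_core[[cr]]
      vi <- v_by_core[[cr]]
      cbind(rep(ui, each = length(vi)), rep.int(vi, length(ui)))
    })
    idx <- do.call(rbind, pieces)
    strings <- paste0(u[idx[, 1L]], substr(u[idx[, 2L]], K - 1L, K - 1L))
    p_pre <- unname(cK1$counts[idx[, 1L]]) / cK1$total_windows
    p_suf <- unname(cK1$counts[idx[, 2L]]) / cK1$total_windows
    p_core <- unname(cK2$counts[substr(strings, 2L, K - 1L)]) / cK2$total_windows
    p0 <- p_pre * p_suf / p_core
    p0[is.na(p0) | !is.finite(p0)] <- 0
  } else {
    p0 <- markov_expected(cK, cK1, cK2, strings)
  }
  p <- unname(cK$counts[strings]) / cK$total_windows
  p[is.na(p)] <- 0
  score <- ifelse(p0 > 0, (p - p0) / p0, 0)
  names(score) <- strings
  names(p) <- NULL
  names(p0) <- NULL
  structure(list(K = K, species_id = species_id, scores = score,
                 p = p, p0 = p0),
            class = "composition_vector")
}

#' Composition vector of a proteome
#'
#' The CV-matrix row of one species: for every K-string with observed or
#' Markov-expected frequency above zero, the background-subtracted score
#' `(p - p0) / p0` (0 by convention when `p0 = 0`). Absent strings are
#' implicitly 0; the representation is sparse.
#'
#' @param x A [proteome].
#' @param K String length, `K >= 3` (default 5).
#' @param strings Optional character vector restricting the support (used for
#'   key-set projection).
#' @return An object of class `"composition_vector"` with elements `K`,
#'   `species_id`, sparse named `scores`, and parallel `p`/`p0` vectors.
#' @examples
#' cv <- composition_vector(proteome("sp1", c(g1 = "MKVLAMKVLA")), K = 5)
#' @export
composition_vector <- function(x, K = 5, strings = NULL) {
  stopifnot(inherits(x, "proteome"), K >= 3)
  K <- as.integer(K)
  cv_from_counts(count_kstrings(x, K),
                 count_kstrings(x, K - 1L),
                 count_kstrings(x, K - 2L),
                 species_id = x$species_id, strings = strings)
}

#' @export
print.composition_vector <- function(x, ...) {
  cat("Composition vector (K = ", x$K, ") for '", x$species_id, "': ",
      length(x$scores), " non-trivial entries\n", sep = "")
  invisible(x)
}

#' Composition-vector matrix of a species group
#'
#' One sparse CV row per species, all at the same `K`, in input order.
#'
#' @param proteomes List of [proteome] objects with unique species ids.
#' @param K String length (default 5).
#' @param strings Optional support restriction, as in [composition_vector].
#' @return Named list of `"composition_vector"` objects.
#' @export
cv_matrix <- function(proteomes, K = 5, strings = NULL) {
  ids <- vapply(proteomes, `[[`, "", "species_id")
  if (anyDuplicated(ids))
    stop("duplicate species_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- lapply(proteomes, composition_vector, K = K, strings = strings)
  names(out) <- ids
  out
}
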