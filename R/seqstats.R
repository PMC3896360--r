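#' Composition profile of a key set
#'
#' Pattern frequencies over the strings of a key set: single residues
#' (`mono`), contiguous pairs (`dimer`), pairs at distance 2
#' (`gapped_dimer`) or contiguous triples (`triplet`). A string of length K
#' contributes K, K-1, K-2 and K-2 patterns respectively.
#'
#' @param keys A non-empty [keyset].
#' @param mode One of `"mono"`, `"dimer"`, `"gapped_dimer"`, `"triplet"`.
#' @return An object of class `"composition_profile"`: `mode` and a named
#'   numeric vector `frequencies` summing to 1.
#' @export
composition_profile <- function(keys,
                                mode = c("mono", "dimer", "gapped_dimer",
                                         "triplet")) {
  mode <- match.arg(mode)
  stopifnot(inherits(keys, "keyset"))
  s <- keys$strings
  if (!length(s)) stop("empty key set")
  K <- keys$K
  pats <- switch(mode,
    mono = unlist(strsplit(s, "")),
    dimer = unlist(lapply(s, function(x) substring(x, 1:(K - 1L), 2:K))),
    gapped_dimer = unlist(lapply(s, function(x)
      paste0(substring(x, 1:(K - 2L), 1:(K - 2L)),
             substring(x, 3:K, 3:K)))),
    triplet = unlist(lapply(s, function(x) substring(x, 1:(K - 2L), 3:K))))
  tab <- table(pats)
  freq <- as.numeric(tab) / sum(tab)
  names(freq) <- names(tab)
  structure(list(mode = mode, frequencies = freq),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, top = 10L, ...) {
  cat("Composition profile (", x$mode, "): ", length(x$frequencies),
      " patterns\n", sep = "")
  print(round(sort(x$frequencies, decreasing = TRUE)[seq_len(min(top, length(x$frequencies)))], 4))
  invisible(x)
}

#' Write a composition profile as TSV
#'
#' @param prof A [composition_profile].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(prof, path) {
  utils::write.table(data.frame(pattern = names(prof$frequencies),
                                frequency = unname(prof$frequencies)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Chi-square test of observed vs Markov-expected K-string counts
#'
#' Pearson statistic `X^2 = sum (O - E)^2 / E` over the tested strings,
#' where `O(s)` is the observed count and `E(s) = total_windows * p0(s)` the
#' (K-2)-order Markov expectation, with `k - 1` degrees of freedom for `k`
#' tested strings. Strings with `E = 0` are dropped with a warning and `k`
#' adjusted. Significance is assessed at the 5% level.
#'
#' @param x A [proteome], or a list of proteomes whose counts are pooled.
#' @param K String length (default 5).
#' @param strings Character vector of K-strings to test (at least 2).
#' @return An object of class `"chisq_kstrings"`: `statistic`, `k`, `dof`,
#'   `p_value`, `significant_at_5pct`, plus the `observed` and `expected`
#'   vectors.
#' @export
chi_square_test <- function(x, K = 5, strings) {
  K <- as.integer(K)
  if (inherits(x, "proteome")) x <- list(x)
  pool <- function(k) {
    parts <- lapply(unname(x), count_kstrings, K = k)
    v <- unlist(unname(lapply(parts, `[[`, "counts")))
    agg <- rowsum(v, names(v))
    counts <- as.integer(agg)
    names(counts) <- rownames(agg)
    structure(list(K = k, counts = counts, total_windows = sum(counts)),
              class = "kstring_counts")
  }
  cK <- pool(K)
  cK1 <- pool(K - 1L)
  cK2 <- pool(K - 2L)
  strings <- unique(strings)
  if (length(strings) < 2L) stop("need at least 2 strings to test")
  E <- cK$total_windows * markov_expected(cK, cK1, cK2, strings)
  drop <- E == 0
  if (any(drop)) {
    warning(sum(drop), " string(s) with zero expected count dropped",
            call. = FALSE)
    strings <- strings[!drop]
    E <- E[!drop]
  }
  k <- length(strings)
  if (k < 2L) stop("fewer than 2 strings with positive expected count")
  O <- unname(cK$counts[strings])
  O[is.na(O)] <- 0
  stat <- sum((O - E)^2 / E)
  dof <- k - 1L
  p <- stats::pchisq(stat, df = dof, lower.tail = FALSE)
  structure(list(statistic = stat, k = k, dof = dof, p_value = p,
                 significant_at_5pct = p < 0.05,
                 observed = stats::setNames(O, strings),
                 expected = stats::setNames(E, strings)),
            class = "chisq_kstrings")
}

#' @export
print.chisq_kstrings <- function(x, ...) {
  cat("Chi-square test of K-string frequencies vs (K-2)-Markov background\n",
      "  X^2 = ", format(x$statistic, digits = 5), ", k = ", x$k,
      ", df = ", x$dof, ", p = ", format.pval(x$p_value), "\n",
      "  significant at 5%: ", x$significant_at_5pct, "\n", sep = "")
  invisible(x)
}
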