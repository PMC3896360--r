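#' Sliding-window conservativity profile of an alignment
#'
#' For each window of `w` alignment columns (step `step`), let `m` be the
#' multiplicity of the most frequent length-`w` row segment (gap characters
#' are ordinary symbols). The window score is
#' `round(scale * (m - 1) / (n - 1))`, an integer on a 0--`scale` scale:
#' `scale` (15 by default) when every row is identical in the window, 0 when
#' all rows differ.
#'
#' @param aln An [aa_alignment].
#' @param w Window size in aligned columns (default 5).
#' @param step Step size (default 1).
#' @param scale Top of the integer score scale (default 15).
#' @return An object of class `"conservation_profile"`: `w`, `step`,
#'   `scale`, integer vector `scores` named by 1-based window start column,
#'   and `L` (alignment length).
#' @export
conservativity_profile <- function(aln, w = 5, step = 1, scale = 15) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (aln$L < w) stop("alignment shorter than window: L = ", aln$L, " < ", w)
  starts <- seq.int(1L, aln$L - w + 1L, by = step)
  n <- aln$n
  scores <- vapply(starts, function(i) {
    seg <- substr(aln$rows, i, i + w - 1L)
    m <- max(tabulate(match(seg, unique(seg))))
    as.integer(round(scale * (m - 1) / (n - 1)))
  }, 0L)
  names(scores) <- starts
  structure(list(w = w, step = step, scale = scale, scores = scores,
                 L = aln$L, n = aln$n),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("Conservation profile: ", length(x$scores), " windows (w = ", x$w,
      ", step = ", x$step, ") on ", x$n, " x ", x$L, " alignment; scores ",
      min(x$scores), "-", max(x$scores), " of ", x$scale, "\n", sep = "")
  invisible(x)
}

#' Map key K-strings onto a sequence
#'
#' Exact, overlap-allowed substring matching of a key set against one
#' sequence; the per-position coverage counts how many key-string
#' occurrences overlap each position. Gapped rows (alignment rows) are
#' matched on their ungapped residues and the coverage is mapped back to
#' alignment columns (gap columns get 0).
#'
#' @param sequence One character string (may contain `-` gaps).
#' @param keys A [keyset].
#' @return Integer coverage vector, one entry per character of `sequence`.
#' @export
map_keys <- function(sequence, keys) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            inherits(keys, "keyset"))
  K <- keys$K
  chars <- strsplit(sequence, "")[[1L]]
  res_cols <- which(chars != "-")
  ungapped <- paste(chars[res_cols], collapse = "")
  n <- nchar(ungapped)
  cov_res <- integer(n)
  if (n >= K && length(keys$strings)) {
    wins <- substring(ungapped, 1:(n - K + 1L), K:n)
    hits <- which(wins %in% keys$strings)
    for (h in hits) cov_res[h:(h + K - 1L)] <- cov_res[h:(h + K - 1L)] + 1L
  }
  cov <- integer(length(chars))
  cov[res_cols] <- cov_res
  cov
}

#' Detect key-string accumulation regions
#'
#' Sums coverage vectors column-wise across species and returns the maximal
#' runs of columns whose total coverage is at least `min_total` and whose
#' length is at least `min_len`, as 1-based inclusive intervals.
#'
#' @param coverages List of equal-length integer coverage vectors
#'   (see [map_keys]) on common alignment columns.
#' @param min_total Minimum summed coverage per column (default 1).
#' @param min_len Minimum run length in columns (default 5).
#' @return A data.frame with columns `start`, `end`, `hit_density` (mean
#'   summed coverage per column in the region); zero rows when nothing
#'   accumulates.
#' @export
accumulation_regions <- function(coverages, min_total = 1, min_len = 5) {
  if (length(unique(lengths(coverages))) != 1L)
    stop("coverage vectors must have equal length")
  total <- Reduce(`+`, coverages)
  r <- rle(total >= min_total)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep],
             hit_density = vapply(which(keep), function(i)
               mean(total[starts[i]:ends[i]]), 0))
}

#' Overlap of accumulation regions with conserved windows
#'
#' Assigns each alignment column the maximum score of the windows covering
#' it, then reports the fraction of accumulation-region columns whose score
#' exceeds `conserved_cutoff`, and the same fraction for all remaining
#' columns as a contrast.
#'
#' @param regions Data.frame from [accumulation_regions].
#' @param prof A [conservativity_profile] on the same alignment columns.
#' @param conserved_cutoff Score a column must exceed to count as conserved
#'   (default 8).
#' @return List with `region_conserved_frac`, `background_conserved_frac`
#'   (each `NA` when its column set is empty), `n_region_cols`,
#'   `n_background_cols`.
#' @export
overlap_summary <- function(regions, prof, conserved_cutoff = 8) {
  stopifnot(inherits(prof, "conservation_profile"))
  L <- prof$L
  w <- prof$w
  colscore <- rep(-Inf, L)
  starts <- as.integer(names(prof$scores))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + w - 1L)
    colscore[idx] <- pmax(colscore[idx], prof$scores[i])
  }
  in_region <- rep(FALSE, L)
  if (nrow(regions))
    for (i in seq_len(nrow(regions)))
      in_region[regions$start[i]:regions$end[i]] <- TRUE
  frac <- function(sel) if (!any(sel)) NA_real_ else
    mean(colscore[sel] > conserved_cutoff)
  list(region_conserved_frac = if (nrow(regions)) frac(in_region) else NA_real_,
       background_conserved_frac = frac(!in_region),
       n_region_cols = sum(in_region),
       n_background_cols = sum(!in_region))
}

#' Write accumulation regions in BED-like form
#'
#' Columns: label, 0-based start, end (half-open), hit density.
#'
#' @param regions Data.frame from [accumulation_regions].
#' @param path Output TSV file.
#' @param label Region label column value.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path, label = "accumulation") {
  utils::write.table(data.frame(label = label, start = regions$start - 1L,
                                end = regions$end,
                                hit_density = regions$hit_density),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
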