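#' Construct a key set
#'
#' A named set of K-strings with provenance describing how it was built.
#'
#' @param strings Character vector of K-strings (deduplicated and sorted).
#' @param K String length; inferred from `strings` when omitted.
#' @param label Short token naming the set.
#' @param provenance Named list recording parameters, seeds, parents.
#' @return An object of class `"keyset"`.
#' @export
keyset <- function(strings, K = NULL, label = "keys", provenance = list()) {
  strings <- sort(unique(as.character(strings)))
  if (is.null(K)) {
    if (!length(strings)) stop("K must be given for an empty key set")
    K <- nchar(strings[1L])
  }
  if (length(strings) && any(nchar(strings) != K))
    stop("all key strings must have length K = ", K)
  bad <- setdiff(unique(unlist(strsplit(strings, ""))), AA_ALPHABET)
  if (length(bad))
    stop("key strings contain non-canonical letters: ", paste(bad, collapse = ", "))
  structure(list(K = as.integer(K), strings = strings, label = label,
                 provenance = provenance),
            class = "keyset")
}

#' @export
print.keyset <- function(x, ...) {
  cat("Key set '", x$label, "': ", length(x$strings),
      " K-strings (K = ", x$K, ")\n", sep = "")
  invisible(x)
}

#' @export
length.keyset <- function(x) length(x$strings)

#' Column variances of a composition-vector matrix
#'
#' For each K-string present in at least one row, the population variance
#' (divide by N) of its scores across the N species; strings absent from a
#' row contribute a score of 0. The critical value is `(1 - reduction)` times
#' the maximum variance (the corner of the L-shaped sorted-variance curve).
#'
#' @param rows List of [composition_vector] rows, all at the same `K`.
#' @param reduction Reduction fraction defining the critical value
#'   (default 0.90, i.e. the threshold is 10% of the maximum variance).
#' @return An object of class `"variance_profile"`: `K`, named numeric
#'   `variances`, `n_species`, `v_max`, `critical_value`, `reduction`.
#' @export
variance_profile <- function(rows, reduction = 0.90) {
  if (length(rows) < 2L) stop("variance needs at least 2 species (rows)")
  Ks <- vapply(rows, `[[`, 0L, "K")
  if (length(unique(Ks)) != 1L) stop("all rows must share the same K")
  N <- length(rows)
  keys <- unique(unlist(lapply(rows, function(r) names(r$scores)), use.names = FALSE))
  sx <- numeric(length(keys))
  sxx <- numeric(length(keys))
  names(sx) <- keys
  for (r in rows) {
    idx <- match(names(r$scores), keys)
    sx[idx] <- sx[idx] + r$scores
    sxx[idx] <- sxx[idx] + r$scores^2
  }
  v <- sxx / N - (sx / N)^2
  v[v < 0] <- 0                       # guard tiny negative rounding
  v_max <- if (length(v)) max(v) else 0
  structure(list(K = Ks[1L], variances = v, n_species = N, v_max = v_max,
                 reduction = reduction,
                 critical_value = (1 - reduction) * v_max),
            class = "variance_profile")
}

#' @export
print.variance_profile <- function(x, ...) {
  cat("Variance profile: ", length(x$variances), " K-strings (K = ", x$K,
      ") over ", x$n_species, " species\n",
      "  v_max = ", format(x$v_max), ", critical value = ",
      format(x$critical_value), " (", 100 * x$reduction, "% reduction)\n",
      sep = "")
  invisible(x)
}

#' Critical point of the sorted-variance L-curve
#'
#' Operationalized as `(1 - reduction) * v_max`; with the default 0.90 the
#' threshold sits at 10% of the maximum column variance.
#'
#' @param vp A [variance_profile].
#' @param reduction Reduction fraction in (0, 1).
#' @return The threshold (a number).
#' @export
critical_point <- function(vp, reduction = 0.90) {
  stopifnot(inherits(vp, "variance_profile"), reduction > 0, reduction < 1)
  (1 - reduction) * vp$v_max
}

#' Select key K-strings above the critical point
#'
#' Strings whose variance is strictly greater than the critical point; when
#' all rows are identical (`v_max = 0`) the key set is empty.
#'
#' @param vp A [variance_profile].
#' @param reduction Reduction fraction (default 0.90).
#' @param label Label for the resulting set.
#' @return A [keyset].
#' @export
select_keys <- function(vp, reduction = 0.90, label = "keys") {
  thr <- critical_point(vp, reduction)
  strings <- if (vp$v_max > 0) names(vp$variances)[vp$variances > thr] else character(0)
  keyset(strings, K = vp$K, label = label,
         provenance = list(n_species = vp$n_species, reduction = reduction,
                           v_max = vp$v_max, critical_value = thr))
}

## Seeded near-equal partition: shuffle, then round-robin so remainder species
## land in the earliest subgroups.
partition_subgroups <- function(ids, n_subgroups, seed = NULL) {
  shuffled <- with_seed(seed, sample(ids))
  split(shuffled, rep_len(seq_len(n_subgroups), length(shuffled)))
}

#' Extract a group's key K-strings via subgroup intersection
#'
#' The species are randomly partitioned (seeded) into `n_subgroups`
#' near-equal subgroups; key strings are selected independently in each
#' subgroup and the intersection of the subgroup key sets is returned.
#' Intersecting across subgroups discards strings whose variance is driven by
#' a single species, keeping only stably discriminative strings.
#'
#' @param proteomes List of [proteome] objects (at least `2 * n_subgroups`).
#' @param K String length (default 5).
#' @param n_subgroups Number of subgroups (default 5).
#' @param reduction Variance-reduction fraction (default 0.90).
#' @param seed Integer seed for the partition.
#' @param cvs Optional precomputed [cv_matrix] rows named by species id
#'   (avoids recounting when called repeatedly).
#' @param label Label for the resulting set.
#' @return A [keyset] (the subgroup intersection), with the partition in its
#'   provenance.
#' @export
extract_group_keys <- function(proteomes, K = 5, n_subgroups = 5,
                               reduction = 0.90, seed = NULL, cvs = NULL,
                               label = "group-keys") {
  ids <- vapply(proteomes, `[[`, "", "species_id")
  if (length(ids) < 2L * n_subgroups)
    stop("need at least ", 2L * n_subgroups, " species for ", n_subgroups,
         " subgroups of >= 2")
  if (is.null(cvs)) cvs <- cv_matrix(proteomes, K = K)
  parts <- partition_subgroups(ids, n_subgroups, seed = seed)
  sets <- lapply(parts, function(grp)
    select_keys(variance_profile(cvs[grp]), reduction = reduction)$strings)
  strings <- Reduce(intersect, sets)
  keyset(strings, K = K, label = label,
         provenance = list(n_species = length(ids), n_subgroups = n_subgroups,
                           reduction = reduction, seed = seed,
                           partition = parts))
}

#' Extract broad key K-strings by repeated random test groups
#'
#' Repeatedly samples `group_size` species (without replacement within a
#' repetition), extracts each test group's key strings via
#' [extract_group_keys], and stops when a new group's keys are at least
#' `convergence` contained in the running union, or after `max_reps`
#' repetitions. The core set is the intersection over groups and the broad
#' set the union.
#'
#' @inheritParams extract_group_keys
#' @param group_size Species per test group (default 20).
#' @param max_reps Maximum repetitions (default 10).
#' @param convergence Containment fraction declaring convergence
#'   (default 0.95).
#' @return List with elements `core` ([keyset]), `broad` ([keyset]),
#'   `groups` (list of per-repetition keysets) and `containment` (numeric).
#' @export
extract_broad_keys <- function(proteomes, K = 5, group_size = 20,
                               n_subgroups = 5, max_reps = 10,
                               convergence = 0.95, reduction = 0.90,
                               seed = NULL, cvs = NULL) {
  ids <- vapply(proteomes, `[[`, "", "species_id")
  names(proteomes) <- ids
  if (group_size < 2L * n_subgroups)
    stop("group_size must be at least 2 * n_subgroups = ", 2L * n_subgroups)
  if (length(ids) < group_size)
    stop("need at least group_size = ", group_size, " species")
  if (is.null(cvs)) cvs <- cv_matrix(proteomes, K = K)
  groups <- list()
  containment <- numeric(0)
  running <- character(0)
  with_seed(seed, {
    for (rep_i in seq_len(max_reps)) {
      grp_ids <- sample(ids, group_size)
      ks <- extract_group_keys(proteomes[grp_ids], K = K,
                               n_subgroups = n_subgroups,
                               reduction = reduction, cvs = cvs[grp_ids],
                               label = paste0("group-", rep_i))
      groups[[rep_i]] <- ks
      frac <- if (length(ks$strings)) mean(ks$strings %in% running) else 1
      containment[rep_i] <- frac
      running <- union(running, ks$strings)
      if (rep_i >= 2L && frac >= convergence) break
    }
  })
  prov <- list(group_size = group_size, n_subgroups = n_subgroups,
               max_reps = max_reps, convergence = convergence,
               reduction = reduction, seed = seed,
               n_groups = length(groups), containment = containment)
  list(core = keyset(Reduce(intersect, lapply(groups, `[[`, "strings")),
                     K = K, label = "core", provenance = prov),
       broad = keyset(running, K = K, label = "broad", provenance = prov),
       groups = groups, containment = containment)
}

#' Extract taxon-specific key K-strings
#'
#' Runs the key-extraction procedure inside each subtaxon (class) of one
#' taxon and unions the per-subtaxon sets together with an optional broad
#' set. Subtaxa large enough are processed with [extract_group_keys];
#' subtaxa too small to split use [select_keys] on the whole subtaxon;
#' subtaxa with fewer than 2 species are skipped with a warning.
#'
#' @inheritParams extract_group_keys
#' @param subtaxa Character vector of subtaxon labels parallel to
#'   `proteomes`; defaults to each proteome's `class_label`, and falls back
#'   to a single pooled group when all labels are missing.
#' @param broad Optional [keyset] unioned into the result.
#' @param reps Maximum repetitions of the subgroup partition per subtaxon.
#'   With `reps = 1` each subtaxon is partitioned once; with more, the
#'   partition-and-intersect step is repeated (stopping early once a new
#'   repetition's keys are at least `convergence` contained in the running
#'   union, as in [extract_broad_keys]) and the repetitions are unioned,
#'   which stabilizes the set against unlucky partitions of small subtaxa.
#' @param convergence Containment fraction for the early stop when
#'   `reps > 1`.
#' @return A [keyset].
#' @export
extract_specific_keys <- function(proteomes, subtaxa = NULL, broad = NULL,
                                  K = 5, n_subgroups = 5, reduction = 0.90,
                                  seed = NULL, cvs = NULL, reps = 1,
                                  convergence = 0.95,
                                  label = "specific") {
  ids <- vapply(proteomes, `[[`, "", "species_id")
  names(proteomes) <- ids
  if (is.null(subtaxa))
    subtaxa <- vapply(proteomes, `[[`, "", "class_label")
  if (all(is.na(subtaxa))) subtaxa <- rep("all", length(proteomes))
  subtaxa[is.na(subtaxa)] <- "unassigned"
  if (is.null(cvs)) cvs <- cv_matrix(proteomes, K = K)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(unique(subtaxa))))
  parts <- split(ids, subtaxa)
  sets <- character(0)
  for (i in seq_along(parts)) {
    grp <- parts[[i]]
    if (length(grp) < 2L) {
      warning("subtaxon '", names(parts)[i], "' has < 2 species; skipped",
              call. = FALSE)
      next
    }
    ## use as many subgroups as the subtaxon supports (each needs >= 2
    ## species); with < 4 species no split is possible and the whole
    ## subtaxon's variance profile is used directly.
    n_eff <- max(1L, min(n_subgroups, length(grp) %/% 2L))
    ks <- if (n_eff < 2L)
      select_keys(variance_profile(cvs[grp]), reduction = reduction)
    else if (reps <= 1L)
      extract_group_keys(proteomes[grp], K = K, n_subgroups = n_eff,
                         reduction = reduction, seed = seeds[i],
                         cvs = cvs[grp])
    else
      extract_broad_keys(proteomes[grp], K = K, group_size = length(grp),
                         n_subgroups = n_eff, max_reps = reps,
                         convergence = convergence, reduction = reduction,
                         seed = seeds[i], cvs = cvs[grp])$broad
    sets <- union(sets, ks$strings)
  }
  if (!is.null(broad)) sets <- union(sets, broad$strings)
  keyset(sets, K = K, label = label,
         provenance = list(subtaxa = names(parts), seed = seed,
                           n_subgroups = n_subgroups, reduction = reduction,
                           broad = if (!is.null(broad)) broad$label))
}

#' Union of key sets into a global set
#'
#' @param sets List of [keyset] objects (e.g. per-phylum specific sets).
#' @param broad Optional broad [keyset] unioned in.
#' @param label Label for the result.
#' @return A [keyset] with provenance listing all parents.
#' @export
global_keys <- function(sets, broad = NULL, label = "global") {
  if (!is.null(broad)) sets <- c(sets, list(broad))
  Ks <- vapply(sets, `[[`, 0L, "K")
  if (length(unique(Ks)) != 1L) stop("all key sets must share the same K")
  keyset(unique(unlist(lapply(sets, `[[`, "strings"))), K = Ks[1L],
         label = label,
         provenance = list(parents = vapply(sets, `[[`, "", "label")))
}
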