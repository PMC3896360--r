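#' Fit an alignment-free key K-string phylogeny
#'
#' The central estimator: builds the composition-vector matrix of the
#' species group at order `K`, performs variance-based dimensional
#' reduction to obtain the key K-strings (unless a key set or `keys =
#' FALSE` is supplied), computes pairwise cosine distances on the
#' (projected) vectors, and estimates an unrooted neighbor-joining tree,
#' optionally with gene-resampling bootstrap support.
#'
#' @param proteomes List of [proteome] objects (at least 3 species).
#' @param K String length (default 5).
#' @param keys Either `NULL` (select key strings from the whole group's
#'   variance profile), a [keyset] to project onto, or `FALSE` to use the
#'   full composition vectors.
#' @param reduction Variance-reduction fraction for key selection
#'   (default 0.90).
#' @param bootstrap Number of gene-resampling bootstrap replicates
#'   (default 0 = none).
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `"key_phylogeny"` with components `call`,
#'   `K`, `cv` (list of composition vectors), `variance`
#'   ([variance_profile]), `keys` (the [keyset] used, or `NULL`), `dist`
#'   (cosine distance matrix), `tree` ([ape::phylo], with bootstrap
#'   supports in `node.label` when requested), `boot` (replicate trees or
#'   `NULL`) and `n_species`.
#' @examples
#' sim <- fixture("twoclade-minimal")
#' fit <- key_phylogeny(sim$proteomes, bootstrap = 0)
#' print(fit)
#' @export
key_phylogeny <- function(proteomes, K = 5, keys = NULL, reduction = 0.90,
                          bootstrap = 0, seed = NULL) {
  if (length(proteomes) < 3L) stop("need at least 3 species")
  cv <- cv_matrix(proteomes, K = K)
  vp <- variance_profile(cv, reduction = reduction)
  use_keys <- if (isFALSE(keys)) NULL
  else if (inherits(keys, "keyset")) keys
  else select_keys(vp, reduction = reduction, label = "group-keys")
  dm <- distance_matrix(cv, keys = use_keys)
  tree <- nj_tree(dm)
  boot <- NULL
  if (bootstrap > 0) {
    boot <- bootstrap_trees(proteomes, n_replicates = bootstrap, K = K,
                            keys = use_keys, seed = seed)
    tree <- consensus_support(tree, boot)
  }
  structure(list(call = match.call(), K = as.integer(K), cv = cv,
                 variance = vp, keys = use_keys, dist = dm, tree = tree,
                 boot = boot, reduction = reduction, seed = seed,
                 n_species = length(proteomes)),
            class = "key_phylogeny")
}

#' @export
print.key_phylogeny <- function(x, ...) {
  cat("Key K-string phylogeny (K = ", x$K, ")\n", sep = "")
  cat("  species:      ", x$n_species, "\n", sep = "")
  cat("  CV columns:   ", length(x$variance$variances),
      " observed K-strings\n", sep = "")
  if (!is.null(x$keys))
    cat("  key strings:  ", length(x$keys$strings), " (",
        formatC(100 * length(x$keys$strings) /
                  max(1L, length(x$variance$variances)),
                format = "f", digits = 2),
        "% of observed; threshold ", format(x$variance$critical_value),
        ")\n", sep = "")
  else cat("  key strings:  none (full composition vectors)\n")
  cat("  tree:         unrooted NJ on cosine distances",
      if (!is.null(x$boot)) paste0(", ", length(x$boot),
                                   " bootstrap replicates"), "\n", sep = "")
  invisible(x)
}

#' @export
summary.key_phylogeny <- function(object, ...) {
  v <- sort(object$variance$variances, decreasing = TRUE)
  ans <- list(K = object$K, n_species = object$n_species,
              n_observed = length(v),
              n_keys = if (!is.null(object$keys))
                length(object$keys$strings) else NA_integer_,
              v_max = object$variance$v_max,
              critical_value = object$variance$critical_value,
              dist_range = range(object$dist[upper.tri(object$dist)]),
              top_variances = utils::head(v, 10L),
              tree = object$tree)
  class(ans) <- "summary.key_phylogeny"
  ans
}

#' @export
print.summary.key_phylogeny <- function(x, ...) {
  cat("Key K-string phylogeny summary\n")
  cat("  K = ", x$K, ", species = ", x$n_species, "\n", sep = "")
  cat("  observed K-strings: ", x$n_observed, "; selected keys: ",
      x$n_keys, "\n", sep = "")
  cat("  v_max = ", format(x$v_max), "; critical value = ",
      format(x$critical_value), "\n", sep = "")
  cat("  cosine distance range: [",
      paste(formatC(x$dist_range, format = "f", digits = 4), collapse = ", "),
      "]\n", sep = "")
  cat("  highest-variance K-strings:\n")
  print(signif(x$top_variances, 4))
  invisible(x)
}

#' Column variances of the fitted CV matrix
#'
#' Returns the per-K-string variances that drive key selection, sorted
#' decreasingly -- the fitted "coefficients" of the dimensional reduction.
#'
#' @param object A [key_phylogeny] fit.
#' @param keys_only Restrict to the selected key strings.
#' @param ... Unused.
#' @return Named numeric vector of variances.
#' @export
coef.key_phylogeny <- function(object, keys_only = FALSE, ...) {
  v <- object$variance$variances
  if (keys_only && !is.null(object$keys)) v <- v[object$keys$strings]
  sort(v, decreasing = TRUE)
}

#' Plot a fitted key K-string phylogeny
#'
#' Left panel: the L-shaped sorted-variance curve with the critical point;
#' right panel: the NJ tree (bootstrap supports as node labels when
#' present).
#'
#' @param x A [key_phylogeny] fit.
#' @param which `"both"`, `"lcurve"` or `"tree"`.
#' @param ... Passed to [ape::plot.phylo].
#' @return `x`, invisibly.
#' @export
plot.key_phylogeny <- function(x, which = c("both", "lcurve", "tree"), ...) {
  which <- match.arg(which)
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "lcurve")) {
    v <- sort(x$variance$variances, decreasing = TRUE)
    graphics::plot(seq_along(v), v, type = "l", log = "",
                   xlab = "K-string rank", ylab = "column variance",
                   main = "Sorted-variance L-curve")
    graphics::abline(h = x$variance$critical_value, lty = 2)
  }
  if (which %in% c("both", "tree"))
    ape::plot.phylo(x$tree, main = "NJ tree (cosine distance)",
                    show.node.label = !is.null(x$tree$node.label), ...)
  invisible(x)
}

#' Extract the fitted tree
#'
#' @param x A [key_phylogeny] fit.
#' @param ... Unused.
#' @return The [ape::phylo] tree.
#' @importFrom ape as.phylo
#' @export
as.phylo.key_phylogeny <- function(x, ...) x$tree
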