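#' Run the full key K-string pipeline
#'
#' Orchestrates the end-to-end analysis: read (or simulate) proteomes,
#' build composition vectors, extract key K-strings, compute distances and
#' the NJ tree with optional bootstrap supports, and write all artifacts
#' (CV TSVs, key sets, PHYLIP distance matrices, Newick trees, sharing
#' table, composition profiles, and a JSON run manifest with parameters,
#' seeds and output checksums). Outputs are staged in a temporary directory
#' and promoted atomically; re-running with an identical configuration is
#' bit-identical.
#'
#' @param config A named list, or the path of a flat YAML file, with keys:
#'   `fasta` (character vector of FASTA paths) and `species_table` (TSV
#'   path), or `fixture` (a [fixture] name) instead of both; optional `K`
#'   (default 5), `reduction` (0.90), `n_subgroups` (5), `bootstrap`
#'   replicates (0), `seed` (1).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- list(K = 5, reduction = 0.90, n_subgroups = 5, bootstrap = 0,
                   seed = 1, fixture = NULL, fasta = NULL,
                   species_table = NULL)
  bad <- setdiff(names(config), names(defaults))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$fixture) && (is.null(cfg$fasta) || is.null(cfg$species_table)))
    stop("config must provide either 'fixture' or both 'fasta' and 'species_table'")

  proteomes <- if (!is.null(cfg$fixture)) fixture(cfg$fixture)$proteomes
  else read_proteomes(cfg$fasta, read_species_table(cfg$species_table))

  stage <- file.path(tempfile("keystrings_run"))
  dir.create(stage, recursive = TRUE)

  cv <- cv_matrix(proteomes, K = cfg$K)
  for (id in names(cv))
    write_cv_tsv(cv[[id]], file.path(stage, paste0("cv_", id, ".tsv")))

  vp <- variance_profile(cv, reduction = cfg$reduction)
  keys <- select_keys(vp, reduction = cfg$reduction, label = "group-keys")
  write_keyset(keys, file.path(stage, "keys_group.txt"))

  phyla <- vapply(proteomes, `[[`, "", "phylum")
  specific <- NULL
  if (length(unique(phyla[!is.na(phyla)])) >= 2L) {
    seeds <- with_seed(cfg$seed, sample.int(1e6, length(unique(phyla))))
    specific <- lapply(seq_along(unique(phyla)), function(i) {
      ph <- unique(phyla)[i]
      sel <- phyla == ph
      if (sum(sel) < 2L) return(NULL)
      extract_specific_keys(proteomes[sel], K = cfg$K,
                            n_subgroups = cfg$n_subgroups,
                            reduction = cfg$reduction, seed = seeds[i],
                            cvs = cv[sel], label = ph)
    })
    specific <- Filter(Negate(is.null), specific)
    for (ks in specific)
      write_keyset(ks, file.path(stage, paste0("keys_", ks$label, ".txt")))
    if (length(specific) >= 2L)
      write_sharing_table(sharing_table(specific),
                          file.path(stage, "sharing_table.tsv"))
  }

  dm_full <- distance_matrix(cv)
  dm_keys <- distance_matrix(cv, keys = keys)
  write_distance_matrix(dm_full, file.path(stage, "dist_full.phy"))
  write_distance_matrix(dm_keys, file.path(stage, "dist_keys.phy"))

  tree_full <- nj_tree(dm_full)
  tree_keys <- nj_tree(dm_keys)
  if (cfg$bootstrap > 0) {
    boot <- bootstrap_trees(proteomes, n_replicates = cfg$bootstrap,
                            K = cfg$K, keys = keys, seed = cfg$seed)
    tree_keys <- consensus_support(tree_keys, boot)
  }
  write_newick(tree_full, file.path(stage, "tree_full.nwk"))
  write_newick(tree_keys, file.path(stage, "tree_keys.nwk"))

  if (length(keys$strings))
    for (mode in c("mono", "dimer", "gapped_dimer", "triplet"))
      write_profile_tsv(composition_profile(keys, mode),
                        file.path(stage, paste0("profile_", mode, ".tsv")))

  files <- sort(list.files(stage))
  manifest <- list(parameters = cfg[c("K", "reduction", "n_subgroups",
                                      "bootstrap", "seed", "fixture")],
                   n_species = length(proteomes),
                   n_keys = length(keys$strings),
                   outputs = as.list(tools::md5sum(file.path(stage, files))))
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  ## promote atomically: stage -> out_dir
  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  dir.create(dirname(out_dir), recursive = TRUE, showWarnings = FALSE)
  if (!file.rename(stage, out_dir)) {     # cross-device fallback
    dir.create(out_dir, recursive = TRUE)
    file.copy(file.path(stage, list.files(stage)), out_dir)
    unlink(stage, recursive = TRUE)
  }
  invisible(manifest)
}
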