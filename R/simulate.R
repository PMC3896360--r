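#' Simulation configuration for clade-structured proteomes
#'
#' Describes a synthetic study: a clade tree over
#' `n_phyla * species_per_phylum` species, a set of genes with
#' mitochondrial-realistic lengths, a per-site substitution rate, optional
#' conserved blocks evolving at a reduced rate, and optional per-phylum
#' discriminative K-string motifs implanted at each phylum ancestor.
#'
#' @param n_phyla Number of phyla (clades).
#' @param species_per_phylum Species per phylum.
#' @param genes Named integer vector of gene lengths (aa). Defaults to the
#'   13 mitochondrial protein-coding genes at realistic sizes.
#' @param rate Substitution rate per site per branch-length unit; the
#'   per-branch substitution probability is `1 - exp(-rate * length)` with a
#'   uniform replacement residue.
#' @param stem_length Branch length of each phylum stem.
#' @param within_length Branch length of each within-phylum branch.
#' @param deep_length Branch length of the internal between-phyla branches
#'   (the phyla are arranged on a balanced binary backbone).
#' @param conserved_blocks Data.frame with columns `gene`, `start`, `end`,
#'   `multiplier` (rate multiplier, at most 1); may be `NULL`.
#' @param motifs Data.frame with columns `phylum` (1-based phylum index),
#'   `gene`, `pos`, `motif`; each motif overwrites the phylum-ancestor
#'   sequence at `pos`. Motifs may not overlap conserved blocks.
#' @param root_freqs Residue frequencies for the root draw (defaults to
#'   mitochondrial-like frequencies).
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_phyla = 4, species_per_phylum = 5,
                       genes = NULL, rate = 0.05,
                       stem_length = 1, within_length = 0.3,
                       deep_length = 0.3,
                       conserved_blocks = NULL, motifs = NULL,
                       root_freqs = MT_AA_FREQS, seed = 1) {
  if (is.null(genes))
    genes <- c(atp6 = 225, atp8 = 55, cox1 = 510, cox2 = 230, cox3 = 260,
               nad1 = 320, nad2 = 345, nad3 = 115, nad4 = 460, nad4L = 95,
               nad5 = 600, nad6 = 170, cob = 380)
  stopifnot(n_phyla >= 1, species_per_phylum >= 1, rate >= 0,
            all(genes >= 1))
  if (!is.null(conserved_blocks)) {
    stopifnot(all(c("gene", "start", "end", "multiplier") %in%
                    names(conserved_blocks)))
    if (any(conserved_blocks$multiplier > 1 | conserved_blocks$multiplier < 0))
      stop("block rate multipliers must lie in [0, 1]")
    if (any(conserved_blocks$start < 1) ||
        any(conserved_blocks$end > genes[conserved_blocks$gene]))
      stop("conserved block outside gene bounds")
  }
  if (!is.null(motifs)) {
    stopifnot(all(c("phylum", "gene", "pos", "motif") %in% names(motifs)))
    if (any(motifs$pos < 1) ||
        any(motifs$pos + nchar(motifs$motif) - 1L > genes[motifs$gene]))
      stop("motif outside gene bounds")
    if (!is.null(conserved_blocks)) {
      for (i in seq_len(nrow(motifs))) {
        b <- conserved_blocks[conserved_blocks$gene == motifs$gene[i], , drop = FALSE]
        m_end <- motifs$pos[i] + nchar(motifs$motif[i]) - 1L
        if (nrow(b) && any(motifs$pos[i] <= b$end & m_end >= b$start))
          stop("motif ", i, " collides with a conserved block in gene '",
               motifs$gene[i], "'")
      }
    }
  }
  structure(list(n_phyla = n_phyla, species_per_phylum = species_per_phylum,
                 genes = genes, rate = rate, stem_length = stem_length,
                 within_length = within_length, deep_length = deep_length,
                 conserved_blocks = conserved_blocks, motifs = motifs,
                 root_freqs = root_freqs, seed = seed),
            class = "sim_config")
}

## Per-site rate multipliers for one gene (1 outside blocks).
gene_multipliers <- function(cfg, gene) {
  mult <- rep(1, cfg$genes[[gene]])
  b <- cfg$conserved_blocks
  if (!is.null(b)) {
    b <- b[b$gene == gene, , drop = FALSE]
    for (i in seq_len(nrow(b)))
      mult[b$start[i]:b$end[i]] <- b$multiplier[i]
  }
  mult
}

## Mutate a residue vector along one branch: each site substitutes with
## probability 1 - exp(-rate * len * multiplier), uniformly to another residue.
evolve_branch <- function(res, rate, len, mult) {
  p <- 1 - exp(-rate * len * mult)
  hit <- which(stats::runif(length(res)) < p)
  for (i in hit) {
    res[i] <- sample(setdiff(AA_ALPHABET, res[i]), 1L)
  }
  res
}

## Balanced-ish rooted shape over k leaves built by successive halving,
## returned as nested lists of leaf indices.
split_shape <- function(idx) {
  if (length(idx) == 1L) return(idx[1L])
  h <- ceiling(length(idx) / 2)
  list(split_shape(idx[seq_len(h)]), split_shape(idx[-seq_len(h)]))
}

#' Simulate clade-structured proteomes with known ground truth
#'
#' Draws a root proteome from the configured residue frequencies, implants
#' per-phylum discriminative motifs at each phylum ancestor, and evolves
#' sequences down a balanced clade tree by per-site substitution, with
#' conserved blocks evolving at `rate * multiplier`. Implanted motif sites
#' are held fixed below their phylum ancestor, emulating clade-diagnostic
#' elements under purifying selection. Deterministic given the config seed.
#'
#' @param cfg A [sim_config].
#' @return A list with `proteomes` (named list of [proteome]), and `truth`:
#'   `tree` (the true [ape::phylo]), `motifs`, `conserved_blocks`,
#'   `root` (the root gene sequences), `phyla` (species-to-phylum map).
#' @export
simulate_proteomes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gene_names <- names(cfg$genes)
  mults <- lapply(gene_names, function(g) gene_multipliers(cfg, g))
  names(mults) <- gene_names
  with_seed(cfg$seed, {
    root <- lapply(cfg$genes, function(L)
      sample(names(cfg$root_freqs), L, replace = TRUE, prob = cfg$root_freqs))
    names(root) <- gene_names
    phyla_names <- sprintf("P%02d", seq_len(cfg$n_phyla))
    species <- list()

    evolve_all <- function(seqs, len, mu) {
      for (g in gene_names)
        seqs[[g]] <- evolve_branch(seqs[[g]], cfg$rate, len, mu[[g]])
      seqs
    }

    ## one phylum: stem from `seqs`, motif implantation at the ancestor
    ## (sites then frozen), balanced within-phylum descent. Returns the
    ## phylum's newick subtree (with stem branch length).
    do_phylum <- function(ph, seqs) {
      anc <- evolve_all(seqs, cfg$stem_length, mults)
      mults_ph <- mults
      if (!is.null(cfg$motifs)) {
        mm <- cfg$motifs[cfg$motifs$phylum == ph, , drop = FALSE]
        for (i in seq_len(nrow(mm))) {
          m <- strsplit(mm$motif[i], "")[[1L]]
          anc[[mm$gene[i]]][mm$pos[i] + seq_along(m) - 1L] <- m
          mults_ph[[mm$gene[i]]][mm$pos[i] + seq_along(m) - 1L] <- 0
        }
      }
      ids <- sprintf("%s_s%02d", phyla_names[ph],
                     seq_len(cfg$species_per_phylum))
      emit <- function(k, seqs) {
        species[[ids[k]]] <<- proteome(
          ids[k], vapply(seqs, paste, "", collapse = ""),
          phylum = phyla_names[ph],
          class_label = sprintf("%s_c%d", phyla_names[ph],
                                ((k - 1L) %/% 2L) + 1L))
      }
      descend <- function(node, seqs) {
        if (!is.list(node)) {
          emit(node, seqs)
          return(ids[node])
        }
        parts <- vapply(node, function(child)
          descend(child, evolve_all(seqs, cfg$within_length, mults_ph)), "")
        paste0("(", paste0(parts, ":", cfg$within_length, collapse = ","), ")")
      }
      if (cfg$species_per_phylum == 1L) {
        emit(1L, anc)
        paste0(ids[1L], ":", cfg$stem_length)
      } else {
        paste0(descend(split_shape(seq_len(cfg$species_per_phylum)), anc),
               ":", cfg$stem_length)
      }
    }

    ## balanced arrangement of the phyla themselves, with internal
    ## between-phyla branches of length deep_length; `seqs` is the state at
    ## the parent, the edge into an internal node is evolved once here
    descend_deep <- function(node, seqs) {
      if (!is.list(node)) return(do_phylum(node, seqs))
      s2 <- evolve_all(seqs, cfg$deep_length, mults)
      parts <- vapply(node, function(child) descend_deep(child, s2), "")
      paste0("(", paste(parts, collapse = ","), "):", cfg$deep_length)
    }
    top <- split_shape(seq_len(cfg$n_phyla))
    newick <- if (!is.list(top)) paste0("(", do_phylum(1L, root), ");")
    else paste0("(",
                paste(vapply(top, function(child)
                  descend_deep(child, root), ""), collapse = ","),
                ");")
    true_tree <- ape::read.tree(text = newick)
    list(proteomes = species,
         truth = list(tree = true_tree, motifs = cfg$motifs,
                      conserved_blocks = cfg$conserved_blocks,
                      root = vapply(root, paste, "", collapse = ""),
                      phyla = vapply(species, `[[`, "", "phylum")))
  })
}

#' Simulate an amino-acid sequence from a first-order Markov chain
#'
#' The chain copies the previous residue with probability `memory` and
#' otherwise draws a fresh residue from `freqs`, i.e. the transition matrix
#' is `T(a, b) = memory * [a == b] + (1 - memory) * freqs[b]`. With
#' `memory = 0` the sequence is i.i.d. Used as a null generator for
#' calibrating [chi_square_test] at `K = 3`, where the (K-2)-order
#' background is exactly first-order.
#'
#' @param n Sequence length.
#' @param freqs Residue frequencies (default mitochondrial-like).
#' @param memory Copy probability in \[0, 1) (default 0.2).
#' @param seed Integer seed.
#' @return A single character string of length `n`.
#' @export
simulate_markov_sequence <- function(n, freqs = MT_AA_FREQS, memory = 0.2,
                                     seed = NULL) {
  stopifnot(n >= 1, memory >= 0, memory < 1)
  with_seed(seed, {
    fresh <- sample(names(freqs), n, replace = TRUE, prob = freqs)
    keep <- c(TRUE, stats::runif(n - 1L) >= memory)
    ## each position takes the most recent fresh draw at or before it
    idx <- which(keep)
    paste(fresh[idx][findInterval(seq_len(n), idx)], collapse = "")
  })
}

#' Named, seed-pinned simulation fixtures
#'
#' Versioned configurations used throughout the test suite:
#' \describe{
#'   \item{`"twoclade-minimal"`}{2 phyla x 4 species, 3 short genes, one
#'     discriminative motif per phylum. Smallest end-to-end case.}
#'   \item{`"small4x5"`}{4 phyla x 5 species, full 13-gene complement, one
#'     engineered discriminative 5-string per phylum in a variable region,
#'     moderate divergence. Used for key-selection recovery and tree
#'     topology checks.}
#'   \item{`"vertebrate-like10x2"`}{5 classes x 2 species with conserved
#'     blocks (10x reduced substitution rate) spanning roughly half of each
#'     gene, high background divergence. Used for the conservation
#'     analysis.}
#' }
#'
#' @param name Fixture name.
#' @return As [simulate_proteomes]: list with `proteomes` and `truth`.
#' @export
fixture <- function(name) {
  cfg <- switch(name,
    "twoclade-minimal" = sim_config(
      n_phyla = 2, species_per_phylum = 4,
      genes = c(g1 = 400, g2 = 300, g3 = 350),
      rate = 0.04, stem_length = 1, within_length = 0.05,
      motifs = data.frame(phylum = c(1L, 2L), gene = "g1",
                          pos = c(30L, 30L),
                          motif = c("WLLLC", "CLLLW")),
      seed = 101),
    "small4x5" = sim_config(
      n_phyla = 4, species_per_phylum = 5,
      rate = 0.25, stem_length = 1, within_length = 0.1,
      motifs = data.frame(phylum = 1:4,
                          gene = c("cox1", "cob", "nad5", "nad4"),
                          pos = c(101L, 51L, 201L, 151L),
                          motif = c("WLLLC", "CLLLW", "YLLLW", "WLLLY")),
      seed = 1),
    "vertebrate-like10x2" = {
      genes <- c(atp6 = 225, atp8 = 55, cox1 = 510, cox2 = 230, cox3 = 260,
                 nad1 = 320, nad2 = 345, nad3 = 115, nad4 = 460, nad4L = 95,
                 nad5 = 600, nad6 = 170, cob = 380)
      blocks <- do.call(rbind, lapply(names(genes), function(g) {
        L <- genes[[g]]
        ## two conserved blocks per gene covering ~half of it
        b1 <- c(max(1L, round(L * 0.10)), round(L * 0.35))
        b2 <- c(round(L * 0.55), round(L * 0.80))
        data.frame(gene = g, start = c(b1[1L], b2[1L]),
                   end = c(b1[2L], b2[2L]), multiplier = 0.1)
      }))
      sim_config(n_phyla = 5, species_per_phylum = 2, genes = genes,
                 rate = 0.7, stem_length = 1, within_length = 0.7,
                 conserved_blocks = blocks, seed = 7)
    },
    stop("unknown fixture '", name, "'; available: ",
         "twoclade-minimal, small4x5, vertebrate-like10x2"))
  simulate_proteomes(cfg)
}
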