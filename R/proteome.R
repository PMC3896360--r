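#' Construct a proteome
#'
#' A proteome is one species' set of named protein sequences (typically the
#' 13 mitochondrial protein-coding genes) together with its taxonomy labels.
#'
#' @param species_id Unique species token.
#' @param proteins Named character vector; names are gene names, values are
#'   amino-acid sequences over the canonical 20-letter alphabet.
#' @param phylum Phylum token (optional).
#' @param class_label Class token (optional).
#' @param display_name Free-text name; defaults to `species_id`.
#' @return An object of class `"proteome"`.
#' @examples
#' proteome("sp1", c(cox1 = "MKVLA"))
#' @export
proteome <- function(species_id, proteins, phylum = NA_character_,
                     class_label = NA_character_, display_name = species_id) {
  stopifnot(is.character(species_id), length(species_id) == 1L, nzchar(species_id))
  if (length(proteins) < 1L)
    stop("proteome '", species_id, "' has no proteins")
  if (is.null(names(proteins)) || anyNA(names(proteins)) || any(!nzchar(names(proteins))))
    stop("all proteins must be named by gene")
  if (anyDuplicated(names(proteins)))
    stop("duplicate gene names in proteome '", species_id, "': ",
         paste(unique(names(proteins)[duplicated(names(proteins))]), collapse = ", "))
  if (any(!nzchar(proteins)))
    stop("empty sequence for gene(s) ",
         paste(names(proteins)[!nzchar(proteins)], collapse = ", "),
         " in proteome '", species_id, "'")
  bad <- setdiff(unique(unlist(strsplit(proteins, ""))), AA_ALPHABET)
  if (length(bad))
    stop("non-canonical residues in proteome '", species_id, "': ",
         paste(bad, collapse = ", "), " (sanitize first, see sanitize_sequence)")
  proteins <- proteins[order_genes(names(proteins))]
  structure(list(species_id = species_id, display_name = display_name,
                 phylum = phylum, class_label = class_label,
                 proteins = proteins),
            class = "proteome")
}

#' @export
print.proteome <- function(x, ...) {
  cat("Proteome '", x$species_id, "'", sep = "")
  if (!is.na(x$phylum)) cat(" [", x$phylum,
                            if (!is.na(x$class_label)) paste0("/", x$class_label),
                            "]", sep = "")
  cat(": ", length(x$proteins), " proteins, ",
      sum(nchar(x$proteins)), " aa\n", sep = "")
  cat("  genes: ", paste(names(x$proteins), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Sanitize an amino-acid sequence
#'
#' Upper-cases the sequence and removes the ambiguity codes B, Z, J, X and the
#' stop character `*`, which can never match a K-string over the canonical
#' 20-letter alphabet. Any other non-canonical character is an error.
#'
#' @param x Character vector of sequences.
#' @param quiet Suppress the message reporting how many characters were removed.
#' @return Character vector of cleaned sequences.
#' @examples
#' sanitize_sequence("mkvX*la")
#' @export
sanitize_sequence <- function(x, quiet = FALSE) {
  x <- toupper(x)
  n_before <- sum(nchar(x))
  x <- gsub(paste0("[", paste(sub("\\*", "\\\\*", AA_AMBIGUOUS), collapse = ""), "]"),
            "", x)
  removed <- n_before - sum(nchar(x))
  if (removed > 0 && !quiet)
    message("sanitize_sequence: removed ", removed, " ambiguous/stop character(s)")
  bad <- setdiff(unique(unlist(strsplit(x, ""))), AA_ALPHABET)
  if (length(bad))
    stop("non-canonical residues remain after sanitation: ",
         paste(bad, collapse = ", "))
  x
}

#' Read a species metadata table
#'
#' Tab-separated file with a header row and columns `species_id`, `phylum`
#' and optionally `class_label`.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with one row per species.
#' @export
read_species_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("species_id", "phylum") %in% names(tab)))
    stop("species table must have columns 'species_id' and 'phylum'")
  if (!"class_label" %in% names(tab)) tab$class_label <- NA_character_
  if (anyDuplicated(tab$species_id))
    stop("duplicate species_id in table: ",
         paste(unique(tab$species_id[duplicated(tab$species_id)]), collapse = ", "))
  tab[, c("species_id", "phylum", "class_label")]
}

#' Read proteomes from multi-FASTA files
#'
#' Each FASTA header encodes `species_id` and `gene_name` separated by
#' `delim` (default `"|"`). Records are grouped by species, sequences are
#' sanitized ([sanitize_sequence]), species are ordered as in the metadata
#' table, and genes follow the canonical mitochondrial gene order.
#'
#' @param fasta_paths Character vector of FASTA file paths.
#' @param table Species metadata data.frame (see [read_species_table]).
#'   Every species id found in a header must have a row.
#' @param delim Header delimiter between species id and gene name.
#' @param quiet Passed to [sanitize_sequence].
#' @return A named list of [proteome] objects, in table order.
#' @export
read_proteomes <- function(fasta_paths, table, delim = "|", quiet = TRUE) {
  seqs <- character(0)
  for (p in fasta_paths) {
    ss <- Biostrings::readAAStringSet(p)
    v <- as.character(ss)
    names(v) <- names(ss)
    seqs <- c(seqs, v)
  }
  if (!length(seqs)) stop("no FASTA records read")
  headers <- sub("\\s.*$", "", names(seqs))
  parts <- strsplit(headers, delim, fixed = TRUE)
  if (any(lengths(parts) < 2L))
    stop("FASTA header(s) lacking '", delim, "' delimiter: ",
         paste(utils::head(headers[lengths(parts) < 2L], 3L), collapse = ", "))
  sp <- vapply(parts, `[[`, "", 1L)
  gene <- vapply(parts, function(z) paste(z[-1L], collapse = delim), "")
  unknown <- setdiff(unique(sp), table$species_id)
  if (length(unknown))
    stop("species id(s) not in metadata table: ", paste(unknown, collapse = ", "),
         " (first offending header: ", headers[sp %in% unknown][1L], ")")
  if (any(!nzchar(seqs)))
    stop("empty sequence for header(s): ",
         paste(utils::head(headers[!nzchar(seqs)], 3L), collapse = ", "))
  seqs <- sanitize_sequence(seqs, quiet = quiet)
  keep <- table$species_id[table$species_id %in% sp]
  out <- lapply(keep, function(id) {
    sel <- sp == id
    prot <- seqs[sel]
    names(prot) <- gene[sel]
    row <- table[table$species_id == id, ]
    miss <- setdiff(MT_GENE_ORDER, names(prot))
    if (length(miss) && length(intersect(names(prot), MT_GENE_ORDER)))
      warning("proteome '", id, "' missing gene(s): ",
              paste(miss, collapse = ", "), call. = FALSE)
    proteome(id, prot, phylum = row$phylum, class_label = row$class_label)
  })
  names(out) <- keep
  out
}

#' Write proteomes to a multi-FASTA file
#'
#' Inverse of [read_proteomes]; headers are `species_id|gene_name`.
#'
#' @param proteomes List of [proteome] objects.
#' @param path Output file.
#' @param delim Header delimiter.
#' @return `path`, invisibly.
#' @export
write_proteomes <- function(proteomes, path, delim = "|") {
  lines <- unlist(lapply(proteomes, function(pr) {
    as.vector(rbind(paste0(">", pr$species_id, delim, names(pr$proteins)),
                    unname(pr$proteins)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write the species metadata table of a set of proteomes
#'
#' @param proteomes List of [proteome] objects.
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(proteomes, path) {
  tab <- data.frame(species_id = vapply(proteomes, `[[`, "", "species_id"),
                    phylum = vapply(proteomes, `[[`, "", "phylum"),
                    class_label = vapply(proteomes, `[[`, "", "class_label"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
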