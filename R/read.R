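#' Read a rooted Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]. The tree must be rooted,
#' have unique leaf labels, and carry a branch length on every edge; missing
#' branch lengths are rejected rather than defaulted, because both the tree
#' covariance and the node features depend on them (or on the topology being
#' an explicit choice).
#'
#' @param path path to a file containing one Newick string, or the string
#'   itself via `text`.
#' @param text optional Newick string (overrides `path`).
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(file.exists(path))
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL
  )
  if (is.null(tree)) {
    # locate the first structurally bad character for the error message
    offset <- newick_error_offset(text)
    abort(paste0("malformed Newick string (near character ", offset, ")."))
  }
  if (!inherits(tree, "phylo")) {
    abort("input must contain exactly one Newick tree.")
  }
  validate_tree(tree)
  tree
}

# best-effort parse-failure position: first unbalanced paren or trailing junk
newick_error_offset <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) return(i)
  }
  length(chars)
}

#' Validate a tree for use with this package
#'
#' @param tree an [ape::phylo] object.
#' @return the tree, invisibly; errors on violation.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("not a `phylo` tree.")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("duplicate leaf labels: ", paste(dup, collapse = ", ")))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("every edge must have a branch length.")
  }
  if (any(tree$edge.length < 0)) abort("negative branch lengths.")
  if (!ape::is.rooted(tree)) {
    abort("tree must be rooted; root it explicitly before analysis.")
  }
  invisible(tree)
}

# header-based delimiter sniffing: tab wins if present, else comma
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_table_auto <- function(path) {
  read.delim(path, sep = detect_delim(path), check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Read a study from delimited text files
#'
#' `counts_path` must hold a sample-by-taxon table whose first column is the
#' sample id; `metadata_path` a table with `sample_id`, `subject_id`, `day`
#' (and optionally `phase`); `taxonomy_path` an optional table with
#' `taxon_id` plus rank columns. Comma or tab delimiters are auto-detected
#' from the header line; ids are case-sensitive.
#'
#' @param counts_path,metadata_path,taxonomy_path file paths; taxonomy is
#'   optional.
#' @return a validated [study_table].
#' @export
read_study <- function(counts_path, metadata_path, taxonomy_path = NULL) {
  raw <- read_table_auto(counts_path)
  ids <- as.character(raw[[1]])
  counts <- as.matrix(raw[, -1, drop = FALSE])
  rownames(counts) <- ids
  if (!is.numeric(counts)) abort("count table has non-numeric entries.")
  metadata <- read_table_auto(metadata_path)
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    tx <- tryCatch(read_table_auto(taxonomy_path), error = function(e) NULL)
    if (!is.null(tx) && nrow(tx) > 0) taxonomy <- tx
  }
  study_table(counts, metadata, taxonomy)
}

#' Read a gene-term table from delimited text
#'
#' @param path file path; first column is the sample id, remaining columns
#'   are gene-term abundances.
#' @return a [gene_table].
#' @export
read_gene_table <- function(path) {
  raw <- read_table_auto(path)
  ab <- as.matrix(raw[, -1, drop = FALSE])
  rownames(ab) <- as.character(raw[[1]])
  gene_table(ab)
}

#' Read a study from a BIOM file
#'
#' Optional interoperability reader behind the same [study_table] contract;
#' requires the `biomformat` package. Sample metadata must still be supplied
#' as a delimited file because BIOM sample metadata fields vary.
#'
#' @param biom_path path to a BIOM file.
#' @param metadata_path delimited metadata file as in [read_study()].
#' @return a [study_table].
#' @export
read_biom_study <- function(biom_path, metadata_path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("the `biomformat` package is required for BIOM input.")
  }
  b <- biomformat::read_biom(biom_path)
  counts <- t(as.matrix(biomformat::biom_data(b)))  # biom stores taxa x samples
  metadata <- read_table_auto(metadata_path)
  study_table(counts, metadata)
}

#' Write a study to delimited text files
#'
#' Emits `counts.tsv`, `metadata.tsv` and (when present) `taxonomy.tsv` into
#' `dir`, in the exact format [read_study()] reads back.
#'
#' @param study a [study_table].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"))
  counts_df <- data.frame(sample_id = rownames(study$counts),
                          study$counts, check.names = FALSE)
  write_tsv_plain(counts_df, paths["counts"])
  write_tsv_plain(as.data.frame(study$metadata), paths["metadata"])
  if (!is.null(study$taxonomy)) {
    write_tsv_plain(as.data.frame(study$taxonomy), paths["taxonomy"])
  } else {
    paths <- paths[c("counts", "metadata")]
  }
  invisible(paths)
}

write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Align a study, a tree, and optionally a gene table
#'
#' Restricts the taxa to the intersection of count-table columns and tree
#' leaves (in tree leaf order), prunes the tree to that set, and restricts a
#' gene table to the samples shared with the study. Dropped ids are reported
#' via a message.
#'
#' @param study a [study_table].
#' @param tree an [ape::phylo] tree.
#' @param genes optional [gene_table].
#' @return list with elements `study`, `tree` and (if given) `genes`.
#' @export
align_study <- function(study, tree, genes = NULL) {
  shared <- intersect(tree$tip.label, colnames(study$counts))
  if (length(shared) == 0) {
    abort("no taxa shared between the count table and the tree.")
  }
  dropped_tree <- setdiff(tree$tip.label, shared)
  dropped_tab <- setdiff(colnames(study$counts), shared)
  if (length(dropped_tree) || length(dropped_tab)) {
    inform(paste0("align: dropped ", length(dropped_tree),
                  " tree leaves and ", length(dropped_tab),
                  " table taxa not shared."))
  }
  if (length(dropped_tree)) {
    tree <- ape::drop.tip(tree, dropped_tree)
  }
  keep <- tree$tip.label  # tree leaf order is the canonical order
  taxonomy <- study$taxonomy
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[match(keep, taxonomy$taxon_id), ]
    taxonomy$taxon_id <- keep
  }
  study <- study_table(study$counts[, keep, drop = FALSE],
                       study$metadata, taxonomy)
  out <- list(study = study, tree = tree)
  if (!is.null(genes)) {
    shared_s <- intersect(rownames(study$counts), rownames(genes$abundances))
    if (length(shared_s) == 0) abort("no shared samples with the gene table.")
    ds <- setdiff(rownames(study$counts), shared_s)
    dg <- setdiff(rownames(genes$abundances), shared_s)
    if (length(ds) || length(dg)) {
      inform(paste0("align: ", length(ds), " study and ", length(dg),
                    " gene-table samples dropped (not shared)."))
      md <- study$metadata[study$metadata$sample_id %in% shared_s, ]
      study <- study_table(study$counts[shared_s, , drop = FALSE], md,
                           study$taxonomy)
      out$study <- study
    }
    out$genes <- gene_table(genes$abundances[shared_s, , drop = FALSE])
  }
  out
}
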