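#' Assemble a longitudinal study table
#'
#' The central exchange object of the package: a sample-by-taxon count matrix
#' together with per-sample metadata (subject, study day relative to the
#' perturbation, phase) and optional per-taxon rank assignments.
#'
#' The `phase` label is defined by the study clock: samples taken within the
#' three days after the perturbation (`1 <= day <= 3`) are `imm_post`, earlier
#' samples (`day <= 0`, including the perturbation day itself) are `pre`, and
#' later samples are `post`. When a supplied `phase` column conflicts with
#' this rule it is recomputed with a warning, since the day is the
#' authoritative record.
#'
#' @param counts integer matrix of nonnegative counts, samples in rows and
#'   taxa in columns, with unique row and column names.
#' @param metadata data frame with columns `sample_id`, `subject_id`, `day`
#'   (integer days relative to the perturbation; day 0 is the perturbation
#'   day) and optionally `phase`. One row per count row.
#' @param taxonomy optional data frame with a `taxon_id` column plus ordered
#'   rank columns (e.g. `phylum` ... `genus`); missing ranks are `NA`.
#'
#' @return An object of class `study_table`: a list with elements `counts`
#'   (integer matrix), `metadata` (tibble, one row per sample, in count-row
#'   order) and `taxonomy` (tibble or `NULL`).
#' @export
#' @examples
#' counts <- matrix(rpois(12, 10), 3, 4,
#'                  dimnames = list(paste0("s", 1:3), paste0("t", 1:4)))
#' md <- data.frame(sample_id = paste0("s", 1:3),
#'                  subject_id = "A", day = c(-7L, 2L, 14L))
#' study_table(counts, md)
study_table <- function(counts, metadata, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have sample row names and taxon column names.")
  }
  if (anyDuplicated(rownames(counts))) {
    abort("duplicate sample ids in `counts` rows.")
  }
  if (anyDuplicated(colnames(counts))) {
    abort("duplicate taxon ids in `counts` columns.")
  }
  if (any(counts < 0)) abort("`counts` has negative entries.")
  if (any(counts != round(counts))) abort("`counts` has non-integer entries.")
  storage.mode(counts) <- "integer"

  metadata <- as_tibble(metadata)
  required <- c("sample_id", "subject_id", "day")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    abort(paste0("metadata lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(rownames(counts), metadata$sample_id)
  if (length(extra)) {
    abort(paste0("samples in counts but not metadata: ",
                 paste(extra, collapse = ", ")))
  }
  orphan <- setdiff(metadata$sample_id, rownames(counts))
  if (length(orphan)) {
    abort(paste0("samples in metadata but not counts: ",
                 paste(orphan, collapse = ", ")))
  }
  metadata <- metadata[match(rownames(counts), metadata$sample_id), ]
  if (any(is.na(metadata$day)) || any(metadata$day != round(metadata$day))) {
    abort("metadata `day` must be integer for every sample.")
  }
  metadata$day <- as.integer(metadata$day)
  metadata$subject_id <- as.character(metadata$subject_id)

  derived <- phase_from_day(metadata$day)
  if ("phase" %in% names(metadata)) {
    bad <- metadata$phase != derived
    if (any(bad)) {
      warn(paste0("phase disagrees with day for ", sum(bad),
                  " sample(s); recomputed from day."))
    }
  }
  metadata$phase <- derived

  if (!is.null(taxonomy)) {
    taxonomy <- as_tibble(taxonomy)
    if (!"taxon_id" %in% names(taxonomy)) {
      abort("taxonomy lacks a `taxon_id` column.")
    }
    taxonomy <- taxonomy[match(colnames(counts), taxonomy$taxon_id), ]
    taxonomy$taxon_id <- colnames(counts)
  }

  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy),
            class = "study_table")
}

#' Phase label implied by the study day
#'
#' @param day integer vector of days relative to the perturbation.
#' @param window length of the immediate-post window in days.
#' @return character vector over `pre`, `imm_post`, `post`.
#' @export
phase_from_day <- function(day, window = 3L) {
  ifelse(day >= 1 & day <= window, "imm_post", ifelse(day <= 0, "pre", "post"))
}

#' @export
print.study_table <- function(x, ...) {
  cat("<study_table> ", nrow(x$counts), " samples x ", ncol(x$counts),
      " taxa; ", length(unique(x$metadata$subject_id)), " subjects; days ",
      min(x$metadata$day), "..", max(x$metadata$day), "\n", sep = "")
  print(table(x$metadata$phase))
  invisible(x)
}

#' @export
dim.study_table <- function(x) dim(x$counts)

#' Long tidy view of a study table
#'
#' @param x a [study_table].
#' @param ... unused.
#' @return Tibble with one row per (sample, taxon) pair: sample metadata,
#'   `taxon_id`, `count`, and `proportion` within the sample.
#' @export
tidy.study_table <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "taxon_id",
                        values_to = "count")
  long <- dplyr::left_join(long, x$metadata, by = "sample_id")
  long |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(proportion = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}

#' @export
glance.study_table <- function(x, ...) {
  tibble(n_samples = nrow(x$counts), n_taxa = ncol(x$counts),
         n_subjects = length(unique(x$metadata$subject_id)),
         n_imm_post = sum(x$metadata$phase == "imm_post"),
         total_reads = sum(as.numeric(x$counts)))
}

#' Assemble a gene-term abundance table
#'
#' Holds a sample-by-gene-term abundance matrix paired with a study table
#' through shared sample ids (e.g. GO-term abundances from shotgun
#' metagenomics, normalized to real values).
#'
#' @param abundances matrix of nonnegative reals, samples in rows, gene terms
#'   in columns, with unique row/column names.
#' @return Object of class `gene_table`.
#' @export
gene_table <- function(abundances) {
  if (!is.matrix(abundances)) abundances <- as.matrix(abundances)
  if (is.null(rownames(abundances)) || is.null(colnames(abundances))) {
    abort("`abundances` must have sample row names and term column names.")
  }
  if (anyDuplicated(rownames(abundances)) ||
      anyDuplicated(colnames(abundances))) {
    abort("duplicate sample or term ids in gene table.")
  }
  if (any(abundances < 0)) abort("gene abundances must be nonnegative.")
  structure(list(abundances = abundances), class = "gene_table")
}

#' @export
print.gene_table <- function(x, ...) {
  cat("<gene_table> ", nrow(x$abundances), " samples x ", ncol(x$abundances),
      " terms\n", sep = "")
  invisible(x)
}

#' Relative abundances of a study table
#'
#' @param study a [study_table].
#' @return numeric matrix of per-sample proportions (rows sum to 1).
#' @export
relative_abundance <- function(study) {
  rs <- rowSums(study$counts)
  if (any(rs == 0)) {
    abort(paste0("all-zero sample(s): ",
                 paste(rownames(study$counts)[rs == 0], collapse = ", ")))
  }
  sweep(study$counts, 1, rs, "/")
}
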