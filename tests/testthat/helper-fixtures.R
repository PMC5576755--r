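# small in-code fixtures shared across test files

toy_counts <- function() {
  matrix(c(10L, 0L, 5L,
           2L, 8L, 5L,
           0L, 4L, 5L,
           1L, 1L, 5L),
         nrow = 3, ncol = 4,
         dimnames = list(c("s1", "s2", "s3"), c("tA", "tB", "tC", "tD")))
}

toy_metadata <- function() {
  data.frame(sample_id = c("s1", "s2", "s3"),
             subject_id = c("P1", "P1", "P2"),
             day = c(-7L, 2L, 14L))
}

toy_taxonomy <- function() {
  data.frame(taxon_id = c("tA", "tB", "tC", "tD"),
             phylum = "PhyX",
             family = c("FamA", "FamA", "FamB", "FamB"),
             genus = c("GenA", "GenA", "GenB", NA))
}

toy_study <- function() study_table(toy_counts(), toy_metadata(),
                                    toy_taxonomy())

write_toy_files <- function(dir, sep = "\t") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    write.table(df, file.path(dir, name), sep = sep, quote = FALSE,
                row.names = FALSE)
  }
  w(data.frame(sample_id = rownames(toy_counts()), toy_counts(),
               check.names = FALSE), "counts.tsv")
  w(toy_metadata(), "metadata.tsv")
  w(toy_taxonomy(), "taxonomy.tsv")
  dir
}

# brute-force tree covariance: explicit root-to-leaf edge paths, summing the
# lengths of shared edges -- independent of the package's implementation
brute_force_Q <- function(tree) {
  p <- length(tree$tip.label)
  root <- p + 1L
  parent <- integer(p + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  edge_len <- setNames(tree$edge.length,
                       paste(tree$edge[, 1], tree$edge[, 2]))
  path_edges <- function(leaf) {
    edges <- character(0)
    node <- leaf
    while (node != root) {
      edges <- c(edges, paste(parent[node], node))
      node <- parent[node]
    }
    edges
  }
  paths <- lapply(seq_len(p), path_edges)
  Q <- matrix(0, p, p, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      shared <- intersect(paths[[i]], paths[[j]])
      Q[i, j] <- sum(edge_len[shared])
    }
  }
  Q
}

# generalized (DPCoA-style) distances under a metric S, by direct quadratic
# forms
quadratic_distances <- function(X, S) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- X[i, ] - X[j, ]
      D[i, j] <- sqrt(drop(t(d) %*% S %*% d))
    }
  }
  D
}

# Cohen's d between imm_post and pre samples on subject-centered axis-1
# scores of an ordination
axis1_standardized_difference <- function(ord, study) {
  cs <- center_scores_by_subject(ord, study)[, 1]
  ph <- study$metadata$phase
  x1 <- cs[ph == "imm_post"]
  x0 <- cs[ph == "pre"]
  sp <- sqrt(((length(x1) - 1) * var(x1) + (length(x0) - 1) * var(x0)) /
               (length(x1) + length(x0) - 2))
  (mean(x1) - mean(x0)) / sp
}
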