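#' Default sampling schedule for the synthetic study
#'
#' Weekly sampling for ten weeks on each side of the perturbation (day 0),
#' daily sampling in the week before and the week after it, and a five-day
#' daily block about six weeks before — mirroring the kind of unequally
#' spaced longitudinal design used for perturbation experiments.
#'
#' @return sorted integer vector of scheduled days.
#' @export
default_schedule <- function() {
  sort(unique(c(seq(-70, -14, by = 7), -47:-43, -7:-1, 1:7,
                seq(14, 70, by = 7))))
}

#' Configuration for the synthetic study generator
#'
#' Defaults describe an 8-subject, roughly 20-week study with strong
#' subject-specific compositions and a transient clade-level perturbation:
#' one "bloom" clade (~10 leaves) whose log-abundance rises by `delta_up`
#' immediately after day 0 and one disjoint "depressed" clade (~8 leaves)
#' falling by `delta_down`, both decaying linearly back to baseline over
#' `recovery_days` days.
#'
#' @param seed master seed; all downstream draws derive from it.
#' @param n_subjects,p_leaves cohort and community sizes.
#' @param schedule integer days sampled per subject.
#' @param subject_effect_sd SD of per-subject, per-taxon log-abundance
#'   offsets (between-subject signal).
#' @param day_noise_sd SD of day-to-day log-abundance noise within subject.
#' @param delta_up,delta_down log-scale effect sizes (>= 0) for the bloom and
#'   depressed clades.
#' @param bloom_size,depressed_size target clade sizes (closest clade is
#'   used).
#' @param recovery_days days over which the effect decays to zero.
#' @param library_size_mean,library_size_log_sd lognormal per-sample
#'   sequencing depth.
#' @param missing_day_prob probability a scheduled sample is not produced.
#' @param n_terms,gene_log_sd gene table: number of gene terms and the
#'   lognormal noise SD per cell.
#' @param phylo_subject_effects draw subject offsets with covariance
#'   proportional to the (unit-diagonal) tree similarity instead of iid,
#'   giving phylogenetically coherent subject signatures.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_subjects = 8L, p_leaves = 60L,
                         schedule = default_schedule(),
                         subject_effect_sd = 1, day_noise_sd = 0.5,
                         delta_up = 2, delta_down = 1,
                         bloom_size = 10L, depressed_size = 8L,
                         recovery_days = 3L,
                         library_size_mean = 5e4,
                         library_size_log_sd = 0.3,
                         missing_day_prob = 0.1,
                         n_terms = 40L, gene_log_sd = 0.5,
                         phylo_subject_effects = FALSE) {
  stopifnot(p_leaves >= 2, n_subjects >= 1,
            subject_effect_sd >= 0, day_noise_sd >= 0,
            delta_up >= 0, delta_down >= 0, recovery_days >= 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Simulate a random rooted tree
#'
#' Pure-birth (Yule) topology with branch lengths redrawn iid Exponential(1)
#' and globally rescaled so the maximum root-to-leaf depth is 1.
#'
#' @param p_leaves number of leaves (labelled `t1 ... tp`).
#' @param seed optional seed; the Newick string is deterministic given it.
#' @return an [ape::phylo] tree.
#' @export
simulate_tree <- function(p_leaves, seed = NULL) {
  draw <- function() {
    tree <- ape::rphylo(p_leaves, birth = 1, death = 0)
    tree$edge.length <- rexp(nrow(tree$edge))
    depth <- max(ape::node.depth.edgelength(tree)[seq_len(p_leaves)])
    tree$edge.length <- tree$edge.length / depth
    tree$tip.label <- paste0("t", seq_len(p_leaves))
    tree
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# disjoint clades closest to the target sizes, deterministic given the tree
pick_clades <- function(tree, bloom_size, depressed_size) {
  p <- length(tree$tip.label)
  desc <- descendant_tips(tree)
  inner <- seq(p + 1L, p + tree$Nnode)
  sizes <- lengths(desc[inner])
  usable <- inner[sizes < p]  # never the root
  bloom <- usable[which.min(abs(lengths(desc[usable]) - bloom_size))]
  bloom_set <- desc[[bloom]]
  disjoint <- usable[vapply(desc[usable],
                            function(d) !any(d %in% bloom_set), logical(1))]
  if (length(disjoint) == 0) {
    # tiny trees: fall back to a singleton clade (one leaf) outside the bloom
    disjoint <- setdiff(seq_len(p), bloom_set)
  }
  depressed <- disjoint[which.min(abs(lengths(desc[disjoint]) -
                                      depressed_size))]
  list(bloom_node = paste0("n", bloom),
       bloom_leaves = tree$tip.label[desc[[bloom]]],
       depressed_node = paste0("n", depressed),
       depressed_leaves = tree$tip.label[desc[[depressed]]])
}

# greedy disjoint cover of the leaves by clades of size <= max_size,
# descending from the root; returns integer group id per leaf
clade_partition <- function(tree, max_size) {
  p <- length(tree$tip.label)
  desc <- descendant_tips(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  groups <- integer(p)
  counter <- 0L
  recurse <- function(node) {
    if (length(desc[[node]]) <= max_size) {
      counter <<- counter + 1L
      groups[desc[[node]]] <<- counter
    } else {
      for (ch in children[[as.character(node)]]) recurse(ch)
    }
  }
  recurse(p + 1L)
  groups
}

# rank labels by nested clade partitions; perturbation clades get fixed
# genus/family names so downstream genus filters are exercisable
synth_taxonomy <- function(tree, truth) {
  leaves <- tree$tip.label
  phylum <- clade_partition(tree, max(2L, length(leaves) %/% 2L))
  family <- clade_partition(tree, 12L)
  genus <- clade_partition(tree, 6L)
  tax <- tibble(taxon_id = leaves,
                phylum = sprintf("Phylum_%02d", phylum),
                family = sprintf("Family_%02d", family),
                genus = sprintf("Genus_%02d", genus))
  tax$genus[leaves %in% truth$bloom_leaves] <- "Bacteroides"
  tax$family[leaves %in% truth$bloom_leaves] <- "Bacteroidaceae"
  tax$genus[leaves %in% truth$depressed_leaves] <- "Ruminococcus"
  tax$family[leaves %in% truth$depressed_leaves] <- "Ruminococcaceae"
  tax
}

#' Simulate a longitudinal perturbation study
#'
#' Log-abundances follow `eta[s, d, j] = m_j + b[s, j] + e[s, d, j] + effect`,
#' with taxon baselines `m_j ~ N(0, 1)`, subject offsets `b[s, j]` (iid
#' `N(0, subject_effect_sd^2)` or tree-correlated), day noise
#' `e ~ N(0, day_noise_sd^2)`, and a transient effect on days `1..L`:
#' `+delta_up * (1 - (d - 1)/L)` on the bloom clade and
#' `-delta_down * (1 - (d - 1)/L)` on the depressed clade. Counts are
#' multinomial draws of a lognormal library size on the softmax of each
#' log-abundance row; scheduled days are dropped independently with
#' `missing_day_prob`.
#'
#' @param config a [synth_config()].
#' @param tree optional tree (default: [simulate_tree()] from the config
#'   seed).
#' @return list with `study` (a [study_table] with taxonomy), `tree`, and
#'   `truth` (the planted clades and effect sizes, for recovery scoring).
#' @export
simulate_study <- function(config, tree = NULL) {
  withr::with_seed(config$seed, {
    if (is.null(tree)) {
      tree <- simulate_tree(config$p_leaves, sample.int(2^31 - 1, 1))
    }
    p <- length(tree$tip.label)
    truth <- pick_clades(tree, config$bloom_size, config$depressed_size)
    truth$delta_up <- config$delta_up
    truth$delta_down <- config$delta_down
    truth$recovery_days <- config$recovery_days
    if (length(intersect(truth$bloom_leaves, truth$depressed_leaves))) {
      abort("perturbation clades overlap.")
    }

    m <- rnorm(p)
    if (config$phylo_subject_effects) {
      Q <- tree_similarity(tree)
      Qn <- stats::cov2cor(Q)
      L <- t(chol(Qn + diag(1e-8, p)))
      b <- t(L %*% matrix(rnorm(p * config$n_subjects), p)) *
        config$subject_effect_sd
    } else {
      b <- matrix(rnorm(config$n_subjects * p, 0, config$subject_effect_sd),
                  config$n_subjects, p)
    }
    bloom_idx <- match(truth$bloom_leaves, tree$tip.label)
    depr_idx <- match(truth$depressed_leaves, tree$tip.label)
    L_rec <- config$recovery_days

    rows <- list(); meta <- list(); r <- 0L
    for (s in seq_len(config$n_subjects)) {
      for (d in config$schedule) {
        if (runif(1) < config$missing_day_prob) next
        eta <- m + b[s, ] + rnorm(p, 0, config$day_noise_sd)
        if (d >= 1 && d <= L_rec) {
          decay <- 1 - (d - 1) / L_rec
          eta[bloom_idx] <- eta[bloom_idx] + config$delta_up * decay
          eta[depr_idx] <- eta[depr_idx] - config$delta_down * decay
        }
        lib <- max(1, round(rlnorm(1, log(config$library_size_mean),
                                   config$library_size_log_sd)))
        pr <- exp(eta - max(eta)); pr <- pr / sum(pr)
        r <- r + 1L
        rows[[r]] <- as.integer(rmultinom(1, lib, pr))
        meta[[r]] <- list(sample_id = paste0("S", s, "_d", d),
                          subject_id = paste0("S", s), day = d)
      }
    }
    counts <- do.call(rbind, rows)
    metadata <- dplyr::bind_rows(lapply(meta, as_tibble))
    rownames(counts) <- metadata$sample_id
    colnames(counts) <- tree$tip.label
    study <- study_table(counts, metadata, synth_taxonomy(tree, truth))
    list(study = study, tree = tree, truth = truth)
  })
}

#' Simulate a linked gene-term table
#'
#' Each gene term is carried by all leaves of one clade (an incidence matrix
#' `M` over taxa x terms); the noiseless term abundance of a sample is its
#' relative abundance vector times `M`, and lognormal noise multiplies each
#' cell. When the planted perturbation clades are supplied, the first two
#' terms are pinned to them so the taxon and gene tables share planted
#' structure.
#'
#' @param study a [study_table].
#' @param tree the matching tree.
#' @param config a [synth_config()] (uses `n_terms`, `gene_log_sd`, `seed`).
#' @param truth optional truth record from [simulate_study()].
#' @return a [gene_table] with terms `go1 ... goK`.
#' @export
simulate_gene_table <- function(study, tree, config, truth = NULL) {
  withr::with_seed(config$seed + 1L, {
    p <- length(tree$tip.label)
    desc <- descendant_tips(tree)
    inner <- seq(p + 1L, p + tree$Nnode)
    nodes <- sample(inner, config$n_terms, replace = TRUE)
    if (!is.null(truth)) {
      nodes[1] <- as.integer(sub("^n", "", truth$bloom_node))
      if (config$n_terms >= 2) {
        nodes[2] <- as.integer(sub("^n", "", truth$depressed_node))
      }
    }
    M <- vapply(nodes, function(nd) {
      z <- numeric(p); z[desc[[nd]]] <- 1; z
    }, numeric(p))
    rel <- relative_abundance(study)[, tree$tip.label, drop = FALSE]
    ab <- rel %*% M
    noise <- matrix(rlnorm(length(ab), 0, config$gene_log_sd), nrow(ab))
    ab <- ab * noise
    colnames(ab) <- paste0("go", seq_len(config$n_terms))
    gt <- gene_table(ab)
    rownames(M) <- tree$tip.label
    colnames(M) <- colnames(ab)
    gt$incidence <- M  # taxon-by-term carriage, kept for recovery scoring
    gt$term_nodes <- paste0("n", nodes)
    gt
  })
}

#' Simulate a complete linked experiment
#'
#' Tree, study table, truth record and gene table in one deterministic call.
#'
#' @param config a [synth_config()].
#' @return list with `study`, `tree`, `genes`, `truth`.
#' @export
simulate_experiment <- function(config = synth_config()) {
  sim <- simulate_study(config)
  sim$genes <- simulate_gene_table(sim$study, sim$tree, config, sim$truth)
  sim
}
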