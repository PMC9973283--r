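# Shared fixture builders; everything is generated in code at test time.

# minimal wide clinical table with all 16 stratification variables
make_clinical_fixture <- function(n = 3, ids = sprintf("S%d", seq_len(n))) {
  set.seed(99)
  df <- data.frame(participant_id = ids,
                   cohort = "discovery",
                   age = round(runif(n, 45, 70)),
                   gender = rep_len(c("female", "male"), n),
                   hba1c = round(runif(n, 5, 7), 2),
                   bmi = round(runif(n, 20, 30), 1),
                   waist = round(runif(n, 75, 95), 1),
                   hip = round(runif(n, 90, 105), 1),
                   triglyceride = round(runif(n, 0.5, 2), 2),
                   hdl = round(runif(n, 0.4, 1.2), 2))
  for (t in c(0, 30, 60, 120, 180)) {
    df[[paste0("glucose_", t)]] <- round(runif(n, 4, 12), 2)
    df[[paste0("insulin_", t)]] <- round(runif(n, 2, 40), 2)
  }
  df
}

write_clinical_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small consistent ASV fixture on disk: counts TSV + taxonomy TSV + newick
make_asv_files <- function(n_samples = 4, n_asvs = 10, drop_from_tree = 0,
                           branch_lengths = TRUE, transpose = FALSE) {
  set.seed(7)
  asvs <- sprintf("ASV%02d", seq_len(n_asvs))
  samples <- sprintf("S%d", seq_len(n_samples))
  counts <- matrix(rpois(n_samples * n_asvs, 50), n_samples,
                   dimnames = list(samples, asvs))
  tree <- ape::rtree(n_asvs, br = if (branch_lengths) stats::rexp else NULL)
  tree$tip.label <- asvs
  if (drop_from_tree > 0) {
    tree <- ape::drop.tip(tree, asvs[seq_len(drop_from_tree)])
  }
  dir <- tempfile(); dir.create(dir)
  cp <- file.path(dir, "counts.tsv")
  cm <- if (transpose) t(counts) else counts
  utils::write.table(data.frame(id = rownames(cm), cm, check.names = FALSE),
                     cp, sep = "\t", quote = FALSE, row.names = FALSE)
  tp <- file.path(dir, "taxonomy.tsv")
  utils::write.table(data.frame(`Feature ID` = asvs,
                                Taxon = paste0("k__Bacteria;g__G", seq_len(n_asvs)),
                                check.names = FALSE),
                     tp, sep = "\t", quote = FALSE, row.names = FALSE)
  np <- file.path(dir, "tree.nwk")
  ape::write.tree(tree, np)
  list(counts = cp, taxonomy = tp, tree = np, matrix = counts)
}

# k planted Gaussian clusters in 2-D, tight enough to stay unambiguous
# after per-column standardization (both coordinates carry the separation)
make_separated_points <- function(sizes, sep = 8, sd = 0.5, seed = 1) {
  set.seed(seed)
  k <- length(sizes)
  centers <- cbind(sep * seq_len(k), sep * (seq_len(k) %% 2))
  pts <- do.call(rbind, lapply(seq_len(k), function(g) {
    cbind(rnorm(sizes[g], centers[g, 1], sd),
          rnorm(sizes[g], centers[g, 2], sd))
  }))
  colnames(pts) <- c("v1", "v2")
  list(x = pts, labels = rep(seq_len(k), sizes))
}

# strat_matrix wrapper around an arbitrary numeric matrix
as_fake_strat_matrix <- function(x, ids = sprintf("P%03d", seq_len(nrow(x)))) {
  rownames(x) <- ids
  z <- scale(x)
  structure(list(z = z, center = attr(z, "scaled:center"),
                 scale = attr(z, "scaled:scale"),
                 excluded = data.frame(participant_id = character(0),
                                       reason = character(0))),
            class = "strat_matrix")
}

# correlated-block compositional counts for network/CAG tests
make_block_counts <- function(n = 60, block_sizes = c(6, 6), load = 0.9,
                              seed = 1) {
  set.seed(seed)
  m <- sum(block_sizes)
  fs <- replicate(length(block_sizes), rnorm(n))
  blk <- rep(seq_along(block_sizes), block_sizes)
  x <- sapply(seq_len(m), function(j) {
    load * fs[, blk[j]] + sqrt(1 - load^2) * rnorm(n)
  })
  counts <- round(exp(x + 5))
  dimnames(counts) <- list(sprintf("S%03d", seq_len(n)),
                           sprintf("A%02d", seq_len(m)))
  list(counts = counts, blocks = blk)
}
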