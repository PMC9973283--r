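# Community-level microbiome analysis: rarefaction, alpha diversity
# (including Faith's PD), the phylogenetic isometric log-ratio transform,
# distance-based global tests (PERMANOVA, Mantel, Procrustes), LDA scores,
# and cluster-specific differential ASV calling.

#' Rarefy a count matrix to even depth
#'
#' Samples whose total is below `depth` are dropped (with a logged count);
#' the rest are subsampled without replacement to exactly `depth`.
#'
#' @param counts Samples x ASVs nonnegative integer matrix, or an
#'   `asv_table`.
#' @param depth Target depth per sample.
#' @param seed RNG seed for the subsampling.
#' @return Rarefied matrix (retained samples x ASVs), row sums all `depth`.
#' @export
rarefy_counts <- function(counts, depth, seed = 1L) {
  if (inherits(counts, "asv_table")) counts <- counts$counts
  stopifnot(depth > 0)
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples are below the rarefaction depth")
  if (any(!keep)) {
    glyco_log(sum(!keep), " sample(s) below depth ", depth, " dropped")
  }
  x <- counts[keep, , drop = FALSE]
  set.seed(seed)
  # rrarefy warns when the smallest nonzero count exceeds 1 (suspecting
  # non-count data); our inputs are validated integer counts
  out <- withCallingHandlers(
    vegan::rrarefy(x, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  storage.mode(out) <- "integer"
  out
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree connecting the present tips
#' and the root; the root's own edge (if any) is excluded.
#'
#' @param counts Samples x ASVs matrix (presence taken as count > 0).
#' @param tree Rooted `phylo` whose tips cover the ASV columns.
#' @return Numeric vector, one PD value per sample (`NA` for empty samples).
#' @export
faith_pd <- function(counts, tree) {
  counts <- as.matrix(counts)
  miss <- setdiff(colnames(counts), tree$tip.label)
  if (length(miss)) stop("ASVs absent from tree: ", paste(miss, collapse = ", "))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  # parent edge lookup: child node -> edge row
  edge_of <- integer(max(tree$edge))
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  apply(counts, 1, function(x) {
    tips <- match(colnames(counts)[x > 0], tree$tip.label)
    if (length(tips) == 0) return(NA_real_)
    used <- logical(nrow(tree$edge))
    for (tip in tips) {
      node <- tip
      while (node != root) {
        e <- edge_of[node]
        if (used[e]) break  # path above already accumulated
        used[e] <- TRUE
        node <- parent_of[node]
      }
    }
    sum(tree$edge.length[used])
  })
}

#' Alpha diversity indices
#'
#' Shannon (natural log), Simpson (1 - sum p^2), observed ASVs, and Faith's
#' phylogenetic diversity per sample.
#'
#' @param counts Rarefied samples x ASVs matrix.
#' @param tree Rooted `phylo` (required for Faith's PD; `NULL` skips it).
#' @return Data frame with `sample_id`, `shannon`, `simpson`,
#'   `observed_asvs`, `faith_pd`.
#' @export
alpha_diversity <- function(counts, tree = NULL) {
  counts <- as.matrix(counts)
  empty <- rowSums(counts) == 0
  sh <- vegan::diversity(counts, index = "shannon")
  si <- vegan::diversity(counts, index = "simpson")
  obs <- rowSums(counts > 0)
  pd <- if (is.null(tree)) rep(NA_real_, nrow(counts)) else faith_pd(counts, tree)
  out <- data.frame(sample_id = rownames(counts), shannon = sh, simpson = si,
                    observed_asvs = obs, faith_pd = pd,
                    row.names = NULL)
  out[empty, c("shannon", "simpson", "observed_asvs", "faith_pd")] <- NA
  out
}

# tip sets of the left/right child of every internal node, in preorder
.philr_basis <- function(tree) {
  ntip <- length(tree$tip.label)
  if (!ape::is.binary(tree)) stop("tree must be binary for the PhILR basis")
  tree <- stats::reorder(tree, "cladewise")
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  # postorder accumulation of descendant tip sets
  po <- stats::reorder(tree, "postorder")$edge
  for (r in seq_len(nrow(po))) {
    p <- po[r, 1]; ch <- po[r, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  # internal nodes in preorder of appearance (cladewise edge matrix)
  internals <- unique(tree$edge[, 1])
  lapply(internals, function(nd) {
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    list(node = nd, left = desc[[ch[1]]], right = desc[[ch[2]]])
  })
}

#' Phylogenetic isometric log-ratio (PhILR) transform
#'
#' Zero counts are handled by adding a pseudocount to every cell before
#' closure. For each internal node of the rooted binary phylogeny with left
#' tip set L (size r) and right tip set R (size s), the balance is
#' sqrt(rs/(r+s)) * ln(gmean(x_L) / gmean(x_R)). Coordinates are ordered by
#' a deterministic preorder traversal; multifurcations must be resolved
#' beforehand (see [resolve_multifurcations()]).
#'
#' @param counts Samples x ASVs matrix (counts or proportions).
#' @param tree Rooted binary `phylo`; tips must match the ASV columns.
#' @param pseudocount Added to every cell before closure (default 1).
#' @return Samples x (tips - 1) balance matrix, columns named `n<node>`.
#' @export
philr_transform <- function(counts, tree, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (!setequal(colnames(counts), tree$tip.label)) {
    stop("count columns and tree tips must match")
  }
  counts <- counts[, tree$tip.label, drop = FALSE]
  x <- counts + pseudocount
  x <- close_rows(x)
  lx <- log(x)
  basis <- .philr_basis(tree)
  out <- vapply(basis, function(b) {
    r <- length(b$left); s <- length(b$right)
    gl <- rowMeans(lx[, b$left, drop = FALSE])
    gr <- rowMeans(lx[, b$right, drop = FALSE])
    sqrt(r * s / (r + s)) * (gl - gr)
  }, numeric(nrow(x)))
  if (nrow(x) == 1) out <- matrix(out, nrow = 1)
  dimnames(out) <- list(rownames(counts),
                        paste0("n", vapply(basis, `[[`, 0L, "node")))
  out
}

#' Resolve multifurcations deterministically
#'
#' Expands every multifurcation into a left-branching series of zero-length
#' internal edges, with children taken in tip-lexicographic order, so the
#' resolution is reproducible across platforms.
#'
#' @param tree A rooted `phylo`.
#' @return A rooted binary `phylo`.
#' @export
resolve_multifurcations <- function(tree) {
  if (ape::is.binary(tree)) return(tree)
  tree <- ape::rotateConstr(tree, sort(tree$tip.label))
  ape::multi2di(tree, random = FALSE)
}

#' PERMANOVA on a distance matrix
#'
#' Pseudo-F from the partition of squared inter-point distances into
#' within- and between-group sums; the p-value is
#' (1 + #permutations with F >= F_obs) / (1 + n_perm) under random label
#' permutation.
#'
#' @param dist `dist` or square distance matrix.
#' @param groups Group label per point (>= 2 groups, each >= 2 members).
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed.
#' @return List with `pseudo_F`, `p`, `df` and the permuted statistics.
#' @export
permanova <- function(dist, groups, n_perm = 999L, seed = 1L) {
  d2 <- as.matrix(dist)^2
  groups <- factor(groups)
  n <- nrow(d2)
  stopifnot(length(groups) == n)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 members")
  k <- nlevels(groups)
  sst <- sum(d2) / (2 * n)
  fstat <- function(lab) {
    ssw <- 0
    for (g in levels(groups)) {
      idx <- which(lab == g)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- fstat(groups)
  set.seed(seed)
  f_perm <- vapply(seq_len(n_perm), function(i) fstat(sample(groups)),
                   numeric(1))
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  list(pseudo_F = f_obs, p = p, df = c(k - 1L, n - k), f_perm = f_perm)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries; the p-value comes
#' from joint row/column permutation of the second matrix.
#'
#' @param d1,d2 `dist` objects or square matrices over the same ids in the
#'   same order.
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed.
#' @return List with `r` and `p`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = 1L) {
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop("mismatched ids between the two distance matrices")
  }
  if (nrow(m1) != nrow(m2)) stop("mismatched sizes")
  ut <- upper.tri(m1)
  r_obs <- stats::cor(m1[ut], m2[ut])
  set.seed(seed)
  n <- nrow(m1)
  r_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(m1[ut], m2[p, p][ut])
  }, numeric(1))
  p <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  list(r = r_obs, p = p)
}

# least-squares Procrustes residual m2 of Y superimposed on X
.procrustes_m2 <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  d <- min(ncol(Xc), ncol(Yc))
  Xc <- cbind(Xc, matrix(0, nrow(Xc), max(0, d - ncol(Xc))))
  Yc <- cbind(Yc, matrix(0, nrow(Yc), max(0, d - ncol(Yc))))
  sv <- svd(crossprod(Xc, Yc))$d
  ssx <- sum(Xc^2); ssy <- sum(Yc^2)
  if (ssx == 0 || ssy == 0) stop("rank-0 configuration")
  1 - sum(sv)^2 / (ssx * ssy)
}

#' Procrustes test between two ordinations
#'
#' Optimal translation/scaling/rotation of `Y` onto `X`; m2 is the
#' normalised residual sum of squares (0 = exact superposition). The
#' p-value permutes the rows of `Y`.
#'
#' @param X,Y Coordinate matrices with matching rows.
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed.
#' @return List with `m2` and `p`.
#' @export
procrustes_test <- function(X, Y, n_perm = 999L, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  m2_obs <- .procrustes_m2(X, Y)
  set.seed(seed)
  m2_perm <- vapply(seq_len(n_perm), function(i) {
    .procrustes_m2(X, Y[sample.int(nrow(Y)), , drop = FALSE])
  }, numeric(1))
  p <- (1 + sum(m2_perm <= m2_obs)) / (1 + n_perm)
  list(m2 = m2_obs, p = p)
}

#' Linear discriminant scores of ordination coordinates
#'
#' Coordinates are first reduced by PCA to the components explaining 95% of
#' the variance (a singularity guard), then Fisher discriminant axes (at
#' most one fewer than the number of classes) are fitted and per-sample
#' scores returned with a deterministic sign convention (the first loading
#' of each axis is nonnegative).
#'
#' @param coords Samples x coordinates matrix (e.g. PhILR balances).
#' @param labels Class label per sample (each class >= 2 samples).
#' @param var_explained PCA variance fraction retained (default 0.95).
#' @return Samples x axes score matrix.
#' @export
lda_scores <- function(coords, labels, var_explained = 0.95) {
  coords <- as.matrix(coords)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 classes")
  if (any(table(labels) < 2)) stop("every class needs >= 2 samples")
  pc <- stats::prcomp(coords, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- max(which(cum >= var_explained)[1], nlevels(labels) - 1)
  ncomp <- min(ncomp, ncol(pc$x), nrow(coords) - nlevels(labels))
  red <- pc$x[, seq_len(ncomp), drop = FALSE]
  fit <- MASS::lda(red, grouping = labels)
  sc <- predict(fit, red)$x
  flip <- ifelse(fit$scaling[1, ] < 0, -1, 1)
  sweep(sc, 2, flip, "*")
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement; input order is
#' preserved.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must be in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Cluster-specific differential ASVs
#'
#' For each pairwise cluster contrast, relative abundances are compared by
#' a two-sided Wilcoxon rank-sum test; p-values are BH-adjusted within the
#' contrast; log2 fold change is log2((mean_A + eps) / (mean_B + eps)) of
#' mean relative abundances. An ASV is cluster-specific when it passes
#' FDR < `fdr_alpha` and |log2FC| > `log2fc_min` in at least one contrast.
#'
#' @param counts Rarefied samples x ASVs matrix.
#' @param labels Cluster label per sample (>= 2 clusters, each with >= 3
#'   samples; the three-cluster design gives the contrasts 1v2, 1v3, 2v3).
#' @param fdr_alpha BH threshold (default 0.05).
#' @param log2fc_min Absolute log2 fold-change threshold (default 1).
#' @param eps Stabiliser in the fold change (default 1e-6).
#' @return A `differential_features` list: `contrasts` (named list of
#'   per-ASV data frames), `cluster_specific` (character vector),
#'   `per_contrast_counts`.
#' @export
differential_asvs <- function(counts, labels, fdr_alpha = 0.05,
                              log2fc_min = 1, eps = 1e-6) {
  counts <- as.matrix(counts)
  labels <- as.integer(factor(labels))
  k <- length(unique(labels))
  if (k < 2) stop("need >= 2 clusters")
  if (any(table(labels) < 3)) stop("every cluster needs >= 3 samples")
  rel <- close_rows(counts)
  pairs <- utils::combn(k, 2, simplify = FALSE)
  contrasts <- list()
  for (pr in pairs) {
    ia <- labels == pr[1]; ib <- labels == pr[2]
    pvals <- apply(rel, 2, function(x) {
      suppressWarnings(stats::wilcox.test(x[ia], x[ib])$p.value)
    })
    pvals[is.na(pvals)] <- 1  # all-tied columns carry no evidence
    ma <- colMeans(rel[ia, , drop = FALSE])
    mb <- colMeans(rel[ib, , drop = FALSE])
    lfc <- log2((ma + eps) / (mb + eps))
    q <- bh_adjust(pvals)
    contrasts[[paste0(pr[1], "v", pr[2])]] <- data.frame(
      asv_id = colnames(rel), p = pvals, fdr_q = q, log2fc = lfc,
      direction = ifelse(lfc > 0, paste0("up_in_", pr[1]),
                         paste0("up_in_", pr[2])),
      significant = q < fdr_alpha & abs(lfc) > log2fc_min,
      row.names = NULL)
  }
  sig_sets <- lapply(contrasts, function(df) df$asv_id[df$significant])
  structure(list(contrasts = contrasts,
                 cluster_specific = sort(Reduce(union, sig_sets)),
                 per_contrast_counts = lengths(sig_sets)),
            class = "differential_features")
}

#' @export
print.differential_features <- function(x, ...) {
  cat("differential ASVs per contrast:",
      paste(names(x$per_contrast_counts), x$per_contrast_counts,
            sep = "=", collapse = ", "),
      "\n  union (cluster-specific):", length(x$cluster_specific), "\n")
  invisible(x)
}
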