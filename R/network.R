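# Per-cluster co-abundance networks from Pearson correlations of prevalent
# ASVs, topology comparison between clusters, and co-abundance groups
# (CAGs) from Ward clustering of the correlation distance with a
# PERMANOVA-gated top-down split recursion.

# two-sided p-value of a Pearson correlation via the t distribution
.cor_pvals <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Build a co-abundance network for one cluster
#'
#' Nodes are ASVs present (count > 0) in strictly more than
#' `prevalence_min` of the cluster's samples. Every node pair is scored by
#' the Pearson correlation of relative abundances with a two-sided t-test
#' p-value; p-values are BH-adjusted across all tested pairs and edges with
#' q < `q_max` are retained.
#'
#' @param counts Rarefied counts restricted to the cluster's samples
#'   (samples x ASVs; >= 10 samples).
#' @param prevalence_min Strict prevalence threshold (default 0.20).
#' @param q_max BH threshold for edges (default 0.05).
#' @param cluster_id Optional identifier carried in the result.
#' @return A `coabundance_network`: list with `cluster_id`, `nodes`,
#'   `edges` (data frame asv_a, asv_b, r, p, q, sign), `topology` (n_nodes,
#'   n_edges, density, degree_centrality).
#' @export
build_network <- function(counts, prevalence_min = 0.20, q_max = 0.05,
                          cluster_id = NA) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (n < 10) stop("need >= 10 samples to build a network")
  prev <- colMeans(counts > 0)
  nodes <- sort(colnames(counts)[prev > prevalence_min])
  if (length(nodes) < 2) stop("fewer than 2 prevalent ASVs")
  rel <- close_rows(counts)[, nodes, drop = FALSE]
  cm <- stats::cor(rel)
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[ut]
  p <- .cor_pvals(r, n)
  q <- bh_adjust(p)
  keep <- q < q_max
  edges <- data.frame(asv_a = nodes[ut[keep, 1]],
                      asv_b = nodes[ut[keep, 2]],
                      r = r[keep], p = p[keep], q = q[keep],
                      sign = ifelse(r[keep] >= 0, "positive", "negative"),
                      row.names = NULL)
  nn <- length(nodes)
  deg <- stats::setNames(numeric(nn), nodes)
  if (nrow(edges) > 0) {
    tab <- table(c(edges$asv_a, edges$asv_b))
    deg[names(tab)] <- as.numeric(tab)
  }
  structure(list(cluster_id = cluster_id, nodes = nodes, edges = edges,
                 topology = list(
                   n_nodes = nn,
                   n_edges = nrow(edges),
                   density = network_density(nn, nrow(edges)),
                   degree_centrality = deg / (nn - 1))),
            class = "coabundance_network")
}

#' Network density
#'
#' Ratio of actual to possible edges of a simple undirected graph:
#' `n_edges / (n_nodes * (n_nodes - 1) / 2)`.
#'
#' @param n_nodes,n_edges Node and edge counts.
#' @return Density in \[0, 1\].
#' @export
network_density <- function(n_nodes, n_edges) {
  n_edges / (n_nodes * (n_nodes - 1) / 2)
}

#' @export
print.coabundance_network <- function(x, ...) {
  cat("co-abundance network (cluster ", x$cluster_id, "): ",
      x$topology$n_nodes, " nodes, ", x$topology$n_edges,
      " edges, density ", round(x$topology$density, 3), "\n", sep = "")
  invisible(x)
}

#' Compare network topologies by degree-centrality distributions
#'
#' Two-sided two-sample Kolmogorov-Smirnov tests between the
#' degree-centrality distributions of each pair of networks.
#'
#' @param networks List of `coabundance_network` objects.
#' @return Data frame with columns `network_a`, `network_b`, `ks_stat`,
#'   `p`.
#' @export
compare_topology <- function(networks) {
  stopifnot(length(networks) >= 2)
  ids <- vapply(seq_along(networks), function(i) {
    id <- networks[[i]]$cluster_id
    if (is.na(id)) as.character(i) else as.character(id)
  }, character(1))
  prs <- utils::combn(length(networks), 2)
  out <- data.frame()
  for (j in seq_len(ncol(prs))) {
    a <- prs[1, j]; b <- prs[2, j]
    da <- networks[[a]]$topology$degree_centrality
    db <- networks[[b]]$topology$degree_centrality
    ks <- suppressWarnings(stats::ks.test(da, db))
    out <- rbind(out, data.frame(network_a = ids[a], network_b = ids[b],
                                 ks_stat = unname(ks$statistic),
                                 p = ks$p.value))
  }
  out
}

# recursive PERMANOVA-gated cut of an hclust tree into CAGs
.cag_cut <- function(merge, members_of, d, node, alpha, n_perm, seed_pool) {
  members <- members_of(node)
  if (length(members) < 3) return(list(members))
  kids <- merge[node, ]
  left <- members_of(kids[1])
  right <- members_of(kids[2])
  if (length(left) < 2 || length(right) < 2) {
    # a singleton daughter cannot be PERMANOVA-tested: conservative merge
    return(list(members))
  }
  lab <- c(rep(1L, length(left)), rep(2L, length(right)))
  idx <- c(left, right)
  pv <- permanova(d[idx, idx], lab, n_perm = n_perm,
                  seed = seed_pool[abs(node) %% length(seed_pool) + 1L])$p
  if (pv < alpha) {
    c(.cag_cut(merge, members_of, d, kids[1], alpha, n_perm, seed_pool),
      .cag_cut(merge, members_of, d, kids[2], alpha, n_perm, seed_pool))
  } else {
    list(members)
  }
}

#' Co-abundance groups (CAGs) from a node universe
#'
#' Pearson correlations among the `node_universe` ASVs are computed across
#' all samples; the signed correlation distance d = 1 - r is clustered with
#' Ward linkage (ward.D2). From the root down, each split is kept only when
#' a PERMANOVA of the two daughter clades on the distance submatrix rejects
#' at `cag_alpha`; otherwise the clade becomes one CAG. Clades with fewer
#' than 3 members become CAGs without testing.
#'
#' @param counts Rarefied counts over all samples (samples x ASVs).
#' @param node_universe ASV ids to cluster (e.g. the union of network
#'   nodes).
#' @param n_perm PERMANOVA permutations (>= 99).
#' @param cag_alpha Split acceptance threshold (default 0.01).
#' @param seed RNG seed.
#' @return A `cag_set`: list with `membership` (named integer vector ASV ->
#'   CAG), `n_cags`, `tree` (the hclust object).
#' @export
build_cags <- function(counts, node_universe, n_perm = 999L,
                       cag_alpha = 0.01, seed = 1L) {
  if (n_perm < 99) stop("n_perm too low for the requested alpha")
  counts <- as.matrix(counts)
  node_universe <- sort(unique(node_universe))
  miss <- setdiff(node_universe, colnames(counts))
  if (length(miss)) stop("node universe ASVs absent from counts: ",
                         paste(miss, collapse = ", "))
  rel <- close_rows(counts)[, node_universe, drop = FALSE]
  if (length(node_universe) < 3) {
    membership <- stats::setNames(rep(1L, length(node_universe)),
                                  node_universe)
    return(structure(list(membership = membership, n_cags = 1L, tree = NULL),
                     class = "cag_set"))
  }
  d <- 1 - stats::cor(rel)
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  m <- length(node_universe)
  # members_of(i): leaves under hclust node i (negative = leaf index)
  memb_cache <- vector("list", m - 1)
  members_of <- function(node) {
    if (node < 0) return(-node)
    if (!is.null(memb_cache[[node]])) return(memb_cache[[node]])
    res <- c(members_of(hc$merge[node, 1]), members_of(hc$merge[node, 2]))
    memb_cache[[node]] <<- res
    res
  }
  seed_pool <- derive_seeds(seed, 1024L)
  groups <- .cag_cut(hc$merge, members_of, d, m - 1L, cag_alpha, n_perm,
                     seed_pool)
  membership <- integer(m)
  for (i in seq_along(groups)) membership[groups[[i]]] <- i
  # deterministic CAG ids: number by first member in lexicographic order
  first <- vapply(split(seq_len(m), membership),
                  function(ix) min(node_universe[ix]), character(1))
  relab <- match(membership, order(first))
  relab <- as.integer(factor(relab, levels = sort(unique(relab))))
  membership <- stats::setNames(relab, node_universe)
  structure(list(membership = membership,
                 n_cags = length(groups), tree = hc),
            class = "cag_set")
}

#' @export
print.cag_set <- function(x, ...) {
  cat("cag_set:", x$n_cags, "CAGs over", length(x$membership), "ASVs\n")
  invisible(x)
}

#' Scaled mean CAG abundance per cluster
#'
#' CAG abundance per sample is the sum of its members' relative abundances;
#' per-cluster means are z-scaled across clusters within each CAG.
#'
#' @param counts Samples x ASVs counts.
#' @param cag_membership Named vector ASV -> CAG id.
#' @param labels Cluster label per sample.
#' @return List with `per_sample` (samples x CAGs), `cluster_means`, and
#'   `scaled_means` (CAG x cluster).
#' @export
summarize_cag_abundance <- function(counts, cag_membership, labels) {
  counts <- as.matrix(counts)
  asvs <- intersect(names(cag_membership), colnames(counts))
  rel <- close_rows(counts)
  cags <- sort(unique(cag_membership[asvs]))
  per_sample <- vapply(cags, function(cg) {
    rowSums(rel[, asvs[cag_membership[asvs] == cg], drop = FALSE])
  }, numeric(nrow(counts)))
  if (nrow(counts) == 1) per_sample <- matrix(per_sample, nrow = 1)
  colnames(per_sample) <- paste0("CAG", cags)
  labels <- factor(labels)
  cluster_means <- t(vapply(levels(labels), function(g) {
    colMeans(per_sample[labels == g, , drop = FALSE])
  }, numeric(ncol(per_sample))))
  scaled <- apply(cluster_means, 2, function(x) {
    if (stats::sd(x) == 0) rep(0, length(x)) else (x - mean(x)) / stats::sd(x)
  })
  rownames(scaled) <- rownames(cluster_means)
  list(per_sample = per_sample, cluster_means = cluster_means,
       scaled_means = t(scaled))
}
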