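# K-medoids stratification: PAM on Euclidean distances of the standardized
# clinical matrix, silhouette-based selection of k, bootstrap Jaccard
# stability, and nearest-center assignment of new cohorts.

#' Partitioning Around Medoids on a distance matrix
#'
#' PAM with greedy BUILD initialisation followed by best-improvement SWAP
#' iterated to a local optimum (no single medoid/non-medoid exchange lowers
#' the total within-cluster dissimilarity). Ties in BUILD, SWAP and point
#' assignment break toward the lowest row index.
#'
#' @param dist A `dist` object or square symmetric matrix with zero diagonal.
#' @param k Number of medoids, 2 <= k < n.
#' @return List with `medoid_ids` (row indices or names), `labels` (cluster
#'   index per point, medoids sorted ascending), `total_cost`.
#' @export
pam_cluster <- function(dist, k) {
  d <- as.matrix(dist)
  if (anyNA(d)) stop("distance matrix contains NA")
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix must be square and symmetric")
  }
  fit <- .pam_fit_cpp(d, as.integer(k))
  ids <- if (!is.null(rownames(d))) rownames(d)[fit$medoids] else fit$medoids
  list(medoid_ids = ids, medoid_idx = fit$medoids,
       labels = fit$labels, total_cost = fit$cost)
}

#' Mean silhouette width of a clustering
#'
#' s_i = (b_i - a_i) / max(a_i, b_i), where a_i is the mean distance of point
#' i to its own cluster and b_i the smallest mean distance to another
#' cluster; members of singleton clusters contribute 0.
#'
#' @param dist `dist` or square distance matrix.
#' @param labels Cluster index per point (>= 2 nonempty clusters).
#' @return Mean silhouette width.
#' @export
silhouette_mean <- function(dist, labels) {
  d <- as.matrix(dist)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("need at least 2 clusters")
  n <- nrow(d)
  sizes <- tabulate(labels, k)
  # mean distance of each point to each cluster
  agg <- matrix(0, n, k)
  for (g in seq_len(k)) {
    agg[, g] <- rowSums(d[, labels == g, drop = FALSE])
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    g <- labels[i]
    if (sizes[g] == 1) { s[i] <- 0; next }
    a <- agg[i, g] / (sizes[g] - 1)
    b <- min(agg[i, -g] / sizes[-g])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Fit the k-medoids stratification model
#'
#' Runs PAM on Euclidean distances of the standardized matrix for each
#' candidate k, selects the k with maximal mean silhouette width (ties to
#' the smallest k), computes bootstrap Jaccard stability of the selected
#' clustering, and derives cluster centers (per-cluster medians of the
#' shared variables) for out-of-sample assignment. Clusters are renumbered
#' by ascending mean glucose AUC of their members when `glucose_auc` is
#' available, so cluster 1 is always the best-glycemia cluster.
#'
#' @param matrix A `strat_matrix` from [build_stratification_matrix()].
#' @param k_range Integer pair of candidate k (default c(2, 20)).
#' @param n_bootstrap Bootstrap resamples for stability (default 100; 0
#'   skips the stability assessment).
#' @param seed RNG seed for the bootstrap.
#' @param glucose_auc Optional named vector (participant id -> glucose AUC)
#'   used to order clusters.
#' @param center_variables Variables used for out-of-sample centers (default
#'   the 14 shared with the testing cohort).
#' @return A `strat_fit` object.
#' @export
stratify_cohort <- function(matrix, k_range = c(2L, 20L), n_bootstrap = 100L,
                            seed = 1L, glucose_auc = NULL,
                            center_variables = SHARED_VARIABLES) {
  z <- matrix$z
  n <- nrow(z)
  ks <- seq.int(max(2L, k_range[1]), min(k_range[2], n - 1L))
  d <- stats::dist(z)
  dm <- as.matrix(d)
  sil <- stats::setNames(numeric(length(ks)), ks)
  fits <- vector("list", length(ks))
  for (j in seq_along(ks)) {
    fits[[j]] <- pam_cluster(dm, ks[j])
    sil[j] <- silhouette_mean(dm, fits[[j]]$labels)
  }
  best <- which.max(sil)            # which.max takes the first (smallest k)
  k <- ks[best]
  fit <- fits[[best]]
  if (max(sil) < 0.25) {
    glyco_log("weak cluster structure: best mean silhouette ",
              round(max(sil), 3))
  }
  labels <- fit$labels
  # deterministic cluster semantics: ascending mean glucose AUC
  if (!is.null(glucose_auc)) {
    auc <- glucose_auc[rownames(z)]
    ord <- order(vapply(seq_len(k), function(g) {
      mean(auc[labels == g], na.rm = TRUE)
    }, numeric(1)))
    relab <- integer(k)
    relab[ord] <- seq_len(k)
    labels <- relab[labels]
    fit$medoid_idx <- fit$medoid_idx[ord]
    fit$medoid_ids <- fit$medoid_ids[ord]
  }
  names(labels) <- rownames(z)
  stability <- if (n_bootstrap > 0) {
    bootstrap_stability(matrix, k = k, B = n_bootstrap, seed = seed,
                        labels = labels)
  } else stats::setNames(rep(NA_real_, k), paste0("cluster", seq_len(k)))
  shared <- intersect(colnames(z), center_variables)
  centers <- t(vapply(seq_len(k), function(g) {
    apply(z[labels == g, shared, drop = FALSE], 2, stats::median)
  }, numeric(length(shared))))
  rownames(centers) <- paste0("cluster", seq_len(k))
  structure(list(k = k,
                 medoid_ids = fit$medoid_ids,
                 labels = labels,
                 silhouette_by_k = sil,
                 jaccard_stability = stability,
                 total_cost = fit$total_cost,
                 centers = centers,
                 center_variables = shared,
                 scaling = list(center = matrix$center[shared],
                                scale = matrix$scale[shared]),
                 excluded = matrix$excluded,
                 outlier_z = 5),
            class = "strat_fit")
}

#' Bootstrap Jaccard stability of a PAM clustering
#'
#' For each of B bootstrap resamples (with replacement), the resampled
#' points are reclustered with PAM(k); each original cluster is matched to
#' the bootstrap cluster maximising the Jaccard similarity of member sets
#' (computed on the unique original points present in the resample), and the
#' per-cluster mean over resamples is reported. Means above 0.7 are
#' conventionally read as stable.
#'
#' @param matrix A `strat_matrix`.
#' @param k Number of clusters.
#' @param B Number of bootstrap resamples (>= 20).
#' @param seed RNG seed.
#' @param labels Optional reference labels (defaults to a fresh PAM fit).
#' @return Named numeric vector of per-cluster mean Jaccard coefficients.
#' @export
bootstrap_stability <- function(matrix, k, B = 100L, seed = 1L,
                                labels = NULL) {
  stopifnot(B >= 20)
  z <- matrix$z
  n <- nrow(z)
  dm <- as.matrix(stats::dist(z))
  if (is.null(labels)) labels <- pam_cluster(dm, k)$labels
  labels <- as.integer(factor(labels))
  set.seed(seed)
  jac <- matrix(NA_real_, B, k)
  b <- 1L
  while (b <= B) {
    idx <- sample.int(n, n, replace = TRUE)
    uniq <- unique(idx)
    if (length(uniq) <= k) {  # degenerate resample: redraw
      glyco_log("degenerate bootstrap resample redrawn")
      next
    }
    sub <- dm[idx, idx, drop = FALSE]
    bl <- pam_cluster(sub, k)$labels
    # labels of the unique original points present in this resample
    first_pos <- match(uniq, idx)
    bl_u <- bl[first_pos]
    for (g in seq_len(k)) {
      orig <- uniq[labels[uniq] == g]
      if (length(orig) == 0) { jac[b, g] <- 0; next }
      best <- 0
      for (h in seq_len(max(bl_u))) {
        boot <- uniq[bl_u == h]
        j <- length(intersect(orig, boot)) / length(union(orig, boot))
        if (j > best) best <- j
      }
      jac[b, g] <- best
    }
    b <- b + 1L
  }
  stats::setNames(colMeans(jac), paste0("cluster", seq_len(k)))
}

#' @export
print.strat_fit <- function(x, ...) {
  cat("k-medoids stratification (PAM)\n")
  cat("  clusters:", x$k, " participants:", length(x$labels), "\n")
  cat("  mean silhouette:", round(max(x$silhouette_by_k), 3), "\n")
  cat("  cluster sizes:", paste(tabulate(x$labels, x$k), collapse = "/"), "\n")
  cat("  Jaccard stability:",
      paste(round(x$jaccard_stability, 2), collapse = "/"), "\n")
  invisible(x)
}

#' @export
summary.strat_fit <- function(object, ...) {
  sizes <- tabulate(object$labels, object$k)
  out <- list(k = object$k, sizes = sizes,
              silhouette_by_k = object$silhouette_by_k,
              jaccard_stability = object$jaccard_stability,
              stable = object$jaccard_stability > 0.7,
              n_excluded = nrow(object$excluded),
              total_cost = object$total_cost)
  class(out) <- "summary.strat_fit"
  out
}

#' @export
print.summary.strat_fit <- function(x, ...) {
  cat("Selected k =", x$k, "(max mean silhouette =",
      round(max(x$silhouette_by_k), 3), ")\n")
  cat("Cluster sizes:", paste(x$sizes, collapse = "/"), "\n")
  cat("Stability (bootstrap Jaccard):",
      paste(sprintf("%.2f%s", x$jaccard_stability,
                    ifelse(x$stable, "*", "")), collapse = " "),
      " (* > 0.7)\n")
  cat("Excluded participants:", x$n_excluded, "\n")
  cat("Silhouette profile:\n")
  print(round(x$silhouette_by_k, 3))
  invisible(x)
}

#' Silhouette profile plot of a stratification fit
#'
#' @param x A `strat_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.strat_fit <- function(x, ...) {
  ks <- as.integer(names(x$silhouette_by_k))
  plot(ks, x$silhouette_by_k, type = "b", pch = 19,
       xlab = "number of clusters k", ylab = "mean silhouette width", ...)
  graphics::abline(v = x$k, lty = 2)
  invisible(x)
}

#' Assign new participants to fitted cluster centers
#'
#' Standardizes the test cohort with the discovery means/SDs, drops rows
#' with missing shared variables or any |z| >= `outlier_z`, and assigns each
#' retained participant to the nearest center by Euclidean distance (ties to
#' the lowest cluster index).
#'
#' @param object A `strat_fit`.
#' @param newdata A `clinical_table` containing the shared variables.
#' @param outlier_z Exclusion threshold (default the fit's, 5).
#' @param ... Unused.
#' @return Named integer vector of cluster labels for retained participants;
#'   excluded ids in attribute `excluded`.
#' @export
predict.strat_fit <- function(object, newdata, outlier_z = object$outlier_z,
                              ...) {
  vars <- object$center_variables
  miss <- setdiff(vars, names(newdata))
  if (length(miss)) stop("test table lacks variables: ",
                         paste(miss, collapse = ", "))
  x <- as.matrix(newdata[, vars])
  rownames(x) <- newdata$participant_id
  z <- scale(x, center = object$scaling$center, scale = object$scaling$scale)
  cc <- stats::complete.cases(z)
  out_rows <- cc & apply(abs(z) >= outlier_z, 1, any)
  keep <- cc & !out_rows
  excluded <- data.frame(
    participant_id = rownames(x)[!keep],
    reason = ifelse(out_rows[!keep], "outlier", "missing"))
  zk <- z[keep, , drop = FALSE]
  # squared distances to each center
  d2 <- outer(rowSums(zk^2), rowSums(object$centers^2), "+") -
    2 * zk %*% t(object$centers)
  lab <- apply(round(d2, 12), 1, which.min)  # round so exact ties go low
  structure(stats::setNames(as.integer(lab), rownames(zk)),
            excluded = excluded)
}
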