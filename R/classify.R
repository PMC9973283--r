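# One-vs-rest random-forest classifiers on the cluster-specific ASV panel,
# scored by leave-one-out cross-validation with ROC/AUC.

#' Trapezoidal ROC AUC
#'
#' Computed as the normalised Mann-Whitney U statistic (ties counted half),
#' which equals the area under the tie-aware ROC staircase.
#'
#' @param scores Numeric classifier scores, higher = more positive.
#' @param labels Logical or 0/1 vector, `TRUE`/1 = positive.
#' @return AUC in \[0, 1\].
#' @export
auc_trapezoid <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# tie-aware ROC staircase from held-out scores
.roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # aggregate tie groups so tied scores form one diagonal segment
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(tapply(l, grp, sum)[unique(grp)])
  fp <- cumsum(tapply(!l, grp, sum)[unique(grp)])
  data.frame(fpr = c(0, unname(fp) / sum(!labels)),
             tpr = c(0, unname(tp) / sum(labels)))
}

#' Random-forest leave-one-out cross-validation for one cluster
#'
#' For each sample, a random forest is trained on all other samples
#' (bootstrap per tree, sqrt(p) features per split) with a per-fold seed
#' derived from the master seed, and the held-out sample's positive-class
#' probability is recorded. The ROC staircase and trapezoidal AUC are
#' computed over the held-out probabilities; the AUC is cross-checked
#' against the Mann-Whitney form on every run.
#'
#' @param features Samples x features matrix (e.g. relative abundances of
#'   the cluster-specific ASVs).
#' @param labels Binary one-vs-rest labels (logical or 0/1; >= 5 of each).
#' @param n_trees Trees per forest (default 500).
#' @param seed Master seed; per-fold seeds are derived from it.
#' @return A `classifier_report`: list with `probabilities`, `roc_points`,
#'   `auc`, `n_trees`, `seed`.
#' @export
rf_loocv <- function(features, labels, n_trees = 500L, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.logical(labels)
  n <- nrow(features)
  stopifnot(length(labels) == n)
  if (sum(labels) < 5 || sum(!labels) < 5) {
    stop("need >= 5 positives and >= 5 negatives")
  }
  y <- factor(ifelse(labels, "pos", "neg"), levels = c("neg", "pos"))
  fold_seeds <- derive_seeds(seed, n)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(fold_seeds[i])
    fit <- randomForest::randomForest(features[-i, , drop = FALSE], y[-i],
                                      ntree = n_trees)
    probs[i] <- predict(fit, features[i, , drop = FALSE],
                        type = "prob")[, "pos"]
  }
  names(probs) <- rownames(features)
  auc <- auc_trapezoid(probs, labels)
  roc <- .roc_points(probs, labels)
  # internal cross-check: staircase area must equal the U form
  trap <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  stopifnot(abs(trap - auc) < 1e-10)
  structure(list(probabilities = probs, labels = labels, roc_points = roc,
                 auc = auc, n_trees = n_trees, seed = seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("random-forest LOOCV:", length(x$probabilities), "samples,",
      x$n_trees, "trees; AUC =", round(x$auc, 3), "\n")
  invisible(x)
}

#' One-vs-rest classifier reports for every cluster
#'
#' @param features Samples x features matrix.
#' @param labels Cluster label per sample.
#' @param n_trees Trees per forest (default 500).
#' @param seed Master seed (one sub-seed per cluster model).
#' @return Named list of `classifier_report`s, one per cluster.
#' @export
rf_one_vs_rest <- function(features, labels, n_trees = 500L, seed = 1L) {
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  seeds <- derive_seeds(seed, length(ks))
  out <- list()
  for (j in seq_along(ks)) {
    pos <- sum(labels == ks[j]); neg <- sum(labels != ks[j])
    if (pos < 5 || neg < 5) {
      glyco_log("skipping one-vs-rest model for cluster ", ks[j],
                ": too few samples (", pos, " vs ", neg, ")")
      next
    }
    out[[paste0("cluster", ks[j])]] <-
      rf_loocv(features, labels == ks[j], n_trees = n_trees, seed = seeds[j])
  }
  out
}
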