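# Feature-phenotype association: arcsine-square-root transformed relative
# abundances in per-pair ordinary linear models with age and gender as
# covariates, plus the generic group tests used on clinical variables and
# the compact letter display for pairwise FDR results.

#' Associate microbiome features with clinical variables
#'
#' For every (feature, variable) pair, fits
#' `asin(sqrt(abundance)) ~ variable + age + gender` by OLS on complete
#' cases, with continuous predictors z-scored and gender coded 0/1
#' (female = 0). The p-value of the variable coefficient is BH-adjusted
#' across all pairs; pairs with q below `assoc_q` are flagged significant.
#'
#' @param features Samples x features relative-abundance matrix (values in
#'   \[0, 1\]), rows aligned with `metadata` participant ids.
#' @param metadata Clinical table containing `variables`, `age`, `gender`.
#' @param variables Clinical variable names to test.
#' @param assoc_q Significance threshold on q (default 0.25).
#' @return Data frame with feature_id, variable, coefficient, p, q, n_used,
#'   significant.
#' @export
associate_features <- function(features, metadata, variables,
                               assoc_q = 0.25) {
  features <- as.matrix(features)
  if (any(features < 0 | features > 1, na.rm = TRUE)) {
    stop("features must be relative abundances in [0, 1]")
  }
  ids <- metadata$participant_id
  if (!is.null(rownames(features))) {
    common <- intersect(rownames(features), ids)
    features <- features[common, , drop = FALSE]
    metadata <- metadata[match(common, ids), , drop = FALSE]
  } else if (nrow(features) != nrow(metadata)) {
    stop("features rows do not align with metadata")
  }
  miss <- setdiff(c(variables, "age", "gender"), names(metadata))
  if (length(miss)) stop("metadata lacks: ", paste(miss, collapse = ", "))
  gender01 <- ifelse(metadata$gender == "male", 1, 0)
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  rows <- list()
  for (f in colnames(features)) {
    y_all <- asin(sqrt(features[, f]))
    for (v in variables) {
      x_all <- metadata[[v]]
      cc <- stats::complete.cases(y_all, x_all, metadata$age, gender01)
      n_used <- sum(cc)
      if (n_used < 5) next
      x <- x_all[cc]; age <- metadata$age[cc]; g <- gender01[cc]
      if (stats::sd(x) == 0 || stats::sd(y_all[cc]) == 0) {
        glyco_log("skipping ", f, " ~ ", v, ": zero variance")
        next
      }
      dat <- data.frame(y = y_all[cc], x = zs(x), age = zs(age), g = g)
      fit <- stats::lm(y ~ x + age + g, data = dat)
      co <- summary(fit)$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = f, variable = v,
        coefficient = co["x", "Estimate"], p = co["x", "Pr(>|t|)"],
        n_used = n_used)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < assoc_q
  out[order(out$q, out$p), ]
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom; all-tied inputs return H = 0, p = 1.
#'
#' @param values Numeric measurements.
#' @param groups Group label per value (>= 2 groups, each >= 2 members).
#' @return List with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 members")
  if (length(unique(values)) == 1) {
    return(list(H = 0, p = 1, df = nlevels(groups) - 1L))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Pearson chi-square test on a contingency table
#'
#' @param table r x c matrix of counts (no continuity correction).
#' @return List with `X2`, `p`, `df`.
#' @export
chi_square_counts <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be nonnegative")
  if (nrow(table) < 2 || ncol(table) < 2) stop("need at least a 2x2 table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal in contingency table")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(X2 = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter))
}

#' Compact letter display for three-group pairwise FDR results
#'
#' Groups share a letter if and only if their pairwise comparison is not
#' significant (q > `alpha`). Letters are the maximal cliques of the
#' non-significance graph, assigned in group order, which is minimal for
#' three groups.
#'
#' @param pairwise_q Named numeric vector with entries `1-2`, `1-3`, `2-3`.
#' @param alpha Significance threshold (default 0.05).
#' @return Character vector of letter codes for groups 1..3.
#' @export
fdr_letters <- function(pairwise_q, alpha = 0.05) {
  need <- c("1-2", "1-3", "2-3")
  if (!all(need %in% names(pairwise_q))) {
    stop("pairwise_q needs entries ", paste(need, collapse = ", "))
  }
  ns <- function(a, b) pairwise_q[paste(min(a, b), max(a, b), sep = "-")] > alpha
  # maximal cliques of the NS graph over {1,2,3}, in deterministic order
  cliques <- list()
  if (ns(1, 2) && ns(1, 3) && ns(2, 3)) {
    cliques <- list(1:3)
  } else {
    for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
      if (ns(pr[1], pr[2])) cliques[[length(cliques) + 1L]] <- pr
    }
    in_clique <- unique(unlist(cliques))
    for (g in setdiff(1:3, in_clique)) {
      cliques[[length(cliques) + 1L]] <- g
    }
    # order cliques by their smallest member for stable letter assignment
    cliques <- cliques[order(vapply(cliques, min, numeric(1)))]
  }
  letters_out <- character(3)
  for (i in seq_along(cliques)) {
    for (g in cliques[[i]]) {
      letters_out[g] <- paste0(letters_out[g], LETTERS[i])
    }
  }
  letters_out
}
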