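test_that("rarefaction drops shallow samples and hits exact depth", {
  set.seed(1)
  counts <- matrix(rpois(60, 40), 6,
                   dimnames = list(paste0("S", 1:6), paste0("A", 1:10)))
  counts[1, ] <- 1  # total 10, below depth
  expect_message(r <- rarefy_counts(counts, depth = 100, seed = 1),
                 "below depth")
  expect_false("S1" %in% rownames(r))
  expect_true(all(rowSums(r) == 100))
  expect_identical(r, rarefy_counts(counts, depth = 100, seed = 1))
  # a sample exactly at depth passes through unchanged
  counts2 <- counts[-1, , drop = FALSE]
  counts2[1, ] <- 10
  r2 <- rarefy_counts(counts2, depth = 100, seed = 2)
  expect_equal(unname(r2[1, ]), rep(10L, 10))
  expect_error(rarefy_counts(counts[1, , drop = FALSE], depth = 100),
               "below the rarefaction depth")
})

test_that("alpha diversity matches closed forms and picante's Faith PD", {
  x <- matrix(c(rep(5, 8), 0, 0), 1,
              dimnames = list("s", paste0("t", 1:10)))
  tree <- ape::rtree(10, br = stats::rexp)
  tree$tip.label <- paste0("t", 1:10)
  a <- alpha_diversity(x, tree)
  expect_equal(a$shannon, log(8), tolerance = 1e-12)
  expect_equal(a$simpson, 1 - 8 * (1 / 8)^2, tolerance = 1e-12)
  expect_equal(a$observed_asvs, 8)

  one <- matrix(c(7, rep(0, 9)), 1, dimnames = dimnames(x))
  a1 <- alpha_diversity(one, tree)
  expect_equal(a1$shannon, 0)
  expect_equal(a1$simpson, 0)
  expect_equal(a1$observed_asvs, 1)

  # 3-tip star tree, unit branches, two tips present -> PD 2
  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  xs <- matrix(c(3, 1, 0), 1, dimnames = list("s", c("a", "b", "c")))
  expect_equal(unname(faith_pd(xs, star)), 2)

  skip_if_not_installed("picante")
  set.seed(6)
  cm <- matrix(rpois(50, 3), 5, dimnames = list(paste0("s", 1:5),
                                                paste0("t", 1:10)))
  ref <- picante::pd(cm, tree, include.root = TRUE)$PD
  expect_equal(unname(faith_pd(cm, tree)), ref, tolerance = 1e-9)
})

test_that("PhILR balances instantiate the formula and are isometric", {
  # 2-tip tree: single balance sqrt(1/2) * ln(x/y)
  t2 <- ape::read.tree(text = "(a:1,b:1);")
  comp <- matrix(c(3, 1), 1, dimnames = list("s", c("a", "b")))
  b <- philr_transform(comp, t2, pseudocount = 0)
  expect_equal(unname(b[1, 1]), sqrt(0.5) * log(3), tolerance = 1e-12)

  # equal abundances give all-zero balances
  t8 <- ape::rtree(8, br = stats::rexp)
  t8$tip.label <- paste0("t", 1:8)
  eq <- matrix(2, 3, 8, dimnames = list(paste0("s", 1:3), t8$tip.label))
  expect_true(max(abs(philr_transform(eq, t8, pseudocount = 0))) < 1e-12)

  # Euclidean distance on balances equals Aitchison distance (CLR oracle)
  set.seed(12)
  comp2 <- matrix(rexp(20 * 8) + 0.05, 20)
  colnames(comp2) <- t8$tip.label
  bal <- philr_transform(comp2, t8, pseudocount = 0)
  rel <- comp2 / rowSums(comp2)
  clr <- t(apply(rel, 1, function(x) log(x) - mean(log(x))))
  expect_lt(max(abs(dist(bal) - dist(clr))), 1e-8)

  # multifurcations must be resolved first; the resolver is deterministic
  multi <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  expect_error(philr_transform(matrix(1, 1, 4,
                                      dimnames = list("s", c("a", "b", "c", "d"))),
                               multi), "binary")
  r1 <- resolve_multifurcations(multi)
  expect_true(ape::is.binary(r1))
  expect_identical(ape::write.tree(r1),
                   ape::write.tree(resolve_multifurcations(multi)))
})

test_that("PERMANOVA matches vegan and the exhaustive permutation oracle", {
  set.seed(5)
  pts <- matrix(rnorm(12), 6, 2)
  D <- dist(pts)
  g <- rep(1:3, each = 2)
  res <- permanova(D, g, n_perm = 999, seed = 1)

  skip_if_not_installed("vegan")
  ref <- vegan::adonis2(D ~ factor(g), permutations = 2)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-9)

  # exhaustive oracle: all 6! label orderings
  idx <- 1:6
  enumerate <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in enumerate(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  all_orders <- enumerate(idx)
  f_all <- vapply(all_orders, function(o) {
    permanova(D, g[o], n_perm = 1, seed = 1)$pseudo_F
  }, numeric(1))
  p_exact <- mean(f_all >= res$pseudo_F - 1e-12)
  # with all permutations the estimate converges to the exact p
  expect_lt(abs(res$p - p_exact), 0.05)
})

test_that("PERMANOVA detects perfect separation and errors on tiny groups", {
  D <- matrix(1, 6, 6) - diag(6)
  D[1:3, 1:3] <- 0; D[4:6, 4:6] <- 0
  res <- permanova(D, rep(1:2, each = 3), n_perm = 199, seed = 1)
  # no label mixing can beat the observed split: the only permutations
  # reaching F_obs are those that reproduce the partition itself
  mixing <- is.finite(res$f_perm)
  expect_true(all(res$f_perm[mixing] < res$pseudo_F))
  expect_equal(res$p, (1 + sum(!mixing)) / 200)
  expect_lt(res$p, 0.2)
  expect_error(permanova(D, c(1, 1, 1, 1, 1, 2)), ">= 2 members")
})

test_that("Mantel and Procrustes agree with direct computation and vegan", {
  set.seed(8)
  a <- matrix(rnorm(20), 10)
  d1 <- dist(a)
  expect_equal(mantel_test(d1, d1, n_perm = 99, seed = 1)$r, 1)

  b <- matrix(rnorm(20), 10)
  d2 <- dist(b)
  m <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  ut <- upper.tri(as.matrix(d1))
  expect_equal(m$r, cor(as.matrix(d1)[ut], as.matrix(d2)[ut]),
               tolerance = 1e-12)

  # rotated copy superimposes exactly
  th <- pi / 5
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pr <- procrustes_test(a, a %*% rot, n_perm = 99, seed = 1)
  expect_lt(pr$m2, 1e-12)
  expect_equal(pr$p, 1 / 100)

  skip_if_not_installed("vegan")
  ref <- vegan::protest(a, b, permutations = 99)
  expect_equal(procrustes_test(a, b, n_perm = 199, seed = 2)$m2,
               ref$ss, tolerance = 1e-9)
})

test_that("LDA scores separate distinct classes and bound the axis count", {
  set.seed(10)
  x <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 6), 30),
             matrix(rnorm(60, 12), 30))
  lab <- rep(1:3, each = 30)
  sc <- lda_scores(x, lab)
  expect_equal(ncol(sc), 2L)  # classes - 1 axes
  # separation on the first axis far exceeds the pooled within-class SD
  m <- tapply(sc[, 1], lab, mean)
  s <- sqrt(mean(tapply(sc[, 1], lab, var)))
  expect_gt((max(m) - min(m)) / s, 5)
  # identical class distributions: no real separation
  x0 <- matrix(rnorm(200), 100)
  sc0 <- lda_scores(x0, rep(1:2, each = 50))
  m0 <- tapply(sc0[, 1], rep(1:2, each = 50), mean)
  expect_lt(abs(m0[1] - m0[2]) / sd(sc0[, 1]), 1.5)
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # stable under reordering
  p <- c(0.04, 0.01, 0.8, 0.03)
  o <- c(3, 1, 4, 2)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
})

test_that("differential calling applies both gates and is order-invariant", {
  set.seed(21)
  labels <- rep(1:3, c(20, 20, 20))
  asv <- simulate_asv_table(
    microbiome_spec(n_asvs = 60, n_differential = 9, depth_mean = 3000,
                    tree_seed = 2), labels, seed = 5)
  diff <- differential_asvs(asv$counts, labels)
  # every cluster-specific ASV passes both thresholds in >= 1 contrast
  for (id in diff$cluster_specific) {
    hit <- any(vapply(diff$contrasts, function(df) {
      row <- df[df$asv_id == id, ]
      row$fdr_q < 0.05 && abs(row$log2fc) > 1
    }, logical(1)))
    expect_true(hit)
  }
  # invariance to ASV and sample order (up to result ordering)
  perm_s <- sample(nrow(asv$counts)); perm_a <- sample(ncol(asv$counts))
  diff2 <- differential_asvs(asv$counts[perm_s, perm_a], labels[perm_s])
  expect_setequal(diff2$cluster_specific, diff$cluster_specific)
  expect_error(differential_asvs(asv$counts, rep(1, 60)), "2 clusters")
  # a two-cluster cohort yields the single 1v2 contrast
  d2 <- differential_asvs(asv$counts, rep(1:2, 30))
  expect_named(d2$contrasts, "1v2")
})

test_that("log2 fold change follows the stabilised formula", {
  # mean relative abundances 0.02 vs 0.005 -> log2fc = 2 (eps negligible)
  counts <- matrix(0L, 12, 3,
                   dimnames = list(paste0("s", 1:12), c("A", "B", "C")))
  counts[, "A"] <- rep(c(20L, 5L), each = 6)
  counts[, "B"] <- rep(c(480L, 495L), each = 6)
  counts[, "C"] <- 500L
  lab <- rep(c(1, 2), each = 6)
  rel <- counts / rowSums(counts)
  lfc <- log2((mean(rel[lab == 1, "A"]) + 1e-6) /
                (mean(rel[lab == 2, "A"]) + 1e-6))
  expect_equal(lfc, 2, tolerance = 1e-3)
})

test_that("small-sample Wilcoxon matches exact enumeration", {
  # the contrast machinery relies on wilcox.test's exact small-sample path;
  # verify against a brute-force enumeration of group assignments
  set.seed(13)
  x <- c(1.2, 3.4, 0.5, 2.2); y <- c(4.1, 5.0, 3.9)
  obs <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
  pool <- c(x, y)
  combos <- utils::combn(7, 4)
  w_obs <- sum(rank(pool)[1:4]) - 4 * 5 / 2
  ws <- apply(combos, 2, function(ix) sum(rank(pool)[ix]) - 10)
  mu <- 4 * 3 / 2
  p_exact <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
  expect_equal(obs, p_exact, tolerance = 1e-12)
})
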