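test_that("PAM separates trivially separable data and honors tie rules", {
  d <- as.matrix(dist(c(0, 0.1, 10, 10.1)))
  fit <- pam_cluster(d, 2)
  expect_equal(fit$labels, c(1L, 1L, 2L, 2L))
  expect_equal(fit$total_cost, 0.2, tolerance = 1e-12)
  expect_error(pam_cluster(matrix(c(0, 1, 2, 0), 2), 2), "symmetric")
  dn <- d; dn[1, 2] <- NA; dn[2, 1] <- NA
  expect_error(pam_cluster(dn, 2), "NA")
})

test_that("PAM at k = n-1 leaves only the closest pair merged", {
  set.seed(4)
  for (i in 1:10) {
    x <- matrix(rnorm(14), 7)
    d <- as.matrix(dist(x))
    fit <- pam_cluster(d, 6)
    expect_equal(fit$total_cost, min(d[upper.tri(d)]), tolerance = 1e-12)
  }
})

test_that("PAM matches cluster::pam on moderate instances", {
  skip_if_not_installed("cluster")
  set.seed(11)
  for (i in 1:20) {
    x <- matrix(rnorm(60), 30)
    d <- as.matrix(dist(x))
    k <- sample(2:4, 1)
    mine <- pam_cluster(d, k)
    ref <- cluster::pam(as.dist(d), k)
    expect_equal(mine$total_cost, unname(ref$objective["swap"]) * 30,
                 tolerance = 1e-8)
    expect_equal(adjusted_rand(mine$labels, ref$clustering), 1)
  }
})

test_that("mean silhouette matches the definition and the reference", {
  # two tight clusters: within 0, between 1 -> silhouette 1
  d <- matrix(1, 4, 4) - diag(4)
  d[1, 2] <- d[2, 1] <- 0
  d[3, 4] <- d[4, 3] <- 0
  expect_equal(silhouette_mean(d, c(1, 1, 2, 2)), 1)

  # random labels on structureless data stay near zero
  set.seed(2)
  x <- matrix(runif(200), 100)
  dm <- as.matrix(dist(x))
  expect_lt(abs(silhouette_mean(dm, sample(1:2, 100, TRUE))), 0.1)

  # singleton clusters contribute exactly zero
  d3 <- as.matrix(dist(c(0, 0.1, 5)))
  expect_equal(silhouette_mean(d3, c(1, 1, 2)),
               mean(c((5 - 0.1) / 5, (4.9 - 0.1) / 4.9, 0)),
               tolerance = 1e-12)

  skip_if_not_installed("cluster")
  set.seed(3)
  lab <- pam_cluster(dm, 3)$labels
  ref <- mean(cluster::silhouette(lab, dmatrix = dm)[, 3])
  expect_equal(silhouette_mean(dm, lab), ref, tolerance = 1e-12)
})

test_that("silhouette model selection finds planted k on separated data", {
  for (k_true in 2:3) {
    pts <- make_separated_points(rep(20, k_true), sep = 8, sd = 0.5,
                                 seed = k_true)
    sm <- as_fake_strat_matrix(pts$x)
    fit <- suppressMessages(
      stratify_cohort(sm, k_range = c(2, 6), n_bootstrap = 0,
                      center_variables = colnames(sm$z)))
    expect_equal(fit$k, k_true)
    expect_equal(adjusted_rand(fit$labels, pts$labels), 1)
    expect_equal(unname(fit$silhouette_by_k[as.character(k_true)]),
                 max(fit$silhouette_by_k))
  }
  # one spherical Gaussian: weak structure, low silhouette, flagged
  set.seed(9)
  sm1 <- as_fake_strat_matrix(matrix(rnorm(300), 60))
  expect_message(
    fit1 <- stratify_cohort(sm1, k_range = c(2, 5), n_bootstrap = 0,
                            center_variables = colnames(sm1$z)),
    "weak cluster structure")
  expect_lt(max(fit1$silhouette_by_k), 0.25)
})

test_that("selection is permutation-equivariant (relabeling only)", {
  pts <- make_separated_points(c(15, 15, 15), seed = 5)
  sm <- as_fake_strat_matrix(pts$x)
  perm <- sample(nrow(pts$x))
  smp <- as_fake_strat_matrix(pts$x[perm, , drop = FALSE],
                              ids = rownames(sm$z)[perm])
  f1 <- suppressMessages(stratify_cohort(sm, c(2, 5), n_bootstrap = 0,
                                         center_variables = colnames(sm$z)))
  f2 <- suppressMessages(stratify_cohort(smp, c(2, 5), n_bootstrap = 0,
                                         center_variables = colnames(sm$z)))
  expect_equal(f1$k, f2$k)
  expect_equal(adjusted_rand(f1$labels[rownames(smp$z)], f2$labels), 1)
})

test_that("bootstrap Jaccard stability is high for separated clusters, low for noise", {
  pts <- make_separated_points(c(20, 20, 20), sep = 10, sd = 0.4, seed = 7)
  sm <- as_fake_strat_matrix(pts$x)
  st <- bootstrap_stability(sm, k = 3, B = 25, seed = 1)
  expect_true(all(st > 0.95))

  set.seed(8)
  smn <- as_fake_strat_matrix(matrix(rnorm(90 * 5), 90))
  stn <- suppressMessages(bootstrap_stability(smn, k = 3, B = 25, seed = 1))
  expect_lt(min(stn), 0.6)
  expect_true(all(stn >= 0 & stn <= 1))
})

test_that("new participants are assigned to the nearest discovery center", {
  pts <- make_separated_points(c(20, 20, 20), sep = 8, sd = 0.5, seed = 3)
  colnames(pts$x) <- c("bmi", "hba1c")
  sm <- as_fake_strat_matrix(pts$x)
  fit <- suppressMessages(
    stratify_cohort(sm, c(2, 5), n_bootstrap = 0,
                    center_variables = c("bmi", "hba1c")))
  # clusters come back ordered by planted position only up to relabeling;
  # map true labels through the fitted ones for the assignment check
  new_pts <- make_separated_points(c(10, 10, 10), sep = 8, sd = 0.5,
                                   seed = 30)
  nd <- data.frame(participant_id = sprintf("T%02d", 1:30),
                   bmi = new_pts$x[, 1], hba1c = new_pts$x[, 2])
  lab <- predict(fit, nd)
  expect_equal(length(lab), 30L)
  expect_equal(adjusted_rand(lab, new_pts$labels), 1)

  # a test row equal to a center maps to that cluster, and exact ties go low
  ctr_raw <- sweep(sweep(fit$centers, 2, fit$scaling$scale, "*"),
                   2, fit$scaling$center, "+")
  nd2 <- data.frame(participant_id = c("C1", "C2", "C3"),
                    bmi = ctr_raw[, "bmi"], hba1c = ctr_raw[, "hba1c"])
  expect_equal(as.integer(predict(fit, nd2)), 1:3)
  expect_error(predict(fit, nd2[, 1:2]), "hba1c")

  mid <- (ctr_raw[1, ] + ctr_raw[2, ]) / 2
  nd3 <- data.frame(participant_id = "M",
                    bmi = mid["bmi"], hba1c = mid["hba1c"])
  # not exactly equidistant in z space unless scaling symmetric; build in z
  zmid <- (fit$centers[1, ] + fit$centers[2, ]) / 2
  raw <- zmid * fit$scaling$scale + fit$scaling$center
  nd3$bmi <- raw["bmi"]; nd3$hba1c <- raw["hba1c"]
  expect_equal(as.integer(predict(fit, nd3)), 1L)
})

test_that("strat_fit methods print, summarise and plot", {
  pts <- make_separated_points(c(12, 12), seed = 2)
  sm <- as_fake_strat_matrix(pts$x)
  fit <- suppressMessages(stratify_cohort(sm, c(2, 4), n_bootstrap = 20,
                                          center_variables = colnames(sm$z)))
  expect_output(print(fit), "k-medoids")
  s <- summary(fit)
  expect_output(print(s), "Selected k = 2")
  expect_equal(sum(s$sizes), 24)
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
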