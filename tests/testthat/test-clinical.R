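test_that("HOMA indices follow the published formulas", {
  h <- homa_indices(5.47, 3.32)
  expect_equal(h$homa_ir, 5.47 * 3.32 / 22.5, tolerance = 1e-12)
  expect_equal(round(h$homa_ir, 3), 0.807)
  expect_equal(h$homa_beta, 20 * 3.32 / (5.47 - 3.5), tolerance = 1e-12)

  # IR x IS = 1 identity, and monotonicity in both arguments
  set.seed(1)
  g <- runif(50, 3, 12); i <- runif(50, 1, 60)
  h2 <- homa_indices(g, i)
  expect_equal(h2$homa_ir * h2$homa_is, rep(1, 50), tolerance = 1e-12)
  expect_true(all(diff(homa_indices(sort(g), 5)$homa_ir) > 0))
  expect_true(all(diff(homa_indices(5, sort(i))$homa_ir) > 0))

  # beta-cell index undefined at or below the 3.5 mmol/L domain boundary
  expect_true(is.na(homa_indices(3.5, 5)$homa_beta))
  expect_error(homa_indices(-1, 5), "glucose")
  expect_error(homa_indices(5, 0), "insulin")
})

test_that("OGTT AUC is the trapezoid over 0-180 min", {
  expect_equal(ogtt_auc(rep(5, 5)), 900)
  expect_equal(ogtt_auc(c(5.47, 9.22, 8.77, 6.66, 4.41)), 1285.2,
               tolerance = 1e-12)
  expect_true(is.na(ogtt_auc(c(5, NA, 6, 7, 5))))
  expect_error(ogtt_auc(c(-1, 5, 5, 5, 5)), "nonnegative")
  # four-point variant over 0-120 min
  expect_equal(ogtt_auc(rep(5, 4), minutes = c(0, 30, 60, 120)), 600)
})

test_that("ADA classification is exhaustive and exclusive over a grid", {
  expect_equal(as.character(ada_classify(5.0, 6.0, 5.2)), "NGT")
  expect_equal(as.character(ada_classify(6.0, 9.0, 5.8)), "CGI")
  expect_equal(as.character(ada_classify(7.2, 6.0, 5.5)), "T2D")
  expect_equal(as.character(ada_classify(6.0, 6.5, 5.5)), "IFG")
  expect_equal(as.character(ada_classify(5.0, 8.5, 5.5)), "IGT")
  expect_equal(as.character(ada_classify(5.0, 6.0, 6.6)), "T2D")
  expect_true(is.na(ada_classify(NA, 6.0, 5.5)))

  grid <- expand.grid(g0 = seq(3, 12, by = 0.25),
                      g120 = seq(3, 16, by = 0.25),
                      hba1c = c(5, 6.4, 6.5, 8))
  cls <- ada_classify(grid$g0, grid$g120, grid$hba1c)
  expect_false(anyNA(cls))  # every complete input gets exactly one class
  expect_setequal(levels(cls), c("NGT", "IFG", "IGT", "CGI", "T2D"))
})

test_that("coefficients of variation use the sample SD", {
  tab <- data.frame(x = c(2, 2, 2, 1, 3, 5))
  cls <- c("a", "a", "a", "b", "b", "c")
  cv <- cv_by_group(tab, cls, "x")
  expect_equal(cv["x", "a"], 0)
  expect_equal(cv["x", "b"], sqrt(2) / 2, tolerance = 1e-12)
  expect_true(is.na(cv["x", "c"]))  # singleton group
})

test_that("stratification matrix standardizes, excludes outliers, re-scales", {
  set.seed(3)
  base <- matrix(rnorm(100 * 16), 100)
  colnames(base) <- STRAT_VARIABLES
  df <- data.frame(participant_id = sprintf("P%03d", 1:100),
                   abs(base) + 1, check.names = FALSE)
  tab <- as_clinical_table(df)
  sm <- build_stratification_matrix(tab, outlier_z = 5, min_rows = 10)
  expect_equal(nrow(sm$excluded), 0L)
  expect_true(all(abs(colMeans(sm$z)) < 1e-9))
  expect_true(all(abs(apply(sm$z, 2, sd) - 1) < 1e-9))

  # standardizing an already-standardized matrix changes nothing
  z2 <- scale(sm$z)
  expect_true(max(abs(z2 - sm$z)) < 1e-9)

  # nine planted extreme rows (each extreme in a different variable, so the
  # contamination does not mask itself through the column SD) are excluded
  tab2 <- tab
  for (i in 1:9) {
    v <- STRAT_VARIABLES[i]
    tab2[[v]][i] <- mean(tab[[v]]) + 10 * sd(tab[[v]])
  }
  sm2 <- build_stratification_matrix(tab2, outlier_z = 5, min_rows = 10)
  expect_equal(sum(sm2$excluded$reason == "outlier"), 9L)
  expect_equal(sort(sm2$excluded$participant_id),
               sprintf("P%03d", 1:9))
  expect_equal(nrow(sm2$z), 91L)

  # zero-variance column is a hard error
  tab3 <- tab
  tab3$hdl <- 1
  expect_error(build_stratification_matrix(tab3, min_rows = 10), "hdl")

  # rows with missing stratification variables are excluded as "missing"
  tab4 <- tab
  tab4$bmi[5] <- NA
  sm4 <- build_stratification_matrix(tab4, min_rows = 10)
  expect_equal(sm4$excluded$reason, "missing")
  expect_equal(sm4$excluded$participant_id, "P005")
})

test_that("derive_metrics appends internally consistent quantities", {
  cl <- suppressMessages(simulate_clinical(cohort_spec(
    n_per_cluster = c(20, 20, 10), seed = 5)))
  d <- derive_metrics(cl)
  expect_equal(d$homa_ir * d$homa_is, rep(1, nrow(d)), tolerance = 1e-9)
  expect_equal(d$whr, d$waist / d$hip)
  expect_equal(d$glucose_auc,
               ogtt_auc(d[, paste0("glucose_", c(0, 30, 60, 120, 180))]))
  expect_true(all(levels(d$ada_class) ==
                    c("NGT", "IFG", "IGT", "CGI", "T2D")))
})
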