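# Published per-cluster summary statistics of the discovery cohort
# (mean, SEM, n per cluster) that parameterise the synthetic generator and
# the in-package composition calculations. SEMs are converted to SDs with
# SD = SEM * sqrt(n) where the generator needs dispersions.

# the 16 stratification variables, in canonical order
STRAT_VARIABLES <- c(
  "hba1c",
  "glucose_0", "glucose_30", "glucose_60", "glucose_120", "glucose_180",
  "insulin_0", "insulin_30", "insulin_60", "insulin_120", "insulin_180",
  "bmi", "waist", "hip", "triglyceride", "hdl"
)

# the 14 variables shared with the testing cohort (no 3-h OGTT samples)
SHARED_VARIABLES <- setdiff(STRAT_VARIABLES, c("glucose_180", "insulin_180"))

# rows: variable; columns: mean1, sem1, n1, mean2, sem2, n2, mean3, sem3, n3
.cluster_profile_table <- function() {
  m <- matrix(c(
    # mean1,  sem1, n1,  mean2,  sem2, n2,  mean3,  sem3, n3
    5.49,  0.03, 132,  5.76,  0.05,  96,  7.10,  0.19, 30,  # hba1c (%)
    5.47,  0.05, 132,  5.70,  0.08,  96,  8.45,  0.28, 30,  # glucose_0
    9.22,  0.15, 129, 10.10,  0.23,  91, 13.06,  0.50, 26,  # glucose_30
    8.77,  0.20, 129, 10.84,  0.32,  91, 16.29,  0.57, 26,  # glucose_60
    6.66,  0.14, 132,  8.76,  0.27,  96, 15.21,  0.52, 30,  # glucose_120
    4.41,  0.11, 125,  5.44,  0.21,  87, 10.12,  0.50, 26,  # glucose_180
    3.32,  0.16, 130,  6.24,  0.41,  91,  3.45,  0.53, 28,  # insulin_0
    20.88,  1.30, 127, 31.80,  2.35,  87,  6.62,  0.84, 28,  # insulin_30
    24.51,  1.29, 127, 42.33,  2.95,  87, 11.18,  1.54, 28,  # insulin_60
    19.64,  1.38, 131, 43.44,  3.77,  91, 13.15,  1.74, 28,  # insulin_120
    5.07,  0.44, 127, 14.44,  1.51,  87,  8.67,  1.19, 28,  # insulin_180
    23.75,  0.18, 132, 27.86,  0.28,  96, 25.17,  0.58, 30,  # bmi
    80.79,  0.51, 132, 91.57,  0.67,  96, 84.82,  1.63, 30,  # waist
    92.54,  0.34, 132, 99.50,  0.57,  96, 96.04,  1.03, 30,  # hip
    0.66,  0.04, 127,  1.30,  0.16,  91,  1.05,  0.25, 27,  # triglyceride
    0.63,  0.04, 127,  0.70,  0.04,  91,  0.56,  0.08, 27,  # hdl
    57.42,  0.57, 131, 57.59,  0.62,  95, 60.83,  1.01, 30,  # age
    160.62,  0.67, 132, 161.81,  0.86,  96, 163.83,  1.06, 30,  # height
    128.62,  1.10, 132, 133.58,  1.41,  96, 127.13,  2.19, 30,  # sbp
    81.58,  0.68, 132, 83.21,  0.74,  96, 82.00,  1.55, 30,  # dbp
    1.84,  0.10, 127,  2.41,  0.16,  91,  1.80,  0.25, 27,  # total_cholesterol
    1.06,  0.10, 127,  1.11,  0.10,  91,  0.80,  0.12, 27   # ldl
  ), ncol = 9, byrow = TRUE)
  rownames(m) <- c(STRAT_VARIABLES, "age", "height", "sbp", "dbp",
                   "total_cholesterol", "ldl")
  colnames(m) <- c("mean1", "sem1", "n1", "mean2", "sem2", "n2",
                   "mean3", "sem3", "n3")
  m
}

# female/male counts per cluster in the discovery cohort
.cluster_gender_counts <- function() {
  matrix(c(68, 64, 53, 43, 11, 19), nrow = 3, byrow = TRUE,
         dimnames = list(paste0("cluster", 1:3), c("female", "male")))
}

#' Glycemic-category composition of the published discovery clusters
#'
#' Counts of participants per ADA glycemic category (rows) in each of the
#' three discovery clusters (columns), as reported for the stratified cohort
#' of 258 participants.
#'
#' @return An integer matrix with rows NGT/IFG/IGT/CGI/T2D and columns
#'   cluster1..cluster3.
#' @export
published_category_counts <- function() {
  matrix(as.integer(c(
    67, 16, 0,   # NGT
    34, 16, 0,   # IFG
    12, 20, 0,   # IGT
    17, 20, 0,   # CGI
    2, 24, 30    # T2D
  )), nrow = 5, byrow = TRUE,
  dimnames = list(c("NGT", "IFG", "IGT", "CGI", "T2D"),
                  paste0("cluster", 1:3)))
}

#' Per-category cluster composition percentages
#'
#' Converts a category-by-cluster count matrix into row percentages: the
#' percentage of participants in each glycemic category that fall into each
#' cluster.
#'
#' @param counts Category-by-cluster integer matrix, e.g.
#'   [published_category_counts()].
#' @return A matrix of the same shape with rows summing to 100.
#' @export
cluster_composition <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  100 * counts / rowSums(counts)
}

#' Published co-abundance network sizes
#'
#' Node and edge counts of the per-cluster co-abundance networks reported for
#' the discovery cohort.
#'
#' @return A data frame with columns `cluster`, `n_nodes`, `n_edges`.
#' @export
published_network_sizes <- function() {
  data.frame(cluster = 1:3,
             n_nodes = c(168L, 153L, 158L),
             n_edges = c(638L, 420L, 332L))
}
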