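# Synthetic three-cluster glycometabolic cohort and compositional ASV
# table generator. Cluster-conditional clinical profiles are the published
# per-cluster means and SEMs of the discovery cohort (SD = SEM * sqrt(n));
# OGTT glucose and insulin curves are drawn as correlated multivariate
# normals. HOMA indices and OGTT areas are never simulated: they are
# derived downstream so derived quantities stay internally consistent.

#' Specification of a synthetic clinical cohort
#'
#' @param n_per_cluster Integer triple of cluster sizes (default 132, 96,
#'   30, the published discovery cluster sizes).
#' @param within_subject_corr Exchangeable correlation of the OGTT
#'   time-series draws (default 0.6).
#' @param seed RNG seed.
#' @return A `cohort_spec` list including per-cluster mean/SD profiles for
#'   the 16 stratification variables plus auxiliary variables.
#' @export
cohort_spec <- function(n_per_cluster = c(132L, 96L, 30L),
                        within_subject_corr = 0.6, seed = 1L) {
  stopifnot(length(n_per_cluster) == 3, all(n_per_cluster >= 2),
            within_subject_corr >= 0, within_subject_corr < 1)
  prof <- .cluster_profile_table()
  profiles <- lapply(1:3, function(g) {
    data.frame(variable = rownames(prof),
               mean = prof[, paste0("mean", g)],
               sd = prof[, paste0("sem", g)] * sqrt(prof[, paste0("n", g)]))
  })
  if (any(vapply(profiles, function(p) any(p$sd <= 0), TRUE))) {
    stop("all profile SDs must be positive")
  }
  structure(list(n_per_cluster = as.integer(n_per_cluster),
                 profiles = profiles,
                 gender_counts = .cluster_gender_counts(),
                 within_subject_corr = within_subject_corr,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# draw one cluster's OGTT block (5 time points) as truncated correlated MVN
.draw_ogtt <- function(n, means, sds, rho, floor = 0.1) {
  p <- length(means)
  R <- matrix(rho, p, p); diag(R) <- 1
  Sigma <- diag(sds) %*% R %*% diag(sds)
  x <- MASS::mvrnorm(n, mu = means, Sigma = Sigma)
  if (n == 1) x <- matrix(x, nrow = 1)
  pmax(x, floor)
}

.rtruncnorm <- function(n, mean, sd, floor = 0.1) pmax(stats::rnorm(n, mean, sd), floor)

#' Simulate a three-cluster clinical cohort
#'
#' @param spec A [cohort_spec()].
#' @return A `clinical_table` with one row per participant, a `cohort`
#'   column, and the true cluster assignment in attribute `true_labels`
#'   (used only by tests and recovery diagnostics).
#' @export
simulate_clinical <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  rows <- list()
  for (g in 1:3) {
    n <- spec$n_per_cluster[g]
    pr <- spec$profiles[[g]]
    pv <- function(v, col) pr[[col]][match(v, pr$variable)]
    g_vars <- paste0("glucose_", c(0, 30, 60, 120, 180))
    i_vars <- paste0("insulin_", c(0, 30, 60, 120, 180))
    glu <- .draw_ogtt(n, pv(g_vars, "mean"), pv(g_vars, "sd"),
                      spec$within_subject_corr)
    ins <- .draw_ogtt(n, pv(i_vars, "mean"), pv(i_vars, "sd"),
                      spec$within_subject_corr)
    colnames(glu) <- g_vars
    colnames(ins) <- i_vars
    solo <- c("hba1c", "bmi", "waist", "hip", "triglyceride", "hdl",
              "age", "height", "sbp", "dbp", "total_cholesterol", "ldl")
    singles <- vapply(solo, function(v) {
      .rtruncnorm(n, pv(v, "mean"), pv(v, "sd"))
    }, numeric(n))
    if (n == 1) singles <- matrix(singles, nrow = 1, dimnames = list(NULL, solo))
    p_female <- spec$gender_counts[g, "female"] / sum(spec$gender_counts[g, ])
    gender <- ifelse(stats::runif(n) < p_female, "female", "male")
    df <- data.frame(glu, ins, singles, gender = gender,
                     check.names = FALSE)
    # weight derived from BMI and height so anthropometrics are consistent
    df$weight <- df$bmi * (df$height / 100)^2
    df$true_cluster <- g
    rows[[g]] <- df
  }
  out <- do.call(rbind, rows)
  out <- data.frame(participant_id = sprintf("P%03d", seq_len(nrow(out))),
                    cohort = "discovery", out, check.names = FALSE)
  true_labels <- stats::setNames(out$true_cluster, out$participant_id)
  out$true_cluster <- NULL
  out <- as_clinical_table(out)
  attr(out, "true_labels") <- true_labels
  out
}

#' Specification of a synthetic microbiome
#'
#' @param n_asvs Total ASVs (default 300).
#' @param n_differential Planted cluster-differential ASVs (default 67).
#' @param planted_log2fc Planted log2 fold change (default 2).
#' @param depth_mean Mean sequencing depth per sample (default 10000).
#' @param dispersion Lognormal sdlog of the per-sample, per-ASV biological
#'   noise on abundances (default 0.8).
#' @param baseline_sdlog Lognormal sdlog of baseline mean abundances across
#'   ASVs (default 1.5).
#' @param depth_sdlog Lognormal sdlog of per-sample depths (default 0.3).
#' @param tree_seed Seed for the random phylogeny.
#' @return A `microbiome_spec` list.
#' @export
microbiome_spec <- function(n_asvs = 300L, n_differential = 67L,
                            planted_log2fc = 2, depth_mean = 10000L,
                            dispersion = 0.8, baseline_sdlog = 1.5,
                            depth_sdlog = 0.3, tree_seed = 1L) {
  stopifnot(n_differential <= n_asvs, n_asvs >= 4, planted_log2fc >= 0,
            depth_mean > 0, dispersion >= 0)
  structure(list(n_asvs = as.integer(n_asvs),
                 n_differential = as.integer(n_differential),
                 planted_log2fc = planted_log2fc,
                 depth_mean = as.integer(depth_mean),
                 dispersion = dispersion,
                 baseline_sdlog = baseline_sdlog,
                 depth_sdlog = depth_sdlog,
                 tree_seed = as.integer(tree_seed)),
            class = "microbiome_spec")
}

# taxonomy lexicon; includes genera/species highlighted in glycometabolic
# microbiome work so synthetic outputs read like real annotations
.taxonomy_lexicon <- function() {
  c("k__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Prevotellaceae;g__Prevotella;s__Prevotella copri",
    "k__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Bacteroidaceae;g__Bacteroides;s__Bacteroides vulgatus",
    "k__Bacteria;p__Firmicutes;c__Clostridia;o__Lachnospirales;f__Lachnospiraceae;g__Ruminococcus;s__Ruminococcus gnavus",
    "k__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Rikenellaceae;g__Alistipes;s__Alistipes shahii",
    "k__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Barnesiellaceae;g__Barnesiella;s__",
    "k__Bacteria;p__Firmicutes;c__Clostridia;o__Oscillospirales;f__Ruminococcaceae;g__Faecalibacterium;s__Faecalibacterium prausnitzii",
    "k__Bacteria;p__Firmicutes;c__Clostridia;o__Lachnospirales;f__Lachnospiraceae;g__Blautia;s__",
    "k__Bacteria;p__Firmicutes;c__Clostridia;o__Lachnospirales;f__Lachnospiraceae;g__Coprococcus;s__",
    "k__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Tannerellaceae;g__Parabacteroides;s__Parabacteroides distasonis",
    "k__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Bacteroidaceae;g__Bacteroides;s__Bacteroides stercoris",
    "k__Bacteria;p__Firmicutes;c__Clostridia;o__Peptostreptococcales;f__Peptostreptococcaceae;g__Paeniclostridium;s__",
    "k__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Muribaculaceae;g__;s__",
    "k__Bacteria;p__Firmicutes;c__Clostridia;o__Oscillospirales;f__Oscillospiraceae;g__UCG-002;s__",
    "k__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Enterobacterales;f__Enterobacteriaceae;g__Escherichia-Shigella;s__",
    "k__Bacteria;p__Actinobacteriota;c__Actinobacteria;o__Bifidobacteriales;f__Bifidobacteriaceae;g__Bifidobacterium;s__",
    "k__Bacteria;p__Firmicutes;c__Clostridia;o__Eubacteriales;f__Eubacteriaceae;g__Eubacterium;s__Eubacterium xylanophilum")
}

#' Simulate a compositional ASV table with planted differential features
#'
#' Baseline mean abundances are lognormal across ASVs; each planted
#' differential ASV is assigned (round-robin) one cluster in which its
#' abundance is multiplied by `2^planted_log2fc`, so it is differential in
#' both pairwise contrasts involving that cluster and the planted set is
#' spread across all three contrasts. Per-sample abundances receive lognormal
#' biological noise (`dispersion`), are closed to proportions, and counts are
#' drawn multinomially at lognormal per-sample depths. The phylogeny is a
#' random rooted bifurcating tree with exponential branch lengths.
#'
#' @param spec A [microbiome_spec()].
#' @param labels Cluster assignment per sample (named integer vector; >= 2
#'   clusters, >= 2 samples).
#' @param seed RNG seed for abundances/counts.
#' @return An `asv_table` with attributes `planted` (differential ASV ids)
#'   and `planted_cluster` (the elevated cluster per planted ASV).
#' @export
simulate_asv_table <- function(spec = microbiome_spec(), labels, seed = 1L) {
  stopifnot(inherits(spec, "microbiome_spec"))
  labels <- stats::setNames(as.integer(labels),
                            names(labels) %||% sprintf("S%03d", seq_along(labels)))
  n <- length(labels)
  if (n < 2) stop("need at least 2 samples")
  if (length(unique(labels)) < 2) stop("labels must cover >= 2 clusters")
  clusters <- sort(unique(labels))
  asv_ids <- sprintf("ASV%04d", seq_len(spec$n_asvs))

  set.seed(spec$tree_seed)
  tree <- ape::rtree(spec$n_asvs, rooted = TRUE, br = stats::rexp)
  tree$tip.label <- asv_ids

  set.seed(seed)
  base <- stats::rlnorm(spec$n_asvs, meanlog = 0, sdlog = spec$baseline_sdlog)
  names(base) <- asv_ids
  planted <- asv_ids[seq_len(spec$n_differential)]
  planted_cluster <- clusters[(seq_len(spec$n_differential) - 1L) %%
                                length(clusters) + 1L]
  names(planted_cluster) <- planted
  shift <- 2^spec$planted_log2fc

  depths <- pmax(50, round(stats::rlnorm(n, log(spec$depth_mean),
                                         spec$depth_sdlog)))
  counts <- matrix(0L, n, spec$n_asvs,
                   dimnames = list(names(labels), asv_ids))
  for (i in seq_len(n)) {
    mu <- base
    up <- planted[planted_cluster == labels[i]]
    mu[up] <- mu[up] * shift
    ab <- mu * stats::rlnorm(spec$n_asvs, 0, spec$dispersion)
    counts[i, ] <- as.integer(stats::rmultinom(1, depths[i], ab / sum(ab)))
  }
  lex <- .taxonomy_lexicon()
  taxonomy <- stats::setNames(lex[(seq_len(spec$n_asvs) - 1L) %% length(lex) + 1L],
                              asv_ids)
  out <- as_asv_table(counts, taxonomy, tree)
  attr(out, "planted") <- planted
  attr(out, "planted_cluster") <- planted_cluster
  out
}

#' Simulate fecal short-chain fatty acid concentrations
#'
#' Butyrate and acetate (umol/g) with cluster means ordered cluster 1 >
#' cluster 2 > cluster 3 and gaussian noise, floored at zero.
#'
#' @param labels Cluster assignment per sample (values 1..3).
#' @param seed RNG seed.
#' @param butyrate_means,acetate_means Per-cluster means (defaults 12/9/6
#'   and 45/38/30 umol/g).
#' @param butyrate_sd,acetate_sd Within-cluster SDs (defaults 3 and 8).
#' @return Data frame with `sample_id`, `butyrate`, `acetate`.
#' @export
simulate_scfa <- function(labels, seed = 1L,
                          butyrate_means = c(12, 9, 6), butyrate_sd = 3,
                          acetate_means = c(45, 38, 30), acetate_sd = 8) {
  ids <- names(labels)
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 1 | labels > 3)) {
    stop("labels must be in 1..3")
  }
  set.seed(seed)
  n <- length(labels)
  data.frame(
    sample_id = ids %||% sprintf("S%03d", seq_len(n)),
    butyrate = pmax(0, stats::rnorm(n, butyrate_means[labels], butyrate_sd)),
    acetate = pmax(0, stats::rnorm(n, acetate_means[labels], acetate_sd)))
}
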