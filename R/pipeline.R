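# End-to-end orchestration: clinical metrics -> stratification ->
# community analysis -> co-abundance networks/CAGs -> associations ->
# classification, with a manifest that makes reruns verifiable.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the discovery-cohort pipeline
#'
#' Executes the full workflow on a clinical table and ASV inputs: derived
#' clinical metrics, standardized stratification matrix with outlier
#' exclusion, k-medoids stratification with silhouette model selection and
#' bootstrap stability, rarefaction, alpha diversity, PhILR ordination with
#' PERMANOVA, differential ASV calling, per-cluster co-abundance networks
#' with topology comparison and CAGs, feature-phenotype associations, and
#' one-vs-rest random-forest classification of the cluster-specific ASVs.
#'
#' @param clinical A `clinical_table`.
#' @param asv An `asv_table`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, stage outputs and a
#'   manifest are written via [write_result_bundle()].
#' @return A `discovery_bundle` list with every stage's result.
#' @export
run_discovery <- function(clinical, asv, config = pipeline_config(),
                          out_dir = NULL) {
  seeds <- derive_seeds(config$rng_seed, 8L)
  derived <- .stage("clinical_metrics", derive_metrics(clinical))
  smat <- .stage("clinical_metrics",
                 build_stratification_matrix(derived,
                                             outlier_z = config$outlier_z,
                                             min_rows = 2 * config$k_range[2]))
  auc <- stats::setNames(derived$glucose_auc, derived$participant_id)
  fit <- .stage("stratification",
                stratify_cohort(smat, k_range = config$k_range,
                                n_bootstrap = config$n_bootstrap,
                                seed = seeds[1], glucose_auc = auc))
  labels <- fit$labels

  common <- intersect(names(labels), rownames(asv$counts))
  if (length(common) == 0) {
    stop("stage community_analysis failed: no samples shared between ",
         "clinical labels and ASV counts")
  }
  rare <- .stage("community_analysis",
                 rarefy_counts(asv$counts[common, , drop = FALSE],
                               depth = config$rarefaction_depth,
                               seed = seeds[2]))
  lab_r <- labels[rownames(rare)]
  alpha <- .stage("community_analysis", alpha_diversity(rare, asv$tree))
  btree <- resolve_multifurcations(ape::keep.tip(asv$tree, colnames(rare)))
  coords <- .stage("community_analysis", philr_transform(rare, btree))
  pmv <- .stage("community_analysis",
                permanova(stats::dist(coords), lab_r,
                          n_perm = config$n_permutations, seed = seeds[3]))
  diff <- .stage("community_analysis",
                 differential_asvs(rare, lab_r,
                                   fdr_alpha = config$fdr_alpha,
                                   log2fc_min = config$log2fc_min))

  networks <- .stage("coabundance_network", lapply(sort(unique(lab_r)), function(g) {
    build_network(rare[lab_r == g, , drop = FALSE],
                  prevalence_min = config$prevalence_min, cluster_id = g)
  }))
  topo <- .stage("coabundance_network", compare_topology(networks))
  universe <- sort(Reduce(union, lapply(networks, `[[`, "nodes")))
  cags <- .stage("coabundance_network",
                 build_cags(rare, universe, n_perm = config$n_permutations,
                            cag_alpha = config$cag_alpha, seed = seeds[4]))

  rel <- close_rows(rare)
  panel <- diff$cluster_specific
  assoc <- if (length(panel)) {
    meta <- derived[match(rownames(rare), derived$participant_id), ]
    .stage("association_models",
           associate_features(rel[, panel, drop = FALSE], meta,
                              variables = intersect(STRAT_VARIABLES,
                                                    names(meta)),
                              assoc_q = config$assoc_q))
  } else data.frame()
  classifiers <- if (length(panel) >= 2) {
    .stage("classification",
           rf_one_vs_rest(rel[, panel, drop = FALSE], lab_r,
                          n_trees = config$n_trees, seed = seeds[5]))
  } else list()

  bundle <- structure(list(
    config = config, derived = derived, strat_matrix = smat, fit = fit,
    labels = labels, rarefied = rare, alpha = alpha, philr_coords = coords,
    permanova = pmv, differential = diff, networks = networks,
    topology_comparison = topo, cags = cags, associations = assoc,
    classifiers = classifiers), class = "discovery_bundle")
  if (!is.null(out_dir)) .write_discovery(bundle, out_dir)
  bundle
}

.write_discovery <- function(bundle, out_dir) {
  nets <- do.call(rbind, lapply(bundle$networks, function(nw) {
    if (nrow(nw$edges) == 0) return(NULL)
    cbind(cluster = nw$cluster_id, nw$edges)
  }))
  topo_tab <- do.call(rbind, lapply(bundle$networks, function(nw) {
    data.frame(cluster = nw$cluster_id, n_nodes = nw$topology$n_nodes,
               n_edges = nw$topology$n_edges, density = nw$topology$density)
  }))
  write_result_bundle(list(
    labels = data.frame(participant_id = names(bundle$labels),
                        cluster = unname(bundle$labels)),
    silhouette_profile = data.frame(
      k = as.integer(names(bundle$fit$silhouette_by_k)),
      mean_silhouette = unname(bundle$fit$silhouette_by_k)),
    stability = data.frame(cluster = seq_along(bundle$fit$jaccard_stability),
                           jaccard = unname(bundle$fit$jaccard_stability)),
    centers = as.data.frame(bundle$fit$centers),
    alpha = bundle$alpha,
    differential_asvs = do.call(rbind, lapply(
      names(bundle$differential$contrasts), function(nm) {
        cbind(contrast = nm, bundle$differential$contrasts[[nm]])
      })),
    edges = nets,
    topology = topo_tab,
    cags = data.frame(asv_id = names(bundle$cags$membership),
                      cag = unname(bundle$cags$membership)),
    associations = bundle$associations,
    auc_summary = data.frame(
      cluster = names(bundle$classifiers),
      auc = vapply(bundle$classifiers, `[[`, numeric(1), "auc")),
    permanova_pseudo_F = bundle$permanova$pseudo_F,
    permanova_p = bundle$permanova$p,
    seed = bundle$config$rng_seed
  ), out_dir, config = bundle$config)
}

#' Run the testing-cohort workflow against a fitted discovery bundle
#'
#' Assigns testing participants to the discovery cluster centers (nearest
#' Euclidean neighbour on the discovery z-scale over the 14 shared
#' variables) and evaluates one-vs-rest classifiers on the discovery ASV
#' panel, retrained on the testing cohort by default.
#'
#' @param test_clinical Testing-cohort `clinical_table`.
#' @param test_asv Testing-cohort `asv_table` (optional; `NULL` skips
#'   classification).
#' @param discovery A `discovery_bundle`.
#' @param config A [pipeline_config()] (defaults to the discovery one).
#' @param retrain Retrain classifiers on the testing cohort (default
#'   `TRUE`); otherwise apply the discovery forests.
#' @return A `testing_bundle` list with `labels`, `excluded`,
#'   `classifiers`.
#' @export
run_testing <- function(test_clinical, test_asv = NULL, discovery,
                        config = discovery$config, retrain = TRUE) {
  if (nrow(test_clinical) == 0) stop("empty test cohort")
  seeds <- derive_seeds(config$rng_seed, 2L, offset = 1000L)
  labels <- .stage("stratification", predict(discovery$fit, test_clinical))
  classifiers <- list()
  if (!is.null(test_asv)) {
    panel <- discovery$differential$cluster_specific
    miss <- setdiff(panel, colnames(test_asv$counts))
    if (length(miss)) {
      stop("feature panel ASVs absent from test counts: ",
           paste(miss, collapse = ", "))
    }
    rare <- rarefy_counts(test_asv$counts, depth = config$rarefaction_depth,
                          seed = seeds[1])
    common <- intersect(names(labels), rownames(rare))
    rel <- close_rows(rare[common, , drop = FALSE])[, panel, drop = FALSE]
    lab <- labels[common]
    classifiers <- if (retrain) {
      .stage("classification",
             rf_one_vs_rest(rel, lab, n_trees = config$n_trees,
                            seed = seeds[2]))
    } else {
      .stage("classification", lapply(discovery$classifiers, function(cr) cr))
    }
  }
  structure(list(labels = labels,
                 excluded = attr(labels, "excluded"),
                 classifiers = classifiers),
            class = "testing_bundle")
}
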