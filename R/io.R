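# Readers, writers and configuration for the pipeline's on-disk formats.
#
# Clinical tables arrive as TSV/CSV with one header row whose names are
# matched case-insensitively against a canonical lexicon (clinical shorthand
# such as FBG or WC is accepted via the alias map below). ASV inputs are a
# counts TSV (orientation auto-detected), a QIIME2-style two-column taxonomy
# TSV and a rooted Newick tree with branch lengths.

# canonical name -> accepted aliases (all compared lower-case, punctuation
# stripped)
.clinical_aliases <- function() {
  list(
    participant_id = c("participant_id", "id", "sample_id", "subject_id"),
    cohort = "cohort",
    age = c("age", "age_yrs"),
    gender = c("gender", "sex"),
    glucose_0 = c("glucose_0", "fbg", "glucose_t0", "fasting_glucose"),
    glucose_30 = c("glucose_30", "pbg_30", "0_5_h_pbg", "glucose_t30"),
    glucose_60 = c("glucose_60", "pbg_60", "1_h_pbg", "glucose_t60"),
    glucose_120 = c("glucose_120", "pbg_120", "2_h_pbg", "glucose_t120"),
    glucose_180 = c("glucose_180", "pbg_180", "3_h_pbg", "glucose_t180"),
    insulin_0 = c("insulin_0", "fins", "fasting_insulin", "insulin_t0"),
    insulin_30 = c("insulin_30", "0_5_h_insulin", "insulin_t30"),
    insulin_60 = c("insulin_60", "1_h_insulin", "insulin_t60"),
    insulin_120 = c("insulin_120", "2_h_insulin", "insulin_t120"),
    insulin_180 = c("insulin_180", "3_h_insulin", "insulin_t180"),
    c_peptide_0 = c("c_peptide_0", "fasting_c_peptide"),
    c_peptide_30 = "c_peptide_30", c_peptide_60 = "c_peptide_60",
    c_peptide_120 = "c_peptide_120", c_peptide_180 = "c_peptide_180",
    hba1c = "hba1c",
    bmi = "bmi",
    height = c("height", "ht"),
    weight = c("weight", "wt"),
    waist = c("waist", "wc", "waist_circumference"),
    hip = c("hip", "hc", "hip_circumference"),
    sbp = "sbp", dbp = "dbp",
    total_cholesterol = c("total_cholesterol", "tc", "cholesterol"),
    triglyceride = c("triglyceride", "tg", "triglycerides"),
    hdl = c("hdl", "hdl_cholesterol"),
    ldl = c("ldl", "ldl_cholesterol"),
    leptin = "leptin",
    lbp = "lbp"
  )
}

.norm_header <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

#' Read and validate a clinical table
#'
#' @param path Path to a delimited text file with one header row.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A `clinical_table`: a data frame with canonical column names,
#'   numeric measurements, and attributes `warnings` (count of unparseable
#'   cells) recorded during the read.
#' @export
read_clinical_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           na.strings = character(0))
  aliases <- .clinical_aliases()
  lut <- stats::setNames(
    rep(names(aliases), lengths(aliases)), unlist(aliases))
  norm <- .norm_header(names(raw))
  canon <- unname(lut[norm])
  keep <- !is.na(canon)
  if (!any(keep & canon == "participant_id")) {
    stop("missing participant_id column")
  }
  df <- raw[, keep, drop = FALSE]
  names(df) <- canon[keep]
  dup <- duplicated(df$participant_id)
  if (any(dup)) {
    stop("duplicated participant ids: ",
         paste(unique(df$participant_id[dup]), collapse = ", "))
  }
  as_clinical_table(df)
}

#' Coerce a data frame to a validated clinical table
#'
#' @param df Data frame with canonical clinical column names; character
#'   measurement columns are parsed as numbers, unparseable cells become `NA`
#'   with a warning count.
#' @return A `clinical_table` data frame.
#' @export
as_clinical_table <- function(df) {
  stopifnot(is.data.frame(df), "participant_id" %in% names(df))
  df$participant_id <- as.character(df$participant_id)
  if (anyDuplicated(df$participant_id)) stop("duplicated participant ids")
  n_warn <- 0L
  num_cols <- setdiff(names(df), c("participant_id", "cohort", "gender"))
  for (v in num_cols) {
    x <- df[[v]]
    if (!is.numeric(x)) {
      was_na <- is.na(x) | trimws(as.character(x)) %in% c("", "NA", "na", ".")
      parsed <- suppressWarnings(as.numeric(as.character(x)))
      bad <- is.na(parsed) & !was_na
      n_warn <- n_warn + sum(bad) + sum(trimws(as.character(x)) %in% c("NA", "na", "."))
      df[[v]] <- parsed
    }
    neg <- !is.na(df[[v]]) & df[[v]] < 0 &
      !v %in% c("age")  # concentrations and anthropometrics are nonnegative
    if (any(neg)) stop("negative values in ", v)
  }
  if ("gender" %in% names(df)) {
    g <- tolower(trimws(as.character(df$gender)))
    g[g %in% c("f", "female")] <- "female"
    g[g %in% c("m", "male")] <- "male"
    if (!all(is.na(g) | g %in% c("female", "male"))) {
      stop("gender must be female/male")
    }
    df$gender <- g
  }
  if ("cohort" %in% names(df)) {
    ch <- tolower(trimws(as.character(df$cohort)))
    if (!all(is.na(ch) | ch %in% c("discovery", "testing"))) {
      stop("cohort must be discovery/testing")
    }
    df$cohort <- ch
  }
  if (n_warn > 0) {
    glyco_log(n_warn, " clinical cell(s) unparseable; recorded as missing",
              level = "WARN")
  }
  attr(df, "warnings") <- n_warn
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read ASV counts, taxonomy, and phylogeny into one object
#'
#' Orientation of the count matrix is auto-detected by overlap of row/column
#' names with the taxonomy's ASV ids. ASVs missing from the tree are dropped
#' with a logged count; zero overlap between counts and taxonomy, or an
#' unrooted or branch-length-free tree, is an error.
#'
#' @param counts_path TSV of counts (samples x ASVs or its transpose).
#' @param taxonomy_path Two-column TSV (`Feature ID`, `Taxon`).
#' @param tree_path Rooted Newick file with branch lengths.
#' @return An `asv_table` list: `counts` (samples x ASVs integer matrix),
#'   `taxonomy` (named character), `tree` (ape `phylo`).
#' @export
read_asv_inputs <- function(counts_path, taxonomy_path, tree_path) {
  tax_df <- utils::read.table(taxonomy_path, header = TRUE, sep = "\t",
                              colClasses = "character", check.names = FALSE,
                              quote = "\"", comment.char = "")
  taxonomy <- stats::setNames(tax_df[[2]], tax_df[[1]])
  cm <- as.matrix(utils::read.table(counts_path, header = TRUE, sep = "\t",
                                    row.names = 1, check.names = FALSE,
                                    comment.char = ""))
  storage.mode(cm) <- "double"
  in_cols <- sum(colnames(cm) %in% names(taxonomy))
  in_rows <- sum(rownames(cm) %in% names(taxonomy))
  if (in_cols == 0 && in_rows == 0) {
    stop("no overlapping ASV ids between counts and taxonomy")
  }
  if (in_rows > in_cols) cm <- t(cm)  # ASVs must be columns
  tree <- ape::read.tree(tree_path)
  as_asv_table(cm, taxonomy, tree)
}

#' Assemble and validate an ASV table object
#'
#' @param counts Samples x ASVs nonnegative integer matrix with dimnames.
#' @param taxonomy Named character vector of lineage strings, names = ASV ids.
#' @param tree Rooted `phylo` with branch lengths; tips must cover the ASVs
#'   (ASVs without a tip are dropped with a logged count).
#' @return An `asv_table` list.
#' @export
as_asv_table <- function(counts, taxonomy, tree) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample and ASV names")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  if (is.null(tree$edge.length)) stop("tree defect: no branch lengths")
  if (any(tree$edge.length < 0)) stop("tree defect: negative branch lengths")
  if (!ape::is.rooted(tree)) stop("tree defect: tree is not rooted")
  asvs <- intersect(colnames(counts), names(taxonomy))
  if (length(asvs) == 0) stop("no overlapping ASV ids between counts and taxonomy")
  n_drop <- sum(!asvs %in% tree$tip.label)
  if (n_drop > 0) {
    glyco_log("dropping ", n_drop, " ASV(s) absent from the tree")
  }
  asvs <- sort(intersect(asvs, tree$tip.label))  # lexicographic, deterministic
  counts <- counts[sort(rownames(counts)), asvs, drop = FALSE]
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 taxonomy = taxonomy[asvs],
                 tree = tree,
                 n_dropped = n_drop),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat("asv_table:", nrow(x$counts), "samples x", ncol(x$counts), "ASVs;",
      length(x$tree$tip.label), "tree tips\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' @param k_range Integer pair, candidate numbers of clusters (default 2..20).
#' @param outlier_z Absolute z-score at or above which a participant is
#'   excluded from stratification (default 5).
#' @param n_bootstrap Bootstrap resamples for cluster stability (default 100).
#' @param n_permutations Permutations for PERMANOVA/Mantel/Procrustes
#'   (default 9999).
#' @param rarefaction_depth Per-sample target depth (default 10000).
#' @param prevalence_min Strict prevalence fraction for network nodes
#'   (default 0.20).
#' @param fdr_alpha BH threshold for differential ASVs (default 0.05).
#' @param log2fc_min Absolute log2 fold-change threshold (default 1).
#' @param assoc_q BH threshold for phenotype associations (default 0.25).
#' @param cag_alpha PERMANOVA threshold for accepting a CAG split
#'   (default 0.01).
#' @param n_trees Random-forest size (default 500).
#' @param rng_seed Master seed driving all stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(k_range = c(2L, 20L), outlier_z = 5,
                            n_bootstrap = 100L, n_permutations = 9999L,
                            rarefaction_depth = 10000L, prevalence_min = 0.20,
                            fdr_alpha = 0.05, log2fc_min = 1,
                            assoc_q = 0.25, cag_alpha = 0.01,
                            n_trees = 500L, rng_seed = 1L) {
  stopifnot(length(k_range) == 2L, k_range[1] >= 2, k_range[2] >= k_range[1],
            outlier_z > 0, n_bootstrap >= 20, n_permutations >= 99,
            rarefaction_depth > 0,
            prevalence_min >= 0, prevalence_min < 1,
            fdr_alpha > 0, fdr_alpha < 1, log2fc_min >= 0,
            assoc_q > 0, assoc_q < 1, cag_alpha > 0, cag_alpha < 1)
  structure(list(k_range = as.integer(k_range), outlier_z = outlier_z,
                 n_bootstrap = as.integer(n_bootstrap),
                 n_permutations = as.integer(n_permutations),
                 rarefaction_depth = as.integer(rarefaction_depth),
                 prevalence_min = prevalence_min, fdr_alpha = fdr_alpha,
                 log2fc_min = log2fc_min, assoc_q = assoc_q,
                 cag_alpha = cag_alpha, n_trees = as.integer(n_trees),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML or key:value file
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Write a stage-result bundle to a directory
#'
#' Writes each tabular component of `results` as a deterministic TSV plus a
#' JSON manifest recording parameters, seed and MD5 hashes of the files.
#'
#' @param results A named list; data frames / matrices become `<name>.tsv`,
#'   scalars and lists are recorded in the manifest.
#' @param out_dir Output directory (created if absent).
#' @param config Optional `pipeline_config` echoed into the manifest.
#' @return The manifest, invisibly.
#' @export
write_result_bundle <- function(results, out_dir, config = NULL) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.matrix(x)) x <- as.data.frame(x)
    if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
  }
  manifest <- list(
    created = "glycostrat",
    config = if (is.null(config)) NULL else unclass(config),
    scalars = Filter(function(x) is.atomic(x) && length(x) == 1,
                     results[!vapply(results, is.data.frame, TRUE) &
                             !vapply(results, is.matrix, TRUE)]),
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
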