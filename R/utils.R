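# internal helpers shared across modules

#' @useDynLib glycostrat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.glyco_env <- new.env(parent = emptyenv())
.glyco_env$log_file <- NULL

#' Direct log messages to a file as well as stderr
#'
#' @param path Path of the log file, or `NULL` to log to stderr only.
#' @return The previous log file path, invisibly.
#' @export
glyco_log_to <- function(path = NULL) {
  old <- .glyco_env$log_file
  .glyco_env$log_file <- path
  invisible(old)
}

# timestamped logging; warnings are real R warnings so tests can catch them
glyco_log <- function(..., level = "INFO") {
  msg <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 level, paste0(...))
  if (!is.null(.glyco_env$log_file)) {
    cat(msg, "\n", file = .glyco_env$log_file, append = TRUE, sep = "")
  }
  if (identical(level, "WARN")) warning(paste0(...), call. = FALSE)
  else message(msg)
  invisible(msg)
}

# derive reproducible 32-bit sub-seeds from one master seed, one per named
# stage, so stages are independent but the whole run is driven by one seed
derive_seeds <- function(seed, n, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) + as.integer(offset))
  sample.int(.Machine$integer.max - 1L, n)
}

# adjusted Rand index between two label vectors (used by tests and the
# pipeline's recovery diagnostics)
#' Adjusted Rand index between two partitions
#'
#' @param a,b Label vectors of equal length.
#' @return A number in \[-1, 1\]; 1 means identical partitions up to relabeling.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# geometric-mean-free closure of a count/abundance matrix to proportions
close_rows <- function(x) {
  sweep(x, 1, rowSums(x), "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
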