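# Ensemble comparison statistics: Z-scores for small structure families,
# exact two-sample Kolmogorov-Smirnov statistics and their
# significance-normalized ratio for large ensembles, heat-map matrices
# over the designated helical parameters, class-conditional histograms,
# and equilibration trimming.

#' Z-score between two parameter samples
#'
#' Standardized difference of means in the Welch form,
#' Z = (mean_a - mean_b) / sqrt(var_a/n_a + var_b/n_b);
#' antisymmetric under swapping the samples.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @export
zscore <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  dm <- mean(a) - mean(b)
  if (va + vb == 0) {
    if (dm == 0) return(0)
    stop("zero variance in both samples with unequal means")
  }
  dm / sqrt(va + vb)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' D = sup_x |ECDF_a(x) - ECDF_b(x)|, evaluated exactly over the merged
#' sample points (ties handled by evaluating after each distinct value).
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @return D in [0, 1].
#' @export
ks_statistic <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  x <- sort(unique(c(a, b)))
  fa <- findInterval(x, sort(a)) / length(a)
  fb <- findInterval(x, sort(b)) / length(b)
  max(abs(fa - fb))
}

#' Significance-normalized Kolmogorov-Smirnov ratio
#'
#' D divided by the asymptotic two-sample critical value at level
#' `alpha`, c(alpha) * sqrt((n_a + n_b) / (n_a * n_b)) with
#' c(alpha) = sqrt(-log(alpha/2) / 2); a ratio above 1 means the two
#' distributions differ at level alpha.
#'
#' @inheritParams ks_statistic
#' @param alpha significance level in (0, 1).
#' @export
ks_ratio <- function(a, b, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  na <- length(a); nb <- length(b)
  crit <- sqrt(-log(alpha / 2) / 2) * sqrt((na + nb) / (na * nb))
  ks_statistic(a, b) / crit
}

#' Heat-map matrix of ensemble comparison statistics
#'
#' One cell per (helical parameter, comparison): rows are the shared
#' parameter columns of the tables, columns the requested pairwise
#' comparisons, cells the chosen statistic.
#'
#' @param tables named list of `param_table`s with identical parameter
#'   columns.
#' @param comparisons list of length-2 character vectors naming the
#'   table pairs to compare; default all unordered pairs.
#' @param statistic `"z"`, `"ks"` or `"ks_ratio"`.
#' @param alpha significance level for `"ks_ratio"`.
#' @return numeric matrix (class `comparison_matrix`) with attributes
#'   `statistic` and `alpha`.
#' @export
comparison_matrix <- function(tables, comparisons = NULL,
                              statistic = c("z", "ks", "ks_ratio"),
                              alpha = 0.05) {
  statistic <- match.arg(statistic)
  stopifnot(is.list(tables), length(tables) >= 1, !is.null(names(tables)))
  params <- setdiff(colnames(tables[[1]]), "frame_index")
  for (tb in tables) {
    if (!identical(setdiff(colnames(tb), "frame_index"), params)) {
      stop("schema error: parameter designations differ between tables")
    }
  }
  if (is.null(comparisons)) {
    nm <- names(tables)
    comparisons <- list()
    for (i in seq_along(nm)) {
      for (j in seq_along(nm)) {
        if (i < j) comparisons[[length(comparisons) + 1]] <- c(nm[i], nm[j])
      }
    }
  }
  cmp_names <- vapply(comparisons, paste, "", collapse = " vs ")
  out <- matrix(NA_real_, length(params), length(comparisons),
                dimnames = list(params, cmp_names))
  fun <- switch(statistic, z = zscore, ks = ks_statistic,
                ks_ratio = function(a, b) ks_ratio(a, b, alpha))
  for (k in seq_along(comparisons)) {
    pa <- tables[[comparisons[[k]][1]]]
    pb <- tables[[comparisons[[k]][2]]]
    for (p in params) out[p, k] <- fun(pa[[p]], pb[[p]])
  }
  structure(out, statistic = statistic, alpha = alpha,
            class = c("comparison_matrix", "matrix", "array"))
}

#' Class-conditional histogram normalized over all frames
#'
#' Bin masses per hydrogen-bond class with a single normalization over
#' the full frame count, so curve areas reflect the relative abundance
#' of the classes. Bin edges default to Freedman-Diaconis on the pooled
#' sample, shared across classes.
#'
#' @param values numeric vector of one helical parameter, one value per
#'   frame.
#' @param classes a `frame_class_table` aligned with `values` by frame
#'   index.
#' @param breaks bin edges; computed from the pooled sample when NULL.
#' @param reference optional list(value=, source=) reference overlay
#'   (e.g. the value in a protein-bound crystal structure).
#' @return list (class `class_histogram`) with `breaks`, `mass` (class x
#'   bin matrix summing to 1 overall), `class_totals`, `reference`.
#' @export
class_histograms <- function(values, classes, breaks = NULL,
                             reference = NULL) {
  if (length(values) != nrow(classes)) {
    stop("alignment error: ", length(values), " values vs ",
         nrow(classes), " class rows")
  }
  if (is.null(breaks)) {
    bw <- 2 * stats::IQR(values) / length(values)^(1 / 3)
    if (bw <= 0) bw <- diff(range(values)) / 30 + 1e-9
    breaks <- seq(min(values) - bw / 2, max(values) + bw, by = bw)
  }
  labs <- unique(classes$class)
  mass <- matrix(0, length(labs), length(breaks) - 1,
                 dimnames = list(labs, NULL))
  n_total <- length(values)
  for (lb in labs) {
    v <- values[classes$class == lb]
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    mass[lb, ] <- h$counts / n_total
  }
  structure(list(breaks = breaks, mass = mass,
                 class_totals = rowSums(mass), reference = reference),
            class = "class_histogram")
}

#' Discard equilibration frames
#'
#' Removes the leading burn-in portion of a parameter table: a fraction
#' (< 1) or an absolute frame count (>= 1); with a `run` column the
#' trimming is applied within each run.
#'
#' @param table a `param_table` (optionally with a `run` column).
#' @param burn_in fraction in [0, 1) or frame count; default 0.4
#'   (keep the final 60 percent, e.g. the last 6 ns of a 10 ns run).
#' @export
trim_equilibration <- function(table, burn_in = 0.4) {
  split_col <- if ("run" %in% colnames(table)) table$run else
    rep(1L, nrow(table))
  keep <- logical(nrow(table))
  for (r in unique(split_col)) {
    idx <- which(split_col == r)
    nb <- if (burn_in < 1) floor(burn_in * length(idx)) else as.integer(burn_in)
    if (nb >= length(idx)) {
      stop("empty-table error: burn-in removes every frame of run ", r)
    }
    keep[idx[seq_along(idx) > nb]] <- TRUE
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  attr(out, "designation") <- attr(table, "designation")
  out
}

#' Write a comparison matrix as tab-separated text
#' @param mat a `comparison_matrix`.
#' @param path file path.
#' @export
write_comparison_matrix <- function(mat, path) {
  df <- data.frame(parameter = rownames(mat), unclass(mat),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
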