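# Helpers for working with published summary tables (class-frequency
# rows and structure-determination restraint statistics) shipped as
# tab-separated text under inst/extdata.

#' Read a published class-frequency table
#'
#' Expects columns `ensemble`, `class`, `percent`; returns one
#' `frequency_table` per ensemble label.
#'
#' @param path TSV file path.
#' @return named list of `frequency_table`s.
#' @export
read_frequency_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("ensemble", "class", "percent") %in% names(df)))
  out <- lapply(split(df, df$ensemble), function(d) {
    frequency_table_from_percent(stats::setNames(d$percent, d$class))
  })
  out
}

#' Distance-constraint bookkeeping from a structural-statistics table
#'
#' Sums the experimental distance-constraint categories (intra-residue,
#' inter-residue, cross-strand) for one structure column and compares
#' with the quoted total.
#'
#' @param path TSV with columns `category` and one column per structure.
#' @param column structure column to check.
#' @return list with `categories`, `sum`, `stated_total`, `consistent`.
#' @export
distance_constraint_check <- function(path, column) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!column %in% names(df)) stop("no column '", column, "'")
  cats <- df[df$category != "total", ]
  total <- df[df$category == "total", column]
  if (length(total) != 1) stop("table must contain one 'total' row")
  s <- sum(cats[[column]])
  list(categories = stats::setNames(cats[[column]], cats$category),
       sum = s, stated_total = total, consistent = s == total)
}
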