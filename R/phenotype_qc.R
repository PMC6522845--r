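#' Asymmetric median absolute deviation
#'
#' Metabolite intensity distributions are skewed -- low intensities are far
#' more frequent than high ones -- so a single MAD over- or under-states
#' the spread of one tail.  This computes the median over all non-missing
#' values (zeros included by default) and then a separate raw MAD for each
#' tail: the median of `|x - med|` over values strictly below (lower) and
#' strictly above (upper) the median.  Values equal to the median belong to
#' neither tail.  No 1.4826 normal-consistency constant is applied; the
#' outlier cut-off `k` is calibrated against raw MAD distances.
#'
#' @param x numeric vector; `NA` allowed (ignored).
#' @param include_zeros include zero intensities when computing the median
#'   and tails (default `TRUE`).
#' @return List with `median`, `lower_mad`, `upper_mad`.  An empty tail
#'   yields `NA` for that side's MAD.
#' @examples
#' asymmetric_mad(c(1, 2, 3, 4, 100)) # median 3, lower 1.5, upper 49
#' @export
asymmetric_mad <- function(x, include_zeros = TRUE) {
  x <- x[!is.na(x)]
  if (!include_zeros) x <- x[x != 0]
  if (length(x) == 0L) {
    stop_data("asymmetric_mad: no non-missing values")
  }
  med <- stats::median(x)
  lower <- x[x < med]
  upper <- x[x > med]
  list(
    median = med,
    lower_mad = if (length(lower)) stats::median(med - lower) else NA_real_,
    upper_mad = if (length(upper)) stats::median(upper - med) else NA_real_
  )
}

#' Flag outliers at k asymmetric MADs from the median
#'
#' A value is flagged when its distance from the median exceeds `k` times
#' the raw MAD of its own tail.  If a tail's MAD is undefined (empty tail)
#' or zero, nothing is flagged on that side and a warning is emitted,
#' since the distance is not measurable there.
#'
#' @param x numeric vector; `NA` values are never flagged.
#' @param k MAD-distance cut-off (default 5).
#' @param scale_constant multiplier applied to both tail MADs before
#'   comparison (default 1 = raw MAD; 1.4826 gives the normal-consistent
#'   variant).
#' @param include_zeros passed to [asymmetric_mad()].
#' @return Logical vector the length of `x`.
#' @examples
#' flag_outliers(c(1, 2, 3, 4, 100), k = 5) # none: 97/49 < 5
#' @export
flag_outliers <- function(x, k = 5, scale_constant = 1, include_zeros = TRUE) {
  m <- asymmetric_mad(x, include_zeros = include_zeros)
  flag <- rep(FALSE, length(x))
  up <- !is.na(x) & x > m$median
  lo <- !is.na(x) & x < m$median
  umad <- m$upper_mad * scale_constant
  lmad <- m$lower_mad * scale_constant
  if (is.na(umad) || umad == 0) {
    warning("upper-tail MAD undefined or zero; upper tail not screened")
  } else if (any(up)) {
    flag[up] <- (x[up] - m$median) / umad > k
  }
  if (is.na(lmad) || lmad == 0) {
    warning("lower-tail MAD undefined or zero; lower tail not screened")
  } else if (any(lo)) {
    flag[lo] <- (m$median - x[lo]) / lmad > k
  }
  flag
}

#' Screen a phenotype intensity matrix for outliers and thin coverage
#'
#' Applies [flag_outliers()] to every metabolite (column), replaces flagged
#' intensities with `NA`, and drops any metabolite left with fewer than
#' `min_valid` non-zero, non-missing, non-outlier values -- the guard
#' against under-represented metabolites.  The boundary is inclusive:
#' exactly `min_valid` valid values keeps the column.
#'
#' @param mat numeric matrix, genotypes in rows, metabolites in columns;
#'   entries are nonnegative intensities, `NA` = missing.
#' @param k MAD-distance cut-off passed to [flag_outliers()].
#' @param min_valid minimum number of non-zero, non-outlier values a
#'   metabolite must retain (default 100).
#' @param scale_constant,include_zeros passed to [flag_outliers()].
#' @return List with `matrix` (flagged entries set to `NA`, dropped columns
#'   removed) and `report`, a data frame with one row per input metabolite:
#'   `phenotype_id`, `median`, `lower_mad`, `upper_mad`, `n_flagged`,
#'   `n_valid`, `kept`.  The flagged cells are attached as
#'   `attr(report, "flagged")` (`phenotype_id`, `genotype_id`, `value`).
#' @export
filter_metabolites <- function(mat, k = 5, min_valid = 100,
                               scale_constant = 1, include_zeros = TRUE) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(colnames(mat))) colnames(mat) <- seq_ids("PH", ncol(mat))
  if (is.null(rownames(mat))) rownames(mat) <- seq_ids("GT", nrow(mat))
  if (any(mat < 0, na.rm = TRUE)) {
    stop_data("filter_metabolites: negative intensities are not allowed")
  }
  rep_rows <- vector("list", ncol(mat))
  flagged_cells <- vector("list", ncol(mat))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    m <- asymmetric_mad(x, include_zeros = include_zeros)
    flag <- suppressWarnings(
      flag_outliers(x, k = k, scale_constant = scale_constant,
                    include_zeros = include_zeros)
    )
    out[flag, j] <- NA
    n_valid <- sum(!is.na(x) & x > 0 & !flag)
    rep_rows[[j]] <- data.frame(
      phenotype_id = colnames(mat)[j],
      median = m$median, lower_mad = m$lower_mad, upper_mad = m$upper_mad,
      n_flagged = sum(flag), n_valid = n_valid,
      kept = n_valid >= min_valid,
      stringsAsFactors = FALSE
    )
    if (any(flag)) {
      flagged_cells[[j]] <- data.frame(
        phenotype_id = colnames(mat)[j],
        genotype_id = rownames(mat)[flag],
        value = x[flag],
        stringsAsFactors = FALSE
      )
    }
  }
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  flagged <- if (any(!vapply(flagged_cells, is.null, logical(1)))) {
    do.call(rbind, flagged_cells[!vapply(flagged_cells, is.null, logical(1))])
  } else {
    data.frame(phenotype_id = character(0), genotype_id = character(0),
               value = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(flagged) <- NULL
  attr(report, "flagged") <- flagged
  list(matrix = out[, report$kept, drop = FALSE], report = report)
}

#' Read / write a phenotype intensity matrix as TSV
#'
#' Genotypes in rows (first column `genotype_id`), metabolites in columns.
#'
#' @param path TSV file path.
#' @return Numeric matrix with dimnames.
#' @export
read_phenotype_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1L]]
  m
}

#' @rdname read_phenotype_matrix
#' @param mat numeric matrix to write.
#' @export
write_phenotype_matrix <- function(mat, path) {
  df <- data.frame(genotype_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an outlier report as TSV or JSON
#'
#' @param report the `report` element of [filter_metabolites()].
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_outlier_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(columns = report, flagged = attr(report, "flagged")),
      path, dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
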