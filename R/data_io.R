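#' Construct an expression matrix
#'
#' Wraps a numeric proteins-by-samples matrix and validates its identifiers.
#' The object is an ordinary numeric matrix carrying three logical state
#' attributes (`quantile_normalized`, `imputed`, `clr_transformed`) that the
#' processing steps set as they are applied.
#'
#' @param values numeric matrix, proteins in rows, samples in columns; both
#'   dimnames must be present and duplicate-free. `NA` marks a missing
#'   (unquantified) protein, never zero.
#' @return a numeric matrix of class `expr_matrix`.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs protein row names and sample column names")
  dup_p <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_p))
    stop("duplicated protein IDs: ", paste(dup_p, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicated sample IDs: ", paste(dup_s, collapse = ", "))
  structure(values,
            quantile_normalized = isTRUE(attr(values, "quantile_normalized")),
            imputed             = isTRUE(attr(values, "imputed")),
            clr_transformed     = isTRUE(attr(values, "clr_transformed")),
            class = c("expr_matrix", class(values)))
}

.set_flag <- function(m, flag) {
  m <- expression_matrix(unclass(m))
  attr(m, flag) <- TRUE
  m
}

#' Read a delimited protein abundance matrix
#'
#' Expects one header row of sample IDs and a first column of protein IDs.
#' Empty cells and the literal strings `NA`/`NaN` become missing values;
#' they are never silently converted to zero. If more than half of the row
#' IDs fail `protein_regex` while the column IDs match it, the matrix is
#' assumed transposed and flipped (overridable with `orientation_hint`).
#'
#' @param path file path to a TSV/CSV table.
#' @param sep field separator; default tab, use "," for CSV.
#' @param orientation_hint one of "auto", "proteins_in_rows",
#'   "samples_in_rows".
#' @param protein_regex regex used by orientation auto-detection.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, sep = "\t",
                                   orientation_hint = c("auto", "proteins_in_rows", "samples_in_rows"),
                                   protein_regex = "^[A-Za-z0-9_.-]+$") {
  orientation_hint <- match.arg(orientation_hint)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("", "NA", "NaN"), comment.char = "")
  if (ncol(df) < 2) stop("expected an ID column plus at least one sample column")
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicated row IDs in ", path, ": ", paste(dup, collapse = ", "))
  cells <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                 ids[bad[1, 1]], colnames(cells)[bad[1, 2]], cells[bad[1, 1], bad[1, 2]]))
  dimnames(num) <- list(ids, colnames(cells))
  if (orientation_hint == "samples_in_rows") {
    num <- t(num)
  } else if (orientation_hint == "auto") {
    row_hit <- mean(grepl(protein_regex, rownames(num)))
    col_hit <- mean(grepl(protein_regex, colnames(num)))
    if (row_hit <= 0.5 && col_hit > 0.5) num <- t(num)
  }
  expression_matrix(num)
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression_matrix()]; round-trips values through
#' full-precision decimal text.
#'
#' @param m expression matrix.
#' @param path output path.
#' @param sep field separator.
#' @param id_column name for the protein ID column.
#' @export
write_expression_matrix <- function(m, path, sep = "\t", id_column = "protein_id") {
  vals <- unclass(m)
  txt <- matrix(vapply(vals, function(v)
    if (is.na(v)) NA_character_ else format(v, digits = 17), ""),
    nrow = nrow(vals), dimnames = dimnames(vals))
  df <- data.frame(rownames(m), txt, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_column, colnames(m))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Quantile normalize a protein abundance matrix
#'
#' Forces every sample column onto the common distribution given by the
#' across-sample mean of sorted columns; tied values receive the mean of the
#' normalized values at their tied ranks. Delegates to
#' `limma::normalizeQuantiles`, the standard implementation for proteomic and
#' array intensity data.
#'
#' @param m expression matrix (missing values allowed; they stay missing).
#' @return normalized matrix with the `quantile_normalized` flag set.
#' @export
quantile_normalize <- function(m) {
  if (ncol(m) < 2) {
    warning("single-sample matrix: quantile normalization is a no-op")
    return(.set_flag(m, "quantile_normalized"))
  }
  out <- limma::normalizeQuantiles(unclass(m), ties = TRUE)
  dimnames(out) <- dimnames(m)
  out <- .copy_flags(out, m)
  .set_flag(out, "quantile_normalized")
}

.copy_flags <- function(to, from) {
  for (f in c("quantile_normalized", "imputed", "clr_transformed"))
    attr(to, f) <- isTRUE(attr(from, f))
  to
}

#' Impute missing abundances at the global minimum
#'
#' Every missing entry is replaced by the minimum observed value across the
#' whole matrix — the convention for left-censored missingness in label-free
#' proteomics, where a protein is usually missing because it sat below the
#' detection limit.
#'
#' @param m expression matrix with at least one observed value.
#' @return matrix with no missing entries and the `imputed` flag set.
#' @export
impute_min <- function(m) {
  obs <- !is.na(m)
  if (!any(obs)) stop("cannot impute an all-missing matrix")
  out <- unclass(m)
  out[!obs] <- min(out[obs])
  out <- .copy_flags(out, m)
  .set_flag(out, "imputed")
}

#' Centered log-ratio transform per sample
#'
#' For each sample column, log-transforms and subtracts the column's mean log
#' value so the output column sums to zero. Defined only for strictly positive
#' input; a pseudo-count (half the smallest positive observed value) can be
#' added to nonpositive entries when `pseudo_count = TRUE`.
#'
#' @param m expression matrix without missing values.
#' @param pseudo_count add half the minimum positive value to entries <= 0
#'   instead of failing. Default `FALSE`.
#' @return transformed matrix with the `clr_transformed` flag set.
#' @export
clr_transform <- function(m, pseudo_count = FALSE) {
  x <- unclass(m)
  if (anyNA(x)) stop("clr_transform requires a complete matrix; impute first")
  if (any(x <= 0)) {
    if (!pseudo_count)
      stop("nonpositive values present; enable pseudo_count or shift the data")
    pc <- 0.5 * min(x[x > 0])
    x[x <= 0] <- x[x <= 0] + pc
    if (any(x <= 0)) stop("pseudo-count did not make all values positive")
  }
  lx <- log(x)
  out <- sweep(lx, 2L, colMeans(lx), "-")
  out <- .copy_flags(out, m)
  .set_flag(out, "clr_transformed")
}

#' Read a clinical survival table
#'
#' @param path TSV/CSV with required columns `sample_id`, `dfs_time`,
#'   `dfs_event` (and optionally `os_time`, `os_event` plus any covariates).
#' @param sep field separator.
#' @return a validated `data.frame` (see [survival_table()]).
#' @export
read_survival_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  survival_table(df)
}

#' Validate a clinical survival table
#'
#' Checks the per-sample follow-up fields: positive times, binary event
#' indicators, unique sample IDs. Extra columns are kept as clinical
#' covariates (e.g. MVI, AFP class, diameter class, TNM stage,
#' differentiation, HBV-DNA).
#'
#' @param df data.frame with `sample_id`, `dfs_time`, `dfs_event` and
#'   optionally `os_time`, `os_event`.
#' @return the validated data.frame.
#' @export
survival_table <- function(df) {
  need <- c("sample_id", "dfs_time", "dfs_event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing clinical columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in clinical table")
  .check_surv_pair <- function(time, event, lab) {
    if (any(!is.na(time) & time <= 0)) stop(lab, " times must be strictly positive")
    ev <- event[!is.na(event)]
    if (!all(ev %in% c(0, 1))) stop(lab, " events must be 0/1")
  }
  .check_surv_pair(df$dfs_time, df$dfs_event, "DFS")
  if (all(c("os_time", "os_event") %in% names(df)))
    .check_surv_pair(df$os_time, df$os_event, "OS")
  df
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, members... Duplicate members within a set are
#' dropped with a warning.
#'
#' @param path GMT file.
#' @return named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), description = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 0L) < 3L)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields in ", path)
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicated set names in ", path)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  ndup <- vapply(sets, anyDuplicated, 0L)
  if (any(ndup > 0))
    warning("duplicate members removed in sets: ",
            paste(nm[ndup > 0], collapse = ", "))
  sets <- lapply(sets, unique)
  names(sets) <- nm
  names(desc) <- nm
  structure(sets, description = desc)
}

#' Write a gene-set collection in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description (recycled); defaults to the
#'   set name.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- names(sets)
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), description, sets)
  writeLines(unname(lines), path)
  invisible(path)
}
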