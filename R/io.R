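# Plain-text I/O: tab-delimited gene-by-time matrices (first column gene
# identifiers, header row of numeric time values or arbitrary column
# names), labels tables, and the normalization used for log-scale yeast
# matrices.

#' Read a gene-by-time expression matrix
#'
#' Expects a tab-delimited file with gene identifiers in the first column
#' and one column per time point. If the header entries parse as numbers
#' they are used as the time coordinates; otherwise sequential indices
#' `0..m-1` are used. Genes with any missing value are dropped with a
#' message; duplicated gene identifiers are disambiguated with suffixes.
#'
#' @param path File path.
#' @return A [time_course_matrix()].
#' @export
read_time_course <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expected gene ids plus at least 2 time columns",
                          call. = FALSE)
  ids <- as.character(df[[1]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      suppressWarnings(num <- as.numeric(vals[[j]]))
      bad <- which(!is.na(vals[[j]]) & is.na(num) &
                     !(vals[[j]] %in% c("NA", "")))
      if (length(bad) > 0) {
        stop("non-numeric value at row ", bad[1], ", column ", j + 1L,
             ": '", vals[bad[1], j], "'", call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  M <- as.matrix(vals)
  keep <- stats::complete.cases(M)
  if (any(!keep)) {
    message("dropping ", sum(!keep), " gene(s) with missing values")
    M <- M[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  if (anyDuplicated(ids)) {
    warning("duplicate gene identifiers disambiguated with suffixes",
            call. = FALSE)
    ids <- make.unique(ids)
  }
  suppressWarnings(times <- as.numeric(colnames(vals)))
  if (anyNA(times)) times <- seq_len(ncol(M)) - 1
  time_course_matrix(M, times = times, gene_ids = ids)
}

#' Write a gene-by-time expression matrix
#'
#' Tab-delimited, with 17 significant digits so a write/read round trip
#' reproduces the values bit-exactly.
#'
#' @param data A [time_course_matrix()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_time_course <- function(data, path) {
  stopifnot(inherits(data, "tc_matrix"))
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  header <- paste(c("gene_id", fmt(data$times)), collapse = "\t")
  rows <- vapply(seq_len(nrow(data$values)), function(i) {
    paste(c(data$gene_ids[i], fmt(data$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Column-then-row standardization of a time-course matrix
#'
#' Optionally log-transforms, then standardizes columns to mean 0 / SD 1,
#' then rows, in that fixed order (the convention used for log-scale yeast
#' matrices normalized "by columns and rows").
#'
#' @param data A [time_course_matrix()].
#' @param log_transform Take `log` first (values must be strictly
#'   positive).
#' @return A normalized [time_course_matrix()].
#' @export
normalize_time_course <- function(data, log_transform = FALSE) {
  stopifnot(inherits(data, "tc_matrix"))
  M <- data$values
  if (log_transform) {
    if (any(M <= 0)) {
      stop("log transform requires strictly positive values", call. = FALSE)
    }
    M <- log(M)
  }
  raw_row_sd <- apply(M, 1L, stats::sd)
  if (any(raw_row_sd < 1e-12)) {
    stop("degenerate normalization: row ", which(raw_row_sd < 1e-12)[1],
         " has zero variance", call. = FALSE)
  }
  col_sd <- apply(M, 2L, stats::sd)
  if (any(col_sd < 1e-12)) {
    stop("degenerate normalization: column ", which(col_sd < 1e-12)[1],
         " has zero variance", call. = FALSE)
  }
  M <- scale(M)
  row_sd <- apply(M, 1L, stats::sd)
  if (any(row_sd < 1e-12)) {
    stop("degenerate normalization: row ", which(row_sd < 1e-12)[1],
         " has zero variance", call. = FALSE)
  }
  M <- t(scale(t(M)))
  time_course_matrix(unclass(M), times = data$times, gene_ids = data$gene_ids)
}

#' Write the standard outputs of a fit
#'
#' Writes `labels.tsv` (gene id, MAP label, max posterior),
#' `posterior.tsv` (full posterior matrix) and `model.txt`
#' (see [write_model()]) into `dir`.
#'
#' @param fit A `tc_fit`.
#' @param data The [time_course_matrix()] that was fitted.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, data, dir) {
  stopifnot(inherits(fit, "tc_fit"), inherits(data, "tc_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  labels <- data.frame(gene_id = data$gene_ids, label = fit$labels,
                       max_posterior = apply(fit$tau, 1L, max))
  utils::write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  post <- data.frame(gene_id = data$gene_ids, fit$tau)
  names(post) <- c("gene_id", paste0("comp", seq_len(ncol(fit$tau))))
  utils::write.table(post, file.path(dir, "posterior.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_model(fit$model, file.path(dir, "model.txt"))
  invisible(dir)
}
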