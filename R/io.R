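# Readers, writers and alignment for beta-value matrices and sample sheets.
#
# The canonical in-memory form of a beta matrix is a base numeric matrix with
# probes in rows and samples in columns; missing entries are NA. Sample sheets
# are data frames with one row per sample.

BOUND_TOL <- 1e-9

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.check_rectangular <- function(path, delim) {
  fields <- utils::count.fields(path, sep = delim, quote = "\"",
                                comment.char = "")
  fields <- fields[!is.na(fields)]
  if (length(fields) > 1L && length(unique(fields)) > 1L) {
    bad <- which(fields != fields[1L])[1L]
    stop("ragged row in '", path, "' at line ", bad,
         ": expected ", fields[1L], " fields, found ", fields[bad])
  }
}

.check_unique <- function(ids, what) {
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate ", what, ": ", paste(unique(dup), collapse = ", "))
  }
}

# Clamp values within round-off of [0,1]; reject anything further out.
.validate_betas <- function(v, context = "beta matrix") {
  bad <- !is.na(v) & (v < -BOUND_TOL | v > 1 + BOUND_TOL)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(context, " contains value ", format(v[i]), " outside [0, 1]")
  }
  pmin(pmax(v, 0), 1)
}

#' Read a beta-value matrix from delimited text
#'
#' Reads a TSV or CSV file (delimiter chosen by extension: `.csv` is
#' comma-separated, anything else tab-separated) holding methylation beta
#' values with one header row and one identifier column. Empty and
#' non-numeric cells become `NA`. Values outside \[0, 1\] by more than 1e-9
#' raise an error; values within round-off of the bounds are clamped.
#'
#' @param path Path to the delimited text file.
#' @param orientation Either `"probes_in_rows"` (the GEO series-matrix
#'   convention, default) or `"probes_in_columns"`; the returned matrix is
#'   always probes x samples.
#' @return A numeric matrix, probes in rows (rownames = probe ids), samples
#'   in columns (colnames = sample ids).
#' @seealso [write_beta_matrix()], [read_sample_sheet()]
#' @export
read_beta_matrix <- function(path,
                             orientation = c("probes_in_rows",
                                             "probes_in_columns")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- .delim_for(path)
  .check_rectangular(path, delim)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected an identifier column plus data columns")
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  .check_unique(row_ids, "row identifiers")
  .check_unique(col_ids, "column identifiers")
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df)))
  )
  vals <- matrix(vals, nrow = nrow(df), ncol = ncol(df) - 1L,
                 dimnames = list(row_ids, col_ids))
  vals[] <- .validate_betas(vals, context = paste0("'", path, "'"))
  if (orientation == "probes_in_columns") vals <- t(vals)
  vals
}

#' Write a beta-value matrix to delimited text
#'
#' Writes probes in rows with a leading `probe_id` column, at full double
#' precision so that a write/read round trip reproduces values to better
#' than 1e-12.
#'
#' @param matrix Numeric probes x samples matrix with dimnames.
#' @param path Output path; `.csv` selects comma-separated, otherwise TSV.
#' @return Invisibly, `path`.
#' @export
write_beta_matrix <- function(matrix, path) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  delim <- .delim_for(path)
  body <- apply(matrix, 2L, function(col) {
    ifelse(is.na(col), "NA", formatC(col, digits = 17, format = "g"))
  })
  body <- matrix(body, nrow = nrow(matrix))
  lines <- c(
    paste(c("probe_id", colnames(matrix)), collapse = delim),
    vapply(seq_len(nrow(matrix)), function(i) {
      paste(c(rownames(matrix)[i], body[i, ]), collapse = delim)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

.SEX_LEVELS <- c("male", "female", "unknown")

.normalize_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("male", "m")] <- "male"
  out[x %in% c("female", "f")] <- "female"
  unrecognized <- !is.na(x) & x != "" & !(x %in% c("male", "m", "female",
                                                   "f", "unknown", "u"))
  if (any(unrecognized)) {
    warning("unrecognized sex label(s) mapped to 'unknown': ",
            paste(unique(x[unrecognized]), collapse = ", "))
  }
  out
}

#' Read a sample sheet of per-sample phenotypes
#'
#' Reads a delimited text file with a header containing at least
#' `sample_id`; the optional columns `tissue`, `eGFR`, `IF`, `age`, `sex`
#' and `BMI` are matched case-insensitively. Missing optional fields are
#' `NA`, never zero. `IF` is interstitial fibrosis in percent and must lie
#' in \[0, 100\]; `eGFR` (mL/min/1.73m2) must be non-negative.
#'
#' @param path Path to the delimited text file.
#' @return A data frame with columns `sample_id`, `tissue`, `eGFR`, `IF`,
#'   `age`, `sex`, `BMI` (one row per sample; unknown fields `NA`, sex
#'   `"unknown"`).
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- .delim_for(path)
  .check_rectangular(path, delim)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  lower <- tolower(colnames(df))
  pick <- function(name) {
    i <- match(tolower(name), lower)
    if (is.na(i)) NULL else df[[i]]
  }
  ids <- pick("sample_id")
  if (is.null(ids)) stop("sample sheet must contain a 'sample_id' column")
  .check_unique(ids, "sample_id")
  num <- function(x) {
    if (is.null(x)) return(rep(NA_real_, length(ids)))
    x[x == ""] <- NA
    suppressWarnings(as.numeric(x))
  }
  chr <- function(x) {
    if (is.null(x)) return(rep(NA_character_, length(ids)))
    x[x == ""] <- NA
    x
  }
  sheet <- data.frame(
    sample_id = ids,
    tissue    = chr(pick("tissue")),
    eGFR      = num(pick("eGFR")),
    IF        = num(pick("IF")),
    age       = num(pick("age")),
    sex       = .normalize_sex(chr(pick("sex"))),
    BMI       = num(pick("BMI")),
    stringsAsFactors = FALSE
  )
  validate_sample_sheet(sheet)
  sheet
}

#' Validate a sample sheet
#'
#' Checks the sample-sheet invariants: unique `sample_id`, `IF` within
#' \[0, 100\] and `eGFR` non-negative wherever present.
#'
#' @param sheet A sample-sheet data frame as returned by
#'   [read_sample_sheet()].
#' @return Invisibly, `sheet`.
#' @export
validate_sample_sheet <- function(sheet) {
  stopifnot(is.data.frame(sheet), "sample_id" %in% colnames(sheet))
  .check_unique(sheet$sample_id, "sample_id")
  if ("IF" %in% colnames(sheet)) {
    bad <- !is.na(sheet$IF) & (sheet$IF < 0 | sheet$IF > 100)
    if (any(bad)) {
      stop("IF outside [0, 100] for sample(s): ",
           paste(sheet$sample_id[bad], collapse = ", "))
    }
  }
  if ("eGFR" %in% colnames(sheet)) {
    bad <- !is.na(sheet$eGFR) & sheet$eGFR < 0
    if (any(bad)) {
      stop("negative eGFR for sample(s): ",
           paste(sheet$sample_id[bad], collapse = ", "))
    }
  }
  invisible(sheet)
}

#' Write a sample sheet to delimited text
#'
#' @param sheet Sample-sheet data frame.
#' @param path Output path; `.csv` selects comma-separated, otherwise TSV.
#' @return Invisibly, `path`.
#' @export
write_sample_sheet <- function(sheet, path) {
  write_results_table(sheet, path, sort_by = "sample_id")
  invisible(path)
}

#' Align a beta matrix with a sample sheet
#'
#' Restricts both objects to their common sample ids and orders both
#' identically (lexicographically by sample id, so the result does not
#' depend on input order). A message reports how many samples were dropped
#' from each side.
#'
#' @param matrix Probes x samples beta matrix.
#' @param sheet Sample-sheet data frame.
#' @return A list with elements `matrix` and `sheet`, sample-aligned.
#' @export
align_samples <- function(matrix, sheet) {
  stopifnot(is.matrix(matrix), is.data.frame(sheet))
  common <- sort(intersect(colnames(matrix), sheet$sample_id))
  if (length(common) == 0L) {
    stop("no samples shared between beta matrix and sample sheet")
  }
  dropped_m <- ncol(matrix) - length(common)
  dropped_s <- nrow(sheet) - length(common)
  if (dropped_m > 0L || dropped_s > 0L) {
    message("align_samples: dropped ", dropped_m, " matrix sample(s) and ",
            dropped_s, " sheet sample(s); ", length(common), " retained")
  }
  list(
    matrix = matrix[, common, drop = FALSE],
    sheet  = sheet[match(common, sheet$sample_id), , drop = FALSE]
  )
}

#' Write a results table as TSV
#'
#' Writes any homogeneous result collection (a data frame) as a
#' tab-separated file with header, full float precision (17 significant
#' digits) and a deterministic row order, so repeated writes of the same
#' records are byte-identical.
#'
#' @param records A data frame of results.
#' @param path Output path.
#' @param sort_by Column used for the deterministic row order; defaults to
#'   `probe_id` or `sample_id` if present, else input order.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(records, path, sort_by = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(sort_by)) {
    sort_by <- intersect(c("probe_id", "sample_id"), colnames(records))[1]
  }
  if (!is.na(sort_by) && !is.null(sort_by) && nrow(records) > 0L) {
    records <- records[order(records[[sort_by]]), , drop = FALSE]
  }
  delim <- .delim_for(path)
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "NA",
                         formatC(out[[j]], digits = 17, format = "g"))
    }
  }
  lines <- paste(colnames(out), collapse = delim)
  if (nrow(out) > 0L) {
    body <- do.call(paste, c(lapply(out, as.character), sep = delim))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a multi-tissue methylation atlas
#'
#' Bundles a probes x samples beta matrix with a per-sample tissue label,
#' the form in which public multi-tissue methylation references are
#' distributed. At least two distinct tissues are required.
#'
#' @param matrix Probes x samples beta matrix.
#' @param tissues Character vector of tissue labels, either named by sample
#'   id or in matrix column order.
#' @return An object of class `tissue_atlas`: a list with elements
#'   `matrix` and `tissues` (named character vector).
#' @export
tissue_atlas <- function(matrix, tissues) {
  stopifnot(is.matrix(matrix), !is.null(colnames(matrix)))
  if (is.null(names(tissues))) {
    stopifnot(length(tissues) == ncol(matrix))
    names(tissues) <- colnames(matrix)
  }
  missing_lab <- setdiff(colnames(matrix), names(tissues))
  if (length(missing_lab) > 0L) {
    stop("samples without a tissue label: ",
         paste(missing_lab, collapse = ", "))
  }
  tissues <- tissues[colnames(matrix)]
  if (length(unique(tissues)) < 2L) {
    stop("an atlas needs at least 2 distinct tissues")
  }
  structure(list(matrix = matrix, tissues = tissues),
            class = "tissue_atlas")
}

#' @export
print.tissue_atlas <- function(x, ...) {
  tab <- table(x$tissues)
  cat("tissue_atlas: ", nrow(x$matrix), " probes x ", ncol(x$matrix),
      " samples, ", length(tab), " tissues\n", sep = "")
  cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
  invisible(x)
}

#' Read a tissue atlas from a beta matrix and sample sheet
#'
#' @param matrix_path Path to the atlas beta matrix.
#' @param sheet_path Path to the sample sheet carrying the `tissue` column.
#' @param orientation Matrix orientation, see [read_beta_matrix()].
#' @return A `tissue_atlas`.
#' @export
read_tissue_atlas <- function(matrix_path, sheet_path,
                              orientation = "probes_in_rows") {
  m <- read_beta_matrix(matrix_path, orientation)
  sheet <- read_sample_sheet(sheet_path)
  if (all(is.na(sheet$tissue))) {
    stop("atlas sample sheet carries no tissue labels")
  }
  al <- align_samples(m, sheet)
  tissue_atlas(al$matrix, stats::setNames(al$sheet$tissue,
                                          al$sheet$sample_id))
}
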