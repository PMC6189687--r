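#' Cp matrix: quantification cycles with sample metadata
#'
#' A `cp_matrix` couples a genes x samples grid of quantification cycles
#' (Cp/Ct values) with a sample sheet describing each column. It is the input
#' container for every stability method in the package.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers, column names are sample identifiers. Missing
#'   reactions (no amplification, "Undetermined") are `NA`.
#' @param samples Data frame with one row per column of `values`, containing
#'   at least `sample_id`, `group`, `timepoint_h` and `replicate`.
#'
#' @return An object of class `cp_matrix`: a list with elements `values`
#'   (numeric matrix) and `samples` (data frame).
#'
#' @details Invariants enforced by [validate_cp_matrix()]: unique gene and
#'   sample identifiers, matching dimensions between grid and sample sheet,
#'   every non-missing Cp finite and strictly positive, `timepoint_h >= 0`
#'   and `replicate >= 1`.
#'
#' @examples
#' m <- cp_matrix(
#'   matrix(c(20, 21, 20.5, 25, 26, 25.5), nrow = 2, byrow = TRUE,
#'          dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))),
#'   data.frame(sample_id = c("s1", "s2", "s3"),
#'              group = c("control", "treated", "treated"),
#'              timepoint_h = c(0, 24, 48), replicate = 1L)
#' )
#' m
#' @export
cp_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(rownames(values)))
    stop("'values' must have gene identifiers as row names")
  if (is.null(colnames(values))) {
    if (!is.null(samples$sample_id) && nrow(samples) == ncol(values))
      colnames(values) <- samples$sample_id
    else stop("'values' must have sample identifiers as column names")
  }
  x <- structure(list(values = values, samples = samples),
                 class = "cp_matrix")
  validate_cp_matrix(x)
}

#' Validate a cp_matrix
#'
#' Checks the structural invariants of a [cp_matrix()] and returns the object
#' invisibly-unchanged, or fails with a message naming the offending cell,
#' gene or sample.
#'
#' @param x A `cp_matrix`.
#' @return `x`, invisibly unchanged, if valid.
#' @export
validate_cp_matrix <- function(x) {
  stopifnot(inherits(x, "cp_matrix"))
  v <- x$values
  s <- x$samples
  need <- c("sample_id", "group", "timepoint_h", "replicate")
  miss <- setdiff(need, names(s))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(rownames(v)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (anyDuplicated(s$sample_id))
    stop("duplicate sample identifiers: ",
         paste(unique(s$sample_id[duplicated(s$sample_id)]), collapse = ", "))
  if (nrow(s) != ncol(v))
    stop("sample sheet has ", nrow(s), " rows but Cp table has ",
         ncol(v), " sample columns")
  if (!all(colnames(v) == s$sample_id))
    stop("sample sheet order does not match Cp table columns; first ",
         "mismatch at column '",
         colnames(v)[which(colnames(v) != s$sample_id)[1]], "'")
  bad <- which(!is.na(v) & (!is.finite(v) | v <= 0), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite or non-positive Cp at gene '",
         rownames(v)[bad[1, 1]], "', sample '", colnames(v)[bad[1, 2]], "'")
  if (any(s$timepoint_h < 0)) stop("timepoint_h must be non-negative")
  if (any(s$replicate < 1)) stop("replicate index must be >= 1")
  invisible(x)
}

#' @export
print.cp_matrix <- function(x, ...) {
  v <- x$values
  cat("Cp matrix: ", nrow(v), " genes x ", ncol(v), " samples\n", sep = "")
  cat("  groups:     ", paste(unique(x$samples$group), collapse = ", "), "\n",
      sep = "")
  cat("  timepoints: ",
      paste(sort(unique(x$samples$timepoint_h)), collapse = ", "),
      " h\n", sep = "")
  nmiss <- sum(is.na(v))
  if (nmiss) cat("  missing Cp: ", nmiss, "\n", sep = "")
  cat("  Cp range:   ",
      sprintf("%.2f-%.2f", min(v, na.rm = TRUE), max(v, na.rm = TRUE)),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.cp_matrix <- function(x) dim(x$values)

#' Gene identifiers of a Cp matrix
#' @param x A `cp_matrix`.
#' @return Character vector of gene identifiers (row order).
#' @export
genes <- function(x) {
  stopifnot(inherits(x, "cp_matrix"))
  rownames(x$values)
}

#' Subset a Cp matrix by genes and/or samples
#' @param x A `cp_matrix`.
#' @param i Gene selector (names or indices).
#' @param j Sample selector (names or indices).
#' @param ... Ignored.
#' @return A `cp_matrix` restricted to the selected rows/columns.
#' @export
`[.cp_matrix` <- function(x, i, j, ...) {
  v <- x$values
  s <- x$samples
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) {
    v <- v[, j, drop = FALSE]
    s <- s[match(colnames(v), s$sample_id), , drop = FALSE]
    rownames(s) <- NULL
  }
  cp_matrix(v, s)
}

missing_tokens <- c("", "NA", "N/A", "NaN", "Undetermined", "undetermined")

#' Read a Cp table and its sample sheet
#'
#' Reads a delimited text file of quantification cycles (first column = gene
#' identifier, header row = sample identifiers) together with a sample sheet
#' (columns `sample_id`, `group`, `timepoint_h`, `replicate`) and returns a
#' validated [cp_matrix()]. Empty cells, `NA`, `N/A` and `Undetermined` become
#' missing values.
#'
#' @param path Path to the Cp table.
#' @param sample_sheet_path Path to the sample sheet.
#' @param sep Field delimiter for both files; `"\t"` (default) or `","`.
#' @param transpose If `TRUE`, the Cp table is samples-in-rows and is
#'   transposed after reading. Orientation is never auto-detected.
#' @return A validated `cp_matrix`. Samples are put in sample-sheet order.
#' @seealso [write_cp_table()] for the inverse operation.
#' @export
read_cp_table <- function(path, sample_sheet_path, sep = "\t",
                          transpose = FALSE) {
  for (p in c(path, sample_sheet_path))
    if (!file.exists(p)) stop("file not found: ", p)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2) stop("Cp table needs a gene column plus >= 1 sample")
  ids <- tab[[1]]
  raw <- as.matrix(tab[, -1, drop = FALSE])
  rownames(raw) <- ids
  if (transpose) raw <- t(raw)
  raw[trimws(raw) %in% missing_tokens] <- NA_character_
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw),
                                dimnames = dimnames(raw)))
  bad <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric Cp value '", raw[bad[1, , drop = FALSE]],
         "' at gene '", rownames(num)[bad[1, 1]], "', sample '",
         colnames(num)[bad[1, 2]], "'")
  sheet <- utils::read.table(sample_sheet_path, sep = sep, header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
  extra <- setdiff(colnames(num), sheet$sample_id)
  if (length(extra))
    stop("sample(s) absent from sample sheet: ", paste(extra, collapse = ", "))
  sheet <- sheet[sheet$sample_id %in% colnames(num), , drop = FALSE]
  rownames(sheet) <- NULL
  num <- num[, sheet$sample_id, drop = FALSE]
  cp_matrix(num, sheet)
}

#' Write a Cp matrix and sample sheet to delimited text
#'
#' @param x A `cp_matrix`.
#' @param path Output path for the Cp table.
#' @param sample_sheet_path Optional output path for the sample sheet.
#' @param sep Field delimiter (default tab).
#' @param digits Significant digits for Cp values (default keeps full
#'   precision via [format()] of the numbers as-is).
#' @return Invisibly, `path`.
#' @export
write_cp_table <- function(x, path, sample_sheet_path = NULL, sep = "\t",
                           digits = 15) {
  stopifnot(inherits(x, "cp_matrix"))
  v <- x$values
  out <- data.frame(gene = rownames(v),
                    format(v, digits = digits, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out[out == "NA"] <- ""
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(sample_sheet_path))
    utils::write.table(x$samples, sample_sheet_path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
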