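# Tabular IO: TSV is the canonical interchange format (tab-delimited,
# header, UTF-8). Panel positions are 1-based (mtDNA convention).

# Column type schemas for the tables the pipeline exchanges.
#' @keywords internal
.schemas <- list(
  guide_reads = c(cell_barcode = "character", guide_id = "character",
                  mapq = "integer", read_id = "character"),
  panel = c(position = "integer", ref = "character", alt = "character"),
  counts = c(cell_barcode = "character", position = "integer",
             ref_count = "integer", alt_count = "integer"),
  calls = c(cell_barcode = "character", heteroplasmy = "double",
            combined_depth = "integer"),
  coverage = c(cell_barcode = "character", total_mt_bases = "integer"),
  metadata = c(cell_barcode = "character"),
  longreads = c(read_id = "character", position = "integer",
                allele = "integer"))

#' Load and validate a tab-separated table
#'
#' Reads a TSV (header line required; CRLF endings tolerated), checks
#' that every schema column is present, coerces column types and rejects
#' rows whose values cannot be coerced, reporting their line numbers.
#'
#' @param path Path to a TSV file.
#' @param schema Either the name of a built-in schema
#'   (`"guide_reads"`, `"panel"`, `"counts"`, `"calls"`, `"coverage"`,
#'   `"metadata"`, `"longreads"`) or a named character vector mapping
#'   column names to types (`"character"`, `"integer"`, `"double"`).
#'   Columns beyond the schema are kept as-is.
#' @return Validated data frame.
#' @export
load_table <- function(path, schema) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (file.size(path) == 0) .stopf("empty file: %s", path)
  if (is.character(schema) && length(schema) == 1L &&
      is.null(names(schema))) {
    if (!schema %in% names(.schemas)) {
      .stopf("unknown schema '%s'", schema)
    }
    schema <- .schemas[[schema]]
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#", quote = "")
  miss <- setdiff(names(schema), names(df))
  if (length(miss)) {
    .stopf("%s: missing required column(s): %s", basename(path),
           paste(miss, collapse = ", "))
  }
  bad_rows <- integer()
  for (col in names(schema)) {
    type <- schema[[col]]
    v <- df[[col]]
    coerced <- switch(type,
      character = as.character(v),
      integer = suppressWarnings(as.integer(v)),
      double = suppressWarnings(as.numeric(v)),
      .stopf("unsupported schema type '%s'", type))
    new_na <- which(is.na(coerced) & !is.na(v))
    bad_rows <- union(bad_rows, new_na)
    df[[col]] <- coerced
  }
  if (length(bad_rows)) {
    .warnf("%s: rejecting %d malformed row(s) at line(s) %s",
           basename(path), length(bad_rows),
           paste(sort(bad_rows) + 1L, collapse = ", "))
    df <- df[-bad_rows, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a table as TSV
#'
#' Tab-delimited, header line, no quoting or row names; numeric columns
#' at full double precision.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a cell x gene expression matrix
#'
#' Accepts either a dense TSV (first column = cell barcode) or a
#' MatrixMarket `.mtx` file with companion row-name and column-name
#' files (`<stem>.rownames.txt` holding cell barcodes, one per line, and
#' `<stem>.colnames.txt` holding gene names).
#'
#' @param path Path to `.tsv`/`.txt` (dense) or `.mtx`.
#' @return Numeric cell x gene matrix with dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (grepl("\\.mtx$", path)) {
    lines <- readLines(path)
    lines <- lines[!grepl("^%", lines)]
    hdr <- scan(text = lines[1], quiet = TRUE)
    trip <- utils::read.table(text = lines[-1])
    m <- matrix(0, nrow = hdr[1], ncol = hdr[2])
    m[cbind(trip[[1]], trip[[2]])] <- trip[[3]]
    stem <- sub("\\.mtx$", "", path)
    rn <- paste0(stem, ".rownames.txt")
    cn <- paste0(stem, ".colnames.txt")
    if (file.exists(rn)) rownames(m) <- readLines(rn)
    if (file.exists(cn)) colnames(m) <- readLines(cn)
    m
  } else {
    df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
}
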