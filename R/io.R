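# Delimited-text readers and writers. Field conventions: TSV or CSV with a
# header row; delimiter inferred from the file extension (.csv = comma,
# anything else = tab) unless given explicitly.

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_delim_quiet <- function(path, delim) {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

#' Read an embedding table
#'
#' Reads a delimited text file (TSV/CSV with header, one row per spot) into
#' an embedding tibble. All non-id columns are coerced to numeric; a cell
#' that cannot be coerced, or a missing/duplicated id, is an error naming
#' the offending row and column.
#'
#' @param path File path.
#' @param id_column Name of the identifier column in the file. The returned
#'   tibble always calls it `spot`.
#' @param delim Field delimiter; `NULL` infers from the extension.
#' @return Embedding tibble (`spot` + numeric dimensions), rows in file order.
#' @export
read_embedding <- function(path, id_column = "spot", delim = NULL) {
  raw <- read_delim_quiet(path, infer_delim(path, delim))
  if (!id_column %in% names(raw)) {
    abort(sprintf("`%s` has no column `%s`; columns are: %s",
                  path, id_column, paste(names(raw), collapse = ", ")))
  }
  ids <- as.character(raw[[id_column]])
  dims <- setdiff(names(raw), id_column)
  vals <- lapply(dims, function(d) {
    v <- raw[[d]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value \"%s\" at row %d, column %s of %s",
                    v[bad[1L]], bad[1L], d, path))
    }
    if (anyNA(num)) {
      abort(sprintf("missing value at row %d, column %s of %s",
                    which(is.na(num))[1L], d, path))
    }
    num
  })
  out <- dplyr::bind_cols(tibble(spot = ids),
                          setNames(as.data.frame(vals), dims))
  embedding_matrix(out)  # validates ids/values; result discarded
  as_tibble(out)
}

#' Write an embedding table
#'
#' @param embedding Embedding tibble.
#' @param path Output path; `.csv` writes comma-separated, else tab.
#' @param delim Field delimiter; `NULL` infers from the extension.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path, delim = NULL) {
  embedding_matrix(embedding)
  readr::write_delim(embedding, path, delim = infer_delim(path, delim),
                     progress = FALSE)
  invisible(path)
}

#' Read spot coordinates
#'
#' Two dialects are supported. `"generic"` expects a header with columns
#' `spot` (or `id_column`), `x`, `y`. `"visium_positions"` expects the 10x
#' `tissue_positions_list.csv` convention — columns barcode, in_tissue,
#' array_row, array_col, pixel_row, pixel_col (with or without a header) —
#' keeps only `in_tissue == 1` rows and uses the array coordinates
#' (x = array_col, y = array_row).
#'
#' @param path File path.
#' @param dialect `"generic"` or `"visium_positions"`.
#' @param id_column Identifier column name for the generic dialect.
#' @param delim Field delimiter; `NULL` infers from the extension.
#' @return Coordinates tibble (`spot`, `x`, `y`).
#' @export
read_coordinates <- function(path, dialect = c("generic", "visium_positions"),
                             id_column = "spot", delim = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "generic") {
    raw <- read_delim_quiet(path, infer_delim(path, delim))
    if (!id_column %in% names(raw)) {
      abort(sprintf("`%s` has no column `%s`.", path, id_column))
    }
    if (!all(c("x", "y") %in% names(raw))) {
      abort(sprintf("`%s` must have columns x and y.", path))
    }
    out <- tibble(spot = as.character(raw[[id_column]]),
                  x = as.numeric(raw$x), y = as.numeric(raw$y))
  } else {
    visium_cols <- c("barcode", "in_tissue", "array_row", "array_col",
                     "pixel_row", "pixel_col")
    first <- readr::read_lines(path, n_max = 1L)
    has_header <- grepl("barcode", first, fixed = TRUE)
    raw <- readr::read_csv(path, col_names = if (has_header) TRUE else visium_cols,
                           show_col_types = FALSE, progress = FALSE)
    if (ncol(raw) < 6L) {
      abort(sprintf("`%s`: the Visium positions dialect needs 6 columns, found %d.",
                    path, ncol(raw)))
    }
    names(raw)[1:6] <- visium_cols
    raw <- raw[as.integer(raw$in_tissue) == 1L, , drop = FALSE]
    out <- tibble(spot = as.character(raw$barcode),
                  x = as.numeric(raw$array_col),
                  y = as.numeric(raw$array_row))
  }
  coordinate_matrix(out)  # validate
  out
}

#' Read ground-truth spot labels
#'
#' Expects a header with an id column and a label column.
#'
#' @param path File path.
#' @param id_column,label_column Column names in the file.
#' @param delim Field delimiter; `NULL` infers from the extension.
#' @return Labels tibble (`spot`, `label`).
#' @export
read_labels <- function(path, id_column = "spot", label_column = "label",
                        delim = NULL) {
  raw <- read_delim_quiet(path, infer_delim(path, delim))
  for (cl in c(id_column, label_column)) {
    if (!cl %in% names(raw)) abort(sprintf("`%s` has no column `%s`.", path, cl))
  }
  out <- tibble(spot = as.character(raw[[id_column]]),
                label = as.character(raw[[label_column]]))
  label_vector(out)  # validate
  out
}
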