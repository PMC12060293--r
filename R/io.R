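#' Read a cell table from delimited text
#'
#' Reads a CSV or TSV (dialect chosen by file extension; \code{.tsv}/
#' \code{.txt} are tab-delimited) with header columns \code{Cell_ID},
#' \code{Sample}, \code{Cell_Type}, \code{x}, \code{y} and optional
#' \code{z}. Unknown columns are ignored. Cell types are kept as character;
#' downstream functions map them onto a stable sorted category order shared
#' across samples.
#'
#' @param path path to the delimited file.
#' @return validated data.frame.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_cell_table(df)
}

# schema checks shared by read_cell_table() and build_niche_network()
validate_cell_table <- function(df) {
  required <- c("Cell_ID", "Sample", "Cell_Type", "x", "y")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- intersect(c(required, "z"), names(df))
  df <- df[, keep]
  num_cols <- intersect(c("x", "y", "z"), names(df))
  for (cc in num_cols) {
    df[[cc]] <- as.numeric(df[[cc]])
    if (anyNA(df[[cc]]) || any(!is.finite(df[[cc]]))) {
      stop("column '", cc, "' contains missing or non-finite coordinates",
           call. = FALSE)
    }
  }
  df$Cell_ID <- as.character(df$Cell_ID)
  df$Sample <- as.character(df$Sample)
  df$Cell_Type <- as.character(df$Cell_Type)
  dup <- unlist(lapply(split(df$Cell_ID, df$Sample), function(id)
    id[duplicated(id)]))
  if (length(dup)) {
    stop("duplicate Cell_ID within a sample: ",
         paste(utils::head(unique(dup), 3), collapse = ", "), call. = FALSE)
  }
  if (length(unique(df$Cell_Type)) < 2) {
    stop("cell table has a single cell type; at least 2 are required",
         call. = FALSE)
  }
  df
}
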