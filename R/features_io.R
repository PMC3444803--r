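#' Write a subject x feature matrix as TSV
#'
#' One row per subject with a leading `subject_id` column; each feature
#' column header encodes its index metadata as
#' `r<radius>_reg<region>_<plane>_bin<bin>` (radius omitted when `meta`
#' has no radius column).  Values are written at full double precision
#' (`%.17g`), so a write/read round-trip is bit-exact.
#'
#' @param features numeric matrix, subjects in rows.
#' @param meta data.frame with one row per column of `features` and columns
#'   `region`, `plane`, `bin` (optionally `radius_mm`).
#' @param path output TSV path.
#' @param subject_ids character; default `rownames(features)` or `S1..Sn`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, meta, path, subject_ids = NULL) {
  features <- as.matrix(features)
  if (nrow(meta) != ncol(features))
    stop("meta has ", nrow(meta), " rows but features has ",
         ncol(features), " columns")
  if (is.null(subject_ids))
    subject_ids <- rownames(features)
  if (is.null(subject_ids))
    subject_ids <- paste0("S", seq_len(nrow(features)))
  hdr <- feature_column_names(meta)
  lines <- paste(c("subject_id", hdr), collapse = "\t")
  if (nrow(features) > 0L) {
    body <- vapply(seq_len(nrow(features)), function(i)
      paste(c(subject_ids[i], sprintf("%.17g", features[i, ])),
            collapse = "\t"), character(1))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

feature_column_names <- function(meta) {
  base <- sprintf("reg%d_%s_bin%d", as.integer(meta$region),
                  as.character(meta$plane), as.integer(meta$bin))
  if (!is.null(meta$radius_mm))
    base <- sprintf("r%g_%s", meta$radius_mm, base)
  base
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV path.
#' @return list with `features` (numeric matrix, subject ids as rownames)
#'   and `meta` (data.frame with `region`, `plane`, `bin` and, when
#'   present in the header, `radius_mm`).
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty feature table: ", path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "subject_id") stop("not a feature table (no subject_id): ", path)
  cols <- hdr[-1]
  meta <- parse_feature_column_names(cols)
  n <- length(lines) - 1L
  X <- matrix(numeric(0), 0L, length(cols))
  ids <- character(0)
  if (n > 0L) {
    parts <- strsplit(lines[-1], "\t", fixed = TRUE)
    bad <- which(lengths(parts) != length(hdr))
    if (length(bad))
      stop("ragged row(s) in feature table: line(s) ",
           paste(bad + 1L, collapse = ", "))
    ids <- vapply(parts, `[`, character(1), 1L)
    X <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  }
  rownames(X) <- if (length(ids)) ids else NULL
  colnames(X) <- cols
  list(features = X, meta = meta)
}

parse_feature_column_names <- function(cols) {
  pat <- "^(?:r([0-9.eE+-]+)_)?reg([0-9]+)_([a-z]+)_bin([0-9]+)$"
  ok <- grepl(pat, cols)
  if (!all(ok)) stop("unparseable feature column name: ", cols[!ok][1])
  rad <- sub(pat, "\\1", cols)
  meta <- data.frame(
    region = as.integer(sub(pat, "\\2", cols)),
    plane = sub(pat, "\\3", cols),
    bin = as.integer(sub(pat, "\\4", cols)),
    stringsAsFactors = FALSE)
  if (any(nzchar(rad))) meta$radius_mm <- as.numeric(rad)
  meta
}

#' Read a subject label table (columns `subject_id`, `class`)
#'
#' @param path TSV with a header row; `class` must be coded 0/1.
#' @return data.frame with character `subject_id` and integer `class`.
#' @export
read_label_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "class") %in% names(df)))
    stop("label table needs columns subject_id, class: ", path)
  if (!all(df$class %in% c(0L, 1L)))
    stop("class column must be 0/1")
  df$subject_id <- as.character(df$subject_id)
  df$class <- as.integer(df$class)
  df
}
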