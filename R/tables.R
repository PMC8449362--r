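# Tabular artifact input/output: every intermediate table (traces, segments,
# filament calls, receptor picks) travels as a plain TSV or a single-block
# STAR-style file, so each stage is independently inspectable.

.table_schemas <- list(
  trace    = c("filament_id", "point_index", "x", "y", "z"),
  segment  = c("filament_id", "segment_index", "x", "y", "z",
               "tx", "ty", "tz"),
  call     = c("filament_id", "n_votes", "n_plus", "n_minus",
               "majority_fraction", "confidence_p", "call"),
  pick     = c("x", "y", "z", "nx", "ny", "nz", "height_above_support",
               "normal_tilt", "kept")
)

validate_table <- function(df, type) {
  req <- .table_schemas[[type]]
  if (is.null(req)) stop("unknown table type: ", type, call. = FALSE)
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop(sprintf("%s table is missing mandatory column(s): %s",
                 type, paste(missing, collapse = ", ")), call. = FALSE)
  if (type == "segment" && "polarity_vote" %in% names(df)) {
    bad <- !df$polarity_vote %in% c(-1L, 0L, 1L)
    if (any(bad))
      stop(sprintf("polarity_vote must be one of -1, 0, +1 (row %d has %s)",
                   which(bad)[1], df$polarity_vote[which(bad)[1]]),
           call. = FALSE)
  }
  invisible(df)
}

#' Write a records table as TSV or single-block STAR
#' @param df data.frame of one record type
#' @param path output file
#' @param dialect "tsv" or "star" (default: by file extension, .star -> star)
#' @param type optional schema name ("trace", "segment", "call", "pick") to
#'   validate mandatory columns before writing
#' @param block STAR data block name
#' @return `path`, invisibly
#' @export
write_table <- function(df, path, dialect = NULL, type = NULL,
                        block = "particles") {
  if (is.null(dialect))
    dialect <- if (grepl("\\.star$", path, ignore.case = TRUE)) "star" else "tsv"
  dialect <- match.arg(dialect, c("tsv", "star"))
  if (!is.null(type)) validate_table(df, type)
  if (dialect == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("data_", block), "", "loop_"), con)
    writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
    body <- do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col)) format(col, digits = 15, trim = TRUE, scientific = FALSE)
      else as.character(col)
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a records table written by [write_table()]
#' @param path TSV or STAR file
#' @param dialect "tsv" or "star" (default: by extension)
#' @param type optional schema name for validation
#' @return data.frame
#' @export
read_table <- function(path, dialect = NULL, type = NULL) {
  if (is.null(dialect))
    dialect <- if (grepl("\\.star$", path, ignore.case = TRUE)) "star" else "tsv"
  dialect <- match.arg(dialect, c("tsv", "star"))
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- trimws(lines)
    loop_at <- which(lines == "loop_")
    if (!length(loop_at)) stop("no loop_ block in STAR file: ", path, call. = FALSE)
    i <- loop_at[1] + 1
    cols <- character()
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      cols <- c(cols, sub("^_([^ \t#]+).*$", "\\1", lines[i]))
      i <- i + 1
    }
    body <- lines[i:length(lines)]
    body <- body[nzchar(body)]
    df <- utils::read.table(text = body, col.names = cols,
                            stringsAsFactors = FALSE)
  }
  if (!is.null(type)) validate_table(df, type)
  df
}

# Filament traces <-> table: one row per polyline point, ordered.
traces_to_table <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(filament_id = tr$filament_id,
               point_index = seq_len(nrow(tr$points)),
               x = tr$points[, 1], y = tr$points[, 2], z = tr$points[, 3],
               true_polarity = if (is.null(tr$true_polarity)) NA_integer_
                               else tr$true_polarity)
  }))
}

table_to_traces <- function(df) {
  validate_table(df, "trace")
  lapply(split(df, df$filament_id), function(g) {
    g <- g[order(g$point_index), ]
    filament_trace(
      filament_id = g$filament_id[1],
      points = as.matrix(g[, c("x", "y", "z")]),
      true_polarity = if ("true_polarity" %in% names(g)) g$true_polarity[1]
                      else NULL)
  })
}
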