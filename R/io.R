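#' Read a nanostructure measurement table
#'
#' Delimited text, UTF-8, header row; comma or tab delimiter auto-detected
#' from the header line. Mandatory columns: \code{sample_id},
#' \code{length_nm}, \code{diameter_nm}.
#'
#' @param path file path.
#' @return data.frame of measurements.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  if (length(header) == 0L) {
    return(data.frame(sample_id = character(0), length_nm = numeric(0),
                      diameter_nm = numeric(0)))
  }
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  x <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                  encoding = "UTF-8")
  missing_cols <- setdiff(MANDATORY_COLS, names(x))
  if (length(missing_cols) > 0L)
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  for (col in c("length_nm", "diameter_nm", "slab_x_mm", "slab_y_mm")) {
    if (col %in% names(x)) {
      v <- suppressWarnings(as.numeric(x[[col]]))
      bad <- which(is.na(v) & !is.na(x[[col]]) & trimws(as.character(x[[col]])) != "")
      if (length(bad) > 0L)
        stop("malformed numeric value in column ", col, " at data line(s) ",
             paste(head(bad, 5L), collapse = ", "), " of ", path)
      x[[col]] <- v
    }
  }
  for (col in c("near_body_cavity", "stacking_evidence"))
    if (col %in% names(x)) x[[col]] <- as_logical_col(x[[col]])
  x
}

#' Write a measurement table as delimited text
#'
#' @param x measurement data.frame.
#' @param path output path; extension \code{.csv} selects comma, anything
#'   else tab.
#' @export
write_measurements <- function(x, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Reports carry a provenance block (seed, package version, parameter
#' digest) so any output can be regenerated from the inputs alone.
#'
#' @param report named list.
#' @param path output path.
#' @param seed seed recorded in provenance (optional).
#' @param params parameter list recorded in provenance (optional).
#' @export
write_report <- function(report, path, seed = NULL, params = NULL) {
  report$provenance <- list(
    package = "paleocolr",
    version = as.character(utils::packageVersion("paleocolr")),
    seed = seed,
    params = params)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
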