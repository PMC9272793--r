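# Delimited-text readers and writers for point tables, palettes and the
# optimized cluster-to-color mapping.

# Infer the field delimiter from a file extension, unless given explicitly.
sniff_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = ",", tsv = "\t", txt = "\t", "\t")
}

#' Read a clustered point table from delimited text
#'
#' Reads a TSV/CSV file of 2-D coordinates (embedding or spatial) with a
#' cluster label per row, validating coordinates and renaming the chosen
#' columns to the standard `x`, `y`, `cluster`.
#'
#' @param path Path to the file; delimiter inferred from the extension
#'   (`.csv` comma, otherwise tab) unless `delim` is given.
#' @param x_col,y_col,cluster_col Column names in the file; defaults
#'   `"x"`, `"y"`, `"cluster"`.
#' @param delim Optional explicit field delimiter.
#' @return A validated tibble with columns `x`, `y`, `cluster`.
#' @export
read_points <- function(path, x_col = "x", y_col = "y",
                        cluster_col = "cluster", delim = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("points file not found: %s", path), call. = FALSE)
  }
  raw <- readr::read_delim(path, delim = sniff_delim(path, delim),
                           show_col_types = FALSE, progress = FALSE)
  wanted <- c(x_col, y_col, cluster_col)
  missing_cols <- setdiff(wanted, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("column(s) %s not found in %s; available columns: %s",
                 paste(missing_cols, collapse = ", "), path,
                 paste(names(raw), collapse = ", ")), call. = FALSE)
  }
  out <- raw[, wanted]
  names(out) <- c("x", "y", "cluster")
  for (col in c("x", "y")) {
    v <- out[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad) > 0) {
        stop(sprintf("non-numeric %s coordinate '%s' at data row %d of %s",
                     col, v[bad[1]], bad[1], path), call. = FALSE)
      }
      out[[col]] <- num
    }
    n_bad <- sum(!is.finite(out[[col]]))
    if (n_bad > 0) {
      stop(sprintf("%d row(s) with missing/non-finite %s coordinates in %s, first at data row %d",
                   n_bad, col, path, which(!is.finite(out[[col]]))[1]),
           call. = FALSE)
    }
  }
  check_points(out)
}

#' Read a palette file
#'
#' One `#RRGGBB` color per line. Blank lines are skipped; a line whose first
#' token is not a hex color but starts with `#` is treated as a comment, and
#' trailing ` # ...` comments after a color are dropped.
#'
#' @param path Path to the palette file.
#' @return Character vector of hex color strings, in file order.
#' @export
read_palette <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("palette file not found: %s", path), call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  first_token <- sub("\\s.*$", "", lines)
  is_hex <- grepl("^#[0-9a-fA-F]{6}$|^#[0-9a-fA-F]{3}$", first_token)
  is_comment <- !is_hex & grepl("^#", lines)
  bad <- which(!is_hex & !is_comment)
  if (length(bad) > 0) {
    stop(sprintf("palette file %s: line %d ('%s') is neither a hex color nor a comment",
                 path, bad[1], lines[bad[1]]), call. = FALSE)
  }
  hex <- first_token[is_hex]
  if (length(hex) == 0) {
    stop(sprintf("palette file %s contains no colors", path), call. = FALSE)
  }
  hex
}

#' Write the cluster-to-color mapping as TSV
#'
#' Writes a two-column tab-separated table (`cluster`, `color`) in canonical
#' (lexicographic) cluster order with Unix line endings, so identical runs
#' produce byte-identical files. Hex strings are preserved byte-for-byte
#' from the input palette.
#'
#' @param x A [optimize_palette()] result, or a data frame with columns
#'   `cluster` and `color`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(x, path) {
  mapping <- if (inherits(x, "palette_fit")) x$mapping else {
    if (!is.data.frame(x) || !all(c("cluster", "color") %in% names(x))) {
      stop("`x` must be a palette_fit or a data frame with columns ",
           "cluster and color", call. = FALSE)
    }
    tibble::as_tibble(x[, c("cluster", "color")])
  }
  mapping <- mapping[order(as.character(mapping$cluster), method = "radix"), ]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("cluster\tcolor",
               paste(mapping$cluster, mapping$color, sep = "\t")),
             con, sep = "\n")
  invisible(path)
}

#' Write a machine-readable run report as JSON
#'
#' Serializes the scores, overlap matrix, score trace and full
#' configuration (including the seed) of a fit.
#'
#' @param fit A [optimize_palette()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path) {
  stopifnot(inherits(fit, "palette_fit"))
  report <- list(
    score = fit$score,
    restart_score = fit$restart_score,
    n_proposals = fit$n_proposals,
    stopped_early = fit$stopped_early,
    mapping = fit$mapping,
    jaccard = fit$overlap$jaccard,
    cutoffs = as.list(fit$overlap$cutoffs),
    trace = fit$trace,
    config = fit$config
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
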