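# Delimited-text I/O for plot headers, occurrences and result tables.
# Comma is the default dialect; tab is accepted via `sep`. UTF-8 only.

PLOT_COLS <- c("plot_id", "x", "y", "uncertainty_m", "year")
OCC_COLS <- c("plot_id", "species_id", "native", "priority")

#' Read a vegetation-plot header table
#'
#' Required columns: `plot_id`, `x`, `y`, `uncertainty_m`, `year`. Optional:
#' `habitat_class` (EUNIS level-1 letter), `country`, `bioregion`. Rows with
#' unparseable coordinates or negative uncertainty are rejected; the rejects
#' are attached as the `rejects` attribute (a data frame with row numbers and
#' reasons). Plots start with `status = "UNCLASSIFIED"`.
#'
#' @param path File path.
#' @param sep Field delimiter: `","` (default) or `"\t"`.
#' @return A data frame of plot records.
#' @export
read_plot_table <- function(path, sep = ",") {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = c(plot_id = "character"))
  missing <- setdiff(PLOT_COLS, names(df))
  if (length(missing) > 0) {
    stop("plot table is missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) {
    warning("empty plot table: ", path)
  }
  for (col in c("habitat_class", "country", "bioregion")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  u <- suppressWarnings(as.numeric(df$uncertainty_m))
  yr <- suppressWarnings(as.integer(df$year))
  bad_coord <- !is.finite(x) | !is.finite(y)
  bad_unc <- !is.finite(u) | u < 0
  bad <- bad_coord | bad_unc
  rejects <- data.frame(
    row = which(bad),
    reason = ifelse(bad_coord[bad], "unparseable coordinates", "negative or missing uncertainty"),
    stringsAsFactors = FALSE
  )
  out <- data.frame(
    plot_id = as.character(df$plot_id), x = x, y = y, uncertainty_m = u,
    year = yr, habitat_class = as.character(df$habitat_class),
    country = as.character(df$country), bioregion = as.character(df$bioregion),
    stringsAsFactors = FALSE
  )
  out$status <- if ("status" %in% names(df)) as.character(df$status) else "UNCLASSIFIED"
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  out
}

#' Write a plot table to CSV
#' @param plots Plot data frame.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_plot_table <- function(plots, path, sep = ",") {
  utils::write.table(plots, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a long-format occurrence table
#'
#' One row per (plot, species). Duplicated (plot_id, species_id) pairs are
#' collapsed to the first row with a warning; rows with `priority = TRUE` but
#' `native = FALSE` violate the priority-implies-native invariant and are
#' rejected.
#'
#' @param path File path.
#' @param sep Field delimiter.
#' @return Data frame with columns `plot_id`, `species_id`, `native`,
#'   `priority`; attributes `n_duplicates` and `n_invalid`.
#' @export
read_occurrences <- function(path, sep = ",") {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = c(plot_id = "character", species_id = "character"))
  missing <- setdiff(OCC_COLS, names(df))
  if (length(missing) > 0) {
    stop("occurrence table is missing required column(s): ", paste(missing, collapse = ", "))
  }
  df$native <- as.logical(df$native)
  df$priority <- as.logical(df$priority)
  invalid <- df$priority & !df$native
  n_invalid <- sum(invalid, na.rm = TRUE)
  if (n_invalid > 0) {
    warning(n_invalid, " occurrence row(s) rejected: priority species flagged non-native")
    df <- df[!invalid, , drop = FALSE]
  }
  key <- paste(df$plot_id, df$species_id, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_dup > 0) {
    warning(n_dup, " duplicated (plot, species) row(s) collapsed (first kept)")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df <- df[, OCC_COLS]
  attr(df, "n_duplicates") <- n_dup
  attr(df, "n_invalid") <- n_invalid
  df
}

#' Write an occurrence table to CSV
#' @param occ Occurrence data frame.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path, sep = ",") {
  utils::write.table(occ[, OCC_COLS], path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write result tables and a run manifest
#'
#' Writes one CSV per named table plus `manifest.json` recording the seed,
#' the configuration, and package/R versions. Output is deterministic for a
#' fixed configuration and seed (no timestamps).
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @param config Configuration list stored in the manifest.
#' @param seed Integer seed stored in the manifest.
#' @return Character vector of written file paths, invisibly.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.table(tables[[nm]], p, sep = ",", row.names = FALSE,
                       quote = TRUE, fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  manifest <- list(
    seed = seed,
    config = strip(config),
    tables = names(tables),
    package_version = as.character(utils::packageVersion("pagap")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, mp))
}
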