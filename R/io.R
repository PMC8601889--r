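# CSV readers/writers.
#
# Abundance tables travel as wide CSV: one row per taxon (first column
# `taxon_id`), one column per month with ISO "YYYY-MM" headers on a
# strictly consecutive grid. Missing months are empty cells — never "NA"
# and never 0, since zero is a legitimate abundance. Metadata is a
# separate CSV (taxon_id, functional_group, cell_radius_um). Dialect is
# fixed: comma separator, "." decimal, UTF-8.

#' Read a community table from CSV
#'
#' @param abundance_path wide abundance CSV (see format above).
#' @param metadata_path metadata CSV with columns `taxon_id`,
#'   `functional_group`, `cell_radius_um`.
#' @return A [community_table()].
#' @export
read_community_csv <- function(abundance_path, metadata_path) {
  fields <- utils::count.fields(abundance_path, sep = ",", quote = "\"")
  if (length(unique(fields)) != 1L) stop("malformed table: ragged rows")
  ab <- tryCatch(
    utils::read.csv(abundance_path, check.names = FALSE,
                    colClasses = "character", fill = FALSE),
    error = function(e) stop("malformed table: ", conditionMessage(e)))
  if (ncol(ab) < 2L || names(ab)[1] != "taxon_id") {
    stop("malformed table: first column must be taxon_id")
  }
  labels <- names(ab)[-1]
  stamps <- lapply(labels, parse_month_label)
  if (any(vapply(stamps, is.null, logical(1)))) {
    stop("broken grid: month headers must be YYYY-MM")
  }
  idx <- vapply(stamps, month_index, integer(1))
  if (!all(diff(idx) == 1L)) stop("broken grid: month headers not consecutive")

  vals <- as.matrix(ab[, -1, drop = FALSE])
  vals[vals == ""] <- NA
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  if (any(is.na(num) & !is.na(vals))) stop("invalid value: non-numeric abundance")
  if (any(num < 0, na.rm = TRUE)) stop("invalid value: negative abundance")
  rownames(num) <- ab$taxon_id

  md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  if (!setequal(md$taxon_id, ab$taxon_id)) {
    stop("invalid metadata: abundance and metadata taxa differ")
  }
  community_table(num, md, start = stamps[[1]])
}

#' Write a community table to CSV
#'
#' Inverse of [read_community_csv()]; round-trips exactly (values printed
#' with 17 significant digits, missing months as empty cells).
#'
#' @param table a [community_table()].
#' @param abundance_path,metadata_path output paths.
#' @return The paths, invisibly.
#' @export
write_community_csv <- function(table, abundance_path, metadata_path) {
  ab <- table$abundance
  chr <- matrix(sprintf("%.17g", ab), nrow = nrow(ab))
  chr[is.na(ab)] <- ""
  df <- data.frame(taxon_id = rownames(ab), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("taxon_id", month_labels(table$start, ncol(ab)))
  utils::write.csv(df, abundance_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(table$metadata, metadata_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(abundance_path, metadata_path))
}

#' Write a predictability-curve results table
#'
#' Tidy CSV, one row per assemblage size x strategy: `size`, `strategy`,
#' `n_trials`, `mean_rho`, `se`, `ci95_half_width`, `mean_surrogate_rho`
#' (empty when surrogates were disabled) and `n_failed`. Values are
#' printed with 17 significant digits so a read-back reproduces them
#' exactly.
#'
#' @param summaries data frame from [predictability_curve()] (extra
#'   columns such as `variant` are kept).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_results <- function(summaries, path) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0L) {
    stop("empty results")
  }
  out <- summaries
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      chr <- sprintf("%.17g", out[[nm]])
      chr[is.na(out[[nm]])] <- ""
      out[[nm]] <- chr
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return Data frame with numeric columns restored.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(names(df), c("mean_rho", "se", "ci95_half_width",
                                    "mean_surrogate_rho"))) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  df
}
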