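# Community table: taxa x months abundance matrix plus per-taxon metadata,
# all sharing one monthly grid (missing months are shared sampling gaps or
# per-taxon NAs; aggregation propagates them either way).

FUNCTIONAL_GROUPS <- c("diatom", "dinoflagellate", "coccolithophore",
                       "phytoflagellate", "other")

#' Construct a community table
#'
#' @param abundance numeric matrix, taxa in rows (rownames = taxon ids),
#'   consecutive months in columns; `NA` marks missing months.
#' @param metadata data frame with columns `taxon_id`, `functional_group`
#'   (one of diatom, dinoflagellate, coccolithophore, phytoflagellate,
#'   other) and `cell_radius_um` (> 0). Row order need not match.
#' @param start length-2 `c(year, month)` of the first column.
#' @return Object of class `"community_table"`.
#' @export
community_table <- function(abundance, metadata, start = c(1, 1)) {
  if (!is.matrix(abundance) || !is.numeric(abundance)) {
    stop("malformed table: abundance must be a numeric matrix")
  }
  if (is.null(rownames(abundance))) stop("malformed table: missing taxon ids")
  if (any(abundance < 0, na.rm = TRUE)) stop("invalid value: negative abundance")
  req <- c("taxon_id", "functional_group", "cell_radius_um")
  if (!all(req %in% names(metadata))) {
    stop("invalid metadata: need taxon_id, functional_group, cell_radius_um")
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!setequal(metadata$taxon_id, rownames(abundance)) ||
      anyDuplicated(metadata$taxon_id)) {
    stop("invalid metadata: taxon ids do not match abundance rows")
  }
  if (!all(metadata$functional_group %in% FUNCTIONAL_GROUPS)) {
    stop("invalid metadata: unknown functional group")
  }
  if (any(!is.finite(metadata$cell_radius_um) | metadata$cell_radius_um <= 0)) {
    stop("invalid metadata: cell radius must be positive")
  }
  metadata <- metadata[match(rownames(abundance), metadata$taxon_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(abundance = abundance, metadata = metadata,
                 start = as.integer(start)),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community table: %d taxa x %d months (start %04d-%02d)\n",
              nrow(x$abundance), ncol(x$abundance), x$start[1], x$start[2]))
  print(table(x$metadata$functional_group))
  invisible(x)
}

#' Number of taxa / months in a community table
#' @param table a [community_table()].
#' @return Integer count.
#' @export
n_taxa <- function(table) nrow(table$abundance)

#' @rdname n_taxa
#' @export
n_months <- function(table) ncol(table$abundance)

#' Extract one taxon's series
#' @param table a [community_table()].
#' @param taxon_id taxon identifier.
#' @return A monthly `ts`.
#' @export
taxon_series <- function(table, taxon_id) {
  if (!taxon_id %in% rownames(table$abundance)) stop("member not found")
  monthly_series(table$abundance[taxon_id, ], start = table$start)
}

#' Keep a subset of taxa
#' @param table a [community_table()].
#' @param ids taxon identifiers to retain.
#' @return A smaller [community_table()].
#' @export
subset_taxa <- function(table, ids) {
  if (!all(ids %in% rownames(table$abundance))) stop("member not found")
  community_table(table$abundance[ids, , drop = FALSE],
                  table$metadata[table$metadata$taxon_id %in% ids, , drop = FALSE],
                  start = table$start)
}

#' Sum member taxa into an assemblage
#'
#' The assemblage abundance at each month is the arithmetic sum of the
#' member abundances; if any member is missing that month the aggregate is
#' missing. Summation order is fixed (sorted taxon id) so aggregation is
#' bit-level reproducible.
#'
#' @param table a [community_table()].
#' @param member_ids character vector of taxon ids (length >= 1).
#' @return Object of class `"assemblage"`: list with `member_ids` (sorted)
#'   and `series` (monthly `ts`).
#' @export
aggregate_taxa <- function(table, member_ids) {
  member_ids <- unique(as.character(member_ids))
  if (length(member_ids) == 0L) stop("empty assemblage")
  if (!all(member_ids %in% rownames(table$abundance))) stop("member not found")
  member_ids <- sort(member_ids)
  sub <- table$abundance[member_ids, , drop = FALSE]
  total <- colSums(sub)                       # NA if any member missing
  structure(list(member_ids = member_ids,
                 series = monthly_series(total, start = table$start)),
            class = "assemblage")
}

#' @export
print.assemblage <- function(x, ...) {
  cat(sprintf("assemblage of %d taxa, %d months\n",
              length(x$member_ids), length(x$series)))
  invisible(x)
}

#' Coefficient of variation of an aggregate series
#'
#' Sample standard deviation over mean, computed over non-missing months.
#' The classic portfolio-effect diagnostic: for independent members of
#' equal scale the aggregate CV shrinks like `1/sqrt(M)`.
#'
#' @param x an `"assemblage"` or any monthly series.
#' @return Scalar CV.
#' @export
coefficient_of_variation <- function(x) {
  v <- if (inherits(x, "assemblage")) as.numeric(x$series) else
    as.numeric(as_monthly_series(x))
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("undefined CV: need >= 2 observed months")
  m <- mean(v)
  if (m == 0) stop("undefined CV: zero mean")
  stats::sd(v) / m
}
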