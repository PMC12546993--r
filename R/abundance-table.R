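# Taxon-by-sample abundance tables: construction, IO, genus collapse,
# prevalence/total filtering.

.RANKS <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
            family = "f", genus = "g", species = "s")

#' Construct a taxon-by-sample abundance table
#'
#' The central input container: a non-negative numeric matrix with taxa as
#' rows and time-ordered samples as columns, optionally carrying a
#' semicolon-delimited taxonomy string per taxon (ranks prefixed
#' \code{k__}, \code{p__}, ..., \code{g__}) and numeric sample timestamps.
#' Column order is the temporal order of the series.
#'
#' @param values numeric matrix, taxa x samples, finite and >= 0. Row and
#'   column names are used as taxon and sample identifiers; defaults are
#'   generated when absent.
#' @param taxonomy optional character vector of taxonomy strings, one per
#'   taxon.
#' @param sample_times optional numeric vector of non-decreasing timestamps,
#'   one per sample.
#' @return an object of class \code{abundance_table}: a list with elements
#'   \code{values}, \code{taxon_ids}, \code{sample_ids}, \code{taxonomy},
#'   \code{sample_times}.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("t", 1:3), paste0("s", 1:4)))
#' abundance_table(m)
#' @export
abundance_table <- function(values, taxonomy = NULL, sample_times = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    .stopf("'values' must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("taxon_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  if (ncol(values) < 2L)
    .stopf("abundance table has fewer than 2 samples (%d)", ncol(values))
  if (anyDuplicated(rownames(values)))
    .stopf("duplicate taxon ids: %s",
           paste(unique(rownames(values)[duplicated(rownames(values))]),
                 collapse = ", "))
  if (anyDuplicated(colnames(values)))
    .stopf("duplicate sample ids: %s",
           paste(unique(colnames(values)[duplicated(colnames(values))]),
                 collapse = ", "))
  if (any(!is.finite(values)))
    .stopf("abundance values must all be finite (non-numeric or NA cells?)")
  if (any(values < 0))
    .stopf("abundance values must be non-negative")
  if (!is.null(taxonomy)) {
    taxonomy <- as.character(taxonomy)
    if (length(taxonomy) != nrow(values))
      .stopf("'taxonomy' must have one entry per taxon")
  }
  if (!is.null(sample_times)) {
    sample_times <- as.numeric(sample_times)
    if (length(sample_times) != ncol(values))
      .stopf("'sample_times' must have one entry per sample")
    if (is.unsorted(sample_times))
      .stopf("'sample_times' must be non-decreasing (samples in temporal order)")
  }
  structure(list(values = values,
                 taxon_ids = rownames(values),
                 sample_ids = colnames(values),
                 taxonomy = taxonomy,
                 sample_times = sample_times),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$taxonomy)) "" else " (with taxonomy)"))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Read an abundance table from TSV
#'
#' Expects taxa as rows: the first column holds taxon ids, the remaining
#' columns one sample each (in temporal order), with an optional trailing
#' \code{taxonomy} column. A leading \code{# Constructed from biom file}
#' comment line (classic BIOM TSV export) is tolerated, as is an
#' \code{#OTU ID} header prefix.
#'
#' @param path path to a tab-separated file.
#' @return an [abundance_table()].
#' @seealso [write_abundance_table()]
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#\\s*Constructed from biom", lines, ignore.case = TRUE)]
  if (length(lines) < 2L) .stopf("file has no data rows: %s", path)
  df <- utils::read.delim(text = lines, header = TRUE, check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE)
  names(df)[1] <- sub("^#\\s*", "", names(df)[1])
  tax_col <- which(tolower(names(df)) == "taxonomy")
  taxonomy <- NULL
  if (length(tax_col)) {
    taxonomy <- as.character(df[[tax_col[1]]])
    df <- df[, -tax_col, drop = FALSE]
  }
  if (ncol(df) < 3L)
    .stopf("fewer than 2 samples in %s", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    .stopf("duplicate taxon ids in %s: %s", path,
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals))
    .stopf("non-numeric abundance cells in %s", path)
  rownames(vals) <- ids
  abundance_table(vals, taxonomy = taxonomy)
}

#' Write an abundance table as TSV
#'
#' Inverse of [read_abundance_table()]: first column \code{taxon_id}, one
#' column per sample, optional trailing \code{taxonomy} column.
#'
#' @param table an [abundance_table()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(taxon_id = table$taxon_ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy)) df$taxonomy <- table$taxonomy
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# split "k__Bacteria; p__Firmicutes; ..." into trimmed rank fields
.split_taxonomy <- function(s) {
  parts <- strsplit(s, ";", fixed = TRUE)
  lapply(parts, function(p) trimws(p))
}

#' Collapse an abundance table to a taxonomic rank
#'
#' Sums all rows whose taxonomy agrees up to the requested rank (default
#' genus, i.e. level 6 of the k/p/c/o/f/g/s hierarchy). Rows whose label at
#' that rank is empty (e.g. a string ending in \code{g__}) or missing are
#' pooled into a single \code{unassigned at <rank>} row rather than dropped,
#' so per-sample column sums are conserved.
#'
#' @param table an [abundance_table()] with taxonomy for every taxon.
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return a new [abundance_table()] whose taxon ids are the taxonomy
#'   prefixes up to \code{rank}.
#' @export
collapse_to_rank <- function(table, rank = "genus") {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(table$taxonomy))
    .stopf("cannot collapse: table has no taxonomy")
  rank <- match.arg(rank, names(.RANKS))
  level <- match(rank, names(.RANKS))
  prefix <- paste0(.RANKS[[rank]], "__")
  labels <- vapply(.split_taxonomy(table$taxonomy), function(p) {
    if (length(p) < level) return(NA_character_)
    entry <- p[level]
    if (!startsWith(entry, prefix) || nchar(entry) <= nchar(prefix))
      return(NA_character_)
    paste(p[seq_len(level)], collapse = ";")
  }, character(1))
  labels[is.na(labels)] <- paste("unassigned at", rank)
  groups <- factor(labels, levels = unique(labels))
  vals <- rowsum(table$values, groups, reorder = FALSE)
  rownames(vals) <- levels(groups)
  abundance_table(vals, taxonomy = levels(groups),
                  sample_times = table$sample_times)
}

#' Filter taxa by total count and prevalence
#'
#' Removes every taxon whose total abundance across all samples is below
#' \code{min_total} or which is present (value > 0) in fewer than
#' \code{min_prevalence} samples. Both thresholds are strict
#' ("fewer than"): a taxon with total exactly \code{min_total} or present in
#' exactly \code{min_prevalence} samples is retained.
#'
#' @param table an [abundance_table()].
#' @param min_total minimum total count across samples (default 10).
#' @param min_prevalence minimum number of samples with non-zero abundance
#'   (default 5).
#' @return the filtered [abundance_table()], with a data frame of removed
#'   taxa (columns \code{taxon_id}, \code{total}, \code{prevalence},
#'   \code{reason}) attached as attribute \code{"removed"}.
#' @export
filter_features <- function(table, min_total = 10, min_prevalence = 5) {
  stopifnot(inherits(table, "abundance_table"))
  .check_scalar_number(min_total, "min_total", min = 0)
  .check_scalar_number(min_prevalence, "min_prevalence", min = 0)
  totals <- rowSums(table$values)
  prev <- rowSums(table$values > 0)
  low_total <- totals < min_total
  low_prev <- prev < min_prevalence
  drop <- low_total | low_prev
  if (all(drop))
    .stopf("filtering removed all %d taxa (min_total = %s, min_prevalence = %s)",
           nrow(table$values), format(min_total), format(min_prevalence))
  removed <- data.frame(
    taxon_id = table$taxon_ids[drop],
    total = totals[drop],
    prevalence = prev[drop],
    reason = ifelse(low_total[drop] & low_prev[drop], "total+prevalence",
                    ifelse(low_total[drop], "total", "prevalence")),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- abundance_table(table$values[!drop, , drop = FALSE],
                         taxonomy = if (!is.null(table$taxonomy))
                           table$taxonomy[!drop],
                         sample_times = table$sample_times)
  attr(out, "removed") <- removed
  out
}

#' Remove taxa with zero abundance in every sample
#'
#' @param table an [abundance_table()].
#' @return the table without all-zero rows; errors if nothing remains.
#' @export
drop_zero_features <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  keep <- rowSums(table$values != 0) > 0
  if (!any(keep)) .stopf("all taxa have zero abundance in every sample")
  if (all(keep)) return(table)
  abundance_table(table$values[keep, , drop = FALSE],
                  taxonomy = if (!is.null(table$taxonomy)) table$taxonomy[keep],
                  sample_times = table$sample_times)
}
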