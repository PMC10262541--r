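#' ASV count table
#'
#' Construct a validated ASV count table: an integer matrix of read counts
#' with samples as rows and amplicon sequence variants (ASVs) as columns.
#' This object is the backbone of every pipeline stage.
#'
#' @param counts numeric matrix of non-negative integer read counts,
#'   samples x ASVs. Row and column names are used as IDs unless
#'   `sample_ids` / `asv_ids` are given.
#' @param sample_ids character vector of unique sample IDs.
#' @param asv_ids character vector of unique ASV IDs.
#' @return An object of class `asv_table`: an integer matrix with
#'   `dimnames` carrying the IDs.
#' @export
asv_table <- function(counts, sample_ids = rownames(counts),
                      asv_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(asv_ids)) {
    stop("`counts` must have sample and ASV IDs (dimnames or arguments)")
  }
  sample_ids <- trimws(as.character(sample_ids))
  asv_ids <- trimws(as.character(asv_ids))
  if (length(sample_ids) != nrow(counts) || length(asv_ids) != ncol(counts)) {
    stop("ID lengths do not match the count matrix dimensions")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(asv_ids)) {
    stop("duplicate ASV IDs: ",
         paste(unique(asv_ids[duplicated(asv_ids)]), collapse = ", "))
  }
  if (anyNA(counts)) stop("counts contain NA")
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integral read counts")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, asv_ids)
  class(counts) <- c("asv_table", "matrix", "array")
  counts
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("<asv_table> %d samples x %d ASVs, %s reads total\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")))
  invisible(x)
}

#' @rdname asv_table
#' @param x object to test.
#' @export
is_asv_table <- function(x) inherits(x, "asv_table")

#' Subset an ASV table keeping its class
#'
#' @param table an [asv_table()].
#' @param samples,asvs character vectors of IDs to keep (default: all).
#' @return An `asv_table` restricted to the requested rows/columns.
#' @export
subset_asv_table <- function(table, samples = rownames(table),
                             asvs = colnames(table)) {
  stopifnot(is_asv_table(table))
  missing_s <- setdiff(samples, rownames(table))
  missing_a <- setdiff(asvs, colnames(table))
  if (length(missing_s)) stop("unknown samples: ", paste(missing_s, collapse = ", "))
  if (length(missing_a)) stop("unknown ASVs: ", paste(missing_a, collapse = ", "))
  m <- unclass(table)[samples, asvs, drop = FALSE]
  asv_table(m, sample_ids = samples, asv_ids = asvs)
}

#' Read an ASV count table
#'
#' Reads a count table from tab-separated text or BIOM-format JSON.  The TSV
#' dialect has a header row and IDs in the first column; samples-as-rows is
#' canonical and `asvs_as_rows = TRUE` transposes at read time.  BIOM tables
#' (observations = ASVs as rows, per the format) are read through the
#' biomformat package and transposed to the samples-x-ASVs orientation.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom-json"`.
#' @param asvs_as_rows logical; for TSV input, set `TRUE` when rows are ASVs.
#' @return An [asv_table()].
#' @export
read_asv_table <- function(path, format = c("tsv", "biom-json"),
                           asvs_as_rows = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- trimws(as.character(df[[1]]))
    if (anyDuplicated(ids)) {
      stop("duplicate row IDs in ", path, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric counts in ", path)
    rownames(m) <- ids
    if (asvs_as_rows) m <- t(m)
  } else {
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))
  }
  asv_table(m)
}

#' Write an ASV count table
#'
#' @inheritParams read_asv_table
#' @param table an [asv_table()].
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(table, path, format = c("tsv", "biom-json")) {
  stopifnot(is_asv_table(table))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(sample_id = rownames(table), unclass(table),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    b <- biomformat::make_biom(t(unclass(table)))
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Per-sample relative abundances
#'
#' Divides each sample's counts by its total so rows sum to one.
#'
#' @param table an [asv_table()] (or numeric matrix, samples x ASVs).
#' @return Numeric matrix of per-sample ASV proportions.
#' @export
relative_abundance <- function(table) {
  m <- unclass(table)
  storage.mode(m) <- "double"
  totals <- rowSums(m)
  if (any(totals <= 0)) {
    stop("zero-total sample(s): ",
         paste(rownames(m)[totals <= 0], collapse = ", "))
  }
  m / totals
}
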