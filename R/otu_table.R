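#' Read a sample-by-OTU read-count table
#'
#' Parses a delimited text file into an integer community matrix with samples
#' as rows and OTUs as columns (the canonical orientation; use
#' `samples_as_rows = FALSE` to transpose on read). Parsing is strict: any
#' non-integer cell or duplicated identifier aborts with a positional message,
#' because silent coercion would corrupt the frequency counts every downstream
#' estimator relies on.
#'
#' @param path path to a CSV or TSV file with a header row of OTU identifiers
#'   and a first column of sample identifiers.
#' @param sep field separator; `NULL` (default) picks `","` for `.csv` and
#'   tab otherwise.
#' @param samples_as_rows if `FALSE` the file stores OTUs as rows and is
#'   transposed after reading.
#' @return an integer matrix, rows = samples, columns = OTUs.
#' @seealso [write_otu_table()], [frequency_counts()]
#' @export
read_otu_table <- function(path, sep = NULL, samples_as_rows = TRUE) {
  if (!file.exists(path)) stop_metadiv("file not found: ", path)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", comment.char = "#",
                    quote = "\"", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop_metadiv("OTU table needs an id column plus at least one count column")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop_metadiv("duplicate row identifier(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(colnames(raw)[-1])) {
    stop_metadiv("duplicate column identifier(s): ",
                 paste(unique(colnames(raw)[-1][duplicated(colnames(raw)[-1])]), collapse = ", "))
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(num) | abs(num - round(num)) > 0 | num < 0)
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(cells)) + 1
    j <- ((bad[1] - 1) %/% nrow(cells)) + 1
    stop_metadiv("non-integer or negative count \"", cells[i, j],
                 "\" at row '", ids[i], "', column '", colnames(cells)[j], "'")
  }
  mat <- matrix(as.integer(num), nrow = nrow(cells),
                dimnames = list(ids, colnames(cells)))
  if (!samples_as_rows) mat <- t(mat)
  validate_otu_table(mat)
}

#' Write a sample-by-OTU table to delimited text
#'
#' @param table integer matrix, rows = samples.
#' @param path output path; `.csv` selects comma separation, anything else tab.
#' @param sep optional explicit separator.
#' @export
write_otu_table <- function(table, path, sep = NULL) {
  table <- validate_otu_table(table)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a community matrix
#'
#' Checks the OtuTable invariants: non-negative integer counts and unique
#' sample/OTU identifiers. Samples with a zero row sum are permitted (empty
#' traps happen) but reported with a warning so that they are not fed to the
#' coverage estimators unnoticed.
#'
#' @param table matrix-like object, rows = samples, columns = OTUs.
#' @return the table as an integer matrix, invisibly usable downstream.
#' @export
validate_otu_table <- function(table) {
  table <- as.matrix(table)
  if (!is_count_vector(as.vector(table))) {
    stop_metadiv("OTU table must contain non-negative integer read counts")
  }
  storage.mode(table) <- "integer"
  if (is.null(rownames(table)) || is.null(colnames(table))) {
    stop_metadiv("OTU table must carry sample (row) and OTU (column) names")
  }
  if (anyDuplicated(rownames(table))) stop_metadiv("duplicate sample identifiers")
  if (anyDuplicated(colnames(table))) stop_metadiv("duplicate OTU identifiers")
  empty <- rownames(table)[rowSums(table) == 0]
  if (length(empty)) {
    warning("sample(s) with zero reads retained but unusable for estimation: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  table
}

#' Per-sample frequency counts
#'
#' Tallies, for one sample, the number of OTUs observed with exactly r reads
#' (f_1 = singletons, f_2 = doubletons, ...), plus the total read count n and
#' the observed richness S_obs. These counts are the sufficient statistics for
#' the singleton filter and every coverage / Hill estimator.
#'
#' @param table community matrix (rows = samples) or a bare named/unnamed
#'   count vector for a single sample.
#' @param sample_id row name, required when `table` is a matrix.
#' @return object of class `freq_counts`: list with elements `sample_id`, `n`,
#'   `S_obs` and `f` (named integer vector, names are the frequencies r).
#' @examples
#' fc <- frequency_counts(c(5, 3, 1, 1))
#' fc$n      # 10
#' fc$f[["1"]]  # 2 singletons
#' @export
frequency_counts <- function(table, sample_id = NULL) {
  if (is.matrix(table) || is.data.frame(table)) {
    table <- validate_otu_table(as.matrix(table))
    if (is.null(sample_id)) stop_metadiv("sample_id required for a matrix input")
    if (!sample_id %in% rownames(table)) stop_metadiv("unknown sample id: ", sample_id)
    x <- table[sample_id, ]
  } else {
    x <- table
  }
  if (!is_count_vector(x)) stop_metadiv("counts must be non-negative integers")
  x <- as.integer(round(x[x > 0]))
  f <- table(x)
  f <- setNames(as.integer(f), names(f))
  structure(list(sample_id = sample_id, n = sum(x), S_obs = length(x), f = f),
            class = "freq_counts")
}

#' @export
print.freq_counts <- function(x, ...) {
  cat("Frequency counts", if (!is.null(x$sample_id)) paste0("[", x$sample_id, "]"),
      ": n =", x$n, ", S_obs =", x$S_obs, "\n")
  shown <- head(x$f, 6L)
  cat(paste0("  f", names(shown), " = ", shown, collapse = "\n"), "\n")
  invisible(x)
}

# number of OTUs with exactly r reads (0 if the tally has no such class)
f_r <- function(fc, r) {
  v <- fc$f[as.character(r)]
  if (is.na(v)) 0L else as.integer(v)
}

# reconstruct the abundance vector (unlabelled) from frequency counts
counts_from_freq <- function(fc) {
  if (fc$S_obs == 0L) return(integer(0))
  rep(as.integer(names(fc$f)), fc$f)
}

# coerce counts / freq_counts to freq_counts
as_freq_counts <- function(x) {
  if (inherits(x, "freq_counts")) x else frequency_counts(x)
}
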