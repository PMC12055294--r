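# readers/writers for the remaining external formats: FASTA alignments,
# Newick trees, calibration tables, taxonomy tables, environmental tables

#' Read (aligned) nucleotide sequences from FASTA
#'
#' Sequences are returned as a named character vector of upper-case strings.
#' The alphabet is validated against IUPAC nucleotide codes plus gap
#' characters; anything else (e.g. amino-acid letters) is a validation error,
#' since a wrong alphabet silently ruins distance estimation.
#'
#' @param path FASTA file.
#' @return named character vector, names = record ids.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_metadiv("file not found: ", path)
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqtype = "DNA")
  seqs <- toupper(vapply(recs, function(s) as.character(s)[1], character(1)))
  names(seqs) <- vapply(recs, function(s) attr(s, "name"), character(1))
  if (anyDuplicated(names(seqs))) stop_metadiv("duplicate FASTA record ids")
  bad <- grepl("[^ACGTURYSWKMBDHVN.-]", seqs)
  if (any(bad)) {
    stop_metadiv("non-IUPAC nucleotide character(s) in record(s): ",
                 paste(names(seqs)[bad], collapse = ", "))
  }
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = 80)
  invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] adding the
#' checks the downstream tree assembly requires: a single tree per file and
#' unique tip labels. Round-trips preserve topology, labels and branch
#' lengths to printing precision.
#'
#' @param path Newick file (one tree).
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_metadiv("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop_metadiv("malformed Newick in ", path, ": ",
                                                  conditionMessage(e)))
  if (is.null(tr)) stop_metadiv("malformed Newick in ", path)
  if (inherits(tr, "multiPhylo")) stop_metadiv("expected a single tree in ", path)
  if (anyDuplicated(tr$tip.label)) {
    stop_metadiv("duplicate tip label(s): ",
                 paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' @rdname read_newick
#' @param tree an [ape::phylo] object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a node-age calibration table
#'
#' Two-column delimited text (`node_label`, `age`), ages in the same time unit
#' as the backbone tree (e.g. Myr before present). Label resolution against a
#' tree happens later, in [calibrate_ages()].
#'
#' @param path TSV/CSV path.
#' @return named numeric vector of ages.
#' @export
read_calibrations <- function(path) {
  df <- read.table(path, header = TRUE, sep = if (grepl("\\.csv$", path)) "," else "\t",
                   stringsAsFactors = FALSE)
  need <- c("node_label", "age")
  if (!all(need %in% colnames(df))) {
    stop_metadiv("calibration table needs columns: ", paste(need, collapse = ", "))
  }
  age <- as.numeric(df$age)
  if (anyNA(age) || any(age < 0)) stop_metadiv("calibration ages must be non-negative numbers")
  if (anyDuplicated(df$node_label)) stop_metadiv("duplicate calibration label(s)")
  setNames(age, df$node_label)
}

#' Read an OTU taxonomy table
#'
#' Delimited text with columns `otu_id`, `family`, `order`. Used to route
#' barcode subtrees to backbone family nodes.
#'
#' @param path TSV/CSV path.
#' @return data.frame with columns otu_id, family, order.
#' @export
read_taxonomy <- function(path) {
  df <- read.table(path, header = TRUE, sep = if (grepl("\\.csv$", path)) "," else "\t",
                   stringsAsFactors = FALSE)
  need <- c("otu_id", "family", "order")
  if (!all(need %in% colnames(df))) {
    stop_metadiv("taxonomy table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$otu_id)) stop_metadiv("duplicate otu_id in taxonomy")
  df[, need]
}

#' Read a per-sample environmental table
#'
#' First column `sample_id`; remaining columns are continuous or categorical
#' variables. Character columns are converted to factors (categorical).
#'
#' @param path TSV/CSV path.
#' @return data.frame with rownames = sample ids.
#' @export
read_env <- function(path) {
  df <- read.table(path, header = TRUE, sep = if (grepl("\\.csv$", path)) "," else "\t",
                   stringsAsFactors = FALSE)
  if (colnames(df)[1] != "sample_id") stop_metadiv("first env column must be sample_id")
  if (anyDuplicated(df$sample_id)) stop_metadiv("duplicate sample_id in env table")
  rownames(df) <- df$sample_id
  df$sample_id <- NULL
  for (j in seq_along(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  df
}
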