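# File-format helpers. FASTA goes through Biostrings; tabular data are plain
# TSV with a header row. Sequences are normalized to upper case on read.

#' Read a FASTA file into a named character vector
#'
#' @param path path to an (uncompressed) FASTA file
#' @return named character vector of uppercase sequences; names are the
#'   first whitespace-delimited token of each header
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line-wrap width
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(toupper(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a TSV file with a header row
#' @param path input path
#' @return data.frame (strings kept as character)
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a data.frame as TSV with a header row
#' @param df data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an hclust dendrogram in Newick format
#' @param hc object of class `hclust`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
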