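## Plain-text readers/writers for the pipeline's interchange formats.
## FASTA via Biostrings; TSV via data.table (tab-separated, with header).

#' Write named sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a TSV into a data.frame
#' @param path TSV file.
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}

#' Write species pools as haplotype FASTA
#'
#' One record per haplotype, id `<gene>|<species>|hap<k>`.
#'
#' @param pool named list of haplotype matrices.
#' @param species species label.
#' @param path output file.
#' @export
write_pool_fasta <- function(pool, species, path) {
  seqs <- character(0)
  for (g in names(pool)) {
    hap <- pool[[g]]
    s <- apply(hap, 1L, paste, collapse = "")
    names(s) <- sprintf("%s|%s|hap%d", g, species, seq_along(s))
    seqs <- c(seqs, s)
  }
  write_fasta(seqs, path)
}
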