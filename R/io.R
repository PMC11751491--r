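#' Read sequences from FASTA or FASTQ (optionally gzipped)
#'
#' The format is autodetected from the first record character ('>' FASTA,
#' '@' FASTQ); multi-line FASTA and gzip compression are supported.
#'
#' @param path input file.
#' @return data.frame with `name`, `seq` and `qual` (NA for FASTA).
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "r")
  first <- tryCatch(readLines(con, n = 1L), finally = close(con))
  if (length(first) == 0L) stop("empty sequence file: ", path)
  lead <- substr(trimws(first), 1L, 1L)
  if (lead == ">") {
    x <- Biostrings::readBStringSet(path, format = "fasta")
    data.frame(name = names(x), seq = as.character(x), qual = NA_character_,
               stringsAsFactors = FALSE, row.names = NULL)
  } else if (lead == "@") {
    x <- Biostrings::readBStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
    data.frame(name = names(x), seq = as.character(x),
               qual = as.character(S4Vectors::mcols(x)$qualities),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    stop("malformed record at line 1 of ", path,
         ": expected '>' (FASTA) or '@' (FASTQ), got '", lead, "'")
  }
}

#' Write sequences as FASTA / FASTQ
#'
#' @param seqs named character vector or `name`/`seq`(/`qual`) data.frame.
#' @param path output file (".gz" suffix compresses).
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_read_table(seqs)
  x <- Biostrings::BStringSet(setNames(seqs$seq, seqs$name))
  Biostrings::writeXStringSet(x, path, format = "fasta",
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(seqs, path) {
  seqs <- as_read_table(seqs)
  qual <- seqs$qual
  qual[is.na(qual)] <- vapply(nchar(seqs$seq)[is.na(qual)], function(n)
    paste(rep("I", n), collapse = ""), character(1))
  x <- Biostrings::BStringSet(setNames(seqs$seq, seqs$name))
  Biostrings::writeXStringSet(
    x, path, format = "fastq", compress = grepl("\\.gz$", path),
    qualities = Biostrings::BStringSet(qual))
  invisible(path)
}
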