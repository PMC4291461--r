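#' Write reads as a standard 4-line FASTQ file
#'
#' Qualities are constant `'I'` (Phred 40 in Sanger encoding); the pipeline
#' never uses base qualities.
#'
#' @param x a `simulated_reads` object or a data.frame with `read_id` and
#'   `sequence` columns.
#' @param path output file path (a `.gz` suffix triggers gzip compression).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  if (inherits(x, "simulated_reads")) x <- x$reads
  stopifnot(all(c("read_id", "sequence") %in% names(x)))
  qual <- strrep("I", nchar(x$sequence))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(rbind(paste0("@", x$read_id), x$sequence, "+", qual), con)
  invisible(path)
}

#' Read a 4-line FASTQ file into a data.frame
#'
#' Transparent to gzip compression. Structural problems (record count not a
#' multiple of four, missing `@`/`+` marker lines) raise an error naming the
#' offending record index.
#'
#' @param path FASTQ file path.
#' @return data.frame with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ (", path, "): ", length(lines),
         " lines is not a multiple of 4 (truncated record ",
         ceiling(length(lines) / 4), ")")
  n <- length(lines) / 4
  hdr <- lines[seq(1, by = 4, length.out = n)]
  sep <- lines[seq(3, by = 4, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(sep, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], " in ", path,
         ": expected '@'/'+' marker lines")
  seqs <- toupper(lines[seq(2, by = 4, length.out = n)])
  data.frame(read_id = sub("^@", "", sub("\\s.*", "", hdr)),
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Write a named character vector of sequences as FASTA
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

# shared TSV writer: plain tab-separated, header, no quoting
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
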