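#' Read promoter sequences from a FASTA file
#'
#' Sequences are uppercased; the gene id is the first whitespace-delimited
#' token of each header. Only A/C/G/T/N characters are allowed.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_promoter_fasta <- function(path) {
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (!length(heads)) stop_format("no FASTA records in ", path)
  ids <- vapply(lines[heads], function(h) {
    strsplit(sub("^>\\s*", "", h), "\\s+")[[1L]][1L]
  }, character(1L), USE.NAMES = FALSE)
  if (anyDuplicated(ids)) stop_format("duplicate sequence ids in ", path)
  ends <- c(heads[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(heads), function(i) {
    if (heads[i] + 1L > ends[i]) return("")
    toupper(paste(lines[(heads[i] + 1L):ends[i]], collapse = ""))
  }, character(1L))
  if (any(grepl("[^ACGTN]", seqs))) {
    stop_format("sequences contain characters outside A/C/G/T/N")
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @param width line-wrap width.
#' @export
write_promoter_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
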