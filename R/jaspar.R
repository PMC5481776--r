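#' Construct a position weight matrix (PWM)
#'
#' Stores a transcription-factor binding motif as a 4 x L matrix of
#' nonnegative base counts (rows A, C, G, T) plus a pseudocount used when
#' converting to log-odds scores.
#'
#' @param tf_name motif/TF name.
#' @param counts 4 x L numeric matrix of nonnegative counts; rows are taken in
#'   A, C, G, T order (row names, if present, are used to reorder).
#' @param pseudocount positive real added to every count during scoring.
#' @return an object of class `PWM`.
#' @export
pwm <- function(tf_name, counts, pseudocount = 0.01) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop_input("PWM needs 4 base rows (A, C, G, T)")
  if (!is.null(rownames(counts))) {
    if (!setequal(rownames(counts), c("A", "C", "G", "T"))) {
      stop_format("PWM row names must be A, C, G, T")
    }
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  } else {
    rownames(counts) <- c("A", "C", "G", "T")
  }
  if (ncol(counts) < 1L) stop_format("PWM must have at least one position")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop_format("PWM counts must be finite and nonnegative")
  }
  if (any(colSums(counts) == 0)) stop_format("PWM has an all-zero column")
  assert_scalar_number(pseudocount, "pseudocount", positive = TRUE)
  structure(list(tf_name = as.character(tf_name), counts = counts,
                 pseudocount = pseudocount), class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat(sprintf("PWM %s: %d positions, pseudocount %g\n",
              x$tf_name, ncol(x$counts), x$pseudocount))
  invisible(x)
}

#' Read motifs from a JASPAR PFM text file
#'
#' Accepts both common text dialects, auto-detected per record: the 2016-style
#' layout with four labelled, bracketed rows (`A [ 1 2 3 ]`) and the plain
#' four-row layout without labels (rows taken as A, C, G, T). Records start
#' with a `>ID NAME` header line.
#'
#' @param path motif file path.
#' @param pseudocount pseudocount stored on every returned [pwm()].
#' @return a named list of `PWM` objects (names = TF names).
#' @export
read_jaspar_pfms <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  starts <- grep("^>", lines)
  if (!length(starts)) stop_format("no motif records ('>' headers) in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    parts <- strsplit(trimws(header), "\\s+")[[1L]]
    name <- if (length(parts) >= 2L) paste(parts[-1L], collapse = "_") else parts[1L]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != 4L) {
      stop_format("motif '", name, "': expected 4 base rows, got ", length(body))
    }
    labelled <- all(grepl("^\\s*[ACGTacgt]\\b", body))
    rows <- lapply(body, function(ln) {
      ln <- gsub("[\\[\\]]", " ", ln, perl = TRUE)
      if (labelled) ln <- sub("^\\s*[ACGTacgt]", " ", ln)
      parse_numeric(strsplit(trimws(ln), "\\s+")[[1L]])
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) {
      stop_format("motif '", name, "': base rows have unequal lengths")
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- if (labelled) {
      toupper(substr(trimws(body), 1L, 1L))
    } else c("A", "C", "G", "T")
    out[[i]] <- pwm(name, counts, pseudocount)
  }
  names(out) <- vapply(out, function(p) p$tf_name, character(1L))
  out
}

#' Write motifs in JASPAR PFM text format
#'
#' Emits the labelled, bracketed dialect, one record per motif.
#'
#' @param pwms a list of [pwm()] objects.
#' @param path output file path.
#' @export
write_jaspar_pfms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(pwms)) {
    p <- pwms[[i]]
    writeLines(sprintf(">M%04d %s", i, p$tf_name), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(sprintf("%.10g", p$counts[b, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}
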