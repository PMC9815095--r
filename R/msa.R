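# A3M / aligned-FASTA multiple sequence alignments.
#
# A3M semantics: uppercase letters and '-' are match columns relative to the
# query; lowercase letters are insertion states and do not consume a column.
# The first sequence is the query and carries no gaps, so alignment column j
# corresponds to query residue j.

#' Construct an MSA object
#'
#' @param names record names (first is the query).
#' @param rows aligned sequences (A3M strings; may contain lowercase
#'   insertion states).
#' @param mask integer vector of masked query positions.
#' @return object of class `masked_msa`.
#' @export
masked_msa <- function(names, rows, mask = integer(0)) {
  stopifnot(length(names) == length(rows), length(rows) >= 1)
  qmatch <- msa_match_positions(rows[1])
  qlen <- length(qmatch)
  qchars <- strsplit(rows[1], "")[[1]][qmatch]
  if (any(qchars == "-")) {
    stop("query row must contain no gaps in match columns", call. = FALSE)
  }
  for (i in seq_along(rows)) {
    n <- length(msa_match_positions(rows[i]))
    if (n != qlen) {
      stop(sprintf("row %d has %d match columns but the query has %d",
                   i, n, qlen), call. = FALSE)
    }
  }
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) > 0 && (min(mask) < 1 || max(mask) > qlen)) {
    stop("mask positions must lie in 1..query length", call. = FALSE)
  }
  structure(list(names = names, rows = rows,
                 query = paste(qchars, collapse = ""),
                 n_col = qlen, col_to_query = seq_len(qlen), mask = mask),
            class = "masked_msa")
}

# positions (in the raw string) of match columns: uppercase or '-'
msa_match_positions <- function(row) {
  ch <- strsplit(row, "")[[1]]
  which(ch == "-" | (ch %in% LETTERS))
}

#' @export
print.masked_msa <- function(x, ...) {
  cat(sprintf("masked_msa: %d rows, query length %d, %d masked positions\n",
              length(x$rows), x$n_col, length(x$mask)))
  invisible(x)
}

#' Read an A3M or aligned-FASTA alignment
#'
#' The first record is the query. Lowercase insertion states are preserved
#' for re-emission but excluded from column bookkeeping. Rows whose
#' match-column count differs from the query raise an error naming the row.
#'
#' @param path A3M/FASTA file.
#' @return a `masked_msa` with an empty mask.
#' @export
load_msa <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty alignment file: ", path, call. = FALSE)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("not FASTA/A3M (first line is not a header): ", path,
                    call. = FALSE)
  idx <- cumsum(hdr)
  names <- sub("^>", "", trimws(lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
  seqs <- gsub("[[:space:]]", "", unname(seqs))
  if (length(seqs) != length(names)) {
    stop("record without sequence in ", path, call. = FALSE)
  }
  masked_msa(names, seqs)
}

#' Write an alignment as A3M
#' @param msa a `masked_msa`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  writeLines(as.vector(rbind(paste0(">", msa$names), msa$rows)), path)
  invisible(path)
}
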