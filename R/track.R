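# Residue score tracks and quality reports: containers plus TSV/JSON I/O.

new_score_track <- function(entries, window = 1L, floor = 1e-6,
                            positions = "ca", diagnostics = list()) {
  structure(list(entries = entries, window = as.integer(window),
                 floor = floor, positions = positions,
                 diagnostics = diagnostics),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("score_track: %d residues, window %d, total windowed %.3f\n",
              nrow(x$entries), x$window, sum(x$entries$windowed)))
  invisible(x)
}

#' Write a score track as TSV
#'
#' Columns: residue_number, insertion_code, aa, raw_daq, windowed_daq,
#' flagged (0/1, windowed below `threshold`). Values are written at full
#' precision so the track round-trips exactly.
#'
#' @param track a `score_track`.
#' @param path output file.
#' @param threshold flagging threshold on the windowed score.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, threshold = -0.5) {
  e <- track$entries
  hdr <- sprintf("# window=%d floor=%.17g threshold=%.17g",
                 track$window, track$floor, threshold)
  body <- sprintf("%d\t%s\t%s\t%.17g\t%.17g\t%d",
                  e$number, e$ins, e$aa, e$raw, e$windowed,
                  as.integer(e$windowed < threshold))
  cols <- "residue_number\tinsertion_code\taa\traw_daq\twindowed_daq\tflagged"
  writeLines(c(hdr, cols, body), path)
  invisible(path)
}

#' Read a score track written by [write_track()]
#' @param path TSV file.
#' @return a `score_track`.
#' @export
read_track <- function(path) {
  lines <- readLines(path)
  window <- 1L
  floor <- 1e-6
  if (grepl("^#", lines[1])) {
    window <- as.integer(sub(".*window=([0-9]+).*", "\\1", lines[1]))
    floor <- as.numeric(sub(".*floor=([-+0-9.eE]+).*", "\\1", lines[1]))
    lines <- lines[-1]
  }
  tab <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                           colClasses = c("integer", "character", "character",
                                          "numeric", "numeric", "integer"),
                           na.strings = NULL, quote = "")
  entries <- data.frame(key = residue_key(tab$residue_number,
                                          tab$insertion_code),
                        number = tab$residue_number,
                        ins = tab$insertion_code, aa = tab$aa,
                        raw = tab$raw_daq, windowed = tab$windowed_daq,
                        stringsAsFactors = FALSE)
  new_score_track(entries, window = window, floor = floor)
}

#' Assemble a quality report
#'
#' @param ca_rmsd Calpha r.m.s.d. in Angstrom.
#' @param per_threshold named fractions at the four GDT-HA thresholds.
#' @param n_pairs number of residue pairs used.
#' @param coverage n_pairs / reference length.
#' @param misaligned data.frame of misaligned segments (`start`, `end`,
#'   `length`).
#' @param total_daq optional total windowed score of the model.
#' @return object of class `quality_report`; `gdt_ha` is the mean of the
#'   four per-threshold fractions.
#' @export
quality_report <- function(ca_rmsd, per_threshold, n_pairs, coverage = NA,
                           misaligned = NULL, total_daq = NULL) {
  stopifnot(length(per_threshold) == 4)
  if (is.null(misaligned)) {
    misaligned <- data.frame(start = character(0), end = character(0),
                             length = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(ca_rmsd = ca_rmsd,
                 gdt_ha = mean(unname(per_threshold)),
                 per_threshold = per_threshold,
                 n_pairs = as.integer(n_pairs), coverage = coverage,
                 misaligned = misaligned, total_daq = total_daq),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("quality_report: Calpha r.m.s.d. %.3f A, GDT-HA %.3f (n = %d pairs)\n",
              x$ca_rmsd, x$gdt_ha, x$n_pairs))
  if (nrow(x$misaligned) > 0) {
    cat(sprintf("  %d misaligned segment(s): %s\n", nrow(x$misaligned),
                paste(sprintf("%s-%s", x$misaligned$start, x$misaligned$end),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Write a quality report as JSON
#' @param report a `quality_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' Read a quality report written by [write_report()]
#' @param path JSON file.
#' @return a `quality_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mis <- as.data.frame(x$misaligned, stringsAsFactors = FALSE)
  if (nrow(mis) == 0) mis <- NULL
  quality_report(ca_rmsd = x$ca_rmsd,
                 per_threshold = unlist(x$per_threshold),
                 n_pairs = x$n_pairs, coverage = x$coverage,
                 misaligned = mis, total_daq = x$total_daq)
}
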