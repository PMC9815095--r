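# Refinement-input preparation: trimmed template, masked MSA, and
# superposition of candidates on the template.
#
# The two operations are complementary by design: the template keeps only
# confident residues (windowed DAQ(AA) > 0) so the predictor preserves them,
# while the MSA loses its columns at exactly those confident positions so
# the predictor has no evolutionary signal to alter them.

#' Trim a model to its confident residues
#'
#' Removes residues whose windowed DAQ(AA) is non-positive (rule `"le0"`,
#' the protocol default) or strictly negative (rule `"lt0"`). Kept residues
#' are untouched: same coordinates, numbering and atom records.
#'
#' @param model a `protein_model`.
#' @param track a smoothed `score_track` aligned to the model.
#' @param rule `"le0"` removes scores <= 0; `"lt0"` removes scores < 0.
#' @return object of class `trimmed_template`: list with `model` (the
#'   subset), `kept`, `removed` (residue keys), `criterion` and `status`
#'   (`"ok"` or `"empty"` when nothing survives trimming).
#' @export
trim_template <- function(model, track, rule = c("le0", "lt0")) {
  rule <- match.arg(rule)
  e <- track$entries
  scoreable <- model$residues$key[!is.na(model$residues$x)]
  if (!identical(sort(e$key), sort(scoreable))) {
    stop("score track does not align with the model's scoreable residues",
         call. = FALSE)
  }
  drop <- if (rule == "le0") e$windowed <= 0 else e$windowed < 0
  removed <- e$key[drop]
  kept <- e$key[!drop]
  status <- "ok"
  if (length(kept) == 0) {
    warning("trimming removed every residue; template is empty",
            call. = FALSE)
    status <- "empty"
  }
  structure(list(model = subset_model(model, kept), kept = kept,
                 removed = removed,
                 criterion = sprintf("windowed DAQ(AA) %s 0 removed",
                                     if (rule == "le0") "<=" else "<"),
                 status = status),
            class = "trimmed_template")
}

#' @export
print.trimmed_template <- function(x, ...) {
  cat(sprintf("trimmed_template: kept %d, removed %d (%s)\n",
              length(x$kept), length(x$removed), x$criterion))
  invisible(x)
}

#' Mask confident positions of an MSA
#'
#' Every query position with windowed DAQ(AA) >= 0 has its match column
#' replaced by the gap character in all non-query rows; the query row is
#' never touched, so the predictor still sees the full target sequence.
#' Masking is idempotent.
#'
#' @param msa a `masked_msa` whose query length equals the number of scored
#'   residues.
#' @param track a smoothed `score_track`.
#' @param threshold positions with `windowed >= threshold` are masked
#'   (default 0).
#' @return a `masked_msa` with updated rows and mask record.
#' @export
mask_msa <- function(msa, track, threshold = 0) {
  e <- track$entries
  if (msa$n_col != nrow(e)) {
    stop(sprintf("MSA query length (%d) does not match track length (%d)",
                 msa$n_col, nrow(e)), call. = FALSE)
  }
  positions <- which(e$windowed >= threshold)
  rows <- msa$rows
  if (length(positions) > 0 && length(rows) > 1) {
    for (i in seq_along(rows)[-1]) {
      ch <- strsplit(rows[i], "")[[1]]
      mcol <- msa_match_positions(rows[i])
      ch[mcol[positions]] <- "-"
      rows[i] <- paste(ch, collapse = "")
    }
  }
  masked_msa(msa$names, rows, mask = union(msa$mask, positions))
}

#' Superpose a candidate model on a trimmed template
#'
#' Rigid (Kabsch) superposition over the Calpha pairs the candidate shares
#' with the template, by residue key; the candidate's internal geometry is
#' unchanged.
#'
#' @param candidate a `protein_model`.
#' @param template a `trimmed_template` or `protein_model`.
#' @return the transformed candidate `protein_model`.
#' @export
superpose_on_template <- function(candidate, template) {
  tmodel <- if (inherits(template, "trimmed_template")) template$model else template
  shared <- intersect(residue_keys(candidate), residue_keys(tmodel))
  shared <- shared[!is.na(candidate$residues$x[match(shared, candidate$residues$key)])]
  if (length(shared) < 3) {
    stop("candidate and template share fewer than 3 residues", call. = FALSE)
  }
  xm <- ca_matrix(candidate)[shared, , drop = FALSE]
  ym <- ca_matrix(tmodel)[shared, , drop = FALSE]
  tf <- kabsch(xm, ym)
  out <- candidate
  has_ca <- !is.na(out$residues$x)
  out$residues[has_ca, c("x", "y", "z")] <-
    apply_transform(tf, as.matrix(out$residues[has_ca, c("x", "y", "z")]))
  out$atoms[, c("x", "y", "z")] <-
    apply_transform(tf, as.matrix(out$atoms[, c("x", "y", "z")]))
  out
}
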