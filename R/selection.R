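# DAQ-based selection among candidate refined models: score every candidate
# against the same probability volume, rank by total windowed DAQ(AA), and
# take the top-ranked model as the final model.

#' Rank candidate models by total DAQ(AA)
#'
#' @param models list of `protein_model`s (optionally named; unnamed
#'   candidates are labelled `model_1`, `model_2`, ...).
#' @param volume the `probability_volume` all candidates are scored against.
#' @param window smoothing window (default 19).
#' @param use ranking total: `"windowed"` (default) or `"raw"`.
#' @param per_residue rank by mean per-residue score instead of the sum
#'   (for candidates of unequal length).
#' @return object of class `candidate_set`: `ranking` data.frame (label,
#'   total, rank, tied), `tracks` and `models` in ranked order; the first
#'   entry is the selected final model. Ties keep input order and are
#'   recorded.
#' @export
rank_candidates <- function(models, volume, window = 19,
                            use = c("windowed", "raw"),
                            per_residue = FALSE) {
  use <- match.arg(use)
  if (length(models) == 0) stop("no candidate models", call. = FALSE)
  labels <- names(models)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- sprintf("model_%d", seq_along(models))
  }
  if (anyDuplicated(labels)) stop("candidate labels must be unique",
                                  call. = FALSE)
  tracks <- lapply(models, daq_score, volume = volume, window = window)
  totals <- vapply(tracks, function(tr) {
    tot <- total_daq(tr, use = use)
    if (per_residue) tot / nrow(tr$entries) else tot
  }, numeric(1))
  ord <- order(-totals, seq_along(totals))
  tied <- duplicated(totals[ord]) | rev(duplicated(rev(totals[ord])))
  ranking <- data.frame(label = labels[ord], total = unname(totals[ord]),
                        rank = seq_along(ord), tied = tied,
                        stringsAsFactors = FALSE)
  structure(list(ranking = ranking, tracks = tracks[ord],
                 models = models[ord], use = use, window = window),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d models ranked by total %s DAQ(AA)\n",
              nrow(x$ranking), x$use))
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Selected (top-ranked) model of a candidate set
#' @param set a `candidate_set`.
#' @return the `protein_model` with the highest total DAQ(AA).
#' @export
final_model <- function(set) set$models[[1]]

#' Correlation between total DAQ(AA) and GDT-HA over a candidate set
#'
#' @param set a `candidate_set` from [rank_candidates()].
#' @param reference the reference `protein_model` for GDT-HA.
#' @return list with `status` (`"ok"` or `"undefined"` when either variable
#'   has zero variance), Pearson `r`, regression `slope` and `intercept`,
#'   and the per-candidate `data` (label, total, gdt_ha).
#' @export
correlate_quality <- function(set, reference) {
  if (nrow(set$ranking) < 3) {
    stop("need at least 3 candidates to correlate", call. = FALSE)
  }
  gdt <- vapply(set$models, function(m) as.numeric(gdt_ha(m, reference)),
                numeric(1))
  tot <- set$ranking$total
  data <- data.frame(label = set$ranking$label, total = tot, gdt_ha = gdt,
                     stringsAsFactors = FALSE)
  if (stats::sd(tot) == 0 || stats::sd(gdt) == 0) {
    return(list(status = "undefined", r = NA_real_, slope = NA_real_,
                intercept = NA_real_, data = data))
  }
  fit <- stats::lm(gdt ~ tot)
  list(status = "ok", r = stats::cor(tot, gdt),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), data = data)
}
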