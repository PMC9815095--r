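# DAQ(AA) scoring: per-residue log-ratio of the modeled amino acid's
# probability at its Calpha to that type's average probability over all
# scored positions, followed by sliding-window smoothing along the chain.
#
#   raw_i = ln( p_i / mean_j p_j^(aa_i) )
#
# where p_i is the probability of type aa_i at the position of residue i and
# the mean runs over all N scoring positions j of the model. A residue whose
# own-type probability exceeds the model-wide average for that type scores
# positive; a residue sitting in density the classifier attributes to other
# types scores negative.

#' Raw per-residue DAQ(AA) scores
#'
#' @param model a `protein_model` (residues without a Calpha are skipped).
#' @param volume a `probability_volume` (grid or per-residue table).
#' @param positions `"ca"` (default): the normalizing average runs over
#'   Calpha positions, one per residue; `"all"`: over every atom position in
#'   the model. Numerators are always taken at the Calpha.
#' @param interpolation passed to [probability_at()] for grid volumes.
#' @param floor probability floor for out-of-grid / vanishing lookups.
#' @return a `score_track` with `windowed` equal to `raw` (window 1); apply
#'   [smooth_track()] for the 19-residue windowed scores.
#' @export
raw_daq_aa <- function(model, volume, positions = c("ca", "all"),
                       interpolation = c("trilinear", "nearest"),
                       floor = 1e-6) {
  positions <- match.arg(positions)
  interpolation <- match.arg(interpolation)
  res <- model$residues[!is.na(model$residues$x), , drop = FALSE]
  if (nrow(res) == 0) stop("model has no scoreable residues", call. = FALSE)

  if (volume$kind == "table") {
    missing <- setdiff(res$key, volume$keys)
    if (length(missing) > 0) {
      stop("probability table lacks residues: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    P <- volume$probs[res$key, , drop = FALSE]
    P[P < floor] <- floor
    n_floored <- 0L
    n_outside <- 0L
  } else {
    pos <- as.matrix(res[, c("x", "y", "z")])
    if (positions == "all") {
      pos <- as.matrix(model$atoms[, c("x", "y", "z")])
    }
    ca <- as.matrix(res[, c("x", "y", "z")])
    f <- sweep(sweep(ca, 2, volume$origin, "-"), 2, volume$spacing, "/")
    outside <- f[, 1] < 0 | f[, 1] > volume$dims[1] - 1 |
      f[, 2] < 0 | f[, 2] > volume$dims[2] - 1 |
      f[, 3] < 0 | f[, 3] > volume$dims[3] - 1
    n_outside <- sum(outside)
    if (n_outside > 0.5 * nrow(ca)) {
      stop(sprintf(
        "%d of %d Calpha positions fall outside the probability grid; check that model and volume share a coordinate frame",
        n_outside, nrow(ca)), call. = FALSE)
    }
    # probabilities of every type at the numerator (Calpha) and denominator
    # (scoring) positions
    n_floored <- 0L
    P <- matrix(NA_real_, nrow = nrow(ca), ncol = 20,
                dimnames = list(res$key, AA_TYPES))
    D <- matrix(NA_real_, nrow = nrow(pos), ncol = 20,
                dimnames = list(NULL, AA_TYPES))
    for (aa in AA_TYPES) {
      v <- probability_at(volume, ca, aa, interpolation = interpolation,
                          floor = floor)
      n_floored <- n_floored + attr(v, "n_floored")
      P[, aa] <- v
      D[, aa] <- if (positions == "ca") v else {
        probability_at(volume, pos, aa, interpolation = interpolation,
                       floor = floor)
      }
    }
  }

  if (volume$kind == "table") D <- P
  mean_type <- colMeans(D)
  p_own <- P[cbind(seq_len(nrow(res)), match(res$aa, AA_TYPES))]
  raw <- log(p_own / mean_type[res$aa])

  entries <- data.frame(key = res$key, number = res$number, ins = res$ins,
                        aa = res$aa, raw = raw, windowed = raw,
                        stringsAsFactors = FALSE)
  new_score_track(entries, window = 1L, floor = floor, positions = positions,
                  diagnostics = list(n_residues = nrow(res),
                                     n_floored = n_floored,
                                     n_outside = n_outside))
}

#' Smooth a score track with a sliding window
#'
#' The windowed score of residue i is the arithmetic mean of the raw scores
#' of the modeled residues within the window centred on i. The window
#' shrinks at chain termini and never crosses a chain break (a jump of more
#' than 1 in author numbering), so unmodeled residues contribute nothing.
#'
#' @param track a `score_track`.
#' @param window odd window length in residues (default 19).
#' @return a `score_track` with updated `windowed` values.
#' @export
smooth_track <- function(track, window = 19) {
  window <- as.integer(window)
  if (window < 1 || window %% 2 == 0) {
    stop("window must be an odd positive integer", call. = FALSE)
  }
  e <- track$entries
  n <- nrow(e)
  half <- (window - 1L) %/% 2L
  # segment id advances at numbering jumps > 1
  brk <- c(FALSE, diff(e$number) > 1)
  seg <- cumsum(brk)
  windowed <- numeric(n)
  for (s in unique(seg)) {
    idx <- which(seg == s)
    raw <- e$raw[idx]
    m <- length(idx)
    cs <- cumsum(c(0, raw))
    lo <- pmax(seq_len(m) - half, 1L)
    hi <- pmin(seq_len(m) + half, m)
    windowed[idx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out <- track
  out$entries$windowed <- windowed
  out$window <- window
  out
}

#' Compute raw and windowed DAQ(AA) in one call
#'
#' @inheritParams raw_daq_aa
#' @param window smoothing window (odd; default 19).
#' @return a smoothed `score_track`.
#' @export
daq_score <- function(model, volume, window = 19, positions = "ca",
                      interpolation = "trilinear", floor = 1e-6) {
  smooth_track(raw_daq_aa(model, volume, positions = positions,
                          interpolation = interpolation, floor = floor),
               window = window)
}

#' Residues whose windowed score falls below a threshold
#'
#' Windowed DAQ(AA) below -0.5 marks residues that are unlikely to fit the
#' local density and deserve attention.
#'
#' @param track a smoothed `score_track`.
#' @param threshold flagging threshold (default -0.5).
#' @return character vector of residue keys with `windowed < threshold`.
#' @export
flag_low_confidence <- function(track, threshold = -0.5) {
  e <- track$entries
  e$key[e$windowed < threshold]
}

#' Total DAQ(AA) of a model
#'
#' @param track a `score_track`.
#' @param use `"windowed"` (default) or `"raw"`.
#' @return sum of the chosen per-residue scores.
#' @export
total_daq <- function(track, use = c("windowed", "raw")) {
  use <- match.arg(use)
  if (nrow(track$entries) == 0) stop("empty score track", call. = FALSE)
  sum(track$entries[[use]])
}
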