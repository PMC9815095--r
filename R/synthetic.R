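# Synthetic fixtures with known ground truth: ideal backbones, oracle
# probability volumes peaked at the true residue types, and injectors for
# the two error classes the score is meant to expose (sequence-register
# shifts and conformational displacements).
#
# The volume emulates the output of a density-based amino-acid classifier:
# each residue imprints a Gaussian bump on its own channel, centred at its
# Calpha, such that the true type carries `peak_prob` there. The remaining
# mass is concentrated on a fixed chemically confusable partner type
# (V<->I, D<->N, E<->Q, ...), controlled by `confusion`; `confusion = 0`
# spreads it uniformly over the 19 other types instead. Far from the model
# every voxel is uniform (1/20 per type).

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Specification of a synthetic fixture
#'
#' @param n_residues chain length (>= 5).
#' @param geometry `"helix"` (1.5 A rise, 100 degree twist, 2.3 A radius),
#'   `"extended"` (3.8 A Calpha spacing zigzag) or `"mixed"` (helix then
#'   extended).
#' @param sequence explicit one-letter sequence, or `NULL` for a random
#'   sequence drawn with `seed`.
#' @param peak_prob probability of the true type at a residue's Calpha
#'   (in (1/20, 1]; default 0.6). At exactly 1/20 the volume is uniform.
#' @param confusion fraction of the off-true mass carried by the fixed
#'   confusable partner type (default 0.95; 0 = uniform background over the
#'   other 19 types).
#' @param blur_sigma Gaussian width of each residue's imprint in Angstrom.
#' @param noise Dirichlet-style perturbation scale on voxel distributions
#'   (0 = none).
#' @param spacing voxel size in Angstrom (default 1, the scan interval).
#' @param pad grid padding around the model in Angstrom (default 5).
#' @param seed RNG seed; identical seeds reproduce identical fixtures.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues = 100, geometry = "helix",
                           sequence = NULL, peak_prob = 0.6,
                           confusion = 0.95, blur_sigma = 1.0, noise = 0,
                           spacing = 1, pad = 5, seed = 1) {
  if (n_residues < 5) stop("n_residues must be >= 5", call. = FALSE)
  if (peak_prob <= 0 || peak_prob > 1 || peak_prob < 1 / 20) {
    stop("peak_prob must lie in [1/20, 1]", call. = FALSE)
  }
  if (confusion < 0 || confusion > 1) stop("confusion must be in [0, 1]",
                                           call. = FALSE)
  structure(list(n_residues = as.integer(n_residues), geometry = geometry,
                 sequence = sequence, peak_prob = peak_prob,
                 confusion = confusion, blur_sigma = blur_sigma,
                 noise = noise, spacing = spacing, pad = pad,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate an ideal-geometry Calpha backbone
#'
#' @param spec a `synthetic_spec`.
#' @return a Calpha-only `protein_model` (chain "A", residues numbered from
#'   1) with the spec's sequence (random draws are a pure function of the
#'   seed).
#' @export
make_backbone <- function(spec) {
  n <- spec$n_residues
  helix_xyz <- function(i) {
    th <- (i - 1) * 100 * pi / 180
    cbind(2.3 * cos(th), 2.3 * sin(th), (i - 1) * 1.5)
  }
  extended_xyz <- function(i, from = c(0, 0, 0)) {
    a <- 3.5
    b <- sqrt(3.8^2 - a^2)
    sweep(cbind((i - 1) * a, ((i - 1) %% 2) * b, 0), 2, from, "+")
  }
  ca <- switch(spec$geometry,
    helix = helix_xyz(seq_len(n)),
    extended = extended_xyz(seq_len(n)),
    mixed = {
      n1 <- ceiling(n / 2)
      h <- helix_xyz(seq_len(n1))
      if (n1 < n) {
        e <- extended_xyz(seq_len(n - n1),
                          from = h[n1, ] + c(3.8, 0, 0))
        rbind(h, e)
      } else h
    },
    stop("unknown geometry: ", spec$geometry, call. = FALSE))
  seq_aa <- spec$sequence
  if (is.null(seq_aa)) {
    restore <- local_seed(spec$seed)
    on.exit(restore())
    seq_aa <- sample(AA_TYPES, n, replace = TRUE)
  } else {
    if (length(seq_aa) == 1) seq_aa <- strsplit(seq_aa, "")[[1]]
    if (length(seq_aa) != n) stop("sequence length must equal n_residues",
                                  call. = FALSE)
  }
  protein_model("A", number = seq_len(n), aa = seq_aa, ca = ca,
                source_path = sprintf("<synthetic %s seed=%d>",
                                      spec$geometry, spec$seed))
}

#' Generate the oracle probability volume for a model
#'
#' @param model the ground-truth `protein_model`.
#' @param spec a `synthetic_spec` (peak, confusion, blur, noise, grid).
#' @return a grid `probability_volume` covering the model with `spec$pad`
#'   Angstrom of padding; every voxel distribution sums to 1.
#' @export
make_probability_volume <- function(model, spec) {
  ca <- ca_matrix(model)
  origin <- floor(apply(ca, 2, min) - spec$pad)
  upper <- ceiling(apply(ca, 2, max) + spec$pad)
  dims <- as.integer((upper - origin) / spec$spacing) + 1L
  nvox <- prod(dims)
  u <- 1 / 20

  channels <- lapply(AA_TYPES, function(a) array(u, dim = dims))
  names(channels) <- AA_TYPES

  if (spec$peak_prob > u + 1e-12) {
    other <- (1 - spec$confusion) * (1 - spec$peak_prob) / 19
    partner_p <- spec$confusion * (1 - spec$peak_prob) + other
    if (other <= 0) other <- u * 1e-12  # confusion = 1: partner takes all
    M <- u / other
    A <- spec$peak_prob * M - u
    Ap <- partner_p * M - u
    reach <- ceiling(4 * spec$blur_sigma / spec$spacing)
    axes <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 1) * spec$spacing)
    res <- model$residues[!is.na(model$residues$x), , drop = FALSE]
    for (r in seq_len(nrow(res))) {
      p <- c(res$x[r], res$y[r], res$z[r])
      iv <- lapply(1:3, function(k) {
        c0 <- round((p[k] - origin[k]) / spec$spacing)
        seq(max(0, c0 - reach), min(dims[k] - 1, c0 + reach)) + 1
      })
      gx <- exp(-(axes[[1]][iv[[1]]] - p[1])^2 / (2 * spec$blur_sigma^2))
      gy <- exp(-(axes[[2]][iv[[2]]] - p[2])^2 / (2 * spec$blur_sigma^2))
      gz <- exp(-(axes[[3]][iv[[3]]] - p[3])^2 / (2 * spec$blur_sigma^2))
      g <- outer(outer(gx, gy), gz)
      aa <- res$aa[r]
      channels[[aa]][iv[[1]], iv[[2]], iv[[3]]] <-
        channels[[aa]][iv[[1]], iv[[2]], iv[[3]]] + A * g
      pa <- AA_CONFUSION[[aa]]
      if (Ap > 0) {
        channels[[pa]][iv[[1]], iv[[2]], iv[[3]]] <-
          channels[[pa]][iv[[1]], iv[[2]], iv[[3]]] + Ap * g
      }
    }
  }

  if (spec$noise > 0) {
    restore <- local_seed(spec$seed + 1L)
    on.exit(restore())
    channels <- lapply(channels, function(ch) {
      array(stats::rgamma(nvox, shape = pmax(ch, 1e-8) / spec$noise, rate = 1),
            dim = dims)
    })
  }

  s <- Reduce(`+`, channels)
  channels <- lapply(channels, function(ch) ch / s)
  probability_volume(origin, spec$spacing, channels)
}

check_region <- function(model, region) {
  region <- as.integer(region)
  if (length(region) == 2) region <- region[1]:region[2]
  if (!all(region %in% model$residues$number)) {
    stop("region lies outside the modeled chain", call. = FALSE)
  }
  region
}

#' Inject a sequence-register shift
#'
#' Reassigns the amino-acid types inside `region` from positions offset by
#' `shift`; coordinates are untouched. This is exactly a
#' sequence-assignment error, not a conformational one.
#'
#' @param model a `protein_model`.
#' @param region residue-number range (`c(from, to)` or vector).
#' @param shift integer offset (types at i come from i + shift).
#' @return the modified `protein_model`.
#' @export
inject_register_shift <- function(model, region, shift) {
  region <- check_region(model, region)
  if (shift == 0) return(model)
  src <- region + shift
  if (!all(src %in% model$residues$number)) {
    stop("shift carries types off the chain end", call. = FALSE)
  }
  out <- model
  i <- match(region, out$residues$number)
  j <- match(src, out$residues$number)
  out$residues$aa[i] <- model$residues$aa[j]
  akey <- out$atoms$number %in% region
  out$atoms$aa[akey] <- out$residues$aa[match(out$atoms$number[akey],
                                              out$residues$number)]
  out
}

#' Inject a coherent conformational error
#'
#' Displaces the Calpha trace of `region` by a rigid offset of the given
#' magnitude (random direction, seeded) plus small per-residue jitter;
#' amino-acid types are unchanged.
#'
#' @param model a `protein_model`.
#' @param region residue-number range.
#' @param displacement offset magnitude in Angstrom.
#' @param jitter_sd per-residue jitter standard deviation (default 2% of
#'   the displacement).
#' @param seed RNG seed for direction and jitter.
#' @return the modified `protein_model`.
#' @export
inject_conformational_error <- function(model, region, displacement,
                                        jitter_sd = 0.02 * displacement,
                                        seed = 1) {
  region <- check_region(model, region)
  if (displacement == 0) return(model)
  restore <- local_seed(seed)
  on.exit(restore())
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  off <- dir * displacement
  out <- model
  i <- match(region, out$residues$number)
  jit <- matrix(stats::rnorm(3 * length(i), sd = jitter_sd), ncol = 3)
  out$residues[i, c("x", "y", "z")] <-
    sweep(as.matrix(model$residues[i, c("x", "y", "z")]), 2, off, "+") + jit
  ak <- which(out$atoms$number %in% region)
  ord <- match(out$atoms$number[ak], region)
  out$atoms[ak, c("x", "y", "z")] <-
    sweep(as.matrix(model$atoms[ak, c("x", "y", "z")]), 2, off, "+") +
    jit[ord, , drop = FALSE]
  out
}

#' Inject a geometric trace shift
#'
#' Replaces the coordinates of the residues in `region` by those of the
#' residues offset by `shift`, keeping types fixed: the chain is traced
#' through the wrong part of the density, the error class the
#' misaligned-segment detector targets. The complement of
#' [inject_register_shift()], which moves types instead of coordinates.
#'
#' @param model a `protein_model`.
#' @param region residue-number range.
#' @param shift integer offset (coordinates at i come from i + shift).
#' @return the modified `protein_model`.
#' @export
inject_trace_shift <- function(model, region, shift) {
  region <- check_region(model, region)
  if (shift == 0) return(model)
  src <- region + shift
  if (!all(src %in% model$residues$number)) {
    stop("shift carries the trace off the chain end", call. = FALSE)
  }
  out <- model
  i <- match(region, out$residues$number)
  j <- match(src, out$residues$number)
  out$residues[i, c("x", "y", "z")] <- model$residues[j, c("x", "y", "z")]
  # Calpha-only atom records follow the residue table
  ak <- match(residue_key(out$residues$number[i], out$residues$ins[i]),
              residue_key(out$atoms$number, out$atoms$ins))
  ok <- !is.na(ak)
  out$atoms[ak[ok], c("x", "y", "z")] <- out$residues[i[ok], c("x", "y", "z")]
  out
}
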