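# Model-quality metrics against a reference structure: optimal rigid
# superposition (Kabsch), Calpha r.m.s.d., GDT-HA with a deterministic
# seed-and-extend superposition search, and the misaligned-segment detector
# (>2 A from the corresponding residue and nearest to a different residue,
# in runs of at least 4).

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation (proper, det = +1) and translation mapping `x`
#' onto `y`.
#'
#' @param x,y n x 3 coordinate matrices of corresponding points.
#' @return list with `R` (3 x 3 rotation, row-vector convention), `cx`,
#'   `cy` (centroids) and `rmsd`, the minimum r.m.s.d. over all rigid
#'   motions. Apply with [apply_transform()].
#' @export
kabsch <- function(x, y) {
  x <- matrix(as.numeric(x), ncol = 3)
  y <- matrix(as.numeric(y), ncol = 3)
  n <- nrow(x)
  if (n < 3 || nrow(y) != n) {
    stop("kabsch needs at least 3 corresponding pairs", call. = FALSE)
  }
  cx <- colMeans(x)
  cy <- colMeans(y)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  sx <- svd(xc)$d
  if (sx[2] <= 1e-8 * max(sx[1], 1)) {
    stop("degenerate geometry: points are collinear or coincident",
         call. = FALSE)
  }
  h <- crossprod(xc, yc)
  s <- svd(h)
  u <- s$u
  if (det(u %*% t(s$v)) < 0) u[, 3] <- -u[, 3]
  rot <- u %*% t(s$v)
  d <- xc %*% rot - yc
  structure(list(R = rot, cx = cx, cy = cy,
                 rmsd = sqrt(mean(rowSums(d * d)))),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param tf a `rigid_transform` from [kabsch()].
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(tf, coords) {
  sweep(sweep(matrix(as.numeric(coords), ncol = 3), 2, tf$cx) %*% tf$R,
        2, tf$cy, "+")
}

# paired Calpha matrices for two models: by shared residue key, or an
# explicit two-column map (model key, reference key)
pair_ca <- function(model, reference, map = NULL) {
  xm <- ca_matrix(model)
  ym <- ca_matrix(reference)
  if (is.null(map)) {
    keys <- intersect(rownames(xm), rownames(ym))
    keys <- rownames(xm)[rownames(xm) %in% keys]
    map <- cbind(keys, keys)
  } else {
    map <- as.matrix(map)
    ok <- map[, 1] %in% rownames(xm) & map[, 2] %in% rownames(ym)
    map <- map[ok, , drop = FALSE]
  }
  if (nrow(map) == 0) stop("no corresponding Calpha pairs", call. = FALSE)
  list(x = xm[map[, 1], , drop = FALSE], y = ym[map[, 2], , drop = FALSE],
       model_key = map[, 1], ref_key = map[, 2])
}

#' Calpha r.m.s.d. between two models
#'
#' @param model,reference `protein_model`s.
#' @param map optional explicit correspondence: two-column matrix or
#'   data.frame of (model key, reference key); default pairs by shared key.
#' @param superpose optimally superpose first (default); `FALSE` computes
#'   the r.m.s.d. in the given frame.
#' @return r.m.s.d. in Angstrom with attribute `n_pairs`.
#' @export
ca_rmsd <- function(model, reference, map = NULL, superpose = TRUE) {
  p <- pair_ca(model, reference, map)
  if (nrow(p$x) < 3 && superpose) {
    stop("need at least 3 Calpha pairs for superposition", call. = FALSE)
  }
  r <- if (superpose) {
    kabsch(p$x, p$y)$rmsd
  } else {
    d <- p$x - p$y
    sqrt(mean(rowSums(d * d)))
  }
  structure(r, n_pairs = nrow(p$x))
}

#' GDT fractions under a seed-and-extend superposition search
#'
#' For each distance threshold the search seeds a superposition from every
#' contiguous residue window of the given lengths plus the global fit, then
#' iteratively refits on the residues currently within the threshold until
#' the inlier set is stable; the reported fraction is the best fraction of
#' pairs within the threshold over all seeds. GDT-HA is the mean fraction
#' over thresholds 0.5, 1, 2 and 4 Angstrom.
#'
#' @param model,reference `protein_model`s.
#' @param thresholds distance thresholds in Angstrom.
#' @param map optional explicit correspondence (see [ca_rmsd()]).
#' @param seed_lengths contiguous-window seed lengths; `"exhaustive"` uses
#'   every length from 3 to n.
#' @param max_iter refinement iterations per seed.
#' @return list with `per_threshold` (named fractions), `gdt` (their mean)
#'   and `n_pairs`.
#' @export
gdt_fractions <- function(model, reference, thresholds = c(0.5, 1, 2, 4),
                          map = NULL, seed_lengths = c(3, 5, 7),
                          max_iter = 20) {
  p <- pair_ca(model, reference, map)
  n <- nrow(p$x)
  if (n < 3) stop("need at least 3 Calpha pairs", call. = FALSE)
  if (identical(seed_lengths, "exhaustive")) seed_lengths <- 3:n
  seeds <- list(seq_len(n))
  for (L in seed_lengths[seed_lengths <= n]) {
    for (s in seq_len(n - L + 1)) seeds[[length(seeds) + 1]] <- s:(s + L - 1)
  }
  frac <- function(idx, t) {
    best <- 0
    cur <- idx
    for (it in seq_len(max_iter)) {
      tf <- tryCatch(kabsch(p$x[cur, , drop = FALSE],
                            p$y[cur, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(tf)) break
      d2 <- rowSums((apply_transform(tf, p$x) - p$y)^2)
      inl <- which(d2 <= t^2)
      best <- max(best, length(inl) / n)
      if (length(inl) < 3 || identical(inl, cur)) break
      cur <- inl
    }
    best
  }
  per <- vapply(thresholds, function(t) {
    max(vapply(seeds, frac, numeric(1), t = t))
  }, numeric(1))
  names(per) <- sprintf("%g", thresholds)
  list(per_threshold = per, gdt = mean(per), n_pairs = n)
}

#' High-accuracy global distance test (GDT-HA)
#' @inheritParams gdt_fractions
#' @return GDT-HA in [0, 1] with attributes `per_threshold` and `n_pairs`.
#' @export
gdt_ha <- function(model, reference, map = NULL, seed_lengths = c(3, 5, 7)) {
  g <- gdt_fractions(model, reference, thresholds = c(0.5, 1, 2, 4),
                     map = map, seed_lengths = seed_lengths)
  structure(g$gdt, per_threshold = g$per_threshold, n_pairs = g$n_pairs)
}

#' Misaligned-segment detection
#'
#' After global superposition, a residue is inconsistent when its Calpha
#' lies more than `dist` from its corresponding reference Calpha while its
#' nearest reference Calpha (within `capture`) belongs to a different
#' residue. Maximal runs of at least `min_run` consecutive inconsistent
#' residues are reported.
#'
#' @param model,reference `protein_model`s.
#' @param dist displacement threshold in Angstrom (default 2.0).
#' @param min_run minimum run length (default 4).
#' @param capture radius within which a nearest reference residue counts
#'   (default 5.0 Angstrom).
#' @param map optional explicit correspondence.
#' @param superpose superpose globally first (default `TRUE`).
#' @return data.frame with one row per segment: `start`, `end` (residue
#'   keys) and `length`.
#' @export
detect_misaligned <- function(model, reference, dist = 2.0, min_run = 4,
                              capture = 5.0, map = NULL, superpose = TRUE) {
  p <- pair_ca(model, reference, map)
  x <- p$x
  if (superpose) x <- apply_transform(kabsch(p$x, p$y), p$x)
  yall <- ca_matrix(reference)
  d_own <- sqrt(rowSums((x - p$y)^2))
  # nearest reference Calpha for every (superposed) model residue
  near_key <- character(nrow(x))
  near_d <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    d2 <- rowSums(sweep(yall, 2, x[i, ])^2)
    j <- which.min(d2)
    near_key[i] <- rownames(yall)[j]
    near_d[i] <- sqrt(d2[j])
  }
  bad <- d_own > dist & near_d <= capture & near_key != p$ref_key

  # runs over consecutive modeled residues (numbering jumps break runs)
  num <- model$residues$number[match(p$model_key, model$residues$key)]
  segs <- data.frame(start = character(0), end = character(0),
                     length = integer(0), stringsAsFactors = FALSE)
  i <- 1
  n <- length(bad)
  while (i <= n) {
    if (bad[i]) {
      j <- i
      while (j < n && bad[j + 1] && num[j + 1] - num[j] <= 1) j <- j + 1
      if (j - i + 1 >= min_run) {
        segs <- rbind(segs, data.frame(start = p$model_key[i],
                                       end = p$model_key[j],
                                       length = j - i + 1L,
                                       stringsAsFactors = FALSE))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  segs
}

#' Full quality report of a model against a reference
#'
#' @inheritParams detect_misaligned
#' @param track optional `score_track` of the model; its total windowed
#'   score is recorded in the report.
#' @return a `quality_report`.
#' @export
evaluate_model <- function(model, reference, map = NULL, dist = 2.0,
                           min_run = 4, capture = 5.0, track = NULL) {
  g <- gdt_fractions(model, reference, map = map)
  r <- ca_rmsd(model, reference, map = map)
  mis <- detect_misaligned(model, reference, dist = dist, min_run = min_run,
                           capture = capture, map = map)
  quality_report(ca_rmsd = as.numeric(r), per_threshold = g$per_threshold,
                 n_pairs = g$n_pairs,
                 coverage = g$n_pairs / nrow(reference$residues),
                 misaligned = mis,
                 total_daq = if (is.null(track)) NULL else total_daq(track))
}
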