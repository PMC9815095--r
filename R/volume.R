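# 20-channel amino-acid probability volumes: MRC-backed grids, a TSV
# per-residue table variant, and interpolated lookups.
#
# Grid convention: 0-based voxel indexing, grid point = origin + index *
# spacing, coordinates in Angstrom in the same frame as the model.

#' Construct a grid probability volume
#'
#' @param origin x/y/z of voxel (0,0,0) in Angstrom.
#' @param spacing Angstrom per voxel along each axis (scalar or length 3).
#' @param channels named list of 20 arrays `dim = dims`, names `AA_TYPES`.
#' @return object of class `probability_volume` (kind `"grid"`).
#' @export
probability_volume <- function(origin, spacing, channels) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(origin) == 3, length(spacing) == 3,
            all(spacing > 0), is.list(channels))
  if (!setequal(names(channels), AA_TYPES)) {
    stop("channels must be named by the 20 canonical one-letter codes",
         call. = FALSE)
  }
  channels <- channels[AA_TYPES]
  dims <- dim(channels[[1]])
  if (length(dims) != 3 || any(dims < 1)) {
    stop("each channel must be a 3D array", call. = FALSE)
  }
  for (ch in channels) {
    if (!identical(dim(ch), dims)) {
      stop("all 20 channels must share dims", call. = FALSE)
    }
  }
  structure(list(kind = "grid", origin = as.numeric(origin),
                 spacing = as.numeric(spacing), dims = as.integer(dims),
                 channels = channels),
            class = "probability_volume")
}

#' Construct a per-residue probability table
#'
#' A degenerate "volume" answering lookups by residue key only.
#'
#' @param keys residue keys.
#' @param probs matrix `length(keys)` x 20, columns named by `AA_TYPES`.
#' @return object of class `probability_volume` (kind `"table"`).
#' @export
probability_table <- function(keys, probs) {
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == length(keys), ncol(probs) == 20)
  if (!setequal(colnames(probs), AA_TYPES)) {
    stop("probability table needs the 20 one-letter codes as columns",
         call. = FALSE)
  }
  probs <- probs[, AA_TYPES, drop = FALSE]
  rownames(probs) <- keys
  structure(list(kind = "table", keys = as.character(keys), probs = probs),
            class = "probability_volume")
}

#' @export
print.probability_volume <- function(x, ...) {
  if (x$kind == "grid") {
    cat(sprintf("probability_volume: grid %d x %d x %d, spacing %.3g A, origin (%.3g, %.3g, %.3g)\n",
                x$dims[1], x$dims[2], x$dims[3], x$spacing[1],
                x$origin[1], x$origin[2], x$origin[3]))
  } else {
    cat(sprintf("probability_volume: per-residue table, %d residues\n",
                length(x$keys)))
  }
  invisible(x)
}

#' Validate the per-voxel channel-sum invariant
#'
#' Channel values must be non-negative and sum to 1 at every voxel.
#'
#' @param vol a `probability_volume`.
#' @param tol_reject worst-voxel deviation that triggers rejection.
#' @param tol_warn deviation that triggers a warning.
#' @return `vol`, invisibly.
#' @export
validate_volume <- function(vol, tol_reject = 1e-3, tol_warn = 1e-6) {
  if (vol$kind == "table") {
    s <- rowSums(vol$probs)
    if (any(vol$probs < 0)) stop("negative probabilities in table", call. = FALSE)
    worst <- which.max(abs(s - 1))
    if (abs(s[worst] - 1) > tol_reject) {
      stop(sprintf("probability rows must sum to 1: row '%s' sums to %.6g",
                   vol$keys[worst], s[worst]), call. = FALSE)
    }
    return(invisible(vol))
  }
  s <- Reduce(`+`, vol$channels)
  for (ch in vol$channels) {
    if (any(ch < 0)) stop("negative probabilities in volume", call. = FALSE)
  }
  dev <- abs(s - 1)
  worst <- arrayInd(which.max(dev), vol$dims)
  wdev <- max(dev)
  if (wdev > tol_reject) {
    stop(sprintf(
      "per-voxel channel sums must be 1: worst voxel (%d, %d, %d) sums to %.6g",
      worst[1] - 1L, worst[2] - 1L, worst[3] - 1L, s[which.max(dev)]),
      call. = FALSE)
  }
  if (wdev > tol_warn) {
    warning(sprintf("channel sums deviate from 1 by up to %.3g", wdev),
            call. = FALSE)
  }
  invisible(vol)
}

## ---- MRC 2014 I/O (single-channel, mode 2 float32) ----

#' Read a single-channel MRC volume
#' @param path MRC file.
#' @return list with `data` (3D array, x fastest), `origin`, `spacing`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readBin(con, "integer", n = 10, size = 4)
  nx <- h[1]; ny <- h[2]; nz <- h[3]; mode <- h[4]
  cella <- readBin(con, "numeric", n = 3, size = 4)
  readBin(con, "numeric", n = 3, size = 4)          # cell angles
  maps <- readBin(con, "integer", n = 3, size = 4)  # mapc, mapr, maps
  readBin(con, "numeric", n = 3, size = 4)          # dmin dmax dmean
  readBin(con, "integer", n = 2, size = 4)          # ispg nsymbt
  readBin(con, "integer", n = 25, size = 4)         # extra
  origin <- readBin(con, "numeric", n = 3, size = 4)
  map_id <- rawToChar(readBin(con, "raw", n = 4))
  readBin(con, "raw", n = 1024 - 53 * 4)            # rest of header
  if (!identical(maps, 1:3)) {
    stop("unsupported MRC axis order in ", path, call. = FALSE)
  }
  if (mode != 2) stop("only mode-2 (float32) MRC supported: ", path, call. = FALSE)
  mx <- h[8]; my <- h[9]; mz <- h[10]
  spacing <- c(cella[1] / mx, cella[2] / my, cella[3] / mz)
  data <- readBin(con, "numeric", n = nx * ny * nz, size = 4)
  if (length(data) != nx * ny * nz) {
    stop("truncated MRC data in ", path, call. = FALSE)
  }
  list(data = array(data, dim = c(nx, ny, nz)), origin = origin,
       spacing = spacing, map_id = map_id)
}

#' Write a single-channel MRC volume (mode 2)
#' @param data 3D array (x fastest).
#' @param origin grid origin in Angstrom.
#' @param spacing Angstrom per voxel (scalar or length 3).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(data, origin, spacing, path) {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  d <- dim(data)
  stopifnot(length(d) == 3)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4)
  writeBin(as.numeric(c(d * spacing, 90, 90, 90)), con, size = 4)
  writeBin(1:3, con, size = 4)
  writeBin(c(min(data), max(data), mean(data)), con, size = 4)
  writeBin(c(1L, 0L), con, size = 4)
  writeBin(integer(25), con, size = 4)
  writeBin(as.numeric(origin), con, size = 4)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  writeBin(as.numeric(stats::sd(data)), con, size = 4)
  writeBin(0L, con, size = 4)
  writeBin(raw(800), con)
  writeBin(as.numeric(data), con, size = 4)
  invisible(path)
}

#' Load a probability volume
#'
#' Accepts a JSON manifest pointing at 20 single-channel MRC files (one per
#' amino-acid type, shared grid geometry), or a TSV per-residue probability
#' table (`key` column plus 20 amino-acid columns). Grid voxels are
#' renormalized to sum exactly 1 after validation (float32 storage
#' quantizes).
#'
#' @param path manifest `.json` or table `.tsv`.
#' @return a validated `probability_volume`.
#' @export
load_probability_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    if (!"key" %in% names(tab) || !all(AA_TYPES %in% names(tab))) {
      stop("probability table needs a 'key' column and the 20 one-letter codes",
           call. = FALSE)
    }
    probs <- apply(as.matrix(tab[, AA_TYPES]), 2, as.numeric)
    probs <- matrix(probs, ncol = 20, dimnames = list(NULL, AA_TYPES))
    vol <- probability_table(tab$key, probs)
    validate_volume(vol)
    return(vol)
  }
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(man$channels) || !setequal(names(man$channels), AA_TYPES)) {
    stop("manifest must list 20 channel files named by one-letter code",
         call. = FALSE)
  }
  dir <- dirname(path)
  first <- NULL
  channels <- vector("list", 20)
  names(channels) <- AA_TYPES
  for (aa in AA_TYPES) {
    f <- man$channels[[aa]]
    if (!file.exists(f)) f <- file.path(dir, man$channels[[aa]])
    m <- read_mrc(f)
    if (is.null(first)) {
      first <- m
    } else if (!identical(dim(m$data), dim(first$data)) ||
               max(abs(m$origin - first$origin)) > 1e-4 ||
               max(abs(m$spacing - first$spacing)) > 1e-6) {
      stop(sprintf("channel '%s' header disagrees with channel '%s'",
                   aa, AA_TYPES[1]), call. = FALSE)
    }
    channels[[aa]] <- m$data
  }
  vol <- probability_volume(first$origin, first$spacing, channels)
  validate_volume(vol, tol_warn = Inf)
  s <- Reduce(`+`, vol$channels)
  vol$channels <- lapply(vol$channels, function(ch) ch / s)
  vol
}

#' Write a probability volume
#'
#' Grid volumes become 20 MRC files plus `manifest.json` in `dir`; table
#' volumes become a single TSV.
#'
#' @param vol a `probability_volume`.
#' @param dir output directory for grids (created if needed), or the `.tsv`
#'   path for tables.
#' @return path of the manifest or TSV, invisibly.
#' @export
write_probability_volume <- function(vol, dir) {
  if (vol$kind == "table") {
    tab <- data.frame(key = vol$keys, vol$probs, check.names = FALSE)
    utils::write.table(format(tab, digits = 17), dir, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    return(invisible(dir))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- setNames(sprintf("%s.mrc", AA_TYPES), AA_TYPES)
  for (aa in AA_TYPES) {
    write_mrc(vol$channels[[aa]], vol$origin, vol$spacing,
              file.path(dir, files[[aa]]))
  }
  man <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(spacing = vol$spacing, dims = vol$dims,
                            origin = vol$origin, channels = as.list(files)),
                       man, auto_unbox = TRUE, digits = NA)
  invisible(man)
}

## ---- lookups ----

#' Interpolated amino-acid probability at a point
#'
#' Trilinear interpolation of one channel; points outside the grid, or
#' values that interpolate below the probability floor, return the floor.
#' The number of floored lookups is attached as attribute `"n_floored"`.
#'
#' @param vol a grid `probability_volume`.
#' @param point numeric length 3, or an n x 3 matrix of points (Angstrom).
#' @param aa one-letter amino-acid type (single).
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param floor minimum probability returned (keeps the log-score finite).
#' @return numeric vector of probabilities.
#' @export
probability_at <- function(vol, point, aa,
                           interpolation = c("trilinear", "nearest"),
                           floor = 1e-6) {
  interpolation <- match.arg(interpolation)
  assert_aa(aa)
  if (vol$kind != "grid") {
    stop("probability_at needs a grid volume; use residue-key lookup for tables",
         call. = FALSE)
  }
  p <- matrix(as.numeric(point), ncol = 3)
  f <- sweep(sweep(p, 2, vol$origin, "-"), 2, vol$spacing, "/")
  ch <- vol$channels[[aa]]
  n <- nrow(p)
  out <- rep(NA_real_, n)
  if (interpolation == "nearest") {
    i <- round(f)
    inside <- i[, 1] >= 0 & i[, 1] <= vol$dims[1] - 1 &
      i[, 2] >= 0 & i[, 2] <= vol$dims[2] - 1 &
      i[, 3] >= 0 & i[, 3] <= vol$dims[3] - 1
    idx <- i[inside, , drop = FALSE] + 1
    out[inside] <- ch[cbind(idx[, 1], idx[, 2], idx[, 3])]
  } else {
    inside <- f[, 1] >= 0 & f[, 1] <= vol$dims[1] - 1 &
      f[, 2] >= 0 & f[, 2] <= vol$dims[2] - 1 &
      f[, 3] >= 0 & f[, 3] <= vol$dims[3] - 1
    i0 <- floor(f)
    # upper boundary points fall in the last cell
    i0 <- sweep(i0, 2, vol$dims - 2, pmin)
    if (any(inside)) {
      ii <- i0[inside, , drop = FALSE]
      tt <- f[inside, , drop = FALSE] - ii
      acc <- numeric(sum(inside))
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        w <- (if (dx) tt[, 1] else 1 - tt[, 1]) *
          (if (dy) tt[, 2] else 1 - tt[, 2]) *
          (if (dz) tt[, 3] else 1 - tt[, 3])
        acc <- acc + w * ch[cbind(ii[, 1] + dx + 1, ii[, 2] + dy + 1,
                                  ii[, 3] + dz + 1)]
      }
      out[inside] <- acc
    }
  }
  floored <- !is.finite(out) | out < floor
  out[floored] <- floor
  attr(out, "n_floored") <- sum(floored)
  out
}
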