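# Canonical amino-acid bookkeeping shared across the package.

#' The 20 canonical amino acids (one-letter codes)
#'
#' Channel order used by every probability volume in the package.
#' @export
AA_TYPES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

AA_ONE <- setNames(names(AA_THREE), AA_THREE)

# Fixed involution pairing each amino acid with the side chain a density-based
# classifier most readily mistakes it for (similar size/shape in 3-4 A maps).
AA_CONFUSION <- c(A = "G", G = "A", V = "I", I = "V", L = "M", M = "L",
                  F = "Y", Y = "F", D = "N", N = "D", E = "Q", Q = "E",
                  K = "R", R = "K", S = "T", T = "S", H = "W", W = "H",
                  C = "P", P = "C")

#' Convert three-letter residue names to one-letter codes
#'
#' @param x character vector of three-letter residue names (e.g. "ALA").
#' @param mapping optional named character vector mapping non-canonical
#'   residue names to canonical three-letter names (e.g. `c(MSE = "MET")`).
#' @return one-letter codes; non-canonical residues without a mapping raise
#'   an error naming the offenders.
#' @export
aa321 <- function(x, mapping = NULL) {
  x <- toupper(x)
  if (!is.null(mapping)) {
    hit <- x %in% names(mapping)
    x[hit] <- unname(mapping[x[hit]])
  }
  bad <- setdiff(unique(x), names(AA_ONE))
  if (length(bad) > 0) {
    stop("non-canonical residue type(s) without a configured mapping: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(AA_ONE[x])
}

#' Convert one-letter codes to three-letter residue names
#' @param x character vector of one-letter codes.
#' @return three-letter names.
#' @export
aa123 <- function(x) {
  x <- toupper(x)
  bad <- setdiff(unique(x), AA_TYPES)
  if (length(bad) > 0) {
    stop("unknown one-letter amino-acid code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(AA_THREE[x])
}

assert_aa <- function(aa) {
  if (!all(aa %in% AA_TYPES)) {
    stop("amino-acid type must be one of the 20 canonical one-letter codes",
         call. = FALSE)
  }
  invisible(aa)
}
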