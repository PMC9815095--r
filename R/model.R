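# Protein model container and PDB/mmCIF I/O.
#
# A protein_model holds one chain: an ordered residue table (author numbering
# plus insertion code, one-letter type, Calpha coordinate) and a full atom
# table. Calpha-only models are valid everywhere in the package.

#' Construct a protein model from residue-level data
#'
#' @param chain_id single chain identifier.
#' @param number integer vector of author residue numbers.
#' @param aa one-letter amino-acid types (length of `number`).
#' @param ca n x 3 matrix of Calpha coordinates in Angstrom (rows may be NA
#'   for residues without a Calpha).
#' @param ins insertion codes, default empty.
#' @param atoms optional atom table (`number`, `ins`, `aa`, `atom`, `x`,
#'   `y`, `z`, `occ`); when omitted a Calpha-only table is derived.
#' @param source_path provenance string.
#' @return an object of class `protein_model`.
#' @export
protein_model <- function(chain_id, number, aa, ca, ins = NULL,
                          atoms = NULL, source_path = "<memory>") {
  n <- length(number)
  if (is.null(ins)) ins <- rep("", n)
  aa <- toupper(aa)
  assert_aa(aa)
  ca <- matrix(as.numeric(ca), ncol = 3)
  stopifnot(nrow(ca) == n, length(aa) == n, length(ins) == n)
  key <- residue_key(number, ins)
  if (anyDuplicated(key)) stop("duplicate residue keys in model", call. = FALSE)
  if (any(diff(number) < 0)) {
    stop("residue numbers must be non-decreasing along the chain", call. = FALSE)
  }
  residues <- data.frame(key = key, number = as.integer(number), ins = ins,
                         aa = aa, x = ca[, 1], y = ca[, 2], z = ca[, 3],
                         stringsAsFactors = FALSE)
  if (is.null(atoms)) {
    has_ca <- !is.na(residues$x)
    atoms <- data.frame(number = residues$number[has_ca],
                        ins = residues$ins[has_ca],
                        aa = residues$aa[has_ca],
                        atom = "CA",
                        x = residues$x[has_ca], y = residues$y[has_ca],
                        z = residues$z[has_ca], occ = 1,
                        stringsAsFactors = FALSE)
  }
  structure(list(chain_id = chain_id, residues = residues, atoms = atoms,
                 source_path = source_path),
            class = "protein_model")
}

residue_key <- function(number, ins) {
  ifelse(is.na(ins) | ins == "", as.character(number),
         paste0(number, ins))
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("protein_model: chain %s, %d residues (%d with Calpha), %d atoms\n",
              x$chain_id, nrow(x$residues), sum(!is.na(x$residues$x)),
              nrow(x$atoms)))
  invisible(x)
}

#' Residue keys of a model
#' @param model a `protein_model`.
#' @return character vector (author number + insertion code).
#' @export
residue_keys <- function(model) model$residues$key

#' Calpha coordinate matrix of a model
#' @param model a `protein_model`.
#' @return matrix with one row per residue holding a Calpha (rownames are
#'   residue keys).
#' @export
ca_matrix <- function(model) {
  r <- model$residues[!is.na(model$residues$x), , drop = FALSE]
  m <- as.matrix(r[, c("x", "y", "z")])
  rownames(m) <- r$key
  m
}

#' One-letter sequence of a model
#' @param model a `protein_model`.
#' @return character vector of one-letter codes in residue order.
#' @export
model_sequence <- function(model) model$residues$aa

#' Keep a subset of residues
#'
#' Membership-only operation: coordinates, numbering and atom records of the
#' kept residues are untouched.
#'
#' @param model a `protein_model`.
#' @param keys residue keys to keep.
#' @return a `protein_model` holding exactly the kept residues, in order.
#' @export
subset_model <- function(model, keys) {
  keep <- model$residues$key %in% keys
  res <- model$residues[keep, , drop = FALSE]
  akey <- residue_key(model$atoms$number, model$atoms$ins)
  atoms <- model$atoms[akey %in% keys, , drop = FALSE]
  out <- model
  out$residues <- res
  out$atoms <- atoms
  rownames(out$residues) <- NULL
  rownames(out$atoms) <- NULL
  out
}

#' Load one chain of a PDB or mmCIF file
#'
#' Waters and heteroatoms are excluded; alternate locations are resolved to
#' the highest occupancy, ties to the first listed; insertion codes are part
#' of the residue key.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`, `.mmcif`) file.
#' @param chain chain identifier to extract.
#' @param mapping optional named vector mapping non-canonical residue names
#'   to canonical three-letter names, e.g. `c(MSE = "MET")`.
#' @return a `protein_model`.
#' @export
load_model <- function(path, chain, mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(sub(".*\\.", "", path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    # bio3d chatters about its cif reader and secondary-structure records;
    # only the atom table is used here
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE))
  } else {
    bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  chains <- unique(at$chain)
  if (!chain %in% chains) {
    stop(sprintf("chain '%s' not present in %s; available chains: %s",
                 chain, path, paste(chains, collapse = ", ")), call. = FALSE)
  }
  at <- at[at$chain == chain, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # altloc: per (residue, atom name) keep highest occupancy, then first listed
  id <- paste(at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(match(id, unique(id)), -at$o, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$insert, at$elety, sep = "\r")), ,
           drop = FALSE]
  at <- at[order(match(paste(at$resno, at$insert, sep = "\r"),
                       unique(paste(at$resno, at$insert, sep = "\r")))), ,
           drop = FALSE]

  rid <- paste(at$resno, at$insert, sep = "\r")
  first <- !duplicated(rid)
  number <- at$resno[first]
  ins <- at$insert[first]
  aa <- aa321(at$resid[first], mapping = mapping)

  ca <- matrix(NA_real_, nrow = sum(first), ncol = 3)
  is_ca <- at$elety == "CA"
  idx <- match(rid[is_ca], rid[first])
  ca[idx, ] <- as.matrix(at[is_ca, c("x", "y", "z")])

  atoms <- data.frame(number = at$resno, ins = at$insert,
                      aa = aa[match(rid, rid[first])],
                      atom = at$elety, x = at$x, y = at$y, z = at$z,
                      occ = at$o, stringsAsFactors = FALSE)
  protein_model(chain_id = chain, number = number, aa = aa, ca = ca,
                ins = ins, atoms = atoms, source_path = path)
}

#' Write a model as PDB
#'
#' Author numbering, insertion codes and coordinates are preserved exactly
#' (to the 3-decimal precision of the PDB format).
#'
#' @param model a `protein_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  a <- model$atoms
  ins <- ifelse(a$ins == "", " ", a$ins)
  name4 <- ifelse(nchar(a$atom) < 4, sprintf(" %-3s", a$atom),
                  sprintf("%-4s", a$atom))
  lines <- sprintf(
    "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(nrow(a)), name4, aa123(a$aa), model$chain_id, a$number, ins,
    a$x, a$y, a$z, a$occ, 0)
  ok <- tryCatch({
    writeLines(c(lines, "TER", "END"), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write PDB to ", path, call. = FALSE)
  invisible(path)
}
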