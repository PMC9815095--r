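# Fixture builders shared across the suite. Everything is generated in code;
# no binary files are shipped.

# hand-written 3-residue PDB (Gly-Ala-Ser with Calpha + one extra atom)
tiny_pdb_text <- function() {
  c("ATOM      1  N   GLY A  10      1.000   2.000   3.000  1.00  0.00",
    "ATOM      2  CA  GLY A  10      2.500   2.000   3.000  1.00  0.00",
    "ATOM      3  CA  ALA A  11      5.000   2.500   3.500  1.00  0.00",
    "ATOM      4  CA  SER A  13      8.000   3.000   4.000  1.00  0.00",
    "TER", "END")
}

# the same content in mmCIF dialect
tiny_cif_text <- function() {
  c("data_tiny",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N   . GLY A 1 1 ? 1.000 2.000 3.000 1.00 0.00 ? 10 GLY A N   1",
    "ATOM 2 C CA  . GLY A 1 1 ? 2.500 2.000 3.000 1.00 0.00 ? 10 GLY A CA  1",
    "ATOM 3 C CA  . ALA A 1 2 ? 5.000 2.500 3.500 1.00 0.00 ? 11 ALA A CA  1",
    "ATOM 4 C CA  . SER A 1 3 ? 8.000 3.000 4.000 1.00 0.00 ? 13 SER A CA  1")
}

write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# uniform 20-channel volume covering a model with padding
uniform_volume <- function(model, pad = 5, spacing = 1) {
  ca <- ca_matrix(model)
  origin <- floor(apply(ca, 2, min) - pad)
  dims <- ceiling(apply(ca, 2, max) + pad - origin) + 1
  channels <- lapply(AA_TYPES, function(a) array(1 / 20, dim = dims))
  names(channels) <- AA_TYPES
  probability_volume(origin, spacing, channels)
}

# per-residue probability table with given own-type probabilities; the
# remaining mass is spread over the other 19 types
table_volume <- function(keys, aa, own_prob) {
  probs <- matrix((1 - own_prob) / 19, nrow = length(keys), ncol = 20,
                  dimnames = list(NULL, AA_TYPES))
  probs[cbind(seq_along(keys), match(aa, AA_TYPES))] <- own_prob
  probability_table(keys, probs)
}

# random proper rotation (QR-based) + translation
random_rigid <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 5))
}

# brute-force rotation-grid r.m.s.d. oracle (centred, Euler-angle grid)
grid_rmsd <- function(x, y, step_deg = 15) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  ang <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  bng <- seq(0, 180, by = step_deg) * pi / 180
  best <- Inf
  for (a in ang) {
    ca_ <- cos(a); sa <- sin(a)
    rz1 <- matrix(c(ca_, sa, 0, -sa, ca_, 0, 0, 0, 1), 3)
    for (b in bng) {
      cb <- cos(b); sb <- sin(b)
      ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3)
      for (g in ang) {
        cg <- cos(g); sg <- sin(g)
        rz2 <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3)
        d <- xc %*% (rz1 %*% ry %*% rz2) - yc
        best <- min(best, mean(rowSums(d * d)))
      }
    }
  }
  sqrt(best)
}
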