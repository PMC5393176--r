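# Independent oracles and small fixture builders used across tests.

# Horn's quaternion method for optimal-superposition RMSD; fully
# independent of the SVD/Kabsch code path it checks.
quaternion_rmsd <- function(moving, fixed) {
  n <- nrow(moving)
  P <- sweep(moving, 2, colMeans(moving))
  Q <- sweep(fixed, 2, colMeans(fixed))
  M <- t(P) %*% Q
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lambda) / n
  sqrt(max(0, msd))
}

# exhaustive-offset aligner: the brute-force oracle for constant
# renumbering recovery in map_residues(alignment)
brute_force_offset_map <- function(model_resno, ref_resno, model_seq, ref_seq) {
  best <- NULL; best_n <- -1
  for (off in seq(-max(model_resno), max(ref_resno))) {
    shifted <- model_resno + off
    idx <- match(shifted, ref_resno)
    ok <- !is.na(idx) & model_seq == ref_seq[ifelse(is.na(idx), 1, idx)]
    if (sum(ok) > best_n) {
      best_n <- sum(ok)
      best <- data.frame(model = which(ok), ref = idx[ok])
    }
  }
  best
}

# a tiny hand-written PDB text (1 chain, 1 residue, 3 atoms)
tiny_pdb_lines <- function() {
  c(
    "ATOM      1  P     G A   1       1.000   2.000   3.000  1.00 20.00           P",
    "ATOM      2  C1'   G A   1       2.500   2.000   3.000  1.00 30.00           C",
    "ATOM      3  N9    G A   1       3.400   3.100   3.000  1.00 40.00           N",
    "END")
}

tiny_cif_lines <- function() {
  c("data_tiny",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.auth_atom_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.type_symbol",
    "ATOM 1 P G A 1 ? 1.000 2.000 3.000 1.00 20.00 P",
    "ATOM 2 \"C1'\" G A 1 ? 2.500 2.000 3.000 1.00 30.00 C",
    "ATOM 3 N9 G A 1 ? 3.400 3.100 3.000 1.00 40.00 N",
    "#")
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
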