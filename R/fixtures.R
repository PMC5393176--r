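# Synthetic structure generator ---------------------------------------------
#
# Idealized A-form duplexes with known ground truth, plus controlled
# degradations (coordinate noise, hinge rotation, uniform torsion shifts).
# The per-nucleotide templates in R/aform-data.R were derived once from
# idealized nucleotide geometry, constrained to the helical parameters
# below and to Watson-Crick hydrogen-bond geometry; the generator only
# applies exact helical symmetry to them, so the constructed pair and
# stack lists are ground truth by construction.

COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

# rotation about arbitrary unit axis (Rodrigues)
rot_axis <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  t <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(t) * K + (1 - cos(t)) * K %*% K
}

element_of <- function(name) {
  toupper(substr(sub("^[0-9]+", "", name), 1, 1))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

template_atoms <- function(tmpl, chain, resno, resname, drop_phosphate = FALSE,
                           b = 30) {
  nm <- rownames(tmpl)
  if (drop_phosphate) {
    keep <- !(nm %in% c("P", "OP1", "OP2"))
    tmpl <- tmpl[keep, , drop = FALSE]
    nm <- nm[keep]
  }
  data.frame(chain = chain, resno = resno, icode = "", resname = resname,
             name = nm, element = element_of(nm),
             x = tmpl[, 1], y = tmpl[, 2], z = tmpl[, 3],
             occ = 1, b = b, het = FALSE, stringsAsFactors = FALSE)
}

#' Build an idealized A-form RNA duplex
#'
#' Strand A carries `sequence` 5' to 3'; strand B is its reverse
#' complement. Nucleotides are placed from the embedded idealized
#' templates by exact helical symmetry (twist 32.7 degrees and rise
#' 2.81 Angstrom per step), so position i of strand A pairs position
#' n+1-i of strand B and all pairs are canonical cis Watson-Crick.
#' 5'-terminal phosphates are omitted.
#'
#' @param sequence character string over A, C, G, U; length >= 2.
#' @param seed integer; recorded for provenance (the construction itself
#'   is deterministic).
#' @return list with `structure` (an `rna_structure`), and `ground_truth`:
#'   `wc_pairs` / `stack_pairs` (data.frames `i`, `j` of residue keys),
#'   `torsions_used` (canonical torsion tuple of the template),
#'   `helical` (twist/rise).
#' @export
build_duplex <- function(sequence, seed = 1L) {
  seq1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(seq1) < 2) stop("build_duplex: sequence length must be >= 2")
  if (!all(seq1 %in% names(COMPLEMENT))) {
    stop("build_duplex: sequence must be over A, C, G, U")
  }
  n <- length(seq1)
  rows <- list()
  for (i in seq_len(n)) {  # strand A, helix index i-1
    R <- rot_z(AFORM_TWIST * (i - 1))
    tm <- AFORM_TEMPLATE_S1[[seq1[i]]] %*% t(R)
    tm <- sweep(tm, 2, c(0, 0, AFORM_RISE * (i - 1)), "+")
    rownames(tm) <- rownames(AFORM_TEMPLATE_S1[[seq1[i]]])
    rows[[i]] <- template_atoms(tm, "A", i, seq1[i], drop_phosphate = i == 1)
  }
  # strand B: partner of strand A position i sits at helix index i-1;
  # 5'->3' order of strand B runs from position n down to 1
  seq2 <- unname(COMPLEMENT[rev(seq1)])  # strand B 5'->3'
  for (j in seq_len(n)) {
    i <- n + 1 - j                      # paired strand A position
    R <- rot_z(AFORM_TWIST * (i - 1))
    tm <- AFORM_TEMPLATE_S2[[seq2[j]]] %*% t(R)
    tm <- sweep(tm, 2, c(0, 0, AFORM_RISE * (i - 1)), "+")
    rownames(tm) <- rownames(AFORM_TEMPLATE_S2[[seq2[j]]])
    rows[[n + j]] <- template_atoms(tm, "B", j, seq2[j], drop_phosphate = j == 1)
  }
  s <- rna_structure(do.call(rbind, rows), id = sprintf("duplex_%s", sequence),
                     source_format = "synthetic")
  keyA <- function(i) res_key("A", i, "")
  keyB <- function(j) res_key("B", j, "")
  wc <- data.frame(i = keyA(seq_len(n)), j = keyB(n + 1 - seq_len(n)),
                   stringsAsFactors = FALSE)
  stacks <- rbind(
    data.frame(i = keyA(seq_len(n - 1)), j = keyA(2:n), stringsAsFactors = FALSE),
    data.frame(i = keyB(seq_len(n - 1)), j = keyB(2:n), stringsAsFactors = FALSE))
  list(structure = s,
       ground_truth = list(wc_pairs = wc, stack_pairs = stacks,
                           torsions_used = AFORM_TORSION_SET,
                           helical = c(twist = AFORM_TWIST, rise = AFORM_RISE),
                           seed = seed))
}

#' Add Gaussian coordinate noise
#'
#' i.i.d. zero-mean Gaussian displacement with standard deviation `sigma`
#' on every coordinate of every atom; deterministic for a fixed seed.
#'
#' @param structure an `rna_structure`.
#' @param sigma standard deviation in Angstrom (>= 0).
#' @param seed integer seed.
#' @return perturbed `rna_structure`.
#' @export
perturb_noise <- function(structure, sigma, seed = 1L) {
  if (sigma < 0) stop("perturb_noise: sigma must be >= 0")
  if (sigma == 0) return(structure)
  n <- nrow(structure$atoms)
  noise <- with_seed(seed, matrix(stats::rnorm(3 * n, 0, sigma), n, 3))
  structure$atoms$x <- structure$atoms$x + noise[, 1]
  structure$atoms$y <- structure$atoms$y + noise[, 2]
  structure$atoms$z <- structure$atoms$z + noise[, 3]
  structure
}

#' Hinge-rotate the tail of a structure
#'
#' All residues strictly after the pivot (file order) are rigidly rotated
#' by `angle` about an axis through the pivot's P atom. Creates a
#' two-domain structure whose intra-domain geometry is untouched -- the
#' regime where global RMSD is poor although both domains are locally
#' accurate.
#'
#' @param structure an `rna_structure`.
#' @param pivot residue key of the hinge point; must be interior to its
#'   chain.
#' @param angle degrees in (-180, 180].
#' @param axis rotation axis (length-3), default x.
#' @param seed unused; kept for interface symmetry with the other perturbations.
#' @return list with `structure` and `domain_split` (two residue-key
#'   vectors).
#' @export
perturb_hinge <- function(structure, pivot, angle, axis = c(1, 0, 0),
                          seed = 1L) {
  ri <- residue_table(structure)
  pos <- match(pivot, ri$key)
  if (is.na(pos)) stop("perturb_hinge: pivot residue not found: ", pivot)
  ch <- ri$chain[pos]
  in_chain <- which(ri$chain == ch)
  if (pos == min(in_chain) || pos == max(in_chain)) {
    stop("perturb_hinge: pivot must be interior to its chain")
  }
  piv_atoms <- residue_atoms(structure, pivot)
  p_row <- which(piv_atoms$name == "P")
  if (length(p_row) == 0) p_row <- 1
  center <- c(piv_atoms$x[p_row[1]], piv_atoms$y[p_row[1]], piv_atoms$z[p_row[1]])
  R <- rot_axis(axis, angle)
  tail_keys <- ri$key[(pos + 1):nrow(ri)]
  sel <- structure$atoms$key %in% tail_keys
  xyz <- coord_matrix(structure$atoms[sel, , drop = FALSE])
  xyz <- sweep(sweep(xyz, 2, center) %*% t(R), 2, center, "+")
  structure$atoms$x[sel] <- xyz[, 1]
  structure$atoms$y[sel] <- xyz[, 2]
  structure$atoms$z[sel] <- xyz[, 3]
  list(structure = structure,
       domain_split = list(head = ri$key[seq_len(pos)], tail = tail_keys))
}

# NeRF atom placement: |CD| = r, angle(B,C,D) = theta, dihedral(A,B,C,D) = tau
nerf_place <- function(a, b, c, r, theta, tau) {
  th <- theta * pi / 180; ta <- tau * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- c((b - a)[2] * bc[3] - (b - a)[3] * bc[2],
         (b - a)[3] * bc[1] - (b - a)[1] * bc[3],
         (b - a)[1] * bc[2] - (b - a)[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- r * c(-cos(th), sin(th) * cos(ta), sin(th) * sin(ta))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

ang3 <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
}

#' Uniform torsion-shift rebuild
#'
#' Rebuilds each chain by sequential atom placement, adding `shift`
#' degrees to every defined backbone torsion (alpha..zeta) and to chi
#' (base rotation about the glycosidic bond). Bond lengths, bond angles,
#' sugar-ring and base internal geometry are preserved exactly, so the
#' torsion profile of the result differs from the input by `shift` in
#' every defined slot.
#'
#' @param structure an `rna_structure` of standard nucleotides.
#' @param shift degrees.
#' @param seed unused; kept for interface symmetry with the other perturbations.
#' @return rebuilt `rna_structure`.
#' @export
perturb_torsions <- function(structure, shift, seed = 1L) {
  if (shift == 0) return(structure)
  at <- structure$atoms
  ri <- residue_table(structure)
  get_xyz <- function(key, name) {
    r <- which(at$key == key & at$name == name)
    if (length(r) == 0) return(NULL)
    c(at$x[r[1]], at$y[r[1]], at$z[r[1]])
  }
  set_xyz <- function(key, name, v) {
    r <- which(at$key == key & at$name == name)
    at$x[r[1]] <<- v[1]; at$y[r[1]] <<- v[2]; at$z[r[1]] <<- v[3]
  }
  orig <- at  # all internal coordinates measured from the original
  oxyz <- function(key, name) {
    r <- which(orig$key == key & orig$name == name)
    if (length(r) == 0) return(NULL)
    c(orig$x[r[1]], orig$y[r[1]], orig$z[r[1]])
  }
  dih <- function(p1, p2, p3, p4) dihedral_angle(rbind(p1, p2, p3, p4))
  for (ch in unique(ri$chain)) {
    keys <- ri$key[ri$chain == ch & ri$is_nt]
    if (length(keys) == 0) next
    for (q in seq_along(keys)) {
      k <- keys[q]
      prev <- if (q > 1) keys[q - 1] else NULL
      # original local geometry
      oC5 <- oxyz(k, "C5'"); oC4 <- oxyz(k, "C4'"); oC3 <- oxyz(k, "C3'")
      oO5 <- oxyz(k, "O5'"); oO3 <- oxyz(k, "O3'"); oP <- oxyz(k, "P")
      if (is.null(oC5) || is.null(oC4) || is.null(oC3)) next
      if (q == 1) {
        # anchor: keep O5', C5', C4'; rebuild C3' with shifted gamma
        nO5 <- get_xyz(k, "O5'"); nC5 <- get_xyz(k, "C5'"); nC4 <- get_xyz(k, "C4'")
        gamma <- dih(oO5, oC5, oC4, oC3)
        nC3 <- nerf_place(nO5, nC5, nC4, sqrt(sum((oC3 - oC4)^2)),
                          ang3(oC5, oC4, oC3), gamma + shift)
      } else {
        pC4 <- get_xyz(prev, "C4'"); pC3 <- get_xyz(prev, "C3'")
        pO3 <- get_xyz(prev, "O3'")
        opC4 <- oxyz(prev, "C4'"); opC3 <- oxyz(prev, "C3'"); opO3 <- oxyz(prev, "O3'")
        eps <- dih(opC4, opC3, opO3, oP)
        nP <- nerf_place(pC4, pC3, pO3, sqrt(sum((oP - opO3)^2)),
                         ang3(opC3, opO3, oP), eps + shift)
        zeta <- dih(opC3, opO3, oP, oO5)
        nO5 <- nerf_place(pC3, pO3, nP, sqrt(sum((oO5 - oP)^2)),
                          ang3(opO3, oP, oO5), zeta + shift)
        alpha <- dih(opO3, oP, oO5, oC5)
        nC5 <- nerf_place(pO3, nP, nO5, sqrt(sum((oC5 - oO5)^2)),
                          ang3(oP, oO5, oC5), alpha + shift)
        beta <- dih(oP, oO5, oC5, oC4)
        nC4 <- nerf_place(nP, nO5, nC5, sqrt(sum((oC4 - oC5)^2)),
                          ang3(oO5, oC5, oC4), beta + shift)
        gamma <- dih(oO5, oC5, oC4, oC3)
        nC3 <- nerf_place(nO5, nC5, nC4, sqrt(sum((oC3 - oC4)^2)),
                          ang3(oC5, oC4, oC3), gamma + shift)
        set_xyz(k, "P", nP); set_xyz(k, "O5'", nO5); set_xyz(k, "C5'", nC5)
        set_xyz(k, "C4'", nC4)
        # OP1/OP2 follow the P-O5' bond (original torsion, unshifted)
        for (opn in c("OP1", "OP2")) {
          oOP <- oxyz(k, opn)
          if (!is.null(oOP)) {
            tau <- dih(oC5, oO5, oP, oOP)
            set_xyz(k, opn, nerf_place(nC5, nO5, nP, sqrt(sum((oOP - oP)^2)),
                                       ang3(oO5, oP, oOP), tau))
          }
        }
      }
      set_xyz(k, "C3'", nC3)
      # rigid sugar (and base) follow via superposition on C5', C4', C3'
      nC5 <- get_xyz(k, "C5'"); nC4 <- get_xyz(k, "C4'")
      sp <- kabsch_superpose(rbind(oC5, oC4, oC3), rbind(nC5, nC4, nC3))
      res_rows <- which(at$key == k)
      done <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'")
      for (r in res_rows) {
        if (at$name[r] %in% done) next
        v <- c(orig$x[r], orig$y[r], orig$z[r])
        v2 <- as.vector(sp$rotation %*% v) + sp$translation
        at$x[r] <- v2[1]; at$y[r] <- v2[2]; at$z[r] <- v2[3]
      }
      # delta: re-place O3' with shifted torsion
      delta <- dih(oC5, oC4, oC3, oO3)
      if (!is.null(oO3)) {
        set_xyz(k, "O3'", nerf_place(nC5, nC4, nC3, sqrt(sum((oO3 - oC3)^2)),
                                     ang3(oC4, oC3, oO3), delta + shift))
      }
      # chi: rotate base atoms about the glycosidic bond by shift
      parent <- ri$parent[match(k, ri$key)]
      n_name <- if (parent %in% c("A", "G")) "N9" else "N1"
      c1 <- get_xyz(k, "C1'"); ng <- get_xyz(k, n_name)
      if (!is.null(c1) && !is.null(ng)) {
        axis <- ng - c1
        Rb <- rot_axis(axis, shift)
        base_names <- c(BASE_ATOMS[[parent]])
        for (r in res_rows) {
          if (!(at$name[r] %in% base_names)) next
          v <- c(at$x[r], at$y[r], at$z[r])
          v2 <- as.vector(Rb %*% (v - c1)) + c1
          at$x[r] <- v2[1]; at$y[r] <- v2[2]; at$z[r] <- v2[3]
        }
      }
    }
  }
  structure$atoms <- at
  structure
}

#' Swap the base of one residue for another parent
#'
#' Replaces the base atoms of `key` with the template base of
#' `new_parent`, positioned by superposing the template sugar onto the
#' residue's sugar (the glycosidic geometry of the template is kept).
#' Useful for engineering wobbles and mismatches into fixture duplexes.
#'
#' @param structure an `rna_structure`.
#' @param key residue key.
#' @param new_parent one of "A", "C", "G", "U".
#' @return modified `rna_structure`.
#' @export
mutate_base <- function(structure, key, new_parent) {
  stopifnot(new_parent %in% c("A", "C", "G", "U"))
  at <- structure$atoms
  res_rows <- which(at$key == key)
  if (length(res_rows) == 0) stop("mutate_base: residue not found: ", key)
  old_parent <- standard_parent(at$resname[res_rows[1]])
  tmpl <- AFORM_TEMPLATE_S1[[new_parent]]
  sugar_names <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  t_idx <- match(sugar_names, rownames(tmpl))
  r_idx <- res_rows[match(sugar_names, at$name[res_rows])]
  if (anyNA(t_idx) || anyNA(r_idx)) stop("mutate_base: incomplete sugar")
  sp <- kabsch_superpose(tmpl[t_idx, , drop = FALSE],
                         cbind(at$x[r_idx], at$y[r_idx], at$z[r_idx]))
  # drop old base atoms, add new ones
  old_base <- BASE_ATOMS[[old_parent]]
  keep <- setdiff(seq_len(nrow(at)), res_rows[at$name[res_rows] %in% old_base])
  new_names <- BASE_ATOMS[[new_parent]]
  bt <- tmpl[match(new_names, rownames(tmpl)), , drop = FALSE]
  bt <- sweep(bt %*% t(sp$rotation), 2, sp$translation, "+")
  proto <- at[res_rows[1], , drop = FALSE]
  add <- do.call(rbind, lapply(seq_along(new_names), function(q) {
    r <- proto
    r$name <- new_names[q]; r$element <- element_of(new_names[q])
    r$x <- bt[q, 1]; r$y <- bt[q, 2]; r$z <- bt[q, 3]
    r
  }))
  out <- rbind(at[keep, , drop = FALSE], add)
  # restore file order: residues in original order, atoms within residue
  ord <- order(match(out$key, unique(at$key)))
  out <- out[ord, , drop = FALSE]
  out$resname[out$key == key] <- new_parent
  structure$atoms <- out
  structure$atoms$key <- res_key(out$chain, out$resno, out$icode)
  structure
}
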