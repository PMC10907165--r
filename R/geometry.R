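# Internal-coordinate backbone building (NeRF placement) used by the
# synthetic structure generators.

# standard backbone geometry (Engh-Huber-style values)
BB_GEOM <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7, a_CA_C_O = 120.8
)

deg2rad <- function(x) x * pi / 180

# place atom D given A-B-C, bond length |C-D|, angle B-C-D and dihedral
# A-B-C-D (degrees); the standard natural-extension reference frame step
nerf_place <- function(A, B, C, bond, angle, dihedral) {
  ang <- deg2rad(angle); dih <- deg2rad(dihedral)
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Build an n-residue poly-alanine backbone (N, CA, C, O per residue) with the
# given phi/psi (scalars or per-residue vectors), omega fixed trans. With
# `with_amide_H` an explicit amide hydrogen is added to every residue (1.0 A
# from N, anti to the preceding carbonyl; the first residue gets the
# periodic image of residue 3's N-H so that a repeating-conformation chain
# is uniformly hydrogenated). Returns a data frame of atoms ready for
# structure_model().
build_backbone <- function(n_res, phi = -139, psi = 135, chain = "A",
                           resid = "ALA", start_resno = 1L,
                           with_amide_H = FALSE) {
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  g <- BB_GEOM
  N <- CA <- C <- O <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_N_CA, 0, 0)
  # first C placed in the xy-plane at the N-CA-C angle
  ang <- deg2rad(g$a_N_CA_C)
  C[1, ] <- CA[1, ] + g$b_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    if (i > 1L) {
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$b_C_N, g$a_CA_C_N, psi[i - 1])
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_N_CA, g$a_C_N_CA, 180)   # omega trans
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                           g$b_CA_C, g$a_N_CA_C, phi[i])
    }
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         g$b_C_O, g$a_CA_C_O, psi[i] + 180)
  }
  per <- function(M, name) data.frame(
    chain = chain, resno = start_resno + seq_len(n_res) - 1L, ins = "",
    resid = resid, elety = name, element = substr(name, 1, 1),
    x = M[, 1], y = M[, 2], z = M[, 3], occ = 1, alt = "",
    stringsAsFactors = FALSE)
  atoms <- rbind(per(N, "N"), per(CA, "CA"), per(C, "C"), per(O, "O"))
  if (with_amide_H) {
    H <- matrix(NA_real_, n_res, 3)
    for (i in 2:n_res) {
      v <- C[i - 1, ] - O[i - 1, ]
      H[i, ] <- N[i, ] + v / sqrt(sum(v^2))
    }
    H[1, ] <- if (n_res >= 3L) N[1, ] + (H[3, ] - N[3, ]) else
      N[1, ] + (H[2, ] - N[2, ])
    atoms <- rbind(atoms, per(H, "H"))
  }
  atoms <- atoms[order(atoms$resno,
                       match(atoms$elety, c("N", "CA", "C", "O", "H"))), ]
  rownames(atoms) <- NULL
  atoms
}

# rotate atom coordinates about an axis through the origin (row-vector conv.)
rotate_atoms <- function(atoms, axis = c("x", "y", "z"), angle_deg) {
  th <- deg2rad(angle_deg)
  cs <- cos(th); sn <- sin(th)
  R <- switch(match.arg(axis),
              x = matrix(c(1, 0, 0, 0, cs, sn, 0, -sn, cs), 3, 3),
              y = matrix(c(cs, 0, -sn, 0, 1, 0, sn, 0, cs), 3, 3),
              z = matrix(c(cs, sn, 0, -sn, cs, 0, 0, 0, 1), 3, 3))
  xyz <- cbind(atoms$x, atoms$y, atoms$z) %*% R
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

translate_atoms <- function(atoms, dx = 0, dy = 0, dz = 0) {
  atoms$x <- atoms$x + dx; atoms$y <- atoms$y + dy; atoms$z <- atoms$z + dz
  atoms
}
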