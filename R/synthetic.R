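# Seeded synthetic-data generators: titrations, motif sequences, and ideal
# structural fixtures. Every generator is deterministic under a fixed seed and
# leaves the caller's RNG stream untouched.

with_isolated_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate an ITC titration
#'
#' Model heats from [itc_injection_heats()] plus independent Gaussian noise.
#' The default protocol reproduces a typical experiment on this system:
#' 20 x 2 uL injections of 1 mM peptide into 200 uL of 100 uM protein at
#' 288 K. The default noise level is 2% of the first model heat.
#'
#' @param Kd,n,dH generating parameters (uM, sites/monomer, kcal/mol).
#' @param protocol an [itc_protocol()].
#' @param noise_sd Gaussian noise SD in ucal; `NULL` (default) uses 2% of the
#'   first injection's model heat magnitude.
#' @param seed integer seed.
#' @return a [titration_series()] in ITC mode whose `truth` field records the
#'   generating parameters, noise and seed.
#' @export
gen_itc_series <- function(Kd, n, dH, protocol = itc_protocol(),
                           noise_sd = NULL, seed = 1) {
  if (!is.null(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0",
                                               call. = FALSE)
  model <- itc_injection_heats(Kd, n, dH, protocol)
  if (is.null(noise_sd)) noise_sd <- 0.02 * abs(model[1])
  heats <- with_isolated_seed(seed, model + stats::rnorm(length(model), 0, noise_sd))
  titration_series("itc", heats = heats, protocol = protocol,
                   truth = list(Kd = Kd, n = n, dH = dH, noise_sd = noise_sd,
                                seed = seed))
}

#' Simulate a fluorescence anisotropy titration
#'
#' Corrected-mode [anisotropy_model()] plus Gaussian noise. The default grid
#' reproduces the assay layout this package targets: 100 nM labeled peptide
#' against a two-fold protein dilution series from 500 down to ~0.5 uM.
#'
#' @param Kd,A0,Amax generating parameters.
#' @param Pt_grid protein totals (uM); default two-fold series 500..0.49.
#' @param Lt labeled peptide total (uM, default 0.1).
#' @param noise_sd anisotropy noise SD (default 0.002).
#' @param seed integer seed.
#' @return a [titration_series()] in anisotropy mode with `truth` metadata.
#' @export
gen_anisotropy_series <- function(Kd, A0 = 0.05, Amax = 0.20,
                                  Pt_grid = 500 / 2^(0:10), Lt = 0.1,
                                  noise_sd = 0.002, seed = 1) {
  Pt_grid <- sort(Pt_grid)
  model <- anisotropy_model(Pt_grid, Lt, A0, Amax, Kd, mode = "corrected")
  A <- with_isolated_seed(seed, model + stats::rnorm(length(model), 0, noise_sd))
  titration_series("anisotropy", Pt = Pt_grid, Lt = Lt, anisotropy = A,
                   truth = list(Kd = Kd, A0 = A0, Amax = Amax, Lt = Lt,
                                noise_sd = noise_sd, mode = "corrected",
                                seed = seed))
}

#' Generate sequences with embedded D-box motifs
#'
#' Random background sequences with `n_motifs` copies of a
#' P-PhiZetaPhiZetaPhiPhiZeta-P block embedded at recorded, non-overlapping
#' positions. Phi positions are sampled from the hydrophobic set, zeta
#' positions from the hydrophilic set (prolines excluded from both). Whole
#' sequences are rejection-sampled until a default [scan_dbox()] recovers
#' exactly the embedded cores -- so the truth table is exact by construction,
#' not just in expectation.
#'
#' @param n number of sequences.
#' @param length residues per sequence (>= 9 * n_motifs + 2).
#' @param n_motifs motifs embedded per sequence.
#' @param background_composition named residue probabilities (default uniform
#'   over the 20 standard residues).
#' @param seed integer seed.
#' @param max_tries rejection-sampling bound per sequence.
#' @return list with `sequences` (list of [annotated_sequence()]) and `truth`
#'   (data frame: seq_id, core_start, core_end, core_seq).
#' @export
gen_motif_sequences <- function(n = 10, length = 60, n_motifs = 1,
                                background_composition = NULL, seed = 1,
                                max_tries = 500) {
  if (length < 9 * n_motifs + 2) {
    stop("length too short for ", n_motifs, " embedded 9-residue motif block(s)",
         call. = FALSE)
  }
  comp <- background_composition
  if (is.null(comp)) comp <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  if (!all(names(comp) %in% AA_STANDARD)) {
    stop("background composition has non-standard residues", call. = FALSE)
  }
  phi <- PHI_SET_DEFAULT
  zeta <- setdiff(AA_STANDARD, c(phi, "P"))
  pattern_cls <- c("F", "z", "F", "z", "F", "F", "z")
  with_isolated_seed(seed, {
    seqs <- vector("list", n)
    truth <- list()
    for (s in seq_len(n)) {
      id <- sprintf("synth%03d", s)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        res <- sample(names(comp), length, replace = TRUE, prob = comp)
        starts <- integer(0)
        if (n_motifs > 0) {
          # place 9-residue blocks without overlap
          slots <- seq_len(length - 8L)
          placed <- integer(0)
          for (m in seq_len(n_motifs)) {
            avail <- slots[vapply(slots, function(p) {
              all(abs(placed - p) >= 9L)
            }, logical(1))]
            if (length(avail) == 0L) break
            placed <- c(placed, sample(avail, 1))
          }
          if (length(placed) < n_motifs) next
          for (p in placed) {
            core <- vapply(pattern_cls, function(cl) {
              if (cl == "F") sample(phi, 1) else sample(zeta, 1)
            }, character(1))
            res[p] <- "P"; res[p + 8L] <- "P"
            res[(p + 1L):(p + 7L)] <- core
          }
          starts <- sort(placed + 1L)
        }
        aseq <- annotated_sequence(id, res)
        hits <- scan_dbox(aseq)
        if (identical(sort(hits$core_start), starts)) {
          seqs[[s]] <- aseq
          if (length(starts) > 0L) {
            truth[[length(truth) + 1L]] <- data.frame(
              seq_id = id, core_start = starts, core_end = starts + 6L,
              core_seq = vapply(starts, function(p) {
                paste(res[p:(p + 6L)], collapse = "")
              }, character(1)),
              stringsAsFactors = FALSE)
          }
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not realize a clean background for sequence ", s,
                    " within ", max_tries, " tries", call. = FALSE)
    }
    truth_df <- if (length(truth) == 0L) {
      data.frame(seq_id = character(), core_start = integer(),
                 core_end = integer(), core_seq = character(),
                 stringsAsFactors = FALSE)
    } else do.call(rbind, truth)
    rownames(truth_df) <- NULL
    list(sequences = seqs, truth = truth_df)
  })
}

# canonicalize a strand: CA centroid at origin, first->last CA along +x
align_strand_x <- function(atoms) {
  ca <- atoms[atoms$elety == "CA", ]
  ca <- ca[order(ca$resno), ]
  X <- cbind(atoms$x, atoms$y, atoms$z)
  ctr <- colMeans(cbind(ca$x, ca$y, ca$z))
  X <- sweep(X, 2, ctr)
  ax <- c(ca$x[nrow(ca)] - ca$x[1], ca$y[nrow(ca)] - ca$y[1],
          ca$z[nrow(ca)] - ca$z[1])
  ax <- ax / sqrt(sum(ax^2))
  tmp <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- tmp - sum(tmp * ax) * ax; e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(ax[2] * e2[3] - ax[3] * e2[2], ax[3] * e2[1] - ax[1] * e2[3],
          ax[1] * e2[2] - ax[2] * e2[1])
  X <- X %*% t(rbind(ax, e2, e3))
  atoms$x <- X[, 1]; atoms$y <- X[, 2]; atoms$z <- X[, 3]
  atoms
}

rot_xyz <- function(ax, ay, az) {
  Rx <- matrix(c(1, 0, 0, 0, cos(ax), sin(ax), 0, -sin(ax), cos(ax)), 3, 3)
  Ry <- matrix(c(cos(ay), 0, -sin(ay), 0, 1, 0, sin(ay), 0, cos(ay)), 3, 3)
  Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

# designed inter-strand bond list for an ideal two-strand pair:
# antiparallel, direct register  -- reciprocal bonds at pairs (k, n+1-k),
#                                   k of the chosen parity (default odd)
# parallel, same register        -- per bridge residue k of chosen parity:
#                                   NH(B_k) -> CO(A_{k-1}), NH(A_{k+1}) -> CO(B_k)
designed_pair_bonds <- function(type, n_res, parity = NULL) {
  des <- list()
  if (type == "antiparallel") {
    start <- if (identical(parity, "even")) 2L else 1L
    for (k in seq(start, n_res, by = 2)) {
      j <- n_res + 1L - k
      des[[length(des) + 1L]] <- list(dc = "A", dr = k, ac = "B", ar = j)
      des[[length(des) + 1L]] <- list(dc = "B", dr = j, ac = "A", ar = k)
    }
  } else {
    start <- if (identical(parity, "odd")) 1L else 2L
    for (k in seq(start, n_res, by = 2)) {
      if (k - 1L >= 1L) {
        des[[length(des) + 1L]] <- list(dc = "B", dr = k, ac = "A", ar = k - 1L)
      }
      if (k + 1L <= n_res) {
        des[[length(des) + 1L]] <- list(dc = "A", dr = k + 1L, ac = "B", ar = k)
      }
    }
  }
  des
}

# rigidly place strand B against a fixed strand A so that the designed
# hydrogen bonds reach textbook geometry (H..O 1.9 A, N..O 2.9 A), by
# deterministic Nelder-Mead from a fixed grid of starting placements
place_partner_strand <- function(A, B, des, flips, sides = c(-1, 1)) {
  getm <- function(atoms, nm) {
    s <- atoms[atoms$elety == nm, ]; s <- s[order(s$resno), ]
    as.matrix(cbind(s$x, s$y, s$z))
  }
  mA <- list(N = getm(A, "N"), H = getm(A, "H"), O = getm(A, "O"))
  mB <- list(N = getm(B, "N"), H = getm(B, "H"), O = getm(B, "O"))
  heavyA <- as.matrix(cbind(A$x, A$y, A$z)[A$element != "H", ])
  heavyB0 <- as.matrix(cbind(B$x, B$y, B$z)[B$element != "H", ])
  score <- function(par) {
    R <- rot_xyz(par[1], par[2], par[3]); tr <- par[4:6]
    Bt <- lapply(mB, function(M) sweep(M %*% R, 2, tr, "+"))
    obj <- 0
    for (d in des) {
      don <- if (d$dc == "A") mA else Bt
      acc <- if (d$ac == "A") mA else Bt
      rOH <- sqrt(sum((don$H[d$dr, ] - acc$O[d$ar, ])^2))
      rON <- sqrt(sum((don$N[d$dr, ] - acc$O[d$ar, ])^2))
      obj <- obj + (rOH - 1.9)^2 + (rON - 2.9)^2
    }
    hB <- sweep(heavyB0 %*% R, 2, tr, "+")
    D2 <- outer(rowSums(heavyA^2), rowSums(hB^2), "+") - 2 * heavyA %*% t(hB)
    obj + 10 * sum(pmax(0, 2.8 - sqrt(pmax(D2, 0)))^2)
  }
  inits <- list()
  for (r0 in flips) for (dx in seq(-3, 3, 1)) for (dy in 4.8 * sides)
    for (dz in c(-1, 0, 1)) {
      inits[[length(inits) + 1L]] <- c(r0, dx, dy, dz)
    }
  vs <- vapply(inits, score, numeric(1))
  best <- NULL
  for (k in order(vs)[1:4]) {
    o <- stats::optim(inits[[k]], score, method = "Nelder-Mead",
                      control = list(maxit = 2500, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
    if (best$value < 1e-3) break
  }
  R <- rot_xyz(best$par[1], best$par[2], best$par[3])
  xyz <- cbind(B$x, B$y, B$z) %*% R
  B$x <- xyz[, 1] + best$par[4]
  B$y <- xyz[, 2] + best$par[5]
  B$z <- xyz[, 3] + best$par[6]
  list(B = B, rss = best$value)
}

# expected Kabsch-Sander bridges implied by the designed bond set
expected_pair_bridges <- function(type, n_res) {
  rows <- list()
  if (type == "antiparallel") {
    for (i in seq_len(n_res)) {
      j <- n_res + 1L - i
      # interior pairs are bridged either by reciprocal bonds (odd i) or by
      # the flanking designed bonds (even i); ends need their own bonds
      formed <- if (i %% 2L == 1L) TRUE
                else (i - 1L >= 1L && i + 1L <= n_res)
      if (formed) rows[[length(rows) + 1L]] <- data.frame(
        resno_i = i, resno_j = j, type = "antiparallel")
    }
    out <- do.call(rbind, rows)
  } else {
    out <- do.call(rbind, lapply(seq(2L, n_res - 1L), function(i) {
      data.frame(resno_i = i, resno_j = i, type = "parallel")
    }))
  }
  rownames(out) <- NULL
  out
}

#' Generate an ideal two-strand beta pair
#'
#' Builds two poly-alanine backbones at textbook beta conformation
#' (antiparallel phi/psi -139/135, parallel -119/113, explicit amide
#' hydrogens) and rigidly places the second strand so that the canonical
#' hydrogen-bond ladder of the requested type forms: target geometry
#' H..O = 1.9 A, N..O = 2.9 A per designed bond, found by deterministic
#' Nelder-Mead over the 6 rigid degrees of freedom from a fixed grid of
#' starting placements (no randomness). The expected bond list and the
#' expected bridge list are enumerated from the designed register, not by
#' running the detector.
#'
#' @param type `"antiparallel"` or `"parallel"`.
#' @param n_res residues per strand (>= 3).
#' @param separation extra rigid offset (A) applied to strand B along +y
#'   after placement; use e.g. 20 to pull the strands apart (default 0).
#' @return list of class `beta_pair_fixture`: `model` (a `structure_model`
#'   with chains A and B), `expected_bonds` (donor/acceptor chain + resno),
#'   `expected_bridges` (resno_i/resno_j/type), `type`, `placement_rss`
#'   (residual of the geometric target; ~0 for a clean fixture).
#' @export
gen_ideal_beta_pair <- function(type = c("antiparallel", "parallel"),
                                n_res = 5L, separation = 0) {
  type <- match.arg(type)
  if (n_res < 3L) stop("n_res must be >= 3", call. = FALSE)
  phi <- if (type == "antiparallel") -139 else -119
  psi <- if (type == "antiparallel") 135 else 113
  A <- align_strand_x(build_backbone(n_res, phi, psi, chain = "A",
                                     with_amide_H = TRUE))
  B <- align_strand_x(build_backbone(n_res, phi, psi, chain = "B",
                                     with_amide_H = TRUE))
  des <- designed_pair_bonds(type, n_res)
  flips <- if (type == "antiparallel") list(c(0, pi, 0), c(0, 0, pi))
           else list(c(0, 0, 0))
  placed <- place_partner_strand(A, B, des, flips)
  B <- placed$B
  B$y <- B$y + separation
  model <- structure_model(rbind(A, B),
                           source = sprintf("ideal %s pair (n=%d)", type, n_res))
  eb <- do.call(rbind, lapply(des, function(d) data.frame(
    donor_chain = d$dc, donor_resno = d$dr,
    acceptor_chain = d$ac, acceptor_resno = d$ar, stringsAsFactors = FALSE)))
  structure(list(model = model, expected_bonds = eb,
                 expected_bridges = expected_pair_bridges(type, n_res),
                 type = type, placement_rss = placed$rss),
            class = "beta_pair_fixture")
}

#' Generate a synthetic two-sheet recruitment complex
#'
#' Emulates the binding mode in which a single extended peptide strand is
#' simultaneously recruited to the sheet edges of two different partner
#' chains: chain `P` (the peptide) forms a parallel hydrogen-bond ladder with
#' chain `A` on one face and an antiparallel ladder with chain `B` on the
#' opposite face, using the alternating up/down orientation of backbone
#' amides along a beta strand. All three strands share one beta conformation
#' (phi -130, psi 130) so the peptide can satisfy both partners.
#'
#' @param n_res residues per strand (>= 5).
#' @return list of class `recruitment_fixture`: `model` (chains P, A, B),
#'   `expected_partner_types` (named: A = "parallel", B = "antiparallel"),
#'   `placement_rss` (named residuals of the two placements).
#' @export
gen_recruitment_complex <- function(n_res = 7L) {
  if (n_res < 5L) stop("n_res must be >= 5", call. = FALSE)
  phi <- -130; psi <- 130
  P <- align_strand_x(build_backbone(n_res, phi, psi, chain = "P",
                                     with_amide_H = TRUE))
  A <- align_strand_x(build_backbone(n_res, phi, psi, chain = "A",
                                     with_amide_H = TRUE))
  B <- align_strand_x(build_backbone(n_res, phi, psi, chain = "B",
                                     with_amide_H = TRUE))
  # in the designed bond lists "A" denotes the fixed strand (here the
  # peptide P) and "B" the moving partner. The parallel ladder engages the
  # peptide's odd residues, the antiparallel ladder (even parity register)
  # its even residues, i.e. the opposite face of the strand.
  pl_par <- place_partner_strand(P, A, designed_pair_bonds("parallel", n_res),
                                 list(c(0, 0, 0)), sides = 1)
  pl_anti <- place_partner_strand(P, B,
                                  designed_pair_bonds("antiparallel", n_res,
                                                      parity = "even"),
                                  list(c(0, pi, 0), c(0, 0, pi)), sides = -1)
  model <- structure_model(rbind(P, pl_par$B, pl_anti$B),
                           source = sprintf("synthetic two-sheet recruitment (n=%d)",
                                            n_res))
  structure(list(model = model,
                 expected_partner_types = c(A = "parallel", B = "antiparallel"),
                 placement_rss = c(parallel = pl_par$rss,
                                   antiparallel = pl_anti$rss)),
            class = "recruitment_fixture")
}

#' Generate an ideal alpha-helix fixture
#'
#' Poly-alanine backbone at standard helical dihedrals (phi -57, psi -47)
#' with explicit amide hydrogens; useful as a negative control for strand
#' detection and a positive control for helix counting.
#'
#' @param n_res helix length (default 12).
#' @param chain chain id.
#' @return a `structure_model`.
#' @export
gen_helix_fixture <- function(n_res = 12L, chain = "A") {
  structure_model(build_backbone(n_res, phi = -57, psi = -47, chain = chain,
                                 with_amide_H = TRUE),
                  source = sprintf("ideal alpha helix (n=%d)", n_res))
}

# idealized valine residue (heavy atoms), used by the burial fixture
valine_atoms <- function(chain = "A", resno = 1L) {
  coords <- rbind(
    N   = c(0.000, 0.000, 0.000),
    CA  = c(1.458, 0.000, 0.000),
    C   = c(2.009, 1.420, 0.000),
    O   = c(1.251, 2.390, 0.000),
    CB  = c(2.010, -0.770, -1.210),
    CG1 = c(3.530, -0.830, -1.240),
    CG2 = c(1.440, -2.180, -1.280))
  data.frame(chain = chain, resno = resno, ins = "", resid = "VAL",
             elety = rownames(coords),
             element = substr(rownames(coords), 1, 1),
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             occ = 1, alt = "", stringsAsFactors = FALSE)
}

#' Generate a burial fixture: one residue inside a closable cage
#'
#' A single idealized valine (chain A) surrounded by a spherical cage of
#' carbon atoms (chain X) centered on the side-chain centroid. With the full
#' cage the side chain is completely occluded (burial ~1); `cage_fraction`
#' keeps only part of the sphere, and 0 removes it entirely.
#'
#' @param pocket_radius cage radius in A (default 5.5; must stay below ~6 so
#'   the probe-expanded cage spheres overlap the side chain's accessible
#'   shell and actually occlude it).
#' @param n_cage cage atoms on the full sphere (default 400).
#' @param cage_fraction fraction of the sphere kept, from the bottom up
#'   (1 = closed cage, 0.5 = hemisphere).
#' @param cage_offset rigid translation (A, along +x) applied to the cage,
#'   e.g. 500 to move the partner far away.
#' @return a `structure_model` with chains A (valine) and X (cage).
#' @export
gen_burial_fixture <- function(pocket_radius = 5.5, n_cage = 400,
                               cage_fraction = 1, cage_offset = 0) {
  val <- valine_atoms()
  side <- val[!(val$elety %in% BACKBONE_ATOMS), ]
  ctr <- c(mean(side$x), mean(side$y), mean(side$z))
  if (pocket_radius < 4.5) stop("pocket_radius too small to enclose a side chain",
                                call. = FALSE)
  if (cage_fraction <= 0) stop("cage_fraction must be > 0; use cage_offset to
  displace the cage instead of deleting it", call. = FALSE)
  atoms <- val
  pts <- sphere_points(n_cage)
  keep <- rank(pts[, 3], ties.method = "first") <= ceiling(cage_fraction * n_cage)
  pts <- pts[keep, , drop = FALSE] * pocket_radius
  cage <- data.frame(chain = "X", resno = seq_len(nrow(pts)), ins = "",
                     resid = "CGE", elety = "C", element = "C",
                     x = pts[, 1] + ctr[1] + cage_offset,
                     y = pts[, 2] + ctr[2],
                     z = pts[, 3] + ctr[3],
                     occ = 1, alt = "", stringsAsFactors = FALSE)
  atoms <- rbind(atoms, cage)
  structure_model(atoms, source = sprintf("burial cage (r=%.1f, fraction=%.2f)",
                                          pocket_radius, cage_fraction))
}
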