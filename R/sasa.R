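# Shrake-Rupley solvent-accessible surface area and burial fractions.

#' Default van der Waals radii for SASA (Angstrom)
#' @export
SASA_RADII_DEFAULT <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                        SE = 1.90, P = 1.80)

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- golden * (i - 0.5)
  cbind(r * cos(theta), r * sin(theta), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the heavy atoms of a model: each atom's sphere
#' of radius `r_vdw + probe` is sampled at `n_points` quasi-uniform points,
#' a point counts as accessible if it lies outside every neighboring atom's
#' expanded sphere, and the atom's area is the accessible fraction of
#' `4*pi*(r+probe)^2`. Waters and hydrogens are excluded by default.
#'
#' @param model a `structure_model`, or a data frame of atoms.
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points sample points per atom (default 960).
#' @param radii named vector of van der Waals radii by element.
#' @param keep_water,keep_hydrogen include these atoms (default FALSE).
#' @return object of class `sasa_result`: list with `atoms` (the atom table
#'   plus an `area` column, Angstrom^2), `residue` (per-residue totals:
#'   `all_atom`, `side_chain`), `probe`, `n_points`.
#' @export
compute_sasa <- function(model, probe = 1.4, n_points = 960,
                         radii = SASA_RADII_DEFAULT,
                         keep_water = FALSE, keep_hydrogen = FALSE) {
  a <- if (inherits(model, "structure_model")) model$atoms else model
  if (!keep_water) a <- a[!a$is_water, , drop = FALSE]
  if (!keep_hydrogen) a <- a[!a$is_hydrogen, , drop = FALSE]
  if (nrow(a) == 0L) stop("no atoms left to compute SASA on", call. = FALSE)
  unknown <- setdiff(unique(a$element), names(radii))
  if (length(unknown) > 0L) {
    ctx <- a[a$element %in% unknown, , drop = FALSE][1, ]
    stop("no radius configured for element(s) ",
         paste(unknown, collapse = ", "), " (first at ", ctx$chain, "/",
         ctx$resid, ctx$resno, "/", ctx$elety, ")", call. = FALSE)
  }
  r <- unname(radii[a$element]) + probe
  xyz <- atom_xyz(a)
  pts <- sphere_points(n_points)
  n <- nrow(a)
  area <- numeric(n)
  # neighbor prefilter: pairs closer than the largest possible contact
  rmax <- max(r)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < r[i] + rmax & seq_len(n) != i)
    nb <- nb[di[nb] < r[i] + r[nb]]
    sp <- sweep(pts * r[i], 2, xyz[i, ], "+")
    if (length(nb) == 0L) {
      acc <- n_points
    } else {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dj <- (sp[free, 1] - xyz[j, 1])^2 + (sp[free, 2] - xyz[j, 2])^2 +
          (sp[free, 3] - xyz[j, 3])^2
        free[free] <- dj > r[j]^2
      }
      acc <- sum(free)
    }
    area[i] <- acc / n_points * 4 * pi * r[i]^2
  }
  a$area <- area
  key <- paste(a$chain, a$resno, a$ins, sep = "\r")
  uk <- unique(key)
  side <- !(a$elety %in% BACKBONE_ATOMS)
  res <- data.frame(
    chain = a$chain[match(uk, key)],
    resno = a$resno[match(uk, key)],
    ins = a$ins[match(uk, key)],
    resid = a$resid[match(uk, key)],
    all_atom = as.numeric(tapply(area, factor(key, levels = uk), sum)),
    side_chain = as.numeric(tapply(area * side, factor(key, levels = uk), sum)),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  structure(list(atoms = a, residue = res, probe = probe, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, total area %.1f A^2 (probe %.2f, %d pts/atom)\n",
              nrow(x$atoms), sum(x$atoms$area), x$probe, x$n_points))
  invisible(x)
}

#' Fractional side-chain burial upon complex formation
#'
#' For each residue of the target selection, computes
#' `1 - SASA_sidechain(in full complex) / SASA_sidechain(target alone)`,
#' clamped to `[0, 1]`. The reference state is the target selection extracted
#' from the complex without moving any atoms, so the burial measures occlusion
#' by the partner (and by the rest of the complex), not conformational change.
#' Glycine has no side-chain heavy atoms and is reported as `NA`.
#'
#' @param complex a `structure_model` containing both sides.
#' @param target_chain chain id of the target (e.g. the recruited peptide).
#' @param target_resno optional author residue numbers to restrict to.
#' @param probe,n_points,radii as in [compute_sasa()].
#' @return data frame: `chain`, `resno`, `resid`, `sasa_alone`,
#'   `sasa_complex` (side-chain Angstrom^2) and `burial` in `[0,1]` (`NA` for
#'   glycine/backbone-only residues).
#' @export
fractional_burial <- function(complex, target_chain, target_resno = NULL,
                              probe = 1.4, n_points = 960,
                              radii = SASA_RADII_DEFAULT) {
  a <- complex$atoms
  tgt <- a$chain %in% target_chain & !a$is_water & !a$is_hydrogen
  if (!is.null(target_resno)) tgt <- tgt & a$resno %in% target_resno
  if (!any(tgt)) stop("empty target selection", call. = FALSE)
  if (all(tgt[!a$is_water & !a$is_hydrogen])) {
    stop("target selection covers the whole model; no partner left",
         call. = FALSE)
  }
  alone <- structure_model(a[tgt, , drop = FALSE], source = "target alone")
  s_alone <- compute_sasa(alone, probe = probe, n_points = n_points, radii = radii)
  s_cplx <- compute_sasa(complex, probe = probe, n_points = n_points, radii = radii)

  ra <- s_alone$residue
  rc <- s_cplx$residue
  keyA <- paste(ra$chain, ra$resno, ra$ins)
  keyC <- paste(rc$chain, rc$resno, rc$ins)
  m <- match(keyA, keyC)
  out <- data.frame(chain = ra$chain, resno = ra$resno, resid = ra$resid,
                    sasa_alone = ra$side_chain,
                    sasa_complex = rc$side_chain[m],
                    stringsAsFactors = FALSE)
  out$burial <- ifelse(out$sasa_alone < 1e-6, NA_real_,
                       pmin(1, pmax(0, 1 - out$sasa_complex / out$sasa_alone)))
  if (!is.null(target_resno)) {
    out <- out[match(target_resno, out$resno), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
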