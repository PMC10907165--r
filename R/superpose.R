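# Optimal rigid-body superposition (Kabsch algorithm) and whole-complex
# C-alpha comparison between crystal forms.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD
#' between `moving %*% R + t` and `reference`, via SVD of the covariance
#' matrix with the determinant correction that forbids reflections.
#'
#' @param reference,moving n x 3 coordinate matrices with corresponding rows.
#' @return list of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom), `n` (paired atoms),
#'   `transformed` (moving coordinates after superposition).
#' @export
kabsch_superpose <- function(reference, moving) {
  reference <- as.matrix(reference); moving <- as.matrix(moving)
  if (ncol(reference) != 3L || ncol(moving) != 3L) {
    stop("coordinate matrices must have 3 columns", call. = FALSE)
  }
  if (nrow(reference) != nrow(moving)) {
    stop("coordinate sets differ in length (", nrow(reference), " vs ",
         nrow(moving), ")", call. = FALSE)
  }
  n <- nrow(reference)
  if (n < 3L) stop("need at least 3 point pairs", call. = FALSE)
  ca <- colMeans(reference); cb <- colMeans(moving)
  A <- sweep(reference, 2, ca); B <- sweep(moving, 2, cb)
  if (max(svd(A)$d) < 1e-9 || svd(A)$d[2] < 1e-9 * max(svd(A)$d, 1)) {
    warning("reference points are (near-)collinear; rotation poorly determined")
  }
  H <- crossprod(B, A)               # 3x3 covariance, row-vector convention
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- as.numeric(ca - cb %*% R)
  moved <- sweep(moving %*% R, 2, t, "+")
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd, n = n,
                 transformed = moved),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A over %d atom pairs\n", x$rmsd, x$n))
  if (!is.null(x$chain_mapping)) {
    cat("chain mapping:",
        paste(names(x$chain_mapping), x$chain_mapping,
              sep = "->", collapse = ", "), "\n")
  }
  invisible(x)
}

# all permutations of a small vector (used for chain-mapping search)
permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' All-C-alpha RMSD between two models of the same complex
#'
#' Pairs C-alpha atoms by author residue number within corresponding chains
#' and superposes the pooled set. Because chemically identical chains (e.g.
#' the two protomers of a homodimer) may carry different labels in different
#' crystal forms, every chain assignment that maps each chain of `modelA`
#' onto a sequence-compatible chain of `modelB` is evaluated and the mapping
#' with the lowest RMSD is returned. Residues missing from either model are
#' excluded and counted.
#'
#' @param modelA,modelB `structure_model`s.
#' @param chainsA chains of `modelA` to include (default: all non-water).
#' @param min_seq_identity fraction of identical residues for two chains to
#'   be considered mappable (default 0.9).
#' @return a `superposition` with extra fields `chain_mapping` (named vector
#'   A-chain -> B-chain), `n_excluded` (residues without a partner), and
#'   `mappings_tried`.
#' @export
complex_ca_rmsd <- function(modelA, modelB, chainsA = NULL,
                            min_seq_identity = 0.9) {
  rtA <- residue_table(modelA); rtB <- residue_table(modelB)
  if (is.null(chainsA)) chainsA <- unique(rtA$chain)
  chainsB <- unique(rtB$chain)
  if (length(chainsB) < length(chainsA)) {
    stop("modelB has fewer chains than requested from modelA", call. = FALSE)
  }
  seq_of <- function(rt, ch) paste(ifelse(is.na(rt$aa[rt$chain == ch]), "X",
                                          rt$aa[rt$chain == ch]), collapse = "")
  compat <- function(sa, sb) {
    k <- min(nchar(sa), nchar(sb))
    if (k == 0L) return(FALSE)
    a <- strsplit(sa, "")[[1]][1:k]; b <- strsplit(sb, "")[[1]][1:k]
    mean(a == b) >= min_seq_identity
  }
  seqsA <- vapply(chainsA, function(ch) seq_of(rtA, ch), character(1))
  seqsB <- vapply(chainsB, function(ch) seq_of(rtB, ch), character(1))

  best <- NULL
  tried <- 0L
  for (perm in permutations(chainsB)) {
    mapping <- perm[seq_along(chainsA)]
    ok <- all(vapply(seq_along(chainsA), function(i) {
      compat(seqsA[i], seqsB[match(mapping[i], chainsB)])
    }, logical(1)))
    if (!ok) next
    tried <- tried + 1L
    XA <- NULL; XB <- NULL; excl <- 0L
    for (i in seq_along(chainsA)) {
      caA <- select_atoms(modelA, chain = chainsA[i], elety = "CA")
      caB <- select_atoms(modelB, chain = mapping[i], elety = "CA")
      common <- intersect(caA$resno, caB$resno)
      excl <- excl + length(setdiff(union(caA$resno, caB$resno), common))
      caA <- caA[match(common, caA$resno), , drop = FALSE]
      caB <- caB[match(common, caB$resno), , drop = FALSE]
      XA <- rbind(XA, atom_xyz(caA)); XB <- rbind(XB, atom_xyz(caB))
    }
    if (is.null(XA) || nrow(XA) < 3L) next
    sp <- kabsch_superpose(XA, XB)
    sp$chain_mapping <- stats::setNames(mapping, chainsA)
    sp$n_excluded <- excl
    if (is.null(best) || sp$rmsd < best$rmsd) best <- sp
  }
  if (is.null(best)) stop("no sequence-compatible chain mapping found",
                          call. = FALSE)
  best$mappings_tried <- tried
  best
}
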