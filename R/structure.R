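# Structure model container and PDB/mmCIF input.
#
# The model is a flat atom table, one row per atom after alternate-location
# resolution, in the spirit of bio3d's pdb$atom but with explicit water and
# hydrogen flags so downstream analyses (SASA, H-bonds) can exclude them
# uniformly.

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

deduce_element <- function(elety, resid) {
  el <- toupper(sub("^([A-Za-z]).*$", "\\1", gsub("[0-9' ]", "", elety)))
  # two-letter elements that occur in protein contexts
  first2 <- toupper(substr(gsub("[ ]", "", elety), 1, 2))
  el[first2 %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "NA", "BR")] <-
    first2[first2 %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "NA", "BR")]
  el
}

#' Construct a structure model from an atom table
#'
#' @param atoms data frame with columns `chain`, `resno` (integer author
#'   number), `ins` (insertion code, `""` if none), `resid` (3-letter residue
#'   name), `elety` (atom name), `element`, `x`, `y`, `z` (Angstrom), `occ`,
#'   `alt`. Missing `element` is deduced from the atom name; missing
#'   `occ`/`alt`/`ins` default to 1/""/"".
#' @param source optional provenance string.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, source = "constructed") {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0L) {
    stop("atom table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(atoms$ins)) atoms$ins <- ""
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$element)) atoms$element <- deduce_element(atoms$elety, atoms$resid)
  atoms$ins[is.na(atoms$ins)] <- ""
  atoms$alt[is.na(atoms$alt)] <- ""
  if (nrow(atoms) == 0L) stop("empty model rejected", call. = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table", call. = FALSE)
  }
  atoms$is_water <- atoms$resid %in% WATER_NAMES
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$elety)
  if (anyDuplicated(key)) {
    stop("duplicate atom names within a residue after altloc resolution",
         call. = FALSE)
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = source), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<structure_model> %d atoms, %d chain(s) [%s], %d water(s); source: %s\n",
              nrow(a), length(unique(a$chain)),
              paste(sort(unique(a$chain)), collapse = ","),
              sum(a$is_water), x$source))
  invisible(x)
}

# keep the highest-occupancy alternate location per atom; ties broken by
# altloc label order
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$ins, atoms$elety)
  ord <- order(key, -atoms$occ, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$ins, atoms$elety)), ,
        drop = FALSE]
}

#' Read a protein structure from PDB or mmCIF
#'
#' Parsing is delegated to bio3d; the result is normalized into a
#' [structure_model()]: first model by default, highest-occupancy alternate
#' location kept (ties by label order), waters retained but flagged,
#' hydrogens retained and flagged.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param model_index which model to keep from a multi-model file (default 1).
#' @return a `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           model_index = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  pdb <- tryCatch(
    suppressWarnings(
      if (format == "cif") {
        bio3d::read.cif(path, multi = model_index > 1L, rm.alt = FALSE,
                        verbose = FALSE)
      } else {
        bio3d::read.pdb(path, multi = model_index > 1L, rm.alt = FALSE,
                        verbose = FALSE)
      }),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (model_index > 1L) {
    if (nrow(pdb$xyz) < model_index) {
      stop("model_index ", model_index, " but file has ", nrow(pdb$xyz),
           " model(s)", call. = FALSE)
    }
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = as.integer(at$resno),
    ins = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    element = if (!is.null(at$elesy) && !all(is.na(at$elesy))) {
      ifelse(is.na(at$elesy) | at$elesy == "",
             deduce_element(at$elety, at$resid), toupper(at$elesy))
    } else deduce_element(at$elety, at$resid),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE
  )
  atoms$.ord <- seq_len(nrow(atoms))
  atoms <- resolve_altloc(atoms)
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain)),
                       atoms$resno, atoms$ins, atoms$.ord), , drop = FALSE]
  atoms$.ord <- NULL
  structure_model(atoms, source = paste0(path, " (", format, ")"))
}

#' Write a structure model as PDB
#'
#' Minimal ATOM/HETATM record writer sufficient for the models this package
#' builds or reads (no CONECT, no multi-model output).
#'
#' @param model a `structure_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  a <- model$atoms
  rec <- ifelse(a$is_water, "HETATM", "ATOM  ")
  name4 <- vapply(seq_len(nrow(a)), function(i) {
    nm <- a$elety[i]
    if (nchar(nm) >= 4L) substr(nm, 1, 4)
    else if (nchar(a$element[i]) == 2L) sprintf("%-4s", nm)
    else sprintf(" %-3s", nm)
  }, character(1))
  lines <- sprintf("%s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(a)), name4, substr(a$alt, 1, 1),
                   sprintf("%3s", a$resid), a$chain, a$resno,
                   substr(paste0(a$ins, " "), 1, 1),
                   a$x, a$y, a$z, a$occ, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Per-residue table of a structure model
#'
#' @param model a `structure_model`.
#' @param include_water keep water residues (default FALSE).
#' @return data frame with one row per residue: `chain`, `resno`, `ins`,
#'   `resid`, `aa` (one-letter or NA for non-standard), `n_atoms`, and a
#'   sequential `index` within each chain.
#' @export
residue_table <- function(model, include_water = FALSE) {
  a <- model$atoms
  if (!include_water) a <- a[!a$is_water, , drop = FALSE]
  key <- paste(a$chain, a$resno, a$ins, sep = "\r")
  first <- !duplicated(key)
  res <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    ins = a$ins[first], resid = a$resid[first],
                    stringsAsFactors = FALSE)
  res$aa <- unname(AA3_TO_1[res$resid])
  res$n_atoms <- as.integer(table(factor(key, levels = key[first])))
  res <- res[order(match(res$chain, unique(res$chain)), res$resno, res$ins), ,
             drop = FALSE]
  res$index <- stats::ave(seq_len(nrow(res)), res$chain,
                          FUN = seq_along)
  rownames(res) <- NULL
  res
}

#' One-letter sequence of one chain of a model
#' @param model a `structure_model`.
#' @param chain chain id.
#' @return character scalar (non-standard residues become `X`).
#' @export
chain_sequence <- function(model, chain) {
  rt <- residue_table(model)
  rt <- rt[rt$chain == chain, , drop = FALSE]
  if (nrow(rt) == 0L) stop("chain '", chain, "' not in model", call. = FALSE)
  paste(ifelse(is.na(rt$aa), "X", rt$aa), collapse = "")
}

# coordinate matrix for a subset of atoms
atom_xyz <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

# select atoms by chain and optional author residue numbers
select_atoms <- function(model, chain = NULL, resno = NULL, elety = NULL,
                         drop_water = TRUE, drop_hydrogen = TRUE) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (drop_water) keep <- keep & !a$is_water
  if (drop_hydrogen) keep <- keep & !a$is_hydrogen
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  a[keep, , drop = FALSE]
}

# apply a rigid transform (rotation R acting on row vectors, then translation)
transform_model <- function(model, R, t) {
  xyz <- atom_xyz(model$atoms) %*% R
  model$atoms$x <- xyz[, 1] + t[1]
  model$atoms$y <- xyz[, 2] + t[2]
  model$atoms$z <- xyz[, 3] + t[3]
  model
}
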