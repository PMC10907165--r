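# Pairwise global alignment, identity, Clustal-style column conservation
# classes, and mapping of conservation onto structure residues.

#' Clustal strong and weak amino-acid groups
#'
#' The residue groups Clustal uses to mark strongly (`:`) and weakly (`.`)
#' conserved alignment columns.
#' @export
CLUSTAL_STRONG_GROUPS <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK",
                           "MILV", "MILF", "HY", "FYW")
#' @rdname CLUSTAL_STRONG_GROUPS
#' @export
CLUSTAL_WEAK_GROUPS <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND",
                         "SNDEQK", "NDEQHK", "NEQHRK", "FVLIM", "HFY")

#' Define an alignment scoring scheme
#'
#' @param matrix substitution matrix name (a matrix shipped with Biostrings,
#'   default `"BLOSUM62"`) or a symmetric numeric matrix.
#' @param gap_open,gap_extend non-negative penalties (default 10 / 0.5).
#' @return list of class `scoring_scheme` with the resolved matrix.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 10,
                           gap_extend = 0.5) {
  if (gap_open < 0 || gap_extend < 0) {
    stop("gap penalties must be non-negative", call. = FALSE)
  }
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  if (!isTRUE(all.equal(matrix, t(matrix)))) {
    stop("substitution matrix must be symmetric", call. = FALSE)
  }
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch with affine gaps, delegated to
#' `Biostrings::pairwiseAlignment`. Non-standard residues are scored via the
#' substitution matrix's `X` column.
#'
#' @param seqA,seqB [annotated_sequence()] objects or character scalars.
#' @param scheme a [scoring_scheme()].
#' @return list of class `alignment_result`: `alignedA`, `alignedB` (equal
#'   length gapped strings), `score`, `percent_identity` (gapless-column
#'   denominator), `columns` (data frame: aligned residues, per-column class
#'   from [CLUSTAL_STRONG_GROUPS] membership -- identical/strong/weak/none/gap
#'   -- and the author numbers in each sequence, `NA` at gaps), `idA`, `idB`.
#' @export
global_align <- function(seqA, seqB, scheme = scoring_scheme()) {
  to_ann <- function(s, id) {
    if (inherits(s, "annotated_sequence")) s else annotated_sequence(id, s)
  }
  seqA <- to_ann(seqA, "seqA"); seqB <- to_ann(seqB, "seqB")
  if (length(seqA$residues) == 0L || length(seqB$residues) == 0L) {
    stop("cannot align an empty sequence", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(seqA$residues, collapse = "")),
    Biostrings::AAString(paste(seqB$residues, collapse = "")),
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    type = "global")
  alnA <- as.character(Biostrings::alignedPattern(pa))
  alnB <- as.character(Biostrings::alignedSubject(pa))
  a <- strsplit(alnA, "")[[1]]; b <- strsplit(alnB, "")[[1]]
  numA <- cumsum(a != "-"); numA[a == "-"] <- NA
  numB <- cumsum(b != "-"); numB[b == "-"] <- NA
  cols <- data.frame(
    resA = a, resB = b,
    posA = ifelse(is.na(numA), NA_integer_, seqA$offset + numA - 1L),
    posB = ifelse(is.na(numB), NA_integer_, seqB$offset + numB - 1L),
    stringsAsFactors = FALSE)
  cols$class <- mapply(column_class_pair, a, b, USE.NAMES = FALSE)
  out <- structure(list(
    alignedA = alnA, alignedB = alnB, score = Biostrings::score(pa),
    columns = cols, idA = seqA$id, idB = seqB$id),
    class = "alignment_result")
  out$percent_identity <- percent_identity(out)
  out
}

# conservation class of one aligned residue pair
column_class_pair <- function(x, y) {
  if (x == "-" || y == "-") return("gap")
  column_class(c(x, y))
}

# conservation class of a full column of residues (no gaps)
column_class <- function(res) {
  if (length(unique(res)) == 1L) return("identical")
  in_all <- function(group) all(vapply(res, grepl, logical(1), x = group,
                                       fixed = TRUE))
  if (any(vapply(CLUSTAL_STRONG_GROUPS, in_all, logical(1)))) return("strong")
  if (any(vapply(CLUSTAL_WEAK_GROUPS, in_all, logical(1)))) return("weak")
  "none"
}

#' Percent identity of a pairwise alignment
#'
#' @param aln an `alignment_result`.
#' @param denominator `"gapless"` (identical pairs / columns aligned in both
#'   sequences, the default), `"alignment"` (full alignment length) or
#'   `"shorter"` (length of the shorter input).
#' @return percentage in `[0, 100]`.
#' @export
percent_identity <- function(aln, denominator = c("gapless", "alignment",
                                                  "shorter")) {
  denominator <- match.arg(denominator)
  cols <- aln$columns
  gapless <- cols$resA != "-" & cols$resB != "-"
  ident <- sum(gapless & cols$resA == cols$resB)
  den <- switch(denominator,
    gapless = sum(gapless),
    alignment = nrow(cols),
    shorter = min(sum(cols$resA != "-"), sum(cols$resB != "-")))
  if (den == 0L) {
    warning("alignment has no aligned columns; identity undefined")
    return(NA_real_)
  }
  100 * ident / den
}

#' Per-reference-residue conservation classes from a star alignment
#'
#' Projects a set of pairwise alignments that share a reference sequence onto
#' the reference positions and classifies each position from the full column
#' of aligned residues: `identical` if all residues agree, `strong`/`weak` if
#' all fall in one published Clustal group, `none` otherwise (a gap in any
#' sequence also gives `none`).
#'
#' @param alignments list of `alignment_result`s, each with the reference as
#'   sequence A.
#' @return data frame: `position` (reference author number), `ref_residue`,
#'   `class`.
#' @export
column_classes <- function(alignments) {
  if (length(alignments) == 0L) stop("no alignments supplied", call. = FALSE)
  refs <- unique(vapply(alignments, function(a) gsub("-", "", a$alignedA),
                        character(1)))
  ids <- unique(vapply(alignments, function(a) a$idA, character(1)))
  if (length(refs) > 1L || length(ids) > 1L) {
    stop("alignments do not share the same reference sequence", call. = FALSE)
  }
  ref_cols <- alignments[[1]]$columns
  ref_pos <- ref_cols$posA[!is.na(ref_cols$posA)]
  ref_res <- ref_cols$resA[!is.na(ref_cols$posA)]
  cls <- vapply(seq_along(ref_pos), function(k) {
    p <- ref_pos[k]
    col <- vapply(alignments, function(a) {
      row <- a$columns[!is.na(a$columns$posA) & a$columns$posA == p, ]
      row$resB[1]
    }, character(1))
    if (any(col == "-")) return("none")
    column_class(c(ref_res[k], col))
  }, character(1))
  data.frame(position = ref_pos, ref_residue = ref_res, class = cls,
             stringsAsFactors = FALSE)
}

#' Map conservation classes onto structure residues
#'
#' Joins a [column_classes()] table to the residues of one chain by author
#' number (after applying `numbering_offset` to the class positions). Every
#' structure residue gets a class or `"unaligned"`; a systematic mismatch
#' (more than `max_unmatched_frac` of residues unaligned) is flagged with a
#' warning, which catches off-by-k numbering errors.
#'
#' @param classes output of [column_classes()].
#' @param model a `structure_model`.
#' @param chain chain id.
#' @param numbering_offset added to `classes$position` to reach structure
#'   author numbering (default 0).
#' @param max_unmatched_frac flag threshold (default 0.2).
#' @return data frame: `chain`, `resno`, `resid`, `class`, plus attribute
#'   `flagged_mismatch`.
#' @export
map_conservation <- function(classes, model, chain, numbering_offset = 0L,
                             max_unmatched_frac = 0.2) {
  rt <- residue_table(model)
  rt <- rt[rt$chain == chain, , drop = FALSE]
  if (nrow(rt) == 0L) stop("chain '", chain, "' not in model", call. = FALSE)
  m <- match(rt$resno, classes$position + numbering_offset)
  out <- data.frame(chain = rt$chain, resno = rt$resno, resid = rt$resid,
                    class = ifelse(is.na(m), "unaligned", classes$class[m]),
                    stringsAsFactors = FALSE)
  frac <- mean(out$class == "unaligned")
  flagged <- frac > max_unmatched_frac
  if (flagged) {
    warning(sprintf(paste("%.0f%% of chain %s residues have no conservation",
                          "class; check the numbering offset"),
                    100 * frac, chain))
  }
  attr(out, "flagged_mismatch") <- flagged
  out
}
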