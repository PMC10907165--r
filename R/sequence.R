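# Sequence container and hydropathy/propensity machinery for D-box scanning.

AA_STANDARD <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")

#' Default hydrophobic residue set
#'
#' Residues treated as hydrophobic (\eqn{\Phi}) when classifying a sequence
#' into the \eqn{\Phi}/\eqn{\zeta} alphabet used by the D-box motif
#' \eqn{\Phi\zeta\Phi\zeta\Phi\Phi\zeta}. Glycine and histidine are assigned
#' to the hydrophilic class; proline is its own class because it delimits the
#' motif rather than participating in it.
#' @export
PHI_SET_DEFAULT <- c("A","C","F","I","L","M","V","W","Y")

#' Chou-Fasman beta-sheet propensity table
#'
#' Classical per-residue beta-sheet conformational propensities P(beta).
#' Values > 1 indicate enrichment in beta strands.
#' @export
CHOU_FASMAN_BETA <- c(
  A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19,
  Q = 1.10, E = 0.37, G = 0.75, H = 0.87, I = 1.60,
  L = 1.30, K = 0.74, M = 1.05, F = 1.38, P = 0.55,
  S = 0.75, T = 1.19, W = 1.37, Y = 1.47, V = 1.70
)

#' Create an annotated protein sequence
#'
#' A thin container pairing a one-letter amino-acid sequence with an
#' identifier and the author-style residue number of its first residue, so
#' that all reported coordinates can use the numbering a structural biologist
#' would use (e.g. the TonB D-box peptide spans author residues 43-54 even
#' though it is only 12 residues long).
#'
#' @param id sequence identifier.
#' @param seq character scalar (one-letter codes) or character vector of
#'   single residues. The 20 standard residues plus `X` are accepted.
#' @param numbering_offset author number of the first residue (default 1).
#' @return an object of class `annotated_sequence` with fields `id`,
#'   `residues` (character vector) and `offset`.
#' @export
annotated_sequence <- function(id, seq, numbering_offset = 1L) {
  if (length(seq) == 1L && (nchar(seq) > 1L || nchar(seq) == 0L)) {
    residues <- strsplit(toupper(seq), "")[[1]]
  } else {
    residues <- toupper(as.character(seq))
  }
  bad <- setdiff(unique(residues), c(AA_STANDARD, "X"))
  if (length(bad) > 0L) {
    stop("non-standard residue code(s) in '", id, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(id = as.character(id), residues = residues,
         offset = as.integer(numbering_offset)),
    class = "annotated_sequence"
  )
}

#' @export
length.annotated_sequence <- function(x) length(x$residues)

#' @export
print.annotated_sequence <- function(x, ...) {
  cat(sprintf("<annotated_sequence> %s (%d aa, numbering starts at %d)\n",
              x$id, length(x$residues), x$offset))
  cat(paste(x$residues, collapse = ""), "\n")
  invisible(x)
}

#' Author-style residue numbers of a sequence
#' @param seq an `annotated_sequence`.
#' @return integer vector, one author number per residue.
#' @export
author_numbers <- function(seq) {
  seq$offset + seq_along(seq$residues) - 1L
}

#' Classify a residue into hydropathy classes
#'
#' Maps a one-letter residue code to one of three classes: `"PHI"`
#' (hydrophobic, \eqn{\Phi}), `"ZETA"` (hydrophilic, \eqn{\zeta}) or `"P"`
#' (proline, treated as its own class because prolines flank rather than form
#' the D-box core).
#'
#' @param residue character vector of one-letter codes (vectorized).
#' @param phi_set residues counted as hydrophobic.
#' @return character vector of class labels (`"PHI"`, `"ZETA"`, `"P"`).
#' @export
classify_hydropathy <- function(residue, phi_set = PHI_SET_DEFAULT) {
  residue <- toupper(residue)
  bad <- setdiff(unique(residue), AA_STANDARD)
  if (length(bad) > 0L) {
    stop("cannot classify non-standard residue code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- ifelse(residue == "P", "P",
                ifelse(residue %in% phi_set, "PHI", "ZETA"))
  unname(out)
}

#' Hydropathy string of a sequence
#'
#' Vectorized [classify_hydropathy()] returning a compact symbol string:
#' `F` for \eqn{\Phi}, `z` for \eqn{\zeta}, `P` for proline. Length is always
#' preserved.
#'
#' @inheritParams classify_hydropathy
#' @param seq an `annotated_sequence` or character scalar.
#' @return single character string of class symbols.
#' @export
hydropathy_string <- function(seq, phi_set = PHI_SET_DEFAULT) {
  res <- if (inherits(seq, "annotated_sequence")) seq$residues
         else strsplit(toupper(seq), "")[[1]]
  if (length(res) == 0L) return("")
  cls <- tryCatch(
    classify_hydropathy(res, phi_set),
    error = function(e) {
      bad <- which(!res %in% AA_STANDARD)
      stop("unclassifiable residue at position(s) ",
           paste(bad, collapse = ", "), ": ",
           paste(res[bad], collapse = ", "), call. = FALSE)
    }
  )
  paste(c(PHI = "F", ZETA = "z", P = "P")[cls], collapse = "")
}

#' Sliding-window beta-strand propensity profile
#'
#' Chou-Fasman-style heuristic standing in for a trained secondary-structure
#' predictor: the score at position i is the mean table propensity over an
#' odd window centered at i. Windows that overhang a sequence end are shrunk
#' to the available context and the position is flagged rather than silently
#' scored.
#'
#' @param seq an `annotated_sequence`.
#' @param window odd positive integer window width (default 5).
#' @param table named per-residue propensity values covering the 20 standard
#'   residues; `X` positions contribute the table mean.
#' @param threshold call threshold stored with the profile (default 1.0).
#' @return object of class `propensity_profile`: data frame with columns
#'   `position` (author number), `residue`, `score`, `truncated` (logical,
#'   window shrunk at this position), plus attributes `window`, `threshold`,
#'   `seq_id`.
#' @export
beta_propensity_profile <- function(seq, window = 5L,
                                    table = CHOU_FASMAN_BETA,
                                    threshold = 1.0) {
  stopifnot(inherits(seq, "annotated_sequence"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be an odd positive integer, got ", window, call. = FALSE)
  }
  if (!all(AA_STANDARD %in% names(table))) {
    stop("propensity table must cover all 20 standard residues", call. = FALSE)
  }
  n <- length(seq$residues)
  vals <- unname(table[seq$residues])
  vals[seq$residues == "X"] <- mean(table[AA_STANDARD])
  half <- (window - 1L) %/% 2L
  score <- numeric(n)
  truncated <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    score[i] <- mean(vals[lo:hi])
    truncated[i] <- (hi - lo + 1L) < window
  }
  out <- data.frame(
    position = author_numbers(seq),
    residue = seq$residues,
    score = score,
    truncated = truncated,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("propensity_profile", "data.frame"),
            window = window, threshold = threshold, seq_id = seq$id)
}

#' Scan a sequence for D-box motifs
#'
#' Finds every 7-residue window whose hydropathy classes read
#' \eqn{\Phi\zeta\Phi\zeta\Phi\Phi\zeta} and (optionally) that is flanked by
#' prolines within `proline_window` residues of each core end. When a
#' `propensity_threshold` is supplied, the mean Chou-Fasman beta propensity of
#' the core is computed and the `passes_propensity` flag set; matches are
#' reported either way so the gate is transparent.
#'
#' @param seq an `annotated_sequence` of length >= 7.
#' @param proline_window how many residues outside each core end to search
#'   for a flanking proline (default 2).
#' @param propensity_threshold numeric or `NA` to disable the gate
#'   (default 1.0).
#' @param require_prolines require a proline on both sides (default TRUE).
#' @param phi_set hydrophobic residue set.
#' @param window odd window for the propensity profile (default 5).
#' @return data frame of class `dbox_matches`, one row per match, with
#'   author-numbered columns `core_start`, `core_end`, `core_seq`,
#'   `proline_up`, `proline_down` (NA when absent), `mean_core_propensity`,
#'   `passes_propensity`; attribute `seq_id`. Zero rows is a valid result.
#' @export
scan_dbox <- function(seq, proline_window = 2L, propensity_threshold = 1.0,
                      require_prolines = TRUE, phi_set = PHI_SET_DEFAULT,
                      window = 5L) {
  stopifnot(inherits(seq, "annotated_sequence"))
  n <- length(seq$residues)
  if (n < 7L) stop("sequence shorter than the 7-residue D-box core", call. = FALSE)
  # X is unclassifiable: matches neither PHI nor ZETA
  cls <- character(n)
  known <- seq$residues %in% AA_STANDARD
  cls[known] <- classify_hydropathy(seq$residues[known], phi_set)
  cls[!known] <- "X"

  pattern <- c("PHI","ZETA","PHI","ZETA","PHI","PHI","ZETA")
  prof <- beta_propensity_profile(seq, window = window,
                                  threshold = if (is.na(propensity_threshold)) 1.0
                                              else propensity_threshold)
  nums <- author_numbers(seq)
  rows <- list()
  for (s in seq_len(n - 6L)) {
    if (!all(cls[s:(s + 6L)] == pattern)) next
    up <- NA_integer_; down <- NA_integer_
    if (proline_window > 0L) {
      up_rng <- seq(max(1L, s - proline_window), s - 1L)
      up_rng <- up_rng[up_rng >= 1L & up_rng < s]
      hit <- up_rng[seq$residues[up_rng] == "P"]
      if (length(hit) > 0L) up <- nums[max(hit)]        # nearest upstream
      dn_rng <- seq(s + 7L, min(n, s + 6L + proline_window))
      dn_rng <- dn_rng[dn_rng <= n & dn_rng > s + 6L]
      hit <- dn_rng[seq$residues[dn_rng] == "P"]
      if (length(hit) > 0L) down <- nums[min(hit)]      # nearest downstream
    }
    if (require_prolines && (is.na(up) || is.na(down))) next
    mcp <- mean(prof$score[s:(s + 6L)])
    rows[[length(rows) + 1L]] <- data.frame(
      seq_id = seq$id,
      core_start = nums[s],
      core_end = nums[s + 6L],
      core_seq = paste(seq$residues[s:(s + 6L)], collapse = ""),
      proline_up = up,
      proline_down = down,
      mean_core_propensity = mcp,
      passes_propensity = if (is.na(propensity_threshold)) NA
                          else mcp >= propensity_threshold,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows) == 0L) {
    data.frame(seq_id = character(), core_start = integer(),
               core_end = integer(), core_seq = character(),
               proline_up = integer(), proline_down = integer(),
               mean_core_propensity = numeric(), passes_propensity = logical(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  rownames(out) <- NULL
  structure(out, class = c("dbox_matches", "data.frame"), seq_id = seq$id)
}

#' Composite motif score
#'
#' Combines the two quantitative signals available for ranking D-box
#' candidates: mean core beta propensity and, when the position of the
#' membrane anchor's periplasmic end is known, proximity to that anchor (the
#' functional motif sits immediately downstream of it). The score is
#' `mean_core_propensity - distance_weight * distance/100`, monotone
#' increasing in propensity and decreasing in anchor distance.
#'
#' @param match one row of a [scan_dbox()] result (data frame row or list).
#' @param profile the [beta_propensity_profile()] of the same sequence.
#' @param anchor_end author number of the residue just after the membrane
#'   anchor, or `NA` to score on propensity alone.
#' @param distance_weight penalty per 100 residues of separation
#'   (default 0.5).
#' @return numeric score.
#' @export
score_motif <- function(match, profile, anchor_end = NA,
                        distance_weight = 0.5) {
  seq_id <- if (!is.null(match$seq_id)) as.character(match$seq_id) else NA
  if (!is.na(seq_id) && !is.null(attr(profile, "seq_id")) &&
      !identical(seq_id, attr(profile, "seq_id"))) {
    stop("match (", seq_id, ") and profile (", attr(profile, "seq_id"),
         ") refer to different sequences", call. = FALSE)
  }
  idx <- profile$position >= match$core_start & profile$position <= match$core_end
  if (!any(idx)) stop("match span not covered by profile", call. = FALSE)
  prop <- mean(profile$score[idx])
  if (is.na(anchor_end)) return(prop)
  dist <- abs(match$core_start - anchor_end)
  prop - distance_weight * dist / 100
}
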