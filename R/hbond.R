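# Backbone hydrogen bonds (Kabsch-Sander energy), beta-bridge typing,
# sheet/helix topology, and strand-recruitment detection.

KS_Q1Q2F <- 27.888        # 0.42 e * 0.20 e * 332 kcal A / mol e^2
KS_CUTOFF_DEFAULT <- -0.5  # kcal/mol

# Extract the backbone of a model as one row per residue with N/CA/C/O
# coordinates, an amide-H position (observed if present, otherwise placed
# 1.0 A from N along the previous peptide's C=O direction), a sequential
# per-chain index, and a has_H flag (FALSE for prolines, chain starts and
# residues after a chain break).
backbone_table <- function(model, break_dist = 2.5) {
  a <- model$atoms[!model$atoms$is_water, , drop = FALSE]
  rt <- residue_table(model)
  n <- nrow(rt)
  get_atom <- function(i, name) {
    hit <- a$chain == rt$chain[i] & a$resno == rt$resno[i] &
      a$ins == rt$ins[i] & a$elety == name
    if (!any(hit)) return(c(NA_real_, NA_real_, NA_real_))
    as.numeric(a[which(hit)[1], c("x", "y", "z")])
  }
  N <- t(vapply(seq_len(n), get_atom, numeric(3), name = "N"))
  CA <- t(vapply(seq_len(n), get_atom, numeric(3), name = "CA"))
  C <- t(vapply(seq_len(n), get_atom, numeric(3), name = "C"))
  O <- t(vapply(seq_len(n), get_atom, numeric(3), name = "O"))
  H <- t(vapply(seq_len(n), get_atom, numeric(3), name = "H"))
  has_H <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (rt$resid[i] == "PRO") next
    if (all(is.finite(H[i, ]))) { has_H[i] <- TRUE; next }
    if (i == 1L || rt$chain[i] != rt$chain[i - 1L]) next
    if (!all(is.finite(N[i, ])) || !all(is.finite(C[i - 1L, ])) ||
        !all(is.finite(O[i - 1L, ]))) next
    if (sqrt(sum((C[i - 1L, ] - N[i, ])^2)) > break_dist) next  # chain break
    v <- C[i - 1L, ] - O[i - 1L, ]
    H[i, ] <- N[i, ] + v / sqrt(sum(v^2))
    has_H[i] <- TRUE
  }
  cbind(rt, data.frame(
    Nx = N[, 1], Ny = N[, 2], Nz = N[, 3],
    Cx = C[, 1], Cy = C[, 2], Cz = C[, 3],
    Ox = O[, 1], Oy = O[, 2], Oz = O[, 3],
    Hx = H[, 1], Hy = H[, 2], Hz = H[, 3],
    has_H = has_H))
}

#' Detect backbone-backbone hydrogen bonds
#'
#' Kabsch-Sander electrostatic criterion: the interaction energy between the
#' donor amide (N-H) of one residue and the acceptor carbonyl (C=O) of
#' another is
#' \deqn{E = 27.888 (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})}
#' (kcal/mol, distances in Angstrom) and a bond is assigned when
#' `E < cutoff`. Amide hydrogens are built from local geometry when absent
#' (in-plane, 1.0 A from N, anti to the preceding carbonyl); prolines cannot
#' donate. Self and sequence-adjacent pairs are excluded; following DSSP, at
#' most the two lowest-energy acceptors are kept per donor. A purely
#' geometric criterion (H..O < 2.5 A, N..O < 3.5 A, N-H..O angle > 120 deg)
#' is available as an alternative.
#'
#' @param model a `structure_model`.
#' @param criterion `"kabsch_sander"` (default) or `"geometric"`.
#' @param cutoff energy cutoff in kcal/mol (default -0.5; ignored by the
#'   geometric criterion).
#' @param max_per_donor acceptors kept per donor (default 2).
#' @return data frame of class `hbond_list`: `donor_chain`, `donor_resno`,
#'   `donor_index`, `acceptor_chain`, `acceptor_resno`, `acceptor_index`,
#'   `energy` (kcal/mol; NA for geometric), `dist_NO` (Angstrom). The
#'   sequential per-chain residue `index` columns key into [residue_table()].
#' @export
detect_backbone_hbonds <- function(model,
                                   criterion = c("kabsch_sander", "geometric"),
                                   cutoff = KS_CUTOFF_DEFAULT,
                                   max_per_donor = 2L) {
  criterion <- match.arg(criterion)
  bb <- backbone_table(model)
  n <- nrow(bb)
  empty <- data.frame(donor_chain = character(), donor_resno = integer(),
                      donor_index = integer(), acceptor_chain = character(),
                      acceptor_resno = integer(), acceptor_index = integer(),
                      energy = numeric(), dist_NO = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("hbond_list", "data.frame")
  if (n < 2L) return(empty)
  Nmat <- as.matrix(bb[, c("Nx", "Ny", "Nz")])
  Hmat <- as.matrix(bb[, c("Hx", "Hy", "Hz")])
  Cmat <- as.matrix(bb[, c("Cx", "Cy", "Cz")])
  Omat <- as.matrix(bb[, c("Ox", "Oy", "Oz")])
  donors <- which(bb$has_H & is.finite(Nmat[, 1]))
  acceptors <- which(is.finite(Cmat[, 1]) & is.finite(Omat[, 1]))
  rows <- list()
  for (d in donors) {
    dNO <- sqrt(colSums((t(Omat[acceptors, , drop = FALSE]) - Nmat[d, ])^2))
    cand <- acceptors[dNO < 5.2]
    cand <- cand[!(bb$chain[cand] == bb$chain[d] &
                     abs(bb$index[cand] - bb$index[d]) < 2L)]
    if (length(cand) == 0L) next
    rON <- sqrt(rowSums(sweep(Omat[cand, , drop = FALSE], 2, Nmat[d, ])^2))
    rOH <- sqrt(rowSums(sweep(Omat[cand, , drop = FALSE], 2, Hmat[d, ])^2))
    rCH <- sqrt(rowSums(sweep(Cmat[cand, , drop = FALSE], 2, Hmat[d, ])^2))
    rCN <- sqrt(rowSums(sweep(Cmat[cand, , drop = FALSE], 2, Nmat[d, ])^2))
    if (criterion == "kabsch_sander") {
      E <- KS_Q1Q2F * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      E[pmin(rON, rOH, rCH, rCN) < 0.5] <- -9.9   # clash guard, DSSP-style cap
      keep <- which(E < cutoff)
    } else {
      # N-H..O angle at the hydrogen
      ang <- vapply(seq_along(cand), function(k) {
        vHN <- Nmat[d, ] - Hmat[d, ]; vHO <- Omat[cand[k], ] - Hmat[d, ]
        acos(pmin(1, pmax(-1, sum(vHN * vHO) /
                            (sqrt(sum(vHN^2)) * sqrt(sum(vHO^2)))))) * 180 / pi
      }, numeric(1))
      E <- rep(NA_real_, length(cand))
      keep <- which(rOH < 2.5 & rON < 3.5 & ang > 120)
    }
    if (length(keep) == 0L) next
    ord <- if (criterion == "kabsch_sander") keep[order(E[keep])]
           else keep[order(rOH[keep])]
    ord <- ord[seq_len(min(max_per_donor, length(ord)))]
    rows[[length(rows) + 1L]] <- data.frame(
      donor_chain = bb$chain[d], donor_resno = bb$resno[d],
      donor_index = bb$index[d],
      acceptor_chain = bb$chain[cand[ord]],
      acceptor_resno = bb$resno[cand[ord]],
      acceptor_index = bb$index[cand[ord]],
      energy = E[ord], dist_NO = rON[ord],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("hbond_list", "data.frame")
  out
}

# helper: fast lookup "does an H-bond donor->acceptor exist"
hb_lookup <- function(hbonds) {
  paste(hbonds$donor_chain, hbonds$donor_index,
        hbonds$acceptor_chain, hbonds$acceptor_index, sep = "\r")
}

#' Classify beta bridges from a hydrogen-bond list
#'
#' Kabsch-Sander bridge rules. Writing `Hbond(a, b)` for the carbonyl of
#' residue `a` accepting the amide hydrogen of residue `b` (the same
#' convention in which an alpha-helical 4-turn is `Hbond(i, i+4)`), a residue
#' pair `(i, j)` is a parallel bridge iff
#' `Hbond(i-1, j) & Hbond(j, i+1)` or `Hbond(j-1, i) & Hbond(i, j+1)`,
#' and an antiparallel bridge iff
#' `Hbond(i, j) & Hbond(j, i)` or `Hbond(i-1, j+1) & Hbond(j-1, i+1)`,
#' where `i-1`/`i+1` are sequence neighbors within the same chain. Pairs
#' closer than 3 residues along one chain are not bridges.
#'
#' @param hbonds output of [detect_backbone_hbonds()].
#' @param model the same `structure_model`.
#' @return data frame of class `bridge_list`: `chain_i`, `resno_i`,
#'   `index_i`, `chain_j`, `resno_j`, `index_j`, `type`
#'   (`"parallel"`/`"antiparallel"`). Each unordered pair appears once.
#' @export
classify_bridges <- function(hbonds, model) {
  rt <- residue_table(model)
  key <- function(ch, idx) paste(ch, idx, sep = "\r")
  hbset <- hb_lookup(hbonds)
  has_hb <- function(ch1, i1, ch2, i2) {
    paste(ch1, i1, ch2, i2, sep = "\r") %in% hbset
  }
  # residues worth considering: anything involved in an H-bond, +-1
  cand <- unique(rbind(
    data.frame(chain = hbonds$donor_chain, index = hbonds$donor_index),
    data.frame(chain = hbonds$acceptor_chain, index = hbonds$acceptor_index)))
  if (nrow(cand) == 0L) {
    out <- data.frame(chain_i = character(), resno_i = integer(),
                      index_i = integer(), chain_j = character(),
                      resno_j = integer(), index_j = integer(),
                      type = character(), stringsAsFactors = FALSE)
    class(out) <- c("bridge_list", "data.frame")
    return(out)
  }
  grow <- rbind(cand,
                transform(cand, index = index - 1L),
                transform(cand, index = index + 1L))
  grow <- unique(grow)
  # keep only residues that exist
  rtk <- key(rt$chain, rt$index)
  grow <- grow[key(grow$chain, grow$index) %in% rtk, , drop = FALSE]
  grow <- grow[order(match(grow$chain, unique(rt$chain)), grow$index), ]
  rows <- list()
  for (a in seq_len(nrow(grow))) {
    for (b in seq_len(nrow(grow))) {
      ci <- grow$chain[a]; i <- grow$index[a]
      cj <- grow$chain[b]; j <- grow$index[b]
      if (ci == cj && j <= i + 2L) next              # order pairs, skip near
      if (ci > cj || (ci == cj && i >= j)) next
      # has_hb(donor chain/index, acceptor chain/index); the Kabsch-Sander
      # Hbond(a, b) predicate is acceptor-CO(a) <- donor-NH(b)
      par <- (has_hb(cj, j, ci, i - 1L) && has_hb(ci, i + 1L, cj, j)) ||
             (has_hb(ci, i, cj, j - 1L) && has_hb(cj, j + 1L, ci, i))
      anti <- (has_hb(cj, j, ci, i) && has_hb(ci, i, cj, j)) ||
              (has_hb(cj, j + 1L, ci, i - 1L) && has_hb(ci, i + 1L, cj, j - 1L))
      if (!par && !anti) next
      type <- if (par && !anti) "parallel"
              else if (anti && !par) "antiparallel"
              else "antiparallel"   # both patterns: reciprocal bonds dominate
      ri <- rt[rt$chain == ci & rt$index == i, ]
      rj <- rt[rt$chain == cj & rt$index == j, ]
      rows[[length(rows) + 1L]] <- data.frame(
        chain_i = ci, resno_i = ri$resno[1], index_i = i,
        chain_j = cj, resno_j = rj$resno[1], index_j = j,
        type = type, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(chain_i = character(), resno_i = integer(), index_i = integer(),
               chain_j = character(), resno_j = integer(), index_j = integer(),
               type = character(), stringsAsFactors = FALSE)
  } else unique(do.call(rbind, rows))
  rownames(out) <- NULL
  class(out) <- c("bridge_list", "data.frame")
  out
}

# group bridges between one chain pair into ladders of consecutive bridges
bridge_ladders <- function(bridges) {
  if (nrow(bridges) == 0L) return(list())
  ladders <- list()
  bridges <- bridges[order(bridges$chain_i, bridges$chain_j, bridges$index_i), ]
  used <- rep(FALSE, nrow(bridges))
  for (s in seq_len(nrow(bridges))) {
    if (used[s]) next
    cur <- s; used[s] <- TRUE
    repeat {
      last <- cur[length(cur)]
      step <- if (bridges$type[last] == "parallel") 1L else -1L
      nxt <- which(!used &
                     bridges$chain_i == bridges$chain_i[last] &
                     bridges$chain_j == bridges$chain_j[last] &
                     bridges$type == bridges$type[last] &
                     bridges$index_i == bridges$index_i[last] + 1L &
                     bridges$index_j == bridges$index_j[last] + step)
      if (length(nxt) == 0L) break
      cur <- c(cur, nxt[1]); used[nxt[1]] <- TRUE
    }
    ladders[[length(ladders) + 1L]] <- bridges[cur, , drop = FALSE]
  }
  ladders
}

#' Sheet and helix topology of one chain
#'
#' Strands are maximal runs (length >= 2) of residues that participate in at
#' least one beta bridge; helices are maximal runs (length >= 4) of residues
#' `i` carrying a Kabsch-Sander 4-turn (amide of `i+4` donating to carbonyl
#' of `i`).
#'
#' @param model a `structure_model`.
#' @param chain chain id to summarize.
#' @param hbonds optional precomputed [detect_backbone_hbonds()] result.
#' @return list: `n_strands`, `n_helices`, `strand_residues` (list of author
#'   resno ranges), `helix_residues`.
#' @export
sheet_topology <- function(model, chain, hbonds = NULL) {
  rt <- residue_table(model)
  rtc <- rt[rt$chain == chain, , drop = FALSE]
  if (nrow(rtc) < 5L) stop("chain '", chain, "' has fewer than 5 residues",
                           call. = FALSE)
  if (is.null(hbonds)) hbonds <- detect_backbone_hbonds(model)
  bridges <- classify_bridges(hbonds, model)
  in_bridge <- sort(unique(c(
    bridges$index_i[bridges$chain_i == chain],
    bridges$index_j[bridges$chain_j == chain])))
  runs_of <- function(idx, min_len) {
    if (length(idx) == 0L) return(list())
    grp <- cumsum(c(1L, diff(idx) != 1L))
    out <- split(idx, grp)
    out[vapply(out, length, integer(1)) >= min_len]
  }
  strands <- runs_of(in_bridge, 2L)
  # 4-turns within this chain
  ft <- hbonds[hbonds$donor_chain == chain & hbonds$acceptor_chain == chain &
                 hbonds$donor_index - hbonds$acceptor_index == 4L, ]
  turn_start <- sort(unique(ft$acceptor_index))
  helices <- runs_of(turn_start, 4L)
  to_resno <- function(run) {
    r <- rtc$resno[match(run, rtc$index)]
    c(min(r), max(r))
  }
  list(chain = chain,
       n_strands = length(strands),
       n_helices = length(helices),
       strand_residues = lapply(strands, to_resno),
       helix_residues = lapply(helices, to_resno))
}

#' Detect beta-strand recruitment of a peptide chain
#'
#' Summarizes, per partner chain, the bridge ladders formed between the
#' peptide and that partner (type and author-numbered residue ranges on both
#' sides) and the side-chain burial fractions of the peptide's hydrophobic
#' (Phi-class) residues. The `recruited_to_two_sheets` flag is set when
#' ladders to at least two distinct partner chains exist -- the signature of
#' a single strand joining the edges of two different sheets.
#'
#' @param model a `structure_model` with the peptide plus >= 1 partner chain.
#' @param peptide_chain chain id of the peptide.
#' @param hbonds optional precomputed H-bond list.
#' @param burial compute Phi-residue burial fractions (default TRUE; needs a
#'   SASA pass, the slow part).
#' @return list of class `recruitment_report`: `peptide_chain`, `partners`
#'   (data frame: partner chain, type, peptide_from/to, partner_from/to,
#'   n_bridges), `recruited_to_two_sheets`, `phi_burial` (data frame or NULL).
#' @export
detect_strand_recruitment <- function(model, peptide_chain, hbonds = NULL,
                                      burial = TRUE) {
  rt <- residue_table(model)
  if (!peptide_chain %in% rt$chain) {
    stop("peptide chain '", peptide_chain, "' not in model (available: ",
         paste(unique(rt$chain), collapse = ", "), ")", call. = FALSE)
  }
  if (length(unique(rt$chain)) < 2L) {
    stop("model has no partner chain", call. = FALSE)
  }
  if (is.null(hbonds)) hbonds <- detect_backbone_hbonds(model)
  bridges <- classify_bridges(hbonds, model)
  pep <- bridges[(bridges$chain_i == peptide_chain) !=
                   (bridges$chain_j == peptide_chain), , drop = FALSE]
  # orient so the peptide is always side i
  flip <- pep$chain_j == peptide_chain
  if (any(flip)) {
    tmp <- pep[flip, ]
    pep[flip, c("chain_i", "resno_i", "index_i")] <-
      tmp[, c("chain_j", "resno_j", "index_j")]
    pep[flip, c("chain_j", "resno_j", "index_j")] <-
      tmp[, c("chain_i", "resno_i", "index_i")]
  }
  ladders <- bridge_ladders(pep)
  partners <- if (length(ladders) == 0L) {
    data.frame(partner = character(), type = character(),
               peptide_from = integer(), peptide_to = integer(),
               partner_from = integer(), partner_to = integer(),
               n_bridges = integer(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(ladders, function(l) data.frame(
      partner = l$chain_j[1], type = l$type[1],
      peptide_from = min(l$resno_i), peptide_to = max(l$resno_i),
      partner_from = min(l$resno_j), partner_to = max(l$resno_j),
      n_bridges = nrow(l), stringsAsFactors = FALSE)))
  }
  rownames(partners) <- NULL
  phi_burial <- NULL
  if (burial) {
    rtp <- rt[rt$chain == peptide_chain & !is.na(rt$aa), , drop = FALSE]
    phi_res <- rtp$resno[classify_hydropathy(rtp$aa) == "PHI"]
    if (length(phi_res) > 0L) {
      phi_burial <- fractional_burial(model, peptide_chain,
                                      target_resno = phi_res)
    }
  }
  structure(list(peptide_chain = peptide_chain,
                 partners = partners,
                 recruited_to_two_sheets = length(unique(partners$partner)) >= 2L,
                 phi_burial = phi_burial),
            class = "recruitment_report")
}

#' @export
print.recruitment_report <- function(x, ...) {
  cat(sprintf("<recruitment_report> peptide chain %s; recruited to two sheets: %s\n",
              x$peptide_chain, x$recruited_to_two_sheets))
  if (nrow(x$partners) > 0L) print(x$partners)
  if (!is.null(x$phi_burial)) {
    cat("Phi-residue side-chain burial:\n")
    print(x$phi_burial[, c("resno", "resid", "burial")])
  }
  invisible(x)
}
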