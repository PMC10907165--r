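# Workflow drivers: each run_* function wraps one analysis stage, reads the
# standard file dialects, and writes self-contained TSV/JSON reports. The
# numbered scripts under analysis/ are thin narratives over these functions.

write_json_report <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ITC titration CSV
#'
#' Expected header: `injection,volume_uL,heat_ucal`. The protocol (cell
#' volume and concentrations) is supplied separately.
#'
#' @param path CSV file.
#' @param cell_volume,cell_concentration,syringe_concentration,temperature
#'   protocol values passed to [itc_protocol()].
#' @return an ITC-mode [titration_series()].
#' @export
read_itc_csv <- function(path, cell_volume = 200, cell_concentration = 100,
                         syringe_concentration = 1000, temperature = 288) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("injection", "volume_uL", "heat_ucal")
  if (!all(need %in% names(df))) {
    stop("ITC CSV ", path, " must have columns ", paste(need, collapse = ","),
         " (found: ", paste(names(df), collapse = ","), ")", call. = FALSE)
  }
  df <- df[order(df$injection), ]
  protocol <- itc_protocol(cell_volume, cell_concentration,
                           syringe_concentration, df$volume_uL, temperature)
  titration_series("itc", heats = df$heat_ucal, protocol = protocol)
}

#' Write an ITC titration CSV
#' @param series ITC-mode [titration_series()].
#' @param path output CSV.
#' @return `path`, invisibly. A `<path>.truth.json` sidecar is written when
#'   the series carries generator truth metadata.
#' @export
write_itc_csv <- function(series, path) {
  stopifnot(series$mode == "itc")
  df <- data.frame(injection = seq_along(series$heats),
                   volume_uL = series$protocol$injection_volumes,
                   heat_ucal = series$heats)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(series$truth)) {
    write_json_report(series$truth, paste0(path, ".truth.json"))
  }
  invisible(path)
}

#' Read a fluorescence anisotropy CSV
#'
#' Expected header: `Pt_uM,anisotropy`; the labeled-peptide total is supplied
#' as an argument.
#'
#' @param path CSV file.
#' @param Lt labeled peptide total (uM).
#' @return an anisotropy-mode [titration_series()].
#' @export
read_anisotropy_csv <- function(path, Lt) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("Pt_uM", "anisotropy")
  if (!all(need %in% names(df))) {
    stop("anisotropy CSV ", path, " must have columns ",
         paste(need, collapse = ","), " (found: ",
         paste(names(df), collapse = ","), ")", call. = FALSE)
  }
  titration_series("anisotropy", Pt = df$Pt_uM, Lt = Lt,
                   anisotropy = df$anisotropy)
}

#' Write a fluorescence anisotropy CSV (plus truth sidecar when present)
#' @param series anisotropy-mode [titration_series()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_anisotropy_csv <- function(series, path) {
  stopifnot(series$mode == "anisotropy")
  df <- data.frame(Pt_uM = series$Pt, anisotropy = series$anisotropy)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(series$truth)) {
    write_json_report(series$truth, paste0(path, ".truth.json"))
  }
  invisible(path)
}

#' Scan a FASTA file for D-box motifs
#'
#' Runs [scan_dbox()] on every record and writes a TSV and a JSON report.
#'
#' @param fasta path to a protein FASTA (headers may carry `id/start-end`
#'   numbering).
#' @param out_dir report directory, or `NULL` to skip writing.
#' @param ... passed to [scan_dbox()].
#' @param anchor_end optional author position of the membrane anchor's end,
#'   used for the composite score column.
#' @return the combined match data frame (one row per motif), invisibly when
#'   writing reports.
#' @export
run_scan <- function(fasta, out_dir = NULL, ..., anchor_end = NA) {
  seqs <- read_fasta_annotated(fasta)
  all <- list()
  for (s in seqs) {
    if (length(s$residues) < 7L) next
    hits <- scan_dbox(s, ...)
    if (nrow(hits) > 0L) {
      prof <- beta_propensity_profile(s)
      hits$score <- vapply(seq_len(nrow(hits)), function(i) {
        score_motif(hits[i, ], prof, anchor_end = anchor_end)
      }, numeric(1))
      all[[length(all) + 1L]] <- hits
    }
  }
  out <- if (length(all) == 0L) {
    data.frame(seq_id = character(), core_start = integer(),
               core_end = integer(), core_seq = character(),
               proline_up = integer(), proline_down = integer(),
               mean_core_propensity = numeric(), passes_propensity = logical(),
               score = numeric(), stringsAsFactors = FALSE)
  } else do.call(rbind, all)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    write_tsv(out, file.path(out_dir, "dbox_matches.tsv"))
    write_json_report(list(n_sequences = length(seqs), n_matches = nrow(out),
                           matches = out),
                      file.path(out_dir, "dbox_matches.json"))
    return(invisible(out))
  }
  out
}

#' Fit a binding isotherm from a titration CSV
#'
#' @param csv input file in the ITC or anisotropy dialect.
#' @param mode `"itc"` or `"anisotropy"`.
#' @param out_dir report directory, or `NULL`.
#' @param Lt labeled-peptide total (anisotropy mode, uM).
#' @param n_boot bootstrap replicates for confidence intervals (0 disables).
#' @param seed bootstrap seed.
#' @param ... protocol arguments for [read_itc_csv()] or fit options.
#' @return the `binding_fit`, with `ci` attached when bootstrapped.
#' @export
run_fit <- function(csv, mode = c("itc", "anisotropy"), out_dir = NULL,
                    Lt = NULL, n_boot = 0, seed = 1, ...) {
  mode <- match.arg(mode)
  series <- if (mode == "itc") read_itc_csv(csv, ...)
            else {
              if (is.null(Lt)) stop("anisotropy mode needs Lt", call. = FALSE)
              read_anisotropy_csv(csv, Lt = Lt)
            }
  fit <- if (mode == "itc") fit_itc(series) else fit_anisotropy(series)
  if (fit$converged && n_boot >= 20) {
    fit$ci <- bootstrap_ci(fit, series, n_boot = n_boot, seed = seed)
  }
  if (!is.null(out_dir)) {
    report <- list(mode = mode, input = csv, converged = fit$converged,
                   parameters = fit$parameters, se = fit$se,
                   rss = fit$rss, diagnostics = fit$diagnostics,
                   ci = fit$ci)
    write_json_report(report, file.path(out_dir, paste0("fit_", mode, ".json")))
    resid_df <- data.frame(index = seq_along(fit$residuals),
                           residual = as.numeric(fit$residuals))
    write_tsv(resid_df, file.path(out_dir, paste0("fit_", mode, "_residuals.tsv")))
  }
  fit
}

#' Full structural analysis of a recruitment complex
#'
#' One call producing the whole structure report: backbone H-bonds, bridge
#' typing, per-chain sheet/helix topology, strand-recruitment summary with
#' hydrophobic side-chain burial, and (optionally) the all-C-alpha
#' superposition against a second crystal form.
#'
#' @param model_path structure file (PDB or mmCIF), or a `structure_model`.
#' @param peptide_chain chain id of the recruited peptide.
#' @param compare_path optional second structure (path or model) for the
#'   crystal-form comparison.
#' @param burial_residues optional author numbers restricting the burial table.
#' @param out_dir report directory, or `NULL`.
#' @return list of class `complex_report`.
#' @export
run_analyze <- function(model_path, peptide_chain, compare_path = NULL,
                        burial_residues = NULL, out_dir = NULL) {
  model <- if (inherits(model_path, "structure_model")) model_path
           else read_structure(model_path)
  hb <- detect_backbone_hbonds(model)
  rec <- detect_strand_recruitment(model, peptide_chain, hbonds = hb)
  chains <- setdiff(unique(model$atoms$chain[!model$atoms$is_water]),
                    peptide_chain)
  topo <- lapply(chains, function(ch) {
    tryCatch(sheet_topology(model, ch, hbonds = hb), error = function(e) NULL)
  })
  names(topo) <- chains
  burial <- if (!is.null(burial_residues)) {
    fractional_burial(model, peptide_chain, target_resno = burial_residues)
  } else rec$phi_burial
  comparison <- NULL
  if (!is.null(compare_path)) {
    other <- if (inherits(compare_path, "structure_model")) compare_path
             else read_structure(compare_path)
    comparison <- complex_ca_rmsd(model, other)
  }
  report <- structure(list(
    source = model$source, peptide_chain = peptide_chain,
    n_hbonds = nrow(hb), recruitment = rec, topology = topo, burial = burial,
    comparison = comparison), class = "complex_report")
  if (!is.null(out_dir)) {
    js <- list(source = report$source, peptide_chain = peptide_chain,
               n_backbone_hbonds = nrow(hb),
               recruited_to_two_sheets = rec$recruited_to_two_sheets,
               partners = rec$partners,
               topology = lapply(topo, function(t) if (is.null(t)) NULL else
                 list(n_strands = t$n_strands, n_helices = t$n_helices)),
               burial = burial,
               comparison = if (is.null(comparison)) NULL else list(
                 rmsd = comparison$rmsd, n = comparison$n,
                 chain_mapping = as.list(comparison$chain_mapping)))
    write_json_report(js, file.path(out_dir, "complex_report.json"))
    if (!is.null(burial)) write_tsv(burial, file.path(out_dir, "burial.tsv"))
    write_tsv(as.data.frame(hb), file.path(out_dir, "hbonds.tsv"))
  }
  report
}

#' Conservation analysis against a reference sequence
#'
#' Aligns every other FASTA record to the reference, reports pairwise
#' identities and per-reference-position conservation classes, and optionally
#' maps the classes onto one chain of a structure.
#'
#' @param fasta multi-record FASTA containing the reference.
#' @param reference_id id of the reference record.
#' @param model_path optional structure (path or `structure_model`).
#' @param chain chain to map onto when a structure is given.
#' @param numbering_offset offset from reference numbering to structure
#'   numbering.
#' @param scheme a [scoring_scheme()].
#' @param out_dir report directory, or `NULL`.
#' @return list: `identity` (data frame), `classes`, `structure_map` (or NULL).
#' @export
run_conserve <- function(fasta, reference_id, model_path = NULL, chain = NULL,
                         numbering_offset = 0L, scheme = scoring_scheme(),
                         out_dir = NULL) {
  seqs <- read_fasta_annotated(fasta)
  if (!reference_id %in% names(seqs)) {
    stop("reference '", reference_id, "' not found in ", fasta,
         " (records: ", paste(names(seqs), collapse = ", "), ")",
         call. = FALSE)
  }
  ref <- seqs[[reference_id]]
  others <- seqs[setdiff(names(seqs), reference_id)]
  if (length(others) == 0L) stop("no sequences besides the reference",
                                 call. = FALSE)
  alns <- lapply(others, function(s) global_align(ref, s, scheme))
  identity <- data.frame(
    reference = reference_id,
    sequence = vapply(alns, function(a) a$idB, character(1)),
    percent_identity = vapply(alns, function(a) a$percent_identity, numeric(1)),
    score = vapply(alns, function(a) a$score, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  classes <- column_classes(alns)
  structure_map <- NULL
  if (!is.null(model_path)) {
    model <- if (inherits(model_path, "structure_model")) model_path
             else read_structure(model_path)
    structure_map <- map_conservation(classes, model, chain, numbering_offset)
  }
  if (!is.null(out_dir)) {
    write_tsv(identity, file.path(out_dir, "identity.tsv"))
    write_tsv(classes, file.path(out_dir, "conservation_classes.tsv"))
    if (!is.null(structure_map)) {
      write_tsv(structure_map, file.path(out_dir, "structure_map.tsv"))
    }
    write_json_report(list(identity = identity,
                           class_counts = as.list(table(classes$class))),
                      file.path(out_dir, "conservation.json"))
  }
  list(identity = identity, classes = classes, structure_map = structure_map)
}
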