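# Shared fixtures. Beta-pair construction involves a placement optimization,
# so built fixtures are cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_beta_pair <- function(type, n_res, separation = 0) {
  key <- paste(type, n_res, separation)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- gen_ideal_beta_pair(type, n_res,
                                                 separation = separation)
  }
  .fixture_cache[[key]]
}

cached_recruitment_complex <- function(n_res = 7L) {
  key <- paste("recruit", n_res)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- gen_recruitment_complex(n_res)
  }
  .fixture_cache[[key]]
}

# minimal hand-written PDB: one glycine, three atoms
minimal_pdb_text <- function() {
  c("ATOM      1  N   GLY A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       2.458   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       3.009   3.420   3.000  1.00  0.00           C",
    "END")
}

# the same glycine as mmCIF
minimal_cif_text <- function() {
  c("data_fixture",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . GLY A 1 1 ? 1.000 2.000 3.000 1.00 0.00 ? 1 GLY A N 1",
    "ATOM 2 C CA . GLY A 1 1 ? 2.458 2.000 3.000 1.00 0.00 ? 1 GLY A CA 1",
    "ATOM 3 C C . GLY A 1 1 ? 3.009 3.420 3.000 1.00 0.00 ? 1 GLY A C 1",
    "#")
}

# PDB with two alternate locations for one atom (B has higher occupancy)
altloc_pdb_text <- function() {
  c("ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       5.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "END")
}

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# three TonB-like ortholog toys with known differences from the reference:
# ortho1 = reference with 2 substitutions, ortho2 = reference exactly
conservation_toy_fasta <- function() {
  ref <- "MKQPISVTMVTPADLEPVKA"
  o1 <- "MKQPISVTMVSPADLKPVKA"   # T11S, E16K
  o2 <- ref
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">ref", ref, ">ortho1", o1, ">ortho2", o2), path)
  path
}
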