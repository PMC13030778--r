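# PDB text fixtures built in code.

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     record = "ATOM", altloc = " ", occ = 1, b = 0,
                     elem = NULL) {
  elem <- elem %||% substr(trimws(name), 1, 1)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), altloc, resname, chain, resno,
          x, y, z, occ, b, elem)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_minimal_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

minimal_two_atom_pdb <- function(path) {
  write_minimal_pdb(path, c(
    pdb_line(1, "N", "ALA", "A", 1, 11.104, 6.134, -6.504),
    pdb_line(2, "CA", "ALA", "A", 1, 11.639, 6.071, -5.147)
  ))
}

table2_fixture <- function() dicer2_distances()

# Build the packaged-fixture pipeline: one scaffold per species, each with the
# published per-pocket distances, the reference species anchoring the model.
build_fixture_config <- function(dir, n_replicates = 3, perturb_sigma = 0,
                                 seed = 1) {
  tbl <- table2_fixture()
  for (i in seq_len(nrow(tbl))) {
    sc <- generate_scaffold(tbl$structure_id[i], tbl$d_3p_riiia[i],
                            tbl$d_5p_riiib[i], seed = 100 + i)
    write_structure(sc$structure,
                    file.path(dir, paste0(tbl$structure_id[i], ".pdb")))
    write_sites(sc$sites,
                file.path(dir, paste0(tbl$structure_id[i], "_sites.tsv")))
  }
  cfg <- list(
    reference = list(id = "dmel", structure = "dmel.pdb",
                     sites = "dmel_sites.tsv", length_nt = 21L),
    targets = lapply(2:nrow(tbl), function(i) {
      list(id = tbl$structure_id[i],
           structure = paste0(tbl$structure_id[i], ".pdb"),
           sites = paste0(tbl$structure_id[i], "_sites.tsv"),
           expected_mean = tbl$reported_mean[i])
    }),
    rise = 2.0, n_replicates = n_replicates, perturb_sigma = perturb_sigma,
    seed = seed
  )
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  path
}
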