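# In-code fixture builders: tiny PDB files, toy ontologies, small ensembles.

pdb_atom_line <- function(serial, name, resname, resno, x, y, z,
                          alt = " ", chain = "A", record = "ATOM  ") {
  sprintf("%s%5d %s%s%s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          record, serial, formatC(name, width = 4), alt, resname, chain,
          resno, x, y, z)
}

write_fixture_pdb <- function(path, xyz, resno = seq_len(nrow(xyz))) {
  lines <- vapply(seq_len(nrow(xyz)), function(i)
    pdb_atom_line(i, " CA ", "ALA", resno[i], xyz[i, 1], xyz[i, 2], xyz[i, 3]),
    character(1))
  writeLines(c(lines, "END"), path)
  path
}

# root R with children A (is_a) and B (is_a)
toy_sibling_ontology <- function() {
  go_ontology(c("R", "A", "B"),
              edges = data.frame(child = c("A", "B"), parent = c("R", "R"),
                                 type = c("is_a", "is_a")))
}

# chain A is_a B is_a R
toy_chain_ontology <- function() {
  go_ontology(c("R", "B", "A"),
              edges = data.frame(child = c("A", "B"), parent = c("B", "R"),
                                 type = c("is_a", "is_a")))
}

# diamond: A is_a B, A part_of C, B is_a R, C is_a R
toy_diamond_ontology <- function() {
  go_ontology(c("R", "B", "C", "A"),
              edges = data.frame(child = c("A", "A", "B", "C"),
                                 parent = c("B", "C", "R", "R"),
                                 type = c("is_a", "part_of", "is_a", "is_a")))
}

canonical_spec <- function(seed, n_members = 10L, core_length = 120L,
                           noise_sd = 0.3) {
  synthetic_spec(n_members, core_length, noise_sd,
                 outlier_plan = list(list(
                   member = 1L,
                   perturbations = plant_two_hinge_outlier(core_length))),
                 seed = seed)
}

# a small protein-like trace for pairwise tests
test_trace <- function(n, seed) generate_core_backbone(max(n, 30L), seed)[seq_len(n), , drop = FALSE]
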