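# Fixture builders shared across the test files. Everything is generated
# in code; no binary data ships with the package.

# record from explicit coordinates, single chain unless chain_id given
toy_record <- function(id = "toy", xyz, b, aa = "ALA", chain = "A",
                       ss = "unassigned") {
  n <- nrow(xyz)
  protein_record(id, data.frame(
    aa_code = rep(aa, length.out = n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b_factor = rep(b, length.out = n),
    chain_id = rep(chain, length.out = n),
    ss_label = rep(ss, length.out = n), stringsAsFactors = FALSE))
}

# ideal alpha-helix / extended-strand C-alpha traces (exact 3.8 A bonds)
ideal_helix <- function(n = 12, id = "helix") {
  tpl <- bflex:::helix_template(n - 1L, 3.8)
  toy_record(id, tpl, b = 10 + seq_len(n))
}

ideal_strand <- function(n = 10, id = "strand") {
  tpl <- bflex:::strand_template(n - 1L, 3.8)
  toy_record(id, tpl, b = 10 + seq_len(n))
}

# a small curated record with non-degenerate geometry in all axes
random_record <- function(n = 30, seed = 1, id = paste0("rnd", seed)) {
  cfg <- synthetic_config(n_min = n, n_max = n)
  generate_chain(cfg, seed = seed, protein_id = id)
}

# quick untrained predictor over the 28-slot encoding
tiny_model <- function(seed = 1, use_lstm = TRUE) {
  build_model(model_config(encoder_widths = 8L, lstm_hidden = 8L,
                           decoder_widths = c(8L, 1L), use_lstm = use_lstm),
              seed = seed)
}

# offsets of each parameter block in the flat vector, from the shape table
param_blocks <- function(model) {
  shapes <- bflex:::nn_shapes_cpp(bflex:::cfg_for_cpp(model$config))
  sizes <- vapply(shapes, function(s) s$rows * s$cols, numeric(1))
  data.frame(kind = vapply(shapes, `[[`, character(1), "kind"),
             rows = vapply(shapes, `[[`, numeric(1), "rows"),
             cols = vapply(shapes, `[[`, numeric(1), "cols"),
             from = cumsum(c(1, sizes[-length(sizes)])),
             to = cumsum(sizes))
}

# write a hand-crafted PDB text fixture; lines supplied by the caller
write_pdb_lines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_line <- function(serial, resname, chain, resno, x, y, z, b,
                          altloc = " ") {
  sprintf("ATOM  %5d  CA %1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, altloc, resname, chain, resno, x, y, z, 1.00, b)
}
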