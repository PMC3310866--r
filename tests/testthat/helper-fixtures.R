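# Shared fixtures for the test suite; everything is generated in code.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     altloc = " ", occ = 1.00, element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1L, 1L)
  sprintf("ATOM  %5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) >= 4, name, paste0(" ", name)),
          altloc, resname, chain, resno, x, y, z, occ, 0, element)
}

# single-atom structure at the origin with a chosen radius
one_atom_structure <- function(element = "C", r = NULL) {
  s <- read_structure(pdb_line(1, paste0(element, "A"), "UNK", "A", 1, 0, 0, 0,
                               element = element))
  if (!is.null(r)) s$atoms$vdw <- r
  s
}

# uniform-valued map covering a small cube around the origin
uniform_map <- function(value, spacing = 0.5, half = 6) {
  n <- 2L * as.integer(half / spacing) + 1L
  grid3d(rep(-half, 3), spacing, rep(n, 3L),
         array(value, rep(n, 3L)))
}

# a hand-made placement object with the given atom types at the origin
fake_placement <- function(types, xyz = NULL, vdw = 1.7) {
  n <- length(types)
  if (is.null(xyz)) xyz <- matrix(0, n, 3L)
  list(position = data.frame(chain = "A", resid = "1"),
       aa = "X", restype = "UNK", rotamer = 1L, chi = numeric(0),
       atoms = data.frame(name = paste0("A", seq_len(n)), element = "C",
                          vdw = vdw, atom_type = types,
                          x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                          stringsAsFactors = FALSE),
       xyz = xyz, clash_free = TRUE)
}

# deterministic small scaffold with an open mutation site
open_scaffold <- function(seed = 2, gap = 4) {
  tc <- make_toy_complex(seed = seed, n_residues_a = 6L, n_residues_b = 6L,
                         interface_gap = gap)
  list(complex = tc$structure,
       scaffold = build_alanine_scaffold(tc$structure,
                                         data.frame(chain = "A", resid = "3")),
       position = data.frame(chain = "A", resid = "3"),
       manifest = tc$manifest)
}
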