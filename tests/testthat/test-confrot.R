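# Rotamer library, alanine scaffold, placement clash filter and
# conformation classification.

test_that("rotamer library loads the shipped table and handles edge rows", {
  lib <- default_rotamer_library()
  tab <- read.delim(system.file("extdata", "rotamers_synthetic.tsv",
                                package = "cdrpref"))
  expect_equal(nrow(lib$LEU), sum(tab$restype == "LEU"))
  expect_equal(nrow(lib$ALA), 1L)
  expect_equal(nrow(lib$GLY), 1L)
  expect_equal(ncol(lib$GLY), 0L)  # no chi angles, no sidechain heavy atoms
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("restype\tchi1\tchi2\tchi3\tchi4\tfreq",
               "SER\t-60\t\t\t\t1", "XXX\t10\t\t\t\t1"), tf)
  expect_warning(lib2 <- load_rotamer_library(tf), "unknown residue")
  expect_equal(nrow(lib2$SER), 1L)
})

test_that("alanine scaffold keeps 5 atoms, builds ideal CB for Gly, errors on missing backbone", {
  tc <- make_toy_complex(seed = 21, n_residues_a = 5, n_residues_b = 3,
                         interface_gap = 8, resnames_a = "GLY")
  pos <- data.frame(chain = "A", resid = "3")
  sc <- build_alanine_scaffold(tc$structure, pos)
  res <- sc$atoms[sc$atoms$chain == "A" & sc$atoms$resid == "3", ]
  expect_setequal(res$name, c("N", "CA", "C", "O", "CB"))
  xyz <- as.matrix(res[, c("x", "y", "z")])
  rownames(xyz) <- res$name
  # independent geometric checks of the constructed CB
  expect_equal(sqrt(sum((xyz["CB", ] - xyz["CA", ])^2)), 1.53,
               tolerance = 1e-6)
  ang <- acos(sum((xyz["N", ] - xyz["CA", ]) * (xyz["CB", ] - xyz["CA", ])) /
                (sqrt(sum((xyz["N", ] - xyz["CA", ])^2)) * 1.53)) * 180 / pi
  expect_equal(ang, 110.4, tolerance = 0.5)
  # L-chirality: dot(CB-CA, cross(N-CA, C-CA)) < 0
  u <- xyz["N", ] - xyz["CA", ]; v <- xyz["C", ] - xyz["CA", ]
  crossuv <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
               u[1] * v[2] - u[2] * v[1])
  expect_lt(sum((xyz["CB", ] - xyz["CA", ]) * crossuv), 0)

  # an already-Ala residue is untouched
  tc2 <- make_toy_complex(seed = 22, n_residues_a = 4, n_residues_b = 3,
                          interface_gap = 8)
  before <- tc2$structure$atoms
  sc2 <- build_alanine_scaffold(tc2$structure,
                                data.frame(chain = "A", resid = "2"))
  expect_equal(sc2$atoms[sc2$atoms$chain == "A", c("name", "x", "y", "z")],
               before[before$chain == "A", c("name", "x", "y", "z")])

  broken <- tc2$structure
  broken$atoms <- broken$atoms[!(broken$atoms$chain == "A" &
                                   broken$atoms$resid == "2" &
                                   broken$atoms$name == "CA"), ]
  expect_error(build_alanine_scaffold(broken,
                                      data.frame(chain = "A", resid = "2")),
               "CA")
})

test_that("a Trp residue is reduced to exactly the 5 kept atoms", {
  fx <- open_scaffold(seed = 23)
  pos <- fx$position
  lib <- default_rotamer_library()
  pl <- enumerate_placements(fx$scaffold, pos, "W", lib, keep_clashing = TRUE)
  full <- pl[[1]]$atoms$name
  # graft the full Trp into the structure, then reduce it again
  s <- fx$scaffold
  sel <- which(s$atoms$chain == "A" & s$atoms$resid == "3")
  graft <- s$atoms[rep(sel[1L], length(full)), ]
  graft$name <- full
  graft$resname <- "TRP"
  graft$serial <- max(s$atoms$serial) + seq_along(full)
  graft$x <- pl[[1]]$xyz[, 1L]; graft$y <- pl[[1]]$xyz[, 2L]
  graft$z <- pl[[1]]$xyz[, 3L]
  s$atoms <- rbind(s$atoms[-sel, ], graft)
  s <- cdrpref:::new_structure3d(s$atoms)
  red <- build_alanine_scaffold(s, pos)
  kept <- red$atoms[red$atoms$chain == "A" & red$atoms$resid == "3", "name"]
  expect_setequal(kept, c("N", "CA", "C", "O", "CB"))
  expect_length(kept, 5L)
})

test_that("placements follow library chi angles and the clash rules", {
  fx <- open_scaffold(seed = 24)
  lib <- default_rotamer_library()
  # Ala: single clash-free conformer on an open scaffold
  pl_a <- enumerate_placements(fx$scaffold, fx$position, "A", lib)
  expect_length(pl_a, 1L)
  expect_true(pl_a[[1]]$clash_free)
  # chi angles are realized on the backbone
  pl_l <- enumerate_placements(fx$scaffold, fx$position, "L", lib,
                               keep_clashing = TRUE)
  for (q in pl_l[1:3]) {
    x <- q$xyz
    chi1 <- cdrpref:::dihedral_angle(x["N", ], x["CA", ], x["CB", ], x["CG", ])
    expect_equal(chi1, q$chi[1L], tolerance = 1e-6)
  }
  # placement count never exceeds the library rotamer count
  for (aa in c("S", "L", "K", "W", "R")) {
    res3 <- cdrpref:::aa_three(aa)
    expect_lte(length(enumerate_placements(fx$scaffold, fx$position, aa, lib)),
               nrow(lib[[res3]]))
  }
  expect_error(enumerate_placements(fx$scaffold,
                                    data.frame(chain = "A", resid = "99"),
                                    "A", lib), "not in scaffold")
})

test_that("an atom planted on a rotamer position removes that rotamer", {
  fx <- open_scaffold(seed = 25)
  lib <- default_rotamer_library()
  pl <- enumerate_placements(fx$scaffold, fx$position, "S", lib)
  expect_gte(length(pl), 1L)
  og <- pl[[1]]$xyz["OG", ]
  s <- fx$scaffold
  blocker <- s$atoms[1L, ]
  blocker$serial <- max(s$atoms$serial) + 1L
  blocker$chain <- "Z"; blocker$resno <- 999L; blocker$name <- "C"
  blocker$x <- og[1L]; blocker$y <- og[2L]; blocker$z <- og[3L]
  s$atoms <- rbind(s$atoms, blocker)
  s <- cdrpref:::new_structure3d(s$atoms)
  pl2 <- enumerate_placements(s, fx$position, "S", lib)
  expect_lt(length(pl2), length(pl))
  kept_chi <- vapply(pl2, function(q) q$chi[1L], numeric(1))
  expect_false(pl[[1]]$chi[1L] %in% kept_chi)
})

test_that("clash filter equals a brute-force all-pairs distance oracle", {
  fx <- open_scaffold(seed = 26)
  lib <- default_rotamer_library()
  scaffold <- fx$scaffold
  sel <- which(scaffold$atoms$chain == "A" & scaffold$atoms$resid == "3")
  oxyz <- as.matrix(scaffold$atoms[-sel, c("x", "y", "z")])
  ovdw <- scaffold$atoms$vdw[-sel]
  for (aa in c("L", "F", "K", "R")) {
    all_pl <- enumerate_placements(scaffold, fx$position, aa, lib,
                                   keep_clashing = TRUE)
    kept <- enumerate_placements(scaffold, fx$position, aa, lib)
    oracle <- vapply(all_pl, function(q) {
      sc <- q$atoms[!(q$atoms$name %in% c("N", "CA", "C", "O", "CB")), ]
      ok <- TRUE
      for (i in seq_len(nrow(sc))) {
        d <- sqrt((oxyz[, 1] - sc$x[i])^2 + (oxyz[, 2] - sc$y[i])^2 +
                    (oxyz[, 3] - sc$z[i])^2)
        if (any(d < sc$vdw[i] + ovdw - 0.6)) ok <- FALSE
      }
      ok
    }, logical(1))
    expect_equal(length(kept), sum(oracle))
    expect_equal(vapply(kept, `[[`, 0L, "rotamer"), which(oracle))
  }
})

test_that("placements are invariant to rigid motion of the scaffold", {
  fx <- open_scaffold(seed = 27)
  lib <- default_rotamer_library()
  pl <- enumerate_placements(fx$scaffold, fx$position, "F", lib)
  set.seed(7)
  R <- cdrpref:::random_rotation()
  shift <- c(5, -3, 2)
  s2 <- fx$scaffold
  xyz <- as.matrix(s2$atoms[, c("x", "y", "z")]) %*% t(R)
  s2$atoms$x <- xyz[, 1L] + shift[1L]
  s2$atoms$y <- xyz[, 2L] + shift[2L]
  s2$atoms$z <- xyz[, 3L] + shift[3L]
  s2 <- cdrpref:::new_structure3d(s2$atoms)
  pl2 <- enumerate_placements(s2, fx$position, "F", lib)
  expect_equal(length(pl2), length(pl))
  for (k in seq_along(pl)) {
    moved <- pl[[k]]$xyz %*% t(R)
    moved <- sweep(moved, 2L, shift, "+")
    expect_equal(unname(pl2[[k]]$xyz), unname(moved), tolerance = 1e-6)
  }
})

test_that("conformation classes follow the half-open phi/psi and chi1 bins", {
  mk <- function(phi, psi) {
    a <- cdrpref:::ideal_backbone_chain(3L, "ALA", "A", phi = phi, psi = psi)
    cdrpref:::new_structure3d(a)
  }
  expect_match(classify_conformation(mk(-60, -45), "A", "2"), "^helix")
  expect_match(classify_conformation(mk(-120, 130), "A", "2"), "^sheet")
  expect_match(classify_conformation(mk(-60, 120), "A", "2"), "^ppii")
  expect_match(classify_conformation(mk(60, 40), "A", "2"), "^left")
  # boundary psi = 0 falls in the lower (bridge) bin, not helix
  expect_match(classify_conformation(mk(-60, 0), "A", "2"), "^bridge")
  # terminal residue: no phi
  expect_equal(classify_conformation(mk(-60, -45), "A", "1"), "unclassified")
  # chi1 binning
  expect_equal(cdrpref:::chi1_bin(-60), "g-")
  expect_equal(cdrpref:::chi1_bin(60), "g+")
  expect_equal(cdrpref:::chi1_bin(180), "t")
  expect_equal(cdrpref:::chi1_bin(0), "g+")   # boundary to the lower bin
  expect_equal(cdrpref:::chi1_bin(-120), "g-")
})

test_that("placements export as a readable multi-model PDB", {
  fx <- open_scaffold(seed = 28)
  lib <- default_rotamer_library()
  pl <- enumerate_placements(fx$scaffold, fx$position, "S", lib)
  tf <- tempfile(fileext = ".pdb")
  write_placements_pdb(pl, tf)
  lines <- readLines(tf)
  expect_equal(sum(grepl("^MODEL", lines)), length(pl))
  expect_true(any(grepl("^ATOM", lines)))
})
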