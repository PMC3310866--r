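# X/Y/Z scoring, rotamer aggregation, contact maps and correlations.

test_that("contact score follows the log10 flooring convention", {
  p_ref <- 1e-10
  maps <- list(t1 = uniform_map(1e-5), t2 = uniform_map(1e-7),
               t3 = uniform_map(0))
  pl <- fake_placement(c("t1", "t2", "t3"),
                       xyz = rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0)))
  # hand arithmetic: 5 + 3 + 0
  expect_equal(contact_score(pl, maps, p_ref), 8)
  # AVE equal to p_ref or floored to 0 contributes nothing
  maps0 <- list(t1 = uniform_map(p_ref), t2 = uniform_map(0),
                t3 = uniform_map(0))
  expect_equal(contact_score(pl, maps0, p_ref), 0)
  expect_error(contact_score(pl, maps[1:2], p_ref), "t3")
})

test_that("X is monotone in the map values", {
  pl <- fake_placement("t1")
  lo <- contact_score(pl, list(t1 = uniform_map(1e-6)))
  hi <- contact_score(pl, list(t1 = uniform_map(1e-5)))
  expect_gt(hi, lo)
})

test_that("hydration score matches a brute-force four-sum oracle", {
  mk <- function(vals) grid3d(c(0, 0, 0), 1, c(5, 1, 1), array(vals, c(5, 1, 1)))
  p_ref <- 1e-10
  wab <- mk(c(1e-4, 1e-6, 0, 0, 0))
  wag <- mk(c(0, 0, 1e-5, 1e-7, 0))
  mab <- mk(c(1, 0, 0, 0, 0))
  mag <- mk(c(0, 0, 0, 0, 1))
  got <- hydration_score(wab, wag, mab, mag, p_ref)
  L <- function(v) log10(pmax(v, p_ref) / p_ref)
  lab <- L(wab$values); lag <- L(wag$values)
  in_ab <- mab$values > 0; in_ag <- mag$values > 0
  ov <- wab$values > p_ref & wag$values > p_ref & !in_ab & !in_ag
  oracle <- -sum(lab[in_ag]) - sum(lag[in_ab]) + sum(lab[ov] + lag[ov])
  expect_equal(got, oracle)
  # both maps zero -> 0
  expect_equal(hydration_score(mk(rep(0, 5)), mk(rep(0, 5)), mab, mag), 0)
  # mirror symmetry: swapping the two sides swaps the desolvation terms
  expect_equal(hydration_score(wab, wag, mab, mag, p_ref),
               hydration_score(wag, wab, mag, mab, p_ref))
  expect_error(hydration_score(wab, uniform_map(0), mab, mag), "match")
})

test_that("structural propensity reproduces direct formula evaluation", {
  aa <- AA20
  p <- setNames(rep(0.05, 20), aa)
  # counts at background frequency with no gaps -> Z = 0
  C0 <- matrix(100 * 0.05, 1, 20, dimnames = list("p1", aa))
  expect_equal(max(abs(structural_propensity(C0, 100, p))), 0)
  # zero count -> deficit
  C1 <- C0; C1[1, "A"] <- 0; C1[1, "R"] <- 10
  expect_lt(structural_propensity(C1, 100, p)[1, "A"], 0)
  # M = 16, B = 4, C = 8, p = 0.05, no gaps: direct hand evaluation
  C2 <- matrix(c(8, rep(8 / 19, 19)), 1, 20, dimnames = list("p1", aa))
  z <- structural_propensity(C2, 16, p, B = 4)[1, 1]
  expect_equal(z, 2 * log2(((8 + 4 * 0.05) / (16 + 4)) / 0.05))
  # gaps: effective counts and pseudo-counts shift accordingly
  C3 <- matrix(0.25, 1, 20, dimnames = list("p1", aa))  # M' = 5, M = 16
  z3 <- structural_propensity(C3, 16, p, B = 4)[1, 1]
  Bp <- 4 + 16 - 5
  expect_equal(z3, 2 * log2(((0.25 + Bp * 0.05) / (5 + Bp)) / 0.05))
  expect_error(structural_propensity(C2, 16, c(0, rep(1 / 19, 19))), "zero")
})

test_that("propensity reduces to the preference form with no gaps and B = sqrt(M)", {
  set.seed(8)
  p <- nnk_background()
  M <- 64
  C <- t(rmultinom(3, M, p))
  colnames(C) <- AA20
  rownames(C) <- paste0("p", 1:3)
  expect_equal(unname(structural_propensity(C, M, p)),
               unname(experimental_preference(C, M, p)$W))
})

scored_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    libp <- make_structure_library(seed = 41, n_structures = 3)
    stp <- collect_interior_contacts(libp$structures, burial_cut = 1.0,
                                     n_points = 92)
    tc <- make_toy_complex(seed = 42, n_residues_a = 6, n_residues_b = 6,
                           interface_gap = 4)
    cx <- assign_atom_types(tc$structure)
    ag <- assign_atom_types(subset_chains(cx, "B"))
    grid <- grid_for_structure(cx, spacing = 1, margin = 7)
    tt <- unique(default_atom_typing()$type)
    tt <- setdiff(tt, "WATER_O")
    maps <- lapply(setNames(tt, tt), function(x)
      build_pdm(ag, x, stp, grid = grid))
    pos <- data.frame(chain = "A", resid = "3")
    scaffold <- build_alanine_scaffold(cx, pos)
    cache <<- list(maps = maps, pos = pos, scaffold = scaffold, grid = grid,
                   ag = ag, stats = stp)
    cache
  }
})

test_that("score_positions aggregates rotamers as max-X and matches recomputation", {
  fx <- scored_fixture()
  lib <- default_rotamer_library()
  types <- c("A", "S", "L", "F")
  st <- score_positions(fx$scaffold, fx$pos, fx$maps, lib, types = types)
  rot <- attr(st, "rotamer_scores")
  for (aa in types) {
    per <- rot[[paste("3-A", aa)]]
    row <- st[st$aa == aa, ]
    expect_equal(row$X, max(per$X))
    expect_equal(row$Y, min(per$Y))
    expect_equal(row$n_rotamers, nrow(per))
    # independent recomputation per rotamer
    pl <- enumerate_placements(fx$scaffold, fx$pos, aa, lib)
    xs <- vapply(pl, contact_score, numeric(1), antigen_maps = fx$maps)
    expect_equal(per$X, xs)
  }
  # single-rotamer type: aggregate equals the single rotamer score
  expect_equal(st$X[st$aa == "A"], rot[["3-A A"]]$X[1L])
  tf <- tempfile(fileext = ".tsv")
  write_score_table_tsv(st, tf)
  expect_equal(nrow(read.delim(tf)), nrow(st))
})

test_that("removing the antigen zeroes all X and blocked positions are flagged", {
  fx <- scored_fixture()
  lib <- default_rotamer_library()
  zero_maps <- lapply(fx$maps, function(m)
    grid3d(m$origin, m$spacing, m$dim))
  st <- score_positions(fx$scaffold, fx$pos, zero_maps, lib,
                        types = c("A", "L", "F"))
  expect_true(all(st$X == 0))
  # a site walled in by blockers has no clash-free bulky rotamer
  s <- fx$scaffold
  sel <- which(s$atoms$chain == "A" & s$atoms$resid == "3" &
                 s$atoms$name == "CB")
  cb <- unlist(s$atoms[sel, c("x", "y", "z")])
  u <- matrix(rnorm(3 * 40), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  blockers <- s$atoms[rep(1L, 40), ]
  blockers$serial <- max(s$atoms$serial) + 1:40
  blockers$chain <- "Z"
  blockers$resno <- 500L + 1:40
  blockers$x <- cb[1] + 2.4 * u[, 1]
  blockers$y <- cb[2] + 2.4 * u[, 2]
  blockers$z <- cb[3] + 2.4 * u[, 3]
  s$atoms <- rbind(s$atoms, blockers)
  s <- cdrpref:::new_structure3d(s$atoms)
  st2 <- score_positions(s, fx$pos, fx$maps, lib, types = c("W"))
  expect_true(st2$excluded[1L])
  expect_equal(st2$X[1L], 0)
  expect_equal(st2$Y[1L], 0)
})

test_that("X ranking over types is invariant to p_ref at or below 1e-10", {
  fx <- scored_fixture()
  lib <- default_rotamer_library()
  types <- c("A", "S", "T", "L", "F", "K", "N", "D")
  st10 <- score_positions(fx$scaffold, fx$pos, fx$maps, lib, types = types,
                          p_ref = 1e-10)
  st12 <- score_positions(fx$scaffold, fx$pos, fx$maps, lib, types = types,
                          p_ref = 1e-12)
  expect_equal(order(-st10$X, st10$aa), order(-st12$X, st12$aa))
})

test_that("Y vanishes for a fully separated complex", {
  wlib <- make_structure_library(seed = 43, n_structures = 3,
                                 planted_offset = c(2.8, 0, 0),
                                 target = list(resname = "HOH", atom = "O"))
  wst <- collect_interior_contacts(wlib$structures, burial_cut = 1.0,
                                   n_points = 92)
  tc <- make_toy_complex(seed = 44, n_residues_a = 5, n_residues_b = 5,
                         interface_gap = 30)
  cx <- assign_atom_types(tc$structure)
  ag <- assign_atom_types(subset_chains(cx, "B"))
  grid <- grid_for_structure(cx, spacing = 1, margin = 7)
  wag <- suppressWarnings(build_water_pdm(ag, wst, grid = grid))
  mask_ag <- volume_mask(ag, grid)
  pos <- data.frame(chain = "A", resid = "3")
  scaffold <- build_alanine_scaffold(cx, pos)
  mask_ab <- volume_mask(subset_chains(scaffold, "A"), grid)
  tt <- unique(default_atom_typing()$type)
  zero_maps <- lapply(setNames(tt, tt), function(x) grid3d(grid$origin, grid$spacing, grid$dim))
  st <- score_positions(scaffold, pos, zero_maps, default_rotamer_library(),
                        types = c("A", "S"), stats = wst, water_map_ag = wag,
                        mask_ab = mask_ab, mask_ag = mask_ag)
  expect_equal(st$Y, c(0, 0))
  expect_equal(st$X, c(0, 0))
})

test_that("antigen contact maps are local and average over models", {
  fx <- scored_fixture()
  lib <- default_rotamer_library()
  pl <- enumerate_placements(fx$scaffold, fx$pos, "F", lib)
  model <- pl[1L]
  got1 <- antigen_contact_map(fx$ag, list(model), fx$maps)
  expect_true(all(got1 >= 0))
  # zero maps -> all zero
  zero_maps <- lapply(fx$maps, function(m) grid3d(m$origin, m$spacing, m$dim))
  expect_equal(antigen_contact_map(fx$ag, list(model), zero_maps),
               rep(0, nrow(fx$ag$atoms)))
  # two identical models average to the single-model strengths
  got2 <- antigen_contact_map(fx$ag, list(model, model), fx$maps)
  expect_equal(got2, got1)
  # locality: only atoms near the placement can score
  axyz <- as.matrix(fx$ag$atoms[, c("x", "y", "z")])
  d <- apply(axyz, 1L, function(p)
    sqrt(min(colSums((t(model[[1L]]$xyz) - p)^2))))
  expect_true(all(got1[d > 6 + 2 * max(fx$ag$atoms$vdw)] == 0))
})

test_that("preference-term correlations hit the exact limiting cases", {
  set.seed(55)
  tab <- data.frame(position = rep(c("p1", "p2"), each = 20),
                    aa = rep(AA20, 2),
                    X = rnorm(40), Y = rnorm(40), Z = 0)
  pref <- data.frame(position = tab$position, aa = tab$aa, W = tab$X)
  cc <- correlate_preferences(tab, pref)
  expect_equal(cc$cc_WX, c(1, 1))
  expect_true(all(is.na(cc$cc_WZ)))  # zero variance in Z
  pref$W <- -tab$Y
  cc2 <- correlate_preferences(tab, pref)
  expect_equal(cc2$cc_WY, c(-1, -1))
})
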