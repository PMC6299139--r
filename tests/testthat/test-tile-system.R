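test_that("edge codes allow at most two absent staples in a row", {
  expect_true(validate_edge_code(c(1, 1, 0, 1, 1, 0, 1, 1, 1))$valid)
  bad <- validate_edge_code(c(1, 0, 0, 0, 1, 1, 1, 1, 1))
  expect_false(bad$valid)
  expect_equal(bad$run_start, 2L)
  expect_equal(bad$run_length, 3L)
  expect_true(validate_edge_code(rep(1, 7))$valid)
  # runs of two are the boundary case; leading/trailing runs count too
  expect_true(validate_edge_code(c(0, 0, 1, 0, 0, 1, 0, 0))$valid)
  expect_false(validate_edge_code(c(1, 1, 1, 0, 0, 0))$valid)
  expect_error(validate_edge_code(integer(0)), "length")
  expect_error(branch_domain_spec(9, c(1, 0, 0, 0, 1, 1, 1, 1, 1)), "invalid")
})

test_that("toehold and branch domain specs enforce their invariants", {
  th <- toehold_spec(4, 2)
  expect_equal(toehold_total_nt(th), 8L)
  expect_equal(toehold_total_nt(toehold_spec(2, 5)), 10L)
  expect_equal(toehold_total_nt(toehold_spec(0, 2)), 0L)
  expect_error(toehold_spec(5, 2), "0..4")
  expect_error(toehold_spec(2, 6), "0..5")
  expect_error(toehold_spec(-1, 2), "0..4")
  bd <- branch_domain_spec()
  expect_equal(bd$n_staples, 7L)
  expect_false(bd$coded)
  coded <- branch_domain_spec(9, c(1, 1, 0, 1, 1, 0, 1, 0, 1))
  expect_true(coded$coded)
  expect_equal(sum(coded$code), 6)
})

test_that("tile types require exactly four edges and valid label placements", {
  expect_error(tile_type("T", list(N = list(), E = list(), S = list())),
               "N, E, S, W")
  expect_error(
    tile_type("T", fluor_mods = list(list(kind = "Z", edge = "N", position = 1))),
    "'F' or 'Q'")
  t1 <- tile_type("T", display_label = "X")
  expect_s3_class(t1, "tile_type")
  expect_equal(names(t1$edges), c("N", "E", "S", "W"))
})

test_that("canonical keys identify equal labeled grids and nothing else", {
  A <- tile_type("A"); B <- tile_type("B")
  mk <- function(tiles) complex_species(tiles, list(
    list(from = c(0L, 0L), to = c(0L, 1L), engages = "b",
         state = bond_state())))
  c1 <- mk(list(list(row = 0L, col = 0L, tile = A),
                list(row = 0L, col = 1L, tile = B)))
  # same grid, different construction order
  c2 <- mk(list(list(row = 0L, col = 1L, tile = B),
                list(row = 0L, col = 0L, tile = A)))
  expect_identical(c1$canonical_key, c2$canonical_key)
  # translation invariance
  c3 <- complex_species(list(list(row = 5L, col = 3L, tile = A),
                             list(row = 5L, col = 4L, tile = B)),
                        list(list(from = c(5L, 3L), to = c(5L, 4L),
                                  engages = "b", state = bond_state())))
  expect_identical(c1$canonical_key, c3$canonical_key)
  # single tile substitution changes the key
  c4 <- mk(list(list(row = 0L, col = 0L, tile = A),
                list(row = 0L, col = 1L, tile = A)))
  expect_false(identical(c1$canonical_key, c4$canonical_key))
  expect_error(complex_species(list(list(row = 0L, col = 0L, tile = A),
                                    list(row = 0L, col = 0L, tile = B))),
               "two tiles")
  expect_error(
    complex_species(list(list(row = 0L, col = 0L, tile = A),
                         list(row = 2L, col = 0L, tile = B)),
                    list(list(from = c(0L, 0L), to = c(2L, 0L),
                              engages = "b", state = bond_state()))),
    "non-adjacent")
})

test_that("bond states stay within their migration range", {
  expect_error(bond_state(branch_position = 2, n_segments = 1), "\\[0, 1\\]")
  expect_error(bond_state(segment_class = "corner", n_segments = 3),
               "exactly 1")
  b <- bond_state(TRUE, 1L, "edge", 1L)
  expect_equal(b$branch_position, 1L)
})

test_that("toehold accessibility is structural: free, covered, revealed", {
  sys <- make_basic_displacement(4, 2)
  ctbt <- sys$species[["CT:BT2"]]$complex
  # toehold staples on the bound edge are not engaged by the cover tile
  expect_true(toehold_accessible(ctbt, c(0, 0), "E"))
  expect_error(toehold_accessible(ctbt, c(3, 3), "E"), "no tile")
  expect_error(toehold_accessible(ctbt, c(0, 1), "N"), "no toehold")
  # sequential array: step-2 toehold is sequestered until step 1 completes
  seq_sys <- make_sequential()
  A0 <- seq_sys$species[["T1a2a34"]]$complex
  A1 <- seq_sys$species[["T1b2a34"]]$complex
  expect_false(toehold_accessible(A0, c(0, 1), "W"))
  expect_true(toehold_accessible(A1, c(0, 1), "W"))
  # outer-edge toehold of the array is accessible from the start
  expect_true(toehold_accessible(A0, c(0, 1), "N"))
})

test_that("presets build valid systems at the documented concentrations", {
  systems <- list(make_basic_displacement(4, 2), make_competitive(),
                  make_sequential(), make_cooperative(TRUE),
                  make_3x3("corner"), make_3x3("edge"), make_3x3("center"),
                  make_2x2_selfassembly(TRUE))
  for (sys in systems) {
    concs <- vapply(sys$species, function(s) s$conc_nM, numeric(1))
    expect_true(all(concs >= 0), label = sys$preset)
  }
  b <- make_basic_displacement(4, 2)
  expect_equal(b$species[["CT:BT2"]]$conc_nM, 2)   # 1x arrays
  expect_equal(b$species[["Inv24"]]$conc_nM, 4)    # 2x invaders
  x3 <- make_3x3("corner")
  expect_equal(x3$species[["T1-9"]]$conc_nM, 4)
  expect_equal(x3$species[["Inv_corner"]]$conc_nM, 8)
  expect_equal(toehold_total_nt(x3$pathways[[1]]$toeholds[[1]]), 10L)
  co <- make_cooperative()
  expect_equal(toehold_total_nt(co$pathways[[1]]$toeholds[[1]]), 6L)
})

test_that("basic preset rejects out-of-range toehold requests", {
  expect_error(make_basic_displacement(5, 2), "0..4")
  expect_error(make_basic_displacement(2, 5), "3x3")
  expect_error(make_basic_displacement(2, 0), "1..2")
})

test_that("zero-toehold basic preset is leak-only", {
  sys <- make_basic_displacement(0, 1)
  expect_length(sys$pathways, 0)
  expect_length(sys$leaks, 1)
})

test_that("3x3 migration path lengths match the geometry exactly", {
  expect_length(make_3x3("corner")$pathways[[1]]$segments, 2)  # 1 edge + 1 corner
  segs <- make_3x3("edge")$pathways[[1]]$segments
  expect_length(segs, 5)                                       # 3 edges + 2 corners
  expect_equal(vapply(segs, `[[`, character(1), "class"),
               c("edge", "corner", "edge", "corner", "edge"))
  expect_true(all(vapply(segs, `[[`, logical(1), "coded")))
  expect_equal(make_3x3("center")$pathways[[1]]$mode, "center")
  expect_error(make_3x3("diagonal"))
})

test_that("sequential preset exposes the first-displaced-tile choice", {
  alt <- make_sequential(first_replaces = "T2a")
  expect_true("T2b" %in% names(alt$species))
  expect_length(alt$pathways, 2)
  # same network shape as the default geometry
  p <- default_rate_params()
  expect_equal(length(enumerate_network(alt, p)$reactions),
               length(enumerate_network(make_sequential(), p)$reactions))
})

test_that("system specs reject inconsistent inputs", {
  expect_error(make_basic_displacement(4, 2, complex_nM = -1), "negative")
  sys <- make_basic_displacement(4, 2)
  bad_dose <- data.frame(time_s = c(100, 50), species = "Inv24",
                         add_nM = c(1, 1))
  expect_error(system_spec(sys$species, sys$pathways, dosing = bad_dose),
               "nondecreasing")
})

test_that("system specifications round-trip through JSON identically", {
  for (sys in list(make_sequential(), make_2x2_selfassembly(TRUE),
                   make_basic_displacement(3, 1))) {
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    write_system_spec(sys, f1)
    s2 <- read_system_spec(f1)
    write_system_spec(s2, f2)
    expect_identical(readLines(f1), readLines(f2), label = sys$preset)
    # and the reloaded system enumerates to the identical network
    p <- default_rate_params()
    expect_identical(format_network(enumerate_network(s2, p)),
                     format_network(enumerate_network(sys, p)))
  }
})
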