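#' Declarative tile-displacement system specification
#'
#' A `system_spec` lists the starting and producible species (multi-tile
#' complexes with tile compositions and initial concentrations in nM), the
#' displacement pathways that connect them (toehold, ordered migration
#' segments, products), spurious leak channels, any extra mass-action
#' reactions, fluorescence observables, and an optional dosing schedule.
#' [enumerate_network()] expands it into a full reaction network.
#'
#' @param species Named list of species entries created with [species_entry()].
#' @param pathways List of [displacement_pathway()] objects.
#' @param leaks List of zero-toehold leak channels, each
#'   `list(name =, invader =, target =, products = c(key, key))`.
#' @param extra_reactions List of raw reactions, each `list(reactants =
#'   c(key = stoich), products = c(key = stoich), class =, rate_rule =,
#'   multiplicity =)`.
#' @param observables List of observables: either `list(name =, type =
#'   "fluor", fluor_tile =, quench_tile =)` (completion = unquenched
#'   fluorophore fraction) or `list(name =, type = "tile_fraction", tile =,
#'   numerator = keys)`.
#' @param dosing Data frame with columns `time_s`, `species`, `add_nM`
#'   (instantaneous additions; times must be nondecreasing).
#' @param preset Name of the generating preset, for reports.
#' @return An object of class `system_spec`.
#' @export
system_spec <- function(species, pathways = list(), leaks = list(),
                        extra_reactions = list(), observables = list(),
                        dosing = NULL, preset = "custom") {
  if (is.null(dosing))
    dosing <- data.frame(time_s = numeric(0), species = character(0),
                         add_nM = numeric(0))
  keys <- vapply(species, function(s) s$key, character(1))
  if (anyDuplicated(keys)) stop("duplicate species keys")
  names(species) <- keys
  for (s in species) {
    if (s$conc_nM < 0) stop("negative initial concentration for ", s$key)
  }
  if (is.unsorted(dosing$time_s)) stop("dosing times must be nondecreasing")
  if (!all(dosing$species %in% keys))
    stop("dosing references unknown species")
  comp_of <- function(k) species[[k]]$composition
  for (p in pathways) {
    refs <- c(p$invaders, p$target, p$bound_product, p$released)
    if (!all(refs %in% keys))
      stop("pathway '", p$name, "' references unknown species")
    lhs <- .comp_sum(lapply(c(p$invaders, p$target), comp_of))
    rhs <- .comp_sum(lapply(c(p$bound_product, p$released), comp_of))
    if (!isTRUE(all.equal(lhs[sort(names(lhs))],
                          rhs[sort(names(rhs))])))
      stop("pathway '", p$name, "' does not conserve tile counts")
  }
  for (l in leaks) {
    if (!all(c(l$invader, l$target, l$products) %in% keys))
      stop("leak '", l$name, "' references unknown species")
  }
  structure(list(species = species, pathways = pathways, leaks = leaks,
                 extra_reactions = extra_reactions, observables = observables,
                 dosing = dosing, temperature_C = 25, preset = preset),
            class = "system_spec")
}

.comp_sum <- function(comps) {
  all_tiles <- unique(unlist(lapply(comps, names)))
  out <- stats::setNames(numeric(length(all_tiles)), all_tiles)
  for (cc in comps) out[names(cc)] <- out[names(cc)] + cc
  out[out != 0]
}

#' Species entry of a system specification
#'
#' @param key Stable species key (colons mark multi-tile complexes).
#' @param composition Named integer vector of tile-type copy counts.
#' @param conc_nM Initial concentration, nM (>= 0).
#' @param complex Optional [complex_species()] grid for structural checks.
#' @return A list describing the species.
#' @export
species_entry <- function(key, composition, conc_nM = 0, complex = NULL) {
  stopifnot(is.numeric(composition), !is.null(names(composition)))
  list(key = key, composition = composition, conc_nM = conc_nM,
       complex = complex)
}

#' Displacement pathway descriptor
#'
#' One toehold-initiated displacement: the invader binds the target through
#' the toehold, branch-migrates through the ordered segment list, and
#' irreversibly releases the displaced complex. Three modes are supported:
#' `"linear"` (a single chain of migration segments), `"center"` (four
#' independent, order-free edge disconnections of a fully surrounded tile;
#' release requires all four), and `"cooperative"` (two invaders that each
#' reversibly half-migrate and jointly release the displaced pair).
#'
#' @param name Pathway name (provenance).
#' @param invaders Character vector of invader species keys (length 1, or 2
#'   for cooperative pathways).
#' @param target Target complex species key.
#' @param toeholds List of [toehold_spec()], one per invader.
#' @param segments For `"linear"`: ordered list of `list(class, coded)`.
#'   For `"center"`: the per-edge segment (one entry, applied to each of the
#'   four edges). For `"cooperative"`: list of two per-side segment lists.
#' @param bound_product Key of the reconfigured array.
#' @param released Key of the released complex.
#' @param mode `"linear"`, `"center"` or `"cooperative"`.
#' @param toehold_site Optional `list(at = c(row, col), edge =)` locating the
#'   (first) toehold on the target's grid; when the target carries a grid,
#'   [enumerate_network()] verifies the toehold is accessible there.
#' @param bind_multiplicity Combinatorial factor on the binding step.
#' @return An object of class `displacement_pathway`.
#' @export
displacement_pathway <- function(name, invaders, target, toeholds, segments,
                                 bound_product, released,
                                 mode = c("linear", "center", "cooperative"),
                                 toehold_site = NULL, bind_multiplicity = 1L) {
  mode <- match.arg(mode)
  if (inherits(toeholds, "toehold_spec")) toeholds <- list(toeholds)
  n_inv <- if (mode == "cooperative") 2L else 1L
  if (length(invaders) != n_inv || length(toeholds) != n_inv)
    stop("pathway '", name, "': expected ", n_inv, " invader(s)/toehold(s)")
  structure(list(name = name, mode = mode, invaders = invaders,
                 target = target, toeholds = toeholds, segments = segments,
                 bound_product = bound_product, released = released,
                 toehold_site = toehold_site,
                 bind_multiplicity = as.integer(bind_multiplicity)),
            class = "displacement_pathway")
}

# ---------------------------------------------------------------------------
# shared tile-building helpers for the presets

.tile <- function(name, ..., display = "plain", fluor = NULL) {
  edges <- list(N = list(), E = list(), S = list(), W = list())
  dots <- list(...)
  for (e in names(dots)) edges[[e]] <- dots[[e]]
  tile_type(name, edges, display_label = display, fluor_mods = fluor)
}

.seg <- function(class = "edge", coded = FALSE) list(class = class, coded = coded)

# ---------------------------------------------------------------------------

#' Basic tile displacement preset
#'
#' One cover:base complex (CT:BTx, 1x = 2 nM) plus an invader at 2x = 4 nM
#' whose toehold has `y` staples (0--4) with `x`-nt sticky ends (1--2). The
#' base tile carries the fluorophore and the cover tile the quencher, so the
#' completion observable is the fraction of cover tiles released. With a
#' zero-strength toehold (`y = 0`), the only channel is the zero-toehold
#' leak.
#'
#' @param y Invader toehold staple count, 0--4.
#' @param x Sticky-end length, 1--2 nt (use [make_3x3()] for 5-nt toeholds).
#' @param complex_nM,invader_nM Initial concentrations.
#' @return A [system_spec()].
#' @examples
#' sys <- make_basic_displacement(4, 2)
#' net <- enumerate_network(sys, default_rate_params())
#' length(net$reactions)  # 3: bind, dissociate, displace
#' @export
make_basic_displacement <- function(y, x, complex_nM = 2, invader_nM = 4) {
  y <- as.integer(y); x <- as.integer(x)
  if (is.na(y) || y < 0L || y > 4L) stop("y (toehold staples) must be in 0..4")
  if (is.na(x) || x < 1L || x > 2L)
    stop("x (sticky nt) must be in 1..2 for the basic preset; ",
         "5-nt toeholds belong to the 3x3 systems (make_3x3)")
  bt <- paste0("BT", x)
  inv <- paste0("Inv", x, y)
  th_recv <- toehold_spec(4L, x, "receiving", "t")
  th_give <- toehold_spec(y, x, "giving", "t")
  BT <- .tile(bt, E = list(th_recv, branch_domain_spec(label = "b")),
              fluor = list(list(kind = "F", edge = "E", position = 2L)))
  CT <- .tile("CT", W = list(branch_domain_spec(label = "b")), display = "O",
              fluor = list(list(kind = "Q", edge = "W", position = 1L)))
  IN <- .tile(inv, W = list(th_give, branch_domain_spec(label = "b")),
              display = "X")
  ctbt <- complex_species(
    tiles = list(list(row = 0L, col = 0L, tile = BT),
                 list(row = 0L, col = 1L, tile = CT)),
    bonds = list(list(from = c(0L, 0L), to = c(0L, 1L), engages = "b",
                      state = bond_state(toehold_bound = FALSE))))
  invbt <- complex_species(
    tiles = list(list(row = 0L, col = 0L, tile = BT),
                 list(row = 0L, col = 1L, tile = IN)),
    bonds = list(list(from = c(0L, 0L), to = c(0L, 1L), engages = c("b", "t"),
                      state = bond_state(TRUE, 1L, "edge", 1L))))
  species <- list(
    species_entry(inv, c(stats::setNames(1, inv)), invader_nM),
    species_entry(paste0("CT:", bt), stats::setNames(c(1, 1), c("CT", bt)),
                  complex_nM, complex = ctbt),
    species_entry(paste0(inv, ":", bt), stats::setNames(c(1, 1), c(inv, bt)),
                  0, complex = invbt),
    species_entry("CT", c(CT = 1), 0))
  pathways <- list()
  leaks <- list()
  if (toehold_total_nt(th_give) > 0L) {
    pathways <- list(displacement_pathway(
      name = sprintf("displace_y%d_x%d", y, x),
      invaders = inv, target = paste0("CT:", bt), toeholds = th_give,
      segments = list(.seg("edge")),
      bound_product = paste0(inv, ":", bt), released = "CT",
      toehold_site = list(at = c(0L, 0L), edge = "E")))
  } else {
    leaks <- list(list(name = "zero_toehold_leak", invader = inv,
                       target = paste0("CT:", bt),
                       products = c(paste0(inv, ":", bt), "CT")))
  }
  system_spec(species, pathways, leaks,
              observables = list(list(name = "completion", type = "fluor",
                                      fluor_tile = bt, quench_tile = "CT")),
              preset = sprintf("basic:y%dx%d", y, x))
}

#' Competitive tile displacement preset
#'
#' One invader pool (2-nt 4-staple giving toehold) shared by two
#' cover:base complexes: CT:BT2 with a matching 2-nt receiving toehold (the
#' fast pathway, rate k_f) and CT:BT1 with a 1-nt receiving toehold (the
#' slow pathway, rate k_s; the invader's extra nucleotide dangles
#' inconsequentially). Both complexes start at 1x = 2 nM and carry distinct
#' fluorophores, so the two products are monitored simultaneously; the fast
#' reaction thresholds the slow one at the fast complex's concentration.
#'
#' @param invader_multiple Invader concentration as a multiple of 1x.
#' @param fast_nM,slow_nM Complex concentrations (1x = 2 nM each).
#' @return A [system_spec()] with observables `"fast"` and `"slow"`.
#' @export
make_competitive <- function(invader_multiple = 2, fast_nM = 2, slow_nM = 2) {
  if (invader_multiple < 0) stop("invader_multiple must be >= 0")
  species <- list(
    species_entry("Inv", c(Inv = 1), invader_multiple * 2),
    species_entry("CT:BT1", c(CT = 1, BT1 = 1), slow_nM),
    species_entry("CT:BT2", c(CT = 1, BT2 = 1), fast_nM),
    species_entry("Inv:BT1", c(Inv = 1, BT1 = 1), 0),
    species_entry("Inv:BT2", c(Inv = 1, BT2 = 1), 0),
    species_entry("CT", c(CT = 1), 0))
  pathways <- list(
    displacement_pathway("fast_2nt4st", "Inv", "CT:BT2",
                         toehold_spec(4L, 2L, "giving", "t2"),
                         list(.seg("edge")), "Inv:BT2", "CT"),
    displacement_pathway("slow_1nt4st", "Inv", "CT:BT1",
                         toehold_spec(4L, 1L, "giving", "t1"),
                         list(.seg("edge")), "Inv:BT1", "CT"))
  system_spec(species, pathways,
              observables = list(
                list(name = "fast", type = "fluor", fluor_tile = "BT2",
                     quench_tile = "CT"),
                list(name = "slow", type = "fluor", fluor_tile = "BT1",
                     quench_tile = "CT")),
              preset = "competitive")
}

# builds the sequential 2x2 grids; step-2 toehold "s" on T2a's W edge is
# engaged by T1a in the initial array and free once T1b has replaced it.
.sequential_grids <- function() {
  T1a <- .tile("T1a",
               E = list(toehold_spec(4L, 2L, "giving", "s"),
                        branch_domain_spec(label = "b12")),
               S = list(branch_domain_spec(label = "b13")))
  T1b <- .tile("T1b",
               E = list(branch_domain_spec(label = "b12")),
               S = list(branch_domain_spec(label = "b13")),
               W = list(toehold_spec(4L, 2L, "receiving", "u")))
  T2a <- .tile("T2a",
               W = list(toehold_spec(4L, 2L, "receiving", "s"),
                        branch_domain_spec(label = "b12")),
               S = list(branch_domain_spec(label = "b24")),
               N = list(toehold_spec(4L, 2L, "receiving", "u")))
  T3 <- .tile("T3", N = list(branch_domain_spec(label = "b13")),
              E = list(branch_domain_spec(label = "b34")),
              fluor = list(list(kind = "F", edge = "E", position = 1L)))
  T4 <- .tile("T4", N = list(branch_domain_spec(label = "b24")),
              W = list(branch_domain_spec(label = "b34")),
              fluor = list(list(kind = "Q", edge = "W", position = 1L)))
  grid <- function(t00) complex_species(
    tiles = list(list(row = 0L, col = 0L, tile = t00),
                 list(row = 0L, col = 1L, tile = T2a),
                 list(row = 1L, col = 0L, tile = T3),
                 list(row = 1L, col = 1L, tile = T4)),
    bonds = list(
      list(from = c(0L, 0L), to = c(0L, 1L),
           engages = if (identical(t00$name, "T1a")) c("b12", "s") else "b12",
           state = bond_state()),
      list(from = c(0L, 0L), to = c(1L, 0L), engages = "b13", state = bond_state()),
      list(from = c(0L, 1L), to = c(1L, 1L), engages = "b24", state = bond_state()),
      list(from = c(1L, 0L), to = c(1L, 1L), engages = "b34", state = bond_state())))
  list(A0 = grid(T1a), A1 = grid(T1b))
}

#' Sequential (cascaded) tile displacement preset
#'
#' A 2x2 array (1x = 2 nM) in which a first invader tile displaces one tile
#' while revealing a previously sequestered toehold, after which a second,
#' two-tile invader displaces two tiles as a pair. Both displacement paths
#' cross a tile corner (edge-corner-edge). The fluorophore/quencher pair
#' sits at the end of the second branch-migration domain, so the observable
#' reports completion of the full cascade. The second invader can also
#' attack the original array through a zero-toehold leak channel, which is
#' what bounds the cascade-free spurious signal.
#'
#' Species names follow the T1a2a34-style convention (colons omitted):
#' the initial array `T1a2a34` is T1a:T2a:T3:T4.
#'
#' @param first_invader,second_invader Include each invader (at 2x = 4 nM)?
#' @param array_nM Initial array concentration.
#' @param first_replaces Which corner tile the first invader replaces
#'   (`"T1a"` or, by symmetry of the 2x2 geometry, `"T2a"`; the kinetics are
#'   identical, only species names change).
#' @return A [system_spec()].
#' @export
make_sequential <- function(first_invader = TRUE, second_invader = TRUE,
                            array_nM = 2, first_replaces = c("T1a", "T2a")) {
  first_replaces <- match.arg(first_replaces)
  key_of <- function(tiles) paste0("T", paste(sub("^T", "", tiles), collapse = ""))
  comp_of <- function(tiles) stats::setNames(rep(1, length(tiles)), tiles)
  if (first_replaces == "T1a") {
    first_old <- "T1a"; first_new <- "T1b"
    pair_old <- c("T2a", "T4"); pair_new <- c("T2b", "T4b")
    f_tile <- "T3"; q_tile <- "T4"
    g <- .sequential_grids()
  } else {
    first_old <- "T2a"; first_new <- "T2b"
    pair_old <- c("T1a", "T3"); pair_new <- c("T1b", "T3b")
    f_tile <- "T4"; q_tile <- "T3"
    g <- list(A0 = NULL, A1 = NULL)  # mirrored geometry; kinetics identical
  }
  arr0 <- c("T1a", "T2a", "T3", "T4")
  arr1 <- sort(c(setdiff(arr0, first_old), first_new))
  arr2 <- sort(c(setdiff(arr1, pair_old), pair_new))
  spur <- sort(c(setdiff(arr0, pair_old), pair_new))
  species <- list(
    species_entry(key_of(arr0), comp_of(arr0), array_nM, complex = g$A0),
    species_entry(first_new, comp_of(first_new), if (first_invader) 4 else 0),
    species_entry(key_of(pair_new), comp_of(pair_new),
                  if (second_invader) 4 else 0),
    species_entry(key_of(arr1), comp_of(arr1), 0, complex = g$A1),
    species_entry(first_old, comp_of(first_old), 0),
    species_entry(key_of(arr2), comp_of(arr2), 0),
    species_entry(key_of(pair_old), comp_of(pair_old), 0),
    species_entry(key_of(spur), comp_of(spur), 0))
  site1 <- if (first_replaces == "T1a") list(at = c(0L, 1L), edge = "N")
  site2 <- if (first_replaces == "T1a") list(at = c(0L, 1L), edge = "W")
  pathways <- list(
    displacement_pathway("step1_single_tile", first_new, key_of(arr0),
                         toehold_spec(4L, 2L, "giving", "u"),
                         list(.seg("edge"), .seg("corner"), .seg("edge")),
                         key_of(arr1), first_old, toehold_site = site1),
    displacement_pathway("step2_two_tile", key_of(pair_new), key_of(arr1),
                         toehold_spec(4L, 2L, "giving", "s"),
                         list(.seg("edge"), .seg("corner"), .seg("edge")),
                         key_of(arr2), key_of(pair_old), toehold_site = site2))
  leaks <- list(list(name = "spurious_step2_on_unreacted_array",
                     invader = key_of(pair_new), target = key_of(arr0),
                     products = c(key_of(spur), key_of(pair_old))))
  system_spec(species, pathways, leaks,
              observables = list(list(name = "completion", type = "fluor",
                                      fluor_tile = f_tile,
                                      quench_tile = q_tile)),
              preset = "sequential")
}

#' Cooperative tile displacement preset
#'
#' Two invader tiles, each with a 2-nt 3-staple toehold (fast-binding yet
#' dissociable), bind opposite sides of a 2x2 array and each reversibly
#' branch-migrates halfway toward the center. Only when both invaders are
#' half-migrated can the displaced two-tile pair be released, making the
#' reconfiguration an AND gate on the two invaders: the release flux is
#' structurally zero with a single invader. Optionally the spurious
#' invader-invader dimerization observed by AFM is included as a dead-end
#' channel that depresses completion.
#'
#' @param include_dimerization Add the Inv1 + Inv2 -> dimer channel?
#' @param array_nM Array concentration (1x = 2 nM).
#' @param inv1_nM,inv2_nM Invader concentrations (2x = 4 nM; set one to 0
#'   for single-invader controls).
#' @return A [system_spec()].
#' @export
make_cooperative <- function(include_dimerization = FALSE, array_nM = 2,
                             inv1_nM = 4, inv2_nM = 4) {
  species <- list(
    species_entry("T1234", c(T1 = 1, T2 = 1, T3 = 1, T4 = 1), array_nM),
    species_entry("I1", c(I1 = 1), inv1_nM),
    species_entry("I2", c(I2 = 1), inv2_nM),
    species_entry("T1:I1:T3:I2", c(T1 = 1, I1 = 1, T3 = 1, I2 = 1), 0),
    species_entry("T2:T4", c(T2 = 1, T4 = 1), 0))
  extra <- list()
  if (include_dimerization) {
    species <- c(species, list(species_entry("I1:I2", c(I1 = 1, I2 = 1), 0)))
    extra <- list(list(reactants = c(I1 = 1, I2 = 1),
                       products = c(`I1:I2` = 1),
                       class = "dimerize",
                       rate_rule = list(kind = "dimer"),
                       multiplicity = 1L))
  }
  pathways <- list(displacement_pathway(
    "cooperative_pair", invaders = c("I1", "I2"), target = "T1234",
    toeholds = list(toehold_spec(3L, 2L, "giving", "c1"),
                    toehold_spec(3L, 2L, "giving", "c2")),
    segments = list(list(.seg("edge")), list(.seg("edge"))),
    bound_product = "T1:I1:T3:I2", released = "T2:T4",
    mode = "cooperative"))
  system_spec(species, pathways, extra_reactions = extra,
              observables = list(list(name = "completion", type = "fluor",
                                      fluor_tile = "T3", quench_tile = "T4")),
              preset = "cooperative")
}

#' 3x3 array displacement presets (corner, edge, center)
#'
#' A 3x3 array at 4 nM with one invader at 8 nM, using 5-nt 2-staple
#' toeholds (10 nt total, comparable in strength to 2-nt 4-staple) and coded
#' branch migration domains (6 of 9 staples). The three reaction types
#' differ in their migration paths:
#'
#' * `corner`: one coded edge then one corner crossing (2 segments);
#' * `edge`: three coded edges across two corners (5 segments);
#' * `center`: four independent toehold-initiated edge disconnections of the
#'   fully surrounded center tile; the old center is released only when all
#'   four of its edges have been disconnected.
#'
#' Because corners are the slowest migration steps, the center reaction
#' (no corners) is the fastest and the edge reaction (two corners) the
#' slowest.
#'
#' @param reaction `"corner"`, `"edge"` or `"center"`.
#' @param array_nM,invader_nM Concentrations (tic-tac-toe scale: 1x = 4 nM,
#'   invaders 2x).
#' @param dosing Optional dosing schedule (e.g. one move per 24 h).
#' @return A [system_spec()].
#' @export
make_3x3 <- function(reaction = c("corner", "edge", "center"),
                     array_nM = 4, invader_nM = 8, dosing = NULL) {
  reaction <- match.arg(reaction)
  toe <- toehold_spec(2L, 5L, "giving", paste0("g_", reaction))
  arr_tiles <- stats::setNames(rep(1, 9), paste0("T", 1:9))
  displaced <- switch(reaction, corner = "T3", edge = "T2", center = "T5")
  invader <- paste0("Inv_", reaction)
  prod_tiles <- arr_tiles[setdiff(names(arr_tiles), displaced)]
  prod_comp <- c(prod_tiles, stats::setNames(1, invader))
  prod_key <- paste0("Array_", reaction)
  species <- list(
    species_entry("T1-9", arr_tiles, array_nM),
    species_entry(invader, stats::setNames(1, invader), invader_nM),
    species_entry(prod_key, prod_comp, 0),
    species_entry(displaced, stats::setNames(1, displaced), 0))
  segs <- switch(reaction,
    corner = list(.seg("edge", TRUE), .seg("corner", TRUE)),
    edge = list(.seg("edge", TRUE), .seg("corner", TRUE), .seg("edge", TRUE),
                .seg("corner", TRUE), .seg("edge", TRUE)),
    center = list(.seg("edge", TRUE)))
  pw <- displacement_pathway(
    name = paste0(reaction, "_displacement"),
    invaders = invader, target = "T1-9", toeholds = toe,
    segments = segs, bound_product = prod_key, released = displaced,
    mode = if (reaction == "center") "center" else "linear",
    bind_multiplicity = if (reaction == "center") 4L else 1L)
  system_spec(species, list(pw), dosing = dosing,
              observables = list(list(name = "completion", type = "fluor",
                                      fluor_tile = "T6",
                                      quench_tile = displaced)),
              preset = paste0("3x3:", reaction))
}

#' 2x2 self-assembly preset with displacement-resolved kinetic traps
#'
#' Coarse species-level bookkeeping of four rotated copies of one tile type
#' self-assembling into 2x2 arrays: monomer M, dimer D, trimer Tr and
#' tetramer Q, with irreversible binding M+M->D, M+D->Tr, M+Tr->Q, D+D->Q.
#' Without displacement, trimers are a kinetic trap (no monomers remain to
#' complete them). With displacement enabled, D+Tr->Q+M and Tr+Tr->Q+D
#' resolve the traps so that all tiles eventually reach tetramers. Binding
#' multiplicities (number of distinct ways to form each product) are
#' explicit integer factors on the rate constants.
#'
#' @param allow_displacement Include the two displacement reactions?
#' @param monomer_nM Initial monomer concentration.
#' @return A [system_spec()] whose `"tetramer_fraction"` observable is the
#'   fraction of all tiles residing in complete 2x2 arrays.
#' @export
make_2x2_selfassembly <- function(allow_displacement = TRUE, monomer_nM = 10) {
  species <- list(
    species_entry("M", c(T = 1), monomer_nM),
    species_entry("D", c(T = 2), 0),
    species_entry("Tr", c(T = 3), 0),
    species_entry("Q", c(T = 4), 0))
  bind_rule <- list(kind = "bind", sticky = 2L)
  disp_rule <- list(kind = "fixed_bi", value = 1e3)
  rxns <- list(
    list(reactants = c(M = 2), products = c(D = 1), class = "assembly_bind",
         rate_rule = bind_rule, multiplicity = 2L),
    list(reactants = c(M = 1, D = 1), products = c(Tr = 1),
         class = "assembly_bind", rate_rule = bind_rule, multiplicity = 2L),
    list(reactants = c(M = 1, Tr = 1), products = c(Q = 1),
         class = "assembly_bind", rate_rule = bind_rule, multiplicity = 1L),
    list(reactants = c(D = 2), products = c(Q = 1), class = "assembly_bind",
         rate_rule = bind_rule, multiplicity = 1L))
  if (allow_displacement) {
    rxns <- c(rxns, list(
      list(reactants = c(D = 1, Tr = 1), products = c(Q = 1, M = 1),
           class = "displacement_swap", rate_rule = disp_rule,
           multiplicity = 2L),
      list(reactants = c(Tr = 2), products = c(Q = 1, D = 1),
           class = "displacement_swap", rate_rule = disp_rule,
           multiplicity = 2L)))
  }
  system_spec(species, extra_reactions = rxns,
              observables = list(list(name = "tetramer_fraction",
                                      type = "tile_fraction", tile = "T",
                                      numerator = "Q")),
              preset = "selfassembly")
}

#' @export
print.system_spec <- function(x, ...) {
  cat(sprintf("<system_spec '%s'>: %d species, %d pathway(s), %d leak(s), %d extra reaction(s)\n",
              x$preset, length(x$species), length(x$pathways),
              length(x$leaks), length(x$extra_reactions)))
  for (s in x$species)
    cat(sprintf("  %-14s %6.3g nM  [%s]\n", s$key, s$conc_nM,
                paste(names(s$composition), collapse = ",")))
  invisible(x)
}
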