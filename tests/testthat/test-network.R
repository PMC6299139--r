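test_that("the basic displacement network is the hand-enumerated three-step model", {
  p <- default_rate_params()
  net <- enumerate_network(make_basic_displacement(4, 2), p)
  expect_setequal(net$species$key,
                  c("Inv24", "CT:BT2", "Inv24~CT:BT2@0", "Inv24:BT2", "CT"))
  expect_length(net$reactions, 3)
  cls <- vapply(net$reactions, function(r) r$rxn_class, character(1))
  expect_setequal(cls, c("toehold_bind", "toehold_dissociate", "release"))
  rates <- vapply(net$reactions, function(r) r$rate, numeric(1))
  names(rates) <- cls
  expect_equal(rates[["toehold_bind"]], k_bind(p, 2))
  expect_equal(rates[["toehold_dissociate"]], k_dissociation(8, p))
  expect_equal(rates[["release"]], p$k_disp_per_s)
})

test_that("a zero-toehold invader with leak disabled yields no reactions", {
  p <- default_rate_params()
  net <- enumerate_network(make_basic_displacement(0, 1), p,
                           include_leak = FALSE)
  expect_length(net$reactions, 0)
  net_leak <- enumerate_network(make_basic_displacement(0, 1), p)
  expect_length(net_leak$reactions, 1)
  expect_equal(net_leak$reactions[[1]]$rxn_class, "displacement_swap")
  expect_equal(net_leak$reactions[[1]]$rate, p$k_leak_per_M_s)
})

test_that("every generated reaction conserves tile-type counts", {
  p <- default_rate_params()
  systems <- list(make_basic_displacement(4, 2), make_competitive(),
                  make_sequential(), make_cooperative(TRUE),
                  make_3x3("corner"), make_3x3("edge"), make_3x3("center"),
                  make_2x2_selfassembly(TRUE))
  for (sys in systems)
    expect_true(check_tile_conservation(enumerate_network(sys, p)),
                label = sys$preset)
})

test_that("binds pair with dissociates and migration steps with reversals", {
  p <- default_rate_params()
  for (sys in list(make_sequential(), make_cooperative(),
                   make_3x3("edge"), make_3x3("center"))) {
    net <- enumerate_network(sys, p)
    sig <- function(r) paste(paste(names(r$reactants), collapse = "+"),
                             paste(names(r$products), collapse = "+"),
                             sep = ">")
    rev_sig <- function(r) paste(paste(names(r$products), collapse = "+"),
                                 paste(names(r$reactants), collapse = "+"),
                                 sep = ">")
    cls <- vapply(net$reactions, function(r) r$rxn_class, character(1))
    fwd <- vapply(net$reactions, sig, character(1))
    for (i in which(cls == "toehold_bind"))
      expect_true(rev_sig(net$reactions[[i]]) %in%
                    fwd[cls == "toehold_dissociate"], label = sys$preset)
    for (i in which(cls == "branch_step_forward"))
      expect_true(rev_sig(net$reactions[[i]]) %in%
                    fwd[cls == "branch_step_backward"], label = sys$preset)
  }
})

test_that("enumeration is deterministic: identical inputs, identical bytes", {
  p <- default_rate_params()
  for (sys in list(make_sequential(), make_cooperative(TRUE))) {
    a <- format_network(enumerate_network(sys, p))
    b <- format_network(enumerate_network(sys, p))
    expect_identical(a, b)
  }
})

test_that("center-tile release happens only from the all-disconnected state", {
  p <- default_rate_params()
  net <- enumerate_network(make_3x3("center"), p)
  rel <- Filter(function(r) r$rxn_class == "release", net$reactions)
  expect_length(rel, 1)
  expect_match(names(rel[[1]]$reactants), "@d4$")
  # disconnection multiplicities count the remaining connected edges
  fwd <- Filter(function(r) r$rxn_class == "branch_step_forward",
                net$reactions)
  mult <- sort(vapply(fwd, function(r) r$multiplicity, integer(1)))
  expect_equal(mult, 1:4)
})

test_that("reachability encodes sequestering and cooperative AND structure", {
  p <- default_rate_params()
  # cooperative with one invader: the released product is unreachable
  co <- enumerate_network(make_cooperative(), p)
  reach1 <- reachable_products(co, c("T1234", "I1"))
  expect_false("T2:T4" %in% reach1)
  expect_true("T2:T4" %in% reachable_products(co, c("T1234", "I1", "I2")))
  # sequential without the first invader: the cascade product is unreachable
  sq <- enumerate_network(make_sequential(), p, include_leak = FALSE)
  reach2 <- reachable_products(sq, c("T1a2a34", "T2b4b"))
  expect_false("T1b2b34b" %in% reach2)
  # with leak enabled only the spurious product becomes reachable
  sq_leak <- enumerate_network(make_sequential(), p)
  reach3 <- reachable_products(sq_leak, c("T1a2a34", "T2b4b"))
  expect_true("T1a2b34b" %in% reach3)
  expect_false("T1b2b34b" %in% reach3)
  # basic closure contains both products; empty initial set stays empty
  ba <- enumerate_network(make_basic_displacement(4, 2), p)
  expect_true(all(c("Inv24:BT2", "CT") %in%
                    reachable_products(ba, c("Inv24", "CT:BT2"))))
  expect_length(reachable_products(ba, character(0)), 0)
})

test_that("the species cap guards against state-space explosion", {
  p <- default_rate_params()
  expect_error(enumerate_network(make_cooperative(), p, species_cap = 6L),
               "species cap")
})

test_that("network serialization round-trips through files", {
  p <- default_rate_params()
  net <- enumerate_network(make_competitive(), p)
  f <- tempfile()
  on.exit(unlink(f))
  write_network(net, f)
  expect_identical(readLines(f), format_network(net))
})

test_that("re-rating a network tracks parameter changes without re-enumeration", {
  p <- default_rate_params()
  net <- enumerate_network(make_basic_displacement(4, 2), p)
  p2 <- .param_set(p, "k_disp_per_s", 0.1)
  net2 <- network_rates(net, p2)
  rel <- Filter(function(r) r$rxn_class == "release", net2$reactions)
  expect_equal(rel[[1]]$rate, 0.1)
})
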