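# Reaction-network enumeration: expands a system_spec into canonical species
# and typed mass-action reactions (toehold binding/dissociation, reversible
# branch-migration steps, irreversible release, leak, dimerization, assembly).

.rate_rule_eval <- function(rule, params) {
  switch(rule$kind,
    bind = k_bind(params, rule$sticky),
    diss = k_dissociation(rule$n_nt, params),
    step = segment_rate(params, rule$class, isTRUE(rule$coded)),
    leak = params$k_leak_per_M_s,
    dimer = params$k_dimer_per_M_s,
    fixed_bi = rule$value,
    fixed_uni = rule$value,
    stop("unknown rate rule kind: ", rule$kind))
}

.rule_bimolecular <- function(rule) {
  rule$kind %in% c("bind", "leak", "dimer", "fixed_bi")
}

.mk_rxn <- function(reactants, products, class, rule, params, multiplicity = 1L,
                    provenance = "") {
  list(reactants = reactants, products = products, rxn_class = class,
       rate = .rate_rule_eval(rule, params),
       bimolecular = .rule_bimolecular(rule),
       rate_rule = rule, multiplicity = as.integer(multiplicity),
       provenance = provenance)
}

#' Enumerate the reaction network of a system
#'
#' Expands a [system_spec()] into the closure of species and typed reactions
#' under the displacement rule set: (i) bimolecular toehold binding between
#' complementary accessible toeholds at the sticky-end binding rate; (ii)
#' unimolecular toehold dissociation (from the pre-migration state only) at
#' the exponential dissociation rate; (iii) reversible branch-migration
#' steps with segment-class- and code-adjusted rates (forward and backward
#' rates equal: an unbiased coarse-grained walk); (iv) irreversible release
#' of the displaced complex once its last bond is migrated through (a
#' released tile retains no toehold, so it cannot spontaneously re-bind);
#' (v) optional zero-toehold leak and invader dimerization channels. For
#' pathways whose target carries a structural grid and a toehold site, the
#' declared toehold is verified to be accessible ([toehold_accessible()])
#' before any binding reaction is generated.
#'
#' Center-tile pathways expand into disconnection states `d = 0..4` (number
#' of the old center tile's edges disconnected; disconnections are
#' independent and order-free) with release only from the all-disconnected
#' state. Cooperative pathways expand into the product space of the two
#' invaders' binding/migration positions with a joint irreversible release
#' only from the doubly half-migrated state.
#'
#' Output order is deterministic: species sorted by key, reactions sorted by
#' class, reactants and products, so identical inputs serialize
#' byte-identically.
#'
#' @param system A [system_spec()].
#' @param params A [rate_params()].
#' @param include_leak Include declared zero-toehold leak channels?
#' @param species_cap Error if enumeration would exceed this many species.
#' @return An object of class `reaction_network` with `species` (data frame:
#'   `key`, `conc_nM`), `compositions` (named list of tile-count vectors),
#'   and `reactions` (list; see [format_network()] for the serialized form).
#' @export
enumerate_network <- function(system, params, include_leak = TRUE,
                              species_cap = 10000L) {
  stopifnot(inherits(system, "system_spec"), inherits(params, "rate_params"))
  comps <- lapply(system$species, function(s) s$composition)
  conc <- vapply(system$species, function(s) s$conc_nM, numeric(1))
  rxns <- list()
  add_species <- function(key, composition, conc_nM = 0) {
    if (!key %in% names(comps)) {
      comps[[key]] <<- composition
      conc[[key]] <<- conc_nM
      if (length(comps) > species_cap)
        stop("species cap exceeded: enumeration produced more than ",
             species_cap, " species (raise species_cap if intended)")
    }
  }
  add_rxn <- function(r) rxns[[length(rxns) + 1L]] <<- r

  for (p in system$pathways) {
    tgt <- system$species[[p$target]]
    if (!is.null(tgt$complex) && !is.null(p$toehold_site)) {
      if (!toehold_accessible(tgt$complex, p$toehold_site$at, p$toehold_site$edge))
        stop("pathway '", p$name, "': declared toehold at (",
             paste(p$toehold_site$at, collapse = ","), ") edge ",
             p$toehold_site$edge, " is sequestered on target ", p$target)
    }
    if (p$mode == "linear") {
      th <- p$toeholds[[1L]]
      if (toehold_total_nt(th) == 0L)
        stop("pathway '", p$name, "' has a zero-strength toehold; ",
             "declare it as a leak channel instead")
      inv <- p$invaders
      S <- length(p$segments)
      icomp <- .comp_sum(list(comps[[inv]], comps[[p$target]]))
      ikeys <- paste0(inv, "~", p$target, "@", seq_len(S) - 1L)
      for (k in ikeys) add_species(k, icomp)
      add_rxn(.mk_rxn(stats::setNames(c(1, 1), c(inv, p$target)),
                      stats::setNames(1, ikeys[1L]), "toehold_bind",
                      list(kind = "bind", sticky = th$sticky_nt), params,
                      p$bind_multiplicity, p$name))
      add_rxn(.mk_rxn(stats::setNames(1, ikeys[1L]),
                      stats::setNames(c(1, 1), c(inv, p$target)),
                      "toehold_dissociate",
                      list(kind = "diss", n_nt = toehold_total_nt(th)),
                      params, 1L, p$name))
      if (S > 1L) {
        for (j in seq_len(S - 1L)) {  # step j: state j-1 -> j, segment j
          sg <- p$segments[[j]]
          rule <- list(kind = "step", class = sg$class, coded = sg$coded)
          add_rxn(.mk_rxn(stats::setNames(1, ikeys[j]),
                          stats::setNames(1, ikeys[j + 1L]),
                          "branch_step_forward", rule, params, 1L, p$name))
          add_rxn(.mk_rxn(stats::setNames(1, ikeys[j + 1L]),
                          stats::setNames(1, ikeys[j]),
                          "branch_step_backward", rule, params, 1L, p$name))
        }
      }
      sg <- p$segments[[S]]
      add_rxn(.mk_rxn(stats::setNames(1, ikeys[S]),
                      stats::setNames(c(1, 1), c(p$bound_product, p$released)),
                      "release",
                      list(kind = "step", class = sg$class, coded = sg$coded),
                      params, 1L, p$name))
    } else if (p$mode == "center") {
      th <- p$toeholds[[1L]]
      inv <- p$invaders
      icomp <- .comp_sum(list(comps[[inv]], comps[[p$target]]))
      dkeys <- paste0(inv, "~", p$target, "@d", 0:4)
      for (k in dkeys) add_species(k, icomp)
      seg <- p$segments[[1L]]
      rule <- list(kind = "step", class = seg$class, coded = seg$coded)
      add_rxn(.mk_rxn(stats::setNames(c(1, 1), c(inv, p$target)),
                      stats::setNames(1, dkeys[1L]), "toehold_bind",
                      list(kind = "bind", sticky = th$sticky_nt), params,
                      p$bind_multiplicity, p$name))
      add_rxn(.mk_rxn(stats::setNames(1, dkeys[1L]),
                      stats::setNames(c(1, 1), c(inv, p$target)),
                      "toehold_dissociate",
                      list(kind = "diss", n_nt = toehold_total_nt(th)),
                      params, 1L, p$name))
      for (d in 0:3) {  # (4 - d) connected edges can disconnect, (d + 1) reconnect
        add_rxn(.mk_rxn(stats::setNames(1, dkeys[d + 1L]),
                        stats::setNames(1, dkeys[d + 2L]),
                        "branch_step_forward", rule, params, 4L - d, p$name))
        add_rxn(.mk_rxn(stats::setNames(1, dkeys[d + 2L]),
                        stats::setNames(1, dkeys[d + 1L]),
                        "branch_step_backward", rule, params, d + 1L, p$name))
      }
      add_rxn(.mk_rxn(stats::setNames(1, dkeys[5L]),
                      stats::setNames(c(1, 1), c(p$bound_product, p$released)),
                      "release", list(kind = "step", class = "edge",
                                      coded = FALSE),
                      params, 1L, p$name))
    } else if (p$mode == "cooperative") {
      invs <- p$invaders
      S1 <- length(p$segments[[1L]]); S2 <- length(p$segments[[2L]])
      pos1 <- c("u", as.character(0:S1)); pos2 <- c("u", as.character(0:S2))
      skey <- function(a, b) paste0(p$target, "~", invs[1L], "@", a, "~",
                                    invs[2L], "@", b)
      scomp <- function(a, b) {
        parts <- list(comps[[p$target]])
        if (a != "u") parts <- c(parts, list(comps[[invs[1L]]]))
        if (b != "u") parts <- c(parts, list(comps[[invs[2L]]]))
        .comp_sum(parts)
      }
      for (a in pos1) for (b in pos2) {
        if (a == "u" && b == "u") next
        add_species(skey(a, b), scomp(a, b))
      }
      side <- function(i, other_pos) {
        th <- p$toeholds[[i]]
        segs <- p$segments[[i]]
        Si <- length(segs)
        at <- function(pos) if (i == 1L) skey(pos, other_pos) else skey(other_pos, pos)
        free_state <- if (other_pos == "u") p$target else at("u")
        bind_react <- if (other_pos == "u")
          stats::setNames(c(1, 1), c(invs[i], p$target))
        else stats::setNames(c(1, 1), c(invs[i], at("u")))
        add_rxn(.mk_rxn(bind_react, stats::setNames(1, at("0")),
                        "toehold_bind",
                        list(kind = "bind", sticky = th$sticky_nt), params,
                        1L, p$name))
        add_rxn(.mk_rxn(stats::setNames(1, at("0")), bind_react,
                        "toehold_dissociate",
                        list(kind = "diss", n_nt = toehold_total_nt(th)),
                        params, 1L, p$name))
        for (j in seq_len(Si)) {
          sg <- segs[[j]]
          rule <- list(kind = "step", class = sg$class, coded = sg$coded)
          add_rxn(.mk_rxn(stats::setNames(1, at(as.character(j - 1L))),
                          stats::setNames(1, at(as.character(j))),
                          "branch_step_forward", rule, params, 1L, p$name))
          add_rxn(.mk_rxn(stats::setNames(1, at(as.character(j))),
                          stats::setNames(1, at(as.character(j - 1L))),
                          "branch_step_backward", rule, params, 1L, p$name))
        }
      }
      for (b in pos2) side(1L, b)
      for (a in pos1) side(2L, a)
      add_rxn(.mk_rxn(stats::setNames(1, skey(as.character(S1), as.character(S2))),
                      stats::setNames(c(1, 1), c(p$bound_product, p$released)),
                      "release", list(kind = "step", class = "edge",
                                      coded = FALSE),
                      params, 1L, p$name))
    }
  }
  if (include_leak) {
    for (l in system$leaks) {
      add_rxn(.mk_rxn(stats::setNames(c(1, 1), c(l$invader, l$target)),
                      stats::setNames(c(1, 1), l$products),
                      "displacement_swap", list(kind = "leak"), params, 1L,
                      l$name))
    }
  }
  for (x in system$extra_reactions) {
    add_rxn(.mk_rxn(x$reactants, x$products, x$class, x$rate_rule, params,
                    x$multiplicity %||% 1L, x$name %||% "extra"))
  }

  # deterministic ordering
  ord <- order(vapply(rxns, function(r)
    paste(r$rxn_class,
          paste(names(r$reactants), r$reactants, collapse = "+"),
          paste(names(r$products), r$products, collapse = "+")),
    character(1)))
  rxns <- rxns[ord]
  keys <- sort(names(comps))
  for (r in rxns) {
    if (!all(c(names(r$reactants), names(r$products)) %in% keys))
      stop("reaction references unknown species")
  }
  net <- structure(list(
    species = data.frame(key = keys, conc_nM = unname(conc[keys]),
                         stringsAsFactors = FALSE),
    compositions = comps[keys],
    reactions = rxns,
    observables = system$observables,
    dosing = system$dosing,
    preset = system$preset), class = "reaction_network")
  .assert_conservation(net)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_conservation <- function(net) {
  for (r in net$reactions) {
    lhs <- .comp_sum(mapply(function(k, s) net$compositions[[k]] * s,
                            names(r$reactants), r$reactants, SIMPLIFY = FALSE))
    rhs <- .comp_sum(mapply(function(k, s) net$compositions[[k]] * s,
                            names(r$products), r$products, SIMPLIFY = FALSE))
    tiles <- sort(unique(c(names(lhs), names(rhs))))
    l <- stats::setNames(numeric(length(tiles)), tiles); l[names(lhs)] <- lhs
    q <- stats::setNames(numeric(length(tiles)), tiles); q[names(rhs)] <- rhs
    if (any(l != q))
      stop("tile-count conservation violated by reaction ",
           paste(names(r$reactants), collapse = "+"), " -> ",
           paste(names(r$products), collapse = "+"))
  }
  invisible(TRUE)
}

#' Check tile-type conservation of a network
#'
#' Verifies that every reaction conserves the copy count of every tile type
#' (total copies across reactants equal total copies across products).
#'
#' @param network A [enumerate_network()] result.
#' @return TRUE (invisibly); errors on violation.
#' @export
check_tile_conservation <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  .assert_conservation(network)
}

#' Recompute reaction rates for new parameters
#'
#' Every enumerated reaction carries its generating rate rule, so a network
#' can be re-rated without re-enumeration (used by the fitter).
#'
#' @param network A `reaction_network`.
#' @param params A [rate_params()].
#' @return The network with updated `rate` fields.
#' @export
network_rates <- function(network, params) {
  network$reactions <- lapply(network$reactions, function(r) {
    r$rate <- .rate_rule_eval(r$rate_rule, params)
    r
  })
  network
}

#' Species reachable from an initial set
#'
#' Graph closure over reactions whose reactants are all reachable; used to
#' verify design claims such as "no intermediate state leads to an undesired
#' product" or that cooperative release is unreachable with one invader.
#'
#' @param network A `reaction_network`.
#' @param initial Character vector of initially present species keys.
#' @return Character vector of reachable species keys (sorted).
#' @export
reachable_products <- function(network, initial) {
  stopifnot(all(initial %in% network$species$key))
  reach <- unique(initial)
  repeat {
    grew <- FALSE
    for (r in network$reactions) {
      if (all(names(r$reactants) %in% reach)) {
        new <- setdiff(names(r$products), reach)
        if (length(new)) { reach <- c(reach, new); grew <- TRUE }
      }
    }
    if (!grew) break
  }
  sort(reach)
}

#' Serialize a reaction network as stable text
#'
#' Two tab-separated sections (species with composition and initial
#' concentration; reactions with class, reactants, products, rate and
#' multiplicity) in deterministic order, suitable for diff-based comparison.
#'
#' @param network A `reaction_network`.
#' @return Character vector of lines (`format_network`); `write_network`
#'   writes them to `path` and returns it invisibly.
#' @export
format_network <- function(network) {
  sp <- vapply(seq_len(nrow(network$species)), function(i) {
    k <- network$species$key[i]
    comp <- network$compositions[[k]]
    sprintf("%s\t%s\t%.10g", k,
            paste(sprintf("%s=%g", names(comp), comp), collapse = ","),
            network$species$conc_nM[i])
  }, character(1))
  side <- function(v) paste(sprintf("%g %s", unname(v), names(v)), collapse = " + ")
  rx <- vapply(network$reactions, function(r) {
    sprintf("%s\t%s\t%s\t%.10g\t%s\t%d", r$rxn_class, side(r$reactants),
            side(r$products), r$rate,
            if (r$bimolecular) "per_M_s" else "per_s", r$multiplicity)
  }, character(1))
  c("# species\tcomposition\tconc_nM", sp,
    "# class\treactants\tproducts\trate\tunits\tmultiplicity", rx)
}

#' @rdname format_network
#' @param path Output file path.
#' @export
write_network <- function(network, path) {
  writeLines(format_network(network), path)
  invisible(path)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network '%s'>: %d species, %d reactions\n",
              x$preset, nrow(x$species), length(x$reactions)))
  cls <- table(vapply(x$reactions, function(r) r$rxn_class, character(1)))
  cat(" ", paste(sprintf("%s: %d", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}
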