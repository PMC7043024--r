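#' Mass-action reaction scheme specification
#'
#' A `kinetic_scheme` is an ordered species list plus a list of elementary
#' (first- or second-order) mass-action reactions, compiled into a
#' stoichiometry matrix, a reactant-index table and a resolved numeric rate
#' vector.  Conserved totals (index sets whose summed stoichiometry is zero
#' in every reaction) are declared explicitly and validated at
#' construction, so conservation in simulated trajectories is structural,
#' not numerical.
#'
#' @param species character vector of unique species names.
#' @param reactions list of reactions; each reaction is a list with
#'   elements `reactants` (character, length 1-2), `products` (character,
#'   possibly empty), and `rate` (a numeric rate constant, or the name of a
#'   field of `params` — `"k_off_star"` resolves via [cycle_closure()]).
#' @param conserved named list of character vectors of species whose sum
#'   must be invariant under every reaction.
#' @param params optional [rate_params()] object (or named list of them)
#'   used to resolve character rate references; for a named list, use
#'   references of the form `"group.rate"`.
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(species, reactions, conserved = list(), params = NULL) {
  stopifnot(is.character(species), !anyDuplicated(species))
  ns <- length(species)
  nr <- length(reactions)
  if (nr == 0L) stop("a scheme needs at least one reaction", call. = FALSE)
  stoich <- matrix(0, ns, nr, dimnames = list(species, NULL))
  reactant_idx <- matrix(0L, 2L, nr)
  rates <- numeric(nr)
  rate_names <- character(nr)
  for (j in seq_len(nr)) {
    rx <- reactions[[j]]
    rs <- rx$reactants
    ps <- rx$products
    if (length(rs) < 1L || length(rs) > 2L)
      stop("reaction ", j, ": 1 or 2 reactants required", call. = FALSE)
    bad <- setdiff(c(rs, ps), species)
    if (length(bad))
      stop("reaction ", j, ": unknown species ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (s in rs) stoich[s, j] <- stoich[s, j] - 1
    for (s in ps) stoich[s, j] <- stoich[s, j] + 1
    reactant_idx[seq_along(rs), j] <- match(rs, species)
    rates[j] <- resolve_rate(rx$rate, params, j)
    rate_names[j] <- if (is.character(rx$rate)) rx$rate else ""
  }
  conserved_idx <- lapply(conserved, function(sp) {
    i <- match(sp, species)
    if (anyNA(i)) stop("conserved total references unknown species", call. = FALSE)
    i
  })
  for (nm in names(conserved_idx)) {
    net <- colSums(stoich[conserved_idx[[nm]], , drop = FALSE])
    if (any(net != 0))
      stop("conserved total '", nm, "' is not invariant under reaction(s) ",
           paste(which(net != 0), collapse = ", "), call. = FALSE)
  }
  structure(list(species = species, stoich = stoich,
                 reactant_idx = reactant_idx, rates = rates,
                 rate_names = rate_names, conserved = conserved_idx,
                 reactions = reactions, params = params),
            class = "kinetic_scheme")
}

resolve_rate <- function(r, params, j) {
  if (is.numeric(r)) {
    if (r < 0) stop("reaction ", j, ": negative rate", call. = FALSE)
    return(as.numeric(r))
  }
  if (!is.character(r) || length(r) != 1L)
    stop("reaction ", j, ": rate must be a number or a name", call. = FALSE)
  if (is.null(params))
    stop("reaction ", j, ": rate '", r, "' needs a params object", call. = FALSE)
  grp <- params
  nm <- r
  if (grepl(".", r, fixed = TRUE)) {
    parts <- strsplit(r, ".", fixed = TRUE)[[1]]
    grp <- params[[parts[1]]]
    nm <- parts[2]
    if (is.null(grp)) stop("unknown parameter group '", parts[1], "'", call. = FALSE)
  }
  if (!inherits(grp, "rate_params"))
    stop("reaction ", j, ": '", r, "' does not resolve to rate parameters",
         call. = FALSE)
  if (nm == "k_off_star") return(cycle_closure(grp))
  v <- grp[[nm]]
  if (is.null(v))
    stop("reaction ", j, ": '", nm, "' is not a rate_params field", call. = FALSE)
  v
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic_scheme> %d species, %d reactions, %d conserved totals\n",
              length(x$species), ncol(x$stoich), length(x$conserved)))
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the mass-action right-hand side of a scheme
#'
#' @param scheme a [kinetic_scheme()].
#' @param conc named or ordered numeric vector of concentrations (uM).
#' @return Named numeric vector of time derivatives, uM s^-1.
#' @export
scheme_rhs <- function(scheme, conc) {
  conc <- as_scheme_conc(scheme, conc)
  flux <- scheme$rates * conc[scheme$reactant_idx[1L, ]]
  i2 <- scheme$reactant_idx[2L, ]
  has2 <- i2 > 0L
  flux[has2] <- flux[has2] * conc[i2[has2]]
  drop(scheme$stoich %*% flux)
}

# Accept named (any order, missing = 0) or positional concentration vectors.
as_scheme_conc <- function(scheme, conc) {
  sp <- scheme$species
  if (!is.null(names(conc))) {
    bad <- setdiff(names(conc), sp)
    if (length(bad))
      stop("unknown species: ", paste(bad, collapse = ", "), call. = FALSE)
    full <- stats::setNames(numeric(length(sp)), sp)
    full[names(conc)] <- conc
    full
  } else {
    if (length(conc) != length(sp))
      stop("concentration vector length mismatch", call. = FALSE)
    stats::setNames(as.numeric(conc), sp)
  }
}

#' Single-substrate alternate-state reaction scheme
#'
#' Builds the two-state scheme: both E and E* bind substrate with the same
#' second-order rate `k1`, the complexes ES and E*S have distinct
#' dissociation (`k_off`, cycle-closed `k_off_star`) and catalytic rates
#' (`kcat_E`, `kcat_Estar`), and the free and bound forms interconvert by
#' slow unimolecular exchange (E <-> E*, ES <-> E*S).
#'
#' @param params a cycle-closed [rate_params()] object.
#' @return A [kinetic_scheme()] with species E, Estar, ES, EstarS, S, P,
#'   ten reactions, and conserved enzyme and peptide totals.
#' @export
build_single_substrate_scheme <- function(params) {
  stopifnot(inherits(params, "rate_params"))
  kinetic_scheme(
    species = c("E", "Estar", "ES", "EstarS", "S", "P"),
    reactions = list(
      list(reactants = c("E", "S"), products = "ES", rate = "k1"),
      list(reactants = "ES", products = c("E", "S"), rate = "k_off"),
      list(reactants = c("Estar", "S"), products = "EstarS", rate = "k1"),
      list(reactants = "EstarS", products = c("Estar", "S"), rate = "k_off_star"),
      list(reactants = "ES", products = c("E", "P"), rate = "kcat_E"),
      list(reactants = "EstarS", products = c("Estar", "P"), rate = "kcat_Estar"),
      list(reactants = "E", products = "Estar", rate = "kE_fwd"),
      list(reactants = "Estar", products = "E", rate = "kE_rev"),
      list(reactants = "ES", products = "EstarS", rate = "kES_fwd"),
      list(reactants = "EstarS", products = "ES", rate = "kES_rev")),
    conserved = list(enzyme = c("E", "Estar", "ES", "EstarS"),
                     substrate = c("S", "ES", "EstarS", "P")),
    params = params)
}

#' Coupled dual-substrate reaction scheme for a bifunctional complex
#'
#' Builds the reaction network for a complex carrying both a demethylase
#' and a deacetylase site acting on three peptide substrates: K4meK9
#' (demethylation only), K4K9ac (deacetylation only) and the doubly
#' modified K4meK9ac, whose processing at either site yields the singly
#' modified peptides, which re-enter as substrates, until the fully
#' processed K4K9 peptide accumulates.  Every deacetylation event releases
#' one acetate.
#'
#' With `single_occupancy = TRUE` (the experimentally supported model) one
#' enzyme pool is shared by all enzyme-substrate complexes, so occupancy at
#' either catalytic site excludes binding at the other.  With
#' `single_occupancy = FALSE` the two sites are independent pools
#' (`E_dem`, `E_hdac`), each at the total complex concentration.  Doubly
#' engaged peptides (one peptide bridging both independent pools) are not
#' modelled: at catalytic enzyme concentrations (nM) against 10-100 uM
#' peptide the doubly bound fraction is negligible.
#'
#' @param params_me rates for demethylation of K4meK9.
#' @param params_ac rates for deacetylation of K4K9ac.
#' @param params_me_on_dual,params_ac_on_dual rates for the two reactions
#'   on the doubly modified substrate; required when
#'   `shared_kinetics = FALSE`, and must be omitted (or identical to the
#'   single-substrate sets) when `shared_kinetics = TRUE`.
#' @param single_occupancy share one enzyme pool across all complexes?
#' @param shared_kinetics tie dual-substrate rate constants to the
#'   single-substrate ones?
#' @param with_alternate_state include the E*/E*S alternate state and its
#'   exchange reactions?
#' @return A [kinetic_scheme()] over the peptide species K4meK9, K4K9ac,
#'   K4meK9ac, K4K9 and acetate plus the enzyme pools and complexes.
#' @export
build_coupled_scheme <- function(params_me, params_ac,
                                 params_me_on_dual = NULL,
                                 params_ac_on_dual = NULL,
                                 single_occupancy = TRUE,
                                 shared_kinetics = TRUE,
                                 with_alternate_state = TRUE) {
  stopifnot(inherits(params_me, "rate_params"), inherits(params_ac, "rate_params"))
  same_rates <- function(a, b) isTRUE(all.equal(unclass(a), unclass(b)))
  if (shared_kinetics) {
    if (!is.null(params_me_on_dual) && !same_rates(params_me_on_dual, params_me))
      stop("inconsistent ties: shared_kinetics with distinct params_me_on_dual",
           call. = FALSE)
    if (!is.null(params_ac_on_dual) && !same_rates(params_ac_on_dual, params_ac))
      stop("inconsistent ties: shared_kinetics with distinct params_ac_on_dual",
           call. = FALSE)
    params_me_on_dual <- params_me
    params_ac_on_dual <- params_ac
  } else {
    if (is.null(params_me_on_dual) || is.null(params_ac_on_dual))
      stop("substrate-specific model needs params_me_on_dual and params_ac_on_dual",
           call. = FALSE)
  }
  pars <- list(me = params_me, ac = params_ac,
               dme = params_me_on_dual, dac = params_ac_on_dual)

  # site table: substrate, products, parameter group, enzyme pool
  sites <- list(
    me  = list(sub = "K4meK9",   prod = "K4K9",                 pool = "dem"),
    ac  = list(sub = "K4K9ac",   prod = c("K4K9", "acetate"),   pool = "hdac"),
    dme = list(sub = "K4meK9ac", prod = "K4K9ac",               pool = "dem"),
    dac = list(sub = "K4meK9ac", prod = c("K4meK9", "acetate"), pool = "hdac"))
  if (single_occupancy) for (s in names(sites)) sites[[s]]$pool <- "shared"

  pools <- unique(vapply(sites, `[[`, "", "pool"))
  pool_name <- function(pool) if (pool == "shared") "E" else paste0("E_", pool)
  # free-enzyme exchange belongs to the pool; demand consistency across the
  # parameter groups that share a pool
  pool_exchange <- list()
  for (s in names(sites)) {
    pl <- sites[[s]]$pool
    ex <- c(pars[[s]]$kE_fwd, pars[[s]]$kE_rev)
    if (is.null(pool_exchange[[pl]])) pool_exchange[[pl]] <- ex
    else if (!isTRUE(all.equal(pool_exchange[[pl]], ex)))
      stop("inconsistent ties: parameter groups sharing the '", pl,
           "' enzyme pool disagree on the E <-> E* exchange rates", call. = FALSE)
  }

  peptides <- c("K4meK9", "K4K9ac", "K4meK9ac", "K4K9")
  species <- c(peptides, "acetate")
  rxns <- list()
  enzyme_cons <- stats::setNames(vector("list", length(pools)), pools)
  complex_species <- character()

  for (pl in pools) {
    g <- pool_name(pl)
    species <- c(species, g)
    enzyme_cons[[pl]] <- g
    if (with_alternate_state) {
      gs <- paste0(g, "star")
      species <- c(species, gs)
      enzyme_cons[[pl]] <- c(enzyme_cons[[pl]], gs)
      ex <- pool_exchange[[pl]]
      rxns <- c(rxns,
        list(list(reactants = g, products = gs, rate = ex[1]),
             list(reactants = gs, products = g, rate = ex[2])))
    }
  }

  for (s in names(sites)) {
    st <- sites[[s]]
    p <- pars[[s]]
    g <- pool_name(st$pool)
    cx <- paste0(g, "_", st$sub, if (st$sub == "K4meK9ac") paste0("_", s) else "")
    species <- c(species, cx)
    complex_species <- c(complex_species, cx)
    enzyme_cons[[st$pool]] <- c(enzyme_cons[[st$pool]], cx)
    rxns <- c(rxns, list(
      list(reactants = c(g, st$sub), products = cx, rate = p$k1),
      list(reactants = cx, products = c(g, st$sub), rate = p$k_off),
      list(reactants = cx, products = c(g, st$prod), rate = p$kcat_E)))
    if (with_alternate_state) {
      gs <- paste0(g, "star")
      cxs <- paste0(cx, "_star")
      species <- c(species, cxs)
      complex_species <- c(complex_species, cxs)
      enzyme_cons[[st$pool]] <- c(enzyme_cons[[st$pool]], cxs)
      rxns <- c(rxns, list(
        list(reactants = c(gs, st$sub), products = cxs, rate = p$k1),
        list(reactants = cxs, products = c(gs, st$sub), rate = cycle_closure(p)),
        list(reactants = cxs, products = c(gs, st$prod), rate = p$kcat_Estar),
        list(reactants = cx, products = cxs, rate = p$kES_fwd),
        list(reactants = cxs, products = cx, rate = p$kES_rev)))
    }
  }

  conserved <- c(stats::setNames(lapply(names(enzyme_cons),
                                        function(pl) enzyme_cons[[pl]]),
                                 paste0("enzyme_", names(enzyme_cons))),
                 list(peptide = c(peptides, complex_species)))
  kinetic_scheme(species, rxns, conserved, params = pars)
}
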