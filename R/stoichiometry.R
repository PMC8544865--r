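#' Derive the stoichiometric matrix from a flat bond graph
#'
#' Walks the junction structure of a flattened model and recovers, for each
#' reaction, the species feeding its forward port and receiving from its
#' reverse port.  Common-potential (0) junction chains are contracted into
#' potential groups (each must contain exactly one species); common-flow
#' (1) junction chains are contracted into affinity-summing groups.  A
#' species attached to a reaction side through k parallel bonds enters with
#' stoichiometry k (k binding sites).
#'
#' @param x a [bondgraph_model()], [bg_module()] or flat model.
#' @return a list with elements `N` (integer species-by-reaction matrix
#'   with dimnames), `species`, `reactions`, `sites_f`, `sites_r` (per
#'   reaction, species indices repeated per binding site, in species
#'   order), `laws`, `K`, `chemostats` (logical mask), `x0`, `temperature`.
#' @export
build_stoichiometry <- function(x) {
  fl <- bg_flatten(x)
  comps <- fl$components
  nm <- names(comps)
  species <- nm[fl$kinds == "species"]
  reactions <- nm[fl$kinds == "reaction"]
  ns <- length(species); nr <- length(reactions)
  sidx <- stats::setNames(seq_len(ns), species)

  ## union-find over potential nodes (species + 0-junctions) and over
  ## 1-junctions
  parent <- stats::setNames(nm, nm)
  find <- function(a) { while (parent[[a]] != a) a <- parent[[a]]; a }
  union_ <- function(a, b) { parent[[find(a)]] <<- find(b) }

  is_pot <- function(p) {
    c <- comps[[p]]
    c$kind == "species" || (c$kind == "junction" && c$jkind == "0")
  }
  is_one <- function(p) {
    c <- comps[[p]]
    c$kind == "junction" && c$jkind == "1"
  }

  for (b in fl$bonds) {
    tp <- b$tail$path; hp <- b$head$path
    if (is_pot(tp) && is_pot(hp)) union_(tp, hp)
    if (is_one(tp) && is_one(hp)) union_(tp, hp)
  }

  ## species of each potential group
  group_species <- list()
  for (s in species) {
    g <- find(s)
    group_species[[g]] <- c(group_species[[g]], s)
  }
  for (p in nm[fl$kinds == "junction"]) {
    if (comps[[p]]$jkind == "0" && find(p) == p && is.null(group_species[[p]]))
      stop(sprintf("0-junction group at '%s' is not attached to any species", p))
  }
  pot_species <- function(p) {
    g <- find(p)
    sps <- group_species[[g]]
    if (is.null(sps))
      stop(sprintf("potential group at '%s' contains no species", p))
    if (length(sps) > 1)
      stop(sprintf("potential group at '%s' contains %d species (%s); merge them",
                   p, length(sps), paste(sps, collapse = ", ")))
    sps
  }

  ## bonds indexed by (path, port)
  bond_at <- list()
  for (b in fl$bonds) {
    bond_at[[paste0(b$tail$path, ":", b$tail$port)]] <- b
    bond_at[[paste0(b$head$path, ":", b$head$port)]] <- b
  }

  side_species <- function(rname, port) {
    b <- bond_at[[paste0(rname, ":", port)]]
    if (is.null(b))
      stop(sprintf("reaction port '%s:%s' is not bonded", rname, port))
    other <- if (b$tail$path == rname && b$tail$port == port) b$head else b$tail
    ## expected orientation: into the reaction at 'f', out of it at 'r'
    inward <- identical(b$head$path, rname) && identical(b$head$port, port)
    if ((port == "f" && !inward) || (port == "r" && inward))
      stop(sprintf("bond at '%s:%s' has unsupported orientation", rname, port))
    if (is_pot(other$path)) return(pot_species(other$path))
    if (!is_one(other$path))
      stop(sprintf("reaction port '%s:%s' must attach to a species, 0- or 1-junction",
                   rname, port))
    g <- find(other$path)
    out <- character()
    for (bb in fl$bonds) {
      t1 <- is_one(bb$tail$path) && find(bb$tail$path) == g
      h1 <- is_one(bb$head$path) && find(bb$head$path) == g
      if (t1 && h1) next               # internal to the group
      if (!t1 && !h1) next
      end <- if (t1) bb$head else bb$tail
      if (end$path == rname) next      # the bond we came from
      if (comps[[end$path]]$kind == "reaction")
        stop(sprintf("1-junction group at '%s' attaches to more than one reaction",
                     other$path))
      ## orientation: species flow toward the junction on 'f', away on 'r'
      toward <- h1
      if ((port == "f" && !toward) || (port == "r" && toward))
        stop(sprintf("bond between '%s' and '%s' has unsupported orientation",
                     bb$tail$path, bb$head$path))
      out <- c(out, pot_species(end$path))
    }
    if (!length(out))
      stop(sprintf("reaction port '%s:%s' is not reachable from any species",
                   rname, port))
    out
  }

  N <- matrix(0L, ns, nr, dimnames = list(species, reactions))
  sites_f <- sites_r <- vector("list", nr)
  names(sites_f) <- names(sites_r) <- reactions
  for (j in seq_len(nr)) {
    rj <- reactions[[j]]
    f <- sort(sidx[side_species(rj, "f")])
    r <- sort(sidx[side_species(rj, "r")])
    sites_f[[j]] <- unname(f)
    sites_r[[j]] <- unname(r)
    for (i in f) N[i, j] <- N[i, j] - 1L
    for (i in r) N[i, j] <- N[i, j] + 1L
  }

  K <- vapply(species, function(s) comps[[s]]$params$K, 0)
  laws <- lapply(reactions, function(r) comps[[r]]$law)
  names(laws) <- reactions
  chem <- species %in% fl$chemostats
  x0 <- stats::setNames(numeric(ns), species)
  common <- intersect(names(fl$x0), species)
  x0[common] <- fl$x0[common]

  list(N = N, species = species, reactions = reactions,
       sites_f = sites_f, sites_r = sites_r, laws = laws, K = K,
       chemostats = stats::setNames(chem, species), x0 = x0,
       temperature = fl$temperature)
}
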