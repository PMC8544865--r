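#' Read and write models as JSON
#'
#' Serialises a [bondgraph_model()] (hierarchy included) to a JSON
#' document and back.  The dialect mirrors the in-memory structure:
#' a `root` module with `children` (species / reaction / junction /
#' module nodes), `bonds` as `"path:port"` endpoint pairs, `exposed`
#' port maps, plus model-level `chemostats`, `x0` and `temperature`.
#' Round-tripping is lossless (numbers are written at full precision).
#'
#' @param model a [bondgraph_model()].
#' @param path file path (`.json`).
#' @return `read_model()` returns a [bondgraph_model()];
#'   `write_model()` returns `path` invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "bondgraph_model"))
  doc <- list(schema = "bondgraphr/1",
              temperature = model$temperature,
              chemostats = as.list(model$chemostats),
              x0 = as.list(model$x0),
              root = module_to_list(model$root))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

module_to_list <- function(m) {
  if (inherits(m, "bg_module")) {
    list(type = "module", name = m$name,
         children = lapply(m$children, module_to_list),
         bonds = lapply(m$bonds, function(b)
           list(tail = paste0(b$tail$path, ":", b$tail$port),
                head = paste0(b$head$path, ":", b$head$port))),
         exposed = lapply(m$exposed, function(e)
           paste0(e$path, ":", e$port)))
  } else if (m$kind == "species") {
    list(type = "species", K = m$params$K)
  } else if (m$kind == "reaction") {
    law <- m$law
    c(list(type = "reaction", law = law$type),
      lapply(law$params, identity))
  } else {
    list(type = "junction", kind = m$jkind,
         nports = if (is.null(m$nports)) 0L else m$nports)
  }
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "bondgraphr/1"))
    stop("/schema: expected \"bondgraphr/1\"")
  root <- list_to_module(doc$root, "/root")
  if (!inherits(root, "bg_module")) stop("/root: must be a module")
  bondgraph_model(root,
                  chemostats = unlist(doc$chemostats) %||% character(),
                  x0 = unlist(doc$x0) %||% numeric(),
                  temperature = doc$temperature %||% 310.15)
}

list_to_module <- function(node, where) {
  ty <- node$type
  if (is.null(ty)) stop(where, ": missing 'type'")
  if (ty == "module") {
    m <- bg_module(node$name %||% "module")
    m$children <- lapply(seq_along(node$children), function(i)
      list_to_module(node$children[[i]],
                     paste0(where, "/children/", names(node$children)[i])))
    names(m$children) <- names(node$children)
    m$bonds <- lapply(seq_along(node$bonds), function(i) {
      b <- node$bonds[[i]]
      if (is.null(b$tail) || is.null(b$head))
        stop(sprintf("%s/bonds/%d: a bond needs 'tail' and 'head'", where, i))
      list(tail = parse_portref(b$tail), head = parse_portref(b$head))
    })
    m$exposed <- lapply(node$exposed, parse_portref)
    m
  } else if (ty == "species") {
    bg_species(K = node$K %||% NA_real_)
  } else if (ty == "reaction") {
    law <- switch(node$law,
      MA = mass_action(node$kappa %||% NA_real_),
      MM = michaelis_menten(node$kappa_bar %||% NA_real_,
                            node$e0 %||% NA_real_,
                            node$Rb0 %||% NA_real_, node$Rb1 %||% NA_real_),
      GK = generalised_kinetics(node$kappa_bar %||% NA_real_,
                                node$e0 %||% NA_real_,
                                unlist(node$Rb_f), unlist(node$Rb_r)),
      stop(where, ": unknown rate law '", node$law, "'"))
    bg_reaction(law)
  } else if (ty == "junction") {
    j <- bg_junction(node$kind)
    j$nports <- as.integer(node$nports %||% 0L)
    j
  } else stop(where, ": unknown component type '", ty, "'")
}

#' Generate a random, detailed-balance-consistent fixture network
#'
#' Draws a small mass-action reaction network with parameters sampled in
#' thermodynamic space (log-uniform `K` and `kappa`), which makes the
#' model thermodynamically consistent by construction: any cycle's
#' equilibrium-constant product is exactly one.  The same seed always
#' yields an identical model (and identical serialised document).
#'
#' @param seed integer seed.
#' @param n_species number of species (>= 2).
#' @param shape `"chain"` (S1 <-> S2 <-> ...), `"cycle"` (chain closed
#'   into a ring), or `"random"` (random 1-2 reactant/product picks).
#' @param chemostats optional species names to chemostat.
#' @param log10_range ranges for log10 K and log10 kappa.
#' @return a [bondgraph_model()] with random positive `x0`.
#' @export
generate_fixture <- function(seed, n_species = 5,
                             shape = c("chain", "cycle", "random"),
                             chemostats = character(),
                             log10_range = c(-2, 2)) {
  shape <- match.arg(shape)
  stopifnot(n_species >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  sp <- paste0("S", seq_len(n_species))
  K <- stats::setNames(10^stats::runif(n_species, log10_range[1], log10_range[2]), sp)
  draw_kappa <- function() 10^stats::runif(1, log10_range[1], log10_range[2])
  rxns <- list()
  if (shape %in% c("chain", "cycle")) {
    ends <- if (shape == "cycle") n_species else n_species - 1
    for (i in seq_len(ends)) {
      j <- if (i == n_species) 1L else i + 1L
      rxns[[paste0("R", i)]] <-
        rxn(stats::setNames(1, sp[i]), stats::setNames(1, sp[j]),
            mass_action(draw_kappa()))
    }
  } else {
    for (i in seq_len(n_species)) {
      nf <- sample(1:2, 1)
      nf <- min(nf, n_species - 1L)
      from <- sample(sp, nf)
      nr <- min(sample(1:2, 1), n_species - nf)
      to <- sample(setdiff(sp, from), nr)
      rxns[[paste0("R", i)]] <-
        rxn(stats::setNames(rep(1, nf), from), stats::setNames(rep(1, nr), to),
            mass_action(draw_kappa()))
    }
  }
  x0 <- stats::setNames(10^stats::runif(n_species, -1, 1) / K, sp)
  root <- reaction_network(species = K, reactions = rxns, name = "fixture")
  bondgraph_model(root, chemostats = chemostats, x0 = x0)
}
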