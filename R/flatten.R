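#' Flatten a hierarchical model
#'
#' Recursively replaces modules by their definitions, producing a flat list
#' of leaf components (species, reactions, junctions) under namespaced
#' dot-paths, and a flat bond list with all exposed-port indirection
#' resolved.  The flat graph induces exactly the same equations as the
#' hierarchy; flattening is idempotent.
#'
#' @param x a [bondgraph_model()], a [bg_module()], or an already-flat
#'   model (returned unchanged).
#' @param check validate that every non-exposed port is bonded and that
#'   all parameters are bound (default `TRUE` for models).
#' @return a `bg_flat` object with elements `components` (named list),
#'   `kinds`, `bonds`, and — when flattening a model — `chemostats`, `x0`
#'   and `temperature`.
#' @export
bg_flatten <- function(x, check = inherits(x, "bondgraph_model")) {
  if (inherits(x, "bg_flat")) return(x)
  if (inherits(x, "bondgraph_model")) {
    fl <- flatten_module(x$root, "")
    fl$chemostats <- x$chemostats
    fl$x0 <- x$x0
    fl$temperature <- x$temperature
  } else if (inherits(x, "bg_module")) {
    fl <- flatten_module(x, "")
    fl$chemostats <- character()
    fl$x0 <- numeric()
    fl$temperature <- 310.15
  } else stop("cannot flatten object of class ", paste(class(x), collapse = "/"))
  fl$kinds <- vapply(fl$components, function(c) c$kind, "")
  class(fl) <- "bg_flat"
  if (check) validate_flat(fl)
  fl
}

## Resolve (path, port) inside `module` down to a leaf, returning the fully
## namespaced flat reference.
resolve_leaf <- function(module, path, port, prefix) {
  node <- get_child(module, path)
  full <- if (nzchar(prefix)) paste0(prefix, ".", path) else path
  if (inherits(node, "bg_module")) {
    ex <- node$exposed[[port]]
    if (is.null(ex))
      stop(sprintf("module '%s' exposes no port '%s'", full, port))
    return(resolve_leaf(node, ex$path, ex$port, full))
  }
  list(path = full, port = port)
}

flatten_module <- function(module, prefix) {
  comps <- list()
  bonds <- list()
  for (nm in names(module$children)) {
    ch <- module$children[[nm]]
    full <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (inherits(ch, "bg_module")) {
      sub <- flatten_module(ch, full)
      comps <- c(comps, sub$components)
      bonds <- c(bonds, sub$bonds)
    } else {
      comps[[full]] <- ch
    }
  }
  for (b in module$bonds) {
    t <- resolve_leaf(module, b$tail$path, b$tail$port, prefix)
    h <- resolve_leaf(module, b$head$path, b$head$port, prefix)
    bonds[[length(bonds) + 1L]] <- list(tail = t, head = h)
  }
  list(components = comps, bonds = bonds)
}

validate_flat <- function(fl) {
  ## ports referenced by bonds, per component
  used <- list()
  for (b in fl$bonds) {
    for (end in list(b$tail, b$head)) {
      key <- paste0(end$path, ":", end$port)
      if (!is.null(used[[key]]))
        stop(sprintf("port '%s' participates in more than one bond", key))
      used[[key]] <- TRUE
    }
  }
  for (nm in names(fl$components)) {
    comp <- fl$components[[nm]]
    need <- switch(comp$kind,
      species  = "p",
      reaction = c("f", "r"),
      junction = if (is.null(comp$nports) || comp$nports == 0L) character()
                 else paste0("b", seq_len(comp$nports)))
    for (p in need)
      if (is.null(used[[paste0(nm, ":", p)]]))
        stop(sprintf("dangling port '%s:%s' (unbonded and not exposed)", nm, p))
    ## unbound parameters
    if (comp$kind == "species" && is.na(comp$params$K))
      stop(sprintf("unbound parameter '%s:K'", nm))
    if (comp$kind == "reaction") {
      for (pn in names(comp$law$params))
        if (anyNA(comp$law$params[[pn]]))
          stop(sprintf("unbound parameter '%s:%s'", nm, pn))
    }
  }
  ## chemostats must name species
  sp <- names(fl$components)[fl$kinds == "species"]
  bad <- setdiff(fl$chemostats, sp)
  if (length(bad))
    stop("unknown chemostat species: ", paste(bad, collapse = ", "))
  invisible(fl)
}

#' @export
print.bg_flat <- function(x, ...) {
  cat(sprintf("<bg_flat: %d species, %d reactions, %d junctions, %d bonds>\n",
              sum(x$kinds == "species"), sum(x$kinds == "reaction"),
              sum(x$kinds == "junction"), length(x$bonds)))
  invisible(x)
}
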