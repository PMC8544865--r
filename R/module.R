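#' Composite modules and hierarchical composition
#'
#' A `bg_module` is a named collection of child components and sub-modules,
#' bonds between their ports, and a set of \emph{exposed} ports through
#' which the module can be wired into a larger model.  Modules are plain
#' values: composing, connecting and instantiating never mutates an
#' existing object, so templates can be reused freely.
#'
#' Ports are addressed with dot-separated instance paths followed by an
#' optional `:port` suffix, e.g. `"cascade.L2.kinase:E"`.  For species the
#' port may be omitted (they have a single port `"p"`); reactions use ports
#' `"f"` and `"r"`; junction ports are allocated automatically when a bond
#' or exposure is attached.  A port participates in at most one bond.
#'
#' @param name module name.
#' @return a `bg_module`.
#' @seealso [bg_add()], [bg_connect()], [bg_expose()], [bg_instantiate()]
#' @export
bg_module <- function(name = "module") {
  structure(list(name = name, children = list(), bonds = list(),
                 exposed = list()),
            class = "bg_module")
}

#' Add a child component or sub-module
#'
#' @param module a [bg_module()].
#' @param child a `bg_component` or `bg_module` to add.
#' @param name instance name; must be unique within `module` and must not
#'   contain the reserved characters `.` or `:`.
#' @return the extended module.
#' @export
bg_add <- function(module, child, name) {
  stopifnot(inherits(module, "bg_module"))
  if (!inherits(child, "bg_component") && !inherits(child, "bg_module"))
    stop("child must be a bg_component or bg_module")
  if (grepl("[.:]", name) || !nzchar(name))
    stop(sprintf("invalid instance name '%s': must be non-empty without '.' or ':'", name))
  if (name %in% names(module$children))
    stop(sprintf("duplicate instance name '%s'", name))
  module$children[[name]] <- child
  module
}

## ---- port references ------------------------------------------------------

parse_portref <- function(ref) {
  parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
  if (length(parts) > 2) stop(sprintf("invalid port reference '%s'", ref))
  list(path = parts[[1]], port = if (length(parts) == 2) parts[[2]] else NA_character_)
}

get_child <- function(module, path) {
  segs <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- module
  for (s in segs) {
    if (!inherits(node, "bg_module") || is.null(node$children[[s]]))
      stop(sprintf("cannot resolve path '%s' (missing '%s')", path, s))
    node <- node$children[[s]]
  }
  node
}

set_child <- function(module, path, value) {
  segs <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(segs) == 1) {
    module$children[[segs]] <- value
  } else {
    sub <- module$children[[segs[1]]]
    module$children[[segs[1]]] <-
      set_child(sub, paste(segs[-1], collapse = "."), value)
  }
  module
}

## Normalise a (path, port) pair: fill in default ports, allocate junction
## ports on demand.  Returns list(module=, path=, port=) because junction
## allocation updates a counter on the junction component.
normalise_port <- function(module, ref, what = "bond") {
  pr <- parse_portref(ref)
  node <- get_child(module, pr$path)
  if (inherits(node, "bg_module")) {
    if (is.na(pr$port))
      stop(sprintf("'%s' is a module; an exposed port label is required", pr$path))
    if (is.null(node$exposed[[pr$port]]))
      stop(sprintf("module '%s' exposes no port '%s'", pr$path, pr$port))
    return(list(module = module, path = pr$path, port = pr$port))
  }
  if (node$kind == "species") {
    if (is.na(pr$port)) pr$port <- "p"
    if (pr$port != "p") stop(sprintf("species '%s' has only port 'p'", pr$path))
  } else if (node$kind == "reaction") {
    if (is.na(pr$port) || !pr$port %in% c("f", "r"))
      stop(sprintf("reaction '%s' requires port 'f' or 'r'", pr$path))
  } else { # junction
    if (is.na(pr$port)) {
      n <- if (is.null(node$nports)) 0L else node$nports
      node$nports <- n + 1L
      pr$port <- paste0("b", n + 1L)
      module <- set_child(module, pr$path, node)
    }
  }
  list(module = module, path = pr$path, port = pr$port)
}

port_in_use <- function(module, path, port) {
  for (b in module$bonds)
    if ((b$tail$path == path && b$tail$port == port) ||
        (b$head$path == path && b$head$port == port)) return(TRUE)
  for (e in module$exposed)
    if (e$path == path && identical(e$port, port)) return(TRUE)
  FALSE
}

#' Connect two ports with a bond
#'
#' Creates an energy bond between two ports of the module's children.  The
#' bond is lossless: both ends share one chemical potential and one molar
#' flow.  Positive flux runs from `tail` to `head`.
#'
#' @param module a [bg_module()].
#' @param tail,head port references such as `"kinase:E"`, `"r1:f"` or a
#'   junction path (a fresh junction port is allocated automatically).
#' @return the module with one more bond.
#' @export
bg_connect <- function(module, tail, head) {
  stopifnot(inherits(module, "bg_module"))
  a <- normalise_port(module, tail); module <- a$module
  b <- normalise_port(module, head); module <- b$module
  if (a$path == b$path && a$port == b$port)
    stop("cannot bond a port to itself")
  for (p in list(a, b))
    if (port_in_use(module, p$path, p$port))
      stop(sprintf("port '%s:%s' is already bonded or exposed", p$path, p$port))
  module$bonds[[length(module$bonds) + 1L]] <-
    list(tail = list(path = a$path, port = a$port),
         head = list(path = b$path, port = b$port))
  module
}

#' Expose an internal port under an external label
#'
#' An exposed port stays free for exactly one bond in an enclosing module;
#' it is how modules present their interface (e.g. the `E`, `X`, `XP`,
#' `ATP`, `ADP` ports of a kinase module).
#'
#' @param module a [bg_module()].
#' @param label external label, unique within the module.
#' @param ref internal port reference (see [bg_connect()]).
#' @return the module with the exposure recorded.
#' @export
bg_expose <- function(module, label, ref) {
  stopifnot(inherits(module, "bg_module"))
  if (label %in% names(module$exposed))
    stop(sprintf("port label '%s' already exposed", label))
  p <- normalise_port(module, ref); module <- p$module
  if (port_in_use(module, p$path, p$port))
    stop(sprintf("port '%s:%s' is already bonded or exposed", p$path, p$port))
  module$exposed[[label]] <- list(path = p$path, port = p$port)
  module
}

## ---- parameters -----------------------------------------------------------

## Enumerate all parameters of a module as "path:param" -> value.
bg_params <- function(module, prefix = "") {
  out <- list()
  for (nm in names(module$children)) {
    ch <- module$children[[nm]]
    p <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (inherits(ch, "bg_module")) {
      out <- c(out, bg_params(ch, p))
    } else if (ch$kind == "species") {
      out[[paste0(p, ":K")]] <- ch$params$K
    } else if (ch$kind == "reaction") {
      for (pn in names(ch$law$params))
        out[[paste0(p, ":", pn)]] <- ch$law$params[[pn]]
    }
  }
  out
}

set_param <- function(module, path, param, value) {
  node <- get_child(module, path)
  if (inherits(node, "bg_module"))
    stop(sprintf("'%s' is a module, not a component", path))
  if (node$kind == "species") {
    if (param != "K") stop(sprintf("species '%s' has no parameter '%s'", path, param))
    node$params$K <- as.numeric(value)
  } else if (node$kind == "reaction") {
    if (!param %in% names(node$law$params))
      stop(sprintf("reaction '%s' (%s law) has no parameter '%s'",
                   path, node$law$type, param))
    node$law$params[[param]] <- as.numeric(value)
  } else stop(sprintf("junction '%s' has no parameters", path))
  set_child(module, path, node)
}

#' Instantiate a module template
#'
#' Returns a deep, independent copy of `template` with the given name and
#' optional parameter overrides.  Instances never alias state or
#' parameters: modifying one copy cannot affect another.
#'
#' @param template a [bg_module()] used as a template.
#' @param name name of the new instance.
#' @param overrides named list of parameter overrides, keyed by
#'   `"path:param"` (e.g. `list("kinase.r1:kappa" = 2)`).  Unknown keys are
#'   an error.
#' @return a new `bg_module`.
#' @export
bg_instantiate <- function(template, name = template$name, overrides = list()) {
  stopifnot(inherits(template, "bg_module"))
  inst <- template
  inst$name <- name
  if (length(overrides)) {
    known <- names(bg_params(inst))
    for (key in names(overrides)) {
      if (!key %in% known)
        stop(sprintf("unknown parameter '%s' (template declares: %s)",
                     key, paste(utils::head(known, 8), collapse = ", ")))
      pr <- parse_portref(key)
      inst <- set_param(inst, pr$path, pr$port, overrides[[key]])
    }
  }
  inst
}

#' @export
print.bg_module <- function(x, ...) {
  kinds <- vapply(x$children, function(ch)
    if (inherits(ch, "bg_module")) "module" else ch$kind, "")
  cat(sprintf("<bg_module '%s': %d children (%s), %d bonds, %d exposed ports>\n",
              x$name, length(x$children),
              paste(sprintf("%d %s", table(kinds), names(table(kinds))),
                    collapse = ", "),
              length(x$bonds), length(x$exposed)))
  if (length(x$exposed))
    cat("  ports:", paste(names(x$exposed), collapse = ", "), "\n")
  invisible(x)
}

#' Wrap a root module into a runnable model
#'
#' A `bondgraph_model` pairs a root module with the run-time context: the
#' chemostat set (species whose amounts are held fixed, modelling exchange
#' with the environment), initial state, and temperature.
#'
#' @param root a [bg_module()] whose non-exposed ports are all bonded.
#' @param chemostats character vector of species names (flattened
#'   dot-paths) to hold fixed.
#' @param x0 named numeric vector of initial amounts/concentrations;
#'   unlisted species start at 0.
#' @param temperature absolute temperature in K (default 310.15).
#' @return a `bondgraph_model`.
#' @export
bondgraph_model <- function(root, chemostats = character(), x0 = numeric(),
                            temperature = 310.15) {
  stopifnot(inherits(root, "bg_module"), temperature > 0)
  structure(list(root = root, chemostats = chemostats, x0 = x0,
                 temperature = temperature),
            class = "bondgraph_model")
}

#' @export
print.bondgraph_model <- function(x, ...) {
  fl <- bg_flatten(x)
  cat(sprintf("<bondgraph_model: %d species, %d reactions, %d junctions, %d bonds>\n",
              sum(fl$kinds == "species"), sum(fl$kinds == "reaction"),
              sum(fl$kinds == "junction"), length(fl$bonds)))
  if (length(x$chemostats))
    cat("  chemostats:", paste(x$chemostats, collapse = ", "), "\n")
  cat(sprintf("  T = %g K\n", x$temperature))
  invisible(x)
}
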