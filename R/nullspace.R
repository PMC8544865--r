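## Exact rational linear algebra for small integer matrices.
##
## Stoichiometric matrices are small with entries of magnitude <= 3, so
## exact Gauss-Jordan elimination over the rationals (numerator/denominator
## kept as exactly-representable doubles) is cheap and avoids any
## floating-point rank ambiguity in moiety and pathway analysis.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}
gcdv <- function(v) Reduce(gcd2, abs(v[v != 0]), accumulate = FALSE)

rat_reduce <- function(num, den) {
  stopifnot(all(den != 0))
  g <- mapply(gcd2, abs(num), abs(den))
  g[g == 0] <- 1
  num <- num / g; den <- den / g
  num[den < 0] <- -num[den < 0]
  den <- abs(den)
  list(num = num, den = den)
}

## Reduced row echelon form over the rationals.  A: integer matrix.
rref_rational <- function(A) {
  m <- nrow(A); n <- ncol(A)
  num <- A * 1.0
  den <- matrix(1, m, n)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    piv <- which(num[row:m, col] != 0)
    if (!length(piv)) next
    piv <- piv[1] + row - 1L
    if (piv != row) {
      num[c(row, piv), ] <- num[c(piv, row), ]
      den[c(row, piv), ] <- den[c(piv, row), ]
    }
    ## scale pivot row to 1
    pn <- num[row, col]; pd <- den[row, col]
    r <- rat_reduce(num[row, ] * pd, den[row, ] * pn)
    num[row, ] <- r$num; den[row, ] <- r$den
    for (i in seq_len(m)) {
      if (i == row || num[i, col] == 0) next
      fn <- num[i, col]; fd <- den[i, col]
      ## row_i <- row_i - f * row_row
      nn <- num[i, ] * fd * den[row, ] - fn * num[row, ] * den[i, ]
      dd <- den[i, ] * fd * den[row, ]
      r <- rat_reduce(nn, dd)
      num[i, ] <- r$num; den[i, ] <- r$den
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(num = num, den = den, pivots = pivots)
}

## Integer basis of the right null space of an integer matrix.
## Returns an n x k integer matrix (k = nullity), each column scaled to a
## minimal integer vector whose first nonzero entry is positive.
null_basis_int <- function(A) {
  n <- ncol(A)
  if (nrow(A) == 0 || n == 0)
    return(diag(1L, n))
  R <- rref_rational(A)
  pivots <- R$pivots
  free <- setdiff(seq_len(n), pivots)
  basis <- matrix(0, n, length(free))
  for (k in seq_along(free)) {
    f <- free[k]
    xn <- numeric(n); xd <- rep(1, n)
    xn[f] <- 1
    for (i in seq_along(pivots)) {
      xn[pivots[i]] <- -R$num[i, f]
      xd[pivots[i]] <- R$den[i, f]
    }
    l <- Reduce(function(a, b) a / gcd2(a, b) * b, xd)   # lcm of denominators
    v <- round(xn * (l / xd))
    g <- gcdv(v); if (is.null(g) || g == 0) g <- 1
    v <- v / g
    fz <- v[v != 0][1]
    if (!is.na(fz) && fz < 0) v <- -v
    basis[, k] <- v
  }
  basis
}

#' Conserved moieties of a stoichiometric matrix
#'
#' Computes an integer basis of the left null space of the stoichiometric
#' matrix restricted to non-chemostat species: weighted species totals
#' \eqn{g^T x} that are invariant along every trajectory of the closed
#' (non-chemostatted) part of the system, e.g. total enzyme across free and
#' bound forms.  Computed in exact rational arithmetic and scaled to
#' minimal integer vectors, in species declaration order.
#'
#' @param x a model (anything accepted by [build_stoichiometry()]) or a
#'   stoichiometry list as returned by it.
#' @param chemostats optional character vector overriding the model's
#'   chemostat set.
#' @return integer matrix with one column per moiety; rows are named by
#'   the non-chemostat species.
#' @export
conserved_moieties <- function(x, chemostats = NULL) {
  st <- as_stoich(x)
  chem <- chem_mask(st, chemostats)
  Ni <- st$N[!chem, , drop = FALSE]
  b <- null_basis_int(t(Ni))
  rownames(b) <- st$species[!chem]
  b
}

#' Steady-state pathway vector
#'
#' For an open (chemostatted) network whose internal stoichiometric matrix
#' has a one-dimensional right null space, returns the unique minimal
#' integer reaction weighting \eqn{w} with \eqn{N_{int} w = 0}: the pathway
#' as a sum of reactions, normalised so its first nonzero weight (in
#' reaction declaration order) is positive.
#'
#' @inheritParams conserved_moieties
#' @param exclude reaction names to leave out of the pathway (e.g.
#'   switched-off enzymes); their weights are reported as 0.
#' @return named integer vector of reaction weights.
#' @export
steady_state_pathway <- function(x, chemostats = NULL, exclude = character()) {
  st <- as_stoich(x)
  chem <- chem_mask(st, chemostats)
  keep <- !(st$reactions %in% exclude)
  Ni <- st$N[!chem, keep, drop = FALSE]
  b <- null_basis_int(Ni)
  if (ncol(b) != 1)
    stop(sprintf("internal null space has dimension %d (expected 1); %s",
                 ncol(b),
                 if (ncol(b)) "decompose the network into elementary pathways"
                 else "the network supports no steady flux"))
  w <- stats::setNames(integer(length(st$reactions)), st$reactions)
  w[keep] <- as.integer(b[, 1])
  w
}

as_stoich <- function(x) {
  if (is.list(x) && !is.null(x$N) && !is.null(x$sites_f)) x
  else build_stoichiometry(x)
}

chem_mask <- function(st, chemostats) {
  if (is.null(chemostats)) return(st$chemostats)
  bad <- setdiff(chemostats, st$species)
  if (length(bad)) stop("unknown chemostat species: ", paste(bad, collapse = ", "))
  st$species %in% chemostats
}
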