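#' Construct a reaction
#'
#' A reaction transforms one complex (a formal nonnegative-integer combination
#' of species, e.g. `X + Y`) into another at a mass-action rate constant.
#' Complexes are given as named numeric vectors of stoichiometric
#' coefficients; species absent from a complex are implicitly zero. The empty
#' complex (for synthesis/degradation reactions such as `P -> 0`) is written
#' as an empty vector, `numeric(0)`.
#'
#' @param reactants named numeric vector of reactant coefficients (all >= 0).
#' @param products named numeric vector of product coefficients (all >= 0).
#' @param rate positive mass-action rate constant.
#' @return an object of class `"reaction"`.
#' @examples
#' reaction(c(X = 1, Y = 1), c(Z = 1), rate = 1)
#' reaction(c(P = 1), numeric(0), rate = 0.5)  # degradation
#' @export
reaction <- function(reactants, products, rate = 1) {
  reactants <- validate_complex(reactants, "reactants")
  products <- validate_complex(products, "products")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a single positive finite number", call. = FALSE)
  if (identical(sort_complex(reactants), sort_complex(products)))
    stop("reactant and product complexes are identical", call. = FALSE)
  structure(list(reactants = reactants, products = products, rate = rate),
            class = "reaction")
}

validate_complex <- function(x, what) {
  if (length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (!is.numeric(x) || is.null(names(x)) || anyNA(x) || any(names(x) == ""))
    stop("'", what, "' must be a named numeric vector", call. = FALSE)
  if (any(x < 0) || any(x != round(x)))
    stop("'", what, "' coefficients must be nonnegative integers", call. = FALSE)
  x <- x[x > 0]  # drop explicit zeros; the empty complex is length 0
  if (anyDuplicated(names(x)))
    stop("duplicate species in '", what, "'", call. = FALSE)
  x
}

sort_complex <- function(x) x[order(names(x))]

#' Construct a reaction network
#'
#' @param species character vector of unique species names; fixes the
#'   coordinate order of every vector the package reports.
#' @param reactions list of [reaction()] objects (or lists with `reactants`,
#'   `products`, `rate` fields, which are coerced).
#' @return an object of class `"reaction_network"`.
#' @examples
#' net <- reaction_network(
#'   c("X", "Y", "Z"),
#'   list(reaction(c(X = 1, Y = 1), c(Z = 1), 1),
#'        reaction(c(Z = 1), c(X = 1, Y = 1), 1)))
#' @export
reaction_network <- function(species, reactions) {
  if (!is.character(species) || length(species) == 0L || anyDuplicated(species))
    stop("'species' must be a nonempty character vector of unique names",
         call. = FALSE)
  if (!is.list(reactions) || length(reactions) == 0L)
    stop("'reactions' must be a nonempty list", call. = FALSE)
  reactions <- lapply(reactions, function(r) {
    if (!inherits(r, "reaction"))
      r <- reaction(unlist_complex(r$reactants), unlist_complex(r$products),
                    r$rate)
    used <- union(names(r$reactants), names(r$products))
    bad <- setdiff(used, species)
    if (length(bad))
      stop("reaction references undeclared species: ",
           paste(bad, collapse = ", "), call. = FALSE)
    r
  })
  structure(list(species = species, reactions = reactions),
            class = "reaction_network")
}

unlist_complex <- function(x) {
  if (is.null(x) || length(x) == 0L) return(numeric(0))
  unlist(x)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("reaction_network:", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  fmt <- function(cx) {
    if (length(cx) == 0L) return("0")
    paste(ifelse(cx == 1, names(cx), paste0(cx, " ", names(cx))),
          collapse = " + ")
  }
  for (r in x$reactions)
    cat(sprintf("  %s -> %s   (k = %g)\n", fmt(r$reactants), fmt(r$products),
                r$rate))
  invisible(x)
}

#' Reaction vector of a single reaction
#'
#' The reaction vector is products-minus-reactants, in the species order of
#' the network (`X + Y -> Z` over `(X, Y, Z)` gives `(-1, -1, 1)`).
#'
#' @param reaction a [reaction()].
#' @param species character vector fixing coordinate order (usually
#'   `network$species`).
#' @return numeric vector named by species.
#' @export
reaction_vector <- function(reaction, species) {
  used <- union(names(reaction$reactants), names(reaction$products))
  bad <- setdiff(used, species)
  if (length(bad))
    stop("reaction references species outside the given order: ",
         paste(bad, collapse = ", "), call. = FALSE)
  v <- stats::setNames(numeric(length(species)), species)
  v[names(reaction$products)] <- v[names(reaction$products)] + reaction$products
  v[names(reaction$reactants)] <- v[names(reaction$reactants)] - reaction$reactants
  v
}

#' Matrix of reaction vectors
#'
#' @param network a [reaction_network()].
#' @return numeric matrix, species in rows, one column per reaction.
#' @export
reaction_matrix <- function(network) {
  stopifnot(inherits(network, "reaction_network"))
  vapply(network$reactions, reaction_vector, numeric(length(network$species)),
         species = network$species)
}

# Relative singular-value cutoff used for every rank/span decision.
.rank_tol <- 1e-10

#' Orthonormal basis for the span of a matrix's columns
#'
#' Singular values below `tol` times the largest are treated as zero.
#'
#' @param m numeric matrix (columns are spanning vectors).
#' @param tol relative singular-value tolerance.
#' @return matrix with orthonormal columns (possibly zero columns).
#' @export
orthonormal_span <- function(m, tol = .rank_tol) {
  m <- as.matrix(m)
  s <- svd(m)
  if (length(s$d) == 0L || max(s$d) == 0)
    return(matrix(0, nrow(m), 0))
  r <- sum(s$d > tol * max(s$d))
  s$u[, seq_len(r), drop = FALSE]
}

#' Stoichiometric subspace
#'
#' Orthonormal basis of the linear span of all reaction vectors and its
#' dimension `s` (the rank of the stacked reaction vectors).
#'
#' @param network a [reaction_network()].
#' @return list with `basis` (species x s orthonormal matrix, rownames =
#'   species) and `dim`.
#' @export
stoichiometric_subspace <- function(network) {
  basis <- orthonormal_span(reaction_matrix(network))
  rownames(basis) <- network$species
  list(basis = basis, dim = ncol(basis))
}

#' Conservation-law basis
#'
#' Orthonormal basis of the orthogonal complement of the stoichiometric
#' subspace in concentration space: every returned vector `w` satisfies
#' `w . v = 0` for all reaction vectors `v`, so `w . c(t)` is constant along
#' any mass-action trajectory (forward invariance of stoichiometric cosets).
#'
#' @param network a [reaction_network()].
#' @return matrix with orthonormal columns, `n_species - s` of them.
#' @export
conservation_basis <- function(network) {
  V <- reaction_matrix(network)
  n <- nrow(V)
  s <- svd(V, nu = n)
  r <- if (max(s$d) == 0) 0L else sum(s$d > .rank_tol * max(s$d))
  W <- s$u[, setdiff(seq_len(n), seq_len(r)), drop = FALSE]
  rownames(W) <- network$species
  W
}

#' Distinct complexes of a network
#'
#' @param network a [reaction_network()].
#' @return list of named coefficient vectors, one per distinct complex; the
#'   empty complex appears as `numeric(0)`.
#' @export
network_complexes <- function(network) {
  keys <- character(0)
  out <- list()
  for (r in network$reactions) {
    for (cx in list(r$reactants, r$products)) {
      key <- complex_key(cx)
      if (!key %in% keys) {
        keys <- c(keys, key)
        out[[length(out) + 1L]] <- cx
      }
    }
  }
  names(out) <- keys
  out
}

complex_key <- function(cx) {
  if (length(cx) == 0L) return("0")
  cx <- sort_complex(cx)
  paste(cx, names(cx), sep = "*", collapse = "+")
}

#' Complex digraph
#'
#' The directed graph whose nodes are the distinct complexes and whose edges
#' are the reactions.
#'
#' @param network a [reaction_network()].
#' @return an [igraph::graph] object.
#' @export
complex_graph <- function(network) {
  cxs <- network_complexes(network)
  edges <- vapply(network$reactions,
                  function(r) c(complex_key(r$reactants),
                                complex_key(r$products)),
                  character(2))
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(cxs), name = names(cxs))
  igraph::add_edges(g, as.vector(edges))
}

#' Deficiency of a reaction network
#'
#' `delta = n - l - s`, with `n` the number of distinct complexes, `l` the
#' number of linkage classes (weakly connected components of the complex
#' digraph) and `s` the dimension of the stoichiometric subspace. Deficiency
#' zero together with weak reversibility is the sufficient condition for
#' complex balancing used throughout the package.
#'
#' @param network a [reaction_network()].
#' @return nonnegative integer.
#' @export
deficiency <- function(network) {
  g <- complex_graph(network)
  n <- igraph::vcount(g)
  l <- igraph::count_components(g, mode = "weak")
  s <- stoichiometric_subspace(network)$dim
  as.integer(n - l - s)
}

#' Weak reversibility
#'
#' TRUE iff every linkage class of the complex digraph is a single strongly
#' connected component, i.e. every reaction lies on a directed cycle.
#'
#' @param network a [reaction_network()].
#' @return logical scalar.
#' @export
is_weakly_reversible <- function(network) {
  g <- complex_graph(network)
  igraph::count_components(g, mode = "strong") ==
    igraph::count_components(g, mode = "weak")
}

#' Mass-action right-hand side
#'
#' Returns the vector field of the mass-action ODE system: the rate of
#' reaction `j` is `k_j * prod(c^a_j)` over its reactant coefficients `a_j`,
#' and `dc/dt` is the reaction matrix times the rate vector.
#'
#' @param network a [reaction_network()].
#' @return function mapping a nonnegative concentration vector (in species
#'   order) to the vector of time derivatives.
#' @export
mass_action_rhs <- function(network) {
  V <- reaction_matrix(network)
  species <- network$species
  rates <- vapply(network$reactions, `[[`, numeric(1), "rate")
  # reactant exponents, species x reactions
  A <- vapply(network$reactions, function(r) {
    a <- stats::setNames(numeric(length(species)), species)
    a[names(r$reactants)] <- r$reactants
    a
  }, numeric(length(species)))
  tA <- t(A)
  function(conc) {
    if (length(conc) != length(species))
      stop("concentration vector has wrong length", call. = FALSE)
    if (any(conc < 0))
      stop("negative concentrations are outside the mass-action domain",
           call. = FALSE)
    # prod(c^a) per reaction as exp(A' log c); a zero exponent contributes
    # exactly 0 * log(clipped c) = 0, preserving the 0^0 = 1 convention
    lc <- log(pmax(conc, 1e-300))
    flux <- rates * exp(drop(tA %*% lc))
    stats::setNames(drop(V %*% flux), species)
  }
}

#' Residual of a log-linear constraint on snapshot data
#'
#' For a constraint vector `v` (a candidate net reaction), computes the
#' sample variance and mean of the projection `v . log(c)` across cells. On
#' data lying exactly on the toric steady-state set the variance is zero and
#' the mean estimates `log(K)` for that constraint.
#'
#' @param log_data numeric matrix, cells x channels, already log-transformed.
#' @param vector numeric constraint vector over channels (at least one
#'   nonzero entry).
#' @return list with `variance` (unbiased sample variance) and `intercept`
#'   (sample mean of the projection).
#' @export
constraint_residual <- function(log_data, vector) {
  log_data <- as.matrix(log_data)
  if (nrow(log_data) == 0L) stop("empty data", call. = FALSE)
  if (!all(is.finite(log_data))) stop("log_data must be finite", call. = FALSE)
  if (length(vector) != ncol(log_data))
    stop("constraint vector length does not match channel count", call. = FALSE)
  if (all(vector == 0)) stop("constraint vector is identically zero", call. = FALSE)
  proj <- drop(log_data %*% vector)
  list(variance = if (length(proj) > 1L) stats::var(proj) else 0,
       intercept = mean(proj))
}
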