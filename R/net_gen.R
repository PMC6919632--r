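# Random network generators and the catalog of worked toy networks.

# Run `code` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

rlnorm_lv <- function(n, log_mean, log_variance) {
  stats::rlnorm(n, meanlog = log_mean, sdlog = sqrt(log_variance))
}

#' Random complex-balanced reaction network
#'
#' Generates a random reaction network whose complexes are single species or
#' unordered pairs of distinct species. A fraction of the possible directed
#' edges between distinct complexes is sampled, the edge set is symmetrized
#' (every reaction gains its reverse, so the result is weakly reversible),
#' and rate constants are drawn log-normally from one of two kinetic classes
#' per reversible pair, creating timescale separation. Candidates are
#' rejected until the deficiency is zero, which (with weak reversibility)
#' guarantees a complex-balanced steady state for all rate constants.
#'
#' @param n_species number of species (>= 2). Default 20.
#' @param edge_fraction probability that any ordered pair of distinct
#'   complexes is sampled as an edge before symmetrization. Default 3e-4
#'   (about 0.03 percent).
#' @param rate_log_means log-means of the two kinetic-constant classes; one
#'   class is assigned to each reversible pair uniformly at random.
#' @param rate_log_variance log-variance of the kinetic constants.
#' @param allow_doubled also include doubled complexes such as `2X` as nodes.
#' @param max_attempts rejection budget for the deficiency-zero filter.
#' @param seed optional integer seed (RNG state is restored on exit).
#' @return a [reaction_network()] with attribute `"attempts"`.
#' @export
random_cb_network <- function(n_species = 20, edge_fraction = 3e-4,
                              rate_log_means = c(2.5, 3),
                              rate_log_variance = 0.05,
                              allow_doubled = FALSE,
                              max_attempts = 10000, seed = NULL) {
  stopifnot(n_species >= 2, edge_fraction > 0, edge_fraction <= 1)
  species <- paste0("S", seq_len(n_species))
  # candidate complexes: singles, unordered pairs, optionally doubles
  nodes <- c(lapply(species, function(s) stats::setNames(1, s)),
             utils::combn(species, 2, simplify = FALSE) |>
               lapply(function(p) stats::setNames(c(1, 1), p)))
  if (allow_doubled)
    nodes <- c(nodes, lapply(species, function(s) stats::setNames(2, s)))
  n_nodes <- length(nodes)

  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      # Bernoulli sample of ordered distinct node pairs
      n_possible <- n_nodes * (n_nodes - 1)
      m <- stats::rbinom(1, n_possible, edge_fraction)
      if (m == 0) next
      picked <- sample.int(n_possible, m)
      from <- (picked - 1) %/% (n_nodes - 1) + 1
      off <- (picked - 1) %% (n_nodes - 1) + 1
      to <- ifelse(off >= from, off + 1, off)
      # symmetrize: unordered reversible pairs
      pairs <- unique(t(apply(cbind(from, to), 1, sort)))
      classes <- sample(rate_log_means, nrow(pairs), replace = TRUE)
      reactions <- list()
      for (i in seq_len(nrow(pairs))) {
        kk <- rlnorm_lv(2, classes[i], rate_log_variance)
        a <- nodes[[pairs[i, 1]]]
        b <- nodes[[pairs[i, 2]]]
        reactions <- c(reactions, list(reaction(a, b, kk[1]),
                                       reaction(b, a, kk[2])))
      }
      net <- reaction_network(species, reactions)
      if (deficiency(net) == 0L) {
        attr(net, "attempts") <- attempt
        return(net)
      }
    }
    stop("no deficiency-zero network found in ", max_attempts, " attempts",
         call. = FALSE)
  })
}

#' Random gene regulatory network
#'
#' Builds the non-complex-balanced gene regulatory network class: `n` genes
#' `Gi`, their proteins `Pi`, and a random ~70 percent of the `n^2` possible
#' protein-bound genes `GiPj`. Reactions are unbound production
#' `Gi -> Gi + Pi`, reversible binding `Gi + Pj <-> GiPj`, bound production
#' `GiPj -> GiPj + Pi`, and degradation `Pi -> 0`. Rate constants are drawn
#' log-normally per class: unbound production (log-mean 1, log-variance 1),
#' bound production (3, 3), binding/unbinding (3, 1); the degradation rate is
#' the fixed value `exp(3)` for every protein.
#'
#' @param n_genes number of genes (>= 2). Default 7.
#' @param bound_fraction fraction of the `n^2` possible bound genes realized.
#' @param seed optional integer seed.
#' @return a [reaction_network()]; attribute `"bound_pairs"` records the
#'   (gene, protein) index pairs realized as bound genes.
#' @export
random_grn <- function(n_genes = 7, bound_fraction = 0.7, seed = NULL) {
  stopifnot(n_genes >= 2, bound_fraction > 0, bound_fraction <= 1)
  genes <- paste0("G", seq_len(n_genes))
  prots <- paste0("P", seq_len(n_genes))
  with_seed(seed, {
    n_bound <- round(bound_fraction * n_genes^2)
    all_pairs <- expand.grid(gene = seq_len(n_genes), prot = seq_len(n_genes))
    sel <- all_pairs[sample.int(nrow(all_pairs), n_bound), , drop = FALSE]
    sel <- sel[order(sel$gene, sel$prot), , drop = FALSE]
    bound <- paste0("G", sel$gene, "P", sel$prot)
    species <- c(genes, prots, bound)
    delta <- exp(3)
    reactions <- list()
    for (i in seq_len(n_genes)) {
      ki <- rlnorm_lv(1, 1, 1)
      reactions <- c(reactions, list(
        reaction(stats::setNames(1, genes[i]),
                 stats::setNames(c(1, 1), c(genes[i], prots[i])), ki)))
    }
    for (b in seq_len(n_bound)) {
      i <- sel$gene[b]; j <- sel$prot[b]
      f <- rlnorm_lv(1, 3, 1)
      r <- rlnorm_lv(1, 3, 1)
      kij <- rlnorm_lv(1, 3, 3)
      gp <- stats::setNames(c(1, 1), c(genes[i], prots[j]))
      bd <- stats::setNames(1, bound[b])
      reactions <- c(reactions, list(
        reaction(gp, bd, f),
        reaction(bd, gp, r),
        reaction(bd, stats::setNames(c(1, 1), c(bound[b], prots[i])), kij)))
    }
    for (i in seq_len(n_genes))
      reactions <- c(reactions, list(
        reaction(stats::setNames(1, prots[i]), numeric(0), delta)))
    net <- reaction_network(species, reactions)
    attr(net, "bound_pairs") <- as.matrix(sel)
    net
  })
}

#' Reversible-binding subnetwork of a GRN
#'
#' Extracts the reversible gene-protein binding reactions from a network
#' produced by [random_grn()] (or any network containing `Gi + Pj <-> GiPj`
#' pairs); its stoichiometric subspace is the reference the fastest-converging
#' covariance eigenvectors are compared with.
#'
#' @param network a GRN [reaction_network()].
#' @return a [reaction_network()] over the same species.
#' @export
grn_binding_subnetwork <- function(network) {
  # true binding (A + B -> AB) and unbinding (AB -> A + B): two unit
  # reactants collapsing into one new species, or the reverse; catalytic
  # production (G -> G + P) shares the shape but keeps its reactant among
  # the products, so it is excluded
  keep <- Filter(function(r) {
    (length(r$reactants) == 2L && length(r$products) == 1L &&
       all(r$reactants == 1) && all(r$products == 1) &&
       !names(r$products) %in% names(r$reactants)) ||
      (length(r$reactants) == 1L && length(r$products) == 2L &&
         all(r$reactants == 1) && all(r$products == 1) &&
         !names(r$reactants) %in% names(r$products))
  }, network$reactions)
  if (length(keep) == 0L) stop("network has no binding reactions", call. = FALSE)
  reaction_network(network$species, keep)
}

toy_catalog_names <- c("xyz", "xyz_slow", "cycle3", "kinase_phosphatase",
                       "kinase_phosphatase_2enz", "kinase_phosphatase_open",
                       "grn2")

#' Worked toy networks
#'
#' Catalog of the small fixture networks used throughout:
#' \describe{
#'   \item{xyz}{`X + Y <-> Z`, `k1 = k-1 = 1`; one-dimensional
#'     stoichiometric subspace spanned by `(-1, -1, 1)`.}
#'   \item{xyz_slow}{the above plus a slow `X <-> Y` with `kf = 0.2`,
#'     `kr = 0.1`, giving two separated timescales.}
#'   \item{cycle3}{the three-species cycle `A -> B <-> C -> A` (rates `k1`,
#'     `k2`/`k_2`, `k3`, default 1) whose steady state obeys
#'     `[A]/[B] = k1 (k_2 + k3) / (k2 k3)`.}
#'   \item{kinase_phosphatase}{`E + S -> E + P`, `F + P -> F + S` (rates
#'     `kf`, `kr`, default 1): toric but not complex-balanced; the log-space
#'     orthogonal complement contains `(1, 1, -1, -1)` over `(E, S, F, P)`.}
#'   \item{kinase_phosphatase_2enz}{two kinases `E1`, `E2` sharing substrate
#'     `S` and product `P` with phosphatase `F` (rates `k1`, `k2`, `kr`).}
#'   \item{kinase_phosphatase_open}{kinase_phosphatase plus enzyme turnover
#'     `2X -> E`, `Y -> E`, `E -> 0` (rates `kx`, `ky`, `delta`), adding a
#'     non-log-linear constraint that leaves the `(1, 1, -1, -1)` relation
#'     intact.}
#'   \item{grn2}{the two-gene regulatory toy: genes `gA`, `gB`, proteins
#'     `pA`, `pB`, bound gene `gAB`; production `gA -> gA + pA` (`kA`),
#'     `gB -> gB + pB` (`kB`), binding `gA + pB <-> gAB` (`f`, `r`), bound
#'     production `gAB -> gAB + pA` (`kAB`), degradation `pA -> 0`,
#'     `pB -> 0` (`delta`). At steady state `kB gB = delta pB`, a log-linear
#'     relation linking `gB` and `pB` in a 1 : -1 ratio.}
#' }
#' Rates printed in the source examples are the defaults; unprinted rates
#' default to 1 and can be overridden by name via `rates`.
#'
#' @param name one of `r paste0('"', toy_catalog_names, '"', collapse = ", ")`.
#' @param rates optional named numeric vector overriding default rate
#'   constants (names as listed above).
#' @return a [reaction_network()].
#' @export
toy_network <- function(name, rates = NULL) {
  if (!name %in% toy_catalog_names)
    stop("unknown toy network '", name, "'; catalog: ",
         paste(toy_catalog_names, collapse = ", "), call. = FALSE)
  defaults <- switch(name,
    xyz = c(k1 = 1, k_1 = 1),
    xyz_slow = c(k1 = 1, k_1 = 1, kf = 0.2, kr = 0.1),
    cycle3 = c(k1 = 1, k2 = 1, k_2 = 1, k3 = 1),
    kinase_phosphatase = c(kf = 1, kr = 1),
    kinase_phosphatase_2enz = c(k1 = 1, k2 = 1, kr = 1),
    kinase_phosphatase_open = c(kf = 1, kr = 1, kx = 1, ky = 1, delta = 1),
    grn2 = c(kA = 1, kB = 1, f = 1, r = 1, kAB = 1, delta = 1))
  k <- defaults
  if (!is.null(rates)) {
    bad <- setdiff(names(rates), names(defaults))
    if (length(bad))
      stop("unknown rate name(s) for '", name, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    k[names(rates)] <- rates
  }
  switch(name,
    xyz = reaction_network(c("X", "Y", "Z"), list(
      reaction(c(X = 1, Y = 1), c(Z = 1), k[["k1"]]),
      reaction(c(Z = 1), c(X = 1, Y = 1), k[["k_1"]]))),
    xyz_slow = reaction_network(c("X", "Y", "Z"), list(
      reaction(c(X = 1, Y = 1), c(Z = 1), k[["k1"]]),
      reaction(c(Z = 1), c(X = 1, Y = 1), k[["k_1"]]),
      reaction(c(X = 1), c(Y = 1), k[["kf"]]),
      reaction(c(Y = 1), c(X = 1), k[["kr"]]))),
    cycle3 = reaction_network(c("A", "B", "C"), list(
      reaction(c(A = 1), c(B = 1), k[["k1"]]),
      reaction(c(B = 1), c(C = 1), k[["k2"]]),
      reaction(c(C = 1), c(B = 1), k[["k_2"]]),
      reaction(c(C = 1), c(A = 1), k[["k3"]]))),
    kinase_phosphatase = reaction_network(c("E", "S", "F", "P"), list(
      reaction(c(E = 1, S = 1), c(E = 1, P = 1), k[["kf"]]),
      reaction(c(F = 1, P = 1), c(F = 1, S = 1), k[["kr"]]))),
    kinase_phosphatase_2enz = reaction_network(
      c("E1", "E2", "S", "F", "P"), list(
        reaction(c(E1 = 1, S = 1), c(E1 = 1, P = 1), k[["k1"]]),
        reaction(c(E2 = 1, S = 1), c(E2 = 1, P = 1), k[["k2"]]),
        reaction(c(F = 1, P = 1), c(F = 1, S = 1), k[["kr"]]))),
    kinase_phosphatase_open = reaction_network(
      c("E", "S", "F", "P", "X", "Y"), list(
        reaction(c(E = 1, S = 1), c(E = 1, P = 1), k[["kf"]]),
        reaction(c(F = 1, P = 1), c(F = 1, S = 1), k[["kr"]]),
        reaction(c(X = 2), c(E = 1), k[["kx"]]),
        reaction(c(Y = 1), c(E = 1), k[["ky"]]),
        reaction(c(E = 1), numeric(0), k[["delta"]]))),
    grn2 = reaction_network(c("gA", "gB", "pA", "pB", "gAB"), list(
      reaction(c(gA = 1), c(gA = 1, pA = 1), k[["kA"]]),
      reaction(c(gB = 1), c(gB = 1, pB = 1), k[["kB"]]),
      reaction(c(gA = 1, pB = 1), c(gAB = 1), k[["f"]]),
      reaction(c(gAB = 1), c(gA = 1, pB = 1), k[["r"]]),
      reaction(c(gAB = 1), c(gAB = 1, pA = 1), k[["kAB"]]),
      reaction(c(pA = 1), numeric(0), k[["delta"]]),
      reaction(c(pB = 1), numeric(0), k[["delta"]]))))
}

#' Table-style rate draw for the two-gene toy GRN
#'
#' Draws a named rate vector for [toy_network]`("grn2")` from the same
#' log-normal classes [random_grn()] uses: production from the unbound gene
#' (log-mean 1, log-variance 1), bound production (3, 3), binding/unbinding
#' (3, 1), degradation fixed at `exp(3)`.
#'
#' @param seed optional integer seed.
#' @return named numeric vector with elements `kA`, `kB`, `f`, `r`, `kAB`,
#'   `delta`.
#' @export
grn2_rates <- function(seed = NULL) {
  with_seed(seed, c(
    kA = rlnorm_lv(1, 1, 1),
    kB = rlnorm_lv(1, 1, 1),
    f = rlnorm_lv(1, 3, 1),
    r = rlnorm_lv(1, 3, 1),
    kAB = rlnorm_lv(1, 3, 3),
    delta = exp(3)))
}
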