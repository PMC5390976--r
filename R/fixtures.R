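# Built-in example models and seeded random instances.
#
# example_model() returns the minimal three-reaction network used throughout
# the documentation (one internal metabolite A, reactions R1: S -> A,
# R2: A -> P, R3: A -> Q with external S, P, Q; R1 and R3 irreversible,
# N = (1, -1, -1)) in all its constraint variants. random_model() generates
# small random networks with a guaranteed-nonempty flux polyhedron for
# property tests; generation is deterministic under the seed.

#' Built-in example model variants
#'
#' @param variant one of:
#'   \describe{
#'     \item{cone}{no constraints (the pure flux cone).}
#'     \item{bounded}{flux bounds r1 <= 2 and r2 >= -1 (a bounded polytope
#'       with five elementary flux vectors).}
#'     \item{optimal_face}{the same bounds plus the equality r2 + r3 = 2
#'       fixing the optimum of the production objective (four constraint
#'       rows, the equality stored as two halves).}
#'     \item{r2_min_1}{the single constraint r2 >= 1 (an unbounded polyhedron
#'       whose yield supremum r3/r1 = 1 is not attained).}
#'     \item{r3_reversible}{no constraints, R3 made reversible (nontrivial
#'       lineality space spanned by (0, -1, 1)).}
#'   }
#' @return list with elements `network` (a `metabolic_network`) and
#'   `constraints` (a `constraint_set`, empty for the cone variants).
#' @export
example_model <- function(variant = c("cone", "bounded", "optimal_face",
                                      "r2_min_1", "r3_reversible")) {
  variant <- match.arg(variant)
  irr <- if (variant == "r3_reversible") "R1" else c("R1", "R3")
  net <- metabolic_network("A", c("R1", "R2", "R3"),
                           matrix(c(1, -1, -1), 1, 3), irr)
  cons <- switch(variant,
    cone = ,
    r3_reversible = build_constraints(net),
    bounded = build_constraints(net, bounds = list(R1 = list(ub = 2),
                                                   R2 = list(lb = -1))),
    optimal_face = build_constraints(net,
      bounds = list(R1 = list(ub = 2), R2 = list(lb = -1)),
      rows = list(list(coeffs = list(R2 = 1, R3 = 1), sense = "=", rhs = 2))),
    r2_min_1 = build_constraints(net, bounds = list(R2 = list(lb = 1))))
  list(network = net, constraints = cons)
}

#' Seeded random small instances
#'
#' Draws a sparse random stoichiometric matrix with integer entries in
#' [-3, 3], assigns reversibility per `rev_frac`, and (optionally) draws flux
#' bounds that are guaranteed to leave the flux polyhedron nonempty: a
#' witness point r0 is first sampled as a conic combination of the network's
#' EFMs and every bound is placed around it. Networks whose flux cone is
#' \{0\} are resampled (bounded retries). Identical seeds give identical
#' instances.
#'
#' @param m number of internal metabolites (>= 0).
#' @param n number of reactions (>= 1).
#' @param rev_frac probability that a reaction is reversible.
#' @param n_bounds number of constraint rows to draw (each a lower or upper
#'   bound on one reaction); capped at n.
#' @param seed integer seed.
#' @return list with `network`, `constraints` and the exact feasibility
#'   `witness` (list(num, den)).
#' @export
random_model <- function(m = 2, n = 4, rev_frac = 0.3, n_bounds = 2,
                         seed = 1) {
  stopifnot(m >= 0, n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (attempt in 1:50) {
    S <- matrix(0, m, n)
    if (m > 0) {
      nz <- matrix(stats::runif(m * n) < 0.6, m, n)
      S[nz] <- sample(c(-3:-1, 1:3), sum(nz), replace = TRUE)
    }
    irr <- which(stats::runif(n) >= rev_frac)
    net <- try(metabolic_network(
      if (m) paste0("M", seq_len(m)) else character(0),
      paste0("R", seq_len(n)), S, irr), silent = TRUE)
    if (inherits(net, "try-error")) next
    efms <- enumerate_efms(net, include_negatives = TRUE)
    if (n_modes(efms) == 0) next
    # witness point: small conic combination of up to 3 EFMs
    pick <- sample(n_modes(efms), min(3, n_modes(efms)))
    wts <- sample(1:2, length(pick), replace = TRUE)
    r0 <- colSums(efms$num[pick, , drop = FALSE] * wts)
    bounds <- list()
    rows_used <- 0
    for (j in sample(n)) {
      if (rows_used >= min(n_bounds, n)) break
      b <- list()
      if (stats::runif(1) < 0.5) b$lb <- r0[j] - sample(0:2, 1)
      else b$ub <- r0[j] + sample(0:2, 1)
      bounds[[net$reaction_ids[j]]] <- b
      rows_used <- rows_used + 1
    }
    cons <- build_constraints(net, bounds)
    return(list(network = net, constraints = cons,
                witness = list(num = r0, den = rep(1, n))))
  }
  stop("random instance generation failed after 50 attempts", call. = FALSE)
}
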