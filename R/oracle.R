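# Definitional brute-force elementary-vector computation.
#
# EVs of a polyhedron P = {x : A x >= b} are the union, over all 2^n closed
# orthants, of the minimal generators (vertices + extreme rays) of the
# pointed subpolyhedra P intersect orthant. This module enumerates them from
# first principles with exact active-set tests and exists purely as the
# verification standard for the production (double-description) path; it is
# guarded to small n.
#
# Vertices of P intersect Omega_s are basic feasible points: n active
# constraints of rank n. The active set at x consists of the rows of A tight
# at x plus the coordinate hyperplanes {x_i = 0} for the zero coordinates of
# x -- the same set for every orthant containing x. Hence a candidate point is
# a vertex of the subpolyhedron of *some* (equivalently, every) orthant
# containing it iff its active rows reach rank n, and the union over orthants
# can be computed from one pass over candidate basic solutions (hyperplane
# subsets). The same argument applies to extreme rays of the recession cone
# with rank n - 1. subpolyhedron_generators() exposes the literal per-orthant
# operation; enumerate_evs_bruteforce() takes the one-pass union.

#' Assemble the inequality description of a flux polyhedron
#'
#' Stacks N, -N, the irreversibility rows and G into a single system
#' A x >= b with b = (0, 0, 0, h).
#'
#' @param network a `metabolic_network`.
#' @param constraints a `constraint_set` or NULL (homogeneous cone).
#' @return an object of class `general_polyhedron` with integer-scaled `A`
#'   and `b`.
#' @export
assemble_polyhedron <- function(network, constraints = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  n <- n_reactions(network)
  N <- network_int_N(network)
  I_irr <- matrix(0, length(network$irr), n)
  if (length(network$irr))
    I_irr[cbind(seq_along(network$irr), network$irr)] <- 1
  q <- n_constraint_rows(constraints)
  if (q > 0) {
    sc <- int_scale_rows(constraints$G_num, constraints$G_den,
                         constraints$h_num, constraints$h_den)
    G <- sc$mat; h <- sc$rhs
  } else { G <- matrix(0, 0, n); h <- numeric(0) }
  A <- rbind(N, -N, I_irr, G)
  b <- c(numeric(2 * nrow(N) + nrow(I_irr)), h)
  structure(list(A = A, b = b, n = n, network = network,
                 constraints = constraints),
            class = "general_polyhedron")
}

#' @export
print.general_polyhedron <- function(x, ...) {
  cat("general_polyhedron:", nrow(x$A), "rows,", x$n, "variables\n")
  invisible(x)
}

# deduplicate hyperplanes (normal, rhs) up to positive/negative scaling
.dedupe_hyperplanes <- function(M, rhs) {
  keys <- character(nrow(M))
  for (i in seq_len(nrow(M))) {
    v <- c(M[i, ], rhs[i])
    g <- vec_gcd(v)
    if (g > 1) v <- v / g
    fz <- which(v != 0)[1]
    if (!is.na(fz) && v[fz] < 0) v <- -v
    keys[i] <- paste(v, collapse = ",")
  }
  keep <- !duplicated(keys) & rowSums(cbind(M, rhs) != 0) > 0
  list(M = M[keep, , drop = FALSE], rhs = rhs[keep])
}

# all candidate basic solutions and directions of P (orthant-independent).
# Returns list(vertices = list of rat vecs, rays = integer matrix rows).
.ev_candidates <- function(P) {
  n <- P$n
  A <- P$A; b <- P$b
  coord <- diag(1, n)
  hp <- .dedupe_hyperplanes(rbind(A, coord), c(b, numeric(n)))
  H <- hp$M; r <- hp$rhs
  nh <- nrow(H)
  is_feasible <- function(xn, xd) {
    for (i in seq_len(nrow(A))) {
      d <- rat_dot(A[i, ], rep(1, n), xn, xd)
      if (rat_cmp(d$num, d$den, b[i], 1) < 0) return(FALSE)
    }
    TRUE
  }
  active_rank <- function(xn, xd, homogeneous = FALSE) {
    act <- matrix(0, 0, n)
    for (i in seq_len(nrow(A))) {
      d <- rat_dot(A[i, ], rep(1, n), xn, xd)
      rhs_i <- if (homogeneous) 0 else b[i]
      if (rat_cmp(d$num, d$den, rhs_i, 1) == 0) act <- rbind(act, A[i, ])
    }
    zero <- which(xn == 0)
    if (length(zero)) {
      Z <- matrix(0, length(zero), n)
      Z[cbind(seq_along(zero), zero)] <- 1
      act <- rbind(act, Z)
    }
    int_rank(act)
  }
  # vertices: solve each rank-n subset of n hyperplanes
  verts <- list(); vkeys <- character(0)
  if (nh >= n) {
    combs <- utils::combn(nh, n)
    for (k in seq_len(ncol(combs))) {
      S <- combs[, k]
      x <- int_solve_unique(H[S, , drop = FALSE], r[S])
      if (is.null(x)) next
      key <- paste(format_rational(x$num, x$den), collapse = ",")
      if (key %in% vkeys) next
      if (!is_feasible(x$num, x$den)) next
      if (active_rank(x$num, x$den) < n) next
      vkeys <- c(vkeys, key)
      verts[[length(verts) + 1L]] <- x
    }
  }
  # extreme rays of the recession cone per orthant: rank n-1 active sets
  rays <- list(); rkeys <- character(0)
  ray_ok <- function(d) {
    if (any(A %*% d < 0)) return(FALSE)
    active_rank(d, rep(1, n), homogeneous = TRUE) == n - 1
  }
  push_ray <- function(d) {
    g <- vec_gcd(d); if (g > 1) d <- d / g
    key <- paste(d, collapse = ",")
    if (!key %in% rkeys && ray_ok(d)) {
      rkeys <<- c(rkeys, key)
      rays[[length(rays) + 1L]] <<- d
    }
  }
  if (n == 1) {
    push_ray(1); push_ray(-1)
  } else {
    combs <- utils::combn(nh, n - 1)
    for (k in seq_len(ncol(combs))) {
      S <- combs[, k]
      B <- int_nullspace(H[S, , drop = FALSE])
      if (ncol(B) != 1) next
      push_ray(B[, 1]); push_ray(-B[, 1])
    }
  }
  list(vertices = verts,
       rays = if (length(rays)) do.call(rbind, rays) else matrix(0, 0, n))
}

#' Minimal generators of a polyhedron restricted to one orthant
#'
#' Computes the vertices and extreme rays of P intersect Omega_s for a sign
#' pattern s in \{-1, +1\}^n, by exhaustive exact active-set enumeration.
#'
#' @param P a `general_polyhedron`.
#' @param orthant sign pattern (vector over \{-1, 1\}).
#' @param max_n guard on the number of variables (default 10).
#' @return list with `vertices` (character matrix of exact rationals, one row
#'   per vertex) and `rays` (primitive integer matrix, one row per extreme
#'   ray).
#' @export
subpolyhedron_generators <- function(P, orthant, max_n = 10) {
  stopifnot(inherits(P, "general_polyhedron"))
  n <- P$n
  if (n > max_n) stop("oracle guard exceeded: n = ", n, " > ", max_n,
                      call. = FALSE)
  stopifnot(length(orthant) == n, all(orthant %in% c(-1, 1)))
  cand <- .ev_candidates(P)
  in_orthant <- function(v) all(v * orthant >= 0)
  verts <- Filter(function(x) in_orthant(x$num), cand$vertices)
  vmat <- if (length(verts))
    do.call(rbind, lapply(verts, function(x) format_rational(x$num, x$den)))
  else matrix(character(0), 0, n)
  rkeep <- apply(cand$rays, 1, in_orthant)
  list(vertices = vmat,
       rays = cand$rays[rkeep, , drop = FALSE])
}

#' Brute-force elementary vectors of a flux polyhedron
#'
#' The definitional computation: the union over all closed orthants of the
#' minimal generators of the subpolyhedra, deduplicated. Vertices become
#' bounded EVs, extreme rays unbounded EVs; rays with A d = 0 lie in the
#' lineality space of the recession cone. Serves as the verification oracle
#' for [enumerate_efvs()] and [enumerate_efms()] on small instances.
#'
#' @param network a `metabolic_network`.
#' @param constraints a `constraint_set` or NULL (flux-cone case).
#' @param max_n guard on the number of reactions (default 10).
#' @return a `mode_set`.
#' @export
enumerate_evs_bruteforce <- function(network, constraints = NULL,
                                     max_n = 10) {
  n <- n_reactions(network)
  if (n > max_n) stop("oracle guard exceeded: n = ", n, " > ", max_n,
                      call. = FALSE)
  P <- assemble_polyhedron(network, constraints)
  cand <- .ev_candidates(P)
  k <- length(cand$vertices) + nrow(cand$rays)
  num <- matrix(0, 0, n); den <- matrix(1, 0, n); classes <- character(0)
  for (x in cand$vertices) {
    num <- rbind(num, x$num); den <- rbind(den, x$den)
    classes <- c(classes, if (all(x$num == 0)) "zero" else "efv_bounded")
  }
  if (nrow(cand$rays)) {
    lin <- apply(cand$rays, 1, function(d) all(P$A %*% d == 0))
    num <- rbind(num, cand$rays)
    den <- rbind(den, matrix(1, nrow(cand$rays), n))
    classes <- c(classes, ifelse(lin, "efv_lineality", "efv_unbounded"))
  }
  ms <- mode_set(num, den, classes = classes, network = network,
                 constraints = constraints)
  # lineality members appear as +/- pairs; normalization maps both to the
  # canonical orientation and deduplication collapses them
  ms
}

#' Deterministic feasible point of a flux polyhedron
#'
#' Returns an exact rational convex combination of the polyhedron's vertices
#' plus a nonnegative combination of its extreme rays, with small seeded
#' integer weights. Feasibility is verified exactly before returning.
#'
#' @param network a `metabolic_network`.
#' @param constraints a `constraint_set` or NULL.
#' @param seed integer seed; the same seed yields the same point.
#' @param use_rays include unbounded directions with seeded weights.
#' @return list(num, den): the exact feasible point.
#' @export
sample_point <- function(network, constraints = NULL, seed = 1,
                         use_rays = TRUE) {
  evs <- enumerate_evs_bruteforce(network, constraints)
  bounded <- which(evs$classes %in% c("efv_bounded", "zero"))
  rays <- which(evs$classes %in% c("efv_unbounded", "efv_lineality"))
  # a nonempty polyhedron always has a vertex in some orthant, so no bounded
  # EV means no feasible point at all
  if (!length(bounded))
    stop("empty polyhedron: no feasible point exists", call. = FALSE)
  n <- n_reactions(network)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pt <- list(num = numeric(n), den = rep(1, n))
  if (length(bounded)) {
    wts <- sample(1:5, length(bounded), replace = TRUE)
    total <- sum(wts)
    for (k in seq_along(bounded)) {
      i <- bounded[k]
      contrib <- rat_mul(rep(wts[k], n), rep(total, n),
                         evs$num[i, ], evs$den[i, ])
      pt <- rat_add(pt$num, pt$den, contrib$num, contrib$den)
    }
  }
  if (use_rays && length(rays)) {
    wts <- sample(0:3, length(rays), replace = TRUE)
    for (k in seq_along(rays)) {
      if (wts[k] == 0) next
      i <- rays[k]
      contrib <- rat_mul(rep(wts[k], n), rep(1, n),
                         evs$num[i, ], evs$den[i, ])
      pt <- rat_add(pt$num, pt$den, contrib$num, contrib$den)
    }
  }
  if (!.steady_state_ok(network, pt$num, pt$den))
    stop("internal error: sampled point infeasible", call. = FALSE)
  if (n_constraint_rows(constraints) > 0 && length(bounded)) {
    s <- .constraint_slacks(constraints, pt$num, pt$den, h_scale = 1)
    if (any(s$num < 0))
      stop("internal error: sampled point violates constraints", call. = FALSE)
  }
  pt
}
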