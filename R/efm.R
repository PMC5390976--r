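# Elementary flux mode enumeration.
#
# EFMs are the nonzero, support-minimal vectors of the flux cone
# FC = {r : N r = 0, r_i >= 0 for i in Irr}. The enumeration splits every
# reversible reaction into forward + backward nonnegative columns; in the
# resulting standard-form cone {x >= 0 : N' x = 0} the support-minimal vectors
# coincide with the extreme rays, which are enumerated by an incremental
# double-description pass over the equality rows. Spurious two-cycles
# (forward + backward of one split reaction, projecting to zero) are dropped
# and the signed vectors are recovered. All arithmetic is integer-exact.

# Extreme rays of {x in R^p : E x = 0, x >= 0} for an integer matrix E.
# Returns a matrix with one primitive integer ray per row.
dd_extreme_rays <- function(E, p) {
  rays <- diag(1, p)
  if (nrow(E) == 0) return(rays)
  remaining <- seq_len(nrow(E))
  while (length(remaining)) {
    if (nrow(rays) == 0) return(rays)
    # growth-limiting heuristic: next process the row cutting fewest pairs;
    # the order affects speed, never the output
    dots <- rays %*% t(E[remaining, , drop = FALSE])
    npos <- colSums(dots > 0); nneg <- colSums(dots < 0)
    pick <- which.min(npos * nneg)
    d <- dots[, pick]
    remaining <- remaining[-pick]
    P <- which(d > 0); Ng <- which(d < 0); Z <- which(d == 0)
    if (!length(P) || !length(Ng)) { rays <- rays[Z, , drop = FALSE]; next }
    zero <- rays == 0
    new_rays <- list()
    for (i in P) {
      zi <- zero[i, ]
      for (j in Ng) {
        zc <- zi & zero[j, ]
        # combinatorial adjacency: no third ray's zero set contains zc
        others <- setdiff(seq_len(nrow(rays)), c(i, j))
        if (length(others)) {
          cover <- rowSums(!zero[others, zc, drop = FALSE]) == 0
          if (any(cover)) next
        }
        v <- d[i] * rays[j, ] - d[j] * rays[i, ]
        .chk_int(v)
        g <- vec_gcd(v)
        if (g > 1) v <- v / g
        new_rays[[length(new_rays) + 1L]] <- v
      }
    }
    rays <- rbind(rays[Z, , drop = FALSE],
                  if (length(new_rays)) do.call(rbind, new_rays))
    if (nrow(rays) > 1) {
      keys <- apply(rays, 1, paste, collapse = ",")
      rays <- rays[!duplicated(keys), , drop = FALSE]
    }
  }
  rays
}

# shared split-and-enumerate kernel: EFMs of {r : E r = 0, r_i >= 0, i in irr}
# over arbitrary integer equality matrix E with column count n.
# Returns signed primitive integer EFMs, one per row (reversible EFMs in the
# canonical orientation only).
.efms_of_cone <- function(E, n, irr) {
  rev_idx <- setdiff(seq_len(n), irr)
  Esplit <- cbind(E, if (length(rev_idx)) -E[, rev_idx, drop = FALSE])
  p <- n + length(rev_idx)
  rays <- dd_extreme_rays(Esplit, p)
  if (nrow(rays) == 0) return(matrix(0, 0, n))
  proj <- rays[, seq_len(n), drop = FALSE]
  if (length(rev_idx))
    proj[, rev_idx] <- proj[, rev_idx] -
      rays[, n + seq_along(rev_idx), drop = FALSE]
  nonzero <- rowSums(proj != 0) > 0
  proj <- proj[nonzero, , drop = FALSE]
  if (nrow(proj) == 0) return(proj)
  out <- t(apply(proj, 1, function(v) {
    g <- vec_gcd(v)
    if (g > 1) v <- v / g
    # canonical orientation for fully reversible modes
    if (!any(which(v != 0) %in% irr)) {
      fz <- which(v != 0)[1]
      if (v[fz] < 0) v <- -v
    }
    v
  }))
  if (nrow(proj) == 1) out <- matrix(out, 1, n)
  out[!duplicated(apply(out, 1, paste, collapse = ",")), , drop = FALSE]
}

#' Enumerate the elementary flux modes of a flux cone
#'
#' Returns one primitive-integer representative per EFM ray of
#' \{r : N r = 0, r_i >= 0 for i in Irr\}. Reversible EFMs (support disjoint
#' from the irreversible set) are valid in both directions; by default one
#' canonical orientation (first nonzero entry positive) is returned with a
#' reversible flag, or both orientations with `include_negatives = TRUE`.
#'
#' @param network a `metabolic_network`.
#' @param include_negatives return both orientations of reversible EFMs.
#' @return a `mode_set` of class-"efm" modes (empty when the cone is \{0\}).
#' @export
enumerate_efms <- function(network, include_negatives = FALSE) {
  stopifnot(inherits(network, "metabolic_network"))
  n <- n_reactions(network)
  E <- network_int_N(network)
  efms <- .efms_of_cone(E, n, network$irr)
  rev <- apply(efms, 1, function(v) !any(which(v != 0) %in% network$irr))
  if (nrow(efms) == 0) rev <- logical(0)
  if (include_negatives && any(rev)) {
    efms <- rbind(efms, -efms[rev, , drop = FALSE])
    rev <- c(rev, rev[rev])
  }
  ms <- mode_set(efms, classes = "efm", network = network,
                 reversible = rev, normalize = FALSE)
  # dedupe + deterministic sort without re-flipping orientations
  if (include_negatives) {
    keep <- !duplicated(apply(efms, 1, paste, collapse = ","))
    ms <- mode_subset(ms, keep)
    ms <- .sort_mode_set(ms)
    ms
  } else .normalize_mode_set(ms)
}

# deterministic sort only (no orientation change, no dedup)
.sort_mode_set <- function(ms) {
  k <- n_modes(ms)
  if (k > 1) {
    supp <- (ms$num != 0) * 1
    approx <- ms$num / ms$den
    ord <- do.call(order, c(split(supp, col(supp)), split(approx, col(approx))))
    ms <- mode_subset(ms, ord)
  }
  colnames(ms$num) <- colnames(ms$den) <- ms$network$reaction_ids
  ms
}

#' Basis of the lineality space of a flux cone
#'
#' The lineality space contains the fully reversible flux vectors: x with both
#' x and -x in the cone, i.e. N x = 0 and x_i = 0 for every irreversible i.
#'
#' @param network a `metabolic_network`.
#' @return matrix whose columns are primitive integer basis vectors (zero
#'   columns when the cone is pointed).
#' @export
lineality_basis <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  n <- n_reactions(network)
  E <- network_int_N(network)
  if (length(network$irr)) {
    I_irr <- matrix(0, length(network$irr), n)
    I_irr[cbind(seq_along(network$irr), network$irr)] <- 1
    E <- rbind(E, I_irr)
  }
  int_nullspace(E)
}

#' Filter a mode set to its support-minimal members
#'
#' Retains exactly the nonzero modes whose support is not a proper superset of
#' any other nonzero mode's support; the zero mode is never retained.
#'
#' @param modes a `mode_set`.
#' @return the filtered `mode_set`.
#' @export
filter_support_minimal <- function(modes) {
  stopifnot(inherits(modes, "mode_set"))
  supp <- mode_support(modes)
  nz <- which(lengths(supp) > 0)
  keep <- logical(n_modes(modes))
  for (i in nz) {
    minimal <- TRUE
    for (j in nz) {
      if (i == j) next
      if (length(supp[[j]]) < length(supp[[i]]) &&
          all(supp[[j]] %in% supp[[i]])) { minimal <- FALSE; break }
    }
    keep[i] <- minimal
  }
  mode_subset(modes, which(keep))
}
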