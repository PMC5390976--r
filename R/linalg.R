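# Exact linear algebra on integer-scaled matrices.
#
# Every rational matrix is brought to integer form by scaling rows with the
# lcm of their denominators (this preserves row space, rank, null space and,
# when the right-hand side is scaled along, solution sets). Elimination is
# fraction-free: rows are combined with integer multipliers and re-reduced by
# their gcd, so entries stay small and exact.

# rational matrix container: list(num, den) of equal-shaped matrices
ratmat <- function(num, den = NULL) {
  num <- as.matrix(num)
  if (is.null(den)) den <- matrix(1, nrow(num), ncol(num))
  den <- as.matrix(den)
  stopifnot(all(dim(num) == dim(den)))
  r <- rat_norm(as.numeric(num), as.numeric(den))
  list(num = matrix(r$num, nrow(num), dimnames = dimnames(num)),
       den = matrix(r$den, nrow(num), dimnames = dimnames(num)))
}

# scale each row of a rational matrix (optionally with a rational rhs) to
# integers; returns list(mat, rhs)
int_scale_rows <- function(num, den, rhs_num = NULL, rhs_den = NULL) {
  num <- as.matrix(num); den <- as.matrix(den)
  out <- num
  rhs <- rhs_num
  for (i in seq_len(nrow(num))) {
    dens <- den[i, ]
    if (!is.null(rhs_den)) dens <- c(dens, rhs_den[i])
    L <- 1
    for (d in unique(dens)) L <- .lcm2(L, d)
    out[i, ] <- .chk_int(num[i, ] * (L / den[i, ]))
    if (!is.null(rhs)) rhs[i] <- .chk_int(rhs_num[i] * (L / rhs_den[i]))
  }
  list(mat = out, rhs = rhs)
}

# fraction-free reduced echelon form of an integer matrix.
# Returns list(mat, pivots, rank); mat is fully reduced (zeros above and
# below each pivot), rows gcd-reduced.
int_rref <- function(M) {
  M <- as.matrix(M)
  nr <- nrow(M); nc <- ncol(M)
  pivots <- integer(0)
  r <- 1L
  for (cc in seq_len(nc)) {
    if (r > nr) break
    cand <- which(M[r:nr, cc] != 0) + r - 1L
    if (!length(cand)) next
    p <- cand[which.min(abs(M[cand, cc]))]
    if (p != r) { tmp <- M[r, ]; M[r, ] <- M[p, ]; M[p, ] <- tmp }
    piv <- M[r, cc]
    others <- which(M[, cc] != 0)
    others <- others[others != r]
    if (length(others)) {
      M[others, ] <- .chk_int(piv * M[others, , drop = FALSE] -
                              outer(M[others, cc], M[r, ]))
      for (j in others) {
        g <- vec_gcd(M[j, ])
        if (g > 1) M[j, ] <- M[j, ] / g
      }
    }
    if (piv < 0) M[r, ] <- -M[r, ]
    g <- vec_gcd(M[r, ])
    if (g > 1) M[r, ] <- M[r, ] / g
    pivots <- c(pivots, cc)
    r <- r + 1L
  }
  list(mat = M, pivots = pivots, rank = length(pivots))
}

int_rank <- function(M) {
  if (nrow(as.matrix(M)) == 0) return(0L)
  int_rref(M)$rank
}

# primitive integer basis of the null space of an integer matrix (columns)
int_nullspace <- function(M) {
  M <- as.matrix(M)
  nc <- ncol(M)
  if (nrow(M) == 0) {
    return(diag(1, nc))
  }
  rr <- int_rref(M)
  free <- setdiff(seq_len(nc), rr$pivots)
  if (!length(free)) return(matrix(0, nc, 0))
  B <- matrix(0, nc, length(free))
  for (k in seq_along(free)) {
    f <- free[k]
    # x[f] = 1; pivot variables from reduced rows: piv * x[p] + M[i,f] = 0
    xn <- numeric(nc); xd <- rep(1, nc)
    xn[f] <- 1
    for (i in seq_along(rr$pivots)) {
      p <- rr$pivots[i]
      r <- rat_norm(-rr$mat[i, f], rr$mat[i, p])
      xn[p] <- r$num; xd[p] <- r$den
    }
    B[, k] <- rat_primitive(xn, xd)
  }
  B
}

# unique rational solution of A x = b (A, b integer). Returns list(num, den)
# or NULL when the system is inconsistent or underdetermined.
int_solve_unique <- function(A, b) {
  A <- as.matrix(A)
  nc <- ncol(A)
  rr <- int_rref(cbind(A, b))
  if ((nc + 1L) %in% rr$pivots) return(NULL)   # inconsistent
  if (rr$rank < nc) return(NULL)               # not unique
  xn <- numeric(nc); xd <- rep(1, nc)
  for (i in seq_along(rr$pivots)) {
    p <- rr$pivots[i]
    r <- rat_norm(rr$mat[i, nc + 1L], rr$mat[i, p])
    xn[p] <- r$num; xd[p] <- r$den
  }
  list(num = xn, den = xd)
}

#' Exact null space basis of a rational matrix
#'
#' Computes n - rank(M) linearly independent exact vectors spanning
#' \{x : M x = 0\}, each scaled to its primitive integer representative.
#'
#' @param num numerator matrix (or an integer/numeric matrix; a `den` of 1 is
#'   assumed when `den` is missing).
#' @param den optional denominator matrix matching `num`.
#' @return a matrix whose columns form the basis (zero columns when the null
#'   space is trivial).
#' @examples
#' nullspace_basis(matrix(c(1, -1, -1), 1, 3))  # two basis vectors
#' @export
nullspace_basis <- function(num, den = NULL) {
  rm_ <- ratmat(num, den)
  M <- int_scale_rows(rm_$num, rm_$den)$mat
  int_nullspace(M)
}
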