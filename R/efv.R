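# Elementary flux vector enumeration via homogenization + slack variables.
#
# The flux polyhedron FP = {r : N r = 0, r_i >= 0 (i in Irr), G r >= h} is
# embedded into the augmented cone
#
#     D w = ( N  0   0 ) (r)        r_i >= 0 (i in Irr),
#           ( G -I  -h ) (s)  = 0,  s >= 0, lambda >= 0,
#                        (lambda)
#
# which has the shape of a flux cone. Its EFMs w = (r, s, lambda) map back to
# the EFVs of FP: lambda > 0 gives the bounded EFV r/lambda, lambda = 0 the
# unbounded EFV r (primitive-normalized). An unbounded EFV with s = 0 and
# r_i = 0 for all irreversible i lies in the lineality space of the recession
# cone. Equality constraints (stored as two half-rows) are by default folded
# into the equality block (appended to N with the homogenized right-hand
# side), which shrinks the enumeration without changing the result; the
# literal two-slack-row treatment is available via `fold_equalities = FALSE`.

#' Homogenize a flux polyhedron into an augmented cone
#'
#' @param network a `metabolic_network`.
#' @param constraints a `constraint_set` over the network (NULL or empty for
#'   the pure flux-cone case, where only the homogenization column is added).
#' @param fold_equalities fold equality-half row pairs into the equality block
#'   instead of giving each half a slack variable (default TRUE; the resulting
#'   EFV set is identical).
#' @return an object of class `augmented_system`: integer matrix `D`, index
#'   maps `r_cols`, `s_cols`, `lambda_col`, the augmented irreversible set
#'   `irr_aug` (= Irr plus all slack columns plus the lambda column), and
#'   `s_tags` naming the constraint row behind each slack column.
#' @export
homogenize <- function(network, constraints = NULL, fold_equalities = TRUE) {
  stopifnot(inherits(network, "metabolic_network"))
  n <- n_reactions(network)
  q <- n_constraint_rows(constraints)
  if (q > 0 && ncol(constraints$G_num) != n)
    stop("constraint set does not match network dimensions", call. = FALSE)
  N <- network_int_N(network)
  m <- nrow(N)
  if (q == 0) {
    D <- cbind(N, matrix(0, m, 1))
    s_cols <- integer(0); s_tags <- character(0)
    eq_rows <- matrix(0, 0, n + 1)
  } else {
    sc <- int_scale_rows(constraints$G_num, constraints$G_den,
                         constraints$h_num, constraints$h_den)
    G <- sc$mat; h <- sc$rhs
    fold <- rep(FALSE, q)
    if (fold_equalities) {
      # keep the first half of each equality pair as an equality row
      eq_tags <- grepl("^equality_half:", constraints$tags)
      fold <- eq_tags
      first_half <- !duplicated(constraints$tags) & eq_tags
      keep_eq <- first_half
    }
    ineq <- which(!fold)
    qi <- length(ineq)
    eq_rows <- if (fold_equalities && any(fold)) {
      idx <- which(!duplicated(constraints$tags) &
                     grepl("^equality_half:", constraints$tags))
      cbind(G[idx, , drop = FALSE], -h[idx])
    } else matrix(0, 0, n + 1)
    D_top <- cbind(N, matrix(0, m, qi), matrix(0, m, 1))
    D_eq <- if (nrow(eq_rows)) cbind(eq_rows[, seq_len(n), drop = FALSE],
                                     matrix(0, nrow(eq_rows), qi),
                                     eq_rows[, n + 1]) else NULL
    D_in <- if (qi) cbind(G[ineq, , drop = FALSE],
                          -diag(1, qi), -h[ineq]) else NULL
    D <- rbind(D_top, D_eq, D_in)
    s_cols <- if (qi) n + seq_len(qi) else integer(0)
    s_tags <- constraints$tags[ineq]
  }
  lambda_col <- ncol(D)
  structure(list(D = D,
                 r_cols = seq_len(n),
                 s_cols = s_cols,
                 lambda_col = lambda_col,
                 irr_aug = sort(c(network$irr, s_cols, lambda_col)),
                 s_tags = s_tags,
                 network = network,
                 constraints = constraints),
            class = "augmented_system")
}

#' @export
print.augmented_system <- function(x, ...) {
  cat("augmented_system: D is", nrow(x$D), "x", ncol(x$D),
      "(", length(x$r_cols), "reactions,", length(x$s_cols),
      "slacks, 1 homogenization column )\n")
  invisible(x)
}

#' Enumerate the elementary flux vectors of a flux polyhedron
#'
#' Runs [enumerate_efms()] machinery on the homogenized + slacked cone and
#' back-maps each augmented EFM w = (r, s, lambda): lambda > 0 yields the
#' bounded EFV r/lambda (the zero EFV, kept with class "zero", when r = 0);
#' lambda = 0 yields an unbounded EFV r, classed "efv_lineality" when s = 0
#' and r vanishes on the irreversible set. Duplicates after projection are
#' removed. With no constraints the nonzero EFVs coincide with the EFMs.
#'
#' @inheritParams homogenize
#' @return a `mode_set`; empty (with a warning) when the polyhedron is empty.
#' @export
enumerate_efvs <- function(network, constraints = NULL,
                           fold_equalities = TRUE) {
  aug <- homogenize(network, constraints, fold_equalities)
  n <- length(aug$r_cols)
  p <- ncol(aug$D)
  W <- .efms_of_cone(aug$D, p, aug$irr_aug)
  lam <- W[, aug$lambda_col]
  if (nrow(W) == 0 || !any(lam > 0)) {
    # empty polyhedron: no point exists. Recession rays (lambda = 0 modes)
    # may still exist and are returned so that knockout filtering and
    # re-enumeration stay consistent; without rays the set is empty.
    if (nrow(W) == 0) {
      warning("flux polyhedron is empty (no feasible point, no recession ray)",
              call. = FALSE)
      return(mode_set(matrix(0, 0, n), classes = character(0),
                      network = network, constraints = constraints))
    }
    warning("flux polyhedron is empty; returning recession-cone rays only",
            call. = FALSE)
  }
  k <- nrow(W)
  num <- matrix(0, k, n); den <- matrix(1, k, n)
  classes <- character(k); keep <- rep(TRUE, k)
  for (i in seq_len(k)) {
    r <- W[i, aug$r_cols]
    if (lam[i] > 0) {
      rr <- rat_norm(r, rep(lam[i], n))
      num[i, ] <- rr$num; den[i, ] <- rr$den
      classes[i] <- if (all(r == 0)) "zero" else "efv_bounded"
    } else {
      if (all(r == 0)) { keep[i] <- FALSE; next }  # pure-slack ray (unreachable)
      g <- vec_gcd(r)
      num[i, ] <- if (g > 1) r / g else r
      s <- W[i, aug$s_cols]
      lin <- all(s == 0) && all(r[network$irr] == 0)
      classes[i] <- if (lin) "efv_lineality" else "efv_unbounded"
    }
  }
  mode_set(num[keep, , drop = FALSE], den[keep, , drop = FALSE],
           classes = classes[keep], network = network,
           constraints = constraints)
}

# exact feasibility checks used by the validator and by decompose ------------

# N r = 0 and r_i >= 0 on Irr, exactly
.steady_state_ok <- function(network, num, den) {
  N <- network_int_N(network)
  if (nrow(N)) {
    for (i in seq_len(nrow(N))) {
      d <- rat_dot(N[i, ], rep(1, ncol(N)), num, den)
      if (d$num != 0) return(FALSE)
    }
  }
  all(num[network$irr] >= 0)
}

# G r - h (exact rational vector); h_scale = 1 uses h, 0 the homogeneous form
.constraint_slacks <- function(constraints, num, den, h_scale = 1) {
  q <- n_constraint_rows(constraints)
  sn <- numeric(q); sd <- rep(1, q)
  for (i in seq_len(q)) {
    d <- rat_dot(constraints$G_num[i, ], constraints$G_den[i, ], num, den)
    r <- rat_sub(d$num, d$den, h_scale * constraints$h_num[i],
                 constraints$h_den[i])
    sn[i] <- r$num; sd[i] <- r$den
  }
  list(num = sn, den = sd)
}

#' Validate the class-specific feasibility of a mode set
#'
#' Re-checks every mode exactly against its claimed class: all classes must
#' satisfy N r = 0 and the irreversibility signs; bounded EFVs must satisfy
#' G r >= h, unbounded EFVs G r >= 0, and lineality members G r >= 0 together
#' with full feasibility of -r under the homogeneous system.
#'
#' @param modes a `mode_set` with EFV classes.
#' @param network the defining network (defaults to the set's own).
#' @param constraints the defining constraints (defaults to the set's own).
#' @return list with `valid` (logical) and a data frame of `violations`.
#' @export
validate_efv_set <- function(modes, network = modes$network,
                             constraints = modes$constraints) {
  stopifnot(inherits(modes, "mode_set"))
  viol <- list()
  flag <- function(i, what)
    viol[[length(viol) + 1L]] <<- data.frame(mode = i, problem = what)
  for (i in seq_len(n_modes(modes))) {
    num <- modes$num[i, ]; den <- modes$den[i, ]
    cls <- modes$classes[i]
    if (cls == "zero" && any(num != 0)) flag(i, "nonzero vector tagged zero")
    if (!.steady_state_ok(network, num, den))
      flag(i, "violates steady state or irreversibility")
    if (n_constraint_rows(constraints) > 0) {
      if (cls %in% c("efv_bounded", "zero")) {
        s <- .constraint_slacks(constraints, num, den, h_scale = 1)
        if (any(s$num < 0)) flag(i, "violates G r >= h")
      } else if (cls %in% c("efv_unbounded", "efv_lineality")) {
        s <- .constraint_slacks(constraints, num, den, h_scale = 0)
        if (any(s$num < 0)) flag(i, "violates recession cone G r >= 0")
        if (cls == "efv_lineality") {
          if (any(s$num != 0) || any(num[network$irr] != 0))
            flag(i, "lineality member with -r infeasible")
        }
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(mode = integer(0), problem = character(0))
  list(valid = nrow(violations) == 0, violations = violations)
}
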