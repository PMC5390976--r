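# Pathway-analysis applications on top of enumerated mode sets:
# conformality, essential/blocked/coupled reactions, linear rate optimization
# with optimal-face extraction, linear-fractional (yield) optimization with
# unattained-supremum detection, knockout filtering, and exact conformal
# decomposition of flux distributions.

#' Rate / yield objective
#'
#' @param network a `metabolic_network`.
#' @param c named coefficients of the linear rate objective c^T r (reaction
#'   id -> coefficient), or a full-length vector.
#' @param d optional denominator coefficients for the yield objective
#'   c^T r / d^T r.
#' @param sense "max" or "min".
#' @return an object of class `objective` with exact rational `c` (and `d`).
#' @export
objective <- function(network, c, d = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  expand <- function(v) {
    n <- n_reactions(network)
    if (!is.null(names(v))) {
      unknown <- setdiff(names(v), network$reaction_ids)
      if (length(unknown)) stop("unknown reaction id in objective: ",
                                paste(unknown, collapse = ", "), call. = FALSE)
      full <- rep("0", n)
      full[match(names(v), network$reaction_ids)] <- as.character(unlist(v))
      parse_rational(full)
    } else {
      if (length(v) != n) stop("objective length mismatch", call. = FALSE)
      parse_rational(v)
    }
  }
  structure(list(c = expand(c), d = if (!is.null(d)) expand(d),
                 sense = sense, network = network), class = "objective")
}

# exact objective value c^T r for one mode
.obj_value <- function(cf, modes, i)
  rat_dot(cf$num, cf$den, modes$num[i, ], modes$den[i, ])

#' Is a sum of flux vectors conformal?
#'
#' The sum is conformal (involves no cancellations) iff the parts add up to
#' the total and, coordinatewise, total = 0 forces all parts to 0, total > 0
#' forces all parts >= 0, and total < 0 forces all parts <= 0.
#'
#' @param parts list of equal-length vectors (numeric, or exact
#'   list(num, den) pairs).
#' @param total the claimed sum.
#' @return TRUE or FALSE.
#' @export
is_conformal_sum <- function(parts, total) {
  as_rat <- function(x) if (is.list(x) && !is.null(x$num)) x else
    parse_rational(x)
  total <- as_rat(total)
  parts <- lapply(parts, as_rat)
  nlen <- length(total$num)
  if (any(vapply(parts, function(p) length(p$num), integer(1)) != nlen))
    stop("length mismatch between parts and total", call. = FALSE)
  acc <- list(num = numeric(nlen), den = rep(1, nlen))
  for (p in parts) {
    acc <- rat_add(acc$num, acc$den, p$num, p$den)
    tsgn <- sign(total$num)
    psgn <- sign(p$num)
    if (any(tsgn == 0 & psgn != 0)) return(FALSE)
    if (any(tsgn > 0 & psgn < 0)) return(FALSE)
    if (any(tsgn < 0 & psgn > 0)) return(FALSE)
  }
  all(rat_cmp(acc$num, acc$den, total$num, total$den) == 0)
}

# nonzero modes, optionally restricted to certain classes
.nonzero_idx <- function(modes)
  which(rowSums(modes$num != 0) > 0)

#' Essential and blocked reactions, flux coupling
#'
#' Implements the mode-set reading of reaction properties: a reaction is
#' essential if it occurs in all nonzero bounded EFVs (or, when no nonzero
#' bounded EFV exists, in all unbounded EFVs), and blocked if it has zero rate
#' in all EFVs. A pair is fully coupled if in every nonzero EFV both rates are
#' zero or both nonzero with one constant exact ratio (including sign);
#' partially coupled if both-zero-or-both-nonzero holds without a constant
#' ratio; directionally coupled (i -> j) if a nonzero rate of i implies a
#' nonzero rate of j in every nonzero EFV. Blocked reactions appear in no
#' coupling pair and the zero EFV is excluded throughout.
#'
#' @param modes a nonempty `mode_set` from [enumerate_efvs()] or
#'   [enumerate_efms()].
#' @return an object of class `coupling_report`: `essential`, `blocked`
#'   (character vectors), `fully_coupled` (data frame with exact `ratio`),
#'   `partially_coupled`, `directionally_coupled` (data frames).
#' @export
coupling <- function(modes) {
  stopifnot(inherits(modes, "mode_set"))
  if (n_modes(modes) == 0)
    stop("reaction properties are undefined on an empty mode set",
         call. = FALSE)
  rid <- modes$network$reaction_ids
  n <- length(rid)
  nz <- .nonzero_idx(modes)
  active <- modes$num[nz, , drop = FALSE] != 0
  blocked <- rid[colSums(active) == 0]
  bounded <- intersect(nz, which(modes$classes == "efv_bounded"))
  unbounded <- intersect(nz, which(modes$classes %in%
                                     c("efv_unbounded", "efv_lineality", "efm")))
  ess_pool <- if (length(bounded)) bounded else unbounded
  essential <- if (length(ess_pool))
    rid[colSums(modes$num[ess_pool, , drop = FALSE] != 0) ==
          length(ess_pool)] else character(0)
  full <- part <- list()
  dir <- list()
  unblocked <- which(colSums(active) > 0)
  for (a in unblocked) for (b in unblocked) {
    if (a >= b) next
    both_or_none <- all(active[, a] == active[, b])
    if (both_or_none) {
      ratio <- NULL; constant <- TRUE
      for (i in nz[active[, a]]) {
        r <- rat_div(modes$num[i, a], modes$den[i, a],
                     modes$num[i, b], modes$den[i, b])
        if (is.null(ratio)) ratio <- r
        else if (rat_cmp(ratio$num, ratio$den, r$num, r$den) != 0) {
          constant <- FALSE; break
        }
      }
      if (constant)
        full[[length(full) + 1L]] <- data.frame(
          i = rid[a], j = rid[b],
          ratio = format_rational(ratio$num, ratio$den))
      part[[length(part) + 1L]] <- data.frame(i = rid[a], j = rid[b])
    }
  }
  for (a in unblocked) for (b in unblocked) {
    if (a == b) next
    if (all(!active[, a] | active[, b]))
      dir[[length(dir) + 1L]] <- data.frame(from = rid[a], to = rid[b])
  }
  bindf <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  structure(list(
    essential = essential,
    blocked = blocked,
    fully_coupled = bindf(full, data.frame(i = character(0), j = character(0),
                                           ratio = character(0))),
    partially_coupled = bindf(part, data.frame(i = character(0),
                                               j = character(0))),
    directionally_coupled = bindf(dir, data.frame(from = character(0),
                                                  to = character(0)))),
    class = "coupling_report")
}

#' @export
print.coupling_report <- function(x, ...) {
  cat("coupling_report:\n  essential:",
      if (length(x$essential)) paste(x$essential, collapse = ", ") else "-",
      "\n  blocked:",
      if (length(x$blocked)) paste(x$blocked, collapse = ", ") else "-",
      "\n  fully coupled pairs:", nrow(x$fully_coupled),
      "\n  partially coupled pairs:", nrow(x$partially_coupled),
      "\n  directionally coupled pairs:", nrow(x$directionally_coupled), "\n")
  invisible(x)
}

#' Essential and blocked reactions
#'
#' Convenience wrapper around [coupling()] returning only the essentiality and
#' blockedness fields.
#'
#' @inheritParams coupling
#' @return a `coupling_report` with `essential` and `blocked` filled in.
#' @export
essential_blocked <- function(modes) {
  rep <- coupling(modes)
  rep$fully_coupled <- rep$fully_coupled[0, ]
  rep$partially_coupled <- rep$partially_coupled[0, ]
  rep$directionally_coupled <- rep$directionally_coupled[0, ]
  rep
}

#' Optimize a linear rate objective over a flux polyhedron
#'
#' Works directly on the enumerated EFVs: the optimum of c^T r over a
#' polyhedron is unbounded iff some unbounded EFV improves the objective
#' (c^T u > 0 for maximization); otherwise it is attained at a bounded EFV
#' (vertex), and the optimal face is generated by all optimum-attaining
#' bounded EFVs together with all unbounded EFVs orthogonal to the objective.
#'
#' @param modes a `mode_set` from [enumerate_efvs()].
#' @param obj an [objective()] (the `d` slot is ignored).
#' @return list with `status` ("bounded"/"unbounded"), exact `optimum`
#'   (list(num, den), NULL when unbounded), its numeric `value`, and
#'   `optimal_modes` (a sub-`mode_set` spanning the optimal face).
#' @export
optimize_rate <- function(modes, obj) {
  stopifnot(inherits(modes, "mode_set"), inherits(obj, "objective"))
  if (n_modes(modes) == 0) stop("empty mode set", call. = FALSE)
  sgn <- if (obj$sense == "max") 1 else -1
  cf <- list(num = sgn * obj$c$num, den = obj$c$den)
  k <- n_modes(modes)
  vals <- lapply(seq_len(k), function(i) .obj_value(cf, modes, i))
  unb <- which(modes$classes %in% c("efv_unbounded", "efm"))
  lin <- which(modes$classes == "efv_lineality")
  improving <- c(unb[vapply(unb, function(i) vals[[i]]$num > 0, logical(1))],
                 lin[vapply(lin, function(i) vals[[i]]$num != 0, logical(1))])
  if (length(improving)) {
    return(list(status = "unbounded", optimum = NULL, value = NA_real_,
                optimal_modes = mode_subset(modes, improving)))
  }
  bounded <- which(modes$classes %in% c("efv_bounded", "zero"))
  if (!length(bounded)) {
    # cone case: all rays non-improving, optimum 0 at the origin
    flat <- c(unb, lin)[vapply(c(unb, lin), function(i) vals[[i]]$num == 0,
                               logical(1))]
    return(list(status = "bounded", optimum = list(num = 0, den = 1),
                value = 0, optimal_modes = mode_subset(modes, flat)))
  }
  best <- bounded[1]
  for (i in bounded[-1])
    if (rat_cmp(vals[[i]]$num, vals[[i]]$den,
                vals[[best]]$num, vals[[best]]$den) > 0) best <- i
  opt <- vals[[best]]
  attain <- bounded[vapply(bounded, function(i)
    rat_cmp(vals[[i]]$num, vals[[i]]$den, opt$num, opt$den) == 0, logical(1))]
  flat_rays <- c(unb, lin)[vapply(c(unb, lin), function(i)
    vals[[i]]$num == 0, logical(1))]
  optimum <- list(num = sgn * opt$num, den = opt$den)
  list(status = "bounded", optimum = optimum,
       value = optimum$num / optimum$den,
       optimal_modes = mode_subset(modes, sort(c(attain, flat_rays))))
}

#' Optimize a yield (linear-fractional) objective over a flux polyhedron
#'
#' Maximizes c^T r / d^T r over the enumerated EFVs. Requires d^T v > 0 for
#' every nonzero bounded EFV and d^T u >= 0 for every unbounded EFV (exact
#' positivity of the denominator over the nonzero polyhedron); the zero EFV is
#' excluded. The per-EFV yield maximum is the supremum over the polyhedron;
#' it is attained iff some bounded EFV reaches it, otherwise (optimum only at
#' an unbounded EFV) the supremum can only be approached along that direction.
#' An unbounded EFV with d^T u = 0 and c^T u > 0 makes the yield unbounded.
#'
#' With `strict = FALSE` the positivity precondition on bounded EFVs is
#' relaxed to d^T v >= 0 and EFVs with a zero denominator are skipped in the
#' per-EFV yield comparison (the classic per-mode yield analysis); note that
#' when such a skipped EFV has c^T v > 0 the supremum over the polyhedron
#' itself is infinite even though the per-EFV maximum is finite.
#'
#' @param modes a `mode_set` from [enumerate_efvs()].
#' @param obj an [objective()] with both `c` and `d`.
#' @param strict enforce d^T v > 0 for every nonzero bounded EFV (default).
#' @return list with exact `optimum` (list(num, den); NULL with
#'   `unbounded = TRUE` when the yield is unbounded), numeric `value`,
#'   `attained` (TRUE iff realized by a bounded EFV), and `optimal_modes`.
#' @export
optimize_yield <- function(modes, obj, strict = TRUE) {
  stopifnot(inherits(modes, "mode_set"), inherits(obj, "objective"))
  if (is.null(obj$d)) stop("yield objective requires a denominator d",
                           call. = FALSE)
  if (obj$sense != "max")
    stop("yield optimization is implemented for sense = 'max'; negate c to ",
         "minimize", call. = FALSE)
  nz <- .nonzero_idx(modes)
  if (!length(nz)) stop("no nonzero modes to optimize over", call. = FALSE)
  dvals <- lapply(seq_len(n_modes(modes)), function(i)
    .obj_value(obj$d, modes, i))
  cvals <- lapply(seq_len(n_modes(modes)), function(i)
    .obj_value(obj$c, modes, i))
  for (i in nz) {
    cls <- modes$classes[i]
    if (cls == "efv_bounded" && dvals[[i]]$num < 0)
      stop("denominator d^T r is negative over the polyhedron; witness ",
           "bounded EFV #", i, call. = FALSE)
    if (strict && cls == "efv_bounded" && dvals[[i]]$num == 0)
      stop("denominator d^T r is not positive over the polyhedron; witness ",
           "bounded EFV #", i, " (use strict = FALSE for per-EFV yields)",
           call. = FALSE)
    if (cls %in% c("efv_unbounded", "efm", "efv_lineality") &&
        dvals[[i]]$num < 0)
      stop("denominator d^T r can become negative along unbounded EFV #", i,
           call. = FALSE)
  }
  yields <- vector("list", n_modes(modes))
  unbounded_yield <- integer(0)
  for (i in nz) {
    if (dvals[[i]]$num == 0) {
      # a recession direction gaining c while not consuming d makes the
      # yield unbounded; a bounded EFV with zero denominator is skipped
      # (per-EFV semantics, non-strict mode only)
      if (cvals[[i]]$num > 0 &&
          modes$classes[i] %in% c("efv_unbounded", "efm", "efv_lineality"))
        unbounded_yield <- c(unbounded_yield, i)
      next
    }
    yields[[i]] <- rat_div(cvals[[i]]$num, cvals[[i]]$den,
                           dvals[[i]]$num, dvals[[i]]$den)
  }
  if (length(unbounded_yield)) {
    return(list(optimum = NULL, value = Inf, attained = FALSE,
                unbounded = TRUE,
                optimal_modes = mode_subset(modes, unbounded_yield)))
  }
  cand <- nz[!vapply(nz, function(i) is.null(yields[[i]]), logical(1))]
  best <- cand[1]
  for (i in cand[-1])
    if (rat_cmp(yields[[i]]$num, yields[[i]]$den,
                yields[[best]]$num, yields[[best]]$den) > 0) best <- i
  opt <- yields[[best]]
  attain <- cand[vapply(cand, function(i)
    rat_cmp(yields[[i]]$num, yields[[i]]$den, opt$num, opt$den) == 0,
    logical(1))]
  attained <- any(modes$classes[attain] == "efv_bounded")
  list(optimum = opt, value = opt$num / opt$den, attained = attained,
       unbounded = FALSE, optimal_modes = mode_subset(modes, attain))
}

#' Knockout filtering of a mode set
#'
#' Returns exactly the modes with zero rate through every deleted reaction;
#' by the subnetwork property this is the mode set of the reduced network, so
#' no re-enumeration is needed.
#'
#' @param modes a `mode_set`.
#' @param deleted character vector of reaction ids (or integer indices).
#' @return the filtered `mode_set`.
#' @export
knockout <- function(modes, deleted) {
  stopifnot(inherits(modes, "mode_set"))
  if (is.numeric(deleted)) idx <- as.integer(deleted)
  else {
    idx <- match(deleted, modes$network$reaction_ids)
    if (anyNA(idx)) stop("unknown reaction id: ",
                         paste(deleted[is.na(idx)], collapse = ", "),
                         call. = FALSE)
  }
  if (!length(idx)) return(modes)
  keep <- rowSums(modes$num[, idx, drop = FALSE] != 0) == 0
  mode_subset(modes, which(keep))
}

# ---- conformal decomposition ----------------------------------------------

# greedy conformal decomposition in a split nonnegative cone.
# gens: rows = generators (all >= 0), target: vector >= 0, same equalities.
# Returns exact rational weights per generator or NULL on failure.
.greedy_conformal <- function(gens, tn, td) {
  k <- nrow(gens)
  wn <- numeric(k); wd <- rep(1, k)
  guard <- 0
  while (any(tn != 0)) {
    guard <- guard + 1
    if (guard > length(tn) + k + 5) return(NULL)
    supp <- tn != 0
    # candidates conformal to the residual: support contained in supp
    cand <- which(vapply(seq_len(k), function(i)
      all(gens[i, !supp] == 0) && any(gens[i, ] != 0), logical(1)))
    if (!length(cand)) return(NULL)
    # largest-step greedy, deterministic tie-break by generator index
    best <- NULL; best_step <- NULL
    for (i in cand) {
      nzg <- which(gens[i, ] != 0)
      step <- NULL
      for (j in nzg) {
        r <- rat_div(tn[j], td[j], gens[i, j], 1)
        if (is.null(step) || rat_cmp(r$num, r$den, step$num, step$den) < 0)
          step <- r
      }
      if (step$num <= 0) next
      if (is.null(best) ||
          rat_cmp(step$num, step$den, best_step$num, best_step$den) > 0) {
        best <- i; best_step <- step
      }
    }
    if (is.null(best)) return(NULL)
    acc <- rat_add(wn[best], wd[best], best_step$num, best_step$den)
    wn[best] <- acc$num; wd[best] <- acc$den
    for (j in which(gens[best, ] != 0)) {
      p <- rat_mul(best_step$num, best_step$den, gens[best, j], 1)
      r <- rat_sub(tn[j], td[j], p$num, p$den)
      tn[j] <- r$num; td[j] <- r$den
    }
  }
  list(num = wn, den = wd)
}

# split a signed rational vector into (pos | neg) halves on the free columns
.split_vector <- function(num, den, free) {
  pos_n <- pmax(num, 0); pos_d <- den
  neg <- numeric(length(free)); neg_d <- rep(1, length(free))
  if (length(free)) {
    neg <- pmax(-num[free], 0)
    neg_d <- den[free]
  }
  list(num = c(pos_n, neg), den = c(pos_d, neg_d))
}

#' Conformally decompose a flux distribution into elementary vectors
#'
#' Writes a feasible target vector as a convex combination of bounded EFVs
#' plus a nonnegative combination of unbounded EFVs (plus signed contributions
#' of lineality members), with every used generator sign-compatible with the
#' target (no cancellations). The weights are exact rationals. The
#' decomposition is in general not unique; a deterministic largest-step greedy
#' over the augmented (homogenized + slacked, reversibility-split) cone is
#' used, which always terminates because every step zeroes at least one
#' residual coordinate.
#'
#' @param target vector of length n (numeric or rational strings), a feasible
#'   point of the defining polyhedron (cone for EFM sets).
#' @param modes a `mode_set` from [enumerate_efvs()] or [enumerate_efms()].
#' @return an object of class `decomposition`: data frame `weights` with
#'   columns `mode` (row index into `modes`), `class`, `weight` (exact
#'   string), `weight_num`/`weight_den`; plus `alpha_sum` (exact, 1 whenever
#'   bounded EFVs are used).
#' @export
decompose <- function(target, modes) {
  stopifnot(inherits(modes, "mode_set"))
  network <- modes$network
  n <- n_reactions(network)
  tt <- parse_rational(target)
  if (length(tt$num) != n) stop("target length mismatch", call. = FALSE)
  if (!.steady_state_ok(network, tt$num, tt$den))
    stop("target is not a steady-state flux vector of the network",
         call. = FALSE)
  cons <- modes$constraints
  polyhedral <- any(modes$classes %in% c("efv_bounded", "zero")) ||
    n_constraint_rows(cons) > 0
  free <- setdiff(seq_len(n), network$irr)
  if (polyhedral) {
    s <- .constraint_slacks(cons, tt$num, tt$den, h_scale = 1)
    if (any(s$num < 0))
      stop("target violates the inhomogeneous constraints", call. = FALSE)
    # augmented coordinates: (r | slacks | lambda), then split free r-columns
    aug_target <- list(num = c(tt$num, s$num, 1), den = c(tt$den, s$den, 1))
    gens <- list(); gidx <- integer(0); gscale <- list()
    for (i in seq_len(n_modes(modes))) {
      cls <- modes$classes[i]
      vn <- modes$num[i, ]; vd <- modes$den[i, ]
      orientations <- list(list(num = vn, den = vd, sgn = 1))
      if (cls == "efv_lineality")
        orientations <- c(orientations, list(list(num = -vn, den = vd,
                                                  sgn = -1)))
      for (o in orientations) {
        hs <- if (cls %in% c("efv_bounded", "zero")) 1 else 0
        sl <- .constraint_slacks(cons, o$num, o$den, h_scale = hs)
        lam <- if (cls %in% c("efv_bounded", "zero")) 1 else 0
        w <- list(num = c(o$num, sl$num, lam), den = c(o$den, sl$den, 1))
        # scale generator to primitive integers; remember the conversion
        # factor so reported weights refer to the stored representative:
        # prim = scale * w, hence a step t on prim contributes t * scale
        # units of the stored mode (lambda is 1 for bounded modes, so this
        # is exactly the convex weight there)
        prim <- rat_primitive(w$num, w$den)
        nz <- which(prim != 0)  # never empty: lambda = 1 for bounded modes
        scale <- rat_div(prim[nz[1]], 1, w$num[nz[1]], w$den[nz[1]])
        gens[[length(gens) + 1L]] <- prim
        gidx <- c(gidx, i * o$sgn)
        gscale[[length(gscale) + 1L]] <- scale
      }
    }
    G <- do.call(rbind, gens)
    split_free <- free  # only reaction coordinates can be negative
    Gs <- cbind(pmax(G, 0)[, , drop = FALSE],
                if (length(split_free))
                  pmax(-G[, split_free, drop = FALSE], 0))
    ts <- .split_vector(aug_target$num, aug_target$den, split_free)
    w <- .greedy_conformal(Gs, ts$num, ts$den)
    if (is.null(w))
      stop("internal error: no conformal decomposition found; the mode set ",
           "does not conformally generate its polyhedron", call. = FALSE)
    rows <- list(); alpha_acc <- list(num = 0, den = 1)
    for (g in seq_along(gidx)) {
      if (w$num[g] == 0) next
      i <- abs(gidx[g])
      eff <- rat_mul(w$num[g], w$den[g], gscale[[g]]$num, gscale[[g]]$den)
      if (gidx[g] < 0) eff$num <- -eff$num
      cls <- modes$classes[i]
      if (cls %in% c("efv_bounded", "zero"))
        alpha_acc <- rat_add(alpha_acc$num, alpha_acc$den, eff$num, eff$den)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = i, class = cls,
        weight = format_rational(eff$num, eff$den),
        weight_num = eff$num, weight_den = eff$den)
    }
  } else {
    # flux-cone case: decompose directly over the (split) EFMs
    gens <- list(); gidx <- integer(0); gscale <- list()
    for (i in seq_len(n_modes(modes))) {
      orientations <- list(list(sgn = 1))
      if (modes$reversible[i]) orientations <- c(orientations,
                                                 list(list(sgn = -1)))
      for (o in orientations) {
        gens[[length(gens) + 1L]] <- o$sgn * modes$num[i, ]
        gidx <- c(gidx, i * o$sgn)
        gscale[[length(gscale) + 1L]] <- list(num = 1, den = 1)
      }
    }
    G <- do.call(rbind, gens)
    Gs <- cbind(pmax(G, 0), if (length(free)) pmax(-G[, free, drop = FALSE], 0))
    ts <- .split_vector(tt$num, tt$den, free)
    w <- .greedy_conformal(Gs, ts$num, ts$den)
    if (is.null(w))
      stop("internal error: no conformal decomposition found", call. = FALSE)
    rows <- list(); alpha_acc <- list(num = 0, den = 1)
    for (g in seq_along(gidx)) {
      if (w$num[g] == 0) next
      i <- abs(gidx[g])
      eff <- list(num = w$num[g] * sign(gidx[g]), den = w$den[g])
      rows[[length(rows) + 1L]] <- data.frame(
        mode = i, class = modes$classes[i],
        weight = format_rational(eff$num, eff$den),
        weight_num = eff$num, weight_den = eff$den)
    }
  }
  weights <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mode = integer(0), class = character(0), weight = character(0),
               weight_num = numeric(0), weight_den = numeric(0))
  structure(list(weights = weights,
                 alpha_sum = format_rational(alpha_acc$num, alpha_acc$den),
                 target = tt, modes = modes),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat("decomposition into", nrow(x$weights), "modes (alpha sum =",
      x$alpha_sum, ")\n")
  print(x$weights[, c("mode", "class", "weight")], row.names = FALSE)
  invisible(x)
}

#' Verify a decomposition exactly
#'
#' Reconstructs the weighted sum and checks exact equality with the target and
#' conformality of every scaled part.
#'
#' @param dec a `decomposition`.
#' @return TRUE or FALSE.
#' @export
verify_decomposition <- function(dec) {
  parts <- lapply(seq_len(nrow(dec$weights)), function(k) {
    i <- dec$weights$mode[k]
    rat_mul(rep(dec$weights$weight_num[k], ncol(dec$modes$num)),
            rep(dec$weights$weight_den[k], ncol(dec$modes$num)),
            dec$modes$num[i, ], dec$modes$den[i, ])
  })
  is_conformal_sum(parts, dec$target)
}
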