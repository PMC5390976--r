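# application layer: conformality, coupling, optimization, decomposition

bounded_case <- function() {
  ex <- example_model("bounded")
  list(ex = ex, ms = enumerate_efvs(ex$network, ex$constraints))
}

test_that("conformal sums are recognized exactly", {
  # the classic cancellation: (1,1,0) + (0,-1,1) = (1,0,1) is not conformal
  expect_false(is_conformal_sum(list(c(1, 1, 0), c(0, -1, 1)), c(1, 0, 1)))
  expect_true(is_conformal_sum(list(c(1, 1, 0)), c(1, 1, 0)))
  expect_error(is_conformal_sum(list(c(1, 1)), c(1, 1, 0)), "length mismatch")
  # same-orthant constructions are always conformal
  set.seed(3)
  for (k in 1:20) {
    sgn <- sample(c(-1, 1), 5, replace = TRUE)
    parts <- lapply(1:3, function(i) sgn * sample(0:3, 5, replace = TRUE))
    total <- Reduce(`+`, parts)
    keep <- total != 0
    parts <- lapply(parts, function(p) p * keep)  # zero-out masked coords
    total <- Reduce(`+`, parts)
    expect_true(is_conformal_sum(parts, total))
  }
})

test_that("essentiality and blockedness follow the mode-set rules", {
  f <- bounded_case()
  rep <- essential_blocked(f$ms)
  expect_length(rep$essential, 0)  # each reaction misses some bounded EFV
  expect_length(rep$blocked, 0)
  # linear chain: single EFM, both reactions essential
  chain <- metabolic_network("A", c("R1", "R2"), matrix(c(1, -1), 1, 2),
                             c("R1", "R2"))
  repc <- essential_blocked(enumerate_efms(chain))
  expect_setequal(repc$essential, c("R1", "R2"))
  # forcing r3 = 0 blocks R3
  ex <- example_model("bounded")
  cs <- build_constraints(ex$network,
                          bounds = list(R1 = list(ub = 2), R2 = list(lb = -1)),
                          rows = list(list(coeffs = list(R3 = 1), sense = "=",
                                           rhs = 0)))
  rep3 <- essential_blocked(enumerate_efvs(ex$network, cs))
  expect_true("R3" %in% rep3$blocked)
  expect_error(essential_blocked(mode_set(matrix(0, 0, 3),
                                          classes = character(0),
                                          network = ex$network)), "empty")
})

test_that("flux coupling matches the definitions applied by brute force", {
  # irreversible chain with stoichiometry 2: full coupling with exact ratio
  chain <- metabolic_network(c("A", "B"), c("R1", "R2", "R3"),
                             matrix(c(1, -2, 0, 0, 1, -1), 2, 3, byrow = TRUE),
                             c("R1", "R2", "R3"))
  rep <- coupling(enumerate_efms(chain))
  expect_equal(nrow(rep$fully_coupled), 3)
  r12 <- rep$fully_coupled$ratio[rep$fully_coupled$i == "R1" &
                                   rep$fully_coupled$j == "R2"]
  expect_equal(r12, "2")
  f <- bounded_case()
  expect_equal(nrow(coupling(f$ms)$fully_coupled), 0)
  # brute-force re-derivation on random instances
  for (s in c(2, 6, 11)) {
    inst <- rand_inst(s)
    ms <- suppressWarnings(enumerate_efvs(inst$network, inst$constraints))
    if (n_modes(ms) == 0) next
    rep <- coupling(ms)
    V <- ms$num / ms$den
    nz <- rowSums(V != 0) > 0
    V <- V[nz, , drop = FALSE]
    act <- V != 0
    unblocked <- which(colSums(act) > 0)
    for (a in unblocked) for (b in unblocked) {
      if (a >= b) next
      partial <- all(act[, a] == act[, b])
      expect_equal(any(rep$partially_coupled$i == ms$network$reaction_ids[a] &
                         rep$partially_coupled$j == ms$network$reaction_ids[b]),
                   partial)
      full <- partial && length(unique(V[act[, a], a] / V[act[, a], b])) == 1
      expect_equal(any(rep$fully_coupled$i == ms$network$reaction_ids[a] &
                         rep$fully_coupled$j == ms$network$reaction_ids[b]),
                   full)
    }
    for (a in unblocked) for (b in unblocked) {
      if (a == b) next
      expect_equal(any(rep$directionally_coupled$from ==
                         ms$network$reaction_ids[a] &
                         rep$directionally_coupled$to ==
                         ms$network$reaction_ids[b]),
                   all(!act[, a] | act[, b]))
    }
  }
})

test_that("rate optimization picks the right vertices and optimal faces", {
  f <- bounded_case()
  net <- f$ex$network
  # max r2 -> unique optimum (2,2,0)
  o <- optimize_rate(f$ms, objective(net, c(R2 = 1)))
  expect_equal(o$status, "bounded")
  expect_equal(o$value, 2)
  expect_equal(modeset_keys(o$optimal_modes), "efv_bounded|2,2,0")
  # max r3 -> (2,-1,3)
  o3 <- optimize_rate(f$ms, objective(net, c(R3 = 1)))
  expect_equal(o3$value, 3)
  expect_equal(modeset_keys(o3$optimal_modes), "efv_bounded|2,-1,3")
  # max r1 -> a three-EFV optimal face
  o1 <- optimize_rate(f$ms, objective(net, c(R1 = 1)))
  expect_setequal(modeset_keys(o1$optimal_modes),
                  c("efv_bounded|2,2,0", "efv_bounded|2,-1,3",
                    "efv_bounded|2,0,2"))
  # max r2 + r3 = 2 (the FBA optimum)
  expect_equal(optimize_rate(f$ms, objective(net, c(R2 = 1, R3 = 1)))$value, 2)
  # min r2 is attained at the two r2 = -1 vertices
  om <- optimize_rate(f$ms, objective(net, c(R2 = 1), sense = "min"))
  expect_equal(om$value, -1)
  # unbounded detection on the r2 >= 1 polyhedron
  ex2 <- example_model("r2_min_1")
  ms2 <- enumerate_efvs(ex2$network, ex2$constraints)
  expect_equal(optimize_rate(ms2, objective(ex2$network, c(R1 = 1)))$status,
               "unbounded")
})

test_that("rate optima agree with exact LP by vertex enumeration", {
  # independent route: optimum over the oracle's vertices / unboundedness via
  # its recession rays (fundamental theorem of linear programming)
  for (s in 1:10) {
    inst <- rand_inst(s, n_max = 5)
    ms <- suppressWarnings(enumerate_efvs(inst$network, inst$constraints))
    if (!any(ms$classes %in% c("efv_bounded", "zero"))) next
    ev <- suppressWarnings(
      enumerate_evs_bruteforce(inst$network, inst$constraints))
    set.seed(100 + s)
    for (rep in 1:3) {
      cv <- sample(-2:2, length(inst$network$reaction_ids), replace = TRUE)
      obj <- objective(inst$network, cv)
      got <- optimize_rate(ms, obj)
      V <- ev$num / ev$den
      vert <- which(ev$classes %in% c("efv_bounded", "zero"))
      rays <- which(ev$classes == "efv_unbounded")
      lin <- which(ev$classes == "efv_lineality")
      unbounded <- any(V[rays, , drop = FALSE] %*% cv > 0) ||
        any(V[lin, , drop = FALSE] %*% cv != 0)
      if (unbounded) {
        expect_equal(got$status, "unbounded")
      } else {
        expect_equal(got$status, "bounded")
        expect_equal(got$value, max(V[vert, , drop = FALSE] %*% cv))
        # returned optimizers attain the optimum
        W <- got$optimal_modes
        bounded_idx <- which(W$classes %in% c("efv_bounded", "zero"))
        vals <- (W$num / W$den)[bounded_idx, , drop = FALSE] %*% cv
        expect_true(all(vals == got$value))
      }
    }
  }
})

test_that("yield optimization handles attained, unattained, trivial cases", {
  net <- example_model("cone")$network
  # unattained supremum: r2 >= 1, max r3/r1 = 1 only along (1,0,1)
  ex2 <- example_model("r2_min_1")
  ms2 <- enumerate_efvs(ex2$network, ex2$constraints)
  y <- optimize_yield(ms2, objective(net, c(R3 = 1), d = c(R1 = 1)))
  expect_equal(y$value, 1)
  expect_false(y$attained)
  expect_equal(modeset_keys(y$optimal_modes), "efv_unbounded|1,0,1")
  # bounded polytope, per-EFV yields: max 3/2 at (2,-1,3)
  f <- bounded_case()
  yb <- optimize_yield(f$ms, objective(net, c(R3 = 1), d = c(R1 = 1)),
                       strict = FALSE)
  expect_equal(yb$optimum$num, 3); expect_equal(yb$optimum$den, 2)
  expect_true(yb$attained)
  expect_equal(modeset_keys(yb$optimal_modes), "efv_bounded|2,-1,3")
  # the strict (theory) precondition rejects the zero-denominator vertex
  expect_error(optimize_yield(f$ms, objective(net, c(R3 = 1), d = c(R1 = 1))),
               "not positive")
  # c = d: yield identically 1, every evaluable mode optimal
  yc <- optimize_yield(ms2, objective(net, c(R1 = 1), d = c(R1 = 1)))
  expect_equal(yc$value, 1)
  expect_true(yc$attained)
  expect_equal(n_modes(yc$optimal_modes), n_modes(ms2))
})

test_that("yields agree with a lifted-LP (Charnes-Cooper) cross-check", {
  # max c.r/d.r over FP == max c.y over {(y,t): N y = 0, irr signs on y,
  # G y - h t >= 0, t >= 0, d.y = 1}; solved independently by vertex
  # enumeration on the lifted polyhedron, with unbounded-t directions giving
  # the unattained-supremum case.
  lifted_max <- function(network, constraints, cv, dv) {
    lifted <- metabolic_network(
      network$metabolite_ids, c(network$reaction_ids, "t_hom"),
      cbind(network$N_num / network$N_den,
            numeric(length(network$metabolite_ids))),
      irreversible = c(network$reaction_ids[network$irr], "t_hom"))
    rows <- list(list(coeffs = stats::setNames(as.list(dv),
                                               network$reaction_ids),
                      sense = "=", rhs = 1))
    q <- length(constraints$h_num)
    for (i in seq_len(q)) {
      cf <- as.list(c(constraints$G_num[i, ] / constraints$G_den[i, ],
                      -constraints$h_num[i] / constraints$h_den[i]))
      names(cf) <- c(network$reaction_ids, "t_hom")
      rows[[length(rows) + 1]] <- list(coeffs = cf, sense = ">=", rhs = 0)
    }
    cs <- build_constraints(lifted, rows = rows)
    ev <- suppressWarnings(enumerate_evs_bruteforce(lifted, cs))
    V <- ev$num / ev$den
    vert <- which(ev$classes %in% c("efv_bounded", "zero"))
    if (!length(vert)) return(NULL)
    vals <- V[vert, seq_along(cv), drop = FALSE] %*% cv
    # attained iff some optimal vertex has t > 0 (maps back into FP)
    best <- max(vals)
    t_at_best <- V[vert[vals == best], ncol(V)]
    list(value = best, attained = any(t_at_best > 0))
  }
  ex2 <- example_model("r2_min_1")
  ms2 <- enumerate_efvs(ex2$network, ex2$constraints)
  ref <- lifted_max(ex2$network, ex2$constraints, c(0, 0, 1), c(1, 0, 0))
  got <- optimize_yield(ms2, objective(ex2$network, c(R3 = 1), d = c(R1 = 1)))
  expect_equal(got$value, ref$value)
  expect_equal(got$attained, ref$attained)
  # a strictly attained case: yield r2/r1 under r2 >= 1
  ref2 <- lifted_max(ex2$network, ex2$constraints, c(0, 1, 0), c(1, 0, 0))
  got2 <- optimize_yield(ms2, objective(ex2$network, c(R2 = 1), d = c(R1 = 1)))
  expect_equal(got2$value, ref2$value)
  expect_equal(got2$value, 1)
})

test_that("knockout filtering reproduces the worked example", {
  f <- bounded_case()
  ko <- knockout(f$ms, "R2")
  expect_setequal(modeset_keys(ko), c("zero|0,0,0", "efv_bounded|2,0,2"))
  expect_same_modeset(knockout(f$ms, character(0)), f$ms)
  expect_error(knockout(f$ms, "RX"), "unknown reaction")
})

test_that("decomposition is exact, conformal and convex where required", {
  f <- bounded_case()
  dec <- decompose(c(2, 1, 1), f$ms)
  expect_true(verify_decomposition(dec))
  expect_equal(dec$alpha_sum, "1")
  w <- dec$weights
  used <- mode_matrix(f$ms)[w$mode, , drop = FALSE]
  expect_setequal(apply(used, 1, paste, collapse = ","),
                  c("2,2,0", "2,0,2"))
  expect_setequal(w$weight, c("1/2", "1/2"))
  # an EFV decomposes onto itself
  i5 <- which(modeset_keys(f$ms) == "efv_bounded|2,0,2")
  dec5 <- decompose(c(2, 0, 2), f$ms)
  expect_equal(dec5$weights$mode, i5)
  expect_equal(dec5$weights$weight, "1")
  # infeasible targets are rejected
  expect_error(decompose(c(3, 1, 2), f$ms), "violates")
  expect_error(decompose(c(1, 2, 3), f$ms), "not a steady-state")
  # random feasible points decompose exactly (oracle-sampled)
  for (s in 1:6) {
    inst <- rand_inst(s, n_max = 5)
    ms <- suppressWarnings(enumerate_efvs(inst$network, inst$constraints))
    if (!any(ms$classes %in% c("efv_bounded", "zero"))) next
    for (seed in 1:3) {
      pt <- sample_point(inst$network, inst$constraints, seed = seed)
      dec <- decompose(format_rational(pt$num, pt$den), ms)
      expect_true(verify_decomposition(dec))
      if (any(dec$weights$class %in% c("efv_bounded", "zero")))
        expect_equal(dec$alpha_sum, "1")
    }
  }
})
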