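# elementary flux vectors via homogenization + slack variables

test_that("homogenize lays out the augmented block matrix exactly", {
  ex <- example_model("bounded")
  aug <- homogenize(ex$network, ex$constraints)
  expect_equal(unname(aug$D),
               rbind(c(1, -1, -1, 0, 0, 0),
                     c(-1, 0, 0, -1, 0, 2),
                     c(0, 1, 0, 0, -1, 1)))
  expect_equal(aug$r_cols, 1:3)
  expect_equal(aug$s_cols, 4:5)
  expect_equal(aug$lambda_col, 6)
  expect_equal(aug$irr_aug, c(1L, 3L, 4L, 5L, 6L))
  # q = 0 reduces to [N | 0] with only the homogenization column
  aug0 <- homogenize(ex$network, NULL)
  expect_equal(unname(aug0$D), matrix(c(1, -1, -1, 0), 1, 4))
  expect_equal(aug0$irr_aug, c(1L, 3L, 4L))
  # shape is forced: (m + q) rows, (n + q + 1) columns
  for (s in c(1, 6)) {
    inst <- rand_inst(s)
    q <- length(inst$constraints$h_num)
    m <- length(inst$network$metabolite_ids)
    n <- length(inst$network$reaction_ids)
    a <- homogenize(inst$network, inst$constraints, fold_equalities = FALSE)
    expect_equal(dim(a$D), c(m + q, n + q + 1))
  }
})

test_that("the bounded example polyhedron has exactly its five EFVs", {
  ex <- example_model("bounded")
  ms <- enumerate_efvs(ex$network, ex$constraints)
  expect_setequal(modeset_keys(ms),
                  c("zero|0,0,0", "efv_bounded|2,2,0", "efv_bounded|2,-1,3",
                    "efv_bounded|0,-1,1", "efv_bounded|2,0,2"))
  expect_true(validate_efv_set(ms)$valid)
})

test_that("without constraints the nonzero EFVs are the EFMs", {
  net <- example_model("cone")$network
  efvs <- enumerate_efvs(net)
  efms <- enumerate_efms(net)
  nz <- which(efvs$classes != "zero")
  expect_setequal(sub("^efv_unbounded", "efm", modeset_keys(efvs)[nz]),
                  modeset_keys(efms))
  expect_true("zero" %in% efvs$classes)
  # same collapse on random instances
  for (s in 1:8) {
    inst <- rand_inst(s)
    efvs <- enumerate_efvs(inst$network, NULL)
    efms <- enumerate_efms(inst$network)
    keys <- modeset_keys(efvs)[efvs$classes != "zero"]
    keys <- sub("^efv_(unbounded|lineality)", "efm", keys)
    expect_setequal(keys, modeset_keys(efms))
  }
})

test_that("a lower bound r2 >= 1 gives the expected bounded/unbounded split", {
  ex <- example_model("r2_min_1")
  ms <- enumerate_efvs(ex$network, ex$constraints)
  expect_setequal(modeset_keys(ms),
                  c("efv_bounded|1,1,0", "efv_unbounded|1,1,0",
                    "efv_unbounded|1,0,1"))
  expect_true(validate_efv_set(ms)$valid)
})

test_that("equality folding and the literal two-row treatment agree", {
  ex <- example_model("optimal_face")
  a <- enumerate_efvs(ex$network, ex$constraints, fold_equalities = TRUE)
  b <- enumerate_efvs(ex$network, ex$constraints, fold_equalities = FALSE)
  expect_same_modeset(a, b)
  # the optimal face of max r2 + r3: every EFV attains the optimum value 2
  expect_true(all(a$num[, 2] / a$den[, 2] + a$num[, 3] / a$den[, 3] == 2))
  for (s in c(3, 7)) {
    inst <- rand_inst(s)
    rows <- list(list(coeffs = stats::setNames(list(1),
                                               inst$network$reaction_ids[1]),
                      sense = "=", rhs = 0))
    cs <- build_constraints(inst$network, rows = rows)
    expect_same_modeset(
      suppressWarnings(enumerate_efvs(inst$network, cs, TRUE)),
      suppressWarnings(enumerate_efvs(inst$network, cs, FALSE)))
  }
})

test_that("an empty polyhedron warns and keeps only recession rays", {
  net <- example_model("cone")$network
  # r1 <= -1 with r1 irreversible: no feasible point; the recession cone
  # still contains the ray (0,-1,1) through the r1 = 0 face
  cs <- build_constraints(net, bounds = list(R1 = list(ub = -1)))
  expect_warning(ms <- enumerate_efvs(net, cs), "empty")
  expect_setequal(modeset_keys(ms), "efv_unbounded|0,-1,1")
  # no point and no ray at all: empty set
  net0 <- metabolic_network("A", c("R1", "R2"), matrix(c(1, 1), 1, 2),
                            c("R1", "R2"))
  cs0 <- build_constraints(net0, bounds = list(R1 = list(lb = 1)))
  expect_warning(ms0 <- enumerate_efvs(net0, cs0), "empty")
  expect_equal(n_modes(ms0), 0)
})

test_that("the validator flags corrupted modes", {
  ex <- example_model("bounded")
  ms <- enumerate_efvs(ex$network, ex$constraints)
  expect_true(validate_efv_set(ms)$valid)
  bad <- ms
  i <- which(bad$classes == "efv_bounded")[1]
  bad$num[i, 1] <- -bad$num[i, 1] - 1  # sign flip breaks feasibility
  rep <- validate_efv_set(bad, ex$network, ex$constraints)
  expect_false(rep$valid)
  expect_true(any(rep$violations$mode == i))
})

test_that("EFV enumeration equals the orthant brute force on random instances", {
  for (s in 1:25) {
    inst <- rand_inst(s)
    a <- suppressWarnings(enumerate_efvs(inst$network, inst$constraints))
    b <- suppressWarnings(
      enumerate_evs_bruteforce(inst$network, inst$constraints))
    expect_setequal(modeset_keys(a), modeset_keys(b))
    expect_true(validate_efv_set(a)$valid)
  }
})

test_that("every EFV support covers some support-minimal EFV", {
  for (s in c(1, 5, 10)) {
    inst <- rand_inst(s)
    ms <- suppressWarnings(enumerate_efvs(inst$network, inst$constraints))
    sm <- filter_support_minimal(ms)
    supp <- mode_support(ms)
    msupp <- mode_support(sm)
    for (i in which(lengths(supp) > 0)) {
      expect_true(any(vapply(msupp, function(sj)
        all(sj %in% supp[[i]]), logical(1))), info = paste("seed", s))
    }
  }
})

test_that("knockout equals re-enumeration with the rate fixed to zero", {
  for (s in 1:10) {
    inst <- rand_inst(s, n_max = 5)
    full <- suppressWarnings(enumerate_efvs(inst$network, inst$constraints))
    for (j in seq_along(inst$network$reaction_ids)) {
      rid <- inst$network$reaction_ids[j]
      ko <- knockout(full, rid)
      # original rows plus the deletion equality r_j = 0 (two halves)
      cs2 <- inst$constraints
      cs2$G_num <- rbind(cs2$G_num, diag(1, ncol(cs2$G_num))[j, ],
                         -diag(1, ncol(cs2$G_num))[j, ])
      cs2$G_den <- rbind(cs2$G_den, rep(1, ncol(cs2$G_den)),
                         rep(1, ncol(cs2$G_den)))
      cs2$h_num <- c(cs2$h_num, 0, 0)
      cs2$h_den <- c(cs2$h_den, 1, 1)
      cs2$tags <- c(cs2$tags, "equality_half:ko", "equality_half:ko")
      re <- suppressWarnings(enumerate_efvs(inst$network, cs2))
      expect_setequal(modeset_keys(ko), modeset_keys(re))
    }
  }
})
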