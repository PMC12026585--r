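# genotype_arithmetic module: constraints, ranges, bistochastic aggregation,
# projections, end-to-end prediction

b7 <- lattice_vector(c(1, 0, 0, 0, 0, 0, 0, 1), c(0, 0, 0, 0, 0, 0, 1, 0))

test_that("fixed-point constraints isolate g correctly", {
  # unit vector at the g position: constraint g >= 0
  e7 <- diag(8)[7, , drop = FALSE]
  sys <- fixed_point_constraints(e7, b7)
  expect_equal(sys$constraints[[1]]$coeff_g, c(num = 1, den = 1))
  expect_equal(sys$constraints[[1]]$constant, c(num = 0, den = 1))

  # last two coordinates: g + 1 >= 0
  h <- matrix(c(0, 0, 0, 0, 0, 0, 1, 1), 1)
  con <- fixed_point_constraints(h, b7)$constraints[[1]]
  expect_equal(con$coeff_g, c(num = 1, den = 1))
  expect_equal(con$constant, c(num = 1, den = 1))

  expect_error(fixed_point_constraints(diag(5), b7), "dimension mismatch")

  # full permuted-identity basis: 8 constraints matching a symbolic
  # dot-product oracle (affine coefficients recovered from two evaluations)
  P <- diag(8)[c(2, 1, 4, 3, 6, 5, 8, 7), ]
  sys8 <- fixed_point_constraints(P, b7)
  expect_length(sys8$constraints, 8)
  for (j in 1:8) {
    con <- sys8$constraints[[j]]
    f0 <- sum(lv_eval_test(b7, 0) * P[j, ])
    f1 <- sum(lv_eval_test(b7, 1) * P[j, ])
    expect_equal(rat_num_test(con$constant), f0)
    expect_equal(rat_num_test(con$coeff_g), f1 - f0)
  }
})

test_that("g ranges: examples, infeasibility, oracle agreement, containment", {
  b <- lattice_vector(c(0, 1), c(1, 0))
  sys <- fixed_point_constraints(rbind(c(1, -1), c(-1, 8)), b)
  r <- solve_g_range(sys)
  expect_equal(r$lower, 1)
  expect_equal(r$upper, 8)
  expect_identical(r$integer_candidates, 1:8)

  r2 <- solve_g_range(fixed_point_constraints(rbind(c(1, 0)), b))
  expect_equal(r2$lower, 0)
  expect_identical(r2$upper, Inf)
  expect_true(r2$truncated)

  rbad <- solve_g_range(fixed_point_constraints(rbind(c(1, -3), c(-1, 1)), b))
  expect_false(rbad$feasible)
  expect_length(rbad$integer_candidates, 0)

  set.seed(13)
  for (rep_ in 1:100) {
    rs <- random_constraint_system(10)
    ri <- solve_g_range(rs$system, "intersect", g_cap = 30)
    rsum <- solve_g_range(rs$system, "summed", g_cap = 30)
    # grid-scan oracle on a fine rational grid
    grid <- seq(-16, 16, by = 1 / 8)
    feas <- vapply(grid, function(g) system_holds(rs$rows, g), logical(1))
    if (!ri$feasible) {
      expect_false(any(feas))
    } else {
      inside <- grid >= ri$lower - 1e-9 & grid <= ri$upper + 1e-9
      expect_identical(feas, inside)
      # intersect range is contained in the summed range
      expect_gte(ri$lower, rsum$lower - 1e-12)
      expect_lte(ri$upper, rsum$upper + 1e-12)
    }
  }
})

test_that("bistochastic aggregation is exact and guards its invariant", {
  set.seed(19)
  perms <- lapply(1:8, function(i) random_permutation_matrix(8))
  M <- aggregate_bistochastic(perms, 8)
  expect_true(all(rowSums(M$num) == 8))
  expect_true(all(colSums(M$num) == 8))
  expect_equal(unique(c(rowSums(M$values), colSums(M$values))), 1)

  I1 <- aggregate_bistochastic(list(diag(4)), 1)
  expect_equal(I1$values, diag(4))

  expect_error(aggregate_bistochastic(perms, 7), "divisor")
  bad <- c(perms[-1], list(diag(8) * 2))
  expect_error(aggregate_bistochastic(bad, 8), "bistochasticity violation")
})

test_that("ratios and maximum projections", {
  shifts <- lapply(0:7, function(s) diag(8)[(seq_len(8) + s - 1) %% 8 + 1, ])
  U <- aggregate_bistochastic(shifts, 8)     # the uniform 1/8 matrix
  expect_equal(unique(as.vector(genotype_phenotype_ratios(U))), 1 / 8)
  expect_true(all(genotype_phenotype_ratios(U) >= 0 &
                    genotype_phenotype_ratios(U) <= 1))
  expect_equal(unname(rowSums(genotype_phenotype_ratios(U))), rep(1, 8))
  # uniform matrix: all rows tie
  expect_identical(max_projection_rows(U, b7, 2), 1:8)

  I <- aggregate_bistochastic(list(diag(8)), 1)
  e1b <- lattice_vector(c(1, rep(0, 7)))
  expect_identical(max_projection_rows(I, e1b, 0), 1L)

  # pipeline matrix against a per-row dot-product oracle
  rep7 <- get_report(7)
  for (gv in c(0, 1, 2)) {
    proj <- as.vector(rep7$bistochastic$values %*%
                        lv_eval_test(b7, gv))
    expect_identical(max_projection_rows(rep7$bistochastic, b7, gv),
                     sort(which(abs(proj - max(proj)) < 1e-12)))
  }
})

test_that("identity sections complete to a permutation matrix", {
  E <- rbind(diag(5)[2, ], diag(5)[5, ], c(1, -1, 0, 0, 0))
  P <- identity_sections_permutation(E)
  expect_true(is_permutation_matrix(P))
  expect_equal(P[1, ], diag(5)[2, ])   # sections first, ascending
  expect_equal(P[2, ], diag(5)[5, ])
  expect_equal(identity_sections_permutation(diag(6)), diag(6),
               ignore_attr = TRUE)
})

test_that("the end-to-end prediction is deterministic and self-consistent", {
  rep7 <- get_report(7)
  expect_identical(rep7$divisor, 8L)
  expect_identical(length(rep7$cones_at_ghat), 8L)   # 7 species + D

  # determinism: a fresh run serializes byte-identically
  rep7b <- predict_binding_sites(7, run_config(7, seed = 1L))
  f1 <- tempfile(); f2 <- tempfile()
  write_prediction_json(rep7, f1)
  write_prediction_json(rep7b, f2)
  expect_identical(readLines(f1), readLines(f2))

  # at least one integer candidate in range is dynamically stable
  expect_false(is.na(rep7$g_hat))
  expect_true(rep7$g_hat %in% rep7$integer_candidates)
  expect_identical(unname(rep7$stability_at_candidates[
    as.character(rep7$g_hat)]), "stable")

  # constraint soundness: every candidate satisfies every inequality exactly
  for (gv in rep7$integer_candidates) {
    for (con in rep7$constraints$constraints) {
      if (con$vacuous) next
      val <- con$coeff_g["num"] / con$coeff_g["den"] * gv +
        con$constant["num"] / con$constant["den"]
      expect_gte(val, 0)
    }
  }

  # intersect range inside summed range
  expect_gte(rep7$g_range$lower, rep7$g_range_summed$lower)
  expect_lte(rep7$g_range$upper, rep7$g_range_summed$upper)
})

test_that("known structural orders are recovered across the family", {
  # the admissible range must contain the true g, and the report's
  # stability call at the true g must match a direct classification
  results <- expand.grid(n = 3:7, g_true = 1:4)
  results$contained <- NA
  for (i in seq_len(nrow(results))) {
    n <- results$n[i]; g_true <- results$g_true[i]
    rep_ <- get_report(n)
    results$contained[i] <- rep_$g_range$feasible &&
      g_true >= rep_$g_range$lower && g_true <= rep_$g_range$upper
    if (g_true %in% rep_$integer_candidates) {
      direct <- linearize_and_classify(
        build_end_product_cascade(n, g = g_true))$classification
      expect_identical(
        unname(rep_$stability_at_candidates[as.character(g_true)]), direct)
    }
  }
  rate <- mean(results$contained)
  # report the per-configuration outcome, then assert full containment
  expect_true(all(results$contained),
              info = paste("containment rate:", rate))
})
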