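# hilbert_monoid module: cones, duals, Hilbert bases, decomposition,
# Normaliz interchange

test_that("rational cones clear denominators and record pointedness", {
  cn <- rational_cone(rbind(c(0.5, 1.5), c(1, 0)))
  expect_equal(cn$generators[1, ], c(1, 3))
  expect_true(rational_cone(diag(2))$pointed)
  expect_false(rational_cone(rbind(c(1, 0), c(-1, 0), c(0, 1)))$pointed)
})

test_that("dual cones: self-dual examples and double dualization", {
  d1 <- dual_cone(rational_cone(diag(2)))
  expect_equal(row_set(d1$generators), row_set(diag(2)))

  d2 <- dual_cone(rational_cone(rbind(c(1, 1), c(1, -1))))
  expect_equal(row_set(d2$generators), row_set(rbind(c(1, 1), c(1, -1))))

  # dual(dual(s)) and s agree as membership predicates on a test box
  set.seed(5)
  box <- as.matrix(expand.grid(-3:3, -3:3, -3:3))
  for (rep_ in 1:20) {
    G <- random_cone_matrix(3)
    cn <- rational_cone(G)
    dd <- dual_cone(dual_cone(cn))
    in1 <- apply(box %*% t(cn$generators) >= 0, 1, all)
    in2 <- apply(box %*% t(dd$generators) >= 0, 1, all)
    expect_identical(in1, in2)
  }
})

test_that("hilbert_basis handles the textbook cones", {
  hb <- hilbert_basis(rational_cone(diag(2)))
  expect_equal(row_set(hb$elements), row_set(diag(2)))

  # monoid {v : v1 >= 0, v1 + 2 v2 >= 0} needs the boundary vector (2, -1)
  hb2 <- hilbert_basis(rational_cone(rbind(c(1, 0), c(1, 2))))
  expect_equal(row_set(hb2$elements),
               row_set(rbind(c(1, 0), c(0, 1), c(2, -1))))

  # trivial monoid {0}: empty basis
  hb0 <- hilbert_basis(rational_cone(rbind(diag(2), -diag(2))))
  expect_identical(nrow(hb0$elements), 0L)

  expect_error(hilbert_basis(rational_cone(matrix(c(1, 0), 1, 2))),
               "not pointed")
})

test_that("magic-square monoid is generated by the permutation matrices", {
  hb3 <- hilbert_basis(magic_square_cone(3))
  expect_identical(nrow(hb3$elements), 6L)
  for (i in seq_len(6)) {
    expect_true(is_permutation_matrix(matrix(hb3$elements[i, ], 3, 3)))
  }
})

test_that("native basis equals the exhaustive oracle on random cones", {
  set.seed(17)
  for (trial in 1:15) {
    d <- sample(2:4, 1)
    C <- random_cone_matrix(d)
    hb <- hilbert_basis(rational_cone(C))$elements
    oracle <- oracle_hilbert(C, box = 6L)
    inbox <- apply(abs(hb) <= 6, 1, all)
    expect_identical(row_set(hb[inbox, , drop = FALSE]), row_set(oracle))
    # minimality: no element is the sum of two monoid elements in the box
    # (that is exactly what the oracle asserts); generation is witnessed by
    # decomposition below
  }
})

test_that("monoid membership agrees with a direct inner-product loop", {
  cn <- rational_cone(diag(2))
  expect_true(is_in_monoid(c(0, 0), cn))
  expect_false(is_in_monoid(c(-1, 0), cn))
  expect_error(is_in_monoid(c(1, 0, 0), cn), "dimension")
  set.seed(23)
  for (rep_ in 1:30) {
    d <- sample(2:4, 1)
    C <- random_cone_matrix(d)
    cn <- rational_cone(C)
    v <- sample(-4:4, d, replace = TRUE)
    direct <- TRUE
    for (i in seq_len(nrow(cn$generators))) {
      if (sum(cn$generators[i, ] * v) < 0) direct <- FALSE
    }
    expect_identical(is_in_monoid(v, cn), direct)
  }
})

test_that("decomposition witnesses generation", {
  hb <- hilbert_basis(rational_cone(rbind(c(1, 0), c(1, 2))))
  # a basis element decomposes as itself
  co <- decompose_in_basis(hb$elements[1, ], hb)
  expect_identical(sum(co), 1L)
  # non-member
  expect_null(decompose_in_basis(c(-5, 0), hb))
  # random members reconstruct exactly
  set.seed(31)
  for (rep_ in 1:20) {
    lam <- sample(0:3, nrow(hb$elements), replace = TRUE)
    v <- as.vector(lam %*% hb$elements)
    co <- decompose_in_basis(v, hb)
    expect_false(is.null(co))
    rebuilt <- colSums(hb$elements[as.integer(names(co)), , drop = FALSE] *
                         as.vector(co))
    expect_equal(unname(rebuilt), unname(v))
  }
})

test_that("integer magic squares with line sum s split into s permutations", {
  hb3 <- hilbert_basis(magic_square_cone(3))
  set.seed(41)
  for (s in 1:3) {
    picks <- sample(6, s, replace = TRUE)
    v <- colSums(hb3$elements[picks, , drop = FALSE])
    co <- decompose_in_basis(v, hb3)
    expect_identical(sum(co), s)   # Birkhoff: s permutation matrices
  }
})

test_that("Normaliz files round-trip and outputs parse", {
  G <- matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1, 1, 1, -1), 4, 3, byrow = TRUE)
  cn <- rational_cone(G)
  f <- tempfile(fileext = ".in")
  write_normaliz(cn, f)
  expect_equal(read_normaliz(f)$generators, cn$generators)

  # hand-written output fragment with a two-element basis block
  out <- tempfile(fileext = ".out")
  writeLines(c("preamble", "", "2 Hilbert basis elements:",
               "1 0", "0 1", "", "trailing"), out)
  parsed <- parse_normaliz_output(out)
  expect_equal(row_set(parsed$elements), row_set(diag(2)))

  # the native basis agrees with a Normaliz-style output file for the
  # quadrant (cross-tool route via the file interface; if a normaliz
  # binary is on PATH, exercise it for real)
  native <- hilbert_basis(rational_cone(diag(2)))
  expect_equal(row_set(native$elements), row_set(parsed$elements))
  if (Sys.which("normaliz") != "") {
    fin <- tempfile(fileext = ".in")
    write_normaliz(magic_square_cone(3), fin)
    system2("normaliz", fin, stdout = FALSE)
    nz <- parse_normaliz_output(sub("\\.in$", ".out", fin))
    expect_equal(row_set(nz$elements),
                 row_set(hilbert_basis(magic_square_cone(3))$elements))
  }

  # block writer round-trips through the parser
  bf <- tempfile(fileext = ".out")
  write_hilbert_block(native, bf)
  expect_equal(row_set(parse_normaliz_output(bf)$elements),
               row_set(native$elements))

  # malformed inputs fail with line numbers
  bad <- tempfile()
  writeLines(c("2", "oops", "1 0"), bad)
  expect_error(read_normaliz(bad), "line 2")
  bad2 <- tempfile()
  writeLines(c("3", "2", "1 0", "0 1"), bad2)
  expect_error(read_normaliz(bad2), "parse error")
})
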