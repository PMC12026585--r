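# Genotype arithmetic: torus fixed-point constraints over the unknown
# kinetic order g, their admissible range, and the doubly stochastic
# aggregation of monoid generators.
#
# The monomial map X^<b,h> has a finite limit as X -> 0 exactly when the
# exponent <b, h> is non-negative; applied to the symbolic lattice vector
# b(g) of the feedback equation and every Hilbert-basis element h_j this
# yields one linear inequality coeff_g * g + constant >= 0 per generator.

#' Torus fixed-point constraints from a Hilbert basis
#'
#' For each basis element \eqn{h_j} forms the inequality
#' \eqn{\langle b(g), h_j\rangle \ge 0} with the symbolic g isolated:
#' `coeff_g * g + constant >= 0`, both coefficients exact rationals.
#' Constraints with both coefficients zero are flagged vacuous.
#'
#' @param basis a [hilbert_basis()] or a plain integer matrix of generators
#'   (rows).
#' @param b a symbolic [lattice_vector()] of matching (homogenized) length.
#' @param label optional provenance tag recorded on every constraint.
#' @return object of class `g_constraint_system`: list of constraints, each
#'   with fields `coeff_g`, `constant` (rational pairs), `vacuous`,
#'   `source` (basis element and label).
#' @examples
#' b <- lattice_vector(c(1, 0, 0, 1), c(0, 0, 1, 0))    # (1, 0, g, 1)
#' fixed_point_constraints(diag(4), b)
#' @export
fixed_point_constraints <- function(basis, b, label = NULL) {
  E <- if (inherits(basis, "hilbert_basis")) basis$elements else as.matrix(basis)
  stopifnot(inherits(b, "lattice_vector"))
  if (ncol(E) != lv_length(b)) {
    stop("dimension mismatch: basis elements have length ", ncol(E),
         ", b has length ", lv_length(b))
  }
  bc <- lapply(b$const, as_rat)
  bg <- lapply(b$gcoef, as_rat)
  cons <- lapply(seq_len(nrow(E)), function(j) {
    h <- E[j, ]
    acc_c <- rat(0); acc_g <- rat(0)
    for (k in seq_along(h)) {
      if (h[k] == 0) next
      acc_c <- rat_add(acc_c, rat_mul(bc[[k]], rat(h[k])))
      acc_g <- rat_add(acc_g, rat_mul(bg[[k]], rat(h[k])))
    }
    list(coeff_g = acc_g, constant = acc_c,
         vacuous = acc_g[1] == 0 && acc_c[1] == 0,
         source = list(element = h, index = j, label = label))
  })
  structure(list(constraints = cons), class = "g_constraint_system")
}

#' Merge constraint systems
#'
#' @param ... `g_constraint_system` objects.
#' @return a single `g_constraint_system`.
#' @export
merge_constraint_systems <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "g_constraint_system")))
  structure(list(constraints = do.call(c, lapply(parts, `[[`, "constraints"))),
            class = "g_constraint_system")
}

#' @export
print.g_constraint_system <- function(x, ...) {
  cat("constraint system with", length(x$constraints), "inequalities\n")
  for (con in x$constraints) {
    if (con$vacuous) next
    cat("  ", rat_fmt(con$coeff_g), "* g +", rat_fmt(con$constant), ">= 0",
        if (!is.null(con$source$label)) paste0("   [", con$source$label, "]"),
        "\n")
  }
  invisible(x)
}

.range_from_pairs <- function(pairs, g_cap) {
  lower <- NULL; upper <- NULL; feasible <- TRUE
  for (p in pairs) {
    a <- p$coeff_g; c0 <- p$constant
    if (a[1] == 0) {
      if (c0[1] < 0) feasible <- FALSE
      next
    }
    bound <- rat_div(rat_neg(c0), a)
    if (a[1] > 0) {
      if (is.null(lower) || rat_cmp(bound, lower) > 0) lower <- bound
    } else {
      if (is.null(upper) || rat_cmp(bound, upper) < 0) upper <- bound
    }
  }
  if (feasible && !is.null(lower) && !is.null(upper) &&
      rat_cmp(lower, upper) > 0) {
    feasible <- FALSE
  }
  lo_num <- if (is.null(lower)) -Inf else rat_num(lower)
  up_num <- if (is.null(upper)) Inf else rat_num(upper)
  truncated <- FALSE
  if (feasible) {
    clo <- if (is.null(lower)) { truncated <- TRUE; -g_cap } else rat_ceil(lower)
    cup <- if (is.null(upper)) { truncated <- TRUE; g_cap } else rat_floor(upper)
    cand <- if (clo <= cup) seq(clo, cup) else integer(0)
    if (!truncated && length(cand) > 0 &&
        (clo < -g_cap || cup > g_cap)) {
      cand <- cand[cand >= -g_cap & cand <= g_cap]
      truncated <- TRUE
    }
  } else {
    cand <- integer(0)
  }
  structure(list(lower = lo_num, upper = up_num,
                 lower_rat = lower, upper_rat = upper,
                 feasible = feasible, integer_candidates = as.integer(cand),
                 truncated = truncated),
            class = "g_range")
}

#' Admissible range of the unknown kinetic order
#'
#' Solves a constraint system for g.  `mode = "intersect"` (default) returns
#' the tightest interval satisfying every inequality; `mode = "summed"`
#' solves the single inequality obtained by summing all coefficient pairs
#' (the weaker aggregate, so the intersect range is always contained in it).
#' An infeasible system yields an empty, flagged range rather than an error.
#'
#' @param system a [fixed_point_constraints()] system.
#' @param mode `"intersect"` or `"summed"`.
#' @param g_cap window half-width used to list integer candidates when a
#'   bound is infinite (the range is then flagged `truncated`).
#' @return object of class `g_range` with fields `lower`, `upper` (numeric,
#'   possibly infinite), exact `lower_rat`/`upper_rat`, `feasible`,
#'   `integer_candidates`, `truncated`.
#' @examples
#' b <- lattice_vector(c(0, -1), c(1, 0))
#' sys <- fixed_point_constraints(rbind(c(1, 1), c(-1, -8)), b)  # g>=1, 8>=g
#' solve_g_range(sys)$integer_candidates
#' @export
solve_g_range <- function(system, mode = c("intersect", "summed"),
                          g_cap = 12L) {
  stopifnot(inherits(system, "g_constraint_system"))
  mode <- match.arg(mode)
  cons <- Filter(function(con) !con$vacuous, system$constraints)
  if (length(system$constraints) == 0L) stop("empty constraint system")
  if (mode == "summed") {
    a <- rat(0); c0 <- rat(0)
    for (con in cons) {
      a <- rat_add(a, con$coeff_g)
      c0 <- rat_add(c0, con$constant)
    }
    cons <- list(list(coeff_g = a, constant = c0))
  }
  out <- .range_from_pairs(cons, g_cap)
  out$mode <- mode
  out
}

#' @export
print.g_range <- function(x, ...) {
  if (!x$feasible) {
    cat("g range (", x$mode, "): infeasible (empty)\n", sep = "")
    return(invisible(x))
  }
  lo <- if (is.finite(x$lower)) rat_fmt(x$lower_rat) else "-Inf"
  up <- if (is.finite(x$upper)) rat_fmt(x$upper_rat) else "+Inf"
  cat("g range (", x$mode, "): [", lo, ", ", up, "]",
      if (x$truncated) "  (candidates truncated)", "\n", sep = "")
  cat("integer candidates:",
      if (length(x$integer_candidates)) paste(x$integer_candidates,
                                              collapse = " ") else "(none)",
      "\n")
  invisible(x)
}

#' Aggregate monoid generator matrices into a bistochastic matrix
#'
#' Sums the per-cone generator matrices (the convex hull of the network) and
#' divides by the number of contributing cones.  Because each contributing
#' matrix is a permutation of the identity, every row and column of the
#' aggregate sums to exactly 1; the check is exact (integer numerators over
#' a common divisor) and a violation raises an error, signalling that some
#' upstream generator matrix is not a permutation matrix.
#'
#' @param generator_matrices list of square integer matrices of equal size.
#' @param divisor positive integer; must equal the number of contributing
#'   matrices (species cones plus constraint cones).
#' @return object of class `bistochastic_matrix`: `values` (numeric),
#'   `num` (integer numerators), `divisor`, `components`.
#' @examples
#' p1 <- diag(3); p2 <- diag(3)[c(2, 3, 1), ]; p3 <- diag(3)[c(3, 1, 2), ]
#' aggregate_bistochastic(list(p1, p2, p3), 3)$values
#' @export
aggregate_bistochastic <- function(generator_matrices, divisor) {
  stopifnot(length(generator_matrices) >= 1)
  dims <- vapply(generator_matrices, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != ncol(m)) stop("generator matrices must be square")
    nrow(m)
  }, integer(1))
  if (length(unique(dims)) != 1L) stop("generator matrices differ in shape")
  if (divisor != length(generator_matrices)) {
    stop("divisor (", divisor, ") must equal the number of contributing ",
         "matrices (", length(generator_matrices), ")")
  }
  S <- Reduce(`+`, lapply(generator_matrices, as.matrix))
  if (any(S != round(S)) || any(S < 0)) {
    stop("generator matrices must have non-negative integer entries")
  }
  if (any(rowSums(S) != divisor) || any(colSums(S) != divisor)) {
    stop("bistochasticity violation: line sums of the aggregate are not all ",
         "equal to the divisor; upstream generators are not permutation ",
         "matrices")
  }
  structure(list(values = S / divisor, num = S, divisor = divisor,
                 components = generator_matrices),
            class = "bistochastic_matrix")
}

#' @export
print.bistochastic_matrix <- function(x, ...) {
  cat("bistochastic ", nrow(x$num), "x", ncol(x$num), " matrix, divisor ",
      x$divisor, "\n", sep = "")
  print(x$values)
  invisible(x)
}

#' Genotype/phenotype ratios
#'
#' The entries of the normalized aggregate matrix read as occupancy
#' probabilities: binding sites per molecule in the network, i.e. the
#' probability that the transcription factor for phenotype i occupies
#' binding-site class j.  Entries lie in [0, 1] and each row sums to 1.
#'
#' @param M a [aggregate_bistochastic()] matrix.
#' @return numeric matrix of ratios (the entries of `M`).
#' @export
genotype_phenotype_ratios <- function(M) {
  stopifnot(inherits(M, "bistochastic_matrix"))
  M$values
}

#' Rows of maximal projection onto the feedback lattice vector
#'
#' Returns the indices of all rows of the bistochastic matrix attaining the
#' maximal inner product with \eqn{b(g)} (the peak molar-concentration
#' direction); ties are all reported, in ascending order.  The comparison is
#' exact (integer arithmetic over the common denominator).
#'
#' @param M a [aggregate_bistochastic()] matrix.
#' @param b a [lattice_vector()] of matching length.
#' @param g_value numeric value substituted for the symbolic g.
#' @return integer vector of row indices.
#' @export
max_projection_rows <- function(M, b, g_value) {
  stopifnot(inherits(M, "bistochastic_matrix"), inherits(b, "lattice_vector"))
  if (ncol(M$num) != lv_length(b)) stop("dimension mismatch")
  wts <- lv_eval(b, g_value)
  den <- common_denominator(wts)
  wi <- round(wts * den)
  proj <- as.vector(M$num %*% wi)
  sort(which(proj == max(proj)))
}

#' Complete Hilbert-basis identity sections to a permutation matrix
#'
#' For the cascade family the computed bases contain "sections of the
#' identity": unit-vector generators.  This mechanizes their completion to a
#' full permuted identity matrix (the construction performed manually in the
#' original analyses): the unit vectors present are placed first in
#' ascending column order, then the missing unit vectors fill the remaining
#' rows, also ascending.
#'
#' @param basis a [hilbert_basis()] or an integer matrix of generators.
#' @return a square 0/1 permutation matrix of size `ncol(elements)`.
#' @export
identity_sections_permutation <- function(basis) {
  E <- if (inherits(basis, "hilbert_basis")) basis$elements else as.matrix(basis)
  d <- ncol(E)
  is_unit <- apply(E, 1, function(r) sum(r != 0) == 1L && sum(r) == 1L)
  cols <- sort(unique(apply(E[is_unit, , drop = FALSE], 1, which.max)))
  order_cols <- c(cols, setdiff(seq_len(d), cols))
  P <- matrix(0L, d, d)
  P[cbind(seq_len(d), order_cols)] <- 1L
  P
}

# The constraint equation D: the normalization cone over the homogenizing
# block, built from the zero monomial and the all-ones monomial.
constraint_cone_matrix <- function(n) {
  zero <- homogenize(lattice_vector(numeric(n)))
  ones <- homogenize(lattice_vector(rep(1, n)))
  build_cone_matrix(list(zero, ones), species_index = NA_integer_)
}

#' Run configuration for the prediction pipeline
#'
#' @param n pathway length (3..12).
#' @param alpha,beta,h optional rate vectors (defaults: all ones).
#' @param seed integer seed used for every stochastic choice.
#' @param temperature Boltzmann temperature.
#' @param search_radius base candidate box radius (raised automatically per
#'   cone to cover its own entries).
#' @param g_max largest candidate integer g swept (and range cap).
#' @param mode default range mode reported, `"intersect"` or `"summed"`.
#' @param sampler `"deterministic"` or `"stochastic"` dual-matrix mode.
#' @param sample_count matrices per cone in stochastic mode.
#' @param backend `"native"` Hilbert-basis engine or `"normaliz"` (requires
#'   the external binary; file interchange only).
#' @return object of class `run_config`.
#' @export
run_config <- function(n, alpha = NULL, beta = NULL, h = NULL, seed = 1L,
                       temperature = 1, search_radius = 2L, g_max = 12L,
                       mode = c("intersect", "summed"),
                       sampler = c("deterministic", "stochastic"),
                       sample_count = 1L,
                       backend = c("native", "normaliz")) {
  mode <- match.arg(mode); sampler <- match.arg(sampler)
  backend <- match.arg(backend)
  if (!is.numeric(n) || n != round(n) || n < 3 || n > 12) {
    stop("n must be an integer in 3..12")
  }
  n <- as.integer(n)
  chk <- function(v, nm) {
    if (is.null(v)) return(rep(1, n))
    if (length(v) != n || any(v <= 0)) stop(nm, " must be positive, length n")
    v
  }
  structure(list(n = n, alpha = chk(alpha, "alpha"), beta = chk(beta, "beta"),
                 h = chk(h, "h"), seed = as.integer(seed),
                 temperature = temperature,
                 search_radius = as.integer(search_radius),
                 g_max = as.integer(g_max), mode = mode, sampler = sampler,
                 sample_count = as.integer(sample_count), backend = backend),
            class = "run_config")
}

# cones (species + constraint D) of the cascade at a numeric g
cascade_cones <- function(config, g_value) {
  n <- config$n
  model_g <- build_end_product_cascade(n, g = g_value, alpha = config$alpha,
                                       beta = config$beta, h = config$h)
  cones <- lapply(seq_len(n), function(i) {
    build_cone_matrix(exponent_vectors(model_g$equations[[i]], n),
                      species_index = i, g_order = g_value)
  })
  names(cones) <- paste0("X", seq_len(n))
  cones$D <- constraint_cone_matrix(n)
  cones
}

# monoid basis of one cone: sample the dual matrix, then take the Hilbert
# basis of the integral closure of the cone it spans (double dual)
cone_monoid_basis <- function(cone, config, g_value) {
  C <- cone_matrix_numeric(cone, g_value)
  radius <- max(config$search_radius, ceiling(max(abs(C))), 1)
  bc <- boltzmann_config(temperature = config$temperature, seed = config$seed,
                         search_radius = radius,
                         sample_count = config$sample_count,
                         mode = config$sampler)
  sampled <- boltzmann_dual_matrices(cone, bc, g_value)[[1]]
  basis <- hilbert_basis(dual_cone(rational_cone(sampled)))
  list(sampled = sampled, basis = basis)
}

#' Predict the number of binding sites of the feedback regulator
#'
#' End-to-end pipeline: build the symbolic cascade; for every candidate
#' integer g in `0..g_max` construct the per-species lattice cones plus the
#' constraint cone D, sample dual-feasible matrices, and compute the Hilbert
#' basis of each sampled cone's lattice monoid; form the torus fixed-point
#' constraint system over the union of all basis elements against the
#' symbolic feedback vector \eqn{b(g) = (1, 0, \dots, 0, g, 1)}; solve the
#' admissible range in both intersect and summed modes; classify dynamical
#' stability at every integer candidate; and aggregate the per-cone
#' permuted-identity generator matrices (divisor = species cones +
#' constraint cones) into the bistochastic genotype/phenotype matrix.
#' Fully deterministic under a fixed configuration.
#'
#' @param n pathway length (3..12); ignored when `config` is supplied.
#' @param config a [run_config()].
#' @return object of class `prediction_report`.
#' @examples
#' \donttest{
#' rep7 <- predict_binding_sites(7)
#' rep7$divisor                     # 8: 7 species cones + constraint D
#' }
#' @export
predict_binding_sites <- function(n, config = run_config(n)) {
  stopifnot(inherits(config, "run_config"))
  n <- config$n
  model <- build_end_product_cascade(n, g = NA, alpha = config$alpha,
                                     beta = config$beta, h = config$h)
  bc <- numeric(n + 1); bc[1] <- 1; bc[n + 1] <- 1
  bg <- numeric(n + 1); bg[n] <- 1
  b <- lattice_vector(bc, bg)            # (1, 0, ..., 0, g, 1)

  candidates <- 0:config$g_max
  stage <- function(what, gv, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", what, "' failed at candidate g = ", gv, ": ",
           conditionMessage(e))
    })
  }
  per_candidate <- vector("list", length(candidates))
  elements <- list()          # union of basis elements, keyed by value
  for (ci in seq_along(candidates)) {
    gv <- candidates[ci]
    cones <- stage("lattice-cones", gv, cascade_cones(config, gv))
    monoids <- lapply(names(cones), function(nm) {
      stage(paste0("monoid-basis[", nm, "]"), gv,
            cone_monoid_basis(cones[[nm]], config, gv))
    })
    names(monoids) <- names(cones)
    per_candidate[[ci]] <- monoids
    for (nm in names(monoids)) {
      E <- monoids[[nm]]$basis$elements
      for (r in seq_len(nrow(E))) {
        key <- paste(E[r, ], collapse = ",")
        if (is.null(elements[[key]])) {
          elements[[key]] <- list(h = E[r, ], sources = character(0))
        }
        elements[[key]]$sources <-
          union(elements[[key]]$sources, paste0(nm, "@g", gv))
      }
    }
  }
  E <- do.call(rbind, lapply(elements, `[[`, "h"))
  system <- fixed_point_constraints(E, b, label = "union")
  for (j in seq_along(elements)) {
    system$constraints[[j]]$source$label <-
      paste(elements[[j]]$sources, collapse = ";")
  }
  g_range <- solve_g_range(system, "intersect", g_cap = config$g_max)
  g_range_summed <- solve_g_range(system, "summed", g_cap = config$g_max)

  cand <- g_range$integer_candidates
  cand <- cand[cand >= 0 & cand <= config$g_max]
  stability <- vapply(cand, function(gv) {
    linearize_and_classify(model, gv)$classification
  }, character(1))
  names(stability) <- as.character(cand)
  stable <- cand[stability == "stable"]
  g_hat <- if (length(stable)) max(stable) else NA_integer_
  g_geom <- if (!is.na(g_hat)) g_hat else 0L

  monoids_hat <- per_candidate[[which(candidates == g_geom)]]
  perms <- lapply(monoids_hat, function(m) {
    identity_sections_permutation(m$basis)
  })
  bisto <- aggregate_bistochastic(unname(perms), divisor = n + 1L)
  ratios <- genotype_phenotype_ratios(bisto)
  mpr <- max_projection_rows(bisto, b, g_value = g_geom)

  structure(list(n = n, config = config, b = b,
                 g_range = g_range, g_range_summed = g_range_summed,
                 integer_candidates = cand,
                 stability_at_candidates = stability,
                 g_hat = g_hat,
                 divisor = n + 1L,
                 bistochastic = bisto, ratios = ratios,
                 max_projection_rows = mpr,
                 constraints = system,
                 cones_at_ghat = monoids_hat),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("binding-site prediction for pathway length n =", x$n, "\n")
  print(x$g_range)
  print(x$g_range_summed)
  cat("stability at integer candidates:\n")
  if (length(x$stability_at_candidates)) {
    for (g in names(x$stability_at_candidates)) {
      cat("  g =", g, "->", x$stability_at_candidates[[g]], "\n")
    }
  } else cat("  (no integer candidates)\n")
  cat("largest stable candidate g_hat =", x$g_hat, "\n")
  cat("divisor:", x$divisor, "(", x$n, "species cones + 1 constraint )\n")
  cat("max-projection rows:", paste(x$max_projection_rows, collapse = " "),
      "\n")
  invisible(x)
}

#' Serialize a prediction report
#'
#' `write_prediction_json()` stores the machine-readable report;
#' `write_prediction_csv()` the bistochastic matrix;
#' `write_prediction_text()` a human-readable account mirroring the pipeline
#' columns (equation, cone, sampled matrix, Hilbert basis, constraints).
#'
#' @param report a [predict_binding_sites()] report.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_prediction_json <- function(report, path) {
  stopifnot(inherits(report, "prediction_report"))
  rng <- function(r) list(lower = r$lower, upper = r$upper,
                          feasible = r$feasible, truncated = r$truncated,
                          integer_candidates = r$integer_candidates)
  doc <- list(
    n = report$n,
    config = unclass(report$config),
    divisor = report$divisor,
    g_range_intersect = rng(report$g_range),
    g_range_summed = rng(report$g_range_summed),
    integer_candidates = report$integer_candidates,
    stability_at_candidates = as.list(report$stability_at_candidates),
    g_hat = report$g_hat,
    max_projection_rows = report$max_projection_rows,
    bistochastic = list(num = report$bistochastic$num,
                        divisor = report$bistochastic$divisor),
    ratios = report$ratios)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_prediction_json
#' @export
write_prediction_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report$bistochastic$values), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_prediction_json
#' @export
write_prediction_text <- function(report, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("genotype arithmetic report, n = ", report$n)
  w("seed = ", report$config$seed, ", sampler = ", report$config$sampler,
    ", g_max = ", report$config$g_max)
  w("")
  r <- report$g_range
  w("intersect range: [", if (is.finite(r$lower)) r$lower else "-Inf", ", ",
    if (is.finite(r$upper)) r$upper else "+Inf", "]",
    if (r$truncated) "  (candidates truncated)" else "")
  rs <- report$g_range_summed
  w("summed range:    [", if (is.finite(rs$lower)) rs$lower else "-Inf", ", ",
    if (is.finite(rs$upper)) rs$upper else "+Inf", "]")
  w("integer candidates: ", paste(report$integer_candidates, collapse = " "))
  w("stability: ", paste(names(report$stability_at_candidates),
                         report$stability_at_candidates,
                         sep = "=", collapse = "  "))
  w("g_hat (largest stable candidate) = ", report$g_hat)
  w("divisor = ", report$divisor)
  w("max projection rows: ", paste(report$max_projection_rows, collapse = " "))
  w("")
  for (nm in names(report$cones_at_ghat)) {
    m <- report$cones_at_ghat[[nm]]
    w("== cone ", nm, " ==")
    w("sampled dual matrix:")
    utils::write.table(m$sampled, con, row.names = FALSE, col.names = FALSE)
    w("Hilbert basis:")
    utils::write.table(m$basis$elements, con, row.names = FALSE,
                       col.names = FALSE)
    w("")
  }
  w("bistochastic aggregate (numerators over divisor ",
    report$bistochastic$divisor, "):")
  utils::write.table(report$bistochastic$num, con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
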