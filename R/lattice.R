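# Exponent-space lattice vectors and the per-species lattice cones.
#
# A lattice vector holds one exponent per species plus a trailing
# homogenizing coordinate (default 1).  Entries are affine in the single
# symbolic unknown g: entry_k = const_k + gcoef_k * g, so subtraction, inner
# products and substitution stay exact and affine.

#' Lattice vectors over the exponent space
#'
#' @param const numeric vector: the constant part of each entry (the last
#'   entry is the homogenizing coordinate).
#' @param gcoef numeric vector of the same length: coefficient of the
#'   symbolic unknown g in each entry.  At most one entry may be symbolic.
#' @return an object of class `lattice_vector`.
#' @examples
#' # the length-8 vector (1,0,0,0,0,0,g,1) of a 7-step cascade:
#' lattice_vector(c(1, 0, 0, 0, 0, 0, 0, 1), c(0, 0, 0, 0, 0, 0, 1, 0))
#' @export
lattice_vector <- function(const, gcoef = numeric(length(const))) {
  stopifnot(length(const) == length(gcoef))
  if (sum(gcoef != 0) > 1L) {
    stop("at most one entry of a lattice vector may be symbolic")
  }
  structure(list(const = as.numeric(const), gcoef = as.numeric(gcoef)),
            class = "lattice_vector")
}

#' @export
print.lattice_vector <- function(x, ...) {
  ent <- mapply(function(c0, c1) {
    if (c1 == 0) return(format(c0))
    gpart <- if (c1 == 1) "g" else if (c1 == -1) "-g" else paste0(c1, "g")
    if (c0 == 0) gpart else paste0(c0, ifelse(c1 > 0, "+", ""), gpart)
  }, x$const, x$gcoef)
  cat("(", paste(ent, collapse = ","), ")\n", sep = "")
  invisible(x)
}

lv_length <- function(v) length(v$const)
lv_is_symbolic <- function(v) any(v$gcoef != 0)
lv_eval <- function(v, g = NULL) {
  if (lv_is_symbolic(v) && is.null(g)) {
    stop("lattice vector is symbolic; supply a value for g")
  }
  if (is.null(g)) g <- 0
  v$const + v$gcoef * g
}
lv_sub <- function(a, b) lattice_vector(a$const - b$const, a$gcoef - b$gcoef)
lv_equal <- function(a, b) all(a$const == b$const) && all(a$gcoef == b$gcoef)

#' Homogenize / dehomogenize exponent vectors
#'
#' `homogenize()` appends the homogenizing coordinate (value 1 on original
#' monomial vectors, by construction 0 on differences); `dehomogenize()`
#' strips it.  Stripping then re-homogenizing is the identity on original
#' vectors.
#'
#' @param v a [lattice_vector()].
#' @param value homogenizing coordinate to append (default 1).
#' @return a [lattice_vector()].
#' @export
homogenize <- function(v, value = 1) {
  lattice_vector(c(v$const, value), c(v$gcoef, 0))
}

#' @rdname homogenize
#' @export
dehomogenize <- function(v) {
  k <- lv_length(v)
  lattice_vector(v$const[-k], v$gcoef[-k])
}

#' Exponent vectors of a rate-law equation
#'
#' Rewrites an S-system equation as a rational function with all exponents in
#' the numerator (degradation exponents keep their own sign) and returns one
#' homogenized lattice vector per monomial term.  When the production term
#' carries negative or symbolic exponents (the inhibitory feedback), the
#' combined vector of the factored form -- degradation exponents minus
#' production exponents -- is appended; for the first equation of a length-7
#' cascade this is the vector (1,0,0,0,0,0,g,1).
#'
#' @param equation one element of `model$equations` from
#'   [build_end_product_cascade()].
#' @param n number of species (ambient exponent dimension before
#'   homogenization).
#' @return list of [lattice_vector()]s of length `n + 1`.
#' @export
exponent_vectors <- function(equation, n) {
  stopifnot(inherits(equation, "ssys_equation"))
  term_lv <- function(term) {
    lattice_vector(term$exponents$const, term$exponents$gcoef)
  }
  prods <- lapply(equation$production, term_lv)
  degs <- lapply(equation$degradation, term_lv)
  out <- lapply(c(prods, degs), homogenize)
  needs_combined <- any(vapply(prods, function(v) {
    any(v$const < 0) || any(v$gcoef != 0)
  }, logical(1)))
  if (needs_combined && length(prods) == 1L && length(degs) == 1L) {
    out <- c(out, list(homogenize(lv_sub(degs[[1]], prods[[1]]))))
  }
  # drop duplicates (e.g. the factored form at g = 0 equals the degradation)
  uniq <- list()
  for (v in out) {
    if (!any(vapply(uniq, lv_equal, logical(1), v))) {
      uniq[[length(uniq) + 1L]] <- v
    }
  }
  uniq
}

#' Gene interaction matrix (lattice cone) of a set of exponent vectors
#'
#' Orders the vectors lexicographically, then stacks: the first original
#' vector, the pairwise differences of lexicographically adjacent originals,
#' and the last original vector.  The differences build the convex geometry
#' of the cone; first and last rows keep provenance `"original"`, interior
#' rows `"difference"`.
#'
#' Symbolic entries are admitted as long as the differences stay affine in g
#' (always true here); for ordering they are evaluated at `g_order`.
#'
#' @param vectors list of [lattice_vector()]s (>= 2, equal length).
#' @param species_index optional integer tag for reporting.
#' @param g_order numeric value of g used only for the lexicographic sort of
#'   symbolic vectors (default 1).
#' @return an object of class `gene_interaction_matrix` with fields `rows`
#'   (list of lattice vectors), `provenance`, `species_index`.
#' @examples
#' v <- list(lattice_vector(c(1, 0)), lattice_vector(c(0, 1)))
#' build_cone_matrix(v)   # rows (0,1), (1,-1), (1,0)
#' @export
build_cone_matrix <- function(vectors, species_index = NA_integer_, g_order = 1) {
  if (length(vectors) < 2L) {
    stop("need at least 2 exponent vectors to build a cone matrix")
  }
  lens <- vapply(vectors, lv_length, integer(1))
  if (length(unique(lens)) != 1L) stop("exponent vectors differ in length")
  num <- t(vapply(vectors, lv_eval, numeric(lens[1]), g = g_order))
  ord <- do.call(order, as.data.frame(num))
  vs <- vectors[ord]
  k <- length(vs)
  rows <- vector("list", k + 1L)
  rows[[1L]] <- vs[[1L]]
  if (k > 1L) for (i in seq_len(k - 1L)) {
    rows[[i + 1L]] <- lv_sub(vs[[i + 1L]], vs[[i]])
  }
  rows[[k + 1L]] <- vs[[k]]
  structure(list(rows = rows,
                 provenance = c("original", rep("difference", k - 1L), "original"),
                 species_index = species_index),
            class = "gene_interaction_matrix")
}

#' @export
print.gene_interaction_matrix <- function(x, ...) {
  cat("gene interaction matrix",
      if (!is.na(x$species_index)) paste0(" Con(X", x$species_index, ")"),
      ", ", length(x$rows), " rows\n", sep = "")
  for (i in seq_along(x$rows)) {
    cat(sprintf("%-10s ", x$provenance[i])); print(x$rows[[i]])
  }
  invisible(x)
}

# numeric integer matrix of the cone rows at a given g
cone_matrix_numeric <- function(cone, g_value = NULL) {
  rows <- t(vapply(cone$rows, lv_eval, numeric(lv_length(cone$rows[[1]])),
                   g = g_value))
  t(apply(rows, 1, function(r) {
    if (all(abs(r - round(r)) < 1e-9)) return(round(r))
    r * common_denominator(r)
  }))
}

#' Sampling configuration for dual-matrix construction
#'
#' @param temperature positive; Boltzmann weight is exp(-|v|^2 / temperature).
#' @param seed integer RNG seed (stochastic mode only, but always recorded).
#' @param search_radius positive integer bound on candidate entries
#'   (max-norm box).
#' @param sample_count number of matrices to draw in stochastic mode.
#' @param mode `"deterministic"` (default): the shortest dual-feasible
#'   vectors, ties broken by descending lexicographic order, kept greedily
#'   while they increase rank.  `"stochastic"`: sampling without replacement
#'   with Boltzmann weights, same rank filter.
#' @return an object of class `boltzmann_config`.
#' @export
boltzmann_config <- function(temperature = 1, seed = 1L, search_radius = 2L,
                             sample_count = 1L,
                             mode = c("deterministic", "stochastic")) {
  mode <- match.arg(mode)
  stopifnot(temperature > 0, search_radius >= 1, sample_count >= 1)
  structure(list(temperature = temperature, seed = as.integer(seed),
                 search_radius = as.integer(search_radius),
                 sample_count = as.integer(sample_count), mode = mode),
            class = "boltzmann_config")
}

# Candidate enumeration for the dual region {v : C v >= 0}.
#
# Small ambient dimension: the full max-norm box (exhaustive).  Larger
# dimension: signed unit vectors plus, on demand, a sub-box over the
# "coupled" coordinates (those appearing in constraint rows with more than
# one nonzero entry).  A shortest dual-feasible vector that increases rank
# beyond the feasible units can always be chosen with coupled support
# (zeroing the uncoupled coordinates of a feasible vector preserves
# feasibility and shortens it), so the staged search is exact for the
# deterministic shortest-vector semantics.
.feasible_rows <- function(M, C) {
  if (nrow(M) == 0L) return(M)
  M[apply(M %*% t(C) >= 0, 1, all) & rowSums(abs(M)) > 0, , drop = FALSE]
}

.coupled_coords <- function(C) {
  multi <- rowSums(C != 0) > 1L
  sort(unique(unlist(apply(C[multi, , drop = FALSE], 1,
                           function(r) which(r != 0)))))
}

.coupled_box <- function(C, radius) {
  d <- ncol(C)
  coupled <- .coupled_coords(C)
  if (length(coupled) == 0L) return(matrix(0, 0, d))
  if ((2 * radius + 1)^length(coupled) > 2e6) {
    stop("dual-candidate search space too large (", length(coupled),
         " coupled coordinates at radius ", radius, ")")
  }
  sub <- as.matrix(expand.grid(rep(list(seq(-radius, radius)),
                                   length(coupled))))
  box <- matrix(0, nrow(sub), d)
  box[, coupled] <- sub
  .feasible_rows(box, C)
}

.full_box <- function(C, radius) {
  d <- ncol(C)
  box <- as.matrix(expand.grid(rep(list(seq(-radius, radius)), d)))
  dimnames(box) <- NULL
  .feasible_rows(box, C)
}

# ascending norm, descending lexicographic tie-break
.order_candidates <- function(P) {
  if (nrow(P) < 2L) return(P)
  ord <- do.call(order, c(list(rowSums(P^2)),
                          lapply(seq_len(ncol(P)), function(j) -P[, j])))
  P[ord, , drop = FALSE]
}

.greedy_rank <- function(P, d, radius) {
  sel <- matrix(0, 0, d)
  for (i in seq_len(nrow(P))) {
    if (nrow(sel) == d) break
    cand <- rbind(sel, P[i, ])
    if (.int_rank(cand) > nrow(sel)) sel <- cand
  }
  dimnames(sel) <- NULL
  sel
}

#' Dual-feasible integer matrices of a lattice cone
#'
#' Builds square integer matrices of size `n + 1` whose rows lie in the dual
#' region \eqn{\{v : \langle v, c\rangle \ge 0\}} of the cone's rows, with
#' entries bounded by `config$search_radius`.  In the default deterministic
#' mode rows are the shortest feasible vectors (ties broken by descending
#' lexicographic order) kept while they increase the matrix rank; in
#' stochastic mode rows are drawn without replacement with probability
#' proportional to `exp(-|v|^2 / temperature)`, with the same rank filter.
#' Identical configurations give identical output.
#'
#' @param cone a [build_cone_matrix()] result.
#' @param config a [boltzmann_config()].
#' @param g_value numeric g substituted into symbolic entries (required when
#'   the cone is symbolic).
#' @return list of integer matrices (one in deterministic mode,
#'   `sample_count` in stochastic mode).
#' @export
boltzmann_dual_matrices <- function(cone, config = boltzmann_config(),
                                    g_value = NULL) {
  stopifnot(inherits(cone, "gene_interaction_matrix"),
            inherits(config, "boltzmann_config"))
  C <- cone_matrix_numeric(cone, g_value)
  d <- ncol(C)
  radius <- config$search_radius
  small <- (2 * radius + 1)^d <= 2e5
  insufficient <- function(sel) {
    stop("insufficient dual-feasible candidates within search radius ",
         radius, " (got rank ", nrow(sel), " of ", d, "); raise search_radius")
  }
  if (config$mode == "deterministic") {
    if (small) {
      pool <- .order_candidates(.full_box(C, radius))
      sel <- .greedy_rank(pool, d, radius)
    } else {
      # units first (all norm-1 vectors are units), coupled box on demand
      pool <- .order_candidates(.feasible_rows(rbind(diag(d), -diag(d)), C))
      sel <- .greedy_rank(pool, d, radius)
      if (nrow(sel) < d) {
        pool <- .order_candidates(unique(rbind(pool, .coupled_box(C, radius))))
        sel <- .greedy_rank(pool, d, radius)
      }
    }
    if (nrow(sel) < d) insufficient(sel)
    return(list(sel))
  }
  pool <- if (small) .full_box(C, radius) else {
    unique(rbind(.feasible_rows(rbind(diag(d), -diag(d)), C),
                 .coupled_box(C, radius)))
  }
  pool <- .order_candidates(pool)
  norm2 <- rowSums(pool^2)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  out <- vector("list", config$sample_count)
  for (s in seq_len(config$sample_count)) {
    set.seed(config$seed + (s - 1L) * 1009L)
    w <- exp(-norm2 / config$temperature)
    perm <- sample.int(nrow(pool), nrow(pool), replace = FALSE, prob = w)
    sel <- .greedy_rank(pool[perm, , drop = FALSE], d, radius)
    if (nrow(sel) < d) insufficient(sel)
    out[[s]] <- sel
  }
  out
}
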