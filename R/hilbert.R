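#' Rational polyhedral cones
#'
#' A `rational_cone` stores the generating vectors of a lattice cone
#' \eqn{\sigma} as the rows of an integer matrix.  Rational generators are
#' admitted and scaled row-wise to primitive integer form (an integer monoid
#' extends to a rational one by clearing denominators, and the cone is
#' unchanged under positive row scaling).
#'
#' The monoid attached to \eqn{\sigma} throughout the package is the set of
#' lattice points of the dual region,
#' \eqn{\sigma^\vee \cap Z^n = \{v \in Z^n : \langle v, c\rangle \ge 0
#' \ \forall c \in \sigma\}}.
#'
#' @param generators numeric matrix, one generator per row; entries must be
#'   rational (integers, or values recognisable as fractions).
#' @return An object of class `rational_cone` with fields `generators`
#'   (primitive integer matrix), `ambient_dim`, and `pointed` (whether the
#'   cone spanned by the generators is pointed, i.e. contains no line).
#' @examples
#' rational_cone(diag(2))               # the positive quadrant
#' rational_cone(rbind(c(1, 0), c(1, 2)))
#' @export
rational_cone <- function(generators) {
  G <- as.matrix(generators)
  if (nrow(G) == 0L || ncol(G) == 0L) stop("cone needs at least one generator")
  if (any(!is.finite(G))) stop("cone generators must be finite")
  Gi <- t(apply(G, 1, function(row) {
    if (all(abs(row - round(row)) < 1e-9)) return(.primitivize(row))
    .primitivize(row * common_denominator(row))
  }))
  if (ncol(Gi) != ncol(G)) Gi <- matrix(Gi, ncol = ncol(G)) # 1-row case
  # cone(G) is pointed iff its dual {v : G v >= 0} is full-dimensional
  dual <- .dd_rays(Gi)
  span <- rbind(dual$rays, dual$lineality)
  pointed <- nrow(span) > 0L && .int_rank(span) == ncol(Gi)
  structure(list(generators = Gi, ambient_dim = ncol(Gi), pointed = pointed),
            class = "rational_cone")
}

#' @export
print.rational_cone <- function(x, ...) {
  cat("rational cone in Z^", x$ambient_dim, ", ", nrow(x$generators),
      " generator(s), ", if (x$pointed) "pointed" else "not pointed",
      "\n", sep = "")
  print(x$generators)
  invisible(x)
}

#' Dual of a rational cone
#'
#' Computes a generator description of the dual region
#' \eqn{\{v : \langle v, c\rangle \ge 0 \ \forall c\}} by double description.
#' When the dual contains lines, both signs of a lineality basis are included
#' among the generators so that the result is again a generated cone.
#' For a full-dimensional pointed cone, `dual_cone(dual_cone(x))` returns the
#' original cone up to ordering and scaling of generators.
#'
#' @param cone a [rational_cone()].
#' @return a `rational_cone` generated by the extreme rays (and any lineality
#'   directions) of the dual region.
#' @examples
#' dual_cone(rational_cone(diag(2)))    # self-dual
#' @export
dual_cone <- function(cone) {
  stopifnot(inherits(cone, "rational_cone"))
  dd <- .dd_rays(cone$generators)
  G <- rbind(dd$rays, dd$lineality, -dd$lineality)
  if (nrow(G) == 0L) G <- matrix(0, 1, cone$ambient_dim) # dual is {0}
  rational_cone(G)
}

#' Membership in the monoid of a cone
#'
#' Tests whether an integer vector lies in \eqn{\sigma^\vee \cap Z^n}, i.e.
#' has non-negative inner product with every generator of `cone`.
#'
#' @param v integer vector of length `cone$ambient_dim`.
#' @param cone a [rational_cone()].
#' @return `TRUE` or `FALSE`.
#' @export
is_in_monoid <- function(v, cone) {
  stopifnot(inherits(cone, "rational_cone"))
  if (length(v) != cone$ambient_dim) {
    stop("dimension mismatch: vector has length ", length(v),
         ", cone lives in Z^", cone$ambient_dim)
  }
  all(cone$generators %*% v >= 0)
}

#' Hilbert basis of the monoid of a cone
#'
#' Computes the unique minimal generating set (Hilbert basis, finite by
#' Gordan's lemma) of the monoid \eqn{\sigma^\vee \cap Z^n} attached to a
#' cone \eqn{\sigma}.  The monoid must be pointed, which for
#' \eqn{\{v : Gv \ge 0\}} is equivalent to the generator matrix having full
#' column rank; non-pointed input raises an error, since the minimal
#' generating set is then not unique.
#'
#' The algorithm: extreme rays of the dual region by double description;
#' reduction to coordinates of the saturated lattice of their span; pulling
#' triangulation into simplicial subcones; enumeration of the lattice points
#' of each fundamental half-open parallelepiped; and a global irreducibility
#' sweep (an element is dropped iff it is the sum of two nonzero monoid
#' elements) ordered by a strictly positive linear functional.
#'
#' @param cone a [rational_cone()] whose monoid is pointed.
#' @return An object of class `hilbert_basis`: list with `elements` (integer
#'   matrix, rows sorted lexicographically) and `cone`.
#' @examples
#' hilbert_basis(rational_cone(diag(2)))$elements        # the two unit vectors
#' # boundary generator (2, -1) beyond the extreme rays:
#' hilbert_basis(rational_cone(rbind(c(1, 0), c(1, 2))))$elements
#' @export
hilbert_basis <- function(cone) {
  stopifnot(inherits(cone, "rational_cone"))
  C <- cone$generators
  n <- ncol(C)
  if (.int_rank(C) < n) {
    stop("monoid is not pointed (generator matrix has rank < ambient ",
         "dimension); its minimal generating set is not unique")
  }
  dd <- .dd_rays(C)
  if (nrow(dd$lineality) > 0L) {
    stop("internal error: lineality in a pointed monoid")
  }
  Rz <- dd$rays
  if (nrow(Rz) == 0L) {
    return(structure(list(elements = matrix(0, 0, n), cone = cone),
                     class = "hilbert_basis"))
  }
  B <- .saturation_basis(Rz)
  X <- .lattice_coords(Rz, B)
  simplices <- .triangulate(X)
  cand <- X
  for (S in simplices) cand <- rbind(cand, .parallelepiped_points(S))
  cand <- unique(cand)
  Cd <- C %*% t(B)                    # constraints in lattice coordinates
  wvec <- colSums(Cd)                 # strictly positive on the monoid
  w <- as.vector(cand %*% wvec)
  ord <- order(w)
  cand <- cand[ord, , drop = FALSE]; w <- w[ord]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    for (j in seq_len(nrow(cand))) {
      if (w[j] >= w[i]) break
      dif <- cand[i, ] - cand[j, ]
      if (any(dif != 0) && all(Cd %*% dif >= 0)) { keep[i] <- FALSE; break }
    }
  }
  elements <- .sort_rows(cand[keep, , drop = FALSE] %*% B)
  structure(list(elements = elements, cone = cone), class = "hilbert_basis")
}

#' @export
print.hilbert_basis <- function(x, ...) {
  cat("Hilbert basis with", nrow(x$elements), "element(s)\n")
  print(x$elements)
  invisible(x)
}

#' Decompose a monoid element over a Hilbert basis
#'
#' Finds non-negative integer coefficients over the basis elements summing to
#' `v`, witnessing the generation property of Gordan's lemma.  Returns `NULL`
#' when `v` is not in the monoid (or not reachable, which cannot happen for a
#' correct basis).
#'
#' @param v integer vector.
#' @param basis a [hilbert_basis()] (its `cone` supplies the membership test;
#'   a plain matrix of generators with a `cone` attribute is not supported).
#' @return named integer vector of coefficients (names = basis row indices,
#'   only nonzero entries), or `NULL`.
#' @examples
#' hb <- hilbert_basis(rational_cone(diag(2)))
#' decompose_in_basis(c(2, 3), hb)
#' @export
decompose_in_basis <- function(v, basis) {
  stopifnot(inherits(basis, "hilbert_basis"))
  E <- basis$elements
  if (length(v) != ncol(E)) stop("dimension mismatch")
  C <- basis$cone$generators
  member <- function(x) all(C %*% x >= 0)
  if (!member(v)) return(NULL)
  wvec <- colSums(C)
  wE <- as.vector(E %*% wvec)
  ordE <- order(-wE)                   # try heavy generators first
  coef <- integer(nrow(E))
  if (all(v == 0)) return(coef[integer(0)])
  failed <- new.env(parent = emptyenv())
  search <- function(target, from) {
    wt <- sum(target * wvec)
    if (wt == 0 && all(target == 0)) return(TRUE)
    key <- paste(c(from, target), collapse = ",")
    if (!is.null(failed[[key]])) return(FALSE)
    for (kk in seq(from, length(ordE))) {
      i <- ordE[kk]
      if (wE[i] > wt) next
      rem <- target - E[i, ]
      if (!member(rem)) next
      coef[i] <<- coef[i] + 1L
      if (search(rem, kk)) return(TRUE)
      coef[i] <<- coef[i] - 1L
    }
    failed[[key]] <- TRUE
    FALSE
  }
  if (!search(v, 1L)) return(NULL)
  out <- coef[coef > 0L]
  names(out) <- which(coef > 0L)
  out
}

#' The magic-square cone
#'
#' Builds the cone whose monoid is the set of k-by-k magic squares:
#' non-negative integer matrices (flattened row-major into \eqn{Z^{k^2}})
#' whose row sums and column sums all agree.  By the Birkhoff-von Neumann
#' theorem its Hilbert basis consists of exactly the \eqn{k!} permutation
#' matrices.
#'
#' @param k side length (>= 2).
#' @return a [rational_cone()] in \eqn{Z^{k^2}}.
#' @examples
#' nrow(hilbert_basis(magic_square_cone(3))$elements)   # 6
#' @export
magic_square_cone <- function(k) {
  stopifnot(k >= 2)
  n <- k * k
  idx <- function(i, j) (i - 1) * k + j
  eqs <- list()
  for (i in 2:k) {
    v <- numeric(n); v[idx(i, 1:k)] <- 1
    v[idx(1, 1:k)] <- v[idx(1, 1:k)] - 1
    eqs[[length(eqs) + 1L]] <- v
  }
  for (j in 1:k) {
    v <- numeric(n); v[idx(1:k, j)] <- 1
    v[idx(1, 1:k)] <- v[idx(1, 1:k)] - 1
    eqs[[length(eqs) + 1L]] <- v
  }
  E <- do.call(rbind, eqs)
  rational_cone(rbind(diag(n), E, -E))
}
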