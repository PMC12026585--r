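# Integer linear algebra and polyhedral primitives used by the Hilbert-basis
# engine.  Everything operates on plain numeric matrices whose entries are
# integers carried in doubles (exact below 2^53); inputs at the scale of this
# package (dimension <= ~16, entries of magnitude <= ~30) stay far inside
# that range.

.primitivize <- function(v) {
  v <- round(v)
  g <- 0
  for (x in v) if (x != 0) g <- .gcd2(g, x)
  if (g > 1) v <- v / g
  v
}

# Row Hermite normal form: returns list(H, U, rank) with U %*% M == H,
# U unimodular, H in row echelon form with positive pivots.
.hnf <- function(M) {
  M <- round(M)
  n <- nrow(M); m <- ncol(M)
  U <- diag(n); H <- M
  r <- 1L
  for (j in seq_len(m)) {
    if (r > n) break
    repeat {
      nz <- which(H[r:n, j] != 0) + r - 1L
      if (length(nz) == 0L) break
      p <- nz[which.min(abs(H[nz, j]))]
      if (p != r) { H[c(r, p), ] <- H[c(p, r), ]; U[c(r, p), ] <- U[c(p, r), ] }
      if (H[r, j] < 0) { H[r, ] <- -H[r, ]; U[r, ] <- -U[r, ] }
      others <- setdiff(which(H[r:n, j] != 0) + r - 1L, r)
      if (length(others) == 0L) break
      for (i in others) {
        q <- floor(H[i, j] / H[r, j])
        H[i, ] <- H[i, ] - q * H[r, ]
        U[i, ] <- U[i, ] - q * U[r, ]
      }
    }
    if (H[r, j] != 0) {
      if (r > 1L) for (i in seq_len(r - 1L)) {
        q <- floor(H[i, j] / H[r, j])
        if (q != 0) { H[i, ] <- H[i, ] - q * H[r, ]; U[i, ] <- U[i, ] - q * U[r, ] }
      }
      r <- r + 1L
    }
  }
  list(H = H, U = U, rank = r - 1L)
}

.int_rank <- function(M) {
  if (nrow(M) == 0L) return(0L)
  .hnf(M)$rank
}

# Integer basis (rows) of the saturated lattice {x in Z^m : M %*% x = 0}.
.right_kernel <- function(M) {
  h <- .hnf(t(M))
  zero <- apply(h$H, 1, function(r) all(r == 0))
  h$U[zero, , drop = FALSE]
}

# Basis (rows) of span_Q(rows of R) intersected with Z^n (the saturation).
.saturation_basis <- function(R) {
  n <- ncol(R)
  K <- .right_kernel(R)
  if (nrow(K) == 0L) return(diag(n))
  .right_kernel(K)
}

# Integer coordinates X with X %*% B == R (rows of R lie in the lattice
# spanned by rows of B).
.lattice_coords <- function(R, B) {
  G <- B %*% t(B)
  X <- t(solve(G, B %*% t(R)))
  Xr <- round(X)
  if (max(abs(Xr %*% B - R)) > 1e-7) {
    stop("internal error: rays do not lie in the saturated lattice")
  }
  Xr
}

# Double description: extreme rays and lineality of {v : A v >= 0}.
# Rays are primitive integer vectors; the combinatorial adjacency test keeps
# the representation minimal at every step.
.dd_rays <- function(A) {
  n <- ncol(A)
  L <- diag(n)
  R <- matrix(0, 0, n)
  proc <- matrix(0, 0, n)
  for (k in seq_len(nrow(A))) {
    a <- A[k, ]
    sl <- if (nrow(L)) as.vector(L %*% a) else numeric(0)
    if (any(sl != 0)) {
      i0 <- which(sl != 0)[1]
      l0 <- L[i0, ]; s0 <- sl[i0]
      if (s0 < 0) { l0 <- -l0; s0 <- -s0 }
      Lk <- L[-i0, , drop = FALSE]; slk <- sl[-i0]
      if (nrow(Lk)) {
        Lk <- t(vapply(seq_len(nrow(Lk)), function(i)
          .primitivize(s0 * Lk[i, ] - slk[i] * l0), numeric(n)))
      }
      if (nrow(R)) {
        sr <- as.vector(R %*% a)
        R <- t(vapply(seq_len(nrow(R)), function(i)
          .primitivize(s0 * R[i, ] - sr[i] * l0), numeric(n)))
      }
      R <- rbind(R, .primitivize(l0))
      L <- Lk
      proc <- rbind(proc, a)
    } else {
      if (nrow(R) == 0L) { proc <- rbind(proc, a); next }
      t_ <- as.vector(R %*% a)
      pos <- which(t_ > 0); neg <- which(t_ < 0); zer <- which(t_ == 0)
      if (length(neg)) {
        tight <- lapply(seq_len(nrow(R)), function(i) {
          if (nrow(proc)) which(proc %*% R[i, ] == 0) else integer(0)
        })
        newR <- list()
        for (p in pos) for (q in neg) {
          Tpq <- intersect(tight[[p]], tight[[q]])
          adjacent <- TRUE
          if (nrow(R) > 2L) {
            for (r2 in seq_len(nrow(R))) {
              if (r2 == p || r2 == q) next
              if (all(Tpq %in% tight[[r2]])) { adjacent <- FALSE; break }
            }
          }
          if (adjacent) {
            newR[[length(newR) + 1L]] <-
              .primitivize(t_[p] * R[q, ] - t_[q] * R[p, ])
          }
        }
        R <- rbind(R[c(pos, zer), , drop = FALSE],
                   if (length(newR)) do.call(rbind, newR))
        R <- unique(R)
      }
      proc <- rbind(proc, a)
    }
  }
  list(rays = R, lineality = L)
}

# Pulling triangulation of the cone spanned by the rows of X (integer).
# Returns a list of simplex matrices (rows = rays).  `memo` caches faces.
.triangulate <- function(X, memo = new.env(parent = emptyenv())) {
  key <- paste(t(X), collapse = ",")
  got <- memo[[key]]
  if (!is.null(got)) return(got)
  r <- .int_rank(X)
  if (nrow(X) == r) { memo[[key]] <- list(X); return(list(X)) }
  d <- ncol(X)
  if (r < d) {
    B <- .saturation_basis(X)
    Xc <- .lattice_coords(X, B)
  } else { B <- NULL; Xc <- X }
  fac <- .dd_rays(Xc)$rays   # facet normals of the full-dim cone
  v1 <- Xc[1, ]
  res <- list()
  for (i in seq_len(nrow(fac))) {
    a <- fac[i, ]
    if (sum(a * v1) <= 0) next         # only facets the pulled ray sees
    face_idx <- which(Xc %*% a == 0)
    if (length(face_idx) == 0L) next
    sub <- .triangulate(Xc[face_idx, , drop = FALSE], memo)
    for (S in sub) res[[length(res) + 1L]] <- rbind(v1, S)
  }
  if (!is.null(B)) res <- lapply(res, function(S) S %*% B)
  memo[[key]] <- res
  res
}

# Nonzero lattice points in the half-open fundamental parallelepiped
# {sum lambda_i s_i : 0 <= lambda_i < 1} of a full-dim simplex (rows of S).
.parallelepiped_points <- function(S) {
  d <- ncol(S)
  dt <- round(det(S)); m <- abs(dt)
  if (m <= 1) return(matrix(0, 0, d))
  H <- .hnf(S)$H
  adj <- round(dt * solve(S))          # integer adjugate
  if (max(abs(adj %*% S - diag(d) * dt)) > 1e-6) {
    stop("internal error: adjugate reconstruction failed")
  }
  reps <- as.matrix(expand.grid(lapply(diag(H), function(h) 0:(h - 1))))
  out <- matrix(0, nrow(reps), d)
  keep <- logical(nrow(reps))
  for (i in seq_len(nrow(reps))) {
    x <- reps[i, ]
    fl <- floor(as.vector(x %*% adj) / dt)
    p <- x - as.vector(fl %*% S)
    if (any(p != 0)) { out[i, ] <- p; keep[i] <- TRUE }
  }
  unique(out[keep, , drop = FALSE])
}

.sort_rows <- function(M) {
  if (nrow(M) < 2L) return(M)
  M[do.call(order, as.data.frame(M)), , drop = FALSE]
}
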