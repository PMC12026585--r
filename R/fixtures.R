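# Deterministic fixture generation: cones with brute-forced bases, cascades
# with known structural g, and a hand-written Normaliz output example.

# Exhaustive Hilbert basis of {v : C v >= 0} over the box [-box, box]^d.
# Independent of the production engine (no double description, no
# triangulation); used for fixtures and as a cross-check at small dimension.
brute_hilbert_box <- function(C, box = 6L) {
  d <- ncol(C)
  grid <- as.matrix(expand.grid(rep(list(seq(-box, box)), d)))
  dimnames(grid) <- NULL
  mem <- grid[apply(grid %*% t(C) >= 0, 1, all), , drop = FALSE]
  mem <- mem[rowSums(abs(mem)) > 0, , drop = FALSE]
  w <- as.vector(mem %*% colSums(C))
  ord <- order(w)
  mem <- mem[ord, , drop = FALSE]; w <- w[ord]
  keyset <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(mem))) {
    assign(paste(mem[i, ], collapse = ","), TRUE, envir = keyset)
  }
  irred <- rep(TRUE, nrow(mem))
  for (i in seq_len(nrow(mem))) {
    for (j in seq_len(nrow(mem))) {
      if (w[j] >= w[i]) break
      dif <- mem[i, ] - mem[j, ]
      if (all(dif == 0)) next
      if (!is.null(keyset[[paste(dif, collapse = ",")]])) {
        irred[i] <- FALSE; break
      }
    }
  }
  .sort_rows(mem[irred, , drop = FALSE])
}

# random pointed cone: generator entries in [-2, 2], full column rank
random_pointed_cone <- function(d, extra = 1L) {
  repeat {
    G <- matrix(sample(-2:2, d * (d + extra), replace = TRUE), ncol = d)
    if (.int_rank(G) == d) return(rational_cone(G))
  }
}

#' Generate deterministic test fixtures
#'
#' Writes (a) random pointed cones of dimension <= 4 in Normaliz plain
#' format together with their brute-forced Hilbert bases (JSON), (b)
#' cascade models for n = 3..9 with known structural g and symmetric rates
#' (JSON, steady state verified to 1e-10), and (c) a hand-written Normaliz
#' output file.  Regeneration with the same seed is byte-identical.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @return `dir`, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  cone_dir <- file.path(dir, "cones")
  dir.create(cone_dir, showWarnings = FALSE)
  # the positive orthant is always fixture 1
  cones <- c(list(rational_cone(diag(2))),
             lapply(1:5, function(i) random_pointed_cone(sample(2:4, 1))))
  for (i in seq_along(cones)) {
    base <- file.path(cone_dir, sprintf("cone_%02d", i))
    write_normaliz(cones[[i]], paste0(base, ".in"))
    hb <- brute_hilbert_box(cones[[i]]$generators, box = 6L)
    jsonlite::write_json(list(elements = hb), paste0(base, ".basis.json"),
                         digits = NA, matrix = "rowmajor")
  }

  casc_dir <- file.path(dir, "cascades")
  dir.create(casc_dir, showWarnings = FALSE)
  for (n in 3:9) {
    g_true <- sample(1:4, 1)
    m <- build_end_product_cascade(n, g = g_true)
    ss <- solve_steady_state(m)
    if (ss$residual_norm > 1e-10) {
      stop("fixture cascade n = ", n, " failed the steady-state residual ",
           "check (", format(ss$residual_norm), ")")
    }
    write_cascade_json(m, file.path(casc_dir, sprintf("cascade_n%d.json", n)))
  }

  # hand-written Normaliz-style output fragment (positive orthant in Z^2)
  writeLines(c("2 Hilbert basis elements:",
               "1 0",
               "0 1",
               "",
               "2 extreme rays:",
               "1 0",
               "0 1"),
             file.path(dir, "orthant.out"))
  invisible(dir)
}
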