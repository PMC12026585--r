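# S-system (power-law) models of end-product-inhibition cascades.
#
# The rate law for species i is
#   dXi/dt = sum_k alpha_ik prod_j Xj^g_ijk - sum_k beta_ik prod_j Xj^h_ijk
# The cascade builder produces the single-term special case: a linear chain
# X1 -> X2 -> ... -> Xn in which the end product Xn inhibits the first,
# allosteric step.  The unknown kinetic order g counts regulator binding
# sites; it is stored as a non-negative structural value and applied with
# negative sign in the rate law (Xn^-g), the usual end-product-inhibition
# convention.

new_power_law_term <- function(rate_constant, const, gcoef = numeric(length(const))) {
  if (!is.finite(rate_constant) || rate_constant <= 0) {
    stop("rate constants must be positive")
  }
  list(rate_constant = rate_constant,
       exponents = list(const = as.numeric(const), gcoef = as.numeric(gcoef)))
}

new_ssys_equation <- function(species_index, production, degradation) {
  if (length(production) == 0L || length(degradation) == 0L) {
    stop("production and degradation must each contain at least one term")
  }
  structure(list(species_index = as.integer(species_index),
                 production = production, degradation = degradation),
            class = "ssys_equation")
}

# resolve the structural (non-negative) value of g for a model
resolve_g <- function(model, g_value = NULL) {
  if (is.null(g_value)) {
    if (is.na(model$g)) {
      stop("model has a symbolic kinetic order; supply g_value")
    }
    return(model$g)
  }
  if (!is.finite(g_value)) stop("g_value must be finite")
  abs(g_value)   # negative input read as the raw (inhibitory) exponent
}

#' Build an end-product-inhibition cascade
#'
#' Constructs the S-system for a linear chain of `n` reactions with a single
#' inhibitory feedback edge from the end product to the first step:
#' \deqn{dX_1/dt = \alpha_1 X_n^{-g} - \beta_1 X_1^{h_1}, \quad
#'       dX_i/dt = \alpha_i X_{i-1} - \beta_i X_i^{h_i}\ (i \ge 2).}
#' The chain has `n - 2` intermediate species.  `g` is the structural number
#' of binding sites (non-negative; a negative value is read as the raw
#' exponent, i.e. its magnitude); `NA` leaves it symbolic.
#'
#' @param n pathway length (>= 3).
#' @param g numeric kinetic order, or `NA` for the symbolic unknown.
#' @param alpha,beta positive production/degradation rate constants, length n.
#' @param h positive degradation kinetic orders, length n.
#' @return an object of class `cascade_model`.
#' @examples
#' m <- build_end_product_cascade(7, g = 2)
#' m$intermediates            # 5
#' @export
build_end_product_cascade <- function(n, g = NA,
                                      alpha = rep(1, n), beta = rep(1, n),
                                      h = rep(1, n)) {
  if (!is.numeric(n) || length(n) != 1 || n != round(n) || n < 3) {
    stop("invalid pathway length: n must be an integer >= 3")
  }
  n <- as.integer(n)
  if (length(alpha) != n || length(beta) != n || length(h) != n) {
    stop("alpha, beta and h must each have length n")
  }
  if (any(alpha <= 0) || any(beta <= 0) || any(h <= 0)) {
    stop("rate constants and kinetic orders must be positive")
  }
  symbolic <- is.na(g) || identical(g, "symbolic")
  gs <- if (symbolic) NA_real_ else abs(as.numeric(g))
  eqs <- vector("list", n)
  p1c <- numeric(n); p1g <- numeric(n)
  if (symbolic) p1g[n] <- -1 else p1c[n] <- -gs
  d1c <- numeric(n); d1c[1] <- h[1]
  eqs[[1]] <- new_ssys_equation(1L,
    list(new_power_law_term(alpha[1], p1c, p1g)),
    list(new_power_law_term(beta[1], d1c)))
  for (i in 2:n) {
    pc <- numeric(n); pc[i - 1] <- 1
    dc <- numeric(n); dc[i] <- h[i]
    eqs[[i]] <- new_ssys_equation(i,
      list(new_power_law_term(alpha[i], pc)),
      list(new_power_law_term(beta[i], dc)))
  }
  structure(list(n = n, alpha = alpha, beta = beta, h = h, g = gs,
                 symbolic = symbolic, equations = eqs,
                 unknown_position = c(equation = 1L, species = n),
                 feedback_edge = c(source = n, target = 1L),
                 intermediates = n - 2L),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat("end-product-inhibition cascade, n =", x$n,
      "(", x$intermediates, "intermediates )\n")
  cat("  g =", if (x$symbolic) "symbolic" else x$g,
      " feedback: X", x$feedback_edge["source"], " -| X",
      x$feedback_edge["target"], "\n", sep = "")
  invisible(x)
}

term_value <- function(term, conc, g) {
  e <- term$exponents$const + term$exponents$gcoef * g
  term$rate_constant * prod(conc^e)
}

#' Evaluate the rate law
#'
#' Returns dX/dt for a cascade model at concentrations `X`, with the
#' symbolic unknown (if any) replaced by `g_value`.
#'
#' @param model a [build_end_product_cascade()] model.
#' @param X positive concentration vector of length `model$n`.
#' @param g_value structural kinetic order substituted for the symbolic g
#'   (defaults to the model's own value when numeric).
#' @return numeric vector dX/dt.
#' @export
evaluate_rates <- function(model, X, g_value = NULL) {
  stopifnot(inherits(model, "cascade_model"))
  if (length(X) != model$n) stop("X must have length n = ", model$n)
  if (any(!is.finite(X)) || any(X <= 0)) {
    stop("concentrations must be positive (power laws with negative ",
         "exponents are undefined at X <= 0)")
  }
  g <- resolve_g(model, g_value)
  vapply(model$equations, function(eq) {
    sum(vapply(eq$production, term_value, numeric(1), conc = X, g = g)) -
      sum(vapply(eq$degradation, term_value, numeric(1), conc = X, g = g))
  }, numeric(1))
}

#' Jacobian of the rate law
#'
#' Analytic Jacobian of [evaluate_rates()] with respect to X.
#'
#' @inheritParams evaluate_rates
#' @return an n-by-n numeric matrix.
#' @export
cascade_jacobian <- function(model, X, g_value = NULL) {
  stopifnot(inherits(model, "cascade_model"))
  g <- resolve_g(model, g_value)
  n <- model$n
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    eq <- model$equations[[i]]
    for (term in eq$production) {
      e <- term$exponents$const + term$exponents$gcoef * g
      v <- term$rate_constant * prod(X^e)
      J[i, ] <- J[i, ] + v * e / X
    }
    for (term in eq$degradation) {
      e <- term$exponents$const + term$exponents$gcoef * g
      v <- term$rate_constant * prod(X^e)
      J[i, ] <- J[i, ] - v * e / X
    }
  }
  J
}

#' Steady state of a cascade
#'
#' The S-system steady state is linear in log-concentrations: each equation
#' \eqn{\alpha X^p = \beta X^q} becomes \eqn{(q - p) \cdot y =
#' \log(\alpha/\beta)} with \eqn{y = \log X}.  The default method solves this
#' linear system exactly and polishes with damped Newton if needed; `method =
#' "newton"` runs damped Newton in log space from y = 0 as an independent
#' route.
#'
#' @inheritParams evaluate_rates
#' @param method `"loglinear"` (default) or `"newton"`.
#' @param tol residual max-norm tolerance for convergence.
#' @param max_iter Newton iteration cap.
#' @return object of class `steady_state`: `concentrations`,
#'   `residual_norm`, `method`.
#' @export
solve_steady_state <- function(model, g_value = NULL,
                               method = c("loglinear", "newton"),
                               tol = 1e-10, max_iter = 200) {
  stopifnot(inherits(model, "cascade_model"))
  method <- match.arg(method)
  g <- resolve_g(model, g_value)
  n <- model$n
  residual <- function(y) evaluate_rates(model, exp(y), g)
  newton <- function(y) {
    for (it in seq_len(max_iter)) {
      f <- residual(y)
      if (max(abs(f)) < tol) return(y)
      X <- exp(y)
      Jy <- cascade_jacobian(model, X, g) * rep(X, each = n)  # d f / d y
      step <- tryCatch(solve(Jy, -f), error = function(e) NULL)
      if (is.null(step)) stop("steady-state Newton: singular Jacobian")
      lam <- 1
      repeat {
        y2 <- y + lam * step
        f2 <- residual(y2)
        if (max(abs(f2)) < max(abs(f)) || lam < 1e-8) break
        lam <- lam / 2
      }
      if (lam < 1e-8) {
        stop("steady-state solver did not converge: damping underflow at ",
             "residual ", format(max(abs(f))))
      }
      y <- y2
    }
    f <- residual(y)
    if (max(abs(f)) >= tol) {
      stop("steady-state solver did not converge within ", max_iter,
           " iterations (residual ", format(max(abs(f))), ")")
    }
    y
  }
  y <- NULL
  if (method == "loglinear") {
    single <- all(vapply(model$equations, function(eq) {
      length(eq$production) == 1L && length(eq$degradation) == 1L
    }, logical(1)))
    if (single) {
      A <- matrix(0, n, n); b <- numeric(n)
      for (i in seq_len(n)) {
        eq <- model$equations[[i]]
        p <- eq$production[[1]]$exponents
        q <- eq$degradation[[1]]$exponents
        A[i, ] <- (q$const + q$gcoef * g) - (p$const + p$gcoef * g)
        b[i] <- log(eq$production[[1]]$rate_constant /
                    eq$degradation[[1]]$rate_constant)
      }
      y <- tryCatch(solve(A, b), error = function(e) NULL)
      if (!is.null(y) && max(abs(residual(y))) >= tol) y <- newton(y)
    }
    if (is.null(y)) y <- newton(numeric(n))
  } else {
    y <- newton(numeric(n))
  }
  X <- exp(y)
  structure(list(concentrations = X,
                 residual_norm = max(abs(evaluate_rates(model, X, g))),
                 method = method),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("steady state (", x$method, "), residual ",
      format(x$residual_norm), "\n", sep = "")
  print(x$concentrations)
  invisible(x)
}

#' Linearize at the steady state and classify stability
#'
#' Computes the eigenvalues of the Jacobian at the steady state and
#' classifies the local dynamics: `stable` when all real parts are below
#' `-tol`; `marginal` when the largest real part lies within `tol` of zero;
#' otherwise `unstable_oscillatory` if a crossing eigenvalue has nonzero
#' imaginary part, else `unstable_divergent`.
#'
#' @inheritParams evaluate_rates
#' @param tol eigenvalue real-part tolerance (default 1e-9).
#' @return object of class `stability_report`: `eigenvalues`,
#'   `classification`, `steady_state`.
#' @export
linearize_and_classify <- function(model, g_value = NULL, tol = 1e-9) {
  ss <- solve_steady_state(model, g_value)
  g <- resolve_g(model, g_value)
  J <- cascade_jacobian(model, ss$concentrations, g)
  ev <- eigen(J, only.values = TRUE)$values
  maxre <- max(Re(ev))
  classification <- if (maxre < -tol) {
    "stable"
  } else if (abs(maxre) <= tol) {
    "marginal"
  } else {
    crossing <- ev[Re(ev) > tol]
    if (any(abs(Im(crossing)) > tol)) "unstable_oscillatory"
    else "unstable_divergent"
  }
  structure(list(eigenvalues = ev, classification = classification,
                 steady_state = ss),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("stability:", x$classification, "\n")
  cat("eigenvalues:\n"); print(x$eigenvalues)
  invisible(x)
}

#' Numerical stability threshold in g
#'
#' Bisects the structural kinetic order g for the smallest value at which the
#' cascade stops being classified `stable` (the feedback strength at which a
#' conjugate eigenvalue pair crosses the imaginary axis).
#'
#' @param model a cascade model (g may be symbolic).
#' @param g_max upper search bound.
#' @param tol bisection tolerance on g.
#' @return numeric threshold, or `Inf` if stable throughout `[0, g_max]`.
#' @export
stability_threshold <- function(model, g_max = 16, tol = 1e-4) {
  stable_at <- function(g) {
    linearize_and_classify(model, g)$classification == "stable"
  }
  if (stable_at(g_max)) return(Inf)
  lo <- 0; hi <- g_max
  if (!stable_at(lo)) return(0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stable_at(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Dormand-Prince 5(4) coefficients
.dp_a <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(44 / 45, -56 / 15, 32 / 9),
  c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
  c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
  c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
.dp_b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
.dp_b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
            187 / 2100, 1 / 40)
.dp_c <- c(0, 1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)

#' Simulate a cascade time course
#'
#' Integrates the rate law with an adaptive Dormand-Prince RK45 in
#' log-concentration space, which keeps trajectories structurally positive
#' (the vector field is smooth in log space for power laws).  Output is
#' produced exactly at the requested time grid.
#'
#' @inheritParams evaluate_rates
#' @param X0 positive initial concentrations.
#' @param t_grid strictly increasing time points (first entry = start time).
#' @param rtol,atol local error tolerances in log space.
#' @return numeric matrix with columns `t, X1, ..., Xn`.
#' @export
simulate_cascade <- function(model, g_value = NULL, X0, t_grid,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "cascade_model"))
  if (any(X0 <= 0)) stop("X0 must be positive")
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing with at least 2 points")
  }
  g <- resolve_g(model, g_value)
  n <- model$n
  f <- function(y) evaluate_rates(model, exp(y), g) / exp(y)
  y <- log(X0)
  out <- matrix(NA_real_, length(t_grid), n + 1L)
  colnames(out) <- c("t", paste0("X", seq_len(n)))
  out[1, ] <- c(t_grid[1], X0)
  t <- t_grid[1]
  h <- min(0.1, diff(range(t_grid)) / 100)
  k1 <- f(y)
  for (gi in 2:length(t_grid)) {
    tend <- t_grid[gi]
    while (t < tend) {
      h <- min(h, tend - t)
      K <- matrix(0, 7, n)
      K[1, ] <- k1
      for (s in 2:6) {
        K[s, ] <- f(y + h * as.vector(.dp_a[[s - 1]] %*%
                                        K[seq_len(s - 1), , drop = FALSE]))
      }
      y5 <- y + h * as.vector(.dp_b5[1:6] %*% K[1:6, , drop = FALSE])
      K[7, ] <- f(y5)
      y4 <- y + h * as.vector(.dp_b4 %*% K)
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (!is.finite(err)) {
        cond <- simpleError(paste0("integrator failure at t = ", format(t)))
        cond$last_state <- c(t = t, exp(y))
        stop(cond)
      }
      if (err <= 1) {
        t <- t + h
        y <- y5
        k1 <- K[7, ]          # FSAL
      }
      fac <- if (err > 0) 0.9 * err^(-0.2) else 5
      h <- h * min(5, max(0.2, fac))
      if (h < 1e-12 * max(1, abs(tend))) {
        cond <- simpleError(paste0("integrator step underflow at t = ",
                                   format(t)))
        cond$last_state <- c(t = t, exp(y))
        stop(cond)
      }
    }
    out[gi, ] <- c(tend, exp(y))
  }
  out
}

#' Read and write cascade models as JSON
#'
#' The document stores `n`, `alpha`, `beta`, `h`, `g` (number or
#' `"symbolic"`) and `unknown_position`.
#'
#' @param model a cascade model.
#' @param path file path.
#' @return `read_cascade_json` returns a `cascade_model`;
#'   `write_cascade_json` returns `path` invisibly.
#' @export
write_cascade_json <- function(model, path) {
  stopifnot(inherits(model, "cascade_model"))
  doc <- list(n = model$n, alpha = model$alpha, beta = model$beta,
              h = model$h,
              g = if (model$symbolic) "symbolic" else model$g,
              unknown_position = as.list(model$unknown_position))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cascade_json
#' @export
read_cascade_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- if (identical(doc$g, "symbolic")) NA else as.numeric(doc$g)
  build_end_product_cascade(doc$n, g = g, alpha = doc$alpha,
                            beta = doc$beta, h = doc$h)
}

#' Write a trajectory matrix as CSV
#'
#' @param traj matrix from [simulate_cascade()].
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
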