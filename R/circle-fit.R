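# Circle fitting in the plane. Algebraic fits describe a circle as
# A(x^2+y^2) + Bx + Cy + D = 0 and minimize the algebraic residual
# sum(A z_i + B x_i + C y_i + D)^2 with z_i = x_i^2 + y_i^2, subject to a
# normalization constraint: B^2 + C^2 - 4AD = 1 (Pratt) or
# 4A^2 zbar + 4AB xbar + 4AC ybar + B^2 + C^2 = 1 (Taubin). The geometric
# Gauss-Newton fit minimizes the orthogonal distances directly. All results
# are reported in the Pratt normalization so radius = 1/(2|A|).

.degenerate_check <- function(x, y) {
  n <- length(x)
  if (n < 3) stop("degenerate circle fit: need at least 3 points")
  M <- cbind(x - mean(x), y - mean(y))
  sv <- svd(M, nu = 0, nv = 0)$d
  if (sv[2] <= 1e-12 * max(sv[1], 1))
    stop("degenerate circle fit: points are collinear")
  invisible(NULL)
}

.circle_rms <- function(x, y, center, r) {
  sqrt(mean((sqrt((x - center[1])^2 + (y - center[2])^2) - r)^2))
}

# Normalized CircleModel from a center and radius.
.circle_model <- function(center, r, x, y, method, converged = TRUE) {
  if (!is.finite(r) || r <= 0) stop("degenerate circle fit: non-positive radius")
  A <- 1 / (2 * r)
  # build by slot assignment: an argument named `C` in new() would partially
  # match its `Class` formal
  obj <- new("CircleModel")
  obj@A <- A
  obj@B <- -2 * A * center[1]
  obj@C <- -2 * A * center[2]
  obj@D <- (center[1]^2 + center[2]^2 - r^2) * A
  obj@center <- as.numeric(center)
  obj@radius <- r
  obj@rms_residual <- .circle_rms(x, y, center, r)
  obj@n_points <- length(x)
  obj@method <- method
  obj@converged <- converged
  validObject(obj)
  obj
}

.as_xy <- function(points) {
  if (is(points, "PointCloud")) points <- coords(points)[, 1:2]
  points <- as.matrix(points)
  if (ncol(points) < 2) stop("points must have x and y columns")
  list(x = as.numeric(points[, 1]), y = as.numeric(points[, 2]))
}

#' Pratt algebraic circle fit
#'
#' Minimizes the algebraic residual subject to the Pratt constraint
#' B^2 + C^2 - 4AD = 1, solved as the generalized eigenproblem of the moment
#' matrix against the (constant) Pratt constraint matrix. Exact on noiseless
#' circular data; data are centered at their centroid before solving for
#' numerical stability.
#'
#' @param points n x 2 matrix (or [PointCloud-class], whose x/y are used) of
#'   planar points; n >= 3, not collinear.
#' @return A [CircleModel-class].
#' @examples
#' th <- seq(0, 2 * pi, length.out = 9)[-9]
#' fitCirclePratt(cbind(1 + 0.5 * cos(th), 2 + 0.5 * sin(th)))
#' @export
fitCirclePratt <- function(points) {
  p <- .as_xy(points)
  .degenerate_check(p$x, p$y)
  mx <- mean(p$x); my <- mean(p$y)
  x <- p$x - mx; y <- p$y - my
  z <- x^2 + y^2
  Z <- cbind(z, x, y, 1)
  M <- crossprod(Z) / length(x)
  # Pratt constraint matrix P: v' P v = B^2 + C^2 - 4AD; P^{-1} is known.
  Pinv <- matrix(c(0, 0, 0, -0.5,
                   0, 1, 0, 0,
                   0, 0, 1, 0,
                   -0.5, 0, 0, 0), 4, 4, byrow = TRUE)
  e <- eigen(Pinv %*% M)
  lam <- e$values
  best <- NULL; best_lam <- Inf
  for (i in seq_along(lam)) {
    if (abs(Im(lam[i])) > 1e-8 * (1 + abs(Re(lam[i])))) next
    v <- Re(e$vectors[, i])
    con <- v[2]^2 + v[3]^2 - 4 * v[1] * v[4]
    if (con <= 1e-14) next                       # not normalizable
    eta <- Re(lam[i])
    if (eta < -1e-9) next                        # negative objective branch
    if (eta < best_lam) { best_lam <- eta; best <- v / sqrt(con) }
  }
  if (is.null(best)) stop("degenerate circle fit: no admissible Pratt solution")
  if (abs(best[1]) < 1e-14) stop("degenerate circle fit: solution is a line")
  center <- c(-best[2] / (2 * best[1]), -best[3] / (2 * best[1]))
  r <- 1 / (2 * abs(best[1]))
  .circle_model(center + c(mx, my), r, p$x, p$y, "pratt")
}

#' Taubin algebraic circle fit
#'
#' Minimizes the same algebraic residual as the Pratt fit under the Taubin
#' constraint 4A^2 zbar + 4AB xbar + 4AC ybar + B^2 + C^2 = 1. Because the
#' offset D does not enter the constraint it is eliminated analytically, and
#' the remaining 3 x 3 problem is a symmetric-definite generalized
#' eigenproblem solved through a Cholesky reduction. The result is
#' renormalized to the Pratt convention for comparability.
#'
#' @inheritParams fitCirclePratt
#' @return A [CircleModel-class].
#' @export
fitCircleTaubin <- function(points) {
  p <- .as_xy(points)
  .degenerate_check(p$x, p$y)
  mx <- mean(p$x); my <- mean(p$y)
  x <- p$x - mx; y <- p$y - my
  z <- x^2 + y^2
  zb <- mean(z)
  # optimal D for fixed (A,B,C): D = -(A zbar + B xbar + C ybar) = -A zbar here
  W <- cbind(z - zb, x, y)
  M3 <- crossprod(W) / length(x)
  N <- diag(c(4 * zb, 1, 1))
  L <- chol(N)                      # N = L'L
  Li <- backsolve(L, diag(3))       # L^{-1}
  S <- t(Li) %*% M3 %*% Li
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  w <- Li %*% es$vectors[, 3]       # smallest eigenvalue
  A <- w[1]; B <- w[2]; C <- w[3]
  if (abs(A) < 1e-14) stop("degenerate circle fit: solution is a line")
  D <- -A * zb
  center <- c(-B / (2 * A), -C / (2 * A))
  r2 <- (B^2 + C^2 - 4 * A * D) / (4 * A^2)
  mod <- .circle_model(center + c(mx, my), sqrt(r2), p$x, p$y, "taubin")
  mod
}

#' Gauss-Newton geometric circle fit
#'
#' Iteratively minimizes the sum of squared orthogonal distances
#' sum(sqrt((x - xc)^2 + (y - yc)^2) - r)^2 from an initial circle (the
#' Pratt fit by default), with step halving so the objective is monotone
#' non-increasing. Stops when the parameter update falls below `tol` or at
#' `max_iter` iterations (the result is then flagged unconverged).
#'
#' @inheritParams fitCirclePratt
#' @param init optional initial [CircleModel-class]; default is the Pratt fit.
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on the parameter update, meters.
#' @return A [CircleModel-class] with `converged` set accordingly.
#' @export
fitCircleGaussNewton <- function(points, init = NULL, max_iter = 50,
                                 tol = 1e-8) {
  p <- .as_xy(points)
  .degenerate_check(p$x, p$y)
  if (tol <= 0) stop("tol must be positive")
  if (is.null(init)) init <- fitCirclePratt(points)
  par <- c(init@center, init@radius)
  obj <- function(q) {
    sum((sqrt((p$x - q[1])^2 + (p$y - q[2])^2) - q[3])^2)
  }
  f <- obj(par)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    d <- sqrt((p$x - par[1])^2 + (p$y - par[2])^2)
    d[d < 1e-12] <- 1e-12
    res <- d - par[3]
    J <- cbind(-(p$x - par[1]) / d, -(p$y - par[2]) / d, -1)
    step <- tryCatch(solve(crossprod(J), crossprod(J, res)),
                     error = function(e) NULL)
    if (is.null(step)) break
    step <- as.numeric(step)
    # damped update: halve until the objective does not increase
    lambda <- 1
    repeat {
      cand <- par - lambda * step
      fc <- obj(cand)
      if (fc <= f + 1e-15 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (fc > f) { converged <- TRUE; break }  # objective at its numeric floor
    moved <- max(abs(lambda * step))
    par <- cand; f <- fc
    if (moved < tol) { converged <- TRUE; break }
  }
  if (max_iter == 0) par <- c(init@center, init@radius)
  .circle_model(par[1:2], par[3], p$x, p$y, "gauss-newton",
                converged = converged)
}

#' Center and radius of an algebraic circle
#'
#' For A(x^2+y^2) + Bx + Cy + D = 0 with A != 0 the center is
#' (-B/2A, -C/2A) and the radius sqrt(B^2 + C^2 - 4AD) / (2|A|).
#'
#' @param A,B,C,D algebraic circle coefficients.
#' @return list with `center` (length-2) and `radius`.
#' @examples
#' circleParams(0.5, -1, -2, 2)  # center (1, 2)
#' @export
circleParams <- function(A, B, C, D) {
  if (A == 0) stop("A = 0 describes a line, not a circle")
  disc <- B^2 + C^2 - 4 * A * D
  if (disc <= 0) stop("coefficients do not describe a real circle")
  list(center = c(-B / (2 * A), -C / (2 * A)),
       radius = sqrt(disc) / (2 * abs(A)))
}
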