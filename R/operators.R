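# Sparse finite-difference operator toolkit for the structured solvers.
#
# Operators are built as sparse matrices over a 1D node set plus an affine
# "external" coefficient vector for boundary values that are prescribed at
# run time (e.g., the pulsatile inlet). 2D operators are Kronecker products
# of the 1D pieces (column-major vectorization, first index fastest).

# Fornberg-style weights: derivative of order m at x0 from nodes xs
.fd_weights <- function(xs, x0, m) {
  n <- length(xs)
  # solve the Vandermonde moment system sum w (x-x0)^k = m! [k == m]
  V <- t(vapply(0:(n - 1), function(k) (xs - x0)^k, numeric(n)))
  rhs <- rep(0, n)
  rhs[m + 1] <- factorial(m)
  solve(V, rhs)
}

# 1D derivative operator on nodes x with boundary conditions.
#   der: derivative order (1 or 2)
#   bias: "c" centered, "m" backward (minus), "p" forward (plus)
#   bc_lo / bc_hi: list(type, pos) with type one of
#     "dirichlet" - external value at position pos (goes into the ext vector)
#     "mirror"    - even symmetry about pos (ghost folded in)
#     "copy"      - zero-gradient ghost one spacing beyond (folded in)
#     "none"      - shrink the stencil inward
# Returns list(M = n x n dgCMatrix, ext_lo, ext_hi = n-vectors of external
# value coefficients).
fd_op_1d <- function(x, der, bias, bc_lo, bc_hi) {
  n <- length(x)
  tri_i <- integer(0); tri_j <- integer(0); tri_x <- numeric(0)
  ext_lo <- numeric(n); ext_hi <- numeric(n)
  width <- if (der == 2 || bias != "c") 3 else 3
  for (i in seq_len(n)) {
    # candidate stencil node offsets relative to i
    offs <- switch(bias,
                   c = c(-1, 0, 1),
                   m = c(-2, -1, 0),
                   p = c(0, 1, 2))
    nodes <- list()   # list of (pos, kind, index) kind: 0 interior, -1 lo ext, 1 hi ext
    for (o in offs) {
      k <- i + o
      if (k >= 1 && k <= n) {
        nodes[[length(nodes) + 1]] <- list(pos = x[k], kind = 0L, idx = k)
      } else if (k < 1) {
        depth <- 1 - k   # 1 for first ghost, 2 for second
        t_lo <- bc_lo$type
        if (t_lo == "dirichlet" && depth == 1) {
          nodes[[length(nodes) + 1]] <- list(pos = bc_lo$pos, kind = -1L, idx = NA)
        } else if (t_lo == "mirror") {
          mpos <- 2 * bc_lo$pos - x[depth]
          nodes[[length(nodes) + 1]] <- list(pos = mpos, kind = 0L, idx = depth)
        } else if (t_lo == "copy" && depth == 1) {
          nodes[[length(nodes) + 1]] <- list(pos = x[1] - (x[2] - x[1]), kind = 0L, idx = 1L)
        } # else drop (shrink)
      } else {
        depth <- k - n
        t_hi <- bc_hi$type
        if (t_hi == "dirichlet" && depth == 1) {
          nodes[[length(nodes) + 1]] <- list(pos = bc_hi$pos, kind = 1L, idx = NA)
        } else if (t_hi == "mirror") {
          mpos <- 2 * bc_hi$pos - x[n + 1 - depth]
          nodes[[length(nodes) + 1]] <- list(pos = mpos, kind = 0L, idx = n + 1L - depth)
        } else if (t_hi == "copy" && depth == 1) {
          nodes[[length(nodes) + 1]] <- list(pos = x[n] + (x[n] - x[n - 1]), kind = 0L, idx = n)
        }
      }
    }
    # need at least der+1 distinct positions; shrink gracefully by adding
    # interior nodes if too few
    while (length(nodes) < der + 1) {
      have <- vapply(nodes, function(nd) nd$idx %||% -99L, numeric(1))
      cand <- setdiff(seq_len(n), have[!is.na(have)])
      cand <- cand[order(abs(cand - i))][1]
      nodes[[length(nodes) + 1]] <- list(pos = x[cand], kind = 0L, idx = cand)
    }
    pos <- vapply(nodes, `[[`, numeric(1), "pos")
    w <- .fd_weights(pos, x[i], der)
    for (q in seq_along(nodes)) {
      nd <- nodes[[q]]
      if (nd$kind == 0L) {
        tri_i <- c(tri_i, i); tri_j <- c(tri_j, nd$idx); tri_x <- c(tri_x, w[q])
      } else if (nd$kind == -1L) {
        ext_lo[i] <- ext_lo[i] + w[q]
      } else {
        ext_hi[i] <- ext_hi[i] + w[q]
      }
    }
  }
  M <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x, dims = c(n, n))
  list(M = M, ext_lo = ext_lo, ext_hi = ext_hi)
}

# Kronecker lift of a 1D operator acting along dimension 1 (fast index, size
# n1) or dimension 2 (slow index, size n2) of an n1 x n2 field.
op_dim1 <- function(op, n2) Matrix::kronecker(Matrix::Diagonal(n2), op)
op_dim2 <- function(op, n1) Matrix::kronecker(op, Matrix::Diagonal(n1))

# external contribution lift: 1D ext vector along dim 1 with external values
# varying along dim 2 -> (n1 n2) x n2 matrix (maps the dim-2 vector of
# external values to field contributions)
ext_dim1 <- function(ext, n2) Matrix::kronecker(Matrix::Diagonal(n2), Matrix::Matrix(ext, ncol = 1))
# ext vector along dim 2, external values varying along dim 1
ext_dim2 <- function(ext, n1) Matrix::kronecker(Matrix::Matrix(ext, ncol = 1), Matrix::Diagonal(n1))

# diagonal scaling of an operator bundle (matrix + ext maps)
scale_rows <- function(coef, M) Matrix::Diagonal(x = as.numeric(coef)) %*% M
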