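# Thin wrappers around the compiled CSC kernels: one-time conversion of
# Matrix objects into raw slot lists, so the stepping loop pays no S4
# dispatch cost.

fop <- function(M) {
  M <- methods::as(methods::as(M, "CsparseMatrix"), "generalMatrix")
  list(p = M@p, i = M@i, x = M@x, nrow = nrow(M))
}

fmv <- function(F, v) spmv_csc(F$p, F$i, F$x, F$nrow, v)

# sparse LU factorization unpacked for the compiled triangular solves
flu <- function(M) {
  f <- Matrix::lu(M)
  e <- Matrix::expand(f)
  list(L = fop(e$L), U = fop(e$U), pperm = e$P@perm, qperm = e$Q@perm)
}

fsolve <- function(F, b) {
  # A = P' L U Q'  =>  x = Q U^{-1} L^{-1} P b
  z <- trsolve_lower_csc(F$L$p, F$L$i, F$L$x, b[F$pperm])
  w <- trsolve_upper_csc(F$U$p, F$U$i, F$U$x, z)
  x <- numeric(length(w))
  x[F$qperm] <- w
  x
}
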