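# Oblique gradient-projection rotation with the quartimin (oblimin,
# gamma = 0) criterion. Standard GPA iteration: minimize Q(Lambda) over
# oblique rotation matrices T with unit-length columns, where
# Lambda = A (T')^{-1}.

vgQ_quartimin <- function(L) {
  L2 <- L^2
  k <- ncol(L)
  N <- matrix(1, k, k) - diag(k)
  M <- L2 %*% N
  list(f = sum(L2 * M) / 4, Gq = L * M)
}

gpa_oblimin <- function(A, maxit = 500, eps = 1e-6) {
  k <- ncol(A)
  if (k < 2) return(list(loadings = A, Phi = diag(k), converged = TRUE))
  Tm <- diag(k)
  al <- 1
  L <- A %*% t(solve(Tm))
  vg <- vgQ_quartimin(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% solve(Tm))
  s <- Inf
  for (it in seq_len(maxit)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G))
    s <- sqrt(sum(Gp^2))
    if (s < eps) break
    al <- 2 * al
    for (half in 0:24) {
      X <- Tm - al * Gp
      X <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      L2 <- A %*% t(solve(X))
      vg2 <- vgQ_quartimin(L2)
      if (vg2$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tm <- X
    f <- vg2$f
    L <- L2
    G <- -t(t(L) %*% vg2$Gq %*% solve(Tm))
  }
  list(loadings = L, Phi = t(Tm) %*% Tm, converged = s < eps)
}
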