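# Arnoldi (Krylov) approximation of the action of a matrix exponential,
# w = exp(t M) v, for a dense square matrix M of moderate size. Used for
# the collocation operator, whose spectrum is not that of a generator, so
# uniformization does not apply. Substeps are chosen adaptively from the
# standard residual-based local error estimate (Saad); each substep costs
# at most m matrix-vector products.
expmvKrylov <- function(M, v, t, tol = 1e-10, m = 30L) {
  n <- length(v)
  if (t == 0 || n == 0L) return(v)
  m <- min(m, n)
  # start optimistic: the per-substep halving loop reuses the Arnoldi basis,
  # so an over-large trial step only costs small-matrix exponentials
  tau <- t
  done <- 0
  w <- v
  while (done < t * (1 - 1e-14)) {
    tau <- min(tau, t - done)
    beta <- sqrt(sum(w^2))
    if (beta == 0) return(w)
    V <- matrix(0, n, m + 1L)
    H <- matrix(0, m + 2L, m + 2L)
    V[, 1L] <- w / beta
    happy <- FALSE
    mk <- m
    for (j in seq_len(m)) {
      p <- as.numeric(M %*% V[, j])
      for (i in seq_len(j)) {        # modified Gram-Schmidt
        H[i, j] <- sum(V[, i] * p)
        p <- p - H[i, j] * V[, i]
      }
      h1 <- sqrt(sum(p^2))
      # one reorthogonalisation pass for robustness
      for (i in seq_len(j)) {
        c2 <- sum(V[, i] * p)
        H[i, j] <- H[i, j] + c2
        p <- p - c2 * V[, i]
      }
      h1 <- sqrt(sum(p^2))
      if (h1 <= 1e-14 * max(1, abs(H[j, j]))) { happy <- TRUE; mk <- j; break }
      H[j + 1L, j] <- h1
      V[, j + 1L] <- p / h1
    }
    repeat {
      if (happy) {
        Hs <- H[seq_len(mk), seq_len(mk), drop = FALSE]
        E <- expmDense(tau * Hs)
        wnew <- beta * as.numeric(V[, seq_len(mk), drop = FALSE] %*% E[, 1L])
        err <- 0
      } else {
        # augmented matrix trick: the (m+1, m+2) corrected error estimate
        Ha <- H[seq_len(mk + 2L), seq_len(mk + 2L), drop = FALSE]
        Ha[1L, mk + 1L] <- 0
        Ha[mk + 1L, mk + 2L] <- 1
        E <- expmDense(tau * Ha)
        phi1 <- abs(beta * H[mk + 1L, mk] * E[mk, mk + 1L])
        phi2 <- abs(beta * H[mk + 1L, mk] * E[mk, mk + 2L]) * tau
        err <- max(phi1, phi2)
        wnew <- beta *
          as.numeric(V[, seq_len(mk), drop = FALSE] %*%
                       E[seq_len(mk), 1L])
      }
      if (err <= tol * max(1, sqrt(sum(wnew^2))) || tau <= 1e-12 * t) break
      tau <- tau / 2
    }
    if (any(!is.finite(wnew)))
      stop("collocation step produced non-finite values; ",
           "reduce the time step or improve basis conditioning")
    w <- wnew
    done <- done + tau
    if (!happy && err < tol / 10) tau <- tau * 2
  }
  w
}

# scaling-and-squaring Pade (13/13) exponential for small dense matrices
expmDense <- function(A) {
  n <- nrow(A)
  if (n == 1L) return(matrix(exp(A[1L, 1L]), 1L, 1L))
  nrmA <- max(colSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrmA, .Machine$double.eps) / 5.37)))
  A <- A / 2^s
  b <- c(64764752532480000, 32382376266240000, 7771770303897600,
         1187353796428800, 129060195264000, 10559470521600, 670442572800,
         33522128640, 1323241920, 40840800, 960960, 16380, 182, 1)
  I <- diag(n)
  A2 <- A %*% A; A4 <- A2 %*% A2; A6 <- A2 %*% A4
  U <- A %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
                b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * I)
  V <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
    b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * I
  E <- solve(V - U, V + U)
  for (i in seq_len(s)) E <- E %*% E
  E
}
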