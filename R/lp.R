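# Dense two-phase primal simplex for box-constrained linear programs,
#
#   max (or min) c'x   s.t.  A x = b,  0 <= x <= upper  (upper finite),
#
# used as the LP backend of the flux module. Bland's anti-cycling rule
# (smallest-index entering variable, smallest-basic-index leaving variable)
# makes the solver deterministic and guarantees finite termination; the
# reduced-cost row is recomputed from the tableau at every iteration, which
# is cheap at the problem sizes seed validation produces and avoids drift.
# Upper bounds enter as explicit slack rows, so phase 1 always starts from
# the identity basis of bound slacks plus equality artificials.

simplex_box <- function(cvec, A, b, upper, maximize = TRUE, tol = 1e-9,
                        max_iter = 20000L) {
  n <- length(cvec)
  m1 <- if (is.null(A)) 0L else nrow(A)
  stopifnot(length(upper) == n, all(upper >= 0), all(is.finite(upper)))
  if (m1) stopifnot(ncol(A) == n, length(b) == m1)

  neg <- if (m1) b < 0 else logical(0)
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }

  N <- 2L * n + m1                      # x, bound slacks, artificials
  M <- m1 + n
  Tm <- matrix(0, M, N + 1L)
  if (m1) {
    Tm[seq_len(m1), seq_len(n)] <- A
    Tm[cbind(seq_len(m1), 2L * n + seq_len(m1))] <- 1
    Tm[seq_len(m1), N + 1L] <- b
  }
  Tm[cbind(m1 + seq_len(n), seq_len(n))] <- 1
  Tm[cbind(m1 + seq_len(n), n + seq_len(n))] <- 1
  Tm[m1 + seq_len(n), N + 1L] <- upper
  basis <- c(if (m1) 2L * n + seq_len(m1), n + seq_len(n))

  pivot <- function(r, j) {
    Tm[r, ] <<- Tm[r, ] / Tm[r, j]
    fac <- Tm[, j]
    fac[r] <- 0
    hit <- which(abs(fac) > 0)
    if (length(hit)) {
      Tm[hit, ] <<- Tm[hit, ] - outer(fac[hit], Tm[r, ])
    }
    basis[r] <<- j
  }

  run_phase <- function(f, allowed) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return("iterlimit")
      costrow <- f - drop(f[basis] %*% Tm[, seq_len(N), drop = FALSE])
      enter <- which(allowed & costrow < -tol)
      if (!length(enter)) return("optimal")
      j <- enter[[1L]]                              # Bland
      col <- Tm[, j]
      pos <- which(col > tol)
      if (!length(pos)) return("unbounded")
      ratios <- Tm[pos, N + 1L] / col[pos]
      tmin <- min(ratios)
      cand <- pos[ratios <= tmin + tol * (1 + abs(tmin))]
      r <- cand[[which.min(basis[cand])]]           # Bland
      pivot(r, j)
    }
  }

  art <- if (m1) 2L * n + seq_len(m1) else integer(0)
  allowed <- rep(TRUE, N)
  f1 <- numeric(N)
  f1[art] <- 1
  st <- run_phase(f1, allowed)
  if (st != "optimal") return(list(status = "error", x = NULL, objective = NA_real_))
  phase1 <- drop(f1[basis] %*% Tm[, N + 1L])
  scale <- max(1, abs(b))
  if (phase1 > 1e-7 * scale) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  allowed[art] <- FALSE
  # drive remaining artificials (necessarily at zero) out of the basis
  drop_rows <- integer(0)
  for (r in which(basis %in% art)) {
    j <- which(allowed & abs(Tm[r, seq_len(N)]) > tol)
    if (length(j)) pivot(r, j[[1L]]) else drop_rows <- c(drop_rows, r)
  }
  if (length(drop_rows)) {
    Tm <- Tm[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }

  f2 <- numeric(N)
  f2[seq_len(n)] <- if (maximize) -cvec else cvec
  st2 <- run_phase(f2, allowed)
  if (st2 == "iterlimit") return(list(status = "error", x = NULL, objective = NA_real_))
  if (st2 == "unbounded") return(list(status = "unbounded", x = NULL, objective = NA_real_))
  xfull <- numeric(N)
  xfull[basis] <- Tm[, ncol(Tm)]
  x <- xfull[seq_len(n)]
  list(status = "optimal", x = x, objective = sum(cvec * x))
}
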