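# Bounded-variable two-phase primal simplex.
#
# Solves   max c'x   s.t.  A x = b,  l <= x <= u
# with possibly infinite bounds.  Dense linear algebra; Bland's smallest-
# index rule throughout, which guarantees finite termination on the
# degenerate vertices flux cones are full of.  Built for the model sizes
# this package meets (tens to a few thousand reactions); not a general
# purpose LP code.
#
# Returns list(status = "optimal" | "infeasible" | "unbounded",
#              x = numeric(n), objective = double).

lp_solve_bounded <- function(A, b, c, l, u, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(b) == m, length(c) == n, length(l) == n, length(u) == n)
  if (any(l > u + tol)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }

  if (m == 0L) {
    # pure box problem: optimum at the bound selected by the cost sign
    x <- ifelse(c > 0, u, ifelse(c < 0, l, ifelse(is.finite(l), l, pmin(u, 0))))
    if (any(!is.finite(x) & c != 0)) {
      return(list(status = "unbounded", x = NULL, objective = NA_real_))
    }
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", x = x, objective = sum(c * x)))
  }

  ntot <- n + m                        # structural + artificial
  Afull <- cbind(A, diag(1, m))
  lf <- c(l, rep(0, m))
  uf <- c(u, rep(Inf, m))

  # start: structural vars nonbasic at the finite bound nearest zero
  start_val <- function(lo, hi) {
    if (is.finite(lo) && is.finite(hi)) if (abs(lo) <= abs(hi)) lo else hi
    else if (is.finite(lo)) lo
    else if (is.finite(hi)) hi
    else 0
  }
  x <- numeric(ntot)
  stat <- character(ntot)              # "basic", "lower", "upper", "free"
  for (j in seq_len(n)) {
    x[j] <- start_val(l[j], u[j])
    stat[j] <- if (!is.finite(l[j]) && !is.finite(u[j])) "free"
               else if (x[j] == l[j]) "lower" else "upper"
  }
  r <- as.numeric(b - A %*% x[seq_len(n)])
  sgn <- ifelse(r >= 0, 1, -1)
  Afull[, n + seq_len(m)] <- diag(sgn, m)
  x[n + seq_len(m)] <- abs(r)
  stat[n + seq_len(m)] <- "basic"
  basis <- n + seq_len(m)

  run_simplex <- function(cost, x, stat, basis, uf) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) stop("simplex iteration limit reached", call. = FALSE)
      B <- Afull[, basis, drop = FALSE]
      # refresh basic values from the nonbasic ones (numerical hygiene)
      nonbasic <- setdiff(seq_len(ntot), basis)
      rhs <- b - Afull[, nonbasic, drop = FALSE] %*% x[nonbasic]
      xb <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xb)) stop("singular basis in simplex", call. = FALSE)
      x[basis] <- as.numeric(xb)
      y <- solve(t(B), cost[basis])
      d <- cost[nonbasic] - as.numeric(crossprod(Afull[, nonbasic, drop = FALSE], y))
      can_up <- (stat[nonbasic] %in% c("lower", "free")) & d > tol
      can_dn <- (stat[nonbasic] %in% c("upper", "free")) & d < -tol
      cand <- nonbasic[can_up | can_dn]
      if (!length(cand)) {
        return(list(x = x, stat = stat, basis = basis,
                    objective = sum(cost * x)))
      }
      j <- min(cand)                                # Bland: entering
      delta <- if ((stat[j] %in% c("lower", "free")) &&
                   d[match(j, nonbasic)] > tol) 1 else -1
      w <- as.numeric(solve(B, Afull[, j]))
      # ratio test: t >= 0 is the movement of x_j along delta
      t_best <- Inf
      leave_pos <- NA_integer_
      leave_to <- NA_character_
      dw <- delta * w
      for (k in seq_len(m)) {
        i <- basis[k]
        if (dw[k] > tol) {
          tk <- (x[i] - lf[i]) / dw[k]
          if (is.finite(tk) &&
              (tk < t_best - tol ||
               (tk < t_best + tol && (is.na(leave_pos) || i < basis[leave_pos])))) {
            t_best <- tk; leave_pos <- k; leave_to <- "lower"
          }
        } else if (dw[k] < -tol) {
          tk <- (uf[i] - x[i]) / (-dw[k])
          if (is.finite(tk) &&
              (tk < t_best - tol ||
               (tk < t_best + tol && (is.na(leave_pos) || i < basis[leave_pos])))) {
            t_best <- tk; leave_pos <- k; leave_to <- "upper"
          }
        }
      }
      span <- uf[j] - lf[j]                          # own-bound flip
      flip <- FALSE
      if (is.finite(span) && span < t_best - tol) {
        t_best <- span; flip <- TRUE
      }
      if (!is.finite(t_best)) {
        return(list(unbounded = TRUE, x = x, stat = stat, basis = basis))
      }
      t_best <- max(t_best, 0)
      x[j] <- x[j] + delta * t_best
      x[basis] <- x[basis] - t_best * dw
      if (flip) {
        stat[j] <- if (stat[j] == "lower") "upper" else "lower"
      } else {
        i_out <- basis[leave_pos]
        stat[i_out] <- leave_to
        x[i_out] <- if (leave_to == "lower") lf[i_out] else uf[i_out]
        basis[leave_pos] <- j
        stat[j] <- "basic"
      }
    }
  }

  # phase 1: drive the artificials to zero
  cost1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_simplex(cost1, x, stat, basis, uf)
  if (isTRUE(ph1$unbounded)) stop("phase-1 unbounded: inconsistent state",
                                  call. = FALSE)
  if (ph1$objective < -1e-7) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  # phase 2: artificials frozen at zero
  uf2 <- uf
  uf2[n + seq_len(m)] <- 0
  x2 <- ph1$x
  x2[n + seq_len(m)] <- 0
  stat2 <- ph1$stat
  nb_art <- which(stat2[n + seq_len(m)] != "basic") + n
  stat2[nb_art] <- "lower"
  cost2 <- c(c, rep(0, m))
  ph2 <- run_simplex(cost2, x2, stat2, ph1$basis, uf2)
  if (isTRUE(ph2$unbounded)) {
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  }
  xs <- ph2$x[seq_len(n)]
  list(status = "optimal", x = xs, objective = sum(c * xs))
}
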