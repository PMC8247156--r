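#' Dense linear-programming solver (bounded-variable two-phase simplex)
#'
#' Solves \code{max/min c'x} subject to \code{A x = b} and \code{lb <= x <= ub}.
#' This is the numerical core behind every flux computation in the package
#' (FBA, FVA, knockouts, kapp sweeps): a dense two-phase primal simplex with
#' explicit variable bounds and Bland's anti-cycling rule, sized for the
#' desk-scale models the package analyses.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A dense numeric equality-constraint matrix, m x n.
#' @param b right-hand side, length m.
#' @param lb,ub variable bounds, length n; \code{ub} entries may be \code{Inf}
#'   and \code{lb} entries \code{-Inf} (handled by substitution).
#' @param maximize logical; maximize (default) or minimize.
#' @param tol tolerance on reduced costs and basic feasibility (default 1e-9).
#' @return list with \code{status} ("optimal", "infeasible" or "unbounded"),
#'   \code{objective} (NA unless optimal) and \code{x} (primal solution).
#' @export
solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub)) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  cc <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # Substitutions so every column has a finite lower bound:
  #   lb=-Inf, ub finite : x = ub - t       (t >= 0, column negated)
  #   lb=-Inf, ub=Inf    : x = xp - xm      (extra mirrored column)
  flip <- which(!is.finite(lb) & is.finite(ub))
  free <- which(!is.finite(lb) & !is.finite(ub))
  flip_ub <- ub[flip]
  if (length(flip)) {
    b <- b - drop(A[, flip, drop = FALSE] %*% flip_ub)
    A[, flip] <- -A[, flip, drop = FALSE]
    cc[flip] <- -cc[flip]
    lb[flip] <- 0; ub[flip] <- Inf
  }
  if (length(free)) {
    A <- cbind(A, -A[, free, drop = FALSE])
    cc <- c(cc, -cc[free])
    lb[free] <- 0
    lb <- c(lb, rep(0, length(free)))
    ub <- c(ub, rep(Inf, length(free)))
  }

  # Shift to zero lower bounds: y = x - lb, 0 <= y <= u.
  shift <- lb
  b0 <- b - drop(A %*% shift)
  u <- ub - lb

  res <- simplex_bounded(cc, A, b0, u, tol = tol)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_, x = rep(NA_real_, n)))
  }
  y <- res$x + shift
  x <- y[seq_len(n)]
  if (length(free)) x[free] <- x[free] - y[n + seq_along(free)]
  if (length(flip)) x[flip] <- flip_ub - y[flip]
  list(status = "optimal", objective = sum(obj * x), x = x)
}

# Two-phase bounded-variable primal simplex for
#   min c'x  s.t.  A x = b,  0 <= x <= u  (u may be Inf).
# Nonbasic variables sit at a bound; Bland's smallest-index rule governs both
# the entering and the leaving choice, guaranteeing termination.
simplex_bounded <- function(cc, A, b, u, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  sgn <- ifelse(b < 0, -1, 1)
  Afull <- cbind(A, diag(sgn, m, m))   # artificials start basic at |b|
  ufull <- c(u, rep(Inf, m))
  ntot <- n + m

  state <- list(basis = n + seq_len(m),
                at_upper = rep(FALSE, ntot),
                xB = abs(b))

  run_phase <- function(cost, st, phase1) {
    basis <- st$basis; at_upper <- st$at_upper; xB <- st$xB
    it_max <- 500L * (ntot + 10L)
    for (it in seq_len(it_max)) {
      Bmat <- Afull[, basis, drop = FALSE]
      yv <- tryCatch(solve(t(Bmat), cost[basis]), error = function(e) NULL)
      if (is.null(yv)) return(list(status = "singular"))
      in_basis <- logical(ntot); in_basis[basis] <- TRUE

      enter <- 0L; enter_dir <- 0
      for (j in seq_len(ntot)) {
        if (in_basis[j] || ufull[j] <= tol) next   # fixed columns can't move
        dj <- cost[j] - sum(yv * Afull[, j])
        if (!at_upper[j] && dj < -tol) { enter <- j; enter_dir <- 1L; break }
        if (at_upper[j] && dj > tol)   { enter <- j; enter_dir <- -1L; break }
      }
      if (enter == 0L) {
        return(list(status = "optimal", basis = basis, at_upper = at_upper, xB = xB))
      }

      w <- solve(Bmat, Afull[, enter])
      g <- -enter_dir * w                      # d(xB)/dt as x_enter moves by t
      # ratio test: largest t keeping 0 <= xB <= u_B and t <= u_enter
      tvals <- rep(Inf, m)
      to_upper <- logical(m)
      for (i in seq_len(m)) {
        if (g[i] < -tol) {
          tvals[i] <- xB[i] / (-g[i])
        } else if (g[i] > tol && is.finite(ufull[basis[i]])) {
          tvals[i] <- (ufull[basis[i]] - xB[i]) / g[i]
          to_upper[i] <- TRUE
        }
      }
      tstar <- min(c(tvals, ufull[enter]))
      if (!is.finite(tstar)) {
        return(list(status = if (phase1) "infeasible" else "unbounded"))
      }
      tstar <- max(tstar, 0)
      if (ufull[enter] <= tstar + tol && all(tvals >= ufull[enter] - tol)) {
        # entering variable flips to its opposite bound; basis unchanged
        xB <- xB + ufull[enter] * g
        at_upper[enter] <- !at_upper[enter]
      } else {
        cand <- which(tvals <= tstar + tol)
        leave_row <- cand[which.min(basis[cand])]   # Bland: smallest var index
        xB <- xB + tstar * g
        lv <- basis[leave_row]
        at_upper[lv] <- to_upper[leave_row]
        basis[leave_row] <- enter
        xB[leave_row] <- if (enter_dir == 1L) tstar else ufull[enter] - tstar
        at_upper[enter] <- FALSE
      }
      xB[abs(xB) < 1e-11] <- 0
    }
    list(status = "iteration_limit")
  }

  p1 <- run_phase(c(rep(0, n), rep(1, m)), state, phase1 = TRUE)
  if (p1$status != "optimal") return(list(status = "infeasible"))
  if (sum(p1$xB[p1$basis > n]) > 1e-7) return(list(status = "infeasible"))
  ufull[(n + 1):ntot] <- 0                       # retire artificials
  p1$xB[p1$basis > n] <- 0

  p2 <- run_phase(c(cc, rep(0, m)), p1, phase1 = FALSE)
  if (p2$status == "unbounded") return(list(status = "unbounded"))
  if (p2$status != "optimal") return(list(status = p2$status))

  x <- ifelse(p2$at_upper[seq_len(n)] & is.finite(u), u, 0)
  keep <- p2$basis <= n
  x[p2$basis[keep]] <- p2$xB[keep]
  x <- pmin(pmax(x, 0), ifelse(is.finite(u), u, Inf))
  list(status = "optimal", x = x)
}
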