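# Linear-programming layer: a dense two-phase simplex for bounded
# variables. Stoichiometric LPs are small (tens of reactions) but
# numerically awkward — exact conservation relations make the equality
# system rank-deficient, and flux-variability subproblems sit on a
# degenerate optimal face. The solver below handles both: redundant
# equality rows are reduced away up front (with a consistency check), and
# pivoting falls back to Bland's anti-cycling rule when degeneracy stalls
# progress.

.lp_big <- 1e6
.lp_tol <- 1e-9

# Drop linearly dependent equality rows. A dropped row must be implied by
# the kept ones: if the augmented system has higher rank than the
# coefficient matrix the equalities are inconsistent (infeasible).
reduce_equalities <- function(A, b, tol = 1e-9) {
  if (is.null(A) || nrow(A) <= 1L) {
    return(list(A = A, b = b, infeasible = FALSE))
  }
  q <- qr(t(A), tol = tol)
  if (q$rank == nrow(A)) return(list(A = A, b = b, infeasible = FALSE))
  q_aug <- qr(t(cbind(A, b)), tol = tol)
  if (q_aug$rank > q$rank) {
    return(list(A = A, b = b, infeasible = TRUE))
  }
  keep <- sort(q$pivot[seq_len(q$rank)])
  list(A = A[keep, , drop = FALSE], b = b[keep], infeasible = FALSE)
}

# Minimise c'x subject to A x = b, l <= x <= u (all bounds finite).
# Returns list(status = "optimal"|"infeasible", x, value).
simplex_bounded <- function(cc, A, b, l, u, tol = .lp_tol) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {
    x <- ifelse(cc > 0, l, ifelse(cc < 0, u, l))
    return(list(status = "optimal", x = x, value = sum(cc * x)))
  }

  # start with structural variables at the bound closer to zero
  x0 <- ifelse(abs(l) <= abs(u), l, u)
  r <- b - as.numeric(A %*% x0)
  sg <- ifelse(r >= 0, 1, -1)
  # artificial columns diag(sg): artificials start at |r| >= 0
  Aext <- cbind(A, diag(sg, m))
  lext <- c(l, rep(0, m))
  uext <- c(u, rep(.lp_big * m + sum(abs(r)), m))
  at_upper <- abs(l) > abs(u)

  st <- list(
    A = Aext, l = lext, u = uext,
    basis = n + seq_len(m),
    at_upper = c(at_upper, rep(FALSE, m)),
    x = c(x0, abs(r)),
    n_struct = n
  )

  # phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(1, m))
  st <- simplex_iterate(st, c1, tol, allow = seq_len(n + m))
  if (is.null(st)) return(list(status = "infeasible", x = NULL, value = NA_real_))
  if (sum(st$x[n + seq_len(m)]) > 1e-6) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  # freeze artificials at zero (basic zero-valued artificials are harmless)
  st$u[n + seq_len(m)] <- 0
  st$x[n + seq_len(m)] <- 0

  # phase 2
  c2 <- c(cc, rep(0, m))
  st <- simplex_iterate(st, c2, tol, allow = seq_len(n))
  if (is.null(st)) return(list(status = "infeasible", x = NULL, value = NA_real_))
  x <- st$x[seq_len(n)]
  list(status = "optimal", x = x, value = sum(cc * x))
}

# simplex iterations for one phase; `allow` restricts entering candidates.
# Returns updated state, or NULL on numerical failure.
simplex_iterate <- function(st, cc, tol, allow) {
  m <- length(st$basis)
  ntot <- ncol(st$A)
  max_iter <- 200L * (ntot + m)
  bland_after <- 10L * (ntot + m)
  for (it in seq_len(max_iter)) {
    B <- st$A[, st$basis, drop = FALSE]
    Blu <- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Blu)) return(NULL)
    y <- as.numeric(crossprod(Blu, cc[st$basis]))   # B' y = c_B
    nonbasic <- setdiff(allow, st$basis)
    if (!length(nonbasic)) return(st)
    d <- cc[nonbasic] - as.numeric(crossprod(st$A[, nonbasic, drop = FALSE], y))
    up <- st$at_upper[nonbasic]
    viol <- ifelse(up, d, -d)                        # positive = improving
    cand <- which(viol > tol)
    if (!length(cand)) return(st)
    j_rel <- if (it > bland_after) cand[1] else cand[which.max(viol[cand])]
    j <- nonbasic[j_rel]
    sgn <- if (st$at_upper[j]) -1 else 1             # direction of x_j change
    w <- as.numeric(Blu %*% st$A[, j])               # B^-1 a_j
    # ratio test: basic vars move by -sgn * w * t
    xB <- st$x[st$basis]
    delta <- -sgn * w
    t_best <- st$u[j] - st$l[j]                      # bound-flip limit
    leave <- 0L
    for (i in seq_len(m)) {
      if (delta[i] > tol) {
        ti <- (st$u[st$basis[i]] - xB[i]) / delta[i]
      } else if (delta[i] < -tol) {
        ti <- (xB[i] - st$l[st$basis[i]]) / (-delta[i])
      } else next
      if (ti < t_best - tol ||
          (ti < t_best + tol && leave > 0L && st$basis[i] < st$basis[leave])) {
        t_best <- ti
        leave <- i
      }
    }
    if (t_best > .lp_big * 10) return(NULL)          # should not happen: bounded
    t_best <- max(t_best, 0)
    st$x[st$basis] <- xB + delta * t_best
    st$x[j] <- st$x[j] + sgn * t_best
    if (leave == 0L) {
      st$at_upper[j] <- !st$at_upper[j]              # bound flip
    } else {
      lv <- st$basis[leave]
      st$at_upper[lv] <- delta[leave] > 0            # hit upper if moving up
      st$x[lv] <- if (st$at_upper[lv]) st$u[lv] else st$l[lv]
      st$basis[leave] <- j
    }
  }
  NULL
}

# Solve: max/min obj'v  s.t.  Aeq v = beq, lb <= v <= ub, plus optional
# extra rows A v (<=|>=|=) rhs. Returns list(status, value, v).
lp_solve_raw <- function(obj, Aeq, beq, lb, ub, maximize = TRUE,
                         A = NULL, dir = NULL, rhs = NULL) {
  n <- length(obj)
  lb <- pmax(lb, -.lp_big)
  ub <- pmin(ub, .lp_big)
  if (any(lb > ub)) return(list(status = "infeasible", value = NA_real_,
                                v = NULL))
  red <- reduce_equalities(Aeq, beq)
  if (red$infeasible) return(list(status = "infeasible", value = NA_real_,
                                  v = NULL))
  Afull <- red$A; bfull <- red$b
  ls <- numeric(0); us <- numeric(0)
  if (!is.null(A)) {
    nex <- length(dir)
    slackA <- matrix(0, nrow(Afull), nex)
    Afull <- cbind(rbind(Afull, A),
                   rbind(slackA, diag(1, nex)))
    bfull <- c(bfull, rhs)
    ls <- ifelse(dir == "<=", 0, ifelse(dir == ">=", -.lp_big, 0))
    us <- ifelse(dir == "<=", .lp_big, ifelse(dir == ">=", 0, 0))
  }
  cc <- c(if (maximize) -obj else obj, rep(0, length(ls)))
  res <- simplex_bounded(cc, Afull, bfull, c(lb, ls), c(ub, us))
  if (res$status != "optimal") {
    return(list(status = "infeasible", value = NA_real_, v = NULL))
  }
  v <- res$x[seq_len(n)]
  list(status = "optimal", value = sum(obj * v), v = v)
}

# Linear FBA-type problem over a model: optimise obj'v subject to S v = 0
# and the model bounds, plus optional extra linear rows.
lp_model <- function(model, obj, maximize = TRUE, A = NULL, dir = NULL,
                     rhs = NULL, bounds_override = NULL) {
  S <- as.matrix(model$S)
  lb <- model$rxns$lower_bound
  ub <- model$rxns$upper_bound
  if (!is.null(bounds_override)) {
    lb <- bounds_override$lb
    ub <- bounds_override$ub
  }
  lp_solve_raw(obj, Aeq = S, beq = numeric(nrow(S)), lb = lb, ub = ub,
               maximize = maximize, A = A, dir = dir, rhs = rhs)
}

# Minimise sum_j w_j |v_j| subject to S v = 0, bounds, and optional extra
# rows over v. Variables are split v = p - n with p, n >= 0.
lp_min_weighted_abs <- function(model, weights, A = NULL, dir = NULL,
                                rhs = NULL) {
  n <- nrow(model$rxns)
  S <- as.matrix(model$S)
  lb <- pmax(model$rxns$lower_bound, -.lp_big)
  ub <- pmin(model$rxns$upper_bound, .lp_big)
  lb2 <- numeric(2 * n)
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  Aeq <- cbind(S, -S)
  # bounds on v = p - n that the split bounds do not already imply
  addA <- NULL; adddir <- NULL; addrhs <- NULL
  pos <- which(lb > 0)
  if (length(pos)) {
    M <- matrix(0, length(pos), 2 * n)
    M[cbind(seq_along(pos), pos)] <- 1
    M[cbind(seq_along(pos), n + pos)] <- -1
    addA <- rbind(addA, M); adddir <- c(adddir, rep(">=", length(pos)))
    addrhs <- c(addrhs, lb[pos])
  }
  neg <- which(ub < 0)
  if (length(neg)) {
    M <- matrix(0, length(neg), 2 * n)
    M[cbind(seq_along(neg), neg)] <- 1
    M[cbind(seq_along(neg), n + neg)] <- -1
    addA <- rbind(addA, M); adddir <- c(adddir, rep("<=", length(neg)))
    addrhs <- c(addrhs, ub[neg])
  }
  if (!is.null(A)) {
    addA <- rbind(addA, cbind(A, -A)); adddir <- c(adddir, dir)
    addrhs <- c(addrhs, rhs)
  }
  res <- lp_solve_raw(obj = c(weights, weights), Aeq = Aeq,
                      beq = numeric(nrow(S)), lb = lb2, ub = ub2,
                      maximize = FALSE, A = addA, dir = adddir, rhs = addrhs)
  if (res$status != "optimal") return(res)
  v <- res$v[seq_len(n)] - res$v[n + seq_len(n)]
  list(status = "optimal", value = res$value, v = v)
}
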