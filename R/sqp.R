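# Sparse sequential quadratic programming solver for the collocation NLPs:
# Gauss-Newton Lagrangian Hessian, equality constraints handled through a
# sparse KKT system, simple bounds through an active-set loop on the QP, and
# a backtracking line search on an l1 merit function. Levenberg-style
# damping guards indefinite curvature.

#' Solver settings
#'
#' @param tol convergence tolerance for the scaled NLP (KKT) error; runs can
#'   also end with status `"stalled_progress"` once the objective is flat at
#'   a point satisfying `constraint_tol`.
#' @param max_iterations iteration cap.
#' @param constraint_tol feasibility tolerance on the unscaled dynamics
#'   residuals.
#' @param restarts number of random initial guesses for standing calibration.
#' @param seed RNG seed used for the random restarts (recorded in results).
#' @param verbose print per-iteration solver progress.
#' @return object of class `solver_settings`.
#' @export
solver_settings <- function(tol = 1e-4, max_iterations = 2e4,
                            constraint_tol = 1e-3, restarts = 10, seed = 1L,
                            verbose = FALSE) {
  stopifnot(tol > 0, constraint_tol > 0, restarts >= 1)
  structure(list(tol = tol, max_iterations = max_iterations,
                 constraint_tol = constraint_tol, restarts = restarts,
                 seed = seed, verbose = verbose), class = "solver_settings")
}

# Node-interleaved permutation of the collocation KKT system: states and
# controls of node k, followed by the multipliers of the backward-Euler block
# ending at node k (the first-node closure multipliers ride with node 2).
# In this ordering the KKT matrix is block tridiagonal.
kkt_block_structure <- function(N, nv, nf) {
  nz <- N * nv
  sizes <- c(nv, nv + nf + (nf - 6), rep(nv + nf, max(0, N - 2)))
  bstart <- c(0L, cumsum(sizes))
  zpos <- integer(nz)
  for (k in seq_len(N)) zpos[(k - 1) * nv + seq_len(nv)] <- bstart[k] + seq_len(nv)
  mcon <- (N - 1) * nf + nf - 6
  lpos <- integer(mcon)
  for (kb in seq_len(N - 1))
    lpos[(kb - 1) * nf + seq_len(nf)] <- bstart[kb + 1] + nv + seq_len(nf)
  lpos[(N - 1) * nf + seq_len(nf - 6)] <- bstart[2] + nv + nf + seq_len(nf - 6)
  list(N = N, nv = nv, nf = nf, nz = nz, mcon = mcon, dim = bstart[N + 1],
       bstart = as.integer(bstart), zpos = zpos, lpos = lpos)
}

as_triplets <- function(M) {
  Tm <- methods::as(M, "TsparseMatrix")
  list(i = Tm@i + 1L, j = Tm@j + 1L, x = Tm@x)
}

# Block-tridiagonal KKT solve with an add-only active set on the bounds.
solve_kkt_blocked <- function(H, g, A, cc, lo, hi, damp, st) {
  ht <- as_triplets(H)
  at <- as_triplets(A)
  nz <- st$nz; m <- st$mcon
  ti <- c(st$zpos[ht$i], st$lpos[at$i], st$zpos[at$j], st$zpos[seq_len(nz)],
          st$lpos[seq_len(m)])
  tj <- c(st$zpos[ht$j], st$zpos[at$j], st$lpos[at$i], st$zpos[seq_len(nz)],
          st$lpos[seq_len(m)])
  tx <- c(ht$x, at$x, at$x, rep(damp, nz), rep(-1e-10, m))
  rhs <- numeric(st$dim)
  rhs[st$zpos] <- -g
  rhs[st$lpos] <- -cc
  fixed <- integer(0); fval <- numeric(0)
  d <- NULL; lam <- NULL
  for (pass in 1:10) {
    sol <- cpp_block_tridiag_solve(ti - 1L, tj - 1L, tx, st$bstart, rhs,
                                   st$zpos[fixed] - 1L, fval)
    if (!isTRUE(sol$ok)) return(NULL)
    d <- sol$x[st$zpos]
    lam <- sol$x[st$lpos]
    viol <- (d < lo - 1e-12) | (d > hi + 1e-12)
    viol[fixed] <- FALSE
    if (!any(viol)) return(list(d = d, lam = lam))
    newfix <- which(viol)
    fixed <- c(fixed, newfix)
    fval <- c(fval, pmin(pmax(d[newfix], lo[newfix]), hi[newfix]))
  }
  d <- pmin(pmax(d, lo), hi)
  list(d = d, lam = lam)
}

# Solve the bounded equality-constrained QP
#   min 0.5 d'Hd + g'd  s.t.  A d = -c,  lo <= d <= hi
# via a sparse KKT solve plus an add-only active set on the bounds.
solve_kkt_bounded <- function(H, g, A, cc, lo, hi, damp, st = NULL) {
  if (!is.null(st)) {
    out <- solve_kkt_blocked(H, g, A, cc, lo, hi, damp, st)
    if (!is.null(out)) return(out)
    # fall through to the general sparse path on block-solver failure
  }
  solve_kkt_general(H, g, A, cc, lo, hi, damp)
}

solve_kkt_general <- function(H, g, A, cc, lo, hi, damp) {
  nz <- length(g); m <- length(cc)
  fixed <- rep(FALSE, nz)
  dfix <- numeric(nz)
  Hd <- H + Matrix::Diagonal(nz, damp)
  for (pass in 1:10) {
    free <- which(!fixed)
    nf <- length(free)
    rhs_g <- -g[free]
    rhs_c <- -cc
    if (any(fixed)) {
      idx <- which(fixed)
      rhs_g <- rhs_g - as.vector(Hd[free, idx, drop = FALSE] %*% dfix[idx])
      rhs_c <- rhs_c - as.vector(A[, idx, drop = FALSE] %*% dfix[idx])
    }
    K <- rbind(cbind(Hd[free, free, drop = FALSE], Matrix::t(A[, free, drop = FALSE])),
               cbind(A[, free, drop = FALSE], -Matrix::Diagonal(m, 1e-10)))
    sol <- tryCatch(as.vector(Matrix::solve(K, c(rhs_g, rhs_c))),
                    error = function(e) NULL)
    if (is.null(sol) || !all(is.finite(sol))) return(NULL)
    d <- dfix
    d[free] <- sol[seq_len(nf)]
    lam <- sol[nf + seq_len(m)]
    viol <- (d < lo - 1e-12) | (d > hi + 1e-12)
    viol[fixed] <- FALSE
    if (!any(viol)) return(list(d = d, lam = lam))
    dfix[viol] <- pmin(pmax(d[viol], lo[viol]), hi[viol])
    fixed <- fixed | viol
  }
  d <- pmin(pmax(d, lo), hi)
  list(d = d, lam = lam)
}

# Generic SQP driver.
#   obj_fn(z, derivs): list(J, breakdown, [grad, hess])
#   con_fn(z, derivs): list(c, [A]) -- raw (unscaled) residuals and Jacobian
# Returns the solution, multipliers and a convergence log.
sqp_solve <- function(z0, obj_fn, con_fn, lower, upper, zscale, cscale,
                      settings, quiet = TRUE, structure = NULL) {
  t_wall0 <- Sys.time()
  t_cpu0 <- proc.time()
  nlp_cpu <- 0
  eval_point <- function(z, derivs) {
    t1 <- proc.time()
    o <- obj_fn(z, derivs)
    cn <- con_fn(z, derivs)
    nlp_cpu <<- nlp_cpu + sum((proc.time() - t1)[1:2])
    list(o = o, cn = cn)
  }
  z <- pmin(pmax(z0, lower), upper)
  nz <- length(z)
  ev <- eval_point(z, TRUE)
  m <- length(ev$cn$c)
  lam <- rep(0, m)
  damp <- 1e-4
  nu <- 1
  filter <- list()
  theta_max <- Inf  # set from the initial violation on the first iteration
  best_J <- Inf; flat <- 0L
  best <- NULL  # best feasible iterate seen (returned on non-KKT stops)
  status <- "max_iterations"
  kkt <- Inf; rawviol <- Inf; iter <- 0
  Dz <- Matrix::Diagonal(nz, zscale)
  for (iter in seq_len(settings$max_iterations)) {
    # adaptive variable equilibration on top of the static scales: strongly
    # weighted tracking terms otherwise leave the KKT matrix with a numeric
    # range the sparse LU cannot pivot through
    H1 <- Dz %*% ev$o$hess %*% Dz
    s2 <- 1 / pmax(1, sqrt(Matrix::diag(H1)))
    zs <- zscale * s2
    Dzs <- Matrix::Diagonal(nz, zs)
    g <- ev$o$grad * zs
    H <- Matrix::Diagonal(nz, s2) %*% H1 %*% Matrix::Diagonal(nz, s2)
    A <- Matrix::Diagonal(m, 1 / cscale) %*% ev$cn$A %*% Dzs
    cc <- ev$cn$c / cscale
    # dynamic row equilibration: exponential muscle/contact terms can blow
    # the Jacobian's dynamic range far from feasibility
    rn <- pmax(1, Matrix::rowSums(abs(A)) / 10)
    A <- Matrix::Diagonal(m, 1 / rn) %*% A
    cc <- cc / rn
    if (iter == 1) theta_max <- max(1e3, 100 * sum(abs(cc)))
    dual <- g + as.vector(Matrix::crossprod(A, lam))
    # bound multipliers absorb the dual residual at active bounds
    at_lo <- z <= lower + 1e-9
    at_hi <- z >= upper - 1e-9
    di <- abs(dual)
    di[at_lo] <- pmax(0, -dual[at_lo])
    di[at_hi] <- pmax(0, dual[at_hi])
    di[at_lo & at_hi] <- 0
    sd <- max(100, sum(abs(lam)) / max(1, m)) / 100
    kkt <- max(max(di) / sd, max(abs(cc)))
    rawviol <- max(abs(ev$cn$c))
    if (!quiet)
      message(sprintf("it %4d  J=%.6g  kkt=%.3g  viol=%.3g  damp=%.1g",
                      iter, ev$o$J, kkt, rawviol, damp))
    if (rawviol <= settings$constraint_tol &&
        (is.null(best) || ev$o$J < best$J))
      best <- list(z = z, J = ev$o$J, breakdown = ev$o$breakdown,
                   c = ev$cn$c, kkt = kkt, viol = rawviol, lam = lam)
    if (kkt <= settings$tol && rawviol <= settings$constraint_tol) {
      status <- "converged"; break
    }
    # progress watchdog: once feasible, stop when the objective has been
    # essentially flat for a stretch of iterations
    if (rawviol <= settings$constraint_tol) {
      if (is.finite(best_J) &&
          ev$o$J > best_J - 1e-9 * max(1, abs(best_J))) {
        flat <- flat + 1L
        if (flat >= 40L) { status <- "stalled_progress"; break }
      } else flat <- 0L
      best_J <- min(best_J, ev$o$J)
    }
    lo_s <- (lower - z) / zs
    hi_s <- (upper - z) / zs
    qp <- solve_kkt_bounded(H, g, A, cc, lo_s, hi_s, damp, structure)
    if (is.null(qp)) {
      damp <- damp * 10
      if (damp > 1e10) { status <- "kkt_failure"; break }
      next
    }
    d <- qp$d
    # filter line search (Fletcher-Leyffer style): a trial point is accepted
    # if it improves either feasibility or the objective against the filter
    # entries and the current point; this avoids the l1-merit deadlock on
    # strongly curved constraint manifolds (stiff contact)
    th0 <- sum(abs(cc))
    J0 <- ev$o$J
    theta_of <- function(evp) sum(abs(evp$cn$c / (cscale * rn)))
    acceptable <- function(th, J) {
      if (!is.finite(th) || !is.finite(J) || th > theta_max) return(FALSE)
      # throttle feasibility excursions: large constraint violations are
      # cheap to accumulate and expensive to repair
      if (th > max(1.5 * th0, 100 * settings$tol)) return(FALSE)
      for (e in filter)
        if (th >= (1 - 1e-5) * e[1] && J >= e[2] - 1e-5 * e[1]) return(FALSE)
      th < (1 - 1e-5) * th0 || J < J0 - 1e-5 * th0 - 1e-14
    }
    alpha <- 1; accepted <- FALSE
    for (ls in 1:30) {
      zt <- pmin(pmax(z + alpha * (zs * d), lower), upper)
      evt <- tryCatch(eval_point(zt, FALSE), error = function(e) NULL)
      finite_pt <- !is.null(evt) && is.finite(evt$o$J) && all(is.finite(evt$cn$c))
      if (finite_pt && acceptable(theta_of(evt), evt$o$J)) { accepted <- TRUE; break }
      if (ls == 1 && finite_pt) {
        # second-order correction: re-solve the constraints at the trial
        # point to recover feasibility lost to constraint curvature
        cc_t <- evt$cn$c / (cscale * rn)
        soc <- solve_kkt_bounded(H, numeric(nz), A, cc_t,
                                 lo_s - d, hi_s - d, damp, structure)
        if (!is.null(soc)) {
          zt2 <- pmin(pmax(z + zs * (d + soc$d), lower), upper)
          evt2 <- tryCatch(eval_point(zt2, FALSE), error = function(e) NULL)
          if (!is.null(evt2) && is.finite(evt2$o$J) && all(is.finite(evt2$cn$c)) &&
              acceptable(theta_of(evt2), evt2$o$J)) {
            zt <- zt2; evt <- evt2; accepted <- TRUE; break
          }
        }
      }
      alpha <- alpha / 2
    }
    if (accepted && !(evt$o$J < J0 - 1e-5 * th0)) {
      # feasibility-type step: augment the filter
      filter[[length(filter) + 1]] <- c((1 - 1e-5) * th0, J0 - 1e-5 * th0)
      if (length(filter) > 200) filter <- filter[-1]
    }
    if (!accepted && th0 > settings$tol) {
      # feasibility restoration: minimum-curvature step onto the linearized
      # constraint manifold, accepted on violation decrease alone
      qr2 <- solve_kkt_bounded(H, numeric(nz), A, cc, lo_s, hi_s,
                               max(damp, 1e-4), structure)
      if (!is.null(qr2)) {
        alpha <- 1
        for (ls in 1:20) {
          zt <- pmin(pmax(z + alpha * (zs * qr2$d), lower), upper)
          evt <- tryCatch(eval_point(zt, FALSE), error = function(e) NULL)
          if (!is.null(evt) && all(is.finite(evt$cn$c)) && is.finite(evt$o$J) &&
              theta_of(evt) < (1 - 1e-4 * alpha) * th0) {
            accepted <- TRUE; break
          }
          alpha <- alpha / 2
        }
      }
    }
    if (!accepted) {
      damp <- damp * 10
      if (damp > 1e10) { status <- "stalled"; break }
      next
    }
    z <- zt
    lam <- qp$lam
    ev <- eval_point(z, TRUE)
    damp <- max(damp / 3, 1e-8)
  }
  cpu <- sum((proc.time() - t_cpu0)[1:2])
  # return the best feasible iterate (and the KKT error measured there)
  # when the run did not end exactly at the KKT test
  if (!is.null(best) && (status != "converged" || best$J < ev$o$J)) {
    z <- best$z; lam <- best$lam
    ev <- list(o = list(J = best$J, breakdown = best$breakdown),
               cn = list(c = best$c))
    kkt <- best$kkt; rawviol <- best$viol
  }
  list(z = z, lambda = lam, objective = ev$o$J, breakdown = ev$o$breakdown,
       constraints = ev$cn$c, status = status, iterations = iter,
       scaled_nlp_error = kkt, max_violation = rawviol,
       wall_time_s = as.numeric(difftime(Sys.time(), t_wall0, units = "secs")),
       cpu_time_s = cpu, nlp_cpu_s = nlp_cpu,
       nlp_eval_share_pct = if (cpu > 0) 100 * nlp_cpu / cpu else NA_real_)
}
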