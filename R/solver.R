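#' Solver configuration
#'
#' @param dt time step in s (default 1e-4).
#' @param cycles maximum number of cardiac cycles to run.
#' @param newton_tol relative Newton convergence tolerance.
#' @param newton_max maximum Newton iterations per step.
#' @param periodicity_tol early-exit tolerance: relative L2 difference of
#'   the inlet pressure between consecutive cycles.
#' @param max_halvings maximum dt halvings when Newton fails.
#' @param snapshots number of full-field snapshots kept per cycle.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(dt = 1e-4, cycles = 5, newton_tol = 1e-8,
                          newton_max = 25, periodicity_tol = 0.005,
                          max_halvings = 4, snapshots = 200) {
  stopifnot(dt > 0, cycles >= 1)
  structure(list(dt = dt, cycles = cycles, newton_tol = newton_tol,
                 newton_max = newton_max, periodicity_tol = periodicity_tol,
                 max_halvings = max_halvings, snapshots = snapshots),
            class = "solver_config")
}

# ---------------------------------------------------------------------------
# Assemble the static description of the nonlinear system: global unknown
# layout [A1 Q1 A2 Q2 ... | Pc1 Pc2 per terminal], per-vessel geometry, and
# the row map.  Equations: 2 per mesh cell (sub-domain collocation of the
# continuity and momentum equations with a composite trapezoidal rule in
# space), one inflow row at the root, mass + pressure-continuity rows at
# each junction, one coupling row and two lumped-state rows per terminal.
# ---------------------------------------------------------------------------
build_system <- function(mesh, beds, blood, wall) {
  nv <- length(mesh$vessels)
  node_off <- integer(nv)
  g <- 0L
  nodes <- list()
  for (v in seq_len(nv)) {
    n <- length(mesh$vessels[[v]]$x)
    node_off[v] <- g
    g <- g + n
    nodes[[v]] <- list(
      n = n,
      ai = 2L * (node_off[v] + seq_len(n)) - 1L,
      qi = 2L * (node_off[v] + seq_len(n)),
      h = diff(mesh$vessels[[v]]$x),
      A0 = mesh$vessels[[v]]$A0,
      r0 = mesh$vessels[[v]]$r0)
  }
  nnode <- g
  term <- vapply(beds, `[[`, numeric(1), "vessel")
  nt <- length(beds)
  N <- 2L * nnode + 2L * nt
  pc1 <- 2L * nnode + 2L * seq_len(nt) - 1L
  pc2 <- 2L * nnode + 2L * seq_len(nt)

  for (v in seq_len(nv)) {
    nodes[[v]]$c0 <- wave_speed(nodes[[v]]$r0, blood, wall)
    nodes[[v]]$b <- tube_exponent(nodes[[v]]$r0, blood, wall)
  }

  # row allocation
  row <- 0L
  for (v in seq_len(nv)) {
    n <- nodes[[v]]$n
    nodes[[v]]$rc <- row + seq_len(n - 1L)             # continuity rows
    nodes[[v]]$rm <- row + (n - 1L) + seq_len(n - 1L)  # momentum rows
    row <- row + 2L * (n - 1L)
  }
  roots <- mesh$roots
  if (length(roots) != 1L)
    stop("solver expects a single rooted tree per run (one coronary side)")
  row_inlet <- row + 1L
  row <- row + 1L
  junctions <- list()
  for (v in seq_len(nv)) {
    ch <- mesh$vessels[[v]]$children
    if (!length(ch)) next
    jr <- list(parent = v, children = ch,
               row_mass = row + 1L,
               row_pres = row + 1L + seq_along(ch))
    row <- row + 1L + length(ch)
    junctions[[length(junctions) + 1L]] <- jr
  }
  row_term <- row + seq_len(nt)
  row <- row + nt
  row_bed1 <- row + 2L * seq_len(nt) - 1L
  row_bed2 <- row + 2L * seq_len(nt)
  row <- row + 2L * nt
  stopifnot(row == N)
  list(nodes = nodes, nnode = nnode, N = N, nv = nv,
       pc1 = pc1, pc2 = pc2, term = term, nt = nt,
       root = roots, row_inlet = row_inlet, junctions = junctions,
       row_term = row_term, row_bed1 = row_bed1, row_bed2 = row_bed2,
       blood = blood, wall = wall, beds = beds)
}

# residual and Jacobian triplets at state U with time-derivative operator
# Udot = a0*U + hist (a0 = 0 gives the steady problem)
system_residual <- function(sys, U, a0, hist, Qin_t, plvdot, jacobian = TRUE) {
  blood <- sys$blood; wall <- sys$wall
  rho <- blood$rho; mu <- blood$mu
  fric <- 22 * pi * mu / rho
  Udot <- a0 * U + hist
  F <- numeric(sys$N)
  ti <- tj <- integer(0); tx <- numeric(0)
  add <- function(i, j, x) {
    ti <<- c(ti, i); tj <<- c(tj, j); tx <<- c(tx, x)
  }
  Pend <- numeric(sys$nv)       # tube-law pressure at each vessel's ends
  dPend <- numeric(sys$nv)
  Pstart <- numeric(sys$nv)
  dPstart <- numeric(sys$nv)
  gamma <- wall$Gamma

  for (v in seq_len(sys$nv)) {
    nd <- sys$nodes[[v]]
    A <- U[nd$ai]; Q <- U[nd$qi]
    if (any(A <= 0))
      stop(sprintf("solver abort: non-positive area at vessel %d node %d",
                   v, which(A <= 0)[1]))
    Adot <- Udot[nd$ai]; Qdot <- Udot[nd$qi]
    tl <- tube_law_terms(A, nd$A0, nd$c0, nd$b, rho, wall$P0, wall$Pext)
    P <- tl$p + gamma / (nd$A0 * sqrt(nd$A0)) * Adot
    dPdA <- tl$dpda + gamma / (nd$A0 * sqrt(nd$A0)) * a0
    n <- nd$n
    i1 <- 1:(n - 1); i2 <- 2:n
    h <- nd$h
    # continuity
    F[nd$rc] <- 0.5 * (Adot[i1] + Adot[i2]) + (Q[i2] - Q[i1]) / h
    # momentum
    QA <- Q^2 / A
    Abar <- 0.5 * (A[i1] + A[i2])
    QoA <- Q / A
    F[nd$rm] <- 0.5 * (Qdot[i1] + Qdot[i2]) + (QA[i2] - QA[i1]) / h +
      Abar / rho * (P[i2] - P[i1]) / h + fric * 0.5 * (QoA[i1] + QoA[i2])
    if (jacobian) {
      # continuity rows
      add(nd$rc, nd$ai[i1], rep(0.5 * a0, n - 1))
      add(nd$rc, nd$ai[i2], rep(0.5 * a0, n - 1))
      add(nd$rc, nd$qi[i1], -1 / h)
      add(nd$rc, nd$qi[i2], 1 / h)
      # momentum rows
      dP <- (P[i2] - P[i1])
      add(nd$rm, nd$qi[i1], 0.5 * a0 - 2 * QoA[i1] / h + fric * 0.5 / A[i1])
      add(nd$rm, nd$qi[i2], 0.5 * a0 + 2 * QoA[i2] / h + fric * 0.5 / A[i2])
      add(nd$rm, nd$ai[i1], QA[i1] / (A[i1] * h) + 0.5 / rho * dP / h -
            Abar / rho * dPdA[i1] / h - fric * 0.5 * QoA[i1] / A[i1])
      add(nd$rm, nd$ai[i2], -QA[i2] / (A[i2] * h) + 0.5 / rho * dP / h +
            Abar / rho * dPdA[i2] / h - fric * 0.5 * QoA[i2] / A[i2])
    }
    Pstart[v] <- P[1]; dPstart[v] <- dPdA[1]
    Pend[v] <- P[n]; dPend[v] <- dPdA[n]
  }

  # inflow at the root
  root <- sys$root
  q1 <- sys$nodes[[root]]$qi[1]
  F[sys$row_inlet] <- U[q1] - Qin_t
  if (jacobian) add(sys$row_inlet, q1, 1)

  # junctions: mass conservation + static pressure continuity
  for (jn in sys$junctions) {
    p <- jn$parent
    np <- sys$nodes[[p]]$n
    qp <- sys$nodes[[p]]$qi[np]
    ap <- sys$nodes[[p]]$ai[np]
    qs <- vapply(jn$children, function(c) sys$nodes[[c]]$qi[1], integer(1))
    F[jn$row_mass] <- U[qp] - sum(U[qs])
    if (jacobian) {
      add(jn$row_mass, qp, 1)
      add(rep(jn$row_mass, length(qs)), qs, rep(-1, length(qs)))
    }
    for (ci in seq_along(jn$children)) {
      cv <- jn$children[ci]
      F[jn$row_pres[ci]] <- Pstart[cv] - Pend[p]
      if (jacobian) {
        add(jn$row_pres[ci], sys$nodes[[cv]]$ai[1], dPstart[cv])
        add(jn$row_pres[ci], ap, -dPend[p])
      }
    }
  }

  # terminals: 1D/0D coupling + lumped states
  for (k in seq_len(sys$nt)) {
    bed <- sys$beds[[k]]
    v <- sys$term[k]
    n <- sys$nodes[[v]]$n
    qn <- sys$nodes[[v]]$qi[n]
    an <- sys$nodes[[v]]$ai[n]
    Pc1 <- U[sys$pc1[k]]; Pc2 <- U[sys$pc2[k]]
    Pc1dot <- Udot[sys$pc1[k]]; Pc2dot <- Udot[sys$pc2[k]]
    F[sys$row_term[k]] <- U[qn] - (Pend[v] - Pc1) / bed$R1
    F[sys$row_bed1[k]] <- bed$C1 * Pc1dot - U[qn] + (Pc1 - Pc2) / bed$R2
    F[sys$row_bed2[k]] <- bed$C2 * (Pc2dot - plvdot[k]) -
      (Pc1 - Pc2) / bed$R2 + (Pc2 - bed$Pven) / bed$R3
    if (jacobian) {
      add(sys$row_term[k], qn, 1)
      add(sys$row_term[k], an, -dPend[v] / bed$R1)
      add(sys$row_term[k], sys$pc1[k], 1 / bed$R1)
      add(sys$row_bed1[k], sys$pc1[k], bed$C1 * a0 + 1 / bed$R2)
      add(sys$row_bed1[k], sys$pc2[k], -1 / bed$R2)
      add(sys$row_bed1[k], qn, -1)
      add(sys$row_bed2[k], sys$pc2[k], bed$C2 * a0 + 1 / bed$R2 + 1 / bed$R3)
      add(sys$row_bed2[k], sys$pc1[k], -1 / bed$R2)
    }
  }
  list(F = F, i = ti, j = tj, x = tx)
}

# one Newton solve; returns updated U or signals non-convergence
newton_solve <- function(sys, U, a0, hist, Qin_t, plvdot, scale, tol, maxit) {
  for (it in seq_len(maxit)) {
    res <- system_residual(sys, U, a0, hist, Qin_t, plvdot)
    # equilibrate: columns by the unknown scales, rows by their largest
    # entry, so the rigid-wall limit (tube-law stiffness ~ 1e13) stays
    # solvable by sparse LU
    xs <- res$x * scale[res$j]
    rmax <- rep(1e-300, sys$N)
    ax <- abs(xs)
    agg <- tapply(ax, res$i, max)
    rmax[as.integer(names(agg))] <- agg
    J <- Matrix::sparseMatrix(i = res$i, j = res$j, x = xs / rmax[res$i],
                              dims = c(sys$N, sys$N))
    dU <- tryCatch(scale * as.numeric(Matrix::solve(J, -res$F / rmax)),
                   error = function(e) NULL)
    if (is.null(dU)) return(NULL)
    # damped update keeping areas positive
    lam <- 1
    ai_all <- unlist(lapply(sys$nodes, `[[`, "ai"))
    repeat {
      Unew <- U + lam * dU
      if (all(Unew[ai_all] > 0) || lam < 1e-4) break
      lam <- lam / 2
    }
    U <- Unew
    if (max(abs(lam * dU) / scale) < tol) return(U)
  }
  NULL
}

#' Solve the coupled 1D-0D system on a coronary tree
#'
#' Implicit solution of the 1D continuity and momentum equations closed by
#' the elastic tube law, with prescribed periodic inflow at the root and a
#' three-resistance / two-compliance coronary Windkessel bed at every
#' terminal.  Space is discretised by sub-domain collocation (composite
#' trapezoidal rule over each mesh cell); time by second-order backward
#' differences (first step backward Euler), and each step's nonlinear
#' system is solved by a damped Newton iteration on the full set of
#' unknowns, so junction mass balance and pressure continuity hold to
#' solver precision at every step.  The run stops after `cycles` cycles or
#' as soon as the inlet pressure of consecutive cycles agrees within the
#' periodicity tolerance.
#'
#' @param mesh a [mesh1d()] (single rooted tree: one coronary side).
#' @param inflow an [inflow_waveform()] (pulsatile mode) or a single number
#'   (steady inflow, cm^3/s).
#' @param beds list of `windkessel_bed`s from [distribute_terminals()].
#' @param blood a [blood_properties()].
#' @param wall a [wall_law()].
#' @param config a [solver_config()].
#' @param mode `"pulsatile"` or `"steady"`.  Steady mode drops the time
#'   derivatives and solves directly for the equilibrium.
#' @return an object of class `ffr_solution`: node table (`vessel`, `x`,
#'   `r0`), cycle-mean `P_mean`/`Q_mean`/`A_mean` per node, snapshot arrays
#'   `P`, `Q`, `A` (nodes x times) with `times`, the inlet pressure series,
#'   the maximum relative junction mass imbalance, and per-cycle
#'   periodicity measures.
#' @export
solve_1d0d <- function(mesh, inflow, beds, blood = blood_properties(),
                       wall = wall_law(), config = solver_config(),
                       mode = c("pulsatile", "steady")) {
  mode <- match.arg(mode)
  stopifnot(inherits(mesh, "mesh1d"))
  sys <- build_system(mesh, beds, blood, wall)

  if (inherits(inflow, "inflow_waveform")) {
    Qfun <- inflow_function(inflow)
    s <- inflow$samples
    Qmean <- sum((s$Q[-1] + s$Q[-nrow(s)]) / 2 * diff(s$t)) / inflow$period
    period <- inflow$period
  } else if (is.function(inflow)) {
    # analytic waveform: function of time with a "period" attribute
    Qfun <- inflow
    period <- attr(inflow, "period")
    if (is.null(period)) stop("function inflow needs a 'period' attribute")
    tgrid <- seq(0, period, length.out = 401)
    Qmean <- mean(Qfun(tgrid[-1]))
  } else {
    Qmean <- as.numeric(inflow)
    Qfun <- function(t) rep(Qmean, length(t))
    period <- NA_real_
  }

  # initial state: areas at reference, flows by downstream Murray fraction,
  # bed states at their steady values for the mean flow
  U <- numeric(sys$N)
  downstream <- numeric(sys$nv)
  for (k in seq_len(sys$nt)) {
    v <- sys$term[k]
    repeat {
      downstream[v] <- downstream[v] + sys$beds[[k]]$fraction
      v <- mesh$vessels[[v]]$parent
      if (v == 0) break
    }
  }
  for (v in seq_len(sys$nv)) {
    U[sys$nodes[[v]]$ai] <- sys$nodes[[v]]$A0
    U[sys$nodes[[v]]$qi] <- Qmean * downstream[v]
  }
  for (k in seq_len(sys$nt)) {
    bed <- sys$beds[[k]]
    Qk <- Qmean * bed$fraction
    U[sys$pc2[k]] <- bed$Pven + Qk * bed$R3
    U[sys$pc1[k]] <- U[sys$pc2[k]] + Qk * bed$R2
  }
  scale <- numeric(sys$N)
  for (v in seq_len(sys$nv)) {
    scale[sys$nodes[[v]]$ai] <- sys$nodes[[v]]$A0
    scale[sys$nodes[[v]]$qi] <- max(abs(Qmean), 0.1)
  }
  scale[c(sys$pc1, sys$pc2)] <- max(wall$P0, mmHg_to_dyn(10))

  node_tab <- do.call(rbind, lapply(seq_len(sys$nv), function(v)
    data.frame(vessel = v, id = mesh$vessels[[v]]$id,
               node = seq_len(sys$nodes[[v]]$n),
               x = mesh$vessels[[v]]$x,
               r0 = sys$nodes[[v]]$r0, A0 = sys$nodes[[v]]$A0)))
  ai_all <- unlist(lapply(sys$nodes, `[[`, "ai"))
  qi_all <- unlist(lapply(sys$nodes, `[[`, "qi"))
  pressures_of <- function(U) {
    p <- numeric(sys$nnode)
    pos <- 0L
    for (v in seq_len(sys$nv)) {
      nd <- sys$nodes[[v]]
      tl <- tube_law_terms(U[nd$ai], nd$A0, nd$c0, nd$b, blood$rho,
                           wall$P0, wall$Pext)
      p[pos + seq_len(nd$n)] <- tl$p
      pos <- pos + nd$n
    }
    p
  }
  junction_imbalance <- function(U) {
    if (!length(sys$junctions)) return(0)
    max(vapply(sys$junctions, function(jn) {
      np <- sys$nodes[[jn$parent]]$n
      qp <- U[sys$nodes[[jn$parent]]$qi[np]]
      qs <- sum(vapply(jn$children, function(c) U[sys$nodes[[c]]$qi[1]],
                       numeric(1)))
      abs(qp - qs) / max(abs(qp), 1e-12)
    }, numeric(1)))
  }

  # steady solve (also the initial condition of a pulsatile run, taken at
  # Q(0) so the inflow is continuous across the start)
  plv0 <- rep(0, sys$nt)
  Q0 <- if (mode == "pulsatile") Qfun(0)[1] else Qmean
  Ust <- newton_solve(sys, U, 0, numeric(sys$N), Q0, plv0, scale,
                      config$newton_tol, 4 * config$newton_max)
  if (is.null(Ust))
    stop("Newton iteration failed on the steady problem")
  U <- Ust

  if (mode == "steady") {
    P <- pressures_of(U)
    sol <- list(mode = "steady", nodes = node_tab,
                P_mean = P, Q_mean = U[qi_all], A_mean = U[ai_all],
                P = matrix(P), Q = matrix(U[qi_all]), A = matrix(U[ai_all]),
                times = 0, inlet_series = NULL,
                junction_imbalance = junction_imbalance(U),
                periodicity = numeric(0), cycles_run = 0L,
                mesh = mesh, beds = beds, config = config,
                root_inlet = which(node_tab$vessel == sys$root)[1])
    class(sol) <- "ffr_solution"
    return(sol)
  }

  dt <- config$dt
  nstep <- max(2L, as.integer(round(period / dt)))
  dt <- period / nstep
  snap_every <- max(1L, nstep %/% config$snapshots)
  plv_hist <- matrix(0, 3, sys$nt)   # PLV at t_new, t_n, t_nm1 per bed
  for (k in seq_len(sys$nt)) plv_hist[, k] <- sys$beds[[k]]$PLV(0)

  Uprev <- U; Uprev2 <- NULL
  inlet_q1 <- sys$nodes[[sys$root]]$ai[1]
  inlet_p_cycle <- numeric(nstep)
  prev_cycle_inlet <- NULL
  periodicity <- numeric(0)
  max_imb <- 0
  snap_t <- c(); snap_P <- list(); snap_Q <- list(); snap_A <- list()
  Psum <- numeric(sys$nnode); Qsum <- numeric(sys$nnode)
  Asum <- numeric(sys$nnode)

  for (cyc in seq_len(config$cycles)) {
    Psum[] <- 0; Qsum[] <- 0; Asum[] <- 0
    snap_t <- c(); snap_P <- list(); snap_Q <- list(); snap_A <- list()
    for (st in seq_len(nstep)) {
      t_new <- (cyc - 1) * period + st * dt
      if (is.null(Uprev2)) {            # backward Euler start
        a0 <- 1 / dt
        hist <- -Uprev / dt
      } else {                          # BDF2
        a0 <- 1.5 / dt
        hist <- (-2 * Uprev + 0.5 * Uprev2) / dt
      }
      plv_new <- vapply(sys$beds, function(b) b$PLV(t_new), numeric(1))
      plvdot <- if (is.null(Uprev2)) (plv_new - plv_hist[2, ]) / dt
                else (1.5 * plv_new - 2 * plv_hist[2, ] + 0.5 * plv_hist[3, ]) / dt
      Unew <- newton_solve(sys, Uprev, a0, hist, Qfun(t_new), plvdot, scale,
                           config$newton_tol, config$newton_max)
      if (is.null(Unew)) {
        # sub-step fallback: backward Euler micro-steps
        ok <- FALSE
        for (halve in seq_len(config$max_halvings)) {
          nsub <- 2^halve
          Usub <- Uprev
          tsub0 <- t_new - dt
          good <- TRUE
          for (ss in seq_len(nsub)) {
            hsub <- dt / nsub
            tss <- tsub0 + ss * hsub
            plvd <- (vapply(sys$beds, function(b) b$PLV(tss), numeric(1)) -
                     vapply(sys$beds, function(b) b$PLV(tss - hsub), numeric(1))) / hsub
            Usub <- newton_solve(sys, Usub, 1 / hsub, -Usub / hsub,
                                 Qfun(tss), plvd, scale,
                                 config$newton_tol, config$newton_max)
            if (is.null(Usub)) { good <- FALSE; break }
          }
          if (good) { Unew <- Usub; Uprev2 <- NULL; ok <- TRUE; break }
        }
        if (!ok) {
          res <- system_residual(sys, Uprev, a0, hist, Qfun(t_new), plvdot,
                                 jacobian = FALSE)
          stop(sprintf(paste0("Newton failed at t = %.5f s after %d dt ",
                              "halvings; max |residual| = %.3g"),
                       t_new, config$max_halvings, max(abs(res$F))))
        }
      } else {
        Uprev2 <- Uprev
      }
      Uprev <- Unew
      max_imb <- max(max_imb, junction_imbalance(Unew))
      P <- pressures_of(Unew)
      Psum <- Psum + P; Qsum <- Qsum + Unew[qi_all]; Asum <- Asum + Unew[ai_all]
      inlet_p_cycle[st] <- P[if (sys$root == 1) 1L else
        sum(vapply(sys$nodes[seq_len(sys$root - 1)], `[[`, integer(1), "n")) + 1L]
      if (st %% snap_every == 0) {
        snap_t <- c(snap_t, t_new)
        snap_P[[length(snap_P) + 1L]] <- P
        snap_Q[[length(snap_Q) + 1L]] <- Unew[qi_all]
        snap_A[[length(snap_A) + 1L]] <- Unew[ai_all]
      }
      plv_hist[3, ] <- plv_hist[2, ]
      plv_hist[2, ] <- plv_new
    }
    if (!is.null(prev_cycle_inlet)) {
      rel <- sqrt(sum((inlet_p_cycle - prev_cycle_inlet)^2)) /
        sqrt(sum(prev_cycle_inlet^2))
      periodicity <- c(periodicity, rel)
      if (rel < config$periodicity_tol && cyc < config$cycles) {
        prev_cycle_inlet <- inlet_p_cycle
        # run one more cycle to report converged-cycle fields? fields of
        # this cycle are already periodic within tolerance: stop here.
        break
      }
    }
    prev_cycle_inlet <- inlet_p_cycle
    inlet_p_cycle <- numeric(nstep)
    last_cycle <- cyc
  }
  cycles_run <- length(periodicity) + 1L

  sol <- list(mode = "pulsatile", nodes = node_tab,
              P_mean = Psum / nstep, Q_mean = Qsum / nstep,
              A_mean = Asum / nstep,
              P = do.call(cbind, snap_P), Q = do.call(cbind, snap_Q),
              A = do.call(cbind, snap_A), times = snap_t,
              inlet_series = prev_cycle_inlet,
              junction_imbalance = max_imb,
              periodicity = periodicity, cycles_run = cycles_run,
              dt = dt, period = period,
              mesh = mesh, beds = beds, config = config,
              root_inlet = which(node_tab$vessel == sys$root)[1])
  class(sol) <- "ffr_solution"
  sol
}

#' @export
print.ffr_solution <- function(x, ...) {
  cat(sprintf("<ffr_solution> %s, %d nodes", x$mode, nrow(x$nodes)))
  if (x$mode == "pulsatile")
    cat(sprintf(", %d cycle(s), periodicity %s", x$cycles_run,
                paste(sprintf("%.2e", x$periodicity), collapse = " ")))
  cat(sprintf("\n  inlet P_mean %.1f mmHg, junction imbalance %.2e\n",
              dyn_to_mmHg(x$P_mean[x$root_inlet]), x$junction_imbalance))
  invisible(x)
}

#' @export
summary.ffr_solution <- function(object, ...) {
  nd <- object$nodes
  nd$P_mean_mmHg <- dyn_to_mmHg(object$P_mean)
  nd$Q_mean <- object$Q_mean
  sp <- split(nd, nd$vessel)
  cat(sprintf("Solution over %d vessel(s):\n", length(sp)))
  for (s in sp) {
    cat(sprintf("  %s: P %.1f -> %.1f mmHg, Q %.3g -> %.3g cm^3/s\n",
                s$id[1], s$P_mean_mmHg[1], s$P_mean_mmHg[nrow(s)],
                s$Q_mean[1], s$Q_mean[nrow(s)]))
  }
  invisible(nd)
}

#' Plot the cycle-mean pressure profile of a solution
#'
#' Cycle-mean pressure (mmHg) against cumulative arc length from the tree
#' root, one line per vessel.
#'
#' @param x an `ffr_solution`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ffr_solution <- function(x, ...) {
  nd <- x$nodes
  # cumulative arc length: vessel offset = parent end position
  off <- numeric(length(x$mesh$vessels))
  for (v in seq_along(x$mesh$vessels)) {
    p <- x$mesh$vessels[[v]]$parent
    off[v] <- if (p == 0) 0 else off[p] + x$mesh$vessels[[p]]$length
  }
  xs <- nd$x + off[nd$vessel]
  graphics::plot(range(xs), range(dyn_to_mmHg(x$P_mean)), type = "n",
                 xlab = "arc length from root (cm)",
                 ylab = "cycle-mean pressure (mmHg)", ...)
  for (v in unique(nd$vessel)) {
    sel <- nd$vessel == v
    graphics::lines(xs[sel], dyn_to_mmHg(x$P_mean[sel]), col = v)
  }
  invisible(x)
}

#' Computed fractional flow reserve at a location
#'
#' `cFFR = Pd / Pa`: the cycle-mean pressure at the query location divided
#' by the cycle-mean pressure at the inlet of the coronary tree the
#' location belongs to.  By convention the default query point is the node
#' of minimum reference radius (the stenosis throat).
#'
#' @param sol an `ffr_solution`.
#' @param location `NULL` (minimum-radius node), a node index, or a list
#'   `list(vessel =, x =)` naming a vessel (index or id) and an arc-length
#'   position in cm.
#' @return an object of class `cffr_result` with `cffr`, `Pd_mean`,
#'   `Pa_mean` (mmHg), `vessel`, `x`.
#' @export
compute_cffr <- function(sol, location = NULL) {
  stopifnot(inherits(sol, "ffr_solution"))
  nd <- sol$nodes
  if (is.null(location)) {
    node <- which.min(nd$r0)
  } else if (is.numeric(location) && length(location) == 1) {
    node <- as.integer(location)
    if (node < 1 || node > nrow(nd))
      stop("location outside mesh; valid nodes are 1..", nrow(nd),
           " in vessels ", paste(unique(nd$id), collapse = ", "))
  } else {
    v <- location$vessel
    if (is.character(v)) {
      vi <- match(v, vapply(sol$mesh$vessels, `[[`, character(1), "id"))
      if (is.na(vi))
        stop("location outside mesh; valid vessel ids: ",
             paste(vapply(sol$mesh$vessels, `[[`, character(1), "id"),
                   collapse = ", "))
      v <- vi
    }
    if (v < 1 || v > length(sol$mesh$vessels))
      stop("location outside mesh; valid vessel ids: ",
           paste(vapply(sol$mesh$vessels, `[[`, character(1), "id"),
                 collapse = ", "))
    sel <- which(nd$vessel == v)
    node <- sel[which.min(abs(nd$x[sel] - location$x))]
  }
  Pa <- sol$P_mean[sol$root_inlet]
  Pd <- sol$P_mean[node]
  structure(list(cffr = Pd / Pa,
                 Pd_mean = dyn_to_mmHg(Pd), Pa_mean = dyn_to_mmHg(Pa),
                 vessel = nd$id[node], x = nd$x[node], node = node),
            class = "cffr_result")
}

#' @export
print.cffr_result <- function(x, ...) {
  cat(sprintf("cFFR = %.3f at %s, x = %.2f cm (Pd %.1f / Pa %.1f mmHg)\n",
              x$cffr, x$vessel, x$x, x$Pd_mean, x$Pa_mean))
  invisible(x)
}
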