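# Reduced-order 0D/1D network solver.
#
# The 3-D field problem is replaced by a nodal network: generalized
# Poiseuille viscous resistance integrated from d(s), Young-Tsai quadratic
# losses at lumen narrowings, and three-element Windkessel ODEs at the
# terminals. Pressure drop on an edge is dP = R*Q + K2*Q*|Q|, which is
# monotone in Q and inverted in closed form, so the nodal equations are
# solved by damped Newton iteration with an analytic Jacobian.

# Locate quadratic (convective) loss terms on a lumen profile: every
# interior local diameter minimum that both falls below and recovers above
# its neighbouring maxima by depth_tol counts as a narrowing, with the
# reference area taken at the preceding maximum. A pure taper has no
# recovery and contributes no quadratic loss.
quadratic_loss_terms <- function(s_mm, d_mm, density, kt = 1.52,
                                 depth_tol = 0.02) {
  n <- length(d_mm)
  out <- list()
  if (n < 5L) return(out)
  dd <- diff(d_mm)
  sgn <- sign(dd)
  nz <- which(sgn != 0)
  if (length(nz) < 2L) return(out)
  minima <- integer(0)
  for (k in 2:length(nz)) {
    if (sgn[nz[k - 1]] < 0 && sgn[nz[k]] > 0) {
      rng <- (nz[k - 1] + 1):nz[k]
      minima <- c(minima, rng[which.min(d_mm[rng])])
    }
  }
  prev <- 1L
  for (i in minima) {
    prox_max <- max(d_mm[prev:i])
    nxt <- minima[minima > i]
    hi <- if (length(nxt)) min(nxt) else n
    dist_max <- max(d_mm[i:hi])
    if (prox_max >= d_mm[i] * (1 + depth_tol) &&
        dist_max >= d_mm[i] * (1 + depth_tol)) {
      a_min <- pi * (d_mm[i] / 10)^2 / 4
      a_0 <- pi * (prox_max / 10)^2 / 4
      out[[length(out) + 1L]] <- list(
        s_mm = s_mm[i],
        k2 = kt * (density / 2) * (1 / a_min - 1 / a_0)^2)
      prev <- i
    }
  }
  out
}

# Build the nodal network from a tree: segments are cut at interior branch
# points; each resulting edge carries a resampled sub-profile, its viscous
# resistance (with cumulative profile for pressure evaluation along the
# edge) and its quadratic loss terms.
build_network <- function(tree, ds = 0.25, viscosity = 0.035,
                          density = 1.050, kt = 1.52) {
  edges <- list()
  edges_df <- NULL
  node_of_attach <- list() # segment id -> function of s giving node name
  seg_cutpoints <- list()
  for (id in names(tree$segments)) {
    prof <- tree$segments[[id]]$profile
    s0 <- prof$s_mm[1]
    s1 <- prof$s_mm[length(prof$s_mm)]
    cuts <- c(s0, s1)
    for (k in names(tree$segments)) {
      sg <- tree$segments[[k]]
      if (!is.null(sg$parent) && sg$parent == id && !is.null(sg$branch_s_mm))
        cuts <- c(cuts, sg$branch_s_mm)
    }
    cuts <- sort(unique(round(cuts, 9)))
    seg_cutpoints[[id]] <- cuts
  }
  node_name <- function(seg, s) sprintf("%s@%.6f", seg, s)
  attach_node <- function(seg) {
    # node where segment `seg` starts
    sgm <- tree$segments[[seg]]
    if (is.null(sgm$parent)) return(node_name(seg, seg_cutpoints[[seg]][1]))
    ps <- sgm$branch_s_mm
    if (is.null(ps)) {
      pc <- seg_cutpoints[[sgm$parent]]
      return(node_name(sgm$parent, pc[length(pc)]))
    }
    node_name(sgm$parent, round(ps, 9))
  }
  rows <- list()
  for (id in names(tree$segments)) {
    prof <- tree$segments[[id]]$profile
    f <- stats::splinefun(prof$s_mm, prof$r_mm, method = "monoH.FC")
    cuts <- seg_cutpoints[[id]]
    start_node <- attach_node(id)
    for (j in seq_len(length(cuts) - 1L)) {
      a <- cuts[j]
      b <- cuts[j + 1L]
      ss <- seq(a, b, by = ds)
      if (ss[length(ss)] < b) ss <- c(ss, b)
      dd <- 2 * f(ss)
      dd[dd <= 0] <- min(dd[dd > 0])
      from <- if (j == 1L) start_node else node_name(id, a)
      to <- node_name(id, b)
      integ <- 128 * viscosity / (pi * (dd / 10)^4)
      rcum <- c(0, cumsum(diff(ss / 10) *
                          (utils::head(integ, -1) + utils::tail(integ, -1)) / 2))
      qt <- quadratic_loss_terms(ss, dd, density, kt)
      edges[[length(edges) + 1L]] <- list(
        segment = id, from = from, to = to, s = ss, d = dd,
        r_lin = rcum[length(rcum)], rcum = rcum,
        quad = qt, k2_tot = sum(vapply(qt, function(q) q$k2, 0)),
        d_rep = mean(dd[seq_len(min(3L, length(dd)))]))
      rows[[length(rows) + 1L]] <- data.frame(
        segment = id, from = from, to = to, s_start = a, s_end = b,
        r_lin = rcum[length(rcum)],
        k2_tot = edges[[length(edges)]]$k2_tot,
        d_rep = edges[[length(edges)]]$d_rep)
    }
  }
  edges_df <- do.call(rbind, rows)
  nodes <- unique(c(edges_df$from, edges_df$to))
  out_deg <- table(factor(edges_df$from, levels = nodes))
  inlet_node <- attach_node(tree$inlet)
  terminal_nodes <- setdiff(nodes[out_deg[nodes] == 0], inlet_node)
  node_out <- lapply(nodes, function(n) which(edges_df$from == n))
  node_in <- lapply(nodes, function(n) which(edges_df$to == n))
  names(node_out) <- names(node_in) <- nodes
  list(nodes = nodes, inlet_node = inlet_node, terminal_nodes = terminal_nodes,
       edges = edges, edges_df = edges_df, node_out = node_out,
       node_in = node_in, tree = tree)
}

# Murray's-law flow fractions per edge and per terminal, plus the edge path
# from the inlet to each terminal.
terminal_fractions <- function(net, murray_exponent = 3) {
  edge_fraction <- numeric(nrow(net$edges_df))
  path <- list()
  fraction <- list()
  walk <- function(node, frac, edges_so_far) {
    out <- net$node_out[[node]]
    if (length(out) == 0L) {
      path[[node]] <<- edges_so_far
      fraction[[node]] <<- frac
      return(invisible())
    }
    w <- murray_fractions(net$edges_df$d_rep[out], murray_exponent)
    for (k in seq_along(out)) {
      e <- out[k]
      edge_fraction[e] <<- frac * w[k]
      walk(net$edges_df$to[e], frac * w[k], c(edges_so_far, e))
    }
  }
  walk(net$inlet_node, 1, integer(0))
  list(edge_fraction = edge_fraction, fraction = fraction, path = path)
}

# invert dP = r*q + k2*q|q|  (monotone; closed form)
edge_flow_from_dp <- function(dp, r, k2) {
  if (k2 <= 0) return(dp / r)
  s <- sign(dp)
  s * (-r + sqrt(r * r + 4 * k2 * abs(dp))) / (2 * k2)
}

#' Solver configuration for the pulsatile network solve
#'
#' @param dt time step (s)
#' @param n_cycles maximum number of cardiac cycles to integrate
#' @param periodicity_tol maximum relative change of cycle-mean nodal
#'   pressures between successive cycles accepted as periodic
#' @param newton_tol nonlinear residual tolerance, relative to inlet flow
#' @param newton_maxit maximum Newton iterations per solve
#' @return object of class `solver_config`
#' @export
solver_config <- function(dt = 0.004, n_cycles = 12L, periodicity_tol = 1e-6,
                          newton_tol = 1e-12, newton_maxit = 60L) {
  stopifnot(dt > 0, n_cycles >= 1, periodicity_tol >= 0)
  structure(list(dt = dt, n_cycles = as.integer(n_cycles),
                 periodicity_tol = periodicity_tol, newton_tol = newton_tol,
                 newton_maxit = as.integer(newton_maxit)),
            class = "solver_config")
}

# Match a list of outlets to the network's terminal nodes: either the list
# is already named by terminal node, or it has one entry per terminal and
# is matched in order.
align_outlets <- function(net, outlets) {
  if (all(net$terminal_nodes %in% names(outlets))) return(outlets)
  if (length(outlets) == length(net$terminal_nodes)) {
    names(outlets) <- net$terminal_nodes
    return(outlets)
  }
  stop_ffrct("outlet list (%d) does not match the %d terminal nodes",
             length(outlets), length(net$terminal_nodes),
             class = "ffrct_solver_error")
}

# Damped Newton solve of the nodal equations. Outlet boundary at terminal t:
# Q_out = (P_t - a_t) / b_t  (steady Windkessel: a = p_v, b = rp + rd).
newton_network <- function(net, a_term, b_term, q_in, p_init = NULL,
                           tol = 1e-12, maxit = 60L) {
  nodes <- net$nodes
  nn <- length(nodes)
  idx <- stats::setNames(seq_len(nn), nodes)
  ed <- net$edges_df
  ef <- idx[ed$from]
  et <- idx[ed$to]
  r <- ed$r_lin
  k2 <- ed$k2_tot
  term_i <- idx[net$terminal_nodes]
  a_t <- a_term[net$terminal_nodes]
  b_t <- b_term[net$terminal_nodes]
  inlet_i <- idx[[net$inlet_node]]

  residual <- function(p) {
    dp <- p[ef] - p[et]
    q <- mapply(edge_flow_from_dp, dp, r, k2)
    res <- numeric(nn)
    for (e in seq_along(q)) {
      res[ef[e]] <- res[ef[e]] - q[e]
      res[et[e]] <- res[et[e]] + q[e]
    }
    res[inlet_i] <- res[inlet_i] + q_in
    res[term_i] <- res[term_i] - (p[term_i] - a_t) / b_t
    list(res = res, q = q)
  }
  jac <- function(p, q) {
    g <- 1 / (r + 2 * k2 * abs(q))
    J <- matrix(0, nn, nn)
    for (e in seq_along(q)) {
      J[ef[e], ef[e]] <- J[ef[e], ef[e]] - g[e]
      J[ef[e], et[e]] <- J[ef[e], et[e]] + g[e]
      J[et[e], ef[e]] <- J[et[e], ef[e]] + g[e]
      J[et[e], et[e]] <- J[et[e], et[e]] - g[e]
    }
    for (k in seq_along(term_i))
      J[term_i[k], term_i[k]] <- J[term_i[k], term_i[k]] - 1 / b_t[k]
    J
  }
  p <- if (is.null(p_init)) rep(mean(a_t), nn) else p_init
  rs <- residual(p)
  rn <- max(abs(rs$res)) / max(q_in, 1e-12)
  for (it in seq_len(maxit)) {
    if (rn < tol) break
    J <- jac(p, rs$q)
    step <- tryCatch(solve(J, -rs$res), error = function(e)
      stop_ffrct("singular network Jacobian (residual %.3e)", rn,
                 class = "ffrct_solver_error"))
    lambda <- 1
    for (h in 1:30) {
      p_new <- p + lambda * step
      rs_new <- residual(p_new)
      rn_new <- max(abs(rs_new$res)) / max(q_in, 1e-12)
      if (is.finite(rn_new) && (rn_new < rn || rn_new < tol)) break
      lambda <- lambda / 2
    }
    p <- p_new
    rs <- rs_new
    rn <- rn_new
  }
  if (rn >= tol)
    stop_ffrct("network Newton iteration did not converge (residual %.3e)", rn,
               class = "ffrct_solver_error")
  list(p = p, q = rs$q, residual = rn)
}

#' Steady network solve
#'
#' Solves the steady limit of the reduced-order model: nodal pressures such
#' that flow is conserved at every junction, with series viscous plus
#' stenosis losses on edges and purely resistive outlets
#' `Q = (P - Pv) / (Rp + Rd)`. The nonlinear system is solved by damped
#' Newton iteration; with no quadratic losses it converges in one step.
#'
#' @param tree a [coronary_tree()]
#' @param outlets from [assign_outlets()]
#' @param qbar inlet flow (mL/s), > 0
#' @param props [blood_properties()]
#' @param config [solver_config()]
#' @return object of class `hemodynamic_solution`
#' @export
solve_steady <- function(tree, outlets, qbar, props = blood_properties(),
                         config = solver_config()) {
  if (qbar <= 0)
    stop_ffrct("inlet flow must be positive", class = "ffrct_solver_error")
  net <- attr(outlets, "network") %||%
    build_network(tree, viscosity = props$viscosity, density = props$density)
  outlets <- align_outlets(net, outlets)
  a_term <- vapply(outlets, function(o) o$p_v, 0)
  b_term <- vapply(outlets, function(o) o$rp + o$rd, 0)
  sol <- newton_network(net, a_term, b_term, qbar,
                        tol = config$newton_tol, maxit = config$newton_maxit)
  p <- stats::setNames(sol$p, net$nodes)
  q <- sol$q
  structure(list(network = net, node_pressure = p, edge_flow = q,
                 edge_qabsq = q * abs(q),
                 inlet_pressure = p[[net$inlet_node]],
                 p_v = a_term[[1]], qbar = qbar, converged = TRUE,
                 type = "steady", trace = NULL),
            class = "hemodynamic_solution")
}

#' Pulsatile network solve (BDF2 time integration)
#'
#' Advances the Windkessel outlet states with second-order backward
#' differentiation (implicit Euler on the first step) while solving the
#' nonlinear nodal system at each time level with the inlet flow
#' `Qbar * w(t)`. Integration runs for `n_cycles` cardiac cycles or until
#' the cycle-mean nodal pressures change by less than `periodicity_tol`
#' between successive cycles. States are initialized from the steady
#' solution at the mean flow, so a constant waveform reproduces the steady
#' solve without transient.
#'
#' @param tree a [coronary_tree()]
#' @param outlets from [assign_outlets()]
#' @param inflow an [inflow_model()]
#' @param props [blood_properties()]
#' @param config [solver_config()]
#' @param init optional list with `node_pressure` and `pc` (named numeric)
#'   overriding the steady-state initialization
#' @return object of class `hemodynamic_solution`; cycle means are taken
#'   over the last completed cycle, and `trace` holds the full time series
#'   of nodal pressures and Windkessel states
#' @export
solve_unsteady <- function(tree, outlets, inflow, props = blood_properties(),
                           config = solver_config(), init = NULL) {
  net <- attr(outlets, "network") %||%
    build_network(tree, viscosity = props$viscosity, density = props$density)
  outlets <- align_outlets(net, outlets)
  period <- inflow$period
  n_t <- max(2L, round(period / config$dt))
  dt <- period / n_t
  qbar <- inflow$qbar_ml_s
  w <- inflow$waveform
  terms <- net$terminal_nodes
  rp <- vapply(outlets[terms], function(o) o$rp, 0)
  rd <- vapply(outlets[terms], function(o) o$rd, 0)
  cc <- vapply(outlets[terms], function(o) o$c, 0)
  pv <- vapply(outlets[terms], function(o) o$p_v, 0)

  steady <- solve_steady(tree, outlets, qbar, props, config)
  p <- steady$node_pressure
  q_term <- (p[terms] - pv) / (rp + rd)
  pc <- pv + q_term * rd
  if (!is.null(init)) {
    if (!is.null(init$node_pressure)) p <- init$node_pressure
    if (!is.null(init$pc)) pc <- init$pc[terms]
  }
  pc_hist1 <- pc   # previous value
  pc_hist2 <- pc   # value before that
  first_step <- TRUE

  n_steps <- n_t * config$n_cycles
  trace_t <- numeric(n_steps)
  trace_p <- matrix(NA_real_, n_steps, length(net$nodes),
                    dimnames = list(NULL, net$nodes))
  trace_pc <- matrix(NA_real_, n_steps, length(terms),
                     dimnames = list(NULL, terms))
  ne <- nrow(net$edges_df)
  mean_prev <- NULL
  converged <- FALSE
  cyc_p <- matrix(0, n_t, length(net$nodes))
  cyc_q <- matrix(0, n_t, ne)
  last_means <- NULL

  step <- 0L
  for (cyc in seq_len(config$n_cycles)) {
    for (k in seq_len(n_t)) {
      step <- step + 1L
      t_now <- step * dt
      beta <- if (first_step) dt else 2 * dt / 3
      hist <- if (first_step) pc_hist1 else (4 * pc_hist1 - pc_hist2) / 3
      a_t <- numeric(length(terms))
      b_t <- numeric(length(terms))
      for (i in seq_along(terms)) {
        if (cc[i] > 0) {
          D <- 1 + beta / (rd[i] * cc[i])
          a_t[i] <- (hist[i] + beta * pv[i] / (rd[i] * cc[i])) / D
          b_t[i] <- rp[i] + (beta / cc[i]) / D
        } else {
          a_t[i] <- pv[i]
          b_t[i] <- rp[i] + rd[i]
        }
      }
      names(a_t) <- names(b_t) <- terms
      q_in <- qbar * w(t_now)
      sol <- newton_network(net, a_t, b_t, q_in, p_init = unname(p),
                            tol = config$newton_tol, maxit = config$newton_maxit)
      p <- stats::setNames(sol$p, net$nodes)
      q_term <- (p[terms] - a_t) / b_t
      pc_new <- numeric(length(terms))
      for (i in seq_along(terms)) {
        if (cc[i] > 0) {
          D <- 1 + beta / (rd[i] * cc[i])
          pc_new[i] <- (hist[i] + beta * (q_term[i] / cc[i] +
                                          pv[i] / (rd[i] * cc[i]))) / D
        } else pc_new[i] <- pv[i] + q_term[i] * rd[i]
      }
      pc_hist2 <- pc_hist1
      pc_hist1 <- pc_new
      first_step <- FALSE
      trace_t[step] <- t_now
      trace_p[step, ] <- p
      trace_pc[step, ] <- pc_new
      cyc_p[k, ] <- p
      cyc_q[k, ] <- sol$q
    }
    means <- colMeans(cyc_p)
    if (!is.null(mean_prev)) {
      rel <- max(abs(means - mean_prev)) / max(abs(means))
      if (rel < config$periodicity_tol) {
        converged <- TRUE
        last_means <- means
        break
      }
    }
    mean_prev <- means
    last_means <- means
  }
  if (!converged)
    warning(sprintf(paste0("pulsatile solve did not reach periodicity in %d ",
                           "cycles (tolerance %.1e)"),
                    config$n_cycles, config$periodicity_tol))
  used <- seq_len(step)
  structure(list(network = net,
                 node_pressure = stats::setNames(last_means, net$nodes),
                 edge_flow = colMeans(cyc_q),
                 edge_qabsq = colMeans(cyc_q * abs(cyc_q)),
                 inlet_pressure = last_means[[which(net$nodes == net$inlet_node)]],
                 p_v = pv[[1]], qbar = qbar, converged = converged,
                 type = "unsteady",
                 trace = list(time = trace_t[used],
                              node_pressure = trace_p[used, , drop = FALSE],
                              pc = trace_pc[used, , drop = FALSE],
                              dt = dt)),
            class = "hemodynamic_solution")
}

#' @export
print.hemodynamic_solution <- function(x, ...) {
  cat(sprintf("<hemodynamic_solution> %s, inlet %.2f mmHg, inlet flow %.3f mL/s, converged: %s\n",
              x$type, x$inlet_pressure / MMHG, x$qbar, x$converged))
  invisible(x)
}

# cycle-mean pressure at (segment, s) from a solution
pressure_at <- function(solution, segment, s) {
  ed <- solution$network$edges_df
  cand <- which(ed$segment == segment & ed$s_start - 1e-9 <= s &
                  ed$s_end + 1e-9 >= s)
  if (length(cand) == 0L)
    stop_ffrct("location (%s, %.2f mm) is outside the tree", segment, s,
               class = "ffrct_solver_error")
  e <- cand[1]
  edge <- solution$network$edges[[e]]
  p_from <- solution$node_pressure[[edge$from]]
  rc <- stats::approx(edge$s, edge$rcum, xout = s, rule = 2)$y
  qm <- solution$edge_flow[e]
  qq <- solution$edge_qabsq[e]
  drop <- rc * qm
  for (qt in edge$quad) if (qt$s_mm <= s) drop <- drop + qt$k2 * qq
  p_from - drop
}

#' Fractional flow reserve at a location
#'
#' `FFR = (mean pressure at the location - Pv) / (mean inlet pressure - Pv)`,
#' from cycle-mean pressures (steady values in the steady limit). With the
#' default Pv = 0 this is the pure distal-to-aortic pressure ratio Pd/Pa.
#'
#' @param solution a `hemodynamic_solution`
#' @param segment segment id
#' @param s arc length on the segment (mm)
#' @return FFR, dimensionless in (0, 1] under forward flow
#' @export
compute_ffr <- function(solution, segment, s) {
  if (!isTRUE(solution$converged))
    warning("solution is not converged; FFR may be inaccurate")
  pd <- pressure_at(solution, segment, s)
  (pd - solution$p_v) / (solution$inlet_pressure - solution$p_v)
}

#' FFR profile along every segment
#'
#' @param solution a `hemodynamic_solution`
#' @return data frame with columns `segment`, `s_mm`, `ffr`
#' @export
ffr_profile <- function(solution) {
  net <- solution$network
  rows <- list()
  denom <- solution$inlet_pressure - solution$p_v
  for (e in seq_along(net$edges)) {
    edge <- net$edges[[e]]
    p_from <- solution$node_pressure[[edge$from]]
    qm <- solution$edge_flow[e]
    qq <- solution$edge_qabsq[e]
    drop <- edge$rcum * qm
    for (qt in edge$quad) drop <- drop + ifelse(edge$s >= qt$s_mm, qt$k2 * qq, 0)
    rows[[e]] <- data.frame(segment = edge$segment, s_mm = edge$s,
                            ffr = (p_from - drop - solution$p_v) / denom)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a solution as CSV files
#'
#' Writes the FFR profile (`segment, s_mm, ffr`) and, for pulsatile
#' solutions, the nodal pressure time series in mmHg.
#'
#' @param solution a `hemodynamic_solution`
#' @param ffr_path path for the FFR-profile CSV
#' @param trace_path optional path for the time-series CSV
#' @return `ffr_path`, invisibly
#' @export
write_solution_csv <- function(solution, ffr_path, trace_path = NULL) {
  utils::write.csv(ffr_profile(solution), ffr_path, row.names = FALSE)
  if (!is.null(trace_path) && !is.null(solution$trace)) {
    tr <- data.frame(time_s = solution$trace$time,
                     solution$trace$node_pressure / MMHG, check.names = FALSE)
    utils::write.csv(tr, trace_path, row.names = FALSE)
  }
  invisible(ffr_path)
}
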