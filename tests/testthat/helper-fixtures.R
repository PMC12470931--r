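# Fixtures built in code: simple vessels with known closed-form behaviour.

# straight tube, uniform diameter
tube_tree <- function(d_mm = 3, len_mm = 100, vm = 120, ds = 1) {
  s <- seq(0, len_mm, by = ds)
  if (s[length(s)] < len_mm) s <- c(s, len_mm)
  coronary_tree(list(main = list(
    profile = centerline_profile(s, rep(d_mm / 2, length(s))), parent = NULL)),
    inlet = "main", myocardial_volume_ml = vm)
}

# cosine narrowing multiplier over (a, b) with given fractional depth
cosine_narrowed_d <- function(s, d0, a, b, depth) {
  d <- rep(d0, length(s))
  inside <- s >= a & s <= b
  d[inside] <- d0 * (1 - depth * (1 - cos(2 * pi * (s[inside] - a) / (b - a))) / 2)
  d
}

# tube with one cosine lesion
lesion_tree <- function(d0 = 3, len = 100, a = 40, b = 60, depth = 0.5,
                        vm = 120, ds = 0.5) {
  s <- seq(0, len, by = ds)
  if (s[length(s)] < len) s <- c(s, len)
  d <- cosine_narrowed_d(s, d0, a, b, depth)
  coronary_tree(list(main = list(
    profile = centerline_profile(s, d / 2), parent = NULL)),
    inlet = "main", myocardial_volume_ml = vm)
}

# symmetric bifurcation: parent plus two identical daughters
bifurcation_tree <- function(d_parent = 3.5, d_child = 2.5, vm = 120) {
  s_p <- seq(0, 40, 1)
  s_c <- seq(0, 40, 1)
  coronary_tree(list(
    parent = list(profile = centerline_profile(s_p, rep(d_parent / 2, 41)),
                  parent = NULL),
    left = list(profile = centerline_profile(s_c, rep(d_child / 2, 41)),
                parent = "parent"),
    right = list(profile = centerline_profile(s_c, rep(d_child / 2, 41)),
                 parent = "parent")),
    inlet = "parent", myocardial_volume_ml = vm)
}

# hyperemic steady FFR at a site, building everything from the tree
steady_ffr <- function(tree, segment, s, hyperemia_factor = 0.24,
                       constant_waveform = TRUE) {
  inflow <- inflow_model(tree$myocardial_volume_ml,
                         waveform = aortic_waveform(constant = TRUE))
  outlets <- assign_outlets(tree, inflow, hyperemia_factor = hyperemia_factor)
  sol <- solve_steady(tree, outlets, inflow$qbar_ml_s)
  compute_ffr(sol, segment, s)
}

# independent brute-force Passing-Bablok oracle: literal double loop over
# pairs, sort all slopes, index the defined ranks
pb_bruteforce <- function(x, y, conf = 0.95) {
  n <- length(x)
  slopes <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]
    dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) next
    s_ij <- if (dx == 0) (if (dy > 0) Inf else -Inf) else dy / dx
    if (s_ij == -1) next
    slopes <- c(slopes, s_ij)
  }
  slopes <- sort(slopes)
  N <- length(slopes)
  K <- sum(slopes < -1)
  slope <- if (N %% 2 == 1) slopes[(N + 1) / 2 + K] else
    (slopes[N / 2 + K] + slopes[N / 2 + 1 + K]) / 2
  z <- qnorm(1 - (1 - conf) / 2)
  C <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- max(1, min(N, floor((N - C) / 2) + K))
  m2 <- max(1, min(N, ceiling((N + C) / 2) + K))
  list(slope = slope, slope_ci = c(slopes[m1], slopes[m2]),
       intercept = median(y - slope * x))
}

# exact null distribution of the signed-rank statistic by full enumeration
# of all sign patterns (independent of psignrank)
signed_rank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}

# junction mass-conservation residual relative to inlet flow
junction_residual <- function(sol) {
  net <- sol$network
  interior <- setdiff(net$nodes, c(net$inlet_node, net$terminal_nodes))
  if (length(interior) == 0L) return(0)
  worst <- 0
  for (nd in interior) {
    flux <- sum(sol$edge_flow[net$node_in[[nd]]]) -
      sum(sol$edge_flow[net$node_out[[nd]]])
    worst <- max(worst, abs(flux))
  }
  worst / sol$qbar
}
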