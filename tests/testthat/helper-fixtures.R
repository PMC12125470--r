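# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written with different discretizations / formulations than the
# package implementation.

# single-segment network (inlet == outlet segment) plus its flow at rate Q
make_single_channel <- function(Q = 1e-7, shape = "circular",
                                radius = 1.5e-4, width = 2e-3,
                                length = 5e-3, epithelium = "olfactory",
                                axis = c(1, 0, 0)) {
  seg <- channel_segment("only", length, shape, radius, width = width,
                         epithelium = epithelium, axis = axis)
  net <- channel_network(
    seg, tibble::tibble(from = character(), to = character()),
    inlet_ids = "only", outlet_ids = "only",
    column_groups = if (epithelium == "olfactory") list(c1 = "only")
                    else list()
  )
  list(network = net, flow = solve_flow(net, Q, dm_flow_fraction = NULL))
}

# layered series-parallel random network: every segment of layer j joins the
# shared junction between layers j and j+1. Returns the network with the node
# incidence attached for the independent flow oracle.
random_layered_network <- function(seed, n_layers = NULL) {
  withr::with_seed(seed, {
    n_layers <- n_layers %||% sample(3:6, 1)
    widths <- sample(1:4, n_layers, replace = TRUE)
    widths[1] <- 1
    widths[n_layers] <- 1
    segs <- list()
    edges <- list()
    tails <- integer(0)
    heads <- integer(0)
    prev_ids <- character(0)
    for (j in seq_len(n_layers)) {
      ids <- sprintf("s%d_%d", j, seq_len(widths[j]))
      for (i in seq_along(ids)) {
        shape <- sample(c("circular", "slot"), 1)
        segs[[length(segs) + 1L]] <- channel_segment(
          ids[i], length = stats::runif(1, 1e-3, 1e-2), shape = shape,
          radius_or_halfgap = stats::runif(1, 5e-5, 5e-4),
          width = stats::runif(1, 1e-3, 5e-3),
          epithelium = sample(c("respiratory", "olfactory",
                                "nonabsorbing"), 1),
          axial_start = (j - 1) * 5e-3
        )
        tails <- c(tails, j)
        heads <- c(heads, j + 1L)
      }
      if (j > 1) {
        edges[[length(edges) + 1L]] <-
          expand.grid(from = prev_ids, to = ids,
                      stringsAsFactors = FALSE)
      }
      prev_ids <- ids
    }
    segments <- purrr::list_rbind(segs)
    # column groups must partition olfactory segments
    olf <- segments$id[segments$epithelium == "olfactory"]
    net <- channel_network(
      segments, dplyr::bind_rows(edges),
      inlet_ids = segments$id[1],
      outlet_ids = segments$id[nrow(segments)],
      column_groups = if (length(olf)) stats::setNames(as.list(olf), olf)
                      else list()
    )
    attr(net, "tail_node") <- tails
    attr(net, "head_node") <- heads
    net
  })
}

# independent flow oracle: stacked linear system in (node pressures, edge
# flows), solved dense by qr.solve
flow_oracle <- function(network, Q, mu = 1.8e-5) {
  segs <- network$segments
  n <- nrow(segs)
  tails <- attr(network, "tail_node")
  heads <- attr(network, "head_node")
  n_nodes <- max(heads)
  R <- vapply(seq_len(n), function(i) {
    s <- segs[i, ]
    if (s$shape == "circular") 8 * mu * s$length / (pi * s$radius_or_halfgap^4)
    else 12 * mu * s$length / (s$width * (2 * s$radius_or_halfgap)^3)
  }, numeric(1))
  # unknowns: P_1..P_nodes (Pa), x_1..x_n with q = Q * x (scaled for
  # conditioning)
  n_unk <- n_nodes + n
  A <- matrix(0, 0, n_unk); b <- numeric(0)
  for (i in seq_len(n)) {       # constitutive rows P_t - P_h = R q
    row <- numeric(n_unk)
    row[tails[i]] <- 1; row[heads[i]] <- -1; row[n_nodes + i] <- -R[i] * Q
    A <- rbind(A, row); b <- c(b, 0)
  }
  for (v in seq_len(n_nodes)) { # conservation rows
    row <- numeric(n_unk)
    for (i in seq_len(n)) {
      if (heads[i] == v) row[n_nodes + i] <- row[n_nodes + i] + 1
      if (tails[i] == v) row[n_nodes + i] <- row[n_nodes + i] - 1
    }
    inj <- 0
    if (v == 1) inj <- -1
    if (v == n_nodes) inj <- 1
    A <- rbind(A, row); b <- c(b, inj)
  }
  row <- numeric(n_unk); row[n_nodes] <- 1  # ground the outlet node
  A <- rbind(A, row); b <- c(b, 0)
  sol <- qr.solve(A, b)
  list(P = sol[seq_len(n_nodes)], q = Q * sol[n_nodes + seq_len(n)])
}

# independent uptake oracle: cell-centered finite-volume discretization with
# Crank-Nicolson axial marching and a series-resistance wall flux closure
fv_uptake_oracle <- function(shape, a, L, U, D, k_w, M = 96, n_axial = 240) {
  h <- a / M
  r <- (seq_len(M) - 0.5) * h              # cell centers
  u <- if (shape == "circular") 2 * U * (1 - (r / a)^2)
       else 1.5 * U * (1 - (r / a)^2)
  faces <- seq_len(M - 1) * h
  Lmat <- matrix(0, M, M)
  for (i in seq_len(M)) {
    geom <- if (shape == "circular") r[i] * h else h
    if (i > 1) {
      f <- if (shape == "circular") faces[i - 1] else 1
      Lmat[i, i - 1] <- Lmat[i, i - 1] + D * f / (h * geom)
      Lmat[i, i] <- Lmat[i, i] - D * f / (h * geom)
    }
    if (i < M) {
      f <- if (shape == "circular") faces[i] else 1
      Lmat[i, i + 1] <- Lmat[i, i + 1] + D * f / (h * geom)
      Lmat[i, i] <- Lmat[i, i] - D * f / (h * geom)
    }
  }
  # wall flux: conduction from last cell center to the wall in series with k_w
  k_eff <- 1 / (1 / k_w + (h / 2) / D)
  f_wall <- if (shape == "circular") a else 1
  geom_M <- if (shape == "circular") r[M] * h else h
  Lmat[M, M] <- Lmat[M, M] - k_eff * f_wall / geom_M
  dz <- L / n_axial
  A1 <- diag(u) - (dz / 2) * Lmat
  A0 <- diag(u) + (dz / 2) * Lmat
  cvec <- rep(1, M)
  for (k in seq_len(n_axial)) cvec <- solve(A1, A0 %*% cvec)[, 1]
  wt <- u * if (shape == "circular") r else rep(1, M)
  1 - sum(wt * cvec) / sum(wt)
}

# Wilke-Chang reference evaluated independently in log space
wilke_chang_reference <- function(M_B, phi, T, mu, V_A) {
  exp(log(7.4e-8) + 0.5 * (log(phi) + log(M_B)) + log(T) -
        log(mu) - 0.6 * log(V_A)) * 1e-4
}
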