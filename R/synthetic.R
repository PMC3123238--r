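# Deterministic fixture generators. The defaults encode the study
# conditions the analysis operations are validated under; each generator is
# bit-reproducible for a given seed.

#' Synthetic planar surface-patch pair
#'
#' Two congruent flat square dot grids at separation `gap`, the lower patch's
#' normals pointing up and the upper patch's normals down (`opposing`) or up
#' (`parallel`). Every point's nearest neighbour on the other patch is its
#' direct opposite, so the analytic patch complementarity is
#' `+/- exp(-0.5 * gap^2)` — the oracle for the complementarity scorer.
#'
#' @param gap Patch separation in Angstrom (non-negative).
#' @param density Dots per square Angstrom (default 10).
#' @param extent Lateral side length of the square patches (default 6).
#' @param normal_mode `"opposing"` or `"parallel"`.
#' @return A surface tibble in [dot_surface()] layout holding both patches as
#'   residues `"1"` (lower) and `"2"` (upper), all points side-chain.
#' @export
gen_patch_pair <- function(gap, density = 10, extent = 6,
                           normal_mode = c("opposing", "parallel")) {
  abort_if(gap < 0, "gap must be non-negative")
  normal_mode <- match.arg(normal_mode)
  h <- 1 / sqrt(density)
  gxy <- seq(-extent / 2, extent / 2, by = h)
  grid <- expand.grid(x = gxy, y = gxy)
  npt <- nrow(grid)
  up <- c(0, 0, 1)
  n2 <- if (normal_mode == "opposing") -up else up
  patch <- function(res, zval, normal, serial0) tibble::tibble(
    x = grid$x, y = grid$y, z = zval,
    nx = normal[1], ny = normal[2], nz = normal[3],
    atom_serial = serial0, residue = res, resid = "SYN",
    is_side_chain = TRUE, area_weight = 1 / density,
    point_index = seq_len(npt)
  )
  out <- dplyr::bind_rows(patch("1", 0, up, 1L),
                          patch("2", gap, n2, 2L))
  attr(out, "density") <- density
  out
}

#' Random graph generator with optional constraints
#'
#' Either Bernoulli edges at link density `l_d` (see [random_graph()]) or a
#' uniform draw of exactly `edge_count` edges, optionally respecting a
#' maximum node degree and/or rejected until connected. Deterministic per
#' seed.
#'
#' @param n Number of nodes.
#' @param l_d Link density (exclusive with `edge_count`).
#' @param edge_count Exact number of edges (exclusive with `l_d`).
#' @param max_degree Degree cap (default none).
#' @param connected Reject samples until the graph is connected.
#' @param seed Integer seed.
#' @param max_tries Rejection cap.
#' @return An igraph graph.
#' @export
gen_random_graph <- function(n, l_d = NULL, edge_count = NULL,
                             max_degree = Inf, connected = FALSE, seed = NULL,
                             max_tries = 10000) {
  abort_if(is.null(l_d) == is.null(edge_count),
           "give exactly one of l_d or edge_count")
  if (!is.null(edge_count)) {
    abort_if(edge_count > choose(n, 2), "edge_count exceeds the complete graph")
    abort_if(edge_count > floor(n * max_degree / 2),
             "edge_count infeasible under the degree cap")
    abort_if(connected && edge_count < n - 1,
             "a connected graph needs at least n - 1 edges")
  }
  if (connected) {
    abort_if(!is.null(edge_count) && n > 2 && max_degree < 2,
             "connectivity impossible with max_degree < 2")
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  # constructive draw for an exact edge count: a degree-respecting random
  # spanning tree first (when connectivity is required), then additional
  # edges sampled among pairs with spare degree; may dead-end and is then
  # retried
  draw_exact <- function() {
    deg <- integer(n)
    adj <- matrix(FALSE, n, n)
    edges <- matrix(integer(0), ncol = 2)
    add_edge <- function(u, v) {
      adj[u, v] <<- adj[v, u] <<- TRUE
      deg[u] <<- deg[u] + 1L
      deg[v] <<- deg[v] + 1L
      edges <<- rbind(edges, c(u, v))
    }
    if (connected) {
      order_in <- sample.int(n)
      for (k in 2:n) {
        v <- order_in[k]
        host <- order_in[seq_len(k - 1)]
        host <- host[deg[host] < max_degree]
        if (!length(host)) return(NULL)
        add_edge(sample(rep(host, 2), 1), v) # rep: sample() scalar quirk
      }
    }
    while (nrow(edges) < edge_count) {
      free <- which(deg < max_degree)
      cand <- pairs[pairs[, 1] %in% free & pairs[, 2] %in% free, ,
                    drop = FALSE]
      cand <- cand[!adj[cand], , drop = FALSE]
      if (nrow(cand) == 0) return(NULL)
      pick <- cand[sample.int(nrow(cand), 1), ]
      add_edge(pick[1], pick[2])
    }
    edges
  }
  draw_density <- function() {
    sel <- which(stats::runif(nrow(pairs)) < l_d)
    pairs[sel, , drop = FALSE]
  }
  for (i in seq_len(max_tries)) {
    e <- if (is.null(l_d)) draw_exact() else draw_density()
    if (is.null(e)) next
    g <- igraph::make_empty_graph(n, directed = FALSE)
    igraph::V(g)$name <- as.character(seq_len(n))
    if (nrow(e)) g <- igraph::add_edges(g, as.vector(t(e)))
    deg_ok <- n == 0 || max(igraph::degree(g), 0) <= max_degree
    conn_ok <- !connected || igraph::is_connected(g)
    if (deg_ok && conn_ok) return(g)
  }
  stop("no admissible graph found within max_tries; parameters may be infeasible",
       call. = FALSE)
}

#' Synthetic triplet frames with prescribed geometry
#'
#' Places three residue frames whose origin triangle has the prescribed side
#' lengths and whose tilt/swivel angles relative to the triangle's global
#' frame equal the prescribed values, so the analysis operations recover the
#' parameters exactly (round-trip oracle).
#'
#' @param sides `(r_12, r_13, r_23)` in Angstrom; must satisfy the triangle
#'   inequality.
#' @param tilts Three tilt angles in degrees, in `(0, 180)`.
#' @param swivels Three swivel angles in degrees, `[0, 360)`.
#' @param residues Residue labels for the three frames.
#' @return List of three `residue_frame` objects (order R1, R2, R3).
#' @export
gen_triplet_frames <- function(sides, tilts = c(90, 90, 90),
                               swivels = c(0, 0, 0),
                               residues = c("SYN", "SYN", "SYN")) {
  abort_if(length(sides) != 3, "need three side lengths")
  r12 <- sides[1]; r13 <- sides[2]; r23 <- sides[3]
  abort_if(r12 + r13 <= r23 || r12 + r23 <= r13 || r13 + r23 <= r12,
           "side lengths violate the triangle inequality")
  # triangle in the z = 0 plane with (o2-o1) x (o3-o1) along +z
  o1 <- c(0, 0, 0)
  o2 <- c(r12, 0, 0)
  x3 <- (r12^2 + r13^2 - r23^2) / (2 * r12)
  y3 <- sqrt(max(0, r13^2 - x3^2))
  abort_if(y3 < 1e-9, "degenerate (collinear) triangle")
  o3 <- c(x3, y3, 0)
  centroid <- (o1 + o2 + o3) / 3
  origins <- list(o1 - centroid, o2 - centroid, o3 - centroid)
  z_tr <- c(0, 0, 1)
  frames <- purrr::map(1:3, function(i) {
    th <- tilts[i] * pi / 180
    abort_if(tilts[i] <= 0 || tilts[i] >= 180,
             "tilts must lie strictly between 0 and 180 for a defined swivel")
    z_i <- c(sin(th), 0, cos(th))
    zp <- unitize(z_tr - sum(z_tr * z_i) * z_i)
    x_i <- rotate_about(zp, z_i, -swivels[i])
    new_residue_frame(origins[[i]], x = x_i, z = z_i, residue = residues[i])
  })
  frames
}

# Rodrigues rotation of v about unit axis by angle (degrees)
rotate_about <- function(v, axis, angle) {
  th <- angle * pi / 180
  axis <- unitize(axis)
  v * cos(th) + cross3(axis, v) * sin(th) + axis * sum(axis * v) * (1 - cos(th))
}

# minimal proper rotation taking unit vector a onto unit vector b
rotation_from_to <- function(a, b) {
  a <- unitize(a); b <- unitize(b)
  v <- cross3(a, b)
  c_ <- sum(a * b)
  if (vnorm(v) < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    axis <- unitize(cross3(a, if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    return(rotation_matrix(axis, 180))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

rotation_matrix <- function(axis, angle) {
  axis <- unitize(axis)
  th <- angle * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  ux <- axis[1]; uy <- axis[2]; uz <- axis[3]
  matrix(c(
    c1 + ux^2 * (1 - c1), ux * uy * (1 - c1) + uz * s1, ux * uz * (1 - c1) - uy * s1,
    ux * uy * (1 - c1) - uz * s1, c1 + uy^2 * (1 - c1), uy * uz * (1 - c1) + ux * s1,
    ux * uz * (1 - c1) + uy * s1, uy * uz * (1 - c1) - ux * s1, c1 + uz^2 * (1 - c1)
  ), 3, 3)
}

#' Toy all-atom structure with designed side-chain contacts
#'
#' Builds a small cluster of ideal-geometry leucines (see [build_peptide()])
#' arranged so the surface-contact pipeline has a known answer. The
#' `packed-core` layout places `n_residues` core residues in a ring with each
#' side-chain tip wedged against the next residue's fork face, enclosed by
#' two lid residues and a ring of wall residues: the crowding focuses every
#' core patch onto its facing neighbour (as a real protein core does), so the
#' intended core contacts pass the surface thresholds (Sm >= 0.4,
#' Ov >= 0.08) while no lid or wall contact does — for `n_residues = 3` the
#' surface contact network is a single triplet clique. Core residues come out
#' partially buried (ratio <= 0.3) and the crowd exposed, so the
#' burial-filtered point-atom network reproduces the same topology. The
#' `loose` layout uses the same ring expanded far beyond the contact range:
#' no surface contact forms. Deterministic per seed (the seed only perturbs
#' small rolls of the residues about their facing axes).
#'
#' @param layout `"packed-core"` or `"loose"`.
#' @param n_residues Number of core residues (>= 3).
#' @param seed Integer seed.
#' @param core_radius Core ring radius in Angstrom; defaults 3.2
#'   (packed-core) or 12 (loose).
#' @return Atom tibble in the standard layout; core residues are numbered
#'   `1..n_residues`.
#' @export
gen_toy_structure <- function(layout = c("packed-core", "loose"),
                              n_residues = 3, seed = 1, core_radius = NULL) {
  layout <- match.arg(layout)
  abort_if(n_residues < 3, "need at least three residues")
  packed <- layout == "packed-core"
  rho <- core_radius %||% if (packed) 3.2 else 12
  lid_z <- 3.8
  wall_r <- rho + 2.3
  template <- build_peptide("LEU")
  f0 <- residue_frame(template)
  m0 <- cbind(f0$x, f0$y, f0$z)
  coords0 <- sweep(as.matrix(template[, c("x", "y", "z")]), 2, f0$origin)
  place <- function(origin, x_t, n_k, resno, roll = 0) {
    x_t <- unitize(x_t - sum(x_t * n_k) * n_k)
    if (roll != 0) x_t <- rotate_about(x_t, n_k, roll)
    y_t <- cross3(n_k, x_t)
    rot <- cbind(x_t, y_t, n_k) %*% t(m0)
    coords <- sweep(coords0 %*% t(rot), 2, origin, `+`)
    res <- template
    res$x <- coords[, 1]; res$y <- coords[, 2]; res$z <- coords[, 3]
    res$resno <- resno
    res
  }
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  n_wall <- 2 * n_residues
  core_roll <- stats::runif(n_residues, -3, 3)
  wall_roll <- stats::runif(n_wall, -10, 10)
  origins <- lapply(seq_len(n_residues), function(k) {
    a <- 2 * pi * (k - 1) / n_residues
    rho * c(cos(a), sin(a), 0)
  })
  pieces <- vector("list", n_residues)
  for (k in seq_len(n_residues)) {
    nxt <- origins[[k %% n_residues + 1]]
    x_k <- unitize(nxt - origins[[k]])          # tip points at the next core
    n_k <- rotate_about(x_k, c(0, 0, 1), -90)   # fork face receives previous
    pieces[[k]] <- place(origins[[k]], x_k, n_k, k, roll = core_roll[k])
  }
  if (packed) {
    nn <- n_residues
    for (s in c(1, -1)) {
      nn <- nn + 1
      pieces[[nn]] <- place(c(0, 0, s * lid_z), c(1, 0, 0), c(0, 0, -s), nn)
    }
    for (i in seq_len(n_wall)) {
      nn <- nn + 1
      th <- 2 * pi * (i - 1) / n_wall + pi / n_wall
      e <- c(cos(th), sin(th), 0)
      pieces[[nn]] <- place(e * wall_r, c(0, 0, 1), -e, nn,
                            roll = wall_roll[i])
    }
  }
  out <- dplyr::bind_rows(pieces)
  out$atom_serial <- seq_len(nrow(out))
  out
}

#' Random tilt-angle samples
#'
#' `isotropic` draws the angle between a uniformly random unit vector and a
#' fixed axis (density `sin(theta)/2` — the tilt null); `concentrated` draws
#' angles peaked around `mu` with spread `1/sqrt(kappa)` radians (reflected
#' into `[0, 180]`), for power checks.
#'
#' @param n Sample size.
#' @param mode `"isotropic"` or `"concentrated"`.
#' @param mu Centre (degrees) for the concentrated mode.
#' @param kappa Concentration (> 0) for the concentrated mode.
#' @param seed Integer seed.
#' @return Numeric vector of angles in degrees.
#' @export
gen_tilt_sample <- function(n, mode = c("isotropic", "concentrated"),
                            mu = 90, kappa = NULL, seed = NULL) {
  mode <- match.arg(mode)
  abort_if(n < 1, "n must be at least 1")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  if (mode == "isotropic") {
    return(acos(stats::runif(n, -1, 1)) * 180 / pi)
  }
  abort_if(is.null(kappa) || kappa <= 0, "concentrated mode needs kappa > 0")
  x <- mu + stats::rnorm(n, 0, (1 / sqrt(kappa)) * 180 / pi)
  x <- abs(x) %% 360
  ifelse(x > 180, 360 - x, x)
}
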