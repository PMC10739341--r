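# Stochastic root-architecture growth engine: per-axis elongation toward a
# maximal length, best-of-N tropism steering, truncated-normal parameter
# realization, lateral branching at regularly spaced sites, radial
# thickening, and reflection confinement inside a slab or cylinder.
# Internal geometry is mm (depth positive down); parameters arrive in the
# cm / cm/d / mm/h units of the parameter table and are converted here.

#' Draw from a truncated normal distribution
#'
#' Rejection sampling from N(mean, sd) restricted to `[lower, upper]`, with
#' an inverse-CDF fallback when the window lies far in the tail. `sd = 0`
#' returns the mean clamped into the bounds. Uses R's global RNG stream.
#'
#' @param n Number of draws.
#' @param mean,sd Normal parameters (`sd >= 0`).
#' @param lower,upper Truncation bounds, `lower < upper` (may be infinite).
#' @return Numeric vector of `n` draws, all inside the bounds.
#' @export
#' @examples
#' set.seed(1)
#' sample_truncated_normal(5, mean = 0, sd = 1, lower = -0.5, upper = 0.5)
sample_truncated_normal <- function(n = 1, mean, sd, lower = -Inf,
                                    upper = Inf) {
  if (!is.finite(mean) || sd < 0) stop("need finite mean, sd >= 0",
                                       call. = FALSE)
  if (!(lower < upper)) stop("invalid truncation bounds", call. = FALSE)
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(0)
  tries <- 0
  while (length(out) < n && tries < 50) {
    draws <- stats::rnorm(max(2 * (n - length(out)), 100), mean, sd)
    out <- c(out, draws[draws >= lower & draws <= upper])
    tries <- tries + 1
  }
  if (length(out) < n) {
    # window deep in a tail: inverse-CDF on the truncated quantile scale
    plo <- stats::pnorm(lower, mean, sd)
    phi <- stats::pnorm(upper, mean, sd)
    extra <- stats::qnorm(stats::runif(n - length(out), plo, phi), mean, sd)
    out <- c(out, pmin(pmax(extra, lower), upper))
  }
  out[seq_len(n)]
}

#' Target axis length at a given age
#'
#' Negative-exponential elongation toward the maximal root length:
#' `l(age) = l_max * (1 - exp(-r * age / l_max))`, with initial slope `r`
#' and asymptote `l_max` (growth saturates, never halts). Units follow the
#' inputs (cm with cm/d, or mm with mm/d).
#'
#' @param age Axis age, days (`>= 0`; vectorised).
#' @param r Initial elongation rate.
#' @param l_max Maximal root length.
#' @return Length at `age`, same units as `l_max`.
#' @export
#' @examples
#' axis_target_length(1, r = 1, l_max = 10)
axis_target_length <- function(age, r, l_max) {
  if (any(age < 0)) stop("negative age", call. = FALSE)
  if (r <= 0 || l_max <= 0) stop("r and l_max must be > 0", call. = FALSE)
  l_max * (1 - exp(-r * age / l_max))
}

# ---- geometry helpers ----------------------------------------------------

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# orthonormal pair spanning the plane normal to unit vector h
perp_basis <- function(h) {
  ref <- if (abs(h[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- unitv(cross3(h, ref))
  list(u = u, v = cross3(h, u))
}

rotate_about <- function(h, polar, azimuth) {
  b <- perp_basis(h)
  unitv(cos(polar) * h +
          sin(polar) * (cos(azimuth) * b$u + sin(azimuth) * b$v))
}

#' Tropism-steered heading update
#'
#' Draws `N` candidate headings, each the current heading rotated by a
#' random polar angle ~ N(0, `sigma_dx`) about a uniform random azimuth, and
#' keeps the candidate that best satisfies the tropism: gravitropism
#' minimises the angle to the downward vertical, plagiotropism the angle to
#' the horizontal plane, exotropism the angle to the axis's initial heading.
#' `sigma_dx` is the per-substep angular standard deviation in radians, the
#' product of the axial resolution (cm) and the angular-change density sigma
#' (1/cm). With `sigma_dx = 0` the heading is returned unchanged.
#'
#' @param heading Current unit heading (length-3, depth positive down).
#' @param sigma_dx Angular sd per substep, radians.
#' @param N Number of candidate trials (tropism strength), `>= 1`.
#' @param mode `"gravitropism"`, `"plagiotropism"` or `"exotropism"`.
#' @param initial_heading Unit heading at axis birth (exotropism target).
#' @return New unit heading.
#' @export
tropism_direction <- function(heading, sigma_dx, N,
                              mode = c("gravitropism", "plagiotropism",
                                       "exotropism"),
                              initial_heading = heading) {
  mode <- match.arg(mode)
  if (vnorm(heading) == 0) stop("zero heading vector", call. = FALSE)
  heading <- unitv(heading)
  if (sigma_dx == 0) return(heading)
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  polar <- stats::rnorm(N, 0, sigma_dx)
  azim <- stats::runif(N, 0, 2 * pi)
  cands <- vapply(seq_len(N), function(i) {
    rotate_about(heading, polar[i], azim[i])
  }, numeric(3))
  objective <- switch(mode,
    gravitropism = function(h) acos(pmin(pmax(h[3], -1), 1)),
    plagiotropism = function(h) abs(asin(pmin(pmax(h[3], -1), 1))),
    exotropism = function(h) {
      acos(pmin(pmax(sum(h * initial_heading), -1), 1))
    }
  )
  scores <- apply(cands, 2, objective)
  unitv(cands[, which.min(scores)])
}

# ---- domains -------------------------------------------------------------

#' Growth domains
#'
#' `domain_slab()` is a thin box (germination-paper pouch): x spans the
#' width, y the thickness, z the height downward from the stem base at the
#' origin. `domain_cylinder()` is a pot (Deepot): radius in x-y, depth in z.
#'
#' @param width_mm,height_mm,thickness_mm Slab dimensions, mm.
#' @param diameter_mm,depth_mm Cylinder dimensions, mm.
#' @return A `root_domain` object.
#' @export
domain_slab <- function(width_mm = 279.4, height_mm = 381,
                        thickness_mm = 3.175) {
  stopifnot(width_mm > 0, height_mm > 0, thickness_mm > 0)
  structure(list(kind = "slab", width = width_mm, height = height_mm,
                 thickness = thickness_mm),
            class = "root_domain")
}

#' @rdname domain_slab
#' @export
domain_cylinder <- function(diameter_mm = 63.5, depth_mm = 254) {
  stopifnot(diameter_mm > 0, depth_mm > 0)
  structure(list(kind = "cylinder", radius = diameter_mm / 2,
                 depth = depth_mm),
            class = "root_domain")
}

min_domain_dim <- function(domain) {
  switch(domain$kind,
    slab = min(domain$width, domain$height, domain$thickness),
    cylinder = min(2 * domain$radius, domain$depth)
  )
}

# dimensions the 2*delta_x feasibility check applies to: slab thickness is
# exempt because planar reflection is an exact fold, which keeps quasi-2D
# germination-paper pouches (3.175 mm) usable with a 5 mm primary substep
check_domain_dim <- function(domain) {
  switch(domain$kind,
    slab = min(domain$width, domain$height),
    cylinder = min(2 * domain$radius, domain$depth)
  )
}

# fold coordinate p into [lo, hi] by repeated mirror reflection; returns the
# folded value and whether the net reflection count is odd (heading flips)
fold_reflect <- function(p, lo, hi) {
  L <- hi - lo
  q <- (p - lo) %% (2 * L)
  flipped <- q > L
  list(value = lo + ifelse(flipped, 2 * L - q, q), flipped = flipped)
}

#' Reflect a point back inside the growth domain
#'
#' Points outside the slab/cylinder are mirrored across the violated
#' boundary and the heading component normal to that boundary is negated;
#' interior points pass through unchanged.
#'
#' @param point Length-3 position, mm.
#' @param domain A `root_domain`.
#' @param heading Optional unit heading carried along the step.
#' @return List with elements `point` and `heading`.
#' @export
confine <- function(point, domain, heading = c(0, 0, 1)) {
  if (any(!is.finite(point))) stop("non-finite point", call. = FALSE)
  if (domain$kind == "slab") {
    fx <- fold_reflect(point[1], -domain$width / 2, domain$width / 2)
    fy <- fold_reflect(point[2], -domain$thickness / 2,
                       domain$thickness / 2)
    fz <- fold_reflect(point[3], 0, domain$height)
    point <- c(fx$value, fy$value, fz$value)
    if (fx$flipped) heading[1] <- -heading[1]
    if (fy$flipped) heading[2] <- -heading[2]
    if (fz$flipped) heading[3] <- -heading[3]
  } else {
    fz <- fold_reflect(point[3], 0, domain$depth)
    point[3] <- fz$value
    if (fz$flipped) heading[3] <- -heading[3]
    for (iter in 1:8) {
      rho <- sqrt(point[1]^2 + point[2]^2)
      if (rho <= domain$radius || rho == 0) break
      n <- c(point[1], point[2], 0) / rho
      point[1:2] <- point[1:2] * abs(2 * domain$radius - rho) / rho
      heading <- heading - 2 * sum(heading * n) * n
    }
  }
  list(point = point, heading = unitv(heading))
}

# ---- configuration -------------------------------------------------------

#' Simulation configuration
#'
#' @param total_days Simulated time span, days (`>= 0`).
#' @param dt Time step, days (> 0).
#' @param seed Integer seed; fixes every random draw of the run.
#' @param domain A `root_domain`.
#' @param n_primary_roots Number of stem-borne primary axes.
#' @param tropism Named character vector mapping root order (`"1"`..`"3"`)
#'   to `"gravitropism"`, `"plagiotropism"` or `"exotropism"`. Orders not
#'   named default to gravitropism for primaries and exotropism for laterals.
#' @param sd_frac Stochasticity policy: each realized parameter is drawn
#'   from a truncated normal with sd = `sd_frac` x mean, truncated at
#'   [max(0, mean - 2 sd), mean + 2 sd]. `sd_frac = 0` gives a deterministic
#'   run. May be a single number or named per parameter.
#' @param max_order Deepest root order to branch to (defaults to the orders
#'   present in the parameter table at simulation time).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(total_days, dt = 1, seed = 1,
                              domain = domain_slab(),
                              n_primary_roots = 1,
                              tropism = NULL, sd_frac = 0.1,
                              max_order = NULL) {
  stopifnot(total_days >= 0, dt > 0, n_primary_roots >= 1)
  structure(list(total_days = total_days, dt = dt, seed = as.integer(seed),
                 domain = domain, n_primary_roots = n_primary_roots,
                 tropism = tropism, sd_frac = sd_frac, max_order = max_order),
            class = "simulation_config")
}

tropism_for_order <- function(config, order) {
  if (!is.null(config$tropism) && as.character(order) %in%
        names(config$tropism)) {
    return(config$tropism[[as.character(order)]])
  }
  if (order == 1) "gravitropism" else "exotropism"
}

#' Write / read a simulation config as JSON
#' @param config A `simulation_config`.
#' @param path JSON path.
#' @export
write_sim_config <- function(config, path) {
  obj <- unclass(config)
  obj$domain <- unclass(obj$domain)
  if (!is.null(obj$tropism)) obj$tropism <- as.list(obj$tropism)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dom <- if (obj$domain$kind == "slab") {
    domain_slab(obj$domain$width, obj$domain$height, obj$domain$thickness)
  } else {
    domain_cylinder(2 * obj$domain$radius, obj$domain$depth)
  }
  simulation_config(obj$total_days, obj$dt, obj$seed, dom,
                    obj$n_primary_roots,
                    if (length(obj$tropism)) unlist(obj$tropism) else NULL,
                    obj$sd_frac,
                    if (is.null(obj$max_order)) NULL else obj$max_order)
}

# ---- RNG streams ---------------------------------------------------------

# Each axis owns an RNG stream so that axis order never perturbs another
# axis's draws; child streams derive from stable (parent id, site) indices.
derive_seed <- function(base, a, b = 0) {
  as.integer((abs(as.double(base)) * 1000003 + a * 7919 + b * 104729) %%
               2147483629)
}

capture_rng_state <- function(seed) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  st <- get(".Random.seed", globalenv(), inherits = FALSE)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  st
}

with_rng_state <- function(state, fn) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", state, globalenv())
  res <- fn()
  st <- get(".Random.seed", globalenv(), inherits = FALSE)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  list(result = res, state = st)
}

# ---- axis / system construction ------------------------------------------

# realize one axis's parameter set: truncated-normal draw per parameter
realize_params <- function(prow, sd_frac) {
  drawn <- c("l_b", "l_a", "l_n", "l_max", "r", "a_i", "a_max", "a_r",
             "theta")
  out <- as.list(prow)
  frac_of <- function(nm) {
    if (length(sd_frac) > 1 && nm %in% names(sd_frac)) sd_frac[[nm]]
    else if (length(sd_frac) == 1) as.numeric(sd_frac)
    else 0.1
  }
  for (nm in drawn) {
    m <- prow[[nm]]
    s <- frac_of(nm) * abs(m)
    out[[nm]] <- if (s == 0 || m == 0) m else {
      sample_truncated_normal(1, m, s, max(0, m - 2 * s), m + 2 * s)
    }
  }
  out
}

new_axis <- function(id, order, birth_day, base_point, heading, prow,
                     config, parent_id = NA_integer_,
                     branch_arc_mm = NA_real_, seed = 1L) {
  st <- with_rng_state(capture_rng_state(seed), function() {
    realize_params(prow, config$sd_frac)
  })
  p <- st$result
  dx_mm <- p$delta_x * 10
  lmax_mm <- p$l_max * 10
  # lateral sites: from the basal unbranched zone to the start of the
  # distal unbranched zone, spaced l_n apart (fencepost inclusive)
  sites <- numeric(0)
  lb_mm <- p$l_b * 10; la_mm <- p$l_a * 10; ln_mm <- p$l_n * 10
  if (ln_mm > 0 && lmax_mm - la_mm >= lb_mm) {
    sites <- seq(lb_mm, lmax_mm - la_mm, by = ln_mm)
  }
  list(id = as.integer(id), order = as.integer(order),
       birth_day = birth_day,
       parent_id = parent_id, branch_arc_mm = branch_arc_mm,
       nodes = matrix(base_point, nrow = 1),
       node_birth = birth_day,
       heading = heading, initial_heading = heading,
       params = p, dx_mm = dx_mm, lmax_mm = lmax_mm,
       r_mm = p$r * 10,
       sigma_dx = p$delta_x * p$sigma * pi / 180,  # deg-based sigma -> rad
       sites = sites, next_site = 1L,
       arc_mm = 0,
       rng = st$state)
}

#' Initialise a root system
#'
#' Creates `n_primary_roots` primary axes at the stem base (origin, heading
#' straight down; multiple primaries are ringed 1.5 mm around the base) and
#' a clock at day 0. Grow it with [grow_step()] or run the whole span with
#' [simulate_root_system()].
#'
#' @param params Parameter tibble (one row per root order, cm units).
#' @param config A `simulation_config`.
#' @return A `root_system` object.
#' @export
init_root_system <- function(params, config) {
  max_avail <- max(params$order)
  max_order <- config$max_order %||% max_avail
  if (max_order > max_avail) {
    stop("branching to order ", max_order, " requested but parameters stop",
         " at order ", max_avail, call. = FALSE)
  }
  dx_max <- max(params$delta_x[params$order <= max_order]) * 10
  if (check_domain_dim(config$domain) < 2 * dx_max) {
    stop("domain thinner than twice the axial resolution", call. = FALSE)
  }
  p1 <- params[params$order == 1, ]
  if (nrow(p1) != 1) stop("need exactly one order-1 parameter row",
                          call. = FALSE)
  n <- config$n_primary_roots
  axes <- vector("list", n)
  for (i in seq_len(n)) {
    base <- if (n == 1) c(0, 0, 0) else {
      # ring the stem base; the out-of-plane offset is capped separately so
      # thin slabs spread primaries along the paper, not through it
      ang <- 2 * pi * (i - 1) / n
      rx <- if (config$domain$kind == "slab") {
        min(1.5, config$domain$width / 8)
      } else {
        min(1.5, config$domain$radius / 4)
      }
      ry <- if (config$domain$kind == "slab") {
        min(1.5, config$domain$thickness * 0.4)
      } else {
        rx
      }
      c(rx * cos(ang), ry * sin(ang), 0)
    }
    base <- confine(base, config$domain)$point
    axes[[i]] <- new_axis(i, 1L, 0, base, c(0, 0, 1), p1, config,
                          seed = derive_seed(config$seed, i))
  }
  structure(list(axes = axes, params = params, config = config,
                 clock = 0, max_order = max_order,
                 next_id = as.integer(n) + 1L),
            class = "root_system")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# point and local heading on an axis polyline at arc length s (mm)
point_at_arc <- function(axis, s) {
  nodes <- axis$nodes
  if (nrow(nodes) == 1) {
    return(list(point = nodes[1, ], heading = axis$heading))
  }
  seglen <- sqrt(rowSums((nodes[-1, , drop = FALSE] -
                            nodes[-nrow(nodes), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  s <- min(max(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(i, length(seglen))
  f <- if (seglen[i] > 0) (s - cum[i]) / seglen[i] else 0
  dirv <- unitv(nodes[i + 1, ] - nodes[i, ])
  list(point = nodes[i, ] + f * (nodes[i + 1, ] - nodes[i, ]),
       heading = dirv)
}

# extend one axis by dl mm, in tropism-steered substeps of <= dx_mm
extend_axis <- function(axis, dl, config, clock) {
  if (dl <= 1e-12) return(axis)
  mode <- tropism_for_order(config, axis$order)
  N <- axis$params$N
  res <- with_rng_state(axis$rng, function() {
    nodes <- axis$nodes
    births <- axis$node_birth
    heading <- axis$heading
    pos <- nodes[nrow(nodes), ]
    remaining <- dl
    while (remaining > 1e-12) {
      step <- min(remaining, axis$dx_mm)
      heading <- tropism_direction(heading, axis$sigma_dx, N, mode,
                                   axis$initial_heading)
      cand <- pos + heading * step
      cf <- confine(cand, config$domain, heading)
      pos <- cf$point
      heading <- cf$heading
      nodes <- rbind(nodes, pos)
      births <- c(births, clock)
      remaining <- remaining - step
    }
    list(nodes = nodes, births = births, heading = heading)
  })
  axis$nodes <- res$result$nodes
  axis$node_birth <- res$result$births
  axis$heading <- res$result$heading
  axis$rng <- res$state
  axis$arc_mm <- axis$arc_mm + dl
  axis
}

#' Advance a root system by one time step
#'
#' Elongates every axis by the increment of its target-length curve,
#' steering each substep by the configured tropism; spawns laterals whose
#' branch sites the parent tip has overtaken (insertion polar angle drawn
#' around theta, azimuth uniform in 0-360 degrees); radii thicken from
#' `a_i` toward `a_max` at rate `a_r` as a function of node age.
#'
#' @param system A `root_system`.
#' @param dt Time step, days.
#' @return The advanced `root_system`.
#' @export
grow_step <- function(system, dt = system$config$dt) {
  stopifnot(dt > 0)
  config <- system$config
  clock <- system$clock
  for (i in seq_along(system$axes)) {
    ax <- system$axes[[i]]
    age0 <- clock - ax$birth_day
    if (age0 < 0) next
    dl <- axis_target_length(age0 + dt, ax$r_mm, ax$lmax_mm) -
      axis_target_length(age0, ax$r_mm, ax$lmax_mm)
    system$axes[[i]] <- extend_axis(ax, dl, config, clock + dt)
  }
  # lateral emergence: a site initiates the step after the parent tip passes
  n_ax <- length(system$axes)
  for (i in seq_len(n_ax)) {
    parent <- system$axes[[i]]
    if (parent$order >= system$max_order) next
    child_order <- parent$order + 1L
    prow <- system$params[system$params$order == child_order, ]
    if (nrow(prow) == 0) {
      stop("branching to order ", child_order,
           " requested but no parameters supplied", call. = FALSE)
    }
    while (parent$next_site <= length(parent$sites) &&
             parent$arc_mm > parent$sites[parent$next_site]) {
      s <- parent$sites[parent$next_site]
      at <- point_at_arc(parent, s)
      seed_c <- derive_seed(config$seed, parent$id, parent$next_site)
      draw <- with_rng_state(capture_rng_state(seed_c), function() {
        th_mean <- prow$theta
        th_sd <- (if (length(config$sd_frac) == 1) config$sd_frac
                  else config$sd_frac[["theta"]] %||% 0.1) * abs(th_mean)
        th <- if (th_sd == 0) th_mean else {
          sample_truncated_normal(1, th_mean, th_sd,
                                  max(0, th_mean - 2 * th_sd),
                                  min(180, th_mean + 2 * th_sd))
        }
        list(theta = th * pi / 180, azim = stats::runif(1, 0, 2 * pi))
      })
      heading0 <- rotate_about(at$heading, draw$result$theta,
                               draw$result$azim)
      child <- new_axis(system$next_id, child_order, system$clock + dt,
                        at$point, heading0, prow, config,
                        parent_id = parent$id, branch_arc_mm = s,
                        seed = derive_seed(seed_c, 1))
      system$axes[[length(system$axes) + 1]] <- child
      system$next_id <- system$next_id + 1L
      parent$next_site <- parent$next_site + 1L
    }
    system$axes[[i]] <- parent
  }
  system$clock <- clock + dt
  system
}

#' Simulate a root system over the configured time span
#'
#' @inheritParams init_root_system
#' @return The grown `root_system`.
#' @export
#' @examples
#' params <- example_parameters()
#' cfg <- simulation_config(10, seed = 1, n_primary_roots = 2, sd_frac = 0)
#' sys <- simulate_root_system(params, cfg)
#' glance(sys)
simulate_root_system <- function(params, config) {
  system <- init_root_system(params, config)
  n_steps <- if (config$total_days == 0) 0 else
    ceiling(config$total_days / config$dt - 1e-9)
  for (k in seq_len(n_steps)) {
    dt <- min(config$dt, config$total_days - system$clock)
    system <- grow_step(system, dt)
  }
  system
}

#' A plausible example parameter table
#'
#' Two root orders with magnitudes typical of young adventitious root
#' systems of hardwood cuttings; handy for examples and smoke tests.
#' @return A `root_type_parameters` tibble.
#' @export
example_parameters <- function() {
  out <- tibble::tibble(
    order = 1:2,
    l_b = c(1.2, 0.4), l_a = c(1.5, 0.5), l_n = c(0.8, 0.4),
    l_max = c(25, 6), r = c(1.2, 0.5),
    delta_x = c(0.5, 0.1), sigma = c(20, 25), theta = c(25, 60),
    N = 1:2, a_i = c(0.03, 0.015), a_max = c(0.08, 0.03),
    a_r = c(0.006, 0.002)
  )
  class(out) <- c("root_type_parameters", class(out))
  out
}

# node radius at the current clock: a_i -> a_max at a_r (mm/h -> mm/d)
node_radii <- function(axis, clock) {
  age <- pmax(clock - axis$node_birth, 0)
  pmin(axis$params$a_max * 10,
       axis$params$a_i * 10 + axis$params$a_r * 24 * age)
}

#' Tidy a root system into a segments table
#'
#' One row per polyline sub-segment with endpoints, radius (at the current
#' clock) and topology, the canonical flat form of the simulated geometry.
#'
#' @param x A `root_system`.
#' @param ... Unused.
#' @return Tibble: `axis_id`, `parent_id`, `order`, `x1..z2` (mm),
#'   `radius_mm`, `birth_day`.
#' @export
tidy.root_system <- function(x, ...) {
  rows <- lapply(x$axes, function(ax) {
    n <- nrow(ax$nodes)
    if (n < 2) return(NULL)
    r <- node_radii(ax, x$clock)
    tibble::tibble(
      axis_id = ax$id, parent_id = ax$parent_id, order = ax$order,
      x1 = ax$nodes[-n, 1], y1 = ax$nodes[-n, 2], z1 = ax$nodes[-n, 3],
      x2 = ax$nodes[-1, 1], y2 = ax$nodes[-1, 2], z2 = ax$nodes[-1, 3],
      radius_mm = (r[-n] + r[-1]) / 2,
      birth_day = ax$node_birth[-1]
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
glance.root_system <- function(x, ...) {
  seg <- tidy.root_system(x)
  total <- if (nrow(seg) == 0) 0 else {
    sum(sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2 +
               (seg$z2 - seg$z1)^2))
  }
  tibble::tibble(
    n_axes = length(x$axes),
    n_segments = nrow(seg),
    total_length_mm = total,
    max_depth_mm = if (nrow(seg) == 0) 0 else max(seg$z2, seg$z1),
    clock_days = x$clock
  )
}

#' @export
print.root_system <- function(x, ...) {
  g <- glance.root_system(x)
  cat(sprintf(
    "root_system: %d axes, %.1f mm total length, %.1f mm deep, day %g\n",
    g$n_axes, g$total_length_mm, g$max_depth_mm, g$clock_days))
  invisible(x)
}

#' Export / import the segments table as CSV
#'
#' @param system A `root_system`.
#' @param path CSV path.
#' @return `read_segments_csv()` returns the segments tibble.
#' @export
export_segments_csv <- function(system, path) {
  readr::write_csv(tidy.root_system(system), path)
  invisible(path)
}

#' @rdname export_segments_csv
#' @export
read_segments_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Export a root system as RSML 1.0
#'
#' Writes the scene/plant/root hierarchy with polyline geometry, per-node
#' diameter as a point-level function, and the root order as an annotation.
#' `read_rsml()` recovers topology, nodes and diameters.
#'
#' @param system A `root_system`.
#' @param path RSML path.
#' @export
export_rsml <- function(system, path) {
  doc <- xml2::xml_new_root("rsml")
  meta <- xml2::xml_add_child(doc, "metadata")
  xml2::xml_add_child(meta, "version", "1")
  xml2::xml_add_child(meta, "unit", "mm")
  xml2::xml_add_child(meta, "resolution", "1")
  xml2::xml_add_child(meta, "software", "rhizobridge")
  scene <- xml2::xml_add_child(doc, "scene")
  plant <- xml2::xml_add_child(scene, "plant", id = "1",
                               label = "cutting")
  add_root <- function(parent_node, ax) {
    rn <- xml2::xml_add_child(parent_node, "root",
                              ID = as.character(ax$id),
                              label = paste0("order", ax$order))
    geom <- xml2::xml_add_child(rn, "geometry")
    poly <- xml2::xml_add_child(geom, "polyline")
    for (i in seq_len(nrow(ax$nodes))) {
      xml2::xml_add_child(poly, "point",
                          x = format(ax$nodes[i, 1], digits = 12),
                          y = format(ax$nodes[i, 2], digits = 12),
                          z = format(ax$nodes[i, 3], digits = 12))
    }
    fns <- xml2::xml_add_child(rn, "functions")
    fn <- xml2::xml_add_child(fns, "function", name = "diameter",
                              domain = "polyline")
    for (d in 2 * node_radii(ax, system$clock)) {
      xml2::xml_add_child(fn, "sample", value = format(d, digits = 12))
    }
    ann <- xml2::xml_add_child(rn, "annotations")
    a <- xml2::xml_add_child(ann, "annotation", name = "order")
    xml2::xml_add_child(a, "value", as.character(ax$order))
    kids <- Filter(function(a2) identical(a2$parent_id, ax$id), system$axes)
    for (k in kids) add_root(rn, k)
    rn
  }
  for (ax in system$axes) {
    if (is.na(ax$parent_id)) add_root(plant, ax)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname export_rsml
#' @return `read_rsml()` returns a tibble with one row per root (`id`,
#'   `order`, `parent_id`, `n_nodes`) and a list-column `nodes` of node
#'   matrices.
#' @export
read_rsml <- function(path) {
  doc <- xml2::read_xml(path)
  roots <- xml2::xml_find_all(doc, ".//root")
  rows <- lapply(roots, function(rn) {
    pts <- xml2::xml_find_all(rn, "./geometry/polyline/point")
    nodes <- cbind(
      x = as.numeric(xml2::xml_attr(pts, "x")),
      y = as.numeric(xml2::xml_attr(pts, "y")),
      z = as.numeric(xml2::xml_attr(pts, "z"))
    )
    par <- xml2::xml_parent(xml2::xml_parent(rn))
    par_id <- if (xml2::xml_name(xml2::xml_parent(rn)) == "root") {
      as.integer(xml2::xml_attr(xml2::xml_parent(rn), "ID"))
    } else {
      NA_integer_
    }
    diam <- as.numeric(xml2::xml_attr(
      xml2::xml_find_all(rn, "./functions/function/sample"), "value"))
    tibble::tibble(
      id = as.integer(xml2::xml_attr(rn, "ID")),
      order = as.integer(xml2::xml_text(
        xml2::xml_find_first(rn, "./annotations/annotation/value"))),
      parent_id = par_id,
      n_nodes = nrow(nodes),
      nodes = list(nodes),
      diameter = list(diam)
    )
  })
  dplyr::bind_rows(rows)
}

# ---- rendering -----------------------------------------------------------

#' Render a root system to a binary mask
#'
#' Orthographic projection of all axes onto the x-z or y-z plane, each
#' polyline stroked at its local diameter, returned as a simulated
#' `root_image` ready for trait extraction. `trim_radius_mm` drops geometry
#' farther than that 3D distance from the stem base (mirrors trimming
#' excised root crowns to a fixed radius before imaging).
#'
#' @param system A `root_system`.
#' @param plane `"xz"` or `"yz"`.
#' @param scale_mm_per_px Pixel size, mm.
#' @param trim_radius_mm Optional trim radius, mm.
#' @param pad_mm Margin around the geometry, mm.
#' @return A `root_image` (provenance `"simulated"`).
#' @export
render_projection <- function(system, plane = c("xz", "yz"),
                              scale_mm_per_px = 0.5, trim_radius_mm = NULL,
                              pad_mm = 3) {
  plane <- match.arg(plane)
  stopifnot(scale_mm_per_px > 0)
  seg <- tidy.root_system(system)
  if (nrow(seg) == 0) {
    return(root_image(matrix(0L, 16, 16), scale_mm_per_px, "simulated"))
  }
  u1 <- if (plane == "xz") seg$x1 else seg$y1
  u2 <- if (plane == "xz") seg$x2 else seg$y2
  # sample points along each segment at half-pixel spacing
  pts <- vector("list", nrow(seg))
  half <- scale_mm_per_px / 2
  for (i in seq_len(nrow(seg))) {
    len <- sqrt((seg$x2[i] - seg$x1[i])^2 + (seg$y2[i] - seg$y1[i])^2 +
                  (seg$z2[i] - seg$z1[i])^2)
    ns <- max(2L, ceiling(len / half) + 1L)
    f <- seq(0, 1, length.out = ns)
    pts[[i]] <- cbind(u = u1[i] + f * (u2[i] - u1[i]),
                      z = seg$z1[i] + f * (seg$z2[i] - seg$z1[i]),
                      r = seg$radius_mm[i],
                      d3 = sqrt((seg$x1[i] + f * (seg$x2[i] - seg$x1[i]))^2 +
                                  (seg$y1[i] + f * (seg$y2[i] - seg$y1[i]))^2 +
                                  (seg$z1[i] + f * (seg$z2[i] - seg$z1[i]))^2))
  }
  pts <- do.call(rbind, pts)
  if (!is.null(trim_radius_mm)) {
    pts <- pts[pts[, "d3"] <= trim_radius_mm, , drop = FALSE]
    if (nrow(pts) == 0) {
      return(root_image(matrix(0L, 16, 16), scale_mm_per_px, "simulated"))
    }
  }
  umin <- min(pts[, "u"] - pts[, "r"]) - pad_mm
  umax <- max(pts[, "u"] + pts[, "r"]) + pad_mm
  zmin <- min(pts[, "z"] - pts[, "r"]) - pad_mm
  zmax <- max(pts[, "z"] + pts[, "r"]) + pad_mm
  nc <- max(8L, ceiling((umax - umin) / scale_mm_per_px))
  nr <- max(8L, ceiling((zmax - zmin) / scale_mm_per_px))
  col <- pmin(pmax(1L, as.integer(floor((pts[, "u"] - umin) /
                                          scale_mm_per_px)) + 1L), nc)
  row <- pmin(pmax(1L, as.integer(floor((pts[, "z"] - zmin) /
                                          scale_mm_per_px)) + 1L), nr)
  # stroke width 2k+1 px best approximates the true diameter 2r when
  # k = round(r/scale - 0.5): the centre pixel already contributes one pixel
  r_px <- pmax(0L, as.integer(round(pts[, "r"] / scale_mm_per_px - 0.5)))
  mask <- matrix(0L, nr, nc)
  # stroke by radius group: paint centres, then dilate with a disc brush
  for (rp in sort(unique(r_px))) {
    sel <- r_px == rp
    layer <- matrix(0L, nr, nc)
    layer[cbind(row[sel], col[sel])] <- 1L
    if (rp > 0) {
      brush <- EBImage::makeBrush(2 * rp + 1, shape = "disc")
      layer <- EBImage::dilate(layer, brush)
    }
    mask <- pmax(mask, layer)
  }
  root_image(mask, scale_mm_per_px, "simulated")
}

#' @export
autoplot.root_system <- function(object, plane = c("xz", "yz"), ...) {
  plane <- match.arg(plane)
  seg <- tidy.root_system(object)
  if (nrow(seg) == 0) return(ggplot2::ggplot())
  if (plane == "xz") {
    seg$u1 <- seg$x1; seg$u2 <- seg$x2
  } else {
    seg$u1 <- seg$y1; seg$u2 <- seg$y2
  }
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$u1, y = -.data$z1,
                                       xend = .data$u2, yend = -.data$z2,
                                       colour = factor(.data$order),
                                       linewidth = .data$radius_mm)) +
    ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(substr(plane, 1, 1), "(mm)"), y = "depth (mm)",
                  colour = "order") +
    ggplot2::theme_minimal()
}
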