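test_that("truncated normal sampling respects bounds and degenerate sd", {
  expect_equal(sample_truncated_normal(1, 5, 0, 0, 10), 5)
  expect_equal(sample_truncated_normal(1, 15, 0, 0, 10), 10)  # clamped
  set.seed(1)
  x <- sample_truncated_normal(1e5, 0, 1, -0.5, 0.5)
  expect_true(all(x >= -0.5 & x <= 0.5))
  expect_lt(abs(mean(x)), 0.01)            # symmetric truncation
  set.seed(2)
  y <- sample_truncated_normal(1e4, 5, 1, 0, Inf)
  expect_gte(min(y), 0)
  # far-tail window still returns in-bound draws
  set.seed(3)
  z <- sample_truncated_normal(100, 0, 1, 8, 9)
  expect_true(all(z >= 8 & z <= 9))
  expect_error(sample_truncated_normal(1, 0, 1, 2, 1), "bounds")
  expect_error(sample_truncated_normal(1, 0, -1, 0, 1), "sd")
})

test_that("axis target length follows the saturating exponential", {
  expect_equal(axis_target_length(0, 1, 10), 0)
  expect_equal(axis_target_length(1, 1, 10), 10 * (1 - exp(-0.1)))
  expect_lt(abs(axis_target_length(1e6, 1, 10) - 10), 1e-9 * 10)
  expect_error(axis_target_length(-1, 1, 10), "negative")
  # monotone, slope r at origin
  ages <- seq(0, 50, by = 0.5)
  l <- axis_target_length(ages, 1.5, 20)
  expect_true(all(diff(l) > 0))
  expect_equal((axis_target_length(1e-6, 1.5, 20)) / 1e-6, 1.5,
               tolerance = 1e-4)
})

test_that("tropism steering is identity at sigma 0 and directs headings", {
  h <- c(1, 0, 0)
  expect_equal(tropism_direction(h, 0, 50, "gravitropism"), h)
  # gravitropism steers a horizontal heading to vertical over chained steps
  set.seed(42)
  cur <- c(1, 0, 0)
  for (i in 1:200) cur <- tropism_direction(cur, 0.3, 50, "gravitropism")
  expect_lt(acos(cur[3]) * 180 / pi, 10)
  # N = 1 is a pure random walk with half-normal mean turning angle
  set.seed(43)
  sdx <- 0.2
  turns <- replicate(1e4, {
    nh <- tropism_direction(c(0, 0, 1), sdx, 1, "gravitropism")
    acos(min(max(nh[3], -1), 1))
  })
  half_normal_mean <- sdx * sqrt(2 / pi)
  se <- sdx * sqrt(1 - 2 / pi) / sqrt(1e4)
  expect_lt(abs(mean(turns) - half_normal_mean), 3 * se)
  # plagiotropism drives toward the horizontal plane
  set.seed(44)
  cur <- c(0, 0, 1)
  for (i in 1:200) cur <- tropism_direction(cur, 0.3, 50, "plagiotropism")
  expect_lt(abs(asin(cur[3])) * 180 / pi, 10)
  expect_error(tropism_direction(c(0, 0, 0), 0.1, 5, "gravitropism"),
               "zero heading")
})

test_that("confinement reflects across violated boundaries only", {
  cyl <- domain_cylinder(63.5, 254)
  inside <- confine(c(5, 5, 100), cyl)
  expect_equal(inside$point, c(5, 5, 100))
  # 1 mm beyond the wall lands 1 mm inside, radially
  out <- confine(c(32.75, 0, 50), cyl)
  expect_equal(out$point, c(30.75, 0, 50))
  # below the floor reflects above it
  deep <- confine(c(0, 0, 260), cyl)
  expect_equal(deep$point[3], 248)
  # heading normal component flips at the wall
  h <- confine(c(32.75, 0, 50), cyl, heading = c(1, 0, 0))
  expect_equal(h$heading, c(-1, 0, 0))
  # slab folding keeps arbitrarily thin slabs inside
  slab <- domain_slab(100, 200, 3)
  p <- confine(c(0, 7.3, 50), slab)
  expect_lte(abs(p$point[2]), 1.5)
})

test_that("deterministic single root matches the closed form exactly", {
  p <- straight_params()
  cfg <- simulation_config(10, dt = 1, seed = 5, n_primary_roots = 1,
                           sd_frac = 0)
  sys <- simulate_root_system(p, cfg)
  g <- glance(sys)
  expect_equal(g$n_axes, 1)
  expect_lt(abs(g$total_length_mm -
                  10 * axis_target_length(10, p$r, p$l_max)), 1e-6)
  seg <- tidy(sys)
  expect_true(all(abs(c(seg$x1, seg$x2, seg$y1, seg$y2)) < 1e-12))
  # zero-day simulation: primaries exist with zero length
  sys0 <- simulate_root_system(p, simulation_config(0, seed = 1,
                                                    n_primary_roots = 3))
  expect_equal(glance(sys0)$n_axes, 3)
  expect_equal(glance(sys0)$total_length_mm, 0)
})

test_that("lateral sites follow the fencepost count", {
  # branch zone 6 cm, spacing 1 cm -> 7 sites at maturity
  p <- example_parameters()
  p$sigma <- c(0, 0)
  p1 <- p[1, ]; p1$l_b <- 2; p1$l_a <- 2; p1$l_max <- 10; p1$l_n <- 1
  p1$r <- 5
  p2 <- p[2, ]; p2$l_n <- 100; p2$l_max <- 3; p2$r <- 0.3
  pp <- dplyr::bind_rows(p1, p2)
  cfg <- simulation_config(40, seed = 1, n_primary_roots = 1, sd_frac = 0)
  sys <- simulate_root_system(pp, cfg)
  expect_equal(sum(vapply(sys$axes, function(a) a$order == 2, logical(1))),
               7)
  # random parameter sets: spawned laterals = floor(zone/l_n) + 1 when the
  # parent has grown past its whole branching zone
  set.seed(9)
  for (i in 1:8) {
    lb <- runif(1, 0.5, 2); la <- runif(1, 0.5, 2)
    lmax <- runif(1, 6, 12); ln <- runif(1, 0.4, 1.5)
    q1 <- p1; q1$l_b <- lb; q1$l_a <- la; q1$l_max <- lmax; q1$l_n <- ln
    q1$r <- lmax                 # near-saturated within the run
    qq <- dplyr::bind_rows(q1, p2)
    sysi <- simulate_root_system(qq,
      simulation_config(60, seed = i, n_primary_roots = 1, sd_frac = 0))
    got <- sum(vapply(sysi$axes, function(a) a$order == 2, logical(1)))
    expect_equal(got, floor((lmax - la - lb) / ln) + 1)
  }
  # requesting deeper orders than parameterized fails loudly
  expect_error(
    simulate_root_system(p1, simulation_config(5, seed = 1, max_order = 2)),
    "order 2")
})

test_that("identical config and seed give bit-identical segment exports", {
  params <- example_parameters()
  cfg <- simulation_config(12, seed = 77, n_primary_roots = 3)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_segments_csv(simulate_root_system(params, cfg), f1)
  export_segments_csv(simulate_root_system(params, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  seg <- read_segments_csv(f1)
  sys <- simulate_root_system(params, cfg)
  expect_equal(nrow(seg),
               sum(vapply(sys$axes, function(a) nrow(a$nodes) - 1,
                          numeric(1))))
})

test_that("growth respects monotonicity, l_max and slab planarity", {
  params <- example_parameters()
  cfg <- simulation_config(14, seed = 3, n_primary_roots = 2)
  sys <- init_root_system(params, cfg)
  prev <- 0
  for (d in 1:14) {
    sys <- grow_step(sys, 1)
    tot <- glance(sys)$total_length_mm
    expect_gte(tot, prev)
    prev <- tot
    for (ax in sys$axes) {
      expect_lte(ax$arc_mm, ax$lmax_mm + 1e-6)
    }
  }
  seg <- tidy(sys)
  expect_lte(max(abs(c(seg$y1, seg$y2))), 3.175 / 2 + 1e-9)
  # node radii grow toward a_max and never shrink tip-to-base
  ax <- sys$axes[[1]]
  r <- rhizobridge:::node_radii(ax, sys$clock)
  expect_true(all(diff(r) <= 1e-12))        # younger nodes are thinner
  expect_lte(max(r), ax$params$a_max * 10 + 1e-12)
})

test_that("gravitropic systems end deeper than plagiotropic ones", {
  # steering needs several trials per substep; primaries default to
  # N = root order = 1 (a pure random walk), so raise N for this contrast
  params <- example_parameters()[1, ]
  params$l_n <- 100
  params$N <- 10L
  depth_for <- function(mode, seed) {
    cfg <- simulation_config(8, seed = seed, n_primary_roots = 1,
                             tropism = c(`1` = mode), max_order = 1)
    glance(simulate_root_system(params, cfg))$max_depth_mm
  }
  g <- vapply(1:15, function(s) depth_for("gravitropism", s), numeric(1))
  p <- vapply(1:15, function(s) depth_for("plagiotropism", s), numeric(1))
  expect_lt(t.test(p, g, alternative = "less")$p.value, 0.05)
})

test_that("projection rendering supports trimming and empty systems", {
  p <- straight_params(l_max = 30, r = 30)   # ~150 mm deep in 8 days
  cfg <- simulation_config(8, seed = 2, n_primary_roots = 1, sd_frac = 0)
  sys <- simulate_root_system(p, cfg)
  expect_gt(glance(sys)$max_depth_mm, 120)
  img <- render_projection(sys, "xz", 1, trim_radius_mm = 100)
  fg <- which(img$mask == 1, arr.ind = TRUE)
  extent_mm <- (max(fg[, 1]) - min(fg[, 1]) + 1) * img$scale_mm_per_px
  expect_lte(extent_mm, 100 + 2 * 1 + 2)     # trim + stroke + digitization
  empty <- init_root_system(example_parameters(),
                            simulation_config(0, seed = 1))
  img0 <- render_projection(empty, "xz", 1)
  expect_equal(sum(img0$mask), 0)
  expect_equal(img0$provenance, "simulated")
})

test_that("RSML export round-trips topology and geometry", {
  params <- example_parameters()
  cfg <- simulation_config(10, seed = 21, n_primary_roots = 2)
  sys <- simulate_root_system(params, cfg)
  f <- withr::local_tempfile(fileext = ".rsml")
  export_rsml(sys, f)
  back <- read_rsml(f)
  expect_equal(nrow(back), length(sys$axes))
  expect_setequal(back$id, vapply(sys$axes, `[[`, integer(1), "id"))
  for (i in seq_len(nrow(back))) {
    ax <- sys$axes[[which(vapply(sys$axes, `[[`, integer(1), "id") ==
                            back$id[i])]]
    expect_equal(back$n_nodes[i], nrow(ax$nodes))
    expect_equal(unname(back$nodes[[i]][, "z"]), unname(ax$nodes[, 3]),
                 tolerance = 1e-6)
    expect_equal(back$order[i], ax$order)
    expect_equal(back$parent_id[i], ax$parent_id)
  }
  # empty system: valid document with zero roots
  f0 <- withr::local_tempfile(fileext = ".rsml")
  export_rsml(init_root_system(example_parameters(),
                               simulation_config(0, seed = 1)), f0)
  doc <- xml2::read_xml(f0)
  expect_equal(length(xml2::xml_find_all(doc, ".//root")),
               1L)   # one zero-length primary polyline
})

test_that("simulation configs round-trip through JSON", {
  cfg <- simulation_config(21, dt = 0.5, seed = 99,
                           domain = domain_cylinder(63.5, 254),
                           n_primary_roots = 4,
                           tropism = c(`1` = "gravitropism",
                                       `2` = "exotropism"),
                           sd_frac = 0.15, max_order = 2)
  f <- withr::local_tempfile(fileext = ".json")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  expect_equal(back$total_days, 21)
  expect_equal(back$dt, 0.5)
  expect_equal(back$seed, 99L)
  expect_equal(back$domain$radius, 31.75)
  expect_equal(back$n_primary_roots, 4)
  expect_equal(unname(back$tropism["2"]), "exotropism")
  expect_equal(back$sd_frac, 0.15)
})
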