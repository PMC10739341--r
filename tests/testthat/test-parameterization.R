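# a synthetic trait summary with controllable operand values
toy_records <- function(n = 5, len = c(300, 350, 400, 450, 500)) {
  tibble::tibble(
    number_of_root_tips = c(10, 12, 14, 16, 20)[seq_len(n)],
    total_root_length = len[seq_len(n)],
    network_area = total_root_length * 1.1,
    convex_area = network_area * 4,
    solidity = 0.25,
    max_depth = total_root_length / 4,
    avg_diameter = c(0.8, 0.9, 1.0, 1.1, 1.2)[seq_len(n)],
    max_diameter = avg_diameter * 3,
    surface_area = pi * avg_diameter * total_root_length,
    avg_root_orientation = c(20, 25, 30, 35, 40)[seq_len(n)]
  )
}

test_that("trait summaries use order statistics with midpoint medians", {
  one <- summarize_traits(toy_records(1), t = 35)
  row <- one$stats[one$stats$trait == "total_root_length", ]
  expect_equal(c(row$min, row$median, row$max), rep(300, 3))
  s <- summarize_traits(tibble::tibble(total_root_length = c(10, 20, 40),
                                       x = 1:3), t = 10)
  r <- s$stats[s$stats$trait == "total_root_length", ]
  expect_equal(r$median, 20); expect_equal(r$max, 40)
  s2 <- summarize_traits(tibble::tibble(total_root_length = c(10, 30)),
                         t = 10)
  expect_equal(s2$stats$median[s2$stats$trait == "total_root_length"], 20)
  expect_error(summarize_traits(toy_records(0), 10), "no trait records")
  expect_error(summarize_traits(toy_records(2), 0), "positive")
})

test_that("fixed Table rows hold: delta_x, N, theta, sigma, a_r", {
  summ <- summarize_traits(toy_records(), t = 35)
  p1 <- derive_root_type_parameters(summ, 1)
  p2 <- derive_root_type_parameters(summ, 2)
  p3 <- derive_root_type_parameters(summ, 3)
  expect_equal(p1$delta_x, 0.5)
  expect_equal(p2$delta_x, 0.1)
  expect_equal(p3$delta_x, 0.1)
  expect_equal(c(p1$N, p2$N, p3$N), 1:3)
  expect_equal(p1$theta, 30)                       # median orientation
  expect_equal(p1$sigma, sd(toy_records()$avg_root_orientation))
  # a_r = (a_max - a_i), cm -> mm, per hour
  expect_equal(p1$a_r, (p1$a_max - p1$a_i) * 10 / (35 * 24))
  expect_error(derive_root_type_parameters(summ, 4), "1, 2 or 3")
})

test_that("derived lengths are length-homogeneous in the linear operands", {
  recs <- toy_records()
  summ1 <- summarize_traits(recs, t = 35)
  p1 <- derive_root_type_parameters(summ1, 1)
  c_scale <- 2.5
  recs2 <- dplyr::mutate(recs,
    dplyr::across(c(total_root_length, max_depth, avg_diameter,
                    max_diameter), ~ .x * c_scale))
  p2 <- derive_root_type_parameters(summarize_traits(recs2, t = 35), 1)
  for (nm in c("l_b", "l_a", "l_max", "r", "a_i", "a_max")) {
    expect_equal(p2[[nm]], c_scale * p1[[nm]], tolerance = 1e-12)
  }
  # theta and sigma are invariant to record order
  shuf <- recs[c(4, 1, 5, 3, 2), ]
  p3 <- derive_root_type_parameters(summarize_traits(shuf, t = 35), 1)
  expect_equal(p3$theta, p1$theta)
  expect_equal(p3$sigma, p1$sigma)
})

test_that("zero divisors and inconsistent sets are reported by name", {
  recs <- toy_records()
  recs$number_of_root_tips <- 0
  expect_error(
    derive_root_type_parameters(summarize_traits(recs, t = 35), 1),
    "number_of_root_tips")
  p <- example_parameters()[1, ]
  p$l_b <- 2; p$l_a <- 3; p$l_max <- 4
  d <- validate_parameters(p)
  expect_true(any(d$check == "branching_zone"))
  p2 <- example_parameters()[1, ]
  p2$a_i <- 0.1; p2$a_max <- 0.05
  expect_true(any(validate_parameters(p2)$check == "radius"))
  expect_equal(nrow(validate_parameters(example_parameters())), 0)
})

test_that("parameter JSON round-trips losslessly and rejects bad files", {
  params <- derive_parameter_table(summarize_traits(toy_records(), 35), 1:3)
  f <- withr::local_tempfile(fileext = ".json")
  write_parameters(params, f)
  back <- read_parameters(f)
  for (nm in setdiff(names(params), "order")) {
    expect_identical(back[[nm]], params[[nm]])
  }
  obj <- jsonlite::read_json(f)
  obj$order_2$r <- NULL
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, f2, auto_unbox = TRUE, digits = NA)
  expect_error(read_parameters(f2), "r.*order_2|missing field")
  obj2 <- jsonlite::read_json(f)
  obj2$order_1$l_max <- -4
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj2, f3, auto_unbox = TRUE, digits = NA)
  expect_error(read_parameters(f3), "negative")
  obj3 <- jsonlite::read_json(f)
  obj3$order_1$bogus <- 1
  f4 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj3, f4, auto_unbox = TRUE, digits = NA)
  expect_error(read_parameters(f4), "unknown field")
  obj4 <- jsonlite::read_json(f)
  obj4$order_2 <- NULL
  f5 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj4, f5, auto_unbox = TRUE, digits = NA)
  expect_error(read_parameters(f5), "missing root order")
})

test_that("simulate-extract-rederive recovers parameter ordering", {
  # across parameter sets grown close to maturity, the re-derived r and
  # l_max must correlate strongly in rank with the truth (the loose 2D
  # fidelity contract; depth only reveals l_max once growth approaches it)
  set.seed(11)
  sets <- tibble::tibble(
    l_max = seq(8, 30, length.out = 20),
    r = l_max * runif(20, 0.5, 1.2)
  )
  derived <- purrr::pmap_dfr(sets, function(l_max, r) {
    p <- straight_params(l_max = l_max, r = r)
    p$sigma <- 10
    recs <- dplyr::bind_rows(lapply(1:4, function(i) {
      cfg <- simulation_config(10, seed = i * 100 + round(l_max * 7),
                               n_primary_roots = 1, sd_frac = 0.08,
                               max_order = 1,
                               domain = domain_slab(height_mm = 600))
      measure_root_image(render_projection(
        simulate_root_system(p, cfg), "xz", 0.5))
    }))
    dp <- derive_root_type_parameters(
      summarize_traits(dplyr::select(recs, -empty), t = 10), 1)
    tibble::tibble(r_hat = dp$r, l_max_hat = dp$l_max)
  })
  expect_gt(cor(sets$l_max, derived$l_max_hat, method = "spearman"), 0.7)
  expect_gt(cor(sets$r, derived$r_hat, method = "spearman"), 0.7)
})
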