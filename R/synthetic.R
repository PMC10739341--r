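# Synthetic fixtures with analytic ground truth: weather series, rooting
# cohorts, stroked root masks, and simulate-render-extract round trips.
# Every generator is fully determined by its arguments and seed, and ships
# its ground truth alongside the data so tests never re-derive it.

#' Generate a synthetic daily weather series
#'
#' Sinusoidal annual cycle plus Gaussian noise for the daily mean; max/min
#' are the mean plus/minus an absolute half-range draw.
#'
#' @param n_days Number of consecutive days (>= 1).
#' @param mean_temp Annual mean temperature, degC.
#' @param annual_amplitude Amplitude of the annual sinusoid, degC.
#' @param noise_sd Day-to-day Gaussian noise sd, degC (>= 0).
#' @param seed Integer seed.
#' @param start_date First date.
#' @param half_range_mean Mean of the |half-range| draw separating t_max and
#'   t_min from t_mean, degC.
#' @return Weather tibble (`date`, `t_mean`, `t_max`, `t_min`).
#' @export
synth_weather <- function(n_days, mean_temp = 10, annual_amplitude = 8,
                          noise_sd = 1.5, seed = 1,
                          start_date = as.Date("2022-10-15"),
                          half_range_mean = 4) {
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  set.seed(seed)
  day <- seq_len(n_days)
  t_mean <- mean_temp +
    annual_amplitude * sin(2 * pi * (day - 80) / 365.25) +
    stats::rnorm(n_days, 0, noise_sd)
  half <- abs(stats::rnorm(n_days, half_range_mean, half_range_mean / 4))
  tibble::tibble(
    date = start_date + day - 1,
    t_mean = t_mean,
    t_max = t_mean + half,
    t_min = t_mean - half
  )
}

#' Generate a synthetic rooting cohort
#'
#' Per-cutting rooting day drawn from a log-logistic time-to-event
#' distribution with median `true_t50` and shape `slope`; draws beyond
#' `max_day` are censored (`NA`). Ground truth is attached as attributes.
#'
#' @param true_t50 True median rooting time, days (> 0).
#' @param slope Log-logistic shape (steepness); large = synchronous rooting.
#' @param n Cohort size.
#' @param max_day Observation window end; later rooting is censored.
#' @param seed Integer seed.
#' @param collection_date Cohort collection date.
#' @return Tibble with `cohort_id`, `collection_date`, `cutting_id`,
#'   `root_day` (`NA` = censored), with attributes `true_t50`, `slope`.
#' @export
synth_rooting_cohort <- function(true_t50, slope, n, max_day = 60, seed = 1,
                                 collection_date = as.Date("2022-10-15")) {
  if (true_t50 <= 0) stop("true_t50 must be > 0", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  u <- stats::runif(n)
  # inverse CDF of F(t) = 1 / (1 + (t / t50)^(-slope))
  t <- true_t50 * (u / (1 - u))^(1 / slope)
  # rooting is recorded at the first daily check at or after the event, so
  # the fraction recorded by day d equals the underlying F(d) exactly
  day <- pmax(1, ceiling(t))
  day[day > max_day] <- NA
  out <- tibble::tibble(
    cohort_id = format(collection_date, "%Y-%m-%d"),
    collection_date = collection_date,
    cutting_id = seq_len(n),
    root_day = as.numeric(day)
  )
  attr(out, "true_t50") <- true_t50
  attr(out, "slope") <- slope
  out
}

#' Rasterize polylines into a root mask with analytic ground truth
#'
#' Strokes each polyline at its width onto a binary image and returns both
#' the image and the exact constructed truth (summed length, per-polyline
#' orientation from the downward vertical, width statistics, tip count), so
#' extraction accuracy can be scored against construction rather than
#' against another extractor.
#'
#' @param polylines List of lists, each with `points` (n x 2 matrix of
#'   (x, depth) mm coordinates) and `width_mm`.
#' @param width_mm,height_mm Image extent, mm.
#' @param scale_mm_per_px Pixel size, mm (default 0.1, a typical close-up
#'   camera scale).
#' @return List: `image` (a `root_image`) and `truth` (one-row tibble with
#'   `total_root_length`, `avg_root_orientation`, `avg_diameter`,
#'   `max_diameter`, `number_of_root_tips`, `n_polylines`).
#' @export
synth_root_mask <- function(polylines, width_mm = 60, height_mm = 120,
                            scale_mm_per_px = 0.1) {
  nr <- ceiling(height_mm / scale_mm_per_px)
  nc <- ceiling(width_mm / scale_mm_per_px)
  mask <- matrix(0L, nr, nc)
  lens <- numeric(0); angs <- numeric(0); widths <- numeric(0)
  for (pl in polylines) {
    pts <- pl$points
    if (any(pts[, 1] < 0 | pts[, 1] > width_mm |
              pts[, 2] < 0 | pts[, 2] > height_mm)) {
      stop("polyline exits image bounds", call. = FALSE)
    }
    w <- pl$width_mm
    r_px <- max(0L, as.integer(round(w / 2 / scale_mm_per_px - 0.5)))
    pl_len <- 0
    pl_ang <- 0
    for (i in seq_len(nrow(pts) - 1)) {
      a <- pts[i, ]; b <- pts[i + 1, ]
      seg <- sqrt(sum((b - a)^2))
      pl_len <- pl_len + seg
      ang <- atan2(abs(b[1] - a[1]), abs(b[2] - a[2])) * 180 / pi
      pl_ang <- pl_ang + ang * seg
      ns <- max(2L, ceiling(seg / (scale_mm_per_px / 2)) + 1L)
      f <- seq(0, 1, length.out = ns)
      col <- pmin(pmax(1L, as.integer(floor((a[1] + f * (b[1] - a[1])) /
                                              scale_mm_per_px)) + 1L), nc)
      row <- pmin(pmax(1L, as.integer(floor((a[2] + f * (b[2] - a[2])) /
                                              scale_mm_per_px)) + 1L), nr)
      layer <- matrix(0L, nr, nc)
      layer[cbind(row, col)] <- 1L
      if (r_px > 0) {
        layer <- EBImage::dilate(layer,
                                 EBImage::makeBrush(2 * r_px + 1, "disc"))
      }
      mask <- pmax(mask, layer)
    }
    lens <- c(lens, pl_len)
    angs <- c(angs, pl_ang / pl_len)
    widths <- c(widths, w)
  }
  truth <- tibble::tibble(
    total_root_length = sum(lens),
    avg_root_orientation = sum(angs * lens) / sum(lens),
    avg_diameter = sum(widths * lens) / sum(lens),
    max_diameter = max(widths),
    number_of_root_tips = 2L * length(polylines),
    n_polylines = length(polylines)
  )
  list(image = root_image(mask, scale_mm_per_px, "observed"), truth = truth)
}

#' Simulate, render and re-extract with packaged ground truth
#'
#' The full simulator round trip as a testable unit: grows a root system
#' from a known parameter table, renders the x-z projection, extracts
#' traits from the rendering, and returns the analytic truths (realized
#' simulator totals) alongside.
#'
#' @param params Parameter tibble.
#' @param config A `simulation_config`.
#' @param scale_mm_per_px Rendering resolution.
#' @return List: `system`, `image`, `traits` (extracted one-row tibble),
#'   `truth` (tibble with the simulator's own `total_length_mm`,
#'   `max_depth_mm`, `n_axes`, `mean_diameter_mm`).
#' @export
synth_roundtrip <- function(params, config, scale_mm_per_px = 0.5) {
  sys <- simulate_root_system(params, config)
  img <- render_projection(sys, "xz", scale_mm_per_px = scale_mm_per_px)
  traits <- measure_root_image(img)
  seg <- tidy.root_system(sys)
  g <- glance.root_system(sys)
  truth <- tibble::tibble(
    total_length_mm = g$total_length_mm,
    max_depth_mm = g$max_depth_mm,
    n_axes = g$n_axes,
    mean_diameter_mm = if (nrow(seg) == 0) NA_real_ else {
      seglen <- sqrt((seg$x2 - seg$x1)^2 + (seg$y2 - seg$y1)^2 +
                       (seg$z2 - seg$z1)^2)
      2 * sum(seg$radius_mm * seglen) / sum(seglen)
    }
  )
  list(system = sys, image = img, traits = traits, truth = truth)
}

#' Generate a cohort of synthetic "observed" root images
#'
#' Stand-in for a germination-paper imaging campaign: each sample is a
#' simulated root system grown with sample-to-sample stochasticity,
#' rendered and measured, giving a trait table with realistic between-plant
#' variation for exercising the parameterization/evaluation loop. The
#' images are synthetic; they mimic segmented mask geometry, not photographs.
#'
#' @param n_samples Number of plants/images.
#' @param params Parameter table the cohort grows from.
#' @param config Base `simulation_config`; per-sample seeds derive from its
#'   seed.
#' @param scale_mm_per_px Rendering resolution.
#' @return Trait tibble, one row per sample, with a `sample_id` column.
#' @export
synth_observed_cohort <- function(n_samples, params = example_parameters(),
                                  config = simulation_config(
                                    14, seed = 1, n_primary_roots = 3),
                                  scale_mm_per_px = 0.5) {
  rows <- lapply(seq_len(n_samples), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 7000 + i)
    img <- render_projection(simulate_root_system(params, cfg), "xz",
                             scale_mm_per_px = scale_mm_per_px)
    dplyr::mutate(measure_root_image(img), sample_id = i, .before = 1)
  })
  dplyr::bind_rows(rows)
}
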