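#' Summarize trait records for parameter derivation
#'
#' Reduces a table of per-image trait records to per-trait minimum, median
#' and maximum (standard midpoint median for even counts) plus the elapsed
#' observation time, the operands the growth-model parameter equations
#' consume.
#'
#' @param records Data frame of trait records (one row per image), e.g. from
#'   [measure_root_image()] or [read_trait_csv()].
#' @param t Elapsed days of the observation window; must be > 0.
#' @return An object of class `trait_summary`: tibble `stats` with columns
#'   `trait`, `min`, `median`, `max`, plus `t` and `sigma_orientation` (the
#'   sample standard deviation of per-record average orientation).
#' @export
summarize_traits <- function(records, t) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no trait records supplied", call. = FALSE)
  }
  if (!is.numeric(t) || length(t) != 1 || t <= 0) {
    stop("`t` must be a single positive number of days", call. = FALSE)
  }
  num <- dplyr::select(tibble::as_tibble(records), dplyr::where(is.numeric))
  stats_tbl <- tidyr::pivot_longer(num, dplyr::everything(),
                                   names_to = "trait") |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(min = min(.data$value),
                     median = stats::median(.data$value),
                     max = max(.data$value), .groups = "drop")
  sigma <- if ("avg_root_orientation" %in% names(num) && nrow(num) > 1) {
    stats::sd(num$avg_root_orientation)
  } else {
    0
  }
  structure(list(stats = stats_tbl, t = t, sigma_orientation = sigma,
                 n_records = nrow(records)),
            class = "trait_summary")
}

#' @export
print.trait_summary <- function(x, ...) {
  cat(sprintf("trait_summary over %d records, t = %g d\n", x$n_records, x$t))
  print(x$stats, n = 5)
  invisible(x)
}

summary_operand <- function(summary, trait, stat) {
  row <- summary$stats[summary$stats$trait == trait, ]
  if (nrow(row) == 0) {
    stop("trait summary lacks operand trait `", trait, "`", call. = FALSE)
  }
  row[[stat]]
}

# Declarative parameter equation table. Trait operands arrive in mm / mm^2
# from the trait tables and are converted to cm (cm^2) before use; every
# derived length/rate is therefore in cm (cm/d). Operand grouping of each
# row is a single place to edit should a different transcription be needed.
#   f(op, order): op = list(min/median/max accessor), order = root order
parameter_equations <- function() {
  list(
    l_b = function(op, k, t) op("total_root_length", "min") /
      op("number_of_root_tips", "min") * (1 / k),
    l_a = function(op, k, t) (op("total_root_length", "max") -
      op("total_root_length", "median")) /
      op("number_of_root_tips", "max") * (1 / k),
    l_n = function(op, k, t) op("surface_area", "median") /
      op("number_of_root_tips", "median") * 5 / k^2,
    l_max = function(op, k, t) op("max_depth", "max") * 1.2 / k^3,
    r = function(op, k, t) (op("total_root_length", "max") -
      op("total_root_length", "min")) / t * 1.5 / k,
    a_i = function(op, k, t) op("avg_diameter", "min") /
      op("number_of_root_tips", "min") * (1 / k^2),
    a_max = function(op, k, t) op("max_diameter", "max") / (5 * k^2)
  )
}

mm_to_cm <- function(x) x / 10
mm2_to_cm2 <- function(x) x / 100

#' Derive growth-model parameters for one root order
#'
#' Converts a trait summary into the 12-parameter set driving one root
#' order (primary = 1, secondary = 2, tertiary = 3) of the stochastic root
#' simulator. Fixed values: `delta_x` = 0.5 cm for primaries, 0.1 cm
#' otherwise; `N` (tropism trial count) = root order; `theta` (insertion
#' angle) = the median average root orientation; `sigma` = the sample SD of
#' per-record orientation. The radial growth rate `a_r = (a_max - a_i) / t`
#' is reported in mm/h (radii cm -> mm, days -> hours).
#'
#' Length operands are converted mm -> cm before the equations apply, so all
#' derived lengths are cm and `r` is cm/d.
#'
#' @param summary A `trait_summary` from [summarize_traits()].
#' @param order Root order, integer 1-3. Orders beyond 3 are rejected.
#' @return A one-row tibble of class `root_type_parameters` with columns
#'   `order`, `l_b`, `l_a`, `l_n`, `l_max`, `r`, `delta_x`, `sigma`, `theta`,
#'   `N`, `a_i`, `a_max`, `a_r`.
#' @export
derive_root_type_parameters <- function(summary, order) {
  stopifnot(inherits(summary, "trait_summary"))
  if (!order %in% 1:3) {
    stop("root order must be 1, 2 or 3 (primary/secondary/tertiary)",
         call. = FALSE)
  }
  # operand accessor with mm -> cm conversion at the boundary
  op <- function(trait, stat) {
    v <- summary_operand(summary, trait, stat)
    if (trait %in% c("total_root_length", "max_depth", "avg_diameter",
                     "max_diameter")) {
      v <- mm_to_cm(v)
    } else if (trait %in% c("surface_area", "network_area", "convex_area")) {
      v <- mm2_to_cm2(v)
    }
    v
  }
  eqs <- parameter_equations()
  # name any zero divisor explicitly before evaluating
  divisors <- list(
    l_b = c("number_of_root_tips", "min"),
    l_a = c("number_of_root_tips", "max"),
    l_n = c("number_of_root_tips", "median"),
    a_i = c("number_of_root_tips", "min")
  )
  for (nm in names(divisors)) {
    d <- summary_operand(summary, divisors[[nm]][1], divisors[[nm]][2])
    if (d == 0) {
      stop("cannot derive ", nm, ": operand ", divisors[[nm]][1], "_",
           divisors[[nm]][2], " is zero", call. = FALSE)
    }
  }
  vals <- lapply(eqs, function(f) f(op, order, summary$t))
  neg <- names(vals)[vapply(vals, function(v) is.finite(v) && v < 0,
                            logical(1))]
  if (length(neg) > 0) {
    stop("negative derived length/rate: ", paste(neg, collapse = ", "),
         call. = FALSE)
  }
  theta <- summary_operand(summary, "avg_root_orientation", "median")
  a_r_mm_h <- (vals$a_max - vals$a_i) * 10 / (summary$t * 24)
  out <- tibble::tibble(
    order = as.integer(order),
    l_b = vals$l_b, l_a = vals$l_a, l_n = vals$l_n, l_max = vals$l_max,
    r = vals$r,
    delta_x = if (order == 1) 0.5 else 0.1,
    sigma = summary$sigma_orientation,
    theta = theta,
    N = as.integer(order),
    a_i = vals$a_i, a_max = vals$a_max,
    a_r = a_r_mm_h
  )
  class(out) <- c("root_type_parameters", class(out))
  out
}

#' Derive a parameter table for several root orders
#'
#' @inheritParams derive_root_type_parameters
#' @param orders Integer vector of root orders (subset of 1:3).
#' @return Row-bound `root_type_parameters` tibble, one row per order.
#' @export
derive_parameter_table <- function(summary, orders = 1:2) {
  out <- dplyr::bind_rows(lapply(orders, function(k) {
    derive_root_type_parameters(summary, k)
  }))
  class(out) <- c("root_type_parameters", class(out))
  out
}

#' Diagnose a parameter set
#'
#' Pure diagnostics, never mutates: reports an empty branching zone
#' (`l_b + l_a > l_max`), non-positive elongation rate, initial radius above
#' the maximum, and insertion angles outside [0, 180] degrees.
#'
#' @param params One or more rows of growth-model parameters.
#' @return A tibble with columns `order`, `check`, `message` (zero rows when
#'   everything is consistent).
#' @export
validate_parameters <- function(params) {
  out <- list()
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    add <- function(check, msg) {
      out[[length(out) + 1]] <<- tibble::tibble(order = p$order, check = check,
                                                message = msg)
    }
    if (p$l_b + p$l_a > p$l_max) {
      add("branching_zone",
          sprintf("branching zone empty: l_b + l_a = %.3g > l_max = %.3g",
                  p$l_b + p$l_a, p$l_max))
    }
    if (p$r <= 0) add("elongation", "elongation rate r <= 0")
    if (p$a_i > p$a_max) add("radius", "initial radius a_i exceeds a_max")
    if (p$theta < 0 || p$theta > 180) {
      add("insertion_angle", "theta outside [0, 180] degrees")
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(order = integer(), check = character(),
                          message = character()))
  }
  dplyr::bind_rows(out)
}

param_keys <- c("l_b", "l_a", "l_n", "l_max", "r", "delta_x", "sigma",
                "theta", "N", "a_i", "a_max", "a_r")

#' Write / read growth-model parameter files
#'
#' JSON with one object per root order keyed `"order_<k>"`, holding exactly
#' the parameter keys plus a shared `units` block. The round trip is
#' lossless; unknown fields or missing orders/keys are errors.
#'
#' @param params Parameter tibble (one row per order).
#' @param path JSON path.
#' @return `read_parameters()` returns the parameter tibble.
#' @export
write_parameters <- function(params, path) {
  obj <- list(units = list(length = "cm", rate = "cm/d", a_r = "mm/h",
                           theta = "degrees"))
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    obj[[paste0("order_", p$order)]] <- as.list(p[param_keys])
  }
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  orders <- grep("^order_", names(obj), value = TRUE)
  if (length(orders) == 0) stop("no root orders in parameter file",
                                call. = FALSE)
  ks <- as.integer(sub("order_", "", orders))
  if (!identical(sort(ks), seq_len(max(ks)))) {
    stop("missing root order(s): expected 1..", max(ks), call. = FALSE)
  }
  rows <- lapply(orders[order(ks)], function(nm) {
    p <- obj[[nm]]
    miss <- setdiff(param_keys, names(p))
    if (length(miss) > 0) {
      stop("parameter file missing field(s) ", paste(miss, collapse = ", "),
           " for ", nm, call. = FALSE)
    }
    extra <- setdiff(names(p), param_keys)
    if (length(extra) > 0) {
      stop("unknown field(s) in ", nm, ": ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
    bad <- param_keys[vapply(param_keys, function(k) {
      k %in% c("l_b", "l_a", "l_n", "l_max", "r", "a_i", "a_max", "a_r") &&
        p[[k]] < 0
    }, logical(1))]
    if (length(bad) > 0) {
      stop("negative parameter(s) in ", nm, ": ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p <- lapply(p, as.numeric)
    tibble::as_tibble(p[param_keys])
  })
  out <- dplyr::bind_rows(rows)
  out$order <- sort(ks)
  out$N <- as.integer(out$N)
  out <- dplyr::relocate(out, "order")
  class(out) <- c("root_type_parameters", class(out))
  out
}
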