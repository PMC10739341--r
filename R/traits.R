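#' Construct a binary root image
#'
#' Wraps a binary mask and its physical scale. Row 1 is the top of the image
#' and depth grows with the row index; columns span the width. Any nonzero
#' pixel is foreground (root).
#'
#' @param mask Numeric/integer/logical matrix; nonzero = root.
#' @param scale_mm_per_px Physical size of one pixel, mm. Must be > 0; never
#'   auto-detected.
#' @param provenance `"observed"` or `"simulated"`.
#' @return An object of class `root_image`.
#' @export
root_image <- function(mask, scale_mm_per_px,
                       provenance = c("observed", "simulated")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  if (!is.numeric(scale_mm_per_px) || length(scale_mm_per_px) != 1 ||
      scale_mm_per_px <= 0) {
    stop("`scale_mm_per_px` must be a single positive number", call. = FALSE)
  }
  m <- matrix(as.integer(mask != 0), nrow = nrow(mask))
  structure(list(mask = m, scale_mm_per_px = scale_mm_per_px,
                 provenance = provenance),
            class = "root_image")
}

#' @export
print.root_image <- function(x, ...) {
  cat(sprintf("root_image %d x %d px (%.3g mm/px, %s), %d foreground px\n",
              nrow(x$mask), ncol(x$mask), x$scale_mm_per_px, x$provenance,
              sum(x$mask)))
  invisible(x)
}

#' Read / write binary root masks
#'
#' PNG (and TIFF, if the tiff package is available) masks with nonzero pixels
#' as root. Multichannel images are collapsed by channel maximum.
#'
#' @param path Image file path (extension decides the format).
#' @param scale_mm_per_px Pixel size in mm (must be supplied; no ruler
#'   detection).
#' @param provenance `"observed"` or `"simulated"`.
#' @return `read_root_mask()` returns a `root_image`.
#' @export
read_root_mask <- function(path, scale_mm_per_px, provenance = "observed") {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("tiff package required for TIFF masks", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(arr)) == 3) arr <- apply(arr, c(1, 2), max)
  root_image(arr > 0, scale_mm_per_px, provenance)
}

#' @rdname read_root_mask
#' @param image A `root_image`.
#' @export
write_root_mask <- function(image, path) {
  stopifnot(inherits(image, "root_image"))
  png::writePNG(image$mask * 1.0, path)
  invisible(path)
}

# ---- connected components ------------------------------------------------

# 8-connected labeling: EBImage::bwlabel is 4-connected, so merge its labels
# across diagonal adjacencies with a union-find pass.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask != 0), nrow = nrow(mask)))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # SE diagonal
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # SW diagonal
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relabel <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  out
}

#' Remove small foreground components from a binary mask
#'
#' Drops every 8-connected foreground component with fewer than `min_px`
#' pixels, mirroring the pre-extraction filtering of background specks
#' smaller than 2 pixels. Idempotent; larger components are untouched.
#'
#' @param mask Binary matrix, or a `root_image` (returned as the same class).
#' @param min_px Minimum component size kept, pixels. Default 2 (i.e. only
#'   single-pixel specks removed; a 2-px component is retained).
#' @return Filtered mask of the same type as the input.
#' @export
filter_small_components <- function(mask, min_px = 2) {
  if (inherits(mask, "root_image")) {
    mask$mask <- filter_small_components(mask$mask, min_px)
    return(mask)
  }
  m <- matrix(as.integer(mask != 0), nrow = nrow(mask))
  if (sum(m) == 0 || min_px <= 1) return(m)
  lab <- label_components_8(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  matrix(as.integer(lab %in% keep), nrow = nrow(m))
}

# ---- skeletonization -----------------------------------------------------

# one sub-iteration of Zhang-Suen thinning, vectorised over the whole grid
zs_pass <- function(img, step) {
  nr <- nrow(img); nc <- ncol(img)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- img
  sh <- function(dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  P2 <- sh(-1, 0); P3 <- sh(-1, 1); P4 <- sh(0, 1); P5 <- sh(1, 1)
  P6 <- sh(1, 0); P7 <- sh(1, -1); P8 <- sh(0, -1); P9 <- sh(-1, -1)
  B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
  A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
    (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
    (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
  if (step == 1) {
    cond <- img == 1 & B >= 2 & B <= 6 & A == 1 &
      (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
  } else {
    cond <- img == 1 & B >= 2 & B <= 6 & A == 1 &
      (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
  }
  img[cond] <- 0L
  img
}

#' Skeletonize a root mask and measure local radii
#'
#' Thins the (filtered) binary mask to a one-pixel-wide topological skeleton
#' (Zhang-Suen), attaches a local radius to every skeleton pixel from the
#' Euclidean distance transform of the mask, and classifies skeleton pixels
#' by their 8-neighbourhood degree: tips (degree <= 1) and branch points
#' (degree >= 3).
#'
#' @param image A `root_image` (ideally after [filter_small_components()]).
#' @return An object of class `root_skeleton`: logical matrix `skeleton`,
#'   matrix `radius_mm` (NA off-skeleton), integer matrix `degree`, tip and
#'   branch pixel counts, and the source scale.
#' @export
skeletonize_and_measure <- function(image) {
  stopifnot(inherits(image, "root_image"))
  m <- image$mask
  sk <- m
  if (sum(sk) > 0) {
    repeat {
      before <- sk
      sk <- zs_pass(sk, 1)
      sk <- zs_pass(sk, 2)
      if (identical(sk, before)) break
    }
  }
  dist_px <- EBImage::distmap(m)            # Euclidean distance to background
  radius <- matrix(NA_real_, nrow(m), ncol(m))
  # distance is measured centre-to-centre; the stroke edge lies half a pixel
  # closer, so the local radius is (distance - 0.5) px
  radius[sk == 1] <- pmax(dist_px[sk == 1] - 0.5, 0.5) *
    image$scale_mm_per_px
  sk_log <- sk == 1
  steps <- skeleton_steps(sk_log)
  # node degree from the pruned step graph, not the raw 8-neighbourhood
  deg <- matrix(NA_integer_, nrow(m), ncol(m))
  deg[sk_log] <- 0L
  if (nrow(steps) > 0) {
    nr <- nrow(m)
    ends <- c((steps[, "c1"] - 1) * nr + steps[, "r1"],
              (steps[, "c2"] - 1) * nr + steps[, "r2"])
    tab <- table(ends)
    deg[as.integer(names(tab))] <- as.integer(tab)
  }
  n_tips <- sum(deg <= 1, na.rm = TRUE)     # isolated pixel counts as a tip
  n_branch <- sum(deg >= 3, na.rm = TRUE)
  structure(list(skeleton = sk_log, radius_mm = radius, degree = deg,
                 steps = steps, n_tips = n_tips, n_branch_points = n_branch,
                 scale_mm_per_px = image$scale_mm_per_px),
            class = "root_skeleton")
}

# number of 8-neighbours that are foreground, per pixel
neighbor_count <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  p <- matrix(0L, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- img
  sh <- function(dr, dc) p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  sh(-1, -1) + sh(-1, 0) + sh(-1, 1) + sh(0, -1) + sh(0, 1) +
    sh(1, -1) + sh(1, 0) + sh(1, 1)
}

#' @export
print.root_skeleton <- function(x, ...) {
  cat(sprintf("root_skeleton: %d px, %d tips, %d branch points\n",
              sum(x$skeleton), x$n_tips, x$n_branch_points))
  invisible(x)
}

# ---- trait extraction ----------------------------------------------------

# enumerate unique skeleton steps (edges between 8-adjacent skeleton pixels),
# returning one row per edge: rows/cols of both endpoints + step length (px).
# A diagonal edge whose endpoints share an orthogonal skeleton neighbour is
# redundant (the path runs through the corner) and would double-count length
# and inflate node degrees, so it is dropped.
skeleton_steps <- function(sk) {
  idx <- which(sk, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(matrix(numeric(0), ncol = 5,
                  dimnames = list(NULL, c("r1", "c1", "r2", "c2", "len"))))
  }
  nr <- nrow(sk)
  key <- (idx[, 2] - 1) * nr + idx[, 1]
  on <- logical(nr * ncol(sk)); on[key] <- TRUE
  # scan each pixel's E, SE, S, SW neighbour once so edges are not duplicated
  offs <- rbind(c(0, 1, 1), c(1, 1, sqrt(2)), c(1, 0, 1), c(1, -1, sqrt(2)))
  out <- list()
  for (k in 1:4) {
    r2 <- idx[, 1] + offs[k, 1]; c2 <- idx[, 2] + offs[k, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(sk)
    ok[ok] <- on[(c2[ok] - 1) * nr + r2[ok]]
    if (any(ok)) {
      out[[k]] <- cbind(r1 = idx[ok, 1], c1 = idx[ok, 2],
                        r2 = r2[ok], c2 = c2[ok], len = offs[k, 3])
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(matrix(numeric(0), ncol = 5,
                  dimnames = list(NULL, c("r1", "c1", "r2", "c2", "len"))))
  }
  is_diag <- out[, "len"] > 1
  if (any(is_diag)) {
    at <- function(r, c) {
      ok <- r >= 1 & r <= nr & c >= 1 & c <= ncol(sk)
      v <- logical(length(r))
      v[ok] <- on[(c[ok] - 1) * nr + r[ok]]
      v
    }
    corner <- at(out[, "r1"], out[, "c2"]) | at(out[, "r2"], out[, "c1"])
    out <- out[!(is_diag & corner), , drop = FALSE]
  }
  out
}

# decompose the pruned skeleton graph into maximal paths: chains running
# end/junction -> end/junction (plus any pure cycles). Returns a list of
# linear-index vectors into the mask.
skeleton_paths <- function(sk, steps) {
  if (nrow(steps) == 0) return(list())
  nr <- nrow(sk)
  e1 <- (steps[, "c1"] - 1) * nr + steps[, "r1"]
  e2 <- (steps[, "c2"] - 1) * nr + steps[, "r2"]
  adj <- split(c(e2, e1), c(e1, e2))
  deg <- lengths(adj)
  eid <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  paths <- list()
  walk <- function(start, nxt) {
    path <- c(start, nxt)
    prev <- start; cur <- nxt
    while (deg[[as.character(cur)]] == 2 && cur != start) {
      nb <- adj[[as.character(cur)]]
      nx <- nb[nb != prev][1]
      if (is.na(nx)) break
      path <- c(path, nx); prev <- cur; cur <- nx
    }
    path
  }
  emit <- function(p) {
    for (i in seq_len(length(p) - 1)) assign(eid(p[i], p[i + 1]), TRUE, seen)
    paths[[length(paths) + 1]] <<- p
  }
  nodes <- as.integer(names(adj))
  for (t in nodes[deg != 2]) {
    for (nb in adj[[as.character(t)]]) {
      if (is.null(seen[[eid(t, nb)]])) emit(walk(t, nb))
    }
  }
  for (k in seq_along(e1)) {       # leftover pure cycles
    if (is.null(seen[[eid(e1[k], e2[k])]])) emit(walk(e1[k], e2[k]))
  }
  paths
}

# polyline metrics of one skeleton path, smoothed by subsampling every
# `stride` pixels (suppresses chain-code staircase noise): length (px),
# length-weighted |angle from downward vertical| numerator (deg * px), and
# surface-area numerator (pi * 2r * chord, mm * px) from local radii
path_metrics <- function(idx, nr, radius_mm, stride = 4L) {
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  n <- length(idx)
  if (n < 2) return(c(len = 0, ang = 0, surf = 0))
  at <- unique(c(seq(1L, n, by = stride), n))
  dr <- diff(r[at]); dc <- diff(c[at])
  chord <- sqrt(dr^2 + dc^2)
  ang <- atan2(abs(dc), abs(dr)) * 180 / pi
  rad <- radius_mm[idx]
  mrad <- vapply(seq_len(length(at) - 1), function(i) {
    mean(rad[at[i]:at[i + 1]])
  }, numeric(1))
  c(len = sum(chord), ang = sum(ang * chord),
    surf = sum(pi * 2 * mrad * chord))
}

#' Extract architecture traits from a skeletonized root image
#'
#' Computes a RhizoVision-style trait record: counts (tips, branch points,
#' holes), lengths (total root length from skeleton steps, max depth/width),
#' areas (network, convex hull, surface), diameter statistics from the
#' distance transform, solidity, and the length-weighted mean absolute
#' orientation of skeleton steps from the downward vertical (0 degrees =
#' straight down, 90 = horizontal). All outputs in mm / mm^2 / degrees.
#'
#' The convex hull is taken over foreground pixel *corners* (centres +- half
#' a pixel) so that a solid convex blob has solidity exactly 1. Holes are
#' 4-connected background components not touching the image border.
#'
#' @param skeleton A `root_skeleton` from [skeletonize_and_measure()].
#' @param image The `root_image` the skeleton was derived from.
#' @return A one-row tibble (a trait record). An empty mask yields zero
#'   counts/lengths, `NA` solidity and diameters, and `empty = TRUE`.
#' @export
extract_traits <- function(skeleton, image) {
  stopifnot(inherits(skeleton, "root_skeleton"), inherits(image, "root_image"))
  s <- image$scale_mm_per_px
  m <- image$mask
  fg <- which(m == 1, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    return(tibble::tibble(
      number_of_root_tips = 0L, number_of_branch_points = 0L,
      total_root_length = 0, network_area = 0, convex_area = 0,
      solidity = NA_real_, max_depth = 0, max_width = 0,
      avg_diameter = NA_real_, median_diameter = NA_real_,
      max_diameter = NA_real_, surface_area = 0,
      avg_root_orientation = NA_real_, holes = 0L, empty = TRUE
    ))
  }
  steps <- skeleton$steps %||% skeleton_steps(skeleton$skeleton)
  paths <- skeleton_paths(skeleton$skeleton, steps)
  pm <- vapply(paths, path_metrics, numeric(3), nr = nrow(m),
               radius_mm = skeleton$radius_mm)
  if (length(paths) > 0 && sum(pm["len", ]) > 0) {
    total_len <- sum(pm["len", ]) * s
    avg_orient <- sum(pm["ang", ]) / sum(pm["len", ])
    surf <- sum(pm["surf", ]) * s     # mm radius * px chord -> mm^2
    # tip compensation: thinning stops about one local radius short of each
    # stroke cap, so extend every tip to the cap it points at
    tip_r <- skeleton$radius_mm[!is.na(skeleton$degree) &
                                  skeleton$degree <= 1]
    ext <- pmax(tip_r - 0.5 * s, 0)
    total_len <- total_len + sum(ext)
    surf <- surf + sum(pi * 2 * tip_r * ext)
  } else {
    total_len <- 0
    avg_orient <- 0   # single-pixel skeleton: no steps, define as vertical
    surf <- 0
  }
  network_area <- nrow(fg) * s^2
  convex_area <- hull_area_px(fg) * s^2
  radii <- skeleton$radius_mm[skeleton$skeleton]
  diam <- 2 * radii
  tibble::tibble(
    number_of_root_tips = skeleton$n_tips,
    number_of_branch_points = skeleton$n_branch_points,
    total_root_length = total_len,
    network_area = network_area,
    convex_area = convex_area,
    solidity = network_area / convex_area,
    max_depth = (max(fg[, 1]) - min(fg[, 1]) + 1) * s,
    max_width = (max(fg[, 2]) - min(fg[, 2]) + 1) * s,
    # length-weighted along skeleton paths (junction pixels carry no extra
    # weight); falls back to the pixel mean for step-free skeletons
    avg_diameter = if (total_len > 0) surf / (pi * total_len) else mean(diam),
    median_diameter = stats::median(diam),
    max_diameter = max(diam),
    surface_area = surf,
    avg_root_orientation = avg_orient,
    holes = count_holes(m),
    empty = FALSE
  )
}

# convex hull area over pixel corners (shoelace), px^2
hull_area_px <- function(fg) {
  if (nrow(fg) == 1) return(1)
  h1 <- grDevices::chull(fg)          # hull of centres first, to shrink input
  corners <- do.call(rbind, lapply(list(c(-0.5, -0.5), c(-0.5, 0.5),
                                        c(0.5, -0.5), c(0.5, 0.5)),
                                   function(d) sweep(fg[h1, , drop = FALSE],
                                                     2, -d)))
  h <- grDevices::chull(corners)
  x <- corners[h, 1]; y <- corners[h, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# background components (4-connected) fully enclosed by foreground
count_holes <- function(m) {
  bg <- matrix(as.numeric(m == 0), nrow = nrow(m))
  lab <- EBImage::bwlabel(bg)          # 4-connected, matching hole duality
  if (max(lab) == 0) return(0L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sum(!seq_len(max(lab)) %in% border)
}

#' Full mask-to-traits pipeline
#'
#' Convenience wrapper: filter small components, skeletonize, extract.
#'
#' @inheritParams skeletonize_and_measure
#' @param min_px Passed to [filter_small_components()].
#' @return One-row trait tibble.
#' @export
measure_root_image <- function(image, min_px = 2) {
  image <- filter_small_components(image, min_px)
  extract_traits(skeletonize_and_measure(image), image)
}

# ---- trait table IO ------------------------------------------------------

key_traits <- c("number_of_root_tips", "total_root_length", "network_area",
                "convex_area", "solidity", "avg_diameter")

#' Read / write trait tables
#'
#' CSV round trip of trait records. Reading checks that the key traits
#' (number of roots, total root length, network area, convex area, solidity,
#' average diameter) are present and preserves any extra columns verbatim.
#'
#' @param path CSV path.
#' @param records Data frame of trait records (one row per image).
#' @return `read_trait_csv()` returns a tibble.
#' @export
read_trait_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(key_traits, names(x))
  if (length(miss) > 0) {
    stop("trait table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname read_trait_csv
#' @export
write_trait_csv <- function(records, path) {
  readr::write_csv(tibble::as_tibble(records), path)
  invisible(path)
}
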