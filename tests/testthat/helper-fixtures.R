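# shared fixture builders; everything is generated in code at test time

# solid vertical bar mask: `len` px tall, `width` px wide, 1 px = scale mm
bar_mask <- function(len = 100, width = 5, nr = len + 20, nc = width + 35,
                     top = 11, left = 18) {
  m <- matrix(0L, nr, nc)
  m[top:(top + len - 1), left:(left + width - 1)] <- 1L
  m
}

# three-armed "Y": one vertical arm down, two diagonal arms up
y_mask <- function(arm = 40) {
  m <- matrix(0L, 100, 100)
  for (k in 0:(arm - 1)) {
    m[50 + k, 50] <- 1L
    m[50 - k, 50 - k] <- 1L
    m[50 - k, 50 + k] <- 1L
  }
  m
}

ring_mask <- function(n = 60, r_in = 15, r_out = 20) {
  ctr <- n / 2
  d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  matrix(as.integer(d >= r_in & d <= r_out), n, n)
}

# single-order, single-root parameter row used in deterministic limits
straight_params <- function(l_max = 25, r = 1.2) {
  p <- example_parameters()[1, ]
  p$sigma <- 0
  p$l_n <- l_max * 10       # no lateral sites inside the axis
  p$l_max <- l_max
  p$r <- r
  p
}

# lateral-free wiggly primary for render/extract round trips
roundtrip_cfg <- function(seed, days = 12) {
  simulation_config(days, seed = seed, n_primary_roots = 1, sd_frac = 0.1,
                    max_order = 1)
}

# moderately-wiggly gravitropic primary whose projection stays legible
# (no self-occlusion), the precondition of the length-recovery contract
roundtrip_params <- function() {
  p <- example_parameters()[1, ]
  p$sigma <- 10
  p$N <- 8L
  p
}
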