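# shared fixtures, all generated in code

# a smooth deterministic test image in [0, 1] (bilinear-friendly, unlike noise)
smooth_image <- function(side = 32) {
  g <- seq(0, 1, length.out = side)
  outer(g, g, function(r, c) (sin(4 * r) * cos(3 * c) + 1) / 2)
}

# a tiny two-class dataset of flat images; fast to split and count
toy_dataset <- function(n_ms = 6, n_hc = 6, side = 8) {
  imgs <- lapply(seq_len(n_ms + n_hc), function(i) {
    m <- matrix(i / (n_ms + n_hc + 1), side, side)
    m[1, 1] <- 0; m[side, side] <- 1  # non-degenerate range
    m
  })
  image_dataset(imgs, c(rep("MS", n_ms), rep("HC", n_hc)))
}

# small synthetic study used by several training tests: normalized images,
# 32x32, both classes
small_study <- function(n = 60, seed = 42, contrast = 0.35, side = 32) {
  normalize_dataset(generate_dataset(
    synth_params(image_side = side, plaque_contrast = contrast),
    n_ms = n, n_hc = n, seed = seed))
}

# a micro architecture for 32x32 experiments
micro_config <- function(pooling = "stochastic", dropout_p = 0.2) {
  small_config(pooling, input_side = 32, widths = c(6, 12), fc_dim = 8,
               dropout_p = dropout_p)
}

# independent naive signed-rank enumeration: walks every sign vector via
# bit masks (never shares code with exact_tail)
naive_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  rk <- rank(abs(d))
  w_obs <- min(sum(rk[d < 0]), sum(rk[d > 0]))
  total <- 0L
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    if (sum(rk[signs]) <= w_obs + 1e-9) total <- total + 1L
  }
  min(1, 2 * total / 2^n)
}
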