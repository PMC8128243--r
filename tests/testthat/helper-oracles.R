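# Independent oracles and small fixture builders used across tests.

# Brute-force image-source enumeration: repeatedly mirror across the four
# wall planes, recording the minimal reflection count per position.
oracle_image_sources <- function(room, src, max_order) {
  reflect <- function(p) list(
    c(-p[1], p[2]), c(2 * room$width_m - p[1], p[2]),
    c(p[1], -p[2]), c(p[1], 2 * room$depth_m - p[2]))
  key <- function(p) paste(round(p, 9), collapse = ",")
  seen <- new.env(parent = emptyenv())
  assign(key(src), 0L, envir = seen)
  frontier <- list(src)
  for (o in seq_len(max_order)) {
    nxt <- list()
    for (p in frontier) for (q in reflect(p)) {
      k <- key(q)
      if (!exists(k, envir = seen)) {
        assign(k, o, envir = seen)
        nxt <- c(nxt, list(q))
      }
    }
    frontier <- nxt
  }
  ls(seen)
}

# Long-format null within-subject table: n subjects x a x b iid Gaussian.
null_rm_table <- function(n, a, b) {
  expand.grid(participant = seq_len(n), A = letters[seq_len(a)],
              B = seq_len(b), KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE) |>
    transform(y = rnorm(n * a * b))
}

# Population-mean VAE contrast accounting for between-participant jitter:
# E[ M (1 - exp(-T / tau)) ] with M ~ N(m, sd_m) truncated at 0 and
# log(tau) ~ N(log(t0), sd_lt), by quadrature.
expected_vae <- function(m, t0, duration, sd_m, sd_lt) {
  e_m <- {
    a <- -m / sd_m
    m + sd_m * dnorm(a) / (1 - pnorm(a))   # truncated-normal mean
  }
  e_sat <- integrate(function(z)
    (1 - exp(-duration / exp(log(t0) + sd_lt * z))) * dnorm(z),
    -8, 8)$value
  e_m * e_sat
}

make_seed <- function(...) set.seed(42)
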