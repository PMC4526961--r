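# Brute-force enumeration oracles, written independently of the package's
# exact paths (bitmask subset sweeps; the package uses combn / convolution).

oracle_mw_p <- function(x, y) {
  m <- length(x)
  N <- m + length(y)
  r <- rank(c(x, y))
  mu <- m * (N + 1) / 2
  obs <- abs(sum(r[seq_len(m)]) - mu)
  bits <- 2^(0:(N - 1))
  cnt <- 0L
  tot <- 0L
  for (mask in 0:(2^N - 1)) {
    idx <- which(bitwAnd(mask, bits) > 0)
    if (length(idx) != m) next
    tot <- tot + 1L
    if (abs(sum(r[idx]) - mu) >= obs - 1e-9) cnt <- cnt + 1L
  }
  cnt / tot
}

oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  mu <- n * (n + 1) / 4
  obs <- abs(sum(r[d > 0]) - mu)
  bits <- 2^(0:(n - 1))
  cnt <- 0L
  for (mask in 0:(2^n - 1)) {
    pos <- bitwAnd(mask, bits) > 0
    if (abs(sum(r[pos]) - mu) >= obs - 1e-9) cnt <- cnt + 1L
  }
  cnt / 2^n
}

# a complete record with every scored question favorable; overrides by name
favorable_record <- function(map = default_scoring_map(), ...) {
  over <- list(...)
  rec <- list()
  for (id in names(map)) {
    d <- map[[id]]
    if (d$documentation_only) {
      rec[[id]] <- d$vocabulary[1]
    } else {
      best <- d$vocabulary[which.max(d$scores)]
      rec[[id]] <- best
    }
  }
  for (id in names(over)) rec[[id]] <- over[[id]]
  rec
}

record_df <- function(..., patient_id = "P1") {
  rec <- favorable_record(...)
  cbind(data.frame(patient_id = patient_id, stringsAsFactors = FALSE),
        as.data.frame(rec, stringsAsFactors = FALSE, check.names = FALSE))
}

# tiny cohort CSV on disk for I/O tests
write_tiny_cohort <- function(path, n = 3) {
  sc <- sim_scenario(n_eligible = n, noneligible_ratio = 0.5, seed = 42)
  co <- simulate_cohort(sc)
  write_responses(co, path)
  co
}
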