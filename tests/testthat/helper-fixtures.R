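# Small fixtures shared across test files. Everything is generated in code;
# heavy objects are computed once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# A psd object holding an exact analytic spectrum (no estimation noise).
analytic_psd <- function(freq, power) {
  structure(list(freq = freq, power = power, meta = list()), class = "psd")
}

# Exact power law sampled on an integer grid.
power_law_psd <- function(beta, f_max = 100, offset = 1) {
  f <- seq_len(f_max)
  analytic_psd(f, offset * f^(-beta))
}

# Short simulated series reused by several files.
short_ts <- function() cached("short_ts", synthesize(
  sim_spec(1.5, duration_s = 30, f_sample = 500, seed = 11)))
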