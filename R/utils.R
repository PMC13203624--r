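# internal helpers shared across modules

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic 31-bit sub-seed from a master seed and a string key, so each
# (category, scenario) record gets its own reproducible RNG substream and
# adding a record never perturbs another record's draws.
derive_seed <- function(master_seed, key) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

stop_config <- function(...) {
  stop(structure(class = c("herdfit_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
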