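# Internal helpers: seeded random streams and argument checks.

# Named offsets for the single-seed stream-splitting scheme.  Every stage of
# the generator and every stochastic analysis step draws from its own stream
# so that toggling one stage never perturbs another.
.stream_offsets <- c(
  groups      = 11L,
  probes      = 23L,
  genotypes   = 37L,
  expression  = 53L,
  covariates  = 67L,
  survival    = 79L,
  marks       = 97L,
  rotation    = 113L,
  classifier  = 131L,
  discovery   = 149L,
  pipeline    = 167L
)

#' Derive a stream seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' streams, so stages are independently reproducible.
#'
#' @param seed master integer seed.
#' @param stream stream name, one of the documented stage names.
#' @return an integer seed below 2^31 for `set.seed()`.
#' @keywords internal
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!stream %in% names(.stream_offsets)) {
    stop("unknown random stream: ", stream)
  }
  off <- as.numeric(.stream_offsets[[stream]])
  as.integer((abs(seed) * 1009 + off * 9973) %% 2147483647)
}

set_stream <- function(seed, stream) {
  set.seed(stream_seed(seed, stream))
}

# Row-wise variance of a matrix with denominator n - 1.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 columns for a variance")
  mu <- rowMeans(x)
  (rowSums(x * x) - n * mu * mu) / (n - 1)
}

# Stop unless all names in `need` are columns of data.frame `df`.
check_columns <- function(df, need, what = deparse(substitute(df))) {
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}
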