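#' @keywords internal
"_PACKAGE"

# Tolerance for "fractions sum to one" checks on DVHs.
.VOL_TOL <- 1e-6

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package internals never perturb the
#' caller's random stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

#' Derive a deterministic substream seed from a master seed and string labels
#'
#' Polynomial rolling hash modulo 2^31 - 1 so each (patient, modality, organ)
#' triple owns an independent stream: adding an organ or patient never
#' perturbs other draws.
#' @noRd
substream_seed <- function(seed, ...) {
  labels <- paste(unlist(list(...)), collapse = "/")
  m <- 2147483647
  h <- as.double(seed %% m)
  for (code in utf8ToInt(labels)) h <- (h * 31 + code) %% m
  as.integer(h %% 2147483646L + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
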