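# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_vf <- function(...) stop(sprintf(...), call. = FALSE)

warn_vf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == round(x) && x >= 0

#' Derive a reproducible sub-seed from a master seed
#'
#' Expands one master seed into independent per-stage / per-subject streams by
#' a deterministic multiplicative hash; every source of randomness in the
#' package draws its seed through this so that one integer reproduces an entire
#' cohort and analysis.
#'
#' @param master Integer master seed.
#' @param ... One or more integers or strings identifying the stream
#'   (e.g. subject index, session, stage name).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  parts <- list(...)
  h <- as.double(master) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    for (v in as.double(p)) {
      h <- (h * 48271 + v + 11) %% 2147483647
    }
  }
  as.integer(h %% 2147483645 + 1)
}

# run expr with a local RNG state seeded by `seed`, restoring the caller's state
with_seed <- function(seed, expr) {
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

# deterministic polynomial hash of a character scalar, for report provenance
config_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

check_square <- function(x, what) {
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop_vf("%s must be a square matrix", what)
}

check_symmetric <- function(x, what, tol = 1e-8) {
  check_square(x, what)
  if (max(abs(x - t(x))) > tol)
    stop_vf("%s must be symmetric (max asymmetry %.3g)", what,
            max(abs(x - t(x))))
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = is.matrix(x))
    if (is.matrix(bad)) {
      stop_vf("%s contains non-finite values (first at row %d, column %d)",
              what, bad[1, 1], bad[1, 2])
    }
    stop_vf("%s contains non-finite values (first at index %d)", what, bad[1])
  }
}
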