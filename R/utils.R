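# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded generators do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derived from a master seed and a label, so that
# per-group / per-condition random streams do not depend on how many other
# groups are present in the same call.
derive_seed <- function(master, label) {
  codes <- utf8ToInt(as.character(label))
  h <- sum(codes * (seq_along(codes) %% 97L + 1L)) %% 1000003L
  as.integer((abs(as.numeric(master)) %% 65011 + 7919 * h) %% 2147483629)
}

# Beta-binomial draws parameterized by the intraclass correlation rho.
# rho = 0 reduces exactly to the binomial.
rbetabinom <- function(n, size, prob, rho) {
  stopifnot(rho >= 0, rho < 1)
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  if (rho == 0) {
    return(stats::rbinom(n, size, prob))
  }
  nu <- 1 / rho - 1
  p <- stats::rbeta(n, prob * nu, (1 - prob) * nu)
  stats::rbinom(n, size, p)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Reserved label for the empty control plasmid; every ARG is compared to it.
VECTOR_LABEL <- "VECTOR"

`%||%` <- function(a, b) if (is.null(a)) b else a
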