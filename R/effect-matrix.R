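# Strain x ARG effect matrix: per-cell mean effect ratio, measurement sd
# and replicate count. This is the container handed to the community
# simulator and produced by both the synthetic generator and the assay
# aggregation.

effect_matrix_new <- function(mean, sd, n) {
  stopifnot(identical(dim(mean), dim(sd)), identical(dim(mean), dim(n)))
  if (any(sd[is.finite(sd)] < 0)) stop("sd must be >= 0", call. = FALSE)
  if (any(n[is.finite(n)] < 0)) stop("n must be >= 0", call. = FALSE)
  structure(list(
    strains = rownames(mean), args = colnames(mean),
    mean = mean, sd = sd, n = n
  ), class = "effect_matrix")
}

#' Build a strain-by-ARG effect matrix
#'
#' Reshapes an `arg_effect_table` (from [aggregate_effects()] or
#' [fit_arg_effects()]) into matrices of mean effect ratio, measurement
#' uncertainty and replicate count. The `sd` slot is the standard error of
#' the mean effect (replicate scatter over the vector mean, divided by
#' `sqrt(n)`): it quantifies how uncertain the estimate itself is, which is
#' what the community simulator's fitness draws are meant to propagate.
#' The vector-control column's mean is pinned at exactly 1 (it is its own
#' denominator) while keeping its own uncertainty. Missing combinations
#' hold `NA` means and `n = 0`, and are reported, not silently zeroed.
#'
#' @param x an `arg_effect_table` or an `arg_fit` object.
#' @param environment which environment to extract (required when `x`
#'   covers more than one).
#' @return An object of class `effect_matrix` with elements `strains`,
#'   `args`, `mean`, `sd`, `n`.
#' @export
effect_matrix <- function(x, environment = NULL) {
  if (inherits(x, "arg_fit")) x <- x$effects
  stopifnot(inherits(x, "data.frame"))
  envs <- unique(x$environment)
  if (is.null(environment)) {
    if (length(envs) > 1) {
      stop("multiple environments present; pick one of: ",
           paste(envs, collapse = ", "), call. = FALSE)
    }
    environment <- envs
  }
  x <- x[x$environment == environment, , drop = FALSE]
  if (nrow(x) == 0) stop("no rows for environment ", environment, call. = FALSE)
  strains <- sort(unique(x$strain_id))
  args <- c(sort(setdiff(unique(x$arg_id), VECTOR_LABEL)), VECTOR_LABEL)
  shape <- function(fill) {
    matrix(fill, length(strains), length(args),
           dimnames = list(strains, args))
  }
  m <- shape(NA_real_); s <- shape(NA_real_); nn <- shape(0L)
  i <- cbind(match(x$strain_id, strains), match(x$arg_id, args))
  m[i] <- x$effect_ratio
  # standard error of the mean effect: replicate fitness scatter over the
  # vector mean in that strain, divided by sqrt(n); for the vector itself
  # this is the uncertainty of its own mean.
  vrows <- x[x$arg_id == VECTOR_LABEL, , drop = FALSE]
  vecW <- stats::setNames(vrows$mean_W, vrows$strain_id)
  s[i] <- x$sd_W / unname(vecW[x$strain_id]) / sqrt(pmax(x$n, 1))
  nn[i] <- x$n
  m[, VECTOR_LABEL] <- ifelse(is.na(m[, VECTOR_LABEL]), NA, 1)
  n_missing <- sum(is.na(m))
  if (n_missing > 0) {
    message(n_missing, " strain x ARG cell(s) have no estimate")
  }
  effect_matrix_new(m, s, nn)
}

#' @export
print.effect_matrix <- function(x, ...) {
  cat("Effect matrix:", length(x$strains), "strains x",
      length(x$args), "ARGs (incl. vector)\n")
  cat("mean effect ratios:\n")
  print(round(x$mean, 4))
  invisible(x)
}
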