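# Resampling-based many-against-one comparisons: every ARG group is tested
# against the shared vector-control group with a max-|t| null distribution,
# so the family-wise error rate over the whole set of comparisons is
# controlled (the resampling analogue of a Dunnett test).

#' Many-against-one test with max-|t| resampling adjustment
#'
#' Computes a pooled-variance two-sample t statistic for each comparison
#' group against the control group, then builds the joint null by
#' resampling: residuals (values minus their group mean) are bootstrap
#' resampled within each group, the t statistics recomputed, and the
#' maximum |t| across groups recorded per resample. The adjusted p-value of
#' a group is the add-one-corrected fraction of null max-|t| values at
#' least as large as its observed |t|; the unadjusted p-value uses the
#' group's own null |t| values. By construction the adjusted p-value is
#' never smaller than the unadjusted one, and (because each group's
#' resampling stream is seeded from its own label) adding further
#' comparison groups can only increase adjusted p-values.
#'
#' @param values numeric vector of replicate-level values (e.g. relative
#'   fitness or ARG-effect estimates).
#' @param groups group label per value; must include `control`.
#' @param control label of the control group (default `"VECTOR"`).
#' @param n_resamples number of null resamples.
#' @param seed master seed for the resampling streams.
#' @return Data frame with one row per non-control group: `group`, `n`,
#'   `mean`, `t`, `p`, `p_adj`.
#' @export
many_to_one_test <- function(values, groups, control = VECTOR_LABEL,
                             n_resamples = 999, seed = 1) {
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values)
  values <- values[keep]
  groups <- as.character(groups)[keep]
  if (!control %in% groups) {
    stop("pairing error: control group '", control, "' missing",
         call. = FALSE)
  }
  labs <- setdiff(unique(groups), control)
  if (length(labs) == 0) stop("no comparison groups", call. = FALSE)
  split_vals <- split(values, groups)
  ns <- vapply(split_vals, length, integer(1))
  if (any(ns < 2)) {
    stop("each group needs n >= 2 (offending: ",
         paste(names(ns)[ns < 2], collapse = ", "), ")", call. = FALSE)
  }
  pooled_t <- function(xa, xc) {
    na <- length(xa); nc <- length(xc)
    sp2 <- ((na - 1) * stats::var(xa) + (nc - 1) * stats::var(xc)) /
      (na + nc - 2)
    d <- mean(xa) - mean(xc)
    if (sp2 <= 0) {
      return(if (d == 0) 0 else sign(d) * Inf)
    }
    d / sqrt(sp2 * (1 / na + 1 / nc))
  }

  xc <- split_vals[[control]]
  t_obs <- vapply(labs, function(g) pooled_t(split_vals[[g]], xc), numeric(1))

  # Null resamples: per-group bootstrap of centred residuals. Streams are
  # seeded by group label so they are invariant to the rest of the family.
  boot_group <- function(g) {
    x <- split_vals[[g]]
    res <- x - mean(x)
    with_seed(derive_seed(seed, paste0("maxt_", g)), {
      matrix(sample(res, n_resamples * length(x), replace = TRUE),
             nrow = n_resamples)
    })
  }
  ctrl_boot <- boot_group(control)
  t_null <- matrix(NA_real_, n_resamples, length(labs),
                   dimnames = list(NULL, labs))
  for (g in labs) {
    gb <- boot_group(g)
    na <- ns[[g]]; nc <- ns[[control]]
    ma <- rowMeans(gb)
    mc <- rowMeans(ctrl_boot)
    va <- pmax((rowSums(gb^2) - na * ma^2) / (na - 1), 0)
    vc <- pmax((rowSums(ctrl_boot^2) - nc * mc^2) / (nc - 1), 0)
    sp2 <- ((na - 1) * va + (nc - 1) * vc) / (na + nc - 2)
    tt <- (ma - mc) / sqrt(sp2 * (1 / na + 1 / nc))
    tt[sp2 <= 0 & (ma - mc) == 0] <- 0
    t_null[, g] <- tt
  }
  max_null <- apply(abs(t_null), 1, max)
  p <- vapply(labs, function(g) {
    (1 + sum(abs(t_null[, g]) >= abs(t_obs[[g]]))) / (n_resamples + 1)
  }, numeric(1))
  p_adj <- vapply(labs, function(g) {
    (1 + sum(max_null >= abs(t_obs[[g]]))) / (n_resamples + 1)
  }, numeric(1))
  data.frame(
    group = labs,
    n = as.integer(ns[labs]),
    mean = vapply(labs, function(g) mean(split_vals[[g]]), numeric(1)),
    t = unname(t_obs),
    p = unname(p),
    p_adj = unname(p_adj),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
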