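# Competitive-fitness estimation from flow-cytometry competition counts,
# the start-frequency quality filter, replicate aggregation, and the two
# assay-bias diagnostics (plasmid loss, compensatory mutations), plus qPCR
# copy-number math.

day0_test_freq <- function(records) {
  records$test_day0 / (records$test_day0 + records$ref_day0)
}

#' Filter competitions by starting frequency
#'
#' Clumping of cells in the cytometer flow cell can distort event counts.
#' Records are excluded when the measured day-0 frequency of either
#' competitor differs from the 50:50 target by more than the tolerance
#' (default 15 absolute percentage points, boundary inclusive). The decision
#' uses only day-0 data, never the fitness implied by the frequency change.
#'
#' @param records a `competition_records` data frame.
#' @param target target day-0 test-competitor frequency (default 0.5).
#' @param tolerance allowed absolute deviation in frequency units, in
#'   `(0, 0.5)`.
#' @param relative if `TRUE`, interpret `tolerance` as a fraction of
#'   `target` instead of an absolute deviation.
#' @return List with `retained` and `removed` (both `competition_records`),
#'   and `reasons`, a per-record character vector (`"ok"` or a message
#'   giving the offending day-0 frequency).
#' @export
filter_start_frequency <- function(records, target = 0.5, tolerance = 0.15,
                                   relative = FALSE) {
  records <- as_competition_records(as.data.frame(records))
  if (tolerance <= 0 || tolerance >= 0.5) {
    stop("tolerance must be in (0, 0.5)", call. = FALSE)
  }
  p0 <- day0_test_freq(records)
  tol <- if (relative) tolerance * target else tolerance
  # |p_test - target| == |p_ref - (1 - target)| for two competitors, so one
  # check covers both; small epsilon keeps the boundary inclusive under
  # floating-point representation of count ratios.
  keep <- abs(p0 - target) <= tol + 1e-12
  reasons <- ifelse(keep, "ok",
                    sprintf("day-0 test frequency %.3f outside [%.2f, %.2f]",
                            p0, target - tol, target + tol))
  list(
    retained = records[keep, , drop = FALSE],
    removed = records[!keep, , drop = FALSE],
    reasons = reasons
  )
}

#' Relative fitness from competition counts
#'
#' For each record, the fitness of the test competitor relative to the
#' GFP-tagged reference is the ratio of realized log fold-changes over one
#' competition cycle:
#' \deqn{W = \frac{\ln(d\, p_{t,1} / p_{t,0})}{\ln(d\, p_{r,1} / p_{r,0})}}
#' where \eqn{p_{t,\cdot}} and \eqn{p_{r,\cdot}} are the day-0/day-1
#' proportions of test and reference events and \eqn{d} is the net
#' fold-growth per cycle. The growth multiplier applies to both competitors.
#' Records with a day-0 or day-1 proportion of exactly 0 or 1 yield a
#' non-finite estimate and are flagged rather than pseudocounted.
#'
#' @param records a `competition_records` data frame (normally the
#'   `retained` part of [filter_start_frequency()]).
#' @return The records with columns added: `W` (relative fitness, `NA` when
#'   undefined), `W_ok` (logical) and `W_note` (reason when not ok).
#' @export
relative_fitness <- function(records) {
  records <- as_competition_records(as.data.frame(records))
  p_t0 <- records$test_day0 / (records$test_day0 + records$ref_day0)
  p_t1 <- records$test_day1 / (records$test_day1 + records$ref_day1)
  p_r0 <- 1 - p_t0
  p_r1 <- 1 - p_t1
  d <- records$dilution
  degenerate <- p_t0 <= 0 | p_t0 >= 1 | p_t1 <= 0 | p_t1 >= 1
  W <- rep(NA_real_, nrow(records))
  num <- log(d * p_t1 / p_t0)
  den <- log(d * p_r1 / p_r0)
  ok <- !degenerate & is.finite(num) & is.finite(den) & den != 0
  W[ok] <- num[ok] / den[ok]
  records$W <- W
  records$W_ok <- ok
  records$W_note <- ifelse(ok, "ok",
                           ifelse(degenerate,
                                  "proportion at 0 or 1; estimate undefined",
                                  "non-finite log fold-change"))
  records
}

#' Fitness effect of an ARG relative to the vector control
#'
#' The effect of an ARG in a strain is the fitness of the ARG-plasmid
#' carrier relative to the same strain carrying the empty vector. Both the
#' ratio of replicate means (`effect_ratio = mean(W_ARG) / mean(W_Vec)`,
#' the primary estimand; percent cost is `(1 - effect_ratio) * 100`) and
#' the difference of means (`effect_diff`) are returned, with a two-sided
#' t-interval on the ratio scale computed from the ARG replicates scaled by
#' the vector mean.
#'
#' @param w_arg numeric vector of replicate fitness estimates for the
#'   ARG-plasmid carrier.
#' @param w_vec numeric vector of replicate fitness estimates for the
#'   vector-only carrier, from the same strain and environment.
#' @param strain,environment optional labels; if both carry attributes
#'   `strain`/`environment` they must match or a pairing error is raised.
#' @param conf confidence level for the t-interval.
#' @return One-row data frame: `effect_ratio`, `effect_diff`, `cost_pct`,
#'   `n`, `ci_low`, `ci_high` (ratio scale; `NA` with a single replicate).
#' @export
arg_effect <- function(w_arg, w_vec, strain = NULL, environment = NULL,
                       conf = 0.95) {
  for (lab in c("strain", "environment")) {
    a <- attr(w_arg, lab)
    b <- attr(w_vec, lab)
    if (!is.null(a) && !is.null(b) && !identical(a, b)) {
      stop("pairing error: ", lab, " mismatch ('", a, "' vs '", b, "')",
           call. = FALSE)
    }
  }
  w_arg <- w_arg[is.finite(w_arg)]
  w_vec <- w_vec[is.finite(w_vec)]
  if (length(w_arg) < 1 || length(w_vec) < 1) {
    stop("both estimate sets must be nonempty", call. = FALSE)
  }
  m_vec <- mean(w_vec)
  scaled <- w_arg / m_vec
  n <- length(scaled)
  ratio <- mean(scaled)
  ci <- c(NA_real_, NA_real_)
  if (n >= 2 && stats::sd(scaled) > 0) {
    hw <- stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(scaled) / sqrt(n)
    ci <- ratio + c(-1, 1) * hw
  } else if (n >= 2) {
    ci <- c(ratio, ratio)
  }
  data.frame(
    strain_id = strain %||% NA_character_,
    environment = environment %||% NA_character_,
    effect_ratio = ratio,
    effect_diff = mean(w_arg) - m_vec,
    cost_pct = (1 - ratio) * 100,
    n = n, ci_low = ci[1], ci_high = ci[2],
    stringsAsFactors = FALSE
  )
}

#' Aggregate replicate fitness estimates into an ARG-effect table
#'
#' Splits record-level fitness estimates by strain, ARG and environment;
#' within each strain and environment the vector-control mean fitness is the
#' denominator for every ARG in that strain. Cells report the replicate
#' count, mean fitness, effect ratio and difference, and a two-sided 95%
#' t-interval on the ratio scale. Cells with a single replicate have their
#' interval flagged as undefined (`ci_low`/`ci_high` `NA`); combinations
#' with no vector control in the same strain and environment get `NA`
#' effects and a note, never a silent zero.
#'
#' @param fitness records augmented by [relative_fitness()]; only rows with
#'   `W_ok` contribute.
#' @param conf confidence level.
#' @return Data frame of class `arg_effect_table` with one row per
#'   strain x ARG x environment (vector rows included, ratio 1 by
#'   construction).
#' @export
aggregate_effects <- function(fitness, conf = 0.95) {
  stopifnot(all(c("W", "W_ok") %in% names(fitness)))
  fitness <- fitness[fitness$W_ok, , drop = FALSE]
  if (nrow(fitness) == 0) stop("no usable fitness estimates", call. = FALSE)
  out <- list()
  for (env in unique(fitness$environment)) {
    fe <- fitness[fitness$environment == env, , drop = FALSE]
    for (st in unique(fe$strain_id)) {
      fs <- fe[fe$strain_id == st, , drop = FALSE]
      w_vec <- fs$W[fs$arg_id == VECTOR_LABEL]
      m_vec <- if (length(w_vec) > 0) mean(w_vec) else NA_real_
      for (a in unique(fs$arg_id)) {
        w <- fs$W[fs$arg_id == a]
        n <- length(w)
        if (is.na(m_vec)) {
          row <- data.frame(
            strain_id = st, arg_id = a, environment = env, n = n,
            mean_W = mean(w), sd_W = stats::sd(w),
            effect_ratio = NA_real_, effect_diff = NA_real_,
            ci_low = NA_real_, ci_high = NA_real_,
            note = "no vector control in this strain/environment",
            stringsAsFactors = FALSE
          )
        } else {
          scaled <- w / m_vec
          ratio <- mean(scaled)
          sds <- stats::sd(scaled)
          if (n >= 2) {
            hw <- stats::qt(1 - (1 - conf) / 2, n - 1) * sds / sqrt(n)
            ci <- ratio + c(-1, 1) * hw
            note <- "ok"
          } else {
            ci <- c(NA_real_, NA_real_)
            note <- "single replicate; CI undefined"
          }
          row <- data.frame(
            strain_id = st, arg_id = a, environment = env, n = n,
            mean_W = mean(w), sd_W = ifelse(n >= 2, stats::sd(w), NA_real_),
            effect_ratio = ratio, effect_diff = mean(w) - m_vec,
            ci_low = ci[1], ci_high = ci[2], note = note,
            stringsAsFactors = FALSE
          )
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("arg_effect_table", "data.frame")
  res
}

#' First-order fitness inflation from plasmid loss
#'
#' Reference cells that lose their GFP plasmid during a competition day are
#' miscounted as the test competitor, inflating the test fitness estimate.
#' For a 50:50, truly neutral competition with net fold-growth `dilution`,
#' counting a fraction `f_loss` of reference events as test events inflates
#' the estimate by `ln(1 + f_loss) / ln(dilution)` (test-side inflation
#' only, the conservative bound for the misassignment direction). With
#' `two_sided = TRUE` the simultaneous depletion of the reference count is
#' also modelled and the inflation is
#' `ln(d (1 + f)) / ln(d (1 - f)) - 1`.
#'
#' @param f_loss misclassified fraction per day, in `[0, 1)`.
#' @param dilution net fold-growth per day (> 1).
#' @param two_sided model reference-side depletion as well.
#' @return Dimensionless inflation of W over the true value.
#' @export
#' @examples
#' plasmid_loss_inflation(0.004, 100) # < 0.001
plasmid_loss_inflation <- function(f_loss, dilution = 100,
                                   two_sided = FALSE) {
  if (f_loss < 0 || f_loss >= 1) stop("f_loss must be in [0, 1)", call. = FALSE)
  if (dilution <= 1) stop("dilution must be > 1", call. = FALSE)
  if (two_sided) {
    log(dilution * (1 + f_loss)) / log(dilution * (1 - f_loss)) - 1
  } else {
    log1p(f_loss) / log(dilution)
  }
}

#' Deterministic trajectory of a beneficial mutant
#'
#' Frequency of a haploid mutant with per-generation selection coefficient
#' `s` after `t` generations of deterministic selection:
#' \deqn{p_t = \frac{p_0 e^{st}}{1 - p_0 + p_0 e^{st}}}
#' Used to bound the influence of compensatory mutations arising during a
#' competition assay: a strongly beneficial mutant starting from a handful
#' of copies stays at negligible frequency over the assay's ~60 generations.
#'
#' @param p0 initial frequency in `(0, 1)`.
#' @param s selection coefficient per generation.
#' @param t generations (vectorized, >= 0).
#' @return Mutant frequency at each `t`.
#' @export
#' @examples
#' mutant_trajectory(1.2e-8, 0.15, 60) # ~1e-4
mutant_trajectory <- function(p0, s, t) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  g <- p0 * exp(s * t)
  g / (1 - p0 + g)
}

#' Plasmid copy number by the comparative-Ct method
#'
#' Per strain, the plasmid-to-chromosome ratio is
#' `2^-(ct_plasmid - ct_chromosome)`; the `ddct` column normalizes that
#' ratio to a reference strain (whose `ddct` is exactly 1).
#'
#' @param measurements data frame with columns `strain_id`, `ct_plasmid`,
#'   `ct_chromosome` (see [read_qpcr()]).
#' @param reference_strain strain id used for normalization.
#' @return Data frame `strain_id`, `delta_ct_ratio`, `ddct`.
#' @export
copy_number <- function(measurements, reference_strain) {
  need <- c("strain_id", "ct_plasmid", "ct_chromosome")
  if (!all(need %in% names(measurements))) {
    stop("measurements must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!reference_strain %in% measurements$strain_id) {
    stop("reference strain '", reference_strain,
         "' not present in measurements", call. = FALSE)
  }
  ratio <- 2^(-(measurements$ct_plasmid - measurements$ct_chromosome))
  ref <- ratio[match(reference_strain, measurements$strain_id)]
  data.frame(
    strain_id = measurements$strain_id,
    delta_ct_ratio = ratio,
    ddct = ratio / ref,
    stringsAsFactors = FALSE
  )
}
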