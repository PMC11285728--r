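# Readers and writers for the tabular formats and Newick trees used by the
# pipeline. CSV with a header row is the canonical dialect; event counts are
# stored as raw integers and proportions are always derived downstream.

competition_columns <- c(
  "strain_id", "arg_id", "environment", "block",
  "test_day0", "ref_day0", "test_day1", "ref_day1"
)

#' Validate a data frame of competition records
#'
#' One row is one competition assay: a test competitor (ARG- or
#' vector-plasmid carrier, not expressing GFP) mixed roughly 50:50 with a
#' GFP-tagged reference, with flow-cytometry event counts recorded at day 0
#' and day 1 of the competition cycle. The `dilution` column holds the net
#' fold-growth per daily cycle (serial batch transfer; defaults to 100).
#'
#' @param df data frame with columns `strain_id`, `arg_id`, `environment`,
#'   `block`, `test_day0`, `ref_day0`, `test_day1`, `ref_day1` and optionally
#'   `dilution`.
#' @return The validated data frame with class `competition_records`.
#' @export
as_competition_records <- function(df) {
  stopifnot(is.data.frame(df))
  missing <- setdiff(competition_columns, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"dilution" %in% names(df)) df$dilution <- 100
  df$dilution[is.na(df$dilution)] <- 100
  for (col in c("test_day0", "ref_day0", "test_day1", "ref_day1")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(bad) > 0) {
      stop(sprintf("negative or missing count in column '%s' at row %d",
                   col, bad[1]), call. = FALSE)
    }
  }
  if (any(df$test_day0 + df$ref_day0 <= 0)) {
    stop("day-0 total event count must be positive (row ",
         which(df$test_day0 + df$ref_day0 <= 0)[1], ")", call. = FALSE)
  }
  if (any(df$test_day1 + df$ref_day1 <= 0)) {
    stop("day-1 total event count must be positive (row ",
         which(df$test_day1 + df$ref_day1 <= 0)[1], ")", call. = FALSE)
  }
  if (any(df$dilution <= 1)) {
    stop("dilution (fold-growth per cycle) must be > 1 (row ",
         which(df$dilution <= 1)[1], ")", call. = FALSE)
  }
  class(df) <- unique(c("competition_records", class(df)))
  df
}

#' Read competition records from CSV
#'
#' @param path path to a CSV file with the columns listed in
#'   [as_competition_records()].
#' @return A `competition_records` data frame, one record per row. A missing
#'   `dilution` column defaults to 100-fold growth per cycle.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_competitions(gen_competitions(
#'   gen_effect_matrix(synth_config(n_strains = 2, n_args = 1))$truth,
#'   synth_config(n_strains = 2, n_args = 1, replicates = 2)), f)
#' nrow(read_competitions(f))
read_competitions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_competition_records(df)
}

#' Write competition records to CSV
#'
#' @param records a `competition_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_competitions <- function(records, path) {
  records <- as_competition_records(as.data.frame(records))
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read per-strain growth parameters
#'
#' Growth parameters summarize a monoculture growth curve in a batch cycle:
#' `lag` (hours before growth starts), `rate` (maximum specific growth rate
#' per hour) and `yield` (saturation density per unit of limiting resource).
#'
#' @param path CSV with columns `strain_id`, `lag`, `rate`, `yield`.
#' @return Data frame of validated growth parameters.
#' @export
read_growth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("strain_id", "lag", "rate", "yield"), names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$lag < 0)) stop("lag must be >= 0", call. = FALSE)
  if (any(df$rate <= 0)) stop("rate must be > 0", call. = FALSE)
  if (any(df$yield <= 0)) stop("yield must be > 0", call. = FALSE)
  df
}

#' Write growth parameters to CSV
#' @param growth data frame with columns `strain_id`, `lag`, `rate`, `yield`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_growth <- function(growth, path) {
  utils::write.csv(growth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read qPCR Ct measurements
#'
#' One row per strain: threshold cycle of the plasmid amplicon
#' (`ct_plasmid`) and of the single-copy chromosomal amplicon
#' (`ct_chromosome`), as used by the comparative-Ct copy-number method.
#'
#' @param path CSV with columns `strain_id`, `ct_plasmid`, `ct_chromosome`.
#' @return Data frame of validated measurements.
#' @export
read_qpcr <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("strain_id", "ct_plasmid", "ct_chromosome"), names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$ct_plasmid)) || any(!is.finite(df$ct_chromosome))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  df
}

#' Write qPCR measurements to CSV
#' @param qpcr data frame with columns `strain_id`, `ct_plasmid`,
#'   `ct_chromosome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qpcr <- function(qpcr, path) {
  utils::write.csv(qpcr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Wraps [ape::read.tree()] with the validation the signal tests require:
#' unique non-empty tip labels, branch lengths present and non-negative, and
#' at least three tips. Polytomies and non-ultrametric trees are accepted.
#'
#' @param path Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path, call. = FALSE)
  validate_tree(tree)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree", call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  if (any(!nzchar(tree$tip.label))) {
    stop("tree has unlabelled tips", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("tip labels must be unique", call. = FALSE)
  }
  if (length(tree$tip.label) < 3) {
    stop("tree must have at least 3 tips", call. = FALSE)
  }
  tree
}

#' Write a phylogeny to a Newick file
#' @param tree an [ape::phylo] tree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
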