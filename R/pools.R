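#' Construct a pool metadata table
#'
#' A pool is a DNA sample made from many individuals sequenced together; the
#' number of chromosomes it contains (haploid genome copies) governs the pool
#' correction in all diversity estimators.
#'
#' @param label Character vector of unique short pool labels.
#' @param latitude Numeric vector, decimal degrees north.
#' @param n_chromosomes Integer vector, haploid genome copies per pool
#'   (for pools of diploid females this is twice the number of flies).
#' @param n_flies Optional integer vector, number of individuals pooled
#'   (provenance only; not used in any estimator).
#' @return A `data.table` with one row per pool, ordered as given.
#' @export
pool_profiles <- function(label, latitude, n_chromosomes, n_flies = NA_integer_) {
  stopifnot(length(label) == length(latitude),
            length(label) == length(n_chromosomes))
  if (anyDuplicated(label)) stop("pool labels must be unique")
  if (any(!is.finite(latitude))) stop("latitudes must be finite")
  if (any(n_chromosomes < 2)) stop("n_chromosomes must be >= 2")
  data.table::data.table(
    label = as.character(label),
    latitude = as.numeric(latitude),
    n_chromosomes = as.integer(n_chromosomes),
    n_flies = as.integer(n_flies)
  )
}

#' Default three-population east-coast study design
#'
#' Florida (25.53 N, 39 isofemale lines), Pennsylvania (39.88 N, 102 lines)
#' and Maine (44.02 N, 86 lines); pools of diploid females, so each pool
#' carries 2 x n_flies chromosomes.
#'
#' @return A `data.table` of three pools ordered south to north.
#' @export
study_pools <- function() {
  pool_profiles(
    label = c("F", "P", "M"),
    latitude = c(25.53, 39.88, 44.02),
    n_chromosomes = c(78L, 204L, 172L),
    n_flies = c(39L, 102L, 86L)
  )
}

#' Read a pool metadata TSV
#'
#' Expects columns `label`, `latitude`, `n_chromosomes` and optionally
#' `n_flies`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A `data.table` as from [pool_profiles()].
#' @export
read_pools <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  req <- c("label", "latitude", "n_chromosomes")
  if (!all(req %in% names(dt))) {
    stop("pool file must have columns: ", paste(req, collapse = ", "))
  }
  pool_profiles(dt$label, dt$latitude, dt$n_chromosomes,
                if ("n_flies" %in% names(dt)) dt$n_flies else NA_integer_)
}

#' Write pools to TSV
#' @param pools Pool table from [pool_profiles()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pools <- function(pools, path) {
  data.table::fwrite(pools, path, sep = "\t")
  invisible(path)
}

#' All ordered pool pairs of a study
#'
#' Pairs are labelled by concatenating the two pool labels in the order the
#' pools appear in the table (e.g. "FP", "FM", "PM" for the south-to-north
#' default design).
#'
#' @param pools Pool table.
#' @return A `data.table` with columns `pair`, `i`, `j` (row indices into
#'   `pools`).
#' @export
pool_pairs <- function(pools) {
  n <- nrow(pools)
  idx <- utils::combn(n, 2)
  data.table::data.table(
    pair = paste0(pools$label[idx[1, ]], pools$label[idx[2, ]]),
    i = idx[1, ], j = idx[2, ]
  )
}
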