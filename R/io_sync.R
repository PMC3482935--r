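#' @importFrom data.table := .N .SD %chin% data.table as.data.table setorder
#'   setnames fread fwrite tstrsplit setcolorder rbindlist fifelse
NULL

NUCS <- c("A", "T", "C", "G")
SYNC_COLS <- c("A", "T", "C", "G", "N", "del")

count_cols <- function(pools, bases = SYNC_COLS) {
  as.vector(t(outer(pools$label, bases, function(l, b) paste0(b, "_", l))))
}

#' Per-pool count matrix for one base
#'
#' @param sites Site-count table as returned by [read_sync()].
#' @param base One of "A","T","C","G","N","del".
#' @param pools Pool table.
#' @return Integer matrix, sites x pools.
#' @keywords internal
base_matrix <- function(sites, base, pools) {
  as.matrix(sites[, paste0(base, "_", pools$label), with = FALSE])
}

#' Per-pool nucleotide coverage matrix
#'
#' Coverage is the sum of the four nucleotide counts; N and deletion columns
#' never contribute.
#'
#' @inheritParams base_matrix
#' @return Integer matrix, sites x pools.
#' @export
coverage_matrix <- function(sites, pools) {
  m <- base_matrix(sites, "A", pools)
  for (b in c("T", "C", "G")) m <- m + base_matrix(sites, b, pools)
  m
}

#' Read a sync file of pooled allele counts
#'
#' The sync format is tab-separated with columns: chromosome arm, 1-based
#' position, reference base, then one `A:T:C:G:N:del` colon-separated count
#' tuple per pool.
#'
#' @param path Path to a sync file (plain text, no header).
#' @param pools Pool table; its row order must match the count columns.
#' @return A `data.table` with columns `arm`, `pos`, `ref` and six count
#'   columns per pool named `<base>_<label>`.
#' @export
read_sync <- function(path, pools) {
  dt <- if (file.size(path) == 0) {
    data.table::data.table()
  } else {
    data.table::fread(path, sep = "\t", header = FALSE,
                      colClasses = "character", fill = TRUE)
  }
  if (nrow(dt) == 0) {
    out <- data.table::data.table(arm = character(), pos = integer(),
                                  ref = character())
    out[, (count_cols(pools)) := integer()]
    return(out[])
  }
  want <- 3L + nrow(pools)
  if (ncol(dt) != want) {
    stop(sprintf("sync file has %d columns; expected %d for %d pools",
                 ncol(dt), want, nrow(pools)))
  }
  out <- data.table::data.table(arm = dt[[1]], pos = as.integer(dt[[2]]),
                                ref = dt[[3]])
  if (anyNA(out$pos)) {
    stop("malformed sync line (non-integer position) at line ",
         which(is.na(out$pos))[1])
  }
  for (p in seq_len(nrow(pools))) {
    parts <- data.table::tstrsplit(dt[[3L + p]], ":", fixed = TRUE,
                                   type.convert = FALSE)
    if (length(parts) != 6L) {
      stop("malformed count tuple for pool ", pools$label[p],
           " (expected 6 colon-separated fields)")
    }
    for (b in seq_along(SYNC_COLS)) {
      v <- suppressWarnings(as.integer(parts[[b]]))
      if (anyNA(v)) {
        stop("malformed sync count at line ", which(is.na(v))[1],
             " pool ", pools$label[p])
      }
      out[, (paste0(SYNC_COLS[b], "_", pools$label[p])) := v]
    }
  }
  out[]
}

#' Write site counts to a sync file
#'
#' @param sites Site-count table as returned by [read_sync()].
#' @param pools Pool table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sites, pools, path) {
  cols <- list(sites$arm, sites$pos, sites$ref)
  for (p in pools$label) {
    tup <- do.call(paste, c(lapply(SYNC_COLS, function(b) sites[[paste0(b, "_", p)]]),
                            sep = ":"))
    cols[[length(cols) + 1L]] <- tup
  }
  data.table::fwrite(data.table::as.data.table(cols), path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
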