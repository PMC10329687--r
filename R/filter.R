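#' Read a tip-metadata table
#'
#' Tab-separated with header columns \code{tip_id, sample_id, city, region,
#' dedup_score}. \code{dedup_score} is the dereplication quality score used
#' to choose one representative genome per city.
#'
#' @param path TSV path.
#' @return data.frame with one row per tip.
#' @export
read_tip_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_tip_metadata(meta)
}

#' @rdname read_tip_metadata
#' @param meta data.frame to validate.
#' @export
validate_tip_metadata <- function(meta) {
  need <- c("tip_id", "sample_id", "city", "region", "dedup_score")
  .check(all(need %in% names(meta)),
         paste0("metadata must have columns: ", paste(need, collapse = ", ")))
  .check(!anyDuplicated(meta$tip_id), "duplicate tip_id in metadata")
  .check(is.numeric(meta$dedup_score), "dedup_score must be numeric")
  meta
}

#' Deduplicate city tips and drop single-region representatives
#'
#' Pre-test filtering of a distance matrix: (1) among tips sharing a city,
#' only the tip with the highest \code{dedup_score} is kept (ties broken by
#' lexicographically smallest \code{tip_id}); (2) any tip left as the sole
#' representative of its region is dropped; (3) the result is testable only
#' if at least two distinct regions remain. An untestable result is a status
#' flag, not an error, so whole-run drivers can carry it through.
#'
#' The filter is idempotent: applying it to its own output changes nothing.
#'
#' @param D symmetric labeled distance matrix.
#' @param meta tip metadata covering every label of \code{D}.
#' @return list with \code{D} (filtered matrix, possibly 0 columns),
#'   \code{meta} (matching rows), \code{status} (\code{"tested"} or
#'   \code{"untestable"}), \code{kept}, \code{removed_city_dups},
#'   \code{removed_single_region}.
#' @export
filter_tips <- function(D, meta) {
  validate_tip_metadata(meta)
  labels <- rownames(D)
  .check(!is.null(labels), "distance matrix must be labeled")
  .check(all(labels %in% meta$tip_id),
         "every matrix label must appear in the metadata")
  m <- meta[match(labels, meta$tip_id), , drop = FALSE]

  # rule 1: one representative per city, best dedup_score, tie -> smallest id
  ord <- order(m$city, -m$dedup_score, m$tip_id)
  first <- !duplicated(m$city[ord])
  keep1 <- sort(ord[first])
  dup_removed <- setdiff(labels, m$tip_id[keep1])
  m1 <- m[keep1, , drop = FALSE]

  # rule 2: drop tips that are the sole representative of their region
  tab <- table(m1$region)
  lone <- m1$tip_id[tab[m1$region] == 1L]
  m2 <- m1[!(m1$tip_id %in% lone), , drop = FALSE]

  kept <- m2$tip_id
  status <- if (length(unique(m2$region)) >= 2L && length(kept) >= 2L)
    "tested" else "untestable"
  list(D = D[kept, kept, drop = FALSE],
       meta = m2,
       status = status,
       kept = kept,
       removed_city_dups = dup_removed,
       removed_single_region = as.character(lone))
}
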