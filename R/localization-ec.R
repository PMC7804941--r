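# Secretome consensus voting over per-predictor localization calls, and
# EC sub-subfamily bucket assignment.

CALL_LEVELS <- c("secreted", "non-secreted", "other-compartment", "missing")

#' Combine per-predictor localization calls by majority vote
#'
#' A protein is called \code{secreted} when its fraction of secreted calls
#' among non-missing calls strictly exceeds \code{threshold} (default 0.5,
#' so a 3-3 split among six predictors is \code{non-secreted}).
#' \code{other-compartment} counts as non-secreted. Proteins with fewer than
#' \code{min_calls} non-missing calls are \code{undetermined}.
#'
#' @param calls Table with columns \code{seq_id}, \code{predictor},
#'   \code{call} (\code{secreted}, \code{non-secreted},
#'   \code{other-compartment}, or \code{missing}).
#' @param threshold Strict majority threshold (fraction of non-missing calls).
#' @param min_calls Minimum non-missing calls for a determined consensus.
#' @return Tibble with columns \code{seq_id}, \code{consensus},
#'   \code{n_secreted}, \code{n_total} (non-missing calls), one row per
#'   protein in first-appearance order.
#' @examples
#' calls <- tibble::tibble(seq_id = "p1", predictor = paste0("pred", 1:6),
#'                         call = c(rep("secreted", 4), rep("non-secreted", 2)))
#' consensus_vote(calls)
#' @export
consensus_vote <- function(calls, threshold = 0.5, min_calls = 4L) {
  stopifnot(is.data.frame(calls))
  needed <- c("seq_id", "predictor", "call")
  if (!all(needed %in% names(calls))) {
    stop("calls table needs columns seq_id, predictor, call")
  }
  if (nrow(calls) == 0L) {
    return(tibble::tibble(seq_id = character(), consensus = character(),
                          n_secreted = integer(), n_total = integer()))
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1) {
    stop("threshold must be a single fraction in [0, 1)")
  }
  bad <- setdiff(unique(calls$call), CALL_LEVELS)
  if (length(bad)) {
    stop(sprintf("unknown localization call '%s'", bad[[1]]))
  }
  key <- paste(calls$seq_id, calls$predictor, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- calls[duplicated(key), ][1, ]
    stop(sprintf("duplicate call for (%s, %s)", dup$seq_id, dup$predictor))
  }
  ids <- unique(calls$seq_id)
  rows <- lapply(ids, function(id) {
    cc <- calls$call[calls$seq_id == id]
    cc <- cc[cc != "missing"]
    n_total <- length(cc)
    n_secreted <- sum(cc == "secreted")
    consensus <- if (n_total < min_calls) {
      "undetermined"
    } else if (n_secreted / n_total > threshold) {
      "secreted"
    } else {
      "non-secreted"
    }
    tibble::tibble(seq_id = id, consensus = consensus,
                   n_secreted = n_secreted, n_total = n_total)
  })
  dplyr::bind_rows(rows)
}

#' EC bucket side (exo/endo/unknown)
#'
#' @param bucket EC sub-subfamily bucket (e.g. \code{"3.4.23"}) or
#'   \code{"unknown"}.
#' @return \code{"exo"}, \code{"endo"} or \code{"unknown"}, vectorised.
#' @export
ec_side <- function(bucket) {
  bad <- setdiff(unique(bucket), EC_BUCKETS)
  if (length(bad)) stop(sprintf("unknown EC bucket '%s'", bad[[1]]))
  out <- rep("unknown", length(bucket))
  out[bucket %in% EC_EXO] <- "exo"
  out[bucket %in% EC_ENDO] <- "endo"
  out
}

#' Assign an EC bucket to a record or classification result
#'
#' Inventory records carry a per-locus EC field (which resolves subfamilies
#' hosting both exo- and endopeptidases); when only a subfamily is known the
#' catalogue's family-level default applies; otherwise the bucket is
#' \code{unknown}.
#'
#' @param x A \code{classification_result}, an inventory record (one-row data
#'   frame or list with an \code{ec_bucket} or \code{subfamily} field), or a
#'   subfamily id string.
#' @param catalogue A \code{degradome_catalogue}.
#' @return List with \code{bucket} and \code{side}.
#' @examples
#' cat <- load_catalogue()
#' assign_ec_bucket("T1A", cat)
#' assign_ec_bucket("S10", cat)
#' @export
assign_ec_bucket <- function(x, catalogue) {
  stopifnot(inherits(catalogue, "degradome_catalogue"))
  bucket <- NULL
  if (inherits(x, "classification_result")) {
    if (!is.na(x$best_rule) && x$best_rule != "unassigned") {
      bucket <- lookup_rule(catalogue, x$best_rule)$ec_bucket
    }
  } else if (is.data.frame(x) || is.list(x)) {
    if (!is.null(x$ec_bucket) && !is.na(x$ec_bucket[[1]])) {
      bucket <- x$ec_bucket[[1]]
    } else if (!is.null(x$subfamily) && x$subfamily[[1]] != "unassigned") {
      bucket <- lookup_rule(catalogue, x$subfamily[[1]])$ec_bucket
    }
  } else if (is.character(x) && length(x) == 1L) {
    if (x != "unassigned") bucket <- lookup_rule(catalogue, x)$ec_bucket
  } else {
    stop("assign_ec_bucket: unsupported input")
  }
  if (is.null(bucket)) bucket <- "unknown"
  list(bucket = bucket, side = ec_side(bucket))
}
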