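# Degradome composition statistics: per-class marginals, EC breakdown and
# printed-precision percentages.

#' Percentage with half-up rounding
#'
#' Computes \code{100 * numerator / denominator} rounded half-up (0.05 at one
#' decimal rounds to 0.1, unlike banker's rounding) to the stated number of
#' decimals: class-composition figures use 1 decimal, genome-coverage
#' fractions 2 decimals.
#'
#' @param numerator,denominator Counts; denominator must be positive.
#' @param decimals 1 or 2.
#' @return Numeric percentage.
#' @examples
#' percentage(83, 232, 1)    # 35.8
#' percentage(232, 14165, 2) # 1.64
#' @export
percentage <- function(numerator, denominator, decimals = 1L) {
  if (!is.numeric(denominator) || length(denominator) != 1L ||
      denominator <= 0) {
    stop("percentage: denominator must be a single positive count")
  }
  if (!(decimals %in% c(1L, 2L))) {
    stop("percentage: decimals must be 1 or 2")
  }
  round_half_up(100 * numerator / denominator, decimals)
}

round_half_up <- function(x, decimals) {
  p <- 10^decimals
  # tiny nudge guards against values like 34.9999999 arising from binary
  # representation of exact halves
  floor(x * p + 0.5 + 1e-9) / p
}

#' Summarize an inventory into degradome composition statistics
#'
#' Recomputes the per-class marginal counts (gene models, clans, subfamilies,
#' unassigned, inactive, secreted, characterized), the per-subfamily sizes,
#' the EC-bucket/exo-endo breakdown, the class-composition percentages (1
#' decimal) and the genome-coverage fraction (2 decimals). Clans are counted
#' in both bookkeeping modes: \code{clans} counts annotated clans plus one
#' non-classified clan for a class hosting a family without clan assignment
#' (the mode that reproduces the printed per-class clan counts), while
#' \code{clans_pooled} additionally counts an unassigned pseudo-clan for any
#' class with records of unknown family.
#'
#' @param records Inventory tibble (as in \code{catalogue$records}).
#' @param proteome_size Number of protein-coding gene models in the genome,
#'   for the coverage fraction.
#' @return A \code{degradome_summary}.
#' @examples
#' cat <- load_catalogue()
#' summarize_degradome(cat$records)
#' @export
summarize_degradome <- function(records, proteome_size = 14165L) {
  stopifnot(is.data.frame(records))
  classes <- CLASS_ORDER
  by_class <- lapply(classes, function(cl) records[records$class == cl, ])
  names(by_class) <- classes
  n_total <- nrow(records)
  class_table <- tibble::tibble(
    class = classes,
    gene_models = unname(vapply(by_class, nrow, 0L)),
    clans = unname(vapply(by_class, count_clans_table1, 0L)),
    clans_pooled = unname(vapply(by_class, function(d) {
      count_clans_table1(d) +
        as.integer(any(d$clan == "unassigned" & d$subfamily == "unassigned"))
    }, 0L)),
    subfamilies = unname(vapply(by_class, count_subfamilies, 0L)),
    unassigned = unname(vapply(by_class, function(d) {
      sum(d$subfamily == "unassigned")
    }, 0L)),
    inactive = unname(vapply(by_class, function(d) {
      sum(d$activity == "putatively-inactive")
    }, 0L)),
    secreted = unname(vapply(by_class, function(d) sum(d$secreted), 0L)),
    characterized = unname(vapply(by_class, function(d) sum(d$characterized), 0L))
  )
  class_table$pct <- if (n_total > 0) {
    percentage(class_table$gene_models, n_total, 1L)
  } else {
    rep(0, length(classes))
  }
  assigned <- records[records$subfamily != "unassigned", ]
  subfamily_counts <- tibble::tibble(class = character(),
                                     subfamily = character(), n = integer())
  if (nrow(assigned)) {
    sc <- unique(assigned[, c("class", "subfamily")])
    sc <- sc[order(match(sc$class, classes), sc$subfamily), ]
    sc$n <- vapply(seq_len(nrow(sc)), function(i) {
      sum(assigned$class == sc$class[[i]] &
            assigned$subfamily == sc$subfamily[[i]])
    }, 0L)
    subfamily_counts <- tibble::as_tibble(sc)
  }
  ec_counts <- tibble::tibble(bucket = EC_BUCKETS, side = ec_side(EC_BUCKETS))
  ec_counts$n <- vapply(ec_counts$bucket, function(b) {
    sum(records$ec_bucket == b)
  }, 0L)
  side_counts <- c(exo = sum(ec_counts$n[ec_counts$side == "exo"]),
                   endo = sum(ec_counts$n[ec_counts$side == "endo"]),
                   unknown = sum(ec_counts$n[ec_counts$side == "unknown"]))
  structure(list(
    n_total = n_total,
    class_table = class_table,
    subfamily_counts = subfamily_counts,
    ec_counts = ec_counts,
    side_counts = side_counts,
    n_secreted = sum(records$secreted),
    secreted_pct = if (n_total > 0) {
      percentage(sum(records$secreted), n_total, 1L)
    } else 0,
    n_clans = sum(class_table$clans),
    n_clans_pooled = sum(class_table$clans_pooled),
    n_subfamilies = sum(class_table$subfamilies),
    proteome_size = proteome_size,
    coverage_pct = if (n_total > 0) {
      percentage(n_total, proteome_size, 2L)
    } else 0
  ), class = "degradome_summary")
}

#' Combined share of a set of subfamilies
#'
#' @param records Inventory tibble.
#' @param subfamily_ids Non-empty character vector of subfamily ids present
#'   in the records.
#' @return Percentage of the grand total (1 decimal, half-up).
#' @examples
#' cat <- load_catalogue()
#' subfamily_share(cat$records, c("A1A", "T1A", "C19", "S10"))  # 24.1
#' @export
subfamily_share <- function(records, subfamily_ids) {
  stopifnot(is.data.frame(records))
  if (length(subfamily_ids) == 0L) {
    stop("subfamily_share: no subfamilies given")
  }
  known <- unique(records$subfamily)
  bad <- setdiff(subfamily_ids, known)
  if (length(bad)) {
    stop(sprintf("subfamily_share: unknown subfamily '%s'", bad[[1]]))
  }
  percentage(sum(records$subfamily %in% subfamily_ids), nrow(records), 1L)
}

#' Render a summary as a text report
#'
#' Produces a fixed-width grid in the shape of the inventory summary table
#' plus the EC breakdown, byte-stable for a fixed summary. Optionally also
#' writes the grid as TSV.
#'
#' @param summary A \code{degradome_summary}.
#' @param tsv_path Optional path; when given, the class table is written as
#'   TSV there.
#' @return Character vector of report lines (invisibly when printed).
#' @export
render_report <- function(summary, tsv_path = NULL) {
  stopifnot(inherits(summary, "degradome_summary"))
  ct <- summary$class_table
  fmt <- "%-14s %11s %5s %11s %10s %8s %8s %13s %5s"
  lines <- c(
    "Degradome composition summary",
    "",
    sprintf(fmt, "class", "gene_models", "clans", "subfamilies",
            "unassigned", "inactive", "secreted", "characterized", "pct"),
    vapply(seq_len(nrow(ct)), function(i) {
      sprintf(fmt, ct$class[[i]], ct$gene_models[[i]], ct$clans[[i]],
              ct$subfamilies[[i]], ct$unassigned[[i]], ct$inactive[[i]],
              ct$secreted[[i]], ct$characterized[[i]],
              sprintf("%.1f", ct$pct[[i]]))
    }, character(1)),
    sprintf(fmt, "total", summary$n_total, summary$n_clans,
            summary$n_subfamilies, sum(ct$unassigned), sum(ct$inactive),
            summary$n_secreted, sum(ct$characterized),
            if (summary$n_total > 0) "100.0" else "0.0"),
    "",
    sprintf("EC breakdown: exo=%d endo=%d unknown=%d",
            summary$side_counts[["exo"]], summary$side_counts[["endo"]],
            summary$side_counts[["unknown"]]),
    paste0("EC buckets: ",
           paste(sprintf("%s=%d", summary$ec_counts$bucket,
                         summary$ec_counts$n), collapse = " ")),
    sprintf("Secreted: %d (%s%%)", summary$n_secreted,
            format(summary$secreted_pct, nsmall = 1)),
    sprintf("Genome coverage: %d of %d gene models (%s%%)", summary$n_total,
            summary$proteome_size, format(summary$coverage_pct, nsmall = 2)),
    paste0("Clan bookkeeping: ", summary$n_clans,
           " (annotated + non-classified clans); ",
           summary$n_clans_pooled,
           " when pooling unassigned records into a pseudo-clan per class")
  )
  if (!is.null(tsv_path)) {
    utils::write.table(ct, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  lines
}

#' @export
print.degradome_summary <- function(x, ...) {
  cat(paste(render_report(x), collapse = "\n"), "\n")
  invisible(x)
}
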