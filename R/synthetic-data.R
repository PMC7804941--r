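# Ground-truth-labeled synthetic inputs: proteins with one planted family
# architecture each, optional catalytic-residue knockouts, and noisy
# six-predictor localization call tables.

DEFAULT_FAMILY_MIX <- c(A1A = 0.25, S8A = 0.25, S53 = 0.20,
                        A22B = 0.15, S54 = 0.15)
DEFAULT_PREDICTORS <- paste0("predictor", 1:6)

#' Build a simulation configuration
#'
#' The defaults are the study conditions: a mix of families whose
#' architectures carry at least two catalytic-role components (so that a
#' single-residue knockout leaves residual catalytic evidence and the record
#' remains attributable to its family), uniform background residue
#' frequencies, flanks of 30 to 80 residues, and six predictors with
#' independent error.
#'
#' @param n_records Number of synthetic proteins.
#' @param seed Integer seed (mandatory; the entire output is a deterministic
#'   function of the configuration).
#' @param family_mix Named numeric vector of subfamily proportions (sums
#'   to 1).
#' @param flank_range Length-2 integer vector: min/max flank length.
#' @param background Residue frequencies (named over the 20 standard codes)
#'   or NULL for uniform.
#' @param knockout_rate Probability that a record gets one catalytic-role
#'   residue replaced by a residue outside that motif position's set.
#' @param predictor_error_rate Per-predictor probability of flipping the
#'   true localization.
#' @param p_secreted Probability that a record is truly secreted.
#' @param predictors Predictor names for the call table.
#' @return A \code{simulation_config}.
#' @export
simulation_config <- function(n_records, seed,
                              family_mix = DEFAULT_FAMILY_MIX,
                              flank_range = c(30L, 80L),
                              background = NULL,
                              knockout_rate = 0,
                              predictor_error_rate = 0,
                              p_secreted = 0.267,
                              predictors = DEFAULT_PREDICTORS) {
  if (missing(seed) || length(seed) != 1L || is.na(seed)) {
    stop("simulation_config: an integer seed is mandatory")
  }
  stopifnot(length(n_records) == 1L, n_records >= 0)
  if (is.null(names(family_mix)) || any(!nzchar(names(family_mix)))) {
    stop("family_mix must be a named vector of proportions")
  }
  if (abs(sum(family_mix) - 1) > 1e-8) {
    stop("family_mix proportions must sum to 1")
  }
  if (any(family_mix < 0)) stop("family_mix proportions must be non-negative")
  stopifnot(length(flank_range) == 2L, flank_range[[1]] >= 0,
            flank_range[[1]] <= flank_range[[2]])
  for (rate in c(knockout_rate, predictor_error_rate, p_secreted)) {
    if (rate < 0 || rate > 1) stop("rates must lie in [0, 1]")
  }
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  if (!setequal(names(background), AA_STANDARD) ||
      abs(sum(background) - 1) > 1e-8) {
    stop("background must be frequencies over the 20 standard residues")
  }
  background <- background[AA_STANDARD]
  structure(list(n_records = as.integer(n_records),
                 seed = as.integer(seed),
                 family_mix = family_mix,
                 flank_range = as.integer(flank_range),
                 background = background,
                 knockout_rate = knockout_rate,
                 predictor_error_rate = predictor_error_rate,
                 p_secreted = p_secreted,
                 predictors = predictors),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> n=%d seed=%d knockout=%.2f predictor_error=%.2f\n",
              x$n_records, x$seed, x$knockout_rate, x$predictor_error_rate))
  cat("  family mix:", paste(sprintf("%s=%.2f", names(x$family_mix),
                                     x$family_mix), collapse = " "), "\n")
  invisible(x)
}

resample <- function(x, size = 1L, prob = NULL) {
  x[sample.int(length(x), size, replace = TRUE, prob = prob)]
}

random_residues <- function(n, background) {
  if (n == 0L) return("")
  paste(resample(AA_STANDARD, n, prob = background), collapse = "")
}

# Instantiate one motif component; returns per-element residue strings so a
# knockout can surgically replace one position.
instantiate_component <- function(pattern, background) {
  lapply(pattern$elements, function(e) {
    if (e$kind == "gap") {
      len <- resample(seq.int(e$min_gap, e$max_gap), 1L)
      list(kind = "gap", text = random_residues(len, background))
    } else {
      list(kind = "residue-set", text = resample(e$residues),
           residues = e$residues, fixed = length(e$residues) < 20L)
    }
  })
}

#' Generate a synthetic degradome data set
#'
#' Each record carries exactly one planted family architecture: every
#' component of the family rule is instantiated (one residue per
#' alternation or wildcard, one length per gap), components are joined in
#' catalogue order by short random linkers, and random flanks are added.
#' Candidate records whose classification would not recover the planted
#' family and expected activity (for example because the random background
#' accidentally completes a higher-priority rule) are rejected and resampled,
#' up to 100 retries. Knockouts replace one catalytic-role residue with a
#' residue outside that motif position's set. Predictor calls flip from the
#' true localization independently at \code{predictor_error_rate}.
#'
#' @param config A \code{simulation_config}.
#' @param catalogue A \code{degradome_catalogue}.
#' @param max_retries Rejection-sampling cap per record; exceeding it raises
#'   an error (the rule is too permissive to separate from the background).
#' @return A \code{degradome_simulation}: \code{sequences} (named character),
#'   \code{calls} (predictor call tibble), \code{truth} (tibble with
#'   \code{seq_id}, \code{subfamily}, \code{knocked_out}, \code{secreted},
#'   \code{expected_activity}), plus the \code{config}.
#' @examples
#' cat <- load_catalogue()
#' sim <- generate_degradome(simulation_config(5, seed = 42), cat)
#' sim$truth
#' @export
generate_degradome <- function(config, catalogue, max_retries = 100L) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(catalogue, "degradome_catalogue"))
  for (fam in names(config$family_mix)) {
    rule <- lookup_rule(catalogue, fam)
    if (!any(rule$roles == "catalytic")) {
      stop(sprintf("family '%s' is motif-free and cannot be planted", fam))
    }
  }
  set.seed(config$seed)
  n <- config$n_records
  ids <- sprintf("syn%04d", seq_len(n))
  families <- if (n > 0) {
    resample(names(config$family_mix), n, prob = config$family_mix)
  } else {
    character(0)
  }
  sequences <- character(n)
  knocked <- logical(n)
  for (i in seq_len(n)) {
    rule <- lookup_rule(catalogue, families[[i]])
    knock <- config$knockout_rate > 0 &&
      stats::runif(1) < config$knockout_rate
    ok <- FALSE
    for (attempt in seq_len(max_retries)) {
      comps <- lapply(rule$components, instantiate_component,
                      background = config$background)
      if (knock) {
        cat_idx <- which(rule$roles == "catalytic")
        comp_k <- resample(cat_idx)
        fixed <- which(vapply(comps[[comp_k]],
                              function(e) isTRUE(e$fixed), logical(1)))
        el_k <- resample(fixed)
        residues <- comps[[comp_k]][[el_k]]$residues
        comps[[comp_k]][[el_k]]$text <-
          resample(setdiff(AA_STANDARD, residues))
      }
      pieces <- vapply(comps, function(cc) {
        paste(vapply(cc, function(e) e$text, character(1)), collapse = "")
      }, character(1))
      linkers <- vapply(seq_len(length(pieces) - 1L), function(j) {
        random_residues(resample(2:15), config$background)
      }, character(1))
      flanks <- vapply(1:2, function(j) {
        random_residues(resample(seq.int(config$flank_range[[1]],
                                         config$flank_range[[2]])),
                        config$background)
      }, character(1))
      body <- pieces[[1]]
      for (j in seq_along(linkers)) {
        body <- paste0(body, linkers[[j]], pieces[[j + 1L]])
      }
      candidate <- paste0(flanks[[1]], body, flanks[[2]])
      expected <- if (knock) "putatively-inactive" else "active"
      res <- classify_sequence(candidate, catalogue)
      if (!is.na(res$best_rule) && res$best_rule == rule$subfamily_id &&
          res$activity == expected) {
        sequences[[i]] <- candidate
        knocked[[i]] <- knock
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf("generate_degradome: record %d (family %s) rejected %d times; rule too permissive",
                   i, families[[i]], max_retries))
    }
  }
  names(sequences) <- ids
  secreted <- if (n > 0) stats::runif(n) < config$p_secreted else logical(0)
  call_rows <- list()
  for (i in seq_len(n)) {
    flips <- stats::runif(length(config$predictors)) <
      config$predictor_error_rate
    observed <- xor(secreted[[i]], flips)
    call_rows[[i]] <- tibble::tibble(
      seq_id = ids[[i]], predictor = config$predictors,
      call = ifelse(observed, "secreted", "non-secreted"))
  }
  calls <- if (length(call_rows)) {
    dplyr::bind_rows(call_rows)
  } else {
    tibble::tibble(seq_id = character(), predictor = character(),
                   call = character())
  }
  truth <- tibble::tibble(
    seq_id = ids, subfamily = families, knocked_out = knocked,
    secreted = secreted,
    expected_activity = ifelse(knocked, "putatively-inactive", "active"))
  structure(list(sequences = sequences, calls = calls, truth = truth,
                 config = config),
            class = "degradome_simulation")
}

#' @export
print.degradome_simulation <- function(x, ...) {
  cat(sprintf("<degradome_simulation> %d records (seed %d), %d knockouts, %d secreted\n",
              length(x$sequences), x$config$seed, sum(x$truth$knocked_out),
              sum(x$truth$secreted)))
  invisible(x)
}

#' Write simulation artifacts to a directory
#'
#' Writes \code{sequences.fasta}, \code{calls.tsv} and \code{truth.tsv};
#' byte-identical for identical configurations.
#'
#' @param sim A \code{degradome_simulation}.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "degradome_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "sequences.fasta"),
             calls = file.path(dir, "calls.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_protein_fasta(sim$sequences, paths[["fasta"]])
  utils::write.table(sim$calls, paths[["calls"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Closed-form majority-vote accuracy
#'
#' Probability that the strict-majority consensus over \code{n_predictors}
#' independent predictors (each flipping the truth with probability
#' \code{error_rate}) recovers the true label, averaged over the two truth
#' states. With threshold 0.5 and six predictors, a secreted protein is
#' recovered when at least four predictors say secreted, and a non-secreted
#' protein when at most three do.
#'
#' @param error_rate Per-predictor flip probability.
#' @param p_secreted Prior probability of the secreted state.
#' @param n_predictors Number of predictors (all voting).
#' @param threshold Strict-majority threshold.
#' @return Expected consensus accuracy.
#' @export
majority_vote_accuracy <- function(error_rate, p_secreted = 0.267,
                                   n_predictors = 6L, threshold = 0.5) {
  k_needed <- floor(threshold * n_predictors) + 1L  # strict majority count
  p_true_secreted <- stats::pbinom(k_needed - 1L, n_predictors,
                                   1 - error_rate, lower.tail = FALSE)
  p_true_nonsecreted <- stats::pbinom(k_needed - 1L, n_predictors, error_rate)
  p_secreted * p_true_secreted + (1 - p_secreted) * p_true_nonsecreted
}

#' Run a full recovery experiment
#'
#' Generates a synthetic data set, classifies every record, votes the
#' predictor calls, and compares everything against the planted truth.
#'
#' @param config A \code{simulation_config}.
#' @param catalogue A \code{degradome_catalogue}.
#' @return List with \code{no_data} flag, \code{n}, \code{family_accuracy},
#'   \code{activity_accuracy}, \code{secretion_accuracy}, and the underlying
#'   \code{simulation} and classification table.
#' @export
recovery_experiment <- function(config, catalogue) {
  sim <- generate_degradome(config, catalogue)
  if (config$n_records == 0L) {
    return(list(no_data = TRUE, n = 0L, family_accuracy = NA_real_,
                activity_accuracy = NA_real_, secretion_accuracy = NA_real_,
                simulation = sim, classification = NULL))
  }
  cls <- classify_sequences(sim$sequences, catalogue)
  stopifnot(identical(cls$seq_id, sim$truth$seq_id))
  consensus <- consensus_vote(sim$calls)
  consensus <- consensus[match(sim$truth$seq_id, consensus$seq_id), ]
  voted_secreted <- consensus$consensus == "secreted"
  list(no_data = FALSE, n = config$n_records,
       family_accuracy = mean(!is.na(cls$subfamily) &
                                cls$subfamily == sim$truth$subfamily),
       activity_accuracy = mean(cls$activity == sim$truth$expected_activity),
       secretion_accuracy = mean(voted_secreted == sim$truth$secreted),
       simulation = sim, classification = cls)
}
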