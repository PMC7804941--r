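# Per-sequence classification: class/clan/subfamily assignment by motif
# architecture, activity calls, and metallopeptidase tribe reassignment.

#' Classify one protein sequence against the catalogue
#'
#' Evaluates every motif-bearing family rule with
#' \code{\link{match_architecture}} and keeps the rule with the most matched
#' catalytic-role components; ties are broken by specificity (total fixed
#' residue positions matched) and then by catalogue order (classes ordered
#' aspartic, glutamic, threonine, cysteine, serine, metallo). Activity is
#' called \code{active} when every catalytic-role component of the best rule
#' matched, \code{putatively-inactive} when at least one but not all matched.
#' When no catalytic component of any rule matches, homology evidence (if
#' supplied) assigns the family: \code{non-peptidase-homologue} when all of
#' that family's catalytic and metal-binding components are demonstrably
#' absent, otherwise the family is carried with an activity call from the
#' remaining evidence. With neither motifs nor homology the result is
#' \code{unclassified}.
#'
#' @param sequence Protein sequence (single string).
#' @param catalogue A \code{degradome_catalogue}.
#' @param homology Optional asserted subfamily id (homology evidence).
#' @param min_length Sequences shorter than this are unclassified (warning).
#' @param require_accessory If TRUE, accessory/turn components are also
#'   required for an \code{active} call.
#' @param seq_id Identifier carried into the result.
#' @return A \code{classification_result}.
#' @examples
#' cat <- load_catalogue()
#' seq <- paste0(strrep("A", 30), "DTG", strrep("A", 25), "DSG", strrep("A", 30))
#' classify_sequence(seq, cat)$best_rule
#' @export
classify_sequence <- function(sequence, catalogue, homology = NULL,
                              min_length = 20L, require_accessory = FALSE,
                              seq_id = NA_character_) {
  stopifnot(inherits(catalogue, "degradome_catalogue"))
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string")
  }
  sequence <- normalize_sequence(sequence)
  result <- function(best_rule = NA_character_, class = NA_character_,
                     clan = NA_character_, activity = "unclassified",
                     tribe = NA_character_, evidence = NULL,
                     used_homology = FALSE, ambiguous = FALSE) {
    structure(list(seq_id = seq_id, best_rule = best_rule, class = class,
                   clan = clan, activity = activity, tribe = tribe,
                   evidence = evidence, used_homology = used_homology,
                   ambiguous = ambiguous),
              class = "classification_result")
  }
  if (nchar(sequence) < min_length) {
    warning(sprintf("sequence%s shorter than %d residues: unclassified",
                    if (is.na(seq_id)) "" else paste0(" '", seq_id, "'"),
                    min_length))
    return(result())
  }

  motif_rules <- Filter(function(r) any(r$roles == "catalytic"),
                        catalogue$rules)
  matches <- lapply(motif_rules, function(r) {
    match_architecture(sequence, r$components, r$roles,
                       rule_id = r$subfamily_id)
  })
  n_cat <- vapply(matches, function(m) m$n_catalytic_matched, 0L)
  spec <- vapply(matches, function(m) m$specificity, 0L)

  if (length(matches) && max(n_cat) > 0L) {
    best_i <- order(-n_cat, -spec)[[1]]
    rule <- motif_rules[[best_i]]
    m <- matches[[best_i]]
    required <- rule$roles == "catalytic"
    if (require_accessory) required <- rep(TRUE, length(rule$roles))
    comp_ok <- !vapply(m$component_matches, is.null, logical(1))
    activity <- if (all(comp_ok[required])) "active" else "putatively-inactive"
    # pathological cross-class tie: same catalytic count and specificity in
    # a second class
    other_class <- vapply(motif_rules, function(r) r$catalytic_class,
                          character(1)) != rule$catalytic_class
    ambiguous <- any(n_cat[other_class] == n_cat[[best_i]] &
                     spec[other_class] == spec[[best_i]])
    tribe <- if (rule$catalytic_class == "metallo") {
      tribe_for_rule(rule)
    } else {
      NA_character_
    }
    return(result(rule$subfamily_id, rule$catalytic_class, rule$clan_id,
                  activity, tribe, m, used_homology = FALSE,
                  ambiguous = ambiguous))
  }

  if (!is.null(homology)) {
    rule <- lookup_rule(catalogue, homology)
    key_idx <- which(rule$roles %in% c("catalytic", "metal-binding"))
    key_absent <- all(vapply(key_idx, function(k) {
      is.null(scan_first_from(sequence, rule$components[[k]], 1L))
    }, logical(1)))
    tribe <- if (rule$catalytic_class == "metallo") {
      tribe_for_rule(rule)
    } else {
      NA_character_
    }
    if (length(key_idx) == 0L) {
      # motif-free family: homology is the only available evidence; absence
      # of a consensus motif cannot demonstrate a non-peptidase
      return(result(rule$subfamily_id, rule$catalytic_class, rule$clan_id,
                    "active", tribe, NULL, used_homology = TRUE))
    }
    if (key_absent) {
      return(result(rule$subfamily_id, rule$catalytic_class, rule$clan_id,
                    "non-peptidase-homologue", tribe, NULL,
                    used_homology = TRUE))
    }
    # metal-binding evidence present but no catalytic motif anywhere:
    # family carried from homology, activity from missing catalytic residues
    return(result(rule$subfamily_id, rule$catalytic_class, rule$clan_id,
                  "putatively-inactive", tribe, NULL, used_homology = TRUE))
  }
  result()
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result>%s %s (%s/%s) %s%s%s\n",
              if (is.na(x$seq_id)) "" else paste0(" ", x$seq_id),
              x$best_rule %||% NA, x$class, x$clan, x$activity,
              if (!is.na(x$tribe)) paste0(", tribe ", x$tribe) else "",
              if (x$ambiguous) " [ambiguous]" else ""))
  invisible(x)
}

# Tribe from a rule's compiled active-site architecture (decision logic of
# assign_tribe, shared with classify_sequence).
tribe_for_rule <- function(rule) {
  stopifnot(inherits(rule, "family_rule"))
  if (rule$catalytic_class != "metallo") {
    stop("assign_tribe: rule is not a metallopeptidase family")
  }
  comps <- rule$components
  is_set <- function(e, set) e$kind == "residue-set" && setequal(e$residues, set)
  is_sub <- function(e, set) {
    e$kind == "residue-set" && length(e$residues) < 20L &&
      all(e$residues %in% set)
  }
  has_fixed_glu <- function(p) {
    any(vapply(p$elements, function(e) is_set(e, "E"), logical(1)))
  }
  # AAA proteases carry a generic HEXXH that must not be read as a gluzincin:
  # the fold context (FtsH/M41) decides
  if (startsWith(rule$subfamily_id, "M41")) return("AAA")
  for (p in comps) {
    el <- p$elements
    n <- length(el)
    # extended zincin H(Q/E)XXHXXGXXH/D or HEXXHXX(H/F)XXH with a third His
    if (n > 5L && is_set(el[[1]], "H") && is_sub(el[[2]], c("E", "Q")) &&
        is_set(el[[5]], "H") &&
        any(vapply(el[6:n], function(e) is_sub(e, c("H", "D", "F")),
                   logical(1)))) {
      return("metzincin")
    }
  }
  for (k in seq_along(comps)) {
    el <- comps[[k]]$elements
    n <- length(el)
    short_zincin <- (n >= 5L && is_set(el[[1]], "H") && is_set(el[[2]], "E") &&
                     (is_set(el[[min(n, 5L)]], "H") ||
                      (n >= 6L && is_set(el[[6]], "H"))) && n <= 6L)
    if (short_zincin) {
      glu_elsewhere <- any(vapply(seq_along(comps), function(j) {
        j != k && has_fixed_glu(comps[[j]])
      }, logical(1)))
      if (glu_elsewhere) return("gluzincin")
    }
  }
  for (p in comps) {
    el <- p$elements
    if (length(el) >= 5L && is_set(el[[1]], "H") && is_set(el[[4]], "E") &&
        is_set(el[[5]], "H")) {
      return("inverzincin")
    }
  }
  for (p in comps) {
    el <- p$elements
    if (length(el) == 4L && is_set(el[[1]], "H") && is_set(el[[4]], "E")) {
      return("funnelin")
    }
  }
  for (p in comps) {
    el <- p$elements
    if (length(el) >= 6L && is_sub(el[[1]], c("S", "G", "A")) &&
        length(el[[1]]$residues) > 1L && is_set(el[[2]], "H") &&
        is_set(el[[4]], "D") && is_set(el[[6]], "V")) {
      return("aba-exopeptidase:aminoacylase-1")
    }
  }
  for (p in comps) {
    el <- p$elements
    if (length(el) == 2L && is_set(el[[1]], "E") && is_set(el[[2]], "E")) {
      return("aba-exopeptidase:EEM2-MPs")
    }
  }
  "unassigned"
}

#' Reassign a metallopeptidase to its tribe by active-site architecture
#'
#' Applies the architecture-based decision rules (extended three-His zincin
#' motif with Met-turn → metzincin; short HEXXH/HEXXXH zincin with a
#' downstream glutamate ligand → gluzincin; inverted HXXEH → inverzincin;
#' HXXE funnel fold → funnelin; (S/G/A)HXDXV-type co-catalytic exopeptidase →
#' aminoacylase-1 branch; adjacent EE ligands → EEM2-MPs branch; AAA fold
#' context → AAA; otherwise unassigned).
#'
#' @param result A \code{classification_result} with class metallo, or a
#'   subfamily id string.
#' @param catalogue A \code{degradome_catalogue}.
#' @return Tribe label string.
#' @examples
#' cat <- load_catalogue()
#' assign_tribe("M10A", cat)
#' assign_tribe("M16A", cat)
#' @export
assign_tribe <- function(result, catalogue) {
  stopifnot(inherits(catalogue, "degradome_catalogue"))
  if (inherits(result, "classification_result")) {
    if (is.na(result$class) || result$class != "metallo") {
      stop("assign_tribe: classification result is not a metallopeptidase")
    }
    id <- result$best_rule
  } else {
    id <- result
  }
  tribe_for_rule(lookup_rule(catalogue, id))
}

classification_to_row <- function(res) {
  comp_names <- ""
  coords <- ""
  n_matched <- NA_integer_
  n_catalytic <- NA_integer_
  specificity <- NA_integer_
  if (!is.null(res$evidence)) {
    m <- res$evidence
    ok <- which(!vapply(m$component_matches, is.null, logical(1)))
    comp_names <- paste(sprintf("%d:%s", ok, m$roles[ok]), collapse = ",")
    coords <- paste(vapply(ok, function(k) {
      h <- m$component_matches[[k]]
      sprintf("%d-%d", h$start, h$end)
    }, character(1)), collapse = ",")
    n_matched <- m$n_matched
    n_catalytic <- m$n_catalytic_matched
    specificity <- m$specificity
  }
  tibble::tibble(seq_id = res$seq_id, class = res$class, clan = res$clan,
                 subfamily = res$best_rule, activity = res$activity,
                 tribe = res$tribe, n_matched = n_matched,
                 n_catalytic = n_catalytic, specificity = specificity,
                 components_matched = comp_names, coordinates = coords,
                 used_homology = res$used_homology, ambiguous = res$ambiguous)
}

#' Classify every record of a FASTA file
#'
#' @param fasta_path Path to a protein FASTA file.
#' @param catalogue A \code{degradome_catalogue}.
#' @param evidence Optional homology-evidence table with columns
#'   \code{seq_id}, \code{subfamily}, \code{source}.
#' @param ... Passed to \code{\link{classify_sequence}}.
#' @return A tibble with one row per input record, in input order.
#' @export
classify_fasta <- function(fasta_path, catalogue, evidence = NULL, ...) {
  seqs <- read_protein_fasta(fasta_path)
  classify_sequences(seqs, catalogue, evidence = evidence, ...)
}

#' Classify a named vector of sequences
#'
#' @param seqs Named character vector of protein sequences.
#' @inheritParams classify_fasta
#' @return A tibble with one row per sequence, in input order.
#' @export
classify_sequences <- function(seqs, catalogue, evidence = NULL, ...) {
  if (length(seqs) == 0L) {
    return(classification_to_row(
      classify_sequence("A", catalogue, min_length = 0L))[0, ])
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("sequences must be named")
  }
  if (anyDuplicated(names(seqs))) {
    stop(sprintf("duplicate sequence id '%s'",
                 names(seqs)[duplicated(names(seqs))][[1]]))
  }
  if (!is.null(evidence)) {
    stopifnot(all(c("seq_id", "subfamily") %in% names(evidence)))
    for (sf in unique(evidence$subfamily)) lookup_rule(catalogue, sf)
  }
  rows <- lapply(names(seqs), function(id) {
    hom <- NULL
    if (!is.null(evidence) && id %in% evidence$seq_id) {
      hom <- evidence$subfamily[evidence$seq_id == id][[1]]
    }
    classification_to_row(
      classify_sequence(seqs[[id]], catalogue, homology = hom,
                        seq_id = id, ...))
  })
  dplyr::bind_rows(rows)
}
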