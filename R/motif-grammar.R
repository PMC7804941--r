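# Motif-notation grammar: parsing, rendering, scanning, and ordered
# multi-motif architecture matching.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_NONSTANDARD <- c("B", "J", "O", "U", "Z", "X")

#' Parse a protease motif-notation string
#'
#' Parses the compact motif notation used for protease active-site
#' architectures into a matchable pattern. The notation supports fixed
#' residues (one-letter codes), the wildcard \code{X}, parenthesised
#' alternations such as \code{(T/S/G)}, trailing alternations binding to the
#' preceding position (\code{NEXXT/A} reads "T or A at the final position"),
#' and bounded spacers: \code{X_k} is a gap of exactly \code{k} residues,
#' \code{X_a-b} a gap of \code{a} to \code{b} residues, and \code{X_n} an
#' open-ended gap capped at \code{xn_max}.
#'
#' @param text Motif string, e.g. \code{"HEXXH"}, \code{"GXSXX(T/S/G)"},
#'   \code{"HXXGHXXGX_3-8_H"}.
#' @param xn_max Upper bound substituted for the open-ended \code{X_n} gap.
#' @return A \code{motif_pattern} object: the source text plus an ordered list
#'   of elements, each either a residue set or a bounded gap.
#' @examples
#' parse_motif("HEXXH")
#' parse_motif("D(D/T)G")
#' @export
parse_motif <- function(text, xn_max = 100L) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text)) {
    stop("motif text must be a single non-empty string")
  }
  if (grepl("[^A-Za-z0-9/()_-]", text)) {
    bad <- regmatches(text, regexpr("[^A-Za-z0-9/()_-]", text))
    stop(sprintf("motif '%s' contains unsupported character '%s'", text, bad))
  }
  # residue letters are case-insensitive, but the open-gap marker in "X_n_"
  # must stay lowercase, so case is normalized per token rather than globally
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  elements <- list()
  i <- 1L
  res_elt <- function(residues) list(kind = "residue-set", residues = residues)
  gap_elt <- function(lo, hi) list(kind = "gap", min_gap = lo, max_gap = hi)
  check_res <- function(r) {
    bad <- setdiff(r, AA_STANDARD)
    if (length(bad)) {
      stop(sprintf("motif '%s': '%s' is not a standard residue code",
                   text, bad[[1]]))
    }
    r
  }
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "(") {
      close <- NULL
      j <- i + 1L
      while (j <= n) {
        if (chars[[j]] == ")") { close <- j; break }
        j <- j + 1L
      }
      if (is.null(close)) stop(sprintf("motif '%s': unclosed '('", text))
      inner <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      parts <- toupper(strsplit(inner, "/", fixed = TRUE)[[1]])
      if (length(parts) < 2L || !all(nchar(parts) == 1L)) {
        stop(sprintf("motif '%s': malformed alternation '(%s)'", text, inner))
      }
      elements[[length(elements) + 1L]] <- res_elt(check_res(parts))
      i <- close + 1L
    } else if (toupper(ch) == "X" && i < n && chars[[i + 1L]] == "_") {
      rest <- paste(chars[(i + 2L):n], collapse = "")
      m <- regmatches(rest, regexec("^([0-9]+-[0-9]+|[0-9]+|n)_?", rest))[[1]]
      if (length(m) == 0L) {
        stop(sprintf("motif '%s': malformed gap bounds after 'X_'", text))
      }
      spec <- m[[2]]
      if (spec == "n") {
        lo <- 1L; hi <- as.integer(xn_max)
      } else if (grepl("-", spec, fixed = TRUE)) {
        b <- as.integer(strsplit(spec, "-", fixed = TRUE)[[1]])
        lo <- b[[1]]; hi <- b[[2]]
        if (lo > hi) {
          stop(sprintf("motif '%s': gap bounds '%s' have min > max",
                       text, spec))
        }
      } else {
        lo <- hi <- as.integer(spec)
      }
      elements[[length(elements) + 1L]] <- gap_elt(lo, hi)
      i <- i + 2L + nchar(m[[1]])
    } else if (toupper(ch) == "X") {
      elements[[length(elements) + 1L]] <- res_elt(AA_STANDARD)
      i <- i + 1L
    } else if (grepl("^[A-Za-z]$", ch)) {
      # trailing alternation: letter '/' letter ('/' letter ...)
      residues <- check_res(toupper(ch))
      j <- i + 1L
      while (j + 1L <= n && chars[[j]] == "/" &&
             grepl("^[A-Za-z]$", chars[[j + 1L]]) &&
             toupper(chars[[j + 1L]]) != "X") {
        residues <- c(residues, check_res(toupper(chars[[j + 1L]])))
        j <- j + 2L
      }
      elements[[length(elements) + 1L]] <- res_elt(unique(residues))
      i <- j
    } else {
      stop(sprintf("motif '%s': unexpected token '%s' at position %d",
                   text, ch, i))
    }
  }
  if (!any(vapply(elements, function(e) e$kind == "residue-set", logical(1)))) {
    stop(sprintf("motif '%s' has no residue positions", text))
  }
  structure(list(source_text = text, elements = elements),
            class = "motif_pattern")
}

#' Render a motif pattern back to canonical notation
#'
#' @param pattern A \code{motif_pattern}.
#' @return Canonical motif string; \code{parse_motif(render_motif(p))} is
#'   element-wise identical to \code{p}.
#' @export
render_motif <- function(pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  vapply(pattern$elements, function(e) {
    if (e$kind == "gap") {
      if (e$min_gap == e$max_gap) {
        sprintf("X_%d_", e$min_gap)
      } else {
        sprintf("X_%d-%d_", e$min_gap, e$max_gap)
      }
    } else if (length(e$residues) == 20L) {
      "X"
    } else if (length(e$residues) == 1L) {
      e$residues
    } else {
      paste0("(", paste(e$residues, collapse = "/"), ")")
    }
  }, character(1)) |> paste(collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s  (%d elements, span %d-%d)\n",
              x$source_text, length(x$elements),
              motif_min_span(x), motif_max_span(x)))
  invisible(x)
}

motif_min_span <- function(pattern) {
  sum(vapply(pattern$elements,
             function(e) if (e$kind == "gap") e$min_gap else 1L, 0L))
}

motif_max_span <- function(pattern) {
  sum(vapply(pattern$elements,
             function(e) if (e$kind == "gap") e$max_gap else 1L, 0L))
}

# Count of non-wildcard residue positions (alternations count once): used as
# the specificity tie-break when ranking candidate family assignments.
motif_fixed_positions <- function(pattern) {
  sum(vapply(pattern$elements, function(e) {
    e$kind == "residue-set" && length(e$residues) < 20L
  }, logical(1)))
}

# Compile to a lazily-quantified perl regex. Fixed residue sets become
# character classes (which never match non-standard codes such as B or U);
# wildcards and gaps become [A-Z], so non-standard codes only ever match
# wildcard positions.
motif_regex <- function(pattern) {
  paste(vapply(pattern$elements, function(e) {
    if (e$kind == "gap") {
      sprintf("[A-Z]{%d,%d}?", e$min_gap, e$max_gap)
    } else if (length(e$residues) == 20L) {
      "[A-Z]"
    } else if (length(e$residues) == 1L) {
      e$residues
    } else {
      paste0("[", paste(e$residues, collapse = ""), "]")
    }
  }, character(1)), collapse = "")
}

normalize_sequence <- function(sequence) {
  sequence <- toupper(sequence)
  if (grepl("[*-]", sequence)) {
    warning("stripping '*' and '-' characters from sequence")
    sequence <- gsub("[*-]", "", sequence)
  }
  sequence
}

#' Scan a protein sequence for a motif
#'
#' Reports every start position at which the pattern can match. For gapped
#' patterns, each start yields at most one match, the one with the
#' lexicographically smallest feasible gap lengths (earlier gaps shortened
#' first), so coordinates are deterministic. Positions holding non-standard
#' codes (B, J, O, U, X, Z) satisfy wildcard positions only.
#'
#' @param sequence Protein sequence (one-letter codes; case-insensitive;
#'   \code{*} and \code{-} are stripped with a warning).
#' @param pattern A \code{motif_pattern} from \code{\link{parse_motif}}.
#' @return A data frame with columns \code{start}, \code{end} (1-based,
#'   inclusive) and \code{matched_text}, ordered by \code{start}.
#' @examples
#' scan_motif("MHEAAHK", parse_motif("HEXXH"))
#' @export
scan_motif <- function(sequence, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  empty <- data.frame(start = integer(), end = integer(),
                      matched_text = character(),
                      stringsAsFactors = FALSE)
  if (length(sequence) != 1L || is.na(sequence)) {
    stop("sequence must be a single string")
  }
  sequence <- normalize_sequence(sequence)
  n <- nchar(sequence)
  min_span <- motif_min_span(pattern)
  if (n == 0L || min_span > n) return(empty)
  rx <- paste0("^", motif_regex(pattern))
  first <- pattern$elements[[1L]]
  chars <- strsplit(sequence, "")[[1]]
  if (first$kind == "residue-set" && length(first$residues) < 20L) {
    candidates <- which(chars %in% first$residues)
  } else {
    candidates <- seq_len(n)
  }
  candidates <- candidates[candidates <= n - min_span + 1L]
  starts <- integer(0)
  ends <- integer(0)
  for (i in candidates) {
    m <- regexpr(rx, substr(sequence, i, n), perl = TRUE)
    if (m != -1L) {
      starts <- c(starts, i)
      ends <- c(ends, i + attr(m, "match.length") - 1L)
    }
  }
  if (!length(starts)) return(empty)
  data.frame(start = starts, end = ends,
             matched_text = substring(sequence, starts, ends),
             stringsAsFactors = FALSE)
}

# First match of `pattern` with start >= from (and start <= latest, if
# finite); NULL when absent.
scan_first_from <- function(sequence, pattern, from, latest = Inf) {
  n <- nchar(sequence)
  min_span <- motif_min_span(pattern)
  if (from > n - min_span + 1L) return(NULL)
  rx <- paste0("^", motif_regex(pattern))
  first <- pattern$elements[[1L]]
  hi <- min(n - min_span + 1L, latest)
  if (hi < from) return(NULL)
  idx <- from:hi
  if (first$kind == "residue-set" && length(first$residues) < 20L) {
    chars <- strsplit(substr(sequence, from, hi), "")[[1]]
    idx <- idx[chars %in% first$residues]
  }
  for (i in idx) {
    m <- regexpr(rx, substr(sequence, i, n), perl = TRUE)
    if (m != -1L) {
      end <- i + attr(m, "match.length") - 1L
      return(list(start = i, end = end,
                  matched_text = substr(sequence, i, end)))
    }
  }
  NULL
}

#' Match an ordered multi-motif architecture
#'
#' Greedy leftmost assignment of an ordered list of motif components to a
#' sequence: each component is matched at the earliest feasible position
#' after the end of the previously matched component (plus the minimum
#' inter-component gap). Components that cannot be placed are recorded as
#' absent; later components continue from the last matched position, so
#' partial architectures are reported faithfully.
#'
#' @param sequence Protein sequence.
#' @param components List of \code{motif_pattern}s, in architecture order.
#' @param roles Character vector, one role per component
#'   (\code{catalytic}, \code{metal-binding}, \code{turn}, \code{accessory}).
#' @param inter_gap Length-2 numeric: minimum and maximum number of residues
#'   allowed between consecutive components (default 0 to unbounded).
#' @param rule_id Identifier carried into the result.
#' @return An \code{architecture_match}: per-component matches (or NULL),
#'   \code{n_matched}, \code{n_catalytic_matched} (catalytic-role components
#'   placed), and \code{specificity} (total fixed residue positions across
#'   placed components).
#' @export
match_architecture <- function(sequence, components,
                               roles = rep("catalytic", length(components)),
                               inter_gap = c(0, Inf), rule_id = NA_character_) {
  if (length(components) < 1L) stop("architecture needs at least one component")
  stopifnot(length(roles) == length(components))
  sequence <- normalize_sequence(sequence)
  pos <- 1L
  comp_matches <- vector("list", length(components))
  for (k in seq_along(components)) {
    latest <- if (pos == 1L || is.infinite(inter_gap[[2]])) {
      Inf
    } else {
      pos - inter_gap[[1]] + inter_gap[[2]]
    }
    hit <- scan_first_from(sequence, components[[k]], pos, latest)
    if (!is.null(hit)) {
      comp_matches[[k]] <- hit
      pos <- hit$end + 1L + inter_gap[[1]]
    }
  }
  matched <- !vapply(comp_matches, is.null, logical(1))
  specificity <- sum(vapply(which(matched), function(k) {
    motif_fixed_positions(components[[k]])
  }, 0L))
  structure(list(rule_id = rule_id,
                 component_matches = comp_matches,
                 roles = roles,
                 n_matched = sum(matched),
                 n_catalytic_matched = sum(matched & roles == "catalytic"),
                 specificity = as.integer(specificity)),
            class = "architecture_match")
}

#' @export
print.architecture_match <- function(x, ...) {
  cat(sprintf("<architecture_match> %s: %d/%d components (%d catalytic), specificity %d\n",
              x$rule_id, x$n_matched, length(x$component_matches),
              x$n_catalytic_matched, x$specificity))
  invisible(x)
}

#' Scan FASTA sequences for a set of motifs
#'
#' @param fasta_path Path to a protein FASTA file.
#' @param patterns Named list of \code{motif_pattern}s (names become
#'   \code{pattern_id}).
#' @return A tibble with columns \code{seq_id}, \code{pattern_id},
#'   \code{start}, \code{end}, \code{matched_text}.
#' @export
scan_fasta <- function(fasta_path, patterns) {
  seqs <- read_protein_fasta(fasta_path)
  if (is.null(names(patterns)) || any(!nzchar(names(patterns)))) {
    stop("patterns must be a named list")
  }
  out <- list()
  for (id in names(seqs)) {
    for (pid in names(patterns)) {
      hits <- scan_motif(seqs[[id]], patterns[[pid]])
      if (nrow(hits)) {
        hits$seq_id <- id
        hits$pattern_id <- pid
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(seq_id = character(), pattern_id = character(),
                          start = integer(), end = integer(),
                          matched_text = character()))
  }
  res <- dplyr::bind_rows(out)
  tibble::as_tibble(res[, c("seq_id", "pattern_id", "start", "end",
                            "matched_text")])
}

# Multi-record FASTA reader (wrapped or unwrapped) returning a named
# character vector of upper-case sequences.
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file '%s' does not exist", path))
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sequence id '%s' in '%s'",
                 ids[duplicated(ids)][[1]], path))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

write_protein_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(c(paste0(">", id), seqs[[id]]), con)
  }
  invisible(path)
}
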