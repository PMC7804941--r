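# Classification catalogue: family rules, protease inventory, and validation
# against the packaged manifest.

CLASS_ORDER <- c("aspartic", "glutamic", "threonine", "cysteine", "serine",
                 "metallo")
ACTIVITY_LEVELS <- c("active", "putatively-inactive", "non-peptidase-homologue")
COMPONENT_ROLES <- c("catalytic", "metal-binding", "turn", "accessory")
EC_EXO <- c("3.4.11", "3.4.13", "3.4.14", "3.4.16", "3.4.17", "3.4.19")
EC_ENDO <- c("3.4.21", "3.4.22", "3.4.23", "3.4.24", "3.4.25", "3.4.99")
EC_BUCKETS <- c(EC_EXO, EC_ENDO, "unknown")
TRIBE_LEVELS <- c("metzincin", "gluzincin", "inverzincin", "funnelin",
                  "aba-exopeptidase:aminoacylase-1",
                  "aba-exopeptidase:EEM2-MPs", "AAA", "unassigned")

#' Path to a packaged catalogue file
#'
#' @param file File name inside the package's \code{extdata} directory;
#'   with no argument, lists the available files.
#' @return Absolute path (or file listing).
#' @export
catalogue_path <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "degradome")))
  }
  path <- system.file("extdata", file, package = "degradome")
  if (!nzchar(path)) stop(sprintf("no packaged file '%s'", file))
  path
}

#' Load the classification catalogue and protease inventory
#'
#' Reads the structured-text rule file (family rules with motif components,
#' clan/class bindings, EC buckets, metallopeptidase tribes, and the expected
#' per-class manifest) and the inventory TSV (one row per protease gene
#' model), parses every motif, and cross-checks all references.
#'
#' @param rules_path Path to the rules YAML file; default: the packaged
#'   \emph{A. niger} catalogue.
#' @param inventory_path Path to the inventory TSV; default: the packaged
#'   inventory. \code{NULL} loads rules only (empty inventory).
#' @param xn_max Override for the open-ended \code{X_n} gap bound; default
#'   comes from the rule file.
#' @return A \code{degradome_catalogue}: \code{rules} (named list of family
#'   rules, catalogue order), \code{records} (inventory tibble),
#'   \code{manifest}, \code{xn_max}, \code{class_order}.
#' @examples
#' cat <- load_catalogue()
#' length(cat$rules)
#' nrow(cat$records)
#' @export
load_catalogue <- function(rules_path = catalogue_path("aniger_rules.yaml"),
                           inventory_path = catalogue_path("aniger_inventory.tsv"),
                           xn_max = NULL) {
  if (!file.exists(rules_path)) {
    stop(sprintf("rules file '%s' does not exist", rules_path))
  }
  raw <- yaml::read_yaml(rules_path)
  if (is.null(raw$rules) || length(raw$rules) == 0L) {
    stop(sprintf("no rules in catalogue file '%s'", rules_path))
  }
  if (is.null(xn_max)) xn_max <- raw$xn_default_max %||% 100L
  class_order <- raw$class_order %||% CLASS_ORDER

  rules <- list()
  for (entry in raw$rules) {
    id <- entry$subfamily
    if (is.null(id) || !nzchar(id)) stop("rule without a subfamily id")
    if (!is.null(rules[[id]])) stop(sprintf("duplicate rule '%s'", id))
    if (!(entry$class %in% CLASS_ORDER)) {
      stop(sprintf("rule '%s': unknown class token '%s'", id, entry$class))
    }
    clan <- entry$clan %||% "unassigned"
    if (!grepl("^([A-Z]{2}|unassigned)$", clan)) {
      stop(sprintf("rule '%s': unknown clan token '%s'", id, clan))
    }
    if (!(entry$ec_bucket %in% EC_BUCKETS)) {
      stop(sprintf("rule '%s': unknown EC bucket '%s'", id, entry$ec_bucket))
    }
    motif_free <- isTRUE(entry$motif_free)
    comps <- list()
    roles <- character(0)
    for (cmp in entry$components %||% list()) {
      if (!(cmp$role %in% COMPONENT_ROLES)) {
        stop(sprintf("rule '%s': unknown component role '%s'", id, cmp$role))
      }
      comps[[length(comps) + 1L]] <- parse_motif(cmp$motif, xn_max = xn_max)
      roles <- c(roles, cmp$role)
    }
    if (!motif_free && !any(roles == "catalytic")) {
      stop(sprintf("rule '%s' has no catalytic component and is not motif-free",
                   id))
    }
    tribe <- entry$tribe %||% NA_character_
    if (!is.na(tribe)) {
      if (entry$class != "metallo") {
        stop(sprintf("rule '%s': tribe set for non-metallo class", id))
      }
      if (!(tribe %in% TRIBE_LEVELS)) {
        stop(sprintf("rule '%s': unknown tribe '%s'", id, tribe))
      }
    }
    rules[[id]] <- structure(
      list(subfamily_id = id, clan_id = clan, catalytic_class = entry$class,
           archetype = entry$archetype %||% "",
           ec_bucket = entry$ec_bucket, tribe = tribe,
           residue_arrangement = unlist(entry$residue_arrangement),
           motif_free = motif_free, components = comps, roles = roles),
      class = "family_rule")
  }

  # catalogue order: classes as in Table 1, rules in file order within class
  cls <- vapply(rules, function(r) r$catalytic_class, character(1))
  ord <- order(match(cls, class_order), seq_along(rules))
  rules <- rules[ord]

  manifest <- raw$manifest
  if (!is.null(manifest)) {
    manifest$classes <- unlist(manifest$classes)
  }

  records <- empty_inventory()
  if (!is.null(inventory_path)) {
    records <- read_inventory(inventory_path, rules)
  }

  structure(list(rules = rules, records = records, manifest = manifest,
                 xn_max = xn_max, class_order = class_order,
                 source = c(rules = rules_path,
                            inventory = inventory_path %||% NA_character_)),
            class = "degradome_catalogue")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_inventory <- function() {
  tibble::tibble(locus_tag = character(), strain = character(),
                 class = character(), clan = character(),
                 subfamily = character(), provisional_id = character(),
                 activity = character(), secreted = logical(),
                 ec_bucket = character(), characterized = logical(),
                 motif_annotation = character(), note = character())
}

read_inventory <- function(path, rules) {
  if (!file.exists(path)) {
    stop(sprintf("inventory file '%s' does not exist", path))
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE)
  needed <- names(empty_inventory())
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop(sprintf("inventory is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  }
  df <- tibble::as_tibble(df[needed])
  df$secreted <- df$secreted == "TRUE"
  df$characterized <- df$characterized == "TRUE"
  if (anyDuplicated(df$locus_tag)) {
    stop(sprintf("duplicate locus tag '%s' in inventory",
                 df$locus_tag[duplicated(df$locus_tag)][[1]]))
  }
  bad_class <- setdiff(unique(df$class), CLASS_ORDER)
  if (length(bad_class)) {
    stop(sprintf("inventory: unknown class token '%s'", bad_class[[1]]))
  }
  bad_act <- setdiff(unique(df$activity), ACTIVITY_LEVELS)
  if (length(bad_act)) {
    stop(sprintf("inventory: unknown activity token '%s'", bad_act[[1]]))
  }
  bad_ec <- setdiff(unique(df$ec_bucket), EC_BUCKETS)
  if (length(bad_ec)) {
    stop(sprintf("inventory: unknown EC bucket '%s'", bad_ec[[1]]))
  }
  for (i in seq_len(nrow(df))) {
    sf <- df$subfamily[[i]]
    if (sf != "unassigned") {
      rule <- rules[[sf]]
      if (is.null(rule)) {
        stop(sprintf("record '%s': subfamily '%s' not in catalogue",
                     df$locus_tag[[i]], sf))
      }
      if (rule$catalytic_class != df$class[[i]]) {
        stop(sprintf("record '%s': class '%s' disagrees with rule '%s'",
                     df$locus_tag[[i]], df$class[[i]], sf))
      }
      if (rule$clan_id != df$clan[[i]]) {
        stop(sprintf("record '%s': clan '%s' disagrees with rule '%s'",
                     df$locus_tag[[i]], df$clan[[i]], sf))
      }
    }
    if (df$class[[i]] == "threonine" && df$secreted[[i]]) {
      stop(sprintf("record '%s': secreted threonine protease violates inventory invariant",
                   df$locus_tag[[i]]))
    }
  }
  df
}

#' Look up a family rule by subfamily identifier
#'
#' @param catalogue A \code{degradome_catalogue}.
#' @param subfamily_id Subfamily identifier, e.g. \code{"A1A"}, \code{"M16A"}.
#' @return The \code{family_rule}.
#' @examples
#' lookup_rule(load_catalogue(), "A22B")
#' @export
lookup_rule <- function(catalogue, subfamily_id) {
  stopifnot(inherits(catalogue, "degradome_catalogue"))
  rule <- catalogue$rules[[subfamily_id]]
  if (is.null(rule)) {
    stop(sprintf("subfamily '%s' not found in catalogue", subfamily_id))
  }
  rule
}

#' @export
print.family_rule <- function(x, ...) {
  cat(sprintf("<family_rule> %s (clan %s, class %s)%s\n", x$subfamily_id,
              x$clan_id, x$catalytic_class,
              if (!is.na(x$tribe)) paste0(", tribe ", x$tribe) else ""))
  if (x$motif_free) cat("  motif-free (homology-based family)\n")
  for (k in seq_along(x$components)) {
    cat(sprintf("  [%d] %-12s %s\n", k, x$roles[[k]],
                x$components[[k]]$source_text))
  }
  invisible(x)
}

#' @export
print.degradome_catalogue <- function(x, ...) {
  cat(sprintf("<degradome_catalogue> %d family rules, %d inventory records\n",
              length(x$rules), nrow(x$records)))
  invisible(x)
}

# Count distinct clans per Table 1 bookkeeping: annotated clans plus one
# non-classified clan when the class hosts a family without clan assignment
# (clan 'unassigned' but a real subfamily).
count_clans_table1 <- function(records) {
  annotated <- unique(records$clan[records$clan != "unassigned"])
  extra <- any(records$clan == "unassigned" & records$subfamily != "unassigned")
  length(annotated) + as.integer(extra)
}

count_subfamilies <- function(records) {
  length(unique(records$subfamily[records$subfamily != "unassigned"]))
}

#' Validate the inventory against the packaged manifest
#'
#' Recomputes every manifest row (per class and total) from the inventory
#' records and reports cell-by-cell agreement. Rows that cannot be derived
#' from the record fields alone (new members and new active sites, which
#' compare against an earlier annotation) are carried from the manifest and
#' marked as not recomputable.
#'
#' @param records Inventory tibble (as in \code{catalogue$records}).
#' @param manifest Manifest list (as in \code{catalogue$manifest}).
#' @return An \code{inventory_validation} with a cell-level comparison table
#'   and an overall \code{ok} flag.
#' @examples
#' cat <- load_catalogue()
#' validate_inventory(cat$records, cat$manifest)
#' @export
validate_inventory <- function(records, manifest) {
  stopifnot(is.data.frame(records), is.list(manifest))
  classes <- manifest$classes
  by_class <- lapply(classes, function(cl) records[records$class == cl, ])
  names(by_class) <- classes
  recompute <- list(
    gene_models = unname(vapply(by_class, nrow, 0L)),
    clans = unname(vapply(by_class, count_clans_table1, 0L)),
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
  rows <- list()
  for (row_name in setdiff(names(manifest), c("classes", "proteome_size"))) {
    expected <- unlist(manifest[[row_name]])
    recomputable <- row_name %in% names(recompute)
    observed <- if (recomputable) recompute[[row_name]] else expected
    rows[[length(rows) + 1L]] <- tibble::tibble(
      row = row_name,
      class = c(classes, "total"),
      expected = c(expected, sum(expected)),
      observed = as.integer(c(observed, sum(observed))),
      recomputed = recomputable)
  }
  table <- dplyr::bind_rows(rows)
  table$equal <- table$expected == table$observed
  structure(list(table = table,
                 ok = all(table$equal[table$recomputed]),
                 n_records = nrow(records)),
            class = "inventory_validation")
}

#' @export
print.inventory_validation <- function(x, ...) {
  cat(sprintf("<inventory_validation> %d records: %s\n", x$n_records,
              if (x$ok) "all recomputable manifest cells match" else
                "MISMATCH in recomputable manifest cells"))
  bad <- x$table[x$table$recomputed & !x$table$equal, ]
  if (nrow(bad)) {
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("  %s / %s: expected %d, observed %d\n", bad$row[[i]],
                  bad$class[[i]], bad$expected[[i]], bad$observed[[i]]))
    }
  }
  invisible(x)
}
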