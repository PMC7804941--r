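# Catalogue loading, rule lookup, inventory validation.

test_that("the packaged catalogue has 71 family rules over six classes", {
  cat <- test_catalogue()
  expect_length(cat$rules, 71)
  classes <- vapply(cat$rules, function(r) r$catalytic_class, character(1))
  expect_setequal(unique(classes),
                  c("aspartic", "glutamic", "threonine", "cysteine",
                    "serine", "metallo"))
  # catalogue order groups classes in Table-1 order
  expect_equal(unique(classes),
               c("aspartic", "glutamic", "threonine", "cysteine",
                 "serine", "metallo"))
})

test_that("clan identifiers count 26 with the non-classified clan", {
  cat <- test_catalogue()
  clans <- vapply(cat$rules, function(r) r$clan_id, character(1))
  annotated <- unique(clans[clans != "unassigned"])
  # 25 annotated clans plus the one family without clan assignment
  expect_length(annotated, 25)
  expect_true(any(clans == "unassigned"))
})

test_that("all motif strings are parsed and all cross-references resolve", {
  cat <- test_catalogue()
  for (rule in cat$rules) {
    expect_true(rule$motif_free || any(rule$roles == "catalytic"),
                info = rule$subfamily_id)
    for (p in rule$components) expect_s3_class(p, "motif_pattern")
    if (!is.na(rule$tribe)) {
      expect_equal(rule$catalytic_class, "metallo", info = rule$subfamily_id)
    }
  }
  for (sf in setdiff(unique(cat$records$subfamily), "unassigned")) {
    expect_false(is.null(cat$rules[[sf]]), info = sf)
  }
})

test_that("loading twice yields identical object graphs", {
  c1 <- load_catalogue()
  c2 <- load_catalogue()
  expect_identical(c1$rules, c2$rules)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$manifest, c2$manifest)
})

test_that("an empty rule file raises a 'no rules' error", {
  f <- tempfile(fileext = ".yaml")
  writeLines("schema_version: 1\nrules: []", f)
  expect_error(load_catalogue(f, NULL), "no rules")
  writeLines("schema_version: 1", f)
  expect_error(load_catalogue(f, NULL), "no rules")
})

test_that("bad rule files raise named load errors", {
  f <- tempfile(fileext = ".yaml")
  writeLines(paste(
    "rules:",
    "  - subfamily: Q1",
    "    clan: QA",
    "    class: quantum",
    "    ec_bucket: unknown",
    "    components:",
    "      - {motif: DTG, role: catalytic}", sep = "\n"), f)
  expect_error(load_catalogue(f, NULL), "unknown class token 'quantum'")
  writeLines(paste(
    "rules:",
    "  - subfamily: A1A",
    "    clan: AA",
    "    class: aspartic",
    "    ec_bucket: unknown",
    "    components:",
    "      - {motif: 'DT(G', role: catalytic}", sep = "\n"), f)
  expect_error(load_catalogue(f, NULL), "unclosed")
})

test_that("lookup_rule retrieves families and rejects unknown ids", {
  cat <- test_catalogue()
  a22b <- lookup_rule(cat, "A22B")
  expect_equal(vapply(a22b$components, function(p) p$source_text,
                      character(1))[1:2], c("YD", "GXGD"))
  m16a <- lookup_rule(cat, "M16A")
  expect_equal(m16a$tribe, "inverzincin")
  expect_match(m16a$components[[1]]$source_text, "HXXEH")
  expect_error(lookup_rule(cat, "Z9Z"), "not found")
})

test_that("duplicate locus tags are rejected at load time", {
  cat <- test_catalogue()
  inv <- tempfile(fileext = ".tsv")
  df <- utils::read.delim(catalogue_path("aniger_inventory.tsv"),
                          colClasses = "character")
  df2 <- rbind(df, df[1, ])
  utils::write.table(df2, inv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_catalogue(inventory_path = inv), "duplicate locus tag")
})

test_that("a secreted threonine record violates the inventory invariant", {
  df <- utils::read.delim(catalogue_path("aniger_inventory.tsv"),
                          colClasses = "character")
  i <- which(df$class == "threonine")[1]
  df$secreted[i] <- "TRUE"
  inv <- tempfile(fileext = ".tsv")
  utils::write.table(df, inv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_catalogue(inventory_path = inv), "secreted threonine")
})

test_that("unknown tokens in the inventory are rejected", {
  df <- utils::read.delim(catalogue_path("aniger_inventory.tsv"),
                          colClasses = "character")
  df$class[1] <- "mystery"
  inv <- tempfile(fileext = ".tsv")
  utils::write.table(df, inv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_catalogue(inventory_path = inv), "unknown class token")
})

test_that("validate_inventory reproduces every Table-style marginal", {
  cat <- test_catalogue()
  rep <- validate_inventory(cat$records, cat$manifest)
  expect_true(rep$ok)
  expect_true(all(rep$table$equal[rep$table$recomputed]))
  gm <- rep$table[rep$table$row == "gene_models", ]
  expect_equal(gm$observed, c(17L, 5L, 14L, 41L, 72L, 83L, 232L))
  ch <- rep$table[rep$table$row == "characterized", ]
  expect_equal(ch$observed[ch$class == "total"], 19L)
})

test_that("validate_inventory flags disagreements cell by cell", {
  cat <- test_catalogue()
  records <- cat$records[-1, ]  # drop one aspartic record
  rep <- validate_inventory(records, cat$manifest)
  expect_false(rep$ok)
  bad <- rep$table[!rep$table$equal & rep$table$recomputed, ]
  expect_true(all(bad$class %in% c("aspartic", "total")))
})

test_that("EC buckets partition the inventory", {
  cat <- test_catalogue()
  expect_equal(nrow(cat$records), 232)
  sides <- ec_side(cat$records$ec_bucket)
  expect_equal(sum(table(sides)), 232)
})
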