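# Motif notation: parsing, rendering, scanning, architecture matching.

test_that("parse_motif handles fixed residues and wildcards", {
  p <- parse_motif("HEXXH")
  expect_s3_class(p, "motif_pattern")
  expect_length(p$elements, 5)
  expect_equal(p$elements[[1]]$residues, "H")
  expect_equal(p$elements[[2]]$residues, "E")
  expect_length(p$elements[[3]]$residues, 20)
  expect_length(p$elements[[4]]$residues, 20)
  expect_equal(p$elements[[5]]$residues, "H")
})

test_that("parse_motif handles parenthesised alternations", {
  p <- parse_motif("GXSXX(T/S/G)")
  expect_length(p$elements, 6)
  expect_setequal(p$elements[[6]]$residues, c("T", "S", "G"))
  expect_equal(p$elements[[3]]$residues, "S")
})

test_that("a single residue parses to a one-element pattern", {
  p <- parse_motif("A")
  expect_length(p$elements, 1)
  expect_equal(p$elements[[1]]$residues, "A")
})

test_that("trailing alternation binds to the preceding position", {
  p <- parse_motif("NEXXT/A")
  expect_length(p$elements, 5)
  expect_setequal(p$elements[[5]]$residues, c("T", "A"))
  p2 <- parse_motif("HXXEHX_76_EXXV/H")
  expect_setequal(p2$elements[[length(p2$elements)]]$residues, c("V", "H"))
})

test_that("gap bounds parse as specified", {
  p <- parse_motif("HXXGHXXGX_3-8_H")
  expect_length(p$elements, 10)
  gap <- p$elements[[9]]
  expect_equal(gap$kind, "gap")
  expect_equal(gap$min_gap, 3)
  expect_equal(gap$max_gap, 8)
  pk <- parse_motif("HGX_41_C")
  expect_equal(pk$elements[[3]]$min_gap, 41)
  expect_equal(pk$elements[[3]]$max_gap, 41)
})

test_that("open-ended X_n takes the configured bound", {
  p <- parse_motif("EX_n_H")
  expect_equal(p$elements[[2]]$min_gap, 1)
  expect_equal(p$elements[[2]]$max_gap, 100)
  p2 <- parse_motif("EX_n_H", xn_max = 30)
  expect_equal(p2$elements[[2]]$max_gap, 30)
})

test_that("malformed motifs raise parse errors naming the token", {
  expect_error(parse_motif(""), "non-empty")
  expect_error(parse_motif("H(ES"), "unclosed")
  expect_error(parse_motif("H()G"), "malformed alternation")
  expect_error(parse_motif("HX_8-3_G"), "min > max")
  expect_error(parse_motif("HX__G"), "gap bounds")
  expect_error(parse_motif("H#G"), "unsupported character")
  expect_error(parse_motif("HBG"), "not a standard residue")
  expect_error(parse_motif("X_1-2_"), "no residue positions")
})

test_that("parse-render round trip is idempotent", {
  for (txt in c("HEXXH", "GXSXX(T/S/G)", "NEXXT/A", "HXXGHXXGX_3-8_H",
                "EX_n_HXHX_10_D", "D(D/T)G", "HGX_41-53_(A/S)C")) {
    p1 <- parse_motif(txt)
    canon <- render_motif(p1)
    p2 <- parse_motif(canon)
    expect_equal(p2$elements, p1$elements, info = txt)
    expect_equal(render_motif(p2), canon, info = txt)
  }
})

test_that("every catalogue motif round-trips through its canonical form", {
  cat <- test_catalogue()
  for (rule in cat$rules) {
    for (p in rule$components) {
      p2 <- parse_motif(render_motif(p), xn_max = cat$xn_max)
      expect_equal(p2$elements, p$elements, info = p$source_text)
    }
  }
})

test_that("scan_motif finds the printed example matches", {
  hits <- scan_motif("MHEAAHK", parse_motif("HEXXH"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 2)
  expect_equal(hits$end, 6)
  expect_equal(hits$matched_text, "HEAAH")
  expect_equal(nrow(scan_motif("MHEAH", parse_motif("HEXXH"))), 0)
})

test_that("empty and short sequences scan to empty results", {
  expect_equal(nrow(scan_motif("", parse_motif("HEXXH"))), 0)
  expect_equal(nrow(scan_motif("HE", parse_motif("HEXXH"))), 0)
})

test_that("scanning is case-insensitive and strips * and - with a warning", {
  expect_equal(scan_motif("mheaahk", parse_motif("HEXXH"))$start, 2)
  expect_warning(hits <- scan_motif("MHE-AAH*K", parse_motif("HEXXH")),
                 "stripping")
  expect_equal(hits$start, 2)
})

test_that("non-standard codes match only wildcard positions", {
  p <- parse_motif("HEXXH")
  expect_equal(scan_motif("HEBZH", p)$start, 1)   # B, Z on wildcards: fine
  expect_equal(nrow(scan_motif("BEAAH", p)), 0)   # B on fixed H: no match
  expect_equal(nrow(scan_motif("HEAAX", p)), 0)   # X code on fixed H: no match
  expect_equal(scan_motif("AXB", parse_motif("XXX"))$start, 1)
})

test_that("each start yields the leftmost-shortest gap assignment", {
  # gap can be 1..4; the shortest completion (G at position 3) must win
  hits <- scan_motif("AAGGG", parse_motif("AX_1-4_G"))
  expect_equal(hits$start, c(1, 2))
  expect_equal(hits$end, c(3, 4))
})

test_that("scan is deterministic and monotone in gap width", {
  set.seed(4001)
  for (i in 1:25) {
    seq1 <- random_sequence(40, 120)
    narrow <- parse_motif("HX_0-2_E")
    wide <- parse_motif("HX_0-6_E")
    h1 <- scan_motif(seq1, narrow)
    h2 <- scan_motif(seq1, narrow)
    expect_identical(h1, h2)
    expect_true(all(h1$start %in% scan_motif(seq1, wide)$start))
  }
})

test_that("scan_motif equals the brute-force oracle on random cases", {
  set.seed(4002)
  for (i in 1:200) {
    p <- parse_motif(random_pattern_text())
    seq1 <- random_sequence(20, 300)
    got <- scan_motif(seq1, p)
    want <- oracle_scan(seq1, p)
    expect_identical(got$start, want$start, info = p$source_text)
    expect_identical(got$end, want$end, info = p$source_text)
  }
})

test_that("match_architecture assigns components greedily left to right", {
  seq1 <- "AAADTGAAAAAAAAAADSGAAA"
  m <- match_architecture(seq1, list(parse_motif("DTG"), parse_motif("DSG")))
  expect_equal(m$n_matched, 2)
  expect_equal(m$component_matches[[1]]$start, 4)
  expect_equal(m$component_matches[[2]]$start, 17)
  # reversed order: DSG found at 17, no DTG after it
  m2 <- match_architecture(seq1, list(parse_motif("DSG"), parse_motif("DTG")))
  expect_equal(m2$n_matched, 1)
  expect_equal(m2$component_matches[[1]]$start, 17)
  expect_null(m2$component_matches[[2]])
})

test_that("architecture matches are ordered and non-overlapping", {
  set.seed(4003)
  for (i in 1:20) {
    seq1 <- random_sequence(60, 200, nonstandard = FALSE)
    comps <- list(parse_motif("DX_0-3_G"), parse_motif("HE"),
                  parse_motif("SG"))
    m <- match_architecture(seq1, comps,
                            roles = c("catalytic", "catalytic", "accessory"))
    hits <- Filter(Negate(is.null), m$component_matches)
    if (length(hits) > 1) {
      for (k in 2:length(hits)) {
        expect_gt(hits[[k]]$start, hits[[k - 1]]$end)
      }
    }
    expect_lte(m$n_catalytic_matched, m$n_matched)
  }
})

test_that("n_catalytic_matched and specificity follow roles and fixed positions", {
  seq1 <- paste0("AAADTGAAA", "HEAAH", "AAA")
  comps <- list(parse_motif("DTG"), parse_motif("HEXXH"))
  m <- match_architecture(seq1, comps, roles = c("catalytic", "accessory"))
  expect_equal(m$n_matched, 2)
  expect_equal(m$n_catalytic_matched, 1)
  expect_equal(m$specificity, 6)  # D,T,G + H,E,H
})

test_that("scan_fasta reports tidy per-pattern hits", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", "MHEAAHK", ">s2", "MAAADTGAAA"), fa)
  hits <- scan_fasta(fa, list(zincin = parse_motif("HEXXH"),
                              pepsin = parse_motif("DTG")))
  expect_equal(names(hits),
               c("seq_id", "pattern_id", "start", "end", "matched_text"))
  expect_equal(nrow(hits), 2)
  expect_equal(hits$seq_id, c("s1", "s2"))
  expect_equal(hits$pattern_id, c("zincin", "pepsin"))
})

test_that("FASTA reading rejects duplicate ids and missing files", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">dup", "MHEAAHK", ">dup", "MAAA"), fa)
  expect_error(scan_fasta(fa, list(z = parse_motif("HEXXH"))), "dup")
  expect_error(scan_fasta(tempfile(), list(z = parse_motif("HEXXH"))),
               "does not exist")
})
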