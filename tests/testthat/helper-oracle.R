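# Independent brute-force oracles and random-case generators shared by the
# unit and acceptance tests.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA26 <- c(AA20, c("B", "J", "O", "U", "Z", "X"))

# Exhaustive window/gap enumeration: for every start position, backtracking
# over gap lengths in increasing order (earlier gaps first), i.e. the
# lexicographically minimal feasible gap vector. Entirely independent of the
# regex-based implementation in the package.
oracle_scan <- function(sequence, pattern) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  el <- pattern$elements
  match_char <- function(ch, e) {
    if (length(e$residues) == 20L) grepl("^[A-Z]$", ch) else ch %in% e$residues
  }
  try_from <- function(k, pos) {
    if (k > length(el)) return(pos - 1L)
    e <- el[[k]]
    if (e$kind == "gap") {
      for (len in e$min_gap:e$max_gap) {
        if (pos + len - 1L > n) break
        r <- try_from(k + 1L, pos + len)
        if (!is.null(r)) return(r)
      }
      return(NULL)
    }
    if (pos > n || !match_char(chars[[pos]], e)) return(NULL)
    try_from(k + 1L, pos + 1L)
  }
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_len(n)) {
    r <- try_from(1L, i)
    if (!is.null(r)) {
      starts <- c(starts, i)
      ends <- c(ends, r)
    }
  }
  data.frame(start = starts, end = ends)
}

# Random motif with total gap span <= 12 (the acceptance envelope).
random_pattern_text <- function() {
  n_el <- sample(2:6, 1)
  txt <- character(0)
  span <- 0
  for (k in seq_len(n_el)) {
    kind <- sample(c("res", "set", "wild", "gap"), 1,
                   prob = c(0.4, 0.2, 0.25, 0.15))
    if (kind == "gap" && span < 12 && k > 1 && k < n_el) {
      a <- sample(0:3, 1)
      b <- a + sample(0:min(4, 12 - span - a), 1)
      span <- span + b
      txt <- c(txt, sprintf("X_%d-%d_", a, b))
    } else if (kind == "set") {
      rs <- sample(AA20, sample(2:3, 1))
      txt <- c(txt, paste0("(", paste(rs, collapse = "/"), ")"))
    } else if (kind == "wild") {
      txt <- c(txt, "X")
    } else {
      txt <- c(txt, sample(AA20, 1))
    }
  }
  paste(txt, collapse = "")
}

random_sequence <- function(min_len = 20, max_len = 300,
                            nonstandard = TRUE) {
  alphabet <- if (nonstandard) AA26 else AA20
  weights <- if (nonstandard) c(rep(1, 20), rep(0.05, 6)) else rep(1, 20)
  paste(sample(alphabet, sample(min_len:max_len, 1), replace = TRUE,
               prob = weights), collapse = "")
}

test_catalogue <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- load_catalogue()
    cached
  }
})
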