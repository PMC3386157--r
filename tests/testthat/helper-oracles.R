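# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths.

# Score a pair of gapped protein strings under BLOSUM62 with affine gap
# costs: each maximal gap run costs gap_open + gap_ext * length. Terminal
# gaps are charged (global alignment).
score_gapped_pair <- function(qa, ra, gap_open = 10, gap_ext = 0.5) {
  B <- get_blosum62()
  q <- strsplit(qa, "")[[1]]; r <- strsplit(ra, "")[[1]]
  stopifnot(length(q) == length(r))
  sc <- 0
  run <- "none"   # current gap state: none / q / r
  for (i in seq_along(q)) {
    if (q[i] == "-") {
      sc <- sc - gap_ext - if (run != "q") gap_open else 0
      run <- "q"
    } else if (r[i] == "-") {
      sc <- sc - gap_ext - if (run != "r") gap_open else 0
      run <- "r"
    } else {
      sc <- sc + B[q[i], r[i]]
      run <- "none"
    }
  }
  sc
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Enumerate every global alignment of two short sequences (Delannoy-number
# many; fine for lengths <= 5) and return the maximum affine-gap score.
brute_force_align_score <- function(s1, s2, gap_open = 10, gap_ext = 0.5) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  best <- -Inf
  rec <- function(i, j, qa, ra) {
    if (i > length(a) && j > length(b)) {
      sc <- score_gapped_pair(paste(qa, collapse = ""),
                              paste(ra, collapse = ""), gap_open, gap_ext)
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i <= length(a) && j <= length(b))
      rec(i + 1, j + 1, c(qa, a[i]), c(ra, b[j]))
    if (i <= length(a))
      rec(i + 1, j, c(qa, a[i]), c(ra, "-"))
    if (j <= length(b))
      rec(i, j + 1, c(qa, "-"), c(ra, b[j]))
  }
  rec(1, 1, character(), character())
  best
}

# Reference panel rows as rate_constants objects, hydrolysis-complete only.
panel_rcs <- function() {
  panel <- galpha_reference_panel()
  panel <- panel[is.finite(panel$k_cat), ]
  stats::setNames(
    lapply(seq_len(nrow(panel)),
           function(i) rate_constants(panel$k_obs_binding[i], panel$k_cat[i])),
    panel$name)
}
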