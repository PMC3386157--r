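#' Paired codon alignment
#'
#' Two aligned coding sequences for pairwise dN/dS. Gaps (`-`) must come in
#' codon-aligned triplets; neither ungapped sequence may contain an internal
#' stop codon (strip a terminal stop before constructing). Domain ranges are
#' named 1-based inclusive codon intervals on the alignment.
#'
#' @param cds1,cds2 Aligned nucleotide strings of equal length divisible
#'   by 3 (A/C/G/T/N/-).
#' @param domain_ranges Named list of length-2 integer vectors
#'   `c(start_codon, end_codon)`.
#' @return An object of class `codon_alignment`.
#' @export
codon_alignment <- function(cds1, cds2, domain_ranges = list()) {
  cds1 <- toupper(cds1); cds2 <- toupper(cds2)
  if (nchar(cds1) != nchar(cds2))
    stop("aligned sequences must have equal length", call. = FALSE)
  if (nchar(cds1) %% 3 != 0)
    stop("alignment length must be divisible by 3", call. = FALSE)
  for (s in list(cds1, cds2)) {
    bad <- regmatches(s, regexpr("[^ACGTN-]", s))
    if (length(bad) && nzchar(bad))
      stop("illegal nucleotide character: ", bad, call. = FALSE)
  }
  n_codons <- nchar(cds1) / 3
  codons1 <- substring(cds1, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
  codons2 <- substring(cds2, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
  for (cods in list(codons1, codons2)) {
    partial <- grepl("-", cods) & cods != "---"
    if (any(partial))
      stop("gaps must be codon-aligned triplets (codon ",
           which(partial)[1], ")", call. = FALSE)
  }
  code <- Biostrings::GENETIC_CODE
  for (cods in list(codons1, codons2)) {
    plain <- cods[!grepl("[N-]", cods)]
    if (any(code[plain] == "*"))
      stop("internal stop codon in coding sequence", call. = FALSE)
  }
  for (nm in names(domain_ranges)) {
    r <- domain_ranges[[nm]]
    if (length(r) != 2L || r[1] < 1 || r[2] > n_codons || r[1] > r[2])
      stop("invalid domain range '", nm, "'", call. = FALSE)
  }
  structure(list(codons1 = codons1, codons2 = codons2,
                 n_codons = n_codons, domain_ranges = domain_ranges),
            class = "codon_alignment")
}

#' Read a domain-range configuration
#'
#' JSON of the form `{"region": [start_codon, end_codon], ...}` (1-based,
#' inclusive).
#'
#' @param path JSON file.
#' @return Named list of integer ranges.
#' @export
read_domain_ranges <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(cfg, function(r) as.integer(r))
}

# --- Nei-Gojobori (1986) machinery ---------------------------------------

ng_bases <- c("A", "C", "G", "T")

# Synonymous / nonsynonymous site counts of one codon: at each position the
# fraction of the three possible single-nucleotide changes that preserve the
# amino acid. Changes creating a stop codon count as nonsynonymous.
ng_codon_sites <- function(codon, code = Biostrings::GENETIC_CODE) {
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(ng_bases, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (code[[mut]] == aa) s <- s + 1 / 3
    }
  }
  c(S = s, N = 3 - s)
}

# Synonymous / nonsynonymous difference counts between two codons, averaged
# with equal weight over all mutational pathways (orderings of the differing
# positions). Pathways passing through a stop codon are excluded; if every
# pathway is blocked, all are used.
ng_codon_diffs <- function(c1, c2, code = Biostrings::GENETIC_CODE) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(diff_pos)
  if (nd == 0L) return(c(Sd = 0, Nd = 0))
  perms <- if (nd == 1L) list(diff_pos) else {
    idx <- if (nd == 2L) list(1:2, 2:1)
           else list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                     c(3, 1, 2), c(3, 2, 1))
    lapply(idx, function(o) diff_pos[o])
  }
  paths <- lapply(perms, function(ord) {
    cur <- c1
    steps <- matrix(0, nrow = length(ord), ncol = 2)
    blocked <- FALSE
    for (i in seq_along(ord)) {
      nxt <- cur
      substr(nxt, ord[i], ord[i]) <- substr(c2, ord[i], ord[i])
      if (code[[nxt]] == "*") blocked <- TRUE
      steps[i, ] <- if (code[[nxt]] == code[[cur]]) c(1, 0) else c(0, 1)
      cur <- nxt
    }
    list(sd = sum(steps[, 1]), nd = sum(steps[, 2]), blocked = blocked)
  })
  ok <- !vapply(paths, `[[`, TRUE, "blocked")
  use <- if (any(ok)) paths[ok] else paths
  c(Sd = mean(vapply(use, `[[`, 0, "sd")),
    Nd = mean(vapply(use, `[[`, 0, "nd")))
}

# Jukes-Cantor multiple-hit correction; NA (undefined) when p >= 3/4.
jukes_cantor <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise dN/dS by Nei-Gojobori pathway counting
#'
#' Computes the nonsynonymous and synonymous substitution rates per site for
#' a region of a pairwise codon alignment using the Nei-Gojobori (1986)
#' method: per-codon synonymous/nonsynonymous site fractions (summing to 3
#' per codon), difference counts averaged with equal weight over all
#' mutational pathways, and the Jukes-Cantor correction
#' `d = -3/4 ln(1 - 4p/3)`. Site totals are averaged between the two
#' sequences. Codons containing gaps or ambiguous bases (N) are excluded and
#' counted in `n_skipped`.
#'
#' @param aln A [codon_alignment()].
#' @param region Name of a domain range defined on the alignment, or `NULL`
#'   for the whole alignment.
#' @return An object of class `dnds_result`: site totals (`S_sites`,
#'   `N_sites`), difference totals (`S_diff`, `N_diff`), proportions
#'   (`pS`, `pN`), corrected distances (`dS`, `dN`), `ratio` (dN/dS), the
#'   codon counts, and `flags` (`dS_undefined`, `dN_undefined`,
#'   `ratio_infinite`, `ratio_undefined`).
#' @export
nei_gojobori_dnds <- function(aln, region = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  idx <- seq_len(aln$n_codons)
  if (!is.null(region)) {
    if (!region %in% names(aln$domain_ranges))
      stop("region '", region, "' is not defined on this alignment",
           call. = FALSE)
    r <- aln$domain_ranges[[region]]
    idx <- seq.int(r[1], r[2])
  }
  c1 <- aln$codons1[idx]; c2 <- aln$codons2[idx]
  usable <- !grepl("[N-]", c1) & !grepl("[N-]", c2)
  n_skipped <- sum(!usable)
  c1 <- c1[usable]; c2 <- c2[usable]
  if (length(c1) == 0L)
    stop("no usable codons in region", call. = FALSE)

  sites1 <- vapply(c1, ng_codon_sites, c(S = 0, N = 0))
  sites2 <- vapply(c2, ng_codon_sites, c(S = 0, N = 0))
  S_sites <- (sum(sites1["S", ]) + sum(sites2["S", ])) / 2
  N_sites <- (sum(sites1["N", ]) + sum(sites2["N", ])) / 2
  diffs <- mapply(ng_codon_diffs, c1, c2)
  S_diff <- sum(diffs["Sd", ]); N_diff <- sum(diffs["Nd", ])

  pS <- if (S_sites > 0) S_diff / S_sites else NA_real_
  pN <- if (N_sites > 0) N_diff / N_sites else NA_real_
  dS <- jukes_cantor(pS)
  dN <- jukes_cantor(pN)

  flags <- character()
  if (!is.na(pS) && pS >= 0.75) flags <- c(flags, "dS_undefined")
  if (!is.na(pN) && pN >= 0.75) flags <- c(flags, "dN_undefined")
  ratio <- NA_real_
  if (!is.na(dS) && !is.na(dN)) {
    if (dS == 0 && dN == 0) {
      flags <- c(flags, "ratio_undefined")
    } else if (dS == 0) {
      ratio <- Inf
      flags <- c(flags, "ratio_infinite")
    } else {
      ratio <- dN / dS
    }
  }
  structure(list(region = if (is.null(region)) "all" else region,
                 n_codons = length(c1), n_skipped = n_skipped,
                 S_sites = S_sites, N_sites = N_sites,
                 S_diff = S_diff, N_diff = N_diff,
                 pS = pS, pN = pN, dS = dS, dN = dN,
                 ratio = ratio, flags = flags),
            class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("<dnds_result> region %s: %d codons (%d skipped)\n",
              x$region, x$n_codons, x$n_skipped))
  cat(sprintf("  dN = %.4g (Nd %.3g / N %.3g), dS = %.4g (Sd %.3g / S %.3g)\n",
              x$dN, x$N_diff, x$N_sites, x$dS, x$S_diff, x$S_sites))
  cat(sprintf("  dN/dS = %.4g%s\n", x$ratio,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}
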