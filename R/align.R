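#' Protein sequence record
#'
#' @param id Sequence identifier.
#' @param sequence Amino-acid string, IUPAC one-letter (20 standard residues
#'   plus X); case-insensitive.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence) {
  if (!is.character(id) || !nzchar(id)) stop("id must be a non-empty string",
                                             call. = FALSE)
  if (!is.character(sequence) || !nzchar(sequence))
    stop("sequence must be a non-empty string", call. = FALSE)
  sequence <- toupper(sequence)
  ok <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% ok)
  if (length(bad))
    stop(sprintf("illegal residue '%s' at position %d in %s",
                 chars[bad[1]], bad[1], id), call. = FALSE)
  structure(list(id = id, sequence = sequence), class = "protein_record")
}

#' Read protein records from FASTA
#'
#' @param path FASTA file.
#' @return Named list of [protein_record()] objects.
#' @export
read_protein_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aas))
  recs <- lapply(seq_along(aas), function(i)
    protein_record(ids[i], as.character(aas[[i]])))
  stats::setNames(recs, ids)
}

#' Write protein records to FASTA
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  if (inherits(records, "protein_record")) records <- list(records)
  seqs <- Biostrings::AAStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap costs
#' (opening 10, extension 0.5 per residue). Ties are broken deterministically
#' by the aligner's fixed traceback preference.
#'
#' @param query,reference [protein_record()] objects.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return An object of class `galpha_alignment` with the aligned strings
#'   (`query_aln`, `ref_aln`), the `score`, and the input ids.
#' @export
global_align <- function(query, reference, gap_open = 10, gap_extend = 0.5) {
  stopifnot(inherits(query, "protein_record"),
            inherits(reference, "protein_record"))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query$sequence),
    subject = Biostrings::AAString(reference$sequence),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_extend)
  structure(list(
    query_id = query$id, ref_id = reference$id,
    query_aln = as.character(Biostrings::alignedPattern(pa)),
    ref_aln = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)
  ), class = "galpha_alignment")
}

#' @export
print.galpha_alignment <- function(x, ...) {
  cat(sprintf("<galpha_alignment> %s vs %s, score %.1f, %d columns\n",
              x$query_id, x$ref_id, x$score, nchar(x$query_aln)))
  invisible(x)
}

# Column table of an alignment: for each column, the (1-based) ungapped
# positions in query and reference (NA at gaps).
alignment_columns <- function(aln) {
  q <- strsplit(aln$query_aln, "")[[1]]
  r <- strsplit(aln$ref_aln, "")[[1]]
  data.frame(
    column = seq_along(q), query_char = q, ref_char = r,
    query_pos = ifelse(q == "-", NA_integer_, cumsum(q != "-")),
    ref_pos = ifelse(r == "-", NA_integer_, cumsum(r != "-")),
    stringsAsFactors = FALSE)
}

#' Map a reference position through an alignment (and back)
#'
#' @param aln A `galpha_alignment`.
#' @param pos 1-based ungapped position on the reference
#'   (`map_ref_to_query`) or on the query (`map_query_to_ref`).
#' @return List with `pos` (mapped 1-based position or `NA` if the site
#'   aligns to a gap) and `residue` (the character at the mapped site, or
#'   `"-"`).
#' @export
map_ref_to_query <- function(aln, pos) {
  cols <- alignment_columns(aln)
  row <- cols[which(cols$ref_pos == pos), , drop = FALSE]
  if (nrow(row) == 0L)
    stop(sprintf("position %d is beyond the reference length", pos),
         call. = FALSE)
  list(pos = row$query_pos[1], residue = row$query_char[1])
}

#' @rdname map_ref_to_query
#' @export
map_query_to_ref <- function(aln, pos) {
  cols <- alignment_columns(aln)
  row <- cols[which(cols$query_pos == pos), , drop = FALSE]
  if (nrow(row) == 0L)
    stop(sprintf("position %d is beyond the query length", pos),
         call. = FALSE)
  list(pos = row$ref_pos[1], residue = row$ref_char[1])
}

#' Call the switch-I RGS-coupling determinant of a Galpha sequence
#'
#' Aligns a query Galpha to a reference and reads the residue homologous to
#' the reference switch-I threonine (position 194 in the Arabidopsis
#' AtGPA1 numbering). Classification: Thr or Ser — `rgs_couplable` (the
#' RGS-interacting state; Ser is accepted as a conservative substitution at
#' this hydrogen-bonding site); Asn — `grass_uncoupled` (the substitution
#' fixed in grass Galpha that weakens RGS binding); Lys — `g12_like` (the
#' residue carried by animal Galpha12/13, which are not RGS substrates);
#' anything else — `other`; alignment gap — `unaligned`.
#'
#' @param query,reference [protein_record()] objects; the reference must
#'   carry Thr/Ser at `ref_position`.
#' @param ref_position 1-based determinant position on the reference
#'   (default 194).
#' @return An object of class `switch1_call`: `query_id`, `ref_position`,
#'   `query_position` (NA if gapped), `residue`, `coupling_class`.
#' @export
switch1_residue <- function(query, reference, ref_position = 194) {
  stopifnot(inherits(query, "protein_record"),
            inherits(reference, "protein_record"))
  if (ref_position < 1 || ref_position > nchar(reference$sequence))
    stop(sprintf("ref_position %d is beyond the reference length (%d)",
                 ref_position, nchar(reference$sequence)), call. = FALSE)
  aln <- global_align(query, reference)
  hit <- map_ref_to_query(aln, ref_position)
  cls <- if (hit$residue == "-") "unaligned"
  else switch(hit$residue,
              "T" = , "S" = "rgs_couplable",
              "N" = "grass_uncoupled",
              "K" = "g12_like",
              "other")
  structure(list(query_id = query$id, ref_position = ref_position,
                 query_position = hit$pos, residue = hit$residue,
                 coupling_class = cls),
            class = "switch1_call")
}

#' @export
print.switch1_call <- function(x, ...) {
  cat(sprintf("<switch1_call> %s: %s at position %s -> %s\n",
              x$query_id, x$residue,
              if (is.na(x$query_position)) "gap" else x$query_position,
              x$coupling_class))
  invisible(x)
}
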