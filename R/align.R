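#' Build a simple substitution matrix
#'
#' Constructs a 21-letter (20 amino acids plus `X`) substitution matrix with a
#' uniform match and mismatch score. `X` always scores as a mismatch, against
#' itself included — an unknown residue never rewards alignment.
#'
#' @param match Score for identical letters.
#' @param mismatch Score for differing letters (and anything involving `X`).
#' @return A numeric matrix with amino-acid dimnames, usable as the `matrix`
#'   argument of [align_global()].
#' @export
score_matrix <- function(match = 1, mismatch = 0) {
  aas <- c(AA1, "X")
  m <- matrix(mismatch, length(aas), length(aas), dimnames = list(aas, aas))
  diag(m) <- match
  m["X", "X"] <- mismatch
  m
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

check_aa_seq <- function(seq, arg) {
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop_dicer(paste0(arg, " must be a non-empty amino-acid string"),
               "empty_sequence")
  }
  letters_used <- unique(strsplit(seq, "")[[1]])
  bad <- setdiff(letters_used, c(AA1, "X"))
  if (length(bad) > 0) {
    stop_dicer(paste0("unknown residue letter(s) in ", arg, ": ",
                      paste(bad, collapse = ", ")), "alphabet")
  }
  invisible(seq)
}

#' Global pairwise alignment of two protein sequences
#'
#' End-to-end (Needleman–Wunsch) alignment under affine gap scoring, used to
#' carry functional-site annotations from a reference Dicer-2 to an ortholog.
#' A gap of length L scores `gap_open + L * gap_extend`. The default scoring is
#' BLOSUM62 with gap open −10 and gap extend −1.
#'
#' @param ref_seq,tgt_seq Amino-acid strings over the 20 standard letters
#'   plus `X`.
#' @param matrix `"BLOSUM62"` or a numeric substitution matrix with amino-acid
#'   dimnames (see [score_matrix()]).
#' @param gap_open,gap_extend Gap penalties (non-positive).
#' @return An object of class `aa_alignment`: a list with `aligned_ref` and
#'   `aligned_tgt` (gapped strings), `score`, and `ref_to_tgt`, an integer
#'   vector mapping each reference position (1-based) to its aligned target
#'   position (`NA` opposite a gap). `tidy()` returns the position-level
#'   correspondence as a tibble.
#' @examples
#' al <- align_global("ACDE", "ACDE", matrix = score_matrix(1, 0),
#'                    gap_open = -5, gap_extend = -1)
#' al$score
#' @export
align_global <- function(ref_seq, tgt_seq, matrix = "BLOSUM62",
                         gap_open = -10, gap_extend = -1) {
  check_aa_seq(ref_seq, "ref_seq")
  check_aa_seq(tgt_seq, "tgt_seq")
  if (gap_open > 0 || gap_extend > 0) {
    stop_dicer("gap_open and gap_extend must be <= 0", "gap_penalty")
  }
  submat <- if (is.character(matrix) && identical(matrix, "BLOSUM62")) {
    blosum62_matrix()
  } else {
    matrix
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref_seq), Biostrings::AAString(tgt_seq),
    substitutionMatrix = submat,
    gapOpening = -gap_open, gapExtension = -gap_extend,
    type = "global"
  )
  aligned_ref <- as.character(Biostrings::alignedPattern(pa))
  aligned_tgt <- as.character(Biostrings::alignedSubject(pa))
  out <- list(
    aligned_ref = unname(aligned_ref),
    aligned_tgt = unname(aligned_tgt),
    score = Biostrings::score(pa),
    ref_to_tgt = gapped_mapping(aligned_ref, aligned_tgt),
    ref_seq = ref_seq,
    tgt_seq = tgt_seq
  )
  class(out) <- "aa_alignment"
  out
}

# Position mapping from a pair of gapped strings: ref index -> tgt index or NA.
gapped_mapping <- function(aligned_ref, aligned_tgt) {
  rc <- strsplit(aligned_ref, "")[[1]]
  tc <- strsplit(aligned_tgt, "")[[1]]
  ri <- cumsum(rc != "-")
  ti <- cumsum(tc != "-")
  keep <- rc != "-"
  map <- ifelse(tc[keep] != "-", ti[keep], NA_integer_)
  as.integer(map)
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("<aa_alignment> score:", x$score, "\n")
  cat(" ref:", substr(x$aligned_ref, 1, 60),
      if (nchar(x$aligned_ref) > 60) "..." else "", "\n")
  cat(" tgt:", substr(x$aligned_tgt, 1, 60),
      if (nchar(x$aligned_tgt) > 60) "..." else "", "\n")
  invisible(x)
}

#' @export
tidy.aa_alignment <- function(x, ...) {
  n <- nchar(x$ref_seq)
  tibble(
    ref_pos = seq_len(n),
    ref_aa = strsplit(x$ref_seq, "")[[1]],
    tgt_pos = x$ref_to_tgt,
    tgt_aa = ifelse(is.na(x$ref_to_tgt), NA_character_,
                    strsplit(x$tgt_seq, "")[[1]][x$ref_to_tgt])
  )
}

#' @export
glance.aa_alignment <- function(x, ...) {
  tibble(score = x$score,
         n_ref = nchar(x$ref_seq), n_tgt = nchar(x$tgt_seq),
         n_aligned = sum(!is.na(x$ref_to_tgt)),
         identity = mean(strsplit(x$ref_seq, "")[[1]][!is.na(x$ref_to_tgt)] ==
                           strsplit(x$tgt_seq, "")[[1]][x$ref_to_tgt[
                             !is.na(x$ref_to_tgt)]]))
}

#' Transfer site annotations to an ortholog through an alignment
#'
#' Maps each resolved site entry of a reference annotation onto the aligned
#' ortholog position. Entries aligned opposite a gap become unresolved (`"?"`),
#' mirroring the convention of the published residue table; with
#' `strict = TRUE`, entries whose target amino acid differs from the reference
#' one also become unresolved (off by default, since pocket residues are not
#' conserved across species).
#'
#' @param sites A `site_map` tibble annotating the reference structure.
#' @param alignment An `aa_alignment` from [align_global()] (reference first).
#' @param ref_numbering,tgt_numbering Integer vectors giving the author residue
#'   number of each sequence position (defaults: sequential 1..n). Author
#'   numbering is how structures and site tables address residues, so an
#'   N-terminally truncated ortholog induces a constant offset here.
#' @param structure_id Structure id for the transferred map (default: the
#'   target id derived from the reference id).
#' @param strict Drop entries whose target amino acid differs from the
#'   reference amino acid.
#' @return A `site_map` tibble for the target structure; transferred entries
#'   carry the target's author number and amino acid, unmapped entries are
#'   unresolved.
#' @export
transfer_sites <- function(sites, alignment, ref_numbering = NULL,
                           tgt_numbering = NULL, structure_id = NULL,
                           strict = FALSE) {
  n_ref <- nchar(alignment$ref_seq)
  n_tgt <- nchar(alignment$tgt_seq)
  ref_numbering <- ref_numbering %||% seq_len(n_ref)
  tgt_numbering <- tgt_numbering %||% seq_len(n_tgt)
  if (length(ref_numbering) != n_ref) {
    stop_dicer("ref_numbering length differs from the aligned reference sequence",
               "length_mismatch")
  }
  if (length(tgt_numbering) != n_tgt) {
    stop_dicer("tgt_numbering length differs from the aligned target sequence",
               "length_mismatch")
  }
  tgt_aa <- strsplit(alignment$tgt_seq, "")[[1]]
  ref_aa <- strsplit(alignment$ref_seq, "")[[1]]
  sid <- structure_id %||% paste0(unique(sites$structure_id)[1], "_transfer")

  rows <- purrr::pmap(as_tibble(sites), function(structure_id, site, chain,
                                                 resno, expected_aa, resolved,
                                                 ...) {
    unresolved_row <- tibble(structure_id = sid, site = site, chain = chain,
                             resno = NA_integer_, expected_aa = "?",
                             resolved = FALSE)
    if (!resolved) return(unresolved_row)
    i <- match(resno, ref_numbering)
    if (is.na(i)) {
      stop_dicer(paste0("site residue ", resno,
                        " is outside the reference sequence numbering"),
                 "length_mismatch")
    }
    j <- alignment$ref_to_tgt[i]
    if (is.na(j)) return(unresolved_row)
    if (strict && tgt_aa[j] != ref_aa[i]) return(unresolved_row)
    tibble(structure_id = sid, site = site, chain = chain,
           resno = as.integer(tgt_numbering[j]), expected_aa = tgt_aa[j],
           resolved = TRUE)
  })
  new_site_map(dplyr::bind_rows(rows))
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop_dicer(paste0("FASTA file '", path, "' does not exist"), "io")
  }
  seqs <- Biostrings::readAAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}
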