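#' HaeIII PCR-RFLP assay definition for the COI haplotypes
#'
#' The haplotyping assay: a 546-bp COI amplicon incubated with HaeIII
#' (recognition site `GGCC`, blunt cut between the two central bases).
#' Haplotype HT2 carries the site and is cut into 342- and 204-bp
#' fragments; HT1 lacks it and stays undigested. Gel calls tolerate a
#' +/- 5 bp fragment-size error.
#'
#' @param amplicon_length Expected amplicon length in bp (default 546).
#' @param cut_fragments Fragment profile diagnostic for HT2 (default
#'   `c(342, 204)`).
#' @param tol Gel-resolution tolerance in bp (default 5).
#' @return A list of class `"rflp_assay"` with fields `motif`,
#'   `cut_offset`, `amplicon_length`, `cut_fragments`, `tol`.
#' @export
haeiii_assay <- function(amplicon_length = 546,
                         cut_fragments = c(342, 204), tol = 5) {
  structure(list(motif = "GGCC", cut_offset = 2L,
                 amplicon_length = amplicon_length,
                 cut_fragments = cut_fragments, tol = tol),
            class = "rflp_assay")
}

#' In-silico restriction digest of an amplicon
#'
#' Finds every exact occurrence of the enzyme's recognition motif on the
#' given strand and cuts `cut_offset` bases into each occurrence.
#' Ambiguity codes never match the motif (conservative no-cut), so
#' poor-quality sequence cannot create spurious fragments.
#'
#' @param seq A single nucleotide sequence: character string,
#'   [Biostrings::DNAString] or length-1 [Biostrings::DNAStringSet].
#'   Uppercased before matching.
#' @param motif Recognition motif (default HaeIII, `"GGCC"`).
#' @param cut_offset Cut position within the motif, in \[0, motif length\]
#'   (default 2: blunt cut between GG and CC).
#' @return A list of class `"rflp_digest"` with `fragments` (ordered
#'   lengths, bp; empty for an empty sequence), `cut_positions` (base
#'   after which each cut falls, strictly increasing) and `length`
#'   (input length). Fragment lengths always sum to the input length.
#' @examples
#' digest_amplicon("GGCCGGCC")$fragments  # 2 4 2
#' @export
digest_amplicon <- function(seq, motif = "GGCC", cut_offset = 2L) {
  seq <- .as_sequence_string(seq)
  if (nchar(motif) < 1L) stop("'motif' must be non-empty", call. = FALSE)
  if (cut_offset < 0L || cut_offset > nchar(motif))
    stop("'cut_offset' must lie within the motif", call. = FALSE)
  n <- nchar(seq)
  if (n == 0L)
    return(structure(list(fragments = integer(0),
                          cut_positions = integer(0), length = 0L),
                     class = "rflp_digest"))
  hits <- gregexpr(motif, seq, fixed = TRUE)[[1L]]
  cuts <- if (hits[1L] == -1L) integer(0) else as.integer(hits) + cut_offset - 1L
  cuts <- cuts[cuts > 0L & cuts < n]      # end-of-sequence cuts split nothing
  structure(list(fragments = as.integer(diff(c(0L, cuts, n))),
                 cut_positions = cuts, length = n),
            class = "rflp_digest")
}

.as_sequence_string <- function(seq) {
  if (inherits(seq, "DNAStringSet")) {
    if (length(seq) != 1L)
      stop("expected a single sequence", call. = FALSE)
    seq <- seq[[1L]]
  }
  if (inherits(seq, "DNAString")) seq <- as.character(seq)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("'seq' must be a single nucleotide sequence", call. = FALSE)
  toupper(seq)
}

#' @export
print.rflp_digest <- function(x, ...) {
  cat(sprintf("RFLP digest: %d bp, %d cut(s), fragments: %s\n",
              x$length, length(x$cut_positions),
              paste(x$fragments, collapse = " + ")))
  invisible(x)
}

#' Call the mitochondrial haplotype from a digest result
#'
#' `HT1` if the amplicon stayed undigested (a single fragment of the
#' assay's full amplicon length, within gel tolerance); `HT2` if the
#' fragment multiset matches the assay's diagnostic cut profile within
#' tolerance; otherwise `unknown` -- mirroring the bench protocol where
#' unclear gels are sent for sequencing.
#'
#' @param result An `"rflp_digest"` (or a bare integer vector of fragment
#'   lengths).
#' @param assay An [haeiii_assay()]-style assay definition.
#' @return `"HT1"`, `"HT2"` or `"unknown"`.
#' @examples
#' call_haplotype(digest_amplicon(strrep("A", 546)))
#' @export
call_haplotype <- function(result, assay = haeiii_assay()) {
  frags <- if (inherits(result, "rflp_digest")) result$fragments else
    as.integer(result)
  tol <- assay$tol
  if (length(frags) == 1L &&
      abs(frags - assay$amplicon_length) <= tol)
    return("HT1")
  exp_f <- sort(assay$cut_fragments)
  if (length(frags) == length(exp_f) &&
      all(abs(sort(frags) - exp_f) <= tol))
    return("HT2")
  "unknown"
}

#' Type a set of amplicons by PCR-RFLP
#'
#' Digests each sequence and calls its haplotype, producing a tidy report.
#'
#' @param sequences A named character vector or [Biostrings::DNAStringSet]
#'   (e.g. from [read_amplicons()]).
#' @param assay An [haeiii_assay()]-style assay definition.
#' @return A data frame with columns `id`, `length`, `n_fragments`,
#'   `fragments` (lengths joined by `+`) and `call`.
#' @examples
#' rflp_type(generate_fixture_amplicons())
#' @export
rflp_type <- function(sequences, assay = haeiii_assay()) {
  if (inherits(sequences, "DNAStringSet")) {
    ids <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- ids
  }
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  rows <- lapply(names(sequences), function(id) {
    d <- digest_amplicon(sequences[[id]], assay$motif, assay$cut_offset)
    data.frame(id = id, length = d$length,
               n_fragments = length(d$fragments),
               fragments = paste(d$fragments, collapse = "+"),
               call = call_haplotype(d, assay),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read / write amplicon FASTA files
#'
#' Thin wrappers around Biostrings FASTA I/O returning/accepting
#' `DNAStringSet` objects.
#'
#' @param path FASTA file path.
#' @return `read_amplicons()` returns a [Biostrings::DNAStringSet].
#' @export
read_amplicons <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_amplicons
#' @param sequences A [Biostrings::DNAStringSet] or named character vector.
#' @export
write_amplicons <- function(sequences, path) {
  if (!inherits(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}
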