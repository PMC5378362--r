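#' Read a genome FASTA into a plain character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning named
#' uppercase character strings, the representation used by the sequence-level
#' operations (fast `substr` access in the simulation loop).
#'
#' @param path FASTA file.
#' @return Named character vector, one element per contig. Names are truncated
#'   at the first whitespace, as aligners do.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  class(out) <- c("nmd_genome", "character")
  out
}

#' Write a genome FASTA
#' @param genome Named character vector of contig sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- as.character(unclass(genome))
  names(x) <- names(genome)
  ss <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

as_genome_chr <- function(genome) {
  if (inherits(genome, "nmd_genome")) return(genome) # already normalised
  if (methods::is(genome, "DNAStringSet")) {
    out <- toupper(as.character(genome))
    names(out) <- sub("\\s.*$", "", names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome must be named by contig")
    out <- toupper(genome)
  } else stop("genome must be a named character vector or DNAStringSet")
  class(out) <- c("nmd_genome", "character")
  out
}

#' Spliced mRNA sequence of a transcript
#'
#' Concatenates the exon sequences 5' to 3'; minus-strand transcripts are
#' reverse-complemented.
#'
#' @param tx An `nmd_transcript`.
#' @param genome Named character vector (see [read_genome_fasta()]) or a
#'   `DNAStringSet`.
#' @return A single character string over the alphabet `ACGTN`.
#' @examples
#' tx <- new_transcript("t", "g", "c", "+", c(1, 7), c(3, 9))
#' splice_sequence(tx, c(c = "ATGCCCTAA"))  # "ATGTAA"
#' @export
splice_sequence <- function(tx, genome) {
  genome <- as_genome_chr(genome)
  if (!tx$chrom %in% names(genome))
    stop("contig ", tx$chrom, " not in genome", call. = FALSE)
  contig <- genome[[tx$chrom]]
  if (max(tx$exon_end) > nchar(contig) || min(tx$exon_start) < 1)
    stop("exon outside contig bounds for transcript ", tx$transcript_id,
         call. = FALSE)
  s <- paste(substring(contig, tx$exon_start, tx$exon_end), collapse = "")
  if (tx$strand == "-") revcomp(s) else s
}

# index (1-based, nt) of the last base of the first in-frame stop codon at or
# after mRNA position `from`; NA when no stop before the end
first_stop_end <- function(seq, from) {
  n <- nchar(seq)
  if (from + 2 > n) return(NA_integer_)
  starts <- seq.int(from, n - 2L, 3L)
  cod <- substring(seq, starts, starts + 2L)
  hit <- which(cod == "TAA" | cod == "TAG" | cod == "TGA")
  if (!length(hit)) return(NA_integer_)
  as.integer(starts[hit[1L]] + 2L)
}

#' Infer the main ORF of an assembled transcript sequence
#'
#' Performs three-frame conceptual translation in the given (assembler
#' supplied) orientation: every `ATG` in the sequence opens a candidate
#' reading frame, and the candidate covering the most coding nucleotides —
#' from the `ATG` through its in-frame stop codon inclusive, or through the
#' sequence end when no in-frame stop exists — is returned as the main coding
#' region. Ties are broken towards the 5'-most start. Codons containing `N`
#' never match `ATG` or a stop codon.
#'
#' @param seq mRNA sequence (character scalar, alphabet `ACGTN`).
#' @return A list of class `nmd_main_orf` with elements `start` (mRNA
#'   coordinate of the `A` of the start codon), `stop_end` (mRNA coordinate of
#'   the last stop-codon base, `NA` if the ORF runs off the end), `frame`
#'   (0/1/2), `length` (coding nucleotides) and `has_terminal_stop`.
#' @examples
#' find_main_orf("ATGAAATAA")  # start 1, stop_end 9
#' @export
find_main_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 3) stop("sequence shorter than one codon", call. = FALSE)
  best <- NULL
  for (f in 0:2) {
    starts <- seq.int(1L + f, n - 2L, 3L)
    if (!length(starts)) next
    cod <- substring(seq, starts, starts + 2L)
    atg <- which(cod == "ATG")
    if (!length(atg)) next
    stp <- which(cod == "TAA" | cod == "TAG" | cod == "TGA")
    # first stop codon index at or after each ATG
    nxt <- stp[findInterval(atg - 1L, stp) + 1L]
    has_stop <- !is.na(nxt)
    len <- ifelse(has_stop, (nxt - atg + 1L) * 3L, n - starts[atg] + 1L)
    i <- which.max(len) # ties resolve to the 5'-most ATG within the frame
    cand <- list(start = as.integer(starts[atg[i]]),
                 stop_end = if (has_stop[i])
                   as.integer(starts[nxt[i]] + 2L) else NA_integer_,
                 frame = f,
                 length = as.integer(len[i]),
                 has_terminal_stop = has_stop[i])
    if (is.null(best) || cand$length > best$length ||
        (cand$length == best$length && cand$start < best$start))
      best <- cand
  }
  if (is.null(best))
    stop("no ORF: sequence contains no ATG", call. = FALSE)
  structure(best, class = "nmd_main_orf")
}

# main ORF of an annotated transcript, in mRNA coordinates, derived from its
# CDS (assumed stop-inclusive after reader normalisation)
main_orf_from_cds <- function(tx) {
  if (!has_cds(tx)) return(NULL)
  start_m <- to_mrna_coords(tx, tx_start_codon_pos(tx))
  stop_m <- to_mrna_coords(tx, tx_cds_end_pos(tx))
  structure(list(start = start_m, stop_end = stop_m,
                 frame = (start_m - 1L) %% 3L,
                 length = stop_m - start_m + 1L,
                 has_terminal_stop = TRUE),
            class = "nmd_main_orf")
}

# resolve the main ORF of a transcript: annotated CDS when trusted, otherwise
# three-frame conceptual translation of the spliced sequence
resolve_main_orf <- function(tx, genome = NULL, de_novo = tx$de_novo) {
  if (!de_novo && has_cds(tx)) return(main_orf_from_cds(tx))
  if (is.null(genome))
    stop("genome required to infer the ORF of ", tx$transcript_id,
         call. = FALSE)
  find_main_orf(splice_sequence(tx, genome))
}
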