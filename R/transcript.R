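#' Construct a transcript
#'
#' The transcript is the unit of every analysis in nmdscan: a strand-aware
#' chain of exons with genomic coordinates, optionally carrying a CDS (also as
#' genomic intervals) and an annotation biotype such as `"protein_coding"` or
#' `"nonsense_mediated_decay"`.
#'
#' Exons are stored sorted by genomic start and must be non-overlapping with a
#' gap of at least 1 nt between consecutive exons. Every CDS interval must lie
#' inside an exon. On the minus strand the *transcript* order (5' to 3') is the
#' reverse of the genomic order; all coordinate conversions account for this.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exon_start,exon_end Integer vectors of exon coordinates, 1-based
#'   inclusive.
#' @param cds_start,cds_end Integer vectors of CDS coordinates (possibly
#'   empty). The CDS is assumed to *include* the stop codon; GTF input with
#'   separate `stop_codon` features is normalised on read.
#' @param biotype Annotation biotype, `NA` when the source does not carry one.
#' @param de_novo Logical flag marking transcripts from de novo assembly (no
#'   trusted CDS; the main ORF is inferred from sequence).
#' @param validate Check structural invariants (disable only in hot loops
#'   where inputs are constructed to be valid).
#' @return An object of class `nmd_transcript`.
#' @export
new_transcript <- function(transcript_id, gene_id, chrom, strand,
                           exon_start, exon_end,
                           cds_start = numeric(0), cds_end = numeric(0),
                           biotype = NA_character_, de_novo = FALSE,
                           validate = TRUE) {
  o <- order(exon_start)
  exon_start <- as.numeric(exon_start)[o]
  exon_end <- as.numeric(exon_end)[o]
  if (length(cds_start)) {
    oc <- order(cds_start)
    cds_start <- as.numeric(cds_start)[oc]
    cds_end <- as.numeric(cds_end)[oc]
  } else {
    cds_start <- numeric(0)
    cds_end <- numeric(0)
  }
  tx <- structure(list(
    transcript_id = transcript_id, gene_id = gene_id,
    chrom = chrom, strand = strand,
    exon_start = exon_start, exon_end = exon_end,
    cds_start = cds_start, cds_end = cds_end,
    biotype = biotype, de_novo = isTRUE(de_novo)
  ), class = "nmd_transcript")
  if (validate) validate_transcript(tx)
  tx
}

validate_transcript <- function(tx) {
  id <- tx$transcript_id
  if (!tx$strand %in% c("+", "-"))
    stop("transcript ", id, ": strand must be '+' or '-'", call. = FALSE)
  n <- length(tx$exon_start)
  if (n == 0) stop("transcript ", id, ": no exons", call. = FALSE)
  if (any(tx$exon_end < tx$exon_start))
    stop("transcript ", id, ": exon end < start", call. = FALSE)
  if (n > 1 && any(tx$exon_start[-1] <= tx$exon_end[-n] + 1))
    stop("transcript ", id, ": exons overlap or are adjacent", call. = FALSE)
  if (length(tx$cds_start)) {
    if (any(tx$cds_end < tx$cds_start))
      stop("transcript ", id, ": CDS end < start", call. = FALSE)
    host <- findInterval(tx$cds_start, tx$exon_start)
    bad <- host < 1 | tx$cds_end > tx$exon_end[pmax(host, 1)] |
      tx$cds_start < tx$exon_start[pmax(host, 1)]
    if (any(bad))
      stop("transcript ", id, ": CDS interval not contained in an exon",
           call. = FALSE)
  }
  invisible(tx)
}

#' @export
print.nmd_transcript <- function(x, ...) {
  cat(sprintf("<nmd_transcript> %s (%s) %s:%s %d exon(s), %d CDS nt, biotype %s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              length(x$exon_start), cds_length(x),
              ifelse(is.na(x$biotype), "NA", x$biotype)))
  invisible(x)
}

#' Spliced (mRNA) length of a transcript
#' @param tx An `nmd_transcript`.
#' @return Total exonic length in nucleotides.
#' @export
spliced_length <- function(tx) sum(tx$exon_end - tx$exon_start + 1)

#' Spliced CDS length of a transcript
#' @param tx An `nmd_transcript`.
#' @return Total CDS length in nucleotides (0 if no CDS).
#' @export
cds_length <- function(tx) {
  if (!length(tx$cds_start)) return(0)
  sum(tx$cds_end - tx$cds_start + 1)
}

n_exons <- function(tx) length(tx$exon_start)

has_cds <- function(tx) length(tx$cds_start) > 0

# exon lengths in transcript (5'->3') order
exon_lengths_tx_order <- function(tx) {
  l <- tx$exon_end - tx$exon_start + 1
  if (tx$strand == "-") rev(l) else l
}

#' Map genomic positions to spliced transcript coordinates
#'
#' Converts genomic positions lying within the exons of a transcript to
#' 1-based coordinates counted from the 5' end of the spliced mRNA (so the
#' mapping runs right-to-left on the minus strand). The inverse mapping is
#' [to_genomic_coords()].
#'
#' @param tx An `nmd_transcript`.
#' @param genomic_position Vector of genomic positions; every position must be
#'   exonic, intronic or out-of-transcript positions raise an error.
#' @return Integer vector of mRNA coordinates in `1..spliced_length(tx)`.
#' @examples
#' tx <- new_transcript("t", "g", "chr1", "+", c(100, 301), c(200, 400))
#' to_mrna_coords(tx, 301)  # 102
#' @export
to_mrna_coords <- function(tx, genomic_position) {
  gp <- as.numeric(genomic_position)
  i <- findInterval(gp, tx$exon_start)
  bad <- i < 1 | gp > tx$exon_end[pmax(i, 1)]
  if (any(bad))
    stop("position(s) ", paste(gp[bad], collapse = ", "),
         " not exonic in transcript ", tx$transcript_id, call. = FALSE)
  lens <- tx$exon_end - tx$exon_start + 1
  if (tx$strand == "+") {
    before <- cumsum(c(0, lens))[i]
    as.integer(before + (gp - tx$exon_start[i] + 1))
  } else {
    n <- length(lens)
    after <- rev(cumsum(c(0, rev(lens))))[-1] # exonic bases right of exon i
    as.integer(after[i] + (tx$exon_end[i] - gp + 1))
  }
}

#' Map spliced transcript coordinates back to genomic positions
#'
#' Inverse of [to_mrna_coords()].
#'
#' @param tx An `nmd_transcript`.
#' @param mrna_position Vector of mRNA coordinates in
#'   `1..spliced_length(tx)`.
#' @return Numeric vector of genomic positions.
#' @export
to_genomic_coords <- function(tx, mrna_position) {
  mp <- as.numeric(mrna_position)
  L <- spliced_length(tx)
  if (any(mp < 1 | mp > L))
    stop("mRNA position out of range 1..", L, " for transcript ",
         tx$transcript_id, call. = FALSE)
  lens <- tx$exon_end - tx$exon_start + 1
  if (tx$strand == "+") {
    cum <- cumsum(lens)
    i <- findInterval(mp - 1e-9, c(0, cum)) # exon index holding mp
    offs <- mp - c(0, cum)[i] - 1
    tx$exon_start[i] + offs
  } else {
    lens_tx <- rev(lens)
    cum <- cumsum(lens_tx)
    j <- findInterval(mp - 1e-9, c(0, cum))
    offs <- mp - c(0, cum)[j] - 1
    n <- length(lens)
    i <- n - j + 1 # genomic exon index
    tx$exon_end[i] - offs
  }
}

# genomic intervals (sorted by start) covered by the mRNA window [m1, m2]
mrna_window_to_intervals <- function(tx, m1, m2) {
  stopifnot(m1 <= m2)
  g1 <- to_genomic_coords(tx, m1)
  g2 <- to_genomic_coords(tx, m2)
  lo <- min(g1, g2)
  hi <- max(g1, g2)
  s <- pmax(tx$exon_start, lo)
  e <- pmin(tx$exon_end, hi)
  keep <- s <= e
  list(start = s[keep], end = e[keep])
}

# genomic position of the first base of the start codon (strand-aware)
tx_start_codon_pos <- function(tx) {
  if (!has_cds(tx)) return(NA_real_)
  if (tx$strand == "+") tx$cds_start[1] else tx$cds_end[length(tx$cds_end)]
}

# genomic position of the last CDS base in transcript orientation
tx_cds_end_pos <- function(tx) {
  if (!has_cds(tx)) return(NA_real_)
  if (tx$strand == "+") tx$cds_end[length(tx$cds_end)] else tx$cds_start[1]
}

#' Construct a gene
#'
#' @param gene_id Identifier.
#' @param chrom,strand Shared location of all member transcripts.
#' @param transcripts List of `nmd_transcript` objects.
#' @return An object of class `nmd_gene`.
#' @export
new_gene <- function(gene_id, chrom, strand, transcripts = list()) {
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts),
            class = "nmd_gene")
}

#' Construct a gene set
#'
#' A gene set is the in-memory image of one annotation file: genes keyed by
#' `gene_id` plus provenance (dialect, source path) and a skip log of records
#' the reader refused (non-coding structures are kept; transcripts spanning
#' several chromosomes or strands are dropped and logged).
#'
#' @param genes List of `nmd_gene` objects.
#' @param dialect Annotation dialect the set was read with.
#' @param path Source file (or `NA` for programmatic sets).
#' @param skip_log Named integer vector of skipped-record counts.
#' @return An object of class `nmd_geneset`.
#' @export
new_geneset <- function(genes = list(), dialect = NA_character_,
                        path = NA_character_, skip_log = integer(0)) {
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  tx_ids <- unlist(lapply(genes, function(g) names(g$transcripts)),
                   use.names = FALSE)
  if (anyDuplicated(tx_ids))
    stop("duplicate transcript_id(s): ",
         paste(unique(tx_ids[duplicated(tx_ids)]), collapse = ", "),
         call. = FALSE)
  tx_index <- rep(names(genes), vapply(genes, function(g)
    length(g$transcripts), 0L))
  names(tx_index) <- tx_ids
  structure(list(genes = genes, dialect = dialect, path = path,
                 skip_log = skip_log, tx_index = tx_index),
            class = "nmd_geneset")
}

#' @export
print.nmd_geneset <- function(x, ...) {
  cat(sprintf("<nmd_geneset> %d gene(s), %d transcript(s), dialect %s\n",
              length(x$genes), length(x$tx_index),
              ifelse(is.na(x$dialect), "NA", x$dialect)))
  invisible(x)
}

#' Look up a transcript by id
#' @param geneset An `nmd_geneset`.
#' @param transcript_id Transcript identifier.
#' @return The `nmd_transcript`, or an error if absent.
#' @export
get_transcript <- function(geneset, transcript_id) {
  g <- geneset$tx_index[[transcript_id]]
  if (is.null(g)) stop("unknown transcript_id: ", transcript_id, call. = FALSE)
  geneset$genes[[g]]$transcripts[[transcript_id]]
}

#' All transcripts of a gene set as a flat list
#' @param geneset An `nmd_geneset`.
#' @return Named list of `nmd_transcript` objects.
#' @export
all_transcripts <- function(geneset) {
  out <- unlist(lapply(geneset$genes, `[[`, "transcripts"), recursive = FALSE,
                use.names = FALSE)
  if (is.null(out)) return(list())
  names(out) <- vapply(out, `[[`, "", "transcript_id")
  out
}

#' Transcript ids annotated as NMD targets
#'
#' Returns the transcripts whose biotype is `"nonsense_mediated_decay"` — the
#' annotation-provided gold standard used when detection is skipped.
#'
#' @param geneset An `nmd_geneset`.
#' @return Sorted character vector of transcript ids.
#' @export
annotated_nmdts <- function(geneset) {
  txs <- all_transcripts(geneset)
  bt <- vapply(txs, `[[`, "", "biotype")
  sort(names(txs)[!is.na(bt) & bt == "nonsense_mediated_decay"])
}

# a transcript that can serve as comparison baseline: annotated CDS and not
# itself flagged as an NMD target
is_coding_isoform <- function(tx) {
  has_cds(tx) &&
    (is.na(tx$biotype) || !tx$biotype %in% c("nonsense_mediated_decay"))
}
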