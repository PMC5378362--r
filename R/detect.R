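# NMDT detection: 50-NT distance rule plus the alternative rules used for
# benchmarking (upstream ORF presence, long 3'UTR).

#' Distance between a stop codon and the last exon-exon junction
#'
#' The quantity of the 50-NT rule: a positive distance means the stop codon
#' lies upstream of the last exon-exon junction of the spliced transcript.
#' The junction coordinate is the mRNA position of the final base of the
#' penultimate exon; by default the stop codon is anchored at its *last* base
#' (`anchor = "stop_end"`). Anchoring at the first base shifts every distance
#' up by 2 and is exposed because published formulations leave the anchor
#' open.
#'
#' @param tx An `nmd_transcript` with at least one exon.
#' @param main_orf The transcript's main ORF (an `nmd_main_orf`); defaults to
#'   the ORF implied by the annotated CDS.
#' @param anchor `"stop_end"` (default) or `"stop_start"`.
#' @return A list of class `nmd_ptc_report`: `distance` (signed nt, `NA` when
#'   undefined), `last_junction_mrna`, `no_junction` (single-exon transcript),
#'   `anchor`.
#' @export
ptc_junction_distance <- function(tx, main_orf = NULL,
                                  anchor = c("stop_end", "stop_start")) {
  anchor <- match.arg(anchor)
  if (is.null(main_orf)) main_orf <- main_orf_from_cds(tx)
  if (is.null(main_orf))
    stop("transcript ", tx$transcript_id, " has no CDS and no main_orf given",
         call. = FALSE)
  if (n_exons(tx) < 2)
    return(structure(list(distance = NA_real_, last_junction_mrna = NA_real_,
                          no_junction = TRUE, anchor = anchor),
                     class = "nmd_ptc_report"))
  lens <- exon_lengths_tx_order(tx)
  last_junction <- spliced_length(tx) - lens[length(lens)]
  if (is.na(main_orf$stop_end) || !isTRUE(main_orf$has_terminal_stop))
    return(structure(list(distance = NA_real_,
                          last_junction_mrna = last_junction,
                          no_junction = FALSE, anchor = anchor),
                     class = "nmd_ptc_report"))
  a <- if (anchor == "stop_end") main_orf$stop_end else main_orf$stop_end - 2
  structure(list(distance = last_junction - a,
                 last_junction_mrna = last_junction,
                 no_junction = FALSE, anchor = anchor),
            class = "nmd_ptc_report")
}

#' Call a transcript as an NMD target under a detection rule
#'
#' Three rules are implemented. `"distance"` — the 50-NT rule: the transcript
#' is an NMD target iff its stop codon lies *strictly more than* `threshold`
#' nucleotides upstream of the last exon-exon junction (single-exon
#' transcripts are never called). `"uorf"` — a complete upstream ORF (ATG and
#' in-frame stop, at least two codons) lies entirely within the 5'UTR.
#' `"utr3"` — the spliced 3'UTR is strictly longer than `utr3_min`
#' nucleotides.
#'
#' @param tx An `nmd_transcript`.
#' @param rule `"distance"`, `"uorf"` or `"utr3"`.
#' @param threshold Distance threshold in nt for the distance rule
#'   (default 50; the comparison is strict).
#' @param anchor Stop-codon anchor for the distance rule, see
#'   [ptc_junction_distance()].
#' @param utr3_min Length threshold in nt for the 3'UTR rule (default 650).
#' @param genome Genome sequences; required for the uORF rule and for any
#'   transcript whose ORF must be inferred (`de_novo` mode).
#' @param de_novo Infer the main ORF by conceptual translation instead of
#'   trusting the annotated CDS.
#' @return `TRUE`/`FALSE`.
#' @export
detect_nmdt <- function(tx, rule = c("distance", "uorf", "utr3"),
                        threshold = 50, anchor = "stop_end",
                        utr3_min = 650, genome = NULL, de_novo = tx$de_novo) {
  rule <- match.arg(rule)
  orf <- resolve_main_orf(tx, genome = genome, de_novo = de_novo)
  if (rule == "distance") {
    rep <- ptc_junction_distance(tx, orf, anchor = anchor)
    return(!is.na(rep$distance) && rep$distance > threshold)
  }
  if (rule == "utr3") {
    if (is.na(orf$stop_end) || !orf$has_terminal_stop) return(FALSE)
    return(spliced_length(tx) - orf$stop_end > utr3_min)
  }
  # uORF rule: needs the actual 5'UTR sequence
  if (is.null(genome))
    stop("genome required for the uORF rule", call. = FALSE)
  seq <- splice_sequence(tx, genome)
  has_uorf(seq, orf$start)
}

# complete ORF (ATG .. in-frame stop, >= 2 codons) fully inside [1, cds_start)
has_uorf <- function(seq, cds_start) {
  utr_len <- cds_start - 1
  if (utr_len < 6) return(FALSE)
  utr <- substr(seq, 1L, utr_len)
  n <- nchar(utr)
  for (f in 0:2) {
    starts <- seq.int(1L + f, n - 2L, 3L)
    if (length(starts) < 2) next
    cod <- substring(utr, starts, starts + 2L)
    atg <- which(cod == "ATG")
    if (!length(atg)) next
    stp <- which(cod == "TAA" | cod == "TAG" | cod == "TGA")
    if (!length(stp)) next
    nxt <- stp[findInterval(atg - 1L, stp) + 1L]
    if (any(!is.na(nxt))) return(TRUE)
  }
  FALSE
}

#' Detect NMD targets across a gene set
#'
#' In `"annotated"` mode with no rule given, returns the transcripts the
#' annotation itself flags (`biotype == "nonsense_mediated_decay"`) —
#' detection is skipped, mirroring the default treatment of Ensembl/NCBI
#' input. Supplying a rule applies it to every transcript with a resolvable
#' main ORF. In `"de_novo"` mode the main ORF of every transcript is inferred
#' from the genome by three-frame conceptual translation.
#'
#' @param geneset An `nmd_geneset`.
#' @param rule `NULL` (annotated mode default), `"distance"`, `"uorf"` or
#'   `"utr3"`.
#' @param mode `"annotated"` or `"de_novo"` (the latter requires `genome`).
#' @param genome Genome sequences (named character vector or `DNAStringSet`).
#' @param ... Passed to [detect_nmdt()] (`threshold`, `anchor`, `utr3_min`).
#' @return Sorted character vector of transcript ids called as NMD targets.
#'   Transcripts without a resolvable ORF are skipped and counted in the
#'   `"skipped"` attribute.
#' @export
detect_all <- function(geneset, rule = NULL, mode = c("annotated", "de_novo"),
                       genome = NULL, ...) {
  mode <- match.arg(mode)
  if (mode == "annotated" && is.null(rule)) return(annotated_nmdts(geneset))
  if (mode == "de_novo" && is.null(genome))
    stop("de_novo mode requires a genome", call. = FALSE)
  if (is.null(rule)) rule <- "distance"
  txs <- all_transcripts(geneset)
  skipped <- 0L
  hit <- logical(length(txs))
  for (i in seq_along(txs)) {
    tx <- txs[[i]]
    res <- tryCatch(
      detect_nmdt(tx, rule = rule, genome = genome,
                  de_novo = (mode == "de_novo"), ...),
      error = function(e) NA)
    if (is.na(res)) skipped <- skipped + 1L else hit[i] <- res
  }
  structure(sort(names(txs)[hit]), skipped = skipped)
}
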