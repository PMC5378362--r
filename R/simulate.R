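# Structural-alteration simulator: inject a single exon deletion, intronic
# exon insertion or exon-boundary change into a coding transcript, decide by
# the 50-NT rule whether the product is an NMD target, classify it against
# its best partner and score the call against the injected truth.

#' Empirical sampler of internal coding-exon lengths
#'
#' Collects the lengths of all internal (non-terminal) exons overlapping the
#' CDS of every coding transcript in the set and returns a closure that
#' samples from this multiset with replacement — artificial exons then follow
#' the length distribution of real coding exons.
#'
#' @param geneset An `nmd_geneset` with at least one internal coding exon.
#' @return `function(n)` returning `n` sampled lengths.
#' @export
empirical_exon_lengths <- function(geneset) {
  lens <- numeric(0)
  for (tx in all_transcripts(geneset)) {
    if (!has_cds(tx) || n_exons(tx) < 3) next
    i <- internal_coding_exons(tx)
    if (length(i)) lens <- c(lens, tx$exon_end[i] - tx$exon_start[i] + 1)
  }
  if (!length(lens))
    stop("gene set contains no internal coding exon", call. = FALSE)
  function(n = 1) lens[sample.int(length(lens), n, replace = TRUE)]
}

# genomic-order indices of internal exons overlapping the CDS span
internal_coding_exons <- function(tx) {
  n <- n_exons(tx)
  if (n < 3 || !has_cds(tx)) return(integer(0))
  lo <- tx$cds_start[1]
  hi <- tx$cds_end[length(tx$cds_end)]
  i <- 2:(n - 1)
  i[tx$exon_end[i] >= lo & tx$exon_start[i] <= hi]
}

ineligible <- function(what) {
  stop(structure(class = c("nmd_ineligible", "error", "condition"),
                 list(message = paste0("ineligible: ", what), call = NULL)))
}

alt_tx <- function(src, exon_start, exon_end, suffix) {
  new_transcript(paste0(src$transcript_id, suffix), src$gene_id, src$chrom,
                 src$strand, exon_start, exon_end,
                 biotype = "artificial", validate = FALSE)
}

#' Randomly delete an internal coding exon
#'
#' Removes one uniformly chosen internal coding exon. Terminal exons are not
#' eligible: altering them would move the translation start or the annotated
#' end and break the shared-start premise of the partner comparison.
#'
#' @param tx A coding `nmd_transcript` with at least 3 exons.
#' @return A list with `transcript` (the altered transcript, no CDS — its ORF
#'   is re-derived from sequence) and `truth` (event type, target span,
#'   source id). Raises an `nmd_ineligible` condition when no exon qualifies.
#' @export
inject_deletion <- function(tx) {
  elig <- internal_coding_exons(tx)
  if (!length(elig)) ineligible("no internal coding exon")
  i <- elig[sample.int(length(elig), 1)]
  list(transcript = alt_tx(tx, tx$exon_start[-i], tx$exon_end[-i], ":del"),
       truth = list(event_type = "deletion",
                    span = c(tx$exon_start[i], tx$exon_end[i]),
                    source = tx$transcript_id))
}

#' Randomly turn part of an intron into a coding exon
#'
#' Samples an exon length from `length_sampler`, selects an intron between
#' two coding exons that can host it while keeping at least 1 intronic nt on
#' each side (both junctions preserved), and places the new exon uniformly at
#' random inside the intron. The length is resampled up to 10 times before
#' the transcript is declared ineligible.
#'
#' @param tx A coding `nmd_transcript`.
#' @param length_sampler Closure from [empirical_exon_lengths()].
#' @return As [inject_deletion()], with `event_type = "insertion"`.
#' @export
inject_insertion <- function(tx, length_sampler) {
  n <- n_exons(tx)
  if (n < 2 || !has_cds(tx)) ineligible("no intron between coding exons")
  lo <- tx$cds_start[1]; hi <- tx$cds_end[length(tx$cds_end)]
  coding <- tx$exon_end >= lo & tx$exon_start <= hi
  host <- which(coding[-n] & coding[-1]) # intron i between exons i, i+1
  if (!length(host)) ineligible("no intron between coding exons")
  ia <- tx$exon_end[host] + 1
  ib <- tx$exon_start[host + 1] - 1
  for (try in 1:10) {
    L <- length_sampler(1)
    ok <- (ib - ia + 1) >= L + 2
    if (!any(ok)) next
    k <- which(ok)[sample.int(sum(ok), 1)]
    s <- ia[k] + sample.int(ib[k] - L - ia[k], 1) # uniform in [ia+1, ib-L]
    e <- s + L - 1                                # leaves >=1 nt flank each side
    es <- sort(c(tx$exon_start, s))
    ee <- sort(c(tx$exon_end, e))
    return(list(transcript = alt_tx(tx, es, ee, ":ins"),
                truth = list(event_type = "insertion", span = c(s, e),
                             source = tx$transcript_id)))
  }
  ineligible("no intron can host the sampled length")
}

#' Randomly change an exon boundary
#'
#' Selects an internal coding exon and a target length from `length_sampler`;
#' the exon is extended (sampled length larger) or abridged (smaller) at its
#' 5', 3' or both ends, chosen with equal probability in transcript
#' orientation. For `"both"` the length change is split as evenly as
#' possible, the extra base going to the 5' side. Extensions are clamped so
#' at least 1 intronic nt remains towards each neighbouring exon; shrinks are
#' clamped so the exon keeps length >= 1. A sampled length equal to the
#' current one is rejected and resampled (10 attempts).
#'
#' @param tx A coding `nmd_transcript` with an internal coding exon.
#' @param length_sampler Closure from [empirical_exon_lengths()].
#' @return As [inject_deletion()]; `truth$event_type` is one of
#'   `"boundary_5"`, `"boundary_3"`, `"boundary_both"` and `truth$span` the
#'   union of the old and new exon intervals.
#' @export
inject_boundary_change <- function(tx, length_sampler) {
  elig <- internal_coding_exons(tx)
  if (!length(elig)) ineligible("no internal coding exon")
  i <- elig[sample.int(length(elig), 1)]
  s0 <- tx$exon_start[i]; e0 <- tx$exon_end[i]
  len <- e0 - s0 + 1
  max_left <- s0 - (tx$exon_end[i - 1] + 2)     # genomic-left extension room
  max_right <- (tx$exon_start[i + 1] - 2) - e0  # genomic-right extension room
  plus <- tx$strand == "+"
  for (try in 1:10) {
    L <- length_sampler(1)
    if (L == len) next
    delta <- L - len
    side <- sample(c("5", "3", "both"), 1)
    # split |delta| across transcript-orientation sides (extra to 5')
    a <- abs(delta)
    d5 <- switch(side, "5" = a, "3" = 0, both = ceiling(a / 2))
    d3 <- a - d5
    # map transcript sides to genomic left/right
    dl <- if (plus) d5 else d3
    dr <- if (plus) d3 else d5
    if (delta > 0) {
      dl <- min(dl, max(0, max_left))
      dr <- min(dr, max(0, max_right))
      if (dl + dr == 0) next
      s <- s0 - dl; e <- e0 + dr
    } else {
      tot <- min(a, len - 1)
      if (tot == 0) next
      if (dl + dr > tot) { # rescale the split, 5' side keeps the extra
        d5 <- switch(side, "5" = tot, "3" = 0, both = ceiling(tot / 2))
        d3 <- tot - d5
        dl <- if (plus) d5 else d3
        dr <- if (plus) d3 else d5
      }
      s <- s0 + dl; e <- e0 - dr
    }
    es <- tx$exon_start; ee <- tx$exon_end
    es[i] <- s; ee[i] <- e
    return(list(
      transcript = alt_tx(tx, es, ee, ":bnd"),
      truth = list(event_type = paste0("boundary_",
                                       if (side == "both") "both" else side),
                   span = c(min(s0, s), max(e0, e)),
                   side = side, source = tx$transcript_id)))
  }
  ineligible("no feasible boundary change")
}

#' Simulation configuration
#'
#' @param n_transcripts Artificial transcripts per replicate (default 5000).
#' @param n_sims Number of replicates (default 1000; scale down for quick
#'   runs).
#' @param seed Base RNG seed; replicate `r` uses `seed + r - 1`.
#' @param weights Event-type mixture over deletion / insertion / boundary
#'   change (default uniform; normalised to sum 1).
#' @param threshold Distance threshold of the 50-NT rule used to decide which
#'   products are NMD targets.
#' @param keep_events Keep the per-event truth/prediction table.
#' @return A list of class `nmd_sim_config`.
#' @export
sim_config <- function(n_transcripts = 5000, n_sims = 1000, seed = 1,
                       weights = c(deletion = 1, insertion = 1, boundary = 1),
                       threshold = 50, keep_events = TRUE) {
  stopifnot(all(weights >= 0), sum(weights) > 0, length(weights) == 3)
  structure(list(n_transcripts = n_transcripts, n_sims = n_sims,
                 seed = as.integer(seed), weights = weights / sum(weights),
                 threshold = threshold, keep_events = isTRUE(keep_events)),
            class = "nmd_sim_config")
}

#' Run the classification-accuracy simulation
#'
#' For each replicate, `n_transcripts` single structural alterations are
#' injected into uniformly drawn (with replacement) coding transcripts.
#' Whether each product is an NMD target is decided by the 50-NT rule applied
#' to its re-derived ORF (translation from the source's start codon to the
#' first in-frame stop in the altered spliced sequence). NMD-target products
#' are classified against their best partner; a call is *correct* when the
#' category is consistent with the injected event (deletion: NMD_ex /
#' multi_NMD_ex; insertion: NMD_in / multi_NMD_in / NMD_IR; boundary: A5SS /
#' A3SS / A5SS+A3SS) and the causal group's span overlaps the altered span.
#' Replicate accuracy is correct calls over NMD-target-producing events.
#'
#' @param geneset Annotation providing source transcripts and partners.
#' @param genome Genome sequences matching `geneset`.
#' @param config A [sim_config()].
#' @return A list of class `nmd_sim_result`: `accuracy` (one value per
#'   replicate), `mean_accuracy`, `n_events`, `n_nmdt`, `n_ineligible` and,
#'   when `keep_events`, a per-event `events` data frame.
#' @export
run_simulation <- function(geneset, genome, config = sim_config()) {
  genome <- as_genome_chr(genome)
  sampler <- empirical_exon_lengths(geneset)
  pool_tx <- list(); pool_gene <- character(0)
  for (g in geneset$genes) for (tx in g$transcripts)
    if (is_coding_isoform(tx) &&
        !is.na(tx$biotype) && tx$biotype == "protein_coding") {
      pool_tx[[length(pool_tx) + 1L]] <- tx
      pool_gene <- c(pool_gene, g$gene_id)
    }
  if (!length(pool_tx)) stop("no protein_coding source transcripts")
  npool <- length(pool_tx)
  types <- c("deletion", "insertion", "boundary")
  nT <- config$n_transcripts; nS <- config$n_sims
  acc <- numeric(nS)
  n_inelig <- 0L
  tot <- nS * nT
  ev_type <- character(if (config$keep_events) tot else 0)
  ev_nmdt <- logical(length(ev_type))
  ev_cat <- character(length(ev_type))
  ev_ok <- logical(length(ev_type))
  ev_sim <- integer(length(ev_type))
  ev_src <- character(length(ev_type))
  row <- 0L
  cat_ok <- list(
    deletion = c("NMD_ex", "multi_NMD_ex"),
    insertion = c("NMD_in", "multi_NMD_in", "NMD_IR"),
    boundary = c("A5SS", "A3SS", "A5SS+A3SS"))
  for (r in seq_len(nS)) {
    set.seed(config$seed + r - 1L)
    n_correct <- 0L; n_nmdt <- 0L
    for (j in seq_len(nT)) {
      k <- sample.int(npool, 1)
      src <- pool_tx[[k]]
      type <- types[sample.int(3L, 1, prob = config$weights)]
      inj <- tryCatch(switch(type,
        deletion = inject_deletion(src),
        insertion = inject_insertion(src, sampler),
        boundary = inject_boundary_change(src, sampler)),
        nmd_ineligible = function(e) NULL)
      if (config$keep_events) {
        row <- row + 1L
        ev_sim[row] <- r; ev_src[row] <- src$transcript_id
        ev_type[row] <- type
      }
      if (is.null(inj)) { n_inelig <- n_inelig + 1L; next }
      alt <- inj$transcript
      seq <- splice_sequence(alt, genome)
      start_g <- tx_start_codon_pos(src)
      start_m <- to_mrna_coords(alt, start_g)
      stop_m <- first_stop_end(seq, start_m)
      is_target <- FALSE
      if (!is.na(stop_m) && n_exons(alt) >= 2) {
        lens <- exon_lengths_tx_order(alt)
        dist <- (spliced_length(alt) - lens[length(lens)]) - stop_m
        is_target <- dist > config$threshold
      }
      if (config$keep_events) ev_nmdt[row] <- is_target
      if (!is_target) next
      n_nmdt <- n_nmdt + 1L
      cds <- mrna_window_to_intervals(alt, start_m, stop_m)
      alt$cds_start <- cds$start; alt$cds_end <- cds$end
      gene <- geneset$genes[[pool_gene[k]]]
      cl <- classify_event(alt, gene)
      sp <- inj$truth$span
      ok <- cl$category %in% cat_ok[[type]] &&
        !is.null(cl$causal_span) &&
        cl$causal_span[1] <= sp[2] && cl$causal_span[2] >= sp[1]
      if (ok) n_correct <- n_correct + 1L
      if (config$keep_events) { ev_cat[row] <- cl$category; ev_ok[row] <- ok }
    }
    acc[r] <- if (n_nmdt > 0) n_correct / n_nmdt else NA_real_
  }
  out <- list(accuracy = acc, mean_accuracy = mean(acc, na.rm = TRUE),
              n_events = tot, n_nmdt = if (config$keep_events)
                sum(ev_nmdt) else NA_integer_,
              n_ineligible = n_inelig, config = config)
  if (config$keep_events)
    out$events <- data.frame(sim = ev_sim, source = ev_src,
                             event_type = ev_type, is_nmdt = ev_nmdt,
                             category = ev_cat, correct = ev_ok,
                             stringsAsFactors = FALSE)
  structure(out, class = "nmd_sim_result")
}

#' @export
print.nmd_sim_result <- function(x, ...) {
  cat(sprintf(paste0("<nmd_sim_result> %d replicate(s) x %d event(s); mean ",
                     "accuracy %.4f (range %.4f-%.4f)\n"),
              length(x$accuracy), x$config$n_transcripts, x$mean_accuracy,
              min(x$accuracy, na.rm = TRUE), max(x$accuracy, na.rm = TRUE)))
  invisible(x)
}
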