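# Pairwise NMDT / best-partner comparison: exon grouping, cumulative
# reading-frame differences with rescue handling, and the event taxonomy.

NMD_CATEGORIES <- c("NMD_ex", "NMD_in", "multi_NMD_ex", "multi_NMD_in",
                    "A5SS", "A3SS", "A5SS+A3SS", "NMD_IR", "nNMD_IR",
                    "UTR_Diff", "UTR_Diff_CDSdiff_NoFrameDiff", "Complex")

#' Fraction of an NMD target's nucleotides shared with a candidate isoform
#'
#' Positionwise: the number of genomic positions exonic in both transcripts,
#' divided by the spliced length of the NMD target (or by the union for
#' `denominator = "jaccard"`).
#'
#' @param nmdt,candidate Transcripts of the same gene and strand.
#' @param denominator `"nmdt"` (default) or `"jaccard"`.
#' @return A number in `[0, 1]`.
#' @export
shared_fraction <- function(nmdt, candidate,
                            denominator = c("nmdt", "jaccard")) {
  denominator <- match.arg(denominator)
  ov <- ivl_overlap_total(nmdt$exon_start, nmdt$exon_end,
                          candidate$exon_start, candidate$exon_end)
  if (denominator == "nmdt") return(ov / spliced_length(nmdt))
  ov / (spliced_length(nmdt) + spliced_length(candidate) - ov)
}

#' Select the best-partner coding isoform for an NMD target
#'
#' Candidates are the gene's coding isoforms (annotated CDS, biotype not
#' `nonsense_mediated_decay`) whose start codon begins at the same genomic
#' position as the NMD target's. Among candidates the one sharing the largest
#' proportion of nucleotides with the NMD target wins; exact ties go to the
#' candidate with more identical exon boundaries, then to the
#' lexicographically smallest transcript id.
#'
#' @param nmdt An `nmd_transcript` with a CDS (the start codon must be
#'   resolvable).
#' @param gene The `nmd_gene` holding the candidate isoforms.
#' @param denominator Overlap normalisation, see [shared_fraction()].
#' @return The partner `nmd_transcript`, or `NULL` when no coding isoform
#'   shares the start site.
#' @export
select_best_partner <- function(nmdt, gene, denominator = "nmdt") {
  start_g <- tx_start_codon_pos(nmdt)
  if (is.na(start_g))
    stop("NMD target ", nmdt$transcript_id, " has no resolvable start codon",
         call. = FALSE)
  best <- NULL
  best_key <- c(-Inf, -Inf, "")
  for (tx in gene$transcripts) {
    if (tx$transcript_id == nmdt$transcript_id) next
    if (!is_coding_isoform(tx)) next
    if (tx$strand != nmdt$strand) next
    if (!isTRUE(tx_start_codon_pos(tx) == start_g)) next
    frac <- shared_fraction(nmdt, tx, denominator = denominator)
    nb <- sum(c(nmdt$exon_start, nmdt$exon_end) %in%
                c(tx$exon_start, tx$exon_end))
    if (is.null(best) ||
        frac > best_key[[1]] ||
        (frac == best_key[[1]] && nb > best_key[[2]]) ||
        (frac == best_key[[1]] && nb == best_key[[2]] &&
           tx$transcript_id < best_key[[3]])) {
      best <- tx
      best_key <- list(frac, nb, tx$transcript_id)
    }
  }
  best
}

#' Merge the exons of an NMD target and its partner into exon groups
#'
#' Exons whose genomic regions overlap by at least one nucleotide are merged,
#' transitively, into exon groups; exons overlapping nothing in the other
#' transcript form singleton groups. Groups are returned in transcript (5' to
#' 3') order.
#'
#' @param nmdt,partner Transcripts on the same chromosome and strand.
#' @return A list of class `nmd_exon_groups`; each element has `span_start`,
#'   `span_end` (union span) and `nmdt_exons` / `partner_exons` (genomic-order
#'   exon indices of each transcript).
#' @export
build_exon_groups <- function(nmdt, partner) {
  if (nmdt$chrom != partner$chrom || nmdt$strand != partner$strand)
    stop("transcripts on different chromosome or strand", call. = FALSE)
  s <- c(nmdt$exon_start, partner$exon_start)
  e <- c(nmdt$exon_end, partner$exon_end)
  who <- rep(c(TRUE, FALSE), c(length(nmdt$exon_start),
                               length(partner$exon_start)))
  idx <- c(seq_along(nmdt$exon_start), seq_along(partner$exon_start))
  o <- order(s, e)
  cmax <- cummax(e[o])
  new_grp <- c(TRUE, s[o][-1] > cmax[-length(cmax)])
  gid <- cumsum(new_grp)
  ng <- gid[length(gid)]
  groups <- vector("list", ng)
  for (g in seq_len(ng)) {
    m <- o[gid == g]
    groups[[g]] <- list(
      span_start = min(s[m]), span_end = max(e[m]),
      nmdt_exons = sort(idx[m][who[m]]),
      partner_exons = sort(idx[m][!who[m]]))
  }
  if (nmdt$strand == "-") groups <- rev(groups)
  structure(groups, class = "nmd_exon_groups",
            strand = nmdt$strand,
            nmdt_id = nmdt$transcript_id, partner_id = partner$transcript_id)
}

#' Cumulative reading-frame difference profile over exon groups
#'
#' For each exon group, the CDS nucleotides of the two transcripts inside
#' the group are counted and their differences summed 5' to 3', modulo 3.
#' UTR bases contribute nothing on either side, which is what routes
#' pure-UTR differences away from the structural categories; a transcript
#' compared against itself yields an identically zero profile.
#'
#' @param groups Output of [build_exon_groups()].
#' @param nmdt,partner The two transcripts (both must carry a CDS).
#' @return Integer vector of cumulative frame differences (values 0/1/2), one
#'   per group in transcript order, with per-group coding lengths attached as
#'   attributes `nmdt_len` and `partner_len`.
#' @export
frame_profile <- function(groups, nmdt, partner) {
  if (!has_cds(nmdt) || !has_cds(partner))
    stop("both transcripts must carry a CDS", call. = FALSE)
  # per-exon CDS bases: each CDS is contiguous in mRNA, so clipping the
  # exons to the genomic CDS span recovers the per-exon coding lengths
  n_cd <- pmax(0, pmin(nmdt$exon_end, nmdt$cds_end[length(nmdt$cds_end)]) -
                 pmax(nmdt$exon_start, nmdt$cds_start[1]) + 1)
  p_cd <- pmax(0, pmin(partner$exon_end,
                       partner$cds_end[length(partner$cds_end)]) -
                 pmax(partner$exon_start, partner$cds_start[1]) + 1)
  nl <- pl <- numeric(length(groups))
  for (g in seq_along(groups)) {
    nl[g] <- sum(n_cd[groups[[g]]$nmdt_exons])
    pl[g] <- sum(p_cd[groups[[g]]$partner_exons])
  }
  prof <- as.integer(cumsum(nl - pl) %% 3)
  attr(prof, "nmdt_len") <- nl
  attr(prof, "partner_len") <- pl
  prof
}

#' Locate the first non-rescued frameshift in a frame profile
#'
#' Scans 5' to 3'. The first group at which the cumulative frame difference
#' becomes non-zero is provisionally causal; if a later group returns the
#' cumulative difference to zero (a rescue), the provisional event is
#' discarded and the scan re-initiates after the rescue group. The caller is
#' responsible for truncating the profile at the group containing the
#' premature stop codon.
#'
#' @param profile Integer vector from [frame_profile()] (already truncated to
#'   the groups under consideration).
#' @return 1-based group index of the first non-rescued frameshift, or
#'   `NA_integer_` if the profile ends balanced.
#' @export
find_causal_group <- function(profile) {
  k <- length(profile)
  i <- 1L
  while (i <= k) {
    nz <- which(profile[i:k] != 0L)
    if (!length(nz)) return(NA_integer_)
    j <- i + nz[1L] - 1L
    if (j == k) return(j)
    z <- which(profile[(j + 1L):k] == 0L)
    if (!length(z)) return(j)
    i <- j + z[1L] + 1L # re-scan after the rescue group
  }
  NA_integer_
}

#' Structural signature of one exon group
#'
#' Determines which splicing alteration a group represents, from the counts
#' and coordinates of its member exons: exons private to the NMD target are
#' inclusions, exons private to the partner are exclusions, a one-vs-one pair
#' with mismatched edges is an alternative splice-site event, one exon
#' spanning two exons (plus the intervening intron) of the other transcript
#' is intron retention, and anything compatible with several signatures is
#' complex.
#'
#' @param group One element of [build_exon_groups()] output.
#' @param nmdt,partner The two transcripts.
#' @param ss_convention `"donor_is_5"` (default): a mismatch at the exon edge
#'   facing the donor site (the exon's 3'/downstream edge) is called A5SS and
#'   a mismatch at the acceptor-facing (upstream) edge A3SS.
#'   `"exon_edge_is_5"` reverses the naming (upstream edge mismatch = A5SS).
#' @return One of `"identical"`, `"inclusion"`, `"multi_inclusion"`,
#'   `"exclusion"`, `"multi_exclusion"`, `"A5SS"`, `"A3SS"`, `"A5SS+A3SS"`,
#'   `"NMD_IR"`, `"nNMD_IR"`, `"Complex"`.
#' @export
group_signature <- function(group, nmdt, partner,
                            ss_convention = c("donor_is_5",
                                              "exon_edge_is_5")) {
  ss_convention <- match.arg(ss_convention)
  nn <- length(group$nmdt_exons)
  np <- length(group$partner_exons)
  if (np == 0L) return(if (nn >= 2L) "multi_inclusion" else "inclusion")
  if (nn == 0L) return(if (np >= 2L) "multi_exclusion" else "exclusion")
  if (nn == 1L && np == 1L) {
    i <- group$nmdt_exons; j <- group$partner_exons
    d_start <- nmdt$exon_start[i] != partner$exon_start[j]
    d_end <- nmdt$exon_end[i] != partner$exon_end[j]
    if (!d_start && !d_end) return("identical")
    if (d_start && d_end) return("A5SS+A3SS")
    # which transcript-orientation edge differs?
    upstream_edge_differs <- if (nmdt$strand == "+") d_start else d_end
    if (ss_convention == "donor_is_5")
      return(if (upstream_edge_differs) "A3SS" else "A5SS")
    return(if (upstream_edge_differs) "A5SS" else "A3SS")
  }
  if (nn == 1L && np == 2L) return("NMD_IR")
  if (nn == 2L && np == 1L) return("nNMD_IR")
  "Complex"
}

signature_to_category <- function(sig) {
  switch(sig,
         inclusion = "NMD_in", multi_inclusion = "multi_NMD_in",
         exclusion = "NMD_ex", multi_exclusion = "multi_NMD_ex",
         identical = "Complex", # frames differ but structure does not
         sig)
}

#' Classify the structural event behind one NMD target
#'
#' Implements the minimal-evolution comparison: select the best partner
#' ([select_best_partner()]); if the CDS structures are identical the event
#' is a pure UTR alteration (`UTR_Diff`). Otherwise exon groups are built,
#' the cumulative frame-difference profile is scanned over the groups
#' upstream of the one containing the premature stop, and the first
#' non-rescued frameshift group is causal; its [group_signature()] names the
#' category. When the scan stays balanced but the pair differs structurally
#' at or upstream of the premature stop, the structural difference nearest
#' the stop is reported as causal (`mechanism = "stop_introduction"`): a
#' premature stop requires either a frameshift or a sequence change that
#' introduces the stop codon, and the nearest upstream change is the most
#' parsimonious origin — this covers in-frame inserted exons that carry
#' their own stop codon. Only when no structural difference exists upstream
#' of the stop is the event reported as `UTR_Diff_CDSdiff_NoFrameDiff`.
#'
#' @param nmdt The NMD-targeted transcript (must carry a CDS ending at its
#'   premature stop).
#' @param gene The gene providing candidate partners.
#' @param ss_convention Splice-site naming, see [group_signature()].
#' @param denominator Overlap normalisation for partner selection.
#' @return A list of class `nmd_classification`: `nmdt_id`, `partner_id`,
#'   `category`, `causal_group` (1-based index in transcript order, `NA` for
#'   the UTR categories), `causal_span` (genomic `c(start, end)` or `NULL`),
#'   `frame_profile`, `mechanism` (`"frameshift"`, `"stop_introduction"` or
#'   `"none"`).
#' @export
classify_event <- function(nmdt, gene, ss_convention = "donor_is_5",
                           denominator = "nmdt") {
  res <- function(partner_id, category, causal = NA_integer_, span = NULL,
                  profile = integer(0), mechanism = "none")
    structure(list(nmdt_id = nmdt$transcript_id, partner_id = partner_id,
                   category = category, causal_group = causal,
                   causal_span = span, frame_profile = profile,
                   mechanism = mechanism),
              class = "nmd_classification")
  if (!has_cds(nmdt))
    stop("NMD target ", nmdt$transcript_id,
         " has no resolvable CDS; cannot classify", call. = FALSE)
  partner <- select_best_partner(nmdt, gene, denominator = denominator)
  if (is.null(partner)) return(res(NA_character_, "Unpartnered"))
  if (length(nmdt$cds_start) == length(partner$cds_start) &&
      all(nmdt$cds_start == partner$cds_start) &&
      all(nmdt$cds_end == partner$cds_end))
    return(res(partner$transcript_id, "UTR_Diff"))
  groups <- build_exon_groups(nmdt, partner)
  prof <- frame_profile(groups, nmdt, partner)
  ptc <- tx_cds_end_pos(nmdt)
  ptc_grp <- which(vapply(groups, function(g)
    ptc >= g$span_start && ptc <= g$span_end, TRUE))[1]
  # frameshift scan runs over the groups strictly upstream of the premature
  # stop: inside the stop's own group the truncated CDS always disagrees
  # with the partner, which carries no frameshift information
  causal <- find_causal_group(prof[seq_len(ptc_grp - 1L)])
  mech <- "frameshift"
  if (is.na(causal)) {
    sigs <- vapply(seq_len(ptc_grp), function(g)
      group_signature(groups[[g]], nmdt, partner, ss_convention), "")
    nz <- which(sigs != "identical")
    if (!length(nz))
      return(res(partner$transcript_id, "UTR_Diff_CDSdiff_NoFrameDiff",
                 profile = prof))
    causal <- nz[length(nz)] # structural difference nearest the stop
    mech <- "stop_introduction"
    sig <- sigs[causal]
  } else {
    sig <- group_signature(groups[[causal]], nmdt, partner, ss_convention)
  }
  g <- groups[[causal]]
  res(partner$transcript_id, signature_to_category(sig), causal,
      c(g$span_start, g$span_end), prof, mech)
}

#' Classify every NMD target of a gene set
#'
#' @param geneset An `nmd_geneset`.
#' @param nmdt_ids Transcript ids to classify; defaults to the annotation's
#'   own NMD targets ([annotated_nmdts()]).
#' @param ss_convention,denominator See [classify_event()].
#' @return A list with `summary` (data frame of category counts over the
#'   twelve-class taxonomy plus `Unpartnered` and `Total`), `details` (one row
#'   per classified transcript) and `skipped` (ids without a resolvable CDS).
#' @export
classify_transcriptome <- function(geneset, nmdt_ids = NULL,
                                   ss_convention = "donor_is_5",
                                   denominator = "nmdt") {
  if (is.null(nmdt_ids)) nmdt_ids <- annotated_nmdts(geneset)
  nmdt_ids <- sort(nmdt_ids)
  cats <- character(length(nmdt_ids))
  partners <- character(length(nmdt_ids))
  spans <- character(length(nmdt_ids))
  grp <- integer(length(nmdt_ids))
  ok <- logical(length(nmdt_ids))
  for (i in seq_along(nmdt_ids)) {
    id <- nmdt_ids[i]
    gene <- geneset$genes[[geneset$tx_index[[id]]]]
    nmdt <- gene$transcripts[[id]]
    if (!has_cds(nmdt)) next
    cl <- classify_event(nmdt, gene, ss_convention = ss_convention,
                         denominator = denominator)
    cats[i] <- cl$category
    partners[i] <- cl$partner_id
    grp[i] <- ifelse(is.na(cl$causal_group), NA_integer_, cl$causal_group)
    spans[i] <- if (is.null(cl$causal_span)) NA_character_ else
      paste0(cl$causal_span[1], "-", cl$causal_span[2])
    ok[i] <- TRUE
  }
  lv <- c(NMD_CATEGORIES, "Unpartnered")
  counts <- table(factor(cats[ok], levels = lv))
  summary <- data.frame(category = c(lv, "Total"),
                        count = c(as.integer(counts), sum(ok)),
                        stringsAsFactors = FALSE)
  details <- data.frame(nmdt_id = nmdt_ids[ok], partner_id = partners[ok],
                        category = cats[ok], causal_group = grp[ok],
                        causal_span = spans[ok], stringsAsFactors = FALSE)
  list(summary = summary, details = details, skipped = nmdt_ids[!ok])
}
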