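# Fully synthetic multi-isoform annotation + genome generator. Every other
# module is testable against its output without downloading real data.

CODONS64 <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                  paste0), c("T", "C", "A", "G"), paste0))
CODONS61 <- setdiff(CODONS64, STOP_CODONS)

rand_bases <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# 5'UTR free of ATG so the annotated start is the true main-ORF start
rand_utr5 <- function(n, gc = 0.5) {
  for (i in 1:50) {
    s <- rand_bases(n, gc)
    if (!grepl("ATG", s, fixed = TRUE)) return(s)
  }
  gsub("ATG", "ACG", s, fixed = TRUE)
}

#' Generate a synthetic genome and multi-isoform annotation
#'
#' Builds protein-coding genes whose structure and sequence are mutually
#' consistent: each gene carries one reference coding isoform (genuine
#' `ATG..stop` ORF in the emitted sequence, no internal in-frame stop), one
#' or more coding decoy isoforms that share the translation start and differ
#' only in 3'UTR length, and (with probability `p_nmdt`) one NMD-target
#' isoform obtained by truncating the 3' boundary of an internal exon by a
#' frame-shifting amount, with its CDS re-derived by translation to the
#' premature stop and checked to satisfy the 50-NT rule. The translation
#' start lies in the first exon and the normal stop in the last, so all
#' internal exons are fully coding and eligible for simulated alterations.
#'
#' @param n_genes Number of genes.
#' @param isoforms_per_gene Coding isoforms per gene (>= 2; one reference
#'   plus decoys differing in 3'UTR).
#' @param p_nmdt Probability that a gene additionally carries an annotated
#'   NMD-target isoform.
#' @param exon_count Range (2-vector) of exons per transcript.
#' @param internal_exon_len,intron_len,utr5_len,utr3_len Ranges in nt.
#' @param gc GC content of UTR, intronic and intergenic sequence.
#' @param seed RNG seed; output is byte-identical for equal seeds.
#' @param out_prefix When given, writes `<prefix>.gtf` and `<prefix>.fa`.
#' @return A list with `geneset` (an `nmd_geneset`), `genome` (named
#'   character vector) and `nmdt_ids`.
#' @export
generate_synthetic_annotation <- function(n_genes = 200,
                                          isoforms_per_gene = 2,
                                          p_nmdt = 0.3,
                                          exon_count = c(5, 9),
                                          internal_exon_len = c(60, 180),
                                          intron_len = c(90, 400),
                                          utr5_len = c(30, 60),
                                          utr3_len = c(50, 200),
                                          gc = 0.5,
                                          seed = 1,
                                          out_prefix = NULL) {
  stopifnot(isoforms_per_gene >= 2, exon_count[1] >= 3)
  if (internal_exon_len[1] < 10 || intron_len[1] < 20)
    stop("infeasible length parameters", call. = FALSE)
  set.seed(seed)
  genes_per_chrom <- 25L
  chrom_seq <- list() # chrom -> list of sequence pieces
  chrom_len <- integer(0)
  genes <- list()
  nmdt_ids <- character(0)
  gap <- 300L
  for (gi in seq_len(n_genes)) {
    gid <- sprintf("G%04d", gi)
    chrom <- paste0("chr", (gi - 1L) %/% genes_per_chrom + 1L)
    strand <- sample(c("+", "-"), 1)

    n_ex <- sample(exon_count[1]:exon_count[2], 1)
    n_int <- n_ex - 2L
    int_len <- sample(internal_exon_len[1]:internal_exon_len[2], n_int,
                      replace = TRUE)
    u5 <- sample(utr5_len[1]:utr5_len[2], 1)
    u3 <- sample(utr3_len[1]:utr3_len[2], 1)
    c1 <- 3L * sample(10:30, 1)
    cN <- 3L * sample(10:30, 1)
    cN <- cN + (3L - (c1 + sum(int_len) + cN) %% 3L) %% 3L # whole codons
    ilen <- sample(intron_len[1]:intron_len[2], n_ex - 1L, replace = TRUE)
    elen <- c(u5 + c1, int_len, cN + u3)

    # local (sense-strand) exon coordinates
    starts <- cumsum(c(1L, head(elen, -1) + ilen))
    ends <- starts + elen - 1L

    # sequence: UTR5 | CDS codons | UTR3 threaded through the exons
    cds_total <- c1 + sum(int_len) + cN
    ncod <- cds_total %/% 3L
    codons <- c("ATG", CODONS61[sample.int(61L, ncod - 2L, replace = TRUE)],
                STOP_CODONS[sample.int(3L, 1)])
    cds_seq <- paste(codons, collapse = "")
    exon_seq <- character(n_ex)
    off <- 0L
    for (k in seq_len(n_ex)) {
      cod_here <- if (k == 1L) c1 else if (k == n_ex) cN else int_len[k - 1L]
      body <- substr(cds_seq, off + 1L, off + cod_here)
      off <- off + cod_here
      exon_seq[k] <- if (k == 1L) paste0(rand_utr5(u5, gc), body)
        else if (k == n_ex) paste0(body, rand_bases(u3, gc)) else body
    }
    intr_seq <- vapply(ilen, rand_bases, "", gc = gc)
    local_seq <- paste0(paste0(exon_seq[-n_ex], intr_seq, collapse = ""),
                        exon_seq[n_ex])

    # reference isoform CDS in local coordinates
    cds_s <- starts; cds_e <- ends
    cds_s[1] <- starts[1] + u5
    cds_e[n_ex] <- starts[n_ex] + cN - 1L

    isoforms <- list(A = list(es = starts, ee = ends, cs = cds_s, ce = cds_e,
                              biotype = "protein_coding"))
    # decoys: same structure, 3'UTR extended by a distinct amount
    ext <- 0L
    for (d in seq_len(isoforms_per_gene - 1L)) {
      ext <- ext + 3L * sample(10:30, 1)
      ee2 <- ends; ee2[n_ex] <- ends[n_ex] + ext
      isoforms[[paste0("B", d)]] <-
        list(es = starts, ee = ee2, cs = cds_s, ce = cds_e,
             biotype = "protein_coding")
    }
    max_ext <- ext
    local_seq <- paste0(local_seq, rand_bases(max_ext, gc))
    glen <- nchar(local_seq)

    # optional NMD-target isoform: frame-shifting 3'-boundary truncation of
    # an internal exon, CDS re-derived by translation to the premature stop
    if (stats::runif(1) < p_nmdt && n_int >= 1L) {
      combos <- expand.grid(k = 2:(n_ex - 1L), d = c(4L, 5L, 7L, 8L))
      combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
      for (ci in seq_len(nrow(combos))) {
        k <- combos$k[ci]; d <- combos$d[ci]
        if (elen[k] - d < 10L) next
        ee2 <- ends; ee2[k] <- ends[k] - d
        cand <- new_transcript("tmp", gid, "local", "+", starts, ee2,
                               validate = FALSE)
        mseq <- paste0(substring(local_seq, starts, ee2), collapse = "")
        start_m <- u5 + 1L
        stop_m <- first_stop_end(mseq, start_m)
        if (is.na(stop_m)) next
        lens <- ee2 - starts + 1L
        dist <- (sum(lens) - lens[n_ex]) - stop_m
        if (dist <= 50L) next
        cds <- mrna_window_to_intervals(cand, start_m, stop_m)
        isoforms$N <- list(es = starts, ee = ee2, cs = cds$start,
                           ce = cds$end, biotype = "nonsense_mediated_decay")
        break
      }
    }

    # place the gene on its chromosome (minus-strand genes are mirrored)
    if (is.null(chrom_seq[[chrom]])) {
      chrom_seq[[chrom]] <- list()
      chrom_len[chrom] <- 0L
    }
    offset <- chrom_len[chrom] + 1L
    placed_seq <- if (strand == "+") local_seq else revcomp(local_seq)
    txs <- list()
    for (iso in names(isoforms)) {
      z <- isoforms[[iso]]
      if (strand == "+") {
        es <- offset + z$es - 1L; ee <- offset + z$ee - 1L
        cs <- offset + z$cs - 1L; ce <- offset + z$ce - 1L
      } else {
        es <- offset + (glen - z$ee); ee <- offset + (glen - z$es)
        cs <- offset + (glen - z$ce); ce <- offset + (glen - z$cs)
      }
      tid <- paste0(gid, ".", iso)
      txs[[tid]] <- new_transcript(tid, gid, chrom, strand, es, ee, cs, ce,
                                   biotype = z$biotype)
      if (z$biotype == "nonsense_mediated_decay")
        nmdt_ids <- c(nmdt_ids, tid)
    }
    genes[[gid]] <- new_gene(gid, chrom, strand, txs)
    chrom_seq[[chrom]] <- c(chrom_seq[[chrom]],
                            list(placed_seq, rand_bases(gap, gc)))
    chrom_len[chrom] <- chrom_len[chrom] + glen + gap
  }
  genome <- vapply(chrom_seq, function(p) paste(unlist(p), collapse = ""), "")
  class(genome) <- c("nmd_genome", "character")
  gs <- new_geneset(genes, dialect = "synthetic", path = NA_character_)
  if (!is.null(out_prefix)) {
    write_gtf(gs, paste0(out_prefix, ".gtf"))
    write_genome_fasta(genome, paste0(out_prefix, ".fa"))
  }
  list(geneset = gs, genome = genome, nmdt_ids = sort(nmdt_ids))
}
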