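# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately written as naive enumerations, independent of the
# package's implementation paths.

make_tx <- function(id, es, ee, cs = numeric(0), ce = numeric(0),
                    strand = "+", gene = "g1", chrom = "chr1",
                    biotype = "protein_coding") {
  new_transcript(id, gene, chrom, strand, es, ee, cs, ce, biotype = biotype)
}

random_dna <- function(n, with_n = FALSE) {
  ab <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(ab, n, replace = TRUE), collapse = "")
}

# brute-force main-ORF oracle: enumerate every ATG, walk codon by codon to
# the first stop, score coding length (through stop, or sequence end),
# prefer longest then 5'-most
orf_oracle <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  for (s in seq_len(n - 2)) {
    if (substr(seq, s, s + 2) != "ATG") next
    stop_end <- NA_integer_
    p <- s
    while (p + 2 <= n) {
      if (substr(seq, p, p + 2) %in% c("TAA", "TAG", "TGA")) {
        stop_end <- p + 2L
        break
      }
      p <- p + 3L
    }
    len <- if (!is.na(stop_end)) stop_end - s + 1L else n - s + 1L
    if (is.null(best) || len > best$length ||
        (len == best$length && s < best$start))
      best <- list(start = s, stop_end = stop_end, length = len,
                   has_terminal_stop = !is.na(stop_end))
  }
  best
}

# positionwise shared-fraction oracle
shared_oracle <- function(a, b) {
  pa <- unlist(mapply(seq, a$exon_start, a$exon_end, SIMPLIFY = FALSE))
  pb <- unlist(mapply(seq, b$exon_start, b$exon_end, SIMPLIFY = FALSE))
  length(intersect(pa, pb)) / length(pa)
}

# MCC oracle: Pearson correlation of the expanded binary vectors
mcc_cor_oracle <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  if (length(unique(truth)) < 2 || length(unique(pred)) < 2) return(0)
  stats::cor(truth, pred)
}

# Frame-ledger worked fixture: partner with four exons, NMD target carrying
# one inserted exon of length 22 (= 1 mod 3) whose frameshift creates a
# premature stop in the third exon group.
fig_insertion_pair <- function() {
  partner <- make_tx("P", c(1, 201, 401, 601), c(100, 300, 500, 700),
                     c(31, 201, 401, 601), c(100, 300, 500, 660))
  nmdt <- make_tx("N", c(1, 121, 201, 401, 601),
                  c(100, 142, 300, 500, 700),
                  c(31, 121, 201), c(100, 142, 250),
                  biotype = "nonsense_mediated_decay")
  list(nmdt = nmdt, partner = partner)
}

# Rescue fixture: insertion (+1) at group (ii), compensating +2 boundary
# change at group (iii), then a +1 boundary change at group (iv) that is
# maintained to the premature stop in group (v).
fig_rescue_pair <- function() {
  partner <- make_tx("P", c(1, 201, 401, 601, 801),
                     c(100, 300, 500, 700, 900),
                     c(31, 201, 401, 601, 801),
                     c(100, 300, 500, 700, 860))
  nmdt <- make_tx("N", c(1, 121, 201, 401, 601),
                  c(100, 142, 302, 501, 700),
                  c(31, 121, 201, 401, 601), c(100, 142, 302, 501, 630),
                  biotype = "nonsense_mediated_decay")
  list(nmdt = nmdt, partner = partner)
}

# gene whose NMD target differs from its coding partner only downstream of
# the shared stop codon (extra 3'UTR exon introducing the NMD-triggering
# junction)
utr_diff_gene <- function() {
  coding <- make_tx("C", c(1, 201), c(100, 420), c(31, 201), c(100, 350))
  nmdt <- make_tx("U", c(1, 201, 501), c(100, 400, 640),
                  c(31, 201), c(100, 350),
                  biotype = "nonsense_mediated_decay")
  g <- new_gene("g1", "chr1", "+", list(coding, nmdt))
  list(gene = g, nmdt = nmdt, coding = coding)
}

# random multi-exon coding transcript on either strand (structure only)
random_coding_tx <- function(id = "t", strand = sample(c("+", "-"), 1)) {
  n_ex <- sample(3:6, 1)
  elen <- sample(30:120, n_ex, replace = TRUE)
  ilen <- sample(40:150, n_ex - 1, replace = TRUE)
  starts <- cumsum(c(sample(1:50, 1), head(elen, -1) + ilen))
  ends <- starts + elen - 1
  u5 <- min(10, elen[1] - 1)
  cs <- starts; ce <- ends
  if (strand == "+") {
    cs[1] <- starts[1] + u5
    ce[n_ex] <- ends[n_ex] - min(10, elen[n_ex] - 1)
  } else {
    ce[n_ex] <- ends[n_ex] - u5
    cs[1] <- starts[1] + min(10, elen[n_ex] - 1)
  }
  make_tx(id, starts, ends, cs, ce, strand = strand)
}
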