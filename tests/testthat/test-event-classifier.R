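# Best-partner selection, exon grouping, frame-difference scanning and the
# event taxonomy.

test_that("shared_fraction is positionwise overlap over NMDT length", {
  a <- make_tx("a", c(100, 300), c(199, 399))
  expect_equal(shared_fraction(a, a), 1)
  expect_equal(shared_fraction(a, make_tx("b", 1000, 1100)), 0)
  b <- make_tx("b", 150, 349)
  expect_equal(shared_fraction(a, b), shared_oracle(a, b))
  expect_equal(shared_fraction(a, b), 0.5) # 50 + 50 shared positions of 200
  # Jaccard variant
  expect_equal(shared_fraction(a, b, denominator = "jaccard"), 100 / 300)
})

test_that("select_best_partner filters on the start codon first", {
  nmdt <- make_tx("N", c(1, 201), c(100, 300), c(31, 201), c(100, 260),
                  biotype = "nonsense_mediated_decay")
  share_lowov <- make_tx("A", c(1, 801), c(100, 1400), c(31, 801), c(100, 1000))
  noshare_hiov <- make_tx("B", c(1, 201), c(100, 300), c(41, 201), c(100, 290))
  g <- new_gene("g1", "chr1", "+", list(nmdt, share_lowov, noshare_hiov))
  expect_identical(select_best_partner(nmdt, g)$transcript_id, "A")
})

test_that("select_best_partner maximises overlap and breaks ties stably", {
  nmdt <- make_tx("N", c(1, 201, 401), c(100, 300, 500),
                  c(31, 201, 401), c(100, 300, 430),
                  biotype = "nonsense_mediated_decay")
  hi <- make_tx("A", c(1, 201, 401), c(100, 300, 520),
                c(31, 201, 401), c(100, 300, 430))
  lo <- make_tx("B", c(1, 401), c(100, 520), c(31, 401), c(100, 430))
  g <- new_gene("g1", "chr1", "+", list(nmdt, hi, lo))
  expect_identical(select_best_partner(nmdt, g)$transcript_id, "A")
  # exact overlap tie: the candidate with more identical exon boundaries wins
  t1 <- make_tx("T1", c(1, 201, 401), c(100, 300, 560),
                c(31, 201, 401), c(100, 300, 430))
  t2 <- make_tx("T2", c(1, 181, 401), c(100, 300, 540),
                c(31, 181, 401), c(100, 300, 430))
  g2 <- new_gene("g1", "chr1", "+", list(nmdt, t1, t2))
  expect_identical(select_best_partner(nmdt, g2)$transcript_id, "T1")
  # still tied: lexicographically smallest id
  t3 <- make_tx("T3", c(1, 201, 401), c(100, 300, 560),
                c(31, 201, 401), c(100, 300, 430))
  g3 <- new_gene("g1", "chr1", "+", list(nmdt, t3, t1))
  expect_identical(select_best_partner(nmdt, g3)$transcript_id, "T1")
  # non-coding and NMD-biotype isoforms are never candidates
  dec <- make_tx("AA", c(1, 201, 401), c(100, 300, 560),
                 c(31, 201, 401), c(100, 300, 430),
                 biotype = "nonsense_mediated_decay")
  g4 <- new_gene("g1", "chr1", "+", list(nmdt, dec))
  expect_null(select_best_partner(nmdt, g4))
})

test_that("exon grouping reproduces the worked overlap examples", {
  a <- make_tx("a", 100, 500)
  b <- make_tx("b", 300, 700)
  gr <- build_exon_groups(a, b)
  expect_length(gr, 1)
  expect_equal(gr[[1]]$span_start, 100)
  expect_equal(gr[[1]]$span_end, 700)

  a2 <- make_tx("a", 2000, 2500)
  b2 <- make_tx("b", c(1800, 2300), c(2200, 2700))
  gr2 <- build_exon_groups(a2, b2)
  expect_length(gr2, 1)
  expect_equal(gr2[[1]]$span_start, 1800)
  expect_equal(gr2[[1]]$span_end, 2700)
  expect_identical(group_signature(gr2[[1]], a2, b2), "NMD_IR")

  # an exon overlapping nothing forms a singleton group
  a3 <- make_tx("a", c(100, 900), c(500, 950))
  gr3 <- build_exon_groups(a3, b)
  expect_length(gr3, 2)
  expect_equal(gr3[[2]]$span_start, 900)
  expect_length(gr3[[2]]$partner_exons, 0)
})

test_that("grouping is symmetric and covers every exon exactly once", {
  set.seed(31)
  for (i in 1:25) {
    strand <- sample(c("+", "-"), 1)
    a <- random_coding_tx("a", strand)
    b <- random_coding_tx("b", strand)
    ga <- build_exon_groups(a, b)
    gb <- build_exon_groups(b, a)
    expect_equal(lapply(ga, `[[`, "span_start"),
                 lapply(gb, `[[`, "span_start"))
    expect_equal(lapply(ga, `[[`, "nmdt_exons"),
                 lapply(gb, `[[`, "partner_exons"))
    expect_setequal(unlist(lapply(ga, `[[`, "nmdt_exons")),
                    seq_along(a$exon_start))
    expect_setequal(unlist(lapply(ga, `[[`, "partner_exons")),
                    seq_along(b$exon_start))
    # groups are disjoint and ordered in transcript orientation
    ss <- vapply(ga, `[[`, 0, "span_start")
    se <- vapply(ga, `[[`, 0, "span_end")
    o <- if (strand == "+") order(ss) else order(-ss)
    expect_equal(o, seq_along(ss))
    gss <- sort(ss); gse <- sort(se)
    if (length(ss) > 1) expect_true(all(gss[-1] > gse[-length(gse)]))
  }
})

test_that("boundary signatures follow the splice-site convention", {
  # + strand: downstream (donor-side) edge differs
  a <- make_tx("a", 100, 520)
  b <- make_tx("b", 100, 500)
  g <- build_exon_groups(a, b)[[1]]
  expect_identical(group_signature(g, a, b), "A5SS")
  expect_identical(group_signature(g, a, b, ss_convention = "exon_edge_is_5"),
                   "A3SS")
  # + strand: upstream (acceptor-side) edge differs
  a2 <- make_tx("a", 80, 500)
  expect_identical(group_signature(build_exon_groups(a2, b)[[1]], a2, b),
                   "A3SS")
  # mirrored on the minus strand
  am <- make_tx("a", 100, 520, strand = "-")
  bm <- make_tx("b", 100, 500, strand = "-")
  expect_identical(group_signature(build_exon_groups(am, bm)[[1]], am, bm),
                   "A3SS")
  # both edges differ
  a3 <- make_tx("a", 100, 500)
  b3 <- make_tx("b", 300, 700)
  expect_identical(group_signature(build_exon_groups(a3, b3)[[1]], a3, b3),
                   "A5SS+A3SS")
})

test_that("a transcript against itself has an identically zero profile", {
  set.seed(41)
  for (i in 1:15) {
    tx <- random_coding_tx()
    gr <- build_exon_groups(tx, tx)
    expect_true(all(frame_profile(gr, tx, tx) == 0L))
  }
})

test_that("the frame profile tracks the worked insertion and rescue cases", {
  # (the scan consumes the groups upstream of the premature stop, where the
  # CDS of both transcripts is complete)
  p <- fig_insertion_pair()
  gr <- build_exon_groups(p$nmdt, p$partner)
  prof <- frame_profile(gr, p$nmdt, p$partner)
  expect_equal(prof[1:2], c(0L, 1L)) # +1 at the insertion, held
  expect_equal(attr(prof, "nmdt_len")[2], 22)
  expect_equal(attr(prof, "partner_len")[2], 0)

  r <- fig_rescue_pair()
  gr2 <- build_exon_groups(r$nmdt, r$partner)
  prof2 <- frame_profile(gr2, r$nmdt, r$partner)
  expect_equal(prof2[1:4], c(0L, 1L, 0L, 1L)) # rescue at (iii), reset at (iv)
})

test_that("find_causal_group implements the rescue re-initiation rule", {
  expect_equal(find_causal_group(c(0L, 1L, 1L, 1L)), 2L)
  expect_equal(find_causal_group(c(0L, 1L, 0L, 2L, 2L)), 4L)
  expect_true(is.na(find_causal_group(c(0L, 0L, 0L))))
  expect_true(is.na(find_causal_group(c(0L, 1L, 2L, 0L)))) # ends balanced
  expect_equal(find_causal_group(c(1L)), 1L)
})

test_that("classify_event reproduces the worked scenarios", {
  p <- fig_insertion_pair()
  g <- new_gene("g1", "chr1", "+", list(p$nmdt, p$partner))
  cl <- classify_event(p$nmdt, g)
  expect_identical(cl$category, "NMD_in")
  expect_equal(cl$causal_group, 2L) # group (ii)
  expect_identical(cl$mechanism, "frameshift")
  expect_equal(cl$causal_span, c(121, 142))

  r <- fig_rescue_pair()
  g2 <- new_gene("g1", "chr1", "+", list(r$nmdt, r$partner))
  cl2 <- classify_event(r$nmdt, g2)
  expect_equal(cl2$causal_group, 4L) # group (iv), after the rescue
  expect_identical(cl2$category, "A5SS")
})

test_that("UTR-only differences and unpartnered targets are routed apart", {
  u <- utr_diff_gene()
  cl <- classify_event(u$nmdt, u$gene)
  expect_identical(cl$category, "UTR_Diff")
  expect_true(is.na(cl$causal_group))
  # no coding isoform sharing the start site
  lone <- make_tx("L", c(1, 201), c(100, 300), c(31, 201), c(100, 260),
                  biotype = "nonsense_mediated_decay")
  g <- new_gene("g1", "chr1", "+", list(lone))
  expect_identical(classify_event(lone, g)$category, "Unpartnered")
})

test_that("a multi-signature causal group is classified Complex", {
  # exon inclusion in the NMD target inside an intron retained by the partner
  nmdt <- make_tx("N", c(1, 201, 281, 361, 501), c(100, 260, 340, 400, 600),
                  c(31, 201, 281, 361), c(100, 260, 340, 380),
                  biotype = "nonsense_mediated_decay")
  partner <- make_tx("P", c(1, 201, 501), c(100, 400, 600),
                     c(31, 201, 501), c(100, 400, 560))
  g <- new_gene("g1", "chr1", "+", list(nmdt, partner))
  cl <- classify_event(nmdt, g)
  expect_identical(cl$category, "Complex")
  expect_equal(cl$causal_span, c(201, 400))
})

test_that("an in-frame inserted exon carrying its own stop is causal", {
  # inserted exon length 21 (frame-preserving) holding the premature stop:
  # the profile stays flat, yet the insertion is the stop-introducing event
  partner <- make_tx("P", c(1, 201, 401), c(100, 300, 500),
                     c(31, 201, 401), c(100, 300, 460))
  nmdt <- make_tx("N", c(1, 121, 201, 401), c(100, 141, 300, 500),
                  c(31, 121), c(100, 135),
                  biotype = "nonsense_mediated_decay")
  g <- new_gene("g1", "chr1", "+", list(nmdt, partner))
  cl <- classify_event(nmdt, g)
  expect_identical(cl$category, "NMD_in")
  expect_equal(cl$causal_group, 2L)
  expect_identical(cl$mechanism, "stop_introduction")
})

test_that("CDS differences without frameshift or upstream structure remain", {
  # identical structure up to the stop; the pair differs only downstream
  partner <- make_tx("P", c(1, 201, 401), c(100, 300, 500),
                     c(31, 201, 401), c(100, 300, 460))
  nmdt <- make_tx("N", c(1, 201, 401), c(100, 300, 500),
                  c(31, 201), c(100, 240),
                  biotype = "nonsense_mediated_decay")
  g <- new_gene("g1", "chr1", "+", list(nmdt, partner))
  cl <- classify_event(nmdt, g)
  expect_identical(cl$category, "UTR_Diff_CDSdiff_NoFrameDiff")
})

test_that("classify_transcriptome tallies categories deterministically", {
  # three known targets: an insertion, a rescue-then-boundary, a UTR change
  p <- fig_insertion_pair(); r <- fig_rescue_pair(); u <- utr_diff_gene()
  relabel <- function(tx, gene) { tx$gene_id <- gene; tx }
  g1 <- new_gene("g1", "chr1", "+", lapply(list(p$nmdt, p$partner),
                                           relabel, "g1"))
  # distinct transcript ids are required across genes
  g2b <- new_gene("g2", "chr1", "+", list(
    relabel(make_tx("N2", r$nmdt$exon_start, r$nmdt$exon_end,
                    r$nmdt$cds_start, r$nmdt$cds_end,
                    biotype = "nonsense_mediated_decay"), "g2"),
    relabel(make_tx("P2", r$partner$exon_start, r$partner$exon_end,
                    r$partner$cds_start, r$partner$cds_end), "g2")))
  g3 <- new_gene("g3", "chr1", "+", list(
    relabel(make_tx("U3", u$nmdt$exon_start, u$nmdt$exon_end,
                    u$nmdt$cds_start, u$nmdt$cds_end,
                    biotype = "nonsense_mediated_decay"), "g3"),
    relabel(make_tx("C3", u$coding$exon_start, u$coding$exon_end,
                    u$coding$cds_start, u$coding$cds_end), "g3")))
  gs <- new_geneset(list(g1, g2b, g3))
  res <- classify_transcriptome(gs)
  cnt <- setNames(res$summary$count, res$summary$category)
  expect_equal(cnt[["NMD_in"]], 1L)
  expect_equal(cnt[["A5SS"]], 1L)
  expect_equal(cnt[["UTR_Diff"]], 1L)
  expect_equal(cnt[["Total"]], 3L)
  expect_equal(sum(cnt[setdiff(names(cnt), "Total")]), cnt[["Total"]])
  # identical call twice -> identical tables
  expect_identical(res, classify_transcriptome(gs))
  # empty target list -> all-zero table
  res0 <- classify_transcriptome(gs, nmdt_ids = character(0))
  expect_true(all(res0$summary$count == 0))
})
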