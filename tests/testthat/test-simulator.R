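# Structural-alteration injections, the synthetic generator and the
# end-to-end accuracy simulation.

syn_small <- generate_synthetic_annotation(n_genes = 25, seed = 17)

test_that("empirical exon-length sampler reproduces observed frequencies", {
  g <- new_gene("g", "chr1", "+", list(
    make_tx("t1", c(1, 101, 301, 701), c(50, 200, 600, 800),
            c(11, 101, 301, 701), c(50, 200, 600, 750), gene = "g"),
    make_tx("t2", c(1, 101, 401), c(50, 200, 500),
            c(11, 101, 401), c(50, 200, 450), gene = "g")))
  # internal coding exon lengths: 100, 300 (t1) and 100 (t2)
  gs <- new_geneset(list(g))
  sampler <- empirical_exon_lengths(gs)
  set.seed(1)
  draws <- sampler(10000)
  expect_setequal(unique(draws), c(100, 300))
  p100 <- mean(draws == 100)
  expect_true(abs(p100 - 2 / 3) < 4 * sqrt(2 / 9 / 10000)) # binomial 4 sigma
  # a single observed length is returned always
  g1 <- new_gene("g", "chr1", "+", list(
    make_tx("t", c(1, 101, 301), c(50, 190, 400),
            c(11, 101, 301), c(50, 190, 350), gene = "g")))
  s1 <- empirical_exon_lengths(new_geneset(list(g1)))
  expect_true(all(s1(50) == 90))
  expect_error(empirical_exon_lengths(new_geneset(list())), "no internal")
})

test_that("inject_deletion removes one internal coding exon", {
  tx <- make_tx("t", c(1, 101, 301), c(50, 200, 400),
                c(11, 101, 301), c(50, 200, 350))
  set.seed(2)
  out <- inject_deletion(tx)
  expect_equal(n_exons(out$transcript), 2)
  expect_equal(out$truth$span, c(101, 200)) # the only eligible exon
  expect_identical(out$truth$event_type, "deletion")
  # deleting then re-inserting the span restores the chain
  es <- sort(c(out$transcript$exon_start, out$truth$span[1]))
  ee <- sort(c(out$transcript$exon_end, out$truth$span[2]))
  expect_equal(es, tx$exon_start)
  expect_equal(ee, tx$exon_end)
  # two-exon transcripts are ineligible
  tx2 <- make_tx("t", c(1, 101), c(50, 200), c(11, 101), c(50, 150))
  expect_error(inject_deletion(tx2), class = "nmd_ineligible")
})

test_that("inject_insertion places a whole exon inside a hosting intron", {
  tx <- make_tx("t", c(1, 201, 401), c(100, 300, 500),
                c(31, 201, 401), c(100, 300, 460))
  set.seed(3)
  for (i in 1:200) {
    out <- inject_insertion(tx, function(n) rep(50, n))
    alt <- out$transcript
    sp <- out$truth$span
    expect_equal(sp[2] - sp[1] + 1, 50)
    expect_equal(n_exons(alt), 4)
    # placed in an intron with at least 1 nt flank on each side
    in1 <- sp[1] >= 102 && sp[2] <= 199
    in2 <- sp[1] >= 302 && sp[2] <= 399
    expect_true(in1 || in2)
    validate_alt <- new_transcript("v", "g", alt$chrom, alt$strand,
                                   alt$exon_start, alt$exon_end)
    expect_s3_class(validate_alt, "nmd_transcript")
  }
  # forced placement when the intron barely fits (length L + 2)
  out <- inject_insertion(tx, function(n) rep(98, n))
  expect_true(identical(out$truth$span, c(102, 199)) ||
                identical(out$truth$span, c(302, 399)))
  # nothing can host an oversized exon
  expect_error(inject_insertion(tx, function(n) rep(500, n)),
               class = "nmd_ineligible")
})

test_that("inject_boundary_change respects clamps and side uniformity", {
  tx <- make_tx("t", c(1, 201, 401), c(100, 300, 500),
                c(31, 201, 401), c(100, 300, 460))
  set.seed(4)
  sides <- character(3000)
  for (i in seq_along(sides)) {
    out <- inject_boundary_change(tx, function(n)
      sample(c(60, 90, 110, 130), n, replace = TRUE))
    alt <- out$transcript
    sides[i] <- out$truth$side
    # altered exon keeps >= 1 intronic nt towards both neighbours
    expect_true(alt$exon_start[2] >= 102)
    expect_true(alt$exon_end[2] <= 399)
    expect_true(alt$exon_end[2] >= alt$exon_start[2])
    expect_true(out$truth$span[1] <= 201 || out$truth$span[2] >= 300)
  }
  chi <- stats::chisq.test(table(sides))
  expect_gt(chi$p.value, 0.01)
  # a sampler stuck on the current length finds no feasible change
  expect_error(inject_boundary_change(tx, function(n) rep(100, n)),
               class = "nmd_ineligible")
})

test_that("the synthetic generator is deterministic and self-consistent", {
  a <- generate_synthetic_annotation(n_genes = 6, seed = 9)
  b <- generate_synthetic_annotation(n_genes = 6, seed = 9)
  expect_identical(a$genome, b$genome)
  expect_identical(names(a$geneset$tx_index), names(b$geneset$tx_index))
  d1 <- withr::local_tempdir()
  generate_synthetic_annotation(n_genes = 4, seed = 2,
                                out_prefix = file.path(d1, "x"))
  generate_synthetic_annotation(n_genes = 4, seed = 2,
                                out_prefix = file.path(d1, "y"))
  expect_identical(readLines(file.path(d1, "x.gtf")),
                   readLines(file.path(d1, "y.gtf")))
  expect_identical(readLines(file.path(d1, "x.fa")),
                   readLines(file.path(d1, "y.fa")))
  # written FASTA reads back to the in-memory genome
  g2 <- read_genome_fasta(file.path(d1, "x.fa"))
  g1 <- generate_synthetic_annotation(n_genes = 4, seed = 2)$genome
  expect_equal(unclass(g2)[order(names(g2))], unclass(g1)[order(names(g1))])
})

test_that("generated ORFs and NMD-target isoforms honour their contracts", {
  gs <- syn_small$geneset
  genome <- syn_small$genome
  for (tx in all_transcripts(gs)) {
    if (is.na(tx$biotype) || tx$biotype != "protein_coding") next
    o <- find_main_orf(splice_sequence(tx, genome))
    expect_equal(o$start, to_mrna_coords(tx, tx_start_codon_pos(tx)))
    expect_equal(o$stop_end, to_mrna_coords(tx, tx_cds_end_pos(tx)))
  }
  for (id in syn_small$nmdt_ids) {
    tx <- get_transcript(gs, id)
    expect_gt(ptc_junction_distance(tx)$distance, 50)
    # the annotated premature stop is a genuine stop codon in the sequence
    seq <- splice_sequence(tx, genome)
    sm <- to_mrna_coords(tx, tx_start_codon_pos(tx))
    em <- to_mrna_coords(tx, tx_cds_end_pos(tx))
    expect_true(substr(seq, em - 2, em) %in% c("TAA", "TAG", "TGA"))
    expect_equal((em - sm + 1) %% 3, 0)
  }
})

test_that("altered transcripts from all injectors remain structurally valid", {
  gs <- syn_small$geneset
  sampler <- empirical_exon_lengths(gs)
  pool <- Filter(function(t) !is.na(t$biotype) &&
                   t$biotype == "protein_coding", all_transcripts(gs))
  set.seed(8)
  for (i in 1:300) {
    src <- pool[[sample.int(length(pool), 1)]]
    out <- switch(sample(3, 1),
                  inject_deletion(src),
                  inject_insertion(src, sampler),
                  inject_boundary_change(src, sampler))
    alt <- out$transcript
    expect_silent(new_transcript("v", "g", alt$chrom, alt$strand,
                                 alt$exon_start, alt$exon_end))
    expect_true(out$truth$span[1] <= out$truth$span[2])
  }
})

test_that("run_simulation is seed-deterministic", {
  cfg <- sim_config(n_transcripts = 120, n_sims = 2, seed = 5)
  r1 <- run_simulation(syn_small$geneset, syn_small$genome, cfg)
  r2 <- run_simulation(syn_small$geneset, syn_small$genome, cfg)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$events, r2$events)
  r3 <- run_simulation(syn_small$geneset, syn_small$genome,
                       sim_config(n_transcripts = 120, n_sims = 2, seed = 6))
  expect_false(identical(r1$events$source, r3$events$source))
})

test_that("simulation accuracy is near-perfect when partners are clean", {
  cfg <- sim_config(n_transcripts = 400, n_sims = 2, seed = 21)
  res <- run_simulation(syn_small$geneset, syn_small$genome, cfg)
  expect_true(all(res$accuracy >= 0.99))
  ev <- res$events[res$events$is_nmdt, ]
  expect_gt(nrow(ev), 200) # a healthy share of alterations produce targets
  # frame-preserving alterations that create no stop stay out of the
  # denominator: every non-target event has an empty category
  expect_true(all(res$events$category[!res$events$is_nmdt] == ""))
})
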