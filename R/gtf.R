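# GTF I/O. The reader is dialect-aware: Ensembl releases up to V75 store the
# transcript biotype in the *source* column (column 2), later releases and
# most other producers use a `transcript_biotype` / `transcript_type`
# attribute. Parsing is line-oriented so malformed records can be reported
# with their file line number, which generic importers do not expose.

GTF_BIOTYPE_WORDS <- c(
  "protein_coding", "nonsense_mediated_decay", "processed_transcript",
  "retained_intron", "lincRNA", "pseudogene", "processed_pseudogene",
  "unprocessed_pseudogene", "antisense", "miRNA", "snoRNA", "snRNA",
  "misc_RNA", "rRNA", "non_stop_decay", "polymorphic_pseudogene",
  "sense_intronic", "sense_overlapping", "TEC"
)

# extract a quoted attribute value, NA when absent
gtf_attr <- function(attrs, key) {
  pat <- paste0(key, '\\s+"([^"]*)"')
  m <- regexpr(pat, attrs, perl = TRUE)
  out <- rep(NA_character_, length(attrs))
  hit <- which(m > 0)
  if (length(hit)) {
    frag <- substring(attrs[hit], m[hit], m[hit] + attr(m, "match.length")[hit] - 1L)
    out[hit] <- sub(pat, "\\1", frag, perl = TRUE)
  }
  out
}

#' Read a GTF annotation
#'
#' Parses a 9-column tab-separated GTF into a gene set. `exon`, `CDS` and
#' `stop_codon` features are used; other feature types are ignored (their
#' count is recorded in the skip log). `stop_codon` features are merged into
#' the CDS so that the stored CDS always *includes* the stop codon; when they
#' are absent the annotated CDS is assumed to already include it.
#'
#' @param path GTF file.
#' @param dialect `"auto"` (default) sniffs the first 100 feature records:
#'   when no `transcript_biotype`/`transcript_type` attribute is present but
#'   the source column carries biotype words, the Ensembl-V75 convention
#'   (biotype in the source column) is used. `"ensembl"` forces the attribute
#'   convention with source-column fallback, `"generic"` uses attributes only.
#' @return An `nmd_geneset`.
#' @details Transcripts whose features span several chromosomes or strands are
#'   skipped (and logged), not repaired. Duplicate identical exon records are
#'   deduplicated with a warning; unsorted exon lines are sorted on load.
#'   Malformed coordinates (non-integer, or end < start) and exon/CDS records
#'   without a `transcript_id` are hard errors naming the offending line.
#' @export
read_gtf <- function(path, dialect = c("auto", "ensembl", "generic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines))
    return(new_geneset(list(), dialect = dialect, path = path))
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(f) < 9)
    stop("not a 9-column GTF: ", path, call. = FALSE)
  chrom <- f[[1]]; src <- f[[2]]; type <- f[[3]]
  start_c <- f[[4]]; end_c <- f[[5]]; strand <- f[[7]]; attrs <- f[[9]]

  bad <- !is_wholenumber(start_c) | !is_wholenumber(end_c)
  if (any(bad))
    stop("malformed coordinate at line ", lineno[which(bad)[1]], " of ", path,
         call. = FALSE)
  start <- as.numeric(start_c); end <- as.numeric(end_c)
  bad <- end < start
  if (any(bad))
    stop("end < start at line ", lineno[which(bad)[1]], " of ", path,
         call. = FALSE)

  used <- type %in% c("exon", "CDS", "stop_codon")
  skip_log <- c(table(type[!used]))
  storage.mode(skip_log) <- "integer"

  idx <- which(used)
  attrs_u <- attrs[idx]
  tx_id <- gtf_attr(attrs_u, "transcript_id")
  if (anyNA(tx_id))
    stop("missing transcript_id attribute at line ",
         lineno[idx[which(is.na(tx_id))[1]]], " of ", path, call. = FALSE)
  gene_id <- gtf_attr(attrs_u, "gene_id")
  gene_id[is.na(gene_id)] <- tx_id[is.na(gene_id)]

  bio_attr <- gtf_attr(attrs_u, "transcript_biotype")
  alt <- is.na(bio_attr)
  if (any(alt)) bio_attr[alt] <- gtf_attr(attrs_u[alt], "transcript_type")
  use_source <- switch(dialect,
    generic = FALSE,
    ensembl = TRUE,
    auto = {
      head_n <- seq_len(min(100L, length(idx)))
      all(is.na(bio_attr[head_n])) &&
        any(src[idx][head_n] %in% GTF_BIOTYPE_WORDS)
    })
  biotype <- bio_attr
  if (use_source) {
    miss <- is.na(biotype) & src[idx] %in% GTF_BIOTYPE_WORDS
    biotype[miss] <- src[idx][miss]
  }

  build_geneset(
    tx_id = tx_id, gene_id = gene_id, chrom = chrom[idx],
    strand = strand[idx], type = type[idx], start = start[idx],
    end = end[idx], biotype = biotype,
    dialect = if (use_source) "ensembl_v75" else "generic",
    path = path, skip_log = skip_log)
}

# shared assembly of a geneset from flat per-feature vectors
build_geneset <- function(tx_id, gene_id, chrom, strand, type, start, end,
                          biotype, dialect, path, skip_log = integer(0)) {
  skipped_multi <- 0L
  dedup <- 0L
  genes <- list()
  ord <- order(gene_id, tx_id)
  sp <- split(seq_along(tx_id)[ord], tx_id[ord])
  tx_objs <- vector("list", length(sp))
  tx_gene <- character(length(sp))
  ok <- logical(length(sp))
  for (k in seq_along(sp)) {
    i <- sp[[k]]
    id <- tx_id[i[1]]
    if (length(unique(chrom[i])) > 1L || length(unique(strand[i])) > 1L) {
      skipped_multi <- skipped_multi + 1L
      next
    }
    is_ex <- type[i] == "exon"
    is_cds <- type[i] != "exon" # CDS + stop_codon, merged below
    es <- start[i][is_ex]; ee <- end[i][is_ex]
    dup <- duplicated(paste(es, ee))
    if (any(dup)) {
      dedup <- dedup + sum(dup)
      es <- es[!dup]; ee <- ee[!dup]
    }
    cs <- start[i][is_cds]; ce <- end[i][is_cds]
    if (length(cs)) {
      o <- order(cs); cs <- cs[o]; ce <- ce[o]
      m <- merge_adjacent(cs, ce)
      cs <- m$start; ce <- m$end
    }
    bt <- biotype[i]
    bt <- if (all(is.na(bt))) NA_character_ else bt[!is.na(bt)][1]
    tx_objs[[k]] <- new_transcript(id, gene_id[i[1]], chrom[i[1]], strand[i[1]],
                                   es, ee, cs, ce, biotype = bt)
    tx_gene[k] <- gene_id[i[1]]
    ok[k] <- TRUE
  }
  if (dedup > 0)
    warning(dedup, " duplicate exon record(s) removed", call. = FALSE)
  tx_objs <- tx_objs[ok]
  tx_gene <- tx_gene[ok]
  for (gid in unique(tx_gene)) {
    members <- tx_objs[tx_gene == gid]
    genes[[gid]] <- new_gene(gid, members[[1]]$chrom, members[[1]]$strand,
                             members)
  }
  if (skipped_multi > 0)
    skip_log <- c(skip_log, multi_chrom_or_strand = skipped_multi)
  new_geneset(genes, dialect = dialect, path = path, skip_log = skip_log)
}

# merge book-ended intervals (gap 0), e.g. CDS + its stop_codon feature
merge_adjacent <- function(s, e) {
  if (length(s) < 2) return(list(start = s, end = e))
  ns <- s[1]; ne <- e[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in 2:length(s)) {
    if (s[i] <= ne + 1) {
      ne <- max(ne, e[i])
    } else {
      out_s <- c(out_s, ns); out_e <- c(out_e, ne)
      ns <- s[i]; ne <- e[i]
    }
  }
  list(start = c(out_s, ns), end = c(out_e, ne))
}

#' Write a gene set as GTF
#'
#' Emits one `exon` line per exon and one `CDS` line per CDS interval, with
#' `gene_id`, `transcript_id` and (when known) `transcript_biotype`
#' attributes. Reading the file back with [read_gtf()] reproduces the
#' intervals, identifiers and biotypes exactly.
#'
#' @param geneset An `nmd_geneset`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(geneset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (gid in sort(names(geneset$genes))) {
    g <- geneset$genes[[gid]]
    for (tid in sort(names(g$transcripts))) {
      tx <- g$transcripts[[tid]]
      src <- if (is.na(tx$biotype)) "nmdscan" else tx$biotype
      at <- sprintf('gene_id "%s"; transcript_id "%s";%s', gid, tid,
                    if (is.na(tx$biotype)) "" else
                      sprintf(' transcript_biotype "%s";', tx$biotype))
      lines <- c(
        sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                tx$chrom, src, as.integer(tx$exon_start),
                as.integer(tx$exon_end), tx$strand, at),
        if (has_cds(tx))
          sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                  tx$chrom, src, as.integer(tx$cds_start),
                  as.integer(tx$cds_end), tx$strand, at))
      writeLines(lines, con)
    }
  }
  invisible(path)
}
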