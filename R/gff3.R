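# GFF3 reader (NCBI dialect): gene -> mRNA -> exon/CDS linked via ID/Parent.

gff3_attr <- function(attrs, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regexpr(pat, attrs, perl = TRUE)
  out <- rep(NA_character_, length(attrs))
  hit <- which(m > 0)
  if (length(hit)) {
    frag <- substring(attrs[hit], m[hit],
                      m[hit] + attr(m, "match.length")[hit] - 1L)
    out[hit] <- sub(pat, "\\1", frag, perl = TRUE)
  }
  out
}

#' Read a GFF3 annotation
#'
#' Accepts the gene/mRNA/exon/CDS feature hierarchy linked by `ID`/`Parent`
#' attributes (the NCBI convention). `transcript` features are treated like
#' `mRNA`. An exon or CDS whose `Parent` resolves to no mRNA is a hard error
#' listing the orphan ids. The transcript biotype is taken from a
#' `transcript_biotype` or `biotype` attribute when present.
#'
#' @param path GFF3 file.
#' @return An `nmd_geneset` with the same contract as [read_gtf()].
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines))
    return(new_geneset(list(), dialect = "gff3", path = path))
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(f) < 9) stop("not a 9-column GFF3: ", path, call. = FALSE)
  chrom <- f[[1]]; type <- f[[3]]
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

  is_gene <- type == "gene"
  is_mrna <- type %in% c("mRNA", "transcript")
  is_part <- type %in% c("exon", "CDS")
  skip_log <- c(table(type[!(is_gene | is_mrna | is_part)]))
  storage.mode(skip_log) <- "integer"

  gene_ids <- gff3_attr(attrs[is_gene], "ID")
  mrna_id <- gff3_attr(attrs[is_mrna], "ID")
  mrna_parent <- gff3_attr(attrs[is_mrna], "Parent")
  mrna_bio <- gff3_attr(attrs[is_mrna], "transcript_biotype")
  miss <- is.na(mrna_bio)
  if (any(miss)) mrna_bio[miss] <- gff3_attr(attrs[is_mrna][miss], "biotype")
  if (anyNA(mrna_id))
    stop("mRNA feature without ID at line ",
         lineno[which(is_mrna)[which(is.na(mrna_id))[1]]], call. = FALSE)
  # mRNA parent gene: strip any "gene:" style prefixes? keep verbatim; an
  # mRNA without a resolvable gene parent becomes its own single-tx gene
  tx2gene <- ifelse(!is.na(mrna_parent) & mrna_parent %in% gene_ids,
                    mrna_parent, mrna_id)
  names(tx2gene) <- mrna_id
  names(mrna_bio) <- mrna_id

  part_parent <- gff3_attr(attrs[is_part], "Parent")
  # an exon may be shared between several mRNAs: Parent holds a comma list
  plist <- strsplit(ifelse(is.na(part_parent), "", part_parent), ",",
                    fixed = TRUE)
  reps <- lengths(plist)
  if (any(reps == 0))
    stop("exon/CDS without Parent at line ",
         lineno[which(is_part)[which(reps == 0)[1]]], call. = FALSE)
  pvec <- unlist(plist, use.names = FALSE)
  orphan <- setdiff(unique(pvec), mrna_id)
  if (length(orphan))
    stop("orphan exon/CDS Parent id(s): ", paste(orphan, collapse = ", "),
         call. = FALSE)
  pi <- which(is_part)
  ri <- rep(pi, reps)
  build_geneset(
    tx_id = pvec,
    gene_id = unname(tx2gene[pvec]),
    chrom = chrom[ri], strand = strand[ri], type = type[ri],
    start = start[ri], end = end[ri],
    biotype = unname(mrna_bio[pvec]),
    dialect = "gff3", path = path, skip_log = skip_log)
}
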