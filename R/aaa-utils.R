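# Internal helpers. All genomic coordinates in this package are 1-based and
# inclusive (GTF convention); half-open arithmetic never leaves a function.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stringi stri_reverse
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# total number of positions covered by both interval sets (each set disjoint)
ivl_overlap_total <- function(as, ae, bs, be) {
  if (!length(as) || !length(bs)) return(0)
  lo <- outer(as, bs, pmax)
  hi <- outer(ae, be, pmin)
  d <- hi - lo + 1
  sum(d[d > 0])
}

# overlap of one interval set with a single interval [s, e] (may be infinite)
ivl_clip_total <- function(as, ae, s, e) {
  d <- pmin(ae, e) - pmax(as, s) + 1
  sum(d[d > 0])
}

is_wholenumber <- function(x, tol = 1e-8) {
  v <- suppressWarnings(as.numeric(x))
  !is.na(v) & abs(v - round(v)) < tol
}
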