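# SAM flag bits
FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MATE_REVERSE <- 0x20L
FLAG_FIRST <- 0x40L
FLAG_SECOND <- 0x80L

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

#' Construct an alignment table
#'
#' The package's in-memory alignment representation: one row per SAM record
#' with a contig (`@SQ`) table attached.  Mapped records carry a 1-based
#' leftmost position and a CIGAR over `{M,S}` (external SAM with the full op
#' alphabet is accepted by the depth machinery); unmapped records have
#' `rname = "*"`, `pos = 0`, `mapq = 0`.
#'
#' @param df data.frame with columns qname, flag, rname, pos, mapq, cigar,
#'   rnext, pnext, tlen, seq, qual and optionally nm (mismatch count).
#' @param contigs named integer vector of contig lengths (the header).
#' @return object of class `covmark_aln` (a data.frame).
#' @export
alignments <- function(df, contigs) {
  need <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "rnext", "pnext", "tlen", "seq", "qual")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("alignment table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(df$nm)) df$nm <- NA_integer_
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contig table must have unique names")
  bad <- df$rname != "*" & !(df$rname %in% names(contigs))
  if (any(bad))
    stop("alignment record ", which(bad)[1], " (", df$qname[which(bad)[1]],
         ") references unknown contig '", df$rname[which(bad)[1]], "'")
  attr(df, "contigs") <- contigs
  class(df) <- c("covmark_aln", "data.frame")
  df
}

aln_contigs <- function(aln) attr(aln, "contigs")

#' Write alignments as SAM text
#'
#' @param aln a `covmark_aln` table.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_sam <- function(aln, path) {
  contigs <- aln_contigs(aln)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  nm_tag <- ifelse(is.na(aln$nm), "", sprintf("\tNM:i:%d", aln$nm))
  records <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s%s",
                     aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq,
                     aln$cigar, aln$rnext, aln$pnext, aln$tlen,
                     aln$seq, aln$qual, nm_tag)
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read SAM text into an alignment table
#'
#' Accepts externally produced SAM as long as it carries `@SQ` header lines;
#' only the 11 mandatory fields plus `NM:i:` are retained.
#'
#' @param path SAM file.
#' @return a `covmark_aln` table.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  sq <- lines[grepl("^@SQ\t", lines)]
  if (length(sq) == 0) stop("SAM file has no @SQ header lines")
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  body <- lines[!hdr]
  if (length(body) == 0) {
    df <- data.frame(qname = character(0), flag = integer(0),
                     rname = character(0), pos = integer(0),
                     mapq = integer(0), cigar = character(0),
                     rnext = character(0), pnext = integer(0),
                     tlen = integer(0), seq = character(0),
                     qual = character(0), nm = integer(0),
                     stringsAsFactors = FALSE)
    return(alignments(df, setNames(ln, sn)))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11))
    stop("malformed SAM record at line ", which(!hdr)[which(nf < 11)[1]])
  get <- function(i) vapply(fields, `[[`, character(1), i)
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag) == 0) NA_integer_ else as.integer(sub("^NM:i:", "", tag[1]))
  }, integer(1))
  df <- data.frame(qname = get(1), flag = as.integer(get(2)),
                   rname = get(3), pos = as.integer(get(4)),
                   mapq = as.integer(get(5)), cigar = get(6),
                   rnext = get(7), pnext = as.integer(get(8)),
                   tlen = as.integer(get(9)), seq = get(10), qual = get(11),
                   nm = nm, stringsAsFactors = FALSE)
  alignments(df, setNames(ln, sn))
}

#' @export
print.covmark_aln <- function(x, ...) {
  n_mapped <- sum(!has_flag(x$flag, FLAG_UNMAPPED))
  cat("covmark_aln:", nrow(x), "records (", n_mapped, "mapped) on",
      length(aln_contigs(x)), "contigs\n")
  invisible(x)
}
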