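#' @importFrom Biostrings DNAString DNAStringSet readBStringSet writeXStringSet reverseComplement
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

# Internal: normalize any sequence input (character, DNAString, DNAStringSet
# element) to a single uppercase character string and check the alphabet.
.as_bases <- function(x, what = "sequence") {
  if (inherits(x, "XString") || inherits(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1L)
    stop(what, " must be a single character string or DNAString", call. = FALSE)
  bases <- toupper(x)
  if (nchar(bases) == 0L) stop(what, " is empty", call. = FALSE)
  bad <- regexpr("[^ACGTN]", bases)
  if (bad > 0L)
    stop(sprintf("%s contains invalid character '%s' at position %d",
                 what, substr(bases, bad, bad), bad), call. = FALSE)
  bases
}

#' Read a FASTA file into a set of DNA sequences
#'
#' Records are uppercased on ingest; `U` is converted to `T` with a warning.
#' Ambiguity codes other than `N` are rejected with the offending record and
#' position named, so downstream design code never sees them.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by the FASTA headers
#'   (first whitespace-delimited token).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("FASTA file contains no records: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(raw))
  if (any(grepl("U", seqs, fixed = TRUE))) {
    warning("RNA-style 'U' bases converted to 'T' on ingest", call. = FALSE)
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
  }
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L)
      stop(sprintf("record '%s' has an empty sequence", ids[i]), call. = FALSE)
    bad <- regexpr("[^ACGTN]", seqs[i])
    if (bad > 0L)
      stop(sprintf("record '%s' has invalid character '%s' at position %d",
                   ids[i], substr(seqs[i], bad, bad), bad), call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    nm <- names(seqs)
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
    names(seqs) <- if (is.null(nm)) paste0("seq", seq_along(seqs)) else nm
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick complement, reversed; `N` maps to `N`. An involution:
#' `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param seq A single character string, [Biostrings::DNAString], or
#'   [Biostrings::DNAStringSet].
#' @return Same type as the input.
#' @examples
#' reverse_complement("ACCGG")  # "CCGGT"
#' @export
reverse_complement <- function(seq) {
  if (inherits(seq, "XString") || inherits(seq, "XStringSet"))
    return(Biostrings::reverseComplement(seq))
  bases <- .as_bases(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(bases)))
}

#' Promoter record: a sequence with a TSS anchor and gene orientation
#'
#' The coordinate frame for all distance computations. Positions are 1-based;
#' `tss_pos` is the position of the +1 (first transcribed) base. Human-facing
#' reports use the convention that the first base upstream of the TSS is -1
#' (there is no position 0).
#'
#' @param seq Promoter sequence (character or DNAString); uppercased on ingest.
#' @param tss_pos 1-based position of the +1 base within `seq`.
#' @param gene_strand `"forward"` if the gene reads left-to-right on `seq`,
#'   `"reverse"` otherwise.
#' @param id Identifier for the record.
#' @return An object of class `promoter_record` with elements `seq`, `tss_pos`,
#'   `gene_strand`, `id`.
#' @export
promoter_record <- function(seq, tss_pos, gene_strand = c("forward", "reverse"),
                            id = "promoter") {
  bases <- .as_bases(seq, "promoter sequence")
  gene_strand <- match.arg(gene_strand)
  tss_pos <- as.integer(tss_pos)
  if (is.na(tss_pos) || tss_pos < 1L || tss_pos > nchar(bases))
    stop("tss_pos must lie within the sequence (1..", nchar(bases), ")",
         call. = FALSE)
  structure(list(seq = bases, tss_pos = tss_pos, gene_strand = gene_strand,
                 id = as.character(id)),
            class = "promoter_record")
}

#' @export
print.promoter_record <- function(x, ...) {
  cat(sprintf("<promoter_record> %s: %d nt, TSS at %d, gene on %s strand\n",
              x$id, nchar(x$seq), x$tss_pos, x$gene_strand))
  invisible(x)
}

#' Read a side-car TSS annotation table
#'
#' Tab-delimited, no header, three columns: record id, 1-based TSS position,
#' gene strand (`forward`/`reverse` or `+`/`-`).
#'
#' @param path Path to the annotation file.
#' @return A data.frame with columns `id`, `tss_pos`, `gene_strand`.
#' @export
read_tss_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("id", "tss_pos", "gene_strand"))
  tab$tss_pos <- as.integer(tab$tss_pos)
  tab$gene_strand <- ifelse(tab$gene_strand %in% c("+", "forward"),
                            "forward", "reverse")
  tab
}

#' Write target sites as BED6
#'
#' Each site becomes one BED6 line covering the protospacer+PAM interval
#' (0-based half-open on disk, handled by [rtracklayer::export]). The score
#' column is the window score scaled to 0-1000; the strand column is the
#' strand carrying protospacer+PAM.
#'
#' @param sites A site table as returned by [find_pam_sites()] or
#'   [rank_sites()].
#' @param promoter The [promoter_record()] the sites refer to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, promoter, path) {
  stopifnot(inherits(promoter, "promoter_record"))
  if (nrow(sites) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (any(sites$start < 1L) || any(sites$end > nchar(promoter$seq)))
    stop("site interval outside promoter sequence bounds", call. = FALSE)
  score <- if ("window_score" %in% names(sites)) sites$window_score else 0
  gr <- GenomicRanges::GRanges(
    seqnames = promoter$id,
    ranges = IRanges::IRanges(start = sites$start, end = sites$end),
    strand = sites$site_strand,
    name = .site_label(sites),
    score = as.integer(round(score * 1000)))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# Site labels report position in the signed TSS-relative convention:
# upstream distances print as negative positions (-85), downstream as +n.
.site_label <- function(sites) {
  pos <- ifelse(sites$tss_distance >= 0,
                paste0("-", sites$tss_distance),
                paste0("+", -sites$tss_distance))
  paste0("site", pos, "_", sites$strand_class)
}
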