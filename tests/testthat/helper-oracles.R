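# Independent oracles used across the suite. These deliberately take the
# dumbest possible route (exhaustive enumeration, run-length encoding, set
# intersection) so they share no code path with the implementation.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

# Brute-force scanner: slide a 23-nt window over the sequence; a window
# whose last two bases are GG is a + site, a window whose reverse
# complement ends in GG is a - site. The >= 20 nt 5' context requirement
# falls out of the window fitting.
brute_force_sites <- function(seq) {
  L <- nchar(seq)
  out <- list()
  if (L >= 23L) {
    for (s in 1:(L - 22L)) {
      w <- substr(seq, s, s + 22L)
      if (substr(w, 22L, 23L) == "GG")
        out[[length(out) + 1L]] <- data.frame(
          protospacer = substr(w, 1L, 20L), pam = substr(w, 21L, 23L),
          start = s, end = s + 22L, site_strand = "+",
          stringsAsFactors = FALSE)
      wrc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
      if (substr(wrc, 22L, 23L) == "GG")
        out[[length(out) + 1L]] <- data.frame(
          protospacer = substr(wrc, 1L, 20L), pam = substr(wrc, 21L, 23L),
          start = s, end = s + 22L, site_strand = "-",
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(protospacer = character(), pam = character(),
                      start = integer(), end = integer(),
                      site_strand = character()))
  do.call(rbind, out)
}

# Canonical key for comparing site sets regardless of ordering.
site_key <- function(sites) {
  sort(paste(sites$start, sites$end, sites$site_strand, sites$protospacer,
             sites$pam, sep = "|"))
}

# Run-length-encoding homopolymer oracle.
rle_has_long_run <- function(seq, max_run = 3L) {
  r <- rle(strsplit(seq, "")[[1]])
  any(r$lengths > max_run)
}

# Exhaustive-substring TF-site oracle: enumerate every substring of the
# site's length on both strands and test set membership.
substring_tf_hit <- function(seq, site) {
  n <- nchar(site)
  if (n > nchar(seq)) return(FALSE)
  subs <- substring(seq, 1:(nchar(seq) - n + 1L), n:nchar(seq))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  subs_rc <- substring(rc, 1:(nchar(rc) - n + 1L), n:nchar(rc))
  site %in% c(subs, subs_rc)
}

# k-mer set-intersection homology oracle.
kmer_sets_intersect <- function(query, genome, k) {
  km <- function(s) if (nchar(s) < k) character() else
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  grc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome)))
  length(intersect(km(query), union(km(genome), km(grc)))) > 0L
}
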