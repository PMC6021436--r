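# Generation of PAM-periodic synthetic promoter arrays: candidates built
# from a repeating base unit, screened through homopolymer, TF-binding-site
# and genome-homology filters, with a deterministic "first passing
# candidate" selection and fragment extraction.

#' Design parameters for a PAM tiling array
#'
#' The defaults reproduce the published generation scale: 10,000 candidate
#' sequences of 500 nt built from the base unit 5'-NNNCCNNNGG-3' (an NGG PAM
#' every 10 nt on each strand), with random N bases tuned so the expected
#' whole-sequence GC fraction matches the E. coli genomic GC content
#' (0.508), candidates with homopolymer runs of four or more discarded, and
#' a 170 bp fragment extracted from the chosen array.
#'
#' @param base_unit Repeat unit; non-N characters are fixed, each `N` is
#'   drawn at random.
#' @param candidate_length Length of each candidate in nt; truncated to a
#'   multiple of the base-unit length with a warning if necessary.
#' @param n_candidates Number of candidates to generate and screen.
#' @param gc_target Target whole-sequence GC fraction in (0, 1). Because the
#'   base unit fixes 4 G/C bases per 10 nt, targets at or below 0.4 are
#'   infeasible for the default unit.
#' @param max_homopolymer_run Longest allowed run of one base (runs longer
#'   than this are rejected).
#' @param fragment_length Length of the fragment extracted from the chosen
#'   array; defaults to 170 nt, capped at `candidate_length`.
#' @param rng_seed Integer seed; `(seed, params)` fully determine the design.
#' @param kmer_k k-mer size for the genome homology screen.
#' @return An object of class `design_params`.
#' @export
design_params <- function(base_unit = "NNNCCNNNGG",
                          candidate_length = 500L,
                          n_candidates = 10000L,
                          gc_target = 0.508,
                          max_homopolymer_run = 3L,
                          fragment_length = NULL,
                          rng_seed = 1L,
                          kmer_k = 15L) {
  base_unit <- toupper(base_unit)
  if (grepl("[^ACGTN]", base_unit))
    stop("base_unit may contain only A, C, G, T, N", call. = FALSE)
  unit_len <- nchar(base_unit)
  candidate_length <- as.integer(candidate_length)
  if (candidate_length < unit_len)
    stop("candidate_length shorter than the base unit", call. = FALSE)
  if (candidate_length %% unit_len != 0L) {
    new_len <- (candidate_length %/% unit_len) * unit_len
    warning(sprintf("candidate_length %d truncated to %d (multiple of unit length %d)",
                    candidate_length, new_len, unit_len), call. = FALSE)
    candidate_length <- new_len
  }
  if (gc_target <= 0 || gc_target >= 1)
    stop("gc_target must lie in (0, 1)", call. = FALSE)
  fragment_length <- if (is.null(fragment_length))
    min(170L, candidate_length) else as.integer(fragment_length)
  if (fragment_length < 1L || fragment_length > candidate_length)
    stop("fragment_length must lie in 1..candidate_length", call. = FALSE)
  p <- .n_gc_prob(base_unit, gc_target)  # validates feasibility
  structure(list(base_unit = base_unit, candidate_length = candidate_length,
                 n_candidates = as.integer(n_candidates),
                 gc_target = gc_target, n_gc_prob = p,
                 max_homopolymer_run = as.integer(max_homopolymer_run),
                 fragment_length = fragment_length,
                 rng_seed = as.integer(rng_seed),
                 kmer_k = as.integer(kmer_k)),
            class = "design_params")
}

# Per-N probability of drawing G or C so that the expected whole-sequence GC
# fraction equals gc_target, given the fixed G/C bases of the unit:
#   (n_fixed_gc + n_N * p) / unit_len = gc_target
# For the default unit (4 fixed G/C in 10 nt): p = (10 * gc_target - 4) / 6.
.n_gc_prob <- function(base_unit, gc_target) {
  chars <- strsplit(base_unit, "")[[1]]
  n_fixed_gc <- sum(chars %in% c("G", "C"))
  n_N <- sum(chars == "N")
  if (n_N == 0L) stop("base_unit has no N positions to sample", call. = FALSE)
  p <- (nchar(base_unit) * gc_target - n_fixed_gc) / n_N
  if (p < 0)
    stop(sprintf(paste0("gc_target %.3f is below the floor imposed by the %d ",
                        "fixed G/C bases per %d-nt unit (minimum %.3f)"),
                 gc_target, n_fixed_gc, nchar(base_unit),
                 n_fixed_gc / nchar(base_unit)), call. = FALSE)
  if (p > 1)
    stop("gc_target requires per-N G/C probability > 1; infeasible", call. = FALSE)
  p
}

# Draw one candidate from the current RNG stream (no reseeding): repeats of
# the base unit with fixed positions preserved and each N independent, with
# P(G) = P(C) = p/2 and P(A) = P(T) = (1-p)/2.
.draw_candidate <- function(params) {
  unit <- strsplit(params$base_unit, "")[[1]]
  n_rep <- params$candidate_length %/% length(unit)
  template <- rep(unit, n_rep)
  n_idx <- which(template == "N")
  p <- params$n_gc_prob
  template[n_idx] <- sample(c("G", "C", "A", "T"), length(n_idx),
                            replace = TRUE,
                            prob = c(p / 2, p / 2, (1 - p) / 2, (1 - p) / 2))
  paste(template, collapse = "")
}

#' Generate one base-unit-periodic candidate sequence
#'
#' Fills every repeat of the base unit, preserving its fixed C/G positions
#' and drawing each `N` independently with G/C probability chosen so the
#' expected whole-sequence GC fraction equals `gc_target`. Deterministic
#' given `params$rng_seed`.
#'
#' @param params A [design_params()].
#' @param seed Optional seed overriding `params$rng_seed`.
#' @return A single character string of length `params$candidate_length`.
#' @export
fill_base_units <- function(params, seed = params$rng_seed) {
  stopifnot(inherits(params, "design_params"))
  set.seed(seed)
  .draw_candidate(params)
}

#' Generate a stream of candidate arrays from one seeded RNG stream
#'
#' Candidate i is the i-th draw from the stream seeded with
#' `params$rng_seed` — the same stream [design_array()] screens, so the
#' n-th candidate here is byte-identical to the n-th candidate considered
#' there.
#'
#' @param params A [design_params()].
#' @param n Number of candidates (defaults to `params$n_candidates`).
#' @return Character vector of `n` sequences.
#' @export
generate_candidates <- function(params, n = params$n_candidates) {
  stopifnot(inherits(params, "design_params"))
  set.seed(params$rng_seed)
  vapply(seq_len(n), function(i) .draw_candidate(params), character(1))
}

#' Homopolymer run filter
#'
#' Fails any sequence containing a run of four or more (by default)
#' consecutive identical nucleotides, reporting the first offending
#' interval.
#'
#' @param seq Character sequence.
#' @param max_run Longest allowed run (default 3; runs >= 4 fail).
#' @return A list with `pass` (logical) and, on failure, `interval`
#'   (`c(start, end)`, 1-based inclusive) and `base` of the first offending
#'   run.
#' @export
homopolymer_filter <- function(seq, max_run = 3L) {
  bases <- .as_bases(seq)
  pat <- sprintf("([ACGTN])\\1{%d,}", max_run)
  m <- regexpr(pat, bases, perl = TRUE)
  if (m < 0L) return(list(pass = TRUE))
  list(pass = FALSE,
       interval = c(as.integer(m), as.integer(m) + attr(m, "match.length") - 1L),
       base = substr(bases, m, m))
}

#' Read a transcription-factor binding-site list
#'
#' Tab-delimited, no header, two columns: site id, site sequence
#' (RegulonDB-style flat export). Non-nucleotide characters in a site
#' sequence raise an error naming the site id.
#'
#' @param path Path to the file.
#' @return A data.frame with columns `site_id`, `site_seq`.
#' @export
read_tf_sites <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("site_id", "site_seq"))
  tab$site_seq <- toupper(tab$site_seq)
  bad <- grepl("[^ACGTN]", tab$site_seq)
  if (any(bad))
    stop("non-nucleotide characters in TF site '", tab$site_id[which(bad)[1]],
         "'", call. = FALSE)
  tab
}

#' Transcription-factor binding-site exclusion filter
#'
#' Fails if any listed site sequence occurs as an exact substring of the
#' candidate or of its reverse complement; all matched site ids are
#' reported. Sites longer than the candidate cannot match.
#'
#' @param seq Character sequence.
#' @param site_list A data.frame from [read_tf_sites()], or a path to such a
#'   file.
#' @return A list with `pass` and `matched_ids` (character vector, empty on
#'   pass).
#' @export
tf_site_filter <- function(seq, site_list) {
  bases <- .as_bases(seq)
  if (is.character(site_list) && length(site_list) == 1L &&
      file.exists(site_list))
    site_list <- read_tf_sites(site_list)
  if (nrow(site_list) == 0L) return(list(pass = TRUE, matched_ids = character()))
  rc <- reverse_complement(bases)
  hit <- vapply(site_list$site_seq, function(s)
    grepl(s, bases, fixed = TRUE) || grepl(s, rc, fixed = TRUE),
    logical(1), USE.NAMES = FALSE)
  list(pass = !any(hit), matched_ids = site_list$site_id[hit])
}

# All k-mers of a string as a character vector (positions 1..L-k+1).
.kmers <- function(bases, k) {
  L <- nchar(bases)
  if (k > L) return(character())
  substring(bases, 1:(L - k + 1L), k:L)
}

#' Genome homology screen by exact shared k-mers
#'
#' Fails if the candidate shares any exact k-mer (default k = 15) with the
#' genome on either strand. The count of query k-mer positions matching the
#' genome and the first shared k-mer are reported. This is a deterministic
#' exact-match screen for "no detectable homology"-style checks.
#'
#' @param seq Character sequence (the query).
#' @param genome Genome sequence(s): character vector, DNAStringSet, or a
#'   path to a FASTA file.
#' @param k k-mer size; must not exceed the query length.
#' @return A list with `pass`, `shared_count` and `first_shared` (NA on
#'   pass).
#' @export
genome_homology_filter <- function(seq, genome, k = 15L) {
  bases <- .as_bases(seq)
  k <- as.integer(k)
  if (k > nchar(bases))
    stop("k exceeds the query length", call. = FALSE)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  if (inherits(genome, "XStringSet")) genome <- as.character(genome)
  genome <- toupper(genome)
  genome_kmers <- unlist(lapply(genome, function(g)
    c(.kmers(g, k), .kmers(reverse_complement(g), k))), use.names = FALSE)
  qk <- .kmers(bases, k)
  shared <- qk %in% genome_kmers
  if (!any(shared))
    return(list(pass = TRUE, shared_count = 0L, first_shared = NA_character_))
  list(pass = FALSE, shared_count = sum(shared),
       first_shared = qk[which(shared)[1]])
}

#' Generate and screen a PAM tiling array
#'
#' Draws seeded candidates in order and applies the constraint filters in a
#' fixed order (homopolymer, then TF binding sites, then genome homology);
#' returns the first candidate passing all applicable filters together with
#' an attrition summary. The published procedure's "arbitrarily chose one"
#' step is made reproducible as first-passing-index under the seed. The
#' promoter-proximal fragment is extracted with [select_fragment()].
#'
#' @param params A [design_params()].
#' @param tf_sites Optional TF site list (data.frame or path); when `NULL`
#'   the TF filter is skipped.
#' @param genome Optional genome (sequence(s) or FASTA path) for the
#'   homology screen; when `NULL` the screen is skipped.
#' @param placement Fragment placement passed to [select_fragment()].
#' @return An object of class `tiling_design`: `seq` (the chosen array),
#'   `fragment`, `params`, `seed_used`, `candidate_index`,
#'   `filters_passed` (named logical), and `attrition` (candidates rejected
#'   per filter).
#' @export
design_array <- function(params, tf_sites = NULL, genome = NULL,
                         placement = "three_prime") {
  stopifnot(inherits(params, "design_params"))
  if (is.character(tf_sites) && length(tf_sites) == 1L)
    tf_sites <- read_tf_sites(tf_sites)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  attrition <- c(homopolymer = 0L, tf_sites = 0L, genome_homology = 0L)
  set.seed(params$rng_seed)
  for (i in seq_len(params$n_candidates)) {
    cand <- .draw_candidate(params)
    if (!homopolymer_filter(cand, params$max_homopolymer_run)$pass) {
      attrition["homopolymer"] <- attrition["homopolymer"] + 1L
      next
    }
    if (!is.null(tf_sites) && !tf_site_filter(cand, tf_sites)$pass) {
      attrition["tf_sites"] <- attrition["tf_sites"] + 1L
      next
    }
    if (!is.null(genome) &&
        !genome_homology_filter(cand, genome, params$kmer_k)$pass) {
      attrition["genome_homology"] <- attrition["genome_homology"] + 1L
      next
    }
    design <- structure(list(
      seq = cand,
      params = params,
      seed_used = params$rng_seed,
      candidate_index = i,
      filters_passed = c(homopolymer = TRUE,
                         tf_sites = if (is.null(tf_sites)) NA else TRUE,
                         genome_homology = if (is.null(genome)) NA else TRUE),
      attrition = attrition,
      fragment = NULL, fragment_placement = NULL),
      class = "tiling_design")
    design$fragment <- select_fragment(design, params$fragment_length,
                                       placement)
    design$fragment_placement <- placement
    return(design)
  }
  stop("all ", params$n_candidates, " candidates rejected; attrition: ",
       paste(names(attrition), attrition, sep = "=", collapse = ", "),
       call. = FALSE)
}

#' @export
print.tiling_design <- function(x, ...) {
  cat(sprintf("<tiling_design> %d nt array (candidate %d, seed %d)\n",
              nchar(x$seq), x$candidate_index, x$seed_used))
  cat(sprintf("  fragment: %d nt (%s)\n",
              if (is.null(x$fragment)) 0L else nchar(x$fragment),
              if (is.null(x$fragment_placement)) "none" else x$fragment_placement))
  cat("  attrition:", paste(names(x$attrition), x$attrition, sep = "=",
                            collapse = ", "), "\n")
  invisible(x)
}

#' Extract a fragment from a designed array
#'
#' Default placement is `"three_prime"` — the promoter-proximal end when the
#' array sits upstream of a minimal promoter, matching the published use of
#' a 170 bp fragment placed upstream of a weak constitutive promoter.
#'
#' @param design A `tiling_design` (or a plain character sequence).
#' @param fragment_length Fragment length in nt.
#' @param placement `"three_prime"`, `"five_prime"`, or a 1-based integer
#'   offset of the fragment start.
#' @return The fragment as a character string.
#' @export
select_fragment <- function(design, fragment_length,
                            placement = "three_prime") {
  seq <- if (inherits(design, "tiling_design")) design$seq else .as_bases(design)
  L <- nchar(seq)
  fragment_length <- as.integer(fragment_length)
  if (fragment_length > L)
    stop("fragment_length exceeds the design length", call. = FALSE)
  start <- if (identical(placement, "three_prime")) {
    L - fragment_length + 1L
  } else if (identical(placement, "five_prime")) {
    1L
  } else if (is.numeric(placement)) {
    off <- as.integer(placement)
    if (off < 1L || off + fragment_length - 1L > L)
      stop("fragment offset out of bounds", call. = FALSE)
    off
  } else stop("placement must be 'three_prime', 'five_prime', or an offset",
              call. = FALSE)
  substr(seq, start, start + fragment_length - 1L)
}
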