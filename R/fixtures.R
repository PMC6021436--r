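# Deterministic generators of synthetic test inputs: toy promoters with
# planted target sites at known TSS distances, toy genomes with optionally
# planted k-mers, and toy TF binding-site lists. Every other module is
# testable against these with no external data.

#' Specification for a synthetic promoter fixture
#'
#' @param rng_seed Integer seed; fixtures are byte-reproducible from
#'   `(seed, spec)`.
#' @param promoter_length Total promoter length in nt.
#' @param tss_offset 1-based position of the +1 base.
#' @param planted_sites data.frame with columns `distance` (bases upstream
#'   of the TSS where the anchor base must land) and `strand_class`
#'   (`"non-template"` or `"template"`). Sites must not overlap and must
#'   fit within the promoter.
#' @param decoy_density GC weight of the unconstrained background
#'   downstream of the TSS.
#' @param tf_decoys Number of decoy TF binding sites for
#'   [make_tf_site_list()].
#' @param genome_length Length of the toy genome for [make_toy_genome()].
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(rng_seed = 1L, promoter_length = 200L,
                         tss_offset = 150L,
                         planted_sites = data.frame(distance = integer(),
                                                    strand_class = character()),
                         decoy_density = 0.5, tf_decoys = 5L,
                         genome_length = 2000L) {
  planted_sites <- as.data.frame(planted_sites)
  if (nrow(planted_sites) &&
      !all(planted_sites$strand_class %in% c("non-template", "template")))
    stop("strand_class must be 'non-template' or 'template'", call. = FALSE)
  structure(list(rng_seed = as.integer(rng_seed),
                 promoter_length = as.integer(promoter_length),
                 tss_offset = as.integer(tss_offset),
                 planted_sites = planted_sites,
                 decoy_density = decoy_density,
                 tf_decoys = as.integer(tf_decoys),
                 genome_length = as.integer(genome_length)),
            class = "fixture_spec")
}

# Offset of the anchor base from the protospacer+PAM interval start,
# inverse of the scanner's anchor arithmetic.
.anchor_offset <- function(site_strand, anchor) {
  if (site_strand == "+") {
    switch(anchor, pam_proximal_end = 19L, pam_distal_end = 0L,
           protospacer_center = 9L, pam_start = 20L)
  } else {
    switch(anchor, pam_proximal_end = 3L, pam_distal_end = 22L,
           protospacer_center = 13L, pam_start = 2L)
  }
}

# Random DNA with no adjacent identical G/C pair (kills every NGG/CCN PAM),
# respecting already-fixed neighbors. Used for the scanned upstream window.
.sample_pam_free <- function(chars, idx) {
  for (i in idx) {
    banned <- character()
    if (i > 1L && !is.na(chars[i - 1L]) && chars[i - 1L] %in% c("G", "C"))
      banned <- c(banned, chars[i - 1L])
    if (i < length(chars) && !is.na(chars[i + 1L]) &&
        chars[i + 1L] %in% c("G", "C"))
      banned <- c(banned, chars[i + 1L])
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), banned), 1L)
  }
  chars
}

#' Build a toy promoter with target sites planted at known TSS distances
#'
#' The upstream window (and a 2-nt margin past the TSS) is sampled free of
#' unintended PAMs on both strands — no two adjacent identical G/C bases,
#' so no NGG can arise outside the planted sites — while the region
#' downstream of the margin is unconstrained random sequence. Each planted
#' site's protospacer+PAM is inserted so that the configured anchor base
#' lands exactly at the requested distance upstream of the TSS on the
#' requested strand class (gene on the forward strand). The returned ground
#' truth is the oracle for scanner tests: within the upstream window the
#' scanner must recover exactly these sites.
#'
#' @param spec A [fixture_spec()].
#' @param anchor Distance anchor convention, as in [find_pam_sites()].
#' @return A list with `promoter` (a [promoter_record()]) and `truth` (a
#'   data.frame with the planted sites' `protospacer`, `pam`, `start`,
#'   `end`, `site_strand`, `strand_class`, `tss_distance`).
#' @export
make_promoter_with_sites <- function(spec,
                                     anchor = c("pam_proximal_end",
                                                "pam_distal_end",
                                                "protospacer_center",
                                                "pam_start")) {
  stopifnot(inherits(spec, "fixture_spec"))
  anchor <- match.arg(anchor)
  set.seed(spec$rng_seed)
  L <- spec$promoter_length
  tss <- spec$tss_offset
  chars <- rep(NA_character_, L)
  truth <- list()

  sites <- spec$planted_sites
  for (r in seq_len(nrow(sites))) {
    d <- as.integer(sites$distance[r])
    cls <- sites$strand_class[r]
    site_strand <- if (cls == "non-template") "+" else "-"
    ap <- tss - d                       # anchor base position, forward gene
    start <- ap - .anchor_offset(site_strand, anchor)
    end <- start + 22L
    if (start < 1L || end > L)
      stop(sprintf("planted site at distance %d does not fit in the promoter",
                   d), call. = FALSE)
    if (any(!is.na(chars[start:end])))
      stop("planted sites collide", call. = FALSE)
    # protospacer free of adjacent G/C pairs so it cannot spawn extra PAMs
    proto <- paste(.sample_pam_free(rep(NA_character_, 20L), 1:20),
                   collapse = "")
    if (site_strand == "+") {
      chars[start:(start + 19L)] <- strsplit(proto, "")[[1]]
      chars[(start + 20L):end] <- c("A", "G", "G")
      pam <- "AGG"
    } else {
      chars[start:(start + 2L)] <- c("C", "C", "T")  # "AGG" on the - strand
      chars[(start + 3L):end] <- strsplit(reverse_complement(proto), "")[[1]]
      pam <- "AGG"
    }
    truth[[r]] <- data.frame(protospacer = proto, pam = pam,
                             start = start, end = end,
                             site_strand = site_strand, strand_class = cls,
                             tss_distance = d, stringsAsFactors = FALSE)
  }

  window_end <- min(L, tss + 2L)
  bg_window <- which(is.na(chars[1:window_end]))
  chars <- .sample_pam_free(chars, bg_window)
  bg_down <- which(is.na(chars))
  if (length(bg_down)) {
    p <- spec$decoy_density
    chars[bg_down] <- sample(c("G", "C", "A", "T"), length(bg_down),
                             replace = TRUE,
                             prob = c(p / 2, p / 2, (1 - p) / 2, (1 - p) / 2))
  }
  promoter <- promoter_record(paste(chars, collapse = ""), tss,
                              gene_strand = "forward",
                              id = sprintf("toy_promoter_seed%d", spec$rng_seed))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(protospacer = character(), pam = character(),
               start = integer(), end = integer(), site_strand = character(),
               strand_class = character(), tss_distance = integer())
  truth <- truth[order(truth$tss_distance), , drop = FALSE]
  rownames(truth) <- NULL
  list(promoter = promoter, truth = truth)
}

#' Generate a toy genome, optionally with one planted k-mer
#'
#' @param spec A [fixture_spec()].
#' @param embed Optional k-mer to plant at a recorded offset (mid-genome).
#' @return A character string with attribute `embed_offset` (1-based start
#'   of the planted k-mer, or `NA`).
#' @export
make_toy_genome <- function(spec, embed = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$rng_seed + 1L)
  g <- paste(sample(c("A", "C", "G", "T"), spec$genome_length,
                    replace = TRUE), collapse = "")
  offset <- NA_integer_
  if (!is.null(embed)) {
    embed <- .as_bases(embed, "embedded k-mer")
    if (nchar(embed) > spec$genome_length)
      stop("embedded k-mer longer than the genome", call. = FALSE)
    offset <- as.integer((spec$genome_length - nchar(embed)) %/% 2L) + 1L
    substr(g, offset, offset + nchar(embed) - 1L) <- embed
  }
  attr(g, "embed_offset") <- offset
  g
}

#' Generate a toy TF binding-site list
#'
#' Decoy sites are guaranteed absent (both strands) from `include_from`
#' when given; with `positive_control = TRUE` one site is copied verbatim
#' from `include_from` so the exclusion filter must fire.
#'
#' @param spec A [fixture_spec()].
#' @param include_from Optional sequence the decoys must avoid / the
#'   positive control is copied from.
#' @param positive_control Add one site copied from `include_from`.
#' @param site_length Length of each site (default 12).
#' @param path Optional output path; when given the list is also written
#'   tab-delimited (readable by [read_tf_sites()]).
#' @return data.frame with columns `site_id`, `site_seq`.
#' @export
make_tf_site_list <- function(spec, include_from = NULL,
                              positive_control = FALSE,
                              site_length = 12L, path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (positive_control && is.null(include_from))
    stop("positive_control requires include_from", call. = FALSE)
  set.seed(spec$rng_seed + 2L)
  target <- if (is.null(include_from)) NULL else .as_bases(include_from)
  target_rc <- if (is.null(target)) NULL else reverse_complement(target)
  decoys <- character()
  while (length(decoys) < spec$tf_decoys) {
    s <- paste(sample(c("A", "C", "G", "T"), site_length, replace = TRUE),
               collapse = "")
    if (!is.null(target) &&
        (grepl(s, target, fixed = TRUE) || grepl(s, target_rc, fixed = TRUE)))
      next
    decoys <- c(decoys, s)
  }
  out <- data.frame(site_id = sprintf("decoy%02d", seq_along(decoys)),
                    site_seq = decoys, stringsAsFactors = FALSE)
  if (positive_control) {
    start <- sample.int(nchar(target) - site_length + 1L, 1L)
    out <- rbind(out, data.frame(
      site_id = "positive_control",
      site_seq = substr(target, start, start + site_length - 1L)))
  }
  if (!is.null(path)) write_tf_sites(out, path)
  out
}

#' Write a TF binding-site list
#'
#' Tab-delimited, no header: site id, site sequence — the dialect
#' [read_tf_sites()] reads.
#'
#' @param sites data.frame with `site_id`, `site_seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tf_sites <- function(sites, path) {
  utils::write.table(sites[, c("site_id", "site_seq")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
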