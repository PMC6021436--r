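# SpCas9 NGG target-site enumeration around a promoter, TSS distance and
# strand classification, and scoring against empirically determined
# activation windows.

PROTOSPACER_LEN <- 20L
PAM_LEN <- 3L

#' Construct a TSS-distance window model
#'
#' A window model holds, per strand class, a set of non-overlapping distance
#' bands (in bases upstream of the TSS, positive numbers corresponding to the
#' usual negative-position convention: the band 80-90 covers positions -80 to
#' -90). A site whose TSS distance falls in a band receives that band's score;
#' sites outside all bands, and all sites downstream of the TSS, score 0.
#'
#' The default bands place full weight on the empirically effective CRISPRa
#' region: 80-90 bases upstream on the non-template strand and 50-80 bases
#' upstream on the template strand. Note that a narrower template-strand
#' range (60-80) is also reported in the literature; the model is data, so
#' users can recalibrate (see [read_window_model()]).
#'
#' @param non_template,template Data frames (or lists coercible to data
#'   frames) with columns `lo`, `hi`, `score`: inclusive distance bounds in
#'   bases upstream of the TSS and a score in \[0, 1\].
#' @return An object of class `window_model`.
#' @examples
#' default_window_model()
#' @export
window_model <- function(non_template, template) {
  bands <- list(non_template = as.data.frame(non_template),
                template = as.data.frame(template))
  for (cls in names(bands)) {
    b <- bands[[cls]]
    if (nrow(b) == 0L) next
    if (!all(c("lo", "hi", "score") %in% names(b)))
      stop("window bands need columns lo, hi, score", call. = FALSE)
    if (any(b$lo > b$hi))
      stop("window band with lo > hi in ", cls, " strand class", call. = FALSE)
    if (any(b$score < 0 | b$score > 1))
      stop("window scores must lie in [0, 1]", call. = FALSE)
    b <- b[order(b$lo), , drop = FALSE]
    if (nrow(b) > 1L && any(b$lo[-1L] <= b$hi[-nrow(b)]))
      stop("overlapping windows in ", cls, " strand class", call. = FALSE)
    bands[[cls]] <- b
  }
  structure(bands, class = "window_model")
}

#' @rdname window_model
#' @export
default_window_model <- function() {
  window_model(
    non_template = data.frame(lo = 80, hi = 90, score = 1),
    template     = data.frame(lo = 50, hi = 80, score = 1))
}

#' Read a window model from a YAML config
#'
#' Expected layout: top-level keys `non_template` and `template`, each a list
#' of bands with fields `lo`, `hi`, `score`. Malformed models (overlapping
#' bands, scores outside \[0,1\]) are rejected at load.
#'
#' @param path Path to the YAML file.
#' @return A `window_model`.
#' @export
read_window_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  to_df <- function(x) {
    if (is.null(x) || length(x) == 0L)
      return(data.frame(lo = numeric(), hi = numeric(), score = numeric()))
    do.call(rbind, lapply(x, function(b)
      data.frame(lo = b$lo, hi = b$hi, score = b$score)))
  }
  window_model(non_template = to_df(cfg$non_template),
               template = to_df(cfg$template))
}

#' @export
print.window_model <- function(x, ...) {
  cat("<window_model> bands (bases upstream of TSS):\n")
  for (cls in names(x)) {
    b <- x[[cls]]
    if (nrow(b) == 0L) { cat(" ", cls, ": none\n"); next }
    cat(sprintf("  %s: %s\n", cls,
                paste(sprintf("%g-%g -> %g", b$lo, b$hi, b$score),
                      collapse = ", ")))
  }
  invisible(x)
}

# Anchor position (1-based, promoter coordinates) of a site, per convention.
# For a + site the protospacer occupies [start, start+19] and the PAM
# [start+20, start+22]; for a - site the PAM occupies [start, start+2]
# (reading CCN on the + strand) and the protospacer [start+3, start+22].
.anchor_pos <- function(start, site_strand, anchor) {
  if (site_strand == "+") {
    switch(anchor,
           pam_proximal_end   = start + 19L,
           pam_distal_end     = start,
           protospacer_center = start + 9L,
           pam_start          = start + 20L)
  } else {
    switch(anchor,
           pam_proximal_end   = start + 3L,
           pam_distal_end     = start + 22L,
           protospacer_center = start + 13L,
           pam_start          = start + 2L)
  }
}

# Signed TSS distance of an anchor base: positive = bases upstream of the
# TSS with respect to gene_strand; downstream sites get negative values in
# +1-based downstream numbering (the TSS base itself is downstream +1).
.tss_distance_at <- function(pos, promoter) {
  t <- promoter$tss_pos
  if (promoter$gene_strand == "forward") {
    if (pos < t) t - pos else -(pos - t + 1L)
  } else {
    if (pos > t) pos - t else -(t - pos + 1L)
  }
}

#' Enumerate NGG target sites on both strands of a promoter
#'
#' Every NGG occurrence on either strand with at least 20 nt of sequence 5'
#' of the PAM (on that strand) yields one candidate site: 20-nt protospacer,
#' 3-nt PAM, the interval covered by protospacer+PAM, the strand carrying
#' them, the strand class relative to the gene (non-template if the
#' protospacer appears on the coding strand), and the TSS distance of the
#' configured anchor base. Overlapping sites are all reported. Sites are
#' sorted by TSS distance ascending, ties broken + strand first.
#'
#' @param promoter A [promoter_record()].
#' @param region Optional `c(start, end)` (1-based, inclusive) restricting
#'   the scan: only sites whose protospacer+PAM interval lies within the
#'   region are returned.
#' @param anchor Which protospacer/PAM base defines the TSS distance:
#'   `"pam_proximal_end"` (default; the protospacer base adjacent to the
#'   PAM), `"pam_distal_end"`, `"protospacer_center"`, or `"pam_start"`.
#' @return A data.frame with one row per site: `protospacer`, `pam`,
#'   `start`, `end`, `site_strand`, `strand_class`, `tss_distance`,
#'   `downstream`. `tss_distance` is positive for upstream sites; downstream
#'   sites are flagged and carry a negative value.
#' @export
find_pam_sites <- function(promoter, region = NULL,
                           anchor = c("pam_proximal_end", "pam_distal_end",
                                      "protospacer_center", "pam_start")) {
  stopifnot(inherits(promoter, "promoter_record"))
  anchor <- match.arg(anchor)
  seq <- promoter$seq
  L <- nchar(seq)
  empty <- data.frame(protospacer = character(), pam = character(),
                      start = integer(), end = integer(),
                      site_strand = character(), strand_class = character(),
                      tss_distance = integer(), downstream = logical(),
                      stringsAsFactors = FALSE)
  if (L < PROTOSPACER_LEN + PAM_LEN) {
    warning("sequence shorter than 23 nt; no sites possible", call. = FALSE)
    return(empty)
  }
  if (!is.null(region)) {
    region <- as.integer(region)
    if (length(region) != 2L || region[1] < 1L || region[2] > L ||
        region[1] >= region[2])
      stop("region must be c(start, end) within the sequence", call. = FALSE)
  }

  # + strand: PAM is NGG, i.e. "GG" at the two positions after the N.
  gg <- gregexpr("(?=GG)", seq, perl = TRUE)[[1]]
  gg <- if (gg[1] == -1L) integer() else as.integer(gg)
  plus_pam_start <- gg - 1L                       # the N of NGG
  plus_pam_start <- plus_pam_start[plus_pam_start >= PROTOSPACER_LEN + 1L &
                                   plus_pam_start + 2L <= L]
  # - strand: NGG on the minus strand reads CCN on the plus strand.
  cc <- gregexpr("(?=CC)", seq, perl = TRUE)[[1]]
  cc <- if (cc[1] == -1L) integer() else as.integer(cc)
  minus_pam_start <- cc[cc + 2L + PROTOSPACER_LEN <= L & cc >= 1L]

  rows <- list()
  for (p in plus_pam_start) {
    start <- p - PROTOSPACER_LEN
    rows[[length(rows) + 1L]] <- list(
      protospacer = substr(seq, start, p - 1L),
      pam = substr(seq, p, p + 2L),
      start = start, end = p + 2L, site_strand = "+")
  }
  for (p in minus_pam_start) {
    proto_plus <- substr(seq, p + 3L, p + 22L)
    pam_plus <- substr(seq, p, p + 2L)
    rows[[length(rows) + 1L]] <- list(
      protospacer = reverse_complement(proto_plus),
      pam = reverse_complement(pam_plus),
      start = p, end = p + 22L, site_strand = "-")
  }
  if (length(rows) == 0L) return(empty)
  sites <- do.call(rbind, lapply(rows, as.data.frame))
  sites$start <- as.integer(sites$start)
  sites$end <- as.integer(sites$end)

  if (!is.null(region))
    sites <- sites[sites$start >= region[1] & sites$end <= region[2], ,
                   drop = FALSE]
  if (nrow(sites) == 0L) return(empty)

  sites$strand_class <- vapply(sites$site_strand, function(s)
    .classify(s, promoter$gene_strand), character(1), USE.NAMES = FALSE)
  sites$tss_distance <- mapply(function(st, ss)
    .tss_distance_at(.anchor_pos(st, ss, anchor), promoter),
    sites$start, sites$site_strand)
  sites$tss_distance <- as.integer(sites$tss_distance)
  sites$downstream <- sites$tss_distance < 0L

  ord <- order(sites$tss_distance, sites$site_strand != "+", sites$start)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

.classify <- function(site_strand, gene_strand) {
  same <- (site_strand == "+" && gene_strand == "forward") ||
          (site_strand == "-" && gene_strand == "reverse")
  if (same) "non-template" else "template"
}

#' Classify a target site's strand relative to the gene
#'
#' A site is on the non-template (coding) strand when the strand carrying
#' the protospacer+PAM equals the gene strand, i.e. the protospacer sequence
#' appears on the mRNA-identical strand; otherwise it is on the template
#' strand.
#'
#' @param site_strand `"+"` or `"-"`, or a site table row with a
#'   `site_strand` column.
#' @param promoter A [promoter_record()] (or `"forward"`/`"reverse"`).
#' @return `"non-template"` or `"template"` (vectorized over sites).
#' @export
classify_strand <- function(site_strand, promoter) {
  if (is.data.frame(site_strand)) site_strand <- site_strand$site_strand
  gene_strand <- if (inherits(promoter, "promoter_record"))
    promoter$gene_strand else match.arg(promoter, c("forward", "reverse"))
  vapply(site_strand, .classify, character(1), gene_strand = gene_strand,
         USE.NAMES = FALSE)
}

#' TSS distance of a target site under a configurable anchor
#'
#' Returns the count of bases between the anchor base and the +1 base as a
#' positive "bases upstream" value. Sites downstream of the TSS (with
#' respect to the gene strand) are reported as negative values using the
#' convention that the TSS base itself is downstream position 1; such sites
#' always receive window score 0.
#'
#' @param site One row of a site table from [find_pam_sites()] (or a list
#'   with `start` and `site_strand`).
#' @param promoter The [promoter_record()].
#' @param anchor See [find_pam_sites()].
#' @return Integer distance (positive upstream, negative downstream).
#' @export
distance_to_tss <- function(site, promoter,
                            anchor = c("pam_proximal_end", "pam_distal_end",
                                       "protospacer_center", "pam_start")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(promoter, "promoter_record"))
  pos <- .anchor_pos(as.integer(site$start), site$site_strand, anchor)
  .tss_distance_at(pos, promoter)
}

#' Score a site against a window model
#'
#' Returns the score of the band whose `[lo, hi]` contains the site's TSS
#' distance for its strand class, or 0 if no band contains it. Downstream
#' sites always score 0 (they may matter for CRISPRi, not for activation).
#'
#' @param site A site table (one or more rows) with `tss_distance` and
#'   `strand_class` columns.
#' @param model A [window_model()]; defaults to the empirical activation
#'   windows.
#' @return Numeric vector of scores in \[0, 1\], one per site row.
#' @export
score_window <- function(site, model = default_window_model()) {
  stopifnot(inherits(model, "window_model"))
  d <- site$tss_distance
  cls <- sub("-", "_", site$strand_class, fixed = TRUE)
  mapply(function(di, ci) {
    if (di < 0) return(0)
    b <- model[[ci]]
    hit <- which(b$lo <= di & di <= b$hi)
    if (length(hit)) b$score[hit[1]] else 0
  }, d, cls, USE.NAMES = FALSE)
}

#' Rank all target sites of a promoter by activation window score
#'
#' Composes site discovery, TSS distance, strand classification and window
#' scoring into one report, sorted by descending window score then ascending
#' TSS distance.
#'
#' @inheritParams find_pam_sites
#' @param model A [window_model()].
#' @return The site data.frame of [find_pam_sites()] with an added
#'   `window_score` column and a `label` column in the signed TSS-relative
#'   convention, re-sorted by (descending score, ascending distance).
#' @export
rank_sites <- function(promoter, model = default_window_model(),
                       region = NULL,
                       anchor = c("pam_proximal_end", "pam_distal_end",
                                  "protospacer_center", "pam_start")) {
  anchor <- match.arg(anchor)
  sites <- find_pam_sites(promoter, region = region, anchor = anchor)
  sites$window_score <- if (nrow(sites)) score_window(sites, model) else numeric()
  sites$label <- if (nrow(sites)) .site_label(sites) else character()
  ord <- order(-sites$window_score, sites$tss_distance, sites$site_strand != "+")
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  sites
}
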