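# Assembly and validation of guide RNA / scaffold RNA constructs for the
# scaffold dialects compared in bacterial CRISPRa work: plain gRNA, 3' MS2
# scaffold RNAs with and without the tracr terminator hairpin (b1/b2), a
# two-hairpin 2x MS2 design, a PP7-aptamer variant, and sgRNA 2.0 with
# internally embedded MS2 hairpins.

SPACER_PLACEHOLDER <- "[SPACER]"
SPACER_LEN <- 20L

#' Construct a scaffold template
#'
#' A template is an RNA-alphabet sequence containing exactly one
#' `"[SPACER]"` placeholder, plus hairpin annotations (label + 1-based
#' interval in template-string coordinates, counting the placeholder token
#' literally). The templates shipped with the package
#' (`synthetic_scaffold_stubs.yaml`) are synthetic structural stand-ins,
#' not published construct sequences; see [load_scaffold_templates()].
#'
#' @param name Variant name, e.g. `"scRNA.b1"`.
#' @param sequence Template string with one `"[SPACER]"` placeholder;
#'   RNA alphabet (A, C, G, U) outside the placeholder.
#' @param annotations data.frame with columns `label`, `start`, `end`.
#' @return An object of class `scaffold_template`.
#' @export
scaffold_template <- function(name, sequence, annotations = NULL) {
  sequence <- toupper(sequence)
  n_ph <- length(gregexpr(SPACER_PLACEHOLDER, sequence, fixed = TRUE)[[1]])
  if (!grepl(SPACER_PLACEHOLDER, sequence, fixed = TRUE) || n_ph != 1L)
    stop("template '", name, "' must contain exactly one ",
         SPACER_PLACEHOLDER, " placeholder", call. = FALSE)
  body <- gsub(SPACER_PLACEHOLDER, "", sequence, fixed = TRUE)
  if (grepl("[^ACGU]", body))
    stop("template '", name, "' contains non-RNA characters", call. = FALSE)
  if (is.null(annotations))
    annotations <- data.frame(label = character(), start = integer(),
                              end = integer(), stringsAsFactors = FALSE)
  annotations <- as.data.frame(annotations)
  ph_start <- regexpr(SPACER_PLACEHOLDER, sequence, fixed = TRUE)[1]
  ph_end <- ph_start + nchar(SPACER_PLACEHOLDER) - 1L
  if (nrow(annotations)) {
    if (any(annotations$start < 1L | annotations$end > nchar(sequence) |
            annotations$start > annotations$end))
      stop("annotation interval outside template '", name, "'", call. = FALSE)
    if (any(annotations$start <= ph_end & annotations$end >= ph_start))
      stop("annotation overlaps the spacer placeholder in '", name, "'",
           call. = FALSE)
  }
  structure(list(name = name, sequence = sequence, annotations = annotations,
                 placeholder_start = as.integer(ph_start)),
            class = "scaffold_template")
}

#' Load scaffold templates from a YAML config
#'
#' The packaged default config ships clearly-labelled synthetic stubs that
#' preserve the structural relationships between the variants (one-base
#' b1/b2 difference, hairpin identities and counts) so that design and
#' validation logic can be exercised without the published supplementary
#' sequences; users supply their own config with the real sequences for
#' bench work.
#'
#' @param path YAML file mapping variant name to `sequence` and
#'   `annotations`; defaults to the packaged synthetic stubs.
#' @return Named list of [scaffold_template()] objects.
#' @export
load_scaffold_templates <- function(path = system.file(
    "extdata", "synthetic_scaffold_stubs.yaml", package = "crisprad")) {
  cfg <- yaml::read_yaml(path)
  tpl <- cfg$templates
  if (is.null(tpl)) stop("config has no 'templates' key", call. = FALSE)
  out <- lapply(names(tpl), function(nm) {
    ann <- tpl[[nm]]$annotations
    ann <- if (is.null(ann)) NULL else
      do.call(rbind, lapply(ann, function(a)
        data.frame(label = a$label, start = as.integer(a$start),
                   end = as.integer(a$end), stringsAsFactors = FALSE)))
    scaffold_template(nm, tpl[[nm]]$sequence, ann)
  })
  stats::setNames(out, names(tpl))
}

#' Assemble a guide RNA construct from a spacer and a scaffold template
#'
#' The 20-nt DNA spacer (written as the protospacer on the targeted-site
#' strand) is transcribed to its U-form and substituted for the template's
#' placeholder; annotation coordinates downstream of the placeholder are
#' shifted accordingly. The assembled length is always
#' `nchar(template) - nchar(placeholder) + 20`.
#'
#' @param spacer 20-nt DNA string (A/C/G/T).
#' @param template A [scaffold_template()].
#' @param target_site_ref Optional one-row site table (see
#'   [find_pam_sites()]) recording the intended target; used by
#'   [validate_guide()].
#' @return An object of class `guide_construct` with elements `spacer`
#'   (DNA), `scaffold` (variant name), `full_sequence` (RNA),
#'   `annotations` (shifted), `target_site_ref`.
#' @export
assemble_guide <- function(spacer, template, target_site_ref = NULL) {
  stopifnot(inherits(template, "scaffold_template"))
  spacer <- toupper(spacer)
  if (nchar(spacer) != SPACER_LEN)
    stop("spacer must be exactly ", SPACER_LEN, " nt (got ", nchar(spacer),
         ")", call. = FALSE)
  if (grepl("[^ACGT]", spacer))
    stop("spacer must be DNA (A/C/G/T only)", call. = FALSE)
  spacer_rna <- gsub("T", "U", spacer, fixed = TRUE)
  full <- sub(SPACER_PLACEHOLDER, spacer_rna, template$sequence, fixed = TRUE)
  shift <- SPACER_LEN - nchar(SPACER_PLACEHOLDER)
  ann <- template$annotations
  if (nrow(ann)) {
    after <- ann$start > template$placeholder_start
    ann$start[after] <- ann$start[after] + shift
    ann$end[after] <- ann$end[after] + shift
  }
  structure(list(spacer = spacer, scaffold = template$name,
                 full_sequence = full, annotations = ann,
                 target_site_ref = target_site_ref),
            class = "guide_construct")
}

#' @export
print.guide_construct <- function(x, ...) {
  cat(sprintf("<guide_construct> %s, %d nt\n  spacer (DNA): %s\n",
              x$scaffold, nchar(x$full_sequence), x$spacer))
  if (nrow(x$annotations))
    cat("  hairpins:", paste(sprintf("%s[%d-%d]", x$annotations$label,
                                     x$annotations$start, x$annotations$end),
                             collapse = ", "), "\n")
  invisible(x)
}

#' DNA form of a guide construct
#'
#' Guides are assembled in RNA form; the DNA form (U -> T) is what is
#' ordered for cloning.
#'
#' @param construct A `guide_construct`.
#' @return Character string, DNA alphabet.
#' @export
guide_dna <- function(construct) {
  stopifnot(inherits(construct, "guide_construct"))
  gsub("U", "T", construct$full_sequence, fixed = TRUE)
}

#' Positional differences between two assembled constructs
#'
#' Equal-length constructs are compared position by position (no
#' alignment); unequal lengths produce a length-difference report listing
#' the differing positions within the shared prefix plus the unshared tail
#' interval.
#'
#' @param a,b `guide_construct` objects (or plain character sequences).
#' @return A list with `positions` (integer vector of differing positions
#'   within the compared span), `length_difference` (0 for equal lengths),
#'   and `tail_interval` (`c(start, end)` of the unshared tail, or `NULL`).
#' @export
diff_constructs <- function(a, b) {
  sa <- if (inherits(a, "guide_construct")) a$full_sequence else toupper(a)
  sb <- if (inherits(b, "guide_construct")) b$full_sequence else toupper(b)
  la <- nchar(sa); lb <- nchar(sb)
  n <- min(la, lb)
  ca <- strsplit(substr(sa, 1L, n), "")[[1]]
  cb <- strsplit(substr(sb, 1L, n), "")[[1]]
  pos <- which(ca != cb)
  list(positions = pos,
       length_difference = abs(la - lb),
       tail_interval = if (la == lb) NULL else c(n + 1L, max(la, lb)))
}

# Expected hairpin annotation counts per shipped variant.
.expected_hairpins <- list(
  gRNA           = c(tracr_terminator = 1L),
  scRNA_original = c(MS2 = 1L, tracr_terminator = 1L),
  scRNA.b1       = c(MS2 = 1L),
  scRNA.b2       = c(MS2 = 1L),
  scRNA_2xMS2    = c(MS2 = 2L),
  scRNA_PP7_b1   = c(PP7 = 1L),
  sgRNA2.0       = c(MS2 = 2L, tracr_terminator = 1L))

#' Validate an assembled guide construct
#'
#' Pure report (never mutates the construct). Checks that the spacer
#' matches the referenced protospacer when a target site is attached, and
#' that the expected hairpin annotations for the variant are present (one
#' MS2 for scRNA.b1/b2, two for the 2x MS2 design, a PP7 hairpin for the
#' PP7 variant). sgRNA 2.0 constructs pass structural checks but carry an
#' efficacy warning: that design shows no detectable activity in E. coli
#' CRISPRa even though it is effective in eukaryotic cells.
#'
#' @param construct A `guide_construct`.
#' @return A list with `ok` (logical), `checks` (data.frame of check name,
#'   pass, detail) and `warnings` (character vector).
#' @export
validate_guide <- function(construct) {
  stopifnot(inherits(construct, "guide_construct"))
  checks <- list()
  warnings <- character()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  if (!is.null(construct$target_site_ref)) {
    proto <- toupper(construct$target_site_ref$protospacer[1])
    add("spacer_matches_protospacer", identical(construct$spacer, proto),
        if (identical(construct$spacer, proto)) "" else
          sprintf("spacer %s != protospacer %s", construct$spacer, proto))
  }
  expected <- .expected_hairpins[[construct$scaffold]]
  if (!is.null(expected)) {
    have <- table(construct$annotations$label)
    for (lab in names(expected)) {
      n_have <- if (lab %in% names(have)) as.integer(have[[lab]]) else 0L
      add(paste0("hairpin_", lab),
          n_have == expected[[lab]],
          sprintf("expected %d, found %d", expected[[lab]], n_have))
    }
  }
  if (identical(construct$scaffold, "sgRNA2.0"))
    warnings <- c(warnings, paste(
      "sgRNA 2.0 scaffolds show no detectable CRISPRa activity in E. coli",
      "despite being effective in eukaryotic cells"))
  checks <- if (length(checks)) do.call(rbind, checks) else
    data.frame(check = character(), pass = logical(), detail = character())
  list(ok = all(checks$pass), checks = checks, warnings = warnings)
}
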