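test_that("sequences without G/C PAM dinucleotides yield no sites", {
  p <- promoter_record(strrep("AT", 20), 35, "forward")
  expect_equal(nrow(find_pam_sites(p)), 0L)
})

test_that("short sequences warn and return an empty site table", {
  p <- promoter_record("ACGTACGTACGT", 6, "forward")
  expect_warning(sites <- find_pam_sites(p), "shorter than 23")
  expect_equal(nrow(sites), 0L)
})

test_that("a single embedded AGG with full 5' context gives one + site", {
  # 40-mer: 20 nt of A/T/C (no GG/CC pairs), then AGG, then A/T filler
  proto <- "ATCTATCATATCTATACTAT"
  seq <- paste0(proto, "AGG", strrep("AT", 8), "A")
  p <- promoter_record(seq, 40, "forward")
  sites <- find_pam_sites(p)
  plus <- sites[sites$site_strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$protospacer, proto)
  expect_equal(plus$pam, "AGG")
  expect_equal(plus$start, 1L)
  expect_equal(plus$end, 23L)
})

test_that("scanner matches the brute-force all-23-mers oracle", {
  set.seed(42)
  for (i in 1:30) {
    L <- sample(23:400, 1)
    s <- random_dna(L, gc = runif(1, 0.3, 0.7))
    p <- promoter_record(s, sample(seq_len(L), 1), "forward")
    got <- find_pam_sites(p)
    want <- brute_force_sites(s)
    expect_identical(site_key(got), site_key(want))
  }
})

test_that("scanning the reverse complement mirrors the site set", {
  set.seed(99)
  for (i in 1:10) {
    L <- sample(30:300, 1)
    s <- random_dna(L)
    fwd <- find_pam_sites(promoter_record(s, 1, "forward"))
    rev <- find_pam_sites(promoter_record(reverse_complement(s), 1, "forward"))
    # mirror: a + site at [st, en] maps to a - site at [L-en+1, L-st+1]
    mirrored <- data.frame(
      start = L - rev$end + 1L, end = L - rev$start + 1L,
      site_strand = ifelse(rev$site_strand == "+", "-", "+"),
      protospacer = rev$protospacer, pam = rev$pam)
    expect_identical(site_key(fwd), site_key(mirrored))
  }
})

test_that("strand classification follows the full 2x2 truth table", {
  expect_equal(classify_strand("+", "forward"), "non-template")
  expect_equal(classify_strand("-", "forward"), "template")
  expect_equal(classify_strand("+", "reverse"), "template")
  expect_equal(classify_strand("-", "reverse"), "non-template")
})

test_that("TSS distance respects the anchor convention", {
  spec <- fixture_spec(rng_seed = 5, promoter_length = 160, tss_offset = 120,
                       planted_sites = data.frame(
                         distance = 91, strand_class = "non-template"))
  fx <- make_promoter_with_sites(spec)
  sites <- find_pam_sites(fx$promoter, region = c(1, fx$promoter$tss_pos))
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$tss_distance, 91L)

  # anchor immediately 5' of the TSS has distance 1
  expect_equal(
    crisprad:::.tss_distance_at(fx$promoter$tss_pos - 1L, fx$promoter), 1L)

  # pam-proximal vs pam-distal anchors differ by the protospacer length - 1
  d_prox <- distance_to_tss(sites[1, ], fx$promoter, "pam_proximal_end")
  d_dist <- distance_to_tss(sites[1, ], fx$promoter, "pam_distal_end")
  expect_equal(abs(d_dist - d_prox), 19L)
})

test_that("downstream sites are flagged, reported negative, and score 0", {
  spec <- fixture_spec(rng_seed = 8, promoter_length = 120, tss_offset = 20,
                       decoy_density = 0.6)
  fx <- make_promoter_with_sites(spec)
  sites <- rank_sites(fx$promoter)
  down <- sites[sites$downstream, , drop = FALSE]
  if (nrow(down)) {
    expect_true(all(down$tss_distance < 0))
    expect_true(all(down$window_score == 0))
  }
  expect_true(all(sites$tss_distance != 0))
})

test_that("window scoring matches the empirical activation bands", {
  m <- default_window_model()
  score_at <- function(d, cls)
    score_window(data.frame(tss_distance = d, strand_class = cls), m)
  expect_equal(score_at(85, "non-template"), 1.0)
  expect_equal(score_at(80, "non-template"), 1.0)  # inclusive bounds
  expect_equal(score_at(90, "non-template"), 1.0)
  expect_equal(score_at(65, "template"), 1.0)
  expect_equal(score_at(50, "template"), 1.0)
  expect_equal(score_at(85, "template"), 0)
  expect_equal(score_at(65, "non-template"), 0)
  expect_equal(score_at(300, "non-template"), 0)
  expect_equal(score_at(300, "template"), 0)
  expect_equal(score_at(30, "non-template"), 0)
})

test_that("malformed window models are rejected at load", {
  expect_error(window_model(
    non_template = data.frame(lo = c(80, 85), hi = c(90, 95),
                              score = c(1, 1)),
    template = data.frame(lo = 50, hi = 80, score = 1)), "overlapping")
  expect_error(window_model(
    non_template = data.frame(lo = 90, hi = 80, score = 1),
    template = data.frame(lo = 50, hi = 80, score = 1)), "lo > hi")
  expect_error(window_model(
    non_template = data.frame(lo = 80, hi = 90, score = 2),
    template = data.frame(lo = 50, hi = 80, score = 1)), "\\[0, 1\\]")
})

test_that("window models load from YAML config", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("non_template:",
               "  - {lo: 80, hi: 90, score: 1.0}",
               "template:",
               "  - {lo: 60, hi: 80, score: 1.0}"), cfg)
  m <- read_window_model(cfg)
  s <- function(d, cls)
    score_window(data.frame(tss_distance = d, strand_class = cls), m)
  expect_equal(s(55, "template"), 0)   # narrower template band than default
  expect_equal(s(65, "template"), 1)
  expect_equal(s(85, "non-template"), 1)
})

test_that("rank_sites puts in-window sites first and is self-consistent", {
  spec <- fixture_spec(rng_seed = 13, promoter_length = 250, tss_offset = 200,
                       planted_sites = data.frame(
                         distance = c(85, 120),
                         strand_class = c("non-template", "non-template")))
  fx <- make_promoter_with_sites(spec)
  ranked <- rank_sites(fx$promoter, region = c(1, fx$promoter$tss_pos))
  expect_equal(ranked$tss_distance[1], 85L)
  expect_equal(ranked$window_score[1], 1.0)
  expect_true(all(diff(ranked$window_score) <= 0))
  # every reported score equals score_window recomputed on that row
  expect_equal(ranked$window_score, score_window(ranked))
})

test_that("window scores do not depend on site discovery order", {
  spec <- fixture_spec(rng_seed = 17, promoter_length = 300, tss_offset = 250,
                       planted_sites = data.frame(
                         distance = c(85, 65, 30),
                         strand_class = c("non-template", "template",
                                          "template")))
  fx <- make_promoter_with_sites(spec)
  sites <- find_pam_sites(fx$promoter)
  shuffled <- sites[sample(nrow(sites)), ]
  key <- function(x) paste(x$start, x$site_strand)
  expect_equal(score_window(shuffled),
               score_window(sites)[match(key(shuffled), key(sites))])
})
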