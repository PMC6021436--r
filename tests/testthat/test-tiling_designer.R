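test_that("base-unit fill preserves the fixed C/G positions everywhere", {
  p10 <- design_params(candidate_length = 10, n_candidates = 1, rng_seed = 4)
  s <- fill_base_units(p10)
  expect_equal(nchar(s), 10L)
  expect_equal(substr(s, 4, 5), "CC")
  expect_equal(substr(s, 9, 10), "GG")

  p500 <- design_params(rng_seed = 21, n_candidates = 1)
  s <- fill_base_units(p500)
  expect_equal(nchar(s), 500L)
  chars <- strsplit(s, "")[[1]]
  units <- matrix(chars, nrow = 10)     # one column per repeat, 50 repeats
  expect_equal(ncol(units), 50L)
  # all 200 constrained bases: positions 4,5 = C and 9,10 = G in every unit
  expect_true(all(units[4, ] == "C"))
  expect_true(all(units[5, ] == "C"))
  expect_true(all(units[9, ] == "G"))
  expect_true(all(units[10, ] == "G"))
})

test_that("every repeat anchors an NGG PAM on each strand, spaced 10 nt", {
  for (seed in c(1, 77, 2024)) {
    s <- fill_base_units(design_params(rng_seed = seed, n_candidates = 1))
    # + strand anchored PAM: GG at unit offsets 9-10
    gg <- gregexpr("(?=GG)", s, perl = TRUE)[[1]]
    plus_anchored <- gg[(gg - 9) %% 10 == 0]
    expect_length(plus_anchored, 50L)
    expect_true(all(diff(plus_anchored) == 10L))
    # - strand anchored PAM reads CC on the + strand at unit offsets 4-5
    cc <- gregexpr("(?=CC)", s, perl = TRUE)[[1]]
    minus_anchored <- cc[(cc - 4) %% 10 == 0]
    expect_length(minus_anchored, 50L)
    expect_true(all(diff(minus_anchored) == 10L))
  }
})

test_that("scanner sees the anchored sites recur with period 10", {
  s <- fill_base_units(design_params(rng_seed = 31, n_candidates = 1))
  p <- promoter_record(s, nchar(s), "forward")
  sites <- find_pam_sites(p)
  plus <- sites[sites$site_strand == "+", ]
  anchored <- sort(plus$start[(plus$start + 20 - 8) %% 10 == 0])
  expect_true(all(diff(anchored) == 10L))
  expect_equal(length(anchored), 48L)  # first two repeats lack 20 nt context
})

test_that("candidate lengths are truncated to a unit multiple with warning", {
  expect_warning(p <- design_params(candidate_length = 505), "truncated to 500")
  expect_equal(p$candidate_length, 500L)
})

test_that("GC targets below the fixed-base floor are rejected", {
  expect_error(design_params(gc_target = 0.35), "floor")
  expect_error(design_params(gc_target = 1.2), "\\(0, 1\\)")
})

test_that("mean GC of seeded candidates matches the target", {
  params <- design_params(rng_seed = 101, n_candidates = 400)
  cands <- generate_candidates(params)
  gc <- vapply(cands, function(s)
    (nchar(s) - nchar(gsub("[GC]", "", s))) / nchar(s), numeric(1),
    USE.NAMES = FALSE)
  # per-candidate GC = (200 + Binom(300, p)) / 500 with p = (5.08-4)/6
  p <- (10 * 0.508 - 4) / 6
  se <- sqrt(300 * p * (1 - p)) / 500 / sqrt(length(cands))
  expect_lt(abs(mean(gc) - 0.508), 3 * se)
})

test_that("homopolymer filter flags runs of four, not three", {
  expect_true(homopolymer_filter("CGAAATGCA")$pass)
  res <- homopolymer_filter("CAAAAG")
  expect_false(res$pass)
  expect_equal(res$interval, c(2L, 5L))
  expect_equal(res$base, "A")
})

test_that("homopolymer filter agrees with the run-length-encoding oracle", {
  set.seed(55)
  for (i in 1:100) {
    s <- random_dna(sample(4:60, 1), gc = runif(1, 0.2, 0.8))
    expect_equal(homopolymer_filter(s)$pass, !rle_has_long_run(s),
                 info = s)
  }
})

test_that("TF-site filter matches exact substrings on both strands", {
  spec <- fixture_spec(rng_seed = 9, tf_decoys = 6)
  s <- fill_base_units(design_params(rng_seed = 9, n_candidates = 1))

  empty <- data.frame(site_id = character(), site_seq = character())
  expect_true(tf_site_filter(s, empty)$pass)

  decoys <- make_tf_site_list(spec, include_from = s)
  expect_true(tf_site_filter(s, decoys)$pass)

  # a site present only on the reverse strand must be caught and named
  planted <- reverse_complement(substr(s, 101, 112))
  lst <- rbind(decoys, data.frame(site_id = "rc_site", site_seq = planted))
  res <- tf_site_filter(s, lst)
  expect_false(res$pass)
  expect_true("rc_site" %in% res$matched_ids)

  # a site longer than the candidate cannot match
  long <- data.frame(site_id = "toolong",
                     site_seq = strrep("A", nchar(s) + 1))
  expect_true(tf_site_filter(s, long)$pass)
})

test_that("TF-site filter agrees with the exhaustive-substring oracle", {
  set.seed(66)
  for (i in 1:100) {
    s <- random_dna(40)
    site <- random_dna(sample(4:8, 1))
    got <- tf_site_filter(s, data.frame(site_id = "x", site_seq = site))
    expect_equal(!got$pass, substring_tf_hit(s, site), info = paste(s, site))
  }
})

test_that("TF site lists with non-nucleotide characters are rejected by id", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("ok\tACGT", "badsite\tAC-GT"), tsv)
  expect_error(read_tf_sites(tsv), "badsite")
})

test_that("genome homology screen detects planted and self matches", {
  set.seed(77)
  q <- random_dna(60)

  res <- genome_homology_filter(q, q, k = 15)
  expect_false(res$pass)
  expect_gte(res$shared_count, nchar(q) - 15 + 1)

  expect_true(genome_homology_filter(q, strrep("A", 500), k = 15)$pass)

  spec <- fixture_spec(rng_seed = 77, genome_length = 1000)
  g <- make_toy_genome(spec, embed = substr(q, 10, 24))
  res <- genome_homology_filter(q, g, k = 15)
  expect_false(res$pass)
  expect_equal(res$first_shared, substr(q, 10, 24))

  expect_error(genome_homology_filter("ACGT", g, k = 15), "exceeds")
})

test_that("homology screen verdict agrees with the k-mer set oracle", {
  set.seed(88)
  for (i in 1:100) {
    q <- random_dna(30)
    g <- random_dna(200)
    k <- sample(6:9, 1)   # small k so both verdicts occur
    got <- genome_homology_filter(q, g, k = k)
    expect_equal(!got$pass, kmer_sets_intersect(q, g, k),
                 info = paste(k, q))
  }
})

test_that("design_array returns the first passing candidate with attrition", {
  params <- design_params(rng_seed = 202, n_candidates = 50,
                          candidate_length = 100, fragment_length = 60)
  d <- design_array(params)
  # the chosen candidate is the first in the stream passing the
  # homopolymer filter
  cands <- generate_candidates(params, d$candidate_index)
  expect_identical(d$seq, cands[d$candidate_index])
  passes <- vapply(cands, function(s) homopolymer_filter(s)$pass, logical(1))
  expect_true(passes[d$candidate_index])
  if (d$candidate_index > 1) expect_false(any(passes[-d$candidate_index]))
  expect_equal(unname(d$attrition["homopolymer"]), d$candidate_index - 1L)
})

test_that("design_array is byte-identical across runs with the same seed", {
  params <- design_params(rng_seed = 303, n_candidates = 200,
                          candidate_length = 200, fragment_length = 170)
  expect_identical(design_array(params), design_array(params))
})

test_that("filters are independent predicates: order cannot flip a verdict", {
  # each filter is a pure function of the candidate, so the conjunction is
  # order-free; verify all orderings agree on a batch of candidates
  spec <- fixture_spec(rng_seed = 41, genome_length = 500, tf_decoys = 4)
  params <- design_params(rng_seed = 41, n_candidates = 30,
                          candidate_length = 60, fragment_length = 30)
  cands <- generate_candidates(params)
  tf <- make_tf_site_list(spec)
  g <- make_toy_genome(spec)
  verdict <- function(s, order) {
    checks <- list(
      h = function(x) homopolymer_filter(x)$pass,
      t = function(x) tf_site_filter(x, tf)$pass,
      g = function(x) genome_homology_filter(x, g, k = 8)$pass)
    all(vapply(order, function(o) checks[[o]](s), logical(1)))
  }
  for (s in cands) {
    v <- verdict(s, c("h", "t", "g"))
    expect_equal(verdict(s, c("g", "t", "h")), v)
    expect_equal(verdict(s, c("t", "g", "h")), v)
  }
})

test_that("all-candidates-rejected reports the attrition table", {
  # every candidate contains its own TF site: guaranteed rejection
  params <- design_params(rng_seed = 7, n_candidates = 5,
                          candidate_length = 50, fragment_length = 20)
  cands <- generate_candidates(params)
  lst <- data.frame(site_id = paste0("s", seq_along(cands)),
                    site_seq = substr(cands, 11, 22))
  expect_error(design_array(params, tf_sites = lst), "rejected; attrition")
})

test_that("fragment selection slices the intended end of the array", {
  params <- design_params(rng_seed = 9, n_candidates = 20)
  d <- design_array(params)
  expect_equal(nchar(d$fragment), 170L)
  # default three_prime placement: promoter-proximal bases 331-500
  expect_equal(d$fragment, substr(d$seq, 331, 500))
  expect_equal(select_fragment(d, 170, "five_prime"), substr(d$seq, 1, 170))
  expect_equal(select_fragment(d, nchar(d$seq)), d$seq)  # identity
  expect_equal(select_fragment(d, 10, 46), substr(d$seq, 46, 55))
  expect_error(select_fragment(d, 170, 400), "out of bounds")
  expect_error(select_fragment(d, 501), "exceeds")
})
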