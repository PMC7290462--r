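# Planted-cassette generator: truth consistency and determinism.

test_that("mutation extremes behave as specified", {
  tr <- dgrscan:::with_seed(1L, dgrscan:::sample_tr(cassette_spec()))
  s0 <- cassette_spec(p_aton = 0, non_aton_rate = 0, seed = 5L)
  expect_identical(mutate_tr_to_vr(tr, s0)$vr, tr)

  s1 <- cassette_spec(p_aton = 1, non_aton_rate = 0, seed = 5L)
  res <- mutate_tr_to_vr(tr, s1)
  ch <- strsplit(tr, "")[[1]]
  n <- length(ch)
  mutable <- which(ch == "A" & seq_len(n) <= n - s1$imh_len)
  expect_setequal(res$substitutions$offset, mutable - 1L)
  expect_true(all(res$substitutions$vr_base != "A"))  # strict A-to-N
})

test_that("repeated calls with one seed are identical", {
  tr <- dgrscan:::with_seed(2L, dgrscan:::sample_tr(cassette_spec()))
  spec <- cassette_spec(seed = 17L)
  expect_identical(mutate_tr_to_vr(tr, spec), mutate_tr_to_vr(tr, spec))
})

test_that("truth logs reproduce exactly the VR/TR differences in the genome", {
  for (seed in c(3L, 8L)) {
    sim <- generate_genome_with_cassette(20000, spec = cassette_spec(seed = seed))
    g <- sim$genome; tru <- sim$truth
    vr <- substr(g$sequence, tru$elements$vr["start"] + 1L, tru$elements$vr["end"])
    tr <- substr(g$sequence, tru$elements$tr["start"] + 1L, tru$elements$tr["end"])
    expect_identical(vr, tru$vr_seq)
    expect_identical(tr, tru$tr_seq)
    diffs <- which(strsplit(vr, "")[[1]] != strsplit(tr, "")[[1]])
    expect_equal(diffs - 1L, tru$substitutions$offset)
    # IMH inviolability: planted suffixes are identical strings
    n <- nchar(tr); k <- tru$spec$imh_len
    expect_identical(substr(vr, n - k + 1L, n), substr(tr, n - k + 1L, n))
  }
})

test_that("the VR never carries an in-frame stop codon", {
  for (seed in 11:20) {
    spec <- cassette_spec(seed = seed, p_aton = 0.9, non_aton_rate = 0.05)
    tr <- dgrscan:::with_seed(seed, dgrscan:::sample_tr(spec))
    vr <- mutate_tr_to_vr(tr, spec)$vr
    prot <- translate_dna(vr)
    expect_false(grepl("*", prot, fixed = TRUE))
  }
})

test_that("generated genomes are pure functions of the spec", {
  a <- generate_genome_with_cassette(20000, spec = cassette_spec(seed = 6))
  b <- generate_genome_with_cassette(20000, spec = cassette_spec(seed = 6))
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$truth$substitutions, b$truth$substitutions)
  c2 <- generate_genome_with_cassette(20000, spec = cassette_spec(seed = 7))
  expect_false(identical(a$genome$sequence, c2$genome$sequence))
  expect_error(generate_genome_with_cassette(10000), ">= 20000")
})

test_that("class variants plant and omit the right elements", {
  el <- function(spec) names(generate_genome_with_cassette(20000, spec = spec)$truth$elements)
  expect_setequal(el(cassette_spec(seed = 1)),
                  c("tnp", "tg", "vr", "imh", "tr", "imh_star", "rt", "hp", "ihf"))
  expect_setequal(el(cassette_spec(class = "absent", seed = 1)),
                  c("tnp", "hp", "ihf"))
  expect_setequal(el(cassette_spec(class = "incomplete",
                                   variant = "tg_rt_trunc_no_tr", seed = 1)),
                  c("tnp", "tg", "vr", "imh", "rt", "hp", "ihf"))
  expect_setequal(el(cassette_spec(class = "incomplete", variant = "no_repeats",
                                   seed = 1)),
                  c("tnp", "tg", "rt", "hp", "ihf"))
})

test_that("cohort generation honours the class mix deterministically", {
  expect_error(generate_cohort(5, c(complete = 3, absent = 3)), "sum to n")
  expect_error(generate_cohort(2, c(weird = 2)), "named")
  one <- generate_cohort(1, c(complete = 1), seed = 2)
  expect_length(one$genomes, 1L)
  expect_equal(one$truths[[1]]$class, "complete")

  coh <- generate_cohort(6, c(complete = 2, incomplete = 3, absent = 1),
                         seed = 5, genome_len = 20000)
  cls <- vapply(coh$truths, `[[`, character(1), "class")
  expect_equal(sum(cls == "complete"), 2L)
  expect_equal(sum(cls == "incomplete"), 3L)
  expect_equal(sum(cls == "absent"), 1L)
  coh2 <- generate_cohort(6, c(complete = 2, incomplete = 3, absent = 1),
                          seed = 5, genome_len = 20000)
  expect_identical(vapply(coh$genomes, `[[`, character(1), "sequence"),
                   vapply(coh2$genomes, `[[`, character(1), "sequence"))
})

test_that("the reference panel matches the planted genes", {
  coh <- generate_cohort(1, c(complete = 1), seed = 9, genome_len = 20000)
  refs <- coh$refs
  expect_setequal(names(refs$proteins), c("TNP", "IHF", "HP", "RT", "TCFP"))
  expect_identical(refs$tr_dna, coh$template$tr)
  # round-trip through FASTA
  pf <- tempfile(fileext = ".faa"); tf <- tempfile(fileext = ".fa")
  write_reference_panel(refs, pf, tf)
  back <- read_reference_panel(pf, tf)
  expect_identical(back$proteins[names(refs$proteins)], refs$proteins)
  expect_identical(back$tr_dna, refs$tr_dna)
})

test_that("the reference-statistics genome carries the designed signature", {
  ref <- simulate_reference_cassette()
  expect_equal(ref$genome$length, 98458L)
  tru <- ref$truth
  cmp <- compare_vr_tr(tru$vr_seq, tru$tr_seq)
  expect_equal(cmp$n_codons, 35L)
  expect_equal(cmp$n_adenines_tr, 28L)
  expect_equal(cmp$n_aton_variable, 21L)
  expect_equal(cmp$n_non_aton, 2L)
  expect_identical(diversity(tru$tr_seq)$dna_variants, "72057594037927936")
})
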