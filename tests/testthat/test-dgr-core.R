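# Orientation, IMH calling, RT detection, assembly and classification.

# minimal hand-built RepeatPair
fake_pair <- function(base_a, base_b, start_a = 100L, start_b = 400L) {
  n <- length(base_a)
  structure(list(
    genome_id = "fake",
    interval_a = dgrscan:::iv(start_a, start_a + n),
    interval_b = dgrscan:::iv(start_b, start_b + n),
    inverted = FALSE,
    alignment = data.frame(
      position_a = start_a:(start_a + n - 1L),
      position_b = start_b:(start_b + n - 1L),
      base_a = base_a, base_b = base_b,
      match = base_a == base_b, stringsAsFactors = FALSE
    ),
    identity = mean(base_a == base_b), length = n, score = n
  ), class = "RepeatPair")
}

test_that("the copy with adenine at mismatches becomes the TR", {
  a <- c("A", "A", "A", "A", "A", rep("G", 20))
  b <- c("C", "G", "T", "C", "G", rep("G", 20))
  op <- assign_tr_vr(fake_pair(a, b))
  expect_false(op$ambiguous)
  expect_true(op$tr_is_a)
  expect_equal(op$adenine_bias, 1.0)
  expect_equal(unname(op$tr_interval["start"]), 100L)
  # swapped input flips the orientation
  op2 <- assign_tr_vr(fake_pair(b, a))
  expect_false(op2$tr_is_a)
})

test_that("even mismatch split and zero mismatches are ambiguous", {
  a <- c("A", "A", "C", "G", rep("T", 20))
  b <- c("C", "G", "A", "A", rep("T", 20))
  expect_true(assign_tr_vr(fake_pair(a, b))$ambiguous)
  c1 <- rep("G", 24)
  op0 <- assign_tr_vr(fake_pair(c1, c1))
  expect_true(op0$ambiguous)
  expect_equal(op0$n_mismatch, 0L)
})

test_that("IMH is the maximal exact 3' run with the identical flag", {
  # 14 matching suffix columns behind one mismatch
  a <- c(rep("A", 6), "A", rep("G", 14))
  b <- c(rep("C", 6), "C", rep("G", 14))
  op <- assign_tr_vr(fake_pair(a, b))
  imh <- detect_imh(op, min_len = 10L)
  expect_equal(imh$length, 14L)
  expect_true(imh$identical)
  expect_equal(unname(imh$imh_interval["end"]), unname(op$vr_interval["end"]))
  expect_equal(unname(imh$imh_star_interval["end"]), unname(op$tr_interval["end"]))
  # terminal mismatch -> run length 0 -> no annotation
  a2 <- c(rep("A", 10), rep("G", 13), "A")
  b2 <- c(rep("C", 10), rep("G", 13), "C")
  expect_null(detect_imh(assign_tr_vr(fake_pair(a2, b2)), min_len = 10L))
})

test_that("planted cassettes carry an exact IMH of the planted length", {
  sim <- generate_genome_with_cassette(20000, spec = cassette_spec(seed = 41))
  res <- detect_dgr(sim$genome)
  cs <- res$cassettes[[1]]
  expect_false(is.null(cs$imh))
  expect_gte(cs$imh$length, 14L)
  expect_true(cs$imh$identical)
  # re-extract from the genome: IMH and IMH* are equal strings
  s <- sim$genome$sequence
  imh <- substr(s, cs$imh$imh_interval["start"] + 1L, cs$imh$imh_interval["end"])
  imh_star <- substr(s, cs$imh$imh_star_interval["start"] + 1L,
                     cs$imh$imh_star_interval["end"])
  expect_identical(imh, imh_star)
})

test_that("RT motif mode flags x-x-D-D proteins in the size window", {
  mk <- function(p) data.frame(genome_id = "g", start = 0L, end = 3L,
                               strand = "+", frame = 0L, protein = p,
                               label = NA_character_, stringsAsFactors = FALSE)
  long <- paste(rep("G", 350), collapse = "")
  with_motif <- mk(paste0(substr(long, 1, 200), "YMDD", substr(long, 1, 146)))
  expect_equal(nrow(detect_rt(with_motif)), 1L)
  expect_equal(detect_rt(with_motif)$label, "RT")
  expect_equal(nrow(detect_rt(mk(long))), 0L)                 # no motif
  short <- mk("MYMDDAAA")                                     # below size window
  expect_equal(nrow(detect_rt(short)), 0L)
  expect_error(detect_rt(with_motif, mode = "reference"), "refs")
})

test_that("RT reference mode flags a diverged copy of the reference", {
  rt_ref <- synthetic_proteins()[["RT"]]
  diverged <- dgrscan:::with_seed(5L, {
    ch <- strsplit(rt_ref, "")[[1]]
    idx <- sample(seq_along(ch), round(0.1 * length(ch)))
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    ch[idx] <- sample(aa, length(idx), TRUE)
    paste(ch, collapse = "")
  })
  orfs <- data.frame(genome_id = "g", start = 0L, end = 3L, strand = "+",
                     frame = 0L, protein = diverged, label = NA_character_,
                     stringsAsFactors = FALSE)
  hit <- detect_rt(orfs, mode = "reference", refs = c(RT = rt_ref))
  expect_equal(nrow(hit), 1L)
  # an unrelated protein of the same length is not flagged
  other <- dgrscan:::with_seed(6L, dgrscan:::sample_protein(350L))
  orfs2 <- orfs; orfs2$protein <- other
  expect_equal(nrow(detect_rt(orfs2, mode = "reference", refs = c(RT = rt_ref))), 0L)
})

test_that("architecture classification follows the completeness rule", {
  full <- list(target_gene = list(start = 0L, end = 1461L), tg_status = "full",
               vr = dgrscan:::iv(1353L, 1458L), tr = dgrscan:::iv(1700L, 1805L),
               imh = list(length = 14L), rt = list(start = 2000L, end = 3053L),
               rt_status = "full")
  cl <- classify_architecture(full)
  expect_equal(cl$class, "complete")
  expect_equal(cl$architecture, "TG-VR(IMH)-TR(IMH*)-RT")

  none <- list(target_gene = NULL, tg_status = "absent", vr = NULL, tr = NULL,
               imh = NULL, rt = NULL, rt_status = "absent")
  cl0 <- classify_architecture(none)
  expect_equal(cl0$class, "absent")
  expect_equal(cl0$architecture, "")

  part <- list(target_gene = list(start = 0L, end = 700L),
               tg_status = "truncated",
               vr = dgrscan:::iv(590L, 695L), tr = NULL, imh = NULL,
               rt = list(start = 900L, end = 1300L), rt_status = "truncated")
  clp <- classify_architecture(part)
  expect_equal(clp$class, "incomplete")
  expect_equal(clp$architecture, "tg'-VR-rt'")

  # missing IMH alone demotes an otherwise complete cassette
  no_imh <- full; no_imh$imh <- NULL
  expect_equal(classify_architecture(no_imh)$class, "incomplete")
})

test_that("an oriented pair without a nearby ORF yields a partial cassette", {
  sim <- generate_genome_with_cassette(20000, spec = cassette_spec(seed = 42))
  pairs <- find_repeat_pairs(sim$genome)
  oriented <- lapply(pairs, assign_tr_vr)
  cas <- assemble_cassette(sim$genome, dgrscan:::empty_orf_table(), oriented,
                           dgrscan:::empty_orf_table())
  expect_gte(length(cas), 1L)
  expect_equal(cas[[1]]$class, "incomplete")
  expect_null(cas[[1]]$target_gene)
  expect_false(is.null(cas[[1]]$vr))
})

test_that("two planted cassettes in one genome are both recovered and ranked", {
  s1 <- generate_genome_with_cassette(20000, spec = cassette_spec(seed = 43))
  s2 <- generate_genome_with_cassette(20000, spec = cassette_spec(seed = 44))
  g <- genome_record("double", paste0(s1$genome$sequence, s2$genome$sequence))
  res <- detect_dgr(g)
  complete <- Filter(function(cs) cs$class == "complete", res$cassettes)
  expect_equal(length(complete), 2L)
  scores <- vapply(res$cassettes, `[[`, numeric(1), "score")
  expect_true(all(diff(scores) <= 0))
  # one VR in each half
  vr_starts <- sort(vapply(complete, function(cs) unname(cs$vr["start"]), numeric(1)))
  expect_lt(vr_starts[1], 20000)
  expect_gt(vr_starts[2], 20000)
})

test_that("orientation is always correct when non-adenine errors are absent", {
  for (seed in 1:10) {
    spec <- cassette_spec(seed = 100 + seed, p_aton = 0.4, non_aton_rate = 0)
    sim <- generate_genome_with_cassette(20000, spec = spec)
    pairs <- find_repeat_pairs(sim$genome)
    expect_gte(length(pairs), 1L)
    op <- assign_tr_vr(pairs[[1]])
    if (!op$ambiguous) {
      ov <- dgrscan:::iv_overlap_frac(sim$truth$elements$tr, op$tr_interval)
      expect_gte(ov, 0.9)
    }
  }
})

test_that("detection output is byte-identical across repeated runs", {
  sim <- generate_genome_with_cassette(20000, spec = cassette_spec(seed = 45))
  tf1 <- tempfile(fileext = ".json"); tf2 <- tempfile(fileext = ".json")
  r1 <- detect_dgr(sim$genome)
  r2 <- detect_dgr(sim$genome)
  write_cassette_json(r1, sim$genome, tf1, seed = 45)
  write_cassette_json(r2, sim$genome, tf2, seed = 45)
  expect_identical(readLines(tf1), readLines(tf2))
})
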