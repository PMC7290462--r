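# A-to-N statistics, exact diversity arithmetic and logos.

test_that("compare_vr_tr classifies mismatches against the TR adenines", {
  r0 <- compare_vr_tr("ACGTAC", "ACGTAC")
  expect_equal(r0$n_aton_variable + r0$n_non_aton, 0L)

  r <- compare_vr_tr(vr = "ACGTTTGCA", tr = "AAATTTGCA")
  expect_equal(r$n_codons, 3L)
  expect_equal(r$n_adenines_tr, 4L)
  expect_equal(r$n_aton_variable, 2L)
  expect_equal(r$n_non_aton, 0L)
  expect_equal(r$variable_positions$offset, c(1L, 2L))
  expect_error(compare_vr_tr("ACG", "ACGT"), "equal length")
})

test_that("mismatch classes always partition the Hamming distance", {
  dgrscan:::with_seed(7L, {
    for (i in 1:25) {
      n <- 3L * sample(5:12, 1)
      tr <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
      vr <- strsplit(tr, "")[[1]]
      k <- sample.int(n, sample.int(8L, 1))
      for (j in k) vr[j] <- sample(setdiff(c("A", "C", "G", "T"), vr[j]), 1)
      vr <- paste(vr, collapse = "")
      r <- compare_vr_tr(vr, tr)
      hamming <- sum(strsplit(vr, "")[[1]] != strsplit(tr, "")[[1]])
      expect_equal(r$n_aton_variable + r$n_non_aton, hamming)
      expect_lte(r$n_aton_variable, r$n_adenines_tr)
    }
  })
})

test_that("analytic diversity matches simple genetic-code cases", {
  d <- diversity("GCA")
  expect_equal(d$dna_variants, "4")      # one adenine
  expect_equal(d$protein_variants, "1")  # GCN is synonymous (Ala)
  d0 <- diversity("GGTTGC")
  expect_equal(d0$dna_variants, "1")     # no adenines
  expect_equal(d0$protein_variants, "1")
  expect_error(diversity(""), "empty")
})

test_that("diversity equals brute-force enumeration on random small TRs", {
  dgrscan:::with_seed(8L, {
    bases <- c("A", "C", "G", "T")
    for (i in 1:30) {
      repeat {
        n <- 3L * sample(5:12, 1)
        tr <- paste(sample(bases, n, TRUE, prob = c(0.15, 0.3, 0.3, 0.25)),
                    collapse = "")
        if (sum(strsplit(tr, "")[[1]] == "A") <= 8L) break
      }
      for (sh in c("exclude", "include")) {
        a <- diversity(tr, stop_handling = sh)
        b <- diversity_bruteforce(tr, stop_handling = sh)
        expect_identical(a$dna_variants, b$dna_variants)
        expect_identical(a$protein_variants, b$protein_variants)
      }
    }
  })
})

test_that("adding an adenine multiplies DNA diversity by 4 and never shrinks proteins", {
  dgrscan:::with_seed(9L, {
    for (i in 1:20) {
      tr <- paste(sample(c("A", "C", "G", "T"), 3L * sample(4:8, 1), TRUE,
                         prob = c(0.1, 0.3, 0.3, 0.3)), collapse = "")
      d1 <- diversity(tr)
      # appending a lone A adds one adenine outside any complete codon
      d2 <- diversity(paste0(tr, "A"))
      expect_equal(d2$dna_log10 - d1$dna_log10, log10(4), tolerance = 1e-12)
      # replacing a non-A base with A never decreases protein diversity
      ch <- strsplit(tr, "")[[1]]
      nonA <- which(ch != "A")
      if (length(nonA)) {
        j <- nonA[sample.int(length(nonA), 1)]
        ch[j] <- "A"
        d3 <- diversity(paste(ch, collapse = ""))
        expect_gte(d3$protein_log10, d1$protein_log10)
        expect_equal(d3$dna_log10 - d1$dna_log10, log10(4), tolerance = 1e-12)
      }
    }
  })
})

test_that("stop handling distinguishes the two conventions", {
  # TGA with one adenine: outcomes TGN = {W, C, C, *}
  ex <- diversity("TGA", stop_handling = "exclude")
  inc <- diversity("TGA", stop_handling = "include")
  expect_equal(ex$protein_variants, "2")   # W, C
  expect_equal(inc$protein_variants, "3")  # W, C, *
  bx <- diversity_bruteforce("TGA", "exclude")
  bi <- diversity_bruteforce("TGA", "include")
  expect_identical(ex$protein_variants, bx$protein_variants)
  expect_identical(inc$protein_variants, bi$protein_variants)
})

test_that("big-integer arithmetic is exact beyond double precision", {
  expect_identical(dgrscan:::big_to_string(dgrscan:::big_pow_small(4, 28)),
                   "72057594037927936")
  expect_identical(dgrscan:::big_to_string(dgrscan:::big_pow_small(4, 40)),
                   "1208925819614629174706176")   # 2^80
  expect_identical(
    dgrscan:::big_to_string(dgrscan:::big_prod_small(rep(15L, 14L))),
    "29192926025390625")                          # 15^14
  expect_equal(round(dgrscan:::big_log10(dgrscan:::big_pow_small(4, 28))),
               17)
})

test_that("logo information content matches closed-form cases", {
  lg1 <- build_logo(rep("W", 10))
  expect_equal(lg1$information_content, log2(20), tolerance = 1e-12)
  lg0 <- build_logo(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_equal(lg0$information_content, 0, tolerance = 1e-12)
  lg5 <- build_logo(c(rep("K", 5), rep("R", 5)))
  expect_equal(lg5$information_content, log2(20) - 1, tolerance = 1e-12)
})

test_that("logo bounds and frequency normalization hold on random alignments", {
  dgrscan:::with_seed(10L, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (i in 1:10) {
      depth <- sample(3:30, 1); width <- sample(5:40, 1)
      seqs <- vapply(seq_len(depth), function(j) {
        paste(sample(c(aa, "-"), width, TRUE), collapse = "")
      }, character(1))
      lg <- build_logo(seqs)
      expect_true(all(lg$information_content >= -1e-12))
      expect_true(all(lg$information_content <= log2(20) + 1e-12))
      sums <- rowSums(lg$frequencies)
      expect_true(all(abs(sums[lg$counted_depth > 0] - 1) < 1e-12))
      expect_true(all(sums[lg$counted_depth == 0] == 0))
    }
  })
  expect_error(build_logo(character(0)), "empty")
  expect_error(build_logo(c("AA", "AAA")), "equal length")
})

test_that("logo TSV export has one row per position with an IC column", {
  lg <- build_logo(c("MKL", "MRL", "MKL"))
  tf <- tempfile(fileext = ".tsv")
  logo_to_tsv(lg, tf)
  df <- utils::read.delim(tf, check.names = FALSE)
  expect_equal(nrow(df), 3L)
  expect_true("information_bits" %in% names(df))
  expect_equal(df$information_bits, lg$information_content, tolerance = 1e-9)
})
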