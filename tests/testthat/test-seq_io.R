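# Sequence IO, translation and ORF calling.

test_that("read_fasta normalizes case, maps U to T and keeps file order", {
  tf <- write_temp_fasta(c(">g1", "acgt", ">g2 description", "AacgUu"))
  recs <- read_fasta(tf)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$id, "g1")
  expect_equal(recs[[1]]$sequence, "ACGT")
  expect_equal(recs[[1]]$length, 4L)
  expect_equal(recs[[2]]$id, "g2")
  expect_equal(recs[[2]]$sequence, "AACGTT")
})

test_that("illegal characters are rejected with their position", {
  tf <- write_temp_fasta(c(">bad", "ACGXA"))
  expect_error(read_fasta(tf), "position 4")
  expect_error(read_fasta(tempfile()), "not found")
  tf2 <- write_temp_fasta(character(0))
  expect_error(read_fasta(tf2))
})

test_that("FASTA round-trip is byte-identical on sequences", {
  recs <- list(genome_record("a", "ACGTN"),
               genome_record("b", strrep("ACGT", 100)))
  tf <- tempfile(fileext = ".fa")
  write_fasta(recs, tf)
  back <- read_fasta(tf)
  expect_equal(vapply(back, `[[`, character(1), "sequence"),
               vapply(recs, `[[`, character(1), "sequence"))
  expect_equal(vapply(back, `[[`, character(1), "id"), c("a", "b"))
})

test_that("minimal GenBank parsing converts coordinates and strand", {
  tf <- tempfile(fileext = ".gb")
  writeLines(minimal_genbank(), tf)
  gb <- read_genbank(tf)
  expect_equal(gb$genome$length, 60L)
  expect_equal(nrow(gb$orfs), 1L)
  expect_equal(gb$orfs$start, 0L)
  expect_equal(gb$orfs$end, 60L)
  expect_equal(gb$orfs$strand, "+")

  tf2 <- tempfile(fileext = ".gb")
  writeLines(minimal_genbank(cds = "complement(1..60)"), tf2)
  expect_equal(read_genbank(tf2)$orfs$strand, "-")

  # no ORIGIN -> error
  tf3 <- tempfile(fileext = ".gb")
  writeLines(c("LOCUS x", "FEATURES", "//"), tf3)
  expect_error(read_genbank(tf3), "ORIGIN")
})

test_that("translation follows the genetic code with N and stop handling", {
  expect_equal(translate_dna("ATGGCA"), "MA")
  expect_equal(translate_dna(""), "")
  expect_equal(translate_dna("TAA"), "*")
  expect_equal(translate_dna("ATGNNNTAA"), "MX*")
  expect_error(translate_dna("AT"), "multiple of 3")
  expect_error(translate_dna("ATZ"), "illegal")
})

test_that("find_orfs reports maximal start-to-stop ORFs with forward coords", {
  g <- genome_record("g", "ATGAAATAA")
  orfs <- find_orfs(g, min_len = 30L)  # too short at default min_len
  expect_equal(nrow(find_orfs(g, min_len = 30L)), 0L)
  # lower bound is enforced
  expect_error(find_orfs(g, min_len = 9L), "min_len")
  g2 <- genome_record("g2", paste0("ATG", strrep("AAA", 20), "TAA"))
  orfs2 <- find_orfs(g2, min_len = 30L)
  expect_equal(nrow(orfs2), 1L)
  expect_equal(orfs2$start, 0L)
  expect_equal(orfs2$end, g2$length)
  expect_equal(orfs2$protein, paste0("M", strrep("K", 20)))
  expect_equal(nrow(find_orfs(genome_record("c", strrep("C", 120)))), 0L)
})

test_that("ORF calling is strand-symmetric", {
  sim <- generate_genome_with_cassette(20000, spec = cassette_spec(seed = 3))
  g <- sim$genome
  rc <- genome_record("rc", revcomp(g$sequence))
  o1 <- find_orfs(g)
  o2 <- find_orfs(rc)
  expect_equal(nrow(o1), nrow(o2))
  # mirrored coordinates: an ORF [s,e) on + of g appears as [L-e, L-s) on -
  L <- g$length
  key1 <- sort(paste(o1$start, o1$end, o1$strand))
  key2 <- sort(paste(L - o2$end, L - o2$start,
                     ifelse(o2$strand == "+", "-", "+")))
  expect_equal(key1, key2)
})

test_that("every ORF translation equals translate_dna of its codons", {
  sim <- generate_genome_with_cassette(20000, spec = cassette_spec(seed = 4))
  g <- sim$genome
  orfs <- find_orfs(g)
  expect_gt(nrow(orfs), 3L)
  for (i in seq_len(nrow(orfs))) {
    dna <- substr(g$sequence, orfs$start[i] + 1L, orfs$end[i])
    if (orfs$strand[i] == "-") dna <- revcomp(dna)
    expect_equal(sub("\\*$", "", translate_dna(dna)), orfs$protein[i])
  }
})

test_that("GFF3 export is 1-based inclusive", {
  g <- genome_record("g2", paste0("ATG", strrep("AAA", 20), "TAA"))
  orfs <- find_orfs(g, min_len = 30L)
  tf <- tempfile(fileext = ".gff3")
  orfs_to_gff3(orfs, tf)
  lines <- readLines(tf)
  expect_equal(lines[1], "##gff-version 3")
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_equal(as.integer(fields[4]), 1L)
  expect_equal(as.integer(fields[5]), g$length)
})
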