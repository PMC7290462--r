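# Shared fixtures built in code at test time.

# small genome with an exact duplicated segment planted in random background
make_exact_repeat_genome <- function(seg_len = 105L, sep = 400L, seed = 11L,
                                     total = 3000L) {
  dgrscan:::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seg <- paste(sample(bases, seg_len, TRUE), collapse = "")
    bg <- function(n) paste(sample(bases, n, TRUE), collapse = "")
    pre <- 800L
    genome_record("dup", paste0(bg(pre), seg, bg(sep), seg,
                                bg(total - 2L * seg_len - sep - pre)))
  })
}

write_temp_fasta <- function(lines) {
  tf <- tempfile(fileext = ".fa")
  writeLines(lines, tf)
  tf
}

minimal_genbank <- function(n = 60L, cds = "1..60") {
  seqline <- paste(rep("atgaaacccgggtttaaatttcccgggaaatttcccgggaaatttcccgggtttaaataa",
                       1), collapse = "")
  seqline <- substr(strrep(seqline, 3L), 1L, n)
  c("LOCUS       TESTREC                 60 bp    DNA     linear   PHG",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    sprintf("     CDS             %s", cds),
    "                     /product=\"test\"",
    "ORIGIN",
    paste0("        1 ", gsub("(.{10})", "\\1 ", tolower(substr(seqline, 1, 60)))),
    "//")
}
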