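# Synthetic genomes with planted DGR cassettes and machine-readable truth.
#
# The generator emulates the locus organisation of crAss-like phage DGRs:
# a conserved tail-needle-protein (TNP) anchor, the target gene carrying the
# variable repeat (VR) at its 3' end, an intergenic template repeat (TR)
# sharing an exact 3' IMH/IMH* with the VR, a downstream reverse
# transcriptase (RT) gene bearing the x-x-D-D catalytic motif, a
# hypothetical protein (HP) and an integration-host-factor (IHF) anchor.
# Incomplete-architecture variants mirror the truncation/deletion classes
# seen across the genus cohort.

#' Specification of a planted DGR cassette
#'
#' Defaults reproduce the quantitative structure of the reference cassette:
#' a 35-codon TR with adenine fraction ~0.27 (28 adenines in 105 nt), a 0.7
#' per-adenine substitution probability, a 0.02 substitution rate at
#' non-adenine positions, a 14 nt IMH, a 350 aa RT and a 486 aa target
#' protein.
#'
#' @param class `"complete"`, `"incomplete"` or `"absent"`.
#' @param variant For incomplete cassettes, one of
#'   `"tg_rt_trunc_no_tr"` (truncated target gene retaining the VR, no TR,
#'   truncated RT), `"rt_trunc"` (full target gene, VR, TR, truncated RT)
#'   or `"no_repeats"` (truncated target gene without VR, no TR, full RT).
#' @param tr_codons TR length in codons (default 35).
#' @param adenine_fraction Target adenine fraction of the TR (default 0.27).
#'   Adenines are placed codon-structured (enriched at codon positions 1-2,
#'   where A-to-N substitution is non-synonymous).
#' @param p_aton Per-adenine substitution probability outside the IMH
#'   (default 0.7).
#' @param non_aton_rate Substitution probability per non-adenine position
#'   (default 0.02).
#' @param imh_len IMH length in nt; this suffix is never mutated
#'   (default 14).
#' @param rt_len_aa RT protein length (default 350).
#' @param tg_len_aa Target protein length including the VR codons
#'   (default 486).
#' @param seed Integer seed making all outputs deterministic.
#' @return A list of class `CassetteSpec`.
#' @export
cassette_spec <- function(class = "complete", variant = NULL,
                          tr_codons = 35L, adenine_fraction = 0.27,
                          p_aton = 0.7, non_aton_rate = 0.02,
                          imh_len = 14L, rt_len_aa = 350L, tg_len_aa = 486L,
                          seed = 1L) {
  stopifnot(class %in% c("complete", "incomplete", "absent"),
            tr_codons >= 5L, imh_len < 3L * tr_codons,
            p_aton >= 0, p_aton <= 1, non_aton_rate >= 0, non_aton_rate <= 1,
            adenine_fraction > 0, adenine_fraction < 1,
            tg_len_aa > tr_codons)
  if (class == "incomplete" && is.null(variant)) variant <- "tg_rt_trunc_no_tr"
  if (!is.null(variant)) {
    stopifnot(variant %in% c("tg_rt_trunc_no_tr", "rt_trunc", "no_repeats"))
  }
  structure(as.list(environment()), class = "CassetteSpec")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# deterministic synthetic proteins shared by every generated genome
sample_protein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1L, replace = TRUE), collapse = ""))
}

#' Synthetic reference proteins for the anchor and RT genes
#'
#' Deterministic, generated sequences (not derived from any database entry):
#' TNP and IHF anchors, an HP filler and an RT carrying the x-x-D-D
#' catalytic motif.  Used both for planting genes and as the reference
#' panel for reference-mode detection, so no external download is needed.
#'
#' @return Named character vector of amino-acid sequences.
#' @export
synthetic_proteins <- function() {
  tnp <- with_seed(7001, sample_protein(220L))
  ihf <- with_seed(7002, sample_protein(110L))
  hp <- with_seed(7003, sample_protein(180L))
  rt <- with_seed(7004, {
    p <- sample_protein(350L)
    substr(p, 240L, 243L) <- "YADD"
    p
  })
  c(TNP = tnp, IHF = ihf, HP = hp, RT = rt)
}

# random codon for one amino acid under the given genetic code (no stops)
reverse_translate <- function(protein, code = "11") {
  gc <- genetic_code_table(code)
  by_aa <- split(names(gc), unname(gc))
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(aa, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) stop("cannot reverse-translate symbol: ", a)
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

sample_background <- function(n, gc) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Codon-structured TR sampler: adenine probability per codon position is
# adenine_fraction * (1.48, 1.26, 0.26); stop codons are rejected.
sample_tr <- function(spec) {
  p_a <- pmin(0.95, spec$adenine_fraction * c(1.48, 1.26, 0.26))
  oth <- c(C = 0.24, G = 0.24, T = 0.52)
  stops <- stop_codons()
  codons <- character(spec$tr_codons)
  for (i in seq_len(spec$tr_codons)) {
    repeat {
      cod <- paste(vapply(1:3, function(p) {
        if (runif(1) < p_a[p]) "A" else sample(names(oth), 1L, prob = oth)
      }, character(1)), collapse = "")
      if (!cod %in% stops) break
    }
    codons[i] <- cod
  }
  paste(codons, collapse = "")
}

# core mutator (uses ambient RNG); exact = data.frame(offset, vr_base) forces
# the exact substitution set instead of sampling.
mutate_impl <- function(tr, spec, exact = NULL) {
  chars <- strsplit(tr, "", fixed = TRUE)[[1]]
  n <- length(chars)
  protected <- if (spec$imh_len > 0L) (n - spec$imh_len + 1L):n else integer(0)
  vr <- chars
  if (!is.null(exact)) {
    vr[exact$offset + 1L] <- exact$vr_base
  } else {
    for (i in setdiff(seq_len(n), protected)) {
      if (chars[i] == "A") {
        if (runif(1) < spec$p_aton) vr[i] <- sample(c("C", "G", "T"), 1L)
      } else if (runif(1) < spec$non_aton_rate) {
        vr[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
      }
    }
    # the VR is translated in the target gene: remove any stop codon created
    # by resampling one of that codon's substituted positions
    stops <- stop_codons()
    for (ci in seq_len(n %/% 3L)) {
      idx <- (3L * ci - 2L):(3L * ci)
      guard <- 0L
      while (paste(vr[idx], collapse = "") %in% stops && guard < 50L) {
        subbed <- idx[vr[idx] != chars[idx]]
        if (!length(subbed)) break
        j <- subbed[sample.int(length(subbed), 1L)]
        vr[j] <- if (chars[j] == "A") sample(c("C", "G", "T"), 1L)
                 else sample(setdiff(c("A", "C", "G", "T"), chars[j]), 1L)
        guard <- guard + 1L
      }
    }
  }
  diffs <- which(vr != chars)
  list(vr = paste(vr, collapse = ""),
       substitutions = data.frame(offset = diffs - 1L,
                                  tr_base = chars[diffs], vr_base = vr[diffs],
                                  stringsAsFactors = FALSE))
}

#' Mutate a template repeat into a variable repeat
#'
#' Each adenine outside the IMH suffix is substituted with probability
#' `p_aton`, uniformly to one of C/G/T (a strict A-to-N change); each
#' non-adenine position is substituted with probability `non_aton_rate`.
#' The IMH suffix is never touched.  Substitutions that would create a stop
#' codon in the repeat's reading frame are resampled, since the VR is
#' translated as part of the target gene.
#'
#' @param tr TR DNA string.
#' @param spec A [cassette_spec()]; `spec$seed` seeds the substitutions.
#' @return A list with `vr` and `substitutions` (data frame of `offset`
#'   (0-based), `tr_base`, `vr_base`).
#' @export
mutate_tr_to_vr <- function(tr, spec = cassette_spec()) {
  with_seed(spec$seed, mutate_impl(tr, spec))
}

# Shared cassette template: proteins, target-gene 5' portion and the TR.
build_template <- function(spec) {
  prot <- synthetic_proteins()
  list(
    proteins = prot,
    tg5_aa = sample_protein(spec$tg_len_aa - spec$tr_codons),
    tr = sample_tr(spec)
  )
}

#' Generate one genome with a planted DGR cassette
#'
#' Background sequence is i.i.d. at the given GC content (default 0.35;
#' crAss-like genomes are AT-rich).  Planted in order: TNP anchor gene,
#' target gene ending in the VR, intergenic TR ending in IMH*, RT gene,
#' HP gene, IHF anchor gene.  Planted genes use ATG starts and TAA stops,
#' contain no internal stops, and are preceded by an in-frame stop so that
#' the ORF caller reports exactly the planted interval.  Incomplete
#' variants apply the truncations/deletions described in [cassette_spec()].
#'
#' @param genome_len Total genome length in nt (>= 20000).
#' @param gc Background GC fraction (default 0.35).
#' @param spec A [cassette_spec()].
#' @param template Optional shared template from an enclosing
#'   [generate_cohort()] call; by default a fresh one is drawn from
#'   `spec$seed`.
#' @return A list with `genome` (a [genome_record()]) and `truth`
#'   (genome id, planted class/variant, named element intervals, the
#'   substitution log and the spec).
#' @export
generate_genome_with_cassette <- function(genome_len = 30000L, gc = 0.35,
                                          spec = cassette_spec(),
                                          template = NULL) {
  if (genome_len < 20000L) stop("genome_len must be >= 20000")
  with_seed(spec$seed, {
    if (is.null(template)) template <- build_template(spec)
    generate_impl(genome_len, gc, spec, template)
  })
}

generate_impl <- function(genome_len, gc, spec, template, genome_id = NULL,
                          vr_override = NULL) {
  parts <- character(0)
  cursor <- 0L
  elements <- list()
  emit <- function(seqstr, name = NULL, from = 0L) {
    if (!nzchar(seqstr)) return(invisible(NULL))
    parts[[length(parts) + 1L]] <<- seqstr
    if (!is.null(name)) {
      elements[[name]] <<- iv(cursor + from, cursor + nchar(seqstr))
    }
    cursor <<- cursor + nchar(seqstr)
    invisible(NULL)
  }
  # gene = in-frame stop guard, ATG, body codons, TAA; interval covers ATG..TAA
  emit_gene <- function(protein, name) {
    body <- reverse_translate(substr(protein, 2L, nchar(protein)))
    emit(paste0("TAA", "ATG", body, "TAA"), name = name, from = 3L)
  }

  vr_info <- NULL
  has_tg <- spec$class != "absent"
  plant_vr <- has_tg && !identical(spec$variant, "no_repeats")
  has_tr <- spec$class == "complete" || identical(spec$variant, "rt_trunc")
  has_rt <- spec$class != "absent"
  rt_full <- spec$class == "complete" || identical(spec$variant, "no_repeats")
  tg_full <- spec$class == "complete" || identical(spec$variant, "rt_trunc")

  if (plant_vr) {
    vr_info <- if (!is.null(vr_override)) vr_override
               else mutate_impl(template$tr, spec)
  }

  emit(sample_background(600L, gc))
  emit_gene(template$proteins[["TNP"]], "tnp")
  emit(sample_background(400L, gc))

  if (has_tg) {
    tg5_dna <- paste0("ATG", reverse_translate(substr(template$tg5_aa, 2L,
                                                      nchar(template$tg5_aa))))
    if (tg_full) {
      cds <- paste0(tg5_dna, vr_info$vr, "TAA")
      vr_from <- nchar(tg5_dna)
      emit("TAA")
      emit(cds, name = "tg")
      elements[["vr"]] <- iv(cursor - nchar(cds) + vr_from,
                             cursor - nchar(cds) + vr_from + nchar(vr_info$vr))
    } else if (plant_vr) {
      # truncated target gene: 3' fragment without a start codon, VR intact
      cds <- paste0(tg5_dna, vr_info$vr, "TAA")
      frag <- substr(cds, nchar(cds) - 3L * ceiling(0.45 * spec$tg_len_aa) + 1L,
                     nchar(cds))
      vr_from <- nchar(frag) - 3L - nchar(vr_info$vr)
      emit(frag, name = "tg")
      elements[["vr"]] <- iv(cursor - nchar(frag) + vr_from,
                             cursor - nchar(frag) + vr_from + nchar(vr_info$vr))
    } else {
      # 5' fragment: start codon present, VR absent, premature stop
      frag <- substr(tg5_dna, 1L, 3L * floor(0.45 * spec$tg_len_aa))
      emit("TAA")
      emit(paste0(frag, "TAA"), name = "tg")
    }
    if (plant_vr && spec$imh_len > 0L) {
      elements[["imh"]] <- iv(elements$vr["end"] - spec$imh_len, elements$vr["end"])
    }
  }
  emit(sample_background(250L, gc))

  if (has_tr) {
    emit(template$tr, name = "tr")
    if (spec$imh_len > 0L) {
      elements[["imh_star"]] <- iv(elements$tr["end"] - spec$imh_len,
                                   elements$tr["end"])
    }
  }
  emit(sample_background(300L, gc))

  if (has_rt) {
    if (rt_full) {
      emit_gene(template$proteins[["RT"]], "rt")
    } else {
      body <- reverse_translate(substr(template$proteins[["RT"]], 2L, 140L))
      emit("TAA")
      emit(paste0("ATG", body, "TAA"), name = "rt")  # premature stop: truncated
    }
  }
  emit(sample_background(400L, gc))
  emit_gene(template$proteins[["HP"]], "hp")
  emit(sample_background(400L, gc))
  emit_gene(template$proteins[["IHF"]], "ihf")

  if (cursor > genome_len) stop("spec inconsistent with genome length")
  emit(sample_background(genome_len - cursor, gc))

  if (is.null(genome_id)) genome_id <- sprintf("synth_s%d", spec$seed)
  genome <- genome_record(genome_id, paste(parts, collapse = ""),
                          source = "synthetic")
  truth <- list(
    genome_id = genome_id,
    class = spec$class,
    variant = spec$variant,
    elements = elements,
    substitutions = if (!is.null(vr_info)) vr_info$substitutions else NULL,
    tr_seq = if (has_tr || plant_vr) template$tr else NULL,
    vr_seq = if (plant_vr) vr_info$vr else NULL,
    spec = spec
  )
  list(genome = genome, truth = truth)
}

#' Generate a cohort of genomes with a shared ancestral cassette
#'
#' All genomes derive from one template (anchor proteins, target gene and
#' TR) drawn from `seed`; each genome gets its own background, codon usage
#' and VR substitutions from the derived seed `seed + index`.  This mirrors
#' a phage genus in which VRs are homologous across genomes while each
#' genome's VR carries its own A-to-N spectrum, and is what makes
#' reference-based screening and cross-genome VR logos meaningful.
#'
#' @param n Number of genomes.
#' @param class_mix Named integer vector with entries among `complete`,
#'   `incomplete`, `absent`, summing to `n`.  Incomplete genomes cycle
#'   deterministically through the three incomplete variants.
#' @param base_spec A [cassette_spec()] supplying cassette geometry.
#' @param seed Cohort seed.
#' @param genome_len,gc Genome length and background GC per genome.
#' @return A list with `genomes` (list of [genome_record()]), `truths`,
#'   `template`, and `refs` (reference panel as used by [screen_cohort()]).
#' @export
generate_cohort <- function(n, class_mix, base_spec = cassette_spec(),
                            seed = 1L, genome_len = 30000L, gc = 0.35) {
  if (n < 1L) stop("no genomes requested")
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% c("complete", "incomplete", "absent"))) {
    stop("class_mix must be named with complete/incomplete/absent")
  }
  if (sum(class_mix) != n) stop("class_mix counts must sum to n")
  assignment <- with_seed(seed, {
    cls <- rep(names(class_mix), times = class_mix)
    sample(cls)
  })
  template <- with_seed(seed, build_template(base_spec))
  variants <- c("tg_rt_trunc_no_tr", "rt_trunc", "no_repeats")
  genomes <- vector("list", n)
  truths <- vector("list", n)
  inc_i <- 0L
  for (i in seq_len(n)) {
    cls <- assignment[i]
    var <- NULL
    if (cls == "incomplete") {
      inc_i <- inc_i + 1L
      var <- variants[((inc_i - 1L) %% 3L) + 1L]
    }
    spec_i <- cassette_spec(
      class = cls, variant = var,
      tr_codons = base_spec$tr_codons,
      adenine_fraction = base_spec$adenine_fraction,
      p_aton = base_spec$p_aton, non_aton_rate = base_spec$non_aton_rate,
      imh_len = base_spec$imh_len, rt_len_aa = base_spec$rt_len_aa,
      tg_len_aa = base_spec$tg_len_aa, seed = seed + i
    )
    res <- with_seed(spec_i$seed, {
      generate_impl(genome_len, gc, spec_i, template,
                    genome_id = sprintf("synth%03d", i))
    })
    genomes[[i]] <- res$genome
    truths[[i]] <- res$truth
  }
  list(genomes = genomes, truths = truths, template = template,
       refs = reference_panel(template))
}

#' Reference panel derived from a cassette template
#'
#' @param template Template list from [generate_cohort()] (or built
#'   internally by [generate_genome_with_cassette()]).
#' @return A list with `proteins` (named amino-acid sequences: TNP, IHF,
#'   HP, RT and TCFP, the full target protein) and `tr_dna` (the template
#'   repeat DNA used for reference-based VR/TR presence calls).
#' @export
reference_panel <- function(template) {
  tcfp <- paste0(template$tg5_aa,
                 translate_dna(substr(template$tr, 1L,
                                      3L * (nchar(template$tr) %/% 3L))))
  list(proteins = c(template$proteins, TCFP = tcfp), tr_dna = template$tr)
}

#' Write a reference panel to FASTA files
#'
#' @param refs Panel from [reference_panel()].
#' @param proteins_path Output FASTA for the labelled proteins.
#' @param tr_path Optional output FASTA for the TR DNA reference.
#' @return `proteins_path`, invisibly.
#' @export
write_reference_panel <- function(refs, proteins_path, tr_path = NULL) {
  aa <- Biostrings::AAStringSet(refs$proteins)
  Biostrings::writeXStringSet(aa, proteins_path)
  if (!is.null(tr_path)) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(c(TR = refs$tr_dna)), tr_path)
  }
  invisible(proteins_path)
}

#' Read a reference panel from FASTA files
#'
#' @param proteins_path Protein FASTA with labelled entries (TNP, IHF, HP,
#'   RT, TCFP).
#' @param tr_path Optional DNA FASTA holding the TR reference.
#' @return A panel list as produced by [reference_panel()].
#' @export
read_reference_panel <- function(proteins_path, tr_path = NULL) {
  aa <- Biostrings::readAAStringSet(proteins_path)
  prot <- as.character(aa)
  names(prot) <- sub("\\s.*$", "", names(aa))
  tr <- NULL
  if (!is.null(tr_path) && file.exists(tr_path)) {
    dn <- Biostrings::readDNAStringSet(tr_path)
    if (length(dn)) tr <- as.character(dn[[1]])
  }
  list(proteins = prot, tr_dna = tr)
}

#' Deterministic genome reproducing the reference cassette statistics
#'
#' Builds a synthetic genome whose planted cassette carries, by
#' construction, the exact quantitative signature of the deposited
#' crAssphage LMMB cassette: a 35-codon TR with 28 adenines, a VR with 21
#' A-to-N substitutions plus 2 non-A-to-N substitutions, a shared exact
#' 14 nt IMH/IMH*, a 486 aa target protein and a 350 aa RT.  The TR codon
#' design places paired adenines at codon positions 1-2 so that the exact
#' protein diversity falls in the 10^16 regime while DNA diversity is
#' 4^28 ~ 10^17.  All sequence context is synthetic; only the printed
#' summary statistics are modelled on the real cassette.
#'
#' @param genome_len Genome length (default 98458 nt, the deposited genome
#'   length).
#' @return A list with `genome` and `truth` as in
#'   [generate_genome_with_cassette()].
#' @export
simulate_reference_cassette <- function(genome_len = 98458L) {
  a_cod <- "AAT"
  spacers <- c("GGT", "GCT", "TGT", "CCT", "GTT", "TCT", "CTT",
               "GGC", "TTC", "CTG", "GCG", "CGG", "TCC", "GTC")
  codons <- character(35L)
  for (i in 1:28) {
    codons[i] <- if (i %% 2L == 1L) a_cod else spacers[(i %/% 2L - 1L) %% 14L + 1L]
  }
  codons[29:35] <- c("GGT", "CTT", "CGT", "GGT", "TCT", "GCT", "CTG")
  tr <- paste(codons, collapse = "")

  # 21 strict A-to-N substitutions: both adenines of codons 1,3,...,19 and
  # the first adenine of codon 21; substituted bases cycle C,G,T.
  a_offsets <- integer(0)
  for (ci in seq(1L, 19L, by = 2L)) a_offsets <- c(a_offsets, 3L * ci - 3L, 3L * ci - 2L)
  a_offsets <- c(a_offsets, 3L * 21L - 3L)
  sub_bases <- rep(c("C", "G", "T"), length.out = 21L)
  # 2 non-A-to-N substitutions: codon 25 pos 3 (T->C) and codon 31 pos 1
  # (C->T); the latter breaks the column just before the 14 nt IMH so the
  # exact-suffix run is exactly the planted IMH.
  exact <- data.frame(
    offset = c(a_offsets, 3L * 25L - 1L, 3L * 31L - 3L),
    vr_base = c(sub_bases, "C", "T"),
    stringsAsFactors = FALSE
  )
  exact <- exact[order(exact$offset), ]

  spec <- cassette_spec(class = "complete", tr_codons = 35L,
                        adenine_fraction = 0.27, p_aton = 0.7,
                        non_aton_rate = 0.02, imh_len = 14L,
                        rt_len_aa = 350L, tg_len_aa = 486L, seed = 573L)
  with_seed(spec$seed, {
    template <- build_template(spec)
    template$tr <- tr
    vr_info <- mutate_impl(tr, spec, exact = exact)
    generate_impl(genome_len, 0.35, spec, template,
                  genome_id = "refcassette", vr_override = vr_info)
  })
}
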