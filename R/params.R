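# Detection parameter set shared across the pipeline.

#' Detection parameters for DGR cassette discovery
#'
#' Bundles every tunable of the repeat finder, orientation test, IMH caller,
#' RT search and cassette assembly.  Defaults bracket the geometry of known
#' phage DGR cassettes: a 105 nt repeat (35 codons) at roughly 80% identity
#' with an adenine-biased mismatch spectrum.
#'
#' @param k K-mer seed length for repeat discovery (default 12).  A shared
#'   IMH of >= `imh_min_len` guarantees at least one exact seed for any
#'   true cassette with `imh_min_len >= k`.
#' @param min_len,max_len Accepted aligned repeat length range in nt
#'   (defaults 50 and 200).
#' @param min_identity Minimum repeat identity (default 0.70).
#' @param max_separation Maximum nt between the two repeat copies
#'   (default 10000).
#' @param max_kmer_occ K-mers occurring more often than this are treated as
#'   low-complexity and skipped during seeding (default 24).
#' @param xdrop Score drop-off terminating gap-free extension (default 12).
#' @param bias_threshold Fraction of mismatched columns that must carry `A`
#'   in one copy for that copy to be called the template repeat (default
#'   0.60).  The deposited cassette shows 21 of 23 mismatches at template
#'   adenines (~0.91), but with only ~15 mismatched columns the observed
#'   bias of a true TR fluctuates; since the two copies' biases sum to at
#'   most 1, any threshold above 0.5 already makes double qualification
#'   impossible, and 0.6 separates the TR (~0.9) from the VR (~0.1) with
#'   margin.
#' @param imh_min_len Minimum length in nt of the shared exact 3' suffix
#'   reported as IMH/IMH* (default 10).
#' @param orf_min_len Minimum ORF length in nt passed to [find_orfs()]
#'   (default 150).
#' @param tg_tol Maximum nt between the VR 3' end and the target-gene stop
#'   codon (default 50).
#' @param rt_max Maximum nt between the TR and an RT-labelled ORF for
#'   cassette assembly (default 5000).
#' @param rt_min_aa,rt_max_aa RT ORF size window in amino acids for motif
#'   mode (defaults 150 and 900).
#' @param rt_score_min Minimum local-alignment bit score against an RT
#'   reference in reference mode (default 40).
#' @param anchor_score_min Minimum bit score for anchor-gene hits in the
#'   cohort screen (default 40).
#' @param dna_score_min Minimum nucleotide local-alignment score (match +2 /
#'   mismatch -3) for reference-based VR/TR presence calls (default 60).
#' @param trunc_frac An ORF shorter than this fraction of its reference
#'   protein is called truncated (default 0.6).
#' @param refine_ext Number of alignment columns examined on each side of a
#'   rough repeat boundary during probabilistic refinement (default 45).
#' @param p_aton_assumed,non_aton_assumed,adenine_frac_assumed,bg_match_assumed
#'   Column-model rates behind the boundary-refinement likelihood:
#'   probability that a template adenine is substituted in the VR, the
#'   substitution rate at non-adenine positions, the template adenine
#'   fraction, and the chance-match probability of unrelated flanks.
#' @param genetic_code NCBI genetic-code table id (default `"11"`).
#' @return A named list of class `dgr_params`.
#' @export
dgr_params <- function(k = 12L,
                       min_len = 50L,
                       max_len = 200L,
                       min_identity = 0.70,
                       max_separation = 10000L,
                       max_kmer_occ = 24L,
                       xdrop = 12,
                       bias_threshold = 0.60,
                       imh_min_len = 10L,
                       orf_min_len = 150L,
                       tg_tol = 50L,
                       rt_max = 5000L,
                       rt_min_aa = 150L,
                       rt_max_aa = 900L,
                       rt_score_min = 40,
                       anchor_score_min = 40,
                       dna_score_min = 60,
                       trunc_frac = 0.6,
                       refine_ext = 45L,
                       p_aton_assumed = 0.7,
                       non_aton_assumed = 0.02,
                       adenine_frac_assumed = 0.27,
                       bg_match_assumed = 0.2725,
                       genetic_code = "11") {
  p <- as.list(environment())
  stopifnot(p$min_len >= p$k, p$max_len >= p$min_len,
            p$min_identity > 0, p$min_identity <= 1,
            p$bias_threshold > 0.5, p$bias_threshold <= 1)
  structure(p, class = "dgr_params")
}
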