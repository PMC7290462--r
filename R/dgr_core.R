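# DGR cassette detection: TR/VR orientation by adenine bias, probabilistic
# boundary refinement, IMH/IMH* calling, RT identification and cassette
# assembly with architecture classification.

#' Orient a repeat pair into template and variable copies
#'
#' During mutagenic retrohoming, substitutions arise specifically at
#' positions that are adenine in the template repeat (TR); the variable
#' repeat (VR) carries arbitrary bases there.  The copy whose bases at
#' mismatched columns are predominantly `A` is therefore the TR.
#'
#' @param pair A `RepeatPair` from [find_repeat_pairs()].
#' @param bias_threshold Minimum fraction of mismatched columns carrying `A`
#'   for a copy to qualify as the TR (default 0.60; see [dgr_params()]).
#' @return An `OrientedRepeatPair`: fields `pair`, `tr_interval`,
#'   `vr_interval`, `tr_is_a`, `adenine_bias`, `ambiguous`, `n_mismatch`.
#'   `ambiguous` is `TRUE` when both or neither copy reaches the threshold
#'   (including the zero-mismatch case, where orientation is undefined).
#' @export
assign_tr_vr <- function(pair, bias_threshold = 0.60) {
  stopifnot(inherits(pair, "RepeatPair"))
  aln <- pair$alignment
  mm <- !aln$match
  n_mm <- sum(mm)
  if (n_mm == 0L) {
    return(structure(list(
      pair = pair, tr_interval = NULL, vr_interval = NULL, tr_is_a = NA,
      adenine_bias = NA_real_, ambiguous = TRUE, n_mismatch = 0L
    ), class = "OrientedRepeatPair"))
  }
  bias_a <- sum(aln$base_a[mm] == "A") / n_mm
  bias_b <- sum(aln$base_b[mm] == "A") / n_mm
  a_is_tr <- bias_a >= bias_threshold
  b_is_tr <- bias_b >= bias_threshold
  if (a_is_tr == b_is_tr) {
    return(structure(list(
      pair = pair, tr_interval = NULL, vr_interval = NULL, tr_is_a = NA,
      adenine_bias = max(bias_a, bias_b), ambiguous = TRUE, n_mismatch = n_mm
    ), class = "OrientedRepeatPair"))
  }
  structure(list(
    pair = pair,
    tr_interval = if (a_is_tr) pair$interval_a else pair$interval_b,
    vr_interval = if (a_is_tr) pair$interval_b else pair$interval_a,
    tr_is_a = a_is_tr,
    adenine_bias = if (a_is_tr) bias_a else bias_b,
    ambiguous = FALSE, n_mismatch = n_mm
  ), class = "OrientedRepeatPair")
}

#' @export
print.OrientedRepeatPair <- function(x, ...) {
  if (x$ambiguous) {
    cat("<OrientedRepeatPair> ambiguous orientation\n")
  } else {
    cat(sprintf("<OrientedRepeatPair> TR [%d,%d) VR [%d,%d) bias=%.3f\n",
                x$tr_interval["start"], x$tr_interval["end"],
                x$vr_interval["start"], x$vr_interval["end"], x$adenine_bias))
  }
  invisible(x)
}

# TR-side and VR-side base of each alignment column, in column order.
oriented_bases <- function(oriented) {
  aln <- oriented$pair$alignment
  if (oriented$tr_is_a) {
    list(tr = aln$base_a, vr = aln$base_b,
         tr_pos = aln$position_a, vr_pos = aln$position_b)
  } else {
    list(tr = aln$base_b, vr = aln$base_a,
         tr_pos = aln$position_b, vr_pos = aln$position_a)
  }
}

#' Detect the IMH/IMH* elements of an oriented repeat pair
#'
#' The "initiation of mutagenic homing" element is taken operationally as
#' the maximal run of exactly matching aligned columns at the 3' end of the
#' VR/TR alignment, reported when it reaches `min_len`.  The `identical`
#' flag records whether the extracted IMH (VR suffix) and IMH* (TR suffix)
#' sequences are equal strings (always true under this gap-free definition
#' unless `N` columns intervene).
#'
#' @param oriented An unambiguous `OrientedRepeatPair`.
#' @param min_len Minimum run length in nt to report (default 10).
#' @return A list with `imh_interval`, `imh_star_interval` (0-based
#'   half-open suffixes of VR and TR), `length` and `identical`, or `NULL`
#'   when the terminal run is shorter than `min_len`.
#' @export
detect_imh <- function(oriented, min_len = 10L) {
  stopifnot(inherits(oriented, "OrientedRepeatPair"))
  if (oriented$ambiguous) stop("cannot call IMH on an ambiguous pair")
  m <- oriented$pair$alignment$match
  n <- length(m)
  run <- 0L
  while (run < n && m[n - run]) run <- run + 1L
  if (run < min_len) return(NULL)
  ob <- oriented_bases(oriented)
  cols <- (n - run + 1L):n
  imh_seq <- paste(ob$vr[cols], collapse = "")
  imh_star_seq <- paste(ob$tr[cols], collapse = "")
  list(
    imh_interval = iv(oriented$vr_interval["end"] - run, oriented$vr_interval["end"]),
    imh_star_interval = iv(oriented$tr_interval["end"] - run, oriented$tr_interval["end"]),
    length = run,
    identical = identical(imh_seq, imh_star_seq)
  )
}

#' Identify reverse-transcriptase ORFs
#'
#' In `motif` mode, ORFs of `rt_min_aa`-`rt_max_aa` amino acids whose
#' translation contains the RT catalytic pattern x-x-D-D (first position one
#' of Y/L/F/V/I/M) are flagged.  In `reference` mode, ORFs whose local
#' alignment (BLOSUM62) against any supplied reference protein scores at
#' least `rt_score_min` bits are flagged.
#'
#' @param orfs ORF table from [find_orfs()].
#' @param mode `"motif"` or `"reference"`.
#' @param refs Named character vector of reference protein sequences
#'   (required for reference mode).
#' @param params A [dgr_params()] list.
#' @return The subset of `orfs` flagged as RT, with `label` set to `"RT"`.
#' @export
detect_rt <- function(orfs, mode = c("motif", "reference"), refs = NULL,
                      params = dgr_params()) {
  mode <- match.arg(mode)
  if (!nrow(orfs)) return(orfs)
  if (mode == "motif") {
    len <- nchar(orfs$protein)
    hit <- len >= params$rt_min_aa & len <= params$rt_max_aa &
      grepl("[YLFVIM].DD", orfs$protein)
  } else {
    if (is.null(refs) || !length(refs)) stop("reference mode requires refs")
    hit <- vapply(orfs$protein, function(p) {
      any(vapply(refs, function(r) {
        protein_bits(r, p) >= params$rt_score_min
      }, logical(1)))
    }, logical(1))
  }
  out <- orfs[hit, , drop = FALSE]
  if (nrow(out)) out$label <- "RT"
  rownames(out) <- NULL
  out
}

# Local protein alignment bit score (BLOSUM62, ungapped Karlin-Altschul
# constants lambda=0.3176, K=0.134 used as an approximation for the lightly
# gapped alignments scored here).
protein_bits <- function(ref, subject) {
  if (!nzchar(ref) || !nzchar(subject)) return(0)
  s <- pairwise_local_score(ref, subject)
  (0.3176 * s - log(0.134)) / log(2)
}

pairwise_local_score <- function(ref, subject) {
  ref <- gsub("[^ARNDCQEGHILKMFPSTWYVBZX*]", "X", ref)
  subject <- gsub("[^ARNDCQEGHILKMFPSTWYVBZX*]", "X", subject)
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
  )
}

# ---- boundary refinement ---------------------------------------------------
# After orientation the repeat boundaries are re-estimated under an explicit
# column model.  Each aligned column is scored with the log-likelihood ratio
# of "homologous with A-to-N mutagenesis" versus "unrelated flanks"; the
# boundary posterior is computed from cumulative LLR sums and the reported
# boundary maximises the posterior mass within +/-3 nt (one codon), over
# candidates restricted to the target-gene codon grid when the VR lies in a
# called ORF.  The exact IMH suffix makes the 3' posterior very sharp; the
# 5' end is intrinsically fuzzier because mutated-adenine columns carry
# almost no boundary information.

refine_llr_table <- function(params) {
  fA <- params$adenine_frac_assumed
  q1 <- params$p_aton_assumed
  q2 <- params$non_aton_assumed
  # homology-model category probabilities (tr base A or not; match or not)
  p_hom <- c(mA = fA * (1 - q1),
             m0 = (1 - fA) * (1 - q2),
             mmA = fA * q1,
             mm_vrA = (1 - fA) * q2 / 3,
             mm0 = (1 - fA) * q2 * 2 / 3)
  # background: independent bases, AT-rich composition; match prob from params
  pa <- 0.325
  p_bg <- c(mA = pa^2,
            m0 = params$bg_match_assumed - pa^2,
            mmA = pa * (1 - pa),
            mm_vrA = (1 - pa) * pa,
            mm0 = 1 - params$bg_match_assumed - 2 * pa * (1 - pa))
  log(p_hom / p_bg)
}

# Column LLRs for TR/VR base vectors (a = TR side).
column_llr <- function(tr, vr, llr_tab) {
  out <- numeric(length(tr))
  m <- tr == vr & tr != "N" & vr != "N"
  trA <- tr == "A"; vrA <- vr == "A"
  out[m & trA] <- llr_tab["mA"]
  out[m & !trA] <- llr_tab["m0"]
  out[!m & trA] <- llr_tab["mmA"]
  out[!m & !trA & vrA] <- llr_tab["mm_vrA"]
  out[!m & !trA & !vrA] <- llr_tab["mm0"]
  out[tr == "N" | vr == "N"] <- 0
  out
}

# Bayes boundary pick: posterior over boundary positions (log weights `lw`
# indexed by boundary offsets `offs`), restricted to the candidate grid
# `cand` (codon-aligned when the target-gene frame is known).  The reported
# boundary maximises the posterior mass of candidates within +/-3 nt, with a
# small epsilon times the candidate's own posterior atom added so that
# near-ties between overlapping windows resolve toward the exact boundary.
pick_boundary <- function(offs, lw, cand, eps = 0.05) {
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  aw <- w[match(cand, offs)]
  sc <- vapply(seq_along(cand), function(ci) {
    sum(aw[abs(cand - cand[ci]) <= 3L])
  }, numeric(1))
  cand[which.max(sc + eps * aw)]
}

#' Refine the boundaries of an oriented repeat pair
#'
#' Re-estimates the shared 5' and 3' alignment boundaries of a same-strand
#' TR/VR pair under the adenine-aware column model (see Details in the
#' package vignette).  When `tg_frame_anchor` (a 0-based genome coordinate
#' on the target-gene codon grid) is supplied, candidate boundaries are
#' restricted to codon-aligned positions.
#'
#' @param genome The [genome_record()] the pair was found in.
#' @param oriented An unambiguous, non-inverted `OrientedRepeatPair`.
#' @param tg_frame_anchor Optional 0-based coordinate anchoring the
#'   target-gene reading frame (e.g. the ORF start).
#' @param params A [dgr_params()] list.
#' @return A new `OrientedRepeatPair` with updated intervals and alignment.
#' @export
refine_boundaries <- function(genome, oriented, tg_frame_anchor = NULL,
                              params = dgr_params()) {
  stopifnot(inherits(oriented, "OrientedRepeatPair"), !oriented$ambiguous)
  if (oriented$pair$inverted) return(oriented)   # refinement assumes one diagonal
  s <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  L <- genome$length
  llr_tab <- refine_llr_table(params)
  vs <- unname(oriented$vr_interval["start"]); ve <- unname(oriented$vr_interval["end"])
  ts <- unname(oriented$tr_interval["start"]); te <- unname(oriented$tr_interval["end"])
  d <- ts - vs                                   # diagonal offset VR -> TR
  ext <- params$refine_ext
  # widest legal column range along the diagonal (VR coordinates), keeping the
  # two copies from touching
  if (d > 0) { lo_lim <- 0L; hi_lim <- min(L - d, ts) }
  else       { lo_lim <- max(0L, -d, te); hi_lim <- L }
  col_llr <- function(v_pos) {                   # v_pos: VR 0-based positions
    column_llr(s[v_pos + d + 1L], s[v_pos + 1L], llr_tab)
  }
  frame_cand <- function(range_pos) {
    if (is.null(tg_frame_anchor)) range_pos
    else range_pos[(range_pos - tg_frame_anchor) %% 3L == 0L]
  }

  # 5' boundary: window around current start; boundary t means columns >= t
  # are homologous, so log-weight(t) = suffix LLR sum over the window.
  w_lo <- max(lo_lim, vs - ext); w_hi <- min(hi_lim - 1L, vs + ext)
  pos5 <- w_lo:w_hi
  llr5 <- col_llr(pos5)
  offs5 <- c(pos5, w_hi + 1L)                    # boundary may sit after window
  lw5 <- c(rev(cumsum(rev(llr5))), 0)
  cand5 <- frame_cand(offs5)
  if (!length(cand5)) cand5 <- offs5
  new_vs <- pick_boundary(offs5, lw5, cand5)

  # 3' boundary: anchored on the IMH, the exact-match suffix shared by VR
  # and TR.  The boundary is the end of the rightmost exact-match run of at
  # least imh_min_len columns, floor-snapped to the target-gene codon grid
  # (never past the run end, so the refined alignment always terminates in a
  # match).  Falls back to the posterior pick if no qualifying run exists.
  w_lo3 <- max(lo_lim, ve - ext); w_hi3 <- min(hi_lim, ve + ext)
  pos3 <- w_lo3:(w_hi3 - 1L)
  m3 <- s[pos3 + d + 1L] == s[pos3 + 1L] & s[pos3 + 1L] != "N"
  runs <- rle(m3)
  ends <- cumsum(runs$lengths)
  qual <- which(runs$values & runs$lengths >= params$imh_min_len)
  new_ve <- NA_integer_
  if (length(qual)) {
    raw <- pos3[ends[qual[length(qual)]]] + 1L      # exclusive end of last run
    if (!is.null(tg_frame_anchor)) {
      new_ve <- raw - (raw - tg_frame_anchor) %% 3L  # floor to codon grid
    } else {
      new_ve <- raw
    }
  }
  if (is.na(new_ve) || new_ve <= new_vs) {
    llr3 <- col_llr(pos3)
    offs3 <- c(w_lo3, pos3 + 1L)
    lw3 <- c(0, cumsum(llr3))
    cand3 <- frame_cand(offs3)
    if (!length(cand3)) cand3 <- offs3
    new_ve <- pick_boundary(offs3, lw3, cand3)
  }
  if (new_ve - new_vs < params$k) return(oriented)  # degenerate; keep rough call

  new_vr <- iv(new_vs, new_ve)
  new_tr <- iv(new_vs + d, new_ve + d)
  tr_b <- s[(new_vs + d + 1L):(new_ve + d)]
  vr_b <- s[(new_vs + 1L):new_ve]
  match <- tr_b == vr_b & tr_b != "N"
  aln <- if (oriented$tr_is_a) {
    data.frame(position_a = (new_vs + d):(new_ve + d - 1L),
               position_b = new_vs:(new_ve - 1L),
               base_a = tr_b, base_b = vr_b, match = match,
               stringsAsFactors = FALSE)
  } else {
    data.frame(position_a = new_vs:(new_ve - 1L),
               position_b = (new_vs + d):(new_ve + d - 1L),
               base_a = vr_b, base_b = tr_b, match = match,
               stringsAsFactors = FALSE)
  }
  pair <- oriented$pair
  if (oriented$tr_is_a) { pair$interval_a <- new_tr; pair$interval_b <- new_vr }
  else                  { pair$interval_a <- new_vr; pair$interval_b <- new_tr }
  pair$alignment <- aln
  pair$identity <- mean(match)
  pair$length <- length(match)
  mm <- sum(!match)
  bias <- if (mm > 0L) sum(tr_b[!match] == "A") / mm else NA_real_
  structure(list(
    pair = pair, tr_interval = new_tr, vr_interval = new_vr,
    tr_is_a = oriented$tr_is_a, adenine_bias = bias,
    ambiguous = FALSE, n_mismatch = mm
  ), class = "OrientedRepeatPair")
}

# ---- cassette assembly -----------------------------------------------------

# Target gene of a VR: the ORF whose 3' end contains or abuts the VR.
# `end_slack` tolerates a VR whose rough 3' boundary slightly overruns the
# ORF end (the boundary is refined afterwards).
find_target_orf <- function(orfs, vr, tg_tol, end_slack = 0L) {
  if (!nrow(orfs)) return(NULL)
  cand <- integer(0); dist <- numeric(0)
  for (i in seq_len(nrow(orfs))) {
    o <- orfs[i, ]
    if (o$strand == "+") {
      dd <- o$end - vr["end"]
      inside <- vr["start"] >= o$start && vr["end"] <= o$end + end_slack
    } else {
      dd <- vr["start"] - o$start
      inside <- vr["start"] >= o$start - end_slack && vr["end"] <= o$end
    }
    if (inside && dd >= -end_slack && dd <= tg_tol + 3L) {
      cand <- c(cand, i); dist <- c(dist, max(dd, 0))
    }
  }
  if (!length(cand)) return(NULL)
  orfs[cand[which.min(dist)], , drop = FALSE]
}

orf_interval <- function(orf) iv(orf$start, orf$end)

gap_between <- function(a, b) {
  max(0L, max(a["start"], b["start"]) - min(a["end"], b["end"]))
}

#' Assemble DGR cassettes from detected elements
#'
#' For each oriented repeat pair, locates the target gene (the ORF whose 3'
#' end contains or abuts the VR), calls IMH/IMH*, refines the repeat
#' boundaries on the target-gene codon grid, attaches the nearest RT ORF
#' within `rt_max` nt of the TR, classifies the architecture and scores the
#' cassette as `identity * adenine_bias * (1 if IMH else 0.5)`.
#'
#' @param genome A [genome_record()].
#' @param orfs ORF table for the genome.
#' @param oriented_pairs List of `OrientedRepeatPair` objects.
#' @param rts RT-labelled ORF table from [detect_rt()].
#' @param params A [dgr_params()] list.
#' @param refs Optional named protein references (names containing `TCFP`
#'   and `RT` enable truncation calls for target gene and RT).
#' @return A list of `DgrCassette` objects ranked by decreasing score (ties
#'   by leftmost coordinate).
#' @export
assemble_cassette <- function(genome, orfs, oriented_pairs, rts,
                              params = dgr_params(), refs = NULL) {
  out <- list()
  for (op in oriented_pairs) {
    if (op$ambiguous) {
      cas <- new_cassette(genome$id)
      cas$pair <- op$pair
      cas$note <- "ambiguous TR/VR orientation"
      cas <- finish_cassette(cas, params)
      out[[length(out) + 1L]] <- cas
      next
    }
    tg <- find_target_orf(orfs, op$vr_interval, params$tg_tol, end_slack = 12L)
    anchor <- if (!is.null(tg) && tg$strand == "+") tg$start else NULL
    op <- refine_boundaries(genome, op, tg_frame_anchor = anchor, params = params)
    tg <- find_target_orf(orfs, op$vr_interval, params$tg_tol, end_slack = 3L)

    cas <- new_cassette(genome$id)
    cas$pair <- op$pair
    cas$vr <- op$vr_interval
    cas$tr <- op$tr_interval
    cas$adenine_bias <- op$adenine_bias
    cas$identity <- op$pair$identity
    cas$imh <- detect_imh(op, min_len = params$imh_min_len)
    if (!is.null(tg)) {
      cas$target_gene <- tg
      cas$tg_status <- orf_status(tg, refs, "TCFP", params)
    }
    if (nrow(rts)) {
      keep <- rep(TRUE, nrow(rts))
      if (!is.null(tg)) {
        keep <- !(rts$start == tg$start & rts$end == tg$end & rts$strand == tg$strand)
      }
      rts_use <- rts[keep, , drop = FALSE]
      if (nrow(rts_use)) {
        gaps <- vapply(seq_len(nrow(rts_use)), function(i) {
          gap_between(orf_interval(rts_use[i, ]), cas$tr)
        }, numeric(1))
        if (min(gaps) <= params$rt_max) {
          rt <- rts_use[which.min(gaps), , drop = FALSE]
          cas$rt <- rt
          cas$rt_status <- orf_status(rt, refs, "RT", params)
        }
      }
    }
    cas$score <- cas$identity * cas$adenine_bias *
      (if (!is.null(cas$imh)) 1 else 0.5)
    cas <- finish_cassette(cas, params)
    out[[length(out) + 1L]] <- cas
  }
  if (!length(out)) return(out)
  ord <- order(-vapply(out, `[[`, numeric(1), "score"),
               vapply(out, function(cs) {
                 if (!is.null(cs$vr)) cs$vr["start"] else .Machine$integer.max
               }, numeric(1)))
  out[ord]
}

new_cassette <- function(genome_id) {
  structure(list(
    genome_id = genome_id, target_gene = NULL, tg_status = "absent",
    vr = NULL, tr = NULL, imh = NULL, rt = NULL, rt_status = "absent",
    pair = NULL, adenine_bias = NA_real_, identity = NA_real_,
    architecture = "", class = "absent", score = 0, note = NULL
  ), class = "DgrCassette")
}

# full/truncated call: ORF shorter than trunc_frac of its reference protein
# is truncated; without a reference, any called ORF counts as full-length.
orf_status <- function(orf, refs, ref_key, params) {
  if (is.null(orf)) return("absent")
  if (!is.null(refs)) {
    hit <- grep(ref_key, names(refs), ignore.case = TRUE, value = TRUE)
    if (length(hit)) {
      ref_len <- nchar(refs[[hit[1]]])
      return(if (nchar(orf$protein) >= params$trunc_frac * ref_len) "full" else "truncated")
    }
  }
  "full"
}

finish_cassette <- function(cas, params) {
  cl <- classify_architecture(cas)
  cas$class <- cl$class
  cas$architecture <- cl$architecture
  cas
}

#' Classify a cassette architecture
#'
#' `complete` requires a full-length target gene, VR, IMH, TR, IMH* and a
#' full-length RT; `absent` means no DGR element is present; anything else
#' is `incomplete`.  The architecture string concatenates the present
#' elements 5' to 3' in genomic order, with truncated genes in lowercase
#' primes (`tg'`, `rt'`).
#'
#' @param cassette A `DgrCassette` (or a list with the same element fields).
#' @return A list with `class` and `architecture`.
#' @export
classify_architecture <- function(cassette) {
  tg_full <- identical(cassette$tg_status, "full") && !is.null(cassette$target_gene)
  rt_full <- identical(cassette$rt_status, "full") && !is.null(cassette$rt)
  has_vr <- !is.null(cassette$vr)
  has_tr <- !is.null(cassette$tr)
  has_imh <- !is.null(cassette$imh)

  parts <- list()
  if (!is.null(cassette$target_gene)) {
    parts[[length(parts) + 1L]] <- list(
      pos = cassette$target_gene$start,
      lab = if (tg_full) "TG" else "tg'"
    )
  }
  if (has_vr) parts[[length(parts) + 1L]] <- list(
    pos = cassette$vr["start"], lab = if (has_imh) "VR(IMH)" else "VR")
  if (has_tr) parts[[length(parts) + 1L]] <- list(
    pos = cassette$tr["start"], lab = if (has_imh) "TR(IMH*)" else "TR")
  if (!is.null(cassette$rt)) parts[[length(parts) + 1L]] <- list(
    pos = cassette$rt$start, lab = if (rt_full) "RT" else "rt'")

  any_elem <- length(parts) > 0L
  cls <- if (tg_full && has_vr && has_tr && has_imh && rt_full) "complete"
         else if (!any_elem) "absent"
         else "incomplete"
  arch <- if (any_elem) {
    ord <- order(vapply(parts, `[[`, numeric(1), "pos"))
    paste(vapply(parts[ord], `[[`, character(1), "lab"), collapse = "-")
  } else ""
  list(class = cls, architecture = arch)
}

#' @export
print.DgrCassette <- function(x, ...) {
  cat(sprintf("<DgrCassette> %s  %s  class=%s  score=%.3f\n",
              x$genome_id, x$architecture, x$class, x$score))
  invisible(x)
}
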