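# Cohort screening: anchor-gene location by translated local alignment,
# region extraction between/adjacent to anchors, per-genome DGR element
# detection and architecture tabulation.

six_frames <- function(genome) {
  L <- genome$length
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome$sequence else revcomp(genome$sequence)
    for (f in 0:2) {
      n_cod <- (L - f) %/% 3L
      if (n_cod < 1L) next
      aa <- translate_dna(substr(s, f + 1L, f + 3L * n_cod), "11")
      out[[length(out) + 1L]] <- list(aa = aa, strand = strand, frame = f)
    }
  }
  out
}

# genomic interval of an aa range [a1, a2] (1-based inclusive) in a frame
frame_to_genome_iv <- function(L, strand, frame, a1, a2) {
  nt1 <- frame + 3L * (a1 - 1L)
  nt2 <- frame + 3L * a2
  if (strand == "+") iv(nt1, nt2) else iv(L - nt2, L - nt1)
}

# best local protein alignment of `ref` against the six frames of a genome
best_protein_hit <- function(genome, ref, params) {
  frames <- six_frames(genome)
  scores <- vapply(frames, function(fr) pairwise_local_score(ref, fr$aa), numeric(1))
  best <- which.max(scores)
  bits <- (0.3176 * scores[best] - log(0.134)) / log(2)
  if (bits < params$anchor_score_min) return(NULL)
  fr <- frames[[best]]
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(gsub("[^ARNDCQEGHILKMFPSTWYVBZX*]", "X", ref)),
    Biostrings::AAString(gsub("[^ARNDCQEGHILKMFPSTWYVBZX*]", "X", fr$aa)),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  sub <- Biostrings::subject(al)
  ref_cov <- Biostrings::nchar(Biostrings::pattern(al)) / nchar(ref)
  list(
    bits = bits,
    interval = frame_to_genome_iv(genome$length, fr$strand, fr$frame,
                                  Biostrings::start(sub), Biostrings::end(sub)),
    strand = fr$strand,
    ref_coverage = ref_cov
  )
}

#' Locate anchor genes by translated local alignment
#'
#' Searches each labelled reference protein against all six reading frames
#' of the genome and reports the best hit per label at or above
#' `anchor_score_min` bits.
#'
#' @param genome A [genome_record()].
#' @param refs Named character vector of reference proteins (names are the
#'   anchor labels, e.g. `TNP`, `IHF`, `T-CFP`).
#' @param params A [dgr_params()] list.
#' @return A data frame with columns `genome_id`, `label`, `start`, `end`,
#'   `strand`, `score` (bits); one row per hit label.
#' @export
anchor_scan <- function(genome, refs, params = dgr_params()) {
  if (is.null(refs) || !length(refs)) stop("empty reference set")
  rows <- list()
  for (lab in names(refs)) {
    hit <- best_protein_hit(genome, refs[[lab]], params)
    if (is.null(hit)) next
    rows[[length(rows) + 1L]] <- data.frame(
      genome_id = genome$id, label = lab,
      start = unname(hit$interval["start"]), end = unname(hit$interval["end"]),
      strand = hit$strand, score = hit$bits, stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(genome_id = character(0), label = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Extract a genomic region adjacent to an anchor hit
#'
#' @param genome A [genome_record()].
#' @param anchor One row of an [anchor_scan()] result.
#' @param span Maximum region length in nt (default 7500).
#' @param side `"downstream"`, `"upstream"` or `"both"`, relative to the
#'   anchor's strand.
#' @return A `GenomeRegion` (a [genome_record()] with an `offset` field
#'   giving the region's 0-based genomic start, so a feature at region
#'   offset `x` lies at genome coordinate `offset + x`).
#' @export
extract_region <- function(genome, anchor, span = 7500L,
                           side = c("downstream", "upstream", "both")) {
  side <- match.arg(side)
  stopifnot(anchor$genome_id == genome$id)
  L <- genome$length
  fwd <- anchor$strand == "+"
  rng <- switch(side,
    downstream = if (fwd) c(anchor$end, anchor$end + span)
                 else c(anchor$start - span, anchor$start),
    upstream = if (fwd) c(anchor$start - span, anchor$start)
               else c(anchor$end, anchor$end + span),
    both = c(anchor$start - span, anchor$end + span)
  )
  rng <- pmin(pmax(rng, 0L), L)
  region <- genome_record(
    sprintf("%s:%d-%d", genome$id, rng[1], rng[2]),
    substr(genome$sequence, rng[1] + 1L, rng[2]),
    source = genome$source
  )
  region$offset <- as.integer(rng[1])
  region$parent_id <- genome$id
  class(region) <- c("GenomeRegion", class(region))
  region
}

# up to `max_hits` disjoint local DNA hits of ref in subject (mask & repeat)
dna_reference_hits <- function(subject, ref, score_min, max_hits = 2L) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = FALSE)
  hits <- list()
  subj <- subject
  for (i in seq_len(max_hits)) {
    if (nchar(subj) < 20L) break
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(ref), Biostrings::DNAString(subj),
      type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2
    )
    sc <- Biostrings::score(al)
    if (sc < score_min) break
    sub <- Biostrings::subject(al)
    s1 <- Biostrings::start(sub); e1 <- Biostrings::end(sub)
    hits[[length(hits) + 1L]] <- list(score = sc, interval = iv(s1 - 1L, e1))
    substr(subj, s1, e1) <- strrep("N", e1 - s1 + 1L)
  }
  hits
}

# Per-genome screen: anchor, region, detection, classification.
screen_one <- function(genome, refs, params, span) {
  anchor_labels <- intersect(c("TNP", "IHF"), names(refs$proteins))
  anchors <- if (length(anchor_labels)) {
    anchor_scan(genome, refs$proteins[anchor_labels], params)
  } else anchor_scan(genome, refs$proteins[1], params)
  tnp <- anchors[anchors$label == "TNP", , drop = FALSE]
  unanchored <- nrow(tnp) == 0L
  region <- if (!unanchored) {
    extract_region(genome, tnp[1, ], span = span, side = "downstream")
  } else {
    r <- genome
    r$offset <- 0L
    r$parent_id <- genome$id
    class(r) <- c("GenomeRegion", class(r))
    r
  }

  orfs <- find_orfs(region, min_len = params$orf_min_len)
  pairs <- if (region$length >= 2L * params$min_len) {
    find_repeat_pairs(region, params)
  } else list()
  oriented <- lapply(pairs, assign_tr_vr, bias_threshold = params$bias_threshold)
  rts <- if ("RT" %in% names(refs$proteins)) {
    detect_rt(orfs, "reference", refs = refs$proteins["RT"], params = params)
  } else {
    detect_rt(orfs, "motif", params = params)
  }
  cassettes <- assemble_cassette(region, orfs, oriented, rts,
                                 params = params, refs = refs$proteins)
  usable <- Filter(function(cs) !is.null(cs$vr), cassettes)
  cas <- if (length(usable)) usable[[1]] else new_cassette(genome$id)

  # reference-based fallbacks for elements invisible to the repeat finder
  if (is.null(cas$target_gene) && "TCFP" %in% names(refs$proteins)) {
    hit <- best_protein_hit(region, refs$proteins[["TCFP"]], params)
    if (!is.null(hit)) {
      full <- FALSE
      if (nrow(orfs)) {
        ref_len <- nchar(refs$proteins[["TCFP"]])
        for (i in seq_len(nrow(orfs))) {
          if (iv_overlap(orf_interval(orfs[i, ]), hit$interval) > 0L &&
              nchar(orfs$protein[i]) >= params$trunc_frac * ref_len) full <- TRUE
        }
      }
      cas$target_gene <- list(start = unname(hit$interval["start"]),
                              end = unname(hit$interval["end"]))
      cas$tg_status <- if (full) "full" else "truncated"
      if (is.null(cas$vr) && !is.null(refs$tr_dna)) {
        hits <- dna_reference_hits(region$sequence, refs$tr_dna,
                                   params$dna_score_min)
        for (h in hits) {
          near_tg <- iv_overlap(h$interval, hit$interval) > 0L ||
            gap_between(h$interval, hit$interval) <= params$tg_tol
          if (near_tg && is.null(cas$vr)) cas$vr <- h$interval
          else if (is.null(cas$tr)) cas$tr <- h$interval
        }
      }
    }
  }
  if (is.null(cas$rt) && "RT" %in% names(refs$proteins)) {
    if (nrow(rts)) {
      best_rt <- rts[which.max(nchar(rts$protein)), , drop = FALSE]
      cas$rt <- best_rt
      cas$rt_status <- orf_status(best_rt, refs$proteins, "RT", params)
    } else {
      hit <- best_protein_hit(region, refs$proteins[["RT"]], params)
      if (!is.null(hit) && hit$bits >= params$rt_score_min) {
        cas$rt <- list(start = unname(hit$interval["start"]),
                       end = unname(hit$interval["end"]))
        cas$rt_status <- "truncated"
      }
    }
  }
  cl <- classify_architecture(cas)

  offset <- region$offset
  shift <- function(x) if (is.null(x)) NULL else x + offset
  data.frame(
    genome_id = genome$id,
    class = cl$class,
    architecture = cl$architecture,
    unanchored = unanchored,
    has_tg = !is.null(cas$target_gene),
    tg_full = identical(cas$tg_status, "full"),
    has_vr = !is.null(cas$vr),
    has_tr = !is.null(cas$tr),
    has_imh = !is.null(cas$imh),
    has_rt = !is.null(cas$rt),
    rt_full = identical(cas$rt_status, "full"),
    vr_start = if (!is.null(cas$vr)) shift(unname(cas$vr["start"])) else NA_integer_,
    vr_end = if (!is.null(cas$vr)) shift(unname(cas$vr["end"])) else NA_integer_,
    tr_start = if (!is.null(cas$tr)) shift(unname(cas$tr["start"])) else NA_integer_,
    tr_end = if (!is.null(cas$tr)) shift(unname(cas$tr["end"])) else NA_integer_,
    error = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Screen a cohort of genomes for DGR cassettes
#'
#' For each genome: locate the TNP anchor by translated local alignment,
#' take the region downstream of it (whole genome, flagged `unanchored`,
#' when no anchor is found), detect repeat pairs, orient them, call
#' IMH/IMH*, find RT genes in reference mode, assemble and classify the
#' cassette, and apply reference-based fallback calls for target-gene and
#' VR presence in genomes whose repeat pair is degraded.  Per-genome
#' failures are recorded in the output, not fatal.
#'
#' @param genomes List of [genome_record()] objects.
#' @param refs Reference panel: a list with `proteins` (named amino-acid
#'   sequences including `TNP`, `IHF`, `RT`, `TCFP`) and optional `tr_dna`.
#' @param params A [dgr_params()] list.
#' @param span Region span in nt screened downstream of the anchor
#'   (default 7500).
#' @return A `CohortSummary`: `per_genome` (data frame), `counts` and
#'   `percentages` per class (percentages rounded half-up to integers),
#'   `element_counts`, `n`.
#' @export
screen_cohort <- function(genomes, refs, params = dgr_params(), span = 7500L) {
  if (!length(genomes)) stop("no genomes")
  rows <- lapply(genomes, function(g) {
    tryCatch(screen_one(g, refs, params, span), error = function(e) {
      data.frame(genome_id = g$id, class = "error", architecture = "",
                 unanchored = NA, has_tg = NA, tg_full = NA, has_vr = NA,
                 has_tr = NA, has_imh = NA, has_rt = NA, rt_full = NA,
                 vr_start = NA_integer_, vr_end = NA_integer_,
                 tr_start = NA_integer_, tr_end = NA_integer_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  per_genome <- do.call(rbind, rows)
  classes <- c("complete", "incomplete", "absent")
  counts <- vapply(classes, function(cl) sum(per_genome$class == cl), integer(1))
  if (any(per_genome$class == "error")) {
    counts <- c(counts, error = sum(per_genome$class == "error"))
  }
  n <- nrow(per_genome)
  percentages <- vapply(counts, function(x) round_half_up(100 * x / n), numeric(1))
  element_counts <- c(
    TCFP = sum(per_genome$has_tg, na.rm = TRUE),
    VR = sum(per_genome$has_vr, na.rm = TRUE),
    TR = sum(per_genome$has_tr, na.rm = TRUE),
    RT = sum(per_genome$has_rt, na.rm = TRUE)
  )
  structure(list(per_genome = per_genome, counts = counts,
                 percentages = percentages, element_counts = element_counts,
                 n = n),
            class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat(sprintf("<CohortSummary> %d genomes: %s\n", x$n,
              paste(sprintf("%s %d (%d%%)", names(x$counts), x$counts,
                            x$percentages), collapse = ", ")))
  invisible(x)
}

#' Write a cohort summary as TSV
#' @param summary A `CohortSummary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
cohort_to_tsv <- function(summary, path) {
  utils::write.table(summary$per_genome, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a cohort summary as JSON
#' @param summary A `CohortSummary`.
#' @param path Output path.
#' @param provenance Optional named list echoed into the file.
#' @return `path`, invisibly.
#' @export
cohort_to_json <- function(summary, path, provenance = NULL) {
  payload <- list(
    n = summary$n,
    counts = as.list(summary$counts),
    percentages = as.list(summary$percentages),
    element_counts = as.list(summary$element_counts),
    per_genome = summary$per_genome
  )
  if (!is.null(provenance)) payload$provenance <- provenance
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Text report grouping genomes by cassette architecture
#'
#' @param summary A `CohortSummary`.
#' @return Character vector of report lines (one block per architecture,
#'   most common first).
#' @export
cohort_report <- function(summary) {
  pg <- summary$per_genome
  arch <- ifelse(nzchar(pg$architecture), pg$architecture, "(no DGR elements)")
  tab <- sort(table(arch), decreasing = TRUE)
  lines <- c(sprintf("# %d genomes, %d architectures", summary$n, length(tab)), "")
  for (a in names(tab)) {
    ids <- pg$genome_id[arch == a]
    lines <- c(lines,
               sprintf("%-40s %3d genomes", a, tab[[a]]),
               paste0("    ", paste(ids, collapse = " ")), "")
  }
  lines
}
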