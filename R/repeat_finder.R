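# Repeat-pair discovery: exact k-mer seeding followed by gap-free diagonal
# extension with X-drop termination.  Mismatch penalties are softened when
# either base is adenine so that extension is not stopped by the A-to-N
# mismatch spectrum characteristic of DGR repeats; precise boundary placement
# is deferred to the probabilistic refinement in cassette assembly.

DISC_MATCH <- 1
DISC_MM_A <- -0.3
DISC_MM <- -3

#' Find near-identical repeat pairs in a genome
#'
#' Seeds on shared exact k-mers, extends each seed diagonal without gaps
#' under an adenine-tolerant scoring scheme, trims each end to its maximal
#' cumulative score, and reports deduplicated pairs passing the length,
#' identity and separation filters in `params`.  Both same-strand pairs and
#' pairs in which the second copy lies on the reverse strand (`inverted`)
#' are searched.
#'
#' @param genome A [genome_record()].
#' @param params A [dgr_params()] list.
#' @return A list of `RepeatPair` objects ordered by leftmost coordinate
#'   then decreasing score.  Each has fields `genome_id`, `interval_a`,
#'   `interval_b` (0-based half-open, forward strand; `interval_a` is the
#'   leftmost copy for same-strand pairs), `inverted`, `alignment` (a data
#'   frame of aligned columns: `position_a`, `position_b`, `base_a`,
#'   `base_b`, `match`), `identity`, `length` and `score`.
#' @examples
#' seg <- paste(sample(c("A","C","G","T"), 105, TRUE), collapse = "")
#' g <- genome_record("g", paste0(strrep("ACGTC", 100), seg,
#'                                strrep("TTGCA", 100), seg,
#'                                strrep("GATTA", 100)))
#' length(find_repeat_pairs(g, dgr_params()))
#' @export
find_repeat_pairs <- function(genome, params = dgr_params()) {
  stopifnot(inherits(genome, "GenomeRecord"))
  L <- genome$length
  if (L < 2L * params$min_len) {
    stop("genome shorter than twice the minimum repeat length")
  }
  s <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  rc <- strsplit(revcomp(genome$sequence), "", fixed = TRUE)[[1]]
  k <- params$k

  fwd_seeds <- kmer_positions(genome$sequence, k)
  cands <- c(
    collect_candidates(s, s, fwd_seeds, fwd_seeds, params, same = TRUE),
    if (L >= k) collect_candidates(
      s, rc, fwd_seeds, kmer_positions(revcomp(genome$sequence), k),
      params, same = FALSE
    ) else list()
  )
  cands <- Filter(Negate(is.null), cands)
  if (!length(cands)) return(list())

  pairs <- lapply(cands, function(cd) build_repeat_pair(genome, s, rc, cd, params))
  pairs <- Filter(Negate(is.null), pairs)
  if (!length(pairs)) return(list())

  pairs <- dedup_pairs(pairs)
  ord <- order(vapply(pairs, function(p) min(p$interval_a["start"], p$interval_b["start"]),
                      numeric(1)),
               -vapply(pairs, `[[`, numeric(1), "score"))
  pairs[ord]
}

# positions (1-based) of each k-mer, N-free only
kmer_positions <- function(sequence, k) {
  L <- nchar(sequence)
  if (L < k) return(split(integer(0), character(0)))
  starts <- seq_len(L - k + 1L)
  kmers <- substring(sequence, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  split(starts[ok], kmers[ok])
}

# Enumerate seed pairs and extend them; returns list of candidate descriptors.
collect_candidates <- function(s1, s2, idx1, idx2, params, same) {
  k <- params$k
  keys <- if (same) {
    names(idx1)[lengths(idx1) >= 2L]
  } else {
    intersect(names(idx1), names(idx2))
  }
  covered <- new.env(parent = emptyenv())   # per-diagonal extended ranges
  out <- list()
  for (key in keys) {
    p1 <- idx1[[key]]
    p2 <- if (same) p1 else idx2[[key]]
    if (length(p1) > params$max_kmer_occ || length(p2) > params$max_kmer_occ) next
    for (i in p1) {
      for (j in p2) {
        if (same && j <= i) next
        d <- j - i
        dkey <- paste0(if (same) "f" else "r", d)
        rngs <- covered[[dkey]]
        if (!is.null(rngs) &&
            any(i >= rngs[, 1L] & i <= rngs[, 2L])) next
        ext <- extend_seed(s1, s2, i, j, k, params, same)
        covered[[dkey]] <- rbind(rngs, c(ext$aL, ext$aR))
        out[[length(out) + 1L]] <- c(ext, list(same = same))
      }
    }
  }
  out
}

disc_score <- function(a, b) {
  if (a == b) {
    if (a == "N") 0 else DISC_MATCH
  } else if (a == "A" || b == "A") DISC_MM_A else DISC_MM
}

# Gap-free extension of a seed; returns trimmed 1-based inclusive endpoints
# in the coordinate systems of s1 and s2.
extend_seed <- function(s1, s2, i, j, k, params, same) {
  L1 <- length(s1); L2 <- length(s2)
  max_cols <- params$max_len + 30L
  d <- j - i
  # rightward from the seed end
  best_r <- 0; cum <- 0; step_r <- 0L
  a <- i + k; b <- j + k
  n_r <- 0L
  while (a <= L1 && b <= L2 && (k + n_r) < max_cols && (!same || a < j)) {
    cum <- cum + disc_score(s1[a], s2[b])
    n_r <- n_r + 1L
    if (cum > best_r) { best_r <- cum; step_r <- n_r }
    if (cum < best_r - params$xdrop) break
    a <- a + 1L; b <- b + 1L
  }
  # leftward from the seed start
  best_l <- 0; cum <- 0; step_l <- 0L
  a <- i - 1L; b <- j - 1L
  n_l <- 0L
  while (a >= 1L && b >= 1L && (k + step_r + n_l) < max_cols && (!same || b > i + k - 1L)) {
    cum <- cum + disc_score(s1[a], s2[b])
    n_l <- n_l + 1L
    if (cum > best_l) { best_l <- cum; step_l <- n_l }
    if (cum < best_l - params$xdrop) break
    a <- a - 1L; b <- b - 1L
  }
  list(aL = i - step_l, aR = i + k - 1L + step_r,
       bL = j - step_l, bR = j + k - 1L + step_r,
       score = k * DISC_MATCH + best_l + best_r)
}

# Symmetric (orientation-agnostic) column log-likelihood ratios of
# "homologous repeat with A-to-N mutagenesis" vs "unrelated flanks";
# mismatches involving adenine are only weak evidence against homology.
symmetric_llr <- function(a, b) {
  m <- a == b & a != "N" & b != "N"
  anyA <- a == "A" | b == "A"
  out <- ifelse(m & !anyA, 1.45,
         ifelse(m, -0.27,
         ifelse(anyA, -0.82, -3.39)))
  out[a == "N" | b == "N"] <- 0
  out
}

# maximal-scoring contiguous subsegment (Kadane); returns c(start, end)
# indices or NULL when all scores are negative
max_subsegment <- function(sc) {
  best <- -Inf; best_i <- 0L; best_j <- -1L
  cur <- 0; cur_i <- 1L
  for (j in seq_along(sc)) {
    if (cur <= 0) { cur <- sc[j]; cur_i <- j } else cur <- cur + sc[j]
    if (cur > best) { best <- cur; best_i <- cur_i; best_j <- j }
  }
  if (best_j < best_i || best <= 0) return(NULL)
  c(best_i, best_j)
}

# Turn an extension into a RepeatPair, applying all filters; NULL if rejected.
build_repeat_pair <- function(genome, s, rc, cd, params) {
  # trim the rough extension to its maximal-scoring subsegment so that the
  # alignment entering orientation is not padded with unrelated flank columns
  a_all <- s[cd$aL:cd$aR]
  b_all <- if (cd$same) s[cd$bL:cd$bR] else rc[cd$bL:cd$bR]
  seg <- max_subsegment(symmetric_llr(a_all, b_all))
  if (is.null(seg)) return(NULL)
  cd$aL <- cd$aL + seg[1L] - 1L; cd$aR <- cd$aL + (seg[2L] - seg[1L])
  cd$bL <- cd$bL + seg[1L] - 1L; cd$bR <- cd$bL + (seg[2L] - seg[1L])
  len <- cd$aR - cd$aL + 1L
  if (len < params$min_len || len > params$max_len) return(NULL)
  L <- genome$length
  if (cd$same) {
    iv_a <- iv(cd$aL - 1L, cd$aR)
    iv_b <- iv(cd$bL - 1L, cd$bR)
    bases_b <- s[cd$bL:cd$bR]
    pos_b <- (cd$bL:cd$bR) - 1L
  } else {
    iv_a <- iv(cd$aL - 1L, cd$aR)
    iv_b <- iv(L - cd$bR, L - cd$bL + 1L)     # map reverse-strand copy to forward
    bases_b <- rc[cd$bL:cd$bR]
    pos_b <- L - (cd$bL:cd$bR)                # forward 0-based of each aligned base
  }
  if (iv_overlap(iv_a, iv_b) > 0L) return(NULL)
  sep <- max(iv_a["start"], iv_b["start"]) - min(iv_a["end"], iv_b["end"])
  if (sep > params$max_separation) return(NULL)
  bases_a <- s[cd$aL:cd$aR]
  match <- bases_a == bases_b & bases_a != "N"
  identity <- mean(match)
  if (identity < params$min_identity) return(NULL)
  structure(list(
    genome_id = genome$id,
    interval_a = iv_a, interval_b = iv_b,
    inverted = !cd$same,
    alignment = data.frame(
      position_a = (cd$aL:cd$aR) - 1L, position_b = pos_b,
      base_a = bases_a, base_b = bases_b, match = match,
      stringsAsFactors = FALSE
    ),
    identity = identity, length = len, score = cd$score
  ), class = "RepeatPair")
}

# Greedy containment dedup: keep highest-scoring representative of pairs
# whose copies both overlap a kept pair by >= 50%.
dedup_pairs <- function(pairs) {
  ord <- order(-vapply(pairs, `[[`, numeric(1), "score"),
               vapply(pairs, function(p) p$interval_a["start"], numeric(1)))
  kept <- list()
  for (p in pairs[ord]) {
    dup <- any(vapply(kept, function(q) {
      (iv_overlap_frac(p$interval_a, q$interval_a) >= 0.5 &&
         iv_overlap_frac(p$interval_b, q$interval_b) >= 0.5) ||
      (iv_overlap_frac(p$interval_a, q$interval_b) >= 0.5 &&
         iv_overlap_frac(p$interval_b, q$interval_a) >= 0.5)
    }, logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- p
  }
  kept
}

#' @export
print.RepeatPair <- function(x, ...) {
  cat(sprintf("<RepeatPair> %s [%d,%d) ~ [%d,%d)%s len=%d id=%.3f\n",
              x$genome_id, x$interval_a["start"], x$interval_a["end"],
              x$interval_b["start"], x$interval_b["end"],
              if (x$inverted) " (inverted)" else "",
              x$length, x$identity))
  invisible(x)
}
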