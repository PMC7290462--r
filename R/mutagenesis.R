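# A-to-N mutagenesis statistics, exact theoretical diversity and
# amino-acid consensus logos for VR alignments.

#' Compare a variable repeat against its template repeat
#'
#' Position-by-position classification of mismatches between a gap-free
#' aligned VR/TR pair: mismatches at positions where the TR carries `A`
#' are A-to-N events (the retrohoming signature); all others are
#' non-A-to-N.
#'
#' @param vr,tr Equal-length DNA strings (the gap-free aligned pair).
#' @param frame_offset Offset (0..2) of the first complete codon.
#' @return A `MutagenesisReport` list: `n_codons`, `n_adenines_tr`,
#'   `n_aton_variable`, `n_non_aton` and `variable_positions` (data frame
#'   of `offset` (0-based), `tr_base`, `vr_base`).
#' @examples
#' compare_vr_tr("ACGTTTGCA", "AAATTTGCA")
#' @export
compare_vr_tr <- function(vr, tr, frame_offset = 0L) {
  stopifnot(frame_offset %in% 0:2)
  if (nchar(vr) != nchar(tr)) {
    stop("VR and TR must have equal length (gap-free alignment required)")
  }
  vr <- toupper(vr); tr <- toupper(tr)
  v <- strsplit(vr, "", fixed = TRUE)[[1]]
  t_ <- strsplit(tr, "", fixed = TRUE)[[1]]
  mm <- which(v != t_)
  aton <- mm[t_[mm] == "A"]
  structure(list(
    n_codons = (nchar(tr) - frame_offset) %/% 3L,
    n_adenines_tr = sum(t_ == "A"),
    n_aton_variable = length(aton),
    n_non_aton = length(mm) - length(aton),
    variable_positions = data.frame(
      offset = mm - 1L, tr_base = t_[mm], vr_base = v[mm],
      stringsAsFactors = FALSE
    )
  ), class = "MutagenesisReport")
}

#' @export
print.MutagenesisReport <- function(x, ...) {
  cat(sprintf("<MutagenesisReport> %d codons, %d TR adenines, %d A-to-N + %d other mismatches\n",
              x$n_codons, x$n_adenines_tr, x$n_aton_variable, x$n_non_aton))
  invisible(x)
}

# Distinct translation outcomes of one codon when its adenines are free to
# be any base.  Returns the count under the requested stop handling.
codon_outcomes <- function(codon, stop_handling, gc) {
  a_pos <- which(strsplit(codon, "", fixed = TRUE)[[1]] == "A")
  if (!length(a_pos)) {
    aa <- unname(gc[codon])
    if (is.na(aa)) aa <- "X"
    return(if (stop_handling == "exclude" && aa == "*") 0L else 1L)
  }
  bases <- c("A", "C", "G", "T")
  variants <- codon
  for (p in a_pos) {
    variants <- unlist(lapply(variants, function(v) {
      vapply(bases, function(b) { substr(v, p, p) <- b; v }, character(1))
    }))
  }
  aa <- unname(gc[variants])
  aa[is.na(aa)] <- "X"
  if (stop_handling == "exclude") aa <- aa[aa != "*"]
  length(unique(aa))
}

#' Exact theoretical diversity of a template repeat
#'
#' With every adenine of the TR free to become any base during reverse
#' transcription, the number of reachable DNA sequences is exactly
#' `4^A` where `A` is the adenine count.  Protein diversity is the product
#' over codons of the number of distinct translation outcomes reachable by
#' substituting that codon's adenines (codons vary independently, so the
#' product is exact).  Both counts are computed in arbitrary precision.
#'
#' @param tr TR DNA string.
#' @param frame_offset Offset (0..2) of the first complete codon.
#' @param stop_handling `"exclude"` (default) drops variant codons that
#'   translate to a stop before counting; `"include"` counts the stop as an
#'   ordinary outcome symbol.
#' @param code Genetic-code table id (default `"11"`).
#' @return A `DiversitySummary` list: `n_adenines`, `dna_variants` /
#'   `protein_variants` (exact decimal strings), `dna_order_of_magnitude` /
#'   `protein_order_of_magnitude` (nearest integer of log10), `dna_log10`,
#'   `protein_log10`, `stop_handling`.
#' @examples
#' diversity("GCA")$dna_variants       # "4": one adenine
#' diversity("GCA")$protein_variants   # "1": GCN is synonymous
#' @export
diversity <- function(tr, frame_offset = 0L, stop_handling = c("exclude", "include"),
                      code = "11") {
  stop_handling <- match.arg(stop_handling)
  stopifnot(frame_offset %in% 0:2)
  tr <- toupper(tr)
  if (!nzchar(tr)) stop("empty sequence")
  if (nchar(tr) - frame_offset < 3L) stop("no complete codon at this frame offset")
  gc <- genetic_code_table(code)
  n_a <- sum(strsplit(tr, "", fixed = TRUE)[[1]] == "A")
  dna <- big_pow_small(4, n_a)
  n_cod <- (nchar(tr) - frame_offset) %/% 3L
  starts <- frame_offset + 3L * (seq_len(n_cod) - 1L) + 1L
  codons <- substring(tr, starts, starts + 2L)
  factors <- vapply(codons, codon_outcomes, integer(1),
                    stop_handling = stop_handling, gc = gc)
  prot <- big_prod_small(factors)
  structure(list(
    n_adenines = n_a,
    dna_variants = big_to_string(dna),
    dna_order_of_magnitude = as.integer(round(big_log10(dna))),
    dna_log10 = big_log10(dna),
    protein_variants = big_to_string(prot),
    protein_order_of_magnitude = if (big_is_zero(prot)) NA_integer_
                                 else as.integer(round(big_log10(prot))),
    protein_log10 = big_log10(prot),
    stop_handling = stop_handling
  ), class = "DiversitySummary")
}

#' @export
print.DiversitySummary <- function(x, ...) {
  cat(sprintf("<DiversitySummary> %d adenines: %s DNA (~10^%d), %s protein (~10^%s) [stops: %s]\n",
              x$n_adenines, x$dna_variants, x$dna_order_of_magnitude,
              x$protein_variants, x$protein_order_of_magnitude, x$stop_handling))
  invisible(x)
}

#' Brute-force diversity by exhaustive enumeration
#'
#' Independent oracle for [diversity()]: enumerates all `4^A` DNA variants
#' explicitly, translates each, and counts distinct DNA and protein
#' sequences.  Refuses inputs with more than 10 adenines.
#'
#' @inheritParams diversity
#' @return A `DiversitySummary` (exact strings, as [diversity()]).
#' @export
diversity_bruteforce <- function(tr, stop_handling = c("exclude", "include"),
                                 code = "11") {
  stop_handling <- match.arg(stop_handling)
  tr <- toupper(tr)
  if (!nzchar(tr)) stop("empty sequence")
  chars <- strsplit(tr, "", fixed = TRUE)[[1]]
  a_pos <- which(chars == "A")
  if (length(a_pos) > 10L) stop("too many adenines for enumeration (> 10)")
  bases <- c("A", "C", "G", "T")
  grid <- if (length(a_pos)) {
    do.call(expand.grid, c(rep(list(bases), length(a_pos)),
                           list(stringsAsFactors = FALSE)))
  } else data.frame(row.names = 1)
  n_cod <- nchar(tr) %/% 3L
  variants <- character(nrow(grid))
  prots <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    v <- chars
    if (length(a_pos)) v[a_pos] <- as.character(grid[i, ])
    dna <- paste(v, collapse = "")
    variants[i] <- dna
    prots[i] <- if (n_cod > 0L) {
      translate_dna(substr(dna, 1L, 3L * n_cod), code)
    } else ""
  }
  if (stop_handling == "exclude") {
    prots <- prots[!grepl("*", prots, fixed = TRUE)]
  }
  n_dna <- length(unique(variants))
  n_prot <- length(unique(prots))
  dna_b <- big_from_int(n_dna)
  prot_b <- big_from_int(n_prot)
  structure(list(
    n_adenines = length(a_pos),
    dna_variants = big_to_string(dna_b),
    dna_order_of_magnitude = as.integer(round(big_log10(dna_b))),
    dna_log10 = big_log10(dna_b),
    protein_variants = big_to_string(prot_b),
    protein_order_of_magnitude = if (n_prot == 0L) NA_integer_
                                 else as.integer(round(big_log10(prot_b))),
    protein_log10 = big_log10(prot_b),
    stop_handling = stop_handling
  ), class = "DiversitySummary")
}

#' Build a per-position amino-acid frequency logo
#'
#' Computes per-column amino-acid frequencies (over the 20 standard
#' residues; gaps and non-standard symbols are excluded from the counts)
#' and the information content `R = log2(20) - H`, where `H` is the column
#' Shannon entropy in bits.  No small-sample correction is applied by
#' default, matching common sequence-logo practice.
#'
#' @param aligned_aa Character vector of equal-length aligned amino-acid
#'   strings; `-` marks gaps.
#' @param small_sample_correction If `TRUE`, subtract the standard
#'   correction `e_n = 19 / (2 ln 2 * n)` from each column's information
#'   content (floored at 0), with `n` the column's counted depth.
#' @return A `PositionLogo` list: `alignment_depth`, `frequencies` (matrix
#'   positions x 20), `information_content` (bits per position),
#'   `counted_depth` (non-gap residues per column).
#' @examples
#' lg <- build_logo(c("MK", "MK", "MR"))
#' lg$information_content
#' @export
build_logo <- function(aligned_aa, small_sample_correction = FALSE) {
  if (!length(aligned_aa)) stop("empty alignment")
  lens <- nchar(aligned_aa)
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  width <- lens[1]
  mat <- matrix(unlist(strsplit(toupper(aligned_aa), "", fixed = TRUE)),
                nrow = length(aligned_aa), ncol = width, byrow = TRUE)
  freqs <- matrix(0, nrow = width, ncol = 20L, dimnames = list(NULL, aa20))
  ic <- numeric(width)
  depth <- integer(width)
  for (j in seq_len(width)) {
    col <- mat[, j]
    col <- col[col %in% aa20]
    depth[j] <- length(col)
    if (!length(col)) { ic[j] <- 0; next }
    tab <- table(factor(col, levels = aa20))
    p <- as.numeric(tab) / length(col)
    freqs[j, ] <- p
    nz <- p[p > 0]
    h <- -sum(nz * log2(nz))
    r <- log2(20) - h
    if (small_sample_correction) {
      r <- max(0, r - 19 / (2 * log(2) * length(col)))
    }
    ic[j] <- r
  }
  structure(list(
    alignment_depth = length(aligned_aa),
    frequencies = freqs,
    information_content = ic,
    counted_depth = depth
  ), class = "PositionLogo")
}

#' @export
print.PositionLogo <- function(x, ...) {
  cat(sprintf("<PositionLogo> %d sequences x %d positions, IC %.2f-%.2f bits\n",
              x$alignment_depth, length(x$information_content),
              min(x$information_content), max(x$information_content)))
  invisible(x)
}

#' Export a logo as a TSV matrix
#'
#' One row per alignment position: residue frequencies, counted depth and
#' the information-content column (bits).
#'
#' @param logo A `PositionLogo` from [build_logo()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
logo_to_tsv <- function(logo, path) {
  df <- data.frame(position = seq_along(logo$information_content),
                   logo$frequencies,
                   depth = logo$counted_depth,
                   information_bits = logo$information_content,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a simple text-free logo profile
#'
#' Renders the per-position information content as a barplot (base
#' graphics); a lightweight stand-in for graphical logo rendering.
#'
#' @param logo A `PositionLogo`.
#' @param ... Passed to [graphics::barplot()].
#' @return The logo, invisibly.
#' @export
plot_logo <- function(logo, ...) {
  graphics::barplot(logo$information_content,
                    names.arg = seq_along(logo$information_content),
                    xlab = "position", ylab = "information (bits)",
                    ylim = c(0, log2(20)), ...)
  invisible(logo)
}
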