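# End-to-end detection pipeline and report writers.

#' Detect DGR cassettes in a genome
#'
#' Runs the full detection chain: ORF calling, repeat-pair discovery,
#' TR/VR orientation by adenine bias, boundary refinement, IMH/IMH*
#' calling, RT identification (reference mode when an RT reference is
#' supplied, catalytic-motif mode otherwise) and cassette assembly.
#'
#' @param genome A [genome_record()].
#' @param refs Optional reference panel (list with `proteins`, see
#'   [reference_panel()]), or a named character vector of proteins.
#' @param params A [dgr_params()] list.
#' @return A list with `cassettes` (ranked `DgrCassette` list), `orfs`,
#'   `pairs`, and `params`.
#' @examples
#' sim <- generate_genome_with_cassette(30000, spec = cassette_spec(seed = 7))
#' res <- detect_dgr(sim$genome)
#' res$cassettes[[1]]$class
#' @export
detect_dgr <- function(genome, refs = NULL, params = dgr_params()) {
  if (!is.null(refs) && !is.list(refs)) refs <- list(proteins = refs)
  orfs <- find_orfs(genome, min_len = params$orf_min_len,
                    code = params$genetic_code)
  pairs <- if (genome$length >= 2L * params$min_len) {
    find_repeat_pairs(genome, params)
  } else list()
  oriented <- lapply(pairs, assign_tr_vr, bias_threshold = params$bias_threshold)
  rts <- if (!is.null(refs) && "RT" %in% names(refs$proteins)) {
    detect_rt(orfs, "reference", refs = refs$proteins["RT"], params = params)
  } else {
    detect_rt(orfs, "motif", params = params)
  }
  cassettes <- assemble_cassette(genome, orfs, oriented, rts,
                                 params = params,
                                 refs = if (!is.null(refs)) refs$proteins else NULL)
  list(cassettes = cassettes, orfs = orfs, pairs = pairs, params = params)
}

#' Mutagenesis and diversity report for a detected cassette
#'
#' Extracts the VR and TR sequences of a cassette, classifies their
#' mismatches into A-to-N and non-A-to-N, and computes the exact
#' theoretical DNA and protein diversity of the TR under both stop-codon
#' conventions.
#'
#' @param genome The [genome_record()] the cassette was detected in.
#' @param cassette A `DgrCassette` with VR and TR intervals.
#' @return A list with `vr_seq`, `tr_seq`, `frame_offset`, `comparison`
#'   (a [compare_vr_tr()] report), `diversity_exclude_stops` and
#'   `diversity_include_stops` ([diversity()] summaries), and
#'   `target_protein_length` when the target gene is a called ORF.
#' @export
cassette_mutagenesis <- function(genome, cassette) {
  if (is.null(cassette$vr) || is.null(cassette$tr)) {
    stop("cassette lacks a VR/TR pair")
  }
  vr_seq <- extract_interval(genome, cassette$vr)
  tr_seq <- extract_interval(genome, cassette$tr)
  frame_offset <- 0L
  tglen <- NULL
  tg <- cassette$target_gene
  if (!is.null(tg) && is.data.frame(tg)) {
    if (tg$strand == "+") {
      frame_offset <- as.integer((3L - (cassette$vr["start"] - tg$start) %% 3L) %% 3L)
    }
    tglen <- nchar(tg$protein)
  }
  list(
    vr_seq = vr_seq,
    tr_seq = tr_seq,
    frame_offset = frame_offset,
    comparison = compare_vr_tr(vr_seq, tr_seq, frame_offset),
    diversity_exclude_stops = diversity(tr_seq, frame_offset, "exclude"),
    diversity_include_stops = diversity(tr_seq, frame_offset, "include"),
    target_protein_length = tglen
  )
}

provenance_block <- function(params, seed = NULL) {
  list(
    tool = "dgrscan",
    version = as.character(utils::packageVersion("dgrscan")),
    seed = seed,
    params = unclass(params)
  )
}

cassette_to_list <- function(cas) {
  ivl <- function(x) if (is.null(x)) NULL else list(start = unname(x["start"]),
                                                   end = unname(x["end"]))
  orfl <- function(o) {
    if (is.null(o)) return(NULL)
    if (is.data.frame(o)) list(start = o$start, end = o$end, strand = o$strand,
                               protein_length = nchar(o$protein))
    else list(start = o$start, end = o$end)
  }
  list(
    genome_id = cas$genome_id,
    class = cas$class,
    architecture = cas$architecture,
    score = cas$score,
    identity = cas$identity,
    adenine_bias = cas$adenine_bias,
    target_gene = orfl(cas$target_gene),
    tg_status = cas$tg_status,
    vr = ivl(cas$vr),
    tr = ivl(cas$tr),
    imh = if (!is.null(cas$imh)) list(
      imh = ivl(cas$imh$imh_interval),
      imh_star = ivl(cas$imh$imh_star_interval),
      length = cas$imh$length,
      identical = cas$imh$identical
    ) else NULL,
    rt = orfl(cas$rt),
    rt_status = cas$rt_status,
    note = cas$note
  )
}

#' Write a cassette detection report as JSON
#'
#' @param result A [detect_dgr()] result.
#' @param genome The genome it was computed from.
#' @param path Output path.
#' @param seed Optional seed echoed into the provenance block.
#' @return `path`, invisibly.
#' @export
write_cassette_json <- function(result, genome, path, seed = NULL) {
  best <- Filter(function(cs) !is.null(cs$vr) && !is.null(cs$tr),
                 result$cassettes)
  payload <- list(
    provenance = provenance_block(result$params, seed),
    genome = list(id = genome$id, length = genome$length, source = genome$source),
    n_cassettes = length(result$cassettes),
    cassettes = lapply(result$cassettes, cassette_to_list),
    mutagenesis = if (length(best)) {
      m <- cassette_mutagenesis(genome, best[[1]])
      list(
        n_codons = m$comparison$n_codons,
        n_adenines_tr = m$comparison$n_adenines_tr,
        n_aton_variable = m$comparison$n_aton_variable,
        n_non_aton = m$comparison$n_non_aton,
        dna_variants = m$diversity_exclude_stops$dna_variants,
        dna_order_of_magnitude = m$diversity_exclude_stops$dna_order_of_magnitude,
        protein_variants_exclude_stops = m$diversity_exclude_stops$protein_variants,
        protein_order_of_magnitude_exclude_stops =
          m$diversity_exclude_stops$protein_order_of_magnitude,
        protein_variants_include_stops = m$diversity_include_stops$protein_variants,
        protein_order_of_magnitude_include_stops =
          m$diversity_include_stops$protein_order_of_magnitude,
        target_protein_length = m$target_protein_length
      )
    } else NULL
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Write cassette elements as BED
#'
#' One line per element (TG, VR, IMH, TR, IMH*, RT), 0-based half-open as
#' per the BED standard; the name field is the element type.
#'
#' @param cassettes List of `DgrCassette` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cassette_bed <- function(cassettes, path) {
  lines <- character(0)
  for (ci in seq_along(cassettes)) {
    cas <- cassettes[[ci]]
    add <- function(interval, name) {
      if (is.null(interval)) return(invisible(NULL))
      lines[[length(lines) + 1L]] <<- sprintf("%s\t%d\t%d\t%s_%d",
        cas$genome_id, interval["start"], interval["end"], name, ci)
      invisible(NULL)
    }
    if (!is.null(cas$target_gene)) {
      tg <- cas$target_gene
      add(iv(tg$start, tg$end), if (identical(cas$tg_status, "full")) "TG" else "TG_truncated")
    }
    add(cas$vr, "VR")
    if (!is.null(cas$imh)) add(cas$imh$imh_interval, "IMH")
    add(cas$tr, "TR")
    if (!is.null(cas$imh)) add(cas$imh$imh_star_interval, "IMH_star")
    if (!is.null(cas$rt)) {
      rt <- cas$rt
      add(iv(rt$start, rt$end), if (identical(cas$rt_status, "full")) "RT" else "RT_truncated")
    }
  }
  writeLines(lines, path)
  invisible(path)
}
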