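# Sequence input/output, ORF calling and translation.
#
# Coordinate convention used throughout the package: 0-based half-open
# intervals on the forward strand.  GenBank's 1-based inclusive coordinates
# are converted at the parsing boundary; GFF3/BED export converts back to
# the respective standards.

#' Construct a genome record
#'
#' A `GenomeRecord` holds a single uppercase DNA sequence over the alphabet
#' `{A,C,G,T,N}` together with its identifier and a free-text source tag
#' (file path or accession).
#'
#' @param id Character identifier.
#' @param sequence DNA string; lowercase is accepted and uppercased, `U` is
#'   mapped to `T`.
#' @param source Free-text provenance (defaults to `""`).
#' @return An object of class `GenomeRecord` with fields `id`, `sequence`,
#'   `length` and `source`.
#' @examples
#' g <- genome_record("g1", "acgt")
#' g$length
#' @export
genome_record <- function(id, sequence, source = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- chartr("u", "t", sequence)
  sequence <- toupper(sequence)
  sequence <- chartr("U", "T", sequence)
  bad <- first_illegal_base(sequence)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' at position %d of sequence '%s'",
                 substr(sequence, bad, bad), bad, id))
  }
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence), source = source),
    class = "GenomeRecord"
  )
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("<GenomeRecord> %s: %d bp%s\n", x$id, x$length,
              if (nzchar(x$source)) paste0(" [", x$source, "]") else ""))
  invisible(x)
}

#' Read genome sequences from a FASTA file
#'
#' Sequences are uppercased, `U` is mapped to `T`, and any character outside
#' `{A,C,G,T,N}` raises an error naming the offending record and position.
#'
#' @param path Path to a FASTA file.
#' @return A list of [genome_record()] objects, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "acgt"), tf)
#' read_fasta(tf)[[1]]$sequence
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    genome_record(ids[i], as.character(set[[i]]), source = path)
  })
}

#' Write genome records to a FASTA file
#'
#' @param records A list of [genome_record()] objects (or a single one).
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "GenomeRecord")) records <- list(records)
  seqs <- Biostrings::DNAStringSet(vapply(records, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read a GenBank flat file
#'
#' A minimal parser for GenBank flat files with an `ORIGIN` block.  Simple
#' `CDS` feature locations of the forms `a..b` and `complement(a..b)` are
#' converted to [find_orfs()]-style records (0-based half-open, forward
#' strand coordinates); other location forms (e.g. `join(...)`) are skipped
#' with a warning.
#'
#' @param path Path to a GenBank flat file.
#' @return A list with elements `genome` (a [genome_record()]) and
#'   `orfs` (a data frame as returned by [find_orfs()], possibly empty).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  acc <- if (length(locus)) strsplit(trimws(locus[1]), "\\s+")[[1]][2] else basename(path)
  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("malformed GenBank file (no ORIGIN block): ", path)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1]][1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(endrec - 1L)]
  sequence <- gsub("[0-9 /]", "", paste(seq_lines, collapse = ""))
  genome <- genome_record(acc, sequence, source = path)

  # CDS feature locations
  feat_lines <- grep("^\\s{5}CDS\\s+", lines, value = TRUE)
  orfs <- list()
  for (fl in feat_lines) {
    loc <- trimws(sub("^\\s{5}CDS\\s+", "", fl))
    m <- regmatches(loc, regexec("^(complement\\()?<?(\\d+)\\.\\.>?(\\d+)\\)?$", loc))[[1]]
    if (length(m) == 0L) {
      warning("skipping unsupported CDS location: ", loc)
      next
    }
    strand <- if (nzchar(m[2])) "-" else "+"
    start1 <- as.integer(m[3]); end1 <- as.integer(m[4])
    if (is.na(start1) || is.na(end1) || start1 > end1 || end1 > genome$length) {
      stop("malformed feature location: ", loc)
    }
    start0 <- start1 - 1L; end0 <- end1            # 1-based inclusive -> 0-based half-open
    dna <- extract_interval(genome, iv(start0, end0))
    if (strand == "-") dna <- revcomp(dna)
    prot <- if (nchar(dna) %% 3 == 0L) {
      p <- translate_dna(dna)
      sub("\\*$", "", p)
    } else NA_character_
    frame <- if (strand == "+") start0 %% 3L else (genome$length - end0) %% 3L
    orfs[[length(orfs) + 1L]] <- data.frame(
      genome_id = genome$id, start = start0, end = end0, strand = strand,
      frame = frame, protein = prot, label = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  orfs <- if (length(orfs)) do.call(rbind, orfs) else empty_orf_table()
  list(genome = genome, orfs = orfs)
}

empty_orf_table <- function() {
  data.frame(genome_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), frame = integer(0), protein = character(0),
             label = character(0), stringsAsFactors = FALSE)
}

#' Reverse complement of a DNA string
#' @param dna DNA string over `{A,C,G,T,N}`.
#' @return The reverse complement string.
#' @export
revcomp <- function(dna) {
  if (!nzchar(dna)) return(dna)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Extract a subsequence by 0-based half-open interval
#' @noRd
extract_interval <- function(genome, interval) {
  substr(genome$sequence, interval["start"] + 1L, interval["end"])
}

#' Translate a DNA string
#'
#' Standard translation under an NCBI genetic-code table (default 11,
#' bacterial/archaeal/plant plastid, the conventional choice for phage
#' annotation).  Internal and terminal stop codons are rendered as `*`;
#' codons containing `N` translate to `X`.
#'
#' @param dna DNA string; its length must be a multiple of 3.
#' @param code NCBI genetic-code table id as a string (default `"11"`).
#' @return Amino-acid string (empty input gives `""`).
#' @examples
#' translate_dna("ATGGCA")  # "MA"
#' @export
translate_dna <- function(dna, code = "11") {
  stopifnot(is.character(dna), length(dna) == 1L)
  if (!nzchar(dna)) return("")
  if (nchar(dna) %% 3 != 0L) stop("sequence length is not a multiple of 3")
  dna <- toupper(dna)
  bad <- first_illegal_base(dna)
  if (bad > 0L) stop("illegal base at position ", bad)
  gc <- genetic_code_table(code)
  starts <- seq.int(1L, nchar(dna), by = 3L)
  aa <- gc[substring(dna, starts, starts + 2L)]
  aa[is.na(aa)] <- "X"     # codons containing N
  paste(aa, collapse = "")
}

# cached NCBI code tables (Biostrings is the source of truth)
.code_cache <- new.env(parent = emptyenv())

genetic_code_table <- function(code = "11") {
  tab <- .code_cache[[code]]
  if (is.null(tab)) {
    tab <- Biostrings::getGeneticCode(code)
    .code_cache[[code]] <- tab
  }
  tab
}

stop_codons <- function(code = "11") {
  gc <- genetic_code_table(code)
  names(gc)[gc == "*"]
}

#' Call open reading frames on both strands
#'
#' Finds all maximal start-to-stop ORFs in all three frames of both strands.
#' An ORF runs from the first start codon following the previous in-frame
#' stop through its terminating stop codon (inclusive); ORFs without a
#' terminating stop are not reported.  Coordinates are always given on the
#' forward strand, 0-based half-open; `frame` is the frame (0..2) on the
#' ORF's own strand.
#'
#' @param genome A [genome_record()].
#' @param min_len Minimum ORF length in nucleotides including the stop codon
#'   (default 150; must be >= 30 and a multiple of 3).
#' @param starts Character vector of start codons (default `"ATG"`).
#' @param code Genetic-code table id (default `"11"`).
#' @return A data frame with columns `genome_id`, `start`, `end`, `strand`,
#'   `frame`, `protein` (translation without the terminal stop; `N`-containing
#'   codons give `X`), `label` (NA), ordered by `start` then strand.
#' @examples
#' g <- genome_record("g", "ATGAAATAA")
#' find_orfs(g, min_len = 9)
#' @export
find_orfs <- function(genome, min_len = 150L, starts = "ATG", code = "11") {
  stopifnot(inherits(genome, "GenomeRecord"))
  if (min_len < 30L || min_len %% 3L != 0L) {
    stop("min_len must be >= 30 and a multiple of 3")
  }
  stops <- stop_codons(code)
  L <- genome$length
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") genome$sequence else revcomp(genome$sequence)
    for (frame in 0:2) {
      starts_pos <- seq.int(frame + 1L, by = 3L, length.out = (L - frame) %/% 3L)
      if (!length(starts_pos)) next
      codons <- substring(s, starts_pos, starts_pos + 2L)
      is_stop <- codons %in% stops
      is_start <- codons %in% starts
      stop_idx <- which(is_stop)
      prev <- 0L
      for (si in stop_idx) {
        seg <- if (prev + 1L <= si - 1L) (prev + 1L):(si - 1L) else integer(0)
        prev <- si
        if (!length(seg)) next
        st <- seg[is_start[seg]]
        if (!length(st)) next
        first_start <- st[1L]
        orf_nt <- (si - first_start + 1L) * 3L
        if (orf_nt < min_len) next
        a1 <- starts_pos[first_start]              # 1-based on this strand
        b1 <- starts_pos[si] + 2L
        if (strand == "+") {
          start0 <- a1 - 1L; end0 <- b1
        } else {
          start0 <- L - b1; end0 <- L - a1 + 1L
        }
        prot <- translate_dna(paste(codons[first_start:(si - 1L)], collapse = ""), code)
        out[[length(out) + 1L]] <- data.frame(
          genome_id = genome$id, start = start0, end = end0, strand = strand,
          frame = frame, protein = prot, label = NA_character_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) return(empty_orf_table())
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand, method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write ORFs as GFF3
#'
#' Coordinates are converted to the GFF3 standard (1-based inclusive).
#'
#' @param orfs ORF table from [find_orfs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
orfs_to_gff3 <- function(orfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(orfs)) {
    lines <- sprintf("%s\tdgrscan\tCDS\t%d\t%d\t.\t%s\t0\tID=orf%04d%s",
                     orfs$genome_id, orfs$start + 1L, orfs$end, orfs$strand,
                     seq_len(nrow(orfs)),
                     ifelse(is.na(orfs$label), "", paste0(";label=", orfs$label)))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write ORFs as TSV (0-based half-open coordinates)
#'
#' @param orfs ORF table from [find_orfs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
orfs_to_tsv <- function(orfs, path) {
  utils::write.table(orfs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
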