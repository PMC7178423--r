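# Coordinate convention: every in-memory interval is 0-based half-open.
# GTF (1-based closed) is converted at the read/write boundary; BED12 and
# bedgraph are native 0-based half-open.

#' Construct an interval table
#'
#' @param start,end Integer vectors of 0-based half-open coordinates.
#' @return A data.frame with columns `start` and `end`.
#' @keywords internal
intervals <- function(start = integer(), end = integer()) {
  stopifnot(length(start) == length(end))
  data.frame(start = as.integer(start), end = as.integer(end))
}

as_intervals <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("start", "end") %in% names(x)))
    intervals(x$start, x$end)
  } else if (is.numeric(x) && length(x) == 2L) {
    intervals(x[1L], x[2L])
  } else {
    stop("cannot interpret object as interval table", call. = FALSE)
  }
}

interval_width <- function(ivs) sum(ivs$end - ivs$start)

#' Create a transcript model
#'
#' A transcript model holds the exon structure and (possibly empty) 3'-UTR
#' annotation of one transcript on one chromosome and strand. Exons must be
#' sorted by genomic start, pairwise non-overlapping, and every 3'-UTR
#' interval must be contained in the exon union.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Interval data.frame (0-based half-open) of exons.
#' @param utr3 Interval data.frame of annotated 3'-UTR pieces (may be empty).
#' @param biotype Transcript biotype; only `"protein_coding"` models enter
#'   the reannotation and target-prediction stages.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons,
                             utr3 = intervals(), gene_id = NA_character_,
                             biotype = "protein_coding") {
  m <- structure(list(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    biotype = as.character(biotype),
    chrom = as.character(chrom),
    strand = as.character(strand),
    exons = as_intervals(exons),
    utr3 = as_intervals(utr3)
  ), class = "transcript_model")
  validate_model(m)
  m
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s strand %s\n",
              x$transcript_id, x$biotype, x$chrom,
              paste0(min(x$exons$start), "-", max(x$exons$end)), x$strand))
  cat(sprintf("  exons: %d; 3'-UTR intervals: %d (%d nt)\n",
              nrow(x$exons), nrow(x$utr3), interval_width(x$utr3)))
  invisible(x)
}

validate_model <- function(m) {
  id <- m$transcript_id
  if (!m$strand %in% c("+", "-"))
    stop(sprintf("transcript %s: strand must be '+' or '-'", id), call. = FALSE)
  ex <- m$exons
  if (nrow(ex) == 0L)
    stop(sprintf("transcript %s: model has no exons", id), call. = FALSE)
  if (any(ex$end <= ex$start) || any(ex$start < 0L))
    stop(sprintf("transcript %s: invalid exon coordinates", id), call. = FALSE)
  if (is.unsorted(ex$start, strictly = FALSE))
    stop(sprintf("transcript %s: exons not sorted by start", id), call. = FALSE)
  if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)]))
    stop(sprintf("transcript %s: exons overlap", id), call. = FALSE)
  u <- m$utr3
  if (nrow(u) > 0L) {
    if (any(u$end <= u$start))
      stop(sprintf("transcript %s: invalid 3'-UTR coordinates", id), call. = FALSE)
    ord <- order(u$start)
    if (nrow(u) > 1L && any(u$start[ord][-1L] < u$end[ord][-nrow(u)]))
      stop(sprintf("transcript %s: 3'-UTR intervals overlap", id), call. = FALSE)
    # containment in exon union, interval by interval
    for (i in seq_len(nrow(u))) {
      inside <- any(ex$start <= u$start[i] & u$end[i] <= ex$end)
      if (!inside)
        stop(sprintf("transcript %s: 3'-UTR interval [%d,%d) not contained in an exon",
                     id, u$start[i], u$end[i]), call. = FALSE)
    }
  }
  invisible(m)
}

#' Does the model carry a single-interval 3'-UTR annotation?
#' @param model A `transcript_model`.
#' @return Logical scalar.
#' @export
single_exon_utr3 <- function(model) nrow(model$utr3) == 1L

#' Annotated 3'-UTR length of a model (nt)
#' @param model A `transcript_model`.
#' @export
utr3_length <- function(model) interval_width(model$utr3)

# 5' edge of the 3'-UTR in genomic coordinates (start on +, end on -)
utr3_five_prime_edge <- function(model) {
  if (nrow(model$utr3) == 0L) return(NA_integer_)
  if (model$strand == "+") min(model$utr3$start) else max(model$utr3$end)
}

# distal (3') edge of the 3'-UTR in genomic coordinates
utr3_distal_edge <- function(model) {
  if (nrow(model$utr3) == 0L) return(NA_integer_)
  if (model$strand == "+") max(model$utr3$end) else min(model$utr3$start)
}

model_span <- function(model) c(min(model$exons$start), max(model$exons$end))

## ---------------------------------------------------------------- GTF ----

parse_gtf_attributes <- function(attr) {
  # tolerate `key "value";`, `key"value";` and trailing-; variants
  m <- gregexpr('([A-Za-z_][A-Za-z0-9_]*)\\s*"([^"]*)"', attr)
  hits <- regmatches(attr, m)[[1L]]
  keys <- sub('^([A-Za-z_][A-Za-z0-9_]*)\\s*".*$', "\\1", hits)
  vals <- sub('^[A-Za-z_][A-Za-z0-9_]*\\s*"([^"]*)"$', "\\1", hits)
  stats::setNames(vals, keys)
}

#' Read transcript models from a GTF file
#'
#' Parses `exon` and `three_prime_utr` features of an Ensembl-dialect GTF
#' into [transcript_model] objects. GTF 1-based closed coordinates are
#' converted to the package's 0-based half-open convention. Transcripts
#' without any `three_prime_utr` feature get an empty `utr3` table.
#'
#' @param path Path to a GTF file.
#' @return A named list of `transcript_model` objects (in order of first
#'   appearance).
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated columns, found %d",
                 lineno[bad], nf[bad]), call. = FALSE)
  }
  tab <- do.call(rbind, fields)
  feat <- tab[, 3L]
  sel <- feat %in% c("exon", "three_prime_utr")
  if (!any(sel)) return(list())
  tab <- tab[sel, , drop = FALSE]
  lineno <- lineno[sel]
  start0 <- suppressWarnings(as.integer(tab[, 4L])) - 1L
  end0 <- suppressWarnings(as.integer(tab[, 5L]))
  if (anyNA(start0) || anyNA(end0)) {
    bad <- which(is.na(start0) | is.na(end0))[1L]
    stop(sprintf("malformed GTF line %d: non-numeric coordinates", lineno[bad]),
         call. = FALSE)
  }
  if (any(end0 <= start0)) {
    bad <- which(end0 <= start0)[1L]
    stop(sprintf("invalid GTF line %d: end precedes start after coordinate conversion",
                 lineno[bad]), call. = FALSE)
  }
  attrs <- lapply(tab[, 9L], parse_gtf_attributes)
  tid <- vapply(attrs, function(a) unname(a["transcript_id"]), "")
  if (anyNA(tid)) {
    bad <- which(is.na(tid))[1L]
    stop(sprintf("GTF line %d lacks a transcript_id attribute", lineno[bad]),
         call. = FALSE)
  }
  gid <- vapply(attrs, function(a) unname(a["gene_id"]), "")
  bt <- vapply(attrs, function(a) {
    unname(a["transcript_biotype"]) %||% unname(a["gene_biotype"]) %||%
      "protein_coding"
  }, "")
  df <- data.frame(tid = tid, gid = gid, bt = bt, chrom = tab[, 1L],
                   feat = tab[, 3L], strand = tab[, 7L],
                   start = start0, end = end0, stringsAsFactors = FALSE)
  out <- list()
  for (id in unique(df$tid)) {
    d <- df[df$tid == id, , drop = FALSE]
    ex <- d[d$feat == "exon", , drop = FALSE]
    ut <- d[d$feat == "three_prime_utr", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    ut <- ut[order(ut$start), , drop = FALSE]
    out[[id]] <- transcript_model(
      transcript_id = id,
      gene_id = d$gid[1L],
      biotype = d$bt[1L],
      chrom = d$chrom[1L],
      strand = d$strand[1L],
      exons = intervals(ex$start, ex$end),
      utr3 = intervals(ut$start, ut$end)
    )
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1L])) b else a

#' Write transcript models to a GTF file
#'
#' Emits `transcript`, `exon` and `three_prime_utr` lines with `gene_id`,
#' `transcript_id` and `transcript_biotype` attributes, converting back to
#' GTF 1-based closed coordinates.
#'
#' @param models List of `transcript_model` objects.
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  fmt <- function(chrom, feat, start, end, strand, attr) {
    sprintf("%s\tutrtar\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, start + 1L, end, strand, attr)
  }
  lines <- unlist(lapply(models, function(m) {
    attr <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
                    m$gene_id, m$transcript_id, m$biotype)
    sp <- model_span(m)
    c(fmt(m$chrom, "transcript", sp[1L], sp[2L], m$strand, attr),
      fmt(m$chrom, "exon", m$exons$start, m$exons$end, m$strand, attr),
      if (nrow(m$utr3) > 0L)
        fmt(m$chrom, "three_prime_utr", m$utr3$start, m$utr3$end, m$strand, attr))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

## -------------------------------------------------------------- BED12 ----

#' Convert a transcript model to a BED12 record
#'
#' The CDS/UTR boundary is stored in the thickStart/thickEnd columns
#' (genePred convention): on the plus strand `thickEnd` is the 5' edge of
#' the 3'-UTR, on the minus strand `thickStart` is. Models without a 3'-UTR
#' have thick coordinates spanning the whole transcript.
#'
#' @param model A `transcript_model`.
#' @return A one-row data.frame with the 12 standard BED columns.
#' @export
to_bed12 <- function(model) {
  validate_model(model)
  ex <- model$exons
  chrom_start <- min(ex$start)
  chrom_end <- max(ex$end)
  if (nrow(model$utr3) == 0L) {
    thick_start <- chrom_start
    thick_end <- chrom_end
  } else if (model$strand == "+") {
    thick_start <- chrom_start
    thick_end <- utr3_five_prime_edge(model)
  } else {
    thick_start <- utr3_five_prime_edge(model)
    thick_end <- chrom_end
  }
  data.frame(
    chrom = model$chrom,
    chromStart = chrom_start,
    chromEnd = chrom_end,
    name = model$transcript_id,
    score = 0L,
    strand = model$strand,
    thickStart = thick_start,
    thickEnd = thick_end,
    itemRgb = "0",
    blockCount = nrow(ex),
    blockSizes = paste(ex$end - ex$start, collapse = ","),
    blockStarts = paste(ex$start - chrom_start, collapse = ","),
    stringsAsFactors = FALSE
  )
}

bed12_row_to_model <- function(row, gene_id = NA_character_,
                               biotype = "protein_coding") {
  sizes <- as.integer(strsplit(as.character(row$blockSizes), ",")[[1L]])
  starts <- as.integer(strsplit(as.character(row$blockStarts), ",")[[1L]])
  if (length(sizes) != row$blockCount || length(starts) != row$blockCount)
    stop(sprintf("BED12 record %s: block fields inconsistent with blockCount",
                 row$name), call. = FALSE)
  ex <- intervals(row$chromStart + starts, row$chromStart + starts + sizes)
  # 3'-UTR = exonic bases 3' of the thick (coding) region
  if (row$strand == "+") {
    lo <- row$thickEnd; hi <- row$chromEnd
  } else {
    lo <- row$chromStart; hi <- row$thickStart
  }
  us <- pmax(ex$start, lo)
  ue <- pmin(ex$end, hi)
  sel <- us < ue
  transcript_model(row$name, row$chrom, row$strand, exons = ex,
                   utr3 = intervals(us[sel], ue[sel]),
                   gene_id = gene_id, biotype = biotype)
}

#' Read transcript models from a BED12 file
#' @param path Path to a BED12 file.
#' @return A named list of `transcript_model` objects.
#' @export
read_bed12 <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           col.names = c("chrom", "chromStart", "chromEnd",
                                         "name", "score", "strand",
                                         "thickStart", "thickEnd", "itemRgb",
                                         "blockCount", "blockSizes",
                                         "blockStarts"))
  out <- lapply(seq_len(nrow(tab)), function(i) bed12_row_to_model(tab[i, ]))
  stats::setNames(out, vapply(out, function(m) m$transcript_id, ""))
}

#' Write transcript models to a BED12 file
#' @param models List of `transcript_model` objects.
#' @param path Output path.
#' @export
write_bed12 <- function(models, path) {
  rows <- do.call(rbind, lapply(models, to_bed12))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## -------------------------------------------------- genome / sequences ----

#' Bundle a genome with transcript models
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector) of
#'   chromosome sequences.
#' @param models List of `transcript_model` objects.
#' @return An object of class `reference_bundle` with elements `genome`,
#'   `models` and `chrom_lengths`.
#' @export
reference_bundle <- function(genome, models = list()) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"), !is.null(names(genome)))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  for (m in models) {
    if (!m$chrom %in% names(lens))
      stop(sprintf("transcript %s: chromosome %s absent from genome",
                   m$transcript_id, m$chrom), call. = FALSE)
    if (max(m$exons$end) > lens[[m$chrom]])
      stop(sprintf("transcript %s: exon beyond chromosome end",
                   m$transcript_id), call. = FALSE)
  }
  structure(list(genome = genome, models = models, chrom_lengths = lens),
            class = "reference_bundle")
}

#' Read a genome FASTA into a reference bundle
#' @param path Path to a (plain-text) FASTA file.
#' @param models Optional list of transcript models to attach.
#' @export
read_genome_fasta <- function(path, models = list()) {
  gen <- Biostrings::readDNAStringSet(path)
  names(gen) <- sub("\\s.*$", "", names(gen))
  reference_bundle(gen, models)
}

#' Write a genome (or any named sequence set) as FASTA, 60-column wrapped
#' @param seqs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Extract the contiguous 3'-UTR sequence of a transcript
#'
#' Interval substrings are concatenated in transcription (5'-to-3') order;
#' minus-strand intervals are reverse complemented and concatenated from the
#' genomically 3'-most interval backwards, yielding the mRNA-sense sequence
#' in the DNA alphabet.
#'
#' @param bundle A `reference_bundle`.
#' @param model A `transcript_model` on a chromosome of the bundle.
#' @param utr_override Optional interval table to use instead of
#'   `model$utr3` (e.g. a proposed reannotation).
#' @return A single character string (empty if the model has no 3'-UTR).
#' @export
extract_utr_sequence <- function(bundle, model, utr_override = NULL) {
  ivs <- if (is.null(utr_override)) model$utr3 else as_intervals(utr_override)
  if (nrow(ivs) == 0L) return("")
  ivs <- ivs[order(ivs$start), , drop = FALSE]
  chrom_len <- bundle$chrom_lengths[[model$chrom]]
  if (is.null(chrom_len))
    stop(sprintf("chromosome %s absent from genome", model$chrom), call. = FALSE)
  if (any(ivs$start < 0L) || any(ivs$end > chrom_len))
    stop(sprintf("transcript %s: 3'-UTR interval beyond chromosome bounds",
                 model$transcript_id), call. = FALSE)
  chromseq <- bundle$genome[[model$chrom]]
  parts <- vapply(seq_len(nrow(ivs)), function(i) {
    as.character(Biostrings::subseq(chromseq, ivs$start[i] + 1L, ivs$end[i]))
  }, character(1L))
  if (model$strand == "+") {
    paste(parts, collapse = "")
  } else {
    rc <- vapply(parts, function(p) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(p)))
    }, character(1L), USE.NAMES = FALSE)
    paste(rev(rc), collapse = "")
  }
}

#' Extract all 3'-UTR sequences of a model set
#'
#' @param bundle A `reference_bundle`.
#' @param models List of models (defaults to the bundle's). Only
#'   protein-coding models with a non-empty 3'-UTR contribute.
#' @return Named character vector of mRNA-sense UTR sequences.
#' @export
extract_all_utrs <- function(bundle, models = bundle$models) {
  models <- Filter(function(m) m$biotype == "protein_coding" &&
                     nrow(m$utr3) > 0L, models)
  seqs <- vapply(models, function(m) extract_utr_sequence(bundle, m), "")
  stats::setNames(seqs, vapply(models, function(m) m$transcript_id, ""))
}
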