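#' Construct a transcript model
#'
#' A `TranscriptModel` is the exon structure of one spliced isoform together
#' with the Ensembl-style selection metadata (APPRIS label, transcript support
#' level, GENCODE-basic membership, biotype) used to pick one representative
#' isoform per gene.
#'
#' Exons are stored as an [IRanges::IRanges] in genomic order (1-based closed,
#' the GenomicRanges convention); on the minus strand the transcript 5' end is
#' therefore the *last* exon's right edge.
#'
#' @param transcript_id,gene_id Character scalars.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons An [IRanges::IRanges] (or 2-column matrix of 1-based closed
#'   start/end pairs) of exon coordinates; must be non-overlapping.
#' @param gene_name Optional gene symbol.
#' @param appris APPRIS label, one of `"principal1"`..`"principal5"`,
#'   `"alternative1"`, `"alternative2"` or `"none"`.
#' @param tsl Transcript support level, integer 1..5 or `NA`.
#' @param basic Logical; member of the GENCODE basic set?
#' @param biotype Gene biotype string.
#' @return An object of class `TranscriptModel`.
#' @examples
#' m <- transcript_model("t1", "g1", "chr1", "+",
#'                       IRanges::IRanges(c(101, 301), c(200, 400)))
#' spliced_length(m)
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             gene_name = NA_character_, appris = "none",
                             tsl = NA_integer_, basic = FALSE,
                             biotype = NA_character_) {
  if (is.matrix(exons)) {
    exons <- IRanges::IRanges(start = exons[, 1], end = exons[, 2])
  }
  stopifnot(methods::is(exons, "IRanges"), length(exons) > 0L)
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-' for transcript ", transcript_id)
  }
  exons <- sort(exons)
  if (any(IRanges::width(exons) < 1L)) {
    stop("zero-width exon in transcript ", transcript_id)
  }
  if (length(exons) > 1L &&
      any(IRanges::start(exons)[-1L] <= IRanges::end(exons)[-length(exons)])) {
    stop("overlapping or unsorted exons in transcript ", transcript_id)
  }
  appris <- match.arg(appris, c("none", paste0("principal", 1:5),
                                paste0("alternative", 1:2)))
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         gene_name = gene_name, chrom = chrom, strand = strand,
         exons = exons, appris = appris, tsl = as.integer(tsl),
         basic = isTRUE(basic), biotype = biotype),
    class = "TranscriptModel")
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat(sprintf("TranscriptModel %s (gene %s) %s:%s, %d exon(s), %d nt spliced\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              length(x$exons), spliced_length(x)))
  cat(sprintf("  APPRIS %s, TSL %s, basic %s, biotype %s\n",
              x$appris, ifelse(is.na(x$tsl), "NA", x$tsl), x$basic,
              x$biotype))
  invisible(x)
}

#' Spliced (mature mRNA) length of a transcript model
#' @param model A [transcript_model()].
#' @return Integer: sum of exon widths.
#' @export
spliced_length <- function(model) {
  sum(IRanges::width(model$exons))
}

# Exons in transcript (5'->3') order: reversed genomic order on minus strand.
tx_order_exons <- function(model) {
  if (model$strand == "-") rev(model$exons) else model$exons
}

.ATTR_RE <- "(\\S+) +\"([^\"]*)\""

parse_gtf_attributes <- function(attr_string) {
  m <- regmatches(attr_string, gregexpr(.ATTR_RE, attr_string))[[1]]
  keys <- sub(.ATTR_RE, "\\1", m)
  vals <- sub(.ATTR_RE, "\\2", m)
  list(keys = keys, vals = vals)
}

appris_from_tags <- function(tags) {
  hit <- grep("^appris_(principal|alternative)_[0-9]$", tags, value = TRUE)
  if (length(hit) == 0L) return("none")
  sub("^appris_", "", sub("_([0-9])$", "\\1", hit[1L]))
}

tsl_from_value <- function(x) {
  if (is.null(x) || is.na(x)) return(NA_integer_)
  # Ensembl sometimes appends a parenthetical note after the level
  lvl <- sub("^([0-9NA]+).*", "\\1", trimws(x))
  if (lvl %in% as.character(1:5)) as.integer(lvl) else NA_integer_
}

#' Read transcript models from an Ensembl-style GTF file
#'
#' Parses `exon` features into one [transcript_model()] per `transcript_id`.
#' GTF 1-based closed coordinates are kept as-is internally (the
#' GenomicRanges convention). APPRIS labels are recognised from
#' `tag "appris_principal_N"` / `tag "appris_alternative_N"` attributes,
#' GENCODE basic membership from `tag "basic"`, and the transcript support
#' level from a `transcript_support_level` (or `tsl`) attribute; a literal
#' `"NA"` TSL is treated as missing. Missing tags default to APPRIS `"none"`,
#' TSL `NA`, basic `FALSE`.
#'
#' @param path Path to a GTF file (Ensembl dialect).
#' @param chrom_filter Optional character vector; keep only these chromosomes.
#' @return A named list of `TranscriptModel` objects (names = transcript ids).
#' @export
read_gtf <- function(path, chrom_filter = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  acc <- new.env(parent = emptyenv())
  for (i in idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) {
      stop("malformed GTF line ", i, " in ", path, ": expected 9 fields")
    }
    if (f[3] != "exon") next
    if (!is.null(chrom_filter) && !(f[1] %in% chrom_filter)) next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end) || start > end) {
      stop("malformed GTF line ", i, ": bad coordinates '",
           f[4], "'-'", f[5], "'")
    }
    at <- parse_gtf_attributes(f[9])
    get1 <- function(k) {
      j <- match(k, at$keys)
      if (is.na(j)) NULL else at$vals[j]
    }
    tid <- get1("transcript_id"); gid <- get1("gene_id")
    if (is.null(tid) || is.null(gid)) {
      stop("malformed GTF line ", i, ": missing transcript_id/gene_id")
    }
    tags <- at$vals[at$keys == "tag"]
    tslv <- get1("transcript_support_level")
    if (is.null(tslv)) tslv <- get1("tsl")
    rec <- if (!is.null(acc[[tid]])) acc[[tid]] else
      list(transcript_id = tid, gene_id = gid,
           gene_name = NA_character_, chrom = f[1], strand = f[7],
           starts = integer(), ends = integer(),
           appris = "none", tsl = NA_integer_, basic = FALSE,
           biotype = NA_character_)
    if (rec$chrom != f[1] || rec$strand != f[7]) {
      stop("exons of transcript ", tid, " on conflicting chrom/strand ",
           "(line ", i, ")")
    }
    rec$starts <- c(rec$starts, start)
    rec$ends <- c(rec$ends, end)
    gn <- get1("gene_name"); if (!is.null(gn)) rec$gene_name <- gn
    bt <- get1("gene_biotype"); if (!is.null(bt)) rec$biotype <- bt
    ap <- appris_from_tags(tags)
    if (ap != "none") rec$appris <- ap
    if ("basic" %in% tags) rec$basic <- TRUE
    if (!is.null(tslv)) {
      v <- tsl_from_value(tslv)
      if (!is.na(v)) rec$tsl <- v
    }
    acc[[tid]] <- rec
  }
  tids <- ls(acc)
  models <- lapply(tids, function(tid) {
    r <- acc[[tid]]
    o <- order(r$starts)
    transcript_model(r$transcript_id, r$gene_id, r$chrom, r$strand,
                     IRanges::IRanges(r$starts[o], r$ends[o]),
                     gene_name = r$gene_name, appris = r$appris,
                     tsl = r$tsl, basic = r$basic, biotype = r$biotype)
  })
  stats::setNames(models, tids)
}

appris_rank <- function(appris) {
  match(appris, c(paste0("principal", 1:5), paste0("alternative", 1:2)))
}

#' Select the most prominent isoform per gene
#'
#' Implements the hierarchical filter used to define one representative
#' isoform per gene: only transcripts that are in the GENCODE basic set,
#' carry an APPRIS label and have a transcript support level are considered;
#' among those, APPRIS has highest priority (principal1 best, then
#' principal2..5, then alternative1..2), ties are broken by TSL (1 best),
#' then by longer spliced length, then lexicographically by transcript id.
#' Genes with no qualifying isoform are absent from the result.
#'
#' @param models A list of [transcript_model()] objects.
#' @return A named list of `TranscriptModel` (names = gene ids), one per gene.
#' @export
select_most_prominent <- function(models) {
  if (length(models) == 0L) return(stats::setNames(list(), character()))
  ok <- vapply(models, function(m) {
    isTRUE(m$basic) && m$appris != "none" && !is.na(m$tsl)
  }, logical(1))
  models <- models[ok]
  if (length(models) == 0L) return(stats::setNames(list(), character()))
  key <- data.frame(
    gene = vapply(models, `[[`, "", "gene_id"),
    appris = appris_rank(vapply(models, `[[`, "", "appris")),
    tsl = vapply(models, function(m) m$tsl, integer(1)),
    len = vapply(models, spliced_length, integer(1)),
    tid = vapply(models, `[[`, "", "transcript_id"),
    stringsAsFactors = FALSE)
  o <- order(key$gene, key$appris, key$tsl, -key$len, key$tid,
             method = "radix")
  best <- o[!duplicated(key$gene[o])]
  out <- models[best]
  stats::setNames(out, key$gene[best])
}

#' Exon and intron regions of a transcript model
#'
#' Returns exons as stored and introns as the gaps between consecutive
#' exons, both as [GenomicRanges::GRanges]. Region names encode the
#' transcript id and the 5'->3' index on the transcript strand
#' (`<tid>_e1`, `<tid>_i1`, ...), so on a minus-strand transcript `e1` is the
#' genomically last exon.
#'
#' @param model A [transcript_model()].
#' @return A list with `exons` and `introns` GRanges (introns empty for
#'   single-exon transcripts).
#' @export
exon_intron_regions <- function(model) {
  n <- length(model$exons)
  ex_idx <- if (model$strand == "-") rev(seq_len(n)) else seq_len(n)
  exons <- GenomicRanges::GRanges(model$chrom, model$exons,
                                  strand = model$strand)
  names(exons) <- paste0(model$transcript_id, "_e", ex_idx)
  if (n > 1L) {
    intr <- IRanges::IRanges(IRanges::end(model$exons)[-n] + 1L,
                             IRanges::start(model$exons)[-1L] - 1L)
    in_idx <- if (model$strand == "-") rev(seq_len(n - 1L)) else seq_len(n - 1L)
    introns <- GenomicRanges::GRanges(model$chrom, intr,
                                      strand = model$strand)
    names(introns) <- paste0(model$transcript_id, "_i", in_idx)
  } else {
    introns <- GenomicRanges::GRanges()
  }
  list(exons = exons, introns = introns)
}

#' Write a most-prominent-transcript list
#'
#' One transcript id per line, sorted by gene id, as produced by
#' [select_most_prominent()].
#'
#' @param prominent Named list of models (names = gene ids).
#' @param path Output file.
#' @export
write_transcript_list <- function(prominent, path) {
  ids <- vapply(prominent[order(names(prominent))], `[[`, "", "transcript_id")
  writeLines(ids, path)
  invisible(path)
}

#' Merged exon union of a set of transcript models
#'
#' Strand-aware union (reduce) of all exon intervals, typically of the most
#' prominent isoforms, used as the reference exome for overlap
#' classification.
#'
#' @param models List of [transcript_model()] objects.
#' @return A reduced [GenomicRanges::GRanges].
#' @export
exon_union <- function(models) {
  if (length(models) == 0L) return(GenomicRanges::GRanges())
  grl <- lapply(models, function(m) {
    GenomicRanges::GRanges(m$chrom, m$exons, strand = m$strand)
  })
  # chromosomes differ between models; merging seqinfo is intended
  GenomicRanges::reduce(suppressWarnings(do.call(c, unname(grl))))
}
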