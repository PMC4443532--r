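#' Load a genome from a FASTA file
#'
#' Reads a multi-record FASTA file into a named character vector of
#' uppercase DNA sequences, one element per record, named by the first
#' whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped records).
#' @return Named character vector of uppercase sequences.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("FASTA file contains no records: ", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate sequence id in FASTA: ", dup[1L])
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L)) stop("empty sequence in FASTA: ",
                                   ids[nchar(seqs) == 0L][1L])
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("non-DNA characters in sequence: ", ids[bad][1L])
  seqs
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of DNA sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

# Internal constructor + validator for one transcript's gene model.
# Coordinates are 0-based half-open, genomic; `exons` and `cds` are
# integer matrices with columns start, end, ordered 5'->3' in CODING
# orientation (descending genomic coordinate on the minus strand).
new_gene_model <- function(gene_id, transcript_id, chrom, strand,
                           exons, cds, utr_annotated = FALSE) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  cds <- if (is.null(cds) || NROW(cds) == 0L) {
    matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  } else {
    matrix(as.integer(cds), ncol = 2L,
           dimnames = list(NULL, c("start", "end")))
  }
  m <- structure(list(gene_id = gene_id, transcript_id = transcript_id,
                      chrom = chrom, strand = strand, exons = exons,
                      cds = cds, utr_annotated = isTRUE(utr_annotated)),
                 class = "gene_model")
  validate_gene_model(m)
  m
}

validate_gene_model <- function(m) {
  ex <- m$exons
  if (nrow(ex) < 1L) stop("gene model ", m$transcript_id, " has no exons")
  if (any(ex[, "end"] <= ex[, "start"]))
    stop("empty exon interval in ", m$transcript_id)
  # coding-orientation sort: ascending start on +, descending on -
  ord <- if (m$strand == "+") order(ex[, "start"]) else order(-ex[, "start"])
  if (!identical(ord, seq_len(nrow(ex))))
    stop("exons of ", m$transcript_id, " not in coding orientation")
  gex <- ex[order(ex[, "start"]), , drop = FALSE]
  if (nrow(gex) > 1L) {
    gaps <- gex[-1L, "start"] - gex[-nrow(gex), "end"]
    if (any(gaps < 0L)) stop("overlapping exons in ", m$transcript_id)
    if (any(gaps > 0L & gaps < 4L))
      stop("intron shorter than 4 bp in ", m$transcript_id,
           " (annotation error)")
  }
  for (k in seq_len(nrow(m$cds))) {
    inside <- any(m$cds[k, "start"] >= ex[, "start"] &
                  m$cds[k, "end"] <= ex[, "end"])
    if (!inside)
      stop("CDS interval not contained in any exon of ", m$transcript_id)
  }
  invisible(m)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s strand %s  %d exon(s), %d CDS segment(s)%s\n",
              x$transcript_id, x$gene_id, x$chrom,
              paste0(min(x$exons[, "start"]), "-", max(x$exons[, "end"])),
              x$strand, nrow(x$exons), nrow(x$cds),
              if (x$utr_annotated) ", UTRs annotated" else ""))
  invisible(x)
}

#' Load gene models from a GFF3 file
#'
#' Parses a GFF3 annotation (gene -> mRNA -> exon/CDS Parent links) into a
#' list of gene models, one per mRNA.  GFF3 1-based inclusive coordinates are
#' converted to 0-based half-open; on the minus strand exon and CDS lists are
#' reversed into coding (5'->3') orientation.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of `gene_model` objects (names are transcript ids).
#' @export
load_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  is_mrna <- typ %in% c("mRNA", "transcript")
  is_gene <- typ == "gene"
  gene_ids <- gr$ID[is_gene]
  gene_start <- GenomicRanges::start(gr)[is_gene]
  gene_end <- GenomicRanges::end(gr)[is_gene]
  names(gene_start) <- names(gene_end) <- gene_ids

  first_parent <- function(p) vapply(p, function(v)
    if (length(v)) v[[1L]] else NA_character_, character(1))

  models <- list()
  for (i in which(is_mrna)) {
    tid <- gr$ID[i]
    parent <- first_parent(gr$Parent[i])
    kids <- which(vapply(gr$Parent, function(v) tid %in% v, logical(1)))
    ktyp <- typ[kids]
    exo <- kids[ktyp == "exon"]
    cdso <- kids[ktyp == "CDS"]
    utro <- kids[ktyp %in% c("five_prime_UTR", "three_prime_UTR")]
    if (length(exo) == 0L)
      stop("mRNA ", tid, " has no exon children")
    strand <- as.character(GenomicRanges::strand(gr)[i])
    if (!strand %in% c("+", "-"))
      stop("mRNA ", tid, " has no strand")
    to0 <- function(idx) {
      s <- GenomicRanges::start(gr)[idx] - 1L  # 0-based half-open
      e <- GenomicRanges::end(gr)[idx]
      o <- if (strand == "+") order(s) else order(-s)
      cbind(start = s[o], end = e[o])
    }
    ex <- to0(exo)
    if (!is.na(parent) && parent %in% gene_ids) {
      if (min(ex[, "start"]) < gene_start[parent] - 1L ||
          max(ex[, "end"]) > gene_end[parent])
        stop("exon outside parent gene span for mRNA ", tid)
    }
    cds <- if (length(cdso)) to0(cdso) else NULL
    models[[tid]] <- new_gene_model(
      gene_id = if (is.na(parent)) tid else parent,
      transcript_id = tid, chrom = as.character(GenomicRanges::seqnames(gr)[i]),
      strand = strand, exons = ex, cds = cds,
      utr_annotated = length(utro) > 0L ||
        (length(cdso) > 0L && !isTRUE(all.equal(sum(ex[, 2] - ex[, 1]),
                                                sum(GenomicRanges::end(gr)[cdso] -
                                                    GenomicRanges::start(gr)[cdso] + 1L)))))
  }
  models
}

#' Write gene models to a GFF3 file
#'
#' Emits gene, mRNA, exon and CDS features (plus UTR features when the model
#' has annotated UTRs) with Parent links, converting the internal 0-based
#' half-open coordinates back to GFF3 1-based inclusive.
#'
#' @param models List of `gene_model` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_models <- function(models, path) {
  lines <- c("##gff-version 3")
  for (m in models) {
    gx <- m$exons[order(m$exons[, "start"]), , drop = FALSE]
    gs <- min(gx[, "start"]) + 1L
    ge <- max(gx[, "end"])
    lines <- c(lines,
      sprintf("%s\tintronloss\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              m$chrom, gs, ge, m$strand, m$gene_id),
      sprintf("%s\tintronloss\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              m$chrom, gs, ge, m$strand, m$transcript_id, m$gene_id))
    for (k in seq_len(nrow(gx)))
      lines <- c(lines, sprintf(
        "%s\tintronloss\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        m$chrom, gx[k, "start"] + 1L, gx[k, "end"], m$strand,
        m$transcript_id, k, m$transcript_id))
    cx <- m$cds
    if (nrow(cx) > 0L) {
      cxg <- cx[order(cx[, "start"]), , drop = FALSE]
      for (k in seq_len(nrow(cxg)))
        lines <- c(lines, sprintf(
          "%s\tintronloss\tCDS\t%d\t%d\t.\t%s\t.\tID=%s.cds%d;Parent=%s",
          m$chrom, cxg[k, "start"] + 1L, cxg[k, "end"], m$strand,
          m$transcript_id, k, m$transcript_id))
      if (m$utr_annotated) {
        # UTR features: exonic bp outside the CDS span (genomic)
        cs <- min(cxg[, "start"]); ce <- max(cxg[, "end"])
        for (k in seq_len(nrow(gx))) {
          s <- gx[k, "start"]; e <- gx[k, "end"]
          if (s < cs) {
            utype <- if (m$strand == "+") "five_prime_UTR" else "three_prime_UTR"
            lines <- c(lines, sprintf(
              "%s\tintronloss\t%s\t%d\t%d\t.\t%s\t.\tID=%s.utrL%d;Parent=%s",
              m$chrom, utype, s + 1L, min(e, cs), m$strand,
              m$transcript_id, k, m$transcript_id))
          }
          if (e > ce) {
            utype <- if (m$strand == "+") "three_prime_UTR" else "five_prime_UTR"
            lines <- c(lines, sprintf(
              "%s\tintronloss\t%s\t%d\t%d\t.\t%s\t.\tID=%s.utrR%d;Parent=%s",
              m$chrom, utype, max(s, ce) + 1L, e, m$strand,
              m$transcript_id, k, m$transcript_id))
          }
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Keep one transcript per gene
#'
#' When a gene has several mRNAs, retains the one with the longest total CDS,
#' breaking ties by lexicographic transcript id.
#'
#' @param models List of `gene_model` objects.
#' @return Filtered list, one model per gene id.
#' @export
primary_transcripts <- function(models) {
  if (length(models) == 0L) return(models)
  genes <- vapply(models, `[[`, character(1), "gene_id")
  keep <- character(0)
  for (g in unique(genes)) {
    cand <- models[genes == g]
    cdslen <- vapply(cand, function(m) sum(m$cds[, "end"] - m$cds[, "start"]),
                     numeric(1))
    tids <- vapply(cand, `[[`, character(1), "transcript_id")
    o <- order(-cdslen, tids)
    keep <- c(keep, tids[o[1L]])
  }
  models[vapply(models, function(m) m$transcript_id %in% keep, logical(1))]
}

# Extract genome bases [start, end) on the given strand (revcomp for "-").
seq_region <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  L <- nchar(genome[[chrom]])
  if (start < 0L || end > L)
    stop("interval [", start, ",", end, ") exceeds length of ", chrom)
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") revcomp(s) else s
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Spliced sequence of a gene model
#'
#' Concatenates the exon (or CDS) intervals in coding orientation,
#' reverse-complementing minus-strand genes.
#'
#' @param gene A `gene_model`.
#' @param genome Named character vector from [load_genome()].
#' @param region `"transcript"` (exons) or `"cds"`.
#' @return Single uppercase DNA string.
#' @export
spliced_sequence <- function(gene, genome, region = c("transcript", "cds")) {
  region <- match.arg(region)
  iv <- if (region == "transcript") gene$exons else gene$cds
  if (nrow(iv) == 0L) stop("gene ", gene$transcript_id, " has no ",
                           region, " intervals")
  parts <- vapply(seq_len(nrow(iv)), function(k)
    seq_region(genome, gene$chrom, iv[k, "start"], iv[k, "end"], gene$strand),
    character(1))
  paste0(parts, collapse = "")
}

#' Intron inventory of a gene model
#'
#' One row per adjacent exon pair, in coding (5'->3') order.  Donor and
#' acceptor dinucleotides are read in coding orientation.  Phase is the
#' spliced coding length upstream of the intron modulo 3 for introns inside
#' the CDS, and `NA` for UTR introns.
#'
#' @param gene A `gene_model`.
#' @param genome Named character vector from [load_genome()].
#' @return data.frame with columns index, start, end, length, donor2,
#'   acceptor2, phase, context.
#' @export
introns_of <- function(gene, genome) {
  ex <- gene$exons
  n <- nrow(ex)
  empty <- data.frame(index = integer(0), start = integer(0), end = integer(0),
                      length = integer(0), donor2 = character(0),
                      acceptor2 = character(0), phase = integer(0),
                      context = character(0), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  out <- empty
  # cumulative transcript offset of each intron (coding orientation)
  exw <- ex[, "end"] - ex[, "start"]
  cum <- cumsum(exw)
  for (k in seq_len(n - 1L)) {
    if (gene$strand == "+") {
      s <- ex[k, "end"]; e <- ex[k + 1L, "start"]
    } else {
      s <- ex[k + 1L, "end"]; e <- ex[k, "start"]
    }
    len <- e - s
    donor <- if (gene$strand == "+") seq_region(genome, gene$chrom, s, s + 2L, "+")
             else seq_region(genome, gene$chrom, e - 2L, e, "-")
    accep <- if (gene$strand == "+") seq_region(genome, gene$chrom, e - 2L, e, "+")
             else seq_region(genome, gene$chrom, s, s + 2L, "-")
    ph <- NA_integer_
    ctx <- "CDS"
    if (nrow(gene$cds) > 0L) {
      cdsw <- gene$cds[, "end"] - gene$cds[, "start"]
      # coding bp 5' of this intron: CDS segments lie within exons 1..k
      # (intervals are in coding order, so count CDS bp in those exons)
      up_cds <- 0L
      in_up <- logical(nrow(gene$cds))
      for (j in seq_len(nrow(gene$cds))) {
        host <- which(gene$cds[j, "start"] >= ex[, "start"] &
                      gene$cds[j, "end"] <= ex[, "end"])[1L]
        in_up[j] <- host <= k
      }
      up_cds <- sum(cdsw[in_up])
      total_cds <- sum(cdsw)
      if (up_cds == 0L) ctx <- "UTR5"
      else if (up_cds == total_cds) ctx <- "UTR3"
      else ph <- up_cds %% 3L
      # a UTR intron inside a 5'UTR exon boundary with partial CDS in exon k:
      # up_cds strictly between 0 and total => inside CDS
    } else {
      ctx <- "CDS"
      ph <- cum[k] %% 3L
    }
    out <- rbind(out, data.frame(
      index = k, start = s, end = e, length = len, donor2 = donor,
      acceptor2 = accep, phase = ph, context = ctx, stringsAsFactors = FALSE))
  }
  out
}
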