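#' Generator configuration for a synthetic ortholog pair
#'
#' Describes one ancestral gene and the two descendant copies derived from
#' it.  Defaults emulate closely related plant ortholog pairs: pairwise
#' divergence 0.05 (well under 10%), 5-8 exons of 90-240 bp, introns of
#' 60-200 bp (>= 60 bp so retention checks have signal), GC 0.45.
#'
#' @param n_exons Integer range (length 2) for the exon count.
#' @param exon_len,intron_len bp ranges (length 2).
#' @param gc GC fraction of generated sequence.
#' @param divergence Total per-site substitution probability between the two
#'   descendants; split symmetrically, each lineage mutates at
#'   `divergence / 2`.
#' @param utr5_len,utr3_len Untranslated bp inside the first/last exon
#'   (0 disables; must be smaller than the host exon).
#' @param planted List of [planted_event()] objects applied to the
#'   recipient copy (gene B).
#' @param frame_preserving Force all planted CDS changes to a net indel of
#'   0 mod 3 and keep both ORFs stop-free.
#' @param pad Genomic bp flanking the gene on each side.
#' @param strand Length-2 character, strand of gene A and gene B.
#' @param seed Mandatory integer seed; identical configs give
#'   byte-identical bundles.
#' @param ids Named list overriding chrom/gene identifiers
#'   (chrom_a, chrom_b, gene_a, gene_b).
#' @param exon_lengths,intron_lengths Optional exact length vectors
#'   (override the ranges; lengths must fit `n_exons`).
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_exons = c(5L, 8L),
                             exon_len = c(90L, 240L),
                             intron_len = c(60L, 200L),
                             gc = 0.45,
                             divergence = 0.05,
                             utr5_len = 0L, utr3_len = 0L,
                             planted = list(),
                             frame_preserving = FALSE,
                             pad = 150L,
                             strand = c("+", "+"),
                             seed,
                             ids = list(),
                             exon_lengths = NULL,
                             intron_lengths = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (divergence < 0 || divergence >= 0.5)
    stop("divergence must be in [0, 0.5)")
  if (any(c(n_exons, exon_len, intron_len) <= 0))
    stop("ranges must be positive")
  if (length(planted) && inherits(planted, "planted_event"))
    planted <- list(planted)
  defaults <- list(chrom_a = "chrA", chrom_b = "chrB",
                   gene_a = "geneA", gene_b = "geneB")
  ids <- utils::modifyList(defaults, ids)
  structure(list(n_exons = as.integer(n_exons), exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len), gc = gc,
                 divergence = divergence, utr5_len = as.integer(utr5_len),
                 utr3_len = as.integer(utr3_len), planted = planted,
                 frame_preserving = isTRUE(frame_preserving),
                 pad = as.integer(pad), strand = strand,
                 seed = as.integer(seed), ids = ids,
                 exon_lengths = exon_lengths,
                 intron_lengths = intron_lengths),
            class = "generator_config")
}

#' A ground-truth event to plant in the recipient copy
#'
#' @param type One of `"PIL"`, `"IIL"`, `"DE_INTRONIZATION"`,
#'   `"DE_EXONIZATION"`, `"EXON_DELETION"`.
#' @param intron_index Donor intron ordinal (intron-level types and
#'   `whole_exon_codel`).
#' @param exon_index Donor exon ordinal (exon-level types); must be
#'   internal.
#' @param up_del_bp,down_del_bp Exonic bp deleted upstream/downstream of an
#'   imprecise loss (IIL only; their sum must be >= 1 unless
#'   `whole_exon_codel`).
#' @param whole_exon_codel IIL flavor: excise intron `intron_index`
#'   together with the entire downstream exon, leaving the next intron
#'   intact.
#' @return List of class `planted_event`.
#' @export
planted_event <- function(type, intron_index = NA_integer_,
                          exon_index = NA_integer_,
                          up_del_bp = 0L, down_del_bp = 0L,
                          whole_exon_codel = FALSE) {
  type <- match.arg(type, c("PIL", "IIL", "DE_INTRONIZATION",
                            "DE_EXONIZATION", "EXON_DELETION"))
  if (type %in% c("PIL", "IIL", "DE_INTRONIZATION") && is.na(intron_index))
    stop(type, " requires intron_index")
  if (type %in% c("DE_EXONIZATION", "EXON_DELETION") && is.na(exon_index))
    stop(type, " requires exon_index")
  if (type == "PIL" && (up_del_bp != 0L || down_del_bp != 0L))
    stop("PIL must not carry exonic deletions")
  if (type == "IIL" && !whole_exon_codel && up_del_bp + down_del_bp < 1L)
    stop("IIL requires up_del_bp + down_del_bp >= 1 (or whole_exon_codel)")
  structure(list(type = type, intron_index = as.integer(intron_index),
                 exon_index = as.integer(exon_index),
                 up_del_bp = as.integer(up_del_bp),
                 down_del_bp = as.integer(down_del_bp),
                 whole_exon_codel = isTRUE(whole_exon_codel)),
            class = "planted_event")
}

rand_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

STOPS <- c("TAA", "TAG", "TGA")

rand_cds <- function(n_codons, gc) {
  # ATG + stop-free interior + TAA
  inner <- character(n_codons - 2L)
  for (i in seq_len(n_codons - 2L)) {
    repeat {
      cd <- rand_dna(3L, gc)
      if (!cd %in% STOPS) break
    }
    inner[i] <- cd
  }
  paste0("ATG", paste0(inner, collapse = ""), "TAA")
}

rand_intron <- function(len, gc) paste0("GT", rand_dna(len - 4L, gc), "AG")

draw_len <- function(range, n = 1L) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

# ---- internal gene representation: alternating exon/intron segments ------

segs_transcript <- function(segs) {
  paste0(vapply(segs[vapply(segs, `[[`, character(1), "kind") == "exon"],
                `[[`, character(1), "seq"), collapse = "")
}

segs_genomic <- function(segs) {
  paste0(vapply(segs, `[[`, character(1), "seq"), collapse = "")
}

n_exon_segs <- function(segs)
  sum(vapply(segs, `[[`, character(1), "kind") == "exon")

# transcript position (1-based) -> list(seg index, offset within segment)
locate_tpos <- function(segs, tpos) {
  acc <- 0L
  for (i in seq_along(segs)) {
    if (segs[[i]]$kind != "exon") next
    w <- nchar(segs[[i]]$seq)
    if (tpos <= acc + w) return(list(seg = i, off = tpos - acc))
    acc <- acc + w
  }
  stop("transcript position out of range: ", tpos)
}

set_transcript_base <- function(segs, tpos, base) {
  at <- locate_tpos(segs, tpos)
  s <- segs[[at$seg]]$seq
  substr(s, at$off, at$off) <- base
  segs[[at$seg]]$seq <- s
  segs
}

get_transcript_base <- function(segs, tpos) {
  at <- locate_tpos(segs, tpos)
  substr(segs[[at$seg]]$seq, at$off, at$off)
}

# replacement bases for transcript position `tpos` that differ from
# `avoid` and do not create an in-frame stop in the (donor) ORF
safe_replacements <- function(segs, tpos, avoid, utr5, cds_len) {
  cand <- setdiff(c("A", "C", "G", "T"),
                  c(avoid, get_transcript_base(segs, tpos)))
  cpos <- tpos - utr5                       # 1-based CDS position
  if (cpos < 1L || cpos > cds_len) return(cand)
  tx <- segs_transcript(segs)
  cstart <- tpos - ((cpos - 1L) %% 3L)
  keep <- vapply(cand, function(b) {
    codon <- substr(tx, cstart, cstart + 2L)
    substr(codon, tpos - cstart + 1L, tpos - cstart + 1L) <- b
    !codon %in% STOPS
  }, logical(1))
  cand[keep]
}

# make a planted deletion/insertion block unambiguous in the alignment:
# the block [i+1 .. j] (1-based, transcript coords) cannot slide if the
# base before it differs from its last base and the base after it differs
# from its first base.  Bases are changed inside the block when possible
# (they exist only in the donor transcript).
deambiguate_block <- function(segs, i0, j0, utr5, cds_len) {
  # i0 = 0-based block start, j0 = 0-based block end (exclusive)
  tx_len <- nchar(segs_transcript(segs))
  if (i0 >= 1L) {
    before <- get_transcript_base(segs, i0)
    last_in <- get_transcript_base(segs, j0)
    if (before == last_in) {
      cand <- safe_replacements(segs, j0, before, utr5, cds_len)
      if (length(cand)) segs <- set_transcript_base(segs, j0, cand[1L])
    }
  }
  if (j0 + 1L <= tx_len) {
    after <- get_transcript_base(segs, j0 + 1L)
    first_in <- get_transcript_base(segs, i0 + 1L)
    if (after == first_in) {
      cand <- safe_replacements(segs, i0 + 1L, after, utr5, cds_len)
      if (length(cand)) segs <- set_transcript_base(segs, i0 + 1L, cand[1L])
    }
  }
  segs
}

# After a frame-preserving deletion the two junction flanks meet in new
# codons; any stop codon they form is repaired by editing one ancestor base
# (shared by both copies, so no extra divergence), keeping the donor ORF
# stop-free and the identifiability guard intact.
fix_junction_stops <- function(segs, planted, ex_lens, utr5, cds_len) {
  excum <- cumsum(ex_lens)
  for (ev in planted) {
    if (ev$type == "PIL" || ev$type == "DE_INTRONIZATION") next
    if (ev$type == "IIL" && !ev$whole_exon_codel) {
      p <- excum[ev$intron_index]
      blk <- c(p - ev$up_del_bp, p + ev$down_del_bp)
    } else {
      k <- if (ev$type == "IIL") ev$intron_index + 1L else ev$exon_index
      blk <- c(excum[k - 1L], excum[k])
    }
    i0 <- blk[1L]; j0 <- blk[2L]
    shift <- j0 - i0
    for (tries in 1:20) {
      tx <- segs_transcript(segs)
      rec <- paste0(substr(tx, 1L, i0), substr(tx, j0 + 1L, nchar(tx)))
      rcds_len <- cds_len - shift
      rcds <- substr(rec, utr5 + 1L, utr5 + rcds_len)
      codons <- substring(rcds, seq(1L, rcds_len - 2L, 3L),
                          seq(3L, rcds_len, 3L))
      bad <- which(codons[-length(codons)] %in% STOPS)
      # stops can only arise in codons overlapping the junction
      cp <- i0 - utr5                      # recipient CDS bases before junction
      bad <- bad[(bad - 1L) * 3L + 3L >= cp - 1L & (bad - 1L) * 3L < cp + 3L]
      if (!length(bad)) break
      b <- bad[1L]
      fixed <- FALSE
      for (rpos in (b - 1L) * 3L + 1:3) {  # recipient CDS positions of codon
        rtp <- utr5 + rpos                 # recipient transcript position
        atp <- if (rtp <= i0) rtp else rtp + shift  # ancestor position
        avoid <- character(0)
        if (atp == i0) avoid <- get_transcript_base(segs, j0)
        if (atp == j0 + 1L) avoid <- get_transcript_base(segs, i0 + 1L)
        cand <- safe_replacements(segs, atp, avoid, utr5, cds_len)
        for (bch in cand) {
          codon <- codons[b]
          substr(codon, rpos - (b - 1L) * 3L, rpos - (b - 1L) * 3L) <- bch
          if (!codon %in% STOPS) {
            segs <- set_transcript_base(segs, atp, bch)
            fixed <- TRUE
            break
          }
        }
        if (fixed) break
      }
      if (!fixed) stop("could not repair a junction stop codon")
    }
  }
  segs
}

# indices of the intron segments a planted event touches (for overlap checks)
event_introns <- function(ev, n_introns) {
  switch(ev$type,
    PIL = ev$intron_index,
    IIL = if (ev$whole_exon_codel) c(ev$intron_index, ev$intron_index + 1L)
          else ev$intron_index,
    DE_INTRONIZATION = ev$intron_index,
    DE_EXONIZATION = c(ev$exon_index - 1L, ev$exon_index),
    EXON_DELETION = c(ev$exon_index - 1L, ev$exon_index))
}

#' Generate a two-species ortholog fixture with planted events
#'
#' Builds one ancestral gene (GT..AG introns, intact ORF), derives two
#' descendant copies by independent substitution at `divergence / 2` per
#' lineage (splice dinucleotides, start and stop codons are protected),
#' applies the planted events exactly to the recipient copy (gene B), and
#' returns genomes, annotations, an ortholog table and the ground-truth
#' event table.  Identical configs give byte-identical bundles.
#'
#' Boundary bases of every planted insertion/deletion block are adjusted in
#' the ancestor (ORF-safely) so the block's placement in the pairwise
#' alignment cannot slide; without this guard the planted indel split is
#' not recoverable even in principle.
#'
#' @param cfg A [generator_config()].
#' @param dir Optional directory: when given, the bundle files are written
#'   there (see [write_bundle()]).
#' @return List of class `fixture_bundle`: genome_a, genome_b, models_a,
#'   models_b, orthologs, truth, config.
#' @export
generate_locus_pair <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)

  # ---- draw the gene architecture --------------------------------------
  n_ex <- if (!is.null(cfg$exon_lengths)) length(cfg$exon_lengths)
          else draw_len(cfg$n_exons)
  if (n_ex < 2L && length(cfg$planted))
    stop("planted events need at least 2 exons")
  ex_lens <- if (!is.null(cfg$exon_lengths)) as.integer(cfg$exon_lengths)
             else draw_len(cfg$exon_len, n_ex)
  in_lens <- if (!is.null(cfg$intron_lengths)) as.integer(cfg$intron_lengths)
             else draw_len(cfg$intron_len, max(0L, n_ex - 1L))
  if (length(in_lens) != n_ex - 1L)
    stop("need ", n_ex - 1L, " intron lengths")
  if (any(in_lens < 6L)) stop("introns must be >= 6 bp")

  # validate planted events against the architecture
  n_in <- n_ex - 1L
  for (ev in cfg$planted) {
    if (!is.na(ev$intron_index) &&
        (ev$intron_index < 1L || ev$intron_index > n_in))
      stop("planted event references nonexistent intron ", ev$intron_index)
    if (ev$type == "IIL" && ev$whole_exon_codel &&
        ev$intron_index + 1L > n_in)
      stop("whole-exon co-deletion needs an internal downstream exon")
    if (!is.na(ev$exon_index) &&
        (ev$exon_index <= 1L || ev$exon_index >= n_ex))
      stop("exon-level events require an internal exon, got ", ev$exon_index)
    if (cfg$frame_preserving && ev$type == "IIL" && !ev$whole_exon_codel &&
        (ev$up_del_bp + ev$down_del_bp) %% 3L != 0L)
      stop("frame_preserving IIL needs up + down deletions = 0 mod 3")
  }
  sets <- lapply(cfg$planted, event_introns, n_introns = n_in)
  if (length(sets) > 1L) {
    for (i in seq_along(sets)[-1L]) {
      for (j in seq_len(i - 1L)) {
        d <- min(abs(outer(sets[[i]], sets[[j]], "-")))
        if (d < 2L)
          stop("planted events must touch intron indices at least 2 apart")
      }
    }
  }

  # frame adjustments for exon-level events
  if (cfg$frame_preserving) {
    for (ev in cfg$planted) {
      k <- switch(ev$type,
                  DE_EXONIZATION = ev$exon_index,
                  EXON_DELETION = ev$exon_index,
                  IIL = if (ev$whole_exon_codel) ev$intron_index + 1L else NA,
                  NA)
      if (!is.na(k)) ex_lens[k] <- max(3L, ex_lens[k] - ex_lens[k] %% 3L)
      if (ev$type == "DE_INTRONIZATION") {
        j <- ev$intron_index
        in_lens[j] <- max(6L, in_lens[j] - in_lens[j] %% 3L)
      }
    }
  }

  # total CDS must be a whole number of codons
  cds_len <- sum(ex_lens) - cfg$utr5_len - cfg$utr3_len
  adj <- cds_len %% 3L
  if (adj != 0L) {
    free <- setdiff(seq_len(n_ex), unlist(lapply(cfg$planted, function(ev)
      c(ev$exon_index, if (isTRUE(ev$whole_exon_codel)) ev$intron_index + 1L))))
    free <- free[!is.na(free)]
    if (!length(free)) free <- n_ex
    ex_lens[free[length(free)]] <- ex_lens[free[length(free)]] + (3L - adj)
    cds_len <- sum(ex_lens) - cfg$utr5_len - cfg$utr3_len
  }
  if (cds_len < 6L) stop("CDS too short")
  if (cfg$utr5_len >= ex_lens[1L] || cfg$utr3_len >= ex_lens[n_ex])
    stop("UTRs must fit strictly inside the terminal exons")

  # ---- ancestral sequence ----------------------------------------------
  cds <- rand_cds(cds_len %/% 3L, cfg$gc)
  tx <- paste0(rand_dna(cfg$utr5_len, cfg$gc), cds,
               rand_dna(cfg$utr3_len, cfg$gc))
  segs <- list()
  off <- 0L
  for (k in seq_len(n_ex)) {
    segs[[length(segs) + 1L]] <- list(kind = "exon",
                                      seq = substr(tx, off + 1L, off + ex_lens[k]))
    off <- off + ex_lens[k]
    if (k < n_ex)
      segs[[length(segs) + 1L]] <- list(kind = "intron",
                                        seq = rand_intron(in_lens[k], cfg$gc))
  }

  # de-intronization introns must not disrupt the recipient ORF
  if (cfg$frame_preserving) {
    for (ev in cfg$planted) {
      if (ev$type != "DE_INTRONIZATION") next
      j <- 2L * ev$intron_index
      p <- sum(ex_lens[seq_len(ev$intron_index)])
      # a codon reading "TA" + the fixed G of the donor site cannot be
      # repaired by resampling the intron interior; adjust the exon base
      if ((p - cfg$utr5_len) %% 3L == 2L &&
          substr(segs_transcript(segs), p - 1L, p) == "TA") {
        cand <- safe_replacements(segs, p, c("A", "G"), cfg$utr5_len, cds_len)
        if (length(cand)) segs <- set_transcript_base(segs, p, cand[1L])
      }
      tries <- 0L
      repeat {
        merged <- segs
        merged[[j - 1L]]$seq <- paste0(merged[[j - 1L]]$seq, merged[[j]]$seq,
                                       merged[[j + 1L]]$seq)
        merged <- merged[-c(j, j + 1L)]
        mcds <- substr(segs_transcript(merged), cfg$utr5_len + 1L,
                       cfg$utr5_len + cds_len + in_lens[ev$intron_index])
        codons <- substring(mcds, seq(1L, nchar(mcds) - 2L, 3L),
                            seq(3L, nchar(mcds), 3L))
        if (!any(codons[-length(codons)] %in% STOPS)) break
        tries <- tries + 1L
        if (tries > 200L) stop("could not build a stop-free intron")
        segs[[j]]$seq <- rand_intron(in_lens[ev$intron_index], cfg$gc)
      }
    }
  }

  # ---- identifiability guard on planted blocks --------------------------
  excum <- cumsum(ex_lens)
  for (ev in cfg$planted) {
    if (ev$type == "PIL") next
    if (ev$type == "IIL" && !ev$whole_exon_codel) {
      p <- excum[ev$intron_index]
      segs <- deambiguate_block(segs, p - ev$up_del_bp, p + ev$down_del_bp,
                                cfg$utr5_len, cds_len)
    } else if (ev$type %in% c("DE_EXONIZATION", "EXON_DELETION") ||
               (ev$type == "IIL" && ev$whole_exon_codel)) {
      k <- if (ev$type == "IIL") ev$intron_index + 1L else ev$exon_index
      segs <- deambiguate_block(segs, excum[k - 1L], excum[k],
                                cfg$utr5_len, cds_len)
    } else if (ev$type == "DE_INTRONIZATION") {
      p <- excum[ev$intron_index]
      for (tpos in c(p, p + 1L)) {       # neighbours must differ from G
        if (get_transcript_base(segs, tpos) == "G") {
          avoid <- "G"
          if (tpos == p && (p - cfg$utr5_len) %% 3L == 2L &&
              get_transcript_base(segs, p - 1L) == "T")
            avoid <- c("G", "A")         # keep the donor-site codon stop-free
          cand <- safe_replacements(segs, tpos, avoid, cfg$utr5_len, cds_len)
          if (length(cand)) segs <- set_transcript_base(segs, tpos, cand[1L])
        }
      }
    }
  }

  # with frame_preserving, deletion junctions must not create in-frame
  # stop codons in the recipient ORF; repair offending ancestor bases
  if (cfg$frame_preserving)
    segs <- fix_junction_stops(segs, cfg$planted, ex_lens, cfg$utr5_len,
                               cds_len)

  pad5 <- rand_dna(cfg$pad, cfg$gc)
  pad3 <- rand_dna(cfg$pad, cfg$gc)

  # ---- apply planted events to the recipient segment list ---------------
  segs_a <- segs
  segs_b <- segs
  truth <- NULL
  cds_len_b <- cds_len
  ord <- order(vapply(cfg$planted, function(ev)
    if (!is.na(ev$intron_index)) ev$intron_index else ev$exon_index,
    numeric(1)), decreasing = TRUE)
  gene_a <- paste0(cfg$ids$gene_a, ".t1")
  gene_b <- paste0(cfg$ids$gene_b, ".t1")
  for (ev in cfg$planted[ord]) {
    k <- ev$intron_index
    if (ev$type == "PIL") {
      j <- 2L * k
      segs_b[[j - 1L]]$seq <- paste0(segs_b[[j - 1L]]$seq, segs_b[[j + 1L]]$seq)
      segs_b <- segs_b[-c(j, j + 1L)]
      tr <- truth_row(gene_a, gene_b, "PIL", k, NA, in_lens[k], 0L, 0L, 0L)
    } else if (ev$type == "IIL" && !ev$whole_exon_codel) {
      j <- 2L * k
      up <- ev$up_del_bp; down <- ev$down_del_bp
      e1 <- segs_b[[j - 1L]]$seq; e2 <- segs_b[[j + 1L]]$seq
      if (up >= nchar(e1) || down >= nchar(e2))
        stop("IIL deletions larger than the flanking exons")
      segs_b[[j - 1L]]$seq <- paste0(substr(e1, 1L, nchar(e1) - up),
                                     substr(e2, down + 1L, nchar(e2)))
      segs_b <- segs_b[-c(j, j + 1L)]
      cds_len_b <- cds_len_b - up - down
      tr <- truth_row(gene_a, gene_b, "IIL", k, NA, in_lens[k], up, down, 0L)
    } else if (ev$type == "IIL" && ev$whole_exon_codel) {
      j <- 2L * k
      segs_b <- segs_b[-c(j, j + 1L)]       # intron k and exon k+1
      cds_len_b <- cds_len_b - ex_lens[k + 1L]
      tr <- truth_row(gene_a, gene_b, "IIL", k, k + 1L, in_lens[k], 0L, 0L,
                      ex_lens[k + 1L])
    } else if (ev$type == "EXON_DELETION") {
      e <- ev$exon_index
      j <- 2L * e - 1L                       # the exon segment
      segs_b[[j - 1L]]$seq <- paste0(segs_b[[j - 1L]]$seq, segs_b[[j + 1L]]$seq)
      segs_b <- segs_b[-c(j, j + 1L)]
      cds_len_b <- cds_len_b - ex_lens[e]
      tr <- truth_row(gene_a, gene_b, "EXON_DELETION", e, e, 0L, 0L, 0L,
                      ex_lens[e])
    } else if (ev$type == "DE_EXONIZATION") {
      e <- ev$exon_index
      j <- 2L * e - 1L
      segs_b[[j - 1L]]$seq <- paste0(segs_b[[j - 1L]]$seq, segs_b[[j]]$seq,
                                     segs_b[[j + 1L]]$seq)
      segs_b[[j - 1L]]$kind <- "intron"
      segs_b <- segs_b[-c(j, j + 1L)]
      cds_len_b <- cds_len_b - ex_lens[e]
      tr <- truth_row(gene_a, gene_b, "DE_EXONIZATION", e, e, in_lens[e],
                      0L, 0L, ex_lens[e])
    } else {                                  # DE_INTRONIZATION
      j <- 2L * k
      segs_b[[j - 1L]]$seq <- paste0(segs_b[[j - 1L]]$seq, segs_b[[j]]$seq,
                                     segs_b[[j + 1L]]$seq)
      segs_b <- segs_b[-c(j, j + 1L)]
      cds_len_b <- cds_len_b + in_lens[k]
      tr <- truth_row(gene_a, gene_b, "DE_INTRONIZATION", k, NA, in_lens[k],
                      0L, 0L, 0L)
    }
    truth <- rbind(tr, truth)
  }
  if (is.null(truth)) truth <- truth_row(gene_a, gene_b, character(0),
                                         integer(0), integer(0), integer(0),
                                         integer(0), integer(0), integer(0))

  # ---- lineage-specific substitution ------------------------------------
  rate <- cfg$divergence / 2
  segs_a <- mutate_segments(segs_a, rate, cfg$utr5_len, cds_len,
                            cfg$frame_preserving)
  segs_b <- mutate_segments(segs_b, rate, cfg$utr5_len, cds_len_b,
                            cfg$frame_preserving)

  bundle_a <- assemble_gene(segs_a, pad5, pad3, cfg$ids$chrom_a,
                            cfg$ids$gene_a, gene_a, cfg$strand[1L],
                            cfg$utr5_len, cds_len, cfg$utr3_len)
  bundle_b <- assemble_gene(segs_b, pad5, pad3, cfg$ids$chrom_b,
                            cfg$ids$gene_b, gene_b, cfg$strand[2L],
                            cfg$utr5_len, cds_len_b, cfg$utr3_len)

  bundle <- structure(list(
    genome_a = bundle_a$genome, genome_b = bundle_b$genome,
    models_a = stats::setNames(list(bundle_a$model), gene_a),
    models_b = stats::setNames(list(bundle_b$model), gene_b),
    orthologs = data.frame(gene_a = gene_a, gene_b = gene_b,
                           stringsAsFactors = FALSE),
    truth = truth, config = cfg), class = "fixture_bundle")
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

truth_row <- function(gene_a, gene_b, type, intron_index, exon_index,
                      lost_intron_length, up, down, whole_exon) {
  data.frame(
    event_id = if (length(type)) paste(gene_a, intron_index, type, sep = ":")
               else character(0),
    donor_gene = if (length(type)) gene_a else character(0),
    recipient_gene = if (length(type)) gene_b else character(0),
    type = type, intron_index = as.integer(intron_index),
    exon_index = as.integer(exon_index),
    lost_intron_length = as.integer(lost_intron_length),
    up_del_bp = as.integer(up), down_del_bp = as.integer(down),
    whole_exon_lost_bp = as.integer(whole_exon),
    stringsAsFactors = FALSE)
}

# per-site substitution, protecting splice dinucleotides and the
# start/stop codons; with frame_preserving, substitutions that create an
# in-frame stop are reverted.
mutate_segments <- function(segs, rate, utr5, cds_len, frame_preserving) {
  if (rate <= 0) return(segs)
  orig <- segs
  for (i in seq_along(segs)) {
    s <- strsplit(segs[[i]]$seq, "", fixed = TRUE)[[1L]]
    w <- length(s)
    prot <- rep(FALSE, w)
    if (segs[[i]]$kind == "intron" && w >= 4L)
      prot[c(1L, 2L, w - 1L, w)] <- TRUE
    hit <- stats::runif(w) < rate & !prot
    if (any(hit)) {
      for (p in which(hit)) {
        s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
      }
      segs[[i]]$seq <- paste0(s, collapse = "")
    }
  }
  # restore protected start/stop codons
  tx <- segs_transcript(segs)
  for (tp in c(utr5 + 1L, utr5 + 2L, utr5 + 3L,
               utr5 + cds_len - 2L, utr5 + cds_len - 1L, utr5 + cds_len)) {
    want <- get_transcript_base(orig, tp)
    if (get_transcript_base(segs, tp) != want)
      segs <- set_transcript_base(segs, tp, want)
  }
  if (frame_preserving) {
    repeat {
      tx <- segs_transcript(segs)
      cdss <- substr(tx, utr5 + 1L, utr5 + cds_len)
      codons <- substring(cdss, seq(1L, cds_len - 2L, 3L),
                          seq(3L, cds_len, 3L))
      bad <- which(codons[-length(codons)] %in% STOPS)
      if (!length(bad)) break
      # revert one mutated base inside the first offending codon
      cstart <- utr5 + (bad[1L] - 1L) * 3L
      fixed <- FALSE
      for (tp in cstart + 1:3) {
        want <- get_transcript_base(orig, tp)
        if (get_transcript_base(segs, tp) != want) {
          segs <- set_transcript_base(segs, tp, want)
          fixed <- TRUE
          break
        }
      }
      if (!fixed) break  # ancestral codon was not a stop; cannot happen
    }
  }
  segs
}

# build the genomic sequence and gene_model for one lineage
assemble_gene <- function(segs, pad5, pad3, chrom, gene_id, transcript_id,
                          strand, utr5, cds_len, utr3) {
  chrom_seq <- paste0(pad5, segs_genomic(segs), pad3)
  L <- nchar(chrom_seq)
  pos <- nchar(pad5)
  exons <- NULL
  tpos <- 0L
  cds <- NULL
  cds_lo <- utr5          # transcript coords, 0-based half-open
  cds_hi <- utr5 + cds_len
  for (sg in segs) {
    w <- nchar(sg$seq)
    if (sg$kind == "exon") {
      exons <- rbind(exons, c(pos, pos + w))
      lo <- max(tpos, cds_lo); hi <- min(tpos + w, cds_hi)
      if (lo < hi)
        cds <- rbind(cds, c(pos + (lo - tpos), pos + (hi - tpos)))
      tpos <- tpos + w
    }
    pos <- pos + w
  }
  if (strand == "-") {
    chrom_seq <- revcomp(chrom_seq)
    flip <- function(m) {
      m2 <- cbind(L - m[, 2L], L - m[, 1L])
      m2[order(-m2[, 1L]), , drop = FALSE]  # coding orientation
    }
    exons <- flip(exons)
    cds <- if (is.null(cds)) NULL else flip(cds)
  }
  genome <- stats::setNames(chrom_seq, chrom)
  model <- new_gene_model(gene_id, transcript_id, chrom, strand,
                          exons, cds, utr_annotated = (utr5 + utr3) > 0L)
  list(genome = genome, model = model)
}

#' Write a fixture bundle to a directory
#'
#' Writes genome_a.fa, genome_b.fa, genes_a.gff3, genes_b.gff3,
#' orthologs.tsv, truth.tsv, optional support.tsv / genotypes.tsv, and a
#' manifest.json echoing the configuration and seed.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(bundle$genome_a, file.path(dir, "genome_a.fa"))
  write_genome(bundle$genome_b, file.path(dir, "genome_b.fa"))
  write_gene_models(bundle$models_a, file.path(dir, "genes_a.gff3"))
  write_gene_models(bundle$models_b, file.path(dir, "genes_b.gff3"))
  utils::write.table(bundle$orthologs, file.path(dir, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$support))
    utils::write.table(bundle$support, file.path(dir, "support.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$genotypes))
    utils::write.table(bundle$genotypes, file.path(dir, "genotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cfgs <- bundle$config
  if (inherits(cfgs, "generator_config")) cfgs <- list(cfgs)
  manifest <- list(
    n_pairs = nrow(bundle$orthologs),
    seeds = vapply(cfgs, `[[`, integer(1), "seed"),
    configs = lapply(cfgs, function(cf)
      cf[c("n_exons", "exon_len", "intron_len", "gc", "divergence",
           "utr5_len", "utr3_len", "frame_preserving", "pad", "strand",
           "seed")]))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Merge single-pair bundles into one multi-locus bundle
#'
#' @param bundles List of `fixture_bundle`s with distinct chrom/gene ids.
#' @return One `fixture_bundle` spanning all pairs.
#' @export
merge_bundles <- function(bundles) {
  stopifnot(length(bundles) >= 1L)
  g_a <- do.call(c, lapply(bundles, `[[`, "genome_a"))
  g_b <- do.call(c, lapply(bundles, `[[`, "genome_b"))
  if (anyDuplicated(names(g_a)) || anyDuplicated(names(g_b)))
    stop("bundles to merge must use distinct chromosome ids")
  structure(list(
    genome_a = g_a, genome_b = g_b,
    models_a = do.call(c, lapply(bundles, `[[`, "models_a")),
    models_b = do.call(c, lapply(bundles, `[[`, "models_b")),
    orthologs = do.call(rbind, lapply(bundles, `[[`, "orthologs")),
    truth = do.call(rbind, lapply(bundles, `[[`, "truth")),
    config = lapply(bundles, `[[`, "config")), class = "fixture_bundle")
}

#' Generate a cohort of ortholog pairs with planted events
#'
#' Convenience wrapper: one locus pair per planted event, cycling through
#' the requested event types, each pair on its own chromosome pair.
#'
#' @param n_pairs Number of ortholog pairs.
#' @param seed Master seed; per-pair seeds are derived from it.
#' @param types Event types to cycle through.  `"IIL_EXON"` denotes the
#'   whole-exon co-deletion flavor of IIL.
#' @param divergence Passed to [generator_config()].
#' @param ... Further arguments to [generator_config()].
#' @return A merged `fixture_bundle`.
#' @export
generate_cohort <- function(n_pairs, seed,
                            types = c("PIL", "IIL", "IIL_EXON",
                                      "DE_INTRONIZATION", "DE_EXONIZATION",
                                      "EXON_DELETION"),
                            divergence = 0.05, ...) {
  bundles <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    ty <- types[((i - 1L) %% length(types)) + 1L]
    set.seed((seed * 1009L + i) %% 2147483647L)
    n_in <- 4L                        # 5 exons
    k <- sample(2L:(n_in - 1L), 1L)   # internal, away from terminal exons
    ev <- switch(ty,
      PIL = planted_event("PIL", intron_index = k),
      IIL = planted_event("IIL", intron_index = k,
                          up_del_bp = sample(0:30, 1L),
                          down_del_bp = sample(1:30, 1L)),
      IIL_EXON = planted_event("IIL", intron_index = k,
                               whole_exon_codel = TRUE),
      DE_INTRONIZATION = planted_event("DE_INTRONIZATION", intron_index = k),
      DE_EXONIZATION = planted_event("DE_EXONIZATION", exon_index = k),
      EXON_DELETION = planted_event("EXON_DELETION", exon_index = k))
    cfg <- generator_config(
      n_exons = c(5L, 5L), planted = list(ev), divergence = divergence,
      seed = (seed * 7919L + i) %% 2147483647L,
      ids = list(chrom_a = sprintf("chrA_%03d", i),
                 chrom_b = sprintf("chrB_%03d", i),
                 gene_a = sprintf("gA%03d", i),
                 gene_b = sprintf("gB%03d", i)), ...)
    bundles[[i]] <- generate_locus_pair(cfg)
  }
  merge_bundles(bundles)
}

#' Simulate read support for events
#'
#' Draws Poisson read counts per event for an RNA-Seq junction record and a
#' WGS site record.
#'
#' @param truth Truth table (or any data.frame with `event_id`).
#' @param mean_rna,mean_wgs Poisson means (>= 0).
#' @param seed Integer seed.
#' @return data.frame: target_id, source, read_count.
#' @export
simulate_support <- function(truth, mean_rna = 20, mean_wgs = 9, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (mean_rna < 0 || mean_wgs < 0) stop("rates must be >= 0")
  set.seed(seed)
  ids <- truth$event_id
  data.frame(
    target_id = rep(ids, times = 2L),
    source = rep(c("rna_junction", "wgs_site"), each = length(ids)),
    read_count = c(stats::rpois(length(ids), mean_rna),
                   stats::rpois(length(ids), mean_wgs)),
    stringsAsFactors = FALSE)
}

#' Simulate population genotypes for events
#'
#' Each line is independently missing with `missing_rate`, otherwise a
#' carrier with probability `carrier_freq`.
#'
#' @param truth Truth table (or any data.frame with `event_id`).
#' @param n_lines Number of population lines (default 180).
#' @param carrier_freq Carrier probability among called lines.
#' @param missing_rate Per-line missing probability.
#' @param seed Integer seed.
#' @return data.frame: event_id, line_id, state.
#' @export
simulate_population <- function(truth, n_lines = 180L, carrier_freq = 1.0,
                                missing_rate = 0.0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (carrier_freq < 0 || carrier_freq > 1 ||
      missing_rate < 0 || missing_rate > 1)
    stop("fractions must be in [0, 1]")
  set.seed(seed)
  ids <- truth$event_id
  out <- lapply(ids, function(id) {
    miss <- stats::runif(n_lines) < missing_rate
    carrier <- stats::runif(n_lines) < carrier_freq
    state <- ifelse(miss, "missing",
                    ifelse(carrier, "carrier", "non_carrier"))
    data.frame(event_id = id, line_id = sprintf("line%04d", seq_len(n_lines)),
               state = state, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Construct a genotype table with exact carrier counts
#'
#' Deterministic counterpart of [simulate_population()]: the numbers of
#' carrier, non-carrier and missing lines are given exactly; the seed only
#' shuffles which line gets which state.
#'
#' @param event_id Event identifier.
#' @param carriers,non_carriers,missing Line counts.
#' @param seed Integer seed for the line permutation.
#' @return data.frame: event_id, line_id, state.
#' @export
population_table <- function(event_id, carriers, non_carriers,
                             missing = 0L, seed = 1L) {
  set.seed(seed)
  states <- sample(c(rep("carrier", carriers),
                     rep("non_carrier", non_carriers),
                     rep("missing", missing)))
  n <- length(states)
  data.frame(event_id = event_id, line_id = sprintf("line%04d", seq_len(n)),
             state = states, stringsAsFactors = FALSE)
}
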