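#' Simulate a coordinate-sorted mate-pair library (read-level mode)
#'
#' Draws fragments uniformly along the genome with insert length
#' `Normal(insert_mean, insert_sd)` truncated below at `2 * read_len`, then
#' emits the two 50 bp mates flanking each fragment as alignment records.
#' Both mates of a pair point in the same direction (the concordant state of
#' this library chemistry); mates carry each other's placement and a signed
#' insert size. For the tumor sample, fragments are drawn from a
#' purity-weighted mixture of tumor and normal cells, with local tumor copy
#' number modulating the sampling density
#' (`purity * CN/2 + (1 - purity)` relative to diploid), so planted deletions
#' and gains show up in depth. Reads overlapping planted indels on their source
#' haplotype receive correct `I`/`D` CIGAR operations. Fusion breakpoints
#' produce junction-spanning fragments whose mates map to the two partner
#' loci; a small configurable fraction of ordinary fragments have their second
#' mate relocated to a random contig, emulating residual chimeric-ligation
#' artifacts. Per-base substitution errors are applied at the rate implied by
#' the constant base quality.
#'
#' Read-level mode is intended for genomes up to a few Mb; a request implying
#' more than 1e8 reads is refused.
#'
#' @param genome a `sim_genome` from [plant_variants()].
#' @param sample_id `"tumor"` or `"germline"`.
#' @param coverage target mean base coverage; defaults to the config's value
#'   for the sample.
#' @return A `data.table` of class `aln_reads`, coordinate-sorted, with
#'   columns `qname`, `contig`, `start` (0-based), `strand`, `cigar`, `seq`,
#'   `qual`, `mate_contig`, `mate_start`, `isize`, `dup`.
#' @export
simulate_mate_pairs <- function(genome, sample_id = c("tumor", "germline"),
                                coverage = NULL) {
  stopifnot(inherits(genome, "sim_genome"))
  sample_id <- match.arg(sample_id)
  cfg <- genome$config
  if (is.null(coverage))
    coverage <- if (sample_id == "tumor") cfg$mean_coverage_tumor else
      cfg$mean_coverage_germline
  rl <- cfg$read_len
  gs <- cfg$genome_spec
  total_len <- sum(as.numeric(gs))
  n_target <- coverage * total_len / (2 * rl)
  if (2 * n_target > 1e8)
    stop("requested simulation implies > 1e8 reads; read-level mode is desk-scale")
  set.seed(cfg$seed + if (sample_id == "tumor") 101L else 202L)

  frags <- .sim_fragments(cfg, sample_id, n_target)
  reads <- .reads_from_fragments(frags, genome, sample_id)
  reads <- .apply_background_discordance(reads, genome)
  fus <- .fusion_reads(genome, sample_id, coverage)
  if (!is.null(fus)) reads <- rbind(reads, fus)
  reads <- .apply_errors(reads, cfg)
  setorder(reads, contig, start, qname)
  setattr(reads, "class", c("aln_reads", class(reads)))
  reads[]
}

# fragment table: contig, start (0-based), insert, strand, hap in {g1,g2,t1,t2}
.sim_fragments <- function(cfg, sample_id, n_target) {
  gs <- cfg$genome_spec
  rl <- cfg$read_len
  purity <- if (sample_id == "tumor") cfg$purity else 0
  cn_max <- if (!is.null(cfg$cnv_spec) && nrow(cfg$cnv_spec))
    max(c(2L, cfg$cnv_spec$cn)) else 2L
  r_max <- purity * cn_max / 2 + (1 - purity)
  m_draw <- ceiling(n_target * max(r_max, 1))

  ctg <- sample(names(gs), m_draw, TRUE, prob = as.numeric(gs))
  ins <- as.integer(round(rnorm(m_draw, cfg$insert_mean, cfg$insert_sd)))
  ins <- pmax(ins, 2L * rl)
  maxstart <- gs[ctg] - ins
  keep <- maxstart >= 0L
  ctg <- ctg[keep]; ins <- ins[keep]; maxstart <- maxstart[keep]
  start <- as.integer(floor(runif(length(ctg)) * (maxstart + 1)))

  mid <- start + ins %/% 2L
  if (purity > 0) {
    m <- .hap_multiplicity(ctg, mid, cfg)
    cn <- m$m1 + m$m2
    r <- purity * cn / 2 + (1 - purity)
    acc <- runif(length(r)) < r / r_max
    ctg <- ctg[acc]; ins <- ins[acc]; start <- start[acc]
    m1 <- m$m1[acc]; m2 <- m$m2[acc]; cn <- cn[acc]; r <- r[acc]
    # cell of origin, then haplotype within the cell
    p_tumor <- ifelse(r > 0, purity * cn / 2 / r, 0)
    tumor_cell <- runif(length(r)) < p_tumor
    u <- runif(length(r))
    hap <- character(length(r))
    hap[tumor_cell] <- ifelse(u[tumor_cell] < ifelse(cn[tumor_cell] > 0,
                                                     m1[tumor_cell] / pmax(cn[tumor_cell], 1L), 0.5),
                              "t1", "t2")
    hap[!tumor_cell] <- ifelse(u[!tumor_cell] < 0.5, "g1", "g2")
  } else {
    if (length(ctg) > n_target) {
      keep2 <- seq_len(floor(n_target))
      ctg <- ctg[keep2]; ins <- ins[keep2]; start <- start[keep2]
    }
    hap <- ifelse(runif(length(ctg)) < 0.5, "g1", "g2")
  }
  data.table(contig = ctg, start = start, insert = ins,
             strand = ifelse(runif(length(ctg)) < 0.5, "+", "-"), hap = hap)
}

.qual_string <- function(q, n) strrep(intToUtf8(q + 33L), n)

.reads_from_fragments <- function(frags, genome, sample_id) {
  cfg <- genome$config
  rl <- cfg$read_len
  if (!nrow(frags)) return(.empty_reads())
  nf <- nrow(frags)
  qn <- sprintf("%s_f%08d", substr(sample_id, 1, 1), seq_len(nf))
  r1 <- data.table(qname = qn, contig = frags$contig, start = frags$start,
                   strand = frags$strand, hap = frags$hap,
                   mate_contig = frags$contig,
                   mate_start = frags$start + frags$insert - rl,
                   isize = frags$insert)
  r2 <- data.table(qname = qn, contig = frags$contig,
                   start = frags$start + frags$insert - rl,
                   strand = frags$strand, hap = frags$hap,
                   mate_contig = frags$contig, mate_start = frags$start,
                   isize = -frags$insert)
  reads <- rbind(r1, r2)
  .materialize_reads(reads, genome)
}

# fill seq + cigar for reads given (contig, start, hap); fast path for reads
# clear of indels on their haplotype, CIGAR walk otherwise
.materialize_reads <- function(reads, genome) {
  cfg <- genome$config
  rl <- cfg$read_len
  reads[, `:=`(seq = NA_character_, cigar = paste0(rl, "M"))]
  vars <- genome$variants
  for (ctg in unique(reads$contig)) {
    refseq <- genome$reference[[ctg]]
    i <- which(reads$contig == ctg)
    reads$seq[i] <- substring(refseq, reads$start[i] + 1L, reads$start[i] + rl)
    v <- vars[contig == ctg]
    if (!nrow(v)) next
    indels <- v[type %in% c("ins", "del")]
    # slow path: read overlaps an indel carried by its haplotype
    slow <- rep(FALSE, length(i))
    if (nrow(indels)) {
      for (j in seq_len(nrow(indels))) {
        carry <- reads$hap[i] %in% c("g1", "g2", "t1", "t2")[
          c(indels$g1[j], indels$g2[j], indels$t1[j], indels$t2[j])]
        span_end <- indels$pos[j] + ifelse(indels$type[j] == "del", indels$len[j], 0L)
        # conservative margin: a read whose reference span could touch the
        # event (deletions stretch the span by their length) goes slow-path
        ov <- carry & reads$start[i] <= span_end &
          reads$start[i] + rl + indels$len[j] >= indels$pos[j]
        slow <- slow | ov
      }
    }
    snvs <- v[type == "snv"]
    fast <- i[!slow]
    if (nrow(snvs) && length(fast)) {
      # (read, snv) pairs via interval lookup
      o <- IRanges::findOverlaps(
        IRanges::IRanges(reads$start[fast] + 1L, reads$start[fast] + rl),
        IRanges::IRanges(snvs$pos + 1L, snvs$pos + 1L))
      if (length(o)) {
        ri <- fast[S4Vectors_from(o)]
        si <- S4Vectors_to(o)
        carries <- .hap_carries(reads$hap[ri], snvs[si])
        ri <- ri[carries]; si <- si[carries]
        if (length(ri)) {
          off <- snvs$pos[si] - reads$start[ri] + 1L
          reads$seq <- .substitute_at(reads$seq, ri, off, snvs$alt[si])
        }
      }
    }
    for (k in i[slow]) {
      built <- .build_read_walk(refseq, v, reads$hap[k], reads$start[k], rl)
      reads$seq[k] <- built$seq
      reads$cigar[k] <- built$cigar
      reads$start[k] <- built$start
    }
  }
  reads[, hap := NULL]
  reads[, qual := .qual_string(cfg$base_quality, rl)]
  reads[, dup := FALSE]
  reads[, .(qname, contig, start, strand, cigar, seq, qual,
            mate_contig, mate_start, isize, dup)]
}

S4Vectors_from <- function(o) S4Vectors::queryHits(o)
S4Vectors_to <- function(o) S4Vectors::subjectHits(o)

.hap_carries <- function(hap, vtab) {
  out <- logical(length(hap))
  out[hap == "g1"] <- vtab$g1[hap == "g1"]
  out[hap == "g2"] <- vtab$g2[hap == "g2"]
  out[hap == "t1"] <- vtab$t1[hap == "t1"]
  out[hap == "t2"] <- vtab$t2[hap == "t2"]
  out
}

# vectorized single-character substitution; handles multiple edits per string
# by rounds over the first remaining edit of each string
.substitute_at <- function(strings, idx, offset, base) {
  dt <- data.table(idx = idx, offset = offset, base = base)
  setorder(dt, idx, offset)
  while (nrow(dt)) {
    first <- dt[!duplicated(idx)]
    strings[first$idx] <- paste0(
      substr(strings[first$idx], 1L, first$offset - 1L), first$base,
      substring(strings[first$idx], first$offset + 1L))
    dt <- dt[duplicated(idx)]
  }
  strings
}

# construct one read by walking the haplotype from a reference start position
.build_read_walk <- function(refseq, vtab, hap, start, rl) {
  v <- vtab[.hap_carries(rep(hap, nrow(vtab)), vtab)]
  setorder(v, pos)
  dels <- v[type == "del"]
  # a read cannot start inside deleted DNA on this haplotype
  inside <- dels[start > pos & start < pos + len]
  if (nrow(inside)) start <- inside$pos[1] + inside$len[1]
  out <- character(0); ops <- character(0)
  p <- start
  nref <- nchar(refseq)
  done_ins <- integer(0)
  while (length(out) < rl && p < nref) {
    ins_here <- v[type == "ins" & pos == p]
    if (nrow(ins_here) && p > start && !(p %in% done_ins)) {
      take <- strsplit(ins_here$seq[1], "")[[1]]
      take <- take[seq_len(min(length(take), rl - length(out)))]
      out <- c(out, take); ops <- c(ops, rep("I", length(take)))
      done_ins <- c(done_ins, p)
      next
    }
    del_here <- dels[pos == p]
    if (nrow(del_here)) {
      ops <- c(ops, rep("D", del_here$len[1]))
      p <- p + del_here$len[1]
      next
    }
    b <- substr(refseq, p + 1L, p + 1L)
    snv_here <- v[type == "snv" & pos == p]
    if (nrow(snv_here)) b <- snv_here$alt[1]
    out <- c(out, b); ops <- c(ops, "M")
    p <- p + 1L
  }
  # pad at contig end (clip) by truncating to what was built
  r <- rle(ops)
  # trailing deletion carries no information; drop it
  while (length(r$values) && r$values[length(r$values)] == "D") {
    r$values <- r$values[-length(r$values)]
    r$lengths <- r$lengths[-length(r$lengths)]
  }
  list(seq = paste(out, collapse = ""),
       cigar = paste0(r$lengths, r$values, collapse = ""),
       start = start)
}

# junction-spanning fragments for each planted fusion present in this sample
.fusion_reads <- function(genome, sample_id, coverage) {
  cfg <- genome$config
  fus <- cfg$fusion_spec
  if (is.null(fus) || !nrow(fus)) return(NULL)
  rl <- cfg$read_len
  dens <- coverage / (2 * rl)  # fragments per bp
  out <- list()
  for (i in seq_len(nrow(fus))) {
    w <- if (fus$origin[i] == "germline") 1
    else if (sample_id == "tumor") cfg$purity else 0
    if (w <= 0) next
    span_bp <- max(cfg$insert_mean - 2 * rl, 1)
    n <- rpois(1L, dens * span_bp * w)
    if (n == 0) next
    ins <- pmax(as.integer(round(rnorm(n, cfg$insert_mean, cfg$insert_sd))),
                2L * rl + 2L)
    j <- floor(runif(n, rl + 1, ins - rl))  # junction offset inside fragment
    a_start <- as.integer(fus$pos_a[i] - j)
    b_start <- as.integer(fus$pos_b[i] + (ins - j - rl))
    ok <- a_start >= 0 & a_start + rl <= cfg$genome_spec[[fus$contig_a[i]]] &
      b_start >= 0 & b_start + rl <= cfg$genome_spec[[fus$contig_b[i]]]
    if (!any(ok)) next
    a_start <- a_start[ok]; b_start <- b_start[ok]
    m <- length(a_start)
    qn <- sprintf("%s_x%02d_%06d", substr(sample_id, 1, 1), i, seq_len(m))
    strand <- ifelse(runif(m) < 0.5, "+", "-")
    seq_a <- substring(genome$reference[[fus$contig_a[i]]], a_start + 1L, a_start + rl)
    seq_b <- substring(genome$reference[[fus$contig_b[i]]], b_start + 1L, b_start + rl)
    qual <- .qual_string(cfg$base_quality, rl)
    out[[length(out) + 1L]] <- data.table(
      qname = rep(qn, 2L),
      contig = c(rep(fus$contig_a[i], m), rep(fus$contig_b[i], m)),
      start = c(a_start, b_start), strand = rep(strand, 2L),
      cigar = paste0(rl, "M"), seq = c(seq_a, seq_b), qual = qual,
      mate_contig = c(rep(fus$contig_b[i], m), rep(fus$contig_a[i], m)),
      mate_start = c(b_start, a_start), isize = 0L, dup = FALSE)
  }
  if (!length(out)) return(NULL)
  rbindlist(out)
}

# relocate the second mate of a small fraction of pairs to a random other
# contig (chimeric-ligation background); keeps mate bookkeeping consistent.
# Relies on the row layout of .reads_from_fragments: first mates occupy rows
# 1..nf, second mates rows nf+1..2*nf, so row k pairs with row k - nf.
.apply_background_discordance <- function(reads, genome) {
  cfg <- genome$config
  rate <- cfg$background_discordant_rate
  gs <- cfg$genome_spec
  if (rate <= 0 || length(gs) < 2 || !nrow(reads)) return(reads)
  nf <- nrow(reads) %/% 2L
  second <- nf + seq_len(nf)
  pick <- second[runif(nf) < rate]
  if (!length(pick)) return(reads)
  rl <- cfg$read_len
  dest <- vapply(reads$contig[pick],
                 function(c0) sample(setdiff(names(gs), c0), 1L),
                 character(1), USE.NAMES = FALSE)
  pos <- as.integer(floor(runif(length(pick)) * (gs[dest] - rl)))
  seqs <- character(length(pick))
  for (ctg in unique(dest)) {
    i <- which(dest == ctg)
    seqs[i] <- substring(genome$reference[[ctg]], pos[i] + 1L, pos[i] + rl)
  }
  mate <- pick - nf
  reads$contig[pick] <- dest
  reads$start[pick] <- pos
  reads$seq[pick] <- seqs
  reads$cigar[pick] <- paste0(rl, "M")
  reads$mate_contig[pick] <- reads$contig[mate]
  reads$mate_start[pick] <- reads$start[mate]
  reads$isize[pick] <- 0L
  reads$mate_contig[mate] <- dest
  reads$mate_start[mate] <- pos
  reads$isize[mate] <- 0L
  reads
}

# per-base substitution errors at the rate implied by the constant quality
.apply_errors <- function(reads, cfg) {
  err <- 10^(-cfg$base_quality / 10)
  rl <- cfg$read_len
  n_err <- rbinom(nrow(reads), rl, err)
  hit <- which(n_err > 0)
  if (!length(hit)) return(reads)
  idx <- rep(hit, n_err[hit])
  off <- sample.int(rl, length(idx), replace = TRUE)
  cur <- substr(reads$seq[idx], off, off)
  subs <- c("A", "C", "G", "T")
  new <- vapply(cur, function(b) sample(setdiff(subs, b), 1L), character(1),
                USE.NAMES = FALSE)
  reads$seq <- .substitute_at(reads$seq, idx, off, new)
  reads
}

.empty_reads <- function() {
  r <- data.table(qname = character(), contig = character(), start = integer(),
                  strand = character(), cigar = character(), seq = character(),
                  qual = character(), mate_contig = character(),
                  mate_start = integer(), isize = integer(), dup = logical())
  setattr(r, "class", c("aln_reads", class(r)))
  r
}
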