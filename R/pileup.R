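#' Mark PCR-duplicate mate pairs
#'
#' Fragment-level duplicate definition: reads sharing the placement key
#' `(contig, start, strand, mate_contig, mate_start)` are one molecular
#' family; all but the member with the highest total base quality are flagged.
#' Flagged reads must be excluded from every downstream pileup and count; the
#' package's pileup and coverage builders do so.
#'
#' @param reads an `aln_reads` table, coordinate-sorted.
#' @return The table with its `dup` column set.
#' @export
mark_duplicates <- function(reads) {
  reads <- as.data.table(reads)
  if (nrow(reads) > 1) {
    bad <- which(reads$contig[-1] == reads$contig[-nrow(reads)] &
                   diff(reads$start) < 0L)
    if (length(bad))
      stop("input not coordinate-sorted: record ", bad[1] + 1L,
           " (", reads$contig[bad[1] + 1L], ":", reads$start[bad[1] + 1L],
           ") precedes its predecessor")
  }
  if (!nrow(reads)) return(reads)
  tq <- .total_quality(reads$qual)
  reads[, dup := {
    best <- which.max(tq[.I])
    out <- rep(TRUE, .N); out[best] <- FALSE; out
  }, by = .(contig, start, strand, mate_contig, mate_start)]
  setattr(reads, "class", unique(c("aln_reads", class(reads))))
  reads[]
}

.total_quality <- function(qual) {
  vapply(qual, function(q) sum(utf8ToInt(q) - 33L), numeric(1), USE.NAMES = FALSE)
}

# ---- CIGAR helpers ---------------------------------------------------------

.cigar_parse <- function(cigar) {
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]]
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (!length(lens) || length(lens) != length(ops))
    stop("malformed CIGAR: ", cigar)
  list(len = as.integer(lens), op = ops)
}

# reference span consumed by a CIGAR (M/D/N ops)
.cigar_ref_span <- function(cigar, read_len_hint = NULL) {
  simple <- grepl("^[0-9]+M$", cigar)
  out <- integer(length(cigar))
  out[simple] <- as.integer(sub("M$", "", cigar[simple]))
  for (i in which(!simple)) {
    p <- .cigar_parse(cigar[i])
    out[i] <- sum(p$len[p$op %in% c("M", "D", "N")])
  }
  out
}

# aligned (M) reference blocks of one read: data.table(rstart, rend, qstart)
# rstart/rend are 0-based half-open reference coords, qstart 1-based in read
.cigar_blocks <- function(cigar, start) {
  p <- .cigar_parse(cigar)
  rpos <- start; qpos <- 1L
  out <- list()
  for (i in seq_along(p$op)) {
    len <- p$len[i]
    switch(p$op[i],
      M = , `=` = , X = {
        out[[length(out) + 1L]] <- c(rpos, rpos + len, qpos)
        rpos <- rpos + len; qpos <- qpos + len
      },
      D = , N = rpos <- rpos + len,
      I = , S = qpos <- qpos + len,
      H = , P = NULL)
  }
  m <- do.call(rbind, out)
  data.table(rstart = m[, 1], rend = m[, 2], qstart = m[, 3])
}

# insertion/deletion events of one read: (pos, type, len, seq)
.cigar_indel_events <- function(cigar, start, seq) {
  p <- .cigar_parse(cigar)
  rpos <- start; qpos <- 1L
  out <- list()
  for (i in seq_along(p$op)) {
    len <- p$len[i]
    op <- p$op[i]
    if (op %in% c("M", "=", "X")) { rpos <- rpos + len; qpos <- qpos + len }
    else if (op %in% c("D", "N")) {
      out[[length(out) + 1L]] <- data.table(pos = rpos, type = "del",
                                            len = len, seq = NA_character_)
      rpos <- rpos + len
    } else if (op == "I") {
      out[[length(out) + 1L]] <- data.table(
        pos = rpos, type = "ins", len = len,
        seq = substr(seq, qpos, qpos + len - 1L))
      qpos <- qpos + len
    } else if (op == "S") qpos <- qpos + len
  }
  if (!length(out)) return(NULL)
  rbindlist(out)
}

# ---- pileups ---------------------------------------------------------------

#' Build per-site stranded pileups
#'
#' Each non-duplicate read whose alignment places an `M` base on the site
#' contributes one (base, quality) observation to the list for its strand;
#' reads whose CIGAR deletes the site contribute nothing.
#'
#' @param reads an `aln_reads` table (duplicates are dropped here).
#' @param sites `data.frame` with columns `contig`, `pos` (0-based).
#' @param contig_lengths optional named lengths used to validate `sites`.
#' @return A list of `stranded_pileup` objects (fields `contig`, `site`,
#'   `fwd`, `rev`, each strand a list with `base` and `qual` vectors), named
#'   `"contig:pos"`.
#' @export
build_pileups <- function(reads, sites, contig_lengths = NULL) {
  sites <- as.data.table(sites)
  stopifnot(all(c("contig", "pos") %in% names(sites)))
  if (!is.null(contig_lengths)) {
    bad <- sites$pos < 0 | sites$pos >= contig_lengths[sites$contig]
    if (any(bad | is.na(bad)))
      stop("site outside contig: ", sites$contig[which(bad | is.na(bad))[1]],
           ":", sites$pos[which(bad | is.na(bad))[1]])
  }
  obs <- .pileup_observations(reads, sites)
  out <- vector("list", nrow(sites))
  names(out) <- paste0(sites$contig, ":", sites$pos)
  for (i in seq_len(nrow(sites))) {
    o <- obs[[i]]
    out[[i]] <- structure(list(
      contig = sites$contig[i], site = sites$pos[i],
      fwd = list(base = o$base[o$strand == "+"], qual = o$qual[o$strand == "+"]),
      rev = list(base = o$base[o$strand == "-"], qual = o$qual[o$strand == "-"])),
      class = "stranded_pileup")
  }
  out
}

# observation tables per site: list of data.table(base, qual, strand)
.pileup_observations <- function(reads, sites) {
  reads <- as.data.table(reads)
  reads <- reads[dup == FALSE]
  empty <- data.table(base = character(), qual = integer(), strand = character())
  out <- rep(list(empty), nrow(sites))
  if (!nrow(reads)) return(out)
  simple <- grepl("^[0-9]+M$", reads$cigar)
  span <- integer(nrow(reads))
  span[simple] <- as.integer(sub("M$", "", reads$cigar[simple]))
  span[!simple] <- .cigar_ref_span(reads$cigar[!simple])
  for (ctg in unique(sites$contig)) {
    si <- which(sites$contig == ctg)
    ri <- which(reads$contig == ctg)
    if (!length(ri)) next
    o <- IRanges::findOverlaps(
      IRanges::IRanges(reads$start[ri] + 1L, reads$start[ri] + span[ri]),
      IRanges::IRanges(sites$pos[si] + 1L, sites$pos[si] + 1L))
    if (!length(o)) next
    rr <- ri[S4Vectors_from(o)]
    ss <- si[S4Vectors_to(o)]
    for (u in seq_along(rr)) {
      k <- rr[u]
      site <- sites$pos[ss[u]]
      if (simple[k]) {
        off <- site - reads$start[k] + 1L
      } else {
        blocks <- .cigar_blocks(reads$cigar[k], reads$start[k])
        hit <- blocks[rstart <= site & site < rend]
        if (!nrow(hit)) next  # deleted at this site
        off <- hit$qstart[1] + (site - hit$rstart[1])
      }
      b <- substr(reads$seq[k], off, off)
      q <- utf8ToInt(substr(reads$qual[k], off, off)) - 33L
      out[[ss[u]]] <- rbind(out[[ss[u]]],
                            data.table(base = b, qual = q,
                                       strand = reads$strand[k]))
    }
  }
  out
}

#' Binned coverage track for one sample
#'
#' `kind = "base"` counts aligned read bases per bin, reported as mean depth
#' (`bases / bin_size`). `kind = "fragment"` counts mate-pair outer spans
#' (clonal coverage) overlapping each bin; pairs without a same-contig mate
#' contribute to base coverage only.
#'
#' @param reads an `aln_reads` table; duplicates are excluded.
#' @param genome_spec named contig lengths used to tile bins.
#' @param kind `"fragment"` or `"base"`.
#' @param bin_size bin width in bp, default 100.
#' @return `data.table` with columns `contig`, `start`, `depth`; attributes
#'   `bin_size` and `kind`.
#' @export
binned_coverage <- function(reads, genome_spec, kind = c("fragment", "base"),
                            bin_size = 100L) {
  kind <- match.arg(kind)
  if (bin_size <= 0) stop("bin size must be positive")
  reads <- as.data.table(reads)[dup == FALSE]
  out <- lapply(names(genome_spec), function(ctg) {
    len <- genome_spec[[ctg]]
    nb <- as.integer(ceiling(len / bin_size))
    bins <- IRanges::IRanges(start = (seq_len(nb) - 1L) * bin_size + 1L,
                             width = bin_size)
    r <- reads[contig == ctg]
    depth <- numeric(nb)
    if (nrow(r)) {
      if (kind == "base") {
        simple <- grepl("^[0-9]+M$", r$cigar)
        rng <- IRanges::IRanges(r$start[simple] + 1L,
                                width = as.integer(sub("M$", "", r$cigar[simple])))
        if (any(!simple)) {
          blk <- rbindlist(lapply(which(!simple), function(k)
            .cigar_blocks(r$cigar[k], r$start[k])))
          rng <- c(rng, IRanges::IRanges(blk$rstart + 1L, blk$rend))
        }
        cov <- IRanges::coverage(rng, width = nb * bin_size)
        depth <- IRanges::viewSums(IRanges::Views(cov, bins)) / bin_size
      } else {
        fr <- r[isize > 0 & mate_contig == contig]
        if (nrow(fr)) {
          rng <- IRanges::IRanges(fr$start + 1L, width = fr$isize)
          depth <- IRanges::countOverlaps(bins, rng)
        }
      }
    }
    data.table(contig = ctg, start = (seq_len(nb) - 1L) * bin_size,
               depth = as.numeric(depth))
  })
  out <- rbindlist(out)
  setattr(out, "bin_size", as.integer(bin_size))
  setattr(out, "kind", kind)
  out[]
}

#' Pair two single-sample coverage tracks into a tumor/germline track
#'
#' @param germline,tumor outputs of [binned_coverage()] on the two samples,
#'   built with identical binning.
#' @return A `coverage_track` with columns `contig`, `start`, `germline`,
#'   `tumor`.
#' @export
pair_coverage_tracks <- function(germline, tumor) {
  stopifnot(identical(attr(germline, "bin_size"), attr(tumor, "bin_size")))
  g <- as.data.table(germline)[, .(contig, start, germline = depth)]
  t <- as.data.table(tumor)[, .(contig, start, tumor = depth)]
  out <- merge(g, t, by = c("contig", "start"), all = TRUE)
  for (col in c("germline", "tumor"))
    out[is.na(get(col)), (col) := 0]
  setorder(out, contig, start)
  setattr(out, "bin_size", attr(germline, "bin_size"))
  setattr(out, "kind", attr(germline, "kind"))
  setattr(out, "class", c("coverage_track", class(out)))
  out[]
}

# ---- fast mismatch scanning (internal, feeds the SNV callers) --------------

# mismatching aligned bases of simple-CIGAR reads plus a per-read walk for the
# rest: data.table(contig, site, strand, base, qual)
.read_mismatches <- function(reads, reference) {
  reads <- as.data.table(reads)[dup == FALSE]
  out <- list()
  simple <- grepl("^[0-9]+M$", reads$cigar)
  for (ctg in unique(reads$contig)) {
    refseq <- reference[[ctg]]
    i <- which(reads$contig == ctg & simple)
    if (length(i)) {
      rl <- nchar(reads$seq[i])
      refchunk <- substring(refseq, reads$start[i] + 1L, reads$start[i] + rl)
      differs <- which(refchunk != reads$seq[i])
      if (length(differs)) {
        ii <- i[differs]
        w <- max(nchar(reads$seq[ii]))
        for (off in seq_len(w)) {
          rb <- substr(refchunk[differs], off, off)
          sb <- substr(reads$seq[ii], off, off)
          mm <- which(rb != sb & sb != "" & rb != "")
          if (length(mm)) {
            k <- ii[mm]
            qchars <- substr(reads$qual[k], off, off)
            out[[length(out) + 1L]] <- data.table(
              contig = ctg, site = reads$start[k] + off - 1L,
              strand = reads$strand[k], base = sb[mm],
              qual = utf8ToInt(paste(qchars, collapse = "")) - 33L)
          }
        }
      }
    }
    for (k in which(reads$contig == ctg & !simple)) {
      blocks <- .cigar_blocks(reads$cigar[k], reads$start[k])
      for (b in seq_len(nrow(blocks))) {
        len <- blocks$rend[b] - blocks$rstart[b]
        rb <- substring(refseq, blocks$rstart[b] + 1L, blocks$rend[b])
        sb <- substr(reads$seq[k], blocks$qstart[b], blocks$qstart[b] + len - 1L)
        if (rb == sb) next
        rbv <- strsplit(rb, "")[[1]]; sbv <- strsplit(sb, "")[[1]]
        mm <- which(rbv != sbv)
        if (length(mm)) {
          qpos <- blocks$qstart[b] + mm - 1L
          qchars <- vapply(qpos, function(p) substr(reads$qual[k], p, p),
                           character(1))
          out[[length(out) + 1L]] <- data.table(
            contig = ctg, site = blocks$rstart[b] + mm - 1L,
            strand = reads$strand[k], base = sbv[mm],
            qual = utf8ToInt(paste(qchars, collapse = "")) - 33L)
        }
      }
    }
  }
  if (!length(out)) return(data.table(contig = character(), site = integer(),
                                      strand = character(), base = character(),
                                      qual = integer()))
  rbindlist(out)
}

# per-strand aligned depth at sites: data.table(contig, site, n_fwd, n_rev)
.strand_depth_at <- function(reads, sites) {
  reads <- as.data.table(reads)[dup == FALSE]
  sites <- as.data.table(sites)
  span <- .cigar_ref_span(reads$cigar)
  out <- sites[, .(contig, site = pos)]
  out[, `:=`(n_fwd = 0L, n_rev = 0L)]
  for (ctg in unique(sites$contig)) {
    si <- which(out$contig == ctg)
    for (st in c("+", "-")) {
      ri <- which(reads$contig == ctg & reads$strand == st)
      if (!length(ri)) next
      cov <- IRanges::coverage(IRanges::IRanges(reads$start[ri] + 1L,
                                                reads$start[ri] + span[ri]))
      pos1 <- out$site[si] + 1L
      v <- integer(length(pos1))
      inb <- pos1 <= length(cov)
      v[inb] <- as.integer(cov[pos1[inb]])
      if (st == "+") out$n_fwd[si] <- v else out$n_rev[si] <- v
    }
  }
  out
}
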