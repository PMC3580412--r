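# Independent oracles and small constructors, written before the
# implementations they check and kept deliberately naive.

# brute-force KS-like distance: explicit per-category weighted mass loops
oracle_ks <- function(observed, expected, ref, alt) {
  categorize <- function(b) if (b == ref) 1L else if (b == alt) 2L else 3L
  mass <- function(p) {
    w <- 1 - 10^(-p$qual / 10)
    m <- c(0, 0, 0)
    for (i in seq_along(p$base)) {
      k <- categorize(p$base[i])
      m[k] <- m[k] + w[i]
    }
    m / sum(w)
  }
  mo <- mass(observed); me <- mass(expected)
  best <- 0
  co <- 0; ce <- 0
  for (k in 1:3) {
    co <- co + mo[k]; ce <- ce + me[k]
    best <- max(best, abs(co - ce))
  }
  best
}

# brute-force pileup depth: scan every read and walk its CIGAR
oracle_pileup_depth <- function(reads, contig, pos, strand = NULL) {
  n <- 0L
  for (i in seq_len(nrow(reads))) {
    if (reads$dup[i] || reads$contig[i] != contig) next
    if (!is.null(strand) && reads$strand[i] != strand) next
    p <- reads$start[i]
    ops <- regmatches(reads$cigar[i], gregexpr("[0-9]+[MIDNS]", reads$cigar[i]))[[1]]
    covered <- FALSE
    for (o in ops) {
      len <- as.integer(sub("[MIDNS]$", "", o))
      type <- sub("^[0-9]+", "", o)
      if (type == "M") {
        if (pos >= p && pos < p + len) covered <- TRUE
        p <- p + len
      } else if (type %in% c("D", "N")) p <- p + len
    }
    if (covered) n <- n + 1L
  }
  n
}

# brute-force duplicate marking: enumerate placement groups, keep max quality
oracle_duplicates <- function(reads) {
  key <- paste(reads$contig, reads$start, reads$strand,
               reads$mate_contig, reads$mate_start)
  tq <- vapply(reads$qual, function(q) sum(utf8ToInt(q) - 33L), numeric(1))
  dup <- logical(nrow(reads))
  for (k in unique(key)) {
    idx <- which(key == k)
    keep <- idx[which.max(tq[idx])]
    dup[setdiff(idx, keep)] <- TRUE
  }
  dup
}

# hand-rolled read-record constructor for unit tests
mk_read <- function(contig = "chr1", start = 0L, strand = "+", cigar = "50M",
                    seq = strrep("A", 50L), qual = strrep("?", nchar(seq)),
                    mate_contig = contig, mate_start = start + 1450L,
                    isize = 1500L, qname = "r1", dup = FALSE) {
  data.table::data.table(qname = qname, contig = contig,
                         start = as.integer(start), strand = strand,
                         cigar = cigar, seq = seq, qual = qual,
                         mate_contig = mate_contig,
                         mate_start = as.integer(mate_start),
                         isize = as.integer(isize), dup = dup)
}

mk_pileup <- function(fwd_base, fwd_qual, rev_base, rev_qual,
                      contig = "chr1", site = 100L) {
  structure(list(contig = contig, site = site,
                 fwd = list(base = fwd_base, qual = fwd_qual),
                 rev = list(base = rev_base, qual = rev_qual)),
            class = "stranded_pileup")
}

# small paired simulation used by several suites
small_pair_sim <- function(seed, genome = c(chr1 = 100000L), snv = 0L,
                           snp_rate = 1e-4, purity = 0.6, ...) {
  cfg <- sim_config(genome, seed = seed, germline_snp_rate = snp_rate,
                    somatic_snv_count = snv, purity = purity, ...)
  ref <- generate_reference(cfg)
  g <- plant_variants(ref, cfg)
  list(cfg = cfg, ref = ref, genome = g,
       tumor = simulate_mate_pairs(g, "tumor"),
       germline = simulate_mate_pairs(g, "germline"))
}
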