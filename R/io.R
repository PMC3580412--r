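#' Write alignment records as a SAM text file
#'
#' Emits a coordinate-sorted SAM file (header with `@SQ` lines from
#' `genome_spec`) from the package's alignment-record table. Both mates of a
#' pair carry the same-direction orientation flags of this library chemistry;
#' duplicates are written with the 0x400 flag set.
#'
#' @param reads an `aln_reads` table.
#' @param genome_spec named contig lengths for the header.
#' @param path output path (`.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, genome_spec, path) {
  reads <- as.data.table(reads)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome_spec),
                   as.integer(genome_spec)))
  flag <- 1L +
    fifelse(reads$strand == "-", 16L, 0L) +
    fifelse(reads$strand == "-", 32L, 0L) +  # mate same direction
    fifelse(reads$isize >= 0, 64L, 128L) +
    fifelse(reads$dup, 1024L, 0L)
  rnext <- fifelse(reads$mate_contig == reads$contig, "=", reads$mate_contig)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  reads$qname, flag, reads$contig, reads$start + 1L, 60L,
                  reads$cigar, rnext, reads$mate_start + 1L, reads$isize,
                  reads$seq, reads$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignments from SAM/BAM into the package's record table
#'
#' Uses Rsamtools (`asBam` for SAM text, then `scanBam`); the result is the
#' same `aln_reads` table layout the simulator produces, with the duplicate
#' flag taken from the 0x400 bit.
#'
#' @param path SAM or BAM file.
#' @return An `aln_reads` `data.table`.
#' @export
read_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading SAM/BAM requires the Rsamtools package")
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else bam <- path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "cigar", "seq",
             "qual", "mrnm", "mpos", "isize"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  out <- data.table(
    qname = b$qname, contig = as.character(b$rname), start = b$pos - 1L,
    strand = as.character(b$strand), cigar = b$cigar,
    seq = as.character(b$seq), qual = as.character(b$qual),
    mate_contig = as.character(b$mrnm), mate_start = b$mpos - 1L,
    isize = b$isize, dup = bitwAnd(b$flag, 1024L) > 0L)
  setorder(out, contig, start, qname)
  setattr(out, "class", c("aln_reads", class(out)))
  out[]
}

#' Write a truth set as TSV files
#'
#' One file per event class (`germline_snps`, `somatic_snvs`,
#' `somatic_indels`, `cnv_segments`, `fusions`) under a common prefix.
#'
#' @param truth a `truth_set` from [plant_variants()].
#' @param prefix path prefix; files are `<prefix>.<class>.tsv`.
#' @return Character vector of paths, invisibly.
#' @export
write_truth_tsv <- function(truth, prefix) {
  stopifnot(inherits(truth, "truth_set"))
  paths <- character(0)
  for (nm in names(truth)) {
    p <- paste0(prefix, ".", nm, ".tsv")
    write.table(truth[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write germline genotype calls as VCF
#'
#' Minimal VCF 4.2 with per-strand genotype and distance information in
#' INFO; coordinates are 1-based.
#'
#' @param calls [genotype_sites()] output.
#' @param genome_spec named contig lengths for the header.
#' @param path output path.
#' @param sample_name sample column name.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(calls, genome_spec, path,
                               sample_name = "SAMPLE") {
  calls <- as.data.table(calls)
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(genome_spec),
                   as.integer(genome_spec)),
           "##INFO=<ID=SGF,Number=1,Type=String,Description=\"Forward-strand genotype\">",
           "##INFO=<ID=SGR,Number=1,Type=String,Description=\"Reverse-strand genotype\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_name))
  keep <- !is.na(calls$consensus)
  z <- calls[keep]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tSGF=%s;SGR=%s\tGT\t%s",
                  z$contig, z$site + 1L, z$ref,
                  fifelse(is.na(z$alt), ".", z$alt),
                  fifelse(z$variant, "PASS", "."),
                  z$geno_fwd, z$geno_rev,
                  gt_code[z$consensus])
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write somatic SNV calls as VCF
#'
#' FILTER carries the call ledger (`PASS` for consensus calls, otherwise the
#' walker filter status); INFO records the strand statistics and provenance.
#'
#' @param calls consensus (`final`) table from [call_somatic_snvs()].
#' @param genome_spec named contig lengths.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_somatic_vcf <- function(calls, genome_spec, path) {
  calls <- as.data.table(calls)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(genome_spec),
                   as.integer(genome_spec)),
           "##INFO=<ID=ZF,Number=1,Type=Float,Description=\"Forward-strand proportion statistic\">",
           "##INFO=<ID=ZR,Number=1,Type=Float,Description=\"Reverse-strand proportion statistic\">",
           "##INFO=<ID=SET,Number=1,Type=String,Description=\"Parameter set provenance\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tZF=%.3f;ZR=%.3f;SET=%s",
                  calls$contig, calls$site + 1L, calls$ref, calls$alt,
                  calls$stat_fwd, calls$stat_rev, calls$provenance)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write indel candidates as VCF (anchor-base convention)
#'
#' Deletions are written at the base before the deleted run
#' (`REF = anchor + deleted`, `ALT = anchor`); insertions as
#' (`REF = anchor`, `ALT = anchor + inserted`). 1-based coordinates.
#'
#' @param candidates [call_somatic_indels()] output.
#' @param reference named character contig sequences (for anchor bases).
#' @param genome_spec named contig lengths.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_indel_vcf <- function(candidates, reference, genome_spec, path) {
  cand <- as.data.table(candidates)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(genome_spec),
                   as.integer(genome_spec)),
           "##INFO=<ID=SUP,Number=1,Type=Integer,Description=\"Supporting reads\">",
           "##INFO=<ID=STATUS,Number=1,Type=String,Description=\"Somatic status\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    anchor_pos <- cand$start[i]  # 0-based base before the event is start-1+1
    anchor <- substr(reference[[cand$contig[i]]], anchor_pos, anchor_pos)
    if (cand$type[i] == "del") {
      deleted <- substr(reference[[cand$contig[i]]], cand$start[i] + 1L,
                        cand$end[i])
      ref <- paste0(anchor, deleted); alt <- anchor
    } else {
      ref <- anchor; alt <- paste0(anchor, cand$sequence[i])
    }
    body[i] <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\tSUP=%d;STATUS=%s",
                       cand$contig[i], cand$start[i], ref, alt,
                       if (identical(cand$status[i], "somatic")) "PASS"
                       else "germline_window", cand$support[i],
                       cand$status[i] %||% ".")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a windowed-difference track as bedGraph
#'
#' @param windows [windowed_difference()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(windows, path) {
  w <- as.data.table(windows)[!is.na(value)]
  window_bp <- attr(windows, "window_bp") %||% 2000L
  writeLines(c("track type=bedGraph",
               sprintf("%s\t%d\t%d\t%.4f", w$contig, w$start,
                       w$start + window_bp, w$value)), path)
  invisible(path)
}

#' Write copy-number segments as BED (state and mean in extra columns)
#'
#' @param segments [flag_and_segment()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  s <- as.data.table(segments)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%.4f", s$contig, s$start, s$end,
                     s$state, s$mean), path)
  invisible(path)
}

#' Read a BED file of exon intervals
#'
#' @param path BED path (first three columns used; 0-based half-open).
#' @return `data.table(contig, start, end)`.
#' @export
read_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  data.table(contig = x[[1]], start = as.integer(x[[2]]),
             end = as.integer(x[[3]]))
}
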