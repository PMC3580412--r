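#' Windowed discordant-read scan
#'
#' Walks each contig in non-overlapping windows of `step` bp (default: the
#' library insert size) and counts, per window, the aligned reads, the
#' discordant reads (mate on a different contig), the highest-hit partner
#' contig (the contig receiving most of the discordant mates; ties broken by
#' contig name order), its hit count, and the hit proportion
#' `hits / total aligned`.
#'
#' @param reads coordinate-sorted non-duplicate `aln_reads`.
#' @param genome_spec named contig lengths.
#' @param step window/step size in bp (default 1500).
#' @return `data.table(contig, start, total, discordant, partner, hits,
#'   prop)`; attribute `step`.
#' @export
scan_windows <- function(reads, genome_spec, step = 1500L) {
  if (step <= 0) stop("step must be positive")
  reads <- as.data.table(reads)[dup == FALSE]
  out <- lapply(names(genome_spec), function(ctg) {
    nw <- as.integer(ceiling(genome_spec[[ctg]] / step))
    r <- reads[contig == ctg]
    win <- data.table(contig = ctg, start = (seq_len(nw) - 1L) * step,
                      total = 0L, discordant = 0L,
                      partner = NA_character_, hits = 0L, prop = 0)
    if (!nrow(r)) return(win)
    w <- pmin(r$start %/% step + 1L, nw)
    tot <- tabulate(w, nw)
    disc <- r$mate_contig != ctg & !is.na(r$mate_contig)
    win$total <- tot
    if (any(disc)) {
      dd <- data.table(w = w[disc], partner = r$mate_contig[disc])
      dcount <- dd[, .N, by = w]
      win$discordant[dcount$w] <- dcount$N
      hh <- dd[, .(hits = .N), by = .(w, partner)]
      setorder(hh, w, -hits, partner)
      hh <- hh[!duplicated(w)]
      win$partner[hh$w] <- hh$partner
      win$hits[hh$w] <- hh$hits
    }
    win[, prop := fifelse(total > 0, hits / total, 0)]
    win
  })
  out <- rbindlist(out)
  setattr(out, "step", as.integer(step))
  out[]
}

#' Chromosome-wise outlier cutoff on hit proportions
#'
#' Under the working assumption that hit-discordant proportions aggregated
#' across a chromosome's windows are approximately normal, the cutoff is
#' `mean + 3 * SD`; windows strictly above it are translocation candidates.
#' On a zero-variance chromosome the cutoff degenerates to the mean and only
#' windows above the mean can be candidates. Requires at least `min_windows`
#' windows.
#'
#' @param windows one chromosome's rows of [scan_windows()] output.
#' @param n_sd multiple of the SD (default 3).
#' @param min_windows minimum windows required (default 30).
#' @return The cutoff value.
#' @export
outlier_cutoff <- function(windows, n_sd = 3, min_windows = 30L) {
  p <- windows$prop
  if (length(p) < min_windows)
    stop("need at least ", min_windows, " windows for the outlier cutoff")
  s <- sd(p)
  if (!is.finite(s)) s <- 0
  mean(p) + n_sd * s
}

#' Merge candidate windows into translocation calls
#'
#' For each candidate window, the hit reads (discordant reads whose mates map
#' to the window's highest-hit contig) define region A as their span and
#' region B as the span of their mates on the partner contig. Mates scattered
#' more than `cluster_gap` apart on the partner are split into separate
#' clusters (and a cluster spanning more than `max_span` is discarded as
#' scatter); clusters with fewer than `min_pairs` supporting pairs are
#' dropped. Adjacent candidate windows with the same partner contig and
#' overlapping (or near-adjacent) partner clusters are merged into one call.
#'
#' @param windows [scan_windows()] output for one sample.
#' @param reads the same sample's non-duplicate reads.
#' @param cutoffs named numeric vector of per-contig cutoffs from
#'   [outlier_cutoff()].
#' @param min_pairs minimum supporting read pairs (default 5).
#' @param max_span maximum partner-region span (default 1e6).
#' @param cluster_gap partner-position gap starting a new cluster; default
#'   twice the scan step.
#' @param read_len read length used to close region ends (default 50).
#' @return `data.table(contig_a, start_a, end_a, contig_b, start_b, end_b,
#'   n_pairs)`, one row per call.
#' @export
call_regions <- function(windows, reads, cutoffs, min_pairs = 5L,
                         max_span = 1e6, cluster_gap = NULL, read_len = 50L) {
  step <- attr(windows, "step") %||% 1500L
  if (is.null(cluster_gap)) cluster_gap <- 2L * step
  reads <- as.data.table(reads)[dup == FALSE]
  win <- as.data.table(windows)
  win[, keep := prop > cutoffs[contig] & hits >= min_pairs & !is.na(partner)]
  cand <- win[keep == TRUE]
  calls <- list()
  for (i in seq_len(nrow(cand))) {
    ctg <- cand$contig[i]; w0 <- cand$start[i]; pb <- cand$partner[i]
    hr <- reads[contig == ctg & start >= w0 & start < w0 + step &
                  mate_contig == pb]
    if (!nrow(hr)) next
    setorder(hr, mate_start)
    brk <- c(0L, which(diff(hr$mate_start) > cluster_gap), nrow(hr))
    for (j in seq_len(length(brk) - 1L)) {
      cl <- hr[(brk[j] + 1L):brk[j + 1L]]
      if (nrow(cl) < min_pairs) next
      span_b <- max(cl$mate_start) - min(cl$mate_start) + read_len
      if (span_b > max_span) next
      calls[[length(calls) + 1L]] <- data.table(
        contig_a = ctg, start_a = min(cl$start), end_a = max(cl$start) + read_len,
        contig_b = pb, start_b = min(cl$mate_start),
        end_b = max(cl$mate_start) + read_len, n_pairs = nrow(cl))
    }
  }
  empty <- data.table(contig_a = character(), start_a = integer(),
                      end_a = integer(), contig_b = character(),
                      start_b = integer(), end_b = integer(),
                      n_pairs = integer())
  if (!length(calls)) return(empty)
  calls <- rbindlist(calls)
  .merge_adjacent_calls(calls, gap = cluster_gap)
}

# merge calls with same contig pair whose A and B regions are within `gap`
.merge_adjacent_calls <- function(calls, gap) {
  setorder(calls, contig_a, contig_b, start_a, start_b)
  merged <- list()
  cur <- NULL
  for (i in seq_len(nrow(calls))) {
    row <- calls[i]
    if (!is.null(cur) && cur$contig_a == row$contig_a &&
        cur$contig_b == row$contig_b &&
        row$start_a <= cur$end_a + gap &&
        row$start_b <= cur$end_b + gap && row$end_b >= cur$start_b - gap) {
      cur$end_a <- max(cur$end_a, row$end_a)
      cur$end_b <- max(cur$end_b, row$end_b)
      cur$start_b <- min(cur$start_b, row$start_b)
      cur$n_pairs <- cur$n_pairs + row$n_pairs
    } else {
      if (!is.null(cur)) merged[[length(merged) + 1L]] <- cur
      cur <- row
    }
  }
  if (!is.null(cur)) merged[[length(merged) + 1L]] <- cur
  rbindlist(merged)
}

#' Subtract germline translocation calls from tumor calls
#'
#' A tumor call is somatic only if no germline call with the same
#' (unordered) contig pair overlaps it on both corresponding regions by at
#' least one bp.
#'
#' @param tumor_calls,germline_calls [call_regions()] outputs produced with
#'   identical parameters.
#' @return The somatic subset of `tumor_calls`.
#' @export
somatic_subtract <- function(tumor_calls, germline_calls) {
  t <- .canonical_pairs(as.data.table(tumor_calls))
  g <- .canonical_pairs(as.data.table(germline_calls))
  if (!nrow(t)) return(t)
  somatic <- rep(TRUE, nrow(t))
  for (i in seq_len(nrow(t))) {
    for (j in seq_len(nrow(g))) {
      if (t$contig_a[i] != g$contig_a[j] || t$contig_b[i] != g$contig_b[j]) next
      ov_a <- t$start_a[i] < g$end_a[j] && g$start_a[j] < t$end_a[i]
      ov_b <- t$start_b[i] < g$end_b[j] && g$start_b[j] < t$end_b[i]
      if (ov_a || ov_b) { somatic[i] <- FALSE; break }
    }
  }
  t[somatic]
}

# an event is seen from both partner chromosomes; canonicalize region order
# and collapse calls of one contig pair whose regions overlap (within `gap`)
.dedupe_reciprocal <- function(calls, gap = 0L) {
  if (!nrow(calls)) return(calls)
  calls <- .canonical_pairs(calls)
  setorder(calls, contig_a, contig_b, start_a, start_b)
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(calls))) {
    row <- calls[i]
    if (!is.null(cur) && cur$contig_a == row$contig_a &&
        cur$contig_b == row$contig_b &&
        row$start_a <= cur$end_a + gap && row$end_a >= cur$start_a - gap &&
        row$start_b <= cur$end_b + gap && row$end_b >= cur$start_b - gap) {
      cur$start_a <- min(cur$start_a, row$start_a)
      cur$end_a <- max(cur$end_a, row$end_a)
      cur$start_b <- min(cur$start_b, row$start_b)
      cur$end_b <- max(cur$end_b, row$end_b)
      cur$n_pairs <- max(cur$n_pairs, row$n_pairs)  # same fragments, two views
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- row
    }
  }
  out[[length(out) + 1L]] <- cur
  rbindlist(out)
}

# order each call's two regions by contig name so pairs compare consistently
.canonical_pairs <- function(calls) {
  if (!nrow(calls)) return(calls)
  swap <- calls$contig_a > calls$contig_b
  if (any(swap)) {
    tmp <- calls[swap, .(contig_a = contig_b, start_a = start_b, end_a = end_b,
                         contig_b = contig_a, start_b = start_a, end_b = end_a)]
    calls[swap, c("contig_a", "start_a", "end_a",
                  "contig_b", "start_b", "end_b") :=
            tmp[, .(contig_a, start_a, end_a, contig_b, start_b, end_b)]]
  }
  calls
}

#' Full translocation calling on a tumor/germline pair
#'
#' Scans both samples with the same walker settings, computes per-chromosome
#' outlier cutoffs, forms calls in each sample and eliminates tumor calls
#' overlapping germline calls.
#'
#' @param tumor_reads,germline_reads `aln_reads` tables.
#' @param genome_spec named contig lengths.
#' @param step walker step (default 1500, the insert size).
#' @param min_pairs,max_span see [call_regions()].
#' @return List with `somatic`, `tumor_calls`, `germline_calls`,
#'   `tumor_windows`, `germline_windows`, `cutoffs` (tumor-sample cutoffs).
#' @export
call_translocations <- function(tumor_reads, germline_reads, genome_spec,
                                step = 1500L, min_pairs = 5L, max_span = 1e6) {
  one <- function(reads) {
    w <- scan_windows(reads, genome_spec, step)
    cutoffs <- vapply(split(w, by = "contig", sorted = TRUE),
                      function(z) outlier_cutoff(z), numeric(1))
    calls <- call_regions(w, reads, cutoffs, min_pairs = min_pairs,
                          max_span = max_span)
    calls <- .dedupe_reciprocal(calls, gap = step)
    list(windows = w, cutoffs = cutoffs, calls = calls)
  }
  t <- one(tumor_reads)
  g <- one(germline_reads)
  list(somatic = somatic_subtract(t$calls, g$calls),
       tumor_calls = t$calls, germline_calls = g$calls,
       tumor_windows = t$windows, germline_windows = g$windows,
       cutoffs = t$cutoffs)
}

#' Write translocation calls as a paired-line GFF3 file
#'
#' Two feature lines per call share an event identifier in the source column
#' (and `ID`/`Partner` attributes), so each pair of lines names the two
#' genomic regions of one putative translocation. Coordinates are written
#' 1-based inclusive.
#'
#' @param calls [call_regions()] / [somatic_subtract()] output; an optional
#'   `somatic` logical column is carried into the attributes.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_paired_gff <- function(calls, path) {
  calls <- as.data.table(calls)
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(calls))) {
    ev <- sprintf("TL%05d", i)
    som <- if (!is.null(calls$somatic)) paste0(";somatic=",
                                               tolower(calls$somatic[i])) else ""
    np <- calls$n_pairs[i]
    lines <- c(lines,
      sprintf("%s\t%s\ttranslocation_region\t%d\t%d\t%d\t.\t.\tID=%s.A;Partner=%s.B%s",
              calls$contig_a[i], ev, calls$start_a[i] + 1L, calls$end_a[i],
              np, ev, ev, som),
      sprintf("%s\t%s\ttranslocation_region\t%d\t%d\t%d\t.\t.\tID=%s.B;Partner=%s.A%s",
              calls$contig_b[i], ev, calls$start_b[i] + 1L, calls$end_b[i],
              np, ev, ev, som))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a paired-line GFF3 file back into a call table
#'
#' Inverse of [write_paired_gff()]; used for round-trip checks and for
#' consuming the files downstream.
#'
#' @param path GFF3 file written by [write_paired_gff()].
#' @return `data.table(contig_a, start_a, end_a, contig_b, start_b, end_b,
#'   n_pairs)`.
#' @export
read_paired_gff <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  empty <- data.table(contig_a = character(), start_a = integer(),
                      end_a = integer(), contig_b = character(),
                      start_b = integer(), end_b = integer(),
                      n_pairs = integer())
  if (!length(ln)) return(empty)
  f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  dt <- data.table(contig = f[, 1], source = f[, 2],
                   start = as.integer(f[, 4]) - 1L, end = as.integer(f[, 5]),
                   n_pairs = as.integer(f[, 6]), attrs = f[, 9])
  dt[, region := sub("^ID=[^.]+\\.([AB]).*$", "\\1", attrs)]
  a <- dt[region == "A"]; b <- dt[region == "B"]
  m <- merge(a[, .(source, contig_a = contig, start_a = start, end_a = end,
                   n_pairs)],
             b[, .(source, contig_b = contig, start_b = start, end_b = end)],
             by = "source")
  m <- m[, .(contig_a, start_a, end_a, contig_b, start_b, end_b, n_pairs)]
  setorder(m, contig_a, start_a)
  m[]
}
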