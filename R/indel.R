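#' Filter reads by insert size
#'
#' Retains reads whose absolute insert size lies strictly inside
#' `(low, high)` — the open interval, so boundary values are removed. Applied
#' to the tumor alignments before candidate indel detection to discard pairs
#' whose spacing already signals a structural event. Idempotent.
#'
#' @param reads an `aln_reads` table with populated `isize`.
#' @param low,high interval bounds in bp (defaults 500 and 5000).
#' @return The retained reads; the number removed is attached as attribute
#'   `removed` and reported via `message()`.
#' @export
filter_by_insert <- function(reads, low = 500, high = 5000) {
  if (low >= high) stop("insert filter requires low < high")
  reads <- as.data.table(reads)
  keep <- abs(reads$isize) > low & abs(reads$isize) < high
  removed <- sum(!keep)
  message(removed, " reads removed by insert-size filter (", low, ",", high, ")")
  out <- reads[keep]
  setattr(out, "removed", removed)
  setattr(out, "class", unique(c("aln_reads", class(out))))
  out[]
}

#' Detect candidate small indels from tumor CIGARs
#'
#' Groups identical insertion/deletion CIGAR events by
#' `(contig, start, type, sequence)` and emits candidates supported by at
#' least `min_support` reads making up at least `min_fraction` of the reads
#' covering the locus. Coordinates are 0-based half-open; an insertion has
#' `start == end`. Malformed CIGARs skip the record with a warning.
#'
#' @param reads tumor `aln_reads` (insert-filtered upstream; duplicates
#'   excluded here).
#' @param min_support minimum supporting reads (default 3).
#' @param min_fraction minimum support / covering fraction (default 0.1).
#' @return `data.table` of class `indel_candidates`: `contig`, `start`,
#'   `end`, `type`, `sequence`, `support`, `covering`.
#' @export
detect_candidates <- function(reads, min_support = 3L, min_fraction = 0.1) {
  reads <- as.data.table(reads)[dup == FALSE]
  withindel <- which(grepl("[ID]", reads$cigar))
  ev <- list()
  for (k in withindel) {
    e <- tryCatch(.cigar_indel_events(reads$cigar[k], reads$start[k], reads$seq[k]),
                  error = function(cond) {
                    warning("skipping malformed CIGAR record: ", reads$cigar[k])
                    NULL
                  })
    if (!is.null(e)) {
      e[, contig := reads$contig[k]]
      ev[[length(ev) + 1L]] <- e
    }
  }
  empty <- data.table(contig = character(), start = integer(), end = integer(),
                      type = character(), sequence = character(),
                      support = integer(), covering = integer())
  if (!length(ev)) return(.as_indel_candidates(empty))
  ev <- rbindlist(ev)
  # deletions are identified by span, insertions by inserted sequence
  ev[, sequence := fifelse(type == "del", NA_character_, seq)]
  grp <- ev[, .(support = .N),
            by = .(contig, start = pos, type,
                   end = fifelse(type == "del", pos + len, pos), sequence)]
  if (!nrow(grp)) return(.as_indel_candidates(empty))
  cov <- .strand_depth_at(reads, grp[, .(contig, pos = pmax(start - 1L, 0L))])
  grp[, covering := cov$n_fwd + cov$n_rev]
  grp[, covering := pmax(covering, support)]
  out <- grp[support >= min_support & support / covering >= min_fraction,
             .(contig, start, end, type, sequence, support, covering)]
  setorder(out, contig, start)
  .as_indel_candidates(out)
}

.as_indel_candidates <- function(x) {
  setattr(x, "class", unique(c("indel_candidates", class(x))))
  x[]
}

#' Somatic check of an indel candidate against the germline window
#'
#' Examines the germline sample over the window from five bases upstream of
#' the candidate's start to five bases downstream of its end: the candidate
#' is somatic only when no germline read carries any insertion or deletion
#' CIGAR event overlapping that window. With germline coverage over the
#' window below `min_germline_depth` the status is `"undetermined"` (not
#' somatic).
#'
#' @param candidate one row of [detect_candidates()] output (or any list
#'   with `contig`, `start`, `end`).
#' @param germline_reads germline `aln_reads`.
#' @param window bp added on each side (default 5).
#' @param min_germline_depth minimum germline depth across the window
#'   (default 8).
#' @return `"somatic"`, `"germline"`, or `"undetermined"`.
#' @export
somatic_check <- function(candidate, germline_reads, window = 5L,
                          min_germline_depth = 8L) {
  g <- as.data.table(germline_reads)[dup == FALSE]
  lo <- candidate$start - window
  hi <- candidate$end + window
  gc <- g[contig == candidate$contig]
  # minimum aligned depth across the window
  span <- .cigar_ref_span(gc$cigar)
  if (nrow(gc)) {
    cov <- IRanges::coverage(IRanges::IRanges(gc$start + 1L, gc$start + span),
                             width = max(hi + 1L, gc$start + span))
    wpos <- max(lo, 0L):hi + 1L
    mind <- min(as.integer(cov[wpos]))
  } else mind <- 0L
  if (mind < min_germline_depth) return("undetermined")
  withindel <- gc[grepl("[ID]", cigar)]
  if (nrow(withindel)) {
    for (k in seq_len(nrow(withindel))) {
      e <- .cigar_indel_events(withindel$cigar[k], withindel$start[k],
                               withindel$seq[k])
      if (is.null(e)) next
      e_end <- e$pos + fifelse(e$type == "del", e$len, 0L)
      if (any(e$pos <= hi & e_end >= lo)) return("germline")
    }
  }
  "somatic"
}

#' Two-step somatic indel calling on a tumor/germline pair
#'
#' Step one filters the tumor reads to the insert interval and detects
#' candidate small indels from CIGAR events; step two checks each candidate's
#' +-`window` bp germline window and keeps only candidates with no germline
#' indel evidence there.
#'
#' @param tumor_reads,germline_reads `aln_reads` tables.
#' @param insert_low,insert_high insert-size filter bounds.
#' @param min_support,min_fraction candidate thresholds
#'   (see [detect_candidates()]).
#' @param window,min_germline_depth germline check settings
#'   (see [somatic_check()]).
#' @return The candidate table with a `status` column
#'   (`somatic` / `germline` / `undetermined`).
#' @export
call_somatic_indels <- function(tumor_reads, germline_reads,
                                insert_low = 500, insert_high = 5000,
                                min_support = 3L, min_fraction = 0.1,
                                window = 5L, min_germline_depth = 8L) {
  tu <- suppressMessages(filter_by_insert(tumor_reads, insert_low, insert_high))
  cand <- detect_candidates(tu, min_support, min_fraction)
  if (!nrow(cand)) {
    cand[, status := character(0)]
    return(cand[])
  }
  cand[, status := vapply(seq_len(.N), function(i)
    somatic_check(cand[i], germline_reads, window, min_germline_depth),
    character(1))]
  cand[]
}
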