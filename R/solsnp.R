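#' Expected genotype pileups for one strand
#'
#' Constructs, for an observed single-strand pileup, the expected pileups of
#' each genotype: same number of positions, same qualities, bases replaced.
#' `hom_ref` carries the reference base at every position and `hom_alt` the
#' alternative base; the diploid `het` pileup assigns the reference base to
#' the first `ceiling(n/2)` positions and the alternative to the rest (for
#' `n = 1` the het pileup is degenerate — all reference — and is flagged).
#'
#' @param observed list with `base` and `qual` vectors (one strand).
#' @param ref,alt reference and alternative base (must differ).
#' @param ploidy 1 or 2; a haploid genome has no het pileup.
#' @return Named list of expected pileups (`hom_ref`, `het` if diploid,
#'   `hom_alt`), each a list with `base`, `qual`, and for `het` a logical
#'   `degenerate`.
#' @export
expected_pileups <- function(observed, ref, alt, ploidy = 2L) {
  n <- length(observed$base)
  if (n < 1) stop("need at least one observation on the strand")
  if (identical(ref, alt)) stop("ref and alt must differ")
  q <- observed$qual
  out <- list(hom_ref = list(base = rep(ref, n), qual = q))
  if (ploidy == 2L) {
    nref <- ceiling(n / 2)
    out$het <- list(base = c(rep(ref, nref), rep(alt, n - nref)), qual = q,
                    degenerate = n == 1L)
  }
  out$hom_alt <- list(base = rep(alt, n), qual = q)
  out
}

#' Kolmogorov-Smirnov-like distance between two pileups
#'
#' Each observation is weighted by its base confidence
#' `w = 1 - 10^(-q/10)`; the weighted mass of each pileup is laid out over the
#' ordered category alphabet (reference < alternative < other) and the
#' distance is the maximum absolute difference of the two cumulative mass
#' curves. The statistic is symmetric, lies in `[0, 1]`, is zero iff the
#' weighted category masses agree, and degrades to the classical two-sample
#' KS statistic on the category marginal when all qualities are equal.
#'
#' @param observed,expected pileup strands (lists with `base`, `qual`) with
#'   equal position counts.
#' @param ref,alt bases defining the category alphabet; anything else is
#'   "other".
#' @return Distance in `[0, 1]`.
#' @export
ks_distance <- function(observed, expected, ref, alt) {
  if (length(observed$base) != length(expected$base))
    stop("observed and expected pileups must have equal position counts")
  mo <- .category_mass(observed, ref, alt)
  me <- .category_mass(expected, ref, alt)
  max(abs(cumsum(mo) - cumsum(me)))
}

.category_mass <- function(pileup, ref, alt) {
  w <- 1 - 10^(-pileup$qual / 10)
  tw <- sum(w)
  if (tw <= 0) stop("uninformative pileup: all base weights are zero")
  cat <- ifelse(pileup$base == ref, 1L, ifelse(pileup$base == alt, 2L, 3L))
  c(sum(w[cat == 1L]), sum(w[cat == 2L]), sum(w[cat == 3L])) / tw
}

#' Choose the alternative allele of a pileup
#'
#' The non-reference base with the greatest total quality weight across both
#' strands; ties broken lexicographically (alphabetically first base wins).
#' Returns `NA` when no non-reference base is observed (hom-ref shortcut).
#'
#' @param pileup a `stranded_pileup`.
#' @param ref reference base.
#' @return Single base or `NA_character_`.
#' @export
pick_alt <- function(pileup, ref) {
  base <- c(pileup$fwd$base, pileup$rev$base)
  qual <- c(pileup$fwd$qual, pileup$rev$qual)
  keep <- base != ref
  if (!any(keep)) return(NA_character_)
  w <- tapply((1 - 10^(-qual[keep] / 10)), base[keep], sum)
  names(w)[order(-w, names(w))][1]
}

#' Genotype one site from its stranded pileup
#'
#' Per strand, the genotype is the expected pileup at minimal KS distance
#' (ties resolved toward the less variant genotype, in the order hom_ref,
#' het, hom_alt). In `"consensus"` strand mode a consensus genotype exists
#' only when both strand genotypes are identical; in `"any"` mode the site is
#' variant whenever a variant genotype is detected on both strands, identical
#' or not. A strand below `min_strand_depth` yields a no-call with the reason
#' recorded.
#'
#' @param pileup a `stranded_pileup`.
#' @param ref reference base.
#' @param alt alternative base; defaults to [pick_alt()]. If no alternative
#'   exists the site is a hom_ref non-variant call.
#' @param ploidy 1 or 2.
#' @param strand_mode `"consensus"` or `"any"`.
#' @param min_strand_depth minimum observations per strand (default 4).
#' @return A `genotype_call` list: `contig`, `site`, `ref`, `alt`,
#'   `fwd`/`rev` (each genotype + named distance triple), `consensus`,
#'   `variant`, `no_call_reason`.
#' @export
call_site <- function(pileup, ref, alt = NULL, ploidy = 2L,
                      strand_mode = c("consensus", "any"),
                      min_strand_depth = 4L) {
  strand_mode <- match.arg(strand_mode)
  if (is.null(alt)) alt <- pick_alt(pileup, ref)
  base_call <- function(consensus, variant, reason = NA_character_,
                        fwd = NULL, rev = NULL) {
    structure(list(contig = pileup$contig, site = pileup$site, ref = ref,
                   alt = alt, fwd = fwd, rev = rev, consensus = consensus,
                   variant = variant, no_call_reason = reason),
              class = "genotype_call")
  }
  nf <- length(pileup$fwd$base); nr <- length(pileup$rev$base)
  if (nf < min_strand_depth || nr < min_strand_depth)
    return(base_call(NA_character_, FALSE, "strand below minimum depth"))
  if (is.na(alt))
    return(base_call("hom_ref", FALSE))
  strand_geno <- function(obs) {
    exp <- expected_pileups(obs, ref, alt, ploidy)
    d <- vapply(exp, function(e) ks_distance(obs, e, ref, alt), numeric(1))
    list(genotype = names(d)[which.min(d)], distances = d)
  }
  f <- strand_geno(pileup$fwd)
  r <- strand_geno(pileup$rev)
  variant_genos <- c("het", "hom_alt")
  if (strand_mode == "consensus") {
    if (!identical(f$genotype, r$genotype))
      return(base_call(NA_character_, FALSE, "strand genotypes disagree",
                       fwd = f, rev = r))
    cons <- f$genotype
    base_call(cons, cons %in% variant_genos, fwd = f, rev = r)
  } else {
    cons <- if (identical(f$genotype, r$genotype)) f$genotype else NA_character_
    base_call(cons, f$genotype %in% variant_genos &&
                r$genotype %in% variant_genos, fwd = f, rev = r)
  }
}

# ---- vectorized count path -------------------------------------------------
# With a single quality level the KS distance depends only on category counts:
#   dist(hom_ref) = 1 - r ; dist(het) = max(|r - h|, o) ; dist(hom_alt) = max(r, o)
# with r/a/o the category mass fractions and h = ceiling(n/2)/n the het
# reference mass. Agreement with ks_distance() is asserted in the test suite.

.ks_triple_counts <- function(n_ref, n_alt, n_other) {
  n <- n_ref + n_alt + n_other
  r <- n_ref / n; o <- n_other / n
  h <- ceiling(n / 2) / n
  data.table(hom_ref = 1 - r,
             het = pmax(abs(r - h), o),
             hom_alt = pmax(r, o))
}

# batch genotyping from per-strand category counts; returns genotype strings
# per strand plus consensus/variant under the given strand mode
.genotype_counts <- function(n_fwd, alt_fwd, oth_fwd, n_rev, alt_rev, oth_rev,
                             strand_mode = "consensus", min_strand_depth = 4L) {
  geno_one <- function(n, a, o) {
    ref <- n - a - o
    ok <- n > 0
    g <- rep(NA_character_, length(n))
    if (any(ok)) {
      d <- .ks_triple_counts(ref[ok], a[ok], o[ok])
      g[ok] <- c("hom_ref", "het", "hom_alt")[max.col(-as.matrix(d), "first")]
    }
    g
  }
  gf <- geno_one(n_fwd, alt_fwd, oth_fwd)
  gr <- geno_one(n_rev, alt_rev, oth_rev)
  low <- n_fwd < min_strand_depth | n_rev < min_strand_depth
  vg <- c("het", "hom_alt")
  if (strand_mode == "consensus") {
    cons <- fifelse(!low & gf == gr, gf, NA_character_)
    variant <- !is.na(cons) & cons %in% vg
  } else {
    cons <- fifelse(!low & gf == gr, gf, NA_character_)
    variant <- !low & gf %in% vg & gr %in% vg
  }
  list(fwd = gf, rev = gr, consensus = cons, variant = variant, low_depth = low)
}

#' Genotype sites genome-wide from alignments
#'
#' Batch wrapper around the stranded KS genotyper: scans reads for
#' mismatches, picks the top alternative per site, tallies per-strand
#' category counts and genotypes every requested site (or every site with a
#' non-reference observation when `sites` is `NULL`). Assumes the library's
#' single base-quality level, under which the KS distance depends only on
#' category counts.
#'
#' @param reads an `aln_reads` table.
#' @param reference named character vector of contig sequences.
#' @param sites optional `data.frame(contig, pos)` restricting the scan.
#' @param strand_mode,min_strand_depth,ploidy see [call_site()].
#' @return `data.table` with per-site ref/alt, per-strand depths and alt
#'   counts, per-strand genotypes, `consensus` and `variant`.
#' @export
genotype_sites <- function(reads, reference, sites = NULL,
                           strand_mode = c("consensus", "any"),
                           min_strand_depth = 4L, ploidy = 2L) {
  strand_mode <- match.arg(strand_mode)
  if (ploidy != 2L) stop("batch genotyping supports diploid mode; use call_site() for haploid")
  mm <- .read_mismatches(reads, reference)
  counts <- .site_category_counts(reads, mm, sites, reference)
  g <- .genotype_counts(counts$n_fwd, counts$alt_fwd, counts$oth_fwd,
                        counts$n_rev, counts$alt_rev, counts$oth_rev,
                        strand_mode, min_strand_depth)
  counts[, `:=`(geno_fwd = g$fwd, geno_rev = g$rev, consensus = g$consensus,
                variant = g$variant, low_depth = g$low_depth)]
  counts[]
}

# per-site per-strand category counts for the top alternative base
.site_category_counts <- function(reads, mm, sites, reference) {
  if (is.null(sites)) {
    sites <- unique(mm[, .(contig, pos = site)])
  } else sites <- unique(as.data.table(sites)[, .(contig, pos)])
  setorder(sites, contig, pos)
  depth <- .strand_depth_at(reads, sites)
  if (nrow(mm)) {
    agg <- mm[, .(k = .N), by = .(contig, site, base, strand)]
    tot <- agg[, .(tot = sum(k)), by = .(contig, site, base)]
    setorder(tot, contig, site, -tot, base)
    top <- tot[!duplicated(paste(contig, site))][, .(contig, site, alt = base)]
  } else top <- data.table(contig = character(), site = integer(), alt = character())
  out <- merge(depth, top, by = c("contig", "site"), all.x = TRUE)
  out[, ref := NA_character_]
  for (ctg in unique(out$contig)) {
    i <- which(out$contig == ctg)
    out$ref[i] <- substring(reference[[ctg]], out$site[i] + 1L, out$site[i] + 1L)
  }
  fill0 <- function(x) fifelse(is.na(x), 0L, x)
  if (nrow(mm)) {
    agg <- mm[, .(k = .N), by = .(contig, site, base, strand)]
    out <- merge(out, agg[strand == "+", .(contig, site, base, af = k)],
                 by.x = c("contig", "site", "alt"), by.y = c("contig", "site", "base"),
                 all.x = TRUE)
    out <- merge(out, agg[strand == "-", .(contig, site, base, ar = k)],
                 by.x = c("contig", "site", "alt"), by.y = c("contig", "site", "base"),
                 all.x = TRUE)
    allmm <- mm[, .(k = .N), by = .(contig, site, strand)]
    out <- merge(out, allmm[strand == "+", .(contig, site, mf = k)],
                 by = c("contig", "site"), all.x = TRUE)
    out <- merge(out, allmm[strand == "-", .(contig, site, mr = k)],
                 by = c("contig", "site"), all.x = TRUE)
    out[, `:=`(alt_fwd = fill0(af), alt_rev = fill0(ar),
               oth_fwd = fill0(mf) - fill0(af), oth_rev = fill0(mr) - fill0(ar))]
    out[, c("af", "ar", "mf", "mr") := NULL]
  } else out[, `:=`(alt_fwd = 0L, alt_rev = 0L, oth_fwd = 0L, oth_rev = 0L)]
  # mismatch counts can exceed the M-aligned strand depth only through
  # pathological inputs; clamp "other" at zero after the subtraction above
  out[, `:=`(oth_fwd = pmax(oth_fwd, 0L), oth_rev = pmax(oth_rev, 0L))]
  setorder(out, contig, site)
  out[]
}
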