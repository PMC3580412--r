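#' Somatic SNV caller parameter set
#'
#' The caller runs twice, once with a strict and once with a lenient
#' parameter set, and the two consensus call sets are combined downstream.
#' Defaults are calibrated to the study design (60% purity diluting a clonal
#' het to a 0.30 tumor alt fraction at 37x/40x coverage); the derivation is
#' in the methods vignette. Every threshold is configurable.
#'
#' @param stat_threshold minimum site statistic (min over strands of the
#'   pooled two-proportion z).
#' @param min_alt_per_strand minimum tumor alt reads on each strand.
#' @param min_alt_total minimum tumor alt reads across strands.
#' @param germline_max_alt maximum germline alt reads (both strands).
#' @param germline_max_frac maximum germline alt fraction.
#' @param min_depth_per_strand minimum tumor depth per strand.
#' @return A `caller_params` list.
#' @export
caller_params <- function(stat_threshold, min_alt_per_strand, min_alt_total,
                          germline_max_alt, germline_max_frac,
                          min_depth_per_strand) {
  structure(list(stat_threshold = stat_threshold,
                 min_alt_per_strand = as.integer(min_alt_per_strand),
                 min_alt_total = as.integer(min_alt_total),
                 germline_max_alt = as.integer(germline_max_alt),
                 germline_max_frac = germline_max_frac,
                 min_depth_per_strand = as.integer(min_depth_per_strand)),
            class = "caller_params")
}

#' @rdname caller_params
#' @export
strict_params <- function() caller_params(
  stat_threshold = 2.5, min_alt_per_strand = 3L, min_alt_total = 6L,
  germline_max_alt = 1L, germline_max_frac = 0.02, min_depth_per_strand = 8L)

#' @rdname caller_params
#' @export
lenient_params <- function() caller_params(
  stat_threshold = 1.0, min_alt_per_strand = 1L, min_alt_total = 3L,
  germline_max_alt = 2L, germline_max_frac = 0.05, min_depth_per_strand = 4L)

# strict must be at least as stringent as lenient in every component
.check_param_order <- function(strict, lenient) {
  ok <- strict$stat_threshold >= lenient$stat_threshold &&
    strict$min_alt_per_strand >= lenient$min_alt_per_strand &&
    strict$min_alt_total >= lenient$min_alt_total &&
    strict$germline_max_alt <= lenient$germline_max_alt &&
    strict$germline_max_frac <= lenient$germline_max_frac &&
    strict$min_depth_per_strand >= lenient$min_depth_per_strand
  if (!ok) stop("strict parameter set must be componentwise at least as stringent as lenient")
  invisible(TRUE)
}

#' Pooled two-proportion z statistic for one strand
#'
#' `z = (k_t/n_t - k_g/n_g) / sqrt(p*(1-p)*(1/n_t + 1/n_g))` with the pooled
#' `p = (k_t + k_g)/(n_t + n_g)`; defined as 0 when the pooled proportion is
#' 0 or 1 (no evidence either way). Vectorized.
#'
#' @param k_t,n_t tumor alt count and depth on the strand.
#' @param k_g,n_g germline alt count and depth on the strand.
#' @return The z statistic (same length as the inputs).
#' @export
strand_stat <- function(k_t, n_t, k_g, n_g) {
  if (any(n_t < 1) || any(n_g < 1)) stop("strand depths must be >= 1")
  if (any(k_t > n_t) || any(k_g > n_g)) stop("alt counts cannot exceed depths")
  p <- (k_t + k_g) / (n_t + n_g)
  se <- sqrt(p * (1 - p) * (1 / n_t + 1 / n_g))
  z <- (k_t / n_t - k_g / n_g) / se
  fifelse(p <= 0 | p >= 1, 0, z)
}

#' Call somatic SNVs from per-site stranded counts
#'
#' For each site the forward and reverse strands are tested separately with
#' [strand_stat()] and the minimum of the two is the site statistic, so
#' evidence is required in both read directions. Sites with germline alt
#' evidence beyond the parameter caps are filtered as `germline_evidence`
#' (guarding against under-sampled polymorphic germline sites); passing
#' additionally requires the site statistic at threshold, the tumor alt-read
#' minima, and the tumor depth minima.
#'
#' @param counts `data.table` with columns `contig`, `site`, `ref`, `alt`,
#'   tumor `t_n_fwd`, `t_n_rev`, `t_alt_fwd`, `t_alt_rev` and germline
#'   `g_n_fwd`, `g_n_rev`, `g_alt_fwd`, `g_alt_rev`.
#' @param params a [caller_params()].
#' @return The table with `stat_fwd`, `stat_rev`, `stat` (their minimum) and
#'   `filter` in `pass` / `germline_evidence` / `low_stat`.
#' @export
call_somatic <- function(counts, params) {
  stopifnot(inherits(params, "caller_params"))
  out <- as.data.table(counts)
  need <- c("t_n_fwd", "t_n_rev", "t_alt_fwd", "t_alt_rev",
            "g_n_fwd", "g_n_rev", "g_alt_fwd", "g_alt_rev")
  stopifnot(all(need %in% names(out)))
  usable <- out$t_n_fwd >= 1 & out$t_n_rev >= 1 & out$g_n_fwd >= 1 & out$g_n_rev >= 1
  out[, `:=`(stat_fwd = NA_real_, stat_rev = NA_real_, stat = NA_real_)]
  if (any(usable)) {
    out$stat_fwd[usable] <- strand_stat(out$t_alt_fwd[usable], out$t_n_fwd[usable],
                                        out$g_alt_fwd[usable], out$g_n_fwd[usable])
    out$stat_rev[usable] <- strand_stat(out$t_alt_rev[usable], out$t_n_rev[usable],
                                        out$g_alt_rev[usable], out$g_n_rev[usable])
    out$stat[usable] <- pmin(out$stat_fwd[usable], out$stat_rev[usable])
  }
  g_alt <- out$g_alt_fwd + out$g_alt_rev
  g_n <- out$g_n_fwd + out$g_n_rev
  g_frac <- fifelse(g_n > 0, g_alt / g_n, 0)
  germ <- g_alt > params$germline_max_alt | g_frac > params$germline_max_frac
  pass <- usable & !germ &
    out$stat >= params$stat_threshold &
    out$t_alt_fwd >= params$min_alt_per_strand &
    out$t_alt_rev >= params$min_alt_per_strand &
    (out$t_alt_fwd + out$t_alt_rev) >= params$min_alt_total &
    out$t_n_fwd >= params$min_depth_per_strand &
    out$t_n_rev >= params$min_depth_per_strand
  out[, filter := fifelse(germ & usable, "germline_evidence",
                          fifelse(pass, "pass", "low_stat"))]
  out[]
}

#' Combine the two callers' somatic sets under strict and lenient parameters
#'
#' A site enters the strict common set when the KS genotyper finds it somatic
#' (variant in tumor, hom_ref in germline) and the proportion-test caller
#' passes it under strict parameters; the lenient common set likewise under
#' lenient parameters. The final list is the strict set plus those
#' lenient-only calls that survive the automated post-filters (a deterministic
#' replacement for the original manual review): strand alt-fraction asymmetry
#' at most `max_strand_ratio`-fold, and no candidate indel within
#' `indel_margin` bp.
#'
#' @param solsnp_somatic `data.table(contig, site, ref, alt)` of
#'   genotyper-somatic sites.
#' @param walker_strict,walker_lenient outputs of [call_somatic()] on the
#'   same site universe under the two parameter sets.
#' @param strict,lenient the two [caller_params()] (order is validated).
#' @param indel_candidates optional `data.table(contig, start, end)` of
#'   candidate indels for the proximity post-filter.
#' @param max_strand_ratio maximum fold-asymmetry of the two strand alt
#'   fractions (default 2).
#' @param indel_margin bp distance defining indel proximity (default 5).
#' @return `data.table` of final calls with `provenance`
#'   (`strict` / `lenient`) and `post_filter` (`pass` or the reason a
#'   lenient-only call was removed; removed calls are not returned but
#'   counted in the `dropped` attribute).
#' @export
consensus_calls <- function(solsnp_somatic, walker_strict, walker_lenient,
                            strict = strict_params(), lenient = lenient_params(),
                            indel_candidates = NULL, max_strand_ratio = 2,
                            indel_margin = 5L) {
  .check_param_order(strict, lenient)
  sol <- as.data.table(solsnp_somatic)
  ws <- as.data.table(walker_strict)
  wl <- as.data.table(walker_lenient)
  key <- function(x) paste(x$contig, x$site)
  both <- merge(sol[, .(contig, site, ref_sol = ref, alt)],
                wl[, .(contig, site, ref_wal = ref)], by = c("contig", "site"))
  if (nrow(both) && any(both$ref_sol != both$ref_wal))
    stop("inconsistent reference alleles between callers at ",
         both[ref_sol != ref_wal][1, paste0(contig, ":", site)])
  strict_set <- ws[filter == "pass" & key(ws) %in% key(sol)]
  lenient_set <- wl[filter == "pass" & key(wl) %in% key(sol)]
  lenient_only <- lenient_set[!key(lenient_set) %in% key(strict_set)]
  if (nrow(lenient_only)) {
    ff <- lenient_only$t_alt_fwd / lenient_only$t_n_fwd
    fr <- lenient_only$t_alt_rev / lenient_only$t_n_rev
    asym <- pmax(ff, fr) > max_strand_ratio * pmin(ff, fr)
    near_indel <- rep(FALSE, nrow(lenient_only))
    if (!is.null(indel_candidates) && nrow(indel_candidates)) {
      ic <- as.data.table(indel_candidates)
      for (j in seq_len(nrow(ic))) {
        near_indel <- near_indel |
          (lenient_only$contig == ic$contig[j] &
             lenient_only$site >= ic$start[j] - indel_margin &
             lenient_only$site <= ic$end[j] + indel_margin)
      }
    }
    reason <- fifelse(asym, "strand_asymmetry",
                      fifelse(near_indel, "near_indel", "pass"))
    lenient_only[, post_filter := reason]
    dropped <- lenient_only[post_filter != "pass"]
    lenient_only <- lenient_only[post_filter == "pass"]
  } else {
    lenient_only[, post_filter := character(0)]
    dropped <- lenient_only[0]
  }
  if (nrow(strict_set)) strict_set[, post_filter := "pass"]
  else strict_set[, post_filter := character(0)]
  final <- rbind(strict_set[, provenance := "strict"],
                 lenient_only[, provenance := "lenient"], fill = TRUE)
  setorder(final, contig, site)
  setattr(final, "dropped", dropped)
  final[]
}

#' End-to-end somatic SNV calling on paired alignments
#'
#' Runs the full dual-caller design on tumor/germline read tables: mismatch
#' scan, alternative-allele selection, per-strand count assembly, KS
#' genotyping of both samples, proportion-test calling under strict and
#' lenient parameters, and the consensus with automated post-filters.
#'
#' @param tumor_reads,germline_reads `aln_reads` tables (duplicates excluded
#'   internally).
#' @param reference named character vector of contig sequences.
#' @param strict,lenient [caller_params()] sets.
#' @param min_strand_depth KS genotyper strand depth floor.
#' @param indel_candidates optional candidate indel table for the post-filter.
#' @return List with `final` (consensus calls), `strict_set`, `lenient_set`,
#'   `walker_strict`, `walker_lenient`, `solsnp_tumor`, `solsnp_germline`,
#'   `counts` (the per-site count table).
#' @export
call_somatic_snvs <- function(tumor_reads, germline_reads, reference,
                              strict = strict_params(),
                              lenient = lenient_params(),
                              min_strand_depth = 4L,
                              indel_candidates = NULL) {
  .check_param_order(strict, lenient)
  mm_t <- .read_mismatches(tumor_reads, reference)
  if (!nrow(mm_t)) {
    empty <- data.table(contig = character(), site = integer())
    return(list(final = empty, strict_set = empty, lenient_set = empty,
                walker_strict = empty, walker_lenient = empty,
                solsnp_tumor = empty, solsnp_germline = empty, counts = empty))
  }
  # candidate sites: enough same-base tumor alt evidence to be callable at all
  agg <- mm_t[, .(k = .N), by = .(contig, site, base)]
  setorder(agg, contig, site, -k, base)
  top <- agg[!duplicated(paste(contig, site))]
  cand <- top[k >= lenient$min_alt_total, .(contig, pos = site)]
  if (!nrow(cand)) cand <- top[0, .(contig, pos = site)]
  t_tab <- .site_category_counts(tumor_reads, mm_t, cand, reference)
  mm_g <- .read_mismatches(germline_reads, reference)
  g_tab <- .site_category_counts(germline_reads, mm_g, cand, reference)
  # force the germline tally onto the tumor's chosen alt allele
  g_tab <- .retally_alt(g_tab, mm_g, t_tab[, .(contig, site, alt)])

  counts <- merge(
    t_tab[, .(contig, site, ref, alt, t_n_fwd = n_fwd, t_n_rev = n_rev,
              t_alt_fwd = alt_fwd, t_alt_rev = alt_rev,
              t_oth_fwd = oth_fwd, t_oth_rev = oth_rev)],
    g_tab[, .(contig, site, g_n_fwd = n_fwd, g_n_rev = n_rev,
              g_alt_fwd = alt_fwd, g_alt_rev = alt_rev,
              g_oth_fwd = oth_fwd, g_oth_rev = oth_rev)],
    by = c("contig", "site"))

  sol_t <- .genotype_counts(counts$t_n_fwd, counts$t_alt_fwd, counts$t_oth_fwd,
                            counts$t_n_rev, counts$t_alt_rev, counts$t_oth_rev,
                            "consensus", min_strand_depth)
  sol_g <- .genotype_counts(counts$g_n_fwd, counts$g_alt_fwd, counts$g_oth_fwd,
                            counts$g_n_rev, counts$g_alt_rev, counts$g_oth_rev,
                            "consensus", min_strand_depth)
  solsnp_somatic <- counts[sol_t$variant & !is.na(sol_g$consensus) &
                             sol_g$consensus == "hom_ref",
                           .(contig, site, ref, alt)]
  ws <- call_somatic(counts, strict)
  wl <- call_somatic(counts, lenient)
  final <- consensus_calls(solsnp_somatic, ws, wl, strict, lenient,
                           indel_candidates = indel_candidates)
  list(final = final,
       strict_set = ws[filter == "pass" &
                         paste(contig, site) %in% paste(solsnp_somatic$contig, solsnp_somatic$site)],
       lenient_set = wl[filter == "pass" &
                          paste(contig, site) %in% paste(solsnp_somatic$contig, solsnp_somatic$site)],
       walker_strict = ws, walker_lenient = wl,
       solsnp_tumor = cbind(counts[, .(contig, site, ref, alt)],
                            as.data.table(sol_t[c("fwd", "rev", "consensus", "variant")])),
       solsnp_germline = cbind(counts[, .(contig, site, ref, alt)],
                               as.data.table(sol_g[c("fwd", "rev", "consensus", "variant")])),
       counts = counts)
}

# re-derive alt/other strand counts for externally chosen alt alleles
.retally_alt <- function(tab, mm, alt_map) {
  tab <- merge(tab[, -c("alt", "alt_fwd", "alt_rev", "oth_fwd", "oth_rev")],
               alt_map, by = c("contig", "site"), all.x = TRUE)
  fill0 <- function(x) fifelse(is.na(x), 0L, x)
  if (nrow(mm)) {
    agg <- mm[, .(k = .N), by = .(contig, site, base, strand)]
    tab <- merge(tab, agg[strand == "+", .(contig, site, base, af = k)],
                 by.x = c("contig", "site", "alt"), by.y = c("contig", "site", "base"),
                 all.x = TRUE)
    tab <- merge(tab, agg[strand == "-", .(contig, site, base, ar = k)],
                 by.x = c("contig", "site", "alt"), by.y = c("contig", "site", "base"),
                 all.x = TRUE)
    allmm <- mm[, .(k = .N), by = .(contig, site, strand)]
    tab <- merge(tab, allmm[strand == "+", .(contig, site, mf = k)],
                 by = c("contig", "site"), all.x = TRUE)
    tab <- merge(tab, allmm[strand == "-", .(contig, site, mr = k)],
                 by = c("contig", "site"), all.x = TRUE)
    tab[, `:=`(alt_fwd = fill0(af), alt_rev = fill0(ar),
               oth_fwd = pmax(fill0(mf) - fill0(af), 0L),
               oth_rev = pmax(fill0(mr) - fill0(ar), 0L))]
    tab[, c("af", "ar", "mf", "mr") := NULL]
  } else tab[, `:=`(alt_fwd = 0L, alt_rev = 0L, oth_fwd = 0L, oth_rev = 0L)]
  tab
}
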