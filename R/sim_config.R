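#' Simulation configuration for the paired tumor/germline mate-pair simulator
#'
#' Bundles every knob of the synthetic-data generator: the genome layout, tumor
#' purity (tumor-cell fraction of the specimen), target sequence coverages,
#' mate-pair library geometry, the germline substitution model, and the planted
#' somatic events (SNVs, small indels, copy-number segments, inter-chromosomal
#' fusions). Defaults mirror the study design this package reconstructs: a
#' ~60% pure tumor sequenced to 37x against a 40x germline with 1.5 kb-insert
#' 50 bp x 50 bp mate pairs and a germline transition:transversion ratio of
#' 2.12.
#'
#' @param genome_spec named integer vector of contig lengths (bp).
#' @param purity tumor-cell fraction in `(0, 1]`; default 0.6.
#' @param mean_coverage_tumor,mean_coverage_germline target mean base coverage
#'   (fold) for the tumor and germline libraries; defaults 37 and 40.
#' @param insert_mean,insert_sd mate-pair insert (fragment) length mean and SD
#'   in bp; the insert distribution is Normal truncated below at
#'   `2 * read_len`. Defaults 1500 and 150.
#' @param read_len read length in bp (default 50).
#' @param titv_ratio germline transitions per transversion (default 2.12), so a
#'   substitution is a transition with probability `titv / (titv + 1)`.
#' @param germline_snp_rate germline SNP rate per bp (default 1e-3).
#' @param het_fraction fraction of germline SNPs that are heterozygous
#'   (default 2/3, the remainder homozygous alternative).
#' @param somatic_snv_count number of somatic SNVs to plant (default 0).
#' @param somatic_indel_spec `data.frame` with columns `contig`, `start`
#'   (0-based), `len`, `type` (`"ins"`/`"del"`), optional `origin`
#'   (`"somatic"`, default, or `"germline"`).
#' @param cnv_spec `data.frame` with columns `contig`, `start`, `end` (0-based
#'   half-open) and `cn` (tumor copy number in 0..4). Intervals on one contig
#'   must be nested or disjoint.
#' @param fusion_spec `data.frame` with columns `contig_a`, `pos_a`,
#'   `contig_b`, `pos_b`, `origin` (`"somatic"`/`"germline"`).
#' @param base_quality single Phred quality assigned to every base
#'   (default 30); the implied error rate `10^(-Q/10)` is also the simulated
#'   per-base substitution error rate.
#' @param background_discordant_rate fraction of fragments whose second mate is
#'   relocated to a random other contig, emulating residual chimeric-ligation
#'   artifacts of mate-pair circularization (default 2e-4).
#' @param seed integer seed; every simulator operation is deterministic given
#'   the config.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(genome_spec = c(chr1 = 50000L), seed = 1L)
#' cfg$purity
sim_config <- function(genome_spec,
                       purity = 0.6,
                       mean_coverage_tumor = 37,
                       mean_coverage_germline = 40,
                       insert_mean = 1500,
                       insert_sd = 150,
                       read_len = 50L,
                       titv_ratio = 2.12,
                       germline_snp_rate = 1e-3,
                       het_fraction = 2 / 3,
                       somatic_snv_count = 0L,
                       somatic_indel_spec = NULL,
                       cnv_spec = NULL,
                       fusion_spec = NULL,
                       base_quality = 30L,
                       background_discordant_rate = 2e-4,
                       seed = 1L) {
  if (is.null(names(genome_spec)) || any(!nzchar(names(genome_spec))))
    stop("genome_spec must be a named vector of contig lengths")
  genome_spec <- setNames(as.integer(genome_spec), names(genome_spec))
  if (any(is.na(genome_spec)) || any(genome_spec <= 0L))
    stop("contig lengths must be positive integers")
  if (!(purity > 0 && purity <= 1)) stop("purity must lie in (0, 1]")
  if (insert_mean <= 2 * read_len) stop("insert_mean must exceed 2 * read_len")
  if (titv_ratio <= 0) stop("titv_ratio must be positive")
  if (mean_coverage_tumor <= 0 || mean_coverage_germline <= 0)
    stop("coverages must be positive")

  cnv_spec <- .validate_intervals(cnv_spec, genome_spec, c("contig", "start", "end", "cn"))
  if (!is.null(cnv_spec)) {
    if (any(!cnv_spec$cn %in% 0:4)) stop("cnv_spec$cn must be in 0..4")
    .check_nested_or_disjoint(cnv_spec)
  }
  if (!is.null(somatic_indel_spec)) {
    somatic_indel_spec <- as.data.frame(somatic_indel_spec)
    need <- c("contig", "start", "len", "type")
    if (!all(need %in% names(somatic_indel_spec)))
      stop("somatic_indel_spec needs columns ", paste(need, collapse = ", "))
    if (is.null(somatic_indel_spec$origin)) somatic_indel_spec$origin <- "somatic"
    if (any(!somatic_indel_spec$type %in% c("ins", "del")))
      stop("indel type must be 'ins' or 'del'")
    if (any(somatic_indel_spec$len <= 0)) stop("indel len must be positive")
    ends <- somatic_indel_spec$start +
      ifelse(somatic_indel_spec$type == "del", somatic_indel_spec$len, 0L)
    if (any(somatic_indel_spec$start < 0) ||
        any(ends > genome_spec[somatic_indel_spec$contig], na.rm = TRUE) ||
        any(is.na(genome_spec[somatic_indel_spec$contig])))
      stop("somatic_indel_spec outside contig bounds")
  }
  if (!is.null(fusion_spec)) {
    fusion_spec <- as.data.frame(fusion_spec)
    need <- c("contig_a", "pos_a", "contig_b", "pos_b", "origin")
    if (!all(need %in% names(fusion_spec)))
      stop("fusion_spec needs columns ", paste(need, collapse = ", "))
    if (any(!fusion_spec$origin %in% c("somatic", "germline")))
      stop("fusion origin must be 'somatic' or 'germline'")
    ok <- fusion_spec$contig_a %in% names(genome_spec) &
      fusion_spec$contig_b %in% names(genome_spec)
    if (any(!ok)) stop("fusion contigs not in genome_spec")
  }

  structure(list(
    genome_spec = genome_spec, purity = purity,
    mean_coverage_tumor = mean_coverage_tumor,
    mean_coverage_germline = mean_coverage_germline,
    insert_mean = insert_mean, insert_sd = insert_sd,
    read_len = as.integer(read_len), titv_ratio = titv_ratio,
    germline_snp_rate = germline_snp_rate, het_fraction = het_fraction,
    somatic_snv_count = as.integer(somatic_snv_count),
    somatic_indel_spec = somatic_indel_spec, cnv_spec = cnv_spec,
    fusion_spec = fusion_spec, base_quality = as.integer(base_quality),
    background_discordant_rate = background_discordant_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

.validate_intervals <- function(x, genome_spec, need) {
  if (is.null(x)) return(NULL)
  x <- as.data.frame(x)
  if (!all(need %in% names(x)))
    stop("expected columns ", paste(need, collapse = ", "))
  if (any(!x$contig %in% names(genome_spec))) stop("interval contig not in genome_spec")
  if (any(x$start < 0) || any(x$end > genome_spec[x$contig]) || any(x$end <= x$start))
    stop("intervals must be non-empty and lie within their contig")
  x
}

# CNV intervals on one contig must be nested or disjoint (partial overlap is
# ambiguous about which copy number wins)
.check_nested_or_disjoint <- function(cnv) {
  for (ctg in unique(cnv$contig)) {
    z <- cnv[cnv$contig == ctg, , drop = FALSE]
    if (nrow(z) < 2) next
    for (i in seq_len(nrow(z) - 1)) for (j in (i + 1):nrow(z)) {
      a <- z[i, ]; b <- z[j, ]
      disjoint <- a$end <= b$start || b$end <= a$start
      nested <- (a$start <= b$start && b$end <= a$end) ||
        (b$start <= a$start && a$end <= b$end)
      if (!disjoint && !nested)
        stop("cnv_spec intervals on ", ctg, " must be nested or disjoint")
    }
  }
  invisible(TRUE)
}

#' Read or write a simulation configuration as YAML
#'
#' @param path file path.
#' @param config a [sim_config()] object.
#' @return `read_sim_config` returns a `sim_config`; `write_sim_config`
#'   returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (fld in c("somatic_indel_spec", "cnv_spec", "fusion_spec"))
    if (!is.null(y[[fld]])) y[[fld]] <- as.data.frame(y[[fld]])
  y$genome_spec <- unlist(y$genome_spec)
  do.call(sim_config, y)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  y <- unclass(config)
  y$genome_spec <- as.list(y$genome_spec)
  for (fld in c("somatic_indel_spec", "cnv_spec", "fusion_spec"))
    if (!is.null(y[[fld]])) y[[fld]] <- lapply(as.data.frame(y[[fld]]), I)
  y <- Filter(Negate(is.null), y)
  yaml::write_yaml(y, path)
  invisible(path)
}
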