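#' Simulate paired per-bin fragment depths (depth-level mode)
#'
#' The fast fidelity mode for copy-number work on tens of Mb: instead of
#' individual reads, each 100 bp bin receives an independent Poisson fragment
#' depth. Germline bins draw from `Poisson(lambda_germline)`; tumor bins from
#' `Poisson(lambda_tumor * (purity * CN/2 + (1 - purity)))` where `CN` is the
#' planted tumor copy number of the bin (innermost CNV segment wins,
#' background diploid). Deterministic under the config seed.
#'
#' @param config a [sim_config()]; `cnv_spec` supplies the planted segments.
#' @param lambda_germline,lambda_tumor mean depth per bin at copy-neutral
#'   diploid state; default the config's mean coverages.
#' @param bin_size bin width in bp (default 100).
#' @return A `data.table` of class `coverage_track` with columns `contig`,
#'   `start` (bin start, 0-based, multiple of `bin_size`), `germline`,
#'   `tumor`; attributes `bin_size` and `kind = "fragment"`.
#' @export
#' @examples
#' cfg <- sim_config(c(chr1 = 100000L), seed = 3L)
#' head(simulate_bin_depths(cfg))
simulate_bin_depths <- function(config, lambda_germline = NULL,
                                lambda_tumor = NULL, bin_size = 100L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(lambda_germline)) lambda_germline <- config$mean_coverage_germline
  if (is.null(lambda_tumor)) lambda_tumor <- config$mean_coverage_tumor
  if (lambda_germline <= 0 || lambda_tumor <= 0)
    stop("Poisson rates must be positive")
  set.seed(config$seed + 303L)
  out <- lapply(names(config$genome_spec), function(ctg) {
    nb <- as.integer(ceiling(config$genome_spec[[ctg]] / bin_size))
    start <- (seq_len(nb) - 1L) * bin_size
    cn <- tumor_copy_number(rep(ctg, nb), start + bin_size %/% 2L, config)
    rel <- config$purity * cn / 2 + (1 - config$purity)
    data.table(contig = ctg, start = start,
               germline = rpois(nb, lambda_germline),
               tumor = rpois(nb, lambda_tumor * rel))
  })
  out <- rbindlist(out)
  setattr(out, "bin_size", as.integer(bin_size))
  setattr(out, "kind", "fragment")
  setattr(out, "class", c("coverage_track", class(out)))
  out[]
}
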