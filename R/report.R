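#' Read an annotated somatic coding-variant table
#'
#' Parses the packaged Table-2-style TSV of somatic coding point mutations
#' and small indels: genomic position and alleles (point form
#' `ChrN:posR/A`, deletion form `ChrN:start-enddel`), gene symbol, codon
#' change, amino-acid consequence, variant class and SIFT prediction.
#' Class invariants are validated: the deletion-interval form is used exactly
#' for frameshift indels, and nonsense consequences end in a stop (`X`).
#'
#' @param path TSV path; defaults to the packaged table.
#' @return `data.table` with parsed `contig`, `start`, `end`, `ref`, `alt`
#'   plus the annotation columns.
#' @export
read_variant_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "somatic_coding_variants.tsv",
                        package = "somaticmate", mustWork = TRUE)
  x <- as.data.table(read.table(path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE, quote = ""))
  need <- c("position", "gene", "codon_change", "consequence", "class", "sift")
  stopifnot(all(need %in% names(x)))
  bad <- which(!x$class %in% c("missense", "nonsense", "frameshift_indel"))
  if (length(bad))
    stop("unknown variant class '", x$class[bad[1]], "' in row ", bad[1])
  is_del <- grepl("del$", x$position)
  if (any(is_del != (x$class == "frameshift_indel")))
    stop("deletion-interval position form must coincide with frameshift_indel class")
  nons <- x$class == "nonsense"
  if (any(nons != grepl("X$", x$consequence)))
    stop("nonsense class must coincide with consequences ending in X")
  x[, contig := sub(":.*$", "", position)]
  x[, `:=`(start = NA_integer_, end = NA_integer_,
           ref = NA_character_, alt = NA_character_)]
  pt <- !is_del
  x$start[pt] <- as.integer(sub("^[^:]+:([0-9]+).*$", "\\1", x$position[pt]))
  x$end[pt] <- x$start[pt]
  x$ref[pt] <- sub("^[^:]+:[0-9]+([ACGT])/.*$", "\\1", x$position[pt])
  x$alt[pt] <- sub("^.*/([ACGT])$", "\\1", x$position[pt])
  x$start[is_del] <- as.integer(sub("^[^:]+:([0-9]+)-.*$", "\\1", x$position[is_del]))
  x$end[is_del] <- as.integer(sub("^[^:]+:[0-9]+-([0-9]+)del$", "\\1", x$position[is_del]))
  x[]
}

#' Variant-class accounting
#'
#' Counts missense, nonsense, coding point mutations (their sum) and
#' frameshift indels, and the fraction of missense mutations predicted
#' Damaging, rounded to a whole percent.
#'
#' @param records output of [read_variant_table()] (row order irrelevant).
#' @return List with `missense`, `nonsense`, `coding_point_mutations`,
#'   `frameshift_indels`, `damaging`, `damaging_percent` (`NA` on an empty
#'   table).
#' @export
class_counts <- function(records) {
  records <- as.data.table(records)
  bad <- which(!records$class %in% c("missense", "nonsense", "frameshift_indel"))
  if (length(bad))
    stop("unknown variant class '", records$class[bad[1]], "' in row ", bad[1])
  n_mis <- sum(records$class == "missense")
  n_non <- sum(records$class == "nonsense")
  n_ind <- sum(records$class == "frameshift_indel")
  n_dam <- sum(records$class == "missense" & records$sift == "Damaging")
  list(missense = n_mis, nonsense = n_non,
       coding_point_mutations = n_mis + n_non, frameshift_indels = n_ind,
       damaging = n_dam,
       damaging_percent = if (n_mis > 0) as.integer(round(100 * n_dam / n_mis))
       else NA_integer_)
}

#' Transition:transversion ratio
#'
#' Transitions are `A<->G` and `C<->T`; everything else among single-base
#' substitutions is a transversion. With zero transversions the ratio is
#' undefined and returned as `NA` with a warning.
#'
#' @param variants `data.frame` with `ref` and `alt` single-base columns.
#' @return The ratio (numeric).
#' @export
titv <- function(variants) {
  v <- as.data.table(variants)
  stopifnot(all(c("ref", "alt") %in% names(v)))
  pair <- paste0(v$ref, v$alt)
  ti <- pair %in% c("AG", "GA", "CT", "TC")
  n_ti <- sum(ti); n_tv <- sum(!ti)
  if (n_tv == 0) {
    warning("zero transversions: Ti/Tv undefined")
    return(NA_real_)
  }
  n_ti / n_tv
}

#' Genome and read-pair (clonal) coverage
#'
#' Fold coverage is uniquely mapping bases over genome length; read-pair
#' (clonal) coverage is tag pairs times the insert length over genome length
#' — the long insert is what gives mate-pair libraries their power for
#' structural variation.
#'
#' @param n_unique_bases uniquely mapping bases.
#' @param n_tag_pairs uniquely mapping tag pairs.
#' @param insert insert length in bp (default 1500).
#' @param genome_length genome size in bp.
#' @return List with `fold`, `fold_floor`, `read_pair`, `read_pair_floor`.
#' @export
coverage_summary <- function(n_unique_bases, n_tag_pairs, insert = 1500,
                             genome_length) {
  if (genome_length <= 0) stop("genome length must be positive")
  fold <- n_unique_bases / genome_length
  rp <- n_tag_pairs * insert / genome_length
  list(fold = fold, fold_floor = floor(fold),
       read_pair = rp, read_pair_floor = floor(rp))
}

#' Read a qPCR Ct plate
#'
#' Long-format CSV with columns `gene`, `sample` (`tumor`/`normal`), `ct`
#' and optional `reference` flag; triplicate rows per (gene, sample).
#'
#' @param path CSV path.
#' @return `data.table`.
#' @export
read_qpcr_plate <- function(path) {
  x <- as.data.table(read.table(path, sep = ",", header = TRUE,
                                stringsAsFactors = FALSE))
  stopifnot(all(c("gene", "sample", "ct") %in% names(x)))
  if (any(x$ct <= 0)) stop("Ct values must be positive")
  x
}

#' Delta-delta-Ct fold change, tumor versus normal
#'
#' Each sample's mean Ct for the gene is first normalized to the same
#' sample's reference gene (`dCt = Ct(gene) - Ct(reference)`); the tumor
#' quantity is then normalized to its normal counterpart
#' (`ddCt = dCt(tumor) - dCt(normal)`) and the fold change is
#' `2^(-ddCt)`, assuming amplification efficiency 2.
#'
#' @param plate [read_qpcr_plate()] output.
#' @param gene gene of interest.
#' @param reference_gene normalization gene (e.g. GAPDH).
#' @return The fold change (numeric scalar).
#' @export
ddct_fold_change <- function(plate, gene, reference_gene) {
  plate <- as.data.table(plate)
  m <- function(g, s) {
    v <- plate[plate$gene == g & plate$sample == s, ct]
    if (!length(v)) stop("missing Ct measurements for ", g, " in ", s)
    mean(v)
  }
  dct_t <- m(gene, "tumor") - m(reference_gene, "tumor")
  dct_n <- m(gene, "normal") - m(reference_gene, "normal")
  2^(-(dct_t - dct_n))
}

#' Circos-ready tabular summary of all caller outputs
#'
#' One tidy table with a `track` column covering coding point mutations,
#' coding indels, copy-number segments (with state) and translocation region
#' pairs — the data behind a somatic-event wheel plot, without the
#' rendering.
#'
#' @param point_mutations `data.frame(contig, start, end, ...)` or `NULL`.
#' @param coding_indels `data.frame(contig, start, end, ...)` or `NULL`.
#' @param cnv_segments [flag_and_segment()] output or `NULL`.
#' @param translocations call table (`contig_a` ... `contig_b` ...) or
#'   `NULL`.
#' @return `data.table(track, contig, start, end, detail)`; one row per
#'   input record.
#' @export
circos_summary <- function(point_mutations = NULL, coding_indels = NULL,
                           cnv_segments = NULL, translocations = NULL) {
  rows <- list(data.table(track = character(), contig = character(),
                          start = integer(), end = integer(),
                          detail = character()))
  add <- function(track, contig, start, end, detail) {
    rows[[length(rows) + 1L]] <<- data.table(
      track = track, contig = as.character(contig),
      start = as.integer(start), end = as.integer(end),
      detail = as.character(detail))
  }
  if (!is.null(point_mutations) && nrow(point_mutations)) {
    p <- as.data.table(point_mutations)
    add("point_mutation", p$contig, p$start,
        if (!is.null(p$end)) p$end else p$start,
        if (!is.null(p$gene)) p$gene else "")
  }
  if (!is.null(coding_indels) && nrow(coding_indels)) {
    p <- as.data.table(coding_indels)
    add("coding_indel", p$contig, p$start, p$end,
        if (!is.null(p$gene)) p$gene else if (!is.null(p$type)) p$type else "")
  }
  if (!is.null(cnv_segments) && nrow(cnv_segments)) {
    p <- as.data.table(cnv_segments)
    add("cnv_segment", p$contig, p$start, p$end, p$state)
  }
  if (!is.null(translocations) && nrow(translocations)) {
    p <- as.data.table(translocations)
    add("translocation", p$contig_a, p$start_a, p$end_a,
        sprintf("%s:%d-%d", p$contig_b, p$start_b, p$end_b))
  }
  rbindlist(rows)
}
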