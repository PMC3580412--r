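#' Plant germline and somatic variants on a reference
#'
#' Builds the four haplotypes of the matched pair — two germline (`g1`, `g2`)
#' and two tumor (`t1`, `t2`, which inherit the germline variants) — and a
#' truth set recording every planted event. Germline SNPs are drawn at
#' `germline_snp_rate` with a transition probability
#' `titv_ratio / (titv_ratio + 1)` (so the expected transition:transversion
#' ratio equals `titv_ratio`); heterozygous SNPs land on one germline
#' haplotype, homozygous ones on both. Somatic SNVs and somatic indels are
#' applied to tumor haplotype 1 only; germline-origin indels to `g1` (hence
#' also `t1`). Copy-number segments are realized as per-haplotype
#' multiplicities of tumor DNA (`cn` 0..4 maps to haplotype multiplicities
#' (0,0), (1,0), (1,1), (2,1), (2,2)); fusions are recorded for the read
#' simulator.
#'
#' The truth set records, for each somatic SNV, the expected alt-read fraction
#' in the tumor library under the purity mixture:
#' `purity * m1 / (purity * (m1 + m2) + (1 - purity) * 2)`, which is
#' `purity / 2` for a clonal het in a copy-neutral region.
#'
#' @param reference named character vector from [generate_reference()].
#' @param config a [sim_config()].
#' @return A list of class `sim_genome` with elements `reference`, `variants`
#'   (a `data.table`: `contig`, `pos` 0-based, `type` snv/ins/del, `ref`,
#'   `alt`, `len`, `seq`, logical haplotype membership `g1,g2,t1,t2`),
#'   `truth` (class `truth_set`: `germline_snps`, `somatic_snvs`,
#'   `somatic_indels`, `cnv_segments`, `fusions`) and `config`.
#' @export
plant_variants <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  gs <- config$genome_spec
  contigs <- names(gs)

  indels <- config$somatic_indel_spec
  blocked <- data.table(contig = character(), start = integer(), end = integer())
  if (!is.null(indels) && nrow(indels)) {
    ends <- indels$start + ifelse(indels$type == "del", indels$len, 1L)
    blocked <- data.table(contig = indels$contig,
                          start = pmax(0L, as.integer(indels$start - 1L)),
                          end = as.integer(ends + 1L))
  }

  ## --- germline SNPs ------------------------------------------------------
  n_snp <- rbinom(1L, sum(gs), config$germline_snp_rate)
  snp <- .sample_sites(n_snp, gs, blocked)
  snp_tab <- data.table(contig = character(), pos = integer(), ref = character(),
                        alt = character(), genotype = character())
  if (nrow(snp)) {
    refb <- .bases_at(reference, snp$contig, snp$pos)
    alt <- .sample_substitution(refb, config$titv_ratio)
    het <- runif(nrow(snp)) < config$het_fraction
    genotype <- ifelse(het, "het", "hom_alt")
    snp_tab <- data.table(contig = snp$contig, pos = snp$pos, ref = refb,
                          alt = alt, genotype = genotype)
  }

  ## --- somatic SNVs -------------------------------------------------------
  taken <- rbind(blocked,
                 data.table(contig = snp_tab$contig, start = snp_tab$pos,
                            end = snp_tab$pos + 1L))
  som <- .sample_sites(config$somatic_snv_count, gs, taken)
  som_tab <- data.table(contig = character(), pos = integer(), ref = character(),
                        alt = character(), expected_alt_fraction = numeric())
  if (nrow(som)) {
    refb <- .bases_at(reference, som$contig, som$pos)
    alt <- .sample_substitution(refb, config$titv_ratio)
    m <- .hap_multiplicity(som$contig, som$pos, config)
    eaf <- config$purity * m$m1 /
      (config$purity * (m$m1 + m$m2) + (1 - config$purity) * 2)
    som_tab <- data.table(contig = som$contig, pos = som$pos, ref = refb,
                          alt = alt, expected_alt_fraction = eaf)
  }

  ## --- indels -------------------------------------------------------------
  indel_tab <- data.table(contig = character(), pos = integer(), type = character(),
                          len = integer(), seq = character(), origin = character())
  if (!is.null(indels) && nrow(indels)) {
    for (i in seq_len(nrow(indels))) {
      collide <- c(snp_tab[contig == indels$contig[i]]$pos,
                   som_tab[contig == indels$contig[i]]$pos)
      span <- indels$start[i] + seq_len(max(1L, ifelse(indels$type[i] == "del",
                                                       indels$len[i], 1L))) - 1L
      if (any(collide %in% span))
        stop("somatic indel overlaps a planted SNV at the same site")
    }
    seqs <- ifelse(indels$type == "del",
                   substring(reference[indels$contig], indels$start + 1L,
                             indels$start + indels$len),
                   vapply(indels$len, function(l)
                     paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""),
                     character(1)))
    indel_tab <- data.table(contig = indels$contig, pos = as.integer(indels$start),
                            type = indels$type, len = as.integer(indels$len),
                            seq = seqs, origin = indels$origin)
  }

  ## --- haplotype membership ----------------------------------------------
  het <- snp_tab$genotype == "het"
  hap_of_het <- sample(c(TRUE, FALSE), nrow(snp_tab), TRUE)  # TRUE -> hap 1
  variants <- rbindlist(list(
    if (nrow(snp_tab)) data.table(
      contig = snp_tab$contig, pos = snp_tab$pos, type = "snv",
      ref = snp_tab$ref, alt = snp_tab$alt, len = 1L, seq = snp_tab$alt,
      g1 = !het | hap_of_het, g2 = !het | !hap_of_het),
    if (nrow(som_tab)) data.table(
      contig = som_tab$contig, pos = som_tab$pos, type = "snv",
      ref = som_tab$ref, alt = som_tab$alt, len = 1L, seq = som_tab$alt,
      g1 = FALSE, g2 = FALSE),
    if (nrow(indel_tab)) data.table(
      contig = indel_tab$contig, pos = indel_tab$pos, type = indel_tab$type,
      ref = NA_character_, alt = NA_character_, len = indel_tab$len,
      seq = indel_tab$seq,
      g1 = indel_tab$origin == "germline", g2 = FALSE)),
    fill = TRUE
  )
  if (is.null(variants) || ncol(variants) == 0) variants <- data.table(
    contig = character(), pos = integer(), type = character(), ref = character(),
    alt = character(), len = integer(), seq = character(),
    g1 = logical(), g2 = logical())
  variants[, `:=`(t1 = g1, t2 = g2)]
  if (nrow(som_tab))
    variants[type == "snv" & paste(contig, pos) %in%
               paste(som_tab$contig, som_tab$pos), t1 := TRUE]
  if (nrow(indel_tab)) {
    som_ind <- indel_tab[origin == "somatic"]
    if (nrow(som_ind))
      variants[type %in% c("ins", "del") & paste(contig, pos) %in%
                 paste(som_ind$contig, som_ind$pos), t1 := TRUE]
  }
  setorder(variants, contig, pos)

  cnv <- config$cnv_spec
  cnv_tab <- if (is.null(cnv)) {
    data.table(contig = character(), start = integer(), end = integer(), cn = integer())
  } else as.data.table(cnv)[, .(contig, start = as.integer(start),
                                end = as.integer(end), cn = as.integer(cn))]
  fus <- config$fusion_spec
  fus_tab <- if (is.null(fus)) {
    data.table(contig_a = character(), pos_a = integer(), contig_b = character(),
               pos_b = integer(), origin = character())
  } else as.data.table(fus)[, .(contig_a, pos_a = as.integer(pos_a), contig_b,
                                pos_b = as.integer(pos_b), origin)]

  truth <- structure(list(
    germline_snps = snp_tab, somatic_snvs = som_tab, somatic_indels = indel_tab,
    cnv_segments = cnv_tab, fusions = fus_tab), class = "truth_set")

  structure(list(reference = reference, variants = variants, truth = truth,
                 config = config), class = "sim_genome")
}

# sample n distinct sites uniformly over the genome, avoiding blocked intervals
.sample_sites <- function(n, genome_spec, blocked) {
  if (n <= 0) return(data.table(contig = character(), pos = integer()))
  offs <- cumsum(c(0, as.numeric(genome_spec)))[seq_along(genome_spec)]
  total <- sum(as.numeric(genome_spec))
  got <- data.table(contig = character(), pos = integer())
  while (nrow(got) < n) {
    lin <- sort(sample.int(total, min(n * 2L, total)))
    idx <- findInterval(lin - 1, offs)
    cand <- data.table(contig = names(genome_spec)[idx],
                       pos = as.integer(lin - 1 - offs[idx]))
    cand <- unique(rbind(got, cand), by = c("contig", "pos"))
    if (nrow(blocked)) {
      bad <- logical(nrow(cand))
      for (i in seq_len(nrow(blocked)))
        bad <- bad | (cand$contig == blocked$contig[i] &
                        cand$pos >= blocked$start[i] & cand$pos < blocked$end[i])
      cand <- cand[!bad]
    }
    got <- cand
  }
  got <- got[sample.int(nrow(got), n)]
  setorder(got, contig, pos)
  got
}

.bases_at <- function(reference, contig, pos) {
  out <- character(length(contig))
  for (ctg in unique(contig)) {
    i <- which(contig == ctg)
    out[i] <- substring(reference[[ctg]], pos[i] + 1L, pos[i] + 1L)
  }
  out
}

# transition with probability titv/(titv+1); otherwise one of the two
# transversion partners uniformly
.sample_substitution <- function(refb, titv_ratio) {
  p_ti <- if (is.infinite(titv_ratio)) 1 else titv_ratio / (titv_ratio + 1)
  ti_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_partners <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))
  is_ti <- runif(length(refb)) < p_ti
  alt <- ti_partner[refb]
  if (any(!is_ti)) {
    pick <- runif(sum(!is_ti)) < 0.5
    alt[!is_ti] <- mapply(function(b, first) tv_partners[[b]][if (first) 1L else 2L],
                          refb[!is_ti], pick)
  }
  unname(alt)
}

# tumor haplotype multiplicities (m1, m2) at given sites: innermost CNV wins
.hap_multiplicity <- function(contig, pos, config) {
  mult_map <- list(`0` = c(0L, 0L), `1` = c(1L, 0L), `2` = c(1L, 1L),
                   `3` = c(2L, 1L), `4` = c(2L, 2L))
  m1 <- rep(1L, length(pos)); m2 <- rep(1L, length(pos))
  cnv <- config$cnv_spec
  if (!is.null(cnv) && nrow(cnv)) {
    width <- cnv$end - cnv$start
    ord <- order(-width)  # apply outer first so nested (smaller) wins
    for (i in ord) {
      hit <- contig == cnv$contig[i] & pos >= cnv$start[i] & pos < cnv$end[i]
      if (any(hit)) {
        m <- mult_map[[as.character(cnv$cn[i])]]
        m1[hit] <- m[1]; m2[hit] <- m[2]
      }
    }
  }
  list(m1 = m1, m2 = m2)
}

#' Tumor copy number at positions
#'
#' Innermost planted segment wins; background is diploid (CN 2).
#' @param contig,pos vectors of positions (0-based).
#' @param config a [sim_config()].
#' @return integer vector of tumor copy numbers.
#' @export
tumor_copy_number <- function(contig, pos, config) {
  m <- .hap_multiplicity(contig, pos, config)
  as.integer(m$m1 + m$m2)
}
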