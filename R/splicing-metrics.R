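#' Canonical splice-site motif whitelist
#'
#' The six canonical donor/acceptor dinucleotide pairs used to filter
#' junctions: GT/AG, CT/AC, GC/AG, CT/GC, AT/AC, GT/AT.
#'
#' @return character vector of motif labels.
#' @export
canonical_motifs <- function() {
  c("GT/AG", "CT/AC", "GC/AG", "CT/GC", "AT/AC", "GT/AT")
}

#' Gene annotation from exon intervals
#'
#' Builds the derived structures the splicing metrics need from a flat exon
#' table: the set of annotated junctions (introns between consecutive exons
#' of each transcript, as 1-based first/last intronic base) and the exon
#' table itself for base-territory accounting.
#'
#' @param exons data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`, `transcript_id`, `gene_id`.
#' @return an object of class `gene_annotation` with elements `exons` and
#'   `junctions`.
#' @export
gene_annotation <- function(exons) {
  need <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
  stopifnot(is.data.frame(exons), all(need %in% names(exons)),
            nrow(exons) >= 1L, all(exons$start <= exons$end))
  exons <- exons[order(exons$transcript_id, exons$start), need]
  rownames(exons) <- NULL
  by_tx <- split(exons, exons$transcript_id)
  juncs <- lapply(by_tx, function(tx) {
    if (nrow(tx) < 2L) return(NULL)
    if (any(tx$start[-1L] <= tx$end[-nrow(tx)]))
      abort_ss(sprintf("overlapping exons in transcript '%s'",
                       tx$transcript_id[1]), "bad_annotation")
    data.frame(
      chrom = tx$chrom[-nrow(tx)],
      intron_start = tx$end[-nrow(tx)] + 1L,
      intron_end = tx$start[-1L] - 1L,
      strand = tx$strand[-nrow(tx)],
      stringsAsFactors = FALSE
    )
  })
  juncs <- unique(do.call(rbind, juncs))
  if (is.null(juncs))
    juncs <- data.frame(chrom = character(), intron_start = integer(),
                        intron_end = integer(), strand = character())
  rownames(juncs) <- NULL
  structure(list(exons = exons, junctions = juncs), class = "gene_annotation")
}

#' Classify junction records as annotated, unannotated, or rejected
#'
#' A junction is rejected when its motif is not on the whitelist or its
#' maximum overhang is below `min_overhang` (default 15 nt, i.e. 10 percent
#' of a 150-nt read; `min_overhang = 0.10 * read_length` reproduces the
#' read-length-tied variant). Surviving junctions are annotated when their
#' (chromosome, first intronic base, last intronic base, strand) triple is
#' derivable from the annotation, matching without strand when the record's
#' strand is unknown, and unannotated otherwise.
#'
#' @param junctions data frame of junction records with columns `chrom`,
#'   `intron_start`, `intron_end`, `strand`, `motif`, `unique_reads`,
#'   `max_overhang`.
#' @param annotation a [gene_annotation()].
#' @param min_overhang minimum overhang in nt.
#' @param motif_whitelist allowed motif labels.
#' @return factor with levels `annotated`, `unannotated`, `rejected`, one per
#'   junction record.
#' @export
classify_junction <- function(junctions, annotation, min_overhang = 15L,
                              motif_whitelist = canonical_motifs()) {
  stopifnot(inherits(annotation, "gene_annotation"), is.data.frame(junctions))
  ann <- annotation$junctions
  key_s <- paste(ann$chrom, ann$intron_start, ann$intron_end, ann$strand)
  key_u <- paste(ann$chrom, ann$intron_start, ann$intron_end)
  rejected <- !(junctions$motif %in% motif_whitelist) |
    junctions$max_overhang < min_overhang
  unknown <- junctions$strand %in% c("*", "unknown", ".", NA)
  jk_s <- paste(junctions$chrom, junctions$intron_start, junctions$intron_end,
                junctions$strand)
  jk_u <- paste(junctions$chrom, junctions$intron_start, junctions$intron_end)
  in_ann <- ifelse(unknown, jk_u %in% key_u, jk_s %in% key_s)
  out <- ifelse(rejected, "rejected", ifelse(in_ann, "annotated", "unannotated"))
  factor(out, levels = c("annotated", "unannotated", "rejected"))
}

#' Percentage of junction reads on unannotated junctions
#'
#' Rejected junctions (non-canonical motif or short overhang) are excluded
#' from both numerator and denominator.
#'
#' @inheritParams classify_junction
#' @return percentage in `[0, 100]`.
#' @export
pct_unannotated_junction_reads <- function(junctions, annotation,
                                           min_overhang = 15L,
                                           motif_whitelist = canonical_motifs()) {
  cls <- classify_junction(junctions, annotation, min_overhang, motif_whitelist)
  keep <- cls != "rejected"
  denom <- sum(junctions$unique_reads[keep])
  if (denom == 0)
    abort_ss("no junction reads survive the motif/overhang filters",
             "zero_denominator")
  100 * sum(junctions$unique_reads[keep & cls == "unannotated"]) / denom
}

annotation_territories <- function(annotation) {
  ex <- annotation$exons
  exon_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start, ex$end)))
  # gene body = span from first to last exon base of each gene
  body <- do.call(rbind, lapply(split(ex, ex$gene_id), function(g) {
    data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end))
  }))
  gene_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    body$chrom, IRanges::IRanges(body$start, body$end)))
  list(exon = exon_gr, gene = gene_gr)
}

overlap_bases <- function(blocks_gr, territory_gr) {
  hits <- GenomicRanges::findOverlaps(blocks_gr, territory_gr)
  if (length(hits) == 0L) return(0)
  sum(GenomicRanges::width(GenomicRanges::pintersect(
    blocks_gr[S4Vectors::queryHits(hits)],
    territory_gr[S4Vectors::subjectHits(hits)])))
}

#' Base-territory fractions of aligned reads
#'
#' Classifies every aligned base as exonic (overlapping the merged exon
#' territory of any transcript — exon-dominant rule), intronic (inside a gene
#' body but not exonic), or intergenic, and returns the three percentages.
#'
#' @param reads data frame of aligned blocks with columns `chrom`, `start`,
#'   `end` (1-based inclusive); multi-block (spliced) reads contribute one
#'   row per block.
#' @param annotation a [gene_annotation()].
#' @return named numeric vector with components `exonic`, `intronic`,
#'   `intergenic`, summing to 100.
#' @export
base_territory <- function(reads, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"), is.data.frame(reads))
  if (nrow(annotation$exons) == 0L) abort_ss("empty annotation", "bad_annotation")
  if (nrow(reads) == 0L) abort_ss("no aligned bases", "zero_denominator")
  terr <- annotation_territories(annotation)
  blocks <- GenomicRanges::GRanges(reads$chrom,
                                   IRanges::IRanges(reads$start, reads$end))
  total <- sum(GenomicRanges::width(blocks))
  exonic <- overlap_bases(blocks, terr$exon)
  genic <- overlap_bases(blocks, terr$gene)
  intronic <- genic - exonic
  c(exonic = 100 * exonic / total,
    intronic = 100 * intronic / total,
    intergenic = 100 * (total - genic) / total)
}

#' Percentage of aligned bases inside introns
#'
#' @inheritParams base_territory
#' @return percentage in `[0, 100]`.
#' @export
pct_intronic_bases <- function(reads, annotation) {
  unname(base_territory(reads, annotation)[["intronic"]])
}

#' Percent spliced-in from cassette-exon junction counts
#'
#' `PSI = (J1 + J2) / (J1 + J2 + 2 * J3)`, where J1 and J2 are the two
#' inclusion junctions flanking the cassette exon and J3 is the skipping
#' junction. The skip junction is doubled because each skipping transcript
#' contributes one junction read where an including transcript contributes
#' two.
#'
#' @param J1,J2,J3 non-negative read counts (vectorized).
#' @return PSI fraction(s) in `[0, 1]`; `NA` with a warning where the
#'   denominator is zero (low coverage).
#' @export
compute_psi <- function(J1, J2, J3) {
  stopifnot(all(J1 >= 0), all(J2 >= 0), all(J3 >= 0))
  denom <- J1 + J2 + 2 * J3
  if (any(denom == 0))
    warning("zero-coverage event(s): PSI undefined, returned as NA")
  ifelse(denom > 0, (J1 + J2) / denom, NA_real_)
}

#' Classify age-changed, drug-reversed splicing events
#'
#' An event is age-changed when `|psi_old - psi_young| >= delta_threshold`.
#' Among age-changed events, the drug reverses the change when the treated
#' shift `psi_old_treated - psi_old` has the opposite sign to the age shift
#' and its magnitude is at least `reversal_fraction` of the age shift.
#' Events whose coverage is below `min_coverage` are called `low_coverage`.
#'
#' @param psi_young,psi_old,psi_old_treated PSI fractions (vectorized).
#' @param coverage minimum junction-read coverage across the three
#'   conditions per event; `NULL` disables the coverage gate.
#' @param min_coverage coverage threshold in junction reads.
#' @param delta_threshold minimum |delta PSI| to call an age change.
#' @param reversal_fraction fraction of the age shift the drug must undo.
#' @return data frame with the inputs, `delta_age`, `delta_drug`, and `call`
#'   (factor: `age_changed_reversed`, `age_changed_not_reversed`,
#'   `unchanged`, `low_coverage`).
#' @export
classify_reversibility <- function(psi_young, psi_old, psi_old_treated,
                                   coverage = NULL, min_coverage = 20L,
                                   delta_threshold = 0.1,
                                   reversal_fraction = 0.5) {
  n <- length(psi_young)
  stopifnot(length(psi_old) == n, length(psi_old_treated) == n,
            all(c(psi_young, psi_old, psi_old_treated) >= 0, na.rm = TRUE),
            all(c(psi_young, psi_old, psi_old_treated) <= 1, na.rm = TRUE))
  if (is.null(coverage)) coverage <- rep(Inf, n)
  delta_age <- psi_old - psi_young
  delta_drug <- psi_old_treated - psi_old
  call <- rep("unchanged", n)
  aged <- abs(delta_age) >= delta_threshold
  reversed <- aged & sign(delta_drug) == -sign(delta_age) &
    abs(delta_drug) >= reversal_fraction * abs(delta_age)
  call[aged] <- "age_changed_not_reversed"
  call[reversed] <- "age_changed_reversed"
  call[coverage < min_coverage] <- "low_coverage"
  data.frame(
    psi_young = psi_young, psi_old = psi_old,
    psi_old_treated = psi_old_treated,
    delta_age = delta_age, delta_drug = delta_drug,
    call = factor(call, levels = c("age_changed_reversed",
                                   "age_changed_not_reversed",
                                   "unchanged", "low_coverage"))
  )
}

#' Volcano filter for differential features
#'
#' Flags features with `p < p_threshold` and `|log2FC| > lfc_threshold`
#' (both inequalities strict).
#'
#' @param p_value,log2_fold_change numeric vectors of equal length.
#' @param p_threshold p-value cutoff (default 0.05).
#' @param lfc_threshold absolute log2 fold-change cutoff (default 1).
#' @return logical vector.
#' @export
volcano_filter <- function(p_value, log2_fold_change, p_threshold = 0.05,
                           lfc_threshold = 1.0) {
  stopifnot(length(p_value) == length(log2_fold_change))
  p_value < p_threshold & abs(log2_fold_change) > lfc_threshold
}
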