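#' Write and read the 8-column junction TSV dialect
#'
#' Tab-separated with a header line and columns `chrom`, `intron_start`,
#' `intron_end`, `strand`, `motif`, `annotated`, `unique_reads`,
#' `max_overhang`. Coordinates are 1-based first/last intronic base.
#'
#' @param junctions junction-record data frame.
#' @param path output file.
#' @export
write_junction_tsv <- function(junctions, path) {
  cols <- c("chrom", "intron_start", "intron_end", "strand", "motif",
            "unique_reads", "max_overhang")
  stopifnot(all(cols %in% names(junctions)))
  out <- junctions[, cols]
  out$annotated <- if ("annotated" %in% names(junctions))
    junctions$annotated else NA
  out <- out[, c(cols[1:5], "annotated", cols[6:7])]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_junction_tsv
#' @return `read_junction_tsv()` returns the junction data frame.
#' @export
read_junction_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write and read exon annotation as GTF (exon features only)
#'
#' Uses rtracklayer for the GTF dialect; `transcript_id` and `gene_id` are
#' carried as attributes.
#'
#' @param annotation a [gene_annotation()].
#' @param path GTF file path.
#' @export
write_annotation_gtf <- function(annotation, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    abort_ss("rtracklayer is required for GTF output", "missing_dependency")
  ex <- annotation$exons
  gr <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start, ex$end), strand = ex$strand,
    type = "exon", transcript_id = ex$transcript_id, gene_id = ex$gene_id
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_annotation_gtf
#' @return `read_annotation_gtf()` returns a [gene_annotation()].
#' @export
read_annotation_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    abort_ss("rtracklayer is required for GTF input", "missing_dependency")
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  gene_annotation(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = gr$transcript_id, gene_id = gr$gene_id,
    stringsAsFactors = FALSE
  ))
}

#' Write and read long-format survival tables
#'
#' CSV with columns `animal_id`, `group`, `time`, `fate`.
#'
#' @param records survival record data frame.
#' @param path CSV file path.
#' @export
write_survival_csv <- function(records, path) {
  stopifnot(all(c("animal_id", "group", "time", "fate") %in% names(records)))
  utils::write.csv(records[, c("animal_id", "group", "time", "fate")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @return `read_survival_csv()` returns the record data frame.
#' @export
read_survival_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write and read an omics matrix with its sample sheet
#'
#' The matrix is a TSV of features x samples with a `feature` id column; the
#' sample sheet a CSV with `sample_id` and `group`.
#'
#' @param mat features x samples numeric matrix with dimnames.
#' @param samples sample sheet data frame.
#' @param matrix_path,samples_path output files.
#' @export
write_omics_tsv <- function(mat, samples, matrix_path, samples_path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)),
            identical(colnames(mat), samples$sample_id))
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(samples, samples_path, row.names = FALSE, quote = FALSE)
  invisible(matrix_path)
}

#' @rdname write_omics_tsv
#' @return `read_omics_tsv()` returns `list(matrix =, samples =)`.
#' @export
read_omics_tsv <- function(matrix_path, samples_path) {
  df <- utils::read.delim(matrix_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$feature
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  stopifnot(identical(colnames(mat), samples$sample_id))
  list(matrix = mat, samples = samples)
}

#' Write and read a regulon (or pathway) map as two-column TSV
#'
#' Columns `set_id`, `feature_id`; one row per TF-target association.
#'
#' @param regulon named list of target-id vectors.
#' @param path TSV file path.
#' @export
write_regulon_tsv <- function(regulon, path) {
  df <- data.frame(
    set_id = rep(names(regulon), lengths(regulon)),
    feature_id = unlist(regulon, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_regulon_tsv
#' @return `read_regulon_tsv()` returns the named list.
#' @export
read_regulon_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(df$feature_id, df$set_id)
}

#' Write a ground-truth sidecar in YAML
#'
#' Generators attach their truth records to the data they emit; this writes
#' the record alongside the data so downstream checks can assert recovery
#' without re-deriving the truth.
#'
#' @param truth a truth record (any of the `*_truth()` constructors).
#' @param path YAML file path.
#' @export
write_truth_yaml <- function(truth, path) {
  yaml::write_yaml(unclass(truth), path)
  invisible(path)
}

#' @rdname write_truth_yaml
#' @return `read_truth_yaml()` returns the truth record as a list.
#' @export
read_truth_yaml <- function(path) {
  yaml::read_yaml(path)
}

#' Write and read a reporter image pair as TIFF files
#'
#' Each channel is written as a 16-bit single-channel TIFF (intensities are
#' scaled by `scale` into `[0, 1]`), the mask as an 8-bit TIFF; files are
#' `<worm_id>_gfp.tif`, `<worm_id>_mcherry.tif`, `<worm_id>_mask.tif`.
#'
#' @param pair a [reporter_image_pair()].
#' @param dir output directory.
#' @param scale intensity corresponding to full scale (AU).
#' @export
write_reporter_tiffs <- function(pair, dir, scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    abort_ss("the tiff package is required for TIFF output", "missing_dependency")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, pair$worm_id)
  tiff::writeTIFF(pmin(pair$gfp_channel / scale, 1), paste0(base, "_gfp.tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(pmin(pair$mcherry_channel / scale, 1),
                  paste0(base, "_mcherry.tif"), bits.per.sample = 16L)
  tiff::writeTIFF(pair$intestine_mask * 1, paste0(base, "_mask.tif"),
                  bits.per.sample = 8L)
  invisible(base)
}

#' @rdname write_reporter_tiffs
#' @param worm_id worm identifier (file stem).
#' @return `read_reporter_tiffs()` returns a [reporter_image_pair()].
#' @export
read_reporter_tiffs <- function(dir, worm_id, scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    abort_ss("the tiff package is required for TIFF input", "missing_dependency")
  base <- file.path(dir, worm_id)
  gfp <- tiff::readTIFF(paste0(base, "_gfp.tif")) * scale
  mch <- tiff::readTIFF(paste0(base, "_mcherry.tif")) * scale
  mask <- tiff::readTIFF(paste0(base, "_mask.tif")) > 0.5
  reporter_image_pair(gfp, mch, mask, worm_id = worm_id)
}
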