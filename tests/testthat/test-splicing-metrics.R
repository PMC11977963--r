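toy_ann <- function() {
  gene_annotation(data.frame(
    chrom = "chrI",
    start = c(1L, 401L, 851L, 1L, 851L),
    end = c(200L, 600L, 1050L, 200L, 1050L),
    strand = "+",
    transcript_id = c("t1", "t1", "t1", "t2", "t2"),
    gene_id = "g1", stringsAsFactors = FALSE
  ))
}

test_that("annotated junctions are derived from adjacent exons", {
  ann <- toy_ann()
  expect_setequal(
    paste(ann$junctions$intron_start, ann$junctions$intron_end),
    c("201 400", "601 850", "201 850")
  )
})

test_that("junction classification applies motif, overhang and membership rules", {
  ann <- toy_ann()
  recs <- data.frame(
    chrom = "chrI",
    intron_start = c(201L, 201L, 205L, 201L, 201L),
    intron_end = c(400L, 400L, 408L, 400L, 400L),
    strand = "+",
    motif = c("GT/AG", "GT/AG", "GC/AG", "AA/TT", "GT/AG"),
    unique_reads = 10L,
    max_overhang = c(20L, 14L, 15L, 30L, 15L),
    stringsAsFactors = FALSE
  )
  cls <- classify_junction(recs, ann)
  expect_equal(as.character(cls),
               c("annotated",    # canonical, deep overhang, in annotation
                 "rejected",     # overhang 14 < 15
                 "unannotated",  # overhang exactly 15, absent from annotation
                 "rejected",     # non-canonical motif
                 "annotated"))   # overhang exactly 15 is kept
})

test_that("classification agrees with a brute-force membership oracle", {
  set.seed(101)
  whitelist <- canonical_motifs()
  for (case in 1:100) {
    ann <- random_annotation(n_genes = 3)
    n <- 1000L
    # half the junctions copied from the annotation, half perturbed
    pool <- ann$junctions[sample.int(nrow(ann$junctions), n, replace = TRUE), ]
    shift <- sample(c(0L, 0L, 1L, 7L), n, replace = TRUE)
    recs <- data.frame(
      chrom = pool$chrom,
      intron_start = pool$intron_start + shift,
      intron_end = pool$intron_end + shift,
      strand = sample(c(pool$strand[1], "*"), n, replace = TRUE),
      motif = sample(c(whitelist, "AA/TT", "GG/CC"), n, replace = TRUE),
      unique_reads = sample(0:50, n, replace = TRUE),
      max_overhang = sample(5:40, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    got <- as.character(classify_junction(recs, ann))
    key <- paste(ann$junctions$chrom, ann$junctions$intron_start,
                 ann$junctions$intron_end, ann$junctions$strand)
    key_u <- paste(ann$junctions$chrom, ann$junctions$intron_start,
                   ann$junctions$intron_end)
    want <- vapply(seq_len(n), function(i) {
      if (!(recs$motif[i] %in% whitelist) || recs$max_overhang[i] < 15)
        return("rejected")
      k <- if (recs$strand[i] == "*")
        paste(recs$chrom[i], recs$intron_start[i], recs$intron_end[i]) else
        paste(recs$chrom[i], recs$intron_start[i], recs$intron_end[i],
              recs$strand[i])
      pool_keys <- if (recs$strand[i] == "*") key_u else key
      if (k %in% pool_keys) "annotated" else "unannotated"
    }, character(1))
    expect_identical(got, want)
  }
})

test_that("unannotated and annotated read percentages are complementary", {
  ann <- toy_ann()
  recs <- data.frame(
    chrom = "chrI",
    intron_start = c(201L, 601L, 205L, 210L),
    intron_end = c(400L, 850L, 408L, 413L),
    strand = "+",
    motif = c("GT/AG", "GT/AG", "GT/AG", "AA/TT"),
    unique_reads = c(50L, 30L, 20L, 999L),
    max_overhang = c(20L, 20L, 20L, 20L),
    stringsAsFactors = FALSE
  )
  expect_equal(pct_unannotated_junction_reads(recs, ann), 20)  # 20 of 100
  all_ann <- recs[1:2, ]
  expect_equal(pct_unannotated_junction_reads(all_ann, ann), 0)
  only_rej <- recs[4, ]
  expect_error(pct_unannotated_junction_reads(only_rej, ann),
               class = "zero_denominator")
})

test_that("base territory matches a per-base oracle on random annotations", {
  set.seed(77)
  for (case in 1:100) {
    ann <- random_annotation(n_genes = 2)
    ex <- ann$exons
    # random 40-nt single-block reads across the locus, some intergenic
    n <- 40L
    start <- sample(1:9000, n, replace = TRUE)
    reads <- data.frame(chrom = "chrI", start = start, end = start + 39L)
    got <- base_territory(reads, ann)
    exon_pos <- unlist(Map(seq.int, ex$start, ex$end))
    body <- do.call(rbind, lapply(split(ex, ex$gene_id), function(g)
      c(min(g$start), max(g$end))))
    gene_pos <- unlist(apply(body, 1, function(b) seq.int(b[1], b[2]),
                             simplify = FALSE))
    pos <- unlist(Map(seq.int, reads$start, reads$end))
    exonic <- sum(pos %in% exon_pos)
    genic <- sum(pos %in% gene_pos)
    want <- c(exonic = 100 * exonic / length(pos),
              intronic = 100 * (genic - exonic) / length(pos),
              intergenic = 100 * (length(pos) - genic) / length(pos))
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(sum(got), 100, tolerance = 1e-12)
  }
})

test_that("fully exonic and fully intronic reads give the printed percentages", {
  ann <- toy_ann()
  exonic9 <- data.frame(chrom = "chrI", start = rep(1L, 9), end = rep(100L, 9))
  intron1 <- data.frame(chrom = "chrI", start = 251L, end = 350L)
  expect_equal(pct_intronic_bases(exonic9, ann), 0)
  expect_equal(pct_intronic_bases(rbind(exonic9, intron1), ann), 10)
})

test_that("PSI matches its closed form and stays within bounds", {
  expect_equal(compute_psi(0, 0, 5), 0)
  expect_equal(compute_psi(3, 1, 0), 1)
  expect_equal(compute_psi(10, 0, 5), 0.5)
  expect_warning(expect_true(is.na(compute_psi(0, 0, 0))), "zero-coverage")
  set.seed(5)
  j <- matrix(sample(0:200, 3 * 1e4, replace = TRUE), ncol = 3)
  j <- j[rowSums(j) > 0, ]
  psi <- compute_psi(j[, 1], j[, 2], j[, 3])
  expect_true(all(psi >= 0 & psi <= 1))
  # monotone: more inclusion reads never lower PSI, more skips never raise it
  expect_true(all(compute_psi(j[, 1] + 1, j[, 2], j[, 3]) >= psi))
  expect_true(all(compute_psi(j[, 1], j[, 2] + 1, j[, 3]) >= psi))
  expect_true(all(compute_psi(j[, 1], j[, 2], j[, 3] + 1) <= psi))
})

test_that("reversibility calls follow the sign-and-magnitude rule", {
  calls <- classify_reversibility(
    psi_young = c(0.3, 0.3, 0.3, 0.3),
    psi_old = c(0.6, 0.32, 0.6, 0.6),
    psi_old_treated = c(0.35, 0.31, 0.75, 0.5),
    coverage = c(100, 100, 100, 5)
  )
  expect_equal(as.character(calls$call),
               c("age_changed_reversed",   # drug undoes >= half the shift
                 "unchanged",              # |delta_age| below threshold
                 "age_changed_not_reversed", # drug pushes further from young
                 "low_coverage"))
  # downward age shift reversed by an upward drug shift
  down <- classify_reversibility(0.8, 0.5, 0.7)
  expect_equal(as.character(down$call), "age_changed_reversed")
})

test_that("volcano filter applies strict thresholds", {
  p <- c(0.04, 0.04, 0.05, 0.01)
  lfc <- c(1.5, 1.0, 2.0, -1.2)
  expect_equal(volcano_filter(p, lfc), c(TRUE, FALSE, FALSE, TRUE))
})
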