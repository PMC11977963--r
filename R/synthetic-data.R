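#' Ground truth for simulated splicing-reporter images
#'
#' Describes one imaging condition of the dual-fluorescent splicing reporter:
#' a worm intestine expressing GFP (exon inclusion readout) and mCherry
#' (exon skipping readout) over a dark background. The truth record carries
#' the per-channel signal levels, the common additive background, sensor
#' noise, and the mask geometry, so downstream quantification can be checked
#' against `true_ratio = true_gfp_level / true_mcherry_level`.
#'
#' @param true_gfp_level in-mask GFP signal above background (AU).
#' @param true_mcherry_level in-mask mCherry signal above background (AU).
#' @param background_level additive background common to both channels (AU).
#' @param noise_sd standard deviation of i.i.d. Gaussian sensor noise (AU).
#' @param image_shape integer vector `c(rows, cols)` in pixels.
#' @param mask_fraction fraction of the frame covered by the intestine mask,
#'   strictly between 0 and 1.
#' @return an object of class `reporter_truth`.
#' @export
reporter_truth <- function(true_gfp_level = 100, true_mcherry_level = 50,
                           background_level = 10, noise_sd = 5,
                           image_shape = c(128L, 128L),
                           mask_fraction = 0.25) {
  stopifnot(
    is_number(true_gfp_level), true_gfp_level > 0,
    is_number(true_mcherry_level), true_mcherry_level > 0,
    is_number(background_level), background_level >= 0,
    is_number(noise_sd), noise_sd >= 0,
    length(image_shape) == 2L, all(image_shape >= 8),
    is_number(mask_fraction), mask_fraction > 0, mask_fraction < 1
  )
  structure(list(
    true_gfp_level = true_gfp_level,
    true_mcherry_level = true_mcherry_level,
    true_ratio = true_gfp_level / true_mcherry_level,
    background_level = background_level,
    noise_sd = noise_sd,
    image_shape = as.integer(image_shape),
    mask_fraction = mask_fraction
  ), class = "reporter_truth")
}

#' Elongated elliptical intestine mask
#'
#' The intestine is modelled as an axis-aligned ellipse, elongated along the
#' image columns, whose pixel area approximates `mask_fraction` of the frame.
#'
#' @param shape `c(rows, cols)` in pixels.
#' @param mask_fraction target in-mask fraction of the frame.
#' @return logical matrix of dimension `shape`.
#' @export
ellipse_mask <- function(shape, mask_fraction) {
  nr <- shape[1]; nc <- shape[2]
  if (nr <= 0 || nc <= 0) abort_ss("image dimensions must be positive", "bad_image_shape")
  if (mask_fraction <= 0 || mask_fraction >= 1)
    abort_ss("mask_fraction must lie strictly in (0, 1)", "bad_mask_fraction")
  rx <- 0.45 * nc
  ry <- mask_fraction * nr * nc / (pi * rx)
  if (ry > 0.48 * nr) {             # very large fractions: widen instead
    ry <- 0.48 * nr
    rx <- mask_fraction * nr * nc / (pi * ry)
  }
  if (rx > 0.5 * nc)
    abort_ss("mask_fraction too large for an in-frame ellipse", "bad_mask_fraction")
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask <- ((rows - cy) / ry)^2 + ((cols - cx) / rx)^2 <= 1
  if (!any(mask)) abort_ss("mask_fraction produced an empty mask", "empty_mask")
  mask
}

#' Simulate two-channel reporter images with known ratio ground truth
#'
#' Each worm is an elliptical intestine over a uniform background: per-channel
#' intensity is `background_level` outside the mask and
#' `background_level + channel level` inside, plus i.i.d. Gaussian noise
#' (sd `noise_sd`) clipped at zero. Identical `(truth, n_worms, seed)` calls
#' are bit-identical.
#'
#' @param truth a [reporter_truth()] record.
#' @param n_worms number of image pairs to generate.
#' @param seed integer seed.
#' @return list of [reporter_image_pair()] objects; the truth record is
#'   attached as attribute `"truth"`.
#' @export
gen_reporter_images <- function(truth, n_worms, seed = 1L) {
  stopifnot(inherits(truth, "reporter_truth"), is_count(n_worms))
  mask <- ellipse_mask(truth$image_shape, truth$mask_fraction)
  nr <- truth$image_shape[1]; nc <- truth$image_shape[2]
  pairs <- with_seed(seed, lapply(seq_len(n_worms), function(i) {
    gfp <- matrix(truth$background_level, nr, nc)
    mch <- matrix(truth$background_level, nr, nc)
    gfp[mask] <- gfp[mask] + truth$true_gfp_level
    mch[mask] <- mch[mask] + truth$true_mcherry_level
    if (truth$noise_sd > 0) {
      gfp <- gfp + matrix(stats::rnorm(nr * nc, 0, truth$noise_sd), nr, nc)
      mch <- mch + matrix(stats::rnorm(nr * nc, 0, truth$noise_sd), nr, nc)
    }
    gfp[gfp < 0] <- 0
    mch[mch < 0] <- 0
    reporter_image_pair(gfp, mch, mask, worm_id = sprintf("worm_%03d", i))
  }))
  attr(pairs, "truth") <- truth
  pairs
}

#' Ground truth for a simulated splice-junction dataset
#'
#' @param true_psi per-event percent-spliced-in of the cassette exon, a
#'   fraction in `[0, 1]`; recycled across genes.
#' @param unannotated_fraction fraction of junction reads placed on junctions
#'   absent from the annotation.
#' @param intronic_fraction fraction of aligned read bases placed inside
#'   annotated introns (the rest is exonic).
#' @param read_length read length in nt (>= 30).
#' @param sequencing_depth total junction reads in the dataset (also used as
#'   the number of placed genomic reads for base-territory accounting).
#' @param rejected_fraction extra junction reads (relative to
#'   `sequencing_depth`) emitted on junctions that fail the motif/overhang
#'   filters, exercising the rejection path without disturbing the
#'   annotated/unannotated bookkeeping.
#' @return an object of class `junction_truth`.
#' @export
junction_truth <- function(true_psi = 0.5, unannotated_fraction = 0.1,
                           intronic_fraction = 0.05, read_length = 100L,
                           sequencing_depth = 50000L,
                           rejected_fraction = 0.02) {
  stopifnot(
    all(true_psi >= 0 & true_psi <= 1),
    is_number(unannotated_fraction), unannotated_fraction >= 0, unannotated_fraction <= 1,
    is_number(intronic_fraction), intronic_fraction >= 0, intronic_fraction <= 1,
    is_count(read_length, 30), is_count(sequencing_depth),
    is_number(rejected_fraction), rejected_fraction >= 0
  )
  structure(list(
    true_psi = true_psi,
    unannotated_fraction = unannotated_fraction,
    intronic_fraction = intronic_fraction,
    read_length = as.integer(read_length),
    sequencing_depth = as.integer(sequencing_depth),
    rejected_fraction = rejected_fraction
  ), class = "junction_truth")
}

# Toy gene model used by the generator: three 200-nt exons separated by
# introns of 200 and 250 nt, with an inclusion transcript (exons 1-2-3) and a
# skipping transcript (exons 1,3). All event junctions are therefore
# annotated; unannotated junctions are shifted copies of intron 1.
toy_gene_exons <- function(g) {
  o <- (g - 1L) * 10000L + 1L
  data.frame(
    chrom = "chrI",
    start = c(o, o + 400L, o + 850L, o, o + 850L),
    end = c(o + 199L, o + 599L, o + 1049L, o + 199L, o + 1049L),
    strand = "+",
    transcript_id = paste0("g", g, c(".t1", ".t1", ".t1", ".t2", ".t2")),
    gene_id = paste0("g", g),
    stringsAsFactors = FALSE
  )
}

#' Simulate a splice-junction dataset with known PSI and territory fractions
#'
#' Builds `n_genes` toy cassette-exon gene models, then draws junction reads
#' so that each event's inclusion reads (J1 + J2) versus skipping reads (J3)
#' are binomial with inclusion probability `2*psi / (1 + psi)`, which makes
#' the plug-in estimator `PSI = (J1+J2)/(J1+J2+2*J3)` consistent for
#' `true_psi`. A binomial fraction of all junction reads is diverted to
#' unannotated (shifted) junctions, and single-block genomic reads are placed
#' fully inside exons or introns at `intronic_fraction` for base-territory
#' accounting.
#'
#' @param truth a [junction_truth()] record.
#' @param n_genes number of cassette-exon genes (one event per gene).
#' @param seed integer seed.
#' @return list with elements `annotation` ([gene_annotation()]),
#'   `junctions` (junction-record data frame), `events` (J1/J2/J3 counts per
#'   event), `reads` (read placements), and `truth`.
#' @export
gen_junction_dataset <- function(truth, n_genes = 20L, seed = 1L) {
  stopifnot(inherits(truth, "junction_truth"), is_count(n_genes))
  psi <- rep_len(truth$true_psi, n_genes)
  ann <- gene_annotation(do.call(rbind, lapply(seq_len(n_genes), toy_gene_exons)))
  N <- truth$sequencing_depth
  L <- truth$read_length
  with_seed(seed, {
    n_unann <- stats::rbinom(1L, N, truth$unannotated_fraction)
    n_ann <- N - n_unann
    if (n_ann < n_genes && truth$unannotated_fraction < 1)
      abort_ss("sequencing_depth too low to place reads on every event", "depth_too_low")
    depth <- as.vector(stats::rmultinom(1L, n_ann, rep(1, n_genes)))
    q <- 2 * psi / (1 + psi)               # P(read is an inclusion-junction read)
    n_incl <- stats::rbinom(n_genes, depth, q)
    j1 <- stats::rbinom(n_genes, n_incl, 0.5)
    j2 <- n_incl - j1
    j3 <- depth - n_incl
    events <- data.frame(
      event_id = paste0("g", seq_len(n_genes), ".cassette"),
      gene_id = paste0("g", seq_len(n_genes)),
      J1 = j1, J2 = j2, J3 = j3,
      true_psi = psi,
      stringsAsFactors = FALSE
    )
    o <- (seq_len(n_genes) - 1L) * 10000L + 1L
    event_juncs <- data.frame(
      chrom = "chrI",
      intron_start = c(o + 200L, o + 600L, o + 200L),
      intron_end = c(o + 399L, o + 849L, o + 849L),
      strand = "+",
      motif = "GT/AG",
      unique_reads = c(j1, j2, j3),
      max_overhang = pmin(50L, L - 1L),
      stringsAsFactors = FALSE
    )
    # unannotated junctions: intron 1 shifted by +5 nt, canonical motif
    unann_gene <- if (n_unann > 0)
      as.vector(stats::rmultinom(1L, n_unann, rep(1, n_genes))) else integer(n_genes)
    unann_juncs <- data.frame(
      chrom = "chrI",
      intron_start = o + 205L,
      intron_end = o + 404L,
      strand = "+",
      motif = "GT/AG",
      unique_reads = unann_gene,
      max_overhang = pmin(50L, L - 1L),
      stringsAsFactors = FALSE
    )
    # junctions that fail filters: short overhang and non-canonical motif
    n_rej <- round(truth$rejected_fraction * N)
    rej_juncs <- if (n_rej > 0) data.frame(
      chrom = "chrI",
      intron_start = c(o[1] + 210L, o[1] + 215L),
      intron_end = c(o[1] + 409L, o[1] + 414L),
      strand = "+",
      motif = c("GT/AG", "AA/TT"),
      unique_reads = c(ceiling(n_rej / 2), floor(n_rej / 2)),
      max_overhang = c(10L, pmin(50L, L - 1L)),
      stringsAsFactors = FALSE
    ) else NULL
    junctions <- rbind(event_juncs, unann_juncs[unann_juncs$unique_reads > 0, ], rej_juncs)
    rownames(junctions) <- NULL
    # read placements fully inside exon 1 or intron 1 of a random gene
    in_intron <- stats::runif(N) < truth$intronic_fraction
    gene_of <- sample.int(n_genes, N, replace = TRUE)
    og <- (gene_of - 1L) * 10000L + 1L
    start <- ifelse(
      in_intron,
      og + 200L + floor(stats::runif(N) * (200L - L + 1L)),
      og + floor(stats::runif(N) * (200L - L + 1L))
    )
    reads <- data.frame(
      chrom = "chrI",
      start = as.integer(start),
      end = as.integer(start + L - 1L),
      read_id = sprintf("r%06d", seq_len(N)),
      stringsAsFactors = FALSE
    )
    list(annotation = ann, junctions = junctions, events = events,
         reads = reads, truth = truth)
  })
}

#' Ground truth for simulated lifespan cohorts
#'
#' @param control_mean_lifespan mean lifespan of the control arm (days).
#' @param treatment_effect fractional change in mean lifespan of the treated
#'   arm (0.3 = +30 percent).
#' @param censor_rate per-animal probability of leaving the assay without a
#'   death event (crawl-off, bagging, protruding vulva), in `[0, 1)`.
#' @param n_per_arm animals per arm (>= 2).
#' @param hazard_family `"exponential"` or `"weibull"`.
#' @param weibull_shape Weibull shape parameter (only for
#'   `hazard_family = "weibull"`); worm lifespan curves are strongly
#'   rectangularized, so the default is 4.
#' @param round_to_day round observed times up to whole days, emulating daily
#'   scoring (guarantees heavy ties, as in real assays).
#' @return an object of class `survival_truth`.
#' @export
survival_truth <- function(control_mean_lifespan = 20, treatment_effect = 0.3,
                           censor_rate = 0.1, n_per_arm = 80L,
                           hazard_family = c("exponential", "weibull"),
                           weibull_shape = 4, round_to_day = TRUE) {
  hazard_family <- match.arg(hazard_family)
  stopifnot(
    is_number(control_mean_lifespan), control_mean_lifespan > 0,
    is_number(treatment_effect), treatment_effect > -1,
    is_number(censor_rate), censor_rate >= 0, censor_rate < 1,
    is_number(weibull_shape), weibull_shape > 0
  )
  if (!is_count(n_per_arm, 2)) abort_ss("n_per_arm must be at least 2", "bad_n_per_arm")
  structure(list(
    control_mean_lifespan = control_mean_lifespan,
    treatment_effect = treatment_effect,
    censor_rate = censor_rate,
    n_per_arm = as.integer(n_per_arm),
    hazard_family = hazard_family,
    weibull_shape = weibull_shape,
    round_to_day = isTRUE(round_to_day)
  ), class = "survival_truth")
}

#' Fate codes used in survival records
#' @return character vector: the death code followed by the censoring codes.
#' @export
survival_fates <- function() {
  c("death", "censored_crawl_off", "censored_bagging",
    "censored_protruding_vulva", "censored_other")
}

#' Simulate a two-arm lifespan cohort
#'
#' Death times are drawn from the chosen hazard family with arm means
#' `control_mean_lifespan` and `control_mean_lifespan * (1 + treatment_effect)`.
#' Each animal is independently censored with probability `censor_rate`; a
#' censored animal leaves the assay at a uniform fraction of its latent death
#' time, with a fate code drawn uniformly among crawl-off, bagging, and
#' protruding vulva.
#'
#' @param truth a [survival_truth()] record.
#' @param seed integer seed.
#' @param groups labels for the two arms.
#' @return data frame with columns `animal_id`, `group`, `time`, `fate`; the
#'   truth record is attached as attribute `"truth"`.
#' @export
gen_survival <- function(truth, seed = 1L, groups = c("control", "treated")) {
  stopifnot(inherits(truth, "survival_truth"), length(groups) == 2L)
  n <- truth$n_per_arm
  means <- c(truth$control_mean_lifespan,
             truth$control_mean_lifespan * (1 + truth$treatment_effect))
  censor_codes <- c("censored_crawl_off", "censored_bagging",
                    "censored_protruding_vulva")
  with_seed(seed, {
    arms <- lapply(1:2, function(a) {
      t_death <- switch(truth$hazard_family,
        exponential = stats::rexp(n, rate = 1 / means[a]),
        weibull = stats::rweibull(n, shape = truth$weibull_shape,
                                  scale = means[a] / gamma(1 + 1 / truth$weibull_shape))
      )
      censored <- stats::runif(n) < truth$censor_rate
      time <- ifelse(censored, stats::runif(n) * t_death, t_death)
      if (truth$round_to_day) time <- ceiling(time)
      time <- pmax(time, if (truth$round_to_day) 1 else .Machine$double.eps)
      fate <- ifelse(censored, sample(censor_codes, n, replace = TRUE), "death")
      data.frame(
        animal_id = sprintf("%s_%04d", groups[a], seq_len(n)),
        group = groups[a], time = time, fate = fate,
        stringsAsFactors = FALSE
      )
    })
    out <- rbind(arms[[1]], arms[[2]])
    attr(out, "truth") <- truth
    out
  })
}

#' Ground truth for a simulated omics matrix with a planted regulon
#'
#' @param n_features number of features (proteins/metabolites).
#' @param n_per_group samples per group (>= 3).
#' @param n_planted size of the planted (truly shifted) feature set.
#' @param effect_log2fc shift added to planted features in the treated group
#'   (log2 units).
#' @param noise_sd within-group standard deviation (log2 units).
#' @param n_decoy_tfs decoy transcription factors with random target sets of
#'   the same size as the planted set.
#' @return an object of class `omics_truth`.
#' @export
omics_truth <- function(n_features = 500L, n_per_group = 6L, n_planted = 25L,
                        effect_log2fc = 2, noise_sd = 0.5, n_decoy_tfs = 10L) {
  stopifnot(
    is_count(n_features), is_count(n_per_group, 3), is_count(n_planted),
    is_number(effect_log2fc), is_number(noise_sd), noise_sd >= 0,
    is_count(n_decoy_tfs, 0)
  )
  if (n_planted > n_features)
    abort_ss("planted set larger than the feature universe", "bad_planted_set")
  structure(list(
    n_features = as.integer(n_features), n_per_group = as.integer(n_per_group),
    n_planted = as.integer(n_planted), effect_log2fc = effect_log2fc,
    noise_sd = noise_sd, n_decoy_tfs = as.integer(n_decoy_tfs)
  ), class = "omics_truth")
}

#' Simulate a features-by-samples log-intensity matrix with a planted regulon
#'
#' Log2 intensities are i.i.d. Gaussian around per-feature baselines; the
#' planted feature set is shifted by `effect_log2fc` in the treated group.
#' The regulon map contains one transcription factor (`TF_planted`) whose
#' target set equals the planted set, plus decoy TFs with random targets.
#'
#' @param truth an [omics_truth()] record.
#' @param seed integer seed.
#' @return list with `matrix` (features x samples, log2 scale), `samples`
#'   (sample sheet with `sample_id`, `group`), `regulon` (named list of
#'   feature-id vectors), `planted_set` (character), and `truth`.
#' @export
gen_omics <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "omics_truth"))
  p <- truth$n_features; m <- truth$n_per_group
  feat <- sprintf("f%04d", seq_len(p))
  samples <- data.frame(
    sample_id = c(sprintf("ctrl_%02d", seq_len(m)), sprintf("trt_%02d", seq_len(m))),
    group = rep(c("control", "treated"), each = m),
    stringsAsFactors = FALSE
  )
  with_seed(seed, {
    baseline <- stats::runif(p, 6, 14)
    mat <- matrix(stats::rnorm(p * 2 * m, mean = baseline, sd = truth$noise_sd),
                  nrow = p, ncol = 2 * m)
    planted <- sort(sample.int(p, truth$n_planted))
    mat[planted, samples$group == "treated"] <-
      mat[planted, samples$group == "treated"] + truth$effect_log2fc
    dimnames(mat) <- list(feat, samples$sample_id)
    regulon <- c(
      list(TF_planted = feat[planted]),
      stats::setNames(
        lapply(seq_len(truth$n_decoy_tfs),
               function(i) feat[sort(sample.int(p, truth$n_planted))]),
        sprintf("TF_decoy_%02d", seq_len(truth$n_decoy_tfs))
      )
    )
    list(matrix = mat, samples = samples, regulon = regulon,
         planted_set = feat[planted], truth = truth)
  })
}

#' Simulate a full multi-round reporter drug screen, image level up
#'
#' Plants a fraction of active compounds that raise the GFP level (and hence
#' the GFP/mCherry ratio) by `effect`, then runs every round of the screen
#' through the image pipeline: generate reporter image pairs per group,
#' quantify each worm by ROI sampling, and collect per-group statistics
#' ready for [call_screen_hits()].
#'
#' @param n_compounds compounds screened.
#' @param active_fraction fraction of compounds that truly raise the ratio.
#' @param effect fractional ratio increase of an active compound (0.4 = +40
#'   percent).
#' @param n_worms worms per group and round.
#' @param n_rounds scored rounds per compound.
#' @param seed integer seed.
#' @param image_shape image size in pixels (small frames keep the screen
#'   fast; the quantification is resolution-independent).
#' @param box_size ROI side in pixels, scaled to the frame.
#' @param noise_sd sensor noise (AU; the default is 10 percent of the
#'   mCherry signal).
#' @return list with `per_round_stats` (input for [call_screen_hits()]) and
#'   `active_compounds` (the planted truth).
#' @export
simulate_reporter_screen <- function(n_compounds = 40L, active_fraction = 0.05,
                                     effect = 0.4, n_worms = 12L,
                                     n_rounds = 3L, seed = 1L,
                                     image_shape = c(64L, 64L),
                                     box_size = 16L, noise_sd = 5) {
  stopifnot(is_count(n_compounds), is_count(n_worms), is_count(n_rounds),
            active_fraction >= 0, active_fraction <= 1)
  n_active <- round(active_fraction * n_compounds)
  with_seed(seed, {
    actives <- sort(sample.int(n_compounds, n_active))
    compound_ids <- sprintf("cmpd_%03d", seq_len(n_compounds))
    quantify_group <- function(truth, seed_off) {
      pairs <- gen_reporter_images(truth, n_worms,
                                   seed = sample.int(2^30, 1))
      quants <- lapply(seq_along(pairs), function(i)
        quantify_worm(pairs[[i]], box_size = box_size,
                      seed = sample.int(2^30, 1)))
      group_ratio_stats(quants, "group")
    }
    per_round <- lapply(seq_len(n_compounds), function(ci) {
      is_active <- ci %in% actives
      lapply(seq_len(n_rounds), function(r) {
        ctrl_truth <- reporter_truth(100, 50, 10, noise_sd, image_shape, 0.25)
        trt_gfp <- if (is_active) 100 * (1 + effect) else 100
        trt_truth <- reporter_truth(trt_gfp, 50, 10, noise_sd, image_shape,
                                    0.25)
        list(treated = quantify_group(trt_truth),
             control = quantify_group(ctrl_truth))
      })
    })
    names(per_round) <- compound_ids
    list(per_round_stats = per_round,
         active_compounds = compound_ids[actives])
  })
}

#' Simulate a logistic OD600 growth curve
#'
#' Hourly OD600 readings following a logistic trajectory with a lag phase,
#' plus additive Gaussian noise clipped at zero. As `rate -> 0` the curve is
#' flat at `initial_od`; for large times it plateaus at `carrying_capacity`.
#'
#' @param carrying_capacity plateau OD600 (> 0).
#' @param rate logistic growth rate per hour (> 0).
#' @param lag lag phase in hours before growth starts.
#' @param n_hours number of hourly samples after time 0 (>= 2).
#' @param noise_sd additive noise sd in OD units.
#' @param seed integer seed.
#' @param initial_od inoculum OD600.
#' @return data frame with columns `time` (hours) and `od600`.
#' @export
gen_growth_curve <- function(carrying_capacity = 1.2, rate = 0.5, lag = 2,
                             n_hours = 24L, noise_sd = 0.01, seed = 1L,
                             initial_od = 0.05) {
  if (carrying_capacity <= 0)
    abort_ss("carrying capacity must be positive", "bad_carrying_capacity")
  stopifnot(is_number(rate), rate > 0, is_count(n_hours, 2),
            is_number(noise_sd), noise_sd >= 0,
            is_number(initial_od), initial_od > 0,
            initial_od < carrying_capacity)
  t <- 0:n_hours
  te <- pmax(t - lag, 0)
  K <- carrying_capacity; n0 <- initial_od
  od <- K * n0 * exp(rate * te) / (K + n0 * (exp(rate * te) - 1))
  if (noise_sd > 0)
    od <- with_seed(seed, od + stats::rnorm(length(od), 0, noise_sd))
  od[od < 0] <- 0
  data.frame(time = t, od600 = od)
}
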