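#' Per-feature differential statistics for a two-group omics matrix
#'
#' For each feature, `log2_fold_change = mean(treated) - mean(control)` on
#' the log2 scale and a two-sided unpaired Student's t-test (equal
#' variances). Features with zero variance in both groups get an `NA`
#' p-value and a warning.
#'
#' @param mat numeric matrix, features x samples, log2 scale.
#' @param groups character vector over columns with values `"control"` and
#'   `"treated"` (>= 2 samples each).
#' @return data frame with `feature`, `log2_fold_change`, `p_value`.
#' @export
diff_stats <- function(mat, groups) {
  stopifnot(is.matrix(mat), ncol(mat) == length(groups),
            all(groups %in% c("control", "treated")),
            sum(groups == "control") >= 2L, sum(groups == "treated") >= 2L)
  ctrl <- mat[, groups == "control", drop = FALSE]
  trt <- mat[, groups == "treated", drop = FALSE]
  lfc <- rowMeans(trt) - rowMeans(ctrl)
  n1 <- ncol(trt); n2 <- ncol(ctrl)
  v1 <- apply(trt, 1L, stats::var); v2 <- apply(ctrl, 1L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- lfc / se
  p <- 2 * stats::pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)
  p[se == 0 & lfc == 0] <- 1          # identical constant groups: no evidence
  if (any(se == 0 & lfc != 0)) {
    warning("feature(s) with zero within-group variance and nonzero shift: p undefined")
    p[se == 0 & lfc != 0] <- NA_real_
  }
  data.frame(
    feature = if (is.null(rownames(mat))) sprintf("f%04d", seq_len(nrow(mat)))
              else rownames(mat),
    log2_fold_change = unname(lfc), p_value = unname(p),
    stringsAsFactors = FALSE
  )
}

#' Hypergeometric set enrichment over a regulon (or pathway) map
#'
#' For each transcription factor, the one-sided hypergeometric tail
#' `P(X >= overlap)` with the scorable universe as population, the TF's
#' target set as successes, and the flagged features as draws;
#' Benjamini-Hochberg correction across TFs.
#'
#' @param flagged character vector of flagged feature ids (must lie in the
#'   universe).
#' @param regulon named list: TF id -> character vector of target feature
#'   ids (each a subset of the universe).
#' @param universe character vector of all scorable feature ids.
#' @return data frame with one row per TF: `tf`, `overlap`, `set_size`,
#'   `flagged_size`, `universe_size`, `p`, `q`, sorted by `p`.
#' @export
set_enrichment <- function(flagged, regulon, universe) {
  stopifnot(is.list(regulon), length(regulon) >= 1L, !is.null(names(regulon)))
  universe <- unique(universe)
  if (length(universe) == 0L) abort_ss("empty universe", "empty_universe")
  flagged <- unique(flagged)
  if (!all(flagged %in% universe))
    abort_ss("flagged features must lie in the universe", "flagged_outside_universe")
  if (!all(unlist(regulon) %in% universe))
    abort_ss("regulon targets must lie in the universe", "targets_outside_universe")
  N <- length(universe); k <- length(flagged)
  res <- do.call(rbind, lapply(names(regulon), function(tf) {
    targets <- unique(regulon[[tf]])
    m <- length(targets)
    ov <- length(intersect(targets, flagged))
    p <- stats::phyper(ov - 1L, m, N - m, k, lower.tail = FALSE)
    data.frame(tf = tf, overlap = ov, set_size = m, flagged_size = k,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p, res$tf), , drop = FALSE]
}

# NIPALS PLS1 on the centred class indicator; returns per-component weights
# (orthonormal in the deflated spaces), scores, and y-loadings.
pls1_fit <- function(X, y, n_components) {
  W <- matrix(0, ncol(X), n_components)
  TT <- matrix(0, nrow(X), n_components)
  Q <- numeric(n_components)
  Xa <- X; ya <- y
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      abort_ss("degenerate response: no covariance left to model",
               "degenerate_response")
    w <- w / nw
    t_a <- drop(Xa %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xa, t_a)) / tt
    q_a <- sum(ya * t_a) / tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - q_a * t_a
    W[, a] <- w; TT[, a] <- t_a; Q[a] <- q_a
  }
  list(W = W, scores = TT, q = Q)
}

#' PLS-DA variable-importance-in-projection (VIP) scores
#'
#' Fits a two-class partial-least-squares discriminant model (NIPALS, on the
#' centred/scaled matrix with a centred class indicator) and computes the
#' standard VIP score per feature:
#' `VIP_j = sqrt( p * sum_a(w_ja^2 * SSY_a) / sum_a(SSY_a) )`
#' with `SSY_a = q_a^2 * t_a' t_a` the y-variance explained by component
#' `a`. Because each weight vector is unit length, `mean(VIP^2) == 1` on
#' every fit. Following the screening rule for metabolomics, a feature is
#' `significant` when `VIP > 1` and its per-feature t-test `p < 0.05`.
#'
#' @param mat numeric matrix, features x samples, log2 scale.
#' @param groups `"control"`/`"treated"` labels over columns.
#' @param n_components number of PLS components (>= 1, at most
#'   `min(n_samples - 1, n_features)`).
#' @param scale autoscale features to unit variance before fitting
#'   (standard for metabolomics), default `TRUE`.
#' @param alpha p-value threshold entering the significance rule.
#' @return data frame with `feature`, `vip`, `p_value`, `significant`,
#'   sorted as the input features.
#' @export
plsda_vip <- function(mat, groups, n_components = 2L, scale = TRUE,
                      alpha = 0.05) {
  stopifnot(is.matrix(mat), ncol(mat) == length(groups),
            all(groups %in% c("control", "treated")))
  n <- ncol(mat); p <- nrow(mat)
  if (!is_count(n_components) || n_components > min(n - 1L, p))
    abort_ss("n_components must be in 1..min(n_samples - 1, n_features)",
             "bad_components")
  X <- scale(t(mat), center = TRUE, scale = scale)
  X[is.nan(X)] <- 0                    # constant features carry no weight
  y <- ifelse(groups == "treated", 1, 0)
  y <- y - mean(y)
  if (stats::var(y) == 0)
    abort_ss("degenerate response: only one class present", "degenerate_response")
  fit <- pls1_fit(X, y, n_components)
  ssy <- fit$q^2 * colSums(fit$scores^2)
  vip <- sqrt(p * drop(fit$W^2 %*% ssy) / sum(ssy))
  ds <- diff_stats(mat, groups)
  data.frame(
    feature = ds$feature, vip = unname(vip), p_value = ds$p_value,
    significant = !is.na(ds$p_value) & vip > 1 & ds$p_value < alpha,
    stringsAsFactors = FALSE
  )
}
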