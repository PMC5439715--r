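#' Quantile-normalize an intensity matrix
#'
#' Forces every sample (column) to share the same empirical distribution: the
#' value at rank r becomes the mean across samples of each sample's rank-r
#' value, with ties sharing the mean of their tied ranks. Delegates to
#' [limma::normalizeQuantiles()], the standard implementation for array
#' intensity data. Input intensities must be positive (raw scale); apply
#' `log2` afterwards, matching the usual normalize-then-transform order.
#'
#' @param matrix Numeric genes x samples matrix, positive entries, >= 2
#'   columns.
#' @return Matrix of the same shape, quantile-normalized.
#' @export
quantile_normalize <- function(matrix) {
  if (!is.matrix(matrix) || ncol(matrix) < 2) {
    stop("need a matrix with >= 2 samples", call. = FALSE)
  }
  if (any(matrix <= 0)) {
    stop("intensities must be positive before log transformation",
         call. = FALSE)
  }
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Collapse probes to genes
#'
#' Keeps, for each gene, the probe with the highest mean intensity — the
#' usual max-mean collapse rule for bead-array data. Probes missing from the
#' map are dropped.
#'
#' @param matrix Probes x samples matrix with probe rownames.
#' @param probe_map Data frame with columns `probe`, `gene`.
#' @return Genes x samples matrix.
#' @export
collapse_probes <- function(matrix, probe_map) {
  probe_map <- as.data.frame(probe_map)
  if (nrow(probe_map) == 0) stop("empty probe map", call. = FALSE)
  stopifnot(all(c("probe", "gene") %in% names(probe_map)),
            !is.null(rownames(matrix)))
  pm <- probe_map[probe_map$probe %in% rownames(matrix), , drop = FALSE]
  if (nrow(pm) == 0) stop("probe map matches no rows", call. = FALSE)
  means <- rowMeans(matrix)[pm$probe]
  pick <- dplyr::tibble(probe = pm$probe, gene = pm$gene, mean = means) |>
    dplyr::group_by(.data$gene) |>
    dplyr::slice_max(.data$mean, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  out <- matrix[pick$probe, , drop = FALSE]
  rownames(out) <- pick$gene
  out[order(rownames(out)), , drop = FALSE]
}

#' Per-gene, per-batch mean centering
#'
#' Location-only batch adjustment: within each gene, every batch's mean is
#' shifted to the gene's grand mean, so within-batch contrasts are untouched
#' while additive batch offsets are removed exactly. This is a deliberately
#' simple location adjustment (no scale or empirical-Bayes shrinkage);
#' batches with a single sample are passed through with a warning because
#' their offset is confounded with the sample effect.
#'
#' @param matrix Genes x samples matrix (log2 scale).
#' @param batches Character/factor vector, one batch label per column.
#' @return Adjusted matrix of the same shape.
#' @export
batch_mean_center <- function(matrix, batches) {
  stopifnot(is.matrix(matrix), length(batches) == ncol(matrix))
  batches <- as.character(batches)
  tab <- table(batches)
  single <- names(tab)[tab < 2]
  if (length(single) > 0) {
    warning("singleton batch(es) passed through unadjusted: ",
            paste(single, collapse = ", "))
  }
  grand <- rowMeans(matrix)
  out <- matrix
  for (b in names(tab)[tab >= 2]) {
    idx <- which(batches == b)
    out[, idx] <- matrix[, idx] - rowMeans(matrix[, idx, drop = FALSE]) + grand
  }
  out
}

#' Holm step-down multiple-testing adjustment
#'
#' Step-down adjusted p-values controlling the family-wise error rate; a thin
#' validating wrapper over [stats::p.adjust()] with `method = "holm"` (or
#' `"BH"` for a Benjamini-Hochberg sensitivity analysis).
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param method `"holm"` (default) or `"BH"`.
#' @return Adjusted p-values, elementwise >= the input, capped at 1.
#' @export
holm_adjust <- function(p, method = c("holm", "BH")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Differential-expression screen across dose-by-day groups
#'
#' Runs, per gene, a one-way ANOVA across the dose-by-day groups of a study,
#' adjusts p-values by the Holm step-down procedure, computes per-group log2
#' fold-changes against the matched unirradiated control, and flags genes
#' significant when the adjusted p-value is below `q` and the maximal
#' absolute fold-change exceeds `fc_threshold` (linear scale, so the default
#' 1.5 means |log2 FC| >= log2 1.5).
#'
#' The fold-change reference for an irradiated (dose, day) group is the 0 Gy
#' group of the same day (`fc_reference = "same_day"`); when a day lacks a
#' 0 Gy group, or with `fc_reference = "baseline"`, the earliest-day 0 Gy
#' group is used instead.
#'
#' The F statistic is computed by vectorised matrix algebra across all genes
#' at once (identical to per-gene [stats::aov()], which the tests verify).
#' Genes with zero variance everywhere get p = 1.
#'
#' @param study An `expression_study` (see [gen_expression_study()]) whose
#'   matrix is on the log2 scale (use [de_pipeline()] for raw intensities),
#'   or a plain log2 matrix plus `samples`.
#' @param q Family-wise error bound for the Holm-adjusted p (default 0.10).
#' @param fc_threshold Linear fold-change cutoff (default 1.5).
#' @param samples Sample sheet when `study` is a bare matrix.
#' @param fc_reference `"same_day"` or `"baseline"`.
#' @param adjust `"holm"` or `"BH"`.
#' @return A tibble (class `de_result`): `gene`, `f_statistic`, `p_value`,
#'   `p_adjusted`, `max_log2_fc`, `significant`, ordered by `p_value`.
#' @export
anova_screen <- function(study, q = 0.10, fc_threshold = 1.5, samples = NULL,
                         fc_reference = c("same_day", "baseline"),
                         adjust = c("holm", "BH")) {
  fc_reference <- match.arg(fc_reference)
  adjust <- match.arg(adjust)
  if (inherits(study, "expression_study")) {
    m <- study$matrix
    samples <- study$samples
  } else {
    m <- study
    if (is.null(samples)) stop("`samples` required with a bare matrix",
                               call. = FALSE)
  }
  stopifnot(is.matrix(m), nrow(samples) == ncol(m))
  group <- factor(paste(samples$dose_gy, samples$day, sep = ":"))
  tab <- table(group)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with >= 2 replicates each", call. = FALSE)
  }

  k <- length(tab)
  n <- ncol(m)
  gm <- rowMeans(m)
  # group means per gene: genes x groups
  gmeans <- vapply(levels(group),
                   function(g) rowMeans(m[, group == g, drop = FALSE]),
                   numeric(nrow(m)))
  ssb <- drop((gmeans - gm)^2 %*% as.numeric(tab))
  sst <- rowSums((m - gm)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  degenerate <- sst < .Machine$double.eps * pmax(1, abs(gm))^2
  p[degenerate] <- 1
  f[degenerate] <- 0

  # fold-changes vs matched 0 Gy control
  lev <- do.call(rbind, strsplit(levels(group), ":", fixed = TRUE))
  dose <- as.numeric(lev[, 1]); day <- as.numeric(lev[, 2])
  ctrl_days <- day[dose == 0]
  if (length(ctrl_days) == 0) stop("no 0 Gy control groups", call. = FALSE)
  base_day <- min(ctrl_days)
  ref_idx <- vapply(seq_len(k), function(i) {
    if (fc_reference == "same_day" && any(dose == 0 & day == day[i])) {
      which(dose == 0 & day == day[i])
    } else {
      which(dose == 0 & day == base_day)
    }
  }, integer(1))
  irr <- which(dose > 0)
  lfc <- gmeans[, irr, drop = FALSE] - gmeans[, ref_idx[irr], drop = FALSE]
  max_lfc <- lfc[cbind(seq_len(nrow(m)), max.col(abs(lfc)))]

  padj <- holm_adjust(p, method = adjust)
  out <- dplyr::tibble(
    gene = rownames(m) %||% sprintf("gene_%05d", seq_len(nrow(m))),
    f_statistic = unname(f),
    p_value = unname(p),
    p_adjusted = unname(padj),
    max_log2_fc = unname(max_lfc),
    significant = padj < q & abs(max_lfc) > log2(fc_threshold)
  ) |>
    dplyr::arrange(.data$p_value)
  class(out) <- c("de_result", class(out))
  attr(out, "q") <- q
  attr(out, "fc_threshold") <- fc_threshold
  out
}

#' Full expression pre-processing and screening pipeline
#'
#' Applies the canonical order for array intensities: quantile normalization
#' (optionally separately for short-term, days <= `split_day`, and long-term
#' samples, matching designs where the two were hybridised in separate
#' runs), log2 transform, optional probe collapse, per-batch mean centering
#' of the short-term samples, then [anova_screen()].
#'
#' @param study `expression_study` with raw (positive) intensities.
#' @param probe_map Optional probe-to-gene map for [collapse_probes()].
#' @param split_normalization Normalize short- and long-term samples
#'   separately (default TRUE).
#' @param split_day Days greater than this are "long-term" (default 10).
#' @param batch_adjust Mean-center batches within the short-term samples
#'   (default TRUE).
#' @param ... Passed to [anova_screen()].
#' @return A `de_result` tibble; the processed log2 matrix is attached as
#'   attribute `"log2_matrix"`.
#' @export
de_pipeline <- function(study, probe_map = NULL, split_normalization = TRUE,
                        split_day = 10, batch_adjust = TRUE, ...) {
  stopifnot(inherits(study, "expression_study"))
  m <- study$matrix
  s <- study$samples
  short <- s$day <= split_day
  if (split_normalization && any(short) && any(!short)) {
    m[, short] <- quantile_normalize(m[, short, drop = FALSE])
    m[, !short] <- quantile_normalize(m[, !short, drop = FALSE])
  } else {
    m <- quantile_normalize(m)
  }
  m <- log2(m)
  if (!is.null(probe_map)) m <- collapse_probes(m, probe_map)
  if (batch_adjust && any(short) &&
      length(unique(s$batch[short])) > 1) {
    m[, short] <- batch_mean_center(m[, short, drop = FALSE], s$batch[short])
  }
  res <- anova_screen(m, samples = s, ...)
  attr(res, "log2_matrix") <- m
  res
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per well, delta-Ct is the target Ct minus the housekeeping Ct; per
#' condition, delta-delta-Ct is the mean delta-Ct minus the control
#' condition's mean delta-Ct, and the reported expression ratio is
#' `2^(-ddCt)` relative to the control. Invariant to any constant added to
#' all Ct values.
#'
#' @param records Tibble as from [gen_qpcr()]: columns `condition`,
#'   `ct_target`, `ct_housekeeping`, and either `is_control` or a
#'   `control_condition` argument.
#' @param control_condition Label of the control; default taken from the
#'   `is_control` column.
#' @return Tibble: `condition`, `n_wells`, `delta_ct`, `delta_delta_ct`,
#'   `fold_change` (control row has fold change 1).
#' @export
ddct_fold_change <- function(records, control_condition = NULL) {
  records <- as.data.frame(records)
  stopifnot(all(c("condition", "ct_target", "ct_housekeeping")
                %in% names(records)))
  if (any(!is.finite(records$ct_target)) ||
      any(!is.finite(records$ct_housekeeping))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  if (is.null(control_condition)) {
    if (is.null(records$is_control) || !any(records$is_control)) {
      stop("no control: set `control_condition` or an `is_control` column",
           call. = FALSE)
    }
    control_condition <- unique(records$condition[records$is_control])
    if (length(control_condition) != 1) {
      stop("exactly one control condition required", call. = FALSE)
    }
  }
  if (!control_condition %in% records$condition) {
    stop("control condition ", control_condition, " has no records",
         call. = FALSE)
  }
  per_cond <- dplyr::tibble(
    condition = records$condition,
    dct = records$ct_target - records$ct_housekeeping
  ) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_wells = dplyr::n(), delta_ct = mean(.data$dct),
                     .groups = "drop")
  ctrl <- per_cond$delta_ct[per_cond$condition == control_condition]
  per_cond |>
    dplyr::mutate(
      delta_delta_ct = .data$delta_ct - ctrl,
      fold_change = 2^(-.data$delta_delta_ct)
    )
}

#' @rdname anova_screen
#' @param object A `de_result`.
#' @param ... Unused.
#' @export
glance.de_result <- function(object, ...) {
  dplyr::tibble(
    n_genes = nrow(object),
    n_holm_significant = sum(object$p_adjusted < attr(object, "q")),
    n_significant = sum(object$significant),
    q = attr(object, "q"),
    fc_threshold = attr(object, "fc_threshold")
  )
}

#' @rdname anova_screen
#' @export
autoplot.de_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$max_log2_fc,
                               y = -log10(pmax(.data$p_adjusted, 1e-300)),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(attr(object, "fc_threshold")),
                        linetype = 3) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "q")), linetype = 3) +
    ggplot2::labs(x = "max log2 fold-change vs matched control",
                  y = "-log10 adjusted p", colour = "significant")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
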