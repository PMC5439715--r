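#' Simulate a clonogenic assay
#'
#' Draws colony counts for a dose-response clonogenic experiment under the
#' linear-quadratic model: each plated cell forms a colony with probability
#' `plating_efficiency * exp(-alpha*D - beta*D^2)`, so per-dish counts are
#' binomial. This is the ground-truth generator used to validate [fit_lq()].
#'
#' @param alpha,beta LQ parameters (1/Gy, 1/Gy^2), non-negative.
#' @param plating_efficiency Fraction of unirradiated cells forming colonies,
#'   in (0, 1].
#' @param doses Vector of doses in Gy (>= 0); include 0 so fits can
#'   normalise.
#' @param cells_plated Cells plated per dish (>= 1).
#' @param replicates Dishes per dose (>= 1).
#' @param seed Integer seed; the generator uses its own RNG stream and leaves
#'   the global RNG untouched. `NULL` uses the current RNG state.
#' @return Tibble with columns `dose`, `replicate`, `cells_plated`,
#'   `colonies`, `true_survival`.
#' @examples
#' gen_clonogenic(0.335, 0.0154, 0.6, doses = c(0, 2, 4, 8, 16), seed = 1)
#' @export
gen_clonogenic <- function(alpha, beta, plating_efficiency = 1,
                           doses = c(0, 2, 4, 8, 12, 16),
                           cells_plated = 500, replicates = 4, seed = NULL) {
  stopifnot(alpha >= 0, beta >= 0,
            plating_efficiency > 0, plating_efficiency <= 1,
            all(doses >= 0), cells_plated >= 1, replicates >= 1)
  with_gen_seed(seed, {
    grid <- tidyr::expand_grid(dose = doses, replicate = seq_len(replicates))
    surv <- exp(-alpha * grid$dose - beta * grid$dose^2)
    dplyr::tibble(
      dose = grid$dose,
      replicate = grid$replicate,
      cells_plated = as.integer(cells_plated),
      colonies = stats::rbinom(nrow(grid), cells_plated,
                               pmin(1, plating_efficiency * surv)),
      true_survival = surv
    )
  })
}

#' Simulate growth trajectories
#'
#' Generates population growth curves with the qualitative structure seen
#' after high-dose irradiation.
#'
#' * `kind = "invitro"`: cell counts follow a piecewise exponential — a
#'   suppressed rate during a dose-dependent lag, then the control rate
#'   (the post-irradiation "rebound" to pre-irradiated doubling dynamics) —
#'   with multiplicative log-normal noise.
#' * `kind = "invivo"`: tumor volumes grow exponentially after a lag, with
#'   log-normal noise, and each animal independently fails to engraft
#'   ("extinct", no growth) with probability `1 - take_probability`.
#'
#' @param kind `"invitro"` or `"invivo"`.
#' @param spec Data frame with one row per condition: columns `dose` (label,
#'   Gy), `rate` (1/day, post-lag), `lag_days` (suppressed phase length),
#'   optional `lag_rate` (rate during the lag, default 0), optional
#'   `n_subjects` (default 3) and, for in vivo, `take_probability` in [0,1]
#'   (default 1).
#' @param times Sampling times in days (>= 0, increasing).
#' @param v0 Initial value (cells or mm^3) at time 0.
#' @param noise_sd SD of multiplicative log-normal noise (log scale).
#' @param seed Integer seed (own RNG stream).
#' @return Tibble: `kind`, `dose`, `subject`, `time`, `value`, `extinct`.
#' @export
gen_growth_trajectories <- function(kind = c("invitro", "invivo"), spec,
                                    times = seq(0, 90, by = 4), v0 = 1e5,
                                    noise_sd = 0.05, seed = NULL) {
  kind <- match.arg(kind)
  spec <- as.data.frame(spec)
  stopifnot(all(c("dose", "rate", "lag_days") %in% names(spec)))
  if (any(times < 0)) stop("negative times are not allowed", call. = FALSE)
  if (any(!is.finite(spec$rate))) stop("rates must be finite", call. = FALSE)
  if (is.null(spec$lag_rate)) spec$lag_rate <- 0
  if (is.null(spec$n_subjects)) spec$n_subjects <- 3
  if (kind == "invivo" && is.null(spec$take_probability)) {
    spec$take_probability <- 1
  }

  with_gen_seed(seed, {
    purrr::pmap_dfr(spec, function(dose, rate, lag_days, lag_rate,
                                   n_subjects, take_probability = 1, ...) {
      purrr::map_dfr(seq_len(n_subjects), function(subj) {
        extinct <- kind == "invivo" &&
          stats::runif(1) > take_probability
        log_mean <- ifelse(
          times <= lag_days,
          log(v0) + lag_rate * times,
          log(v0) + lag_rate * lag_days + rate * (times - lag_days)
        )
        if (extinct) log_mean <- rep(log(v0), length(times))
        dplyr::tibble(
          kind = kind, dose = dose, subject = subj, time = times,
          value = exp(log_mean + stats::rnorm(length(times), 0, noise_sd)),
          extinct = extinct
        )
      })
    })
  })
}

#' Default 39-sample expression design
#'
#' Three doses (0/8/16 Gy) crossed with days 1, 4 and 6 at three replicates
#' (27 short-term arrays, two processing batches) plus day 35 at four
#' replicates (12 long-term arrays, a third batch): 39 samples in 12
#' dose-by-day groups.
#'
#' @return Tibble: `sample_id`, `dose_gy`, `day`, `replicate`, `batch`.
#' @export
expression_design_default <- function() {
  short <- tidyr::expand_grid(dose_gy = c(0, 8, 16), day = c(1, 4, 6),
                              replicate = 1:3)
  short$batch <- ifelse(short$replicate <= 2, "b1", "b2")
  long <- tidyr::expand_grid(dose_gy = c(0, 8, 16), day = 35, replicate = 1:4)
  long$batch <- "b3"
  des <- dplyr::bind_rows(short, long)
  des |>
    dplyr::mutate(sample_id = sprintf("s%02d_d%g_t%g_r%d",
                                      dplyr::row_number(), .data$dose_gy,
                                      .data$day, .data$replicate)) |>
    dplyr::select("sample_id", "dose_gy", "day", "replicate", "batch")
}

#' Simulate an expression study with planted differential expression
#'
#' Builds a genes x samples intensity matrix on the log2 scale as
#' baseline + planted group effects + batch shifts + Gaussian noise, then
#' exponentiates to raw intensities (the scale microarray scanners report, and
#' the scale [quantile_normalize()] expects). Ground-truth labels are carried
#' alongside so screens can be scored.
#'
#' @param n_genes Number of genes.
#' @param design Sample sheet as from [expression_design_default()].
#' @param de_genes Named list: gene id -> named numeric vector of log2 effects
#'   keyed by group label `"<dose>:<day>"` (e.g. `c("8:6" = 1)`), applied on
#'   top of baseline. Referencing an unknown gene is an error.
#' @param noise_sd Gaussian noise SD, log2 units.
#' @param batch_shift Named numeric vector of per-batch additive shifts (log2
#'   units); unnamed batches shift 0.
#' @param baseline_mean,baseline_sd Per-gene baseline distribution (log2).
#' @param seed Integer seed (own RNG stream).
#' @return An `expression_study`: list with `matrix` (raw intensities,
#'   genes x samples), `samples` (the design tibble), `truth` (tibble gene /
#'   group / log2_effect, zero rows when nothing planted).
#' @export
gen_expression_study <- function(n_genes = 1000,
                                 design = expression_design_default(),
                                 de_genes = list(), noise_sd = 0.2,
                                 batch_shift = c(b2 = 0), baseline_mean = 8,
                                 baseline_sd = 1.5, seed = NULL) {
  design <- dplyr::as_tibble(design)
  stopifnot(n_genes >= 1, noise_sd >= 0,
            all(c("sample_id", "dose_gy", "day", "replicate", "batch")
                %in% names(design)))
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  bad <- setdiff(names(de_genes), genes)
  if (length(bad) > 0) {
    stop("de_genes references unknown gene id(s): ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  n_s <- nrow(design)
  group <- paste(design$dose_gy, design$day, sep = ":")

  with_gen_seed(seed, {
    base <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    log2m <- matrix(base, n_genes, n_s)
    rownames(log2m) <- genes
    colnames(log2m) <- design$sample_id
    for (g in names(de_genes)) {
      eff <- de_genes[[g]]
      for (grp in names(eff)) {
        log2m[g, group == grp] <- log2m[g, group == grp] + eff[[grp]]
      }
    }
    shift <- batch_shift[design$batch]
    shift[is.na(shift)] <- 0
    log2m <- sweep(log2m, 2, shift, `+`)
    if (noise_sd > 0) {
      log2m <- log2m + matrix(stats::rnorm(n_genes * n_s, 0, noise_sd),
                              n_genes, n_s)
    }
    truth <- if (length(de_genes) == 0) {
      dplyr::tibble(gene = character(), group = character(),
                    log2_effect = numeric())
    } else {
      purrr::imap_dfr(de_genes, function(eff, g) {
        dplyr::tibble(gene = g, group = names(eff),
                      log2_effect = unname(eff))
      })
    }
    new_expression_study(2^log2m, design, truth)
  })
}

new_expression_study <- function(matrix, samples, truth = NULL) {
  stopifnot(ncol(matrix) == nrow(samples))
  structure(list(matrix = matrix, samples = dplyr::as_tibble(samples),
                 truth = truth),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  grp <- paste(x$samples$dose_gy, x$samples$day, sep = ":")
  cat(sprintf("Expression study: %d genes x %d samples, %d groups\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(grp))))
  if (!is.null(x$truth) && nrow(x$truth) > 0) {
    cat(sprintf("  planted DE: %d gene(s)\n", length(unique(x$truth$gene))))
  }
  invisible(x)
}

#' Simulate dye-dilution fluorescence intensities
#'
#' Each cell is assigned a division generation `k` with probability
#' `generation_fractions[k+1]`; membrane dye halves with every division, so
#' its log intensity is drawn from `Normal(mu0 - k*ln 2, sd)` where `sd` is
#' derived from the coefficient of variation (`sd = sqrt(log(1 + cv^2))`,
#' the log-normal relation).
#'
#' @param generation_fractions Numeric vector over generations 0..G, summing
#'   to 1 (G <= 10).
#' @param mu0 Log intensity of the undivided (generation 0) peak; > 0.
#' @param cv Coefficient of variation of intensity about a peak; > 0.
#' @param n_cells Number of cells.
#' @param seed Integer seed (own RNG stream).
#' @return Tibble: `intensity` (linear scale), `generation` (ground truth).
#' @export
gen_dye_intensities <- function(generation_fractions, mu0 = 7, cv = 0.15,
                                n_cells = 10000, seed = NULL) {
  f <- generation_fractions
  if (abs(sum(f) - 1) > 1e-9 || any(f < 0)) {
    stop("`generation_fractions` must be a simplex", call. = FALSE)
  }
  if (length(f) > 11) stop("at most 10 divisions supported", call. = FALSE)
  if (cv <= 0) stop("`cv` must be positive", call. = FALSE)
  stopifnot(mu0 > 0, n_cells >= 1)
  sd <- sqrt(log(1 + cv^2))
  with_gen_seed(seed, {
    gen <- sample.int(length(f), n_cells, replace = TRUE, prob = f) - 1L
    dplyr::tibble(
      intensity = exp(stats::rnorm(n_cells, mu0 - gen * log(2), sd)),
      generation = gen
    )
  })
}

#' Simulate a qPCR Ct table
#'
#' Paired target / 18S-housekeeping Ct values per well for a set of
#' conditions, with the control condition flagged. `delta_ct` per condition is
#' the mean target-minus-housekeeping difference the wells are drawn around,
#' so planted delta-delta-Ct values propagate exactly through
#' [ddct_fold_change()] at `sd = 0`.
#'
#' @param conditions Data frame with columns `condition`, `delta_ct` and
#'   optionally `is_control` (exactly one TRUE; defaults to the first row).
#' @param housekeeping_ct Mean housekeeping Ct (18S is typically ~10).
#' @param sd Per-well Gaussian noise SD applied to both channels.
#' @param n Wells per condition (>= 1).
#' @param seed Integer seed (own RNG stream).
#' @return Tibble: `condition`, `well`, `ct_target`, `ct_housekeeping`,
#'   `is_control`.
#' @export
gen_qpcr <- function(conditions, housekeeping_ct = 10, sd = 0.2, n = 3,
                     seed = NULL) {
  conditions <- as.data.frame(conditions)
  stopifnot(all(c("condition", "delta_ct") %in% names(conditions)), n >= 1,
            sd >= 0)
  if (is.null(conditions$is_control)) {
    conditions$is_control <- seq_len(nrow(conditions)) == 1
  }
  with_gen_seed(seed, {
    purrr::pmap_dfr(conditions, function(condition, delta_ct, is_control) {
      hk <- housekeeping_ct + stats::rnorm(n, 0, sd)
      dplyr::tibble(
        condition = condition, well = seq_len(n),
        ct_target = hk + delta_ct + stats::rnorm(n, 0, sd),
        ct_housekeeping = hk,
        is_control = is_control
      )
    })
  })
}

# Run `expr` under a private RNG stream when a seed is given, leaving the
# caller's RNG state untouched.
with_gen_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  withr::with_seed(as.integer(seed), expr)
}
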