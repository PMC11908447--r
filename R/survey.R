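#' Stratification rules for block sampling
#'
#' Strata follow the validation design: a "tiny block" stratum for blocks
#' smaller than `tiny_ha` hectares, housing-unit-density strata cut at
#' `density_breaks` (units per hectare of block area), and optional special
#' classes decided by a user rule (e.g. diked blocks). Only candidate blocks
#' — those partially inside the zone — are stratified; blocks entirely
#' below or entirely above the threshold carry no estimation error and are
#' excluded from ratio estimation.
#'
#' @param tiny_ha area cutoff in hectares for the tiny-block stratum.
#' @param density_breaks increasing vector of units/ha cut points; `k`
#'   breaks give `k + 1` density strata.
#' @param special optional function taking the block tibble and returning a
#'   character vector of special-stratum labels (`NA` for none); applied
#'   before the other rules.
#' @return a list of class `strata_rules`.
#' @export
strata_rules <- function(tiny_ha = 0.25, density_breaks = c(3, 10),
                         special = NULL) {
  if (any(diff(density_breaks) <= 0)) abort("density_breaks must be increasing")
  structure(list(tiny_ha = tiny_ha, density_breaks = density_breaks,
                 special = special), class = "strata_rules")
}

#' Assign candidate blocks to sampling strata
#'
#' @param blocks block tibble with `block_id`, `area_m2`, `housing_units`.
#' @param fractions per-block fractions from [block_zone_fractions()] for
#'   the zone being validated; blocks with `fraction_area` of exactly 0 or
#'   1 are excluded (not candidates).
#' @param rules a [strata_rules()] object.
#' @return tibble `block_id`, `stratum` for the candidate blocks, plus the
#'   per-stratum sizes as attribute `sizes` (named integer vector N_h).
#' @export
stratify_blocks <- function(blocks, fractions, rules = strata_rules()) {
  idx <- match(blocks$block_id, fractions$block_id)
  if (anyNA(idx)) abort("every block needs a row in `fractions`")
  f <- fractions$fraction_area[idx]
  cand <- f > 0 & f < 1
  b <- blocks[cand, ]
  area_ha <- b$area_m2 / 1e4
  dens <- b$housing_units / area_ha
  lab <- rep(NA_character_, nrow(b))
  if (!is.null(rules$special)) {
    sp <- rules$special(b)
    lab[!is.na(sp)] <- sp[!is.na(sp)]
  }
  tiny <- is.na(lab) & area_ha < rules$tiny_ha
  lab[tiny] <- "tiny"
  br <- c(-Inf, rules$density_breaks, Inf)
  dl <- cut(dens, breaks = br, right = FALSE,
            labels = density_labels(rules$density_breaks))
  lab[is.na(lab)] <- as.character(dl[is.na(lab)])
  out <- tibble(block_id = b$block_id, stratum = lab)
  sizes <- table(out$stratum)
  attr(out, "sizes") <- setNames(as.integer(sizes), names(sizes))
  out
}

density_labels <- function(breaks) {
  k <- length(breaks)
  c(sprintf("<%g", breaks[1]),
    if (k > 1) sprintf("%g-%g", breaks[-k], breaks[-1]),
    sprintf(">%g", breaks[k]))
}

#' Draw a stratified simple random sample of blocks
#'
#' Simple random sampling without replacement within each stratum,
#' reproducible under `seed`.
#'
#' @param strata tibble from [stratify_blocks()].
#' @param sizes named integer vector of sample sizes n_h (names are stratum
#'   labels); strata omitted from `sizes` are not sampled.
#' @param seed integer seed.
#' @return tibble `block_id`, `stratum` of sampled blocks, with attributes
#'   `N_h` and `n_h`.
#' @export
draw_sample <- function(strata, sizes, seed) {
  if (is.null(names(sizes)) || any(!nzchar(names(sizes)))) {
    abort("`sizes` must be a named vector of per-stratum sample sizes")
  }
  N_h <- attr(strata, "sizes")
  out <- with_subseed(seed, "draw_sample", {
    dplyr::bind_rows(lapply(names(sizes), function(h) {
      ids <- strata$block_id[strata$stratum == h]
      if (sizes[[h]] > length(ids)) {
        abort(sprintf("sample size %d exceeds stratum '%s' size %d",
                      sizes[[h]], h, length(ids)))
      }
      tibble(block_id = ids[sample.int(length(ids), sizes[[h]])], stratum = h)
    }))
  })
  attr(out, "N_h") <- N_h[names(sizes)]
  attr(out, "n_h") <- setNames(as.integer(sizes), names(sizes))
  out
}

#' Combined ratio estimator over a stratified block sample
#'
#' Estimates the ratio R of observed (true) to model-estimated counts from
#' a stratified sample, using the combined ratio estimator
#' \eqn{\hat R_c = \sum_h N_h \bar y_h / \sum_h N_h \bar x_h} with its
#' large-sample variance (Cochran's classical survey-sampling form),
#' including the finite population correction:
#' \deqn{V(\hat R_c) = \hat X^{-2} \sum_h N_h^2 (1-f_h)/n_h
#'   \left(s_{yh}^2 + \hat R_c^2 s_{xh}^2 - 2 \hat R_c s_{yxh}\right)}
#' Per-stratum ratios \eqn{\hat R_h = \bar y_h / \bar x_h} are reported with
#' the analogous single-stratum variance. Strata sampled with n_h = 1
#' contribute zero estimated variance (warned); a stratum whose sampled
#' estimated counts are all zero while observed counts are not is excluded
#' from the combined ratio with a warning.
#'
#' @param sample tibble with columns `stratum`, `y` (observed count per
#'   block) and `x` (estimated count per block).
#' @param N_h named integer vector of stratum population sizes; defaults to
#'   attribute `N_h` of `sample`.
#' @param x_total optional full-frame estimated total to which the ratio is
#'   applied; the ratio-adjusted total, its standard error, and the
#'   coefficient of variation are reported when given.
#' @return an object of class `ratio_estimate`: list with `strata` (per
#'   stratum n, N, R_hat, se), `R_hat`, `se_R`, `cv`, and when `x_total`
#'   is supplied `adjusted_total` and `se_total`.
#' @export
combined_ratio_estimate <- function(sample, N_h = attr(sample, "N_h"),
                                    x_total = NULL) {
  if (is.null(N_h)) abort("stratum sizes N_h are required")
  hs <- unique(sample$stratum)
  per <- lapply(hs, function(h) {
    s <- sample[sample$stratum == h, ]
    n <- nrow(s); N <- N_h[[h]]
    ybar <- mean(s$y); xbar <- mean(s$x)
    Rh <- if (xbar > 0) ybar / xbar else NA_real_
    if (n == 1L) {
      warn(sprintf("stratum '%s' has a single sampled block; variance taken as 0", h))
      se <- 0
    } else if (xbar > 0) {
      sd2 <- sum((s$y - Rh * s$x)^2) / (n - 1)
      se <- sqrt((1 - n / N) / (n * xbar^2) * sd2)
    } else {
      se <- NA_real_
    }
    list(h = h, n = n, N = N, ybar = ybar, xbar = xbar,
         s_y2 = if (n > 1) var(s$y) else 0,
         s_x2 = if (n > 1) var(s$x) else 0,
         s_yx = if (n > 1) stats::cov(s$y, s$x) else 0,
         R_hat = Rh, se = se)
  })
  bad <- vapply(per, function(p) p$xbar == 0 && p$ybar > 0, TRUE)
  if (any(bad)) {
    warn(sprintf(
      "stratum(s) %s have zero estimated but nonzero observed counts; excluded from the combined ratio",
      paste(vapply(per[bad], `[[`, "", "h"), collapse = ", ")))
  }
  use <- per[!bad]
  Xhat <- sum(vapply(use, function(p) p$N * p$xbar, 0))
  Yhat <- sum(vapply(use, function(p) p$N * p$ybar, 0))
  if (Xhat <= 0) abort("estimated totals are zero in every stratum")
  R <- Yhat / Xhat
  Vsum <- sum(vapply(use, function(p) {
    p$N^2 * (1 - p$n / p$N) / p$n *
      (p$s_y2 + R^2 * p$s_x2 - 2 * R * p$s_yx)
  }, 0))
  se_R <- sqrt(max(Vsum, 0)) / Xhat
  res <- list(
    strata = dplyr::bind_rows(lapply(per, function(p) {
      tibble(stratum = p$h, n = p$n, N = p$N, R_hat = p$R_hat, se = p$se,
             excluded = p$xbar == 0 && p$ybar > 0)
    })),
    R_hat = R, se_R = se_R, cv = if (R > 0) se_R / R else NA_real_)
  if (!is.null(x_total)) {
    res$adjusted_total <- x_total * R
    res$se_total <- x_total * se_R
  }
  structure(res, class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("<ratio_estimate: R = %.3f (se %.3f, cv %.3f)%s>\n",
              x$R_hat, x$se_R, x$cv,
              if (!is.null(x$adjusted_total))
                sprintf(", adjusted total %.1f +- %.1f",
                        x$adjusted_total, x$se_total) else ""))
  print(x$strata)
  invisible(x)
}

#' Coefficients of variation across a set of ratio estimates
#'
#' Summarises ratio estimates and flags those whose one-standard-error
#' interval (read as a 66% confidence range) excludes 1 — i.e. the
#' interpolation method's predicted counts differ detectably from the
#' observed counts.
#'
#' @param estimates named list of `ratio_estimate` objects; names label the
#'   scope (region, method, subgroup...).
#' @return tibble with `scope`, `R_hat`, `se`, `cv`, `excludes_one`.
#' @export
cv_report <- function(estimates) {
  dplyr::bind_rows(lapply(names(estimates), function(nm) {
    e <- estimates[[nm]]
    tibble(scope = nm, R_hat = e$R_hat, se = e$se_R, cv = e$cv,
           excludes_one = abs(e$R_hat - 1) > e$se_R)
  }))
}
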